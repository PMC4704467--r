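lam <- derive_lambdas(jaccard_08())

test_that("the regression attack recovers any hidden fingerprint exactly", {
  # exhaustive at l=8: all 256 hidden fingerprints fall to l probes
  pats <- as.matrix(expand.grid(rep(list(0:1), 8)))
  for (i in seq_len(256)) {
    hidden <- fingerprint(pats[i, ])
    out <- plain_score_attack(function(q) threshold_tversky(hidden, q, lam), 8)
    expect_identical(as.integer(out$fingerprint), as.integer(hidden))
    expect_equal(out$probes, 8)
    expect_equal(out$total_queries, 9)
  }
})

test_that("hit probabilities behave as the thresholding analysis predicts", {
  # theta = 1 closed form under uniform queries: only q = p meets the
  # threshold (score exactly 0), so the non-strict hit rate is 2^-l while
  # the strict rate is 0
  lam1 <- derive_lambdas(tversky_params(theta_n = 1, theta_d = 1))
  p <- fpi(c(1, 4, 9), 10)
  h <- hit_probability(p, lam1, trials = 200000, strict = FALSE, seed = 3)
  f <- attr(h, "f_hat")
  se <- sqrt(2^-10 * (1 - 2^-10) / 200000)
  expect_lt(abs(f - 2^-10), 3 * se)
  expect_equal(attr(hit_probability(p, lam1, trials = 50000, seed = 4),
                    "f_hat"), 0)

  # x = 0 queries can never hit; a sampler that never hits gives 0 always
  expect_equal(as.numeric(hit_probability(p, lam, x = 0, seed = 1)), 0)
  empty_sampler <- function(n) matrix(0L, n, 10)
  expect_equal(as.numeric(hit_probability(p, lam, empty_sampler,
                                          trials = 100, x = 50, seed = 1)), 0)

  # at theta = 4/5 even a million uniform queries rarely hit a typical
  # 166-bit fingerprint, in stark contrast to the 167-query full recovery
  hidden <- random_fingerprints(1, 166, 0.3, seed = 5)[[1]]
  h6 <- hit_probability(hidden, lam, trials = 20000, x = 1e6, seed = 6)
  expect_lt(as.numeric(h6), 0.5)
})

test_that("guessing strategies compute the stated argmax rules", {
  expect_equal(best_guess_prior(c(0.2, 0.5, 0.3)), 2)
  expect_equal(best_guess_prior(c(1, 0, 0)), 1)
  # uniform prior: tie-break spreads over all k
  set.seed(12)
  picks <- replicate(400, best_guess_prior(rep(1 / 4, 4)))
  expect_setequal(unique(picks), 1:4)
  expect_gt(min(table(picks)), 400 / 4 - 3 * sqrt(400 * 0.25 * 0.75))

  expect_equal(best_guess_posterior(c(0.5, 0.3, 0.2), c(1, 2, 1)), 2)
  # zero count eliminates the prior mode
  expect_equal(best_guess_posterior(c(0.6, 0.4), c(0, 5)), 2)
  # tie at 0.6 between indices 1 and 3
  set.seed(13)
  t_picks <- replicate(300, best_guess_posterior(c(0.2, 0.5, 0.3), c(3, 1, 2)))
  expect_setequal(unique(t_picks), c(1, 3))

  # L = 1 reduces to the single-observation rule
  set.seed(14)
  w <- c(0.1, 0.4, 0.5)
  a <- c(4, 1, 2)
  expect_equal(multi_query_posterior(w, list(a)),
               best_guess_posterior(w, a))
  # a zero count in any reply eliminates the index
  expect_equal(multi_query_posterior(c(0.5, 0.5), list(c(3, 1), c(0, 1))), 2)
  expect_equal(multi_query_posterior(c(0.5, 0.5), list(c(1, 2), c(3, 1))), 1)
})

test_that("the dummy-guessing experiment shows the padding-privacy pattern", {
  w <- rand_prior(101, seed = 21)
  expect_equal(sum(w), 1)

  # no dummies: the single received value is the truth
  expect_equal(dummy_guess_experiment(w, n = 0, trials = 500, seed = 22), 1)

  # concentrated prior: always guessable regardless of padding
  w1 <- c(1, rep(0, 50))
  expect_equal(dummy_guess_experiment(w1, n = 200, trials = 300, seed = 23), 1)

  # heavy padding drives success down to the leak-free ideal max w
  heavy <- dummy_guess_experiment(w, n = 101 * 100, trials = 4000, seed = 24)
  ideal <- max(w)
  se <- sqrt(heavy * (1 - heavy) / 4000)
  expect_lt(abs(heavy - ideal), 3 * se + 1e-8)

  # repeating the same query sharpens the multi-query attack
  light_L1 <- dummy_guess_experiment(w, n = 101 * 5, L = 1, trials = 3000,
                                     seed = 25)
  light_L10 <- dummy_guess_experiment(w, n = 101 * 5, L = 10, trials = 3000,
                                      seed = 25)
  se2 <- sqrt(0.25 / 3000)
  expect_gt(light_L10, light_L1 - 3 * se2)
  expect_gt(light_L10, heavy)
})

test_that("perturbed dummy distributions match their construction", {
  u0 <- perturbed_dummy_distribution(50, 0, seed = 1)
  expect_equal(as.numeric(u0), rep(1 / 50, 50))

  u <- perturbed_dummy_distribution(831, 0.1, seed = 2)
  expect_equal(sum(u), 1)
  expect_true(all(u >= 0))
  # k*u ~ r / mean(r) with r ~ N(1, 0.1^2): sd close to 0.1
  expect_lt(abs(sd(831 * as.numeric(u)) - 0.1), 0.01)

  # perturbed generation with a uniform-assuming attacker still converges,
  # though less tightly than exact knowledge would allow
  w <- rand_prior(101, seed = 26)
  up <- perturbed_dummy_distribution(101, 0.2, seed = 27)
  sp <- dummy_guess_experiment(w, n = 101 * 50, dummy_dist = as.numeric(up),
                               trials = 2000, seed = 28)
  expect_lt(sp, 0.2)
})

test_that("synthetic priors are valid distributions", {
  w <- rand_prior(831, seed = 31)
  expect_equal(length(w), 831)
  expect_equal(sum(w), 1)

  ep <- empirical_score_prior(32, lam, samples = 5000, seed = 32)
  expect_equal(sum(ep), 1)
  expect_equal(length(ep), range_size(32, lam))
})
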