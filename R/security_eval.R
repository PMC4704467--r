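# Attack simulators quantifying what different server behaviours leak.
# These run on plaintext scores: the analyses concern information
# disclosure, not the encryption layer, and plaintext simulation makes
# 10^5-trial experiments run in seconds.

#' Regression attack against a score-revealing server
#'
#' When the server returns the exact integer threshold-Tversky score, the
#' whole database fingerprint falls to a linear probe: the difference
#' `score(e_i) - score(0)` between a unit-vector query and the all-zero
#' baseline is positive exactly when bit i of the hidden fingerprint is 1.
#' One baseline query plus one probe per bit — `length + 1` queries in
#' total — recovers the fingerprint exactly. This is the attack that
#' thresholding (returning only the sign) is designed to defeat.
#'
#' @param oracle function taking a query [fingerprint()] and returning the
#'   exact integer score against the hidden entry.
#' @param length fingerprint length in bits.
#' @return List: `fingerprint` (the recovery), `probes` (unit-vector
#'   queries used, always `length`), `total_queries` (`length + 1`).
#' @examples
#' lam <- derive_lambdas(tversky_params())
#' hidden <- random_fingerprints(1, 166, seed = 7)[[1]]
#' oracle <- function(q) threshold_tversky(hidden, q, lam)
#' out <- plain_score_attack(oracle, 166)
#' identical(as.integer(out$fingerprint), as.integer(hidden))
#' @export
plain_score_attack <- function(oracle, length) {
  zero <- fingerprint(integer(length))
  base <- oracle(zero)
  bits <- integer(length)
  for (i in seq_len(length)) {
    e_i <- fingerprint_from_indices(i, length)
    bits[i] <- as.integer(oracle(e_i) - base > 0)
  }
  list(fingerprint = fingerprint(bits), probes = as.integer(length),
       total_queries = as.integer(length) + 1L)
}

#' Probability of hitting a hidden fingerprint under thresholding
#'
#' When only the sign of the score is returned, the attacker's foothold is
#' a "hit" query with strictly positive score against the hidden entry p.
#' This Monte-Carlo estimator draws queries from `query_sampler`, estimates
#' the single-trial hit probability `f_p = Pr(score(p, Q) > 0)`, and
#' returns `1 - (1 - f_p)^x`, the chance of at least one hit in x queries.
#'
#' @param p hidden [fingerprint()].
#' @param lam [derive_lambdas()] output.
#' @param query_sampler function(n) returning an n x length 0/1 matrix of
#'   queries; default draws each bit as a fair coin (uniform fingerprints).
#' @param trials Monte-Carlo sample size for estimating `f_p`.
#' @param x number of queries the attacker may send.
#' @param strict if `TRUE` (default) a hit needs a strictly positive score,
#'   the foothold of the known linear follow-up attack; `FALSE` counts
#'   score zero too (i.e. any query meeting the threshold). The two differ
#'   only on the equality boundary — at theta = 1, for example, only the
#'   exact match q = p meets the threshold and its score is exactly zero,
#'   so the non-strict probability has closed form `2^-length` under
#'   uniform queries while the strict one is zero.
#' @param seed optional integer seed.
#' @return Estimated probability, with the estimate of `f_p` attached as
#'   attribute `"f_hat"`.
#' @export
hit_probability <- function(p, lam, query_sampler = NULL, trials = 10000,
                            x = 1, strict = TRUE, seed = NULL) {
  stopifnot(trials > 0, x >= 0)
  l <- length(p)
  if (is.null(query_sampler))
    query_sampler <- function(n) matrix(rbinom(n * l, 1L, 0.5), n, l)
  f_hat <- with_seed(seed, {
    qm <- query_sampler(trials)
    pv <- as.integer(p)
    cc <- as.vector(qm %*% pv)
    s <- lam$lambda1 * cc - lam$lambda2 * sum(pv) -
      lam$lambda3 * rowSums(qm)
    if (strict) mean(s > 0) else mean(s >= 0)
  })
  structure(1 - (1 - f_hat)^x, f_hat = f_hat)
}

# argmax with uniform tie-breaking; ties detected with a small relative
# tolerance because the scores come from products of integers and
# double-precision weights
argmax_tie <- function(x) {
  m <- max(x)
  tol <- if (is.finite(m)) abs(m) * 1e-12 else 0
  cand <- which(x >= m - tol)
  if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
}

#' Attacker guessing strategies for the true score among dummies
#'
#' `best_guess_prior()` is the no-observation strategy: guess the score
#' value with the largest prior probability `w_i` (uniform tie-break); it
#' succeeds with probability `max_i w_i`, the ideal leak-free baseline.
#' `best_guess_posterior()` uses one observed reply in which value i was
#' received `a_i` times (true score plus uniform dummies): the posterior is
#' proportional to `a_i * w_i`, so the best guess is its argmax.
#' `multi_query_posterior()` covers L repeats of the same query: the
#' posterior is proportional to the product over replies of `a_i^(j) * w_i`,
#' accumulated in log space.
#'
#' @param w prior probability vector over the k possible score values.
#' @param counts integer vector `a_1..a_k` of received-value frequencies
#'   (summing to n + 1).
#' @param obs_list list of such count vectors, one per query.
#' @param seed optional integer seed (tie-breaking).
#' @return The guessed index in `1..k`.
#' @export
best_guess_prior <- function(w, seed = NULL) {
  with_seed(seed, argmax_tie(w))
}

#' @rdname best_guess_prior
#' @export
best_guess_posterior <- function(w, counts, seed = NULL) {
  stopifnot(length(counts) == length(w))
  with_seed(seed, argmax_tie(counts * w))
}

#' @rdname best_guess_prior
#' @export
multi_query_posterior <- function(w, obs_list, seed = NULL) {
  stopifnot(length(obs_list) >= 1)
  s <- rep(0, length(w))
  for (a in obs_list) {
    stopifnot(length(a) == length(w))
    s <- s + log(a * w)
  }
  with_seed(seed, argmax_tie(s))
}

#' Synthetic score priors
#'
#' `rand_prior()` builds the synthetic prior used in the guessing
#' experiments: draw a value uniformly from `1..k` `m` times and take
#' observed frequencies (default `m = 5k`). `empirical_score_prior()`
#' instead estimates the score distribution induced by the synthetic
#' fingerprint generator: it samples random fingerprint pairs, scores them,
#' and tabulates over the attainable score interval.
#'
#' @param k number of possible score values.
#' @param m number of draws.
#' @param seed optional integer seed.
#' @return Probability vector of length k.
#' @export
rand_prior <- function(k, m = 5 * k, seed = NULL) {
  with_seed(seed, tabulate(sample.int(k, m, replace = TRUE), k) / m)
}

#' @param length fingerprint length in bits.
#' @param lam [derive_lambdas()] output.
#' @param samples number of random (entry, query) pairs to score.
#' @param density Bernoulli bit density of the sampled fingerprints.
#' @rdname rand_prior
#' @export
empirical_score_prior <- function(length, lam, samples = 10000,
                                  density = 0.3, seed = NULL) {
  sr <- score_range(length, lam)
  with_seed(seed, {
    pm <- matrix(rbinom(samples * length, 1L, density), samples, length)
    qm <- matrix(rbinom(samples * length, 1L, density), samples, length)
    cc <- rowSums(pm * qm)
    s <- lam$lambda1 * cc - lam$lambda2 * rowSums(pm) -
      lam$lambda3 * rowSums(qm)
    tabulate(s - sr[1] + 1L, sr[2] - sr[1] + 1L) / samples
  })
}

#' Perturbed dummy distribution
#'
#' Builds the near-uniform dummy distribution used to test how precisely an
#' attacker must know the server's dummy distribution: each weight is
#' `u_i = r_i / k` with `r_i ~ N(1, delta^2)`, negative draws truncated to
#' zero, then normalized to sum to one. `delta = 0` gives exactly the
#' uniform distribution.
#'
#' @param k number of score values.
#' @param delta standard deviation of the multiplicative perturbation.
#' @param seed optional integer seed.
#' @return Probability vector of length k with attribute `"delta"`.
#' @export
perturbed_dummy_distribution <- function(k, delta, seed = NULL) {
  stopifnot(delta >= 0)
  with_seed(seed, {
    r <- rnorm(k, mean = 1, sd = delta)
    r[r < 0] <- 0
    u <- r / k
    structure(u / sum(u), delta = delta)
  })
}

#' Dummy-guessing attack experiment
#'
#' Monte-Carlo twin of the padding-privacy experiments. Each trial: the
#' true score index is drawn from the prior `w`; `n` dummies are drawn from
#' `dummy_dist` (uniform by default, or a perturbed distribution — the
#' attacker always assumes uniform dummies either way, so only the
#' generation changes); the attacker sees the per-value receive counts of
#' each of `L` identical queries and guesses by the posterior rule
#' ([best_guess_posterior()] for L = 1, [multi_query_posterior()] beyond).
#' The return value is the fraction of trials in which the guess names the
#' true index. With `n = 0` every trial succeeds (the single received value
#' is the truth); as n grows the ratio falls toward the leak-free ideal
#' `max_i w_i`.
#'
#' Dummy draws are realized as multinomial count vectors rather than n
#' individual draws — distributionally identical and far faster at the
#' 10^5-dummy scale.
#'
#' @param w prior over the k score values.
#' @param n dummies per reply.
#' @param L number of identical queries per trial.
#' @param dummy_dist dummy-generation distribution (default uniform).
#' @param trials number of Monte-Carlo trials.
#' @param seed optional integer seed.
#' @return Success ratio in `[0, 1]`.
#' @export
dummy_guess_experiment <- function(w, n, L = 1, dummy_dist = NULL,
                                   trials = 10000, seed = NULL) {
  stopifnot(trials > 0, n >= 0, L >= 1)
  k <- length(w)
  if (is.null(dummy_dist)) dummy_dist <- rep(1 / k, k)
  stopifnot(length(dummy_dist) == k)
  with_seed(seed, {
    truth <- sample.int(k, trials, replace = TRUE, prob = w)
    s <- matrix(0, k, trials)
    for (j in seq_len(L)) {
      a <- if (n == 0) matrix(0L, k, trials)
           else rmultinom(trials, n, dummy_dist)
      a[cbind(truth, seq_len(trials))] <- a[cbind(truth, seq_len(trials))] + 1L
      s <- s + log(a * w)
    }
    guess <- max.col(t(s), ties.method = "random")
    mean(guess == truth)
  })
}
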