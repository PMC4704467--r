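test_that("tversky_index returns exact reduced fractions", {
  pp <- jaccard_08()
  p <- fpi(c(1, 2, 3), 8)
  q <- fpi(c(2, 3, 4), 8)

  self <- tversky_index(p, p, pp)
  expect_equal(c(self$num, self$den), c(1, 1))

  ti <- tversky_index(p, q, pp)
  expect_equal(c(ti$num, ti$den), c(1, 2))

  dice <- tversky_params(mu_a = 1, mu_b = 1, gamma = 2,
                         theta_n = 4, theta_d = 5)
  td <- tversky_index(p, q, dice)
  expect_equal(c(td$num, td$den), c(2, 3))

  empty <- fingerprint(integer(8))
  expect_error(tversky_index(empty, empty, pp), "undefined")
})

test_that("lambda derivation reproduces the worked settings", {
  lam <- derive_lambdas(jaccard_08())
  expect_equal(c(lam$lambda1, lam$lambda2, lam$lambda3), c(9, 4, 4))

  lam1 <- derive_lambdas(tversky_params(theta_n = 1, theta_d = 1))
  expect_equal(c(lam1$lambda1, lam1$lambda2, lam1$lambda3), c(2, 1, 1))

  # Dice at theta = 1/2
  lamd <- derive_lambdas(tversky_params(mu_a = 1, mu_b = 1, gamma = 2,
                                        theta_n = 1, theta_d = 2))
  expect_equal(c(lamd$lambda1, lamd$lambda2, lamd$lambda3), c(4, 1, 1))

  expect_error(tversky_params(theta_n = 5, theta_d = 4), "theta")
  expect_error(tversky_params(mu_a = 0), "positive")
})

test_that("derived lambdas are always coprime", {
  set.seed(99)
  for (i in 1:200) {
    td <- sample(1:20, 1)
    pp <- tversky_params(mu_a = sample(1:10, 1), mu_b = sample(1:10, 1),
                         gamma = sample(1:10, 1),
                         theta_n = sample(1:td, 1), theta_d = td)
    lam <- derive_lambdas(pp)
    g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b),
                c(lam$lambda1, lam$lambda2, lam$lambda3))
    expect_equal(g, 1)
    expect_gte(lam$lambda1, lam$lambda2)
    expect_gte(lam$lambda1, lam$lambda3)
  }
})

test_that("threshold score matches its worked examples", {
  lam <- derive_lambdas(jaccard_08())
  p <- fpi(c(1, 2, 3, 4, 5), 166)
  expect_equal(threshold_tversky(p, p, lam), 5)   # 9a - 8a = a
  expect_equal(threshold_tversky(fpi(c(1, 2, 3), 8), fpi(c(2, 3, 4), 8), lam),
               -6)
  lam12 <- derive_lambdas(tversky_params(theta_n = 1, theta_d = 2))
  expect_equal(threshold_tversky(fpi(c(1, 2, 3), 8), fpi(c(1, 2), 8), lam12),
               1)
})

test_that("score sign is equivalent to the threshold predicate (exhaustive l=8)", {
  pats <- as.matrix(expand.grid(rep(list(0:1), 8)))
  pc <- rowSums(pats)
  inter <- pats %*% t(pats)
  settings <- list(
    list(pp = tversky_params(1, 1, 1, 1, 2)),
    list(pp = tversky_params(1, 1, 1, 4, 5)),
    list(pp = tversky_params(1, 1, 1, 1, 1)),
    list(pp = tversky_params(1, 1, 2, 1, 2)),   # Dice, theta = 1/2
    list(pp = tversky_params(1, 1, 2, 4, 5)))   # Dice, theta = 4/5
  for (s in settings) {
    pp <- s$pp
    lam <- derive_lambdas(pp)
    score <- lam$lambda1 * inter - outer(lam$lambda2 * pc, lam$lambda3 * pc, "+")
    # exact rational comparison TI >= theta: gamma*c*theta_d >= theta_n*den
    num <- pp$gamma * inter
    den <- pp$gamma * inter +
      pp$mu_a * (outer(pc, rep(1, 256)) - inter) +
      pp$mu_b * (outer(rep(1, 256), pc) - inter)
    defined <- den > 0
    expect_true(all(((score >= 0) ==
                       (num * pp$theta_d >= pp$theta_n * den))[defined]))
  }
})

test_that("score_range matches brute force and the MACCS setting", {
  lam <- derive_lambdas(jaccard_08())
  expect_equal(unname(score_range(166, lam)), c(-664, 166))
  expect_equal(range_size(166, lam), 831)
  expect_equal(unname(score_range(4, lam)), c(-16, 4))
  expect_equal(range_size(4, lam), 21)

  for (len in c(3, 5, 8)) {
    for (pp in list(jaccard_08(), tversky_params(1, 1, 1, 1, 1),
                    tversky_params(2, 3, 2, 1, 3))) {
      lam2 <- derive_lambdas(pp)
      expect_equal(unname(score_range(len, lam2)),
                   unname(score_range_oracle(len, lam2)))
    }
  }
})

test_that("realized scores always lie inside score_range", {
  lam <- derive_lambdas(jaccard_08())
  sr <- score_range(32, lam)
  set.seed(7)
  fps <- random_fingerprints(40, 32, density = 0.5)
  for (i in 1:40) {
    s <- threshold_tversky(fps[[sample(40, 1)]], fps[[sample(40, 1)]], lam)
    expect_gte(s, sr[1])
    expect_lte(s, sr[2])
  }
})
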