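keys <- test_keys(seed = 55)

worked_db <- function() list(fpi(c(1, 2, 3), 8), fpi(c(4, 5), 8),
                             fpi(c(1, 4), 8))

test_that("query messages carry one ciphertext and one proof per bit", {
  q <- fpi(c(1, 3), 8)
  msg <- build_query(keys, q, seed = 2)
  expect_equal(nrow(msg$enc_bits), 8)
  expect_equal(nrow(msg$proofs), 8)
  expect_true(verify_query(msg))
  expect_equal(decrypt(keys, msg$enc_bits, plaintext_range(-2, 2)),
               as.integer(q))
  # all-zero query
  msg0 <- build_query(keys, fingerprint(integer(8)))
  expect_true(verify_query(msg0))
  expect_equal(decrypt(keys, msg0$enc_bits, plaintext_range(-2, 2)),
               integer(8))
})

test_that("illegal queries are detected and refused before scoring", {
  q <- c(0L, 0L, 0L, 0L, 2L, 0L, 0L, 0L)   # encryption of 2 at position 5
  r <- sscc:::rand_scalars(keys$curve, 8)
  ct <- encrypt(keys, q, r)
  pr <- prove_bit(keys, q, r, ct)
  msg <- structure(list(curve = keys$curve, pk = keys$pk, length = 8L,
                        enc_bits = ct, proofs = pr, params = NULL),
                   class = "sscc_query")
  expect_false(verify_query(msg))
  lam <- derive_lambdas(jaccard_08())
  expect_error(encrypted_scores(msg, worked_db(), lam), "refusing")

  # proofs swapped between positions fail even for honest bits
  honest <- build_query(keys, fpi(c(1, 2), 8))
  swapped <- honest
  swapped$proofs <- honest$proofs[c(2, 1, 3:8)]
  expect_false(verify_query(swapped))
})

test_that("encrypted scores decrypt to the threshold Tversky scores", {
  lam <- derive_lambdas(tversky_params(theta_n = 1, theta_d = 2))  # (3,1,1)
  msg <- build_query(keys, fpi(c(1, 2), 8))
  sc <- encrypted_scores(msg, worked_db(), lam)
  expect_equal(decrypt(keys, sc, plaintext_range(-50, 50)), c(1L, -4L, -1L))

  # identical entry scores |q| under (9,4,4); disjoint scores -4|p| - 4|q|
  lam8 <- derive_lambdas(jaccard_08())
  q <- fpi(c(2, 4, 6), 16)
  msg2 <- build_query(keys, q)
  db2 <- list(q, fpi(c(1, 3, 5, 7), 16))
  sc2 <- encrypted_scores(msg2, db2, lam8)
  expect_equal(decrypt(keys, sc2, plaintext_range(-200, 200)),
               c(3L, -4L * 4L - 4L * 3L))
})

test_that("dummy generation counts non-negatives and hits its distribution", {
  cfg <- dummy_config(n = 500, domain = c(-664, 166), seed = 9)
  d <- make_dummies(keys, cfg)
  expect_equal(nrow(d$ct), 500)
  vals <- decrypt(keys, d$ct, plaintext_range(-664, 166))
  expect_equal(d$s_d, sum(vals >= 0))

  # zero counts as non-negative; reproduce the hand-counted example
  vals2 <- c(3, -1, 0, -5)
  expect_equal(sum(vals2 >= 0), 2)

  expect_equal(nrow(make_dummies(keys, dummy_config(0, c(-10, 10)))$ct), 0)
  expect_equal(make_dummies(keys, dummy_config(0, c(-10, 10)))$s_d, 0)

  # uniform draw over [-664, 166]: share of non-negatives near 167/831
  # (tested on the plaintext draw at scale)
  v <- withr::with_seed(10, sscc:::draw_dummy_values(
    dummy_config(1e5, c(-664, 166))))
  p <- 167 / 831
  expect_lt(abs(mean(v >= 0) - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("replies conserve the plaintext multiset and shuffle uniformly", {
  lam <- derive_lambdas(jaccard_08())
  msg <- build_query(keys, fpi(c(1, 5, 9), 16))
  db <- random_fingerprints(3, 16, 0.4, seed = 3)
  sc <- encrypted_scores(msg, db, lam)
  cfg <- dummy_config(n = 4, domain = c(-200, 100), seed = 4)
  d <- make_dummies(keys, cfg)
  reply <- assemble_reply(sc, d$ct, d$s_d, seed = 5)
  expect_equal(nrow(reply$items), 7)

  rng <- plaintext_range(-200, 166)
  got <- sort(decrypt(keys, reply$items, rng))
  want <- sort(c(decrypt(keys, sc, rng), decrypt(keys, d$ct, rng)))
  expect_equal(got, want)

  # fixed seed -> fixed permutation
  reply2 <- assemble_reply(sc, d$ct, d$s_d, seed = 5)
  expect_identical(unclass(reply$items), unclass(reply2$items))
})

test_that("reply evaluation recovers the count from s_c - s_d", {
  vals <- c(5L, -2L, -7L, 1L, 0L)
  reply <- structure(list(items = encrypt(keys, vals), s_d = 2L),
                     class = "sscc_reply")
  res <- evaluate_reply(keys, reply, plaintext_range(-10, 10))
  expect_equal(res$s_c, 3)
  expect_equal(res$count, 1)

  # all dummies, no scores
  d <- make_dummies(keys, dummy_config(6, c(-20, 20), seed = 1))
  res0 <- evaluate_reply(keys,
                         structure(list(items = d$ct, s_d = d$s_d),
                                   class = "sscc_reply"),
                         plaintext_range(-20, 20))
  expect_equal(res0$count, 0)
})

test_that("the protocol count equals the plaintext brute-force counter", {
  # worked example: exactly one entry meets Jaccard >= 1/2
  pp <- tversky_params(theta_n = 1, theta_d = 2)
  res <- run_protocol(fpi(c(1, 2), 8), worked_db(), pp,
                      dummy_config(n = 25), keys = keys, seed = 13)
  expect_equal(res$count, 1)

  # M identical copies all match
  q <- fpi(c(2, 3, 8), 16)
  resM <- run_protocol(q, rep(list(q), 7), jaccard_08(),
                       dummy_config(n = 10), keys = keys, seed = 14)
  expect_equal(resM$count, 7)

  # random instances at l=16, several thresholds, with and without dummies
  set.seed(101)
  for (i in 1:10) {
    pp <- list(tversky_params(1, 1, 1, 1, 2), jaccard_08(),
               tversky_params(1, 1, 1, 1, 1))[[1 + i %% 3]]
    M <- sample(1:20, 1)
    db <- random_fingerprints(M, 16, density = 0.4)
    qq <- random_fingerprints(1, 16, density = 0.4)[[1]]
    n <- c(0, 30)[1 + i %% 2]
    res <- run_protocol(qq, db, pp, dummy_config(n = n), keys = keys,
                        seed = 1000 + i)
    expect_equal(res$count, count_similar(qq, db, pp))
  }
})

test_that("empty query and empty entry count as similar by convention", {
  empty <- fingerprint(integer(8))
  db <- list(empty, fpi(1, 8))
  expect_equal(count_similar(empty, db, jaccard_08()), 1)
  res <- run_protocol(empty, db, jaccard_08(), dummy_config(n = 5),
                      keys = keys, seed = 3)
  expect_equal(res$count, 1)
})
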