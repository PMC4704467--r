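test_that("popcount and intersection size follow set arithmetic", {
  expect_equal(popcount(fingerprint(integer(166))), 0)
  expect_equal(popcount(fingerprint(rep(1L, 166))), 166)
  expect_equal(popcount(fingerprint(c(1, 0, 0, 0, 0, 1, 1, 0))), 3)

  a <- fpi(c(1, 2, 3), 8)
  b <- fpi(c(2, 3, 4), 8)
  expect_equal(intersection_size(a, a), popcount(a))
  expect_equal(intersection_size(fpi(c(1, 2), 8), fpi(c(3, 4), 8)), 0)
  expect_equal(intersection_size(a, b), 2)
  expect_equal(intersection_size(a, b), intersection_size(b, a))
  expect_error(intersection_size(a, fpi(1, 4)), "length")
})

test_that("intersection identity |a∩b| + |a\\b| = |a| holds exhaustively at l=8", {
  pats <- as.matrix(expand.grid(rep(list(0:1), 8)))
  for (i in seq(1, 256, by = 17)) {
    a <- fingerprint(pats[i, ])
    for (j in seq_len(256)) {
      b <- fingerprint(pats[j, ])
      inter <- intersection_size(a, b)
      a_minus_b <- sum(pats[i, ] == 1 & pats[j, ] == 0)
      expect_identical(inter + a_minus_b, popcount(a))
    }
  }
})

test_that("FPS hex decoding uses LSB-first bit order within bytes", {
  # 0xa1 = 1010 0001: LSB-first gives 0-based bits {0, 5, 7} = 1-based {1, 6, 8}
  path <- withr::local_tempfile()
  writeLines(c("#FPS1", "#num_bits=8", "a1\tc1"), path)
  fp <- read_fps(path)[[1]]
  expect_equal(which(as.integer(fp) == 1), c(1, 6, 8))
  expect_equal(attr(fp, "id"), "c1")
})

test_that("FPS reader enforces the header contract", {
  path <- withr::local_tempfile()
  writeLines(c("#FPS1", "#num_bits=8"), path)
  expect_length(read_fps(path), 0)

  writeLines(c("#num_bits=8", "a1b2\tx"), path)  # 16 bits of hex for 8 declared
  expect_error(read_fps(path), "num_bits")

  writeLines(c("#num_bits=12", "ff3f\tx"), path)  # pad bits 13..16 nonzero
  expect_error(read_fps(path), "pad")

  writeLines(c("#num_bits=8", "zz\tx"), path)
  expect_error(read_fps(path), "malformed hex")
})

test_that("write-then-read round trip reproduces bits and ids", {
  fps <- random_fingerprints(10, length = 166, density = 0.3, seed = 11)
  path <- withr::local_tempfile()
  write_fps(fps, path)
  back <- read_fps(path)
  expect_length(back, 10)
  for (i in seq_along(fps)) {
    expect_identical(as.integer(back[[i]]), as.integer(fps[[i]]))
    expect_identical(attr(back[[i]], "id"), attr(fps[[i]], "id"))
  }
  # odd length exercises pad bits
  fps2 <- random_fingerprints(3, length = 13, density = 0.5, seed = 12)
  write_fps(fps2, path)
  back2 <- read_fps(path)
  expect_identical(lapply(back2, as.integer), lapply(fps2, as.integer))
})

test_that("synthetic generator matches its Bernoulli contract", {
  expect_true(all(vapply(random_fingerprints(5, 32, density = 0),
                         popcount, 1) == 0))
  expect_true(all(vapply(random_fingerprints(5, 32, density = 1),
                         popcount, 1) == 32))

  # mean popcount of Bernoulli(0.3) bits at l=166: 49.8, se = sqrt(l*p*(1-p)/n)
  n <- 10000
  fps <- random_fingerprints(n, 166, density = 0.3, seed = 42)
  m <- mean(vapply(fps, popcount, 1))
  se <- sqrt(166 * 0.3 * 0.7 / n)
  expect_lt(abs(m - 49.8), 3 * se)

  # reproducibility
  a <- random_fingerprints(3, 64, 0.4, seed = 5)
  b <- random_fingerprints(3, 64, 0.4, seed = 5)
  expect_identical(lapply(a, as.integer), lapply(b, as.integer))

  # correlated mode still hits the marginal density roughly
  fc <- random_fingerprints(2000, 64, density = 0.2, seed = 6,
                            correlated = TRUE)
  mc <- mean(vapply(fc, popcount, 1)) / 64
  expect_lt(abs(mc - 0.2), 0.02)
})
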