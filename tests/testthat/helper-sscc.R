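# Shared fixtures: a deterministic test key pair and the canonical
# Jaccard/0.8 parameter set.

test_keys <- function(seed = 1234) key_gen(seed = seed)

jaccard_08 <- function() tversky_params(mu_a = 1, mu_b = 1, gamma = 1,
                                        theta_n = 4, theta_d = 5)

# fingerprint from 1-based index set, terse
fpi <- function(idx, len) fingerprint_from_indices(idx, len)

# direct brute-force score range oracle: enumerate every fingerprint pair
# at small l via all popcount/intersection triples realized bit by bit
score_range_oracle <- function(len, lam) {
  stopifnot(len <= 8)
  pats <- expand.grid(rep(list(0:1), len))
  pm <- as.matrix(pats)
  pc <- rowSums(pm)
  scores <- c()
  inter <- pm %*% t(pm)   # |p ∩ q| for all pairs
  s <- lam$lambda1 * inter -
    outer(lam$lambda2 * pc, lam$lambda3 * pc, "+")
  c(min = min(s), max = max(s))
}
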