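#' Tversky similarity parameters
#'
#' The Tversky index with weights alpha and beta, compared against a
#' threshold theta, is configured here with exact rational arithmetic:
#' alpha = mu_a/gamma, beta = mu_b/gamma and theta = theta_n/theta_d, all
#' ratios of non-negative integers. alpha = beta = 1 gives the
#' Jaccard/Tanimoto index and alpha = beta = 1/2 the Dice index.
#'
#' @param mu_a,mu_b,gamma integer numerators/denominator of alpha and beta;
#'   alpha and beta must be positive.
#' @param theta_n,theta_d integer numerator and denominator of the
#'   threshold; 0 < theta <= 1 is required.
#' @return Object of class `"tversky_params"`.
#' @examples
#' tversky_params()                      # Jaccard, theta = 4/5
#' tversky_params(mu_a = 1, mu_b = 1, gamma = 2, theta_n = 1, theta_d = 2)
#' @export
tversky_params <- function(mu_a = 1, mu_b = 1, gamma = 1,
                           theta_n = 4, theta_d = 5) {
  v <- c(mu_a = mu_a, mu_b = mu_b, gamma = gamma,
         theta_n = theta_n, theta_d = theta_d)
  if (anyNA(v) || any(v != floor(v)) || any(v < 0))
    stop("all Tversky parameters must be non-negative integers")
  if (gamma < 1) stop("gamma must be positive")
  if (mu_a < 1 || mu_b < 1) stop("alpha and beta must be positive")
  if (theta_n < 1 || theta_d < 1 || theta_n > theta_d)
    stop("threshold must satisfy 0 < theta_n/theta_d <= 1")
  structure(as.list(as.integer(v)), names = names(v),
            class = "tversky_params")
}

#' @export
print.tversky_params <- function(x, ...) {
  cat(sprintf("<tversky_params: alpha=%d/%d beta=%d/%d theta=%d/%d>\n",
              x$mu_a, x$gamma, x$mu_b, x$gamma, x$theta_n, x$theta_d))
  invisible(x)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Integer lambda parameters of the threshold Tversky score
#'
#' Rescales the predicate "Tversky index >= theta" into the integer score
#' `lambda1*|p∩q| - lambda2*|p| - lambda3*|q|`, whose sign carries the
#' predicate. With g the greatest common divisor of
#' `gamma*(theta_d - theta_n) + theta_n*(mu_a + mu_b)`, `theta_n*mu_a` and
#' `theta_n*mu_b`:
#' `lambda1 = (gamma*(theta_d - theta_n) + theta_n*(mu_a + mu_b))/g`,
#' `lambda2 = theta_n*mu_a/g`, `lambda3 = theta_n*mu_b/g`.
#'
#' @param params a [tversky_params()].
#' @return Object of class `"lambda_params"`: list with `lambda1`,
#'   `lambda2`, `lambda3` and the divisor `g`.
#' @examples
#' derive_lambdas(tversky_params())   # (9, 4, 4) for Jaccard at theta = 4/5
#' @export
derive_lambdas <- function(params) {
  stopifnot(inherits(params, "tversky_params"))
  a <- params$gamma * (params$theta_d - params$theta_n) +
    params$theta_n * (params$mu_a + params$mu_b)
  b <- params$theta_n * params$mu_a
  c <- params$theta_n * params$mu_b
  g <- gcd2(gcd2(a, b), c)
  structure(list(lambda1 = a %/% g, lambda2 = b %/% g, lambda3 = c %/% g,
                 g = g),
            class = "lambda_params")
}

#' @export
print.lambda_params <- function(x, ...) {
  cat(sprintf("<lambda_params: (%d, %d, %d), g=%d>\n",
              x$lambda1, x$lambda2, x$lambda3, x$g))
  invisible(x)
}

#' Exact Tversky index of two fingerprints
#'
#' Returns `|p∩q| / (|p∩q| + alpha*|p\\q| + beta*|q\\p|)` as an exact
#' reduced fraction. The value is undefined (denominator zero) when both
#' fingerprints are empty.
#'
#' @param p,q fingerprints of equal length.
#' @param params a [tversky_params()].
#' @return Object of class `"sscc_fraction"` with integer fields `num` and
#'   `den`; coerce with `as.numeric()`.
#' @examples
#' p <- fingerprint_from_indices(c(1, 2, 3), 8)
#' q <- fingerprint_from_indices(c(2, 3, 4), 8)
#' as.numeric(tversky_index(p, q, tversky_params()))   # 1/2
#' @export
tversky_index <- function(p, q, params = tversky_params()) {
  stopifnot(inherits(params, "tversky_params"))
  if (length(p) != length(q)) stop("fingerprint lengths differ")
  cc <- intersection_size(p, q)
  pd <- popcount(p) - cc
  qd <- popcount(q) - cc
  num <- cc * params$gamma
  den <- cc * params$gamma + params$mu_a * pd + params$mu_b * qd
  if (den == 0)
    stop("Tversky index undefined: both fingerprints are empty")
  g <- if (num == 0) den else gcd2(num, den)
  structure(list(num = as.integer(num / g), den = as.integer(den / g)),
            class = "sscc_fraction")
}

#' @export
as.numeric.sscc_fraction <- function(x, ...) x$num / x$den

#' @export
print.sscc_fraction <- function(x, ...) {
  cat(sprintf("%d/%d (= %.6g)\n", x$num, x$den, x$num / x$den))
  invisible(x)
}

# exact comparison fraction >= theta_n/theta_d
fraction_geq <- function(frac, theta_n, theta_d) {
  frac$num * theta_d >= theta_n * frac$den
}

#' Integer threshold Tversky score
#'
#' The score `lambda1*|p∩q| - lambda2*|p| - lambda3*|q|`. Whenever the
#' Tversky index is defined, the score is non-negative exactly when the
#' index is at least theta. For the empty/empty pair (index undefined) the
#' score is 0, so the protocol counts that pair as similar.
#'
#' @param p,q fingerprints of equal length.
#' @param lam a [derive_lambdas()] result.
#' @return Integer score.
#' @export
threshold_tversky <- function(p, q, lam) {
  stopifnot(inherits(lam, "lambda_params"))
  if (length(p) != length(q)) stop("fingerprint lengths differ")
  as.integer(lam$lambda1 * intersection_size(p, q) -
               lam$lambda2 * popcount(p) - lam$lambda3 * popcount(q))
}

#' Attainable range of the threshold Tversky score
#'
#' Enumerates all feasible cardinality triples (a, b, c) with
#' `0 <= a, b <= length` and `max(0, a + b - length) <= c <= min(a, b)` and
#' returns the exact minimum and maximum of
#' `lambda1*c - lambda2*a - lambda3*b`. Because the score is linear in c,
#' only the two endpoints of the c-interval matter for each (a, b) cell.
#'
#' `range_size()` is `max - min + 1`, the size k of the inclusive integer
#' interval used as the dummy-value domain (some interior integers may be
#' unattainable; the interval is what the uniform-dummy analysis uses).
#'
#' @param length fingerprint length in bits.
#' @param lam a [derive_lambdas()] result.
#' @return `score_range`: integer `c(min, max)`; `range_size`: integer k.
#' @examples
#' lam <- derive_lambdas(tversky_params())   # (9, 4, 4)
#' score_range(166, lam)                     # -664, 166
#' range_size(166, lam)                      # 831
#' @export
score_range <- function(length, lam) {
  stopifnot(inherits(lam, "lambda_params"), length >= 1)
  ab <- expand.grid(a = 0:length, b = 0:length)
  clo <- pmax(0, ab$a + ab$b - length)
  chi <- pmin(ab$a, ab$b)
  base <- -lam$lambda2 * ab$a - lam$lambda3 * ab$b
  scores <- c(base + lam$lambda1 * clo, base + lam$lambda1 * chi)
  stats::setNames(as.integer(c(min(scores), max(scores))), c("min", "max"))
}

#' @rdname score_range
#' @export
range_size <- function(length, lam) {
  r <- score_range(length, lam)
  as.integer(r[2] - r[1] + 1L)
}
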