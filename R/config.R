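#' Parse a fraction string
#'
#' Similarity parameters and thresholds are exchanged as exact fraction
#' strings (`"4/5"`) or plain integers (`"2"`), never as decimal floats, so
#' that both parties derive identical integer lambda parameters.
#'
#' @param x a string like `"N/D"` or `"N"`, or a whole number.
#' @return Integer `c(num, den)`.
#' @export
parse_fraction <- function(x) {
  if (is.numeric(x) && length(x) == 1 && x == floor(x))
    return(c(num = as.integer(x), den = 1L))
  if (!is.character(x) || length(x) != 1)
    stop("expected a fraction string like '4/5'")
  m <- regmatches(x, regexec("^\\s*(\\d+)\\s*(?:/\\s*(\\d+)\\s*)?$", x))[[1]]
  if (length(m) == 0 || !nzchar(m[2]))
    stop(sprintf("invalid fraction string: '%s'", x))
  num <- as.integer(m[2])
  den <- if (nzchar(m[3])) as.integer(m[3]) else 1L
  if (is.na(num) || is.na(den) || den == 0)
    stop(sprintf("invalid fraction string: '%s'", x))
  c(num = num, den = den)
}

#' Protocol configuration
#'
#' Bundles everything both parties must agree on: fingerprint length,
#' similarity parameters, dummy settings, curve, and the seed policy.
#' Defaults are the typical chemical-search operating point: 166-bit
#' MACCS-style fingerprints, Jaccard similarity (alpha = beta = 1),
#' threshold 4/5, and 10,000 dummies.
#'
#' Alpha and beta must share the denominator gamma; supply them as
#' fractions with a common denominator (e.g. both `"1/2"` for Dice).
#' Seeds are honoured only under `seed_policy = "test"`; under `"secure"`
#' all randomness is cryptographic and a supplied seed is an error, so a
#' research configuration cannot silently weaken a deployment.
#'
#' @param length fingerprint bits.
#' @param alpha,beta,theta fraction strings (or whole numbers).
#' @param dummies dummy count n.
#' @param curve prime-order group name.
#' @param seed_policy `"secure"` or `"test"`.
#' @param seed optional integer, only valid under the test policy.
#' @return Object of class `"protocol_config"` with derived
#'   `tversky`, `lambda`, `score_range` and `decode_range` members.
#' @examples
#' cfg <- protocol_config()
#' cfg$lambda$lambda1   # 9
#' @export
protocol_config <- function(length = 166, alpha = "1/1", beta = "1/1",
                            theta = "4/5", dummies = 10000,
                            curve = "secp192k1",
                            seed_policy = c("secure", "test"), seed = NULL) {
  seed_policy <- match.arg(seed_policy)
  if (!is.null(seed) && seed_policy != "test")
    stop("a seed is only honoured under seed_policy = 'test'")
  a <- parse_fraction(alpha)
  b <- parse_fraction(beta)
  t <- parse_fraction(theta)
  if (t[1] > t[2] || t[1] < 1)
    stop(sprintf("theta: threshold %d/%d outside (0, 1]", t[1], t[2]))
  # bring alpha and beta to the common denominator gamma
  g <- gcd2(a[2], b[2])
  gamma <- a[2] %/% g * b[2]
  params <- tversky_params(mu_a = a[1] * (gamma %/% a[2]),
                           mu_b = b[1] * (gamma %/% b[2]),
                           gamma = gamma, theta_n = t[1], theta_d = t[2])
  lam <- derive_lambdas(params)
  sr <- score_range(length, lam)
  structure(list(length = as.integer(length), tversky = params,
                 lambda = lam, score_range = sr,
                 decode_range = plaintext_range(sr[1], sr[2]),
                 dummies = dummy_config(dummies, domain = sr,
                                        seed = if (seed_policy == "test")
                                          seed else NULL),
                 curve = curve, seed_policy = seed_policy, seed = seed),
            class = "protocol_config")
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf(paste0("<protocol_config: l=%d, alpha=%d/%d, beta=%d/%d, ",
                     "theta=%d/%d, lambda=(%d,%d,%d), scores [%d, %d], ",
                     "n=%d, %s, %s>\n"),
              x$length, x$tversky$mu_a, x$tversky$gamma, x$tversky$mu_b,
              x$tversky$gamma, x$tversky$theta_n, x$tversky$theta_d,
              x$lambda$lambda1, x$lambda$lambda2, x$lambda$lambda3,
              x$score_range[1], x$score_range[2], x$dummies$n, x$curve,
              x$seed_policy))
  invisible(x)
}

#' Load and dump configuration files
#'
#' Plain-text `key = value` files; unknown keys raise an error naming the
#' offender. `dump_config()` writes the normalized form; loading it back
#' reproduces the configuration.
#'
#' @param path config file, or `NULL` for pure defaults/overrides.
#' @param ... overrides passed to [protocol_config()].
#' @return A `"protocol_config"`.
#' @export
load_config <- function(path = NULL, ...) {
  args <- list(...)
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    kv <- regmatches(lines, regexec("^\\s*([a-z_]+)\\s*=\\s*(.*?)\\s*$",
                                    lines))
    for (m in kv) {
      if (length(m) == 0) stop("malformed config line")
      key <- m[2]
      val <- m[3]
      known <- c("length", "alpha", "beta", "theta", "dummies", "curve",
                 "seed_policy", "seed")
      if (!key %in% known)
        stop(sprintf("unknown configuration key '%s'", key))
      if (!key %in% names(args))
        args[[key]] <- if (key %in% c("length", "dummies", "seed"))
          as.integer(val) else val
    }
  }
  do.call(protocol_config, args)
}

#' @param cfg a `"protocol_config"`.
#' @rdname load_config
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "protocol_config"))
  p <- cfg$tversky
  lines <- c(sprintf("length = %d", cfg$length),
             sprintf("alpha = %d/%d", p$mu_a, p$gamma),
             sprintf("beta = %d/%d", p$mu_b, p$gamma),
             sprintf("theta = %d/%d", p$theta_n, p$theta_d),
             sprintf("dummies = %d", cfg$dummies$n),
             sprintf("curve = %s", cfg$curve),
             sprintf("seed_policy = %s", cfg$seed_policy))
  if (!is.null(cfg$seed)) lines <- c(lines, sprintf("seed = %d", cfg$seed))
  writeLines(lines, path)
  invisible(path)
}
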