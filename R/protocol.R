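#' Dummy-padding configuration
#'
#' The server pads each reply with `n` encrypted dummy scores drawn from a
#' categorical distribution over an integer interval, shuffles them among
#' the true scores, and discloses only `s_d`, the number of non-negative
#' dummies. The domain defaults (in [run_protocol()]) to the attainable
#' score interval from [score_range()], which is what the uniform-dummy
#' privacy analysis assumes; non-uniform weights support the
#' perturbed-distribution experiments.
#'
#' @param n number of dummies (the performance experiments use 10,000).
#' @param domain integer interval `c(lo, hi)`; `NULL` defers to the
#'   protocol's score range.
#' @param weights optional probability weights over `lo:hi` (default
#'   uniform).
#' @param seed optional integer for reproducible draws (test mode).
#' @return Object of class `"dummy_config"`.
#' @export
dummy_config <- function(n = 10000, domain = NULL, weights = NULL,
                         seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(domain)) {
    stopifnot(length(domain) == 2, domain[1] <= domain[2])
    domain <- as.integer(domain)
    if (!is.null(weights)) {
      if (length(weights) != domain[2] - domain[1] + 1)
        stop("need one weight per domain value")
      if (any(weights < 0) || sum(weights) <= 0)
        stop("weights must be non-negative and sum to a positive value")
      weights <- weights / sum(weights)
    }
  } else if (!is.null(weights)) {
    stop("weights require an explicit domain")
  }
  structure(list(n = as.integer(n), domain = domain, weights = weights,
                 seed = seed),
            class = "dummy_config")
}

#' Client query construction
#'
#' Encrypts each bit of the query fingerprint under the client's public key
#' and attaches a zero-knowledge bit-validity proof per ciphertext. Nothing
#' about the plaintext bits is recoverable from the message without the
#' secret key.
#'
#' @param keys client key pair from [key_gen()].
#' @param q query [fingerprint()].
#' @param params optional [tversky_params()] carried in serialized queries
#'   so both parties derive the same lambda parameters.
#' @param seed optional integer: deterministic encryption randomness (test
#'   mode only).
#' @return Object of class `"sscc_query"`: public key, `length` bits of
#'   ciphertext (`enc_bits`) and proofs.
#' @export
build_query <- function(keys, q, params = NULL, seed = NULL) {
  stopifnot(inherits(keys, "sscc_keypair"), inherits(q, "fingerprint"))
  bits <- as.integer(q)
  r <- with_seed(seed, rand_scalars(keys$curve, length(bits),
                                    secure = is.null(seed)))
  ct <- encrypt(public_key(keys), bits, r)
  pr <- prove_bit(public_key(keys), bits, r, ct)
  structure(list(curve = keys$curve, pk = keys$pk, length = length(bits),
                 enc_bits = ct, proofs = pr, params = params),
            class = "sscc_query")
}

#' @export
print.sscc_query <- function(x, ...) {
  cat(sprintf("<sscc_query: %d encrypted bits + proofs on %s>\n",
              x$length, x$curve))
  invisible(x)
}

#' Server-side query validity verification
#'
#' Checks that every encrypted query bit carries a valid zero-knowledge
#' proof of being 0 or 1. The server must refuse to score a query that
#' fails; this blocks illegal-query attacks in which one huge component
#' would make the encrypted score reveal a database bit.
#'
#' @param msg an `"sscc_query"`.
#' @return `TRUE` iff all proofs verify (and the structure is coherent).
#' @export
verify_query <- function(msg) {
  if (!inherits(msg, "sscc_query")) return(FALSE)
  if (nrow(msg$enc_bits) != msg$length || nrow(msg$proofs) != msg$length)
    return(FALSE)
  pk <- structure(list(curve = msg$curve, pk = msg$pk),
                  class = "sscc_pubkey")
  all(verify_bit(pk, msg$enc_bits, msg$proofs))
}

#' Encrypted threshold-Tversky scores for a database
#'
#' For each database fingerprint p, homomorphically assembles a ciphertext
#' of `lambda1*|p∩q| - lambda2*|p| - lambda3*|q|` from the encrypted query
#' bits: `Enc(|p∩q|)` is the sum of the query-bit ciphertexts selected by
#' p, `Enc(-|q|)` is derived by the server from the query itself (never
#' requested from the client), and `Enc(-|p|)` is encrypted server-side.
#' Every score is rerandomized before release so its bytes carry no
#' structural signal. The query must pass [verify_query()] first.
#'
#' @param msg a verified `"sscc_query"`.
#' @param db list of database fingerprints (length `msg$length` each).
#' @param lam [derive_lambdas()] output.
#' @param seed optional integer (test mode randomness).
#' @return `"sscc_ciphertexts"` with one row per database entry.
#' @export
encrypted_scores <- function(msg, db, lam, seed = NULL) {
  stopifnot(inherits(lam, "lambda_params"))
  if (!verify_query(msg))
    stop("query failed validity verification; refusing to score")
  dbm <- fp_matrix(db)
  if (ncol(dbm) != msg$length)
    stop("database fingerprint length differs from query length")
  M <- nrow(dbm)
  rs <- with_seed(seed, rand_scalars(msg$curve, 2 * M,
                                     secure = is.null(seed)))
  out <- cpp_scores(msg$curve, msg$pk, ct_matrix(msg$enc_bits), dbm,
                    c(lam$lambda1, lam$lambda2, lam$lambda3),
                    rs[seq_len(M)], rs[M + seq_len(M)])
  new_ciphertexts(out, msg$curve)
}

#' Server-side dummy generation
#'
#' Draws `n` dummy score values from the configured distribution, encrypts
#' them under the client's public key, and counts `s_d`, the number of
#' non-negative dummy values (zero counts as non-negative).
#'
#' @param pk client key pair or [public_key()].
#' @param cfg a [dummy_config()] with an explicit domain.
#' @return List with `ct` (`"sscc_ciphertexts"`, `n` rows) and `s_d`.
#' @export
make_dummies <- function(pk, cfg) {
  stopifnot(inherits(cfg, "dummy_config"))
  if (is.null(cfg$domain)) stop("dummy domain not set")
  pk <- as_pub(pk)
  vals_r <- with_seed(cfg$seed, {
    list(v = draw_dummy_values(cfg),
         r = rand_scalars(pk$curve, cfg$n, secure = is.null(cfg$seed)))
  })
  ct <- if (cfg$n == 0) new_ciphertexts(matrix(character(0), 0, 2), pk$curve)
        else encrypt(pk, vals_r$v, vals_r$r)
  list(ct = ct, s_d = sum(vals_r$v >= 0))
}

# plaintext dummy draw (uses the ambient RNG stream; make_dummies wraps it
# in the configured seed)
draw_dummy_values <- function(cfg) {
  if (cfg$n == 0) return(integer(0))
  sample(cfg$domain[1]:cfg$domain[2], cfg$n, replace = TRUE,
         prob = cfg$weights)
}

#' Assemble the server's reply
#'
#' Concatenates the true encrypted scores with the encrypted dummies and
#' applies a uniformly random permutation, so the client cannot tell which
#' items are scores. `s_d` is passed through in the clear.
#'
#' @param scores encrypted scores from [encrypted_scores()].
#' @param dummies encrypted dummies (`$ct` from [make_dummies()]).
#' @param s_d count of non-negative dummy values.
#' @param seed optional integer for a reproducible shuffle (test mode).
#' @return Object of class `"sscc_reply"`: shuffled `items` plus `s_d`.
#' @export
assemble_reply <- function(scores, dummies, s_d, seed = NULL) {
  curve <- attr(scores, "curve")
  items <- rbind(ct_matrix(scores), ct_matrix(dummies))
  perm <- with_seed(seed, sample.int(nrow(items)))
  structure(list(items = new_ciphertexts(items[perm, , drop = FALSE], curve),
                 s_d = as.integer(s_d)),
            class = "sscc_reply")
}

#' @export
print.sscc_reply <- function(x, ...) {
  cat(sprintf("<sscc_reply: %d shuffled ciphertexts, s_d = %d>\n",
              nrow(x$items), x$s_d))
  invisible(x)
}

#' Client-side reply evaluation
#'
#' Decrypts every item of the reply, counts the non-negative plaintexts
#' (`s_c`), and reports `s_c - s_d`: the number of database fingerprints
#' whose Tversky index with the query meets the threshold.
#'
#' @param keys client key pair.
#' @param reply an `"sscc_reply"`.
#' @param range [plaintext_range()] covering the score range and the dummy
#'   domain.
#' @return Object of class `"sscc_result"` with `s_c`, `s_d` and `count`.
#' @export
evaluate_reply <- function(keys, reply, range) {
  stopifnot(inherits(reply, "sscc_reply"))
  vals <- decrypt(keys, reply$items, range)
  s_c <- sum(vals >= 0)
  structure(list(s_c = as.integer(s_c), s_d = reply$s_d,
                 count = as.integer(s_c - reply$s_d)),
            class = "sscc_result")
}

#' @export
print.sscc_result <- function(x, ...) {
  cat(sprintf("similar compounds: %d  (s_c = %d, s_d = %d)\n",
              x$count, x$s_c, x$s_d))
  invisible(x)
}

#' Run the full secure similar-compounds counting protocol
#'
#' End-to-end execution against an in-memory database: client key setup,
#' query encryption with bit proofs, server-side proof verification and
#' homomorphic scoring, dummy padding and shuffling, and client-side
#' decryption and counting. Exactly one client-to-server message (the
#' query) and one server-to-client message (the reply) are exchanged.
#'
#' @param q query [fingerprint()].
#' @param db list of database fingerprints of the same length.
#' @param params [tversky_params()] (similarity weights and threshold).
#' @param cfg [dummy_config()]; a `NULL` domain is filled with the
#'   attainable score interval.
#' @param keys optional pre-generated client key pair.
#' @param seed optional integer making the whole run reproducible (test
#'   mode; real deployments leave it `NULL` for cryptographic randomness).
#' @return `"sscc_result"`; its `count` equals the number of database
#'   entries with Tversky index at least theta (see [count_similar()]).
#' @examples
#' \donttest{
#' q <- fingerprint_from_indices(c(1, 2), 8)
#' db <- list(fingerprint_from_indices(c(1, 2, 3), 8),
#'            fingerprint_from_indices(c(4, 5), 8),
#'            fingerprint_from_indices(c(1, 4), 8))
#' pp <- tversky_params(theta_n = 1, theta_d = 2)
#' run_protocol(q, db, pp, dummy_config(n = 20), seed = 1)$count   # 1
#' }
#' @export
run_protocol <- function(q, db, params = tversky_params(),
                         cfg = dummy_config(), keys = NULL, seed = NULL) {
  lam <- derive_lambdas(params)
  sr <- score_range(length(q), lam)
  if (is.null(cfg$domain))
    cfg <- dummy_config(cfg$n, domain = sr, weights = NULL, seed = cfg$seed)
  seeds <- derive_seeds(seed, c("keys", "query", "scores", "dummies",
                                "shuffle"))
  if (is.null(keys)) keys <- key_gen(seed = seeds$keys)
  msg <- build_query(keys, q, params = params, seed = seeds$query)
  if (!verify_query(msg)) stop("internal error: honest query failed proofs")
  scores <- encrypted_scores(msg, db, lam, seed = seeds$scores)
  if (!is.null(seeds$dummies) && is.null(cfg$seed))
    cfg$seed <- seeds$dummies
  dum <- make_dummies(keys, cfg)
  reply <- assemble_reply(scores, dum$ct, dum$s_d, seed = seeds$shuffle)
  rng <- plaintext_range(min(sr[1], cfg$domain[1]), max(sr[2], cfg$domain[2]))
  evaluate_reply(keys, reply, rng)
}

#' Plaintext brute-force similarity counter
#'
#' Independent oracle for the protocol: counts database fingerprints whose
#' exact Tversky index is at least theta, by direct rational comparison
#' (no lambda rescaling, no encryption). The empty-query/empty-entry pair,
#' where the index is undefined, is counted as similar, matching the
#' integer-score convention (score 0 is non-negative).
#'
#' @param q query fingerprint.
#' @param db list of database fingerprints.
#' @param params [tversky_params()].
#' @return Integer count.
#' @export
count_similar <- function(q, db, params = tversky_params()) {
  if (inherits(db, "fingerprint")) db <- list(db)
  hits <- vapply(db, function(p) {
    if (popcount(p) == 0 && popcount(q) == 0) return(TRUE)
    fraction_geq(tversky_index(p, q, params), params$theta_n, params$theta_d)
  }, logical(1))
  sum(hits)
}
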