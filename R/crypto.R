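#' Prime-order group specification
#'
#' Names the elliptic-curve group over which the additively homomorphic
#' lifted-ElGamal scheme operates. The default, `secp192k1`, is a 192-bit
#' standardized curve of prime order; any named prime-order curve known to
#' the linked OpenSSL build can be used instead.
#'
#' @param name curve short name (e.g. `"secp192k1"`, `"secp256k1"`,
#'   `"prime256v1"`).
#' @return Object of class `"group_spec"` with the curve name, its prime
#'   order (hex) and the fixed generator (compressed hex).
#' @export
group_spec <- function(name = "secp192k1") {
  structure(list(name = name,
                 order = cpp_group_order(name),
                 generator = cpp_group_generator(name)),
            class = "group_spec")
}

# scalars: cryptographic RNG when secure, otherwise derived from the R RNG
# stream (reproducible test mode only)
rand_scalars <- function(curve, n, secure = TRUE) {
  if (n == 0) return(character(0))
  if (secure) return(cpp_rand_scalars(curve, n))
  hexd <- c(0:9, letters[1:6])
  raw <- matrix(sample(hexd, 60L * n, replace = TRUE), nrow = n)
  cpp_scalars_mod_order(curve, apply(raw, 1, paste, collapse = ""))
}

#' Key generation for the lifted-ElGamal scheme
#'
#' Draws a secret scalar in `[1, order - 1]` and computes the public element
#' `pk = sk * G`. Without a seed the scalar comes from the cryptographic
#' RNG; a seed switches to a deterministic derivation from the R RNG stream
#' and is intended only for reproducible tests, never for real use.
#'
#' @param spec a [group_spec()].
#' @param seed optional integer (test reproducibility only).
#' @return Object of class `"sscc_keypair"`: `curve`, `pk` (compressed
#'   point, hex) and `sk` (scalar, hex).
#' @export
key_gen <- function(spec = group_spec(), seed = NULL) {
  stopifnot(inherits(spec, "group_spec"))
  sk <- with_seed(seed, rand_scalars(spec$name, 1, secure = is.null(seed)))
  structure(list(curve = spec$name, pk = cpp_pub_from_sec(spec$name, sk),
                 sk = sk),
            class = "sscc_keypair")
}

#' @export
print.sscc_keypair <- function(x, ...) {
  cat(sprintf("<sscc_keypair on %s: pk %s...>\n", x$curve,
              substr(x$pk, 1, 16)))
  invisible(x)
}

#' Public half of a key pair
#' @param keys an `"sscc_keypair"`.
#' @return Object of class `"sscc_pubkey"` (curve + public element).
#' @export
public_key <- function(keys) {
  structure(list(curve = keys$curve, pk = keys$pk), class = "sscc_pubkey")
}

as_pub <- function(x) {
  if (inherits(x, "sscc_keypair")) public_key(x)
  else if (inherits(x, "sscc_pubkey")) x
  else stop("expected a key pair or public key")
}

new_ciphertexts <- function(mat, curve) {
  structure(mat, curve = curve, class = "sscc_ciphertexts")
}

#' @export
print.sscc_ciphertexts <- function(x, ...) {
  cat(sprintf("<%d lifted-ElGamal ciphertext(s) on %s>\n",
              nrow(x), attr(x, "curve")))
  invisible(x)
}

#' @export
`[.sscc_ciphertexts` <- function(x, i, ...) {
  new_ciphertexts(unclass(x)[i, , drop = FALSE], attr(x, "curve"))
}

ct_matrix <- function(ct) {
  stopifnot(inherits(ct, "sscc_ciphertexts"))
  unclass(ct)
}

#' Additively homomorphic encryption and its operators
#'
#' `encrypt()` produces lifted-ElGamal ciphertexts `(r*G, r*PK + m*G)`; the
#' plaintext rides in the exponent so that ciphertext addition adds
#' plaintexts. Messages may be negative (the scalar is taken mod the group
#' order). `ct_add()` is the homomorphic plaintext addition, with single-row
#' recycling; `ct_scalar_mul()` multiplies the plaintext by a known (possibly
#' negative) integer; `ct_sum()` folds all rows into one ciphertext; and
#' `rerandomize()` re-encrypts in place so serialized bytes are fresh while
#' the plaintext is untouched.
#'
#' @param pk a key pair or [public_key()].
#' @param m integer plaintext vector.
#' @param randomness optional hex scalars (one per message); fresh
#'   cryptographic randomness is drawn when omitted.
#' @return An `"sscc_ciphertexts"` object (n x 2 hex matrix).
#' @examples
#' keys <- key_gen(seed = 1)
#' ct <- encrypt(keys, c(7, -3))
#' decrypt(keys, ct_add(ct[1], ct[2]), plaintext_range(-10, 10))   # 4
#' @export
encrypt <- function(pk, m, randomness = NULL) {
  pk <- as_pub(pk)
  m <- as.numeric(m)
  if (is.null(randomness)) randomness <- rand_scalars(pk$curve, length(m))
  if (length(randomness) != length(m))
    stop("need one randomness scalar per message")
  new_ciphertexts(cpp_encrypt(pk$curve, pk$pk, m, randomness), pk$curve)
}

#' @param ct,ct_a,ct_b ciphertext objects from [encrypt()].
#' @rdname encrypt
#' @export
ct_add <- function(ct_a, ct_b) {
  curve <- attr(ct_a, "curve")
  if (!identical(curve, attr(ct_b, "curve")))
    stop("ciphertexts live on different curves")
  new_ciphertexts(cpp_ct_add(curve, ct_matrix(ct_a), ct_matrix(ct_b)), curve)
}

#' @param e integer multiplier(s), possibly negative.
#' @rdname encrypt
#' @export
ct_scalar_mul <- function(e, ct) {
  curve <- attr(ct, "curve")
  new_ciphertexts(cpp_ct_smul(curve, as.numeric(e), ct_matrix(ct)), curve)
}

#' @rdname encrypt
#' @export
ct_sum <- function(ct) {
  curve <- attr(ct, "curve")
  new_ciphertexts(cpp_ct_sum(curve, ct_matrix(ct)), curve)
}

#' @rdname encrypt
#' @export
rerandomize <- function(pk, ct, randomness = NULL) {
  pk <- as_pub(pk)
  if (is.null(randomness)) randomness <- rand_scalars(pk$curve, nrow(ct))
  new_ciphertexts(cpp_rerandomize(pk$curve, pk$pk, ct_matrix(ct), randomness),
                  pk$curve)
}

#' Bounded plaintext interval for decryption
#'
#' Lifted-ElGamal decryption must solve a small discrete logarithm, so the
#' decoder needs to know the interval the plaintext lives in; the threshold
#' Tversky score of 166-bit fingerprints at the Jaccard/0.8 setting, for
#' instance, lies in `[-664, 166]`.
#'
#' @param lo,hi inclusive integer bounds with `lo <= 0 <= hi`.
#' @return Object of class `"plaintext_range"`.
#' @export
plaintext_range <- function(lo, hi) {
  stopifnot(lo <= 0, hi >= 0, hi - lo < 2^24)
  structure(list(lo = as.integer(lo), hi = as.integer(hi)),
            class = "plaintext_range")
}

#' Decrypt ciphertexts over a bounded plaintext range
#'
#' Recovers each plaintext by a precomputed-table discrete-log search over
#' the supplied range. A plaintext outside the range is a protocol error
#' (misuse or attack) and raises a decode-failure error.
#'
#' @param keys an `"sscc_keypair"` (the secret scalar is required).
#' @param ct ciphertexts from [encrypt()].
#' @param range a [plaintext_range()].
#' @return Integer vector of plaintexts.
#' @export
decrypt <- function(keys, ct, range) {
  stopifnot(inherits(keys, "sscc_keypair"), inherits(range, "plaintext_range"))
  out <- cpp_decrypt(keys$curve, keys$sk, ct_matrix(ct), range$lo, range$hi)
  if (anyNA(out))
    stop(sprintf("decode failure: %d plaintext(s) outside [%d, %d]",
                 sum(is.na(out)), range$lo, range$hi))
  out
}
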