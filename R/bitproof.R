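#' Zero-knowledge proof that a ciphertext encrypts a bit
#'
#' The defense against illegal-query attacks: alongside each encrypted query
#' bit, the client attaches a non-interactive zero-knowledge proof that the
#' plaintext is 0 or 1, and the server refuses to score queries whose proofs
#' fail. The construction is the standard two-branch disjunctive
#' Chaum-Pedersen sigma protocol over the lifted-ElGamal ciphertext
#' ("plaintext is 0" OR "plaintext is 1"), made non-interactive by a
#' Fiat-Shamir challenge: SHA-256 over a domain-separated serialization of
#' (curve, public key, ciphertext, commitments), reduced mod the group
#' order. Completeness, soundness for non-bit plaintexts, and binding to the
#' exact ciphertext and key follow from the sigma-protocol structure.
#'
#' `prove_bit()` runs the honest prover. Forcing it through with a plaintext
#' outside \{0,1\} produces a proof that the verifier rejects (this is how
#' soundness is exercised in tests). `verify_bit()` never throws on
#' malformed encodings; it returns `FALSE`.
#'
#' @param pk key pair or [public_key()].
#' @param m claimed plaintext bits (vector).
#' @param randomness hex scalars used when encrypting `m` (one per bit).
#' @param ct the ciphertexts produced from `m` and `randomness`.
#' @return `prove_bit()`: an `"sscc_bitproofs"` object (n x 8 hex matrix);
#'   `verify_bit()`: logical vector.
#' @examples
#' keys <- key_gen(seed = 1)
#' r <- sscc:::rand_scalars(keys$curve, 2)
#' ct <- encrypt(keys, c(0, 1), r)
#' pr <- prove_bit(keys, c(0, 1), r, ct)
#' verify_bit(keys, ct, pr)        # TRUE TRUE
#' @export
prove_bit <- function(pk, m, randomness, ct) {
  pk <- as_pub(pk)
  m <- as.integer(m)
  if (length(randomness) != length(m) || nrow(ct) != length(m))
    stop("m, randomness and ct must have one entry per bit")
  structure(cpp_prove_bits(pk$curve, pk$pk, m, randomness, ct_matrix(ct)),
            curve = pk$curve, class = "sscc_bitproofs")
}

#' @param proof an `"sscc_bitproofs"` object.
#' @rdname prove_bit
#' @export
verify_bit <- function(pk, ct, proof) {
  pk <- as_pub(pk)
  cpp_verify_bits(pk$curve, pk$pk, ct_matrix(ct),
                  unclass(proof), character(0))
}

#' @export
print.sscc_bitproofs <- function(x, ...) {
  cat(sprintf("<%d bit-validity proof(s) on %s>\n", nrow(x), attr(x, "curve")))
  invisible(x)
}

#' @export
`[.sscc_bitproofs` <- function(x, i, ...) {
  structure(unclass(x)[i, , drop = FALSE], curve = attr(x, "curve"),
            class = "sscc_bitproofs")
}

# Interactive-protocol simulator and verifier (internal; supports the
# zero-knowledge contract test: simulated transcripts, fabricated from the
# public data alone, satisfy the sigma verification equations).
simulate_bit_proof <- function(pk, ct) {
  pk <- as_pub(pk)
  out <- cpp_simulate_bits(pk$curve, pk$pk, ct_matrix(ct))
  list(proof = structure(out[, 1:8, drop = FALSE], curve = pk$curve,
                         class = "sscc_bitproofs"),
       challenge = out[, 9])
}

verify_bit_sigma <- function(pk, ct, proof, challenge) {
  pk <- as_pub(pk)
  cpp_verify_bits(pk$curve, pk$pk, ct_matrix(ct), unclass(proof), challenge)
}
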