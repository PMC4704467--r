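# Plain-text single-document serialization of keys, queries and replies.
# Every file starts with a version tag line; fields are "key: value"; bulk
# payloads are one whitespace-separated hex record per line.

read_kv <- function(lines, key, required = TRUE) {
  pat <- paste0("^", key, ": ")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0) {
    if (required) stop(sprintf("missing field '%s'", key))
    return(NULL)
  }
  sub(pat, "", hit[1])
}

#' Read and write key material, queries and replies as text files
#'
#' Single-document plain-text formats with an explicit version tag. Query
#' files carry the protocol context (curve, fingerprint length, and the
#' five integer Tversky parameters) so client and server derive identical
#' lambda parameters; each of the `length` payload lines holds one
#' ciphertext and its bit proof. Key files hold the curve, the public
#' element and (for the client's own file) the secret scalar. Reply files
#' hold `s_d` and the shuffled ciphertext items.
#'
#' @param keys,msg,reply the object to serialize.
#' @param path file path.
#' @param private if `FALSE`, [write_keys()] omits the secret scalar.
#' @return Readers return the deserialized object; writers invisibly return
#'   `path`.
#' @export
write_keys <- function(keys, path, private = TRUE) {
  stopifnot(inherits(keys, "sscc_keypair") || inherits(keys, "sscc_pubkey"))
  lines <- c("sscc-key-v1",
             paste0("curve: ", keys$curve),
             paste0("pk: ", keys$pk))
  if (private && !is.null(keys$sk)) lines <- c(lines, paste0("sk: ", keys$sk))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_keys
#' @export
read_keys <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "sscc-key-v1") stop("not an sscc key file")
  curve <- read_kv(lines, "curve")
  pk <- read_kv(lines, "pk")
  sk <- read_kv(lines, "sk", required = FALSE)
  if (is.null(sk))
    structure(list(curve = curve, pk = pk), class = "sscc_pubkey")
  else
    structure(list(curve = curve, pk = pk, sk = sk), class = "sscc_keypair")
}

#' @rdname write_keys
#' @export
write_query_message <- function(msg, path) {
  stopifnot(inherits(msg, "sscc_query"))
  hdr <- c("sscc-query-v1",
           paste0("curve: ", msg$curve),
           paste0("length: ", msg$length),
           paste0("pk: ", msg$pk))
  if (!is.null(msg$params)) {
    p <- msg$params
    hdr <- c(hdr, sprintf("params: %d %d %d %d %d", p$mu_a, p$mu_b,
                          p$gamma, p$theta_n, p$theta_d))
  }
  body <- apply(cbind(ct_matrix(msg$enc_bits), unclass(msg$proofs)), 1,
                paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_keys
#' @export
read_query_message <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "sscc-query-v1") stop("not an sscc query file")
  curve <- read_kv(lines, "curve")
  len <- as.integer(read_kv(lines, "length"))
  pk <- read_kv(lines, "pk")
  pstr <- read_kv(lines, "params", required = FALSE)
  params <- NULL
  if (!is.null(pstr)) {
    v <- as.integer(strsplit(pstr, " ")[[1]])
    params <- tversky_params(v[1], v[2], v[3], v[4], v[5])
  }
  body <- lines[!grepl("^(sscc-query-v1$|curve: |length: |pk: |params: )",
                       lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != len)
    stop(sprintf("expected %d payload lines, found %d", len, length(body)))
  fields <- do.call(rbind, strsplit(body, " +"))
  if (ncol(fields) != 10) stop("malformed query payload line")
  structure(list(curve = curve, pk = pk, length = len,
                 enc_bits = new_ciphertexts(fields[, 1:2, drop = FALSE],
                                            curve),
                 proofs = structure(fields[, 3:10, drop = FALSE],
                                    curve = curve, class = "sscc_bitproofs"),
                 params = params),
            class = "sscc_query")
}

#' @rdname write_keys
#' @export
write_reply_message <- function(reply, path) {
  stopifnot(inherits(reply, "sscc_reply"))
  writeLines(c("sscc-reply-v1",
               paste0("curve: ", attr(reply$items, "curve")),
               paste0("s_d: ", reply$s_d),
               apply(ct_matrix(reply$items), 1, paste, collapse = " ")),
             path)
  invisible(path)
}

#' @rdname write_keys
#' @export
read_reply_message <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "sscc-reply-v1") stop("not an sscc reply file")
  curve <- read_kv(lines, "curve")
  s_d <- as.integer(read_kv(lines, "s_d"))
  body <- lines[!grepl("^(sscc-reply-v1$|curve: |s_d: )", lines)]
  body <- body[nzchar(trimws(body))]
  items <- do.call(rbind, strsplit(body, " +"))
  if (!is.null(items) && ncol(items) != 2) stop("malformed reply payload")
  if (is.null(items)) items <- matrix(character(0), 0, 2)
  structure(list(items = new_ciphertexts(items, curve), s_d = s_d),
            class = "sscc_reply")
}
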