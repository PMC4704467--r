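#' Binary molecular fingerprints
#'
#' A fingerprint is a fixed-length bit vector recording the presence or
#' absence of structural keys in a molecule; the 166-key MACCS set is the
#' standard example. `fingerprint()` builds one from a 0/1 vector,
#' `fingerprint_from_indices()` from the set of 1-based positions that are
#' set.
#'
#' @param bits integer (or logical) vector of 0s and 1s.
#' @param id optional character label.
#' @return An object of class `"fingerprint"`: an integer 0/1 vector with an
#'   optional `id` attribute.
#' @examples
#' fp <- fingerprint(c(1, 0, 1, 1, 0, 0, 0, 0), id = "ex")
#' popcount(fp)
#' @export
fingerprint <- function(bits, id = NULL) {
  if (is.logical(bits)) bits <- as.integer(bits)
  bits <- as.integer(bits)
  if (length(bits) < 1) stop("a fingerprint needs at least one bit")
  if (anyNA(bits) || !all(bits %in% c(0L, 1L)))
    stop("fingerprint bits must all be 0 or 1")
  structure(bits, id = id, class = "fingerprint")
}

#' @param indices 1-based positions of the set bits.
#' @param length total number of bits.
#' @rdname fingerprint
#' @export
fingerprint_from_indices <- function(indices, length, id = NULL) {
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > length)) stop("index outside 1..length")
  bits <- integer(length)
  bits[indices] <- 1L
  fingerprint(bits, id = id)
}

#' @export
print.fingerprint <- function(x, ...) {
  id <- attr(x, "id")
  cat(sprintf("<fingerprint%s: %d bits, popcount %d>\n",
              if (is.null(id)) "" else paste0(" ", id), length(x), sum(x)))
  invisible(x)
}

#' Number of set bits
#'
#' @param fp a [fingerprint()].
#' @return Integer count of 1-bits, `|p|`.
#' @export
popcount <- function(fp) {
  sum(as.integer(fp))
}

#' Size of the intersection of two fingerprints
#'
#' Counts positions set in both fingerprints, `|p ∩ q|`.
#'
#' @param a,b fingerprints of equal length.
#' @return Integer intersection cardinality.
#' @export
intersection_size <- function(a, b) {
  if (length(a) != length(b))
    stop(sprintf("fingerprint lengths differ: %d vs %d", length(a), length(b)))
  sum(as.integer(a) & as.integer(b))
}

# ---- FPS-style hex text I/O -------------------------------------------------
#
# Dialect: header lines start with "#" and must include "#num_bits=<l>"; each
# data line is "<hex>\t<id>". Bit i (1-based) lives in byte floor((i-1)/8),
# at bit position (i-1) %% 8 counted from the least significant bit; bytes
# run left to right. Pad bits beyond num_bits in the final byte are zero.

fp_to_hex <- function(fp) {
  bits <- as.integer(fp)
  nb <- ceiling(length(bits) / 8)
  padded <- c(bits, integer(nb * 8 - length(bits)))
  m <- matrix(padded, nrow = 8)          # column = byte, row = bit position
  vals <- as.integer(2^(0:7) %*% m)
  paste(sprintf("%02x", vals), collapse = "")
}

hex_to_bits <- function(hex, num_bits, line_no) {
  hex <- tolower(hex)
  if (!grepl("^[0-9a-f]+$", hex) || nchar(hex) %% 2 != 0)
    stop(sprintf("line %d: malformed hex fingerprint", line_no))
  if (nchar(hex) != 2 * ceiling(num_bits / 8))
    stop(sprintf("line %d: hex length %d does not match num_bits=%d",
                 line_no, nchar(hex), num_bits))
  vals <- strtoi(substring(hex, seq(1, nchar(hex), 2), seq(2, nchar(hex), 2)),
                 base = 16L)
  bits <- as.integer(bitwAnd(rep(vals, each = 8),
                             rep(2^(0:7), length(vals))) > 0)
  if (any(bits[seq_along(bits) > num_bits] != 0L))
    stop(sprintf("line %d: nonzero pad bits beyond num_bits=%d",
                 line_no, num_bits))
  bits[seq_len(num_bits)]
}

#' Read and write fingerprints in FPS-style hex text
#'
#' The file format is a plain-text dialect of the FPS format: comment/header
#' lines beginning `#`, one of which must be `#num_bits=<l>`, followed by
#' data lines `<hex><TAB><id>`. Within each byte, bit 0 is the least
#' significant bit; bytes are ordered left to right; pad bits beyond the
#' declared length must be zero.
#'
#' @param path file path (or, for `read_fps`, anything `readLines` accepts).
#' @return `read_fps` returns a list of [fingerprint()]s; `write_fps`
#'   invisibly returns `path`.
#' @export
read_fps <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines)
  nb_line <- grep("^#num_bits=", lines, value = TRUE)
  if (length(nb_line) == 0) stop("missing #num_bits= header")
  num_bits <- suppressWarnings(as.integer(sub("^#num_bits=", "", nb_line[1])))
  if (is.na(num_bits) || num_bits < 1) stop("invalid #num_bits= header")
  data_idx <- setdiff(which(nzchar(trimws(lines))), header)
  out <- vector("list", length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 1 || !nzchar(parts[1]))
      stop(sprintf("line %d: expected '<hex>\\t<id>'", i))
    bits <- hex_to_bits(parts[1], num_bits, i)
    out[[k]] <- fingerprint(bits, id = if (length(parts) >= 2) parts[2] else NULL)
  }
  out
}

#' @param fps list of fingerprints of equal length.
#' @rdname read_fps
#' @export
write_fps <- function(fps, path) {
  if (is.object(fps) && inherits(fps, "fingerprint")) fps <- list(fps)
  lens <- vapply(fps, length, 1L)
  if (length(unique(lens)) > 1) stop("fingerprints differ in length")
  ids <- vapply(seq_along(fps), function(i) {
    id <- attr(fps[[i]], "id")
    if (is.null(id)) sprintf("fp%d", i) else id
  }, "")
  lines <- c("#FPS1",
             sprintf("#num_bits=%d", lens[1]),
             paste(vapply(fps, fp_to_hex, ""), ids, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic fingerprint generator
#'
#' Generates random fingerprints that stand in for database entries in
#' experiments. By default each bit is an independent Bernoulli draw with
#' the given density, which matches the marginal sparsity of MACCS-style
#' keys without their correlation structure. The optional block-correlated
#' mode switches whole blocks of keys on or off before sampling bits inside
#' active blocks, giving crude positive correlation between neighbouring
#' keys.
#'
#' @param count number of fingerprints.
#' @param length bits per fingerprint (default 166, MACCS-style).
#' @param density marginal probability that a bit is set.
#' @param seed optional integer seed for reproducibility.
#' @param correlated if `TRUE`, use the blockwise-correlated mode.
#' @param block_size block width for the correlated mode.
#' @return List of [fingerprint()]s.
#' @examples
#' fps <- random_fingerprints(3, length = 166, density = 0.3, seed = 1)
#' sapply(fps, popcount)
#' @export
random_fingerprints <- function(count, length = 166, density = 0.3,
                                seed = NULL, correlated = FALSE,
                                block_size = 8) {
  stopifnot(count >= 1, length >= 1, density >= 0, density <= 1)
  with_seed(seed, {
    lapply(seq_len(count), function(i) {
      if (!correlated) {
        bits <- rbinom(length, 1L, density)
      } else {
        nblk <- ceiling(length / block_size)
        # active blocks carry the mass; within-block density is scaled so the
        # marginal stays `density`
        active <- rbinom(nblk, 1L, 0.5)
        inner <- min(1, 2 * density)
        bits <- (rbinom(length, 1L, inner) *
                   rep(active, each = block_size)[seq_len(length)])
      }
      fingerprint(bits, id = sprintf("rand%d", i))
    })
  })
}

# list of fingerprints -> M x l integer matrix (internal)
fp_matrix <- function(fps) {
  if (inherits(fps, "fingerprint")) fps <- list(fps)
  lens <- vapply(fps, length, 1L)
  if (length(unique(lens)) > 1) stop("fingerprints differ in length")
  do.call(rbind, lapply(fps, as.integer))
}
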