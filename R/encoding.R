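#' Deterministic placement offset for the 23 x 175 encoding
#'
#' Each sequence is placed at a site within the middle 145 columns of the
#' input window that is uniform-looking across sequences but always the
#' same for a given (sequence, seed) pair, so a design sees one consistent
#' placement across epochs while the population of designs covers the
#' window. The offset is derived from a documented polynomial byte hash of
#' the sequence mixed with the seed -- never from the language's randomized
#' string hashing -- so results are stable across sessions and platforms.
#'
#' Coordinates are 0-based: residues occupy columns `offset .. offset+len-1`
#' with the legal range `15 <= offset <= 160 - len`; the start symbol `J`
#' sits at `offset - 1` and the stop symbol `O` at `offset + len`.
#'
#' @param primary a primary sequence (character scalar), at most 145 long.
#' @param globalSeed integer seed mixed into the hash.
#' @return Integer 0-based column offset of the first residue.
#' @examples
#' deterministicOffset("MKVLAT", 1L) == deterministicOffset("MKVLAT", 1L)
#' @export
deterministicOffset <- function(primary, globalSeed = 0L) {
  len <- nchar(primary)
  if (len > 145L) {
    stop("sequence longer than 145 residues cannot be placed", call. = FALSE)
  }
  span <- 146L - len   # number of legal offsets in [15, 160 - len]
  h <- .stableHash(paste0(primary, ":", as.integer(globalSeed)))
  15L + as.integer(h %% span)
}

# Polynomial rolling hash modulo a prime < 2^26 so all intermediates stay
# exactly representable in doubles (131 * 2^26 + 255 < 2^53).
.stableHash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261 %% 67108859
  for (b in bytes) h <- (h * 131 + b) %% 67108859
  h
}

#' One-hot encode a primary sequence into the 23 x 175 input window
#'
#' Produces the fixed binary encoding consumed by the evaluator and
#' unfolded-state models: rows follow [primaryAlphabet()] (20 residues,
#' then `X` pad, `J` start, `O` stop); the sequence occupies columns
#' `offset .. offset+len-1` (0-based), flanked by one `J` and one `O`, with
#' `X` elsewhere. Every column sums to one.
#'
#' @param primary primary sequence over the 20-AA alphabet.
#' @param offset 0-based column of the first residue; defaults to the
#'   deterministic per-sequence placement with seed 0.
#' @return For `encodePrimary`, a 23 x 175 binary matrix with an `offset`
#'   attribute. For `decodePrimary`, a list with `primary` and `offset`.
#' @examples
#' m <- encodePrimary("MKVLAT", offset = 20L)
#' decodePrimary(m)$primary
#' @export
encodePrimary <- function(primary, offset = deterministicOffset(primary)) {
  .checkSymbols(primary, .AA20, "primary")
  len <- nchar(primary)
  if (offset < 15L || offset + len - 1L > 159L) {
    stop("offset outside the middle-145 window for this length", call. = FALSE)
  }
  mat <- matrix(0L, nrow = 23L, ncol = 175L,
                dimnames = list(.PRIMARY_EM, NULL))
  cols <- (offset + 1L):(offset + len)          # 1-based columns
  rows <- match(.splitSeq(primary), .PRIMARY_EM)
  mat[cbind(rows, cols)] <- 1L
  mat[match("J", .PRIMARY_EM), offset] <- 1L
  mat[match("O", .PRIMARY_EM), offset + len + 1L] <- 1L
  pad <- setdiff(seq_len(175L), c(offset, cols, offset + len + 1L))
  mat[match("X", .PRIMARY_EM), pad] <- 1L
  attr(mat, "offset") <- as.integer(offset)
  mat
}

#' @rdname encodePrimary
#' @param mat an encoded matrix as returned by the encoder.
#' @export
decodePrimary <- function(mat) {
  sym <- .PRIMARY_EM[max.col(t(mat), ties.method = "first")]
  res <- which(!sym %in% c("X", "J", "O"))
  list(primary = paste(sym[res], collapse = ""),
       offset = as.integer(res[1L] - 1L))
}

#' One-hot encode a secondary string, aligned with its primary encoding
#'
#' Mirrors [encodePrimary()]: rows follow [secondaryAlphabet()]
#' (`L,E,H,X,J,O`), the string is placed at the same 0-based `offset` as
#' the paired primary with `J`/`O` flanks and `X` padding, so the two
#' encodings align column for column. This binary form is the training
#' target for the evaluator's secondary head.
#'
#' @param secondary string over \{L,E,H\}.
#' @param offset 0-based column of the first symbol (same as the paired
#'   primary's offset).
#' @return For `encodeSecondary`, a 6 x 175 binary matrix with an `offset`
#'   attribute; for `decodeSecondary`, a list with `secondary` and `offset`.
#' @export
encodeSecondary <- function(secondary, offset) {
  .checkSymbols(secondary, c("L", "E", "H"), "secondary")
  len <- nchar(secondary)
  if (offset < 15L || offset + len - 1L > 159L) {
    stop("offset outside the middle-145 window for this length", call. = FALSE)
  }
  mat <- matrix(0L, nrow = 6L, ncol = 175L, dimnames = list(.SECONDARY, NULL))
  cols <- (offset + 1L):(offset + len)
  rows <- match(.splitSeq(secondary), .SECONDARY)
  mat[cbind(rows, cols)] <- 1L
  mat[match("J", .SECONDARY), offset] <- 1L
  mat[match("O", .SECONDARY), offset + len + 1L] <- 1L
  pad <- setdiff(seq_len(175L), c(offset, cols, offset + len + 1L))
  mat[match("X", .SECONDARY), pad] <- 1L
  attr(mat, "offset") <- as.integer(offset)
  mat
}

#' @rdname encodeSecondary
#' @param mat an encoded 6 x 175 matrix.
#' @export
decodeSecondary <- function(mat) {
  sym <- .SECONDARY[max.col(t(mat), ties.method = "first")]
  res <- which(sym %in% c("L", "E", "H"))
  list(secondary = paste(sym[res], collapse = ""),
       offset = as.integer(res[1L] - 1L))
}

# Batch encoder: returns a 23 x 175 x n array (double, for the conv kernels).
.encodeBatch <- function(seqs, offsets) {
  n <- length(seqs)
  arr <- array(0, dim = c(23L, 175L, n))
  for (i in seq_len(n)) arr[, , i] <- encodePrimary(seqs[[i]], offsets[[i]])
  arr
}

# Secondary string (over L,E,H) -> 6 x L one-hot without window placement.
secondaryToMatrixRaw <- function(secondary) {
  ch <- .splitSeq(secondary)
  mat <- matrix(0, nrow = 6L, ncol = length(ch),
                dimnames = list(.SECONDARY, NULL))
  mat[cbind(match(ch, .SECONDARY), seq_along(ch))] <- 1
  mat
}
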