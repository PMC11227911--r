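# VHSE8 codec: canonical residues <-> 8-dimensional physicochemical vectors.
#
# Each amino acid is represented by its eight VHSE principal-component
# scores (hydrophobic, steric and electronic properties). A sequence is
# embedded into a fixed frame of `frameLength` rows; rows past the last
# residue are all-zero "gap" vectors. Values are used exactly as published,
# with no rescaling (a standardization switch is exposed for completeness).

.vhseCache <- new.env(parent = emptyenv())

#' The VHSE8 descriptor table
#'
#' Returns the 20 x 8 matrix of VHSE8 principal-component scores, one row
#' per canonical amino acid (rows in alphabetical residue order). The table
#' is shipped as a plain CSV under `inst/extdata/vhse8.csv` and loaded once
#' per session.
#'
#' @param standardize If `TRUE`, columns are centred and scaled to unit
#'   variance across the 20 residues before use. Default `FALSE`: published
#'   values as-is.
#' @return Numeric matrix with rownames `A...Y` and 8 descriptor columns.
#' @examples
#' vhseTable()["W", ]
#' @export
vhseTable <- function(standardize = FALSE) {
  key <- if (standardize) "std" else "raw"
  if (!is.null(.vhseCache[[key]])) return(.vhseCache[[key]])
  path <- system.file("extdata", "vhse8.csv", package = "ProtDiffuser")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L])
  rownames(m) <- tab$residue
  m <- m[AA20, , drop = FALSE]
  if (standardize) m <- scale(m)[, , drop = FALSE]
  storage.mode(m) <- "double"
  .vhseCache[[key]] <- m
  m
}

# 21 candidate code vectors used for decoding: 20 residues + the zero gap.
.vhseCodes <- function(standardize = FALSE) {
  rbind(vhseTable(standardize), `-` = rep(0, 8L))
}

#' Minimum pairwise distance among the 21 code vectors
#'
#' Euclidean distance between the closest pair among the 20 VHSE8 residue
#' vectors and the all-zero gap vector. Decoding by nearest neighbour is
#' exact under any additive perturbation of norm strictly below half this
#' value.
#'
#' @inheritParams vhseTable
#' @return A single nonnegative number.
#' @export
minCodeDistance <- function(standardize = FALSE) {
  min(stats::dist(.vhseCodes(standardize)))
}

#' Encode one protein sequence as a fixed-frame VHSE8 matrix
#'
#' @param seq Character scalar (or `AAString`) over the 20-letter canonical
#'   alphabet, of length at most `frameLength`.
#' @param frameLength Frame length (rows) of the encoding; default 560, the
#'   maximum family sequence length.
#' @param standardize Passed to [vhseTable()].
#' @return A `frameLength` x 8 numeric matrix; row i is the VHSE8 vector of
#'   residue i, rows past the sequence end are exactly zero.
#' @examples
#' m <- encodeSequence("MKTAYIAK", frameLength = 16)
#' all(m[9:16, ] == 0)
#' @export
encodeSequence <- function(seq, frameLength = 560L, standardize = FALSE) {
  seq <- .asSeqChar(as.character(seq))
  if (length(seq) != 1L) stop("encodeSequence() expects a single sequence")
  n <- nchar(seq)
  if (n > frameLength)
    stop(sprintf("sequence length %d exceeds the frame length %d", n, frameLength))
  .checkAlphabet(seq)
  m <- matrix(0, nrow = frameLength, ncol = 8L)
  if (n > 0L) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    m[seq_len(n), ] <- vhseTable(standardize)[chars, , drop = FALSE]
  }
  m
}

#' Encode a batch of sequences
#'
#' Stacks per-sequence encodings into the 4-way batch representation
#' `n x 1 x frameLength x 8` (sample, channel, position, descriptor), the
#' layout used for a training batch (64 x 1 x 560 x 8 at full scale).
#'
#' @param seqs Character vector or `AAStringSet`.
#' @inheritParams encodeSequence
#' @return Numeric array of dim `c(length(seqs), 1, frameLength, 8)`.
#' @export
batchEncode <- function(seqs, frameLength = 560L, standardize = FALSE) {
  seqs <- .asSeqChar(seqs)
  out <- array(0, dim = c(length(seqs), 1L, frameLength, 8L))
  for (i in seq_along(seqs))
    out[i, 1L, , ] <- encodeSequence(seqs[i], frameLength, standardize)
  out
}

# Internal 3-way batch layout (n, L, 8) used by the network code.
.encodeStack <- function(seqs, frameLength, standardize = FALSE) {
  seqs <- .asSeqChar(seqs)
  out <- array(0, dim = c(length(seqs), frameLength, 8L))
  for (i in seq_along(seqs))
    out[i, , ] <- encodeSequence(seqs[i], frameLength, standardize)
  out
}

#' Decode a VHSE8 frame matrix back to a sequence
#'
#' Each row is assigned the nearest of the 21 code vectors (20 residues plus
#' the all-zero gap) in Euclidean distance; a row becomes a gap only when its
#' distance to the zero vector is strictly smaller than to every residue
#' vector by at least `gapMargin`. Residue ties break alphabetically.
#' Trailing gaps are trimmed. Internal gaps are removed from the emitted
#' sequence and counted in the `internalGaps` attribute (set `frame = TRUE`
#' to keep them as `-` in a full frame-coordinate string instead).
#'
#' @param m A `frameLength` x 8 numeric matrix.
#' @param gapMargin Nonnegative margin (in distance units) a gap call must
#'   win by; 0 reproduces the plain strict nearest-neighbour rule.
#' @param frame If `TRUE`, return the full frame-length string with `-` at
#'   gap rows (no trimming); useful for fixed-frame motif screening.
#' @param standardize Passed to [vhseTable()].
#' @return Character scalar. For `frame = FALSE` it carries an integer
#'   attribute `internalGaps` with the number of non-trailing gap calls.
#' @examples
#' decodeMatrix(encodeSequence("MKTAYIAK", frameLength = 16))
#' @export
decodeMatrix <- function(m, gapMargin = 0, frame = FALSE, standardize = FALSE) {
  stopifnot(is.matrix(m), ncol(m) == 8L, gapMargin >= 0)
  codes <- vhseTable(standardize)
  # squared distances to all residue codes, L x 20
  d2 <- outer(rowSums(m^2), rowSums(codes^2), "+") - 2 * m %*% t(codes)
  d2[d2 < 0] <- 0
  best <- max.col(-d2, ties.method = "first")   # alphabetical tie-break
  dRes <- sqrt(d2[cbind(seq_len(nrow(m)), best)])
  dGap <- sqrt(rowSums(m^2))
  isGap <- dGap + gapMargin < dRes
  chars <- ifelse(isGap, "-", AA20[best])
  if (frame) return(paste(chars, collapse = ""))
  lastRes <- if (any(!isGap)) max(which(!isGap)) else 0L
  if (lastRes == 0L) {
    out <- ""
    attr(out, "internalGaps") <- 0L
    return(out)
  }
  head <- chars[seq_len(lastRes)]
  out <- paste(head[head != "-"], collapse = "")
  attr(out, "internalGaps") <- sum(head == "-")
  out
}

# Decode every slice of an (n, L, 8) stack; returns list(seqs, frames, internalGaps).
.decodeStack <- function(x, gapMargin = 0, standardize = FALSE) {
  n <- dim(x)[1L]
  seqs <- character(n); frames <- character(n); ig <- integer(n)
  for (i in seq_len(n)) {
    m <- matrix(x[i, , ], ncol = 8L)
    s <- decodeMatrix(m, gapMargin, frame = FALSE, standardize = standardize)
    seqs[i] <- as.character(s)
    ig[i] <- attr(s, "internalGaps")
    frames[i] <- decodeMatrix(m, gapMargin, frame = TRUE, standardize = standardize)
  }
  list(seqs = seqs, frames = frames, internalGaps = ig)
}
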