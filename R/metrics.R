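# Sequence-space evaluation: conservation, entropy, covariation, identity,
# alignment-free k-tuple distances, and cluster size profiles. All column
# statistics take fixed-frame (equal-length) sequence sets; gap characters
# ('-') are excluded from frequency normalization and tracked separately.
# Logarithms are base 2 throughout (entropies and MI in bits).

# per-column residue counts; returns list(counts L x 20, gaps L)
.columnCounts <- function(seqs) {
  m <- .seqCharMatrix(seqs)
  counts <- matrix(0L, ncol(m), 20L, dimnames = list(NULL, AA20))
  for (a in seq_along(AA20))
    counts[, a] <- as.integer(colSums(m == AA20[a]))
  list(counts = counts, gaps = as.integer(colSums(m == "-")),
       n = nrow(m))
}

.entropyFromCounts <- function(counts) {
  apply(counts, 1L, function(cnt) {
    tot <- sum(cnt)
    if (tot == 0L) return(0)
    p <- cnt[cnt > 0] / tot
    -sum(p * log2(p))
  })
}

#' Per-position Shannon entropy of a fixed-frame sequence set
#'
#' \eqn{H_j = -\sum_a p_{aj} \log_2 p_{aj}} over the residues observed at
#' column j, in bits. Bounded by `log2(20)` (about 4.3219) for the
#' 20-letter alphabet.
#'
#' @param seqs Equal-length sequences (`AAStringSet` or character); `-`
#'   marks gaps, which are excluded from the frequencies.
#' @return Numeric vector, one entropy per column.
#' @examples
#' columnEntropy(c("AC", "AG", "AT", "AA"))
#' @export
columnEntropy <- function(seqs) {
  .entropyFromCounts(.columnCounts(seqs)$counts)
}

#' Column count and frequency statistics at selected positions
#'
#' The per-position residue counts and frequencies used to draw sequence
#' logos, e.g. of the five founder positions across natural versus
#' generated sequence sets.
#'
#' @param seqs Equal-length sequences in frame coordinates.
#' @param positions Positions to report (default: all columns).
#' @return An [MSAStats-class].
#' @export
logoCounts <- function(seqs, positions = NULL) {
  cc <- .columnCounts(seqs)
  L <- nrow(cc$counts)
  positions <- as.integer(positions %||% seq_len(L))
  if (length(positions) && (min(positions) < 1L || max(positions) > L))
    stop("positions outside the frame")
  counts <- cc$counts[positions, , drop = FALSE]
  tot <- rowSums(counts)
  freqs <- counts / ifelse(tot == 0L, 1L, tot)
  methods::new("MSAStats", positions = positions,
               counts = counts, freqs = freqs,
               entropy = .entropyFromCounts(counts),
               gaps = cc$gaps[positions])
}

#' Percent identity between two sequences
#'
#' `mode = "fixed"` compares equal-length sequences position by position.
#' `mode = "global"` aligns first with a Needleman-Wunsch global alignment
#' under BLOSUM62 (gap opening 10, extension 0.5) and reports identical
#' positions over aligned positions (gap-inclusive).
#'
#' @param s1,s2 Sequences (character or `AAString`).
#' @param mode `"global"` or `"fixed"`.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwiseIdentity("AAAA", "AAAT", mode = "fixed")
#' @export
pairwiseIdentity <- function(s1, s2, mode = c("global", "fixed")) {
  mode <- match.arg(mode)
  s1 <- .asSeqChar(as.character(s1)); s2 <- .asSeqChar(as.character(s2))
  if (nchar(s1) == 0L || nchar(s2) == 0L) stop("sequences must be nonempty")
  if (mode == "fixed") {
    if (nchar(s1) != nchar(s2)) stop("fixed-frame identity needs equal lengths")
    a <- strsplit(s1, "")[[1L]]; b <- strsplit(s2, "")[[1L]]
    return(100 * mean(a == b))
  }
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(s1),
                                       Biostrings::AAString(s2),
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5,
                                       type = "global")
  Biostrings::pid(aln, type = "PID1")
}

# multiset of k-mers of one sequence
.kmerTable <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) stop(sprintf("sequence shorter than k = %d", k))
  table(substring(s, seq_len(n), seq_len(n) + k - 1L))
}

#' Alignment-free k-tuple distance
#'
#' \eqn{d = 1 - \frac{\sum_w \min(c_1(w), c_2(w))}{\min(n_1, n_2)}}, where
#' \eqn{c_i(w)} counts k-mer w in sequence i and \eqn{n_i} is its k-mer
#' count. Zero for identical sequences, symmetric, in `[0, 1]`.
#'
#' @param s1,s2 Sequences of length at least `k`.
#' @param k Word length, default 3.
#' @return Nonnegative distance.
#' @export
ktupleDistance <- function(s1, s2, k = 3L) {
  s1 <- .asSeqChar(as.character(s1)); s2 <- .asSeqChar(as.character(s2))
  t1 <- .kmerTable(s1, k); t2 <- .kmerTable(s2, k)
  common <- intersect(names(t1), names(t2))
  shared <- sum(pmin(t1[common], t2[common]))
  1 - shared / min(sum(t1), sum(t2))
}

#' k-tuple distance matrix of a sequence set
#'
#' @param seqs `AAStringSet` or character vector.
#' @param k Word length, default 3.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
ktupleDistanceMatrix <- function(seqs, k = 3L) {
  ch <- .asSeqChar(seqs)
  n <- length(ch)
  tabs <- lapply(ch, .kmerTable, k = k)
  sizes <- vapply(tabs, sum, numeric(1))
  d <- matrix(0, n, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    common <- intersect(names(tabs[[i]]), names(tabs[[j]]))
    shared <- sum(pmin(tabs[[i]][common], tabs[[j]][common]))
    d[i, j] <- d[j, i] <- 1 - shared / min(sizes[i], sizes[j])
  }
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

#' Mutual-information covariation matrix
#'
#' \eqn{MI_{jk} = \sum_{a,b} p_{jk}(a,b) \log_2
#' \frac{p_{jk}(a,b)}{p_j(a)\,p_k(b)}} over residue pairs observed at
#' columns j and k (sequences with a gap in either column are dropped for
#' that pair). Symmetric; the diagonal equals the column entropy. The
#' average-product correction (APC) of coevolution analysis is available as
#' an option; the plain MI is the default.
#'
#' @param seqs At least two equal-length sequences.
#' @param apc If `TRUE`, subtract the average-product correction from the
#'   off-diagonal entries.
#' @return L x L numeric matrix in bits.
#' @export
covariationMI <- function(seqs, apc = FALSE) {
  m <- .seqCharMatrix(seqs)
  if (nrow(m) < 2L) stop("need at least two sequences")
  L <- ncol(m)
  idx <- matrix(match(m, AA20), nrow(m), L)  # NA for gaps
  H <- columnEntropy(seqs)
  mi <- diag(H, L)
  if (L > 1L) for (j in seq_len(L - 1L)) for (k in (j + 1L):L) {
    keep <- !is.na(idx[, j]) & !is.na(idx[, k])
    if (!any(keep)) next
    joint <- tabulate(idx[keep, j] + 20L * (idx[keep, k] - 1L), nbins = 400L) / sum(keep)
    pj <- rowSums(matrix(joint, 20L)); pk <- colSums(matrix(joint, 20L))
    pprod <- as.vector(outer(pj, pk))
    nz <- joint > 0
    mi[j, k] <- mi[k, j] <- sum(joint[nz] * log2(joint[nz] / pprod[nz]))
  }
  if (apc && L > 1L) {
    off <- mi; diag(off) <- 0
    rowm <- rowSums(off) / (L - 1L)
    corr <- outer(rowm, rowm) / (sum(off) / (L * (L - 1L)))
    diag(corr) <- 0
    mi <- mi - corr
    diag(mi) <- H
  }
  mi
}

#' Cluster-size profile at an identity threshold
#'
#' Greedy identity clustering (same engine as [clusterIdentity()]) at the
#' given threshold, reporting the member count of each representative --
#' e.g. 50 percent identity cluster sizes of generated versus natural
#' sequence sets.
#'
#' @param seqs `AAStringSet` or character vector.
#' @param threshold Identity threshold in (0, 1].
#' @param k Word length of the identity estimate.
#' @return Integer vector of cluster sizes, one per representative.
#' @export
clusterSizeProfile <- function(seqs, threshold = 0.5, k = 5L) {
  clusterIdentity(seqs, threshold, k)$sizes
}

#' Simple per-sequence physicochemical summaries
#'
#' Length and mean values of the eight VHSE8 descriptors per sequence;
#' a light-weight check that generated sets occupy the same
#' physicochemical-property range as natural ones.
#'
#' @param seqs `AAStringSet` or character vector.
#' @return A data.frame with one row per sequence.
#' @export
propertySummary <- function(seqs) {
  ch <- .asSeqChar(seqs)
  tab <- vhseTable()
  out <- t(vapply(ch, function(s) {
    rows <- tab[strsplit(s, "")[[1L]], , drop = FALSE]
    c(length = nchar(s), colMeans(rows))
  }, numeric(9L)))
  data.frame(id = names(seqs) %||% seq_along(ch), out, row.names = NULL)
}
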