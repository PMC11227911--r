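# Internal helpers shared across modules.

# The 20 canonical residues, alphabetical. This ordering is the package-wide
# convention for count/frequency matrices and for deterministic tie-breaking.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Evaluate an expression under a local RNG seed
#'
#' All stochastic entry points take an explicit `seed` argument; there is no
#' hidden global RNG contract. When `seed` is `NULL` the expression runs under
#' the caller's RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

# Coerce various sequence-set inputs to a plain uppercase character vector.
.asSeqChar <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (methods::is(x, "WeightedCorpus")) x <- as.character(corpusSequences(x))
  if (!is.character(x)) stop("expected a character vector or AAStringSet of sequences")
  toupper(x)
}

.checkAlphabet <- function(seqs, what = "sequence") {
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "]"), seqs)
  if (any(bad)) {
    stop(sprintf("%s %s contains non-canonical residues (alphabet is the 20 canonical amino acids)",
                 what, paste(which(bad), collapse = ",")))
  }
  invisible(TRUE)
}

# Split equal-length sequences into an n x L character matrix.
.seqCharMatrix <- function(seqs) {
  seqs <- .asSeqChar(seqs)
  if (length(seqs) == 0L) stop("need at least one sequence")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must all have equal length for column statistics")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}
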