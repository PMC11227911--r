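#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet pairwiseAlignment pid width
#' @importFrom stats rnorm runif setNames
NULL

#' Noise schedule of the diffusion process
#'
#' Per-timestep noising coefficients of a denoising diffusion probabilistic
#' model: \eqn{\beta_t}, \eqn{\alpha_t = 1 - \beta_t} and the cumulative
#' product \eqn{\bar\alpha_t = \prod_{s \le t} \alpha_s}.
#'
#' @slot steps Number of diffusion timesteps T.
#' @slot beta Numeric vector of length T, each in (0, 1).
#' @slot alpha `1 - beta`.
#' @slot alphaBar Cumulative product of `alpha`; strictly decreasing.
#' @seealso [makeSchedule()]
#' @exportClass NoiseSchedule
setClass("NoiseSchedule",
  representation(steps = "integer", beta = "numeric",
                 alpha = "numeric", alphaBar = "numeric"))

setValidity("NoiseSchedule", function(object) {
  msg <- character()
  if (length(object@steps) != 1L || object@steps < 1L)
    msg <- c(msg, "steps must be a single positive integer")
  if (length(object@beta) != object@steps)
    msg <- c(msg, "beta must have length steps")
  if (any(object@beta <= 0) || any(object@beta >= 1))
    msg <- c(msg, "beta values must lie strictly in (0, 1)")
  if (length(object@alphaBar) > 1L && any(diff(object@alphaBar) >= 0))
    msg <- c(msg, "alphaBar must be strictly decreasing")
  if (length(msg)) msg else TRUE
})

#' Set of fixed residue constraints for inpainting generation
#'
#' Maps 1-based positions in the fixed sequence frame to required amino
#' acids. The default, [founderConstraints()], fixes the five catalytic
#' pocket founder residues T114, F123, A220, M248 and A317 (CYP706X1
#' numbering in the 560-position family frame).
#'
#' @slot positions Integer vector of 1-based frame positions (unique).
#' @slot residues Character vector of required single-letter residues.
#' @exportClass ConstraintSet
setClass("ConstraintSet",
  representation(positions = "integer", residues = "character"))

setValidity("ConstraintSet", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@residues))
    msg <- c(msg, "positions and residues must have equal length")
  if (anyDuplicated(object@positions))
    msg <- c(msg, "constraint positions must be unique")
  if (length(object@positions) && any(object@positions < 1L))
    msg <- c(msg, "positions must be >= 1")
  if (length(object@residues) && !all(object@residues %in% AA20))
    msg <- c(msg, "residues must be canonical single-letter amino acids")
  if (length(msg)) msg else TRUE
})

#' Categorical profile of a synthetic protein family
#'
#' Positions carry independent categorical residue distributions, except for
#' declared covarying pairs which are drawn jointly from a 20 x 20 coupling
#' table. Fully conserved positions are rows with a single unit entry.
#'
#' @slot length Frame length L of the family.
#' @slot probs L x 20 matrix of per-position residue probabilities
#'   (columns in alphabetical residue order), each row summing to 1.
#' @slot pairs List of covarying pairs, each `list(i, j, joint)` with
#'   `joint` a 20 x 20 joint distribution whose marginals replace rows i, j.
#' @exportClass FamilyProfile
setClass("FamilyProfile",
  representation(length = "integer", probs = "matrix", pairs = "list"))

setValidity("FamilyProfile", function(object) {
  msg <- character()
  if (nrow(object@probs) != object@length || ncol(object@probs) != 20L)
    msg <- c(msg, "probs must be a length x 20 matrix")
  if (any(object@probs < 0))
    msg <- c(msg, "probabilities must be nonnegative")
  if (nrow(object@probs) && any(abs(rowSums(object@probs) - 1) > 1e-8))
    msg <- c(msg, "each probs row must sum to 1")
  for (p in object@pairs) {
    if (!is.list(p) || !all(c("i", "j", "joint") %in% names(p))) {
      msg <- c(msg, "each covarying pair needs fields i, j, joint"); next
    }
    if (p$i < 1L || p$j < 1L || p$i > object@length || p$j > object@length || p$i == p$j)
      msg <- c(msg, "pair positions must be distinct and within the frame")
    if (!is.matrix(p$joint) || any(dim(p$joint) != c(20L, 20L)) ||
        any(p$joint < 0) || abs(sum(p$joint) - 1) > 1e-8)
      msg <- c(msg, "coupling tables must be 20 x 20 joint distributions")
  }
  if (length(msg)) msg else TRUE
})

#' Training corpus with per-record sampling weights
#'
#' Background records carry weight 1; an emphasized subfamily carries a
#' larger weight (default emphasis ratio 600), so that the fine-tuning
#' sampler draws record i with probability \eqn{w_i / \sum_k w_k}.
#'
#' @slot seqs `AAStringSet` of training sequences.
#' @slot weights Positive numeric vector, one weight per record.
#' @exportClass WeightedCorpus
setClass("WeightedCorpus",
  representation(seqs = "AAStringSet", weights = "numeric"))

setValidity("WeightedCorpus", function(object) {
  msg <- character()
  if (length(object@weights) != length(object@seqs))
    msg <- c(msg, "one weight per sequence is required")
  if (length(object@weights) && any(!is.finite(object@weights) | object@weights <= 0))
    msg <- c(msg, "weights must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' Column statistics of a fixed-frame sequence set
#'
#' Per-position residue counts, frequencies (gaps excluded from the
#' normalization and tracked separately) and Shannon entropies in bits.
#'
#' @slot positions Frame positions the statistics refer to.
#' @slot counts positions x 20 integer count matrix.
#' @slot freqs positions x 20 frequency matrix (rows sum to 1 where any
#'   residue was observed).
#' @slot entropy Per-position Shannon entropy in bits.
#' @slot gaps Per-position gap counts.
#' @exportClass MSAStats
setClass("MSAStats",
  representation(positions = "integer", counts = "matrix", freqs = "matrix",
                 entropy = "numeric", gaps = "integer"))

#' A sequence diffusion model
#'
#' Bundles the denoiser parameters, the network hyperparameters, the noise
#' schedule, and the sequence frame length into one checkpointable unit.
#' The denoiser is a U-shaped 1-D convolutional network over the VHSE8
#' channel dimension, with a self-attention block at the bottleneck and a
#' sinusoidal-then-linear timestep embedding added inside each residual
#' block.
#'
#' @slot params Named list of parameter arrays.
#' @slot net Named list of architecture hyperparameters
#'   (`frameLength`, `widths`, `kernel`, `posChannels`, `tembDim`).
#' @slot schedule A [NoiseSchedule-class].
#' @slot frameLength Sequence frame length L (560 for the full family frame).
#' @exportClass SeqDiffusionModel
setClass("SeqDiffusionModel",
  representation(params = "list", net = "list",
                 schedule = "NoiseSchedule", frameLength = "integer"))

setValidity("SeqDiffusionModel", function(object) {
  msg <- character()
  if (object@frameLength < 4L || object@frameLength %% 4L != 0L)
    msg <- c(msg, "frameLength must be a positive multiple of 4 (two 2x down-samplings)")
  if (!identical(object@net$frameLength, object@frameLength))
    msg <- c(msg, "net$frameLength must match frameLength")
  if (length(msg)) msg else TRUE
})
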