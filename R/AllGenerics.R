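#' @describeIn NoiseSchedule-class Number of diffusion timesteps.
#' @param x An object.
#' @export
setGeneric("nsteps", function(x) standardGeneric("nsteps"))

#' @describeIn NoiseSchedule-class Per-step noise rates \eqn{\beta_t}.
#' @export
setGeneric("betas", function(x) standardGeneric("betas"))

#' @describeIn NoiseSchedule-class Cumulative signal fractions \eqn{\bar\alpha_t}.
#' @export
setGeneric("alphaBar", function(x) standardGeneric("alphaBar"))

#' @describeIn SeqDiffusionModel-class Sequence frame length.
#' @export
setGeneric("frameLength", function(x) standardGeneric("frameLength"))

#' @describeIn ConstraintSet-class Constrained frame positions.
#' @export
setGeneric("constraintPositions", function(x) standardGeneric("constraintPositions"))

#' @describeIn ConstraintSet-class Required residues at the constrained positions.
#' @export
setGeneric("constraintResidues", function(x) standardGeneric("constraintResidues"))

#' @describeIn WeightedCorpus-class The sequences of a corpus.
#' @export
setGeneric("corpusSequences", function(x) standardGeneric("corpusSequences"))

#' @describeIn WeightedCorpus-class Per-record sampling weights.
#' @export
setGeneric("corpusWeights", function(x) standardGeneric("corpusWeights"))

#' @describeIn MSAStats-class Per-position residue count matrix.
#' @export
setGeneric("countMatrix", function(x) standardGeneric("countMatrix"))

#' @describeIn MSAStats-class Per-position residue frequency matrix.
#' @export
setGeneric("freqMatrix", function(x) standardGeneric("freqMatrix"))

setMethod("nsteps", "NoiseSchedule", function(x) x@steps)
setMethod("betas", "NoiseSchedule", function(x) x@beta)
setMethod("alphaBar", "NoiseSchedule", function(x) x@alphaBar)
setMethod("frameLength", "SeqDiffusionModel", function(x) x@frameLength)
setMethod("nsteps", "SeqDiffusionModel", function(x) x@schedule@steps)
setMethod("constraintPositions", "ConstraintSet", function(x) x@positions)
setMethod("constraintResidues", "ConstraintSet", function(x) x@residues)
setMethod("corpusSequences", "WeightedCorpus", function(x) x@seqs)
setMethod("corpusWeights", "WeightedCorpus", function(x) x@weights)
setMethod("countMatrix", "MSAStats", function(x) x@counts)
setMethod("freqMatrix", "MSAStats", function(x) x@freqs)

#' @describeIn FamilyProfile-class Number of sequences equivalent: frame length.
#' @export
setMethod("length", "FamilyProfile", function(x) as.integer(x@length))

#' @export
setMethod("length", "ConstraintSet", function(x) length(x@positions))

#' @export
setMethod("length", "WeightedCorpus", function(x) length(x@seqs))

setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf("NoiseSchedule: T = %d, beta in [%.3g, %.3g], alphaBar[T] = %.3g\n",
              object@steps, min(object@beta), max(object@beta),
              object@alphaBar[object@steps]))
})

setMethod("show", "ConstraintSet", function(object) {
  cat(sprintf("ConstraintSet with %d fixed position(s)\n", length(object@positions)))
  if (length(object@positions))
    cat(" ", paste(sprintf("%d:%s", object@positions, object@residues), collapse = " "), "\n")
})

setMethod("show", "FamilyProfile", function(object) {
  conserved <- sum(apply(object@probs, 1L, max) >= 1 - 1e-12)
  cat(sprintf("FamilyProfile: length %d, %d fully conserved position(s), %d covarying pair(s)\n",
              object@length, conserved, length(object@pairs)))
})

setMethod("show", "WeightedCorpus", function(object) {
  w <- object@weights
  cat(sprintf("WeightedCorpus: %d record(s), %d emphasized (weight > 1), max/min weight ratio %.1f\n",
              length(object@seqs), sum(w > 1), if (length(w)) max(w) / min(w) else NA_real_))
})

setMethod("show", "MSAStats", function(object) {
  cat(sprintf("MSAStats over %d position(s); entropy range [%.3f, %.3f] bits\n",
              length(object@positions),
              if (length(object@entropy)) min(object@entropy) else NA_real_,
              if (length(object@entropy)) max(object@entropy) else NA_real_))
})

setMethod("show", "SeqDiffusionModel", function(object) {
  cat(sprintf("SeqDiffusionModel: frame %d x 8 (VHSE8), widths (%s), T = %d, %d parameter(s)\n",
              object@frameLength, paste(object@net$widths, collapse = ", "),
              object@schedule@steps,
              sum(vapply(object@params, length, integer(1)))))
})
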