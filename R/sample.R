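# Reverse (ancestral) sampling, founder-residue-constrained generation
# (inpainting), and the motif screening stage.

#' Construct a residue constraint set
#'
#' @param positions 1-based positions in the sequence frame.
#' @param residues Required single-letter residues, one per position.
#' @return A [ConstraintSet-class].
#' @examples
#' ConstraintSet(c(1, 7), c("M", "W"))
#' @export
ConstraintSet <- function(positions = integer(), residues = character()) {
  methods::new("ConstraintSet", positions = as.integer(positions),
               residues = toupper(as.character(residues)))
}

#' The five founder-residue constraints
#'
#' The catalytic-pocket founder residues whose joint presence confers
#' flavone 6-hydroxylase activity: T114, F123, A220, M248 and A317
#' (CYP706X1 numbering in the 560-position family frame). Fixing them
#' during generation reproduces the "3-point fixation" pocket design.
#'
#' @return A [ConstraintSet-class] with the five founder positions.
#' @export
founderConstraints <- function() {
  ConstraintSet(c(114L, 123L, 220L, 248L, 317L), c("T", "F", "A", "M", "A"))
}

#' One reverse-diffusion (denoising) step
#'
#' Ancestral sampling step of the DDPM:
#' \eqn{x_{t-1} = \frac{1}{\sqrt{\alpha_t}}\left(x_t -
#' \frac{\beta_t}{\sqrt{1-\bar\alpha_t}}\,\hat\epsilon(x_t,t)\right) +
#' \sigma_t z}, with \eqn{\sigma_t^2 = \beta_t} and \eqn{z = 0} at
#' \eqn{t = 1} (the final step is deterministic).
#'
#' @param x Batch `(n, frameLength, 8)` at timestep `t`.
#' @param t Integer timestep in `1..nsteps`.
#' @param model A [SeqDiffusionModel-class].
#' @param z Optional standard-Gaussian noise with the shape of `x`; drawn
#'   internally when `NULL` (and ignored at `t = 1`).
#' @param epsHat Optional externally supplied noise prediction (used for
#'   oracle tests); default is the model's own prediction.
#' @return The batch at timestep `t - 1`.
#' @export
pSampleStep <- function(x, t, model, z = NULL, epsHat = NULL) {
  sched <- model@schedule
  t <- as.integer(t)
  if (t < 1L || t > sched@steps) stop(sprintf("t out of range 1..%d", sched@steps))
  if (is.null(epsHat)) epsHat <- .denoiserFwd(model@params, model@net, x, t, keep = FALSE)$Y
  if (!identical(dim(epsHat), dim(x))) stop("noise prediction violated the shape contract")
  mu <- (x - (sched@beta[t] / sqrt(1 - sched@alphaBar[t])) * epsHat) / sqrt(sched@alpha[t])
  if (t == 1L) return(mu)
  if (is.null(z)) z <- array(rnorm(length(x)), dim = dim(x))
  mu + sqrt(sched@beta[t]) * z
}

# shared reverse loop; clampFn(x, tNext) re-imposes constraints after each
# step (tNext = timestep of the state just produced; 0 = final clean state).
# When clampFn is NULL the RNG stream is untouched by clamping, so an empty
# constraint set reproduces unconstrained sampling bit for bit.
.reverseLoop <- function(model, n, steps, seed = NULL, clampFn = NULL,
                         start = c("noise", "encoded-random")) {
  start <- match.arg(start)
  L <- model@frameLength
  consts <- .netConsts(model@net)
  .withSeed(seed, {
    x <- array(rnorm(n * L * 8L), dim = c(n, L, 8L))
    if (start == "encoded-random") {
      # literal reading: begin from encoded random sequences instead of noise
      rnd <- vapply(seq_len(n), function(i)
        paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
      x <- .encodeStack(rnd, L)
    }
    if (!is.null(clampFn)) x <- clampFn(x, steps)
    for (t in seq(steps, 1L)) {
      epsHat <- .denoiserFwd(model@params, model@net, x, t, keep = FALSE,
                             consts = consts)$Y
      x <- pSampleStep(x, t, model, epsHat = epsHat)
      if (!is.null(clampFn)) x <- clampFn(x, t - 1L)
    }
    x
  })
}

#' Sample encoded sequences from the model
#'
#' Runs `steps` reverse-diffusion steps from standard Gaussian noise.
#'
#' @param model A [SeqDiffusionModel-class].
#' @param n Number of samples.
#' @param seed Optional seed; fixed seed gives bitwise-identical output.
#' @param steps Denoising depth; defaults to the full schedule length
#'   (600 at full scale). Partial depth starts the reverse chain at
#'   `t = steps`.
#' @return Array `(n, frameLength, 8)` of generated encodings.
#' @export
sampleMatrices <- function(model, n, seed = NULL, steps = nsteps(model)) {
  steps <- as.integer(steps)
  if (steps < 1L || steps > model@schedule@steps) stop("invalid sampling depth")
  if (n == 0L) return(array(0, dim = c(0L, model@frameLength, 8L)))
  .reverseLoop(model, n, steps, seed)
}

#' Sample and decode sequences from the model
#'
#' @inheritParams sampleMatrices
#' @param gapMargin Passed to [decodeMatrix()].
#' @return A list: `records` (`AAStringSet`, internal gaps removed),
#'   `frames` (frame-coordinate strings with `-` at gap rows) and
#'   `internalGaps` (per-sequence internal gap count).
#' @export
sampleSequences <- function(model, n, seed = NULL, steps = nsteps(model),
                            gapMargin = 0) {
  x <- sampleMatrices(model, n, seed, steps)
  dec <- .decodeStack(x, gapMargin)
  list(records = Biostrings::AAStringSet(setNames(dec$seqs,
         sprintf("sample_%d", seq_along(dec$seqs)))),
       frames = dec$frames, internalGaps = dec$internalGaps)
}

#' Motif-constrained (inpainting) generation
#'
#' Reverse diffusion in which the constrained coordinates are re-imposed
#' after every denoising step: after the step to level `t`, the rows of the
#' constrained positions are replaced by the closed-form forward noising of
#' their target VHSE8 vectors at level `t` (and by the exact vectors at the
#' final step). Decoded outputs therefore match every constraint exactly,
#' for any model. `clamp = "seed-only"` instead writes the constraint rows
#' only into the starting state, mirroring the literal "random sequence
#' with founder residues as the starting sequence" reading.
#'
#' @param model A [SeqDiffusionModel-class].
#' @param constraints A [ConstraintSet-class]; positions must lie within the
#'   model frame.
#' @param n Number of sequences to generate.
#' @param seed Optional seed.
#' @param steps Denoising depth, default the full schedule (600 at full
#'   scale).
#' @param clamp `"every-step"` (default) or `"seed-only"`.
#' @param start Starting state: `"noise"` (default) or `"encoded-random"`.
#' @param gapMargin Passed to [decodeMatrix()].
#' @return As [sampleSequences()], plus the `constraints` used.
#' @export
generateConstrained <- function(model, constraints, n, seed = NULL,
                                steps = nsteps(model),
                                clamp = c("every-step", "seed-only"),
                                start = c("noise", "encoded-random"),
                                gapMargin = 0) {
  clamp <- match.arg(clamp); start <- match.arg(start)
  stopifnot(methods::is(constraints, "ConstraintSet"))
  pos <- constraints@positions
  if (length(pos) && max(pos) > model@frameLength)
    stop("constraint position beyond the model frame")
  V <- vhseTable()[constraints@residues, , drop = FALSE]  # npos x 8
  sched <- model@schedule
  target <- function(nbatch) aperm(array(t(V), c(8L, length(pos), nbatch)), c(3L, 2L, 1L))
  clampFn <- if (length(pos) == 0L) NULL else if (clamp == "every-step") {
    function(x, t) {
      tgt <- target(dim(x)[1L])
      if (t == 0L) {
        x[, pos, ] <- tgt                       # exact clamp at the final step
      } else {
        ab <- sched@alphaBar[t]                 # level-matched noising
        x[, pos, ] <- sqrt(ab) * tgt +
          sqrt(1 - ab) * array(rnorm(length(tgt)), dim = dim(tgt))
      }
      x
    }
  } else {
    function(x, t) {
      if (t == as.integer(steps)) x[, pos, ] <- target(dim(x)[1L])
      x
    }
  }
  x <- .reverseLoop(model, n, as.integer(steps), seed, clampFn, start)
  dec <- .decodeStack(x, gapMargin)
  list(records = Biostrings::AAStringSet(setNames(dec$seqs,
         sprintf("design_%d", seq_along(dec$seqs)))),
       frames = dec$frames, internalGaps = dec$internalGaps,
       constraints = constraints)
}

#' Screen sequences by a residue motif
#'
#' Keeps exactly the records whose residue at every constrained position
#' equals the required letter. Records are interpreted in frame
#' coordinates (fixed-frame strings, e.g. the `frames` component of
#' [generateConstrained()], or any aligned set); a record shorter than the
#' largest constrained position fails and is reported.
#'
#' @param seqs Character vector or `AAStringSet` in frame coordinates.
#' @param constraints A [ConstraintSet-class].
#' @return The passing subset (same class as the input, order preserved),
#'   with attributes `nFail` (count of failing records) and `tooShort`
#'   (indices of records shorter than the motif span).
#' @export
motifFilter <- function(seqs, constraints) {
  stopifnot(methods::is(constraints, "ConstraintSet"))
  ch <- if (methods::is(seqs, "XStringSet")) as.character(seqs) else as.character(seqs)
  pos <- constraints@positions
  if (length(ch) == 0L) {
    out <- seqs
    attr(out, "nFail") <- 0L; attr(out, "tooShort") <- integer()
    return(out)
  }
  if (length(pos) == 0L) {
    out <- seqs
    attr(out, "nFail") <- 0L; attr(out, "tooShort") <- integer()
    return(out)
  }
  tooShort <- which(nchar(ch) < max(pos))
  ok <- rep(TRUE, length(ch))
  for (i in seq_along(pos))
    ok <- ok & substr(ch, pos[i], pos[i]) == constraints@residues[i]
  ok[tooShort] <- FALSE
  out <- seqs[ok]
  attr(out, "nFail") <- sum(!ok)
  attr(out, "tooShort") <- tooShort
  out
}
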