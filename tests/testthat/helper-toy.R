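# Shared desk-scale fixtures, built in code and memoized across test files.

.toyCache <- new.env(parent = emptyenv())

aa20 <- ProtDiffuser:::AA20

randomSeq <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

# a small trained model on a 16-position family with one conserved block,
# reused by sampling / constrained-generation tests
toyTrainedModel <- function() {
  if (!is.null(.toyCache$trained)) return(.toyCache$trained)
  fam <- withr::with_seed(401, {
    probs <- matrix(1 / 20, 16L, 20L)
    probs[3L, ] <- 0; probs[3L, match("W", aa20)] <- 1
    probs[9L, ] <- 0; probs[9L, c(1L, 2L)] <- c(0.7, 0.3)
    sampleFamily(FamilyProfile(probs), 150L)
  })
  mod <- newDiffusionModel(16L, makeSchedule(40L), widths = c(8L, 12L, 16L),
                           posChannels = 4L, seed = 402)
  fit <- pretrain(mod, fam, maxSteps = 150L, batchSize = 32L, seed = 403)
  .toyCache$trained <- fit$model
  fit$model
}

# an untrained model with parameters perturbed away from the zero-init
# (so its predictions are nonzero and timestep-sensitive)
toyPerturbedModel <- function(frame = 16L, steps = 20L) {
  key <- sprintf("pert_%d_%d", frame, steps)
  if (!is.null(.toyCache[[key]])) return(.toyCache[[key]])
  mod <- newDiffusionModel(frame, makeSchedule(steps), widths = c(6L, 8L, 12L),
                           posChannels = 4L, seed = 404)
  mod@params <- withr::with_seed(405, lapply(mod@params, function(p)
    p + rnorm(length(p), sd = 0.05)))
  .toyCache[[key]] <- mod
  mod
}
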