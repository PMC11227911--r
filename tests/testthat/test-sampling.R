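test_that("the final reverse step is deterministic and shape-preserving", {
  mod <- toyPerturbedModel()
  x <- withr::with_seed(41, array(rnorm(2 * 16 * 8), c(2, 16, 8)))
  a <- pSampleStep(x, 1L, mod)
  b <- pSampleStep(x, 1L, mod)
  expect_identical(a, b)
  expect_identical(dim(a), dim(x))
  expect_error(pSampleStep(x, 0L, mod), "out of range")
  expect_error(pSampleStep(x, 21L, mod), "out of range")
})

test_that("a perfect noise predictor recovers x0 exactly through the chain", {
  # with epsHat_t = (x_t - sqrt(ab_t) x0) / sqrt(1 - ab_t) and sigma_t = 0,
  # the reverse recursion cancels the noise term at t = 1 algebraically
  sched <- makeSchedule(3, betaMin = 0.05, betaMax = 0.3)
  mod <- newDiffusionModel(8L, sched, widths = c(4L, 6L, 8L),
                           posChannels = 4L, seed = 42)
  x0 <- array(encodeSequence("MKTAYIAK", 8L), c(1L, 8L, 8L))
  withr::with_seed(43, {
    eps <- array(rnorm(length(x0)), dim = dim(x0))
    x <- qSample(x0, 3L, eps, sched)
    for (t in 3:1) {
      epsHat <- (x - sqrt(alphaBar(sched)[t]) * x0) / sqrt(1 - alphaBar(sched)[t])
      x <- pSampleStep(x, t, mod, z = array(0, dim = dim(x)), epsHat = epsHat)
    }
    expect_equal(x, x0, tolerance = 1e-10)
  })
})

test_that("sampling is seed-reproducible and seed-sensitive", {
  mod <- toyPerturbedModel()
  a <- sampleMatrices(mod, 2L, seed = 44, steps = 10L)
  b <- sampleMatrices(mod, 2L, seed = 44, steps = 10L)
  c <- sampleMatrices(mod, 2L, seed = 45, steps = 10L)
  expect_identical(a, b)
  expect_gt(max(abs(a - c)), 1e-6)
  expect_identical(dim(sampleMatrices(mod, 0L)), c(0L, 16L, 8L))
})

test_that("an empty constraint set reproduces unconstrained sampling bitwise", {
  mod <- toyPerturbedModel()
  un <- sampleSequences(mod, 3L, seed = 46, steps = 10L)
  co <- generateConstrained(mod, ConstraintSet(), 3L, seed = 46, steps = 10L)
  expect_identical(un$frames, co$frames)
  expect_identical(unname(as.character(un$records)),
                   unname(as.character(co$records)))
})

test_that("clamped generation satisfies every constraint in every sample", {
  mod <- toyTrainedModel()
  cs <- ConstraintSet(c(1L, 5L, 12L), c("M", "W", "K"))
  gen <- generateConstrained(mod, cs, 100L, seed = 47)
  expect_length(gen$frames, 100L)
  for (i in seq_along(constraintPositions(cs)))
    expect_true(all(substr(gen$frames, cs@positions[i], cs@positions[i]) ==
                      cs@residues[i]))
  # the motif filter is a left inverse on constrained output
  kept <- motifFilter(gen$frames, cs)
  expect_identical(as.character(kept), gen$frames)
  # and also holds for an untrained (random-weight) model
  gen2 <- generateConstrained(toyPerturbedModel(), ConstraintSet(1L, "M"),
                              50L, seed = 48, steps = 10L)
  expect_true(all(substr(gen2$frames, 1L, 1L) == "M"))
})

test_that("seed-only clamping fixes the start but not necessarily the output", {
  mod <- toyPerturbedModel()
  cs <- ConstraintSet(c(2L, 9L), c("W", "D"))
  gen <- generateConstrained(mod, cs, 4L, seed = 49, steps = 10L,
                             clamp = "seed-only")
  expect_length(gen$frames, 4L)  # runs; constraint satisfaction not guaranteed
  expect_error(generateConstrained(mod, ConstraintSet(99L, "A"), 1L, seed = 1),
               "beyond the model frame")
})

test_that("the motif filter keeps exact matches, in order, idempotently", {
  cs <- ConstraintSet(c(2L, 4L), c("C", "E"))
  seqs <- c(a = "ACDEF", b = "AGDEF", c = "ACDDF", d = "ACDE", e = "ACDEK")
  kept <- motifFilter(seqs, cs)
  expect_identical(names(kept), c("a", "d", "e"))
  expect_identical(attr(kept, "nFail"), 2L)
  again <- motifFilter(kept, cs)
  expect_identical(as.character(again), as.character(kept))
  # record shorter than the motif span fails and is reported
  short <- motifFilter(c(x = "AC"), cs)
  expect_length(short, 0L)
  expect_identical(attr(short, "tooShort"), 1L)
  # empty input passes through empty
  expect_length(motifFilter(character(), cs), 0L)
  # single mismatch at one constrained position fails
  expect_length(motifFilter("ACDDF", cs), 0L)
})

test_that("the founder constraint set matches the catalytic pocket design", {
  cs <- founderConstraints()
  expect_identical(constraintPositions(cs), c(114L, 123L, 220L, 248L, 317L))
  expect_identical(constraintResidues(cs), c("T", "F", "A", "M", "A"))
})

test_that("a model trained on one repeated sequence reproduces it when sampling", {
  s <- "MKTAYIAK"
  mod <- newDiffusionModel(8L, makeSchedule(60L, betaMin = 1e-3, betaMax = 0.2),
                           widths = c(8L, 12L, 16L), posChannels = 4L, seed = 201)
  fit <- pretrain(mod, rep(s, 32L), maxSteps = 4000L, batchSize = 16L,
                  lr = 1e-2, seed = 202)
  sm <- sampleSequences(fit$model, 50L, seed = 203)
  expect_gte(mean(as.character(sm$records) == s), 0.9)
})
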