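test_that("family sampling honours conserved positions and the seed", {
  probs <- matrix(1 / 20, 12L, 20L)
  probs[5L, ] <- 0; probs[5L, match("W", aa20)] <- 1
  prof <- FamilyProfile(probs)
  fam <- sampleFamily(prof, 200L, seed = 81)
  expect_length(fam, 200L)
  expect_true(all(substr(as.character(fam), 5L, 5L) == "W"))
  expect_identical(as.character(sampleFamily(prof, 50L, seed = 82)),
                   as.character(sampleFamily(prof, 50L, seed = 82)))
  expect_length(sampleFamily(prof, 0L), 0L)
  bad <- probs; bad[1L, 1L] <- 2
  expect_error(FamilyProfile(bad), "sum to 1")
})

test_that("uniform columns reach the maximum entropy within sampling error", {
  prof <- FamilyProfile(matrix(1 / 20, 6L, 20L))
  fam <- sampleFamily(prof, 5000L, seed = 83)
  h <- columnEntropy(fam)
  expect_true(all(abs(h - log2(20)) < 0.02))
})

test_that("a deterministic coupling gives MI equal to the source entropy", {
  probs <- matrix(1 / 20, 8L, 20L)
  joint <- matrix(0, 20L, 20L)
  support <- c(1L, 4L, 9L, 15L)
  joint[cbind(support, rev(support))] <- 1 / 4   # b = f(a), uniform over 4
  prof <- FamilyProfile(probs, pairs = list(list(i = 2L, j = 7L, joint = joint)))
  fam <- sampleFamily(prof, 4000L, seed = 84)
  mi <- covariationMI(fam)
  h <- columnEntropy(fam)
  expect_equal(mi[2, 7], h[2], tolerance = 0.02)
  # the injected pair is the top-ranked off-diagonal cell
  off <- mi; diag(off) <- -Inf
  expect_identical(which(off == max(off), arr.ind = TRUE)[1, ] |> unname() |> sort(),
                   c(2L, 7L))
})

test_that("the benchmark bundle is deterministic and internally consistent", {
  b1 <- makeBenchmarkSuite(seed = 85, nBackground = 300L)
  b2 <- makeBenchmarkSuite(seed = 85, nBackground = 300L)
  expect_identical(as.character(b1$background), as.character(b2$background))
  expect_identical(as.character(b1$emphasized), as.character(b2$emphasized))
  expect_identical(b1$manifest$profileHash, b2$manifest$profileHash)
  expect_false(identical(b1$manifest$profileHash,
                         makeBenchmarkSuite(seed = 86, nBackground = 300L)$manifest$profileHash))
  expect_length(b1$emphasized, 30L)
  expect_length(b1$corpus, 330L)
  expect_identical(sum(corpusWeights(b1$corpus) > 1), 30L)
  expect_identical(max(corpusWeights(b1$corpus)) / min(corpusWeights(b1$corpus)), 600)
})

test_that("every emphasized record carries the founder motif, background almost never", {
  b <- makeBenchmarkSuite(seed = 87, nBackground = 1000L)
  passEm <- motifFilter(b$emphasized, b$constraints)
  expect_length(passEm, 30L)
  # background founder columns are uniform: joint match probability 20^-5
  passBg <- motifFilter(b$background, b$constraints)
  expect_lt(length(passBg) / length(b$background), 0.01)
  # founder constraint positions sit inside the frame and use founder letters
  expect_true(all(constraintPositions(b$constraints) <= b$manifest$frameLength))
  expect_identical(constraintResidues(b$constraints), c("T", "F", "A", "M", "A"))
})

test_that("background column frequencies follow the generating profile", {
  b <- makeBenchmarkSuite(seed = 88, nBackground = 1500L)
  fr <- freqMatrix(logoCounts(as.character(b$background)))
  pr <- b$backgroundProfile@probs
  # goodness of fit per column on a few sampled positions (excluding pairs)
  pairPos <- unlist(lapply(b$backgroundProfile@pairs, function(p) c(p$i, p$j)))
  withr::with_seed(89, {
    multi <- which(rowSums(pr > 0) >= 2L)           # skip conserved columns
    for (j in sample(setdiff(multi, pairPos), 8L)) {
      obs <- countMatrix(logoCounts(as.character(b$background), j))[1, ]
      keep <- pr[j, ] > 0
      gof <- suppressWarnings(chisq.test(obs[keep], p = pr[j, keep]))
      expect_gt(gof$p.value, 1e-4)
    }
  })
})
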