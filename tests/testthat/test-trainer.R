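test_that("length filtering is inclusive at the boundary", {
  seqs <- Biostrings::AAStringSet(c(a = strrep("A", 100), b = strrep("C", 560),
                                    c = strrep("D", 561)))
  kept <- filterByLength(seqs)
  expect_identical(names(kept), c("a", "b"))
  expect_length(filterByLength(Biostrings::AAStringSet(character())), 0L)
  chr <- withr::with_seed(51, replicate(10, randomSeq(sample(10:560, 1))))
  expect_identical(filterByLength(chr), chr)
})

test_that("greedy identity clustering merges duplicates and splits strangers", {
  two <- c("MKTAYIAKQRQISFVK", "MKTAYIAKQRQISFVK")
  cl <- clusterIdentity(two, threshold = 0.9)
  expect_length(cl$representatives, 1L)
  expect_identical(cl$sizes, 2L)
  far <- c(strrep("AC", 10), strrep("WY", 10))
  expect_length(clusterIdentity(far, 0.9)$representatives, 2L)
})

test_that("greedy clustering matches the brute-force all-pairs oracle", {
  base <- "MKTAYIAKQRQISFVKSHGW"
  mut <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  seqs <- c(base,
            mut(base, 3L, "W"),                        # ~95% to base
            mut(mut(base, 3L, "W"), 11L, "C"),         # ~90%
            paste(rev(strsplit(base, "")[[1]]), collapse = ""),  # unrelated order
            strrep("DE", 10L))                         # unrelated
  got <- clusterIdentity(seqs, threshold = 0.5, k = 3L)
  # oracle: independent greedy pass over an explicitly computed identity matrix
  idm <- outer(seq_along(seqs), seq_along(seqs),
               Vectorize(function(i, j) kmerIdentity(seqs[i], seqs[j], 3L)))
  reps <- integer(); assign <- integer(length(seqs))
  for (i in order(nchar(seqs), decreasing = TRUE)) {
    hit <- which(idm[reps, i] >= 0.5)[1]
    if (is.na(hit)) { reps <- c(reps, i); assign[i] <- length(reps) }
    else assign[i] <- hit
  }
  expect_identical(length(got$representatives), length(reps))
  expect_identical(got$sizes, as.integer(tabulate(assign, length(reps))))
})

test_that("the weighted sampler follows the weight law", {
  corp <- WeightedCorpus(withr::with_seed(52, replicate(20, randomSeq(12))))
  draw <- weightedSampler(corp, seed = 53)
  tab <- tabulate(draw(1e5), nbins = 20L)
  gof <- chisq.test(tab, p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 0.01)
  # 600:1 emphasis: per-record draw frequency ratio approaches 600
  corp2 <- WeightedCorpus(withr::with_seed(54, replicate(103, randomSeq(12))),
                          emphasize = 1:3, ratio = 600)
  idx <- weightedSampler(corp2, seed = 55)(2e5)
  tab2 <- tabulate(idx, nbins = 103L)
  ratio <- mean(tab2[1:3]) / mean(tab2[4:103])
  expect_lt(abs(ratio / 600 - 1), 0.1)
  expect_error(weightedSampler(WeightedCorpus(character())), "empty")
})

test_that("the sampler stream is isolated from the global RNG", {
  corp <- WeightedCorpus(c("ACDE", "WYKL", "MNPQ"))
  draw <- weightedSampler(corp, seed = 56)
  a <- draw(5)
  set.seed(999); runif(10)          # perturb the global stream
  b <- draw(5)
  draw2 <- weightedSampler(corp, seed = 56)
  expect_identical(c(a, b), c(draw2(5), draw2(5)))
})

test_that("training is a no-op at zero steps and reproducible under a seed", {
  mod <- newDiffusionModel(16L, makeSchedule(20), widths = c(4L, 6L, 8L),
                           posChannels = 4L, seed = 57)
  fam <- withr::with_seed(58, replicate(20, randomSeq(16)))
  same <- pretrain(mod, fam, maxSteps = 0L)
  expect_identical(same$model@params, mod@params)
  expect_length(same$trace, 0L)
  ftSame <- finetune(mod, WeightedCorpus(fam, emphasize = 1:2, ratio = 600),
                     maxSteps = 0L)
  expect_identical(ftSame$model@params, mod@params)
  a <- pretrain(mod, fam, maxSteps = 12L, batchSize = 8L, seed = 59)
  b <- pretrain(mod, fam, maxSteps = 12L, batchSize = 8L, seed = 59)
  expect_identical(a$trace, b$trace)
  expect_identical(a$model@params, b$model@params)
})

test_that("uniform-weight fine-tuning equals pretraining draw for draw", {
  mod <- newDiffusionModel(16L, makeSchedule(20), widths = c(4L, 6L, 8L),
                           posChannels = 4L, seed = 60)
  fam <- withr::with_seed(61, setNames(replicate(15, randomSeq(16)),
                                       paste0("s", 1:15)))
  a <- pretrain(mod, fam, maxSteps = 10L, batchSize = 8L, seed = 62)
  b <- finetune(mod, WeightedCorpus(fam), maxSteps = 10L, batchSize = 8L, seed = 62)
  expect_identical(a$trace, b$trace)
  expect_identical(a$model@params, b$model@params)
})

test_that("the smoothed training loss decreases on a toy family", {
  fam <- withr::with_seed(63, {
    probs <- matrix(0, 16L, 20L)
    for (j in 1:16) probs[j, sample.int(20L, 2L)] <- c(0.8, 0.2)
    sampleFamily(FamilyProfile(probs), 120L)
  })
  mod <- newDiffusionModel(16L, makeSchedule(40), widths = c(8L, 12L, 16L),
                           posChannels = 4L, seed = 64)
  fit <- pretrain(mod, fam, maxSteps = 250L, batchSize = 32L, seed = 65)
  expect_lt(mean(tail(fit$trace, 50)), mean(head(fit$trace, 50)))
})
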