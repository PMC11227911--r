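test_that("column entropy matches the analytic values", {
  expect_equal(columnEntropy(c("A", "A", "A")), 0)
  # one sequence per residue: exactly uniform, H = log2(20) ~ 4.3219 bits
  expect_equal(columnEntropy(aa20), log2(20))
  expect_equal(columnEntropy(c("A", "A", "A", "C")), 0.811278124459,
               tolerance = 1e-9)
  # permutation invariance and bounds
  withr::with_seed(71, {
    col <- sample(aa20, 50, replace = TRUE)
    expect_equal(columnEntropy(col), columnEntropy(sample(col)))
    h <- columnEntropy(replicate(30, randomSeq(12)))
    expect_true(all(h >= 0 & h <= log2(20) + 1e-12))
  })
  expect_error(columnEntropy(c("AC", "ACD")), "equal length")
})

test_that("logo counts equal a manual tally and flag full conservation", {
  seqs <- c("TAC", "TAG", "TCC", "TAT")
  st <- logoCounts(seqs)
  expect_identical(unname(countMatrix(st)[1, "T"]), 4L)
  expect_equal(unname(freqMatrix(st)[1, "T"]), 1)
  expect_identical(unname(countMatrix(st)[2, "A"]), 3L)
  expect_identical(unname(countMatrix(st)[2, "C"]), 1L)
  expect_identical(countMatrix(st)[3, c("C", "G", "T")], c(C = 2L, G = 1L, T = 1L))
  expect_equal(rowSums(countMatrix(st)), c(4, 4, 4))
  sub <- logoCounts(seqs, positions = 2L)
  expect_identical(dim(countMatrix(sub)), c(1L, 20L))
  empty <- logoCounts(seqs, positions = integer())
  expect_identical(nrow(countMatrix(empty)), 0L)
  expect_error(logoCounts(seqs, positions = 9L), "outside")
  # gap handling: gaps excluded from frequencies, tracked separately
  gapped <- logoCounts(c("A-C", "AAC", "A-C"))
  expect_identical(gapped@gaps, c(0L, 2L, 0L))
  expect_equal(unname(freqMatrix(gapped)[2, "A"]), 1)
})

test_that("pairwise identity behaves in both fixed-frame and global modes", {
  expect_equal(pairwiseIdentity("MKTAYI", "MKTAYI", "fixed"), 100)
  expect_equal(pairwiseIdentity("AAAA", "AAAT", "fixed"), 75)
  expect_error(pairwiseIdentity("AAA", "AAAA", "fixed"), "equal length")
  expect_error(pairwiseIdentity("", "AAA", "fixed"), "nonempty")
  expect_equal(pairwiseIdentity("MKTAYIAKQR", "MKTAYIAKQR", "global"), 100)
  # deletion: 9 identical over 10 aligned columns
  expect_equal(pairwiseIdentity("MKTAYIAKQR", "MKTAIAKQR", "global"), 90,
               tolerance = 0.01)
})

test_that("the k-tuple distance matches brute-force k-mer enumeration", {
  expect_equal(ktupleDistance("ACAC", "ACAC", k = 2), 0)
  # brute force: s1 {AC, CA, AC}, s2 {AC, CC, CA} -> shared 2 of min 3
  expect_equal(ktupleDistance("ACAC", "ACCA", k = 2), 1 - 2 / 3)
  expect_equal(ktupleDistance("ACAC", "ACCA", 2), ktupleDistance("ACCA", "ACAC", 2))
  expect_error(ktupleDistance("AC", "ACDE", k = 3), "shorter")
  withr::with_seed(72, {
    seqs <- replicate(6, randomSeq(15))
    d <- ktupleDistanceMatrix(seqs, k = 3)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    # off-diagonal entries match the pairwise function
    expect_equal(d[2, 5], ktupleDistance(seqs[2], seqs[5], 3))
  })
})

test_that("mutual information matches direct joint-frequency enumeration", {
  aln <- c("ACWTGA", "ADWTCA", "ACYTGC", "ADYTCC", "ACWTGA", "ADYTCA")
  mi <- covariationMI(aln)
  H <- columnEntropy(aln)
  expect_equal(diag(mi), H)
  expect_equal(mi, t(mi))
  # brute-force oracle: direct loops over observed letter pairs
  chars <- do.call(rbind, strsplit(aln, ""))
  oracle <- function(j, k) {
    tab <- table(chars[, j], chars[, k]) / nrow(chars)
    pj <- rowSums(tab); pk <- colSums(tab)
    s <- 0
    for (a in rownames(tab)) for (b in colnames(tab))
      if (tab[a, b] > 0) s <- s + tab[a, b] * log2(tab[a, b] / (pj[[a]] * pk[[b]]))
    s
  }
  for (j in 1:5) for (k in (j + 1):6)
    expect_equal(mi[j, k], oracle(j, k), tolerance = 1e-12)
  # MI is bounded by the smaller column entropy
  expect_true(all(mi <= outer(H, H, pmin) + 1e-9))
  # column 2 determines column 5 in this alignment: MI = H
  expect_equal(mi[2, 5], H[2])
  # APC variant keeps the diagonal and symmetry
  mia <- covariationMI(aln, apc = TRUE)
  expect_equal(diag(mia), H)
  expect_equal(mia, t(mia))
})

test_that("cluster size profiles match a brute-force clustering oracle", {
  expect_identical(clusterSizeProfile(rep("MKTAYIAKQRQISFVK", 5), 0.9), 5L)
  expect_identical(clusterSizeProfile(c(strrep("AC", 8), strrep("WY", 8)), 0.5),
                   c(1L, 1L))
  base1 <- "MKTAYIAKQRQISFVKSHGW"
  base2 <- "DEDEDEDEDEDEDEDEDEDE"
  mut <- function(s, p, to) { substr(s, p, p) <- to; s }
  seqs <- c(base1, mut(base1, 2, "C"), mut(base1, 5, "C"), mut(base1, 9, "W"),
            base2, mut(base2, 3, "K"), mut(base2, 7, "K"),
            "WWWWYYYYWWWWYYYYWWWW")
  got <- sort(clusterSizeProfile(seqs, 0.5, k = 3))
  idm <- outer(seq_along(seqs), seq_along(seqs),
               Vectorize(function(i, j) kmerIdentity(seqs[i], seqs[j], 3L)))
  reps <- integer(); assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {   # equal lengths: original order
    hit <- which(idm[reps, i] >= 0.5)[1]
    if (is.na(hit)) { reps <- c(reps, i); assign[i] <- length(reps) }
    else assign[i] <- hit
  }
  expect_identical(got, sort(as.integer(tabulate(assign, length(reps)))))
})

test_that("per-sequence property summaries average the VHSE descriptors", {
  ps <- propertySummary(c(one = "AC", two = "W"))
  expect_identical(nrow(ps), 2L)
  expect_equal(ps$length, c(2, 1))
  expect_equal(unlist(ps[1, 3:10]), colMeans(vhseTable()[c("A", "C"), ]),
               ignore_attr = TRUE)
  expect_equal(unlist(ps[2, 3:10]), vhseTable()["W", ], ignore_attr = TRUE)
})
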