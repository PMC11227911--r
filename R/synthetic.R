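# Synthetic protein families with controllable conservation, covariation
# and subfamily structure. These stand in for the natural training corpus
# and the emphasized subfamily, so the whole pipeline is testable at desk
# scale without any download.

#' Construct a family profile
#'
#' @param probs L x 20 matrix of per-position residue probabilities
#'   (columns in alphabetical residue order, rows summing to 1).
#' @param pairs Optional list of covarying pairs `list(i, j, joint)`;
#'   `joint` is a 20 x 20 joint distribution from which positions i and j
#'   are drawn together.
#' @return A [FamilyProfile-class].
#' @export
FamilyProfile <- function(probs, pairs = list()) {
  colnames(probs) <- AA20
  methods::new("FamilyProfile", length = nrow(probs),
               probs = probs, pairs = pairs)
}

#' Sample sequences from a family profile
#'
#' Sequences are i.i.d.; positions are independent categorical draws from
#' the profile rows, except covarying pairs which are drawn jointly from
#' their coupling table (overriding the marginal rows). Conserved
#' positions (probability-1 rows) always carry their residue.
#'
#' @param profile A [FamilyProfile-class].
#' @param n Number of sequences.
#' @param seed Optional seed for reproducibility.
#' @return `AAStringSet` of `n` sequences of length `length(profile)`.
#' @examples
#' p <- matrix(1/20, 4, 20)
#' fam <- sampleFamily(FamilyProfile(p), 5, seed = 1)
#' @export
sampleFamily <- function(profile, n, seed = NULL) {
  stopifnot(methods::is(profile, "FamilyProfile"), n >= 0)
  L <- profile@length
  if (n == 0L) return(Biostrings::AAStringSet(character()))
  .withSeed(seed, {
    m <- matrix("", n, L)
    for (j in seq_len(L))
      m[, j] <- sample(AA20, n, replace = TRUE, prob = profile@probs[j, ])
    for (pr in profile@pairs) {
      cell <- sample.int(400L, n, replace = TRUE, prob = as.vector(pr$joint))
      a <- ((cell - 1L) %% 20L) + 1L
      b <- ((cell - 1L) %/% 20L) + 1L
      m[, pr$i] <- AA20[a]
      m[, pr$j] <- AA20[b]
    }
    seqs <- apply(m, 1L, paste, collapse = "")
    Biostrings::AAStringSet(setNames(seqs, sprintf("fam_%d", seq_len(n))))
  })
}

# a moderately conserved profile typical of an enzyme family alignment:
# some invariant columns, many biased columns, some near-uniform ones
.randomProfile <- function(L, seed = NULL, conserved = integer(),
                           uniform = integer()) {
  .withSeed(seed, {
    probs <- matrix(0, L, 20L)
    for (j in seq_len(L)) {
      if (j %in% conserved) {
        probs[j, sample.int(20L, 1L)] <- 1
      } else if (j %in% uniform) {
        probs[j, ] <- 1 / 20
      } else {
        # 2-4 plausible residues with a dominant one
        nres <- sample(2:4, 1L)
        res <- sample.int(20L, nres)
        w <- c(stats::runif(1, 2.5, 6), stats::runif(nres - 1L, 0.3, 1))
        probs[j, res] <- w / sum(w)
      }
    }
    FamilyProfile(probs)
  })
}

#' Deterministic benchmark bundle mirroring the fine-tuning setup
#'
#' Builds a background family, a small emphasized subfamily sharing five
#' fixed "founder" positions, the corresponding weighted fine-tuning
#' corpus, and the matching constraint set. The background profile is
#' near-uniform at the founder positions (so a background sequence matches
#' the full founder motif with probability about \eqn{20^{-5}}), while
#' every emphasized sequence carries the founder residues; the emphasized
#' profile additionally shifts a handful of other positions so that
#' fine-tuning has a measurable target beyond the founders. Two covarying
#' position pairs are injected into both profiles.
#'
#' @param seed Seed; the bundle is a deterministic function of it.
#' @param frameLength Family frame length, default 64 (desk scale; the
#'   full 560 frame remains exercisable through `frameLength = 560`).
#' @param nBackground Background family size, default 2000.
#' @param nEmphasized Emphasized subfamily size, default 30 (the number of
#'   subfamily sequences emphasized during fine-tuning).
#' @param ratio Emphasis sampling weight, default 600.
#' @return A list: `background` and `emphasized` (`AAStringSet`s),
#'   `corpus` (a [WeightedCorpus-class] of both, weights 1 and `ratio`),
#'   `constraints` (a [ConstraintSet-class] of the five founder positions),
#'   `backgroundProfile`, `emphasizedProfile`, and `manifest` (seed,
#'   counts, founder map, profile hash).
#' @export
makeBenchmarkSuite <- function(seed = 1L, frameLength = 64L,
                               nBackground = 2000L, nEmphasized = 30L,
                               ratio = 600) {
  L <- as.integer(frameLength)
  founderPos <- sort(unique(pmin(L, as.integer(round(L * c(0.15, 0.30, 0.45, 0.62, 0.80))))))
  founderRes <- c("T", "F", "A", "M", "A")[seq_along(founderPos)]
  .withSeed(seed, {
    nCons <- max(2L, round(L * 0.12))
    conserved <- sort(sample(setdiff(seq_len(L), founderPos), nCons))
    bgProfile <- .randomProfile(L, seed = NULL, conserved = conserved,
                                uniform = founderPos)
    # two covarying pairs among otherwise free positions
    free <- setdiff(seq_len(L), c(conserved, founderPos))
    pairPos <- sample(free, 4L)
    mkJoint <- function() {
      perm <- sample.int(20L)
      support <- sample.int(20L, 8L)
      joint <- matrix(0, 20L, 20L)
      joint[cbind(support, perm[support])] <- 1 / 8
      joint
    }
    pairs <- list(list(i = pairPos[1L], j = pairPos[2L], joint = mkJoint()),
                  list(i = pairPos[3L], j = pairPos[4L], joint = mkJoint()))
    bgProfile@pairs <- pairs
    # emphasized subfamily: founders fixed + a few shifted positions
    emProbs <- bgProfile@probs
    for (i in seq_along(founderPos)) {
      emProbs[founderPos[i], ] <- 0
      emProbs[founderPos[i], match(founderRes[i], AA20)] <- 1
    }
    avail <- setdiff(free, pairPos)
    shiftPos <- sample(avail, min(6L, length(avail)))
    for (j in shiftPos) {
      emProbs[j, ] <- 0
      emProbs[j, sample.int(20L, 1L)] <- 1
    }
    emProfile <- FamilyProfile(emProbs, pairs)
    background <- sampleFamily(bgProfile, nBackground)
    emphasized <- sampleFamily(emProfile, nEmphasized)
    names(emphasized) <- sprintf("sub_%d", seq_len(nEmphasized))
    all <- c(background, emphasized)
    corpus <- WeightedCorpus(all,
                             emphasize = nBackground + seq_len(nEmphasized),
                             ratio = ratio)
    constraints <- ConstraintSet(founderPos, founderRes)
    list(background = background, emphasized = emphasized, corpus = corpus,
         constraints = constraints, backgroundProfile = bgProfile,
         emphasizedProfile = emProfile,
         manifest = list(seed = as.integer(seed), frameLength = L,
                         nBackground = as.integer(nBackground),
                         nEmphasized = as.integer(nEmphasized),
                         ratio = ratio,
                         founders = setNames(founderRes, founderPos),
                         profileHash = rlang::hash(list(bgProfile@probs, emProbs, pairs))))
  })
}

#' Write a benchmark bundle to disk
#'
#' Emits the background and emphasized FASTA files, the founder constraint
#' CSV, and a JSON manifest.
#'
#' @param bundle A bundle from [makeBenchmarkSuite()].
#' @param dir Output directory (created if needed).
#' @param force Overwrite existing files.
#' @return Invisibly, the paths written.
#' @export
writeBenchmarkSuite <- function(bundle, dir, force = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("background.fasta", "emphasized.fasta",
                            "founders.csv", "manifest.json"))
  writeFastaAA(bundle$background, paths[1L], force = force)
  writeFastaAA(bundle$emphasized, paths[2L], force = force)
  writeConstraints(bundle$constraints, paths[3L], force = force)
  if (file.exists(paths[4L]) && !force) stop("refusing to overwrite ", paths[4L])
  jsonlite::write_json(bundle$manifest, paths[4L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
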