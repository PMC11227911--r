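# Corpus preparation, the DDPM training objective, and the (weighted)
# training loops.

#' Keep sequences not exceeding a maximum length
#'
#' Corpus preparation step: sequences longer than the frame are dropped
#' (boundary inclusive: a sequence of exactly `maxLen` residues is kept),
#' order preserved.
#'
#' @param seqs `AAStringSet` or character vector.
#' @param maxLen Maximum length, default 560.
#' @return Object of the same class as `seqs`, filtered.
#' @export
filterByLength <- function(seqs, maxLen = 560L) {
  if (methods::is(seqs, "XStringSet")) return(seqs[Biostrings::width(seqs) <= maxLen])
  seqs[nchar(seqs) <= maxLen]
}

#' k-mer identity estimate between two sequences
#'
#' Fraction of shared k-mers (multiset intersection) relative to the k-mer
#' count of the shorter sequence; a fast CD-HIT-like screen used by the
#' greedy identity clustering.
#'
#' @param a,b Character sequences.
#' @param k Word length, default 5.
#' @return A number in `[0, 1]`.
#' @export
kmerIdentity <- function(a, b, k = 5L) {
  a <- .asSeqChar(a); b <- .asSeqChar(b)
  na <- nchar(a) - k + 1L; nb <- nchar(b) - k + 1L
  if (na < 1L || nb < 1L) return(0)
  ka <- substring(a, seq_len(na), seq_len(na) + k - 1L)
  kb <- substring(b, seq_len(nb), seq_len(nb) + k - 1L)
  ta <- table(ka); tb <- table(kb)
  common <- intersect(names(ta), names(tb))
  sum(pmin(ta[common], tb[common])) / min(na, nb)
}

#' Greedy identity clustering of a sequence set
#'
#' CD-HIT-style greedy centroid clustering: sequences are visited longest
#' first; each joins the first existing representative whose k-mer identity
#' estimate reaches `threshold`, otherwise it founds a new cluster.
#'
#' @param seqs `AAStringSet` or character vector.
#' @param threshold Identity threshold in (0, 1], default 0.9 (the 90 percent
#'   similarity level used to build fine-tuning sets).
#' @param k Word length of the identity estimate.
#' @return A list with `representatives` (indices into `seqs`, one per
#'   cluster), `assignment` (cluster id per input sequence) and `sizes`.
#' @export
clusterIdentity <- function(seqs, threshold = 0.9, k = 5L) {
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  ch <- .asSeqChar(seqs)
  n <- length(ch)
  assignment <- integer(n)
  if (n == 0L)
    return(list(representatives = integer(), assignment = assignment, sizes = integer()))
  ord <- order(nchar(ch), decreasing = TRUE)
  reps <- integer()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (kmerIdentity(ch[reps[ci]], ch[i], k) >= threshold) {
        assignment[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assignment[i] <- length(reps)
    }
  }
  list(representatives = reps, assignment = assignment,
       sizes = as.integer(tabulate(assignment, nbins = length(reps))))
}

#' Build a weighted training corpus
#'
#' @param seqs `AAStringSet` or character vector of training sequences.
#' @param weights Positive per-record sampling weights; default all 1.
#' @param emphasize Optional index vector (or logical) of emphasized
#'   records; their weight is set to `ratio`.
#' @param ratio Emphasis weight, default 600 (the subfamily:background
#'   sampling weight ratio used for fine-tuning).
#' @return A [WeightedCorpus-class].
#' @export
WeightedCorpus <- function(seqs, weights = NULL, emphasize = NULL, ratio = 600) {
  if (!methods::is(seqs, "AAStringSet")) seqs <- Biostrings::AAStringSet(.asSeqChar(seqs))
  w <- weights %||% rep(1, length(seqs))
  if (!is.null(emphasize)) w[emphasize] <- ratio
  methods::new("WeightedCorpus", seqs = seqs, weights = as.numeric(w))
}

#' Weighted record sampler
#'
#' Returns a draw function over the corpus: each call draws record indices
#' with replacement, record i with probability \eqn{w_i / \sum_k w_k}. The
#' sampler keeps its own RNG stream, so interleaved callers do not perturb
#' it.
#'
#' @param corpus A [WeightedCorpus-class].
#' @param seed Optional seed for the sampler's stream.
#' @return A function `f(n)` returning `n` record indices.
#' @examples
#' corp <- WeightedCorpus(c(a = "ACDK", b = "ACDE"), emphasize = 1, ratio = 3)
#' draw <- weightedSampler(corp, seed = 1)
#' table(draw(1000))
#' @export
weightedSampler <- function(corpus, seed = NULL) {
  n <- length(corpus@seqs)
  if (n == 0L) stop("cannot sample from an empty corpus")
  prob <- corpus@weights / sum(corpus@weights)
  rngState <- .withSeed(seed %||% stats::runif(1, 1, 2^30), {
    stats::runif(1)  # advance once so the stream is seed-derived
    .Random.seed
  })
  function(ndraw = 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", rngState, globalenv())
    idx <- sample.int(n, ndraw, replace = TRUE, prob = prob)
    rngState <<- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    idx
  }
}

#' The DDPM training objective
#'
#' Draws a uniform timestep and standard Gaussian noise for each batch
#' element, forms the closed-form noised batch, and returns the mean squared
#' error between the true and the predicted noise over all
#' `frameLength x 8` coordinates (padding rows included by default: gaps are
#' part of the learned signal, which is what lets the model emit
#' variable-length sequences).
#'
#' @param model A [SeqDiffusionModel-class].
#' @param x0 Clean encoded batch `(n, frameLength, 8)`.
#' @param seed Optional seed for the timestep/noise draws.
#' @param maskGaps If `TRUE`, all-zero (gap) rows of `x0` are excluded from
#'   the loss average.
#' @return Nonnegative scalar loss.
#' @export
ddpmLoss <- function(model, x0, seed = NULL, maskGaps = FALSE) {
  .withSeed(seed, {
    B <- dim(x0)[1L]
    t <- sample.int(model@schedule@steps, B, replace = TRUE)
    eps <- array(rnorm(length(x0)), dim = dim(x0))
    xt <- qSample(x0, t, eps, model@schedule)
    pred <- .denoiserFwd(model@params, model@net, xt, t, keep = FALSE)$Y
    if (!identical(dim(pred), dim(x0))) stop("denoiser violated the shape contract")
    r2 <- (pred - eps)^2
    if (maskGaps) {
      keep <- array(rep(rowSums(abs(x0), dims = 2L) > 0, times = dim(x0)[3L]), dim = dim(x0))
      mean(r2[keep])
    } else mean(r2)
  })
}

# one optimization step; returns updated params/state and the loss
.trainStep <- function(params, net, sched, x0, t, eps, state, lr, weightDecay, consts) {
  xt <- qSample(x0, t, eps, sched)
  fw <- .denoiserFwd(params, net, xt, t, keep = TRUE, consts = consts)
  diff <- fw$Y - eps
  loss <- mean(diff^2)
  grads <- .denoiserBwd(params, net, diff * (2 / length(diff)), fw$cache)
  upd <- .adamwStep(params, grads, state, lr = lr, weightDecay = weightDecay)
  list(params = upd$params, state = upd$state, loss = loss)
}

.trainLoop <- function(model, seqs, prob, maxSteps, batchSize, lr, weightDecay,
                       seed, verbose, logCon = NULL) {
  stopifnot(length(seqs) >= 1L)
  enc <- .encodeStack(seqs, model@frameLength)
  n <- dim(enc)[1L]
  consts <- .netConsts(model@net)
  params <- model@params
  state <- .adamwInit(params)
  trace <- numeric(maxSteps)
  .withSeed(seed, {
    for (step in seq_len(maxSteps)) {
      idx <- sample.int(n, batchSize, replace = TRUE, prob = prob)
      x0 <- enc[idx, , , drop = FALSE]
      t <- sample.int(model@schedule@steps, batchSize, replace = TRUE)
      eps <- array(rnorm(length(x0)), dim = dim(x0))
      st <- .trainStep(params, model@net, model@schedule, x0, t, eps, state,
                       lr, weightDecay, consts)
      params <- st$params; state <- st$state
      trace[step] <- st$loss
      if (!is.null(logCon))
        .logLine(logCon, list(step = step, loss = st$loss, lr = lr))
      if (verbose && (step %% 100L == 0L || step == maxSteps))
        message(sprintf("step %d/%d  loss %.4f", step, maxSteps, st$loss))
    }
  })
  model@params <- params
  list(model = model, trace = trace)
}

#' Pretrain a diffusion model on a sequence corpus
#'
#' Runs `maxSteps` AdamW steps of the DDPM objective on uniformly sampled
#' batches. With `maxSteps = 0` the model is returned unchanged.
#'
#' @param model A [SeqDiffusionModel-class] (untrained or previously trained).
#' @param seqs Training sequences (`AAStringSet` or character), each of
#'   length at most `frameLength(model)`.
#' @param maxSteps Number of optimizer steps.
#' @param batchSize Batch size, default 64.
#' @param lr AdamW learning rate, default 2e-4.
#' @param weightDecay AdamW decoupled weight decay.
#' @param seed Optional seed; a fixed seed makes the whole run (batch order,
#'   timesteps, noise) reproducible.
#' @param verbose Print progress every 100 steps.
#' @param logFile Optional path for a JSON-lines training log.
#' @return A list with `model` (trained) and `trace` (per-step loss).
#' @export
pretrain <- function(model, seqs, maxSteps, batchSize = 64L, lr = 2e-4,
                     weightDecay = 0.01, seed = NULL, verbose = FALSE,
                     logFile = NULL) {
  if (maxSteps == 0L) return(list(model = model, trace = numeric()))
  con <- if (!is.null(logFile)) file(logFile, open = "a") else NULL
  on.exit(if (!is.null(con)) close(con))
  .trainLoop(model, .asSeqChar(seqs), prob = NULL, maxSteps, batchSize, lr,
             weightDecay, seed, verbose, con)
}

#' Fine-tune a diffusion model with weighted record sampling
#'
#' Identical to [pretrain()] except that batches are drawn from a
#' [WeightedCorpus-class]: record i enters a batch with probability
#' proportional to its weight, so an emphasized subfamily at weight 600
#' against background weight 1 is oversampled 600-fold per record. With all
#' weights equal the loop is exactly [pretrain()] on the same seed.
#'
#' @param model A pretrained [SeqDiffusionModel-class].
#' @param corpus A [WeightedCorpus-class].
#' @inheritParams pretrain
#' @return A list with `model` and `trace`.
#' @export
finetune <- function(model, corpus, maxSteps, batchSize = 64L, lr = 2e-4,
                     weightDecay = 0.01, seed = NULL, verbose = FALSE,
                     logFile = NULL) {
  stopifnot(methods::is(corpus, "WeightedCorpus"))
  if (maxSteps == 0L) return(list(model = model, trace = numeric()))
  con <- if (!is.null(logFile)) file(logFile, open = "a") else NULL
  on.exit(if (!is.null(con)) close(con))
  w <- corpus@weights
  # uniform weights reduce exactly to pretrain(): pass prob = NULL so the
  # RNG stream matches the unweighted loop draw for draw
  prob <- if (max(w) == min(w)) NULL else w / sum(w)
  .trainLoop(model, as.character(corpus@seqs), prob, maxSteps, batchSize, lr,
             weightDecay, seed, verbose, con)
}
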