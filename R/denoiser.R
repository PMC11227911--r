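# The denoiser network: a U-shaped 1-D convolutional net over the 8 VHSE8
# channels, three resolution levels (L, L/2, L/4), one self-attention block
# at the bottleneck, and a sinusoidal-then-linear timestep embedding added
# inside every residual block. Forward and backward passes are written out
# explicitly (verified against finite differences in the test suite).
#
# Internals operate on (B*L) x C matrices with row r = b + (l-1)*B, so that
# convolutions become one GEMM per kernel tap on row-subset "shifted" views
# and all reshapes are plain matrix indexing; BLAS does the heavy lifting.
#
# The second convolution of every residual block, the attention output
# projection and the final output convolution are zero-initialized, so a
# fresh network predicts zero noise and training starts from an
# identity-like regime. Fixed sinusoidal positional channels are
# concatenated to the input: conservation in a protein family is tied to
# absolute frame position, which a purely convolutional stack cannot see.

# ---- small primitives ------------------------------------------------------

.silu <- function(x) x / (1 + exp(-x))
.siluGrad <- function(x) { s <- 1 / (1 + exp(-x)); s * (1 + x * (1 - s)) }

# sinusoidal embeddings (timestep and position)
.sinusoid <- function(v, d) {
  half <- d %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  ang <- outer(v, freqs)
  cbind(sin(ang), cos(ang))
}

# Row-index vectors realizing a same-padded conv of kernel k / stride s on
# the (B*L) x C layout. For tap j, idx[[j]] has length B*Lo and points into
# 1..(B*L+1), where row B*L+1 of the padded matrix is all zeros.
.convIdx <- function(B, L, k, stride) {
  Lo <- if (stride == 1L) L else L %/% stride
  half <- (k - 1L) %/% 2L
  centers <- stride * (seq_len(Lo) - 1L) + 1L
  zrow <- B * L + 1L
  lapply(seq_len(k) - 1L - half, function(off) {
    p <- centers + off
    bad <- p < 1L | p > L
    p[bad] <- 1L
    idx <- rep((p - 1L) * B, each = B) + rep.int(seq_len(B), Lo)
    idx[rep(bad, each = B)] <- zrow
    idx
  })
}

# per-(B, L) geometry: conv indices for all layers, upsample maps, pos rows
.geom <- function(B, L, k) {
  L2 <- L %/% 2L; L4 <- L %/% 4L
  up <- function(Lh) {  # nearest x2 upsample on (B*Lh) rows -> (B*2Lh) rows
    src <- rep(seq_len(Lh), each = 2L)
    list(fwd = rep((src - 1L) * B, each = B) + rep.int(seq_len(B), 2L * Lh),
         odd = rep((seq_len(Lh) * 2L - 2L) * B, each = B) + rep.int(seq_len(B), Lh),
         even = rep((seq_len(Lh) * 2L - 1L) * B, each = B) + rep.int(seq_len(B), Lh))
  }
  list(B = B, L = L,
       cL = .convIdx(B, L, k, 1L), cL2 = .convIdx(B, L2, k, 1L),
       cL4 = .convIdx(B, L4, k, 1L),
       dn1 = .convIdx(B, L, k, 2L), dn2 = .convIdx(B, L2, k, 2L),
       up1 = up(L4), up2 = up(L2),
       bRow = list(L = rep.int(seq_len(B), L), L2 = rep.int(seq_len(B), L2),
                   L4 = rep.int(seq_len(B), L4)),
       posRow = rep(seq_len(L), each = B),
       attnRows = lapply(seq_len(B), function(b) b + (seq_len(L4) - 1L) * B))
}

.convFwd <- function(M, W, b, idx, keep = TRUE) {
  Cin <- ncol(M)
  Mp <- rbind(M, 0)
  G <- lapply(idx, function(ix) Mp[ix, , drop = FALSE])
  Y <- G[[1L]] %*% W[seq_len(Cin), , drop = FALSE]
  for (j in seq_along(idx)[-1L])
    Y <- Y + G[[j]] %*% W[((j - 1L) * Cin + 1L):(j * Cin), , drop = FALSE]
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, cache = if (keep) list(G = G, idx = idx, Cin = Cin,
                                     nIn = nrow(Mp)) else NULL)
}

.convBwd <- function(dY, W, cache) {
  Cin <- cache$Cin
  idx <- cache$idx
  dW <- matrix(0, nrow(W), ncol(W))
  dMp <- matrix(0, cache$nIn, Cin)
  for (j in seq_along(idx)) {
    rows <- ((j - 1L) * Cin + 1L):(j * Cin)
    dW[rows, ] <- crossprod(cache$G[[j]], dY)
    dMp[idx[[j]], ] <- dMp[idx[[j]], , drop = FALSE] + tcrossprod(dY, W[rows, , drop = FALSE])
  }
  list(dW = dW, db = colSums(dY), dM = dMp[-cache$nIn, , drop = FALSE])
}

# ---- parameter initialization ---------------------------------------------

.denoiserInit <- function(net, seed = NULL) {
  .withSeed(seed, {
    w <- net$widths; k <- net$kernel; Dt <- net$tembDim; Sd <- net$sinDim
    he <- function(fin, fout) matrix(rnorm(fin * fout, sd = sqrt(2 / fin)), fin, fout)
    xa <- function(fin, fout) matrix(rnorm(fin * fout, sd = sqrt(1 / fin)), fin, fout)
    p <- list(
      t1_W = xa(Sd, Dt), t1_b = numeric(Dt),
      t2_W = xa(Dt, Dt), t2_b = numeric(Dt),
      in_W = he(k * (net$inChannels + net$posChannels), w[1L]), in_b = numeric(w[1L])
    )
    res <- function(name, cin, cout) {
      out <- list(he(k * cin, cout), numeric(cout), xa(Dt, cout), numeric(cout),
                  matrix(0, k * cout, cout), numeric(cout))
      names(out) <- paste0(name, "_", c("c1W", "c1b", "tW", "tb", "c2W", "c2b"))
      if (cin != cout) out[[paste0(name, "_skW")]] <- xa(cin, cout)
      out
    }
    p <- c(p, res("d1", w[1L], w[1L]))
    p$dn1_W <- he(k * w[1L], w[2L]); p$dn1_b <- numeric(w[2L])
    p <- c(p, res("d2", w[2L], w[2L]))
    p$dn2_W <- he(k * w[2L], w[3L]); p$dn2_b <- numeric(w[3L])
    p <- c(p, res("m1", w[3L], w[3L]))
    p$at_qW <- xa(w[3L], w[3L]); p$at_kW <- xa(w[3L], w[3L])
    p$at_vW <- xa(w[3L], w[3L]); p$at_oW <- matrix(0, w[3L], w[3L]); p$at_ob <- numeric(w[3L])
    p <- c(p, res("m2", w[3L], w[3L]))
    p$up1_W <- he(k * w[3L], w[2L]); p$up1_b <- numeric(w[2L])
    p <- c(p, res("u1", 2L * w[2L], w[2L]))
    p$up2_W <- he(k * w[2L], w[1L]); p$up2_b <- numeric(w[1L])
    p <- c(p, res("u2", 2L * w[1L], w[1L]))
    p$out_W <- matrix(0, k * w[1L], net$inChannels); p$out_b <- numeric(net$inChannels)
    # position-gated output head: learned per-position bias in noise space,
    # scaled by a time-dependent per-channel gate (zero gate at init)
    p$po_E <- matrix(rnorm(net$frameLength * net$inChannels, sd = 0.1),
                     net$frameLength, net$inChannels)
    p$po_gW <- matrix(0, Dt, net$inChannels); p$po_gb <- numeric(net$inChannels)
    p
  })
}

#' Construct an untrained sequence diffusion model
#'
#' Builds the denoiser (randomly initialized) together with its noise
#' schedule and frame length. Channel widths, kernel size and the number of
#' positional-encoding channels are configurable so that desk-scale tests
#' can run small instances of the same architecture.
#'
#' @param frameLength Sequence frame length (multiple of 4); 560 for the
#'   full family frame.
#' @param schedule A [NoiseSchedule-class]; default `makeSchedule()`.
#' @param widths Channel widths of the three resolution levels.
#' @param kernel Odd convolution kernel size.
#' @param posChannels Number of sinusoidal positional channels concatenated
#'   to the VHSE8 input so the network can express position-specific
#'   conservation.
#' @param seed Optional seed for the parameter initialization.
#' @return A [SeqDiffusionModel-class].
#' @examples
#' m <- newDiffusionModel(16, makeSchedule(10), widths = c(4, 6, 8), seed = 1)
#' @export
newDiffusionModel <- function(frameLength = 560L, schedule = makeSchedule(),
                              widths = c(32L, 64L, 128L), kernel = 3L,
                              posChannels = 8L, seed = NULL) {
  frameLength <- as.integer(frameLength)
  if (frameLength %% 4L != 0L) stop("frameLength must be a multiple of 4")
  if (kernel %% 2L != 1L) stop("kernel must be odd")
  if (posChannels %% 2L != 0L) stop("posChannels must be even")
  net <- list(frameLength = frameLength, inChannels = 8L,
              widths = as.integer(widths), kernel = as.integer(kernel),
              posChannels = as.integer(posChannels),
              tembDim = 4L * as.integer(widths[1L]), sinDim = 32L)
  methods::new("SeqDiffusionModel", params = .denoiserInit(net, seed),
               net = net, schedule = schedule, frameLength = frameLength)
}

# ---- residual block --------------------------------------------------------

.resFwd <- function(p, name, M, temb, idx, bRow, keep = TRUE) {
  g <- function(s) p[[paste0(name, "_", s)]]
  c1 <- .convFwd(M, g("c1W"), g("c1b"), idx, keep)
  tproj <- temb %*% g("tW") + rep(g("tb"), each = nrow(temb))
  Z <- c1$Y + tproj[bRow, , drop = FALSE]
  S <- .silu(Z)
  c2 <- .convFwd(S, g("c2W"), g("c2b"), idx, keep)
  skW <- g("skW")
  skip <- if (is.null(skW)) M else M %*% skW
  list(Y = c2$Y + skip,
       cache = if (keep) list(M = if (!is.null(skW)) M else NULL,
                              c1 = c1$cache, c2 = c2$cache, Z = Z,
                              temb = temb, bRow = bRow) else NULL)
}

# returns list(grads, dM, dTemb)
.resBwd <- function(p, name, dY, cache) {
  g <- function(s) p[[paste0(name, "_", s)]]
  gr <- list()
  b2 <- .convBwd(dY, g("c2W"), cache$c2)
  gr[[paste0(name, "_c2W")]] <- b2$dW
  gr[[paste0(name, "_c2b")]] <- b2$db
  dZ <- b2$dM * .siluGrad(cache$Z)
  dTproj <- rowsum(dZ, cache$bRow)
  gr[[paste0(name, "_tW")]] <- crossprod(cache$temb, dTproj)
  gr[[paste0(name, "_tb")]] <- colSums(dTproj)
  dTemb <- dTproj %*% t(g("tW"))
  b1 <- .convBwd(dZ, g("c1W"), cache$c1)
  gr[[paste0(name, "_c1W")]] <- b1$dW
  gr[[paste0(name, "_c1b")]] <- b1$db
  dM <- b1$dM
  skW <- g("skW")
  if (is.null(skW)) {
    dM <- dM + dY
  } else {
    gr[[paste0(name, "_skW")]] <- crossprod(cache$M, dY)
    dM <- dM + dY %*% t(skW)
  }
  list(grads = gr, dM = dM, dTemb = dTemb)
}

# ---- bottleneck self-attention --------------------------------------------

.attnFwd <- function(p, M, rowsPerB, keep = TRUE) {
  C <- ncol(M)
  Q <- M %*% p$at_qW; K <- M %*% p$at_kW; V <- M %*% p$at_vW
  A <- vector("list", length(rowsPerB))
  P <- matrix(0, nrow(M), C)
  sc <- 1 / sqrt(C)
  for (b in seq_along(rowsPerB)) {
    r <- rowsPerB[[b]]
    S <- (Q[r, , drop = FALSE] %*% t(K[r, , drop = FALSE])) * sc
    S <- exp(S - apply(S, 1L, max))
    Ab <- S / rowSums(S)
    P[r, ] <- Ab %*% V[r, , drop = FALSE]
    A[[b]] <- Ab
  }
  out <- M + P %*% p$at_oW + rep(p$at_ob, each = nrow(M))
  list(Y = out, cache = if (keep) list(M = M, Q = Q, K = K, V = V, A = A,
                                       P = P, rowsPerB = rowsPerB) else NULL)
}

.attnBwd <- function(p, dY, cache) {
  C <- ncol(dY)
  gr <- list(at_oW = crossprod(cache$P, dY), at_ob = colSums(dY))
  dP <- dY %*% t(p$at_oW)
  dQ <- matrix(0, nrow(dY), C); dK <- dQ; dV <- dQ
  sc <- 1 / sqrt(C)
  for (b in seq_along(cache$rowsPerB)) {
    r <- cache$rowsPerB[[b]]
    Ab <- cache$A[[b]]
    dPb <- dP[r, , drop = FALSE]
    dA <- dPb %*% t(cache$V[r, , drop = FALSE])
    dV[r, ] <- t(Ab) %*% dPb
    dS <- Ab * (dA - rowSums(dA * Ab))
    dQ[r, ] <- (dS %*% cache$K[r, , drop = FALSE]) * sc
    dK[r, ] <- (t(dS) %*% cache$Q[r, , drop = FALSE]) * sc
  }
  gr$at_qW <- crossprod(cache$M, dQ)
  gr$at_kW <- crossprod(cache$M, dK)
  gr$at_vW <- crossprod(cache$M, dV)
  list(grads = gr, dM = dY + dQ %*% t(p$at_qW) + dK %*% t(p$at_kW) + dV %*% t(p$at_vW))
}

# ---- full network ----------------------------------------------------------

# memoized per-(net) constants; geometry is cached per batch size
.netConsts <- function(net) {
  e <- new.env(parent = emptyenv())
  e$pos <- .sinusoid(seq_len(net$frameLength), net$posChannels)
  e$geo <- list()
  e
}

.geomFor <- function(consts, net, B) {
  key <- as.character(B)
  g <- consts$geo[[key]]
  if (is.null(g)) {
    g <- .geom(B, net$frameLength, net$kernel)
    consts$geo[[key]] <- g
  }
  g
}

.denoiserFwd <- function(p, net, x, t, keep = FALSE, consts = NULL) {
  d <- dim(x); B <- d[1L]; L <- d[2L]
  if (L != net$frameLength || d[3L] != net$inChannels)
    stop("input shape does not match the network frame")
  if (length(t) == 1L) t <- rep(t, B)
  cs <- consts %||% .netConsts(net)
  geo <- .geomFor(cs, net, B)
  w <- net$widths
  ts <- .sinusoid(as.numeric(t), net$sinDim)
  h1 <- ts %*% p$t1_W + rep(p$t1_b, each = B)
  s1 <- .silu(h1)
  temb <- s1 %*% p$t2_W + rep(p$t2_b, each = B)
  Min <- cbind(matrix(x, B * L, net$inChannels), cs$pos[geo$posRow, , drop = FALSE])
  h0 <- .convFwd(Min, p$in_W, p$in_b, geo$cL, keep)
  r1 <- .resFwd(p, "d1", h0$Y, temb, geo$cL, geo$bRow$L, keep)
  g1 <- .convFwd(r1$Y, p$dn1_W, p$dn1_b, geo$dn1, keep)
  r2 <- .resFwd(p, "d2", g1$Y, temb, geo$cL2, geo$bRow$L2, keep)
  g2c <- .convFwd(r2$Y, p$dn2_W, p$dn2_b, geo$dn2, keep)
  m1 <- .resFwd(p, "m1", g2c$Y, temb, geo$cL4, geo$bRow$L4, keep)
  at <- .attnFwd(p, m1$Y, geo$attnRows, keep)
  m2 <- .resFwd(p, "m2", at$Y, temb, geo$cL4, geo$bRow$L4, keep)
  u1c <- .convFwd(m2$Y[geo$up1$fwd, , drop = FALSE], p$up1_W, p$up1_b, geo$cL2, keep)
  r3 <- .resFwd(p, "u1", cbind(u1c$Y, r2$Y), temb, geo$cL2, geo$bRow$L2, keep)
  u2c <- .convFwd(r3$Y[geo$up2$fwd, , drop = FALSE], p$up2_W, p$up2_b, geo$cL, keep)
  r4 <- .resFwd(p, "u2", cbind(u2c$Y, r1$Y), temb, geo$cL, geo$bRow$L, keep)
  s4 <- .silu(r4$Y)
  yc <- .convFwd(s4, p$out_W, p$out_b, geo$cL, keep)
  gate <- temb %*% p$po_gW + rep(p$po_gb, each = B)
  yOut <- yc$Y + gate[geo$bRow$L, , drop = FALSE] * p$po_E[geo$posRow, , drop = FALSE]
  out <- array(yOut, c(B, L, net$inChannels))
  if (!keep) return(list(Y = out))
  list(Y = out,
       cache = list(ts = ts, h1 = h1, s1 = s1, h0 = h0$cache, r1 = r1$cache,
                    g1 = g1$cache, r2 = r2$cache, g2c = g2c$cache, m1 = m1$cache,
                    at = at$cache, m2 = m2$cache, u1c = u1c$cache, r3 = r3$cache,
                    u2c = u2c$cache, r4 = r4$cache, r4Y = r4$Y, out = yc$cache,
                    gate = gate, temb = temb, geo = geo, B = B, L = L))
}

.denoiserBwd <- function(p, net, dY, cache) {
  w <- net$widths
  geo <- cache$geo
  gr <- list()
  merge <- function(g) for (nm in names(g)) gr[[nm]] <<- g[[nm]]
  dYm <- matrix(dY, cache$B * cache$L, net$inChannels)
  gr$po_E <- rowsum(dYm * cache$gate[geo$bRow$L, , drop = FALSE], geo$posRow)
  dGate <- rowsum(dYm * p$po_E[geo$posRow, , drop = FALSE], geo$bRow$L)
  gr$po_gW <- crossprod(cache$temb, dGate); gr$po_gb <- colSums(dGate)
  dTembHead <- dGate %*% t(p$po_gW)
  bOut <- .convBwd(dYm, p$out_W, cache$out)
  gr$out_W <- bOut$dW; gr$out_b <- bOut$db
  dR4 <- bOut$dM * .siluGrad(cache$r4Y)
  b4 <- .resBwd(p, "u2", dR4, cache$r4); merge(b4$grads)
  dTemb <- b4$dTemb + dTembHead
  dU2 <- b4$dM[, seq_len(w[1L]), drop = FALSE]
  dR1skip <- b4$dM[, w[1L] + seq_len(w[1L]), drop = FALSE]
  bu2 <- .convBwd(dU2, p$up2_W, cache$u2c)
  gr$up2_W <- bu2$dW; gr$up2_b <- bu2$db
  dR3 <- bu2$dM[geo$up2$odd, , drop = FALSE] + bu2$dM[geo$up2$even, , drop = FALSE]
  b3 <- .resBwd(p, "u1", dR3, cache$r3); merge(b3$grads)
  dTemb <- dTemb + b3$dTemb
  dU1 <- b3$dM[, seq_len(w[2L]), drop = FALSE]
  dR2skip <- b3$dM[, w[2L] + seq_len(w[2L]), drop = FALSE]
  bu1 <- .convBwd(dU1, p$up1_W, cache$u1c)
  gr$up1_W <- bu1$dW; gr$up1_b <- bu1$db
  dM2 <- bu1$dM[geo$up1$odd, , drop = FALSE] + bu1$dM[geo$up1$even, , drop = FALSE]
  bm2 <- .resBwd(p, "m2", dM2, cache$m2); merge(bm2$grads)
  dTemb <- dTemb + bm2$dTemb
  bat <- .attnBwd(p, bm2$dM, cache$at); merge(bat$grads)
  bm1 <- .resBwd(p, "m1", bat$dM, cache$m1); merge(bm1$grads)
  dTemb <- dTemb + bm1$dTemb
  bg2 <- .convBwd(bm1$dM, p$dn2_W, cache$g2c)
  gr$dn2_W <- bg2$dW; gr$dn2_b <- bg2$db
  b2 <- .resBwd(p, "d2", bg2$dM + dR2skip, cache$r2); merge(b2$grads)
  dTemb <- dTemb + b2$dTemb
  bg1 <- .convBwd(b2$dM, p$dn1_W, cache$g1)
  gr$dn1_W <- bg1$dW; gr$dn1_b <- bg1$db
  b1 <- .resBwd(p, "d1", bg1$dM + dR1skip, cache$r1); merge(b1$grads)
  dTemb <- dTemb + b1$dTemb
  bh0 <- .convBwd(b1$dM, p$in_W, cache$h0)
  gr$in_W <- bh0$dW; gr$in_b <- bh0$db
  gr$t2_W <- crossprod(cache$s1, dTemb); gr$t2_b <- colSums(dTemb)
  dH1 <- (dTemb %*% t(p$t2_W)) * .siluGrad(cache$h1)
  gr$t1_W <- crossprod(cache$ts, dH1); gr$t1_b <- colSums(dH1)
  gr
}

#' Predict the noise component of a noised batch
#'
#' The denoiser contract: a deterministic parameterized mapping from a
#' noised batch and its timesteps to a predicted-noise batch of identical
#' shape.
#'
#' @param model A [SeqDiffusionModel-class].
#' @param x Noised batch, an `(n, frameLength, 8)` array (or a single
#'   `frameLength x 8` matrix).
#' @param t Integer timestep(s), length 1 or one per batch element.
#' @return Predicted noise with the shape of `x`.
#' @export
predictNoise <- function(model, x, t) {
  single <- is.matrix(x)
  if (single) x <- array(x, c(1L, dim(x)))
  out <- .denoiserFwd(model@params, model@net, x, t, keep = FALSE)$Y
  if (single) matrix(out[1L, , ], ncol = dim(out)[3L]) else out
}
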