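# Hand-written AdamW (decoupled weight decay), operating on the flat named
# parameter list of the denoiser.

.adamwInit <- function(params) {
  list(step = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

.adamwStep <- function(params, grads, state, lr = 2e-4, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weightDecay = 0.01) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           weightDecay * params[[nm]])
  }
  list(params = params, state = state)
}
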