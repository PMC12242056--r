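# AdamW optimizer over a named flat list of parameter arrays.
#
# Defaults follow the training recipe used throughout the package:
# lr = 2e-4, beta1 = 0.5, beta2 = 0.999 (decoupled weight decay off by
# default so that tiny fixtures can be memorized exactly).

adamw_init <- function(params, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  state <- list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
    weight_decay = weight_decay, t = 0L,
    m = lapply(params, function(p) {
      z <- p
      z[] <- 0
      z
    }),
    v = lapply(params, function(p) {
      z <- p
      z[] <- 0
      z
    })
  )
  state
}

adamw_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1
  b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + opt$eps)
    if (opt$weight_decay > 0) upd <- upd + opt$weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - opt$lr * upd
  }
  list(opt = opt, params = params)
}
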