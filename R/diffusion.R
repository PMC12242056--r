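# Embedding-space denoising diffusion prior with classifier-free guidance.
#
# The prior maps an EEG embedding (the condition) to a clean image-embedding
# sample: a 6-block residual network with mirrored skip connections predicts
# the noise added to image embeddings under a cosine schedule; ~10% of
# training conditions are replaced by a learned null token so that the same
# network provides conditional and unconditional predictions, blended at
# sampling time as eps_null + w * (eps_cond - eps_null) with w = 3.5 by
# default, over 50 evenly strided ancestral steps.

#' Cosine noise schedule
#'
#' Cumulative signal fractions `alpha_bar[t] = f(t)/f(0)` with
#' `f(t) = cos^2(((t/T + s)/(1 + s)) * pi/2)`, for `t = 0..T` (stored with
#' 1-based offset: element `t + 1` is step `t`). `alpha_bar[0] = 1` exactly
#' and the sequence is strictly decreasing.
#'
#' @param T Number of diffusion steps (>= 1).
#' @param s Small offset (default 0.008) keeping the first steps gentle.
#' @return Object of class `noise_schedule` with fields `T`, `s`, `alpha_bar`
#'   (length `T + 1`).
#' @examples
#' sch <- cosine_alpha_bar(1000)
#' sch$alpha_bar[1] # 1
#' @export
cosine_alpha_bar <- function(T, s = 0.008) {
  if (T < 1) stop_arg("T must be >= 1")
  t <- 0:T
  f <- cos(((t / T + s) / (1 + s)) * pi / 2)^2
  structure(list(T = as.integer(T), s = s, alpha_bar = f / f[1L]),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("Cosine noise schedule: T = %d, s = %g, alpha_bar[T] = %.3g\n",
              x$T, x$s, x$alpha_bar[x$T + 1L]))
  invisible(x)
}

sched_ab <- function(sched, t) {
  if (any(t < 0 | t > sched$T)) stop_arg("t out of range 0..", sched$T)
  sched$alpha_bar[t + 1L]
}

#' Forward diffusion of a clean embedding
#'
#' `I_t = sqrt(alpha_bar[t]) * I0 + sqrt(1 - alpha_bar[t]) * eps`.
#'
#' @param I0 Clean embedding vector (or matrix of rows).
#' @param t Diffusion step in `0..T`.
#' @param eps Noise with the same shape as `I0`.
#' @param sched A [cosine_alpha_bar()] schedule.
#' @return Noisy embedding, same shape as `I0`.
#' @export
forward_diffuse <- function(I0, t, eps, sched) {
  ab <- sched_ab(sched, t)
  sqrt(ab) * I0 + sqrt(1 - ab) * eps
}

#' Diffusion prior configuration
#'
#' @param embed_dim Embedding width `D` the prior operates on.
#' @param n_layers Residual blocks (default 6; mirrored skips: block 4 reuses
#'   block 3's output, 5 reuses 2's, 6 reuses 1's).
#' @param width Residual-stream width (default `max(64, 2 * embed_dim)`).
#' @param T Diffusion steps of the training schedule.
#' @param cond_dropout_p Probability of replacing the condition with the
#'   learned null token during training (default 0.10).
#' @param guidance_w Default guidance scale at sampling (default 3.5).
#' @param sample_steps Default sampling steps (default 50).
#' @param time_dim Sinusoidal time-embedding width.
#' @return A `prior_config` list.
#' @export
prior_config <- function(embed_dim, n_layers = 6, width = NULL, T = 1000,
                         cond_dropout_p = 0.10, guidance_w = 3.5,
                         sample_steps = 50, time_dim = 32) {
  if (cond_dropout_p < 0 || cond_dropout_p >= 1) {
    stop_arg("need 0 <= cond_dropout_p < 1")
  }
  if (guidance_w < 0) stop_arg("guidance_w must be >= 0")
  if (is.null(width)) width <- max(64L, 2L * embed_dim)
  if (sample_steps > T) stop_arg("sample_steps must be <= T")
  structure(
    list(embed_dim = as.integer(embed_dim), n_layers = as.integer(n_layers),
         width = as.integer(width), T = as.integer(T),
         cond_dropout_p = cond_dropout_p, guidance_w = guidance_w,
         sample_steps = as.integer(sample_steps), time_dim = as.integer(time_dim)),
    class = "prior_config"
  )
}

# mirrored bottleneck widths: wide -> narrow -> narrow -> wide
prior_block_widths <- function(cfg) {
  half <- ceiling(cfg$n_layers / 2)
  shrink <- 2^(pmin(seq_len(half), 3L) - 1L)
  down <- pmax(8L, cfg$width %/% shrink)
  c(down, rev(down))[seq_len(cfg$n_layers)]
}

#' Build an untrained diffusion prior
#'
#' @param config A [prior_config()].
#' @param seed Integer seed for parameter initialization.
#' @return Object of class `diffusion_prior` (untrained).
#' @export
build_prior <- function(config, seed = 1) {
  stopifnot(inherits(config, "prior_config"))
  D <- config$embed_dim
  W <- config$width
  widths <- prior_block_widths(config)
  params <- with_seed(seed, {
    p <- list()
    p[["in.W"]] <- init_w(D, W)
    p[["in.b"]] <- rep(0, W)
    p[["null_token"]] <- matrix(0.02 * stats::rnorm(D), 1L, D)
    for (i in seq_len(config$n_layers)) {
      wi <- widths[i]
      p[[paste0("blk", i, ".W1")]] <- init_w(W, wi)
      p[[paste0("blk", i, ".b1")]] <- rep(0, wi)
      p[[paste0("blk", i, ".Wt")]] <- init_w(config$time_dim, wi)
      p[[paste0("blk", i, ".Wtg")]] <- 0.1 * init_w(config$time_dim, wi)
      # zero-initialized: the condition only influences predictions once
      # conditioned batches have produced gradients for it
      p[[paste0("blk", i, ".Wc")]] <- matrix(0, D, wi)
      p[[paste0("blk", i, ".W2")]] <- 0.5 * init_w(wi, W)
      p[[paste0("blk", i, ".b2")]] <- rep(0, W)
    }
    p[["out.W"]] <- init_w(W, D)
    p[["out.b"]] <- rep(0, D)
    # direct linear path from x_t to the prediction: at high noise levels the
    # optimal eps-estimate is close to x_t itself
    p[["skip.W"]] <- diag(D)
    p
  })
  structure(
    list(config = config, params = params,
         schedule = cosine_alpha_bar(config$T), seed = seed,
         history = numeric(0), format_version = 1L),
    class = "diffusion_prior"
  )
}

#' @export
print.diffusion_prior <- function(x, ...) {
  cat(sprintf(
    paste0("Diffusion prior: D = %d, %d residual blocks (width %d), T = %d, ",
           "cond dropout %.2f, guidance %.1f, %d sampling steps%s\n"),
    x$config$embed_dim, x$config$n_layers, x$config$width, x$config$T,
    x$config$cond_dropout_p, x$config$guidance_w, x$config$sample_steps,
    if (length(x$history)) sprintf("; trained, final loss %.4f", utils::tail(x$history, 1)) else "; untrained"
  ))
  invisible(x)
}

# tape forward: x_t (B x D) node, tvec (length B), cond node (B x D)
prior_graph <- function(prior, lv, x_node, tvec, cond_node) {
  cfg <- prior$config
  temb <- ag_const(sinusoid_encoding(tvec / cfg$T * 1000, cfg$time_dim))
  # blocks see the condition relative to the learned null token, so the
  # unconditional branch contributes exactly zero through the condition path
  ones <- ag_const(matrix(1, length(tvec), 1L))
  cond_delta <- ag_sub(cond_node, ag_matmul(ones, lv[["null_token"]]))
  h <- ag_add_bias(ag_matmul(x_node, lv[["in.W"]]), lv[["in.b"]])
  half <- cfg$n_layers %/% 2L
  skips <- vector("list", half)
  for (i in seq_len(cfg$n_layers)) {
    if (i > half && cfg$n_layers - i + 1L <= half) {
      h <- ag_add(h, skips[[cfg$n_layers - i + 1L]]) # mirrored U-Net skip
    }
    u <- ag_add_bias(ag_matmul(h, lv[[paste0("blk", i, ".W1")]]),
                     lv[[paste0("blk", i, ".b1")]])
    # feature-wise modulation: the time embedding supplies both a gain and a
    # shift, so step-dependent linear maps of x_t are expressible; the tanh
    # bounds the gain in (0, 2), preventing multiplicative blow-up across
    # blocks
    gain <- ag_add(ag_const(matrix(1, length(tvec), ncol(u$v))),
                   ag_tanh(ag_matmul(temb, lv[[paste0("blk", i, ".Wtg")]])))
    u <- ag_mul(u, gain)
    u <- ag_add(u, ag_matmul(temb, lv[[paste0("blk", i, ".Wt")]]))
    u <- ag_add(u, ag_matmul(cond_delta, lv[[paste0("blk", i, ".Wc")]]))
    u <- ag_gelu(u)
    h <- ag_add(h, ag_add_bias(ag_matmul(u, lv[[paste0("blk", i, ".W2")]]),
                               lv[[paste0("blk", i, ".b2")]]))
    if (i <= half) skips[[i]] <- h
  }
  out <- ag_add_bias(ag_matmul(h, lv[["out.W"]]), lv[["out.b"]])
  ag_add(out, ag_matmul(x_node, lv[["skip.W"]]))
}

#' Predict the noise component of a noisy embedding
#'
#' @param prior A `diffusion_prior`.
#' @param I_t Noisy embedding (vector or `B x D` matrix).
#' @param t Diffusion step (scalar or length-`B` vector).
#' @param condition EEG embedding rows, or `NULL` for the learned null token
#'   (unconditional branch).
#' @return Noise estimate with the rows of `I_t`; deterministic.
#' @export
prior_predict_noise <- function(prior, I_t, t, condition = NULL) {
  x <- if (is.matrix(I_t)) I_t else matrix(I_t, 1L)
  if (ncol(x) != prior$config$embed_dim) {
    stop_arg("embedding width ", ncol(x), " does not match prior (",
             prior$config$embed_dim, ")")
  }
  B <- nrow(x)
  cond <- if (is.null(condition)) {
    prior$params[["null_token"]][rep(1L, B), , drop = FALSE]
  } else {
    c2 <- if (is.matrix(condition)) condition else matrix(condition, 1L)
    if (ncol(c2) != prior$config$embed_dim) stop_arg("condition width mismatch")
    if (nrow(c2) == 1L && B > 1L) c2 <- c2[rep(1L, B), , drop = FALSE]
    c2
  }
  tvec <- rep_len(t, B)
  if (any(tvec < 0 | tvec > prior$config$T)) stop_arg("t out of range")
  ag_tape_start()
  lv <- make_leaves(prior$params)
  out <- prior_graph(prior, lv, ag_const(x), tvec, ag_const(cond))
  res <- out$v
  if (!is.matrix(I_t)) res <- drop(res)
  res
}

#' Train the diffusion prior on (EEG, image) embedding pairs
#'
#' Minimizes the mean squared error between predicted and true noise over
#' uniformly sampled steps; each batch element's condition is replaced by the
#' learned null token with probability `cond_dropout_p`, which trains the
#' conditional and unconditional model inside one network.
#'
#' @param prior A [build_prior()] object.
#' @param E Condition embeddings (`n x D`).
#' @param I Target clean embeddings (`n x D`), row-paired with `E`.
#' @param steps Optimization steps.
#' @param batch_size Batch size (capped at `n`).
#' @param lr,beta1,beta2 AdamW settings.
#' @param grad_clip Optional global gradient-norm ceiling (`Inf`, the
#'   default, disables). Clipping interacts poorly with Adam's per-coordinate
#'   scaling here, so prefer lowering the learning rate if training
#'   diverges.
#' @param seed Integer seed (batching, noise, condition dropout).
#' @return The trained `diffusion_prior` with a per-step loss `history`.
#' @export
train_prior <- function(prior, E, I, steps = 500, batch_size = 64,
                        lr = 1e-3, beta1 = 0.5, beta2 = 0.999,
                        grad_clip = Inf, seed = 1) {
  E <- as.matrix(E)
  I <- as.matrix(I)
  if (nrow(E) == 0L) stop_arg("no training pairs")
  if (!all(dim(E) == dim(I))) stop_arg("E and I must be row-paired, same shape")
  n <- nrow(E)
  D <- prior$config$embed_dim
  if (ncol(E) != D) stop_arg("embedding width mismatch")
  params <- prior$params
  opt <- adamw_init(params, lr = lr, beta1 = beta1, beta2 = beta2)
  bsz <- min(batch_size, n)
  history <- numeric(steps)
  for (st in seq_len(steps)) {
    dat <- with_seed(derive_seed(seed, paste0("prior", st)), {
      idx <- sample.int(n, bsz, replace = bsz > n)
      tvec <- sample.int(prior$config$T, bsz)
      eps <- matrix(stats::rnorm(bsz * D), bsz)
      drop_mask <- stats::rbinom(bsz, 1L, prior$config$cond_dropout_p)
      list(idx = idx, tvec = tvec, eps = eps, drop = drop_mask)
    })
    ab <- sched_ab(prior$schedule, dat$tvec)
    x_t <- sqrt(ab) * I[dat$idx, , drop = FALSE] + sqrt(1 - ab) * dat$eps
    keep <- 1 - dat$drop
    ag_tape_start()
    lv <- make_leaves(params)
    # kept rows use their EEG condition; dropped rows the learned null token
    cond <- ag_add(
      ag_const(E[dat$idx, , drop = FALSE] * keep),
      ag_matmul(ag_const(matrix(dat$drop, ncol = 1L)), lv[["null_token"]])
    )
    pred <- prior_graph(prior, lv, ag_const(x_t), dat$tvec, cond)
    diff <- ag_sub(pred, ag_const(dat$eps))
    loss <- ag_mean(ag_mul(diff, diff))
    ag_backward(loss)
    grads <- lapply(lv, ag_grad)
    if (is.finite(grad_clip)) {
      gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
      if (gn > grad_clip) grads <- lapply(grads, function(g) g * (grad_clip / gn))
    }
    upd <- adamw_step(opt, params, grads)
    opt <- upd$opt
    params <- upd$params
    history[st] <- as.numeric(loss$v)
  }
  prior$params <- params
  prior$history <- c(prior$history, history)
  prior
}

#' Classifier-free-guided noise prediction
#'
#' `eps_hat = eps(I_t, t, null) + w * (eps(I_t, t, E) - eps(I_t, t, null))`:
#' `w = 0` gives the unconditional branch, `w = 1` the conditional one.
#'
#' @param prior Trained prior.
#' @param I_t Noisy embedding rows.
#' @param t Diffusion step.
#' @param E Condition embedding rows.
#' @param w Guidance scale (>= 0; default the config's 3.5).
#' @return Guided noise estimate.
#' @export
guided_noise <- function(prior, I_t, t, E, w = prior$config$guidance_w) {
  if (w < 0) stop_arg("guidance scale w must be >= 0")
  eps_u <- prior_predict_noise(prior, I_t, t, NULL)
  if (w == 0) {
    return(eps_u)
  }
  eps_c <- prior_predict_noise(prior, I_t, t, E)
  eps_u + w * (eps_c - eps_u)
}

#' Sample a clean embedding from the prior
#'
#' Ancestral denoising over `steps` evenly strided schedule points, starting
#' from Gaussian noise, with classifier-free guidance; deterministic given
#' `seed`.
#'
#' @param prior Trained prior.
#' @param E Condition embedding (vector or matrix of rows; each row sampled
#'   independently with a shared noise stream).
#' @param steps Sampling steps (<= schedule T; default config's 50).
#' @param w Guidance scale (default config's 3.5).
#' @param seed Integer seed.
#' @param x0_max_norm Clean-embedding estimates are clipped to this
#'   Euclidean norm at every step (targets are unit-norm image embeddings).
#' @param eta Scale of the ancestral noise injections relative to the
#'   standard beta-tilde variance (default 1, plain ancestral sampling;
#'   0 gives deterministic denoising).
#' @return Sampled embedding(s), same rows as `E`.
#' @export
sample_embedding <- function(prior, E, steps = prior$config$sample_steps,
                             w = prior$config$guidance_w, seed = 1, eta = 1,
                             x0_max_norm = 1.5) {
  if (steps > prior$config$T) stop_arg("steps must be <= schedule T")
  Em <- if (is.matrix(E)) E else matrix(E, 1L)
  B <- nrow(Em)
  D <- prior$config$embed_dim
  stride <- max(1L, prior$config$T %/% steps)
  ts <- seq(prior$config$T, by = -stride, length.out = steps)
  ts <- sort(unique(pmax(ts, 1L)), decreasing = TRUE)
  ab <- prior$schedule$alpha_bar
  x <- with_seed(derive_seed(seed, "init"), matrix(stats::rnorm(B * D), B))
  for (i in seq_along(ts)) {
    t <- ts[i]
    t_prev <- if (i < length(ts)) ts[i + 1L] else 0L
    eps_hat <- guided_noise(prior, x, t, Em, w)
    # floor alpha_bar and clip the x0 estimate: the cosine tail makes
    # alpha_bar[T] vanish, which would amplify early noise-prediction error
    ab_t <- max(ab[t + 1L], 1e-6)
    ab_p <- ab[t_prev + 1L]
    x0 <- (x - sqrt(1 - ab_t) * eps_hat) / sqrt(ab_t)
    n0 <- sqrt(rowSums(x0^2))
    x0 <- x0 * pmin(1, x0_max_norm / pmax(n0, 1e-12))
    if (t_prev == 0L) {
      x <- x0
    } else {
      # ancestral posterior with the standard beta-tilde variance
      var_p <- (1 - ab_p) / (1 - ab_t) * (1 - ab_t / ab_p)
      var_p <- eta^2 * max(min(var_p, 1 - ab_p), 0)
      z <- with_seed(derive_seed(seed, paste0("z", i)),
                     matrix(stats::rnorm(B * D), B))
      x <- sqrt(ab_p) * x0 + sqrt(max(1 - ab_p - var_p, 0)) * eps_hat +
        sqrt(var_p) * z
    }
  }
  if (!is.matrix(E)) x <- drop(x)
  x
}

#' Save / load a diffusion-prior checkpoint
#'
#' @param prior A `diffusion_prior`.
#' @param path File path.
#' @return `load_prior` returns the restored object.
#' @export
save_prior <- function(prior, path) {
  saveRDS(list(format_version = prior$format_version, config = prior$config,
               seed = prior$seed, params = prior$params,
               history = prior$history), path)
  invisible(path)
}

#' @rdname save_prior
#' @export
load_prior <- function(path) {
  x <- readRDS(path)
  if (is.null(x$format_version) || x$format_version != 1L) {
    stop_arg("unsupported prior checkpoint format")
  }
  pr <- build_prior(x$config, seed = x$seed)
  pr$params <- x$params
  pr$history <- x$history
  pr
}

#' Refine EEG embeddings into image-embedding space
#'
#' The practical two-stage refinement operator: draws `k` guided samples per
#' condition from the prior, unit-normalizes them, and either averages them
#' (an estimate of the conditional mean direction, default) or keeps the
#' candidate most similar to the condition. A moderate guidance scale
#' (default 2) works best for retrieval-oriented refinement in the synthetic
#' embedding space; the stronger generation default (3.5) remains the
#' config's sampling setting.
#'
#' @param prior Trained `diffusion_prior`.
#' @param E Condition embeddings (rows).
#' @param k Samples per condition.
#' @param w Guidance scale.
#' @param steps Sampling steps (default the config's).
#' @param select `"mean"` (average of the k candidates) or `"best"`
#'   (highest cosine to the condition).
#' @param seed Integer seed.
#' @return Unit-norm matrix with the rows of `E`.
#' @export
refine_embeddings <- function(prior, E, k = 8, w = 2,
                              steps = prior$config$sample_steps,
                              select = c("mean", "best"), seed = 1) {
  select <- match.arg(select)
  Em <- if (is.matrix(E)) E else matrix(E, 1L)
  samples <- lapply(seq_len(k), function(j) {
    unit_rows(sample_embedding(prior, Em, steps = steps, w = w,
                               seed = derive_seed(seed, paste0("cand", j))))
  })
  out <- if (select == "mean" || k == 1L) {
    Reduce(`+`, samples) / k
  } else {
    En <- unit_rows(Em)
    sims <- vapply(samples, function(s) rowSums(s * En), numeric(nrow(Em)))
    sims <- matrix(sims, nrow = nrow(Em))
    t(vapply(seq_len(nrow(Em)), function(i) {
      samples[[which.max(sims[i, ])]][i, ]
    }, numeric(ncol(Em))))
  }
  out <- unit_rows(out)
  if (!is.matrix(E)) out <- drop(out)
  out
}
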