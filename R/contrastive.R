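# Symmetric InfoNCE alignment of EEG and image embeddings.
#
# Both modalities pass through small one-hidden-layer GELU MLP projectors
# into a shared space; scaled cosine similarities (learned temperature,
# initialized at log(1/0.07)) feed the symmetric InfoNCE objective, optimized
# with AdamW (lr 2e-4, betas 0.5/0.999).

#' Scaled cosine similarity matrix
#'
#' `values[i, j] = exp(logit_scale) * cos(E_i, I_j)` - the similarity score
#' between EEG embedding `i` and image embedding `j`. Matched pairs sit on
#' the diagonal.
#'
#' @param E Matrix `B x D` of EEG-side embeddings.
#' @param I Matrix `B x D` of image-side embeddings.
#' @param logit_scale Learned log temperature (0 gives plain cosine;
#'   `log(1/0.07)` is the conventional initialization).
#' @return Matrix `B x B` of scaled similarities.
#' @examples
#' E <- diag(3)
#' scaled_similarity(E, E, 0)
#' @export
scaled_similarity <- function(E, I, logit_scale = log(1 / 0.07)) {
  E <- as.matrix(E)
  I <- as.matrix(I)
  if (ncol(E) != ncol(I)) stop_arg("E and I must have the same dimension")
  assert_finite(E, "E")
  assert_finite(I, "I")
  ne <- sqrt(rowSums(E^2))
  ni <- sqrt(rowSums(I^2))
  if (any(ne == 0)) stop_arg("zero-norm EEG embedding at row ", which(ne == 0)[1L])
  if (any(ni == 0)) stop_arg("zero-norm image embedding at row ", which(ni == 0)[1L])
  exp(logit_scale) * ((E / ne) %*% t(I / ni))
}

#' Symmetric InfoNCE loss of a similarity matrix
#'
#' One half of the mean row-wise cross-entropy of `softmax(S)` against the
#' diagonal (EEG retrieves image) plus the same over columns (image retrieves
#' EEG). Equals `log(B)` when all similarities are equal and approaches 0 as
#' the matched diagonal saturates.
#'
#' @param S Square similarity matrix with matched pairs on the diagonal.
#' @return Non-negative scalar.
#' @examples
#' info_nce_loss(matrix(1, 2, 2)) # log(2)
#' @export
info_nce_loss <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop_arg("similarity matrix must be square")
  lse_r <- apply(S, 1L, function(r) {
    m <- max(r)
    m + log(sum(exp(r - m)))
  })
  lse_c <- apply(S, 2L, function(r) {
    m <- max(r)
    m + log(sum(exp(r - m)))
  })
  0.5 * (mean(lse_r - diag(S)) + mean(lse_c - diag(S)))
}

init_projector <- function(d_in, d_hidden, d_out, prefix) {
  p <- list()
  p[[paste0(prefix, ".W1")]] <- init_w(d_in, d_hidden)
  p[[paste0(prefix, ".b1")]] <- rep(0, d_hidden)
  p[[paste0(prefix, ".W2")]] <- init_w(d_hidden, d_out)
  p[[paste0(prefix, ".b2")]] <- rep(0, d_out)
  p
}

# residual when input and output widths match, so the projector starts out
# cosine-preserving and only learns a correction
projector_graph <- function(x, lv, prefix) {
  h <- ag_gelu(ag_add_bias(ag_matmul(x, lv[[paste0(prefix, ".W1")]]),
                           lv[[paste0(prefix, ".b1")]]))
  out <- ag_add_bias(ag_matmul(h, lv[[paste0(prefix, ".W2")]]), lv[[paste0(prefix, ".b2")]])
  if (ncol(x$v) == ncol(out$v)) out <- ag_add(out, x)
  out
}

# tape version of the symmetric InfoNCE on projected, row-normalized nodes
info_nce_graph <- function(e_node, i_node, ls_node) {
  en <- ag_rownorm(e_node)
  inn <- ag_rownorm(i_node)
  S <- ag_scalar_mul(ag_exp(ls_node), ag_matmul(en, ag_t(inn)))
  St <- ag_t(S)
  lr <- ag_mean(ag_sub(ag_logsumexp_rows(S), ag_diag(S)))
  lc <- ag_mean(ag_sub(ag_logsumexp_rows(St), ag_diag(St)))
  ag_scale(ag_add(lr, lc), 0.5)
}

#' Fit the EEG encoder contrastively against image embeddings
#'
#' Trains the encoder, the two modality projectors and the temperature with
#' AdamW. Batches are drawn within subject (each step uses one subject's
#' trials, subjects alternating), matching the within-subject evaluation
#' protocol; the batch size is capped at the per-subject dataset size.
#'
#' @param enc A built [build_encoder()] (untrained or warm).
#' @param dataset A `synthetic_dataset`, or a list with `eeg`
#'   (`n x S x e x d`), `embeddings` (`n x D`) fields.
#' @param epochs Training epochs (0 returns the encoder unchanged with an
#'   empty history).
#' @param lr,beta1,beta2,weight_decay AdamW settings (defaults 2e-4, 0.5,
#'   0.999, 0).
#' @param batch_size Cap 1024, shrunk to the per-subject dataset size.
#' @param augment_sd SD of Gaussian noise added to the EEG batch at each
#'   training step (augmentation only; evaluation inputs are untouched).
#' @param shared_dim Shared-space width; default the image-embedding width.
#' @param seed Integer seed controlling initialization of the projectors,
#'   batch shuffling and dropout.
#' @param verbose Print per-epoch loss?
#' @return Object of class `contrastive_fit` with the trained `encoder`,
#'   projector parameters, `logit_scale`, and a per-step loss `history`.
#' @export
fit_contrastive <- function(enc, dataset, epochs = 60, lr = 2e-4,
                            beta1 = 0.5, beta2 = 0.999, weight_decay = 0,
                            batch_size = 1024, augment_sd = 0.3,
                            shared_dim = NULL, seed = 1, verbose = FALSE) {
  split <- if (inherits(dataset, "synthetic_dataset")) dataset$train else dataset
  eeg <- split$eeg
  emb <- split$embeddings
  if (is.null(eeg) || is.null(emb) || nrow(emb) == 0L) {
    stop_arg("dataset provides no (EEG, image embedding) pairs")
  }
  n <- dim(eeg)[1L]
  n_subj <- dim(eeg)[2L]
  if (n_subj > enc$config$n_subjects) {
    stop_arg("dataset has ", n_subj, " subjects but encoder only ",
             enc$config$n_subjects, " subject maps")
  }
  D_img <- ncol(emb)
  if (is.null(shared_dim)) shared_dim <- D_img
  E <- enc$config$embed_dim

  params <- enc$params
  params <- c(params, with_seed(derive_seed(seed, "proj"), {
    c(init_projector(E, E, shared_dim, "projE"),
      init_projector(D_img, max(D_img, shared_dim), shared_dim, "projI"))
  }))
  params[["logit_scale"]] <- log(1 / 0.07)

  history <- data.frame(step = integer(0), epoch = integer(0), loss = numeric(0))
  if (epochs > 0) {
    opt <- adamw_init(params, lr = lr, beta1 = beta1, beta2 = beta2,
                      weight_decay = weight_decay)
    bsz <- min(batch_size, n)
    step <- 0L
    for (ep in seq_len(epochs)) {
      for (s in seq_len(n_subj)) {
        ord <- with_seed(derive_seed(seed, paste0("ord", ep, "_", s)), sample.int(n))
        starts <- seq(1L, n, by = bsz)
        for (st in starts) {
          idx <- ord[st:min(st + bsz - 1L, n)]
          if (length(idx) < 2L) next
          step <- step + 1L
          xb <- eeg[idx, s, , , drop = FALSE]
          xb <- array(xb, dim(xb)[-2L])
          if (augment_sd > 0) {
            xb <- xb + with_seed(
              derive_seed(seed, paste0("aug", step)),
              augment_sd * stats::sd(xb) * array(stats::rnorm(length(xb)), dim(xb))
            )
          }
          ib <- emb[idx, , drop = FALSE]
          ag_tape_start()
          lv <- make_leaves(params)
          gout <- with_seed(derive_seed(seed, paste0("drop", step)), {
            encoder_graph(enc, lv, ag_const(batch_to_matrix(xb)$m), length(idx),
                          subject_id = s, training = TRUE)
          })
          e_sh <- projector_graph(gout$embedding, lv, "projE")
          i_sh <- projector_graph(ag_const(ib), lv, "projI")
          loss <- info_nce_graph(e_sh, i_sh, lv[["logit_scale"]])
          ag_backward(loss)
          grads <- lapply(lv, ag_grad)
          upd <- adamw_step(opt, params, grads)
          opt <- upd$opt
          params <- upd$params
          params[["logit_scale"]] <- min(params[["logit_scale"]], log(100))
          history <- rbind(history, data.frame(step = step, epoch = ep,
                                               loss = as.numeric(loss$v)))
        }
      }
      if (verbose) {
        cat(sprintf("epoch %3d  loss %.4f\n", ep,
                    mean(history$loss[history$epoch == ep])))
      }
    }
  }

  enc_trained <- enc
  enc_trained$params <- params[names(enc$params)]
  structure(
    list(
      encoder = enc_trained,
      proj = params[grep("^proj[EI]\\.", names(params))],
      logit_scale = params[["logit_scale"]],
      shared_dim = shared_dim,
      history = history,
      opt_config = list(epochs = epochs, lr = lr, beta1 = beta1, beta2 = beta2,
                        weight_decay = weight_decay, batch_size = batch_size,
                        augment_sd = augment_sd),
      seed = seed
    ),
    class = "contrastive_fit"
  )
}

#' @export
print.contrastive_fit <- function(x, ...) {
  cat(sprintf(
    "Contrastive EEG-image fit: %d steps, temperature %.3f%s\n",
    nrow(x$history), exp(x$logit_scale),
    if (nrow(x$history)) sprintf(", final loss %.4f", utils::tail(x$history$loss, 1)) else ""
  ))
  print(x$encoder)
  invisible(x)
}

#' @export
plot.contrastive_fit <- function(x, ...) {
  if (!nrow(x$history)) {
    warning("empty training history")
    return(invisible(x))
  }
  graphics::plot(x$history$step, x$history$loss, type = "l",
                 xlab = "step", ylab = "InfoNCE loss", ...)
  invisible(x)
}

# plain (non-tape) projector forward; mirrors projector_graph exactly
project_matrix <- function(x, proj, prefix) {
  h <- sweep(x %*% proj[[paste0(prefix, ".W1")]], 2L,
             proj[[paste0(prefix, ".b1")]], `+`)
  h <- h * stats::pnorm(h)
  out <- sweep(h %*% proj[[paste0(prefix, ".W2")]], 2L,
               proj[[paste0(prefix, ".b2")]], `+`)
  if (ncol(x) == ncol(out)) out <- out + x
  out
}

#' Embed EEG trials or image embeddings with a contrastive fit
#'
#' @param object A `contrastive_fit`.
#' @param newdata Array `B x e x d` of EEG trials (for
#'   `type = "shared"` / `"embedding"`) or a matrix of image embeddings (for
#'   `type = "image_shared"`).
#' @param subject_id Subject index for EEG inputs.
#' @param type `"shared"` (unit-norm shared-space EEG embedding,  default),
#'   `"embedding"` (raw encoder output), or `"image_shared"` (unit-norm
#'   shared-space projection of image embeddings).
#' @param ... Unused.
#' @return Numeric matrix.
#' @export
predict.contrastive_fit <- function(object, newdata, subject_id = 1L,
                                    type = c("shared", "embedding", "image_shared"),
                                    ...) {
  type <- match.arg(type)
  if (type == "image_shared") {
    return(unit_rows(project_matrix(as.matrix(newdata), object$proj, "projI")))
  }
  emb <- encode_batch(object$encoder, newdata, subject_id = subject_id)
  if (type == "embedding") {
    return(emb)
  }
  unit_rows(project_matrix(emb, object$proj, "projE"))
}

# shared-space embeddings for a whole dataset split, all subjects stacked
shared_embeddings <- function(fit, dataset, split = c("test", "train")) {
  split <- match.arg(split)
  part <- dataset[[split]]
  n <- nrow(part$meta)
  n_subj <- dim(part$eeg)[2L]
  out <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    xb <- array(part$eeg[, s, , , drop = FALSE], dim(part$eeg)[-2L])
    out[[s]] <- predict(fit, xb, subject_id = s, type = "shared")
  }
  list(
    eeg = do.call(rbind, out),
    meta = data.frame(
      image_id = rep(part$meta$image_id, n_subj),
      category_id = rep(part$meta$category_id, n_subj),
      subject = rep(seq_len(n_subj), each = n)
    ),
    img = predict(fit, part$embeddings, type = "image_shared"),
    img_meta = part$meta
  )
}

#' Multi-seed contrastive training
#'
#' Re-initializes and trains the encoder once per seed and reports the final
#' and best per-seed losses, mirroring the multi-session training protocol.
#'
#' @param config Encoder configuration ([nerv_config()]).
#' @param dataset Training dataset.
#' @param seeds Integer vector of seeds.
#' @param ... Passed to [fit_contrastive()].
#' @return List with `fits` (one `contrastive_fit` per seed) and `summary`
#'   (`data.frame` of per-seed final/best loss).
#' @export
fit_contrastive_seeds <- function(config, dataset, seeds = 1:5, ...) {
  fits <- lapply(seeds, function(sd) {
    enc <- build_encoder(config, seed = sd)
    fit_contrastive(enc, dataset, seed = sd, ...)
  })
  summary <- data.frame(
    seed = seeds,
    final_loss = vapply(fits, function(f) {
      if (nrow(f$history)) utils::tail(f$history$loss, 1) else NA_real_
    }, numeric(1)),
    best_loss = vapply(fits, function(f) {
      if (nrow(f$history)) min(f$history$loss) else NA_real_
    }, numeric(1))
  )
  list(fits = fits, summary = summary)
}
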