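# Visual-cortex channel perturbation: replace the six posterior channels
# (O1, O2, Oz, PO3, PO4, POz) with Gaussian noise at evaluation time and
# compare retrieval accuracy and the toy Frechet distance against the
# unperturbed condition.

#' Perturbation specification
#'
#' @param channels Channel names to replace (default the posterior six).
#' @param noise_sd_mode `"matched"` draws noise with each channel's empirical
#'   per-trial SD; `"fixed"` uses `noise_sd` for every replaced channel.
#' @param noise_sd Fixed noise SD (only for `noise_sd_mode = "fixed"`).
#' @param seed Integer seed for the replacement noise.
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(channels = posterior_channels(),
                              noise_sd_mode = c("matched", "fixed"),
                              noise_sd = 1, seed = 1) {
  noise_sd_mode <- match.arg(noise_sd_mode)
  structure(list(channels = channels, noise_sd_mode = noise_sd_mode,
                 noise_sd = noise_sd, seed = seed),
            class = "perturbation_spec")
}

#' Replace channels of a dataset split with Gaussian noise
#'
#' Listed channels are replaced by i.i.d. zero-mean Gaussian samples (SD
#' matched per channel and trial by default); all other channels are bitwise
#' unchanged. An empty channel list is an exact no-op.
#'
#' @param dataset A `synthetic_dataset`.
#' @param spec A [perturbation_spec()].
#' @param split Which split to perturb (default `"test"`: the experiment
#'   perturbs evaluation inputs, not training data).
#' @return The dataset with the chosen split's EEG perturbed.
#' @export
perturb_channels <- function(dataset, spec, split = "test") {
  ch_names <- dataset$fm$channel_names
  missing <- setdiff(spec$channels, ch_names)
  if (length(missing)) {
    stop_arg("unknown channel(s) ", paste(missing, collapse = ", "),
             "; montage has: ", paste(ch_names, collapse = ", "))
  }
  if (length(spec$channels) == 0L) {
    return(dataset)
  }
  eeg <- dataset[[split]]$eeg
  ch_idx <- match(spec$channels, ch_names)
  dims <- dim(eeg) # n x S x e x d
  d <- dims[4L]
  with_seed(spec$seed, {
    for (i in seq_len(dims[1L])) {
      for (s in seq_len(dims[2L])) {
        for (c in ch_idx) {
          sd_c <- if (spec$noise_sd_mode == "matched") {
            stats::sd(eeg[i, s, c, ])
          } else {
            spec$noise_sd
          }
          eeg[i, s, c, ] <- stats::rnorm(d, 0, sd_c)
        }
      }
    }
  })
  dataset[[split]]$eeg <- eeg
  dataset
}

#' Run the channel-perturbation experiment
#'
#' Evaluates retrieval accuracy and the toy Frechet distance (between
#' prior-refined EEG embeddings and the true image embeddings of the test
#' set) with and without the perturbation, using identical evaluation seeds,
#' and reports the deltas.
#'
#' @param fit A trained `contrastive_fit`.
#' @param prior A trained `diffusion_prior` (or `NULL` to skip the
#'   Frechet-distance comparison).
#' @param dataset The evaluation `synthetic_dataset`.
#' @param spec A [perturbation_spec()].
#' @param n_way Panel size for retrieval (default 2).
#' @param n_trials Retrieval trials.
#' @param sample_steps,guidance_w Settings for [refine_embeddings()].
#' @param seed Evaluation seed (shared between conditions).
#' @return Object of class `perturbation_report`: `without`, `with`, `delta`
#'   (accuracy and fid), and the spec.
#' @export
run_perturbation_experiment <- function(fit, prior, dataset, spec,
                                        n_way = 2, n_trials = 1000,
                                        sample_steps = NULL, guidance_w = NULL,
                                        seed = 1) {
  if (!inherits(fit, "contrastive_fit")) {
    stop_arg("fit must be a trained contrastive_fit")
  }
  eval_cond <- function(ds) {
    sh <- shared_embeddings(fit, ds, "test")
    labels <- match(sh$meta$image_id, sh$img_meta$image_id)
    acc <- evaluate_nway(sh$eeg, sh$img, labels, n_way = n_way,
                         n_trials = n_trials, seed = derive_seed(seed, "nway"))$accuracy
    truth <- sh$img[labels, , drop = FALSE]
    # identity feature extractor: features are the embeddings themselves.
    # one-stage = raw EEG embeddings; two-stage = prior-refined embeddings
    fid_one <- fid(truth, sh$eeg)$value
    fid_two <- NA_real_
    if (!is.null(prior)) {
      refined <- refine_embeddings(
        prior, sh$eeg,
        steps = if (is.null(sample_steps)) prior$config$sample_steps else sample_steps,
        w = if (is.null(guidance_w)) 2 else guidance_w,
        seed = derive_seed(seed, "refine")
      )
      fid_two <- fid(truth, refined)$value
    }
    list(accuracy = acc, fid = fid_one, fid_two_stage = fid_two)
  }
  base <- eval_cond(dataset)
  pert <- eval_cond(perturb_channels(dataset, spec))
  structure(
    list(without = base, with = pert,
         delta = list(accuracy = pert$accuracy - base$accuracy,
                      fid = pert$fid - base$fid,
                      fid_two_stage = pert$fid_two_stage - base$fid_two_stage),
         spec = spec, n_way = n_way),
    class = "perturbation_report"
  )
}

#' @export
print.perturbation_report <- function(x, ...) {
  cat(sprintf(
    paste0("Channel perturbation (%s):\n",
           "  %d-way accuracy: %.3f -> %.3f (delta %+.3f)\n",
           "  Frechet distance (one-stage): %.3f -> %.3f (delta %+.3f)\n"),
    if (length(x$spec$channels)) paste(x$spec$channels, collapse = ", ") else "no channels",
    x$n_way, x$without$accuracy, x$with$accuracy, x$delta$accuracy,
    x$without$fid, x$with$fid, x$delta$fid
  ))
  if (!is.na(x$delta$fid_two_stage)) {
    cat(sprintf("  Frechet distance (two-stage): %.3f -> %.3f (delta %+.3f)\n",
                x$without$fid_two_stage, x$with$fid_two_stage,
                x$delta$fid_two_stage))
  }
  invisible(x)
}
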