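# Synthetic RSVP-style EEG / image-embedding generator.
#
# The generator mirrors the structure of large visual-EEG benchmarks: a bank
# of stimulus categories with unit-norm concept vectors in image-embedding
# space, a disjoint train/test category split (zero-shot structure), several
# exemplar images per training category and a single image per test category,
# per-subject trials averaged over repetitions, and a linear forward model
# that concentrates stimulus-related signal on the posterior channels.

#' Create a concept bank
#'
#' Draws `K` unit-norm concept vectors in image-embedding space, organised
#' into `n_clusters` semantic clusters (cluster mates share broad tags in
#' [make_tag_cards()]), and flags `n_test` categories as held-out test
#' categories. Train and test category sets are disjoint by construction.
#'
#' @param K Number of stimulus categories (>= 2).
#' @param D_img Image-embedding dimension (>= 2).
#' @param n_test Number of held-out test categories, `0 < n_test < K`.
#' @param seed Integer seed; the bank is a pure function of its arguments.
#' @param n_clusters Number of semantic clusters, capped at `K`.
#' @param cluster_spread Within-cluster dispersion before renormalisation.
#' @return An object of class `concept_bank` with fields `concepts`
#'   (`K x D_img`, unit rows), `category_ids`, `split` (factor train/test)
#'   and `cluster`.
#' @examples
#' bank <- make_concept_bank(K = 20, D_img = 8, n_test = 5, seed = 1)
#' table(bank$split)
#' @export
make_concept_bank <- function(K, D_img, n_test, seed,
                              n_clusters = 8, cluster_spread = 0.6) {
  if (K < 2) stop_arg("K must be >= 2")
  if (D_img < 2) stop_arg("D_img must be >= 2")
  if (n_test <= 0 || n_test >= K) stop_arg("need 0 < n_test < K")
  n_clusters <- min(n_clusters, K)
  with_seed(seed, {
    centroids <- unit_rows(matrix(stats::rnorm(n_clusters * D_img), n_clusters))
    cluster <- rep_len(seq_len(n_clusters), K)
    concepts <- centroids[cluster, , drop = FALSE] +
      cluster_spread * matrix(stats::rnorm(K * D_img), K)
    concepts <- unit_rows(concepts)
    test_ids <- sort(sample.int(K, n_test))
  })
  split <- factor(ifelse(seq_len(K) %in% test_ids, "test", "train"),
                  levels = c("train", "test"))
  structure(
    list(concepts = concepts, category_ids = seq_len(K), split = split,
         cluster = cluster, D_img = D_img, seed = seed),
    class = "concept_bank"
  )
}

#' @export
print.concept_bank <- function(x, ...) {
  cat(sprintf(
    "Concept bank: %d categories (%d train / %d test), D_img = %d, %d clusters\n",
    length(x$category_ids), sum(x$split == "train"), sum(x$split == "test"),
    x$D_img, length(unique(x$cluster))
  ))
  invisible(x)
}

#' Linear EEG forward model
#'
#' Defines how a concept vector maps to a channels-by-time EEG trial:
#' the concept is projected to `r` source coefficients through a fixed random
#' matrix, sources are mixed into channels through unit-norm spatial loadings
#' and emitted along a unit-norm smooth temporal basis, and the six posterior
#' channels are multiplied by `posterior_boost` before i.i.d. Gaussian sensor
#' noise is added. With unit-norm loadings the expected signal power of a
#' posterior channel is exactly `posterior_boost^2` times that of any other
#' channel.
#'
#' @param channel_names Montage names (must contain the posterior six).
#' @param d Samples per trial.
#' @param D_img Image-embedding dimension of the concept bank it will serve.
#' @param r Number of latent sources.
#' @param posterior_boost Multiplicative gain (>= 1) on posterior channels.
#' @param noise_sd Sensor-noise standard deviation (>= 0).
#' @param sampling_rate Sampling rate in Hz (reference: 250 Hz, 0-1000 ms).
#' @param seed Integer seed fixing loadings, basis and projection.
#' @return An object of class `forward_model`.
#' @export
make_forward_model <- function(channel_names, d, D_img, r = 8,
                               posterior_boost = 4, noise_sd = 1,
                               sampling_rate = d, seed = 1) {
  e <- length(channel_names)
  if (!all(posterior_channels() %in% channel_names)) {
    stop_arg("channel_names must include the six posterior channels")
  }
  if (posterior_boost < 1) stop_arg("posterior_boost must be >= 1")
  if (noise_sd < 0) stop_arg("noise_sd must be >= 0")
  with_seed(seed, {
    spatial <- unit_rows(matrix(stats::rnorm(e * r), e))
    # smooth random temporal waveforms, one per source, unit norm
    tt <- seq(0, 1, length.out = d)
    temporal <- t(vapply(seq_len(r), function(i) {
      w <- sin(2 * pi * stats::runif(1, 1, 8) * tt + stats::runif(1, 0, 2 * pi)) *
        exp(-((tt - stats::runif(1, 0.2, 0.8))^2) / 0.08)
      w / sqrt(sum(w^2))
    }, numeric(d)))
    proj <- matrix(stats::rnorm(r * D_img), r)
  })
  gain <- ifelse(channel_names %in% posterior_channels(), posterior_boost, 1)
  structure(
    list(channel_names = channel_names, d = d, r = r, D_img = D_img,
         spatial_loadings = spatial, temporal_basis = temporal, proj = proj,
         posterior_boost = posterior_boost, channel_gain = gain,
         noise_sd = noise_sd, sampling_rate = sampling_rate, seed = seed),
    class = "forward_model"
  )
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf(
    "EEG forward model: %d channels x %d samples (%g Hz), %d sources, posterior boost %g, noise SD %g\n",
    length(x$channel_names), x$d, x$sampling_rate, x$r, x$posterior_boost, x$noise_sd
  ))
  invisible(x)
}

#' Sample a noisy image embedding for a category
#'
#' Returns `normalize(concept + sigma_img * eta / sqrt(D))` with
#' standard-normal `eta`, the synthetic stand-in for an image encoder applied
#' to one exemplar image of the category. The `1/sqrt(D)` scaling makes
#' `sigma_img` the expected Euclidean norm of the perturbation regardless of
#' the embedding dimension.
#'
#' @param bank A [make_concept_bank()] object.
#' @param category_id Category whose concept to perturb.
#' @param sigma_img Exemplar noise scale (>= 0).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Unit-norm numeric vector of length `D_img`.
#' @export
sample_image_embedding <- function(bank, category_id, sigma_img = 0.1, seed = NULL) {
  if (sigma_img < 0) stop_arg("sigma_img must be >= 0")
  if (!category_id %in% bank$category_ids) {
    stop_arg("unknown category_id: ", category_id)
  }
  D <- ncol(bank$concepts)
  v <- with_seed(seed, {
    bank$concepts[category_id, ] + sigma_img / sqrt(D) * stats::rnorm(D)
  })
  v / sqrt(sum(v^2))
}

new_eeg_trial <- function(data, channel_names, sampling_rate, subject_id,
                          category_id, image_id, n_repetitions_averaged = 1L) {
  stopifnot(nrow(data) == length(channel_names))
  structure(
    list(data = data, channel_names = channel_names,
         sampling_rate = sampling_rate, subject_id = subject_id,
         category_id = category_id, image_id = image_id,
         n_repetitions_averaged = as.integer(n_repetitions_averaged)),
    class = "eeg_trial"
  )
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf(
    "EEG trial: %d channels x %d samples, subject %d, category %d, image %d (%d repetition%s averaged)\n",
    nrow(x$data), ncol(x$data), x$subject_id, x$category_id, x$image_id,
    x$n_repetitions_averaged, if (x$n_repetitions_averaged == 1L) "" else "s"
  ))
  invisible(x)
}

#' Sample one EEG trial for a category
#'
#' Generates `data = diag(gain) . spatial_loadings . diag(proj %*% concept) .
#' temporal_basis + noise_sd * N(0,1)`, the forward model's linear image of
#' the concept plus sensor noise.
#'
#' @param bank Concept bank.
#' @param category_id Category of the presented stimulus.
#' @param fm A [make_forward_model()] object (must match `bank$D_img`).
#' @param subject_id Integer subject label.
#' @param image_id Integer image label.
#' @param seed Optional seed for the sensor noise.
#' @return An `eeg_trial` object (`channels x time`).
#' @export
sample_eeg_trial <- function(bank, category_id, fm, subject_id = 1L,
                             image_id = category_id, seed = NULL) {
  if (fm$D_img != ncol(bank$concepts)) {
    stop_arg("forward model D_img (", fm$D_img, ") does not match bank (",
             ncol(bank$concepts), ")")
  }
  if (!category_id %in% bank$category_ids) {
    stop_arg("unknown category_id: ", category_id)
  }
  concept <- bank$concepts[category_id, ]
  coef <- drop(fm$proj %*% concept)
  signal <- (fm$channel_gain * fm$spatial_loadings) %*%
    (coef * fm$temporal_basis)
  e <- nrow(signal)
  d <- ncol(signal)
  data <- signal
  if (fm$noise_sd > 0) {
    data <- data + with_seed(seed, fm$noise_sd * matrix(stats::rnorm(e * d), e))
  }
  new_eeg_trial(data, fm$channel_names, fm$sampling_rate, subject_id,
                category_id, image_id)
}

#' Average repeated presentations of one image
#'
#' Element-wise mean of trials recorded for the same image and subject;
#' `n_repetitions_averaged` accumulates the inputs' counts. Averaging R
#' independent-noise repetitions shrinks the noise SD by `1/sqrt(R)`.
#'
#' @param trials List of `eeg_trial` objects with identical shape, montage,
#'   subject and image.
#' @return A single averaged `eeg_trial`.
#' @export
average_repetitions <- function(trials) {
  if (length(trials) == 0L) stop_arg("no trials to average")
  ref <- trials[[1L]]
  for (tr in trials[-1L]) {
    ok <- identical(dim(tr$data), dim(ref$data)) &&
      identical(tr$channel_names, ref$channel_names) &&
      identical(tr$subject_id, ref$subject_id) &&
      identical(tr$image_id, ref$image_id)
    if (!ok) stop_arg("trials differ in shape, montage, subject or image")
  }
  acc <- Reduce(`+`, lapply(trials, `[[`, "data")) / length(trials)
  new_eeg_trial(acc, ref$channel_names, ref$sampling_rate, ref$subject_id,
                ref$category_id, ref$image_id,
                sum(vapply(trials, `[[`, integer(1), "n_repetitions_averaged")))
}

#' Image/category layout of a dataset configuration
#'
#' Pure bookkeeping: enumerates the images implied by a bank and an
#' images-per-training-category count (test categories always contribute a
#' single image), without synthesising any EEG.
#'
#' @param bank Concept bank.
#' @param images_per_train_cat Exemplars per training category (>= 1).
#' @return `data.frame` with columns `image_id`, `category_id`, `split`.
#' @examples
#' bank <- make_concept_bank(20, 8, 5, seed = 1)
#' nrow(dataset_layout(bank, 3))
#' @export
dataset_layout <- function(bank, images_per_train_cat) {
  if (images_per_train_cat < 1) stop_arg("images_per_train_cat must be >= 1")
  train_cats <- bank$category_ids[bank$split == "train"]
  test_cats <- bank$category_ids[bank$split == "test"]
  if (length(test_cats) == 0L) stop_arg("bank has no test categories")
  cat_col <- c(rep(train_cats, each = images_per_train_cat), test_cats)
  data.frame(
    image_id = seq_along(cat_col),
    category_id = cat_col,
    split = c(rep("train", length(train_cats) * images_per_train_cat),
              rep("test", length(test_cats))),
    stringsAsFactors = FALSE
  )
}

#' Assemble a synthetic EEG / image-embedding dataset
#'
#' Builds the full paired dataset: for every image, one noisy image embedding
#' and, per subject, one EEG trial averaged over `reps` independent
#' repetitions. Train and test categories are disjoint (zero-shot structure).
#' The scaled default configuration (100 train categories x 3 images, 20 test
#' categories, 2 subjects, 4 repetitions) runs in seconds.
#'
#' @param bank Concept bank.
#' @param fm Forward model.
#' @param images_per_train_cat Exemplars per training category.
#' @param reps Repetitions averaged per image and subject.
#' @param n_subjects Number of subjects.
#' @param sigma_img Exemplar noise for image embeddings.
#' @param seed Integer seed; the dataset is a pure function of its arguments.
#' @return An object of class `synthetic_dataset` with components `train` and
#'   `test`, each holding `meta` (layout data frame), `embeddings`
#'   (`n x D_img`) and `eeg` (array `n x n_subjects x e x d`), plus the bank,
#'   forward model and configuration.
#' @export
assemble_dataset <- function(bank, fm, images_per_train_cat = 3, reps = 4,
                             n_subjects = 2, sigma_img = 0.1, seed = 1) {
  if (reps < 1) stop_arg("reps must be >= 1")
  if (n_subjects < 1) stop_arg("n_subjects must be >= 1")
  layout <- dataset_layout(bank, images_per_train_cat)
  e <- length(fm$channel_names)
  d <- fm$d

  build_split <- function(split_name) {
    meta <- layout[layout$split == split_name, , drop = FALSE]
    n <- nrow(meta)
    emb <- matrix(0, n, bank$D_img)
    eeg <- array(0, c(n, n_subjects, e, d))
    for (i in seq_len(n)) {
      img <- meta$image_id[i]
      cat_id <- meta$category_id[i]
      emb[i, ] <- sample_image_embedding(
        bank, cat_id, sigma_img,
        seed = derive_seed(seed, paste0("img", img))
      )
      for (s in seq_len(n_subjects)) {
        trs <- lapply(seq_len(reps), function(rr) {
          sample_eeg_trial(bank, cat_id, fm, subject_id = s, image_id = img,
                           seed = derive_seed(seed, paste0("eeg", img, "_", s, "_", rr)))
        })
        eeg[i, s, , ] <- average_repetitions(trs)$data
      }
    }
    rownames(meta) <- NULL
    list(meta = meta, embeddings = emb, eeg = eeg)
  }

  structure(
    list(
      train = build_split("train"),
      test = build_split("test"),
      bank = bank, fm = fm,
      config = list(images_per_train_cat = images_per_train_cat, reps = reps,
                    n_subjects = n_subjects, sigma_img = sigma_img, seed = seed)
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    paste0("Synthetic EEG/image dataset: %d train + %d test images, ",
           "%d subjects, %d channels x %d samples, reps = %d\n"),
    nrow(x$train$meta), nrow(x$test$meta), x$config$n_subjects,
    length(x$fm$channel_names), x$fm$d, x$config$reps
  ))
  invisible(x)
}

#' Default scaled dataset
#'
#' Convenience constructor for the package's scaled study conditions:
#' 100 training categories x 3 images, 20 test categories, 2 subjects,
#' 4 repetitions, 17-channel montage, 50 samples per trial, D_img = 16.
#'
#' @param seed Integer seed.
#' @param noise_sd Sensor-noise SD (0 gives the noiseless high-SNR variant).
#' @param posterior_boost Posterior-channel gain.
#' @param n_channels,d,D_img Optional size overrides.
#' @return A `synthetic_dataset`.
#' @export
default_dataset <- function(seed = 1, noise_sd = 1, posterior_boost = 4,
                            n_channels = 17, d = 50, D_img = 16) {
  bank <- make_concept_bank(K = 120, D_img = D_img, n_test = 20,
                            seed = derive_seed(seed, "bank"))
  fm <- make_forward_model(montage_1010(n_channels), d = d, D_img = D_img,
                           posterior_boost = posterior_boost,
                           noise_sd = noise_sd, sampling_rate = d,
                           seed = derive_seed(seed, "fm"))
  assemble_dataset(bank, fm, images_per_train_cat = 3, reps = 4,
                   n_subjects = 2, seed = derive_seed(seed, "data"))
}
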