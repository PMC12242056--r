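# Two-stage pipeline orchestration: simulate -> train encoder -> retrieval
# -> train prior -> refine embeddings -> toy generation -> CAT / Frechet
# metrics -> optional channel perturbation, with a manifest of all outputs.

default_run_config <- function() {
  list(
    dataset = list(seed = 1, noise_sd = 1, posterior_boost = 4,
                   n_channels = 17, d = 50, D_img = 16),
    encoder = list(conv_feature_maps = 20, temporal_kernel = 9,
                   intermediate_dim = 140, embed_dim = 64,
                   n_heads_self = 5, n_heads_channel_attn = 1,
                   n_heads_cross = 4, dropout_p = 0.1),
    training = list(epochs = 60, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                    batch_size = 64, augment_sd = 0.3),
    prior = list(n_layers = 6, width = 128, T = 1000, cond_dropout_p = 0.10,
                 guidance_w = 3.5, sample_steps = 50, train_steps = 1500,
                 lr = 3e-3),
    evaluation = list(n_ways = c(2, 4, 10), n_trials = 1000, top_k = 1),
    perturbation = list(enabled = TRUE, channels = posterior_channels()),
    seed = 1
  )
}

validate_run_config <- function(config) {
  ref <- default_run_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) {
    stop_arg("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in names(config)) {
    if (is.list(ref[[sec]]) && is.list(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
      if (length(bad)) {
        stop_arg("unknown key(s) in config$", sec, ": ",
                 paste(bad, collapse = ", "))
      }
    }
  }
  out <- ref
  for (sec in names(config)) {
    if (is.list(ref[[sec]])) {
      out[[sec]][names(config[[sec]])] <- config[[sec]]
    } else {
      out[[sec]] <- config[[sec]]
    }
  }
  n_test <- 20 # scaled default bank
  if (any(out$evaluation$n_ways > n_test)) {
    stop_arg("evaluation n_way (max ", max(out$evaluation$n_ways),
             ") exceeds the number of test categories (", n_test, ")")
  }
  out
}

#' Run the full two-stage pipeline
#'
#' Executes: dataset simulation, contrastive encoder training, zero-shot
#' retrieval evaluation, diffusion-prior training, one-stage (raw EEG
#' embeddings) and two-stage (prior-refined) toy generation, CAT and Frechet
#' scoring, and optionally the posterior-channel perturbation experiment.
#' Every output file is listed, with its MD5 hash, in `manifest.json`.
#'
#' @param config Nested configuration list (see the vignette), a YAML file
#'   path, or `NULL` for the scaled defaults. Unknown keys are rejected
#'   before any compute.
#' @param out_dir Output directory.
#' @return The manifest, invisibly.
#' @export
run_two_stage <- function(config = NULL, out_dir = tempfile("run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  cfg <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, stages = list(), files = list())
  persist <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  add_file <- function(name, path) {
    manifest$files[[name]] <<- list(
      path = basename(path),
      md5 = unname(tools::md5sum(path))
    )
  }
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- paste("failed:", conditionMessage(e))
      persist()
      stop_arg("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    manifest$stages[[name]] <<- "ok"
    res
  }

  ds <- stage("simulate", function() {
    do.call(default_dataset, cfg$dataset)
  })

  fit <- stage("train_encoder", function() {
    ecfg <- do.call(nerv_config, c(
      list(n_channels = cfg$dataset$n_channels, n_samples = cfg$dataset$d,
           n_subjects = ds$config$n_subjects),
      cfg$encoder
    ))
    enc <- build_encoder(ecfg, seed = cfg$seed)
    f <- do.call(fit_contrastive, c(list(enc = enc, dataset = ds,
                                         seed = cfg$seed), cfg$training))
    hp <- file.path(out_dir, "loss_history.csv")
    utils::write.csv(f$history, hp, row.names = FALSE)
    add_file("loss_history", hp)
    f
  })

  retr <- stage("eval_retrieval", function() {
    r <- retrieval_presets(fit, ds, n_ways = cfg$evaluation$n_ways,
                           n_trials = cfg$evaluation$n_trials, seed = cfg$seed)
    rp <- file.path(out_dir, "retrieval.csv")
    utils::write.csv(r, rp, row.names = FALSE)
    add_file("retrieval", rp)
    r
  })

  sh <- shared_embeddings(fit, ds, "test")
  sh_train <- shared_embeddings(fit, ds, "train")

  prior <- stage("train_prior", function() {
    pcfg <- prior_config(
      embed_dim = ncol(sh_train$img), n_layers = cfg$prior$n_layers,
      width = cfg$prior$width, T = cfg$prior$T,
      cond_dropout_p = cfg$prior$cond_dropout_p,
      guidance_w = cfg$prior$guidance_w, sample_steps = cfg$prior$sample_steps
    )
    pr <- build_prior(pcfg, seed = cfg$seed)
    img_per_subj <- sh_train$img[match(sh_train$meta$image_id,
                                       sh_train$img_meta$image_id), , drop = FALSE]
    train_prior(pr, sh_train$eeg, img_per_subj,
                steps = cfg$prior$train_steps, lr = cfg$prior$lr,
                seed = cfg$seed)
  })

  gen <- stage("generate", function() {
    labels <- match(sh$meta$image_id, sh$img_meta$image_id)
    refined <- refine_embeddings(prior, sh$eeg, seed = derive_seed(cfg$seed, "gen"))
    dec <- toy_decoder(ncol(sh$img), seed = cfg$seed)
    imgs <- lapply(seq_len(nrow(refined)), function(i) {
      toy_generator_and_features(refined[i, ], dec)
    })
    list(one_stage = sh$eeg, two_stage = refined, labels = labels,
         images = imgs)
  })

  stage("score", function() {
    labels <- gen$labels
    target <- sh$img[labels, , drop = FALSE]
    fids <- data.frame(
      stage = c("one_stage", "two_stage"),
      fid = c(fid(target, gen$one_stage)$value,
              fid(target, gen$two_stage)$value)
    )
    # CAT: nearest test image of each refined embedding supplies its tags
    cards <- make_tag_cards(ds$bank, seed = cfg$seed,
                            layout = dataset_layout(ds$bank, ds$config$images_per_train_cat))
    sims <- unit_rows(gen$two_stage) %*% t(unit_rows(sh$img))
    nearest <- apply(sims, 1L, which.max)
    slots <- c("broad_1", "broad_2", "specific", "background", "attribute")
    per_query <- vapply(seq_along(nearest), function(i) {
      pred_card <- cards[match(sh$img_meta$image_id[nearest[i]], cards$image_id), ]
      true_card <- cards[match(sh$meta$image_id[i], cards$image_id), ]
      match_tags(unlist(pred_card[slots], use.names = FALSE),
                 as.list(true_card))
    }, numeric(1))
    # average over subjects so the total is on the 5 * n_images scale
    per_image <- as.integer(round(tapply(per_query, sh$meta$image_id, mean)))
    cat_res <- list(per_image_points = per_image,
                    total = sum(per_image),
                    max_possible = 5L * nrow(sh$img_meta))
    mp <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(list(fid = fids, cat = cat_res), mp,
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    add_file("metrics", mp)
    list(fid = fids, cat = cat_res)
  })

  if (isTRUE(cfg$perturbation$enabled)) {
    stage("perturb", function() {
      rep <- run_perturbation_experiment(
        fit, prior, ds, perturbation_spec(channels = cfg$perturbation$channels,
                                          seed = derive_seed(cfg$seed, "pert")),
        n_way = min(cfg$evaluation$n_ways),
        n_trials = cfg$evaluation$n_trials, seed = cfg$seed
      )
      pp <- file.path(out_dir, "perturbation.json")
      write_report_json(rep, pp)
      add_file("perturbation", pp)
      rep
    })
  }

  persist()
  invisible(manifest)
}
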