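# Convolution-plus-attention EEG encoder.
#
# Pipeline (per batch of channels x time trials):
#   sinusoidal time encoding -> transformer block over the channel axis
#   (channel attention) -> two parallel factorized conv branches (per-map
#   spatial pattern + temporal kernel, average-pooled over time) -> fused
#   token sequence with a second sinusoidal position encoding -> multi-head
#   self-attention block -> cross-attention of a learned class token over the
#   sequence, added back residually -> flatten -> fully connected layer
#   (the "intermediate" representation, 1440-D at the reference
#   configuration) -> per-subject linear map (identity-initialized) ->
#   residual GELU projection head into the final embedding space (1024-D at
#   the reference configuration).

#' Encoder configuration
#'
#' @param n_channels Number of EEG channels `e` (reference: 64).
#' @param n_samples Samples per trial `d` (reference: 250, i.e. 0-1000 ms at
#'   250 Hz).
#' @param conv_feature_maps Feature maps per conv branch, also the attention
#'   width of the fused sequence (default 40).
#' @param temporal_kernel Temporal kernel length (default 25, "valid"
#'   convolution).
#' @param pool_stride Average-pooling stride; `NULL` solves the stride so the
#'   flattened sequence hits `intermediate_dim` exactly.
#' @param n_heads_self Heads of the self-attention block (default 5).
#' @param n_heads_channel_attn Heads of the channel-attention transformer
#'   (default 1).
#' @param n_heads_cross Heads of the class-token cross-attention (default 8).
#' @param intermediate_dim Flattened width entering the fully connected
#'   layer (reference: 1440).
#' @param embed_dim Final embedding width (reference: 1024).
#' @param dropout_p Dropout probability in the projection head (default 0.1).
#' @param n_subjects Number of per-subject linear maps.
#' @return A `nerv_config` list of validated settings.
#' @export
nerv_config <- function(n_channels = 64, n_samples = 250,
                        conv_feature_maps = 40, temporal_kernel = 25,
                        pool_stride = NULL, n_heads_self = 5,
                        n_heads_channel_attn = 1, n_heads_cross = 8,
                        intermediate_dim = 1440, embed_dim = 1024,
                        dropout_p = 0.1, n_subjects = 1) {
  cfg <- list(
    n_channels = as.integer(n_channels), n_samples = as.integer(n_samples),
    conv_feature_maps = as.integer(conv_feature_maps),
    temporal_kernel = as.integer(temporal_kernel),
    pool_stride = if (is.null(pool_stride)) NULL else as.integer(pool_stride),
    n_heads_self = as.integer(n_heads_self),
    n_heads_channel_attn = as.integer(n_heads_channel_attn),
    n_heads_cross = as.integer(n_heads_cross),
    intermediate_dim = as.integer(intermediate_dim),
    embed_dim = as.integer(embed_dim),
    dropout_p = dropout_p, n_subjects = as.integer(n_subjects)
  )
  class(cfg) <- "nerv_config"
  cfg
}

# derive sequence length / pooling geometry; fail loudly naming the stage
solve_encoder_dims <- function(cfg) {
  F <- cfg$conv_feature_maps
  d <- cfg$n_samples
  k <- cfg$temporal_kernel
  if (k >= d) stop_arg("temporal conv: kernel (", k, ") must be < n_samples (", d, ")")
  dp <- d - k + 1L
  if (cfg$intermediate_dim %% F != 0L) {
    stop_arg("flatten stage: intermediate_dim (", cfg$intermediate_dim,
             ") is not a multiple of conv_feature_maps (", F, ")")
  }
  L <- cfg$intermediate_dim %/% F
  s <- if (is.null(cfg$pool_stride)) max(1L, dp %/% L) else cfg$pool_stride
  w <- dp - (L - 1L) * s
  if (L > dp || s < 1L || w < 1L || w > dp) {
    stop_arg("pooling stage: cannot reach a length-", L, " sequence from ",
             dp, " conv outputs (stride ", s, "); intermediate_dim ",
             cfg$intermediate_dim, " is unreachable")
  }
  C <- F
  if (C %% cfg$n_heads_self != 0L) {
    stop_arg("self-attention stage: width ", C, " not divisible by ",
             cfg$n_heads_self, " heads")
  }
  if (C %% cfg$n_heads_cross != 0L) {
    stop_arg("cross-attention stage: width ", C, " not divisible by ",
             cfg$n_heads_cross, " heads")
  }
  if (d %% cfg$n_heads_channel_attn != 0L) {
    stop_arg("channel-attention stage: width ", d, " not divisible by ",
             cfg$n_heads_channel_attn, " heads")
  }
  list(d_conv = dp, seq_len = L, pool_stride = s, pool_window = w, width = C)
}

init_w <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(fan_in)), nr, nc)
}

# parameters of one pre-LN transformer encoder block
init_block <- function(width, n_heads, prefix) {
  hd <- width %/% n_heads
  p <- list()
  p[[paste0(prefix, ".ln1_g")]] <- rep(1, width)
  p[[paste0(prefix, ".ln1_b")]] <- rep(0, width)
  for (h in seq_len(n_heads)) {
    p[[paste0(prefix, ".Wq", h)]] <- init_w(width, hd)
    p[[paste0(prefix, ".Wk", h)]] <- init_w(width, hd)
    p[[paste0(prefix, ".Wv", h)]] <- init_w(width, hd)
  }
  p[[paste0(prefix, ".Wo")]] <- init_w(width, width)
  p[[paste0(prefix, ".bo")]] <- rep(0, width)
  p[[paste0(prefix, ".ln2_g")]] <- rep(1, width)
  p[[paste0(prefix, ".ln2_b")]] <- rep(0, width)
  p[[paste0(prefix, ".ffn_W1")]] <- init_w(width, 2L * width)
  p[[paste0(prefix, ".ffn_b1")]] <- rep(0, 2L * width)
  p[[paste0(prefix, ".ffn_W2")]] <- init_w(2L * width, width)
  p[[paste0(prefix, ".ffn_b2")]] <- rep(0, width)
  p
}

#' Build an EEG encoder
#'
#' Initializes all learnable parameters from `seed` and validates that the
#' convolution / pooling geometry flattens to exactly
#' `config$intermediate_dim` features. The build fails with an error naming
#' the offending stage otherwise.
#'
#' @param config A [nerv_config()].
#' @param seed Integer seed; two builds with the same seed are identical.
#' @return An object of class `eeg_encoder`.
#' @examples
#' enc <- build_encoder(nerv_config(n_channels = 8, n_samples = 40,
#'   conv_feature_maps = 8, temporal_kernel = 7, intermediate_dim = 64,
#'   embed_dim = 32, n_heads_self = 4, n_heads_cross = 4), seed = 1)
#' print(enc)
#' @export
build_encoder <- function(config, seed = 1) {
  stopifnot(inherits(config, "nerv_config"))
  dims <- solve_encoder_dims(config)
  e <- config$n_channels
  d <- config$n_samples
  F <- config$conv_feature_maps
  k <- config$temporal_kernel
  L <- dims$seq_len
  C <- dims$width
  I <- config$intermediate_dim
  E <- config$embed_dim

  params <- with_seed(seed, {
    p <- init_block(d, config$n_heads_channel_attn, "chattn")
    p[["convA.Ws"]] <- init_w(F, e, fan_in = e)
    p[["convA.K"]] <- init_w(F, k, fan_in = k)
    p[["convB.Ws"]] <- init_w(F, e, fan_in = e)
    p[["convB.K"]] <- init_w(F, k, fan_in = k)
    p[["fuse.W"]] <- init_w(2L * F, C)
    p[["fuse.b"]] <- rep(0, C)
    p <- c(p, init_block(C, config$n_heads_self, "sattn"))
    p[["xattn.tok"]] <- matrix(0.02 * stats::rnorm(C), 1L, C)
    hd <- C %/% config$n_heads_cross
    for (h in seq_len(config$n_heads_cross)) {
      p[[paste0("xattn.Wq", h)]] <- init_w(C, hd)
      p[[paste0("xattn.Wk", h)]] <- init_w(C, hd)
      p[[paste0("xattn.Wv", h)]] <- init_w(C, hd)
    }
    p[["xattn.Wo"]] <- init_w(C, C)
    p[["xattn.bo"]] <- rep(0, C)
    p[["fc.W"]] <- init_w(I, I)
    p[["fc.b"]] <- rep(0, I)
    for (s in seq_len(config$n_subjects)) {
      p[[paste0("subj.W", s)]] <- diag(I)
      p[[paste0("subj.b", s)]] <- rep(0, I)
    }
    p[["head.Wp"]] <- init_w(I, E)
    p[["head.bp"]] <- rep(0, E)
    p[["head.W1"]] <- init_w(E, E)
    p[["head.b1"]] <- rep(0, E)
    p[["head.W2"]] <- init_w(E, E)
    p[["head.b2"]] <- rep(0, E)
    p
  })

  consts <- list(
    pe_time = rowMeans(sinusoid_encoding(seq_len(d), 8L)),
    pe_seq = sinusoid_encoding(seq_len(L), C),
    pool = {
      P <- matrix(0, dims$d_conv, L)
      for (l in seq_len(L)) {
        rows <- ((l - 1L) * dims$pool_stride + 1L):
          ((l - 1L) * dims$pool_stride + dims$pool_window)
        P[rows, l] <- 1 / dims$pool_window
      }
      P
    }
  )

  structure(
    list(config = config, dims = dims, params = params, consts = consts,
         seed = seed, format_version = 1L),
    class = "eeg_encoder"
  )
}

#' @export
print.eeg_encoder <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    paste0("EEG encoder: %d ch x %d samples -> %d maps x %d tokens ",
           "-> %d-D intermediate -> %d-D embedding\n",
           "  heads: self %d / channel %d / cross %d; %d subject map%s; ",
           "%s parameters (seed %d)\n"),
    x$config$n_channels, x$config$n_samples, x$config$conv_feature_maps,
    x$dims$seq_len, x$config$intermediate_dim, x$config$embed_dim,
    x$config$n_heads_self, x$config$n_heads_channel_attn,
    x$config$n_heads_cross, x$config$n_subjects,
    if (x$config$n_subjects == 1L) "" else "s",
    format(np, big.mark = ","), x$seed
  ))
  invisible(x)
}

# wrap every parameter array in a tape leaf
make_leaves <- function(params) lapply(params, ag_leaf)

block_params <- function(lv, prefix, n_heads) {
  list(
    Wq = lapply(seq_len(n_heads), function(h) lv[[paste0(prefix, ".Wq", h)]]),
    Wk = lapply(seq_len(n_heads), function(h) lv[[paste0(prefix, ".Wk", h)]]),
    Wv = lapply(seq_len(n_heads), function(h) lv[[paste0(prefix, ".Wv", h)]]),
    Wo = lv[[paste0(prefix, ".Wo")]], bo = lv[[paste0(prefix, ".bo")]]
  )
}

transformer_block <- function(z, lv, prefix, n_heads, B, L) {
  a <- ag_layernorm(z, lv[[paste0(prefix, ".ln1_g")]], lv[[paste0(prefix, ".ln1_b")]])
  z <- ag_add(z, ag_mha(a, a, block_params(lv, prefix, n_heads), B, L, L, n_heads))
  a <- ag_layernorm(z, lv[[paste0(prefix, ".ln2_g")]], lv[[paste0(prefix, ".ln2_b")]])
  h <- ag_gelu(ag_add_bias(ag_matmul(a, lv[[paste0(prefix, ".ffn_W1")]]),
                           lv[[paste0(prefix, ".ffn_b1")]]))
  ag_add(z, ag_add_bias(ag_matmul(h, lv[[paste0(prefix, ".ffn_W2")]]),
                        lv[[paste0(prefix, ".ffn_b2")]]))
}

# batch array (B x e x d) -> channel-major stacked matrix (B*e x d)
batch_to_matrix <- function(batch) {
  if (length(dim(batch)) == 2L) batch <- array(batch, c(1L, dim(batch)))
  B <- dim(batch)[1L]
  e <- dim(batch)[2L]
  d <- dim(batch)[3L]
  list(m = matrix(aperm(batch, c(2L, 1L, 3L)), B * e, d), B = B, e = e, d = d)
}

# builds the tape from input node to (features, embedding); `lv` are leaves
encoder_graph <- function(enc, lv, xnode, B, subject_id = 1L,
                          training = FALSE, dropout_mask = NULL) {
  cfg <- enc$config
  dims <- enc$dims
  e <- cfg$n_channels
  F <- cfg$conv_feature_maps
  L <- dims$seq_len

  z <- ag_add_bias(xnode, ag_const(enc$consts$pe_time))
  z <- transformer_block(z, lv, "chattn", cfg$n_heads_channel_attn, B, e)

  branch <- function(prefix) {
    s <- ag_spatial_mix(z, lv[[paste0(prefix, ".Ws")]], e, B)
    tc <- ag_gelu(ag_temporal_conv(s, lv[[paste0(prefix, ".K")]], F, B))
    pooled <- ag_matmul(tc, ag_const(enc$consts$pool))
    ag_maps_to_seq(pooled, B, F, L)
  }
  seq_z <- ag_add_bias(
    ag_matmul(ag_concat_cols(branch("convA"), branch("convB")), lv[["fuse.W"]]),
    lv[["fuse.b"]]
  )
  seq_z <- ag_add(seq_z, ag_const(enc$consts$pe_seq[rep(seq_len(L), B), , drop = FALSE]))

  seq_z <- transformer_block(seq_z, lv, "sattn", cfg$n_heads_self, B, L)

  tok_rep <- ag_matmul(ag_const(matrix(1, B, 1L)), lv[["xattn.tok"]])
  tok_out <- ag_mha(tok_rep, seq_z, block_params(lv, "xattn", cfg$n_heads_cross),
                    B, 1L, L, cfg$n_heads_cross)
  seq_z <- ag_add_rowrep(seq_z, tok_out, B, L)

  flat <- ag_flatten_seq(seq_z, B, L)
  feats <- ag_add_bias(ag_matmul(flat, lv[["fc.W"]]), lv[["fc.b"]])

  if (subject_id < 1L || subject_id > cfg$n_subjects) {
    stop_arg("unknown subject_id ", subject_id, " (encoder has ",
             cfg$n_subjects, ")")
  }
  sfeats <- ag_add_bias(ag_matmul(feats, lv[[paste0("subj.W", subject_id)]]),
                        lv[[paste0("subj.b", subject_id)]])

  emb0 <- ag_add_bias(ag_matmul(sfeats, lv[["head.Wp"]]), lv[["head.bp"]])
  h <- ag_gelu(ag_add_bias(ag_matmul(emb0, lv[["head.W1"]]), lv[["head.b1"]]))
  if (training && cfg$dropout_p > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(
        stats::rbinom(length(h$v), 1L, 1 - cfg$dropout_p) / (1 - cfg$dropout_p),
        nrow(h$v), ncol(h$v)
      )
    }
    h <- ag_mul(h, ag_const(dropout_mask))
  }
  emb <- ag_add(emb0, ag_add_bias(ag_matmul(h, lv[["head.W2"]]), lv[["head.b2"]]))

  list(features = feats, embedding = emb)
}

check_batch <- function(enc, batch) {
  bm <- batch_to_matrix(batch)
  if (bm$e != enc$config$n_channels || bm$d != enc$config$n_samples) {
    stop_arg("batch shape (", bm$e, " x ", bm$d, ") does not match encoder (",
             enc$config$n_channels, " x ", enc$config$n_samples, ")")
  }
  assert_finite(bm$m, "EEG batch")
  bm
}

#' Intermediate features of a batch
#'
#' Runs the encoder up to (and including) the fully connected layer, i.e.
#' before the subject map and projection head.
#'
#' @param enc An [build_encoder()] object.
#' @param batch Array `B x e x d` (a single `e x d` matrix is promoted).
#' @return Matrix `B x intermediate_dim`.
#' @export
forward_features <- function(enc, batch) {
  bm <- check_batch(enc, batch)
  ag_tape_start()
  lv <- make_leaves(enc$params)
  out <- encoder_graph(enc, lv, ag_const(bm$m), bm$B)
  out$features$v
}

#' Per-subject linear transform of intermediate features
#'
#' @param enc Encoder.
#' @param features Matrix `B x intermediate_dim`.
#' @param subject_id Subject index in `1..n_subjects`.
#' @return Matrix of the same shape. At initialization the map is the
#'   identity, so untrained subjects are interchangeable.
#' @export
subject_transform <- function(enc, features, subject_id) {
  if (subject_id < 1L || subject_id > enc$config$n_subjects) {
    stop_arg("unknown subject_id ", subject_id, " (encoder has ",
             enc$config$n_subjects, ")")
  }
  sweep(features %*% enc$params[[paste0("subj.W", subject_id)]], 2L,
        enc$params[[paste0("subj.b", subject_id)]], `+`)
}

#' Encode a batch of EEG trials
#'
#' Full forward pass to the final embedding space. Evaluation mode
#' (`training = FALSE`, the default) is deterministic; dropout is only active
#' in training mode.
#'
#' @param enc Encoder.
#' @param batch Array `B x e x d`.
#' @param subject_id Subject index.
#' @param training Apply dropout in the projection head?
#' @param seed Seed for the dropout mask when training.
#' @return Matrix `B x embed_dim` of finite embeddings.
#' @export
encode_batch <- function(enc, batch, subject_id = 1L, training = FALSE,
                         seed = NULL) {
  bm <- check_batch(enc, batch)
  ag_tape_start()
  lv <- make_leaves(enc$params)
  out <- with_seed(seed, {
    encoder_graph(enc, lv, ag_const(bm$m), bm$B, subject_id = subject_id,
                  training = training)
  })
  out$embedding$v
}

#' Save / load an encoder checkpoint
#'
#' Single-file archive holding parameters, configuration, seed and a format
#' version; the round trip is lossless.
#'
#' @param enc Encoder.
#' @param path File path.
#' @return `load_encoder` returns the restored `eeg_encoder`.
#' @export
save_encoder <- function(enc, path) {
  saveRDS(list(format_version = enc$format_version, config = enc$config,
               seed = enc$seed, params = enc$params), path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  x <- readRDS(path)
  if (is.null(x$format_version) || x$format_version != 1L) {
    stop_arg("unsupported encoder checkpoint format")
  }
  enc <- build_encoder(x$config, seed = x$seed)
  enc$params <- x$params
  enc
}
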