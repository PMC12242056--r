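# shared fixtures: everything is generated in code at test time

# micro encoder configuration used by shape/gradient tests
micro_config <- function(...) {
  args <- list(n_channels = 4, n_samples = 12, conv_feature_maps = 2,
               temporal_kernel = 3, intermediate_dim = 6, embed_dim = 4,
               n_heads_self = 2, n_heads_channel_attn = 1, n_heads_cross = 2,
               n_subjects = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(nerv_config, args)
}

# small-but-trainable encoder matched to the scaled dataset geometry
mini_config <- function(...) {
  args <- list(n_channels = 17, n_samples = 50, conv_feature_maps = 20,
               temporal_kernel = 9, intermediate_dim = 140, embed_dim = 64,
               n_heads_self = 5, n_heads_channel_attn = 1, n_heads_cross = 4,
               n_subjects = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(nerv_config, args)
}

tiny_bank <- function(K = 12, D = 8, n_test = 4, seed = 42) {
  make_concept_bank(K, D, n_test, seed = seed)
}

tiny_fm <- function(bank, n_channels = 9, d = 20, noise_sd = 0.5,
                    posterior_boost = 2, seed = 7) {
  make_forward_model(montage_1010(n_channels), d = d, D_img = bank$D_img,
                     posterior_boost = posterior_boost, noise_sd = noise_sd,
                     seed = seed)
}

tiny_dataset <- function(seed = 3, noise_sd = 0.5) {
  bank <- tiny_bank()
  fm <- tiny_fm(bank, noise_sd = noise_sd)
  assemble_dataset(bank, fm, images_per_train_cat = 2, reps = 2,
                   n_subjects = 2, seed = seed)
}

# central-difference gradient of f at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x
    xp[i] <- xp[i] + eps
    xm <- x
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# analytic-vs-numeric relative error for a scalar-valued tape builder whose
# single argument is the leaf value
gradcheck <- function(make_loss, x0, tol = 1e-5) {
  fval <- function(x) {
    eegdecode:::ag_tape_start()
    make_loss(eegdecode:::ag_leaf(x))$v
  }
  eegdecode:::ag_tape_start()
  leaf <- eegdecode:::ag_leaf(x0)
  loss <- make_loss(leaf)
  eegdecode:::ag_backward(loss)
  ga <- eegdecode:::ag_grad(leaf)
  gn <- num_grad(fval, x0)
  max(abs(ga - gn)) / max(1e-8, max(abs(gn)))
}
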