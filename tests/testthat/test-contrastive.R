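test_that("scaled similarity matches its closed form", {
  E <- diag(3)
  S0 <- scaled_similarity(E, E, 0)
  expect_equal(diag(S0), rep(1, 3))
  expect_equal(S0[1, 2], 0) # orthogonal unit rows
  S <- scaled_similarity(E, E, log(1 / 0.07))
  expect_equal(diag(S), rep(1 / 0.07, 3), tolerance = 1e-12)
  expect_error(scaled_similarity(rbind(c(0, 0)), rbind(c(1, 0))), "zero-norm")
})

test_that("InfoNCE identities hold: uniform, saturated and the 2x2 hand case", {
  for (B in c(2, 3, 7)) {
    expect_equal(info_nce_loss(matrix(1, B, B)), log(B), tolerance = 1e-12)
  }
  expect_lt(info_nce_loss(100 * diag(4)), 1e-10)
  # hand-computed softmax cross-entropy for [[1,0],[0,1]]
  expect_equal(info_nce_loss(diag(2)), log(1 + exp(-1)), tolerance = 1e-12)
  expect_equal(log(1 + exp(-1)), 0.3133, tolerance = 1e-3)
  expect_error(info_nce_loss(matrix(0, 2, 3)), "square")
})

test_that("InfoNCE is non-negative and invariant to a common rotation", {
  set.seed(1)
  for (i in 1:10) {
    B <- sample(2:6, 1)
    D <- sample(3:8, 1)
    E <- matrix(rnorm(B * D), B)
    I <- matrix(rnorm(B * D), B)
    l0 <- info_nce_loss(scaled_similarity(E, I, 0.3))
    expect_gte(l0, 0)
    Q <- qr.Q(qr(matrix(rnorm(D * D), D))) # random orthogonal matrix
    l1 <- info_nce_loss(scaled_similarity(E %*% Q, I %*% Q, 0.3))
    expect_equal(l0, l1, tolerance = 1e-10)
  }
})

test_that("epochs = 0 leaves the encoder untouched with an empty history", {
  ds <- tiny_dataset()
  enc <- build_encoder(nerv_config(
    n_channels = 9, n_samples = 20, conv_feature_maps = 4, temporal_kernel = 5,
    intermediate_dim = 12, embed_dim = 8, n_heads_self = 2, n_heads_cross = 2,
    n_subjects = 2
  ), seed = 1)
  fit <- fit_contrastive(enc, ds, epochs = 0, seed = 1)
  expect_identical(fit$encoder$params, enc$params)
  expect_equal(nrow(fit$history), 0L)
})

test_that("training is deterministic given the seed and the loss decreases", {
  ds <- tiny_dataset(noise_sd = 0)
  cfg <- nerv_config(n_channels = 9, n_samples = 20, conv_feature_maps = 4,
                     temporal_kernel = 5, intermediate_dim = 12, embed_dim = 8,
                     n_heads_self = 2, n_heads_cross = 2, n_subjects = 2)
  f1 <- fit_contrastive(build_encoder(cfg, 1), ds, epochs = 5, batch_size = 24, seed = 3)
  f2 <- fit_contrastive(build_encoder(cfg, 1), ds, epochs = 5, batch_size = 24, seed = 3)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$encoder$params, f2$encoder$params)
  expect_lt(mean(utils::tail(f1$history$loss, 3)),
            mean(utils::head(f1$history$loss, 3)))
  expect_error(fit_contrastive(build_encoder(cfg, 1),
                               list(eeg = NULL, embeddings = NULL)),
               "pairs")
})

test_that("an 8-pair fixture is memorized: 500 steps drive the loss below 0.1", {
  bank <- make_concept_bank(K = 9, D_img = 8, n_test = 1, seed = 5)
  fm <- tiny_fm(bank, noise_sd = 0)
  ds <- assemble_dataset(bank, fm, images_per_train_cat = 1, reps = 1,
                         n_subjects = 1, seed = 5)
  expect_equal(nrow(ds$train$meta), 8L)
  enc <- build_encoder(nerv_config(
    n_channels = 9, n_samples = 20, conv_feature_maps = 4, temporal_kernel = 5,
    intermediate_dim = 12, embed_dim = 8, n_heads_self = 2, n_heads_cross = 2,
    n_subjects = 1
  ), seed = 5)
  fit <- fit_contrastive(enc, ds, epochs = 500, batch_size = 8, lr = 1e-3,
                         augment_sd = 0, seed = 5)
  expect_equal(nrow(fit$history), 500L)
  expect_lt(utils::tail(fit$history$loss, 1), 0.1)
})

test_that("multi-seed training reports per-seed best losses", {
  ds <- tiny_dataset(noise_sd = 0)
  cfg <- nerv_config(n_channels = 9, n_samples = 20, conv_feature_maps = 4,
                     temporal_kernel = 5, intermediate_dim = 12, embed_dim = 8,
                     n_heads_self = 2, n_heads_cross = 2, n_subjects = 2)
  ms <- fit_contrastive_seeds(cfg, ds, seeds = c(1, 2), epochs = 2,
                              batch_size = 24)
  expect_equal(nrow(ms$summary), 2L)
  expect_true(all(ms$summary$best_loss <= ms$summary$final_loss + 1e-12))
  expect_false(identical(ms$fits[[1]]$encoder$params,
                         ms$fits[[2]]$encoder$params))
})
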