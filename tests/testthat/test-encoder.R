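test_that("the reference configuration yields 1440-D features and 1024-D embeddings", {
  enc <- build_encoder(nerv_config(), seed = 1)
  expect_equal(enc$config$intermediate_dim, 1440L)
  expect_equal(enc$dims$seq_len * enc$config$conv_feature_maps, 1440L)
  set.seed(1)
  x <- array(rnorm(64 * 250), c(1, 64, 250))
  ff <- forward_features(enc, x)
  expect_equal(dim(ff), c(1L, 1440L))
  expect_true(all(is.finite(ff)))
  emb <- encode_batch(enc, x)
  expect_equal(dim(emb), c(1L, 1024L))
})

test_that("the build validates geometry and head divisibility, naming the stage", {
  expect_error(build_encoder(nerv_config(intermediate_dim = 999), seed = 1),
               "flatten|pool")
  expect_error(build_encoder(nerv_config(intermediate_dim = 40 * 300), seed = 1),
               "pool")
  expect_error(build_encoder(micro_config(n_heads_self = 4), seed = 1),
               "self-attention")
  expect_error(build_encoder(micro_config(n_heads_cross = 5), seed = 1),
               "cross-attention")
})

test_that("builds are deterministic in the seed", {
  e1 <- build_encoder(micro_config(), seed = 11)
  e2 <- build_encoder(micro_config(), seed = 11)
  expect_identical(e1$params, e2$params)
  e3 <- build_encoder(micro_config(), seed = 12)
  expect_false(identical(e1$params, e3$params))
})

test_that("forward pass honors the shape contract and rejects mismatches", {
  enc <- build_encoder(micro_config(), seed = 2)
  z <- array(0, c(1, 4, 12))
  expect_true(all(is.finite(forward_features(enc, z))))
  x3 <- array(rnorm(3 * 4 * 12), c(3, 4, 12))
  expect_equal(dim(forward_features(enc, x3)), c(3L, 6L))
  expect_equal(dim(encode_batch(enc, x3)), c(3L, 4L))
  expect_error(forward_features(enc, array(0, c(2, 5, 12))), "shape")
  expect_error(forward_features(enc, array(NaN, c(1, 4, 12))), "finite")
})

test_that("permuting input channels changes the features", {
  enc <- build_encoder(micro_config(), seed = 3)
  set.seed(4)
  x <- array(rnorm(4 * 12), c(1, 4, 12))
  xp <- x[, c(2, 1, 4, 3), , drop = FALSE]
  expect_false(isTRUE(all.equal(forward_features(enc, x),
                                forward_features(enc, xp))))
})

test_that("subject transforms start as the identity and behave linearly", {
  enc <- build_encoder(micro_config(), seed = 5)
  f <- matrix(rnorm(2 * 6), 2, 6)
  expect_equal(subject_transform(enc, f, 1), f)
  expect_equal(subject_transform(enc, f, 2), f)
  expect_error(subject_transform(enc, f, 3), "subject")
  enc$params[["subj.W1"]] <- 2 * diag(6)
  expect_equal(subject_transform(enc, f, 1), 2 * f)
})

test_that("evaluation mode is deterministic and dropout_p = 0 matches eval in training mode", {
  enc <- build_encoder(micro_config(), seed = 6)
  x <- array(rnorm(2 * 4 * 12), c(2, 4, 12))
  expect_identical(encode_batch(enc, x), encode_batch(enc, x))

  enc0 <- build_encoder(micro_config(dropout_p = 0), seed = 6)
  expect_equal(encode_batch(enc0, x, training = TRUE, seed = 1),
               encode_batch(enc0, x))
  # with dropout active, training mode differs
  encd <- build_encoder(micro_config(dropout_p = 0.5), seed = 6)
  expect_false(isTRUE(all.equal(encode_batch(encd, x, training = TRUE, seed = 1),
                                encode_batch(encd, x))))
})

test_that("checkpoints round-trip bitwise", {
  enc <- build_encoder(micro_config(), seed = 7)
  enc$params[["fc.b"]][] <- rnorm(6) # make it distinguishable from a fresh build
  path <- tempfile(fileext = ".rds")
  save_encoder(enc, path)
  enc2 <- load_encoder(path)
  expect_identical(enc2$params, enc$params)
  x <- array(rnorm(4 * 12), c(1, 4, 12))
  expect_identical(encode_batch(enc, x), encode_batch(enc2, x))
})

test_that("one optimizer step on a contrastive batch moves every parameter group", {
  ds <- tiny_dataset()
  enc <- build_encoder(nerv_config(
    n_channels = 9, n_samples = 20, conv_feature_maps = 4, temporal_kernel = 5,
    intermediate_dim = 12, embed_dim = 8, n_heads_self = 2, n_heads_cross = 2,
    n_subjects = 2
  ), seed = 8)
  fit <- fit_contrastive(enc, ds, epochs = 1, batch_size = 24, augment_sd = 0,
                         seed = 1)
  moved <- vapply(names(enc$params), function(nm) {
    !identical(fit$encoder$params[[nm]], enc$params[[nm]])
  }, logical(1))
  expect_true(all(moved), info = paste("dead groups:",
                                       paste(names(moved)[!moved], collapse = ", ")))
})
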