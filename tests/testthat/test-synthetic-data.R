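test_that("concept banks have unit rows, disjoint splits and are deterministic", {
  bank <- make_concept_bank(K = 2, D_img = 4, n_test = 1, seed = 0)
  expect_equal(sqrt(rowSums(bank$concepts^2)), c(1, 1), tolerance = 1e-6)
  expect_equal(as.vector(table(bank$split)), c(1L, 1L))

  big <- make_concept_bank(K = 1854, D_img = 16, n_test = 200, seed = 1)
  expect_equal(sum(big$split == "train"), 1654L)
  expect_equal(sum(big$split == "test"), 200L)
  expect_length(intersect(big$category_ids[big$split == "train"],
                          big$category_ids[big$split == "test"]), 0)

  expect_identical(make_concept_bank(30, 8, 5, seed = 7),
                   make_concept_bank(30, 8, 5, seed = 7))
  expect_error(make_concept_bank(5, 8, 5, seed = 1), "n_test")
  expect_error(make_concept_bank(5, 1, 2, seed = 1), "D_img")
})

test_that("image embeddings are unit-norm perturbations of the concept", {
  bank <- tiny_bank(D = 16)
  expect_equal(sample_image_embedding(bank, 3, sigma_img = 0, seed = 1),
               bank$concepts[3, ])
  draws <- t(vapply(seq_len(1000), function(i) {
    sample_image_embedding(bank, 3, sigma_img = 0.1, seed = i)
  }, numeric(16)))
  expect_equal(sqrt(rowSums(draws^2)), rep(1, 1000), tolerance = 1e-6)
  # Monte-Carlo oracle: at sigma = 0.1 in 16-D the mean cosine to the
  # concept stays above 0.99
  expect_gt(mean(draws %*% bank$concepts[3, ]), 0.99)
  expect_error(sample_image_embedding(bank, 999), "category")
})

test_that("EEG trials follow the forward model and posterior boost sets the power ratio", {
  bank <- tiny_bank()
  fm0 <- tiny_fm(bank, noise_sd = 0, posterior_boost = 1)
  tr1 <- sample_eeg_trial(bank, 1, fm0)
  tr2 <- sample_eeg_trial(bank, 1, fm0)
  expect_identical(tr1$data, tr2$data) # noiseless determinism
  tr3 <- sample_eeg_trial(bank, 2, fm0)
  expect_false(identical(tr1$data, tr3$data)) # injectivity at zero noise
  expect_true(all(is.finite(tr1$data)))
  expect_equal(length(tr1$channel_names), nrow(tr1$data))

  # power-ratio oracle: unit-norm loadings make posterior channels carry
  # boost^2 = 16x the signal power of the others, on average over concepts
  fmb <- tiny_fm(bank, noise_sd = 0, posterior_boost = 4, d = 250)
  post <- fmb$channel_names %in% posterior_channels()
  ratios <- vapply(seq_len(1000), function(i) {
    cat_id <- (i %% nrow(bank$concepts)) + 1L
    x <- sample_eeg_trial(bank, cat_id, fmb)$data
    mean(rowMeans(x[post, ]^2)) / mean(rowMeans(x[!post, ]^2))
  }, numeric(1))
  expect_equal(mean(ratios), 16, tolerance = 0.15 * 16)

  bad_bank <- make_concept_bank(4, 5, 1, seed = 1)
  expect_error(sample_eeg_trial(bad_bank, 1, fmb), "D_img")
})

test_that("repetition averaging is the element-wise mean and shrinks noise like 1/sqrt(R)", {
  bank <- tiny_bank()
  fm <- tiny_fm(bank, noise_sd = 0)
  x <- sample_eeg_trial(bank, 1, fm)
  avg <- average_repetitions(list(x, x))
  expect_equal(avg$data, x$data)
  expect_equal(avg$n_repetitions_averaged, 2L)

  z0 <- x
  z0$data[] <- 0
  z2 <- x
  z2$data[] <- 2
  expect_true(all(average_repetitions(list(z0, z2))$data == 1))

  y <- sample_eeg_trial(bank, 2, fm)
  expect_error(average_repetitions(list(x, y)), "differ")

  # Monte-Carlo oracle: R = 4 halves the residual SD (tolerance 20%)
  fmn <- tiny_fm(bank, noise_sd = 1)
  signal <- sample_eeg_trial(bank, 1, tiny_fm(bank, noise_sd = 0))$data
  sds <- vapply(seq_len(200), function(i) {
    reps <- lapply(1:4, function(r) {
      sample_eeg_trial(bank, 1, fmn, seed = i * 10L + r)
    })
    c(stats::sd(reps[[1]]$data - signal),
      stats::sd(average_repetitions(reps)$data - signal))
  }, numeric(2))
  expect_equal(mean(sds[1, ]) / mean(sds[2, ]), 2, tolerance = 0.2)
})

test_that("posterior share of signal variance increases with the boost", {
  bank <- tiny_bank()
  share <- vapply(c(1, 2, 4), function(b) {
    fm <- tiny_fm(bank, noise_sd = 0, posterior_boost = b)
    post <- fm$channel_names %in% posterior_channels()
    x <- sample_eeg_trial(bank, 1, fm)$data
    sum(x[post, ]^2) / sum(x^2)
  }, numeric(1))
  expect_true(all(diff(share) > 0))
})

test_that("dataset assembly matches the layout contract and is deterministic", {
  # reference configuration, counting only
  big <- make_concept_bank(K = 1854, D_img = 4, n_test = 200, seed = 1)
  layout <- dataset_layout(big, images_per_train_cat = 10)
  expect_equal(nrow(layout), 16740L)
  expect_equal(length(unique(layout$image_id)), 16740L)
  expect_equal(sum(layout$split == "test"), 200L)

  bank <- make_concept_bank(K = 25, D_img = 8, n_test = 5, seed = 2)
  fm <- tiny_fm(bank)
  ds <- assemble_dataset(bank, fm, images_per_train_cat = 3, reps = 2,
                         n_subjects = 2, seed = 9)
  expect_equal(nrow(ds$train$meta), 60L) # 20 train cats x 3
  expect_equal(nrow(ds$test$meta), 5L)   # 1 per test cat
  expect_equal(dim(ds$train$eeg), c(60L, 2L, 9L, 20L))
  expect_length(intersect(ds$train$meta$category_id, ds$test$meta$category_id), 0)

  ds2 <- assemble_dataset(bank, fm, images_per_train_cat = 3, reps = 2,
                          n_subjects = 2, seed = 9)
  expect_identical(ds, ds2)

  no_test <- bank
  no_test$split[] <- "train"
  expect_error(dataset_layout(no_test, 3), "test")
})

test_that("tag cards provide 5 normalized tags per test image and cluster mates share broad tags", {
  bank <- make_concept_bank(K = 250, D_img = 8, n_test = 200, seed = 3)
  cards <- make_tag_cards(bank, seed = 1)
  expect_equal(nrow(cards), 200L)
  slots <- c("broad_1", "broad_2", "specific", "background", "attribute")
  vals <- unlist(cards[slots])
  expect_equal(length(vals), 1000L) # 200 images x 5 tags
  expect_true(all(nzchar(vals)))
  expect_identical(vals, tolower(vals))

  meta <- dataset_layout(bank, 1)
  test_meta <- meta[meta$split == "test", ]
  cl <- bank$cluster[test_meta$category_id]
  expect_true(all(tapply(cards$broad_1, cl, function(x) length(unique(x))) == 1))

  one <- make_concept_bank(K = 8, D_img = 4, n_test = 1, seed = 4)
  c1 <- make_tag_cards(one, seed = 1)
  expect_equal(nrow(c1), 1L)
  expect_true(all(nzchar(unlist(c1[slots]))))

  bad_vocab <- default_tag_vocabulary()
  bad_vocab$background <- character(0)
  expect_error(make_tag_cards(bank, vocab = bad_vocab), "background")
})
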