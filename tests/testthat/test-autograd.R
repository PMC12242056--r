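# The autodiff tape is the foundation under both trained networks, so every
# backward rule is checked against central differences.

ag <- function(name) get(name, envir = asNamespace("eegdecode"))

test_that("elementwise, linear-algebra and softmax ops match numeric gradients", {
  set.seed(1)
  A <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(20), 4, 5)
  C34 <- matrix(rnorm(12), 3, 4)
  g4 <- rnorm(4)
  b4 <- rnorm(4)

  cases <- list(
    matmul_gelu = function(x) ag("ag_mean")(ag("ag_gelu")(ag("ag_matmul")(x, ag("ag_const")(B)))),
    add_bias = function(x) ag("ag_mean")(ag("ag_add_bias")(ag("ag_const")(A), x)),
    softmax = function(x) ag("ag_mean")(ag("ag_mul")(ag("ag_softmax_rows")(x), ag("ag_const")(C34))),
    logsumexp_diag = function(x) {
      s <- ag("ag_matmul")(x, ag("ag_t")(x))
      ag("ag_mean")(ag("ag_sub")(ag("ag_logsumexp_rows")(s), ag("ag_diag")(s)))
    },
    rownorm = function(x) ag("ag_mean")(ag("ag_mul")(ag("ag_rownorm")(x), ag("ag_const")(C34))),
    layernorm = function(x) {
      ag("ag_mean")(ag("ag_mul")(
        ag("ag_layernorm")(x, ag("ag_const")(g4), ag("ag_const")(b4)),
        ag("ag_const")(C34)
      ))
    },
    slice_concat = function(x) {
      ag("ag_mean")(ag("ag_gelu")(ag("ag_concat_cols")(
        ag("ag_slice_cols")(x, c(1L, 3L)), ag("ag_scale")(x, 2)
      )))
    }
  )
  for (nm in names(cases)) {
    x0 <- if (nm == "add_bias") rnorm(4) else A
    expect_lt(gradcheck(cases[[nm]], x0), 1e-5, label = nm)
  }
  # scalar path used by the learned temperature
  expect_lt(gradcheck(function(s) {
    ag("ag_mean")(ag("ag_scalar_mul")(ag("ag_exp")(s), ag("ag_const")(A)))
  }, 0.3), 1e-5)
})

test_that("convolution, sequence-layout and attention primitives match numeric gradients", {
  set.seed(2)
  X66 <- matrix(rnorm(36), 6, 6)   # B = 2, e = 3, d = 6
  W43 <- matrix(rnorm(12), 4, 3)
  Y87 <- matrix(rnorm(56), 8, 7)   # B = 2, F = 4, d = 7
  Z83 <- matrix(rnorm(24), 8, 3)   # B = 2, L = 4, width 3
  K10 <- matrix(rnorm(30), 10, 3)
  V10 <- matrix(rnorm(30), 10, 3)
  M83 <- matrix(rnorm(24), 8, 3)
  M212 <- matrix(rnorm(24), 2, 12)

  expect_lt(gradcheck(function(w) {
    ag("ag_mean")(ag("ag_gelu")(ag("ag_spatial_mix")(ag("ag_const")(X66), w, e = 3, B = 2)))
  }, W43), 1e-5)
  expect_lt(gradcheck(function(x) {
    ag("ag_mean")(ag("ag_gelu")(ag("ag_spatial_mix")(x, ag("ag_const")(W43), e = 3, B = 2)))
  }, X66), 1e-5)
  expect_lt(gradcheck(function(k) {
    ag("ag_mean")(ag("ag_gelu")(ag("ag_temporal_conv")(ag("ag_const")(Y87), k, F = 4, B = 2)))
  }, W43), 1e-5)
  expect_lt(gradcheck(function(y) {
    ag("ag_mean")(ag("ag_gelu")(ag("ag_temporal_conv")(y, ag("ag_const")(W43), F = 4, B = 2)))
  }, Y87), 1e-5)
  expect_lt(gradcheck(function(y) {
    ag("ag_mean")(ag("ag_mul")(ag("ag_maps_to_seq")(y, B = 2, F = 3, L = 4), ag("ag_const")(M83)))
  }, matrix(rnorm(24), 6, 4)), 1e-5)
  expect_lt(gradcheck(function(z) {
    ag("ag_mean")(ag("ag_mul")(ag("ag_flatten_seq")(z, B = 2, L = 4), ag("ag_const")(M212)))
  }, Z83), 1e-5)
  expect_lt(gradcheck(function(tok) {
    ag("ag_mean")(ag("ag_gelu")(ag("ag_add_rowrep")(ag("ag_const")(Z83), tok, B = 2, L = 4)))
  }, matrix(rnorm(6), 2, 3)), 1e-5)

  attn <- function(q, k, v) {
    s <- ag("ag_attn_scores")(q, k, B = 2, Lq = 4, Lk = 5, scale = 0.7)
    ag("ag_mean")(ag("ag_attn_apply")(ag("ag_softmax_rows")(s), v, B = 2, Lq = 4, Lk = 5))
  }
  expect_lt(gradcheck(function(q) attn(q, ag("ag_const")(K10), ag("ag_const")(V10)), Z83), 1e-5)
  expect_lt(gradcheck(function(k) attn(ag("ag_const")(Z83), k, ag("ag_const")(V10)), K10), 1e-5)
  expect_lt(gradcheck(function(v) attn(ag("ag_const")(Z83), ag("ag_const")(K10), v), V10), 1e-5)
})

test_that("gradients through the assembled encoder match numeric gradients", {
  enc <- build_encoder(micro_config(), seed = 5)
  set.seed(6)
  batch <- array(rnorm(2 * 4 * 12), c(2, 4, 12))
  bm <- eegdecode:::batch_to_matrix(batch)
  target <- matrix(rnorm(2 * 4), 2, 4)

  loss_for <- function(params) {
    eegdecode:::ag_tape_start()
    lv <- lapply(params, eegdecode:::ag_leaf)
    out <- eegdecode:::encoder_graph(enc, lv, eegdecode:::ag_const(bm$m), bm$B,
                                     subject_id = 2L)
    d <- eegdecode:::ag_sub(out$embedding, eegdecode:::ag_const(target))
    list(loss = eegdecode:::ag_mean(eegdecode:::ag_mul(d, d)), lv = lv)
  }

  res <- loss_for(enc$params)
  eegdecode:::ag_backward(res$loss)
  grads <- lapply(res$lv, eegdecode:::ag_grad)

  # spot-check a handful of coordinates in every parameter group
  set.seed(7)
  for (nm in names(enc$params)) {
    len <- length(enc$params[[nm]])
    for (i in sample.int(len, min(2L, len))) {
      f <- function(v) {
        p <- enc$params
        p[[nm]][i] <- v
        loss_for(p)$loss$v
      }
      gn <- (f(enc$params[[nm]][i] + 1e-5) - f(enc$params[[nm]][i] - 1e-5)) / 2e-5
      expect_equal(grads[[nm]][i], gn, tolerance = 1e-3,
                   label = paste("d loss /", nm, "[", i, "]"))
    }
  }
})

test_that("gradients through the diffusion prior network match numeric gradients", {
  pr <- build_prior(prior_config(4, width = 16, time_dim = 8), seed = 2)
  set.seed(3)
  x_t <- matrix(rnorm(8), 2, 4)
  cond <- matrix(rnorm(8), 2, 4)
  eps <- matrix(rnorm(8), 2, 4)
  tvec <- c(100, 900)

  loss_for <- function(params) {
    eegdecode:::ag_tape_start()
    lv <- lapply(params, eegdecode:::ag_leaf)
    pred <- eegdecode:::prior_graph(pr, lv, eegdecode:::ag_const(x_t), tvec,
                                    eegdecode:::ag_const(cond))
    d <- eegdecode:::ag_sub(pred, eegdecode:::ag_const(eps))
    list(loss = eegdecode:::ag_mean(eegdecode:::ag_mul(d, d)), lv = lv)
  }
  res <- loss_for(pr$params)
  eegdecode:::ag_backward(res$loss)
  grads <- lapply(res$lv, eegdecode:::ag_grad)
  set.seed(4)
  for (nm in names(pr$params)) {
    len <- length(pr$params[[nm]])
    i <- sample.int(len, 1L)
    f <- function(v) {
      p <- pr$params
      p[[nm]][i] <- v
      loss_for(p)$loss$v
    }
    gn <- (f(pr$params[[nm]][i] + 1e-5) - f(pr$params[[nm]][i] - 1e-5)) / 2e-5
    expect_equal(grads[[nm]][i], gn, tolerance = 1e-3,
                 label = paste("d loss /", nm))
  }
})
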