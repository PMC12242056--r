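# prior trained once on a single pair, reused by the memorization tests
memo <- new.env()
memo_prior <- function() {
  if (is.null(memo$pr)) {
    set.seed(101)
    memo$E <- matrix(rnorm(8), 1)
    memo$I <- eegdecode:::unit_rows(matrix(rnorm(8), 1))
    pr <- build_prior(prior_config(8, T = 1000, width = 64), seed = 1)
    pr <- train_prior(pr, memo$E, memo$I, steps = 2500, batch_size = 32,
                      lr = 3e-3, seed = 1)
    memo$pr <- train_prior(pr, memo$E, memo$I, steps = 1000, batch_size = 32,
                           lr = 3e-4, seed = 2)
  }
  memo
}

test_that("the cosine schedule matches its closed form and is strictly decreasing", {
  sch <- cosine_alpha_bar(100)
  expect_identical(sch$alpha_bar[1], 1)
  expect_true(all(diff(sch$alpha_bar) < 0))

  sch1k <- cosine_alpha_bar(1000, s = 0.008)
  f <- function(t) cos(((t / 1000 + 0.008) / 1.008) * pi / 2)^2
  expect_equal(sch1k$alpha_bar[501], f(500) / f(0), tolerance = 1e-12)
  expect_lt(sch1k$alpha_bar[1001], 0.01)
  expect_error(cosine_alpha_bar(0), "T")
})

test_that("forward diffusion interpolates exactly at the endpoints and matches second moments", {
  sch <- cosine_alpha_bar(1000)
  set.seed(1)
  I0 <- rnorm(8)
  eps <- rnorm(8)
  expect_identical(forward_diffuse(I0, 0, eps, sch), I0)
  expect_equal(forward_diffuse(I0, 1000, eps, sch), eps, tolerance = 1e-15)
  expect_error(forward_diffuse(I0, 1001, eps, sch), "range")

  # E||I_t||^2 = ab * ||I0||^2 + (1 - ab) * D for unit-variance noise
  t <- 400
  ab <- sch$alpha_bar[t + 1]
  m2 <- mean(replicate(3000, sum(forward_diffuse(I0, t, rnorm(8), sch)^2)))
  expect_equal(m2, ab * sum(I0^2) + (1 - ab) * 8, tolerance = 0.05)
})

test_that("noise prediction has the right shape, is deterministic and feeds every block", {
  pr <- build_prior(prior_config(8, width = 32), seed = 3)
  set.seed(3)
  x <- rnorm(8)
  cond <- rnorm(8)
  e1 <- prior_predict_noise(pr, x, 100, cond)
  expect_length(e1, 8)
  expect_true(all(is.finite(e1)))
  expect_identical(e1, prior_predict_noise(pr, x, 100, cond)) # eval determinism
  expect_error(prior_predict_noise(pr, rnorm(5), 10), "width")

  # one MSE step moves parameters in all 6 blocks (and the embedding paths)
  set.seed(4)
  E <- matrix(rnorm(4 * 8), 4)
  I <- matrix(rnorm(4 * 8), 4)
  pr2 <- train_prior(pr, E, I, steps = 1, batch_size = 4, seed = 5)
  moved <- vapply(names(pr$params), function(nm) {
    !identical(pr2$params[[nm]], pr$params[[nm]])
  }, logical(1))
  blocks <- grep("^blk", names(moved), value = TRUE)
  expect_true(all(moved[blocks]))
  expect_true(moved[["in.W"]] && moved[["out.W"]])
})

test_that("condition dropout extremes behave as specified and training is seeded", {
  set.seed(6)
  E <- matrix(rnorm(6 * 8), 6)
  I <- matrix(rnorm(6 * 8), 6)
  p0 <- build_prior(prior_config(8, width = 32, cond_dropout_p = 0), seed = 7)
  a <- train_prior(p0, E, I, steps = 30, seed = 9)
  b <- train_prior(p0, E, I, steps = 30, seed = 9)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)

  # cond_dropout_p = 1: the condition is never seen, so conditional and
  # unconditional predictions coincide after training
  p1 <- build_prior(prior_config(8, width = 32, cond_dropout_p = 0.999), seed = 7)
  p1$config$cond_dropout_p <- 1 # constructor forbids 1; force the extreme
  tr <- train_prior(p1, E, I, steps = 50, seed = 10)
  x <- rnorm(8)
  expect_equal(prior_predict_noise(tr, x, 200, E[1, ]),
               prior_predict_noise(tr, x, 200, NULL), tolerance = 1e-4)
  expect_error(train_prior(p0, E[0, , drop = FALSE], I[0, , drop = FALSE]),
               "pairs")
})

test_that("guidance is the affine combination of the two branches", {
  pr <- build_prior(prior_config(8, width = 32), seed = 11)
  set.seed(12)
  x <- rnorm(8)
  E1 <- rnorm(8)
  eps_u <- prior_predict_noise(pr, x, 300, NULL)
  eps_c <- prior_predict_noise(pr, x, 300, E1)
  expect_identical(guided_noise(pr, x, 300, E1, w = 0), eps_u)
  expect_equal(guided_noise(pr, x, 300, E1, w = 1), eps_c, tolerance = 1e-12)
  expect_equal(guided_noise(pr, x, 300, E1, w = 3.5),
               eps_u + 3.5 * (eps_c - eps_u), tolerance = 1e-12)
  expect_error(guided_noise(pr, x, 300, E1, w = -1), "w")
})

test_that("a single-pair prior is memorized: samples recover the target", {
  m <- memo_prior()
  expect_lt(mean(utils::tail(m$pr$history, 200)), 0.1)
  s <- sample_embedding(m$pr, drop(m$E), steps = 50, w = 1, seed = 3)
  expect_identical(s, sample_embedding(m$pr, drop(m$E), steps = 50, w = 1, seed = 3))
  cs <- vapply(1:4, function(sd) {
    smp <- sample_embedding(m$pr, drop(m$E), steps = 50, w = 1, seed = sd)
    sum(smp * m$I) / sqrt(sum(smp^2) * sum(m$I^2))
  }, numeric(1))
  expect_gt(max(cs), 0.9)   # recovery at the reported seed
  expect_gt(mean(cs), 0.8)  # and robustly close across seeds
})

test_that("prior checkpoints round-trip", {
  m <- memo_prior()
  path <- tempfile(fileext = ".rds")
  save_prior(m$pr, path)
  pr2 <- load_prior(path)
  expect_identical(pr2$params, m$pr$params)
  expect_identical(sample_embedding(pr2, drop(m$E), steps = 10, w = 1, seed = 1),
                   sample_embedding(m$pr, drop(m$E), steps = 10, w = 1, seed = 1))
})
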