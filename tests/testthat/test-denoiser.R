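# a reduced spec keeps the finite-difference and training probes fast
small_spec <- function() {
  denoiser_spec(base_channels = 4L, depth = 2L, swin_window = 2L,
                n_heads = 2L, time_embed_dim = 8L)
}

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  model <- build_denoiser(small_spec(), seed = 3)
  B <- 2L; H <- 8L; W <- 8L
  xt <- matrix(rnorm(B * H * W), ncol = 1)
  y <- matrix(rnorm(B * H * W), ncol = 1)
  lev <- c(0.3, 0.8)
  tgt <- matrix(rnorm(B * H * W), ncol = 1)
  lossf <- function(m) {
    fw <- rsmoco:::denoiser_forward(m, xt, y, lev, B, H, W)
    mean((fw$out - tgt)^2)
  }
  fw <- rsmoco:::denoiser_forward(model, xt, y, lev, B, H, W)
  d <- fw$out - tgt
  g <- rsmoco:::denoiser_backward(model, fw$cache,
                                  matrix(2 * d / length(d), ncol = 1))
  flat <- rsmoco:::flatten_params(model$params)
  gflat <- rsmoco:::flatten_params(g)
  expect_setequal(names(gflat), names(flat))
  eps <- 1e-5
  for (k in names(flat)) {
    nel <- length(flat[[k]])
    for (ii in unique(c(1L, nel))) {
      f <- flat
      f[[k]][ii] <- f[[k]][ii] + eps
      m2 <- model; m2$params <- rsmoco:::assign_flat(m2$params, f)
      lp <- lossf(m2)
      f[[k]][ii] <- f[[k]][ii] - 2 * eps
      m2$params <- rsmoco:::assign_flat(m2$params, f)
      lm <- lossf(m2)
      num <- (lp - lm) / (2 * eps)
      ana <- gflat[[k]][ii]
      expect_lt(abs(num - ana) / max(1e-5, abs(num) + abs(ana)), 1e-3,
                label = sprintf("gradient of %s[%d]", k, ii))
    }
  }
})

test_that("output grid matches input grid across compatible resolutions", {
  model <- build_denoiser(denoiser_spec("tiny"), seed = 1)
  for (n in c(32L, 64L, 96L)) {
    x_t <- matrix(rnorm(n * n), n)
    y <- matrix(runif(n * n), n)
    out <- denoise(model, x_t, y, 0.5)
    expect_equal(dim(out), c(n, n))
    expect_true(all(is.finite(out)))
  }
  expect_error(denoise(model, matrix(0, 30, 30), matrix(0, 30, 30), 0.5),
               "divisible")
})

test_that("inference is deterministic and conditioned on the noise level", {
  model <- build_denoiser(denoiser_spec("tiny"), seed = 2)
  x_t <- matrix(rnorm(32 * 32), 32)
  y <- matrix(runif(32 * 32), 32)
  a <- denoise(model, x_t, y, 0.3)
  b <- denoise(model, x_t, y, 0.3)
  expect_identical(a, b)
  c2 <- denoise(model, x_t, y, 0.9)
  expect_gt(max(abs(a - c2)), 0) # conditioning is live
})

test_that("the tiny preset stays under one million parameters", {
  model <- build_denoiser(denoiser_spec("tiny"), seed = 1)
  expect_lt(n_parameters(model), 1e6)
  expect_gt(n_parameters(model), 1e4)
})

test_that("every trainable parameter receives gradient on a random batch", {
  set.seed(7)
  model <- build_denoiser(small_spec(), seed = 5)
  B <- 2L; H <- 8L; W <- 8L
  fw <- rsmoco:::denoiser_forward(model,
                                  matrix(rnorm(B * H * W), ncol = 1),
                                  matrix(rnorm(B * H * W), ncol = 1),
                                  c(0.2, 0.7), B, H, W)
  g <- rsmoco:::denoiser_backward(model, fw$cache,
                                  matrix(rnorm(B * H * W), ncol = 1))
  gflat <- rsmoco:::flatten_params(g)
  for (k in names(gflat))
    expect_gt(max(abs(gflat[[k]])), 0, label = paste("grad", k))
})

test_that("a tiny model overfits one pair to high fidelity", {
  ps <- tiny_pair(32, "moderate", seed = 2)
  spec <- denoiser_spec(base_channels = 8L, depth = 2L, swin_window = 4L,
                        n_heads = 2L, time_embed_dim = 32L)
  model <- build_denoiser(spec, seed = 1)
  sched <- build_schedule(schedule_config(n_steps = 20))
  model <- train_denoiser(list(ps), model = model, sched = sched,
                          steps = 1000L, lr = 3e-3, ema_decay = 0.995,
                          seed = 4)
  f <- denoise(model, ps$x, ps$y, noise_level(sched, 1))
  expect_lt(sum((f - ps$x)^2) / sum(ps$x^2), 0.01)
})
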