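sched20 <- build_schedule(schedule_config(n_steps = 20))
sched4 <- build_schedule(schedule_config(n_steps = 4))

test_that("forward marginal parameters follow mean x + beta*r, sd gamma*sqrt(beta)", {
  ps <- tiny_pair(64, "moderate", seed = 1)
  # vanishing residual: mean is x at any t
  same <- paired_sample(ps$x, ps$x)
  for (t in c(1L, 10L, 20L)) {
    mp <- forward_marginal_params(same, sched20, t)
    expect_identical(mp$mean, ps$x)
  }
  # printed constants: gamma*sqrt(beta1) = 0.04, t = N std ~ 2*sqrt(0.999)
  mp1 <- forward_marginal_params(ps, sched20, 1)
  expect_equal(mp1$sd, 0.04)
  expect_equal(mp1$mean, ps$x + 4e-4 * ps$r)
  mpN <- forward_marginal_params(ps, sched20, 20)
  expect_equal(mpN$sd, 2 * sqrt(0.999), tolerance = 1e-12)
  expect_lt(max(abs(mpN$mean - ps$y)), (1 - 0.999) * max(abs(ps$r)) + 1e-12)
  expect_error(forward_marginal_params(ps, sched20, 21), "step index")
})

test_that("forward sampling is seed-deterministic with correct moments", {
  ps <- tiny_pair(64, "heavy", seed = 2)
  a <- sample_forward(ps, sched20, 7, seed = 99)
  b <- sample_forward(ps, sched20, 7, seed = 99)
  expect_identical(a$x_t, b$x_t)

  # Monte-Carlo check of the marginal's moments: pixels are i.i.d.
  # given (x, y), so draws pool across the grid
  ps32 <- tiny_pair(32, "heavy", seed = 2)
  t <- 12L
  mp <- forward_marginal_params(ps32, sched20, t)
  resid <- unlist(lapply(1:30, function(i)
    as.vector(sample_forward(ps32, sched20, t, seed = 1e4 + i)$x_t -
                mp$mean)))
  M <- length(resid)
  expect_lt(abs(mean(resid)), 3 * mp$sd / sqrt(M))
  expect_lt(abs(var(resid) - mp$sd^2), 3 * mp$sd^2 * sqrt(2 / (M - 1)))
})

test_that("single transitions have the stated mean and scale", {
  ps <- tiny_pair(64, "minor", seed = 3)
  # zero residual, forced zero noise: identity
  z <- matrix(0, 64, 64)
  out <- withr::with_seed(1, transition_sample(ps$x, z, sched20, 5))
  at <- alpha_at(sched20, 5)
  # subtract the injected noise analytically: same seed reproduces eps
  eps <- withr::with_seed(1, matrix(rnorm(64 * 64), 64))
  expect_equal(out, ps$x + sched20$gamma * sqrt(at) * eps,
               tolerance = 1e-12)
})

test_that("chained transition means telescope onto the direct marginal", {
  ps <- tiny_pair(32, "moderate", seed = 4)
  m <- ps$x
  for (t in 1:20) {
    m <- m + alpha_at(sched20, t) * ps$r
    direct <- forward_marginal_params(ps, sched20, t)$mean
    expect_equal(m, direct, tolerance = 1e-12)
  }
})

test_that("posterior parameters collapse at t = 1 and match derived values", {
  ps <- tiny_pair(64, "moderate", seed = 5)
  x_t <- sample_forward(ps, sched4, 1, seed = 1)$x_t
  pp <- posterior_params(x_t, ps$x, sched4, 1)
  expect_identical(pp$mean, ps$x)
  expect_identical(pp$var, 0)

  # derived coefficients for the default 4-step schedule at t = 2
  b1 <- 4e-4
  b2 <- exp(log(4e-4) + (1 / 3)^0.3 * (log(0.999) - log(4e-4)))
  a2 <- b2 - b1
  pp2 <- posterior_params(x_t, ps$x, sched4, 2)
  expect_equal(pp2$var, 4 * (b1 / b2) * a2, tolerance = 1e-12)
  expect_equal(round(c(b1 / b2, a2 / b2), 4), c(0.0036, 0.9964))
  expect_equal(pp2$var, 1.6e-3, tolerance = 0.01) # 2-figure derived value
})

test_that("posterior composed over the forward marginal reproduces step t-1", {
  # means: E[post mean] = (b_{t-1}/b_t)(x + b_t r) + (a_t/b_t) x = x + b_{t-1} r
  # variances: (b_{t-1}/b_t)^2 g^2 b_t + g^2 b_{t-1} a_t / b_t = g^2 b_{t-1}
  g <- sched20$gamma
  for (t in 2:20) {
    bt <- beta_at(sched20, t); btm1 <- beta_at(sched20, t - 1)
    at <- alpha_at(sched20, t)
    expect_equal((btm1 / bt)^2 * g^2 * bt + g^2 * btm1 * at / bt,
                 g^2 * btm1, tolerance = 1e-12)
  }
})

test_that("training loss satisfies its arithmetic contract", {
  x <- matrix(0.2, 16, 16)
  expect_equal(training_loss(x, x)$total, 0)
  l <- training_loss(x + 0.5, x)
  expect_equal(l$l2_part, 0.25)
  expect_equal(l$l1_part, 0.5)
  expect_equal(l$total, 0.75)
  set.seed(6)
  a <- matrix(rnorm(64), 8); b <- matrix(rnorm(64), 8)
  l2 <- training_loss(a, b)
  expect_equal(l2$total, mean((a - b)^2) + mean(abs(a - b)),
               tolerance = 1e-14)
  expect_identical(l2$total, l2$l2_part + l2$l1_part)
  labl <- training_loss(a, b, l2_only = TRUE)
  expect_identical(labl$l1_part, 0)
  expect_identical(labl$total, labl$l2_part)
})

test_that("a training step is deterministic given its seed", {
  ps <- tiny_pair(32, "moderate", seed = 7)
  spec <- denoiser_spec(base_channels = 8L, depth = 2L, swin_window = 4L,
                        n_heads = 2L, time_embed_dim = 16L)
  model <- build_denoiser(spec, seed = 2)
  a <- training_step(model, list(ps), sched20, seed = 31)
  b <- training_step(model, list(ps), sched20, seed = 31)
  expect_identical(a$loss$total, b$loss$total)
  expect_identical(rsmoco:::flatten_params(a$model$params),
                   rsmoco:::flatten_params(b$model$params))
  abl <- training_step(model, list(ps), sched20, seed = 31, l2_only = TRUE)
  expect_identical(abl$loss$l1_part, 0)
})

test_that("the training loss decreases on a repeated single pair", {
  ps <- tiny_pair(32, "heavy", seed = 8)
  spec <- denoiser_spec(base_channels = 8L, depth = 2L, swin_window = 4L,
                        n_heads = 2L, time_embed_dim = 16L)
  model <- build_denoiser(spec, seed = 3)
  model <- train_denoiser(list(ps), model = model, sched = sched20,
                          steps = 500L, lr = 2e-3, seed = 9)
  h <- attr(model, "loss_history")
  ma <- stats::filter(h, rep(1 / 50, 50), sides = 1)
  expect_lt(ma[500], ma[50] * 0.5)
})

test_that("the sampler is an exact inverse under an oracle denoiser", {
  calls <- 0L
  ps <- tiny_pair(64, "heavy", seed = 9)
  oracle <- function(x_t, y, lev) { calls <<- calls + 1L; ps$x }
  out <- sample_restore(ps$y, oracle, sched4, seed = 77)
  expect_identical(out, ps$x)
  expect_equal(calls, 4L) # exactly N denoiser evaluations
  # the corrupted image is the sampler's other fixed point
  out_y <- sample_restore(ps$y, function(x_t, y, lev) ps$y, sched4,
                          seed = 78)
  expect_identical(out_y, ps$y)
})

test_that("sampling rejects a gamma mismatch between model and schedule", {
  ps <- tiny_pair(32, "minor", seed = 10)
  spec <- denoiser_spec(base_channels = 8L, depth = 2L, swin_window = 4L,
                        n_heads = 2L, time_embed_dim = 16L)
  model <- build_denoiser(spec, seed = 1)
  model <- train_denoiser(list(ps), model = model,
                          sched = build_schedule(schedule_config(
                            n_steps = 4, gamma = 2)),
                          steps = 2L, seed = 1)
  bad <- build_schedule(schedule_config(n_steps = 4, gamma = 1))
  expect_error(sample_restore(ps$y, model, bad), "gamma mismatch")
})
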