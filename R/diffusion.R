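#' Construct a paired sample
#'
#' Bundles a motion-free image \code{x}, its motion-corrupted
#' counterpart \code{y} on the same grid, and the residual
#' \code{r = y - x} that drives the forward diffusion.
#'
#' @param x Motion-free image (matrix).
#' @param y Motion-corrupted image (matrix, same dimensions).
#' @return A list with elements \code{x}, \code{y}, \code{r} of class
#'   \code{"rs_paired_sample"}.
#' @export
paired_sample <- function(x, y) {
  stopifnot(is.matrix(x), all(dim(x) == dim(y)))
  structure(list(x = x, y = y, r = y - x), class = "rs_paired_sample")
}

as_paired_sample <- function(sample) {
  if (inherits(sample, "rs_paired_sample")) return(sample)
  if (is.list(sample) && all(c("x", "y") %in% names(sample)))
    return(paired_sample(sample$x, sample$y))
  stop("`sample` must be a paired sample (x, y)", call. = FALSE)
}

#' Parameters of the forward marginal q(x_t | x, y)
#'
#' At step \eqn{t} the state is Gaussian with mean
#' \eqn{x + \beta_t r} and isotropic standard deviation
#' \eqn{\gamma\sqrt{\beta_t}}: the clean image drifts toward the
#' corrupted one while noise accumulates.
#'
#' @param sample A \code{\link{paired_sample}} (or list with x, y).
#' @param sched An \code{\link{build_schedule}} schedule.
#' @param t Step index in 1..N.
#' @return List with \code{mean} (image) and \code{sd} (scalar).
#' @export
forward_marginal_params <- function(sample, sched, t) {
  sample <- as_paired_sample(sample)
  t <- check_step(sched, t)
  bt <- sched$betas[t + 1L]
  list(mean = sample$x + bt * sample$r, sd = sched$gamma * sqrt(bt))
}

#' Draw x_t from the forward marginal
#'
#' \eqn{x_t = x + \beta_t r + \gamma\sqrt{\beta_t}\,\epsilon} with
#' \eqn{\epsilon} i.i.d. standard normal per pixel.
#'
#' @inheritParams forward_marginal_params
#' @param seed Optional integer seed (NULL uses the current RNG state).
#' @return List with \code{x_t} (image) and \code{t}.
#' @export
sample_forward <- function(sample, sched, t, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  mp <- forward_marginal_params(sample, sched, t)
  eps <- matrix(stats::rnorm(length(mp$mean)), nrow(mp$mean))
  list(x_t = mp$mean + mp$sd * eps, t = t)
}

#' Draw one forward transition q(x_t | x_{t-1}, y)
#'
#' \eqn{x_t = x_{t-1} + \alpha_t r + \gamma\sqrt{\alpha_t}\,\epsilon};
#' chaining transitions from \eqn{x} reproduces the marginal because the
#' increments telescope (\eqn{\sum \alpha = \beta}) and independent
#' Gaussian noise variances add.
#'
#' @param x_prev State at step t-1 (the clean image itself for t = 1).
#' @param r Residual image \code{y - x}.
#' @param sched Schedule.
#' @param t Step index in 1..N.
#' @param seed Optional integer seed.
#' @return Image \eqn{x_t}.
#' @export
transition_sample <- function(x_prev, r, sched, t, seed = NULL) {
  stopifnot(all(dim(x_prev) == dim(r)))
  t <- check_step(sched, t)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  at <- sched$alphas[t]
  eps <- matrix(stats::rnorm(length(x_prev)), nrow(x_prev))
  x_prev + at * r + sched$gamma * sqrt(at) * eps
}

#' Parameters of the reverse posterior q(x_{t-1} | x_t, x, y)
#'
#' The closed-form Gaussian posterior has mean
#' \eqn{(\beta_{t-1}/\beta_t) x_t + (\alpha_t/\beta_t) x_0} and variance
#' \eqn{\gamma^2 (\beta_{t-1}/\beta_t) \alpha_t}; the residual cancels
#' and does not appear. At \eqn{t = 1} (with \eqn{\beta_0 = 0}) the
#' posterior collapses onto \eqn{x_0} with zero variance, which is what
#' makes the final reverse step exact and noiseless.
#'
#' @param x_t State at step t.
#' @param x0_est The (estimated or true) motion-free image.
#' @param sched Schedule.
#' @param t Step index in 1..N.
#' @return List with \code{mean} (image) and \code{var} (scalar).
#' @export
posterior_params <- function(x_t, x0_est, sched, t) {
  stopifnot(all(dim(x_t) == dim(x0_est)))
  t <- check_step(sched, t)
  bt <- sched$betas[t + 1L]
  btm1 <- sched$betas[t]
  at <- sched$alphas[t]
  list(mean = (btm1 / bt) * x_t + (at / bt) * x0_est,
       var = sched$gamma^2 * (btm1 / bt) * at)
}

#' Training loss of the x0-prediction objective
#'
#' Mean-over-pixels squared error plus mean absolute error with equal
#' weighting; \code{l2_only = TRUE} drops the absolute term (the
#' ablation mode).
#'
#' @param f_out Network prediction.
#' @param x Ground-truth motion-free image.
#' @param l2_only Drop the l1 term.
#' @return An object of class \code{"rs_loss"}: list with \code{total},
#'   \code{l2_part}, \code{l1_part}.
#' @export
training_loss <- function(f_out, x, l2_only = FALSE) {
  stopifnot(all(dim(f_out) == dim(x)))
  d <- f_out - x
  l2 <- mean(d^2)
  l1 <- if (l2_only) 0 else mean(abs(d))
  structure(list(total = l2 + l1, l2_part = l2, l1_part = l1),
            class = "rs_loss")
}

# gradient of the combined loss w.r.t. f_out (column layout)
loss_grad <- function(d, l2_only = FALSE) {
  n <- length(d)
  g <- 2 * d / n
  if (!l2_only) g <- g + sign(d) / n
  g
}

#' One stochastic training step
#'
#' Draws a uniform step index per batch element, forms the noisy state
#' via the forward marginal, evaluates the denoiser at the corresponding
#' continuous noise level, and takes one Adam update on the combined
#' loss.
#'
#' @param model An \code{"rs_denoiser"}.
#' @param batch List of paired samples (each with \code{x}, \code{y}),
#'   all on one grid.
#' @param sched Training schedule.
#' @param state Adam optimizer state (from a previous call or NULL).
#' @param lr Learning rate.
#' @param clip Global gradient-norm clipping threshold (the high-noise
#'   states at large t occasionally produce outlier gradients with a
#'   batch of one; clipping keeps the optimizer stable). \code{Inf}
#'   disables it.
#' @param l2_only Ablation switch dropping the l1 loss term.
#' @param seed Optional integer seed for the step's randomness.
#' @return List with updated \code{model}, \code{state} and the
#'   \code{loss} (an \code{"rs_loss"}).
#' @export
training_step <- function(model, batch, sched, state = NULL, lr = 1e-3,
                          clip = 1, l2_only = FALSE, seed = NULL) {
  stopifnot(inherits(model, "rs_denoiser"), length(batch) >= 1L)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  batch <- lapply(batch, as_paired_sample)
  H <- nrow(batch[[1]]$x); W_img <- ncol(batch[[1]]$x)
  check_grid(model$spec, H, W_img)
  B <- length(batch)

  ts <- sample.int(sched$n_steps, B, replace = TRUE)
  xt <- lapply(seq_len(B), function(i)
    sample_forward(batch[[i]], sched, ts[i])$x_t)
  xt_vec <- matrix(unlist(xt, use.names = FALSE), ncol = 1)
  y_vec <- matrix(unlist(lapply(batch, `[[`, "y"), use.names = FALSE),
                  ncol = 1)
  x_vec <- matrix(unlist(lapply(batch, `[[`, "x"), use.names = FALSE),
                  ncol = 1)
  lev <- sqrt(sched$betas[ts + 1L])

  fw <- denoiser_forward(model, xt_vec, y_vec, lev, B, H, W_img)
  d <- fw$out - x_vec
  loss <- training_loss(fw$out, x_vec, l2_only = l2_only)
  if (!is.finite(loss$total))
    stop("non-finite training loss; check inputs/learning rate",
         call. = FALSE)

  grads_tree <- denoiser_backward(model, fw$cache,
                                  matrix(loss_grad(d, l2_only), ncol = 1))
  flat <- flatten_params(model$params)
  gflat <- flatten_params(grads_tree)
  if (is.finite(clip)) {
    gnorm <- sqrt(sum(vapply(gflat, function(g) sum(g^2), numeric(1))))
    if (gnorm > clip) gflat <- lapply(gflat, `*`, clip / gnorm)
  }
  if (is.null(state)) state <- adam_init(flat)
  upd <- adam_update(flat, gflat, state, lr = lr)
  model$params <- assign_flat(model$params, upd$flat)
  list(model = model, state = upd$state, loss = loss)
}

#' Train a denoiser on a paired dataset
#'
#' Runs \code{steps} stochastic training steps, drawing each batch
#' uniformly (with replacement) from the rows of \code{data}. The model
#' records the schedule configuration and normalization convention so
#' sampling is self-describing.
#'
#' @param data Paired dataset tibble with list-columns \code{x},
#'   \code{y} (e.g. a \code{\link{make_fixture_suite}} split), or a list
#'   of paired samples.
#' @param model An \code{"rs_denoiser"} (default: fresh tiny model).
#' @param sched Training schedule (default: 20 steps).
#' @param steps Number of optimizer steps.
#' @param batch_size Images per step.
#' @param lr Peak Adam learning rate; a linear warmup over
#'   \code{warmup} steps is followed by cosine decay to \code{lr / 10},
#'   mirroring the warmup + cosine-annealing protocol of full-scale
#'   training at desk scale.
#' @param warmup Warmup steps.
#' @param ema_decay Decay of the exponential moving average of the
#'   weights; the averaged weights are installed in the returned model
#'   (standard diffusion-model practice, reduces sampling noise from
#'   the last few stochastic updates). Set to 0 to disable.
#' @param l2_only Ablation switch.
#' @param seed Integer seed governing batch selection and noise draws.
#' @param verbose Print a progress line every 200 steps.
#' @return The trained model with a \code{loss_history} attribute
#'   (numeric vector of per-step total losses).
#' @export
train_denoiser <- function(data, model = build_denoiser(),
                           sched = build_schedule(schedule_config()),
                           steps = 2000L, batch_size = 1L, lr = 2e-3,
                           warmup = 50L, ema_decay = 0.998,
                           l2_only = FALSE, seed = 1L, verbose = FALSE) {
  samples <- if (is.data.frame(data)) {
    lapply(seq_len(nrow(data)), function(i)
      paired_sample(data$x[[i]], data$y[[i]]))
  } else {
    lapply(data, as_paired_sample)
  }
  if (length(samples) == 0L) stop("empty training set", call. = FALSE)
  withr::local_seed(as.integer(seed))
  state <- NULL
  ema <- NULL
  hist <- numeric(steps)
  for (s in seq_len(steps)) {
    lr_s <- if (s <= warmup) lr * s / warmup else
      lr * (0.1 + 0.45 * (1 + cos(pi * (s - warmup) / (steps - warmup))))
    idx <- sample.int(length(samples), batch_size, replace = TRUE)
    st <- training_step(model, samples[idx], sched, state, lr = lr_s,
                        l2_only = l2_only)
    model <- st$model; state <- st$state
    hist[s] <- st$loss$total
    if (ema_decay > 0) {
      flat <- flatten_params(model$params)
      if (is.null(ema)) ema <- flat
      else for (k in names(flat))
        ema[[k]] <- ema_decay * ema[[k]] + (1 - ema_decay) * flat[[k]]
    }
    if (verbose && s %% 200L == 0L)
      message(sprintf("step %d/%d loss %.5f", s, steps,
                      mean(hist[max(1, s - 49):s])))
  }
  if (!is.null(ema)) model$params <- assign_flat(model$params, ema)
  model$schedule_config <- sched$config
  model$normalization <- "per-slice max scaling to [0, 1]"
  attr(model, "loss_history") <- hist
  model
}

#' Restore a motion-corrupted image with the few-step reverse sampler
#'
#' Initialises \eqn{x_N \sim N(y, \gamma^2\beta_N I)} and iterates
#' \eqn{t = N, \dots, 1}: the denoiser predicts \eqn{\hat x_0}, the
#' posterior mean \eqn{(\beta_{t-1}/\beta_t) x_t + (\alpha_t/\beta_t)
#' \hat x_0} is formed, and noise with standard deviation
#' \eqn{\gamma\sqrt{\beta_{t-1}\alpha_t/\beta_t}} is added — except at
#' \eqn{t = 1}, where the step is noiseless (and, since
#' \eqn{\beta_0 = 0}, returns the prediction exactly). Exactly N
#' denoiser evaluations are made; the default sampling schedule uses
#' N = 4 with the same endpoints and growth rate as training.
#'
#' @param y Motion-corrupted image (matrix).
#' @param model An \code{"rs_denoiser"} or an oracle function
#'   \code{f(x_t, y, level)}.
#' @param sampler_sched Sampling schedule (default 4 steps).
#' @param seed Optional integer seed.
#' @return The restored image estimate \eqn{\hat x_0}.
#' @export
#' @examples
#' y <- matrix(runif(32 * 32), 32)
#' # oracle that already knows the answer: the sampler is an exact inverse
#' x <- matrix(runif(32 * 32), 32)
#' out <- sample_restore(y, function(x_t, y, lev) x, seed = 1)
#' max(abs(out - x)) == 0
sample_restore <- function(y, model,
                           sampler_sched = build_schedule(
                             schedule_config(n_steps = 4L)),
                           seed = NULL) {
  stopifnot(is.matrix(y))
  if (inherits(model, "rs_denoiser") &&
      !is.null(model$schedule_config) &&
      model$schedule_config$gamma != sampler_sched$gamma)
    stop("schedule/model gamma mismatch", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  N <- sampler_sched$n_steps
  g <- sampler_sched$gamma
  x_t <- y + g * sqrt(sampler_sched$betas[N + 1L]) *
    matrix(stats::rnorm(length(y)), nrow(y))
  for (t in seq(N, 1L)) {
    x0_hat <- denoise(model, x_t, y, noise_level(sampler_sched, t))
    pp <- posterior_params(x_t, x0_hat, sampler_sched, t)
    if (t > 1L) {
      eps <- matrix(stats::rnorm(length(y)), nrow(y))
      x_t <- pp$mean + sqrt(pp$var) * eps
    } else {
      x_t <- pp$mean
    }
  }
  x_t
}

#' @export
print.rs_loss <- function(x, ...) {
  cat(sprintf("loss %.6f (l2 %.6f + l1 %.6f)\n", x$total, x$l2_part,
              x$l1_part))
  invisible(x)
}
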