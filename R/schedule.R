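#' Configuration for the residual-shifting noise schedule
#'
#' The forward diffusion is driven by a monotonically increasing shifting
#' sequence \eqn{\beta_1 < \beta_2 < \dots < \beta_N \le 1}. At step
#' \eqn{t} the state carries a fraction \eqn{\beta_t} of the residual
#' \eqn{r = y - x} plus Gaussian noise with standard deviation
#' \eqn{\gamma\sqrt{\beta_t}}. The sequence interpolates geometrically
#' between its endpoints with a growth-rate exponent \code{p}: smaller
#' \code{p} front-loads the noise (larger \eqn{\beta_t} early on), larger
#' \code{p} back-loads it.
#'
#' The default \code{beta1 = (0.04 / gamma)^2} keeps the step-1 noise
#' magnitude \eqn{\gamma\sqrt{\beta_1} = 0.04} small, so the first noisy
#' state is essentially the clean image; \code{betaN = 0.999} puts the
#' final state essentially at the corrupted image.
#'
#' @param n_steps Number of diffusion steps \eqn{N} (integer, at least 2).
#' @param gamma Global noise scale \eqn{\gamma > 0}.
#' @param beta1 First shifting coefficient, in (0, 1).
#' @param betaN Last shifting coefficient, in (0, 1].
#' @param p Growth-rate exponent, positive.
#' @return An object of class \code{"rs_schedule_config"}.
#' @export
#' @examples
#' cfg <- schedule_config(n_steps = 20)
#' cfg$beta1 # (0.04 / 2)^2 = 4e-4
schedule_config <- function(n_steps = 20L, gamma = 2,
                            beta1 = (0.04 / gamma)^2, betaN = 0.999,
                            p = 0.3) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 2L)
    stop("`n_steps` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0)
    stop("`gamma` must be positive", call. = FALSE)
  if (!is.numeric(p) || p <= 0)
    stop("`p` must be positive", call. = FALSE)
  if (beta1 <= 0 || beta1 >= 1)
    stop("`beta1` must lie in (0, 1)", call. = FALSE)
  if (betaN <= 0 || betaN > 1)
    stop("`betaN` must lie in (0, 1]", call. = FALSE)
  if (beta1 >= betaN)
    stop("`beta1` must be smaller than `betaN` (increasing schedule)",
         call. = FALSE)
  structure(
    list(n_steps = n_steps, beta1 = beta1, betaN = betaN,
         p = p, gamma = gamma),
    class = "rs_schedule_config"
  )
}

#' Build the shifting schedule
#'
#' Computes \eqn{\beta_t = \beta_1 (\beta_N/\beta_1)^{((t-1)/(N-1))^p}}
#' for \eqn{t = 1..N} — a geometric interpolation between the endpoints,
#' which it attains exactly — together with the per-step increments
#' \eqn{\alpha_t = \beta_t - \beta_{t-1}} under the convention
#' \eqn{\beta_0 = 0} (so \eqn{\alpha_1 = \beta_1} and the final reverse
#' step is noiseless). Values are precomputed and stored; the
#' telescoping identity \eqn{\sum_{s \le t} \alpha_s = \beta_t} holds to
#' within one unit in the last place when the increments are re-summed
#' in order.
#'
#' @param cfg An \code{\link{schedule_config}} object (or arguments passed
#'   on to it via \code{...} when \code{cfg} is missing).
#' @param ... Passed to \code{\link{schedule_config}} when \code{cfg} is
#'   not supplied.
#' @return An object of class \code{"rs_schedule"} with elements
#'   \code{betas} (length N + 1, index 1 holds \eqn{\beta_0 = 0}),
#'   \code{alphas} (length N), \code{gamma}, \code{n_steps}, \code{config}.
#' @export
#' @examples
#' sched <- build_schedule(schedule_config(n_steps = 20))
#' beta_at(sched, 20) # 0.999
build_schedule <- function(cfg, ...) {
  if (missing(cfg)) cfg <- schedule_config(...)
  stopifnot(inherits(cfg, "rs_schedule_config"))
  N <- cfg$n_steps
  t <- seq_len(N)
  betas_1N <- cfg$beta1 * (cfg$betaN / cfg$beta1)^(((t - 1) / (N - 1))^cfg$p)
  betas_1N[1] <- cfg$beta1   # endpoints exact by construction
  betas_1N[N] <- cfg$betaN
  betas <- c(0, betas_1N)
  alphas <- diff(betas)
  structure(
    list(betas = betas, alphas = alphas, gamma = cfg$gamma,
         n_steps = N, config = cfg),
    class = "rs_schedule"
  )
}

check_step <- function(sched, t, min_t = 1L) {
  if (!is.numeric(t) || length(t) != 1L || t != round(t) ||
      t < min_t || t > sched$n_steps)
    stop(sprintf("step index t must be an integer in [%d, %d]",
                 min_t, sched$n_steps), call. = FALSE)
  as.integer(t)
}

#' Query schedule coefficients
#'
#' \code{beta_at()} returns \eqn{\beta_t} (with \code{t = 0} allowed,
#' giving 0); \code{alpha_at()} returns \eqn{\alpha_t = \beta_t - \beta_{t-1}} for
#' \code{t} in 1..N; \code{noise_level()} returns \eqn{\sqrt{\beta_t}},
#' the dimensionless noise magnitude the denoiser is conditioned on.
#' Conditioning on this continuous level (rather than the integer index)
#' lets a model trained under one schedule length be queried under
#' another.
#'
#' @param sched An \code{"rs_schedule"}.
#' @param t Step index.
#' @return A scalar coefficient.
#' @export
beta_at <- function(sched, t) {
  stopifnot(inherits(sched, "rs_schedule"))
  t <- check_step(sched, t, min_t = 0L)
  sched$betas[t + 1L]
}

#' @rdname beta_at
#' @export
alpha_at <- function(sched, t) {
  stopifnot(inherits(sched, "rs_schedule"))
  t <- check_step(sched, t)
  sched$alphas[t]
}

#' @rdname beta_at
#' @export
noise_level <- function(sched, t) {
  stopifnot(inherits(sched, "rs_schedule"))
  t <- check_step(sched, t)
  sqrt(sched$betas[t + 1L])
}

#' @export
print.rs_schedule <- function(x, ...) {
  cat(sprintf(
    "<rs_schedule> N = %d steps, gamma = %g, p = %g\n  beta: %.3g .. %.3g\n",
    x$n_steps, x$gamma, x$config$p, x$config$beta1, x$config$betaN))
  invisible(x)
}

#' Tabulate a schedule
#'
#' One row per step with \eqn{\beta_t}, \eqn{\alpha_t} and the noise
#' level \eqn{\sqrt{\beta_t}}; convenient for inspection and CSV export.
#'
#' @param x An \code{"rs_schedule"}.
#' @param ... Unused.
#' @return A tibble with columns \code{t}, \code{beta}, \code{alpha},
#'   \code{noise_level}.
#' @export
schedule_table <- function(x, ...) {
  stopifnot(inherits(x, "rs_schedule"))
  tibble::tibble(
    t = seq_len(x$n_steps),
    beta = x$betas[-1L],
    alpha = x$alphas,
    noise_level = sqrt(x$betas[-1L])
  )
}

#' @importFrom generics tidy
#' @method tidy rs_schedule
#' @export
tidy.rs_schedule <- function(x, ...) schedule_table(x, ...)

#' Plot the shifting sequence
#'
#' Shows \eqn{\beta_t} against \eqn{t}; useful to compare growth-rate
#' exponents.
#'
#' @param object An \code{"rs_schedule"}.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot rs_schedule
#' @export
autoplot.rs_schedule <- function(object, ...) {
  d <- schedule_table(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$beta)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "step t", y = expression(beta[t]),
                  title = sprintf("Shifting sequence (N = %d, p = %g)",
                                  object$n_steps, object$config$p))
}
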