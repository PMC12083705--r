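# Independent reference implementations used as oracles in the tests.
# These deliberately share no code with the package internals.

# brute-force SSIM: explicit double loop over valid window positions
# with Gaussian-weighted local moments
ssim_bruteforce <- function(ref, test, data_range = max(ref),
                            size = 11L, sigma = 1.5,
                            K1 = 0.01, K2 = 0.03) {
  off <- seq_len(size) - (size + 1) / 2
  w1 <- exp(-off^2 / (2 * sigma^2))
  w <- outer(w1, w1)
  w <- w / sum(w)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  h <- (size - 1L) / 2L
  vals <- c()
  for (i in (1 + h):(nrow(ref) - h)) {
    for (j in (1 + h):(ncol(ref) - h)) {
      a <- ref[(i - h):(i + h), (j - h):(j + h)]
      b <- test[(i - h):(i + h), (j - h):(j + h)]
      mx <- sum(w * a); my <- sum(w * b)
      vx <- sum(w * a^2) - mx^2
      vy <- sum(w * b^2) - my^2
      vxy <- sum(w * a * b) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * vxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}

# numeric (grid-quadrature) mean and variance of the scalar reverse
# posterior q(z | x_t, x, y) for one pixel, obtained by pointwise Bayes:
# q(z | x_t, x, y) propto q(x_t | z, y) q(z | x, y)
posterior_oracle <- function(x_t, x, y, sched, t) {
  r <- y - x
  g <- sched$gamma
  bt <- sched$betas[t + 1]
  btm1 <- sched$betas[t]
  at <- sched$alphas[t]
  centre <- (btm1 / bt) * x_t + (at / bt) * x
  sd_guess <- g * sqrt(max(btm1 * at / bt, 1e-12))
  z <- seq(centre - 10 * sd_guess, centre + 10 * sd_guess,
           length.out = 40001)
  logp <- stats::dnorm(x_t, z + at * r, g * sqrt(at), log = TRUE) +
    stats::dnorm(z, x + btm1 * r, g * sqrt(btm1), log = TRUE)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  m <- sum(z * p)
  v <- sum((z - m)^2 * p)
  list(mean = m, var = v)
}

# small, fast phantom + corruption pair for unit tests
tiny_pair <- function(size = 64L, level = "moderate", seed = 1L) {
  x <- make_phantom(phantom_config(size), seed = seed)
  y <- corrupt(x, motion_config(level), seed = seed + 1000L)$image
  paired_sample(x, y)
}
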