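#' Configuration for synthetic brain-like phantoms
#'
#' The generator composes a T1-weighted-looking axial slice from simple
#' geometry: a bright outer annulus standing in for subcutaneous fat and
#' skull (so that ghosting of bright rim tissue is visible after motion
#' corruption), a mid-intensity elliptical "parenchyma", dark
#' ventricle-like ellipses near the centre, and a random collection of
#' small elliptical lesions/structures. Intensities are clipped to
#' [0, 1].
#'
#' @param size Grid edge in pixels (square image). Should be divisible by
#'   the denoiser's downsampling factor if the phantom is used for
#'   training (default 64).
#' @param n_ellipses Integer range (length-2) for the number of random
#'   internal ellipses.
#' @param skull_ring Add the bright outer annulus (default TRUE).
#' @return An object of class \code{"rs_phantom_config"}.
#' @export
phantom_config <- function(size = 64L, n_ellipses = c(4L, 8L),
                           skull_ring = TRUE) {
  size <- as.integer(size)
  if (is.na(size) || size < 16L) stop("`size` must be >= 16", call. = FALSE)
  if (length(n_ellipses) != 2L || any(n_ellipses < 0) ||
      n_ellipses[1] > n_ellipses[2])
    stop("`n_ellipses` must be an increasing integer range", call. = FALSE)
  structure(list(size = size, n_ellipses = as.integer(n_ellipses),
                 skull_ring = isTRUE(skull_ring)),
            class = "rs_phantom_config")
}

# Additively paint an axis-aligned-after-rotation ellipse onto `img`.
paint_ellipse <- function(img, cx, cy, a, b, theta, value) {
  n <- nrow(img)
  xs <- matrix(rep(seq_len(n), n), n) - cx
  ys <- matrix(rep(seq_len(n), each = n), n) - cy
  ct <- cos(theta); st <- sin(theta)
  u <- (xs * ct + ys * st) / a
  v <- (-xs * st + ys * ct) / b
  img + value * (u^2 + v^2 <= 1)
}

#' Generate one synthetic magnitude phantom
#'
#' Deterministic for a given seed; values in [0, 1] with at least two
#' distinct intensity regions.
#'
#' @param cfg A \code{\link{phantom_config}}.
#' @param seed Integer seed controlling all randomness in the phantom.
#' @return A \code{size x size} numeric matrix in [0, 1].
#' @export
#' @examples
#' ph <- make_phantom(phantom_config(size = 64), seed = 1)
#' range(ph)
make_phantom <- function(cfg = phantom_config(), seed = 1L) {
  stopifnot(inherits(cfg, "rs_phantom_config"))
  withr::local_seed(as.integer(seed))
  n <- cfg$size
  c0 <- (n + 1) / 2
  img <- matrix(0, n, n)

  # head outline: slightly eccentric, slightly off-centre
  ha <- n * stats::runif(1, 0.40, 0.44)
  hb <- n * stats::runif(1, 0.34, 0.38)
  hth <- stats::runif(1, -0.15, 0.15)
  hcx <- c0 + stats::runif(1, -1.5, 1.5)
  hcy <- c0 + stats::runif(1, -1.5, 1.5)

  if (cfg$skull_ring) {
    # bright fat/skull rim: outer ellipse minus inner ellipse
    img <- paint_ellipse(img, hcx, hcy, ha, hb, hth, 0.95)
    img <- paint_ellipse(img, hcx, hcy, ha * 0.90, hb * 0.90, hth, -0.95)
  }
  # parenchyma
  brain_lvl <- stats::runif(1, 0.45, 0.60)
  img <- paint_ellipse(img, hcx, hcy, ha * 0.86, hb * 0.86, hth, brain_lvl)

  # dark ventricles: two small ellipses flanking the midline
  voff <- n * stats::runif(1, 0.04, 0.07)
  va <- n * stats::runif(1, 0.05, 0.09)
  vb <- n * stats::runif(1, 0.12, 0.16)
  for (s in c(-1, 1))
    img <- paint_ellipse(img, hcx + s * voff, hcy, va, vb,
                         hth + s * stats::runif(1, 0.1, 0.35),
                         -brain_lvl * stats::runif(1, 0.6, 0.85))

  # random internal structures
  k <- sample(seq(cfg$n_ellipses[1], cfg$n_ellipses[2]), 1)
  for (i in seq_len(k)) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0.08, 0.30) * n
    img <- paint_ellipse(img,
                         hcx + rad * cos(ang) * 0.9,
                         hcy + rad * sin(ang) * 0.7,
                         n * stats::runif(1, 0.02, 0.07),
                         n * stats::runif(1, 0.02, 0.07),
                         stats::runif(1, 0, pi),
                         stats::runif(1, -0.25, 0.35))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a train/validation/test fixture suite of paired samples
#'
#' Draws \code{n} phantoms with distinct seeds, splits them disjointly
#' into train/val/test, and corrupts each with the motion simulator at
#' every requested severity level. The result is the self-contained
#' paired dataset every other stage (training, restoration, evaluation)
#' consumes — no external data needed.
#'
#' @param n Total number of phantoms (>= 3).
#' @param cfg A \code{\link{phantom_config}}.
#' @param levels Character vector of severity levels (subset of
#'   \code{c("minor", "moderate", "heavy")}).
#' @param seed Master seed; per-phantom and per-corruption seeds are
#'   derived from it.
#' @param frac Length-3 train/val/test fractions (summing to 1).
#' @return A list with tibbles \code{train}, \code{val}, \code{test},
#'   each as returned by \code{\link{make_paired_dataset}} (one row per
#'   phantom x level, list-columns \code{x}, \code{y}, \code{r}).
#' @export
make_fixture_suite <- function(n, cfg = phantom_config(),
                               levels = c("minor", "moderate", "heavy"),
                               seed = 1L, frac = c(0.6, 0.2, 0.2)) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("need n >= 3 phantoms to split", call. = FALSE)
  stopifnot(length(frac) == 3L, abs(sum(frac) - 1) < 1e-8)
  seed <- as.integer(seed)
  phantom_seeds <- seed * 1000L + seq_len(n)
  imgs <- lapply(phantom_seeds, function(s) make_phantom(cfg, seed = s))

  n_train <- max(1L, floor(frac[1] * n))
  n_val <- max(1L, floor(frac[2] * n))
  if (n_train + n_val >= n) { # guarantee a non-empty test split
    n_train <- n - 2L; n_val <- 1L
  }
  idx <- list(train = seq_len(n_train),
              val = n_train + seq_len(n_val),
              test = (n_train + n_val + 1L):n)

  out <- lapply(names(idx), function(split) {
    i <- idx[[split]]
    d <- make_paired_dataset(imgs[i], levels = levels,
                             seed = seed + match(split, names(idx)) * 100000L)
    d$phantom_seed <- rep(phantom_seeds[i], each = length(levels))
    d$split <- split
    d
  })
  names(out) <- names(idx)
  out
}
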