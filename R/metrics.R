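#' Normalized mean squared error (percent)
#'
#' \eqn{100 \cdot \|test - ref\|^2 / \|ref\|^2} with sums over all
#' pixels. Lower is better; 0 means a perfect match.
#'
#' @param ref Reference (ground-truth) image, not identically zero.
#' @param test Image under evaluation, same dimensions.
#' @return NMSE in percent.
#' @export
#' @examples
#' nmse(matrix(1, 4, 4), matrix(1.1, 4, 4)) # 1.0000...
nmse <- function(ref, test) {
  stopifnot(all(dim(ref) == dim(test)))
  denom <- sum(ref^2)
  if (denom == 0) stop("reference image is identically zero", call. = FALSE)
  100 * sum((test - ref)^2) / denom
}

#' Peak signal-to-noise ratio (dB)
#'
#' \eqn{10 \log_{10}(\mathrm{range}^2 / \mathrm{MSE})}; returns
#' \code{Inf} for identical images. Higher is better.
#'
#' @param ref,test Images of identical dimensions.
#' @param data_range Dynamic range of the reference; defaults to
#'   \code{max(ref)}.
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, data_range = max(ref)) {
  stopifnot(all(dim(ref) == dim(test)))
  if (data_range <= 0) stop("`data_range` must be positive", call. = FALSE)
  mse <- mean((test - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# 1-D Gaussian kernel, truncated at +/- (size-1)/2, unit sum
gauss_kernel <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable "valid" 2-D Gaussian filtering via band-matrix multiplication
gauss_filter_valid <- function(img, kern) {
  n <- length(kern)
  nr <- nrow(img) - n + 1L; nc <- ncol(img) - n + 1L
  L <- matrix(0, nr, nrow(img))
  for (k in seq_len(n)) L[cbind(seq_len(nr), seq_len(nr) + k - 1L)] <- kern[k]
  R <- matrix(0, ncol(img), nc)
  for (k in seq_len(n)) R[cbind(seq_len(nc) + k - 1L, seq_len(nc))] <- kern[k]
  L %*% img %*% R
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with an 11x11 Gaussian window (\eqn{\sigma = 1.5})
#' and stability constants \eqn{K_1 = 0.01}, \eqn{K_2 = 0.03} — the
#' defaults of the standard image-quality evaluation libraries. Local
#' statistics are Gaussian-weighted moments and the map is averaged over
#' the valid (fully overlapping) window positions. Values lie in
#' [-1, 1]; 1 means structurally identical.
#'
#' @param ref,test Images of identical dimensions, at least 11 pixels
#'   per side.
#' @param data_range Dynamic range; defaults to \code{max(ref)}.
#' @param window_size,sigma Gaussian window parameters.
#' @param K1,K2 Stability constants.
#' @return Scalar SSIM.
#' @export
ssim <- function(ref, test, data_range = max(ref),
                 window_size = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  stopifnot(all(dim(ref) == dim(test)))
  if (any(dim(ref) < window_size))
    stop("image smaller than the SSIM window", call. = FALSE)
  if (data_range <= 0) stop("`data_range` must be positive", call. = FALSE)
  kern <- gauss_kernel(window_size, sigma)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mu_x <- gauss_filter_valid(ref, kern)
  mu_y <- gauss_filter_valid(test, kern)
  sxx <- gauss_filter_valid(ref * ref, kern) - mu_x^2
  syy <- gauss_filter_valid(test * test, kern) - mu_y^2
  sxy <- gauss_filter_valid(ref * test, kern) - mu_x * mu_y
  smap <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  mean(smap)
}

#' Pixel-wise Pearson correlation
#'
#' Product-moment correlation between the flattened pixel values of the
#' two images.
#'
#' @param ref Reference image with non-zero variance.
#' @param test Image under evaluation.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson <- function(ref, test) {
  stopifnot(all(dim(ref) == dim(test)))
  if (stats::var(as.vector(ref)) == 0 || stats::var(as.vector(test)) == 0)
    stop("zero-variance input", call. = FALSE)
  stats::cor(as.vector(ref), as.vector(test))
}

metric_row <- function(ref, test) {
  tibble::tibble(
    nmse_pct = nmse(ref, test),
    ssim = ssim(ref, test),
    psnr_db = psnr(ref, test),
    pearson_rho = pearson(ref, test)
  )
}

#' Evaluate restored images against a paired dataset
#'
#' Computes per-pair NMSE, SSIM, PSNR and Pearson correlation of the
#' restored image against the motion-free ground truth, alongside the
#' same metrics for the corrupted input (the "do-nothing" baseline). The
#' PSNR/SSIM data range is the per-pair maximum of the reference image.
#'
#' @param samples Paired dataset tibble (from
#'   \code{\link{make_paired_dataset}} or a fixture-suite split) with
#'   list-columns \code{x}, \code{y} and a \code{level} column.
#' @param restored List of restored images, one per row of
#'   \code{samples}; when NULL only the corrupted baseline is scored.
#' @return An object of class \code{"rs_metrics"}: a tibble with one row
#'   per (pair, image role) and a \code{role} column distinguishing
#'   \code{"corrupted"} from \code{"restored"}.
#' @export
evaluate_pairs <- function(samples, restored = NULL) {
  stopifnot(is.data.frame(samples), all(c("x", "y", "level") %in%
                                          names(samples)))
  if (!is.null(restored) && length(restored) != nrow(samples))
    stop("need exactly one restored image per sample", call. = FALSE)
  score <- function(imgs, role) {
    rows <- purrr::map2(samples$x, imgs, metric_row)
    out <- dplyr::bind_rows(rows)
    out$pair <- seq_len(nrow(samples))
    out$level <- samples$level
    out$role <- role
    out
  }
  res <- score(samples$y, "corrupted")
  if (!is.null(restored)) res <- dplyr::bind_rows(res, score(restored,
                                                             "restored"))
  res <- dplyr::relocate(res, "pair", "level", "role")
  class(res) <- c("rs_metrics", class(res))
  res
}

#' @importFrom generics tidy glance
#' @method tidy rs_metrics
#' @export
tidy.rs_metrics <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Summarise a metrics report as mean +/- sd per severity level and role
#'
#' @param x An \code{"rs_metrics"} object.
#' @param ... Unused.
#' @return A tibble with one row per (level, role) and mean/sd columns
#'   for each metric.
#' @method glance rs_metrics
#' @export
glance.rs_metrics <- function(x, ...) {
  tibble::as_tibble(unclass(x)) |>
    dplyr::group_by(.data$level, .data$role) |>
    dplyr::summarise(dplyr::across(
      c("nmse_pct", "ssim", "psnr_db", "pearson_rho"),
      list(mean = mean, sd = stats::sd)), n_pairs = dplyr::n(),
      .groups = "drop")
}

#' Boxplots of paired image-quality metrics
#'
#' @param object An \code{"rs_metrics"} object.
#' @param ... Unused.
#' @return A ggplot object faceted by metric.
#' @method autoplot rs_metrics
#' @export
autoplot.rs_metrics <- function(object, ...) {
  d <- tibble::as_tibble(unclass(object)) |>
    tidyr::pivot_longer(c("nmse_pct", "ssim", "psnr_db", "pearson_rho"),
                        names_to = "metric", values_to = "value")
  d$level <- factor(d$level, levels = c("minor", "moderate", "heavy"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$value,
                                  fill = .data$role)) +
    ggplot2::geom_boxplot(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "distortion level", y = NULL, fill = NULL)
}
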