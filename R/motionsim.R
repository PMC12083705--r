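#' Motion-corruption severity configuration
#'
#' Rigid head motion between phase-encode excitations is emulated by
#' replacing slabs of phase-encode k-space lines with the corresponding
#' lines of a rigidly moved copy of the image. A severity preset fixes
#' the total budget of perturbed lines: 7 (\code{minor}), 10
#' (\code{moderate}) or 15 (\code{heavy}). Slab widths are drawn from
#' \code{slab_width_range}, each slab carries one independent rigid
#' motion with rotation uniform in \code{[-rot_deg, rot_deg]} degrees and
#' an in-plane translation uniform in \code{[-trans_mm, trans_mm]} mm per
#' axis.
#'
#' @param level One of \code{"minor"}, \code{"moderate"}, \code{"heavy"}.
#' @param n_lines Total perturbed-line budget; defaults to the preset for
#'   \code{level}.
#' @param slab_width_range Integer interval of slab widths (default 3–7).
#' @param rot_deg Rotation bound in degrees (default 7).
#' @param trans_mm Translation bound in mm per in-plane axis (default 5).
#' @param pixel_spacing_mm Pixel spacing in mm, length 1 or 2 (default 1).
#' @param pe_axis Phase-encoding axis: 1 = rows (default), 2 = columns.
#' @param exclude_center If TRUE, slabs avoid the central 1/8 of k-space
#'   (default FALSE; placement is uniform over all feasible positions).
#' @param noise_sd Standard deviation of optional additive Gaussian noise
#'   applied to the corrupted image (default 0, i.e. pure line
#'   replacement).
#' @return An object of class \code{"rs_motion_config"}.
#' @export
#' @examples
#' motion_config("heavy")$n_lines # 15
motion_config <- function(level = c("moderate", "minor", "heavy"),
                          n_lines = NULL,
                          slab_width_range = c(3L, 7L),
                          rot_deg = 7, trans_mm = 5,
                          pixel_spacing_mm = 1,
                          pe_axis = 1L,
                          exclude_center = FALSE,
                          noise_sd = 0) {
  level <- match.arg(level)
  presets <- c(minor = 7L, moderate = 10L, heavy = 15L)
  if (is.null(n_lines)) n_lines <- presets[[level]]
  n_lines <- as.integer(n_lines)
  slab_width_range <- as.integer(slab_width_range)
  if (length(slab_width_range) != 2L || slab_width_range[1] < 1L ||
      slab_width_range[1] > slab_width_range[2])
    stop("`slab_width_range` must be an increasing positive interval",
         call. = FALSE)
  if (n_lines < slab_width_range[1])
    stop("`n_lines` must be at least the minimum slab width", call. = FALSE)
  if (rot_deg < 0 || trans_mm < 0)
    stop("rotation/translation bounds must be non-negative", call. = FALSE)
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (any(pixel_spacing_mm <= 0))
    stop("`pixel_spacing_mm` must be positive", call. = FALSE)
  if (!pe_axis %in% c(1L, 2L)) stop("`pe_axis` must be 1 or 2", call. = FALSE)
  structure(
    list(level = level, n_lines = n_lines,
         slab_width_range = slab_width_range,
         rot_deg = rot_deg, trans_mm = trans_mm,
         pixel_spacing_mm = pixel_spacing_mm,
         pe_axis = as.integer(pe_axis),
         exclude_center = isTRUE(exclude_center),
         noise_sd = noise_sd),
    class = "rs_motion_config"
  )
}

# centred 2-D spectrum helpers (DC moved to the middle of the grid)
fftshift2 <- function(m) {
  i <- c((floor(nrow(m) / 2) + 1):nrow(m), seq_len(floor(nrow(m) / 2)))
  j <- c((floor(ncol(m) / 2) + 1):ncol(m), seq_len(floor(ncol(m) / 2)))
  m[i, j, drop = FALSE]
}
ifftshift2 <- function(m) {
  i <- c((ceiling(nrow(m) / 2) + 1):nrow(m), seq_len(ceiling(nrow(m) / 2)))
  j <- c((ceiling(ncol(m) / 2) + 1):ncol(m), seq_len(ceiling(ncol(m) / 2)))
  m[i, j, drop = FALSE]
}

# conjugate-mirror row in the centred spectrum: for a real image, line r
# and line mirror_row(r) are complex-conjugate duplicates of one another
# (self-paired at DC and, for even grids, at the Nyquist line).
mirror_row <- function(r, n) {
  if (n %% 2L == 0L) ifelse(r == 1L, 1L, n + 2L - r) else n + 1L - r
}

line_class <- function(r, n) pmin(r, mirror_row(r, n))

#' Plan the perturbed k-space slabs for one corruption
#'
#' Draws slab widths uniformly from the configured range until the total
#' line budget is met (the final slab is truncated so the total equals
#' \code{n_lines} exactly), then places the slabs with starts uniform
#' over the feasible positions, and attaches one rigid motion (rotation
#' + in-plane translation) per slab.
#'
#' Because the images are real-valued (zero-phase) objects, a
#' phase-encode line and its conjugate-mirror line are a single acquired
#' measurement; feasibility is therefore tracked over distinct
#' conjugate-line classes. Slabs are pairwise disjoint, never overlap
#' another slab's mirror image, and never contain both members of a
#' mirror pair — so the plan perturbs exactly \code{n_lines} distinct
#' acquired lines.
#'
#' @param cfg A \code{\link{motion_config}}.
#' @param n_pe_lines Number of phase-encode lines in the grid.
#' @param seed Optional integer seed (NULL uses the current RNG state).
#' @return An object of class \code{"rs_slab_plan"}: a list with
#'   \code{slabs} (tibble: \code{start}, \code{width}, \code{angle_deg},
#'   \code{shift_mm_1}, \code{shift_mm_2}) and \code{total_lines}.
#' @export
select_slabs <- function(cfg, n_pe_lines, seed = NULL) {
  stopifnot(inherits(cfg, "rs_motion_config"))
  n_pe_lines <- as.integer(n_pe_lines)
  if (n_pe_lines <= 2L * cfg$n_lines)
    stop("grid has too few phase-encode lines for the line budget",
         call. = FALSE)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  wmin <- cfg$slab_width_range[1]; wmax <- cfg$slab_width_range[2]
  widths <- integer(0)
  while (sum(widths) < cfg$n_lines) {
    w <- sample(seq(wmin, wmax), 1L)
    if (sum(widths) + w >= cfg$n_lines) w <- cfg$n_lines - sum(widths)
    widths <- c(widths, w)
  }

  forbidden_cls <- integer(0)
  if (cfg$exclude_center) {
    half <- max(1L, floor(n_pe_lines / 16))
    ctr <- floor(n_pe_lines / 2) + 1L
    ctr_rows <- max(1L, ctr - half):min(n_pe_lines, ctr + half)
    forbidden_cls <- unique(line_class(ctr_rows, n_pe_lines))
  }

  place <- function() {
    occupied <- forbidden_cls
    starts <- integer(length(widths))
    for (k in seq_along(widths)) {
      w <- widths[k]
      ok <- vapply(seq_len(n_pe_lines - w + 1L), function(s) {
        cls <- line_class(s:(s + w - 1L), n_pe_lines)
        !anyDuplicated(cls) && !any(cls %in% occupied)
      }, logical(1))
      feas <- which(ok)
      if (length(feas) == 0L) return(NULL)
      s <- if (length(feas) == 1L) feas else sample(feas, 1L)
      starts[k] <- s
      occupied <- c(occupied, line_class(s:(s + w - 1L), n_pe_lines))
    }
    starts
  }
  starts <- NULL
  for (try in 1:100) { # rare packing dead-ends: re-draw placements
    starts <- place()
    if (!is.null(starts)) break
  }
  if (is.null(starts))
    stop("could not place slabs disjointly; line budget infeasible for grid",
         call. = FALSE)

  nslab <- length(widths)
  slabs <- tibble::tibble(
    start = starts,
    width = widths,
    angle_deg = stats::runif(nslab, -cfg$rot_deg, cfg$rot_deg),
    shift_mm_1 = stats::runif(nslab, -cfg$trans_mm, cfg$trans_mm),
    shift_mm_2 = stats::runif(nslab, -cfg$trans_mm, cfg$trans_mm)
  )
  structure(list(slabs = slabs, total_lines = sum(widths)),
            class = "rs_slab_plan")
}

#' Apply an in-plane rigid transform to an image
#'
#' Rotates about the image centre, then translates by \code{shift_mm}
#' (converted to pixels via \code{spacing_mm}). Resampling is bilinear
#' with zero fill outside the field of view. A zero motion returns the
#' input bit-exactly.
#'
#' @param img Numeric matrix (magnitude image).
#' @param angle_deg Rotation angle in degrees (counter-clockwise in array
#'   coordinates).
#' @param shift_mm Length-2 translation (rows, columns) in mm.
#' @param spacing_mm Length-2 pixel spacing in mm (default 1 mm).
#' @return Transformed image, same dimensions.
#' @export
rigid_transform <- function(img, angle_deg, shift_mm = c(0, 0),
                            spacing_mm = c(1, 1)) {
  stopifnot(is.matrix(img), length(shift_mm) == 2L)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (any(spacing_mm <= 0)) stop("`spacing_mm` must be positive", call. = FALSE)
  if (angle_deg == 0 && all(shift_mm == 0)) return(img)

  nr <- nrow(img); nc <- ncol(img)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  sh <- shift_mm / spacing_mm
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)

  # inverse map: output pixel -> source coordinate
  i <- matrix(rep(seq_len(nr), nc), nr) - cr - sh[1]
  j <- matrix(rep(seq_len(nc), each = nr), nr) - cc - sh[2]
  src_i <- ct * i + st * j + cr
  src_j <- -st * i + ct * j + cc

  i0 <- floor(src_i); j0 <- floor(src_j)
  di <- src_i - i0; dj <- src_j - j0

  at <- function(ii, jj) {
    v <- matrix(0, nr, nc)
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    v[ok] <- img[cbind(ii[ok], jj[ok])]
    v
  }
  (1 - di) * (1 - dj) * at(i0, j0) +
    (1 - di) * dj * at(i0, j0 + 1) +
    di * (1 - dj) * at(i0 + 1, j0) +
    di * dj * at(i0 + 1, j0 + 1)
}

#' Corrupt an image with simulated rigid motion
#'
#' Computes the centred 2-D discrete Fourier transform of the (real,
#' zero-phase) magnitude image; for each planned slab, substitutes the
#' slab's phase-encode lines — together with their conjugate-mirror
#' lines, which for a real object carry the same measurement — with the
#' corresponding lines of the rigidly moved image's spectrum. The
#' composite spectrum stays conjugate-symmetric, so the reconstruction
#' is real-valued and lines outside the slabs are untouched: exactly
#' \code{n_lines} distinct phase-encode lines differ from the original
#' spectrum whenever the drawn motions are non-trivial. Gibbs ringing
#' from the line replacement may make the output undershoot zero
#' slightly; values are returned as-is.
#'
#' @param img Non-negative numeric matrix with at least 32 lines along
#'   the phase-encode axis, or a 3-D array (corrupted slice by slice,
#'   each slice drawing its own motions; one plan per slice returned).
#' @param cfg A \code{\link{motion_config}}.
#' @param seed Optional integer seed.
#' @param plan Optionally, a precomputed \code{\link{select_slabs}} plan;
#'   drawn from \code{cfg} when NULL.
#' @return A list with \code{image} (corrupted magnitude image) and
#'   \code{plan} (the \code{"rs_slab_plan"} used).
#' @export
#' @examples
#' ph <- make_phantom(phantom_config(64), seed = 2)
#' cy <- corrupt(ph, motion_config("heavy"), seed = 7)
#' nmse(ph, cy$image) > 0
corrupt <- function(img, cfg, seed = NULL, plan = NULL) {
  if (is.array(img) && length(dim(img)) == 3L) {
    # volumes are corrupted slice by slice, each with its own motion
    if (!is.null(seed)) withr::local_seed(as.integer(seed))
    out <- img
    plans <- vector("list", dim(img)[3])
    for (k in seq_len(dim(img)[3])) {
      res <- corrupt(img[, , k], cfg)
      out[, , k] <- res$image
      plans[[k]] <- res$plan
    }
    return(list(image = out, plan = plans))
  }
  stopifnot(is.matrix(img), inherits(cfg, "rs_motion_config"))
  if (any(img < 0)) stop("`img` must be a non-negative magnitude image",
                         call. = FALSE)
  if (cfg$pe_axis == 2L) { # canonicalize: phase encoding along rows
    cfg2 <- cfg; cfg2$pe_axis <- 1L
    cfg2$pixel_spacing_mm <- rev(cfg$pixel_spacing_mm)
    res <- corrupt(t(img), cfg2, seed = seed, plan = plan)
    res$image <- t(res$image)
    return(res)
  }
  n_pe <- nrow(img)
  if (n_pe < 32L) stop("need at least 32 phase-encode lines", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  if (is.null(plan)) plan <- select_slabs(cfg, n_pe)
  stopifnot(inherits(plan, "rs_slab_plan"))

  ksp <- fftshift2(stats::fft(img))
  for (k in seq_len(nrow(plan$slabs))) {
    s <- plan$slabs[k, ]
    moved <- rigid_transform(img, s$angle_deg,
                             c(s$shift_mm_1, s$shift_mm_2),
                             cfg$pixel_spacing_mm)
    ksp_moved <- fftshift2(stats::fft(moved))
    rows <- s$start:(s$start + s$width - 1L)
    rows <- union(rows, mirror_row(rows, n_pe)) # keep conjugate symmetry
    ksp[rows, ] <- ksp_moved[rows, ]
  }
  out <- Re(stats::fft(ifftshift2(ksp), inverse = TRUE)) / length(img)
  if (cfg$noise_sd > 0)
    out <- pmax(out + matrix(stats::rnorm(length(out), sd = cfg$noise_sd),
                             nrow(out)), 0)
  list(image = out, plan = plan)
}

#' Count phase-encode k-space lines that differ between two images
#'
#' Transforms both images to centred k-space and counts the phase-encode
#' lines whose values differ beyond a small relative tolerance. For
#' real-valued images a line and its conjugate mirror are duplicates of
#' one acquired measurement, so differing lines are counted as distinct
#' conjugate-line classes; the result equals the simulator's perturbed
#' line budget.
#'
#' @param a,b Numeric matrices of identical dimensions.
#' @param pe_axis 1 = rows (default), 2 = columns.
#' @param tol Relative tolerance against the spectrum's maximum modulus.
#' @return Integer count of differing acquired lines.
#' @export
count_differing_lines <- function(a, b, pe_axis = 1L, tol = 1e-9) {
  stopifnot(is.matrix(a), all(dim(a) == dim(b)))
  ka <- fftshift2(stats::fft(a)); kb <- fftshift2(stats::fft(b))
  d <- Mod(ka - kb)
  scale <- max(Mod(ka))
  if (pe_axis == 2L) d <- t(d)
  diffline <- apply(d, 1, max) > tol * scale
  n <- nrow(d)
  length(unique(line_class(which(diffline), n)))
}

#' Build a paired motion-free / motion-corrupted dataset
#'
#' One row per (image, severity level) with the clean image \code{x},
#' the corrupted image \code{y}, the residual \code{r = y - x}, the slab
#' plan, and the seed used — everything needed to reproduce or audit the
#' corruption.
#'
#' @param images List of non-negative numeric matrices.
#' @param levels Character vector of severity levels.
#' @param seed Master integer seed; each corruption gets a distinct
#'   derived seed recorded in the output.
#' @param ... Additional arguments passed to \code{\link{motion_config}}.
#' @return A tibble with columns \code{id}, \code{level}, \code{seed},
#'   and list-columns \code{x}, \code{y}, \code{r}, \code{plan}.
#' @export
make_paired_dataset <- function(images,
                                levels = c("minor", "moderate", "heavy"),
                                seed = 1L, ...) {
  if (!is.list(images) || length(images) == 0L)
    stop("`images` must be a non-empty list of matrices", call. = FALSE)
  levels <- match.arg(levels, c("minor", "moderate", "heavy"),
                      several.ok = TRUE)
  seed <- as.integer(seed)
  grid <- tidyr::expand_grid(id = seq_along(images), level = levels)
  grid$seed <- seed + seq_len(nrow(grid)) - 1L
  rows <- purrr::pmap(grid, function(id, level, seed) {
    clean <- images[[id]]
    res <- corrupt(clean, motion_config(level, ...), seed = seed)
    resid <- res$image - clean
    tibble::tibble(id = id, level = level, seed = seed,
                   x = list(clean), y = list(res$image),
                   r = list(resid), plan = list(res$plan))
  })
  dplyr::bind_rows(rows)
}
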