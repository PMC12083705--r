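test_that("severity presets carry the printed line budgets", {
  expect_equal(motion_config("minor")$n_lines, 7L)
  expect_equal(motion_config("moderate")$n_lines, 10L)
  expect_equal(motion_config("heavy")$n_lines, 15L)
})

test_that("slab plans meet the budget exactly with legal widths", {
  cfg <- motion_config("heavy")
  n_pe <- 128L
  for (seed in 1:200) {
    plan <- select_slabs(cfg, n_pe, seed = seed)
    s <- plan$slabs
    expect_equal(sum(s$width), 15L)
    expect_equal(plan$total_lines, 15L)
    expect_true(all(s$width <= 7L))
    expect_lte(sum(s$width < 3L), 1L) # at most one truncated slab
    # slabs disjoint as conjugate-line classes (hence also as rows)
    cls <- unlist(lapply(seq_len(nrow(s)), function(k)
      rsmoco:::line_class(s$start[k]:(s$start[k] + s$width[k] - 1L), n_pe)))
    expect_false(any(duplicated(cls)))
    expect_true(all(abs(s$angle_deg) <= 7))
    expect_true(all(abs(c(s$shift_mm_1, s$shift_mm_2)) <= 5))
  }
})

test_that("a budget equal to the minimum width yields one slab", {
  cfg <- motion_config("minor", n_lines = 3L)
  plan <- select_slabs(cfg, 64L, seed = 1)
  expect_equal(nrow(plan$slabs), 1L)
  expect_equal(plan$slabs$width, 3L)
})

test_that("infeasible budgets are rejected", {
  cfg <- motion_config("heavy")
  expect_error(select_slabs(cfg, 30L), "too few")
})

test_that("rigid transform: identity, pure translation, rotation round trip", {
  img <- make_phantom(phantom_config(64), seed = 5)
  expect_identical(rigid_transform(img, 0, c(0, 0)), img)

  delta <- matrix(0, 64, 64)
  delta[30, 20] <- 1
  moved <- rigid_transform(delta, 0, c(5, 0), c(1, 1))
  expect_equal(moved[35, 20], 1)
  expect_equal(sum(moved), 1)

  smooth <- outer(dnorm(1:64, 32, 12), dnorm(1:64, 32, 12))
  smooth <- smooth / max(smooth)
  back <- rigid_transform(rigid_transform(smooth, 7, c(0, 0)), -7, c(0, 0))
  expect_lt(max(abs(back - smooth)) / max(smooth), 5e-2)
})

test_that("corruption touches exactly the budgeted phase-encode lines", {
  ph <- make_phantom(phantom_config(128), seed = 2)
  for (lv in c(minor = 7L, moderate = 10L, heavy = 15L)) {
    nm <- names(which(c(minor = 7L, moderate = 10L, heavy = 15L) == lv))
    res <- corrupt(ph, motion_config(nm), seed = 11)
    expect_equal(count_differing_lines(ph, res$image), as.integer(lv))
  }
})

test_that("k-space lines outside the slabs are untouched", {
  ph <- make_phantom(phantom_config(64), seed = 9)
  res <- corrupt(ph, motion_config("moderate"), seed = 4)
  n <- 64L
  ka <- rsmoco:::fftshift2(stats::fft(ph))
  kb <- rsmoco:::fftshift2(stats::fft(res$image))
  s <- res$plan$slabs
  touched <- unlist(lapply(seq_len(nrow(s)), function(k) {
    rows <- s$start[k]:(s$start[k] + s$width[k] - 1L)
    union(rows, rsmoco:::mirror_row(rows, n))
  }))
  untouched <- setdiff(seq_len(n), touched)
  expect_lt(max(Mod(ka[untouched, ] - kb[untouched, ])) / max(Mod(ka)),
            1e-12)
})

test_that("zero-amplitude motion is the identity within FFT round-off", {
  ph <- make_phantom(phantom_config(64), seed = 3)
  res <- corrupt(ph, motion_config("heavy", rot_deg = 0, trans_mm = 0),
                 seed = 8)
  expect_lt(max(abs(res$image - ph)) / max(ph), 1e-6)
})

test_that("corruption is deterministic given a seed", {
  ph <- make_phantom(phantom_config(64), seed = 4)
  a <- corrupt(ph, motion_config("heavy"), seed = 21)
  b <- corrupt(ph, motion_config("heavy"), seed = 21)
  expect_identical(a$image, b$image)
  expect_identical(a$plan$slabs, b$plan$slabs)
})

test_that("phase encoding along columns mirrors the row behaviour", {
  ph <- make_phantom(phantom_config(64), seed = 6)
  res <- corrupt(ph, motion_config("minor", pe_axis = 2L), seed = 13)
  expect_equal(count_differing_lines(ph, res$image, pe_axis = 2L), 7L)
  expect_gt(count_differing_lines(ph, res$image, pe_axis = 1L), 7L)
})

test_that("volumes are corrupted slice by slice", {
  vol <- array(0, c(64, 64, 3))
  for (k in 1:3) vol[, , k] <- make_phantom(phantom_config(64), seed = k)
  res <- corrupt(vol, motion_config("minor"), seed = 5)
  expect_equal(dim(res$image), dim(vol))
  expect_length(res$plan, 3L)
  for (k in 1:3)
    expect_equal(count_differing_lines(vol[, , k], res$image[, , k]), 7L)
  # slices draw independent motions
  expect_false(identical(res$plan[[1]]$slabs, res$plan[[2]]$slabs))
})

test_that("paired datasets record residuals and metadata", {
  imgs <- lapply(1:3, function(s) make_phantom(phantom_config(64), seed = s))
  d <- make_paired_dataset(imgs, levels = c("minor", "heavy"), seed = 2)
  expect_equal(nrow(d), 6L)
  expect_setequal(unique(d$level), c("minor", "heavy"))
  for (i in seq_len(nrow(d)))
    expect_identical(d$r[[i]], d$y[[i]] - d$x[[i]])
  expect_error(make_paired_dataset(list()), "non-empty")
})
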