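test_that("NMSE matches closed forms and a brute-force recomputation", {
  ref <- matrix(1, 8, 8)
  expect_equal(nmse(ref, ref), 0)
  expect_equal(nmse(ref, 1.1 * ref), 1.0, tolerance = 1e-12)
  set.seed(1)
  a <- matrix(runif(256), 16)
  b <- matrix(runif(256), 16)
  expect_equal(nmse(a, b), 100 * sum((b - a)^2) / sum(a^2),
               tolerance = 1e-10)
  expect_error(nmse(matrix(0, 4, 4), matrix(1, 4, 4)), "zero")
})

test_that("PSNR follows its logarithmic closed form", {
  ref <- matrix(0.5, 10, 10)
  test <- ref + 0.1 # MSE = 0.01
  expect_equal(psnr(ref, test, data_range = 1), 20)
  expect_identical(psnr(ref, ref), Inf)
  # doubling the noise std costs ~6.02 dB
  set.seed(2)
  base <- matrix(runif(64 * 64), 64)
  n1 <- matrix(rnorm(64 * 64, sd = 0.05), 64)
  d <- psnr(base, base + n1, 1) - psnr(base, base + 2 * n1, 1)
  expect_equal(d, 20 * log10(2), tolerance = 1e-9)
})

test_that("SSIM matches an independent brute-force implementation", {
  set.seed(3)
  for (i in 1:4) {
    a <- matrix(runif(24 * 24), 24)
    b <- a + matrix(rnorm(24 * 24, sd = 0.1 * i), 24)
    expect_equal(ssim(a, b), ssim_bruteforce(a, b), tolerance = 1e-4)
  }
  ph <- make_phantom(phantom_config(64), seed = 1)
  expect_equal(ssim(ph, ph), 1.0)
  expect_lt(ssim(ph, matrix(mean(ph), 64, 64)), 0.5)
  expect_error(ssim(matrix(1, 5, 5), matrix(1, 5, 5)), "window")
})

test_that("Pearson correlation honours affine invariance and the formula", {
  set.seed(4)
  a <- matrix(runif(100), 10)
  expect_equal(pearson(a, 2 * a + 3), 1.0, tolerance = 1e-12)
  expect_equal(pearson(a, -a), -1.0, tolerance = 1e-12)
  b <- matrix(runif(100), 10)
  av <- as.vector(a); bv <- as.vector(b)
  expected <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(pearson(a, b), expected, tolerance = 1e-12)
  expect_error(pearson(matrix(1, 4, 4), matrix(1, 4, 4)), "variance")
})

test_that("metrics move the right way as noise grows", {
  set.seed(5)
  ph <- make_phantom(phantom_config(64), seed = 2)
  sds <- c(0.02, 0.05, 0.1)
  noisy <- lapply(sds, function(s) ph + matrix(rnorm(64 * 64, sd = s), 64))
  ps <- vapply(noisy, function(v) psnr(ph, v), numeric(1))
  ss <- vapply(noisy, function(v) ssim(ph, v), numeric(1))
  nm <- vapply(noisy, function(v) nmse(ph, v), numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(diff(ss) < 0))
  expect_true(all(diff(nm) > 0))
})

test_that("evaluate_pairs aggregates per-pair metrics faithfully", {
  imgs <- lapply(1:2, function(s) make_phantom(phantom_config(64), seed = s))
  d <- make_paired_dataset(imgs, levels = c("minor", "heavy"), seed = 9)

  # perfect restorer: zero NMSE, unit SSIM
  perfect <- d$x
  m <- evaluate_pairs(d, perfect)
  tm <- generics::tidy(m)
  rest <- tm[tm$role == "restored", ]
  expect_true(all(rest$nmse_pct == 0))
  expect_true(all(rest$ssim == 1))

  # identity restorer reproduces the corrupted baseline rows
  m2 <- evaluate_pairs(d, d$y)
  t2 <- generics::tidy(m2)
  corr <- t2[t2$role == "corrupted", ]
  rest2 <- t2[t2$role == "restored", ]
  expect_equal(rest2$nmse_pct, corr$nmse_pct)
  expect_equal(rest2$ssim, corr$ssim)

  # summary means match direct per-pair recomputation
  g <- generics::glance(m2)
  for (lv in unique(d$level)) {
    got <- g$nmse_pct_mean[g$level == lv & g$role == "corrupted"]
    manual <- mean(vapply(which(d$level == lv), function(i)
      nmse(d$x[[i]], d$y[[i]]), numeric(1)))
    expect_equal(got, manual, tolerance = 1e-12)
  }
  expect_error(evaluate_pairs(d, d$y[1]), "one restored image")
})
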