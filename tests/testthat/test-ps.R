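test_that("central ROI extraction tiles the centred window", {
  img <- matrix(seq_len(512 * 512), 512, 512)
  rois <- extract_central_rois(img, 64, 128)
  expect_length(rois, 4)
  expect_true(all(vapply(rois, function(r) all(dim(r) == c(64, 64)), TRUE)))
  # quadrants of the central 128x128 window (rows/cols 193..320)
  expect_identical(rois[[1]], img[193:256, 193:256])
  expect_identical(rois[[4]], img[257:320, 257:320])
  # window equal to image
  small <- img[1:128, 1:128]
  rois2 <- extract_central_rois(small, 64, 128)
  expect_identical(rois2[[1]], small[1:64, 1:64])
  # degenerate tiling
  expect_length(extract_central_rois(small, 128, 128), 1)
  expect_error(extract_central_rois(img[1:100, 1:100]), "smaller")
  expect_error(extract_central_rois(img, 48, 128), "divisible")
})

test_that("ROI mirroring produces the even-symmetric double block", {
  m <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)  # [[a,b],[c,d]]
  expect_identical(mirror_roi(m),
                   matrix(c(1, 2, 2, 1,
                            3, 4, 4, 3,
                            3, 4, 4, 3,
                            1, 2, 2, 1), 4, 4, byrow = TRUE))
  v <- matrix(7.5, 3, 3)
  expect_true(all(mirror_roi(v) == 7.5))
  set.seed(5)
  r <- matrix(rnorm(64), 8, 8)
  mr <- mirror_roi(r)
  expect_identical(mr, mr[, rev(seq_len(16))])
  expect_identical(mr, mr[rev(seq_len(16)), ])
})

test_that("block power spectrum satisfies the white-noise level and realness", {
  expect_true(all(roi_power_spectrum(matrix(3, 16, 16), 0.75)$values == 0))
  # white Gaussian blocks: PS averages to sigma^2 * spacing^2
  set.seed(1)
  acc <- 0
  for (i in 1:100)
    acc <- acc + mean(roi_power_spectrum(matrix(rnorm(32^2, sd = 2), 32, 32),
                                         0.5)$values)
  expect_equal(acc / 100, 4 * 0.25, tolerance = 0.05)
  # mirrored blocks have a real (cosine-only) transform
  set.seed(2)
  blk <- mirror_roi(matrix(rnorm(256), 16, 16))
  ft <- fft(blk - mean(blk))
  # imaginary part vanishes up to phase factors from the corner-centred grid:
  # compare |DFT|^2 with the squared real part of the phase-shifted transform
  n <- 32
  ph <- exp(1i * pi * (0:(n - 1)) * (n - 1) / n)
  ftc <- outer(ph, ph) * ft  # recentre on the symmetry point
  expect_lt(max(abs(Im(ftc))) / max(Mod(ft)), 1e-10)
})

test_that("Parseval holds exactly per examination", {
  stk <- apply_noise(flat_stack(side = 128, n_slices = 3),
                     noise_model("sharp_kernel", sigma_ref = 20), seed = 4)
  ps <- examination_ps(stk)
  integral <- sum(ps$values) * ps$freq_spacing^2
  rois <- unlist(lapply(1:3, function(k)
    lapply(extract_central_rois(stk$voxels[, , k]), function(r) {
      m <- mirror_roi(r); mean((m - mean(m))^2)
    })))
  expect_equal(integral, mean(rois), tolerance = 1e-12)
})

test_that("examination averaging is idempotent and permutation-invariant", {
  stk <- apply_noise(flat_stack(side = 128, n_slices = 4),
                     noise_model("smooth_kernel", sigma_ref = 10), seed = 6)
  ps1 <- examination_ps(stk)
  # single slice equals the mean of its four ROI spectra
  one <- ct_stack(stk$voxels[, , 1, drop = FALSE], stk$pixel_spacing)
  m <- Reduce(`+`, lapply(extract_central_rois(stk$voxels[, , 1]), function(r)
    roi_power_spectrum(mirror_roi(r), stk$pixel_spacing)$values)) / 4
  expect_equal(examination_ps(one)$values, m, tolerance = 1e-12)
  # duplicating every slice changes nothing
  dup <- ct_stack(stk$voxels[, , rep(1:4, each = 2)], stk$pixel_spacing)
  expect_equal(examination_ps(dup)$values, ps1$values, tolerance = 1e-12)
  # slice order never matters
  perm <- ct_stack(stk$voxels[, , c(3, 1, 4, 2)], stk$pixel_spacing)
  expect_equal(examination_ps(perm)$values, ps1$values, tolerance = 1e-12)
})

test_that("doubling the noise SD quadruples the spectrum", {
  s1 <- apply_noise(flat_stack(side = 128, n_slices = 20),
                    noise_model("smooth_kernel", sigma_ref = 10), seed = 8)
  s2 <- apply_noise(flat_stack(side = 128, n_slices = 20),
                    noise_model("smooth_kernel", sigma_ref = 20), seed = 9)
  c1 <- radial_average(examination_ps(s1))
  c2 <- radial_average(examination_ps(s2))
  sel <- c1$freq > 0.05 & c1$freq < 0.5 & c1$ps > 0
  expect_equal(median(c2$ps[sel] / c1$ps[sel]), 4, tolerance = 0.1)
})

test_that("radial averaging matches the exhaustive enumeration oracle", {
  # all-ones grid -> every bin is 1
  ones <- ctiq:::new_ps2d(matrix(1, 8, 8), pixel_spacing = 1,
                          n_rois = 1L, n_slices = 1L)
  expect_true(all(radial_average(ones)$ps == 1))
  # anisotropic grid value = u^2 (u = frequency along columns): brute force
  for (n in c(8, 12, 16)) {
    f1 <- c(0:(n / 2 - 1), -(n / 2):-1) / n
    vals <- matrix(f1^2, n, n, byrow = TRUE)  # u^2, u the column frequency
    ps <- ctiq:::new_ps2d(vals, pixel_spacing = 1, n_rois = 1L, n_slices = 1L)
    got <- radial_average(ps)
    fr <- sqrt(outer(f1^2, f1^2, "+"))
    fs <- 1 / n
    # oracle: enumerate every non-DC sample into its bin
    bins <- floor(fr[fr > 0] / fs)
    v <- vals[fr > 0]
    exp_ps <- tapply(v, bins, mean)
    exp_fr <- tapply(fr[fr > 0], bins, mean)
    ord <- order(exp_fr)
    expect_equal(got$ps, as.numeric(exp_ps)[ord], tolerance = 1e-14)
    expect_equal(got$freq, as.numeric(exp_fr)[ord], tolerance = 1e-14)
  }
})

test_that("isotropic bin-constant spectra are reproduced exactly", {
  n <- 16
  f1 <- c(0:(n / 2 - 1), -(n / 2):-1) / n
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  fs <- 1 / n
  vals <- floor(fr / fs) + 1  # piecewise constant on the radial bins
  ps <- ctiq:::new_ps2d(vals, pixel_spacing = 1, n_rois = 1L, n_slices = 1L)
  got <- radial_average(ps)
  expect_equal(got$ps, sort(unique(vals[fr > 0])), tolerance = 1e-14)
})

test_that("cohort curves average correctly and report relative SE", {
  base <- data.frame(freq = c(0.1, 0.2, 0.3), ps = c(2, 4, 8))
  c1 <- ctiq:::new_ps_curve(base)
  expect_equal(cohort_ps(list(c1, c1))$relative_se, c(0, 0, 0))
  c3 <- ctiq:::new_ps_curve(transform(base, ps = 3 * ps))
  cc <- cohort_ps(list(c1, c3))
  expect_equal(cc$ps, base$ps * 2)
  # {c, 3c}: SD = sqrt(2) c, SE = c, relative SE = 50%
  expect_equal(cc$relative_se, c(50, 50, 50))
  expect_error(cohort_ps(list(c1, ctiq:::new_ps_curve(base[1:2, ]))),
               "identical frequency bins")
})

test_that("lower dose lifts the spectrum at every frequency above 0.1/mm", {
  nm_hi <- noise_model("smooth_kernel", sigma_ref = 15, dose_factor = 1)
  nm_lo <- noise_model("smooth_kernel", sigma_ref = 15, dose_factor = 0.25)
  hi <- radial_average(examination_ps(
    apply_noise(flat_stack(128, 20), nm_hi, seed = 21)))
  lo <- radial_average(examination_ps(
    apply_noise(flat_stack(128, 20), nm_lo, seed = 22)))
  sel <- hi$freq > 0.1 & hi$ps > 0
  expect_true(all(lo$ps[sel] > hi$ps[sel]))
})

test_that("sharp-kernel round-trip holds away from leakage-dominated bins", {
  # the 64-px mirrored-ROI estimator leaks power from the band-pass peak into
  # the lowest-frequency bins, where the target spectrum is ~15x below peak;
  # above 0.15/mm the generating filter is recovered to the usual tolerance
  nm <- noise_model("sharp_kernel", sigma_ref = 10)
  stk <- apply_noise(flat_stack(side = 256, n_slices = 40), nm, seed = 402)
  cu <- radial_average(examination_ps(stk))
  nyq <- 1 / (2 * 0.75)
  sel <- cu$freq >= 0.15 & cu$freq <= 0.8 * nyq
  est <- cu$ps[sel] / mean(cu$ps[sel])
  target <- radial_filter(nm, cu$freq[sel])^2
  target <- target / mean(target)
  expect_lt(sqrt(mean(((est - target) / target)^2)), 0.05)
  # and the leakage bias is real: the lowest bins overshoot the target
  low <- cu$freq >= 0.05 & cu$freq < 0.1
  est_l <- cu$ps[low] / mean(cu$ps[sel])
  tgt_l <- radial_filter(nm, cu$freq[low])^2 / mean(radial_filter(nm, cu$freq[sel])^2)
  expect_gt(mean(est_l / tgt_l), 1.1)
})
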