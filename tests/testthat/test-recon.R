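# 1D acquisitions here use 256 samples over the full delta-k coverage, so
# the sweep is sampled at or above the FOV Nyquist rate and full-aperture
# deconvolution is well-posed; the 64-line 2D cases exercise the windowed
# (finite Fresnel aperture) reconstruction instead.

ref_pars <- function() encoding_params(ref_beta(), ref_fov)

setup_1d <- function(n = 256) {
  pars <- ref_pars()
  tr <- spen_trajectory(pars, n)
  y <- centered_1d(n, ref_fov)
  list(pars = pars, tr = tr, y = y,
       op = build_forward_operator(pars, tr, y))
}

test_that("reorder reconstruction maps samples to a monotone position sweep", {
  s1 <- setup_1d()
  blob <- gauss_blob_1d(256, ref_fov, 0.021, 0.004)
  s <- synthesize_spen_signal(blob, s1$op, s1$tr)
  r <- reorder_magnitude(s, s1$pars, s1$tr)
  expect_true(all(diff(r$grid) > 0) || all(diff(r$grid) < 0))
  expect_lt(abs(r$grid[which.max(r$image)] - 0.021), 2 * ref_fov / 256)
  # flat phantom: flat interior away from the FOV edges
  flat <- make_bottle_1d(256, ref_fov, 1, edge_fraction = 0)
  rf <- reorder_magnitude(synthesize_spen_signal(flat, s1$op, s1$tr),
                          s1$pars, s1$tr)
  interior <- abs(r$grid) < 0.3 * ref_fov
  v <- rf$image[interior]
  expect_lt(max(abs(v - stats::median(v))) / stats::median(v), 0.1)
  expect_error(reorder_magnitude(s, encoding_params(0, ref_fov), s1$tr),
               "beta")
})

test_that("fresnel reconstruction is the operator adjoint and localizes a point", {
  s1 <- setup_1d()
  blob <- gauss_blob_1d(256, ref_fov, -0.035, 0.003)
  s <- synthesize_spen_signal(blob, s1$op, s1$tr)
  # adjoint identity on the matched grid
  r_adj <- fresnel_recon(s, s1$pars, s1$tr, out_grid = s1$y,
                         weights = "adjoint")
  expect_equal(r_adj$image,
               as.vector(Conj(t(s1$op$matrix)) %*% s$samples),
               tolerance = 1e-12)
  # narrow-source main lobe width consistent with the coverage
  fine <- seq(-0.045, -0.025, length.out = 2001)
  rp <- fresnel_recon(s, s1$pars, s1$tr, out_grid = fine)
  fw <- profile_fwhm(fine, Mod(rp$image))
  intrinsic <- sqrt(8 * log(2)) * 0.003 # source width dominates
  expect_lt(abs(fw - intrinsic) / intrinsic, 0.3)
  expect_lt(abs(fine[which.max(Mod(rp$image))] + 0.035), 5e-4)

  # bottle phantom: interior recovered within 10% after normalization
  ph <- make_bottle_1d(256, ref_fov, 0.5)
  rb <- fresnel_recon(synthesize_spen_signal(ph, s1$op, s1$tr),
                      s1$pars, s1$tr, out_grid = s1$y)
  img <- Mod(rb$image)
  sc <- sum(img * ph$density) / sum(ph$density^2)
  interior <- abs(s1$y) < 0.2 * ref_fov
  expect_lt(sqrt(mean((img[interior] / sc - 1)^2)), 0.1)
})

test_that("point-source resolution follows the delta-k coverage", {
  # an on-grid impulse synthesized through the operator: the main lobe of
  # the conjugate-phase reconstruction has FWHM ~ 2 pi / delta-k
  s1 <- setup_1d()
  d <- rep(0, 256); d[129] <- 1
  s <- synthesize_spen_signal(digital_phantom(d, ref_fov), s1$op, s1$tr)
  fine <- seq(-0.004, 0.004, length.out = 4001)
  rp <- fresnel_recon(s, s1$pars, s1$tr, out_grid = fine)
  fw <- profile_fwhm(fine, Mod(rp$image))
  expect_lt(abs(fw - 2 * pi / s1$pars$delta_k) / (2 * pi / s1$pars$delta_k),
            0.3)
})

test_that("fresnel-synthesize composition is positive semidefinite", {
  n <- 48
  pars <- ref_pars()
  tr <- spen_trajectory(pars, n)
  y <- centered_1d(n, ref_fov)
  a <- build_forward_operator(pars, tr, y)$matrix
  ev <- eigen(Conj(t(a)) %*% a, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
})

test_that("tikhonov reconstruction matches a brute-force least-squares oracle", {
  n <- 64
  pars <- ref_pars()
  tr <- spen_trajectory(pars, n)
  y <- centered_1d(n, ref_fov)
  op <- build_forward_operator(pars, tr, y)
  set.seed(3)
  rho <- pmax(0, sin(8 * pi * y / ref_fov)) + runif(n, 0, 0.1)
  s <- as.vector(op$matrix %*% rho)

  # noiseless, lambda -> 0: exact recovery
  r0 <- tikhonov_recon(s, op, lambda = 0)
  expect_lt(max(Mod(r0$image - rho)) / max(rho), 1e-6)
  expect_lt(r0$residual, 1e-10)

  # independent oracle: stacked real augmented least squares via qr()
  lam_rel <- 0.05
  g <- Conj(t(op$matrix)) %*% op$matrix
  lam_abs <- lam_rel * Re(mean(diag(g)))
  a_big <- rbind(cbind(Re(op$matrix), -Im(op$matrix)),
                 cbind(Im(op$matrix), Re(op$matrix)),
                 sqrt(lam_abs) * diag(2 * n))
  b_big <- c(Re(s), Im(s), rep(0, 2 * n))
  xy <- qr.solve(a_big, b_big)
  oracle <- complex(real = xy[1:n], imaginary = xy[(n + 1):(2 * n)])
  r <- tikhonov_recon(s, op, lambda = lam_rel)
  expect_lt(max(Mod(r$image - oracle)) / max(Mod(oracle)), 1e-8)

  # solution norm decreases monotonically with lambda
  norms <- vapply(c(0, 0.01, 0.1, 1, 10), function(l)
    sqrt(sum(Mod(tikhonov_recon(s, op, l)$image)^2)), 0)
  expect_true(all(diff(norms) < 0))
})

test_that("tikhonov localizes a noisy point source at moderate SNR", {
  n <- 64
  pars <- ref_pars()
  tr <- spen_trajectory(pars, n)
  y <- centered_1d(n, ref_fov)
  op <- build_forward_operator(pars, tr, y)
  d <- rep(0, n); d[41] <- 1
  clean <- as.vector(op$matrix %*% d)
  sd_n <- sqrt(mean(Mod(clean)^2)) / 20 # SNR 20
  set.seed(99)
  hits <- vapply(1:20, function(i) {
    s <- clean + complex(real = rnorm(n, sd = sd_n / sqrt(2)),
                         imaginary = rnorm(n, sd = sd_n / sqrt(2)))
    which.max(Mod(tikhonov_recon(s, op, lambda = 1e-3)$image))
  }, 0L)
  expect_true(all(abs(hits - 41) <= 1))
})

test_that("line alignment recovers integer shifts and flags degenerate input", {
  n <- 64
  phf <- make_rod_phantom(c(256, 64), ref_fov)
  pars <- ref_pars()
  hy1 <- synthesize_epi_hybrid(phf, pars, matrix_size = n, delay = 5e-6)
  al1 <- align_epi_lines(hy1)
  expect_identical(al1$meta$shifts, 1L)
  hy0 <- synthesize_epi_hybrid(phf, pars, matrix_size = n)
  al0 <- align_epi_lines(hy0)
  expect_identical(al0$meta$shifts, 0L)
  # the +1-sample saw-tooth is removed: aligned data match the clean ones
  expect_lt(max(Mod(al1$samples[, -1] - al0$samples[, -1])) /
              max(Mod(al0$samples)), 1e-8)

  # half-sample delay: residual even/odd inconsistency persists
  hyh <- synthesize_epi_hybrid(phf, pars, matrix_size = n, delay = 2.5e-6)
  alh <- align_epi_lines(hyh)
  expect_gt(max(Mod(alh$samples - al0$samples)) / max(Mod(al0$samples)),
            0.01)

  zero <- acquired_signal(matrix(0 + 0i, 8, 8), dft_trajectory(8, ref_fov))
  expect_warning(align_epi_lines(zero), "all-zero")
})

test_that("fourier EPI recon shifts by the off-resonance phase ramp", {
  n <- 32
  nf <- 128
  yy <- matrix(centered_1d(nf, ref_fov), nf, nf)
  blob <- digital_phantom(exp(-((yy - 0.0)^2 + t(yy)^2) / (2 * 0.015^2)),
                          ref_fov)
  esp <- 5e-4
  for (df in c(50, 100)) {
    ph <- blob
    ph$off_resonance <- matrix(df, nf, nf)
    hy <- synthesize_epi_hybrid(ph, encoding_params(0, ref_fov),
                                matrix_size = n, esp = esp)
    rec <- fourier_epi_recon(hy)
    truth <- phantom_downsample(blob, n)
    m <- image_metrics(rec, truth)
    pred_px <- df * esp * n # phase-encode shift of EPI
    # the reversed-dwell phase of even lines adds a small N/2 ghost that
    # biases the magnitude centroid by a fraction of a pixel
    expect_lt(abs(unname(m$centroid_displacement_px["y"]) - pred_px), 0.5)
  }
})

test_that("conjugate-symmetric hybrid data give a real image", {
  # the transform of a real image is conjugate-symmetric; its inverse
  # transform must be real again
  n <- 16
  k <- (seq_len(n) - 1 - n / 2)
  set.seed(5)
  img <- matrix(runif(n * n), n, n)
  wy <- exp(1i * outer(k * 2 * pi / ref_fov, centered_1d(n, ref_fov)))
  s <- wy %*% img %*% t(wy)
  hy <- acquired_signal(s, dft_trajectory(n, ref_fov),
                        meta = list(fov = c(ref_fov, ref_fov),
                                    aligned = TRUE))
  rec <- fourier_epi_recon(hy, align = FALSE)
  expect_lt(max(abs(Im(rec$image))), 1e-10 * max(abs(Re(rec$image))))
})

test_that("2D SPEN recon is accurate, ghost-free and robust at 64 lines", {
  phf <- make_rod_phantom(c(256, 64), ref_fov)
  truth <- phantom_downsample(phf, 64)
  pars <- ref_pars()
  hy <- synthesize_epi_hybrid(phf, pars, matrix_size = 64, delay = 5e-6)
  rec <- spen_epi_recon(hy)
  m <- image_metrics(rec, truth)
  expect_lt(m$rel_rms, 0.1)
  expect_lt(m$ghost_ratio, 0.05)
  # all-zero input reconstructs to an all-zero image
  z <- hy
  z$samples[] <- 0
  expect_warning(rz <- spen_epi_recon(z), "all-zero")
  expect_true(all(Mod(rz$image) == 0))
})

test_that("pre-refocusing (inverted-parabola) data need the inverted kernel", {
  # fine-grid synthesis, 64-sample acquisition, windowed deconvolution:
  # the aperture tracks the stationary point, so the parabola sign is
  # structural (a full-aperture kernel would only change a per-pixel
  # phase, invisible in magnitude)
  nf <- 512
  pars <- ref_pars()
  tr <- spen_trajectory(pars, 64)
  yfine <- centered_1d(nf, ref_fov)
  # an asymmetric density, so that a mirrored reconstruction is visible
  ph <- make_bottle_1d(nf, ref_fov, 0.4)
  ph$density <- ph$density +
    gauss_blob_1d(nf, ref_fov, 0.06, 0.006)$density
  op_post <- build_forward_operator(pars, tr, yfine)
  op_pre <- build_forward_operator(encoding_params(-pars$beta, ref_fov),
                                   tr, yfine)
  s_post <- synthesize_spen_signal(ph, op_post, tr)
  s_pre <- synthesize_spen_signal(ph, op_pre, tr)
  y64 <- centered_1d(64, ref_fov)
  ap <- 4 * sqrt(pars$beta)
  r_post <- fresnel_recon(s_post, pars, tr, out_grid = y64, aperture = ap)
  r_pre <- fresnel_recon(s_pre, pars, tr, out_grid = y64,
                         invert_kernel = TRUE, aperture = ap)
  expect_lt(max(Mod(Mod(r_pre$image) - Mod(r_post$image))) /
              max(Mod(r_post$image)), 0.01)
  # with the wrong kernel the reconstruction degrades badly
  r_wrong <- fresnel_recon(s_pre, pars, tr, out_grid = y64, aperture = ap)
  expect_gt(max(Mod(Mod(r_wrong$image) - Mod(r_post$image))) /
              max(Mod(r_post$image)), 0.2)
})

test_that("image metrics report exact zero error and unit-pixel translations", {
  ph <- make_rod_phantom(64, ref_fov)
  m0 <- image_metrics(recon_result(ph$density), ph)
  expect_equal(m0$rms_error, 0)
  expect_equal(unname(m0$centroid_displacement_px), c(0, 0))
  shifted <- ph$density[c(64, 1:63), ]
  m1 <- image_metrics(recon_result(shifted), ph)
  expect_equal(unname(abs(m1$centroid_displacement_px["y"])), 1,
               tolerance = 0.05)
})
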