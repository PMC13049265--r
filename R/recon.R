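#' Reconstruction result container
#'
#' @param image Complex (or real) image on the requested grid.
#' @param grid Positions (1D) or list of axis grids (2D).
#' @param residual Data-domain RMS residual where the method defines one.
#' @param diagnostics Method diagnostics (e.g. per-parity line shifts).
#' @return An object of class `"recon_result"`.
#' @export
recon_result <- function(image, grid = NULL, residual = NA_real_,
                         diagnostics = list()) {
  structure(list(image = image, grid = grid, residual = residual,
                 diagnostics = diagnostics),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  d <- if (is.matrix(x$image)) paste(dim(x$image), collapse = " x ") else
    length(x$image)
  cat("Reconstruction:", d, "pixels")
  if (is.finite(x$residual)) cat(", residual", signif(x$residual, 4))
  cat("\n")
  invisible(x)
}

#' @export
plot.recon_result <- function(x, ...) {
  if (is.matrix(x$image)) {
    graphics::image(Mod(x$image), useRaster = TRUE, asp = 1,
                    col = grDevices::gray.colors(256, 0, 1), ...)
  } else {
    graphics::plot(seq_along(x$image), Mod(x$image), type = "l",
                   xlab = "position index", ylab = "|density|", ...)
  }
  invisible(x)
}

extract_samples <- function(signal) {
  if (inherits(signal, "acquired_signal")) signal$samples else signal
}

#' Naive reordering reconstruction
#'
#' Assigns sample `i` to its stationary point `y_stat(i) = -k_i/(2 beta)`
#' and returns the magnitude profile: the direct time-to-position map of
#' SPEN, blurred by the intrinsic point-spread function.
#'
#' @param signal An [acquired_signal()] or complex vector (1D SPEN data).
#' @param params An [encoding_params()] with nonzero beta.
#' @param traj The acquisition [k_trajectory()].
#' @return A [recon_result()]; `grid` holds the stationary-point positions
#'   in acquisition order.
#' @export
reorder_magnitude <- function(signal, params, traj) {
  stopifnot(inherits(params, "encoding_params"),
            inherits(traj, "k_trajectory"))
  if (params$beta == 0)
    stop("beta = 0: no stationary-point mapping (use fourier_epi_recon)")
  s <- extract_samples(signal)
  y <- stationary_point(traj$k, params$beta)
  recon_result(Mod(s), grid = y)
}

#' Convolution-based (Fresnel / matched-filter) SPEN reconstruction
#'
#' Compensates the quadratic phase by the conjugate-phase (adjoint) kernel:
#' `rho_hat(y) = sum_i w_i(y) s_i exp(-i (beta y^2 + k_i y))`. With
#' `weights = "trapezoid"` the quadrature weights are `dk_i/(2 pi)`
#' (trapezoid rule over the trajectory), which makes the map the
#' discretized continuous inverse `exp(-i beta y^2) * (1/2pi) int S(k)
#' exp(-i k y) dk`; with `weights = "adjoint"` the weights are the grid
#' spacing, making the result exactly `conj(t(A)) %*% s` for the matched
#' forward operator. `invert_kernel` conjugates the quadratic term, for
#' acquisitions in which the phase parabola was inverted by a refocusing
#' pulse (quadratic event played before the refocusing pulse).
#'
#' `aperture` restricts the summation to a Gaussian window of standard
#' deviation `aperture` (rad/m) around the stationary sample of each output
#' position (`k = -2 beta y`). This is the finite Fresnel aperture of the
#' convolution method: SPEN data are local, so only samples whose
#' stationary point lies near `y` carry its signal, and windowing them out
#' suppresses the k-space replica (aliasing) lobes that a full-aperture
#' adjoint folds in whenever the acquisition is sampled more coarsely than
#' the nominal FOV Nyquist rate. `sqrt(beta)`-proportional apertures keep a
#' fixed number of Fresnel zones; `4*sqrt(|beta|)` is a good default for
#' super-resolved single-shot protocols.
#'
#' @param signal An [acquired_signal()] or complex vector.
#' @param params An [encoding_params()].
#' @param traj The acquisition [k_trajectory()].
#' @param out_grid Output positions in m; defaults to `length(s)` points
#'   across the FOV.
#' @param weights `"trapezoid"` or `"adjoint"` (see Details).
#' @param invert_kernel Use `-beta` in the deconvolution kernel.
#' @param aperture Gaussian window SD in rad/m, or `NULL` for the full
#'   aperture.
#' @return A [recon_result()].
#' @export
fresnel_recon <- function(signal, params, traj, out_grid = NULL,
                          weights = c("trapezoid", "adjoint"),
                          invert_kernel = FALSE, aperture = NULL) {
  stopifnot(inherits(params, "encoding_params"),
            inherits(traj, "k_trajectory"))
  weights <- match.arg(weights)
  s <- extract_samples(signal)
  if (length(s) != length(traj$k))
    stop("signal length does not match the trajectory")
  if (is.null(out_grid)) out_grid <- centered_grid(length(s), params$fov)
  beta <- if (invert_kernel) -params$beta else params$beta
  w <- if (weights == "trapezoid") {
    dk <- abs(diff(traj$k))
    c(dk[1] / 2, (dk[-1] + dk[-length(dk)]) / 2,
      dk[length(dk)] / 2) / (2 * pi)
  } else {
    dy <- if (length(out_grid) > 1) out_grid[2] - out_grid[1] else 1
    rep(dy, length(s))
  }
  # kern[y, i] = exp(-i (beta y^2 + k_i y)); beta y^2 recycles down columns
  kern <- exp(-1i * (beta * out_grid^2 + outer(out_grid, traj$k)))
  if (!is.null(aperture)) {
    if (aperture <= 0) stop("aperture must be positive")
    kern <- kern *
      exp(-outer(2 * beta * out_grid, traj$k, "+")^2 / (2 * aperture^2))
  }
  img <- as.vector(kern %*% (w * s))
  recon_result(img, grid = out_grid)
}

#' Tikhonov-regularized operator inversion
#'
#' Solves `min ||A x - s||^2 + lambda ||x||^2` through the normal
#' equations `(A^H A + lambda I) x = A^H s` (deterministic dense solve).
#'
#' @param signal An [acquired_signal()] or complex vector.
#' @param op A [build_forward_operator()] result.
#' @param lambda Non-negative regularization weight, scaled relative to
#'   the mean diagonal of `A^H A`.
#' @return A [recon_result()] with the data-domain RMS residual.
#' @export
tikhonov_recon <- function(signal, op, lambda = 0) {
  stopifnot(inherits(op, "forward_operator"))
  if (lambda < 0) stop("lambda must be non-negative")
  s <- extract_samples(signal)
  a <- op$matrix
  if (length(s) != nrow(a)) stop("signal length does not match the operator")
  ah <- Conj(t(a))
  n <- ncol(a)
  g <- ah %*% a
  scale <- Re(mean(diag(g)))
  x <- tryCatch(solve(g + (lambda * scale) * diag(n), ah %*% s),
                error = function(e)
                  stop("normal equations singular at lambda = ", lambda,
                       "; retry with lambda > 0 (", conditionMessage(e), ")"))
  x <- as.vector(x)
  recon_result(x, grid = op$grid,
               residual = sqrt(mean(Mod(a %*% x - s)^2)),
               diagnostics = list(lambda = lambda))
}

#' Align the even and odd lines of an EPI hybrid k-space
#'
#' Reverses every second (even-numbered) line and removes the residual
#' integer-sample readout shift between the two parities: the shift is
#' estimated by maximizing the circular cross-correlation of the mean
#' absolute line profiles (even versus odd) and applied to the even lines
#' as a linear phase in the readout transform domain. Shifts are integer
#' only; sub-sample delays cannot be corrected this way and leave residual
#' ghosting.
#'
#' @param hybrid An [acquired_signal()] with a 2D `samples` matrix.
#' @param max_shift Maximum allowed |shift| in samples.
#' @return The aligned [acquired_signal()]; `meta$shifts` records the
#'   applied even-line shift in samples.
#' @export
align_epi_lines <- function(hybrid, max_shift = 4) {
  stopifnot(inherits(hybrid, "acquired_signal"), is.matrix(hybrid$samples))
  if (max_shift < 0 || max_shift != round(max_shift))
    stop("max_shift must be a non-negative integer")
  m <- hybrid$samples
  even <- seq(2, nrow(m), by = 2)
  m[even, ] <- m[even, rev(seq_len(ncol(m))), drop = FALSE]
  if (all(Mod(m) == 0)) {
    warning("all-zero hybrid data; alignment skipped")
    hybrid$samples <- m
    hybrid$meta$shifts <- 0L
    return(hybrid)
  }
  po <- colMeans(abs(m[seq(1, nrow(m), by = 2), , drop = FALSE]))
  pe <- colMeans(abs(m[even, , drop = FALSE]))
  shifts <- -max_shift:max_shift
  score <- vapply(shifts, function(d) sum(circ_shift(pe, d) * po), 0)
  d <- shifts[which.max(score)]
  if (d != 0) {
    n <- ncol(m)
    # integer circular shift by d via linear phase on the DFT of each line
    ph <- exp(-2i * pi * d * dft_index(n) / n)
    for (i in even)
      m[i, ] <- stats::fft(stats::fft(m[i, ]) * ph, inverse = TRUE) / n
  }
  hybrid$samples <- m
  hybrid$meta$shifts <- d
  hybrid$meta$aligned <- TRUE
  hybrid
}

# signed DFT index 0, 1, ..., n/2-1, -n/2, ..., -1
dft_index <- function(n) {
  i <- 0:(n - 1)
  ifelse(i < n / 2, i, i - n)
}

circ_shift <- function(x, d) {
  n <- length(x)
  x[((seq_len(n) - 1 - d) %% n) + 1]
}

# Centered inverse DFT matrix inverting the exp(+i k y) encoding of the
# forward operator: x_j = sum_i s_i exp(-i k_i y_j) dk/(2 pi)
centered_idft <- function(n, fov) {
  y <- centered_grid(n, fov)
  k <- (seq_len(n) - 1 - n / 2) * 2 * pi / fov
  exp(-1i * outer(y, k)) * (1 / fov)
}

#' Fourier EPI reconstruction
#'
#' Line alignment followed by a centered two-dimensional inverse DFT.
#'
#' @param hybrid An [acquired_signal()] from [synthesize_epi_hybrid()] with
#'   `beta = 0`.
#' @param align Run [align_epi_lines()] first.
#' @param max_shift Passed to [align_epi_lines()].
#' @return A [recon_result()] (rows = y, columns = x).
#' @export
fourier_epi_recon <- function(hybrid, align = TRUE, max_shift = 4) {
  stopifnot(inherits(hybrid, "acquired_signal"), is.matrix(hybrid$samples))
  shifts <- 0L
  if (align && !isTRUE(hybrid$meta$aligned)) {
    hybrid <- align_epi_lines(hybrid, max_shift)
    shifts <- hybrid$meta$shifts
  }
  m <- hybrid$samples
  fov <- hybrid$meta$fov
  if (is.null(fov)) fov <- c(1, 1)
  wy <- centered_idft(nrow(m), fov[1])
  wx <- centered_idft(ncol(m), fov[2])
  img <- wy %*% m %*% t(wx)
  recon_result(img, grid = list(y = centered_grid(nrow(m), fov[1]),
                                x = centered_grid(ncol(m), fov[2])),
               diagnostics = list(shifts = shifts))
}

#' SPEN EPI reconstruction
#'
#' Line alignment, inverse DFT along the frequency-encoding (readout)
#' direction, then convolution-based ([fresnel_recon()]) deconvolution per
#' column along the SPEN direction.
#'
#' @param hybrid An [acquired_signal()] from [synthesize_epi_hybrid()] in
#'   SPEN mode.
#' @param params The [encoding_params()] used for synthesis (defaults to
#'   the value recorded in `hybrid$meta`).
#' @param traj The SPEN-axis [k_trajectory()] (defaults to
#'   `hybrid$traj`).
#' @param align Run [align_epi_lines()] first.
#' @param max_shift Passed to [align_epi_lines()].
#' @param invert_kernel Use the inverted deconvolution kernel (quadratic
#'   phase played before the refocusing pulse).
#' @param method `"fresnel"` (default) deconvolves each column with the
#'   finite-aperture conjugate-phase kernel (see [fresnel_recon()]), which
#'   is local and therefore robust to gradient-delay and off-resonance
#'   model error; `"tikhonov"` inverts the SPEN operator on the
#'   acquisition grid, which is sharper on exactly grid-consistent data
#'   but folds k-space replicas when the data deviate from the discrete
#'   model.
#' @param lambda Tikhonov weight for `method = "tikhonov"`.
#' @param aperture Fresnel aperture SD in rad/m for `method = "fresnel"`;
#'   default `4 * sqrt(|beta|)`.
#' @return A [recon_result()] (rows = y, columns = x).
#' @export
spen_epi_recon <- function(hybrid, params = NULL, traj = NULL, align = TRUE,
                           max_shift = 4, invert_kernel = FALSE,
                           method = c("fresnel", "tikhonov"),
                           lambda = 1e-6, aperture = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(hybrid, "acquired_signal"), is.matrix(hybrid$samples))
  if (is.null(params)) params <- hybrid$meta$params
  if (is.null(traj)) traj <- hybrid$traj
  stopifnot(inherits(params, "encoding_params"))
  shifts <- 0L
  if (align && !isTRUE(hybrid$meta$aligned)) {
    hybrid <- align_epi_lines(hybrid, max_shift)
    shifts <- hybrid$meta$shifts
  }
  m <- hybrid$samples
  fov <- hybrid$meta$fov
  if (is.null(fov)) fov <- rep(params$fov, 2)
  wx <- centered_idft(ncol(m), fov[2])
  hx <- m %*% t(wx) # inverse DFT along readout: columns become x positions
  n_out <- length(traj$k)
  out_grid <- centered_grid(n_out, params$fov)
  if (is.null(aperture)) aperture <- 4 * sqrt(abs(params$beta))
  if (method == "tikhonov") {
    beta <- if (invert_kernel) -params$beta else params$beta
    op <- build_forward_operator(beta, traj, out_grid)
    a <- op$matrix
    ah <- Conj(t(a))
    g <- ah %*% a
    scale <- Re(mean(diag(g)))
    img <- solve(g + (lambda * scale) * diag(n_out), ah %*% hx)
  } else {
    img <- matrix(0 + 0i, n_out, ncol(m))
    for (cx in seq_len(ncol(m))) {
      img[, cx] <- fresnel_recon(hx[, cx], params, traj,
                                 out_grid = out_grid,
                                 invert_kernel = invert_kernel,
                                 aperture = aperture)$image
    }
  }
  recon_result(img, grid = list(y = out_grid,
                                x = centered_grid(ncol(m), fov[2])),
               diagnostics = list(shifts = shifts))
}

#' Image comparison metrics
#'
#' Compares a reconstruction with the ground-truth phantom after a global
#' least-squares intensity match: reports the absolute RMS error, the RMS
#' error relative to the mean interior (nonzero-truth) intensity, the
#' centroid displacement in m and in pixels, and the ghost ratio (mean
#' magnitude over fully empty truth rows divided by the mean interior
#' magnitude).
#'
#' @param result A [recon_result()] (or bare image).
#' @param truth A [digital_phantom()] on the same grid.
#' @return A list of metrics.
#' @export
image_metrics <- function(result, truth) {
  stopifnot(inherits(truth, "digital_phantom"))
  img <- Mod(if (inherits(result, "recon_result")) result$image else result)
  tr <- truth$density
  if (!all(dim1(img) == dim1(tr))) stop("image and truth grids differ")
  scale <- sum(img * tr) / sum(tr^2)
  imgn <- img / scale
  interior <- tr > 0
  rms <- sqrt(mean((imgn - tr)^2))
  if (is.matrix(tr)) {
    py <- truth$y; px <- truth$x
    cy <- function(m) sum(rowSums(m) * py) / sum(m)
    cx <- function(m) sum(colSums(m) * px) / sum(m)
    disp_m <- c(y = cy(img) - cy(tr), x = cx(img) - cx(tr))
    disp_px <- disp_m / c(py[2] - py[1], px[2] - px[1])
    empty_rows <- rowSums(tr) == 0
    ghost <- if (any(empty_rows))
      mean(img[empty_rows, ]) / mean(img[interior]) else NA_real_
  } else {
    py <- truth$y
    disp_m <- c(y = sum(img * py) / sum(img) - sum(tr * py) / sum(tr))
    disp_px <- disp_m / (py[2] - py[1])
    ghost <- NA_real_
  }
  list(rms_error = rms,
       rel_rms = rms / mean(tr[interior]),
       centroid_displacement_m = disp_m,
       centroid_displacement_px = disp_px,
       ghost_ratio = ghost,
       scale = scale)
}

dim1 <- function(x) if (is.matrix(x)) dim(x) else length(x)
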