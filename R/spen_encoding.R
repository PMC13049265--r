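# Unit conventions used throughout the package:
#   gradients       gamma*G/2pi       [Hz/m]
#   k               2*pi*int(grad dt) [rad/m]
#   beta            quadratic phase   [rad/m^2]
#   gradient areas  int(grad dt)      [Hz s/m] (so k = 2*pi*area)

#' Gyromagnetic ratio of 1H over 2*pi
#'
#' `gamma/2pi = 42.577e6` Hz/T, used to convert quadratic-gradient
#' coefficients in T/m^2 to phase-evolution rates.
#' @export
GAMMA_BAR_1H <- 42.577e6

#' SPEN encoding parameters
#'
#' Bundles the quadratic phase coefficient `beta` and the field of view,
#' with the derived k-space coverage `delta_k = 2 |beta| fov`.
#'
#' @param beta Quadratic phase coefficient in rad/m^2 (nonzero for SPEN;
#'   `beta = 0` selects plain Fourier encoding).
#' @param fov Field of view in m.
#' @return An object of class `"encoding_params"`.
#' @export
encoding_params <- function(beta, fov) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("beta must be a finite scalar")
  if (!is.numeric(fov) || fov <= 0) stop("fov must be positive")
  structure(list(beta = beta, fov = fov,
                 delta_k = 2 * abs(beta) * fov),
            class = "encoding_params")
}

#' @export
print.encoding_params <- function(x, ...) {
  cat(sprintf("SPEN encoding: beta %.6g rad/m^2, FOV %g mm, delta-k %.6g rad/m\n",
              x$beta, x$fov * 1e3, x$delta_k))
  invisible(x)
}

#' Quadratic-gradient pulse design
#'
#' A spatial encoding field `B(y) = C y^2` applied for a duration `tau_g`.
#'
#' @param coefficient Field coefficient `C` in T/m^2.
#' @param duration Pulse duration `tau_g` in s.
#' @return An object of class `"quad_gradient_design"`.
#' @export
quad_gradient_design <- function(coefficient, duration) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  structure(list(coefficient = coefficient, duration = duration),
            class = "quad_gradient_design")
}

#' Quadratic phase coefficient from a chirped excitation
#'
#' `beta = pi * grad^2 * duration / bandwidth` (rad/m^2) for a chirp of
#' sweep rate `bandwidth/duration` under a constant gradient `grad` in
#' Hz/m.
#'
#' @param grad Excitation gradient in Hz/m.
#' @param bandwidth Swept bandwidth in Hz.
#' @param duration Chirp duration in s.
#' @return beta in rad/m^2.
#' @export
beta_from_chirp <- function(grad, bandwidth, duration) {
  if (bandwidth == 0) stop("bandwidth must be nonzero")
  pi * grad^2 * duration / bandwidth
}

#' Quadratic phase coefficient from a quadratic-gradient pulse
#'
#' `beta = 2*pi * gamma_bar * C * tau_g` in rad/m^2 (the radian version of
#' `gamma C tau_g`).
#'
#' @param design A [quad_gradient_design()], or a coefficient in T/m^2 when
#'   `duration` is given.
#' @param duration Duration in s (when `design` is a bare coefficient).
#' @param gamma_bar Gyromagnetic ratio over 2*pi in Hz/T.
#' @return beta in rad/m^2.
#' @export
beta_from_quadratic_gradient <- function(design, duration = NULL,
                                         gamma_bar = GAMMA_BAR_1H) {
  if (inherits(design, "quad_gradient_design")) {
    co <- design$coefficient; tau <- design$duration
  } else {
    if (is.null(duration)) stop("supply a design or coefficient + duration")
    co <- design; tau <- duration
  }
  2 * pi * gamma_bar * co * tau
}

#' Field of view excited by a chirp under a constant gradient
#'
#' `FOV = bandwidth / grad` with the gradient in Hz/m.
#'
#' @param bandwidth Swept bandwidth in Hz.
#' @param grad Excitation gradient in Hz/m.
#' @return FOV in m.
#' @export
fov_from_chirp <- function(bandwidth, grad) {
  if (grad == 0) stop("gradient must be nonzero")
  bandwidth / grad
}

#' Stationary phase point
#'
#' The vertex of the total phase parabola `beta y^2 + k y`, i.e. the
#' position dominating the acquired signal at k-space coordinate `k`:
#' `y_stat = -k / (2 beta)`.
#'
#' @param k k-space coordinate(s) in rad/m.
#' @param beta Quadratic phase coefficient in rad/m^2 (nonzero).
#' @return Position(s) in m.
#' @export
stationary_point <- function(k, beta) {
  if (beta == 0) stop("beta = 0: no stationary point (Fourier encoding)")
  -k / (2 * beta)
}

#' Total k-space coverage of a SPEN acquisition
#'
#' `delta_k = 2 beta fov`, the acquisition-gradient k-space span needed for
#' the stationary point to sweep exactly one field of view.
#'
#' @param beta Quadratic phase coefficient in rad/m^2.
#' @param fov Field of view in m.
#' @return delta_k in rad/m.
#' @export
delta_k_coverage <- function(beta, fov) 2 * beta * fov

#' Acquisition k-space trajectory
#'
#' @param k Sample k-space coordinates in rad/m, ordered by acquisition
#'   time.
#' @param sample_times Acquisition times in s (strictly increasing);
#'   defaults to a unit-spaced index in ms.
#' @return An object of class `"k_trajectory"` with fields `k`,
#'   `sample_times` and `acq_gradient_area` (the traversed area
#'   `|k_1 - k_n| / 2pi` in Hz s/m).
#' @export
k_trajectory <- function(k, sample_times = NULL) {
  n <- length(k)
  if (n < 2) stop("trajectory needs at least 2 samples")
  if (is.null(sample_times)) sample_times <- (seq_len(n) - 1) * 1e-3
  if (length(sample_times) != n || any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing, one per sample")
  structure(list(k = k, sample_times = sample_times,
                 acq_gradient_area = abs(k[1] - k[n]) / (2 * pi)),
            class = "k_trajectory")
}

#' SPEN sweep trajectory
#'
#' k runs linearly from `+beta*fov` down to `-beta*fov` (endpoints
#' included), so the stationary point sweeps from `-fov/2` to `+fov/2`.
#'
#' @param params An [encoding_params()] with nonzero beta.
#' @param n_samples Number of samples.
#' @param esp Sample (echo) spacing in s.
#' @param direction `+1` sweeps the stationary point upward (default), `-1`
#'   downward.
#' @return A [k_trajectory()].
#' @export
spen_trajectory <- function(params, n_samples, esp = 5e-4, direction = 1) {
  stopifnot(inherits(params, "encoding_params"))
  if (params$beta == 0) stop("beta = 0 has no SPEN sweep")
  k0 <- direction * params$beta * params$fov
  k <- seq(k0, -k0, length.out = n_samples)
  k_trajectory(k, (seq_len(n_samples) - 1) * esp)
}

#' Fourier (DFT) sampling trajectory
#'
#' Centered DFT grid `k_i = (i - 1 - n/2) * 2*pi/fov`.
#'
#' @param n_samples Number of samples.
#' @param fov Field of view in m.
#' @param esp Sample spacing in s.
#' @return A [k_trajectory()].
#' @export
dft_trajectory <- function(n_samples, fov, esp = 5e-4) {
  k <- (seq_len(n_samples) - 1 - n_samples / 2) * 2 * pi / fov
  k_trajectory(k, (seq_len(n_samples) - 1) * esp)
}

#' Check the SPEN gradient-area condition
#'
#' SPEN requires the magnitude of the excitation gradient area to equal the
#' total acquisition gradient area, so that the stationary point sweeps
#' exactly one FOV.
#'
#' @param exc_area Excitation gradient area in Hz s/m (`grad * duration`).
#' @param traj A [k_trajectory()].
#' @param tolerance Relative tolerance.
#' @return A list with `ok`, `exc_area`, `acq_area` and `rel_diff`, of class
#'   `"spen_condition"`.
#' @export
check_spen_condition <- function(exc_area, traj, tolerance = 1e-6) {
  stopifnot(inherits(traj, "k_trajectory"))
  acq <- traj$acq_gradient_area
  rel <- abs(abs(exc_area) - acq) / max(abs(exc_area), acq, .Machine$double.eps)
  structure(list(ok = rel <= tolerance, exc_area = abs(exc_area),
                 acq_area = acq, rel_diff = rel, tolerance = tolerance),
            class = "spen_condition")
}

#' @export
print.spen_condition <- function(x, ...) {
  cat(sprintf(
    "SPEN area condition: |exc| = %.8g, acq = %.8g Hz s/m (rel diff %.3g) -> %s\n",
    x$exc_area, x$acq_area, x$rel_diff, if (x$ok) "OK" else "VIOLATED"))
  invisible(x)
}

#' Build the SPEN (or DFT) forward operator
#'
#' Entries `A[i, j] = exp(i (beta y_j^2 + k_i y_j)) * dy` mapping a
#' discretized spin density on a uniform grid to the acquired samples. With
#' `beta = 0` this is exactly the DFT encoding matrix.
#'
#' @param params An [encoding_params()] (or a bare beta value when `fov` can
#'   be inferred from the grid).
#' @param traj A [k_trajectory()].
#' @param grid Uniformly spaced positions in m.
#' @return An object of class `"forward_operator"` with fields `matrix`
#'   (complex, samples x positions), `grid`, `spacing`, `k`, `beta` and
#'   `mode` (`"spen"` or `"dft"`).
#' @export
build_forward_operator <- function(params, traj, grid) {
  stopifnot(inherits(traj, "k_trajectory"))
  beta <- if (inherits(params, "encoding_params")) params$beta else params
  d <- diff(grid)
  if (length(d) < 1 || any(abs(d - d[1]) > 1e-9 * abs(d[1])))
    stop("grid must be uniformly spaced")
  dy <- d[1]
  phase <- outer(rep(1, length(traj$k)), beta * grid^2) + outer(traj$k, grid)
  structure(list(matrix = exp(1i * phase) * dy, grid = grid, spacing = dy,
                 k = traj$k, beta = beta,
                 mode = if (beta == 0) "dft" else "spen"),
            class = "forward_operator")
}

#' @export
print.forward_operator <- function(x, ...) {
  cat(sprintf("%s forward operator: %d samples x %d positions, beta %.6g rad/m^2\n",
              toupper(x$mode), nrow(x$matrix), ncol(x$matrix), x$beta))
  invisible(x)
}

#' Analytic k-space point-spread function of SPEN
#'
#' The Fourier transform of the spatial chirp `exp(i beta y^2)` is itself a
#' chirp with phase `-k^2/(4 beta)`. This returns the unit-magnitude kernel
#' `exp(-i k^2 / (4 beta))`; the full stationary-phase amplitude is
#' `sqrt(pi/beta) * exp(i pi/4)` times this (the kernel is defined up to
#' that proportionality).
#'
#' @param beta Quadratic phase coefficient in rad/m^2 (nonzero).
#' @param k k-space coordinates in rad/m.
#' @return Complex vector of unit magnitude.
#' @export
kspace_psf <- function(beta, k) {
  if (beta == 0) stop("beta = 0 has no SPEN point-spread function")
  exp(-1i * k^2 / (4 * beta))
}

#' Discretized k-space PSF on a DFT grid
#'
#' The exact transfer function of the FOV-windowed spatial chirp on a
#' centered `n`-point grid: `H_i = sum_j exp(i beta y_j^2) exp(i k_i y_j) dy`
#' with `k_i = (i - 1 - n/2) 2 pi / fov`. Convolving the DFT samples of a
#' density with this kernel (see [spen_convolve()]) reproduces the SPEN
#' samples of [build_forward_operator()] exactly; for `beta * fov^2 >> 1`
#' its phase approaches the analytic [kspace_psf()] form.
#'
#' @param beta Quadratic phase coefficient in rad/m^2.
#' @param n Grid size.
#' @param fov Field of view in m.
#' @return Complex vector of length `n` on the centered DFT k grid.
#' @export
kspace_psf_discrete <- function(beta, n, fov) {
  y <- centered_grid(n, fov)
  k <- (seq_len(n) - 1 - n / 2) * 2 * pi / fov
  as.vector(exp(1i * outer(k, y)) %*% exp(1i * beta * y^2)) * (fov / n)
}

#' Circular k-space convolution on centered grids
#'
#' Computes `(p * h) / (n dy)` by FFT, with both inputs on centered DFT
#' grids. This is the discrete form of the SPEN convolution relation
#' `S(ky) = P(ky) conv H(ky)`: with `p` the DFT samples of a density and
#' `h` from [kspace_psf_discrete()], the result equals the samples of the
#' SPEN forward operator on the same k grid.
#'
#' @param p Complex samples on a centered DFT grid.
#' @param h Convolution kernel on the same grid.
#' @param fov Field of view in m (`n * dy`).
#' @return Complex vector, the convolved samples on the same grid.
#' @export
spen_convolve <- function(p, h, fov) {
  n <- length(p)
  if (length(h) != n) stop("p and h must have the same length")
  sh <- function(x) c(x[(n %/% 2 + 1):n], x[1:(n %/% 2)])
  out <- stats::fft(stats::fft(sh(p)) * stats::fft(sh(h)),
                    inverse = TRUE) / n
  sh(out) / fov
}

# centered uniform grid, half-open [-fov/2, fov/2)
centered_grid <- function(n, fov) (seq_len(n) - 1 - n / 2) * (fov / n)
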