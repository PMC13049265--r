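#' Digital phantom container
#'
#' @param density Non-negative real vector (1D) or matrix (2D, rows = y /
#'   SPEN axis, columns = x / readout axis).
#' @param fov Field of view in m; one value per axis (recycled).
#' @param off_resonance Off-resonance map in Hz, same shape as `density`
#'   (scalar recycled).
#' @return An object of class `"digital_phantom"` with `density`,
#'   `off_resonance`, `fov` and the centered grid(s) in `y` (and `x`).
#' @export
digital_phantom <- function(density, fov, off_resonance = 0) {
  if (any(!is.finite(density)) || any(density < 0))
    stop("density must be finite and non-negative")
  if (is.matrix(density)) {
    fov <- rep_len(fov, 2)
    off_resonance <- if (is.matrix(off_resonance)) off_resonance else
      matrix(off_resonance, nrow(density), ncol(density))
    if (!all(dim(off_resonance) == dim(density)))
      stop("off_resonance map must match the density shape")
    y <- centered_grid(nrow(density), fov[1])
    x <- centered_grid(ncol(density), fov[2])
  } else {
    fov <- fov[1]
    off_resonance <- rep_len(off_resonance, length(density))
    y <- centered_grid(length(density), fov)
    x <- NULL
  }
  structure(list(density = density, off_resonance = off_resonance,
                 fov = fov, y = y, x = x),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  d <- if (is.matrix(x$density)) paste(dim(x$density), collapse = " x ") else
    paste0(length(x$density), " (1D)")
  cat("Digital phantom:", d, "grid, FOV",
      paste(signif(x$fov * 1e3, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' 1D bottle (smoothed top-hat) phantom
#'
#' Uniform spin density occupying `width_fraction` of the FOV with
#' raised-cosine edges, emulating a water-bottle profile.
#'
#' @param grid_n Number of grid points (>= 16).
#' @param fov Field of view in m.
#' @param width_fraction Fraction of the FOV covered by the bottle.
#' @param edge_fraction Width of each raised-cosine edge as a fraction of
#'   the FOV.
#' @return A [digital_phantom()].
#' @export
make_bottle_1d <- function(grid_n, fov, width_fraction = 0.5,
                           edge_fraction = 0.04) {
  if (grid_n < 16) stop("grid_n must be at least 16")
  y <- centered_grid(grid_n, fov)
  half <- width_fraction * fov / 2
  e <- edge_fraction * fov
  d <- abs(y) # raised-cosine roll-off between half - e and half
  dens <- if (e > 0) {
    ifelse(d <= half - e, 1,
           ifelse(d >= half, 0,
                  0.5 * (1 + cos(pi * (d - (half - e)) / e))))
  } else {
    as.numeric(d <= half)
  }
  digital_phantom(dens, fov)
}

#' 2D disk phantom with resolution rods
#'
#' A uniform disk with zero-density circular rods, emulating a structural
#' phantom. Rods must lie inside the disk and must not overlap.
#'
#' @param grid_n Grid size, scalar (square) or `c(ny, nx)`.
#' @param fov Field of view in m.
#' @param rod_radii Rod radii in m (default: four rods from fine to coarse).
#' @param rod_centers Optional 2-column matrix (y, x) of rod centers in m;
#'   by default the rods are spread on a circle of radius `0.45 *
#'   disk_radius`.
#' @param disk_radius Disk radius in m (default `0.35 * fov`).
#' @return A [digital_phantom()].
#' @export
make_rod_phantom <- function(grid_n, fov,
                             rod_radii = fov * c(0.015, 0.025, 0.04, 0.055),
                             rod_centers = NULL,
                             disk_radius = 0.35 * fov) {
  grid_n <- rep_len(grid_n, 2)
  y <- centered_grid(grid_n[1], fov)
  x <- centered_grid(grid_n[2], fov)
  nr <- length(rod_radii)
  if (is.null(rod_centers)) {
    ang <- 2 * pi * (seq_len(nr) - 1) / nr + pi / 4
    r0 <- 0.45 * disk_radius
    rod_centers <- cbind(r0 * sin(ang), r0 * cos(ang))
  }
  if (nrow(rod_centers) != nr) stop("one center per rod radius required")
  for (i in seq_len(nr)) {
    if (sqrt(sum(rod_centers[i, ]^2)) + rod_radii[i] > disk_radius)
      stop("rod ", i, " does not fit inside the disk")
    if (i > 1) for (j in 1:(i - 1)) {
      if (sqrt(sum((rod_centers[i, ] - rod_centers[j, ])^2)) <
          rod_radii[i] + rod_radii[j])
        stop("rods ", j, " and ", i, " overlap")
    }
  }
  yy <- matrix(y, grid_n[1], grid_n[2])
  xx <- matrix(x, grid_n[1], grid_n[2], byrow = TRUE)
  dens <- (yy^2 + xx^2 <= disk_radius^2) * 1
  for (i in seq_len(nr)) {
    dens[(yy - rod_centers[i, 1])^2 + (xx - rod_centers[i, 2])^2 <=
           rod_radii[i]^2] <- 0
  }
  digital_phantom(dens, fov)
}

#' Smooth off-resonance (poor-shim) map
#'
#' A linear plus quadratic field combination with a configurable peak,
#' emulating intentionally degraded shimming. For a 2D phantom the map is
#' `peak * (w * u + (1 - w) * (u^2 + v^2 - 1/2))` with `u, v` the
#' normalized coordinates in [-1/2, 1/2] scaled to peak magnitude `peak`.
#'
#' @param phantom A [digital_phantom()].
#' @param peak Peak |off-resonance| in Hz.
#' @param linear_weight Weight of the linear term in [0, 1].
#' @return The phantom with its `off_resonance` field replaced.
#' @export
with_shim_offresonance <- function(phantom, peak, linear_weight = 0.5) {
  stopifnot(inherits(phantom, "digital_phantom"))
  if (is.matrix(phantom$density)) {
    u <- matrix(phantom$y / phantom$fov[1], length(phantom$y),
                length(phantom$x))
    v <- matrix(phantom$x / phantom$fov[2], length(phantom$y),
                length(phantom$x), byrow = TRUE)
    raw <- linear_weight * u + (1 - linear_weight) * (u^2 + v^2 - 0.25)
  } else {
    u <- phantom$y / phantom$fov
    raw <- linear_weight * u + (1 - linear_weight) * (u^2 - 0.125)
  }
  phantom$off_resonance <- peak * raw / max(abs(raw))
  phantom
}

#' Acquired-signal container
#'
#' @param samples Complex vector (1D acquisition) or matrix (2D hybrid
#'   k-space; rows = SPEN/phase axis samples, columns = readout samples in
#'   acquisition order).
#' @param traj The [k_trajectory()] along the SPEN axis.
#' @param noise_sd Complex noise standard deviation used in synthesis.
#' @param meta List of acquisition metadata.
#' @return An object of class `"acquired_signal"`.
#' @export
acquired_signal <- function(samples, traj = NULL, noise_sd = 0,
                            meta = list()) {
  if (any(!is.finite(Mod(samples)))) stop("samples must be finite")
  structure(list(samples = samples, traj = traj, noise_sd = noise_sd,
                 meta = meta),
            class = "acquired_signal")
}

#' @export
print.acquired_signal <- function(x, ...) {
  d <- if (is.matrix(x$samples)) paste(dim(x$samples), collapse = " x ") else
    length(x$samples)
  cat("Acquired signal:", d, "samples, noise sd", x$noise_sd, "\n")
  invisible(x)
}

complex_noise <- function(n, sd) {
  complex(real = stats::rnorm(n, sd = sd / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sd / sqrt(2)))
}

#' Synthesize a 1D SPEN acquisition
#'
#' `s = A rho + eta` with `A` the forward operator; when the phantom
#' carries off-resonance and the trajectory has sample times, the phase
#' `2*pi*df(y)*t_i` accrues inside the encoding sum. Noise is i.i.d.
#' circular complex Gaussian with total standard deviation `noise_sd` per
#' sample.
#'
#' @param phantom A 1D [digital_phantom()] on the operator grid.
#' @param op A [build_forward_operator()] result.
#' @param traj The [k_trajectory()] used to build `op`.
#' @param noise_sd Complex noise standard deviation.
#' @param seed Optional RNG seed for the noise draw.
#' @return An [acquired_signal()].
#' @export
synthesize_spen_signal <- function(phantom, op, traj, noise_sd = 0,
                                   seed = NULL) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(op, "forward_operator"))
  rho <- phantom$density
  if (is.matrix(rho)) stop("1D synthesis requires a 1D phantom")
  if (length(rho) != ncol(op$matrix))
    stop("phantom grid does not match the operator grid")
  if (max(abs(phantom$y - op$grid)) > 1e-9 * phantom$fov)
    stop("phantom positions do not match the operator grid")
  a <- op$matrix
  if (any(phantom$off_resonance != 0)) {
    a <- a * exp(1i * 2 * pi * outer(traj$sample_times,
                                     phantom$off_resonance))
  }
  s <- as.vector(a %*% rho)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + complex_noise(length(s), noise_sd)
  }
  acquired_signal(s, traj, noise_sd,
                  meta = list(beta = op$beta, fov = phantom$fov))
}

#' Synthesize a 2D SPEN- or Fourier-encoded EPI hybrid k-space
#'
#' Frequency (Fourier) encoding along the readout axis and either SPEN
#' (quadratic phase + sweep) or conventional phase encoding along the
#' second axis, with an alternating-polarity echo-planar readout train.
#' Even-numbered lines are traversed in reverse and are stored in
#' acquisition order (spatially flipped), as in raw EPI data. A constant
#' gradient-timing error `delay` (s) shifts every readout along its own
#' traversal direction, producing the even/odd misalignment that appears as
#' a saw-tooth in hybrid k-space. Off-resonance accrues as
#' `2*pi*df(x,y)*t` with the true per-sample time
#' `t = (i - n/2) esp + (j - n/2) dwell` relative to the echo center.
#'
#' @param phantom A 2D [digital_phantom()] (rows = SPEN axis y). The
#'   phantom grid may be finer than the acquisition matrix; it should
#'   oversample the spatial chirp (grid step below `pi / (|beta| fov)`) so
#'   that the synthesized data carry the continuum localization of SPEN.
#' @param params An [encoding_params()]; `beta = 0` gives conventional EPI.
#' @param matrix_size Acquired matrix `c(n_lines, n_readout)`; defaults to
#'   the phantom dimensions.
#' @param esp Echo spacing (line period) in s.
#' @param dwell Readout dwell time in s.
#' @param delay Readout gradient delay in s (`delay = dwell` is a one-sample
#'   shift).
#' @param noise_sd Complex noise standard deviation per sample.
#' @param seed Optional RNG seed.
#' @return An [acquired_signal()] whose `samples` matrix is lines x readout
#'   samples; `meta` records the encoding mode, spacings and delay.
#' @export
synthesize_epi_hybrid <- function(phantom, params, matrix_size = NULL,
                                  esp = 5e-4, dwell = 5e-6,
                                  delay = 0, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(params, "encoding_params"))
  rho <- phantom$density
  if (!is.matrix(rho)) stop("2D synthesis requires a 2D phantom")
  if (is.null(matrix_size)) matrix_size <- dim(rho)
  matrix_size <- rep_len(matrix_size, 2)
  ny <- matrix_size[1]; nx <- matrix_size[2]
  y <- phantom$y; x <- phantom$x
  fovx <- phantom$fov[2]
  traj <- if (params$beta != 0) spen_trajectory(params, ny, esp) else
    dft_trajectory(ny, phantom$fov[1], esp)
  kx_grid <- (seq_len(nx) - 1 - nx / 2) * 2 * pi / fovx
  dkx <- 2 * pi / fovx
  df <- phantom$off_resonance
  ew <- exp(1i * 2 * pi * df * dwell) # per-dwell off-resonance accrual
  out <- matrix(0 + 0i, ny, nx)
  enc_y <- exp(1i * params$beta * y^2)
  shift_k <- dkx * delay / dwell
  for (i in seq_len(ny)) {
    reversed <- i %% 2 == 0
    # odd lines traverse kx left->right; even lines right->left and carry
    # the gradient-delay k offset relative to the odd lines
    kxs <- if (reversed) rev(kx_grid) + shift_k else kx_grid
    t_line <- (i - 1 - ny / 2) * esp + (0 - nx / 2) * dwell
    w <- rho * (enc_y * exp(1i * traj$k[i] * y)) *
      exp(1i * 2 * pi * df * t_line)
    for (j in seq_len(nx)) {
      out[i, j] <- sum(colSums(w) * exp(1i * kxs[j] * x))
      w <- w * ew
    }
  }
  out <- out * (phantom$fov[1] / nrow(rho)) * (fovx / ncol(rho))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    out <- out + matrix(complex_noise(length(out), noise_sd), ny, nx)
  }
  acquired_signal(out, traj, noise_sd,
                  meta = list(mode = if (params$beta != 0) "spen" else "fourier",
                              params = params, esp = esp, dwell = dwell,
                              delay = delay, fov = phantom$fov,
                              dims = c(ny, nx)))
}

#' Block-average a phantom to a coarser grid
#'
#' Averages the density and off-resonance maps over equal blocks, e.g. to
#' compare a reconstruction on the acquisition matrix with a phantom
#' defined on a finer synthesis grid. Grid sizes must be integer multiples
#' of the target.
#'
#' @param phantom A [digital_phantom()].
#' @param n Target size (scalar or per-axis).
#' @return A [digital_phantom()] on the coarser grid.
#' @export
phantom_downsample <- function(phantom, n) {
  stopifnot(inherits(phantom, "digital_phantom"))
  blockavg <- function(m, ny, nx) {
    fy <- nrow(m) / ny; fx <- ncol(m) / nx
    if (fy != round(fy) || fx != round(fx))
      stop("grid is not an integer multiple of the target size")
    out <- matrix(0, ny, nx)
    for (i in seq_len(ny)) for (j in seq_len(nx))
      out[i, j] <- mean(m[((i - 1) * fy + 1):(i * fy),
                          ((j - 1) * fx + 1):(j * fx)])
    out
  }
  if (is.matrix(phantom$density)) {
    n <- rep_len(n, 2)
    digital_phantom(blockavg(phantom$density, n[1], n[2]), phantom$fov,
                    blockavg(phantom$off_resonance, n[1], n[2]))
  } else {
    f <- length(phantom$density) / n
    if (f != round(f)) stop("grid is not an integer multiple of the target")
    digital_phantom(colMeans(matrix(phantom$density, f, n)), phantom$fov,
                    colMeans(matrix(phantom$off_resonance, f, n)))
  }
}
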