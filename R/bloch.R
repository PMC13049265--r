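#' Spatial grid for Bloch simulation along the SPEN axis
#'
#' @param positions Strictly increasing positions in m along the encoding
#'   axis y.
#' @param gradient Constant gradient in Hz/m (the `gamma*G/2pi` convention,
#'   e.g. 250e3 for 250 kHz/m).
#' @param off_resonance Off-resonance in Hz, scalar or one value per
#'   position.
#' @return An object of class `"sim_grid"`.
#' @export
sim_grid <- function(positions, gradient = 0, off_resonance = 0) {
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (!is.finite(gradient)) stop("gradient must be finite")
  off_resonance <- rep_len(off_resonance, length(positions))
  structure(list(positions = positions, gradient = gradient,
                 off_resonance = off_resonance),
            class = "sim_grid")
}

#' Initial magnetization state
#'
#' @param n Number of positions.
#' @param m A length-3 vector replicated across positions (default
#'   equilibrium `c(0, 0, 1)`).
#' @return A 3 x n matrix (rows Mx, My, Mz).
#' @export
equilibrium_magnetization <- function(n, m = c(0, 0, 1)) {
  matrix(rep(m, n), nrow = 3)
}

#' Hard-pulse Bloch simulation of an RF pulse
#'
#' Piecewise-constant rotations per RF raster sample about the effective
#' field formed by the RF waveform, the gradient at each position, and the
#' off-resonance. Relaxation-free. Norm-preserving by construction.
#'
#' @param pulse An [rf_pulse()].
#' @param grid A [sim_grid()], or `NULL` if `offsets` is given.
#' @param offsets Frequency offsets in Hz; alternative to `grid` for
#'   off-resonance-axis simulations.
#' @param initial 3 x P initial magnetization; defaults to equilibrium.
#' @return A 3 x P magnetization matrix with attribute `"axis"` holding the
#'   positions or offsets.
#' @export
simulate_pulse <- function(pulse, grid = NULL, offsets = NULL,
                           initial = NULL) {
  stopifnot(inherits(pulse, "rf_pulse"))
  if (is.null(grid) == is.null(offsets))
    stop("supply exactly one of 'grid' or 'offsets'")
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "sim_grid"))
    df <- grid$gradient * grid$positions + grid$off_resonance
    axis <- grid$positions
  } else {
    df <- offsets
    axis <- offsets
  }
  df <- df - pulse$carrier_offset
  p <- length(df)
  if (is.null(initial)) initial <- equilibrium_magnetization(p)
  if (nrow(initial) != 3L || ncol(initial) != p)
    stop("initial magnetization does not match the grid")
  m <- bloch_hard_pulse(Re(pulse$samples), Im(pulse$samples),
                        pulse$raster, df, initial)
  attr(m, "axis") <- axis
  m
}

#' Flip-angle profile versus frequency offset
#'
#' Simulates the pulse from equilibrium at each offset and reports
#' `flip = atan2(|Mxy|, Mz)` together with the transverse phase.
#'
#' @param pulse An [rf_pulse()].
#' @param offsets Frequency offsets in Hz.
#' @return An object of class `"excitation_profile"` with fields `offsets`,
#'   `flip_angle` (rad) and `transverse_phase` (rad, wrapped).
#' @export
flip_angle_profile <- function(pulse, offsets) {
  m <- simulate_pulse(pulse, offsets = offsets)
  mxy <- sqrt(m[1, ]^2 + m[2, ]^2)
  structure(list(offsets = offsets,
                 flip_angle = atan2(mxy, m[3, ]),
                 transverse_phase = atan2(m[2, ], m[1, ])),
            class = "excitation_profile")
}

#' @export
plot.excitation_profile <- function(x, what = c("flip", "phase"), ...) {
  what <- match.arg(what)
  ax <- if (!is.null(x$positions)) x$positions * 1e3 else x$offsets / 1e3
  xl <- if (!is.null(x$positions)) "position [mm]" else "offset [kHz]"
  if (what == "flip")
    graphics::plot(ax, x$flip_angle * 180 / pi, type = "l", xlab = xl,
                   ylab = "flip angle [deg]", ...)
  else
    graphics::plot(ax, x$transverse_phase, type = "l", xlab = xl,
                   ylab = "phase [rad]", ...)
  invisible(x)
}

#' Post-excitation phase profile along the SPEN axis
#'
#' Simulates the pulse on a spatial grid under its companion excitation
#' gradient and returns the unwrapped transverse phase versus position. For
#' an up-swept chirp the raw profile is `-(beta y^2 + beta FOV y) + const`;
#' a refocusing lobe of gradient area `gradient*duration/2` (applied here as
#' a phase ramp when `remove_linear = TRUE`) cancels the linear term, and
#' `prephase` (rad/m) adds an additional linear phase `prephase * y`, e.g.
#' to reposition the parabola vertex at one FOV edge.
#'
#' Unwrapping proceeds outward from the grid center; positions whose flip
#' angle is below `flip_threshold` are marked unusable (`NA` phase) since
#' their phase is ill-defined.
#'
#' @param pulse An [rf_pulse()] produced by one of the chirp designers.
#' @param grid A [sim_grid()] whose `gradient` is the excitation gradient.
#' @param remove_linear Apply the linear-term refocusing lobe.
#' @param prephase Additional linear phase coefficient in rad/m.
#' @param flip_threshold Minimum flip angle (rad) for a usable phase sample.
#' @return An `"excitation_profile"` with fields `positions`, `flip_angle`,
#'   `transverse_phase` (unwrapped, rad).
#' @export
encoded_phase_profile <- function(pulse, grid, remove_linear = FALSE,
                                  prephase = 0,
                                  flip_threshold = pi / 180) {
  stopifnot(inherits(grid, "sim_grid"))
  m <- simulate_pulse(pulse, grid = grid)
  y <- grid$positions
  mxy <- complex(real = m[1, ], imaginary = m[2, ])
  if (remove_linear) {
    d <- attr(pulse, "design")
    if (is.null(d)) stop("pulse carries no chirp design; cannot refocus")
    # up-sweep (start below carrier): natural linear term is -2*pi*(g*T/2)*y
    sweep_sign <- if (d$start_frequency <= d$center_frequency) 1 else -1
    lobe_area <- sweep_sign * grid$gradient * d$duration / 2
    mxy <- mxy * exp(1i * 2 * pi * lobe_area * y)
  }
  if (prephase != 0) mxy <- mxy * exp(1i * prephase * y)
  flip <- atan2(Mod(mxy), m[3, ])
  ok <- flip >= flip_threshold
  ph <- rep(NA_real_, length(y))
  ph[ok] <- Arg(mxy[ok])
  uw <- unwrap_from_center(ph)
  if (all(is.na(uw)))
    stop("unwrap failure: no position exceeds the flip threshold; ",
         "use a finer grid or lower 'flip_threshold'")
  structure(list(positions = y, flip_angle = flip, transverse_phase = uw),
            class = "excitation_profile")
}

# Sequential 1D phase unwrap outward from the central usable sample.
# NA entries (below flip threshold) stay NA and break the chain at the ends.
unwrap_from_center <- function(ph) {
  n <- length(ph)
  out <- rep(NA_real_, n)
  ok <- which(!is.na(ph))
  if (length(ok) == 0L) return(out)
  c0 <- ok[which.min(abs(ok - (n + 1) / 2))]
  out[c0] <- ph[c0]
  if (c0 < n) for (j in (c0 + 1):n) {
    if (is.na(ph[j])) break
    out[j] <- out[j - 1] + wrap_pi(ph[j] - out[j - 1])
  }
  if (c0 > 1) for (j in (c0 - 1):1) {
    if (is.na(ph[j])) break
    out[j] <- out[j + 1] + wrap_pi(ph[j] - out[j + 1])
  }
  out
}

wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Full width at half maximum of a sampled profile
#'
#' Linear interpolation of the half-maximum crossings on either side of the
#' profile maximum.
#'
#' @param x Abscissa (monotone increasing).
#' @param y Profile values.
#' @return FWHM in the units of `x`.
#' @export
profile_fwhm <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 samples")
  half <- max(y) / 2
  above <- which(y >= half)
  if (length(above) == 0L || min(above) == 1L || max(above) == length(y))
    stop("profile does not fall below half maximum on both sides")
  i1 <- min(above); i0 <- i1 - 1
  lo <- x[i0] + (half - y[i0]) * (x[i1] - x[i0]) / (y[i1] - y[i0])
  i1 <- max(above); i2 <- i1 + 1
  hi <- x[i1] + (half - y[i1]) * (x[i2] - x[i1]) / (y[i2] - y[i1])
  hi - lo
}

#' Quadratic fit of an encoded phase profile
#'
#' Fits `a0 + a1 y + a2 y^2` to the unwrapped phase over the central
#' `central_fraction` of the position range (the FOV edges are excluded
#' because the swept excitation attenuates there). Returns the coefficients
#' and the parabola vertex `-a1/(2 a2)`.
#'
#' @param profile An `"excitation_profile"` from [encoded_phase_profile()].
#' @param central_fraction Fraction of the position range kept for the fit.
#' @return List with `coefficients` (a0, a1, a2), `vertex` (m) and
#'   `rms_residual` (rad).
#' @export
fit_quadratic_phase <- function(profile, central_fraction = 0.8) {
  y <- profile$positions
  ph <- profile$transverse_phase
  half <- central_fraction * (max(y) - min(y)) / 2
  mid <- (max(y) + min(y)) / 2
  sel <- abs(y - mid) <= half & !is.na(ph)
  if (sum(sel) < 5) stop("too few usable phase samples for a quadratic fit")
  co <- stats::coef(stats::lm(ph[sel] ~ y[sel] + I(y[sel]^2)))
  names(co) <- c("a0", "a1", "a2")
  fitv <- co[1] + co[2] * y[sel] + co[3] * y[sel]^2
  list(coefficients = co,
       vertex = unname(-co[2] / (2 * co[3])),
       rms_residual = sqrt(mean((ph[sel] - fitv)^2)))
}
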