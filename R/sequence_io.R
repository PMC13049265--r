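# Event timelines for SPEN / Fourier spin-echo EPI and a text Pulseq-subset
# writer/reader.
#
# A timeline is an ordered list of blocks; each block owns the events that
# play concurrently in it (an RF pulse with its companion gradient, a
# readout gradient with its ADC, ...). Starts and durations are integer
# multiples of the governing raster (RF 1 us, gradients 10 us by default).

#' Sequence configuration for the SE-EPI builders
#'
#' Defaults reproduce the reference protocol: 64 x 64 matrix, 50 kHz chirp
#' over 4 ms (WURST order 40) under the Eq.-5-consistent excitation
#' gradient `bandwidth/fov`, TE 60 ms, and a 313 mT/m^2 / 5 ms quadratic
#' gradient event for the nonlinear-gradient variant.
#'
#' @param matrix_size Samples per axis (square matrix).
#' @param fov Field of view in m.
#' @param te Echo time in s (excitation center to echo center).
#' @param bandwidth Chirp sweep bandwidth in Hz.
#' @param chirp_duration Chirp duration in s.
#' @param wurst_order WURST amplitude-modulation order.
#' @param gradient SPEN excitation gradient in Hz/m; `NULL` derives
#'   `bandwidth / fov`.
#' @param quad_coefficient Quadratic gradient coefficient in T/m^2.
#' @param quad_duration Quadratic gradient event duration in s.
#' @param placement `"post"` plays the quadratic event after the refocusing
#'   pulse; `"pre"` before it (inverting the phase parabola, flagged for
#'   reconstruction).
#' @param esp Echo spacing (EPI line period) in s.
#' @param dwell ADC dwell time in s.
#' @param ramp Readout gradient ramp time in s.
#' @param blip_duration Encoding blip duration in s.
#' @param rf180_duration Refocusing (hard) pulse duration in s.
#' @param sinc_duration,sinc_tbw Slice-selective excitation sinc parameters.
#' @param slice_thickness Nominal slice thickness in m (bookkeeping).
#' @param rf_raster,grad_raster RF and gradient rasters in s.
#' @param max_gradient Linear-gradient amplitude limit in Hz/m.
#' @param max_quad Quadratic-gradient coefficient limit in T/m^2.
#' @return A list of class `"spen_config"`.
#' @export
spen_config <- function(matrix_size = 64, fov = 0.2, te = 60e-3,
                        bandwidth = 50e3, chirp_duration = 4e-3,
                        wurst_order = 40, gradient = NULL,
                        quad_coefficient = 0.313, quad_duration = 5e-3,
                        placement = c("post", "pre"),
                        esp = 5e-4, dwell = 4e-6, ramp = 8e-5,
                        blip_duration = 4e-5, rf180_duration = 1e-3,
                        sinc_duration = 3e-3, sinc_tbw = 4,
                        slice_thickness = 5e-3,
                        rf_raster = 1e-6, grad_raster = 1e-5,
                        max_gradient = 4.5e6, max_quad = 0.4) {
  placement <- match.arg(placement)
  if (is.null(gradient)) gradient <- bandwidth / fov
  cfg <- list(matrix_size = matrix_size, fov = fov, te = te,
              bandwidth = bandwidth, chirp_duration = chirp_duration,
              wurst_order = wurst_order, gradient = gradient,
              quad_coefficient = quad_coefficient,
              quad_duration = quad_duration, placement = placement,
              esp = esp, dwell = dwell, ramp = ramp,
              blip_duration = blip_duration,
              rf180_duration = rf180_duration,
              sinc_duration = sinc_duration, sinc_tbw = sinc_tbw,
              slice_thickness = slice_thickness,
              rf_raster = rf_raster, grad_raster = grad_raster,
              max_gradient = max_gradient, max_quad = max_quad)
  class(cfg) <- "spen_config"
  cfg
}

snap <- function(x, raster) {
  r <- round(x / raster) * raster
  if (abs(r - x) > 1e-6 * raster + 1e-12)
    stop("timing violates the raster: ", x, " s is not a multiple of ",
         raster, " s")
  r
}

new_event <- function(kind, start, duration, block, payload = list()) {
  c(list(kind = kind, start = start, duration = duration, block = block),
    payload)
}

trap_area <- function(ev) {
  ev$amplitude * (ev$flat + (ev$ramp_up + ev$ramp_down) / 2)
}

#' Event timeline container
#'
#' @param events List of sequence events (built by the `build_*` functions).
#' @param te Echo time in s.
#' @param mode `"chirp_spen"`, `"quadgrad_spen"` or `"fourier"`.
#' @param config The [spen_config()] used.
#' @param meta Bookkeeping (encoding beta, areas, trajectory, flags).
#' @return An object of class `"event_timeline"`.
#' @export
event_timeline <- function(events, te, mode, config, meta = list()) {
  tl <- structure(list(events = events, te = te, mode = mode,
                       config = config, meta = meta),
                  class = "event_timeline")
  validate_timeline(tl)
  tl
}

validate_timeline <- function(tl) {
  ev <- tl$events
  for (kind in c("rf", "adc")) {
    sel <- Filter(function(e) e$kind == kind, ev)
    if (length(sel) > 1) {
      iv <- t(vapply(sel, function(e) c(e$start, e$start + e$duration),
                     numeric(2)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-12))
        stop("overlapping ", kind, " events")
    }
  }
  for (e in ev) {
    if (e$kind == "delay") {
      if (e$duration < 0) stop("negative delay")
    } else if (e$duration <= 0) stop("non-positive event duration")
  }
  invisible(tl)
}

#' @export
print.event_timeline <- function(x, ...) {
  cat(sprintf("%s timeline: %d events, TE %g ms, total %.4g ms\n",
              x$mode, length(x$events), x$te * 1e3,
              total_duration(x) * 1e3))
  invisible(x)
}

#' Total duration of a timeline
#'
#' End of the last event minus start of the first; 0 for an empty timeline.
#'
#' @param t An [event_timeline()] (or a bare event list).
#' @return Duration in s.
#' @export
total_duration <- function(t) {
  ev <- if (inherits(t, "event_timeline")) t$events else t
  if (length(ev) == 0L) return(0)
  ends <- vapply(ev, function(e) e$start + e$duration, 0)
  starts <- vapply(ev, function(e) e$start, 0)
  max(ends) - min(starts)
}

# --- internal build machinery -------------------------------------------

check_gradient_limit <- function(amp, cfg, what) {
  if (abs(amp) > cfg$max_gradient)
    stop("gradient limit violated for ", what, ": |", signif(amp, 4),
         "| Hz/m exceeds ", cfg$max_gradient, " Hz/m")
  amp
}

# EPI readout train shared by all three modes. Returns events plus the
# readout geometry. Blip areas (Hz s/m, on the encoding axis) are supplied
# by the caller: length N-1 (between lines) or N (one after each line).
build_epi_train <- function(cfg, train_start, blip_areas) {
  n <- cfg$matrix_size
  gr <- cfg$grad_raster
  flat <- ceiling(n * cfg$dwell / gr) * gr
  line_len <- 2 * cfg$ramp + flat
  if (cfg$esp < line_len + cfg$blip_duration)
    stop("echo spacing too short: need at least ",
         (line_len + cfg$blip_duration) * 1e3, " ms")
  gx_amp <- check_gradient_limit((n / cfg$fov) / flat, cfg, "readout")
  adc_delay <- (flat - n * cfg$dwell) / 2
  ev <- list()
  blk <- 0L
  for (i in seq_len(n)) {
    t0 <- train_start + (i - 1) * cfg$esp
    blk <- blk + 1L
    ev[[length(ev) + 1L]] <- new_event("grad_trap", t0, line_len, blk,
      list(channel = "x", amplitude = gx_amp * (-1)^(i - 1),
           ramp_up = cfg$ramp, flat = flat, ramp_down = cfg$ramp))
    ev[[length(ev) + 1L]] <- new_event("adc", t0 + cfg$ramp + adc_delay,
      n * cfg$dwell, blk, list(n_samples = n, dwell = cfg$dwell))
    if (i <= length(blip_areas)) {
      blk <- blk + 1L
      amp <- check_gradient_limit(
        blip_areas[i] / (cfg$blip_duration / 2), cfg, "blip")
      ev[[length(ev) + 1L]] <- new_event("grad_trap", t0 + line_len,
        cfg$esp - line_len, blk,
        list(channel = "y", amplitude = amp,
             ramp_up = cfg$blip_duration / 2, flat = 0,
             ramp_down = cfg$blip_duration / 2))
    }
  }
  list(events = ev, line_len = line_len, flat = flat,
       echo_center = train_start + (n / 2) * cfg$esp + line_len / 2)
}

# shift block ids of a list of events by an offset
shift_blocks <- function(ev, off) {
  lapply(ev, function(e) { e$block <- e$block + off; e })
}

trap_for_area <- function(area, duration, ramp, channel, start, block, cfg) {
  flat <- duration - 2 * ramp
  if (flat < 0) stop("trapezoid shorter than its ramps")
  amp <- check_gradient_limit(area / (flat + ramp), cfg, channel)
  new_event("grad_trap", start, duration, block,
            list(channel = channel, amplitude = amp, ramp_up = ramp,
                 flat = flat, ramp_down = ramp))
}

# shortest raster-aligned trapezoid duration that realizes `area` at no
# more than 90% of the amplitude limit (minimum 1 ms)
auto_trap_duration <- function(area, ramp, cfg) {
  eff <- abs(area) / (0.9 * cfg$max_gradient) # flat + ramp needed
  dur <- max(1e-3, ramp + eff)
  ceiling(dur / cfg$grad_raster) * cfg$grad_raster
}

hard_180 <- function(start, block, cfg, selective) {
  amp <- 0.5 / cfg$rf180_duration # 2*pi*A*T = pi
  p <- rf_pulse(rep(amp, round(cfg$rf180_duration / cfg$rf_raster)),
                cfg$rf_raster)
  new_event("rf", start, cfg$rf180_duration, block,
            list(pulse = p, flip = pi, selective = selective,
                 label = "refocus"))
}

# place the train so that its echo center lands at exc_center + te
locate_train <- function(cfg, exc_center, earliest) {
  n <- cfg$matrix_size
  gr <- cfg$grad_raster
  flat <- ceiling(n * cfg$dwell / gr) * gr
  line_len <- 2 * cfg$ramp + flat
  train_start <- snap(exc_center + cfg$te - (n / 2) * cfg$esp - line_len / 2,
                      gr)
  if (train_start < earliest - 1e-12) {
    min_te <- cfg$te + (earliest - train_start)
    stop(sprintf(
      "TE infeasible: events end at %.4g ms but the readout train must start at %.4g ms; minimum TE is %.4g ms",
      earliest * 1e3, train_start * 1e3, min_te * 1e3))
  }
  train_start
}

#' Build a chirped-RF SPEN spin-echo EPI timeline
#'
#' WURST chirp excitation under the SPEN encoding gradient, a linear-term
#' refocusing lobe, a hard refocusing pulse, the stationary-point
#' prephaser, and an alternating-polarity EPI readout whose SPEN blips
#' satisfy the gradient-area condition exactly.
#'
#' @param config A [spen_config()].
#' @return An [event_timeline()]; `meta` records the encoding beta, the
#'   excitation area and the SPEN-axis [k_trajectory()].
#' @export
build_chirp_spen_se_epi <- function(config = spen_config()) {
  cfg <- config
  g <- cfg$gradient
  beta <- beta_from_chirp(g, cfg$bandwidth, cfg$chirp_duration)
  exc_area <- g * cfg$chirp_duration
  chirp <- design_wurst_chirp(
    chirp_design(cfg$bandwidth, cfg$chirp_duration, cfg$wurst_order),
    cfg$rf_raster)
  gr <- cfg$grad_raster
  ev <- list()
  # block 1: excitation gradient + chirp on its flat top
  exc_dur <- cfg$chirp_duration + 2 * cfg$ramp
  ev[[1]] <- new_event("grad_trap", 0, exc_dur, 1L,
    list(channel = "y", amplitude = check_gradient_limit(g, cfg, "excitation"),
         ramp_up = cfg$ramp, flat = cfg$chirp_duration,
         ramp_down = cfg$ramp))
  ev[[2]] <- new_event("rf", cfg$ramp, cfg$chirp_duration, 1L,
    list(pulse = chirp, flip = pi / 2, selective = FALSE,
         label = "chirp_excitation"))
  exc_center <- cfg$ramp + cfg$chirp_duration / 2
  # block 2: linear-term refocusing lobe (area -g*T/2)
  lobe_dur <- 1e-3
  ev[[3]] <- trap_for_area(-exc_area / 2, lobe_dur, gr * 10, "y",
                           exc_dur, 2L, cfg)
  cursor <- exc_dur + lobe_dur
  # block 3/4: delay + refocusing pulse centered at exc_center + te/2
  rf180_start <- snap(exc_center + cfg$te / 2 - cfg$rf180_duration / 2, gr)
  if (rf180_start < cursor)
    stop("TE infeasible: refocusing pulse overlaps the excitation events")
  ev[[4]] <- new_event("delay", cursor, rf180_start - cursor, 3L)
  ev[[5]] <- hard_180(rf180_start, 4L, cfg, selective = TRUE)
  cursor <- rf180_start + cfg$rf180_duration
  # block 5: SPEN prephaser (k0 = +beta*fov) and readout prephaser
  pre_dur <- 1e-3
  ev[[6]] <- trap_for_area(beta * cfg$fov / (2 * pi), pre_dur, gr * 10,
                           "y", cursor, 5L, cfg)
  n <- cfg$matrix_size
  ev[[7]] <- trap_for_area(-(n / 2) / cfg$fov, pre_dur, gr * 10,
                           "x", cursor, 5L, cfg)
  cursor <- cursor + pre_dur
  train_start <- locate_train(cfg, exc_center, cursor)
  ev[[8]] <- new_event("delay", cursor, train_start - cursor, 6L)
  # SPEN blips: N-1 steps of -delta_k/(N-1) between lines
  dk_area <- 2 * beta * cfg$fov / (2 * pi)
  blips <- rep(-dk_area / (n - 1), n - 1)
  tr <- build_epi_train(cfg, train_start, blips)
  ev <- c(ev, shift_blocks(tr$events, 6L))
  params <- encoding_params(beta, cfg$fov)
  traj <- spen_trajectory(params, n, cfg$esp)
  event_timeline(ev, cfg$te, "chirp_spen", cfg,
                 meta = list(beta = beta, params = params, traj = traj,
                             exc_area = exc_area,
                             exc_center = exc_center,
                             echo_center = tr$echo_center,
                             invert_kernel = FALSE))
}

#' Build a quadratic-gradient SPEN spin-echo EPI timeline
#'
#' Slice-selective sinc excitation, hard refocusing, a quadratic gradient
#' event (by default the nominal hardware setting, 313 mT/m^2 for 5 ms)
#' placed in the TE delay after ("post") or before ("pre") the refocusing
#' pulse, and the same EPI readout train as the chirp variant. The
#' encoding beta used for the SPEN blips, prephaser and reconstruction is
#' matched to the chirp design of the same configuration (`beta_mode =
#' "matched"`, the default) or taken from the quadratic event itself
#' (`beta_mode = "native"`).
#'
#' @param config A [spen_config()].
#' @param beta_mode `"matched"` or `"native"` (see Details).
#' @return An [event_timeline()].
#' @export
build_quadgrad_spen_se_epi <- function(config = spen_config(),
                                       beta_mode = c("matched", "native")) {
  cfg <- config
  beta_mode <- match.arg(beta_mode)
  if (abs(cfg$quad_coefficient) > cfg$max_quad)
    stop("quadratic gradient limit violated: |", cfg$quad_coefficient,
         "| T/m^2 exceeds ", cfg$max_quad)
  beta <- if (beta_mode == "matched")
    beta_from_chirp(cfg$gradient, cfg$bandwidth, cfg$chirp_duration)
  else
    beta_from_quadratic_gradient(cfg$quad_coefficient, cfg$quad_duration)
  gr <- cfg$grad_raster
  n <- cfg$matrix_size
  ev <- list()
  # block 1: slice-selective sinc excitation
  exc_dur <- cfg$sinc_duration + 2 * cfg$ramp
  gs <- check_gradient_limit(
    cfg$sinc_tbw / (cfg$sinc_duration * cfg$slice_thickness), cfg, "slice")
  ev[[1]] <- new_event("grad_trap", 0, exc_dur, 1L,
    list(channel = "z", amplitude = gs, ramp_up = cfg$ramp,
         flat = cfg$sinc_duration, ramp_down = cfg$ramp))
  sinc <- design_sinc(sinc_design(cfg$sinc_duration, cfg$sinc_tbw),
                      cfg$rf_raster)
  ev[[2]] <- new_event("rf", cfg$ramp, cfg$sinc_duration, 1L,
    list(pulse = sinc, flip = pi / 2, selective = TRUE,
         label = "sinc_excitation"))
  exc_center <- cfg$ramp + cfg$sinc_duration / 2
  # block 2: slice rephaser
  reph_dur <- 6e-4
  ev[[3]] <- trap_for_area(-gs * (cfg$sinc_duration + cfg$ramp) / 2,
                           reph_dur, gr * 10, "z", exc_dur, 2L, cfg)
  cursor <- exc_dur + reph_dur
  blk <- 3L
  rf180_start <- snap(exc_center + cfg$te / 2 - cfg$rf180_duration / 2, gr)
  place_quad <- function(start, block) {
    new_event("grad_quad", start, cfg$quad_duration, block,
              list(coefficient = cfg$quad_coefficient))
  }
  if (cfg$placement == "pre") {
    if (cursor + cfg$quad_duration > rf180_start)
      stop("timing error: quadratic event does not fit before the ",
           "refocusing pulse")
    ev[[length(ev) + 1L]] <- place_quad(cursor, blk); blk <- blk + 1L
    cursor <- cursor + cfg$quad_duration
  }
  if (rf180_start < cursor)
    stop("TE infeasible: refocusing pulse overlaps earlier events")
  ev[[length(ev) + 1L]] <- new_event("delay", cursor, rf180_start - cursor,
                                     blk); blk <- blk + 1L
  ev[[length(ev) + 1L]] <- hard_180(rf180_start, blk, cfg,
                                    selective = FALSE); blk <- blk + 1L
  cursor <- rf180_start + cfg$rf180_duration
  if (cfg$placement == "post") {
    ev[[length(ev) + 1L]] <- place_quad(cursor, blk); blk <- blk + 1L
    cursor <- cursor + cfg$quad_duration
  }
  # prephasers (duration adapts to the amplitude limit for strong beta)
  pre_area <- beta * cfg$fov / (2 * pi)
  pre_dur <- auto_trap_duration(pre_area, gr * 10, cfg)
  ev[[length(ev) + 1L]] <- trap_for_area(pre_area, pre_dur,
                                         gr * 10, "y", cursor, blk, cfg)
  ev[[length(ev) + 1L]] <- trap_for_area(-(n / 2) / cfg$fov, pre_dur,
                                         gr * 10, "x", cursor, blk, cfg)
  blk <- blk + 1L
  cursor <- cursor + pre_dur
  train_start <- locate_train(cfg, exc_center, cursor)
  if (cfg$placement == "post" &&
      rf180_start + cfg$rf180_duration + cfg$quad_duration + pre_dur >
        train_start)
    stop("timing error: quadratic event does not fit in the TE delay")
  ev[[length(ev) + 1L]] <- new_event("delay", cursor, train_start - cursor,
                                     blk)
  dk_area <- 2 * beta * cfg$fov / (2 * pi)
  blips <- rep(-dk_area / (n - 1), n - 1)
  tr <- build_epi_train(cfg, train_start, blips)
  ev <- c(ev, shift_blocks(tr$events, blk))
  params <- encoding_params(beta, cfg$fov)
  traj <- spen_trajectory(params, n, cfg$esp)
  event_timeline(ev, cfg$te, "quadgrad_spen", cfg,
                 meta = list(beta = beta, beta_mode = beta_mode,
                             params = params, traj = traj,
                             exc_area = dk_area,
                             exc_center = exc_center,
                             echo_center = tr$echo_center,
                             invert_kernel = cfg$placement == "pre"))
}

#' Build a conventional Fourier SE-EPI timeline
#'
#' Identical excitation, refocusing and readout train to the
#' quadratic-gradient variant, with conventional phase-encode blips (one
#' per line, total area `N/fov`) in place of SPEN encoding.
#'
#' @param config A [spen_config()].
#' @return An [event_timeline()].
#' @export
build_fourier_se_epi <- function(config = spen_config()) {
  cfg <- config
  gr <- cfg$grad_raster
  n <- cfg$matrix_size
  ev <- list()
  exc_dur <- cfg$sinc_duration + 2 * cfg$ramp
  gs <- check_gradient_limit(
    cfg$sinc_tbw / (cfg$sinc_duration * cfg$slice_thickness), cfg, "slice")
  ev[[1]] <- new_event("grad_trap", 0, exc_dur, 1L,
    list(channel = "z", amplitude = gs, ramp_up = cfg$ramp,
         flat = cfg$sinc_duration, ramp_down = cfg$ramp))
  sinc <- design_sinc(sinc_design(cfg$sinc_duration, cfg$sinc_tbw),
                      cfg$rf_raster)
  ev[[2]] <- new_event("rf", cfg$ramp, cfg$sinc_duration, 1L,
    list(pulse = sinc, flip = pi / 2, selective = TRUE,
         label = "sinc_excitation"))
  exc_center <- cfg$ramp + cfg$sinc_duration / 2
  reph_dur <- 6e-4
  ev[[3]] <- trap_for_area(-gs * (cfg$sinc_duration + cfg$ramp) / 2,
                           reph_dur, gr * 10, "z", exc_dur, 2L, cfg)
  cursor <- exc_dur + reph_dur
  rf180_start <- snap(exc_center + cfg$te / 2 - cfg$rf180_duration / 2, gr)
  if (rf180_start < cursor) stop("TE infeasible")
  ev[[4]] <- new_event("delay", cursor, rf180_start - cursor, 3L)
  ev[[5]] <- hard_180(rf180_start, 4L, cfg, selective = TRUE)
  cursor <- rf180_start + cfg$rf180_duration
  pre_dur <- 1e-3
  ev[[6]] <- trap_for_area(-(n / 2) / cfg$fov, pre_dur, gr * 10, "y",
                           cursor, 5L, cfg)
  ev[[7]] <- trap_for_area(-(n / 2) / cfg$fov, pre_dur, gr * 10, "x",
                           cursor, 5L, cfg)
  cursor <- cursor + pre_dur
  train_start <- locate_train(cfg, exc_center, cursor)
  ev[[8]] <- new_event("delay", cursor, train_start - cursor, 6L)
  blips <- rep(1 / cfg$fov, n) # one blip after each line
  tr <- build_epi_train(cfg, train_start, blips)
  ev <- c(ev, shift_blocks(tr$events, 6L))
  traj <- dft_trajectory(n, cfg$fov, cfg$esp)
  event_timeline(ev, cfg$te, "fourier", cfg,
                 meta = list(beta = 0, traj = traj,
                             exc_center = exc_center,
                             echo_center = tr$echo_center))
}

#' Verify the SPEN area condition of a built timeline
#'
#' Sums the SPEN-axis blip areas of the readout train and compares them
#' with the excitation-side encoding area recorded at build time.
#'
#' @param timeline An [event_timeline()] in a SPEN mode.
#' @param tolerance Relative tolerance.
#' @return A `"spen_condition"` object (see [check_spen_condition()]).
#' @export
timeline_spen_condition <- function(timeline, tolerance = 1e-6) {
  stopifnot(inherits(timeline, "event_timeline"))
  if (timeline$mode == "fourier") stop("not a SPEN timeline")
  check_spen_condition(timeline$meta$exc_area, timeline$meta$traj,
                       tolerance)
}
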