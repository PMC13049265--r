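# Text writer/reader for a version-stamped subset of the Pulseq .seq
# format: [VERSION], [DEFINITIONS], [BLOCKS], [RF], [TRAP], [ADC],
# [SHAPES], plus a [QUAD] extension section for quadratic-gradient events
# (their coefficient is also recorded under [DEFINITIONS]). Shapes are
# stored uncompressed (magnitude normalized to the peak, phase in rad).

fmt_num <- function(x) sprintf("%.10g", x)

#' Export an event timeline to a Pulseq-subset .seq text file
#'
#' Deterministic: the same timeline always produces byte-identical output.
#' Events must sit on their rasters; violations refuse to write.
#'
#' @param timeline An [event_timeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_pulseq <- function(timeline, path) {
  stopifnot(inherits(timeline, "event_timeline"))
  ev <- timeline$events
  gr <- timeline$config$grad_raster %||% 1e-5
  rr <- timeline$config$rf_raster %||% 1e-6
  blocks <- sort(unique(vapply(ev, function(e) e$block, 0L)))
  # registries with deduplication
  rf_tab <- list(); trap_tab <- list(); adc_tab <- list()
  quad_tab <- list(); shape_tab <- list()
  intern <- function(tab, key, make) {
    if (!is.null(tab[[key]])) return(list(tab = tab, id = tab[[key]]$id))
    entry <- make(length(tab) + 1L)
    tab[[key]] <- entry
    list(tab = tab, id = entry$id)
  }
  block_rows <- list()
  t_cursor <- 0
  for (b in blocks) {
    bev <- Filter(function(e) e$block == b, ev)
    starts <- vapply(bev, function(e) e$start, 0)
    ends <- vapply(bev, function(e) e$start + e$duration, 0)
    b_start <- min(starts)
    if (abs(b_start - t_cursor) > 1e-9)
      stop("blocks are not contiguous at block ", b)
    dur <- max(ends) - b_start
    ticks <- dur / gr
    if (abs(ticks - round(ticks)) > 1e-6)
      stop("refusing to write: block ", b,
           " duration is not a multiple of the gradient raster")
    row <- list(id = b, dur = round(ticks), rf = 0L, gx = 0L, gy = 0L,
                gz = 0L, adc = 0L, quad = 0L)
    for (e in bev) {
      delay <- e$start - b_start
      if (e$kind == "rf") {
        p <- e$pulse
        amp <- max(Mod(p$samples))
        mag <- if (amp > 0) Mod(p$samples) / amp else Mod(p$samples)
        phs <- Arg(p$samples)
        r1 <- intern(shape_tab, paste(c("m", fmt_num(mag)), collapse = ","),
                     function(id) list(id = id, samples = mag))
        shape_tab <- r1$tab
        r2 <- intern(shape_tab, paste(c("p", fmt_num(phs)), collapse = ","),
                     function(id) list(id = id, samples = phs))
        shape_tab <- r2$tab
        key <- paste("rf", fmt_num(amp), r1$id, r2$id, fmt_num(delay),
                     fmt_num(p$carrier_offset), fmt_num(p$raster))
        r <- intern(rf_tab, key, function(id)
          list(id = id, amp = amp, mag = r1$id, phase = r2$id,
               delay = delay, freq = p$carrier_offset, raster = p$raster))
        rf_tab <- r$tab
        row$rf <- r$id
      } else if (e$kind == "grad_trap") {
        key <- paste("tr", fmt_num(e$amplitude), fmt_num(e$ramp_up),
                     fmt_num(e$flat), fmt_num(e$ramp_down), fmt_num(delay))
        r <- intern(trap_tab, key, function(id)
          list(id = id, amp = e$amplitude, rise = e$ramp_up,
               flat = e$flat, fall = e$ramp_down, delay = delay))
        trap_tab <- r$tab
        col <- paste0("g", e$channel)
        if (row[[col]] != 0L) stop("two gradients on channel ", e$channel,
                                   " in block ", b)
        row[[col]] <- r$id
      } else if (e$kind == "adc") {
        key <- paste("adc", e$n_samples, fmt_num(e$dwell), fmt_num(delay))
        r <- intern(adc_tab, key, function(id)
          list(id = id, num = e$n_samples, dwell = e$dwell, delay = delay))
        adc_tab <- r$tab
        row$adc <- r$id
      } else if (e$kind == "grad_quad") {
        key <- paste("q", fmt_num(e$coefficient), fmt_num(e$duration))
        r <- intern(quad_tab, key, function(id)
          list(id = id, coefficient = e$coefficient,
               duration = e$duration))
        quad_tab <- r$tab
        row$quad <- r$id
      } # delays contribute only to the block duration
    }
    block_rows[[length(block_rows) + 1L]] <- row
    t_cursor <- b_start + dur
  }

  out <- c("# Pulseq sequence (subset)", "",
           "[VERSION]", "major 1", "minor 4", "revision 0", "",
           "[DEFINITIONS]",
           paste("GradientRasterTime", fmt_num(gr)),
           paste("RadiofrequencyRasterTime", fmt_num(rr)),
           paste("Mode", timeline$mode),
           paste("TE", fmt_num(timeline$te)),
           paste("FOV", fmt_num(timeline$config$fov %||% NA)))
  if (!is.null(timeline$meta$beta))
    out <- c(out, paste("EncodingBeta", fmt_num(timeline$meta$beta)))
  if (!is.null(timeline$meta$exc_area))
    out <- c(out, paste("ExcitationArea", fmt_num(timeline$meta$exc_area)))
  if (length(quad_tab) > 0) {
    q1 <- quad_tab[[1]]
    out <- c(out, paste("QuadCoefficient", fmt_num(q1$coefficient)),
             paste("QuadDuration", fmt_num(q1$duration)))
  }
  out <- c(out, "", "[BLOCKS]", "# id dur rf gx gy gz adc quad")
  for (r in block_rows)
    out <- c(out, paste(r$id, r$dur, r$rf, r$gx, r$gy, r$gz, r$adc,
                        r$quad))
  if (length(rf_tab) > 0) {
    out <- c(out, "", "[RF]", "# id amp mag_id phase_id delay freq raster")
    for (r in rf_tab[order(vapply(rf_tab, `[[`, 0L, "id"))])
      out <- c(out, paste(r$id, fmt_num(r$amp), r$mag, r$phase,
                          fmt_num(r$delay), fmt_num(r$freq),
                          fmt_num(r$raster)))
  }
  if (length(trap_tab) > 0) {
    out <- c(out, "", "[TRAP]", "# id amp rise flat fall delay")
    for (r in trap_tab[order(vapply(trap_tab, `[[`, 0L, "id"))])
      out <- c(out, paste(r$id, fmt_num(r$amp), fmt_num(r$rise),
                          fmt_num(r$flat), fmt_num(r$fall),
                          fmt_num(r$delay)))
  }
  if (length(adc_tab) > 0) {
    out <- c(out, "", "[ADC]", "# id num dwell delay")
    for (r in adc_tab[order(vapply(adc_tab, `[[`, 0L, "id"))])
      out <- c(out, paste(r$id, r$num, fmt_num(r$dwell), fmt_num(r$delay)))
  }
  if (length(quad_tab) > 0) {
    out <- c(out, "", "[QUAD]", "# id coefficient duration")
    for (r in quad_tab[order(vapply(quad_tab, `[[`, 0L, "id"))])
      out <- c(out, paste(r$id, fmt_num(r$coefficient),
                          fmt_num(r$duration)))
  }
  if (length(shape_tab) > 0) {
    out <- c(out, "", "[SHAPES]")
    for (r in shape_tab[order(vapply(shape_tab, `[[`, 0L, "id"))]) {
      out <- c(out, paste("shape_id", r$id),
               paste("num_samples", length(r$samples)),
               fmt_num(r$samples), "")
    }
  }
  writeLines(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import a Pulseq-subset .seq file
#'
#' Reads files written by [export_pulseq()] (or a conforming subset).
#' Unknown sections raise an unsupported-feature error rather than being
#' skipped; malformed content raises a parse error with the line number.
#'
#' @param path Path to a .seq file.
#' @return An [event_timeline()].
#' @export
import_pulseq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  known <- c("VERSION", "DEFINITIONS", "BLOCKS", "RF", "TRAP", "ADC",
             "QUAD", "SHAPES")
  perr <- function(i, msg) stop("parse error at line ", i, ": ", msg)
  sec <- NULL
  defs <- list(); blocks <- list(); rf <- list(); trap <- list()
  adc <- list(); quad <- list(); shapes <- list()
  cur_shape <- NULL
  finish_shape <- function(i) {
    if (!is.null(cur_shape)) {
      if (length(cur_shape$samples) != cur_shape$num)
        perr(i, sprintf("shape %d truncated: expected %d samples, got %d",
                        cur_shape$id, cur_shape$num,
                        length(cur_shape$samples)))
      shapes[[cur_shape$id]] <<- cur_shape$samples
      cur_shape <<- NULL
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, "[")) {
      finish_shape(i)
      name <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!(name %in% known))
        stop("unsupported Pulseq section [", name, "] at line ", i,
             "; this reader handles only the exported subset")
      sec <- name
      next
    }
    if (is.null(sec)) perr(i, "content before any section header")
    tok <- strsplit(ln, "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(tok))
    if (sec == "VERSION") {
      # "major 1" etc; tolerated and checked loosely
      if (length(tok) != 2) perr(i, "malformed version entry")
    } else if (sec == "DEFINITIONS") {
      if (length(tok) < 2) perr(i, "malformed definition")
      defs[[tok[1]]] <- tok[2]
    } else if (sec == "BLOCKS") {
      if (length(tok) != 8 || any(is.na(num)))
        perr(i, "block row must have 8 numeric fields")
      blocks[[length(blocks) + 1L]] <- as.list(stats::setNames(
        num, c("id", "dur", "rf", "gx", "gy", "gz", "adc", "quad")))
    } else if (sec == "RF") {
      if (length(tok) != 7 || any(is.na(num)))
        perr(i, "RF row must have 7 numeric fields")
      rf[[num[1]]] <- as.list(stats::setNames(
        num, c("id", "amp", "mag", "phase", "delay", "freq", "raster")))
    } else if (sec == "TRAP") {
      if (length(tok) != 6 || any(is.na(num)))
        perr(i, "TRAP row must have 6 numeric fields")
      trap[[num[1]]] <- as.list(stats::setNames(
        num, c("id", "amp", "rise", "flat", "fall", "delay")))
    } else if (sec == "ADC") {
      if (length(tok) != 4 || any(is.na(num)))
        perr(i, "ADC row must have 4 numeric fields")
      adc[[num[1]]] <- as.list(stats::setNames(
        num, c("id", "num", "dwell", "delay")))
    } else if (sec == "QUAD") {
      if (length(tok) != 3 || any(is.na(num)))
        perr(i, "QUAD row must have 3 numeric fields")
      quad[[num[1]]] <- as.list(stats::setNames(
        num, c("id", "coefficient", "duration")))
    } else if (sec == "SHAPES") {
      if (tok[1] == "shape_id") {
        finish_shape(i)
        cur_shape <- list(id = as.integer(tok[2]), num = NA_integer_,
                          samples = numeric(0))
      } else if (tok[1] == "num_samples") {
        if (is.null(cur_shape)) perr(i, "num_samples before shape_id")
        cur_shape$num <- as.integer(tok[2])
      } else {
        if (is.null(cur_shape)) perr(i, "shape sample before shape_id")
        if (any(is.na(num))) perr(i, "non-numeric shape sample")
        cur_shape$samples <- c(cur_shape$samples, num)
      }
    }
  }
  finish_shape(length(lines) + 1L)
  if (length(blocks) == 0) perr(length(lines), "no [BLOCKS] section content")
  gr <- as.numeric(defs$GradientRasterTime %||% "1e-5")
  ev <- list()
  t0 <- 0
  for (brow in blocks) {
    dur <- brow$dur * gr
    placed <- FALSE
    if (brow$rf > 0) {
      r <- rf[[brow$rf]]
      if (is.null(r)) perr(NA, paste("missing RF id", brow$rf))
      mag <- shapes[[r$mag]]; phs <- shapes[[r$phase]]
      if (is.null(mag) || is.null(phs))
        stop("parse error: RF ", r$id, " references a missing shape")
      p <- rf_pulse(r$amp * mag * exp(1i * phs), r$raster,
                    carrier_offset = r$freq)
      ev[[length(ev) + 1L]] <- new_event("rf", t0 + r$delay, p$duration,
        brow$id, list(pulse = p, flip = NA_real_, selective = NA,
                      label = "imported"))
      placed <- TRUE
    }
    for (ch in c("x", "y", "z")) {
      gid <- brow[[paste0("g", ch)]]
      if (gid > 0) {
        g <- trap[[gid]]
        if (is.null(g)) stop("parse error: missing TRAP id ", gid)
        ev[[length(ev) + 1L]] <- new_event("grad_trap", t0 + g$delay,
          g$rise + g$flat + g$fall, brow$id,
          list(channel = ch, amplitude = g$amp, ramp_up = g$rise,
               flat = g$flat, ramp_down = g$fall))
        placed <- TRUE
      }
    }
    if (brow$adc > 0) {
      a <- adc[[brow$adc]]
      if (is.null(a)) stop("parse error: missing ADC id ", brow$adc)
      ev[[length(ev) + 1L]] <- new_event("adc", t0 + a$delay,
        a$num * a$dwell, brow$id,
        list(n_samples = a$num, dwell = a$dwell))
      placed <- TRUE
    }
    if (brow$quad > 0) {
      q <- quad[[brow$quad]]
      if (is.null(q)) stop("parse error: missing QUAD id ", brow$quad)
      ev[[length(ev) + 1L]] <- new_event("grad_quad", t0, q$duration,
        brow$id, list(coefficient = q$coefficient))
      placed <- TRUE
    }
    if (!placed)
      ev[[length(ev) + 1L]] <- new_event("delay", t0, dur, brow$id)
    t0 <- t0 + dur
  }
  meta <- list()
  if (!is.null(defs$EncodingBeta))
    meta$beta <- as.numeric(defs$EncodingBeta)
  if (!is.null(defs$ExcitationArea))
    meta$exc_area <- as.numeric(defs$ExcitationArea)
  cfg <- list(grad_raster = gr,
              rf_raster = as.numeric(defs$RadiofrequencyRasterTime %||%
                                       "1e-6"),
              fov = as.numeric(defs$FOV %||% NA))
  event_timeline(ev, te = as.numeric(defs$TE %||% NA),
                 mode = defs$Mode %||% "imported", config = cfg,
                 meta = meta)
}
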