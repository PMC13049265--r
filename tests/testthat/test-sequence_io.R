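test_that("all three sequence modes hit the echo time exactly", {
  cfg <- spen_config()
  for (tl in list(build_chirp_spen_se_epi(cfg),
                  build_quadgrad_spen_se_epi(cfg),
                  build_fourier_se_epi(cfg))) {
    expect_equal(tl$te, 60e-3)
    expect_lt(abs((tl$meta$echo_center - tl$meta$exc_center) - tl$te),
              cfg$grad_raster + 1e-12)
  }
})

test_that("SPEN builds satisfy the gradient-area condition constructively", {
  for (tl in list(build_chirp_spen_se_epi(),
                  build_quadgrad_spen_se_epi())) {
    cond <- timeline_spen_condition(tl, tolerance = 1e-6)
    expect_true(cond$ok)
    # blip areas in the event list reproduce the trajectory coverage
    blips <- Filter(function(e) e$kind == "grad_trap" &&
                      e$channel == "y" && e$flat == 0, tl$events)
    tot <- sum(vapply(blips, function(e)
      e$amplitude * (e$flat + (e$ramp_up + e$ramp_down) / 2), 0))
    expect_equal(abs(tot), tl$meta$traj$acq_gradient_area,
                 tolerance = 1e-9)
  }
  expect_error(timeline_spen_condition(build_fourier_se_epi()), "SPEN")
})

test_that("chirp timeline is longer than the quadratic-gradient timeline", {
  cfg <- spen_config()
  d_chirp <- total_duration(build_chirp_spen_se_epi(cfg))
  d_quad <- total_duration(build_quadgrad_spen_se_epi(cfg))
  d_fourier <- total_duration(build_fourier_se_epi(cfg))
  expect_gt(d_chirp, d_quad)
  expect_gt(d_chirp, d_fourier)
  # quadgrad and fourier differ only by the trailing encoding blip block
  expect_equal(d_quad, d_fourier, tolerance = 2e-3)
  # duration bookkeeping basics
  expect_equal(total_duration(list()), 0)
  tl <- build_fourier_se_epi(cfg)
  tl$events[[length(tl$events) + 1L]] <-
    spenr:::new_event("delay", total_duration(tl), 0,
                      max(vapply(tl$events, `[[`, 0L, "block")) + 1L)
  expect_equal(total_duration(tl), d_fourier)
})

test_that("readout trains are identical across modes except encoding events", {
  ro <- function(tl) {
    # readout gradients (short flat tops) and ADCs; excludes the readout
    # prephaser, whose timing differs with the encoding events
    evs <- Filter(function(e) e$kind %in% c("adc") ||
                    (e$kind == "grad_trap" && e$channel == "x" &&
                       e$flat > 0 && e$flat < 5e-4), tl$events)
    t(vapply(evs, function(e) c(e$start, e$duration), numeric(2)))
  }
  r1 <- ro(build_quadgrad_spen_se_epi())
  r2 <- ro(build_fourier_se_epi())
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("fourier phase-encode blips cover the full k-space", {
  cfg <- spen_config()
  tl <- build_fourier_se_epi(cfg)
  blips <- Filter(function(e) e$kind == "grad_trap" &&
                    e$channel == "y" && e$flat == 0, tl$events)
  tot <- sum(vapply(blips, function(e)
    e$amplitude * (e$ramp_up + e$ramp_down) / 2, 0))
  expect_equal(2 * pi * tot, 2 * pi * cfg$matrix_size / cfg$fov,
               tolerance = 1e-9)
})

test_that("infeasible timing and limit violations are rejected", {
  expect_error(build_chirp_spen_se_epi(spen_config(te = 5e-3)),
               "TE infeasible")
  expect_error(build_quadgrad_spen_se_epi(
    spen_config(te = 12e-3, placement = "pre", quad_duration = 20e-3)),
    "quadratic event")
  expect_error(build_quadgrad_spen_se_epi(
    spen_config(quad_coefficient = 0.9)), "limit")
  expect_error(build_chirp_spen_se_epi(spen_config(esp = 3e-4)),
               "echo spacing")
})

test_that("quadratic-gradient beta modes select the encoding strength", {
  tlm <- build_quadgrad_spen_se_epi(beta_mode = "matched")
  expect_equal(tlm$meta$beta, beta_from_chirp(250e3, 50e3, 4e-3),
               tolerance = 1e-9)
  # the native 313 mT/m^2 x 5 ms event encodes ~27x more strongly than
  # the chirp, so its blips need more time under the amplitude limit
  cfg_n <- spen_config(te = 70e-3, esp = 7e-4, blip_duration = 2e-4)
  tln <- build_quadgrad_spen_se_epi(cfg_n, beta_mode = "native")
  expect_equal(tln$meta$beta, beta_from_quadratic_gradient(0.313, 5e-3),
               tolerance = 1e-9)
  expect_true(timeline_spen_condition(tln, 1e-6)$ok)
  # pre placement flags the inverted reconstruction kernel
  expect_true(build_quadgrad_spen_se_epi(
    spen_config(placement = "pre"))$meta$invert_kernel)
  expect_false(tlm$meta$invert_kernel)
})

test_that("pulseq export is deterministic and round-trips the timeline", {
  tl <- build_quadgrad_spen_se_epi()
  f1 <- tempfile(fileext = ".seq"); f2 <- tempfile(fileext = ".seq")
  export_pulseq(tl, f1)
  export_pulseq(tl, f2)
  expect_identical(readLines(f1), readLines(f2))

  # nominal hardware setting appears verbatim in the file
  txt <- readLines(f1)
  expect_true(any(grepl("^QuadCoefficient 0.313$", txt)))
  expect_true(any(grepl("^QuadDuration 0.005$", txt)))

  im <- import_pulseq(f1)
  expect_equal(im$te, tl$te)
  expect_identical(im$mode, tl$mode)
  expect_equal(total_duration(im), total_duration(tl),
               tolerance = 1e-5) # within raster quantization
  # per-kind event counts survive the round trip
  count <- function(t, k) sum(vapply(t$events, function(e)
    e$kind == k, NA))
  for (k in c("rf", "adc", "grad_quad"))
    expect_equal(count(im, k), count(tl, k))
  # gradient areas survive the round trip
  area_sum <- function(t) sum(vapply(Filter(function(e)
    e$kind == "grad_trap", t$events), function(e)
      e$amplitude * (e$flat + (e$ramp_up + e$ramp_down) / 2), 0))
  expect_equal(area_sum(im), area_sum(tl), tolerance = 1e-6)
})

test_that("exported chirp RF shape has the designed sample count", {
  tl <- build_chirp_spen_se_epi()
  f <- tempfile(fileext = ".seq")
  export_pulseq(tl, f)
  im <- import_pulseq(f)
  rfs <- Filter(function(e) e$kind == "rf", im$events)
  ns <- vapply(rfs, function(e) length(e$pulse$samples), 0L)
  expect_true(4000 %in% ns) # 4 ms chirp at 1 us raster
  # waveform samples survive within formatting precision
  orig <- Filter(function(e) e$kind == "rf", tl$events)
  chirp_o <- orig[[which(vapply(orig, function(e)
    length(e$pulse$samples), 0L) == 4000)]]$pulse
  chirp_i <- rfs[[which(ns == 4000)]]$pulse
  expect_lt(max(Mod(chirp_i$samples - chirp_o$samples)) /
              max(Mod(chirp_o$samples)), 1e-6)
})

test_that("the importer rejects malformed and foreign files", {
  tl <- build_fourier_se_epi()
  f <- tempfile(fileext = ".seq")
  export_pulseq(tl, f)
  lines <- readLines(f)

  # truncation inside a shape: parse error naming a line
  cut <- tempfile(fileext = ".seq")
  writeLines(lines[1:(length(lines) - 5)], cut)
  expect_error(import_pulseq(cut), "line")

  # unsupported section: explicit unsupported-feature error
  foreign <- tempfile(fileext = ".seq")
  writeLines(c(lines, "[EXTENSIONS]", "1 2 3"), foreign)
  expect_error(import_pulseq(foreign), "unsupported")

  # malformed numeric row
  bad <- tempfile(fileext = ".seq")
  i <- grep("^\\[BLOCKS\\]", lines)
  writeLines(append(lines, "1 2 three", after = i + 1), bad)
  expect_error(import_pulseq(bad), "parse error")
})

test_that("events respect raster alignment on export", {
  tl <- build_fourier_se_epi()
  # nudge one event off the raster: the writer must refuse
  idx <- which(vapply(tl$events, function(e) e$kind == "grad_trap", NA))[1]
  tl$events[[idx]]$duration <- tl$events[[idx]]$duration + 3e-6
  expect_error(export_pulseq(tl, tempfile()), "raster|contiguous")
})
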