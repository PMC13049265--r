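# Reference protocol designs used across the suite: a 50 kHz / 4 ms
# WURST-40 chirp (TBW 200) paired with a 250 kHz/m excitation gradient
# (FOV 0.2 m), and a 3 ms / TBW 4 Hamming sinc.

ref_chirp_design <- function(flip = pi / 2) {
  chirp_design(bandwidth = 50e3, duration = 4e-3, wurst_order = 40,
               flip = flip)
}

ref_sinc_design <- function() sinc_design(3e-3, 4)

ref_gradient <- 250e3 # Hz/m
ref_fov <- 0.2 # m
ref_beta <- function() beta_from_chirp(ref_gradient, 50e3, 4e-3)

# Plain-R Rodrigues-rotation Bloch step oracle, independent of the
# compiled hard-pulse loop (same physical convention).
bloch_oracle <- function(b1, raster, df, m0 = c(0, 0, 1)) {
  m <- m0
  for (s in seq_along(b1)) {
    w <- 2 * pi * c(Re(b1[s]), Im(b1[s]), df)
    wn <- sqrt(sum(w^2))
    if (wn == 0) next
    axis <- w / wn
    th <- -wn * raster
    m <- m * cos(th) + pracma_cross(axis, m) * sin(th) +
      axis * sum(axis * m) * (1 - cos(th))
  }
  m
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

centered_1d <- function(n, fov) (seq_len(n) - 1 - n / 2) * (fov / n)

# Gaussian blob phantom (a physically realizable point-like source)
gauss_blob_1d <- function(n, fov, center, sd) {
  y <- (seq_len(n) - 1 - n / 2) * (fov / n)
  digital_phantom(exp(-(y - center)^2 / (2 * sd^2)), fov)
}
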