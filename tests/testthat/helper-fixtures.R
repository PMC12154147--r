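# Shared fixtures and independent oracles used across test files.

# A corner background ROI for images where nothing is rendered near origin.
corner_roi <- function(shape, size = 15L) {
  roi <- matrix(FALSE, shape[1], shape[2])
  roi[seq_len(size), seq_len(size)] <- TRUE
  roi
}

# Construct a pulse_spectrum object directly (bypassing the FFT) so dose
# bookkeeping can be tested against hand-built spectra.
make_spectrum <- function(frequency, amplitude, band_low = 3e6, band_high = 9e6,
                          sampling_rate = 50e6) {
  structure(list(frequency = frequency, amplitude = amplitude,
                 band_mask = frequency >= band_low & frequency <= band_high,
                 df = frequency[2] - frequency[1],
                 n_samples = 2L * (length(frequency) - 1L),
                 sampling_rate = sampling_rate),
            class = "pulse_spectrum")
}

# Independent brute-force dose oracle: a single function looping over the
# frequency grid, classifying every bin from first principles.
brute_force_doses <- function(spectrum, settings) {
  f <- spectrum$frequency
  a <- spectrum$amplitude
  hw <- settings$peak_window_width / 2
  tonal_h <- settings$harmonic_orders * settings$center_frequency
  tonal_u <- settings$ultraharmonic_half_orders / 2 * settings$center_frequency
  tonal_h <- tonal_h[tonal_h >= settings$band_low & tonal_h <= settings$band_high]
  tonal_u <- tonal_u[tonal_u >= settings$band_low & tonal_u <= settings$band_high]
  tonal_u <- setdiff(tonal_u, tonal_h)
  h <- u <- r <- b <- numeric(0)
  for (i in seq_along(f)) {
    if (f[i] < settings$band_low || f[i] > settings$band_high) next
    b <- c(b, a[i])
    in_h <- any(abs(f[i] - tonal_h) <= hw)
    in_u <- !in_h && any(abs(f[i] - tonal_u) <= hw)
    if (in_h) h <- c(h, a[i]) else if (in_u) u <- c(u, a[i]) else r <- c(r, a[i])
  }
  rms0 <- function(x) if (length(x)) sqrt(mean(x^2)) else 0
  list(scdh = rms0(h), scdu = rms0(u), icd = rms0(r), cd_total = rms0(b),
       e_h = sum(h^2), e_u = sum(u^2), e_r = sum(r^2), e_b = sum(b^2))
}

# Minimal pulse_dose stub for accumulation arithmetic tests.
make_dose <- function(scdh, scdu, icd, cd_total = scdh + scdu + icd) {
  structure(list(scdh = scdh, scdu = scdu, icd = icd, cd_total = cd_total,
                 energy = c(harmonic = scdh^2, ultraharmonic = scdu^2,
                            residual = icd^2, band = cd_total^2)),
            class = "pulse_dose")
}

# Brute-force enrichment-score oracle: single explicit loop down the list.
brute_force_es <- function(ranked, gene_set, w = 1) {
  hit <- ranked$gene %in% gene_set
  N <- nrow(ranked)
  k <- sum(hit)
  wts <- abs(ranked$score)^w
  tot <- sum(wts[hit])
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (tot > 0) wts[i] / tot else 1 / k
    } else {
      -1 / (N - k)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Noiseless five-vessel fixture used by the end-to-end microscopy tests:
# calibers 6/8/12/16/4 um, vessels 1-3 leaky, TJ strands on both edges of
# vessel 1 (gaps 1.0 and 3.0 um on one edge).
noiseless_fixture <- function() {
  vessels <- list(
    list(p0 = c(12, 14), p1 = c(72, 14), diameter = 6, is_leaky = TRUE),
    list(p0 = c(12, 42), p1 = c(72, 42), diameter = 8, is_leaky = TRUE),
    list(p0 = c(12, 70), p1 = c(72, 70), diameter = 12, is_leaky = TRUE),
    list(p0 = c(12, 98), p1 = c(72, 98), diameter = 16, is_leaky = FALSE),
    list(p0 = c(12, 126), p1 = c(72, 126), diameter = 4, is_leaky = FALSE))
  strands <- list(
    list(vessel = 1, side = 1, gaps = data.frame(position = c(20, 40), length = c(1, 3))),
    list(vessel = 1, side = -1, gaps = data.frame(position = numeric(0), length = numeric(0))))
  scene <- vessel_scene(vessels, strands, image_shape = c(700, 420),
                        noise_sd = c(glut1 = 0, tracer = 0, egfp = 0))
  gen_vessel_image(scene)
}
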