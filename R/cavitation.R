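#' Spectral settings for cavitation dose decomposition
#'
#' Defines the tonal bookkeeping used to split a PCD pulse spectrum into
#' stable-harmonic, stable-ultraharmonic, and inertial (broadband residual)
#' contributions: harmonics at n·f_c, ultraharmonics at (n/2)·f_c for odd n,
#' a peak/dose window of total width `peak_window_width` centered on each
#' tonal frequency, and an analysis bandpass `[band_low, band_high]` applied
#' to the energy spectral density.
#'
#' With the defaults (f_c = 1.5 MHz, band 3-9 MHz) the in-band tonal set is
#' harmonics \{3, 4.5, 6, 7.5, 9\} MHz and ultraharmonics
#' \{3.75, 5.25, 6.75\} MHz; the 1.5 MHz fundamental and the 2.25 MHz
#' ultraharmonic fall below the bandpass and are excluded (and reported as
#' such by [locate_tonal_peaks()]).
#'
#' @param center_frequency f_c in Hz.
#' @param harmonic_orders Integer harmonic orders n.
#' @param ultraharmonic_half_orders Odd integers n; tones at (n/2)·f_c.
#' @param peak_window_width Total window width in Hz centered on each tonal
#'   frequency (i.e. ± half this width).
#' @param band_low,band_high Bandpass edges in Hz.
#' @param use_hann Apply a Hann window to the pulse before the DFT. Off by
#'   default (rectangular window); exposed to document the sensitivity of the
#'   doses to windowing.
#' @return An object of class `spectral_settings`.
#' @export
spectral_settings <- function(center_frequency = 1.5e6,
                              harmonic_orders = 1:6,
                              ultraharmonic_half_orders = c(3, 5, 7, 9),
                              peak_window_width = 20e3,
                              band_low = 3e6,
                              band_high = 9e6,
                              use_hann = FALSE) {
  check_scalar_pos(center_frequency, "center_frequency")
  check_scalar_pos(peak_window_width, "peak_window_width")
  check_scalar_pos(band_low, "band_low")
  check_scalar_pos(band_high, "band_high")
  if (band_low >= band_high) stop_field("band_low", "band_low must be < band_high")
  if (any(harmonic_orders < 1)) stop_field("harmonic_orders", "orders must be >= 1")
  if (any(ultraharmonic_half_orders %% 2 != 1))
    stop_field("ultraharmonic_half_orders", "must be odd integers")
  structure(list(center_frequency = center_frequency,
                 harmonic_orders = harmonic_orders,
                 ultraharmonic_half_orders = ultraharmonic_half_orders,
                 peak_window_width = peak_window_width,
                 band_low = band_low, band_high = band_high,
                 use_hann = isTRUE(use_hann)),
            class = "spectral_settings")
}

#' Tonal frequency table for a settings object
#'
#' Harmonic and ultraharmonic frequencies, deduplicated (harmonics take
#' precedence when a frequency is both), with an in-band flag.
#'
#' @param settings A [spectral_settings()].
#' @return Data frame with columns `frequency`, `type`, `order`, `in_band`.
#' @export
tonal_frequencies <- function(settings) {
  h <- data.frame(frequency = settings$harmonic_orders * settings$center_frequency,
                  type = "harmonic", order = settings$harmonic_orders,
                  stringsAsFactors = FALSE)
  u <- data.frame(frequency = settings$ultraharmonic_half_orders / 2 * settings$center_frequency,
                  type = "ultraharmonic", order = settings$ultraharmonic_half_orders,
                  stringsAsFactors = FALSE)
  tab <- rbind(h, u[!(u$frequency %in% h$frequency), , drop = FALSE])
  tab$in_band <- tab$frequency >= settings$band_low & tab$frequency <= settings$band_high
  tab[order(tab$frequency), , drop = FALSE]
}

#' Compute the one-sided magnitude spectrum of a PCD pulse
#'
#' Discrete Fourier transform of the full pulse; amplitudes are energy
#' spectral density amplitudes `|fft(x)| / fs` on the one-sided grid
#' 0..Nyquist, so that the two-sided sum of squared amplitudes times the
#' grid spacing equals the time-domain pulse energy (Parseval). The band
#' mask marks `[band_low, band_high]`; the bandpass is a frequency-domain
#' mask on the spectrum, not a time-domain filter.
#'
#' @param trace A [pulse_trace()].
#' @param settings A [spectral_settings()].
#' @return An object of class `pulse_spectrum`: list with `frequency`,
#'   `amplitude`, `band_mask`, `df`, `n_samples`, `sampling_rate`.
#' @export
compute_spectrum <- function(trace, settings) {
  stopifnot(inherits(trace, "pulse_trace"), inherits(settings, "spectral_settings"))
  fs <- trace$sampling_rate
  if (fs <= 2 * settings$band_high)
    stop("sampling rate must exceed twice band_high (aliasing)", call. = FALSE)
  x <- trace$samples
  n <- length(x)
  if (settings$use_hann) {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    x <- x * w
  }
  half <- floor(n / 2) + 1L
  amp <- Mod(stats::fft(x))[seq_len(half)] / fs
  freq <- (seq_len(half) - 1) * fs / n
  structure(list(frequency = freq, amplitude = amp,
                 band_mask = freq >= settings$band_low & freq <= settings$band_high,
                 df = fs / n, n_samples = n, sampling_rate = fs),
            class = "pulse_spectrum")
}

# Partition the in-band frequency grid into harmonic / ultraharmonic /
# residual regions. Windows are +/- width/2 around each in-band tonal
# frequency; overlaps are resolved with harmonic precedence so every bin
# belongs to exactly one region and the energy partition is exact.
spectral_regions <- function(spectrum, settings) {
  f <- spectrum$frequency
  hw <- settings$peak_window_width / 2
  tab <- tonal_frequencies(settings)
  tab <- tab[tab$in_band, , drop = FALSE]
  region <- ifelse(spectrum$band_mask, "residual", "out")
  for (i in which(tab$type == "ultraharmonic"))
    region[spectrum$band_mask & abs(f - tab$frequency[i]) <= hw] <- "ultraharmonic"
  for (i in which(tab$type == "harmonic"))
    region[spectrum$band_mask & abs(f - tab$frequency[i]) <= hw] <- "harmonic"
  factor(region, levels = c("harmonic", "ultraharmonic", "residual", "out"))
}

#' Peak spectral amplitude around each tonal frequency
#'
#' For each in-band tonal frequency f, returns the maximum spectral amplitude
#' over `[f - width/2, f + width/2]`. Tonal frequencies outside the bandpass
#' are omitted from the peak map and reported in the `excluded` attribute.
#'
#' @param spectrum A [compute_spectrum()] result.
#' @param settings A [spectral_settings()].
#' @return Data frame with columns `frequency`, `type`, `peak`; excluded
#'   tonal frequencies in `attr(, "excluded")`.
#' @export
locate_tonal_peaks <- function(spectrum, settings) {
  stopifnot(inherits(spectrum, "pulse_spectrum"))
  if (spectrum$df > settings$peak_window_width)
    stop("peak window (", settings$peak_window_width,
         " Hz) is narrower than one frequency bin (", spectrum$df,
         " Hz); use longer pulses or zero-padding", call. = FALSE)
  tab <- tonal_frequencies(settings)
  inb <- tab[tab$in_band, , drop = FALSE]
  if (nrow(inb) == 0L) stop("no tonal frequency inside the bandpass", call. = FALSE)
  hw <- settings$peak_window_width / 2
  inb$peak <- vapply(inb$frequency, function(f0) {
    sel <- abs(spectrum$frequency - f0) <= hw
    if (!any(sel)) NA_real_ else max(spectrum$amplitude[sel])
  }, numeric(1))
  out <- inb[, c("frequency", "type", "peak")]
  rownames(out) <- NULL
  attr(out, "excluded") <- tab[!tab$in_band, c("frequency", "type", "order")]
  out
}

#' Decompose a pulse spectrum into cavitation doses
#'
#' The per-pulse cavitation dose of a spectral region is the root mean
#' square of the spectral amplitudes over that region's bins: SCDh over the
#' union of harmonic windows, SCDu over the union of ultraharmonic windows,
#' and the inertial cavitation dose (ICD) over all in-band bins excluded
#' from every tonal window (any in-band energy not attributed to the stable
#' doses). `cd_total` is the RMS over the full band. The summed squared
#' amplitudes of the three regions partition the in-band total exactly.
#'
#' @param spectrum A [compute_spectrum()] result.
#' @param settings A [spectral_settings()].
#' @return An object of class `pulse_dose`: `scdh`, `scdu`, `icd`,
#'   `cd_total` (RMS amplitudes), `energy` (named squared-amplitude sums
#'   `harmonic`, `ultraharmonic`, `residual`, `band`), `n_bins`, and the
#'   tonal `peaks` table.
#' @export
compute_pulse_dose <- function(spectrum, settings) {
  region <- spectral_regions(spectrum, settings)
  a <- spectrum$amplitude
  idx_h <- region == "harmonic"
  idx_u <- region == "ultraharmonic"
  idx_r <- region == "residual"
  if (!any(idx_r))
    stop("tonal windows cover the entire band: inertial (residual) region is empty",
         call. = FALSE)
  inband <- spectrum$band_mask
  dose <- list(
    scdh = rms(a[idx_h]), scdu = rms(a[idx_u]), icd = rms(a[idx_r]),
    cd_total = rms(a[inband]),
    energy = c(harmonic = sum(a[idx_h]^2), ultraharmonic = sum(a[idx_u]^2),
               residual = sum(a[idx_r]^2), band = sum(a[inband]^2)),
    n_bins = c(harmonic = sum(idx_h), ultraharmonic = sum(idx_u),
               residual = sum(idx_r), band = sum(inband)),
    peaks = locate_tonal_peaks(spectrum, settings)
  )
  structure(dose, class = "pulse_dose")
}

#' Accumulate per-pulse doses over a sonication and normalize to baseline
#'
#' Cumulative dose per component is the sum of the per-pulse RMS amplitudes
#' over all treatment pulses (the amplitude integral over the sonication);
#' the squared-amplitude (energy) sums are accumulated alongside. Each
#' component is normalized to the baseline per-pulse mean dose, i.e.
#' `cumulative / (baseline mean x n_pulses)`, the mean per-pulse dose in
#' units of baseline; with no microbubbles this ratio is ~1. A component
#' whose baseline mean is zero gets `NA` with an `undefined` flag rather
#' than an infinite ratio.
#'
#' @param doses List of [compute_pulse_dose()] results for treatment pulses.
#' @param baseline List of `pulse_dose` for baseline (pre-injection) pulses.
#' @return An object of class `sonication_dose_summary` with `cumulative`,
#'   `cumulative_energy`, `baseline_mean`, `normalized`, `undefined`,
#'   `n_pulses`, `n_baseline`.
#' @export
accumulate_doses <- function(doses, baseline) {
  if (length(doses) < 1L) stop("need >= 1 treatment pulse", call. = FALSE)
  if (length(baseline) < 1L) stop("need >= 1 baseline pulse", call. = FALSE)
  comp <- c("scdh", "scdu", "icd", "cd_total")
  get <- function(lst, k) vapply(lst, `[[`, numeric(1), k)
  cumulative <- vapply(comp, function(k) sum(get(doses, k)), numeric(1))
  base_mean <- vapply(comp, function(k) mean(get(baseline, k)), numeric(1))
  energy <- Reduce(`+`, lapply(doses, `[[`, "energy"))
  n <- length(doses)
  undefined <- base_mean == 0
  normalized <- ifelse(undefined, NA_real_, cumulative / (base_mean * n))
  structure(list(cumulative = cumulative, cumulative_energy = energy,
                 baseline_mean = base_mean, normalized = normalized,
                 undefined = undefined, n_pulses = n,
                 n_baseline = length(baseline)),
            class = "sonication_dose_summary")
}

#' Full cavitation pipeline over a trace list
#'
#' Splits traces into baseline and treatment by their `is_baseline` flag,
#' computes the spectrum and dose of every pulse, and accumulates.
#'
#' @param traces List of [pulse_trace()] (e.g. from [gen_pcd_sonication()]).
#' @param settings A [spectral_settings()].
#' @return List with `summary` (a [accumulate_doses()] result) and
#'   `per_pulse` (data frame: pulse_index, is_baseline, scdh, scdu, icd,
#'   cd_total).
#' @export
process_sonication <- function(traces, settings = spectral_settings()) {
  is_base <- vapply(traces, `[[`, logical(1), "is_baseline")
  doses <- lapply(traces, function(tr) compute_pulse_dose(compute_spectrum(tr, settings), settings))
  per_pulse <- data.frame(
    pulse_index = vapply(traces, `[[`, integer(1), "pulse_index"),
    is_baseline = is_base,
    scdh = vapply(doses, `[[`, numeric(1), "scdh"),
    scdu = vapply(doses, `[[`, numeric(1), "scdu"),
    icd = vapply(doses, `[[`, numeric(1), "icd"),
    cd_total = vapply(doses, `[[`, numeric(1), "cd_total"))
  list(summary = accumulate_doses(doses[!is_base], doses[is_base]),
       per_pulse = per_pulse)
}

#' Write per-pulse doses and the sonication summary to disk
#'
#' @param result A [process_sonication()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (per-pulse CSV and summary JSON).
#' @export
write_cavitation_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "per_pulse_doses.csv")
  utils::write.csv(result$per_pulse, csv, row.names = FALSE)
  s <- result$summary
  js <- file.path(dir, "dose_summary.json")
  jsonlite::write_json(list(cumulative = as.list(s$cumulative),
                            cumulative_energy = as.list(s$cumulative_energy),
                            baseline_mean = as.list(s$baseline_mean),
                            normalized = as.list(s$normalized),
                            n_pulses = s$n_pulses, n_baseline = s$n_baseline),
                       js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv, js))
}
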