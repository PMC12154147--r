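#' Sonication specification for the synthetic passive cavitation detector
#'
#' Describes one simulated FUS sonication as recorded by a passive cavitation
#' detector (PCD): a train of received pulses, each a sum of tonal components
#' at harmonics (n·f_c) and ultraharmonics ((n/2)·f_c) of the driving
#' frequency plus Gaussian broadband noise. The defaults mirror a typical
#' murine BBB-opening protocol: 1.5 MHz center frequency, 10 Hz pulse
#' repetition frequency, 120 s sonication, 10 ms pulses sampled at 50 MHz.
#'
#' Emission amplitudes are free parameters of the simulation (microbubble
#' emission spectra are not calibrated here); the defaults put the tonal
#' components well above the broadband floor, as observed with stable
#' cavitation.
#'
#' @param center_frequency Driving frequency f_c in Hz.
#' @param prf Pulse repetition frequency in Hz.
#' @param duration Sonication duration in s; `prf * duration` must be a whole
#'   number of pulses.
#' @param pulse_length Length of each recorded pulse in s.
#' @param sampling_rate PCD digitizer rate in Hz.
#' @param harmonic_amplitudes Named numeric vector, names = integer harmonic
#'   orders n, values = tone amplitudes (a.u.).
#' @param ultraharmonic_amplitudes Named numeric vector, names = odd integers
#'   n interpreted as tones at (n/2)·f_c.
#' @param broadband_level Standard deviation of the additive white noise
#'   (a.u. per sample), emulating broadband inertial-cavitation emissions.
#' @param baseline_pulses Number of noise-only pulses recorded before
#'   microbubble injection, used for dose normalization.
#' @param seed Integer seed making the generated sonication reproducible.
#' @return An object of class `sonication_spec`.
#' @export
sonication_spec <- function(center_frequency = 1.5e6,
                            prf = 10,
                            duration = 120,
                            pulse_length = 10e-3,
                            sampling_rate = 50e6,
                            harmonic_amplitudes = stats::setNames(rep(1, 6), 1:6),
                            ultraharmonic_amplitudes = stats::setNames(rep(0.5, 4), c(3, 5, 7, 9)),
                            broadband_level = 0.02,
                            baseline_pulses = 10,
                            seed = 1L) {
  check_scalar_pos(center_frequency, "center_frequency")
  check_scalar_pos(prf, "prf")
  check_scalar_pos(duration, "duration")
  check_scalar_pos(pulse_length, "pulse_length")
  check_scalar_pos(sampling_rate, "sampling_rate")
  n_pulses <- prf * duration
  if (abs(n_pulses - round(n_pulses)) > 1e-9)
    stop_field("duration", "prf * duration must be an integer pulse count")
  n_samples <- pulse_length * sampling_rate
  if (round(n_samples) < 2)
    stop_field("pulse_length", "pulse_length * sampling_rate must be >= 2 samples")
  check_nonneg_vec(harmonic_amplitudes, "harmonic_amplitudes")
  check_nonneg_vec(ultraharmonic_amplitudes, "ultraharmonic_amplitudes")
  if (length(harmonic_amplitudes) && is.null(names(harmonic_amplitudes)))
    stop_field("harmonic_amplitudes", "must be named by harmonic order")
  if (length(ultraharmonic_amplitudes) && is.null(names(ultraharmonic_amplitudes)))
    stop_field("ultraharmonic_amplitudes", "must be named by half-order n (tone at n*f_c/2)")
  check_scalar_pos(broadband_level, "broadband_level", strict = FALSE)
  check_scalar_pos(baseline_pulses, "baseline_pulses", strict = FALSE)
  structure(list(
    center_frequency = center_frequency, prf = prf, duration = duration,
    pulse_length = pulse_length, sampling_rate = sampling_rate,
    harmonic_amplitudes = harmonic_amplitudes,
    ultraharmonic_amplitudes = ultraharmonic_amplitudes,
    broadband_level = broadband_level,
    baseline_pulses = as.integer(baseline_pulses),
    n_treatment_pulses = as.integer(round(n_pulses)),
    seed = as.integer(seed)
  ), class = "sonication_spec")
}

#' One received PCD pulse
#'
#' @param samples Numeric vector of received voltage samples (a.u.).
#' @param sampling_rate Sampling rate in Hz.
#' @param pulse_index Integer index of the pulse within its train.
#' @param is_baseline Logical; `TRUE` for pulses recorded before microbubble
#'   injection.
#' @return An object of class `pulse_trace`.
#' @export
pulse_trace <- function(samples, sampling_rate, pulse_index = 1L, is_baseline = FALSE) {
  if (length(samples) < 2L) stop_field("samples", "need >= 2 samples")
  check_scalar_pos(sampling_rate, "sampling_rate")
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate,
                 pulse_index = as.integer(pulse_index),
                 is_baseline = isTRUE(is_baseline)),
            class = "pulse_trace")
}

#' Generate a synthetic PCD sonication with exact ground truth
#'
#' Produces `baseline_pulses` noise-only pulses followed by
#' `prf * duration` treatment pulses. Each treatment pulse is a sum of
#' sinusoids at the requested harmonic and ultraharmonic frequencies (random
#' phase per pulse and tone) plus white Gaussian noise of standard deviation
#' `broadband_level`. Ground truth records, per tonal component, the expected
#' pulse energy `amplitude^2 * pulse_length / 2` (exact when the tone
#' completes an integer number of cycles within the pulse, which holds for
#' the defaults), and the expected broadband noise energy
#' `broadband_level^2 * pulse_length`.
#'
#' @param spec A [sonication_spec()].
#' @return A list with `traces` (list of [pulse_trace()], baseline first),
#'   `truth` (list with a `tones` data frame of frequency/amplitude/energy
#'   and scalars `broadband_energy`, `broadband_esd_two_sided`), and `spec`.
#' @export
gen_pcd_sonication <- function(spec) {
  stopifnot(inherits(spec, "sonication_spec"))
  set.seed(spec$seed)
  fs <- spec$sampling_rate
  n <- as.integer(round(spec$pulse_length * fs))
  t <- (seq_len(n) - 1) / fs

  ha <- spec$harmonic_amplitudes
  ua <- spec$ultraharmonic_amplitudes
  tone_freq <- c(as.numeric(names(ha)) * spec$center_frequency,
                 as.numeric(names(ua)) / 2 * spec$center_frequency)
  tone_amp <- c(unname(ha), unname(ua))
  tone_type <- c(rep("harmonic", length(ha)), rep("ultraharmonic", length(ua)))
  keep <- tone_amp > 0 | TRUE  # keep zero-amplitude tones in the truth table
  n_tone <- length(tone_freq)

  # Basis trick: sin(wt + phi) = sin(wt) cos(phi) + cos(wt) sin(phi).  One
  # matrix product per sonication instead of per-pulse trig evaluation.
  basis <- NULL
  if (n_tone > 0) {
    basis <- matrix(0, nrow = n, ncol = 2L * n_tone)
    for (k in seq_len(n_tone)) {
      w <- 2 * pi * tone_freq[k]
      basis[, 2L * k - 1L] <- sin(w * t)
      basis[, 2L * k] <- cos(w * t)
    }
  }

  make_pulse <- function(idx, baseline) {
    x <- rnorm(n, sd = spec$broadband_level)
    if (!baseline && n_tone > 0) {
      phi <- runif(n_tone, 0, 2 * pi)
      coef <- as.numeric(rbind(tone_amp * cos(phi), tone_amp * sin(phi)))
      x <- x + drop(basis %*% coef)
    }
    pulse_trace(x, fs, pulse_index = idx, is_baseline = baseline)
  }

  n_base <- spec$baseline_pulses
  n_treat <- spec$n_treatment_pulses
  traces <- vector("list", n_base + n_treat)
  for (i in seq_len(n_base)) traces[[i]] <- make_pulse(i, TRUE)
  for (i in seq_len(n_treat)) traces[[n_base + i]] <- make_pulse(n_base + i, FALSE)

  truth <- list(
    tones = data.frame(frequency = tone_freq, amplitude = tone_amp,
                       type = tone_type,
                       energy = tone_amp^2 * spec$pulse_length / 2,
                       stringsAsFactors = FALSE),
    broadband_energy = spec$broadband_level^2 * spec$pulse_length,
    broadband_esd_two_sided = spec$broadband_level^2 / fs
  )
  list(traces = traces, truth = truth, spec = spec)
}

#' Generate a synthetic single-cell QC table with planted violations
#'
#' Builds per-cell quality-control records (detected genes, total molecules,
#' mitochondrial read percentage) where a known subset of cells violates one
#' or more of the standard filter rules (genes > 200, 1000 < UMI < 50000,
#' mito % < 20). The planted violations include the exact boundary values
#' (200 genes, 1000 and 50000 molecules, 20 % mito), which the strict
#' inequalities must reject.
#'
#' @param n Number of cells.
#' @param n_violations Number of cells planted to fail at least one rule.
#' @param seed Integer seed.
#' @return A data frame with columns `cell_id`, `n_genes`, `n_molecules`,
#'   `percent_mito`, and a logical ground-truth column `true_keep`.
#' @export
gen_cell_qc_table <- function(n = 100, n_violations = 37, seed = 1L) {
  if (n_violations > n) stop_field("n_violations", "cannot exceed n")
  if (n_violations < 4) stop_field("n_violations", "need >= 4 to plant all boundary cases")
  set.seed(seed)
  id <- sprintf("cell%03d", seq_len(n))
  n_genes <- round(runif(n, 500, 4000))
  n_mol <- round(runif(n, 2000, 40000))
  mito <- runif(n, 0, 15)
  bad <- sample(n, n_violations)
  # Boundary cases first: each sits exactly on a cut and must be rejected.
  n_genes[bad[1]] <- 200
  n_mol[bad[2]] <- 1000
  n_mol[bad[3]] <- 50000
  mito[bad[4]] <- 20
  if (n_violations > 4) {
    for (i in bad[-(1:4)]) {
      which_rule <- sample(3, 1)
      if (which_rule == 1) n_genes[i] <- round(runif(1, 0, 200))
      if (which_rule == 2) n_mol[i] <- if (runif(1) < 0.5) round(runif(1, 0, 1000)) else round(runif(1, 50000, 90000))
      if (which_rule == 3) mito[i] <- runif(1, 20, 80)
    }
  }
  keep <- n_genes > 200 & n_mol > 1000 & n_mol < 50000 & mito < 20
  data.frame(cell_id = id, n_genes = n_genes, n_molecules = n_mol,
             percent_mito = mito, true_keep = keep, stringsAsFactors = FALSE)
}
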