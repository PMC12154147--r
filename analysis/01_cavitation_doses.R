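#!/usr/bin/env Rscript
# Cavitation dose decomposition for two emission regimes.
#
# Simulates a PCD recording of a full sonication (1200 pulses, 10 Hz x 120 s,
# 1 ms pulses at 50 MHz) in two regimes and decomposes every pulse spectrum
# into stable harmonic (SCDh), stable ultraharmonic (SCDu) and inertial (ICD)
# doses, normalized to the pre-injection baseline:
#   - "stable": harmonic tones only, low broadband floor (the signature of
#     low-pressure, safe BBB opening);
#   - "inertial": harmonics + ultraharmonics + elevated broadband noise (the
#     signature of high-pressure exposure).
# Writes per-pulse doses and the normalized summaries under results/.

library(fusbbbo)

dir.create("results/cavitation", showWarnings = FALSE, recursive = TRUE)
settings <- spectral_settings()

regimes <- list(
  stable = sonication_spec(
    pulse_length = 1e-3,
    ultraharmonic_amplitudes = stats::setNames(rep(0, 4), c(3, 5, 7, 9)),
    seed = 1L),
  inertial = sonication_spec(
    pulse_length = 1e-3,
    broadband_level = 0.08,
    seed = 2L))

summary_rows <- NULL
for (nm in names(regimes)) {
  message("processing regime: ", nm)
  run <- process_sonication(gen_pcd_sonication(regimes[[nm]])$traces, settings)
  write_cavitation_result(run, file.path("results/cavitation", nm))
  s <- run$summary
  summary_rows <- rbind(summary_rows, data.frame(
    regime = nm, component = names(s$normalized),
    cumulative = unname(s$cumulative), normalized = unname(s$normalized)))
}
write.csv(summary_rows, "results/cavitation/normalized_doses.csv", row.names = FALSE)

message("normalized doses (baseline units):")
print(summary_rows)
message("Under harmonic-only emissions only SCDh rises above baseline; ",
        "adding broadband noise drives ICD up, the hallmark of inertial cavitation.")
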