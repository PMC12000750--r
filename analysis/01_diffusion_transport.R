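#!/usr/bin/env Rscript
# Solute transport across the chip's hydrogel chamber.
#
# Simulates a time-lapse diffusion experiment (two perfusion channels
# flanking a 1.2 mm chamber, frames every 15 min for 2 h 30), extracts
# cross-section intensity profiles, quantifies centre saturation and
# recovers the diffusivity from the profiles. Two solutes are emulated: a
# fast small dextran-like tracer and a slower albumin-sized one.

suppressPackageStartupMessages(library(osteochip))
seed <- 20260927L
out_dir <- "results/01_diffusion"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

solutes <- list(dextran_10kDa = 150, bsa_66kDa = 45)  # D in um^2/s
profiles <- list()
summary_rows <- list()
for (nm in names(solutes)) {
  D <- solutes[[nm]]
  ser <- generate_diffusion_series(D_um2s = D, noise_sd = 0.02, seed = seed)
  for (i in seq_along(ser$frames)) {
    pr <- extract_profile(ser, i)
    pr$time_min <- ser$times_min[i]
    pr$solute <- nm
    profiles[[paste(nm, i)]] <- pr
  }
  est <- estimate_diffusivity(ser)
  sat <- saturation_time(ser, 0.95)
  summary_rows[[nm]] <- data.frame(
    solute = nm, true_D_um2s = D, fitted_D_um2s = est$D_um2s,
    fit_residual = est$residual,
    saturation_time_min = if (is.na(sat)) NA else sat)
  message(sprintf(
    "%s: D = %.0f um^2/s -> fitted %.1f um^2/s, centre saturation %s",
    nm, D, est$D_um2s,
    if (is.na(sat)) "not reached within 150 min" else
      sprintf("at %d min", sat)))
}
write.csv(do.call(rbind, profiles), file.path(out_dir, "profiles.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, summary_rows), file.path(out_dir, "summary.csv"),
          row.names = FALSE)
write_run_manifest(file.path(out_dir, "manifest.yml"), seed = seed,
                   extra = list(solutes = solutes))
message("The fast tracer saturates the chamber centre well within the ",
        "experiment; the slower solute does not, matching the expectation ",
        "that molecular weight limits nutrient delivery under static supply.")
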