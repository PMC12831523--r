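#!/usr/bin/env Rscript
# Simulates one noisy DECT acquisition of each preset phantom at its tabulated
# Body-scan noise level, derives the RSP map, and scores every insert ROI
# against (a) the noiseless pipeline value and (b) the beam-measured RSP
# reference. Volumes go to scratch/ (binary); the score table to results/.
library(dectrsp)

dir.create("results", showWarnings = FALSE)
seed <- 1L
noise_keys <- c(model467 = "model467_14.55", aed_body = "aed_body_18.85",
                aed_head = "aed_head_18.85", george_body = "george_body_18.85",
                george_head = "george_head_18.85")

rows <- list()
for (p in names(noise_keys)) {
  sim <- simulate_phantom(p, noise = noise_keys[[p]], seed = seed,
                          outdir = file.path("scratch", "volumes", p))
  noiseless <- simulate_phantom(p, noise = NULL, labels = sim$labels)
  for (ins in sim$spec$inserts) {
    m <- extract_roi_mean(sim$rsp, ins)
    t0 <- extract_roi_mean(noiseless$rsp, ins)
    rows[[length(rows) + 1L]] <- data.frame(
      phantom = p, insert = ins$name, noise_key = noise_keys[[p]],
      roi_mean = m, noiseless = t0, rsp_ref = ins$rsp_ref,
      pe_vs_noiseless = percent_error(m, t0),
      pe_vs_ref = percent_error(m, ins$rsp_ref))
  }
  cat(sprintf("%-12s sigma_rsp(meas) = %.4f\n", p,
              noise_sigma(sim$rsp, diameter = if (p %in% c("aed_body", "aed_head")) 1.0 else 2.8)))
}
out <- do.call(rbind, rows)
write.csv(out, "results/synthetic_evaluation.csv", row.names = FALSE)

cat(sprintf("\n%d insert ROIs -> results/synthetic_evaluation.csv\n", nrow(out)))
cat(sprintf("Noise-only regime: MAPE vs noiseless pipeline = %.3f%% (no systematic error).\n",
            mape(out$pe_vs_noiseless)))
cat(sprintf("Against beam-measured references: MAPE = %.2f%% -- dominated by the\n",
            mape(out$pe_vs_ref)))
cat("theory/measurement gap of the low-density plugs, as in the scanner benchmark.\n")
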