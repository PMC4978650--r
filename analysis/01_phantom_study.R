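#!/usr/bin/env Rscript
# Phantom subtraction study: reconstruct the digital resolution phantom with
# the three protocols (P1 full k-space, P2 zero-filled partial Fourier, P3
# partial Fourier + POCS) and quantify the blur visible in the subtraction
# images P2 - P1 and P3 - P1 over each rod, in particular the peripheral
# column. Writes tables and NIfTI images under results/phantom/.

suppressPackageStartupMessages(library(pocsrecon))

cfg <- experiment_config(master_seed = 1234L, out_dir = "results/phantom")
rep <- run_phantom_experiment(cfg)

cat("Phantom subtraction residuals (RMS over each rod ROI):\n")
print(rep$residuals, digits = 3)

peri <- rep$residuals[rep$residuals$rod == "peripheral_column", ]
cat(sprintf(
  "\nPeripheral column: RMS(P3-P1) = %.2e vs RMS(P2-P1) = %.2e (ratio %.2g).\n",
  peri$rms_P3_P1, peri$rms_P2_P1, peri$ratio_P3_over_P2))
cat("Zero-filling leaves a clear residual at every rod; the POCS subtraction\n")
cat("is numerically null, i.e. the iterative phase-constrained recon removes\n")
cat("the truncation blur on this (real-valued, noiseless) phantom.\n")
cat("\nTables and images written under results/phantom/.\n")
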