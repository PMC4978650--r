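#!/usr/bin/env Rscript
# Simulated cohort study: 55 liver-like phantoms, each acquired three times
# (independent noise) and reconstructed with the full, zero-filled
# partial-Fourier and POCS protocols. Measures parenchyma SNR (3 automated
# ROIs), vessel-wall edge sharpness and its surrogate 4-point grade, then
# runs the repeated-measures statistics. Writes tables under results/cohort/.

suppressPackageStartupMessages(library(pocsrecon))

cfg <- experiment_config(master_seed = 1234L, out_dir = "results/cohort")
rep <- run_cohort_experiment(cfg)

cat(sprintf("Cohort: %d subjects x 3 protocols = %d records.\n\n",
            cfg$n_subjects, nrow(rep$records)))
cat("Per-protocol summary (mean +/- SD):\n")
print(rep$summary, digits = 4)

cat("\nSNR: repeated-measures ANOVA\n")
print(rep$stats$snr_anova)
for (r in rep$stats$snr_pairwise)
  cat(sprintf("  %-22s t = %8.3f, p = %.3g, Holm-adjusted p = %.3g\n",
              r$comparison, r$statistic, r$p_value, r$adjusted_p))

cat("\nGrades: Friedman test\n")
print(rep$stats$grade_friedman)
for (r in rep$stats$grade_pairwise)
  cat(sprintf("  %-22s V = %8.1f, p = %.3g, Holm-adjusted p = %.3g\n",
              r$comparison, r$statistic, r$p_value, r$adjusted_p))

s <- rep$summary
sharp <- setNames(s$sharpness_mean, s$protocol)
cat(sprintf(
  "\nEdge sharpness: full and POCS agree within %.1f%%; zero-fill sits %.1f%% below full.\n",
  100 * abs(sharp[["full"]] - sharp[["pocs"]]) / sharp[["full"]],
  100 * (1 - sharp[["zerofill"]] / sharp[["full"]])))
cat("Pattern mirrors the expected full ~ POCS > zero-fill ordering for\n")
cat("sharpness, with zero-fill gaining SNR from its low-pass smoothing and\n")
cat("POCS losing SNR to conjugate-synthesis noise duplication.\n")
cat("\nTables written under results/cohort/.\n")
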