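# pocsrecon

Partial-Fourier MRI reconstruction with the POCS (projection onto convex
sets) algorithm, rebuilt as a fully synthetic, testable analysis pipeline.

MRI scan time scales with the number of phase-encode lines, so a 6/8
partial-Fourier acquisition shortens a breath-hold (here from 17 s to 14 s
at a 256 × 144 matrix) at the cost of a missing quarter of k-space. This
package compares the three ways of dealing with that quarter on digital
phantoms:

| protocol | reconstruction |
|---|---|
| `full` | inverse FFT of fully sampled k-space |
| `zerofill` | missing lines left at zero (asymmetric low-pass → edge blur) |
| `pocs` | iterative phase-constrained estimation of the missing lines |

POCS alternates projections between two convex sets — images consistent
with the measured lines, and images whose phase equals the low-frequency
estimate φ̂ extracted from the symmetric central band of k-space. The
image-domain projection is

ρ_corrected(x) = Re[ρ(x) e^(−iφ̂(x))] e^(iφ̂(x)),

each pass restores the measured lines (hard substitution; the final pass
uses a linear merging-filter ramp across the truncation edge), and the
default iteration count is 2. The package provides the phantom and cohort
generators, the sampling schemes, the three reconstructions, ROI-based SNR
and an automated vessel-sharpness surrogate, and the repeated-measures
statistics (RM-ANOVA + paired t/Holm; tie-corrected Friedman — exact for
small n — + Wilcoxon signed-rank/Holm; Cohen's kappa).

## Worked example

```r
library(pocsrecon)

# one liver-like phantom: parenchyma disc, bright vessels, smooth phase
lp <- make_liver_phantom(liver_phantom_spec(seed = 11))
k  <- simulate_kspace(lp$image, lp$phase, noise_sigma = 0.075, seed = 1)

scheme <- make_pf_mask(144, fraction = 6/8)     # 108 of 144 lines acquired
km     <- apply_mask(k, scheme)

full <- recon_full(k)
zf   <- recon_zerofill(zero_fill(km))
pocs <- recon_pocs(km, scheme, recon_config())$image   # 2 iterations, hann, ramp 8
```

The two experiments are driven by the numbered scripts under `analysis/`.
`analysis/01_phantom_study.R` reconstructs the resolution phantom and
measures the subtraction residuals; on the noiseless phantom it prints

```
Peripheral column: RMS(P3-P1) = 9.15e-17 vs RMS(P2-P1) = 2.36e-02 (ratio 3.9e-15)
```

i.e. zero-filling leaves a clear residual on the peripheral column while
the POCS subtraction is numerically null. `analysis/02_cohort_study.R`
simulates 55 subjects × 3 independently noised acquisitions and prints,
among others (means ± SD over subjects):

```
  protocol snr_mean snr_sd grade_mean grade_sd sharpness_mean scan_time_s
      full    13.51 0.4417      3.127   0.9038         0.7635          17
  zerofill    15.57 0.5315      1.345   0.4799         0.6127          14
      pocs    11.07 0.4316      3.055   0.8481         0.7577          14

Grades: Friedman chi-square = 86.7, p = 1.5e-19
  full vs zerofill   Holm-adjusted p = 6.6e-10
  full vs pocs       Holm-adjusted p = 0.48      (non-significant)
  zerofill vs pocs   Holm-adjusted p = 6.6e-10
```

Vessel sharpness shows the full ≈ POCS > zero-fill pattern (zero-fill
~19% below the other two, full vs POCS within 1%), and the grade
statistics flag exactly the two zero-fill comparisons. SNR is highest for
zero-fill (truncation removes a quarter of the noise lines) and lowest for
POCS: conjugate synthesis duplicates measured noise into the unacquired
half, a reconstruction-side cost that in vivo is offset by the thicker
effective slice profile of the partial acquisition — an acquisition effect
outside this forward model. The methods vignette
(`vignettes/partial-fourier-pocs.Rmd`) derives this and documents every
modelling choice.

## Layout

```
R/                  generators, sampling, reconstruction, metrics, statistics, pipeline
analysis/           01_phantom_study.R  02_cohort_study.R  03_scan_time.R
scripts/            acceptance.R
tests/testthat/     unit, property and end-to-end tests (incl. brute-force oracles)
vignettes/          methods vignette
```
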