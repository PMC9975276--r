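# ftszdyn

Quantitative analysis of FtsZ protofilament dynamics from in vitro
biochemistry and in vivo FRAP data.

FtsZ is the tubulin-homolog GTPase that assembles into single-stranded
protofilaments and forms the contractile "Z ring" at bacterial and
chloroplast division sites. Its assembly behaviour is characterised by a
handful of standard wet-lab assays; this package implements the numerical
side of each of them, for researchers studying FtsZ (or other cytoskeletal
polymer) kinetics:

- **GTPase kinetics.** In a regenerative NADH-coupled assay, each GTP
  hydrolysed oxidises one NADH, so the A340 decline rate reports the
  hydrolysis velocity. Velocity *v* versus FtsZ concentration *C* is linear
  above a critical concentration *Cc*:
  *v* = *a* · max(*C* − *Cc*, 0), where the slope *a* is the GTPase
  activity (GTP min⁻¹ FtsZ⁻¹) and the x-intercept is *Cc* (μM).
  `velocity_from_trace()` converts traces to velocities;
  `fit_kinetics()` / `mixture_activity()` estimate *a* and *Cc* with
  delta-method uncertainties.
- **GTP depletion prediction.** Only protein above *Cc* hydrolyses GTP, so
  the nucleotide pool of a reaction started with GTP concentration *G* is
  exhausted at *t* = *G* / ((*C* − *Cc*) · *a*) × 60 seconds.
  `depletion_time()` implements this with the floor-seconds reporting
  convention.
- **Light scattering.** 90° LS reports assembly (polymerization plus
  bundling) in arbitrary units. `ls_metrics()` extracts baseline,
  amplitude, initial assembly rate, and the disassembly-onset time (a
  sustained-drop criterion plus a plateau/decline breakpoint fit);
  `classify_onset()` places each onset before or after the predicted GTP
  depletion.
- **FRAP.** Subunit turnover in assembled structures is quantified by
  fitting the two-binding-state recovery model
  FRAP(*t*) = (1 − *r*)(1 − *C*₁ e^(−*k*₁*t*) − *C*₂ e^(−*k*₂*t*))
  to double-normalized recovery curves (`normalize_frap()`, `fit_frap()`),
  with multistart bounded least squares; percent recovery is 100·(1 − *r*).
- **Sedimentation.** Pellet fractions pellet/(pellet + supernatant) from
  gel densitometry, compared between nucleotide conditions with unpaired
  t tests (`pellet_fraction()`, `compare_conditions()`).
- **Synthetic data.** Seeded generators (`ground_truth()`,
  `make_gtpase_traces()`, `make_ls_trace()`, `make_frap_trace()`,
  `make_sedimentation_samples()`) emulate all four instrument outputs with
  known parameters, so every estimator has a parameter-recovery test
  surface.

## Worked example

Fit kinetics from velocity points, predict GTP depletion, and analyse a
synthetic LS trace:

```r
library(ftszdyn)

concs <- seq(2, 14, 2)
pts <- data.frame(protein_conc = concs,
                  velocity = pmax(0, 0.59 * (concs - 2.12)))
fit <- fit_kinetics(pts)
fit
#> GTPase kinetic fit
#>   activity: 0.59 +/- 9.4e-17 GTP min^-1 FtsZ^-1
#>   critical concentration: 2.12 +/- 1.2e-15 uM
#>   n = 6 points over 4-14 uM, R^2 = 1.0000

depletion_time(reaction_spec(c(SeFtsZ = 14), gtp_conc = 50, kinetics = fit))
#> GTP depletion prediction
#>   total FtsZ: 14 uM, adjusted (above Cc): 11.88 uM
#>   predicted depletion: 428 s
```

The fitted line has slope 0.59 (the GTPase activity) and x-intercept
2.12 μM (the critical concentration); at 14 μM FtsZ only 11.88 μM is
polymer-competent, and 50 μM GTP is predicted to last 428 s.

```r
gt <- ground_truth(disassembly_onset = 700, seed = 42,
                   noise = list(a340 = 0, ls = 1, frap = 0, sed = 0))
m <- ls_metrics(make_ls_trace(gt, protein_conc = 8, dt = 2))
m
#> LS metrics
#>   baseline 0 a.u., amplitude 147.8 a.u.
#>   initial rate 2.003 a.u./s (window 0-38 s)
#>   disassembly onset: 700 s
classify_onset(m, depletion_time(reaction_spec(c(SeFtsZ = 8), 50, fit)))
#> [1] "before"
```

Disassembly of the 8 μM trace begins at 700 s, before the predicted
depletion at ~864 s — the before/after call the LS pipeline automates.

```r
gt0 <- ground_truth(seed = 42, noise = list(a340 = 0, ls = 0, frap = 0,
                                            sed = 0))
fit_frap(normalize_frap(make_frap_trace(gt0, n_post = 31)), seed = 1)
#> Two-binding-state FRAP fit
#>   r = 0.05 (recovery 95.0%)
#>   c_eq1 = 0.5, koff1 = 0.05 /s
#>   c_eq2 = 0.4, koff2 = 0.005 /s
#>   rss = 2.03e-31, max |residual| = 2.22e-16
```

On a noiseless synthetic curve the fit returns the generating parameters
exactly: two bound fractions (0.5 and 0.4) dissociating at 0.05 s⁻¹ and
0.005 s⁻¹, with 95% recovery.

A thin command-line front end over the same functions is installed at
`inst/scripts/ftszdyn-cli.R` (subcommands `simulate`, `gtpase`, `deplete`,
`ls`, `frap`, `sediment`).

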