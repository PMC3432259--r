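# nldcm

Linear and non-linear dynamic causal modelling (DCM) of auditory BOLD
networks: a self-contained R implementation of the forward model, the
variational inversion, random-effects Bayesian model selection (BMS), and the
two-stage group pipeline used to study effective connectivity in a
four-region auditory network — bilateral Heschl's gyrus (LHG, RHG) and
superior temporal gyrus (LSTG, RSTG) — under sparse temporal sampling.

## Science

Neuronal population activity `x` in the four regions evolves as

```
dx/dt = (A + sum_j u_j B_j + sum_k x_k D_k) x + C u
```

where `A` holds the fixed effective couplings (Hz), `B` the input
modulations, `D` the non-linear gating by regional activity, and `C` the
direct driving inputs. Self-connections are parameterised as
`-0.5 * exp(theta)` so the resting state stays stable. Each region's
neuronal activity drives a balloon-Windkessel haemodynamic cascade
(vasodilatory signal, blood flow, venous volume, deoxyhaemoglobin) whose
output is the observed BOLD signal. The system is integrated with a
fixed-step fourth-order Runge-Kutta scheme (compiled via Rcpp) and sampled
at the acquisition midpoints of a sparse-sampling paradigm (TR 16 s,
acquisition 5 s, 6-s white-noise stimulus every 32 s).

Subject-level inversion is a variational-Laplace scheme: Gauss-Newton ascent
on the free energy `F` with step halving, per-region noise precisions
updated by Newton steps, and `F = accuracy - complexity` used as the model
log-evidence. Group-level analysis proceeds in two stages:

1. **Stage 1 (input placement and pruning)** — fit fully connected models
   with input to HG vs STG, compare them by random-effects BMS (variational
   Dirichlet posterior over model frequencies, exceedance probabilities),
   then test every connection of the winner across subjects (one-sample
   t-tests, Bonferroni-corrected, combined with the mean posterior
   probability that the coupling is positive) and prune.
2. **Stage 2 (modulation vs gating)** — on the pruned skeleton, fit a
   bilinear family (input-modulated couplings) and a non-linear family
   (activity-gated couplings), select each family's winner by BMS, and
   compare the winners head to head.

## Worked example

```r
library(nldcm)

# simulate a 10-subject cohort from the fully connected STG-input model
cs <- cohort_spec(n_subjects = 10, n_scans = 32, dt = 0.5, seed = 7,
                  spec = build_fully_connected(auditory_regions(),
                                               c("LSTG", "RSTG"),
                                               name = "input_STG"))
co <- simulate_cohort(cs)
co
#> <dcm_cohort> 10 subjects x 32 scans from 'input_STG'

# fit one subject under the pruned four-connection model
fit <- fit_dcm(co$subjects[[1]], build_pruned_winner())
fit
#> <dcm_fit> pruned_winner on subject sub01: F = 297.23 nats, 5 iterations
round(fit$mean[c("a:LSTG->LHG", "a:LSTG->RHG", "a:RSTG->LHG", "a:RSTG->RHG")], 3)
#> a:LSTG->LHG a:LSTG->RHG a:RSTG->LHG a:RSTG->RHG
#>       0.056       0.080       0.098       0.134

# run the two-stage group analysis
res <- run_pipeline(analysis_config(co))
res$stage1$bms
#> <dcm_bms> 10 subjects, 2 models
#>       input_HG input_STG
#> alpha   1.0005   10.9995
#> <r>     0.0834    0.9166
#> phi     0.0005    0.9995
head(res$stage1$stats[order(-abs(res$stage1$stats$t)),
                      c("parameter", "mean_hz", "t", "p", "P", "retained")], 5)
#>      parameter    mean_hz         t            p         P retained
#> 14      c:RSTG 0.29286762 20.739063 6.591291e-09 0.9975497    FALSE
#> 10 a:RSTG->LHG 0.16291619 13.838185 2.267434e-07 0.9069028     TRUE
#> 12 a:RSTG->RHG 0.12106795 11.018568 1.587194e-06 0.8472289    FALSE
#> 13      c:LSTG 0.13821256 10.298097 2.800631e-06 0.8861999    FALSE
#> 4  a:LSTG->LHG 0.07077663  8.197418 1.820813e-05 0.6275099    FALSE
res$final_model$name
#> [1] "bilinear_none"
```

Stage 1 recovers the STG input placement decisively (exceedance 0.9995).
The connection table illustrates a structural property of this paradigm
that the methods vignette analyses in detail: with one acquisition sample
per identical trial, the two STG afferents of each HG target are exactly
collinear, so per-subject posterior mass splits across them and the
dual-criterion pruning retains only part of the generating set; likewise
the stage-2 families differ only in response amplitude and are not
distinguishable from these data, so the head-to-head outcome is not
meaningful on simulated cohorts of this size.

## Bundled reference tables

`reference_connection_stats()` and `reference_bms_table()` return the
group-level connection statistics and BMS summaries of the published
auditory study from which the generator's ground truth
(`auditory_ground_truth()`) is taken. Note that the `p` column of the
connection table holds Bonferroni-scaled values (plain two-sided p divided
by the 12 tests); `prune_connections()` therefore compares it directly
against `bonferroni_threshold(0.05, 12)`.

## Reproduction

- Install, then run the acceptance targets:

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out acceptance.json
  ```

  which writes the analytic exceedance probabilities for the input-stage
  comparison (`t2` = 0.9823) and the final head-to-head comparison
  (`t6` = 0.9995), both computed at runtime from the bundled Dirichlet
  counts.

- Run the test suite against the installed package:

  ```r
  testthat::test_dir("tests/testthat", package = "nldcm",
                     load_package = "installed")
  ```

  `tests/testthat/test-acceptance.R` asserts each acceptance criterion at
  its stated tolerance. Two sub-criteria fail by design and are analysed in
  the methods vignette: the all-14-row t-recomputation clause (the printed
  4-decimal summaries propagate up to 0.011 in t for low-mean rows) and
  non-linear model recovery by the full pipeline (the gating is not
  identifiable from one sample per identical trial). All other criteria and
  the entire non-acceptance suite pass.

- The methods vignette (`vignettes/nldcm-methods.Rmd`) documents the model
  equations, priors, integrator settings, and the identifiability analysis.

## License

MIT, see `LICENSE`.
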