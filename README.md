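# nbcascade

Boolean network screening and robustness analysis of the temporal
transcription-factor cascade in *Drosophila* neuroblasts.

During embryonic development of the *Drosophila* central nervous system,
neuroblasts express the transcription factors Hunchback (hb), Krüppel (Kr),
Pdm and Castor (cas) in a fixed order, with a Seven-up (svp) pulse switching
hb off.  This package is for systems biologists who want to ask, for a small
gene network with well-characterized mutant phenotypes: *which regulatory
architectures can generate the observed expression program at all, and is
the actual network special among them?*

It provides:

* a synchronous Boolean model of the cascade,
  `s_i(t+1) = 1 if Σ_j J_ij s_j(t) > 0, 0 if < 0, s0_i if = 0`,
  with three-level regulations `J_ij ∈ {+1, 0, −5}` (one active repressor
  silences any attainable sum of activators) and per-gene default states
  `s0_i` for zero input;
* exhaustive screens of all `3^12 = 531,441` candidate networks over the
  known factors, and all `3^15 = 14,348,907` networks including a
  presumptive extra regulator x, against window-order expression criteria
  for the wild type and eight single-gene mutant genotypes (loss and
  overexpression clamps);
* architecture statistics: regulations common to all surviving networks,
  network distances `N_d` (differing regulations, x and positive
  self-feedback neglected), sign-count-preserving reconnection null
  ensembles, and collapse of positive self-feedback;
* a continuous stochastic transcription–translation model,
  `dM_i = (F_i − d_M M_i) dt + σ dW_i`, `dP_i = (M_i − d_P P_i) dt` with
  `F_i = max(0, S_i + Σ_j J̃_ij h(P_j))` and Hill saturation
  `h(P) = P²/(K_M² + P²)`, integrated in compiled code, used to score each
  surviving network's robustness: the fraction of random parameter draws
  (or noise realizations) under which the discretized dynamics still
  satisfy the wild-type criterion.

## Worked example

```r
library(nbcascade)

dn <- drosophila_network(include_hb_cas = TRUE, include_x = TRUE)
dn
#> sign network (rows: targets, columns: regulators)
#>     hb Kr pdm cas x
#> Kr  +  0  -   0   +
#> pdm -  +  0   -   0
#> cas -  -  +   0   -
#> code: 10584208 (15-slot)

# simulate the wild type with one functional witness
traj <- simulate_boolean(dn, "wt", c(Kr = 0L, pdm = 1L, cas = 1L),
                         input_schedule(t_end = 10, t_x = 6))
traj
#> Boolean trajectory, wt genotype, t = 0..10
#>   hb ##.........
#>   Kr .###.......
#>  pdm ...#####...
#>  cas .......####
#>  svp .#.........
#>    x ######.....
matches_criterion(traj, criterion_for("wt"))
#> [1] TRUE

# the screen over the known factors: many networks reproduce the wild type,
# none explains all eight mutants as well
scan_known_factors(t_end = 10)
#> scan: known_factors  total networks: 531441
#>   WT-compatible: 39929
#>   fully functional: 0

# with the extra factor x (ON -> OFF), 384 networks survive all nine
# genotypes; their shared regulations form the minimum circuit
res <- scan_with_x("on_off", t_end = 10)          # ~3 min
nrow(res$records)
#> [1] 384
ensemble_distances(res$records$code)$mean
#> [1] 2.416667
length(collapse_self_feedback(res$records$code))
#> [1] 120

# robustness of the real architecture vs the minimum circuit
set.seed(1)
param_robustness(dn, n_trials = 2000)$fraction
#> [1] 0.449
param_robustness(minimum_network(), n_trials = 2000)$fraction
#> [1] 0.123
```

The printed trajectory is the wild-type program: hb first (switched off by
the svp pulse), then Kr, pdm and cas in successive windows.  The screen
counts say that wild-type behaviour alone is easy (39,929 of 531,441
networks) but the full mutant panel is impossible without a further
regulator; with x, 0.003% of architectures survive, they differ from the
literature-derived network by only 2.4 regulations on average, and the real
architecture is markedly more robust to parameter variation than the
minimal sufficient circuit.

A thin command-line wrapper is installed with the package
(`system.file("cli", "nbcascade", package = "nbcascade")`) with subcommands
`scan`, `simulate-boolean` and `robustness`; every run writes a JSON
manifest next to its outputs.

## Documentation

The methods vignette (`vignettes/cascade-methods.Rmd`) describes the model,
the expression criteria and their calibration, all tunable parameters with
defaults, the design of the continuous robustness experiments, and known
limitations.
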