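# sidls — secretion kinetics from dynamic-SILAC secretome time courses

Conditioned-medium proteomics at a single time point cannot distinguish a
protein a cell actively secretes from an intracellular protein that leaks
out through damage or death — both are simply "present in the medium".
`sidls` implements the kinetic solution: switch cells into heavy-lysine
(SILAC) medium, sample the medium over a short time course (0.5, 1, 2, 6,
24 h), and track each peptide's relative isotope abundance

    RIA_t = H / (H + L)

where `H` and `L` are the heavy and light extracted-ion-current
intensities. Classically secreted proteins have no large pre-existing
pool diluting new synthesis, so their RIA rises quickly toward 1; leaked
intracellular proteins stay near 0. Each trajectory is fitted with the
one-parameter rise-to-plateau model

    RIA(t) = 1 − exp(−k·t)

and the rate constant `k` (per hour) classifies the protein. Two
companion metrics summarise output: the late-window secreted amount
`P = A(24 h) − A(6 h)` (mean peptide `H + L` abundance) and the
intracellular-to-extracellular flux `flux = k·P`. The kinetic call is
cross-validated against SignalP d-scores (signal-peptide prediction,
secreted iff d > 0.5) with a two-sided Fisher exact test.

The package is aimed at proteomics groups running dynamic-SILAC secretome
experiments: it consumes MaxQuant-style `evidence.txt` tables plus a
run-to-time map and a SignalP score table, applies the PSM- and
trajectory-level quality filters (single-lysine tryptic peptides only,
≥3 RIA points, 6 h and 24 h required, impossible early-high profiles and
instant-plateau requant artifacts rejected), and emits deterministic
per-protein reports. A seeded synthetic-secretome generator with known
ground truth makes the whole pipeline testable without any raw data.

## Worked example

```r
library(sidls)

sim <- simulate_secretome(simulation_config(seed = 42))   # 105 proteins, known truth
res <- sidls(sim$evidence, sim$signalp, sim$design,
             cutoff_strategy = "association")
summary(res)
```

```
SIDLS summary

PSM filter tally:
                 n_input      removed_contaminant          removed_reverse
                    1530                        0                        0
 removed_missed_cleavage removed_multi_label_site      identification_only
                       0                        0                        0
                 kinetic
                    1530

Trajectory statuses:

 IMPOSSIBLE_PROFILE MISSING_LATE_POINTS                PASS      TOO_FEW_POINTS
                 23                 103                  96                  93

Sample SIM: 61 proteins fitted (0 artifacts), 36 SignalP-secreted, 40 high-k
  combined fit k: secreted 0.1636 /h, not-secreted 0.01171 /h; cutoff 0.02 /h; Fisher p 1.04e-12
```

Reading this: of 315 simulated peptide trajectories, 96 pass the
stringent filters (channel dropout costs many of the rest their required
6 h/24 h points); 61 proteins get pooled rate fits. The combined-fit `k`
of the SignalP-secreted class is ~14-fold that of the non-secreted class,
and the SignalP-by-kinetics association is decisive (Fisher p ≈ 1e-12).
A single noiseless trajectory fit recovers its generating rate exactly:

```r
t <- c(0.5, 1, 2, 6, 24)
fit_k(t, model_ria(0.274, t))
#> First-order labeling fit (PEPTIDE level)
#>   k = 0.274 per hour  (t1/2 = 2.53 h)
#>   n = 5 points, RSS = 1.336e-27
```

Real data enter through `load_evidence()` (MaxQuant 1.5.x headers by
default, remappable via `evidence_dialect()`), `load_signalp()` and a
run map; `write_protein_report()`, `write_trajectory_table()`,
`write_filter_tally()` and `write_classification_summary()` produce the
outputs. A thin command-line wrapper lives in `exec/sidls`
(`sidls run ...`, `sidls simulate ...`). The methods vignette
(`vignettes/secretome-kinetics.Rmd`) documents the model, filters,
numerics and the simulator's scope.

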