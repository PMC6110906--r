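# foldnet

Do cortical gyri carry globally shared functional signal better than
sulci? `foldnet` tests this folding-pattern hypothesis on task fMRI: if
gyri are global communication hubs and sulci local units, then within an
intrinsic functional network the fraction of a vertex's BOLD signal
explained by a *whole-brain shared temporal basis* should be higher on
gyral than on sulcal vertices.

The package implements the full analysis as a tested, reusable pipeline:

1. **Sparse factorization** — normalize per-vertex signals and decompose
   the t x n signal matrix as `X ~ D alpha` by online dictionary
   learning with L1 sparse coding (atoms constrained to the unit ball;
   coordinate-descent lasso with verified KKT optimality).
2. **Network identification** — binarize each atom's spatial map (a row
   of `alpha`) and match templates by the overlap rate
   `R(S, T) = |S n T| / |T|`, plus a nearest-vertex volume-to-surface
   mapping.
3. **Representation accuracy** — per vertex,
   `P_v = corr(x_v, D alpha_v)`; network regions are split into gyri
   (`pcurv >= 0`) and sulci (`pcurv < 0`) by principal curvature.
4. **Inference** — one-tailed pooled t-tests per region (Bonferroni
   corrected), 1,000-relabeling permutation tests per network, FA versus
   accuracy correlations, and cohort-level proportion tables.
5. **Synthetic folded cortex** — a generator (sine-folded sheet, block
   paradigm convolved with a double-gamma HRF, planted multi-region
   networks, sulcus-specific unshareable nuisance, FA-like scalars) so
   every stage is testable without neuroimaging data.

Since real whole-brain data cannot ship with the package, the synthetic
world is calibrated to *mirror* the reported effect size (a gyral-sulcal
accuracy gap of about 0.06) rather than reproduce any empirical number.

## Worked example

```r
library(foldnet)
cfg <- fold_config(seed = 7)   # desk-scale synthetic study
rep <- run_pipeline(cfg)
print(rep)
```

```
fold_report
  simulate   ran
  decompose  ran
  identify   ran
  assess     ran
  stats      ran
  template matches:
 template_id atom_index         R size_S size_T flagged
        net1         30 0.9285714    178     98   FALSE
        net2         19 1.0000000    194     98   FALSE
        net3         11 1.0000000    204     98   FALSE
        net4         43 1.0000000    157     98   FALSE
        net5         22 1.0000000    269     98   FALSE
  10/10 region tests significant (adjusted p < 0.05)
```

Each planted network was identified by a dictionary atom whose nonzero
spatial support covers 93-100% of the template (`R`). All ten planted
regions show significantly higher gyral than sulcal accuracy.

```r
rep$summaries$net1
```

```
    roi_id mean_gyri mean_sulci sd_gyri sd_sulci n_gyri n_sulci
 net1_roi1     0.896      0.834  0.0187   0.0276     19      30
 net1_roi2     0.894      0.840  0.0296   0.0527     28      21
    pooled     0.895      0.837  0.0256   0.0395     47      51
```

Gyral vertices are reconstructed from the shared basis at mean accuracy
~0.90 versus ~0.84 on sulci — the calibrated ~0.06 gap. The per-network
permutation tests agree:

```r
rep$network_tests[, c("network_id", "observed_diff", "perm_p")]
```

```
 network_id observed_diff   perm_p
       net1        0.0581 0.000999
       net2        0.0603 0.000999
       net3        0.0618 0.000999
       net4        0.0504 0.000999
       net5        0.0582 0.000999
```

(`0.000999 = 1/1001` is the smallest p the add-one estimator can return
at 1,000 permutations.) A multi-subject cohort summary:

```r
run_cohort(cfg, n_subjects = 12)$proportions
```

All artifacts (mesh, signals, templates, dictionary, match table,
accuracy maps, test tables, JSON report) persist as plain text when
`fold_config(out_dir = ...)` is set, and stages are skipped on re-runs
with an unchanged configuration. A CLI wraps the same pipeline:

```sh
Rscript inst/cli/foldnet.R run-all --seed 7 --out run7
Rscript inst/cli/foldnet.R cohort --seed 7 --subjects 12 --out cohort7
```

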