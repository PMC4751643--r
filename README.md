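# ovcortex

Quantitative histology of cryopreserved ovarian cortex.

When ovarian tissue is slow-frozen for fertility preservation, the
primordial follicle reserve and the stromal compartment both take damage,
and candidate protective additives are screened ex vivo by comparing
tissue that is fresh (F), frozen-thawed (F-T), or cultured for 2 or 6
days after thawing (D2, D6) across treatment arms. `ovcortex` implements
the three quantitative layers of such a study:

* **Image quantification** — stromal proliferation from Ki-67/DAB
  brightfield RGB sections. Contrast is enhanced with the excess-red
  transform *E* = clamp(2R − B − G, 0, 255); cells are segmented at the
  Kapur maximum-entropy threshold of *E*, cleaned by a morphological
  opening and 8-connected small-object removal; the tissue section is
  masked by a three-class Otsu partition of the blue channel (near-white
  classes are background) with hole filling; cell density is the cell
  area divided by the tissue area.
* **Follicle scoring** — primordial follicles (transitional counted as
  primordial) are *degenerated* if they show disorganized granulosa
  cells, shrunken ooplasm or a pyknotic oocyte, and *proliferative* if at
  least one granulosa cell is Ki-67 positive. Per-fragment densities pool
  counts over pooled section areas and are reported as log10(X + 1) per
  mm².
* **Mixed-effects analysis** — REML fit of
  `log_value ~ 0 + arm:condition + (1 | fragment)` on section-level
  observations, with within-arm condition contrasts and drug-vs-vehicle
  contrasts at each condition, flagged at α = 0.01 (Satterthwaite df by
  default).

A synthetic-data module generates IHC images with per-pixel ground truth
and whole simulated studies (4 arms × 4 conditions × 6 punches, 12
density + 3 proliferation sections per punch) with known effect sizes,
so every stage is validated against ground truth rather than against
itself.

## Worked example

```r
library(ovcortex)

## one synthetic Ki-67 section, quantified
g <- generate_ihc_image(image_gen_config(n_cells = 120, seed = 11))
g$truth$true_density
#> [1] 0.1517
quantify_image(g$image)$density
#> cell density: 0.1497 (8346 cell px / 55747 tissue px; threshold 60)

## a full simulated study, scored and analyzed
ann <- generate_follicle_dataset(study_gen_config(seed = 11))
obs <- score_study(ann, level = "section")
fit <- fit_mixed_model(obs, model_spec("total_primordial"))
fit$contrasts[c(7, 10, 19, 20), ]
#>                  pair estimate    se df  p_value significant
#>         S1P: F vs F-T   -0.114 0.107 80 2.90e-01       FALSE
#>        ZVAD: F vs F-T    0.348 0.107 80 1.65e-03        TRUE
#>  ZVAD vs CT_DMSO @ D2    0.178 0.107 80 9.93e-02       FALSE
#>  ZVAD vs CT_DMSO @ D6    0.463 0.107 80 4.24e-05        TRUE
fit$variance_components
#> fragment residual
#>   0.0334   0.0104
```

The painted ground-truth density (0.1517) is recovered to 0.002 by the
segmentation pipeline at the automatically selected threshold (60). In
the simulated study — whose default effect matrix encodes a
fresh-to-culture follicle loss that the drug arms attenuate — the fit
recovers the generating variance components (truth: fragment 0.04,
residual 0.01) and flags, e.g., the ZVAD-vs-vehicle difference at D6
while leaving the S1P freeze-thaw step non-significant.

Each contrast row reads: estimated log10-density difference, its
standard error, Satterthwaite df, p-value, and the flag at α = 0.01.

## Command line

A thin CLI over the same functions:

```sh
inst/cli/ovcortex run-all --out-dir run1 --seed 11
inst/cli/ovcortex simulate --config study.yaml
inst/cli/ovcortex analyze --out-dir run1 --alpha 0.01
```

Subcommands `simulate`, `quantify`, `score`, `analyze`, `run-all`; flags
override a YAML `--config`; exit codes: 0 ok, 2 config error, 3 data
error.

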