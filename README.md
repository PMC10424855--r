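# wgmcat

Chromatic adaptation transforms in the CAT16 cone space, built around the
**weighted geometric mean (WGM)** model of incomplete adaptation.

## The problem

The visual system rescales its cone sensitivities so that object colors stay
roughly constant as the illumination changes. Classic chromatic adaptation
transforms (CATs) model this with von Kries scaling: each cone signal is
divided by the cone response to an *effective adapting white*. When
adaptation is incomplete, the standard transforms (CAT02/CAT16, vK20) build
that effective white as a **linear** mixture of the adapting white `n` and a
fixed reference white `r`,

    effective white = D n + (1 − D) r,        D ∈ [0, 1],

which forces the predicted achromatic point onto the straight chord between
the two anchors in chromaticity. Achromatic-matching data instead place
observers' neutral points along the **Planckian/daylight locus**. The WGM
model replaces the arithmetic mixture with a weighted geometric mean,

    L_a = L / (L_n^D · L_r^(1−D))     (same per channel for M, S),

so the predicted neutral `n^D r^(1−D)` curves along the blackbody locus from
the adapting white (D = 1, "discounting the illuminant") to the reference
(D = 0). At D = 0.5 it reduces to the plain geometric-mean rule that
describes steady-state adaptation across many sensory systems and species.
The reference point is the "sky blue" nominal 15000 K white with CAT16 cone
responses (95.41, 103.87, 169.81).

The package provides, for the von Kries, linear (CAT16 configuration), vK20,
geometric-mean and WGM transforms:

- colorimetric plumbing: XYZ ↔ CAT16 LMS (`M16`), CIE 1976 u′v′, Planckian
  radiator synthesis against the embedded CIE 1931 2° observer,
  Planckian/daylight loci;
- corresponding-color computation, neutral-point prediction;
- the pairwise Δu′v′ evaluation protocol (both members of a corresponding
  pair mapped to the model's reference state; 1 JND ≈ 0.004 u′v′) with
  one-way ANOVA model comparison;
- bounded fitting of the degree of adaptation `D` (per condition or single)
  and of the reference point's CCT, minimizing mean Δu′v′;
- a seeded synthetic generator for achromatic matches and corresponding
  pairs with known ground truth;
- a delimited dataset format and a command-line interface
  (`inst/scripts/wgmcat`).

## Worked example

```r
library(wgmcat)

p <- cat_params("wgm", D = 0.7)          # 70% adaptation, 15000 K reference

# Where does a neutral surface sit for an observer adapted to tungsten light?
predict_neutral("A", p)
#>     up     vp
#> 0.2326 0.5062
locus_distance(predict_neutral("A", p))                       # 0.00188
locus_distance(predict_neutral("A", cat_params("linear", D = 0.7)))  # 0.00604
```

The WGM neutral for a 2856 K adaptor lies 0.0019 u′v′ from the Planckian
locus — within half a JND — while the linear CAT16-style prediction at the
same D sits 0.0060 away, pulled toward equal-energy white.

```r
# Corresponding color of XYZ (40, 45, 30) seen under A, reproduced under D65
corresponding_color(c(40, 45, 30), "A", "D65", p)
#>     X     Y     Z
#> 37.24 45.08 64.21

# Simulate an achromatic-matching experiment and recover the ground truth
spec <- synthetic_spec(D = 0.7, n_trials = 20, noise_sigma = 0.004, seed = 42)
ds   <- generate_neutral_matches(spec)    # 8 Planckian conditions x 20 trials
fit_D(ds, "wgm", mode = "single")
#> <fit_result> model wgm, mode single
#>   D: all=0.6983
#>   objective (mean dupv): 0.004834 over 160 records

evaluate_dataset(ds, spec$params)
#> <evaluation_report> model wgm: 160 records, mean dupv 0.00483 (1.21 JND)
```

The fitted D (0.6983) recovers the simulated 0.7 to well within the observer
scatter, and the true model's mean error (0.0048 ≈ the Rayleigh noise floor
σ√(π/2) = 0.0050) undercuts the best-fitting linear EE-reference transform
(0.0139) and vK20 (0.0058) on the same data.

The same operations are scriptable from a shell:

```sh
Rscript inst/scripts/wgmcat neutral --model wgm --D 0.7 --adapting A --json
Rscript inst/scripts/wgmcat simulate --seed 42 --n 20 --out matches.csv
Rscript inst/scripts/wgmcat fit --input matches.csv --model wgm --mode single --json
```

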