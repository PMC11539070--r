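# cosmoform

Computational preselection of **coformers** for ternary amorphous solid
dispersions (drug + polymer + small-molecular additive), aimed at drugs
with poor glass-forming ability that need a stabilizing third component
before hot melt extrusion.

The package implements the screening funnel end to end:

1. **ORSP preselection.** A candidate must have a total (Hildebrand)
   solubility parameter inside the *overlap range of solubility
   parameter* — the intersection of the drug ± w and polymer ± w
   intervals (w = 10 MPa^0.5 broad rule, w = 7 restrictive rule):

       ORSP(w) = [δ_drug − w, δ_drug + w] ∩ [δ_poly − w, δ_poly + w]

2. **Excess enthalpy.** Surviving candidates are scored by the mixing
   enthalpy with the drug, H_ex = Σ_k x_k (H_k^mix − H_k^pure), at 1:1
   molar ratio and 25 °C, computed with a COSMO-RS-style segment
   thermodynamics engine on σ-profiles (misfit + hydrogen-bond pair
   energies, self-consistent σ-potential, pseudochemical potentials,
   Gibbs–Helmholtz finite-difference enthalpies).

3. **Process-window map.** Candidates are mapped on the (melting point,
   H_ex) plane against the extrusion window of the polymer (100–225 °C
   for hydroxypropyl cellulose): liquid/waxy or low-melting additives
   and high-melters are excluded; the rest are classed promising
   (H_ex ≤ −2 kcal/mol), possible (−2 < H_ex < 0) or unfavorable
   (H_ex ≥ 0), and ranked by H_ex.

Hansen partial solubility parameters can be estimated in-package by a
virtual solubility screen over 29 reference solvents (`fit_hansen()`,
a classed model object with `coef`/`summary`/`predict`/`plot` methods).
σ-profiles are *inputs* (two-column tabulated text); the package does
no quantum chemistry. A synthetic fixture generator provides profiles
and candidate libraries with known ground truth.

## Worked example

```r
library(cosmoform)

# ORSP for a drug with delta 19 and a cellulosic polymer at 24 MPa^0.5
orsp(19, 24, width = 10)
#> ORSP drug / polymer (+/- 10 MPa^0.5, broad rule): 14 - 29 MPa^0.5

# screen a synthetic 20-candidate library against fixture drug A
lib <- generate_candidate_library(n = 20, seed = 13)
cfg <- screen_config(drug = fixture_drugs()$drug_basic_A,
                     drug_delta = 19, polymer_delta = 24)
scr <- run_screen(cfg, lib$candidates)
scr
#> coformer screen: 20 candidates for drug 'drug_basic_A' in polymer HPC
#> ORSP drug_basic_A / HPC (+/- 10 MPa^0.5, broad rule): 14 - 29 MPa^0.5
#>   fates: assessed=12, outside_orsp=8
#>   top ranked:
#>                       name      h_ex melting_point_C promise_class rank
#>  cand_17_complement_strong -5.664227           212.9     promising    1
#>  cand_01_complement_strong -4.425520           175.1     promising    2
#>  cand_11_complement_strong -4.418375           148.8     promising    3
#>  cand_07_complement_strong -3.111380           138.2     promising    4
#>    cand_02_complement_weak -1.367418           174.6      possible    5
```

The ranked table reads exactly like the screening map: the most
negative excess enthalpies (strong donor additives against the
acceptor-type drug, the diacid-like candidates) head the list; weakly
interacting candidates are `possible`; a self-associated
ornithine-like candidate scores H_ex > 0 and is `unfavorable`;
additives melting outside 100–225 °C or dosed as liquids/waxes are
excluded regardless of enthalpy. `write_screen_report(scr, dir)` emits
`results.csv`, `map.csv` and an audit report listing every default and
a provenance block; `plot(scr)` draws the melting-point versus H_ex
map with the window as dashed limits.

A command-line front end with subcommands `orsp`, `simulate`, `hex`,
`fit-hansen`, `screen` and `map` is installed at
`inst/scripts/cosmoform`.

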