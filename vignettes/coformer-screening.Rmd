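---
title: "Screening coformers for ternary amorphous solid dispersions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening coformers for ternary amorphous solid dispersions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmoform)
```

## The problem

Poorly water-soluble drugs are often formulated as amorphous solid
dispersions in a polymer. Drugs with poor glass-forming ability
recrystallize from such dispersions unless a third component — a
small-molecular *coformer* that forms strong specific interactions with
the drug — is added. Testing coformers experimentally by hot melt
extrusion is slow, so `cosmoform` implements an in-silico funnel that
orders the candidate space before any extrusion run:

1. **Preselection** on total (Hildebrand) solubility parameters via the
   *overlap range of solubility parameter* (ORSP).
2. **Thermodynamic scoring** of the survivors by the excess enthalpy of
   mixing with the drug, from a COSMO-RS-style segment engine.
3. **Process mapping** of the scored candidates against the extrusion
   temperature window of the polymer.

## The ORSP preselection

Two components whose total solubility parameters differ by more than
10 MPa$^{0.5}$ are expected immiscible; within 7 MPa$^{0.5}$ they are
expected fully miscible. A useful coformer must be compatible with both
the drug and the polymer, so the candidate's total parameter must fall
in the intersection of the drug $\pm w$ and polymer $\pm w$ intervals:

$$\mathrm{ORSP}(w) = [\delta_{drug} - w,\ \delta_{drug} + w] \cap
  [\delta_{poly} - w,\ \delta_{poly} + w], \qquad w \in \{7, 10\}.$$

Default screening uses the broad rule $w = 10$ (the miscibility limit);
the restrictive rule $w = 7$ is available as a flag. Bounds are treated
as **closed**: a candidate sitting exactly on a bound passes. The
inclusive reading matches how such limits are used in preformulation
practice, where the preselection is deliberately generous and the
engine stage does the discriminating; it is a package choice, stated
here because interval screens are sometimes implemented half-open.

```{r orsp}
orsp(19, 24, width = 10)  # drug delta 19 with a cellulosic polymer at 24
orsp(19, 24, width = 7)
```

## The segment thermodynamics engine

The engine operates on *sigma-profiles*: histograms $p^X(\sigma)$ of a
molecule's surface screening charge density from a conductor-embedding
quantum calculation. Profiles are **inputs** (tabulated text files);
the package performs no quantum chemistry. The sign convention is that
hydrogen-bond **donor** surface carries negative $\sigma$ and
**acceptor** surface positive $\sigma$. The default grid is the
conventional 51 bins on $[-0.025, +0.025]$ e/Å$^2$ with spacing 0.001.

Two surface segments of polarity $\sigma, \sigma'$ interact with

$$E(\sigma,\sigma') = \frac{\alpha'}{2}(\sigma+\sigma')^2 +
  c_{hb}\,\min(0, \sigma_{don} + \sigma_{hb})\,
         \max(0, \sigma_{acc} - \sigma_{hb}),$$

electrostatic misfit plus hydrogen bonding, the latter active only when
a strong donor meets a strong acceptor. The segment chemical potential
$\mu_S(\sigma)$ of the mixture ensemble $S$ solves the self-consistent
equation

$$\mu_S(\sigma) = -RT \ln \sum_{\sigma'} p_S(\sigma')\,
  \exp\!\left[\frac{\mu_S(\sigma') - E(\sigma,\sigma')}{RT}\right],$$

with $p_S$ the area-weighted, normalised ensemble profile. The
pseudochemical potential of compound $X$ is the surface integral
$\mu_X = \mu_{comb} + a_{eff}^{-1}\sum_\sigma p^X(\sigma)\mu_S(\sigma)$,
where $\mu_{comb}$ is the Staverman–Guggenheim area/volume combinatorial
term. Activity coefficients follow as
$\ln\gamma = (\mu_X^S - \mu_X^X)/RT$ against the pure-liquid reference.

We carry $\mu_S$ *per contact* (one segment of area $a_{eff}$); the
formulation in which $a_{eff}/RT$ appears inside the exponent is the
same model in per-area units. One convention is used consistently
throughout.

### Parameters

The engine uses the published open parameterization on the TZVP level:

| constant | value | units | role |
|---|---|---|---|
| $\alpha'$ | 16466.72 | kcal Å$^4$/(mol e$^2$) | misfit prefactor |
| $c_{hb}$ | 85580 | kcal Å$^4$/(mol e$^2$) | hydrogen-bond strength |
| $\sigma_{hb}$ | 0.0084 | e/Å$^2$ | hydrogen-bond threshold |
| $a_{eff}$ | 7.5 | Å$^2$ | effective contact area |
| $r_0, q_0, z$ | 66.69, 79.53, 10 | Å$^3$, Å$^2$, — | combinatorial term |

All constants live in one versioned `cosmo_parameters()` object that can
be written to and read from a flat key–value file and checksummed into
reports. The van der Waals term defaults to zero: a surface-proportional
energy cancels identically in mixing properties, and the funnel only
consumes mixing properties. Exact numerical agreement with proprietary
fragment-based engines is not claimed; their parameterizations are
undisclosed, and the published per-coformer enthalpies exist only as a
plotted map, so there is no numeric anchor to match against. What the
package reproduces is the *decision layer*: worked interval arithmetic,
thermodynamic identities, and the qualitative enthalpy ordering.

### Numerics

The fixed point is solved by damped successive substitution (initial
step $0.6$, adapted between $0.05$ and $0.95$) with a depth-one Anderson
(secant) acceleration that is accepted only when it contracts the
residual by at least 10%. Convergence is declared at a max-norm
residual of $10^{-10}$ kcal/mol (cap 2000 iterations). The tight
tolerance is deliberate: for slowly contracting ensembles the true
error can exceed the residual by orders of magnitude, and the
brute-force cross-checks in the test suite require $10^{-8}$ kcal/mol
agreement. Zero initialization is the deterministic default;
convergence from random starts agrees within ten times the tolerance
for realistic profiles. Degenerate toy profiles in which donors and
acceptors occupy single isolated bins can make the fixed point
non-hyperbolic (the donor–acceptor antisymmetric mode is constrained
only by exponentially small bridging terms); such systems are flagged by
non-convergence rather than silently mis-solved.

### Enthalpy route

The partial molar enthalpy uses the Gibbs–Helmholtz identity
$H = \partial(\mu/T)/\partial(1/T)$, evaluated as a central finite
difference over $[T-\Delta T, T+\Delta T]$ with $\Delta T = 5$ K by
default. The combinatorial term is athermal and drops out exactly. The
step size is configurable, and the suite checks step-halving
consistency. The excess (mixing) enthalpy of a drug–coformer pair,

$$H_{ex} = \Delta H_{mix} = \sum_k x_k (H_k^{mix} - H_k^{pure}),$$

is evaluated at the screening state: **equimolar mixture, 25 °C**, the
components taken as (supercooled) liquids. Negative values indicate
specific drug–coformer attraction; values beyond −2 kcal/mol have been
associated with reliably amorphous products, which is the default
`promising` threshold.

```{r hex}
drugs <- fixture_drugs()
lib <- generate_candidate_library(n = 12, seed = 3)$candidates
diacid_like <- candidate_compound(lib[lib$hb_character == "complement_strong", ][1, ])
excess_enthalpy(drugs$drug_basic_A, diacid_like)
```

## Hansen parameter estimation

When no literature total solubility parameter exists for a compound,
the package estimates one by a virtual solubility screen: the engine's
infinite-dilution $\ln\gamma$ in each of 29 reference solvents is
compared with the regular-solution model

$$\ln\gamma = \frac{V_x}{RT}\left[\alpha(\delta_{d,x}-\delta_{d,i})^2 +
 (\delta_{p,x}-\delta_{p,i})^2 + (\delta_{h,x}-\delta_{h,i})^2\right],$$

with $\alpha = 4$ the universal weighting of the dispersive term
(configurable). Squared parameter differences are in MPa, i.e. J/cm³ —
the conversion is the identity and is centralized in `mpa_to_J_cm3()`
so the unit discipline is testable. Both sides pass through the
sigmoidal transform $f(\ln\gamma) = 1/(1+e^{s(\ln\gamma - c)})$
(defaults $s = 1$, $c = 2$, i.e. $\gamma \approx 7.4$ at the 0.5
crossing), which concentrates the fit on the good/bad-solvent
distinction rather than on extreme $\ln\gamma$ magnitudes, and the
partials minimise $\sum_i [f_i^{engine} - f_i^{Hansen}]^2$.

The objective is multimodal, so `fit_hansen()` multi-starts L-BFGS-B
from a coarse grid over the box $[10,40]\times[0,40]^2$ MPa$^{0.5}$ and
keeps the best of the ten most promising starts. Infinite dilution is
represented by a solute mole fraction of $10^{-6}$, a numerically
stable proxy. The bundled 29-solvent table carries literature Hansen
parameters for common solvents and is user-replaceable by CSV; the
identity of the original screening panel is not public, so the default
set was chosen to span dispersive, polar and hydrogen-bonding space.

```{r hansen}
solv <- reference_solvents()
truth <- hansen_parameters(17, 8, 10)
lg <- vapply(seq_len(nrow(solv)), function(i)
  hansen_lngamma(truth, solv[i, ], V_x = 150), numeric(1))
coef(fit_hansen(lg, solv, V_x = 150))
```

## The process-window map

Candidates that pass the ORSP and have been scored by $H_{ex}$ are
placed on the (melting point, $H_{ex}$) plane against the extrusion
window of the polymer — by default **100–225 °C** for hydroxypropyl
cellulose: the floor reflects polymer processability, the ceiling stays
conservatively below thermal decomposition. The decision rules:

* liquid or waxy additives, or melters below the window:
  `excluded_low_tm` (hard to dose into an extruder barrel);
* melters (or decomposers) above the window: `excluded_high_tm` (only
  particle-surface contact with the drug, no molecular mixing);
* otherwise `promising` if $H_{ex} \le -2$ kcal/mol, `possible` if
  $-2 < H_{ex} < 0$, `unfavorable` if $H_{ex} \ge 0$.

Window bounds are closed, decomposing compounds sit at their
decomposition temperature, and the three-class scheme with a
configurable threshold formalises what is otherwise prose guidance.
Ranking is by $H_{ex}$ ascending with ties broken by lower melting
point, then name, so reports are reproducible.

## What the synthetic fixtures emulate — and what they do not

Real sigma-profiles for the published compounds are not redistributable,
so the generator builds profiles as Gaussian peak mixtures on the
default grid (exact bin-edge quadrature, area conserved to machine
precision):

* two fixture drugs with mostly neutral surface and a distinct
  basic-nitrogen **acceptor** peak (+0.013 to +0.014 e/Å$^2$), echoing
  lipophilic weak bases;
* `complement_strong` / `complement_weak` candidates with free **donor**
  surface (carboxylic-acid-like), giving engine $H_{ex}$ of roughly
  −3 to −6 and −0.7 to −1.5 kcal/mol respectively against the fixture
  drugs;
* `clash` candidates modelled as strongly self-associated zwitterions
  (matched donor and acceptor peaks at ±0.019 e/Å$^2$), whose internal
  hydrogen-bond network is diluted on mixing, giving $H_{ex} > 0$ — the
  behaviour of an ornithine-like negative control;
* `neutral` candidates with no hydrogen-bond surface.

The peak positions and shares were designed once, by verifying the sign
and magnitude bands above with the engine, and then frozen. Candidate
libraries additionally span the ORSP axis (inside/below/above), the
window axis (below/inside/above, plus liquid and waxy states, and
decomposing high-melters) and carry a designed enthalpy and the implied
ground-truth class.

Passing tests on these fixtures demonstrates that the funnel's logic,
thermodynamic identities and qualitative interaction ordering are
correct. It does **not** demonstrate quantitative enthalpy accuracy for
real molecules: real profiles have richer fine structure, conformer
averaging, and the generator's donor/acceptor peaks are idealised.
Quantitative use requires real sigma-profiles and, ideally, calibration
against experimental amorphization outcomes.

## Problem sizes and determinism

The shipped tests and the acceptance script use libraries of 6–34
candidates, 17-candidate libraries across 20 seeds for the decision
rules, and single-pair enthalpies for the engine identities; these sizes
exercise every code path while keeping a full run in the order of
seconds. Every stochastic step takes an explicit seed through
`with_seed()`, which restores the caller's RNG state, so libraries are
reproducible byte-for-byte and the screen's `results.csv` is identical
across repeated runs of the same configuration.

## Known limitations

* No quantum-chemical or fragment-based sigma-surface generation;
  profiles must be supplied.
* No absolute solubility or phase-diagram prediction; the engine serves
  mixing properties only.
* The preselection screens on totals only — no 3D Hansen-sphere
  distance; that is the documented scope of the ORSP stage.
* Physical stability of the final dispersion depends on humidity,
  mobility and kinetics that no equilibrium enthalpy map captures; the
  funnel orders candidates, it does not guarantee outcomes.
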