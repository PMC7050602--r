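---
title: "Saturation, progression and Free-Wilson design of analog series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturation, progression and Free-Wilson design of analog series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(como)
```

## The model

An analog series (AS) is a set of compounds sharing a core scaffold and
differing only in substituents at indexed sites R1..Rk (k between 1 and
6 in practice; hydrogen is an admissible substituent at any site). Two
members form a matched molecular pair (MMP) when they differ at exactly
one site. `como` quantifies two complementary aspects of a series under
lead optimization and then uses the same machinery generatively:

* **Chemical saturation / SAR progression diagnostics.** A population of
  `n_V` virtual analogs (VAs) is enumerated for the series and projected
  with the existing analogs (EAs) into a normalized descriptor space.
  Each EA carves out a ball ("neighborhood", NBH) of fixed radius. With
  `n_N` the number of VAs inside at least one NBH, and `m_i` the number
  of NBHs containing VA `i`:

  * coverage `C = n_N / n_V`,
  * `d_mean = (sum of m_i over in-NBH VAs) / n_N`, density
    `D = 1 - 1/d_mean`,
  * saturation `S = 2CD/(C+D)`, the harmonic mean (S = 0 when C + D = 0),
  * progression `P = sum(w_i * dbar_i) / sum(w_i)` where `dbar_i` is the
    mean absolute pairwise potency difference among the `m_i` EAs whose
    NBHs share VA `i`, with `w_i = 1/m_i` if `m_i > 1` and 0 otherwise.

  High S with low P is the termination signature (space exhausted,
  potency flat); any other quadrant leaves room for expansion.

* **Free-Wilson (FW) design and prediction.** Under the additivity
  assumption, the potency change of a substituent exchange is
  independent of the rest of the molecule. A *FW neighborhood* is a hub
  A with MMP edges to B (site s1) and C (site s2, s1 != s2); B and C do
  not form an MMP themselves. The double-substituted target X satisfies
  `pot(X) = pot(B) + pot(C) - pot(A)`; a target covered by several
  neighborhoods gets the unweighted mean. Targets that exist in the
  series (FW EAs) provide a per-series validation set (each is
  "virtualized": only neighborhoods in which it is the *target*
  contribute, so its own potency never enters its prediction); absent
  targets are new candidate structures (FW VAs). The neighborhood
  saturation score is `N = 1 - n_FW_EA / n_FW_NBH`, where `n_FW_NBH`
  counts neighborhoods whose target is an FW EA. Whether that
  denominator should instead count *all* neighborhoods is ambiguous in
  the verbal definition ("FW NBHs per FW EA"); counting existing-target
  neighborhoods keeps `N` a property of observed data, independent of
  how many virtual targets happen to be constructible.

* **QSAR baselines.** Ridge regression (unpenalized intercept, exact
  linear-algebra solve, dual form when features exceed instances) and
  epsilon-insensitive SVR with the Tanimoto kernel
  `K = |x AND y| / |x OR y|` on 1024-bit folded circular fingerprints of
  bond diameter 4. Model selection follows a double cross-validation
  protocol: per trial an 80/20 split, 5-fold internal grid search on the
  80%, refit and external prediction of the 20%; per-compound
  predictions are averaged over all trials in which the compound was
  external, and flagged compounds (FW EAs) are guaranteed at least one
  external appearance by redrawing splits within a retry budget.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_va` | 2000 | VAs/series | diagnostic population size; binomial noise on C scales as `1/sqrt(n_va)` |
| `radius` | 1.0 | normalized (z-score) distance | NBH radius; upstream parameterization of the published protocol is not restated here, so it is an explicit config knob recorded in every report |
| descriptors | `mw, clogp, tpsa, hbd, hba, rotb, rings` | mixed | a standard 7D physicochemical space; configurable |
| heavy-atom cap | 13 | heavy atoms | maximum substituent size in fragmentation and enumeration |
| `n_trials` | 35 | – | external resampling count (use 10 for quick, scaled-down runs) |
| `rr_alpha_grid` | 7 values, 1e-3..1e3 (log) | – | grid sizes follow the stated protocol; values are the field-standard log grids |
| `svr_c_grid`, `svr_eps_grid` | 18 values 1e-4..1e5; {0.01,0.05,0.1,0.2,0.5} | – | same reasoning |
| `noise_sd` (generator) | 0.2 | log units | the scale of experimental potency reproducibility; predictions within an order of magnitude are considered meaningful |

## The molecular-graph layer and its contracts

No R cheminformatics toolkit is available in the target environment, so
the package carries a small, testable SMILES layer of its own: organic
subset + aromatic lowercase + brackets (charge, explicit H, isotope,
chirality tag, atom maps), branches, ring closures, and wildcard `*`
attachment points. Canonical keys come from Weisfeiler–Lehman
refinement with deterministic tie splitting and a rank-driven DFS
writer. Contracts and their limits:

* Keys are invariant to input atom ordering (tested against an
  independent toolkit's equivalence classes on mixed fixtures).
* Aromaticity is *trusted, not perceived*: a Kekulé benzene and an
  aromatic benzene are different keys. Compare structures written in
  one aromaticity model. E/Z bond marks are stripped; chirality tags are
  carried as atom annotations only.
* Tied canonical ranks are split deterministically; for
  symmetry-equivalent atoms the choice is arbitrary (automorphic), which
  is why series cores must be asymmetric (below).

MMP fragmentation cuts acyclic, non-aromatic single bonds that touch a
ring atom or form a heteroatom (N/O/S) linkage — a compact
retrosynthetic-style eligibility set; implicit hydrogens at ring atoms
and heteroatoms are treated as exchangeable substituents, so H <-> R
pairs are found. A context (core side) must retain at least one ring
atom. Because a large ring-bearing substituent can locally masquerade as
a core, series assembly — not pair detection — resolves such conflicts:
components without a common core are re-split after removing edges whose
context does not dominate the exchanged fragment (more ring atoms, ties
by heavy atoms).

Series assembly selects, per MMP-network component, the largest
hydrogen-filled core (heavy-atom count, ties by lexicographic key)
reachable by independent multi-cuts of every member, then decomposes
each member into one substituent per site. Site identity is the
canonical rank of the attachment atom in the bare core — stable across
members exactly when the open positions are distinguishable by graph
refinement alone. Cores whose open positions are symmetry-equivalent
(e.g., para-positions of a plain ring) would make site assignment
ambiguous; the synthetic generator therefore validates its scaffolds
(2-methylpyridine up to 4 sites, quinoline beyond) and rejects
symmetric ones. Sub/superstructure relations between distinct series
cores are kept separate, not merged.

## What the synthetic generator emulates — and what it does not

`make_series()` builds real structures (asymmetric heteroaromatic core +
grammar-generated substituent fragments) over a full factorial
substituent lattice, with potency
`base + sum(site contributions) + interactions + N(0, noise_sd)`, plus
held-out ground truth for every lattice cell. It emulates the
statistical structure the methods assume: additive SAR with controlled
nonadditivity and noise, realistic series sizes (up to hundreds of
members, 1–6 sites), hydrogen likelihoods per site, and substituent
pools under a 13-heavy-atom cap.

It does **not** emulate: assay heterogeneity and censored measurements,
activity cliffs from binding-mode switches, correlated substituent
choices of real medicinal-chemistry programs, stereochemistry, or the
diversity of a curated multi-thousand substituent pool. A green test on
synthetic data therefore establishes algorithmic correctness (scores
equal their definitions, FW transfer is exact under additivity, models
recover what their assumptions allow) — it does not certify score values
or prediction accuracy on any real series, which depend on upstream
choices (descriptor set, radius, pool) explicitly recorded in each
report.

## Numerical choices

* **Saturation bookkeeping.** `NBH_O_VA` is the total count of
  VA-in-NBH incidences (`sum of m_i` over in-NBH VAs). This reading
  guarantees `d_mean >= 1`, hence `D` in `[0, 1)`, and makes D a pure
  multiplicity ("sampling density") measure. `P` with all `m_i <= 1` is
  reported as `NA` with a flag, never silently 0.
* **Normalization.** z-scores use the sample standard deviation over
  the joint EA+VA population; zero-variance descriptors get scale 1 and
  a warning. Distances are Euclidean (standard for z-scored spaces).
* **SVR solver.** A two-variable SMO on the 2n-variable dual with
  maximal-violating-pair selection, KKT tolerance 1e-8, and
  boundary-tolerant working sets (variables within 1e-10·C of a bound
  are clamped and unselectable — this prevents stuck pairs). The bias is
  the mean of `-z·G` over free variables, else the KKT midpoint; when no
  free support vectors exist the bias is an interval and any midpoint is
  a valid optimum. Tests compare against an independent `quadprog` solve
  of the same dual (with a 1e-6 ridge; the 2n-form is rank-deficient)
  and against an external reference implementation.
* **Ridge.** Exact solve of the penalized normal equations; the dual
  identity `w = X'(XX' + aI)^{-1} y` is used when p > n; `alpha = 0`
  falls back to a QR least-squares solve.
* **Grid-search ties** go to the stronger regularization (larger alpha;
  smaller C, then larger epsilon), making selection deterministic.
* **Determinism.** Every stochastic step (VA draws, lattice occupancy,
  CV splits) runs under a locally scoped RNG seeded from a recorded
  integer; reports embed their seeds and parameters.
* **Degenerate inputs.** Unparsable SMILES become per-compound error
  records; duplicate canonical keys are dropped with a warning; pools
  too small for the requested unique VA count return what is achievable
  and warn; `R²` on zero-variance truth is an error, not a number.

## Known limitations

* Canonicalization is refinement-plus-tie-split, not a full
  automorphism-group canonizer; exotic highly regular graphs could in
  principle collide, chemically sensible structures do not (validated
  against an independent toolkit on fixtures).
* The simplified lipophilicity and reduced polar-surface-area tables are
  coarse (they order compounds sensibly in a z-scored space but are not
  literature-accurate predictions); swap in custom descriptor functions
  for production scoring.
* Symmetric cores are rejected rather than handled by symmetry-aware
  site matching.
* Multi-cut (>1 site) MMPs, scaffold hopping, fuzzy core matching,
  tautomers and stereochemistry-aware exchanges are out of scope; FW
  neighborhoods are strictly the two-edge, two-site pattern, and
  cooperativity between sites is diagnosed (via prediction error) but
  not modeled.
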