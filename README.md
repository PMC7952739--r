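# cgsaxs

Solution-structure inference for multi-domain proteins by coarse-grained
conformational sampling and SAXS-based ensemble selection.

## The problem

Proteins like ER-60 (ERp57/PDIA3) are built from several folded domains —
here the four thioredoxin-like domains **a**, **b**, **b′**, **a′** in a
twisted U-shape — connected by short flexible linkers.  The domains keep
their folds, but their *mutual arrangement* fluctuates in solution and can
shift between functional states (e.g. the oxidized vs reduced forms of the
catalytic CGHC motifs in the edge domains).  Small-angle X-ray scattering
(SAXS) senses this arrangement through the 1D intensity I(q), but one
profile does not determine one structure.

`cgsaxs` closes the gap the standard way, as a tested, reusable R pipeline:

1. **Sample**: one-bead-per-residue structure-based (Gō-type) model — native
   bonds/angles/dihedrals, 12-10 native-contact wells (ε = 0.8 kBT,
   6.5 Å cutoff, |i−j| ≥ 4, intra-unit only), excluded volume, Debye–Hückel
   electrostatics at 150 mM — integrated with BAOAB Langevin dynamics at
   300 K.  Flexible linkers carry no native terms, so domains stay folded
   while the hinges move.
2. **Scatter**: per-snapshot Debye profiles
   I(q) = Σᵢⱼ fᵢfⱼ sin(qrᵢⱼ)/(qrᵢⱼ), Guinier fits, model P(r)/Dmax.
3. **Screen**: scale-fitted χ² = (1/(N−1)) Σ[(c·Iₘ − Iₜ)/σ]² against a
   target profile plus a strict radius-of-gyration window
   (χ² < χ²max, Rg,min < Rg < Rg,max).
4. **Analyse**: centre-of-mass descriptors per model —
   θ₁ = θ(a–b–b′), θ₂ = θ(b–b′–a′), the four-COM dihedral φ, and the
   edge-domain distance D(a–a′) — plus Kabsch-superposed averaged-COM
   models, COM shifts between ensembles, and paired 2D frequency /
   difference maps.

It also ships a simplified aggregate correction
(`extract_monomer_profile()`): given independently measured weight
fractions of residual dimer/trimer, each k-mer is modelled at the Guinier
level with I_k(0) ∝ w_k·M_k and Rg,k = Rg,1·k^(1/3) and subtracted,
recovering the monomer profile from a slightly polydisperse measurement.

A fully seeded synthetic-data module (`make_toy_protein()`,
`make_two_state_ensemble()`, `synthesize_experiment()`) generates every
input with known ground truth, so the complete pipeline runs offline and is
testable end to end.

## Worked example

```r
library(cgsaxs)

# 1. a four-domain toy protein with known COM geometry
toy <- make_toy_protein(toy_spec(seed = 1))
round(toy$realized, 1)
#> theta1 theta2    phi      d
#>   72.1  131.9   61.9   28.0

# 2. coarse-grained model and two conformational states
chain <- toy$chain
topo  <- build_topology(chain)
ens <- make_two_state_ensemble(chain, topo, open_d = 30, closed_d = 26,
                               n_frames = 120, seed = 4,
                               params = sim_params(save_interval = 250))

# 3. a noisy, slightly aggregated (96/3/1 wt%) "experiment", open state
ex <- synthesize_experiment(ens$open, experiment_spec(seed = 11))
c(truth        = guinier_fit(ex$truth)$rg,
  contaminated = guinier_fit(ex$observed)$rg,
  corrected    = guinier_fit(extract_monomer_profile(ex$observed, ex$mixture))$rg)
#>        truth contaminated    corrected
#>     15.84668     16.22727     15.74106

# 4. screen a pooled open+closed trajectory against the observed profile
pool <- combine_trajectories(list(ens$open, ens$closed))
tab  <- score_frames(pool, chain, ex$observed)
rg_hat <- guinier_fit(extract_monomer_profile(ex$observed, ex$mixture))$rg
sel  <- select_models(tab, screening_criteria(7.0, rg_hat - 0.2, rg_hat + 0.2))
length(sel)
#> [1] 60

# 5. domain-conformation analytics of the selected models
gt <- geometry_table(chain, pool$frames[sel])
attr(gt, "summary")
#>        parameter      mean       sd
#> theta1    theta1  80.42229 2.609510
#> theta2    theta2 120.24060 3.951802
#> phi          phi  66.01972 5.251604
#> d              d  29.56889 1.208064
c(mean_D_selected = mean(gt$d), mean_D_open_truth = mean(geometry_table(chain, ens$open)$d))
#>   mean_D_selected mean_D_open_truth
#>          29.56889          30.00913
```

Reading the numbers: the generator realizes the requested U-shape geometry
to a fraction of a degree; 4% aggregates inflate the apparent Guinier Rg
from 15.85 to 16.23 Å and the correction brings it back within ~0.1 Å;
screening the mixed two-state pool against the open-state profile selects
60 of 240 frames whose mean edge-domain distance (29.6 Å) recovers the
generating open state (30.0 Å) within 1.5%, clearly separated from the
closed state (26 Å).

`run_pipeline()` wires the same stages (build → simulate → score → select →
analyze) behind a single configuration object, writing CSV tables, a
multi-model PDB of the selected ensemble, and a `manifest.json` with MD5
checksums that reproduce exactly under an identical seed.

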