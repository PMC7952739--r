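---
title: "Modelling multi-domain solution structure with coarse-grained sampling and SAXS screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multi-domain solution structure with coarse-grained sampling and SAXS screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgsaxs)
```

## The scientific problem

Multi-domain proteins such as ER-60 (ERp57/PDIA3, a four-domain
protein-disulfide-isomerase-family folding enzyme with the domain
architecture a--b--b'--a') do not adopt a single rigid conformation in
solution.  Their folded domains are connected by short flexible linkers, so
the *relative arrangement* of domains fluctuates, and that arrangement — not
the internal fold — is what changes between functional states such as the
oxidized and reduced forms of the catalytic CGHC motifs in the edge domains.
Small-angle X-ray scattering (SAXS) measures a rotationally averaged
intensity $I(q)$ that is sensitive to exactly this inter-domain geometry,
but a single 1D profile cannot be inverted to a unique 3D structure.

`cgsaxs` implements the standard resolution of that impasse:

1. sample a large, physically plausible conformational ensemble with a
   coarse-grained structure-based (Gō-type) model in which domains stay
   folded while linkers hinge;
2. compute a model SAXS profile for every snapshot (Debye formula);
3. keep only the snapshots whose profiles reproduce the measured one
   ($\chi^2$ and radius-of-gyration windows);
4. quantify the selected models through centre-of-mass (COM) descriptors:
   two inter-domain angles $\theta_1 = \theta_{a\text{-}b\text{-}b'}$,
   $\theta_2 = \theta_{b\text{-}b'\text{-}a'}$, the four-COM dihedral
   $\varphi$, and the edge-domain distance $D_{a\text{-}a'}$, plus
   superposition-averaged COM ("ball-and-stick") models and 2D frequency
   maps.

A fully seeded synthetic-data generator provides every input with known
ground truth, so the complete pipeline runs and is tested without any
external database or beamline data.

## The coarse-grained model

Each residue is one bead at its C$\alpha$ position.  The potential is the
sum of

* **backbone bonds** $k_b (r - r_0)^2$ with native lengths, for every
  neighbour pair (default $k_b = 100\,k_BT/\mathrm{\AA}^2$);
* **native angles** $k_\theta (\theta - \theta_0)^2$ and **native
  dihedrals** $k_\varphi [1 - \cos(\varphi - \varphi_0)] +
  \tfrac{k_\varphi}{2} [1 - \cos 3(\varphi - \varphi_0)]$, only where all
  member beads belong to folded regions (defaults
  $k_\theta = 20\,k_BT/\mathrm{rad}^2$, $k_\varphi = 1\,k_BT$); dihedrals
  whose native internal angles are within 15° of collinear are dropped
  because their reference value is ill-conditioned;
* **native contacts**, a 12-10 well
  $\varepsilon [5 (r_0/r)^{12} - 6 (r_0/r)^{10}]$ of depth
  $\varepsilon = 0.8\,k_BT$ at the native separation, for intra-unit bead
  pairs with $|i - j| \ge 4$ and native C$\alpha$ distance $\le 6.5$ Å.
  The b and b' domains share one folded unit — their interface keeps its
  contacts and the pair moves as one rigid body, consistent with the
  near-identity of the b--b' region across independently solved structures —
  while no contacts ever cross the a / b--b' / a' boundaries;
* **flexible beads** (the inter-domain linkers and, for ER-60, the
  Gln490--Leu505 C-tail) receive no structure-based term beyond their
  backbone bonds; a weak *generic* angle
  ($\theta_0 = 120°$, $5\,k_BT/\mathrm{rad}^2$) prevents unphysical chain
  collapse without referencing the native geometry;
* **excluded volume**, a purely repulsive $(\sigma/r)^{12}$ with
  $\sigma = 4$ Å for pairs $|i-j| \ge 4$ that are not native contacts
  (1-2/1-3/1-4 pairs are governed by the bonded terms), cut and shifted at
  $2.5\sigma$;
* **Debye–Hückel electrostatics**
  $l_B q_i q_j e^{-r/\lambda_D} / r$ between charged beads, with the
  screening length computed from the ionic strength (7.9 Å at 150 mM,
  300 K, $\epsilon_r = 78$) and the interaction cut and shifted at 40 Å.
  Linker/tail beads always carry their full titratable charge (+1 Lys/Arg,
  −1 Asp/Glu); folded-region beads are charged only when solvent-exposed
  under a burial proxy (more than 14 neighbour C$\alpha$ within 10 Å counts
  as buried), with an `all-titratable` mode as the simple alternative.
  Histidine is neutral (pH 7.4).  The proxy stands in for surface-charge
  assignment methods that fit bead charges to the all-atom electrostatic
  field; it preserves the qualitative feature that buried titratable
  residues do not contribute;
* an optional short-range **hydrophobic** 12-10 well (depth $0.2\,k_BT$ at
  6 Å) between beads of hydrophobic residues, off by default: published
  parameter sets for this term vary, so it is exposed as a documented toggle
  rather than silently included.

Energies are in units of $k_BT$ at 300 K, lengths in Å, bead masses 1, time
in reduced units.

### Dynamics

Sampling uses the BAOAB discretization of underdamped Langevin dynamics
(friction $\gamma = 1$ per reduced time, default step $dt = 0.005$).  BAOAB
was chosen for its well-known configurational accuracy at practical step
sizes; with the default step the mean kinetic temperature is within the
test tolerance (3%) of the 300 K target, and in the frictionless limit with
$dt = 0.001$ total energy drifts by less than 0.1% over $10^4$ steps.  The
random stream is an explicit Box–Muller transform over `mt19937_64`, seeded
per run, so trajectories are bitwise reproducible across platforms.  The
production protocol mirrors a many-run design (independent runs pooled by
`run_sampling()`, snapshots every `save_interval` steps); the package
default of 8 runs × 10⁶ steps saving every 500 is a desk-scale analogue of
a cluster-scale 40 × 10⁸ / 5000 protocol, which the bookkeeping helper
`sampling_plan_frames()` shows yields 800,000 snapshots.

## Scattering

`debye_profile()` evaluates the Debye double sum
$I(q) = \sum_{ij} f_i f_j \sin(q r_{ij})/(q r_{ij})$ exactly (compiled
kernel; the test suite pins it to a brute-force double sum at $10^{-10}$
relative).  Per-bead amplitudes default to uniform $f_i = 1$ — when the
screening target is itself a bead-model profile this keeps model and target
on exactly the same footing — with a per-residue electron-count mode as an
option.  No hydration-layer or excluded-solvent term is applied; for
bead-vs-bead comparisons it would cancel, and for real data it is absorbed
to first order by the fitted scale.

`guinier_fit()` performs the standard linear fit of $\ln I$ against $q^2$
under $I(q) = I(0)\exp(-R_g^2 q^2/3)$, iterating the window until
$q R_g \le 1.3$ (the conventional Guinier validity limit).
`distance_distribution()` histograms the model pair distances ($P(r)$,
unit area, with $D_{max}$ the largest pair distance) — this is the
model-side quantity; indirect-transform estimation from measured data is
out of scope.  `chi_square()` uses
$\chi^2 = \frac{1}{N-1}\sum_k [(c I_m(q_k) - I_t(q_k))/\sigma_k]^2$ with
the optimal multiplicative scale $c$ in closed form and no additive offset
unless requested, restricted to $q \le 0.25\,\mathrm{\AA}^{-1}$ by default
(the information-rich range for a particle of this size; beyond it the
bead-level model is not meaningful).

### Aggregate-corrected monomer extraction

Real samples retain a small oligomeric fraction even after size-exclusion
chromatography, and because scattering weights species by mass, a few
percent of dimer/trimer visibly inflates the apparent $R_g$.  Given
independently measured weight fractions (e.g. from analytical
ultracentrifugation), `extract_monomer_profile()` models each $k$-mer at
the Guinier level — forward intensity proportional to $w_k M_k$ and
$R_{g,k} = R_{g,1} k^{1/3}$ (density-preserving compact growth) — subtracts
that contribution and rescales by $1/w_1$, refining the monomer $R_g$ once.
This is a deliberately simplified, closed-form variant of
ultracentrifugation-informed profile decomposition: it reproduces the
contract (corrected $R_g$ moves down, towards the monomer truth) and, on
the synthetic data, recovers the uncontaminated Guinier $R_g$ to about 1%.
Its known bias is that real aggregates are not exact Guinier spheres, so a
residual error at the fraction-of-a-percent level remains even with exact
weight fractions.

## Screening and geometry analytics

`score_frames()` computes, per snapshot, the coordinate $R_g$ and the
scale-fitted $\chi^2$ against the target; `select_models()` applies strict
inequalities $\chi^2 < \chi^2_{max}$ and $R_{g,min} < R_g < R_{g,max}$
(printed thresholds in this field are stated as strict; in floating point
ties do not arise, but the contract is fixed).  Coordinate $R_g$ is the
default windowing variable because it is deterministic and noise-free; a
flag switches to the Guinier $R_g$ of the computed profile.

Geometry descriptors use equal-mass COMs of the folded beads of each domain
(flexible linkers and tails are excluded: they carry no structural signal
for the inter-domain arrangement and would only blur the COMs).  The
dihedral follows the right-handed convention with the sign exposed;
reporting can flip handedness where a reference geometry was published with
the opposite sign.  `averaged_com_model()` superposes every frame onto a
reference over the b--b' C$\alpha$ beads (Kabsch, reflection-corrected) and
averages each domain COM; `com_shift()` then measures how far an averaged
domain position moves between two ensembles — the compact summary of a
state-dependent conformational change.  `frequency_maps()` produces the
paired, unit-normalized 2D histograms and their difference map.  Default
bin widths are 5° for angles, 10° for the dihedral and 1 Å for distances —
comparable to the ensembles' own standard deviations, so the maps are
neither empty nor over-smoothed.

## The synthetic study

`make_toy_protein()` builds a four-domain U-shaped chain with known ground
truth.  Each domain is a maximally collapsed self-avoiding walk — a
serpentine path through a jittered cubic lattice at the C$\alpha$ spacing
(3.8 Å) — because at $\varepsilon = 0.8\,k_BT$ per contact a blob is only
thermodynamically folded if its contact network is as dense as a real
globular domain core (4–5 contacts per bead); looser random-walk blobs melt
at 300 K.  Among admissible jitter draws the generator keeps the one with
the densest contact network, deterministically from the seed.  The four
blobs are placed so that their COMs realize a requested
$(\theta_1, \theta_2, \varphi, D)$ exactly (internal-coordinate
construction; the arm lengths are solved numerically to meet $D$), oriented
so chain termini face their junction partners, joined by two-bead flexible
linkers at the a--b and b'--a' hinges (b and b' are sequence-contiguous and
share a folded unit, mirroring the rigid central pair), and relaxed by
L-BFGS-B under a provisional topology with harmonic COM restraints.  The
generator verifies its own output — realized angles within 2° and $D$
within 2% — and errors otherwise.  The default target
$(72°, 132°, 62°, 28\,\mathrm{\AA})$ keeps the crystal-like U-shape twist
while choosing $D$ so the hinge gaps are spannable by the linkers at
physical bond lengths; larger $D$ (e.g. a 54.5 Å crystal-analog) is
reachable by raising the domain size and linker length.

`make_two_state_ensemble()` emulates two redox-like states by Langevin
sampling under a harmonic restraint on the a--a' COM distance (default
stiffness $3\,k_BT/\mathrm{\AA}^2$, 4000 equilibration steps discarded).
The restraint metadata is recorded on the trajectories so tests can keep
biased data out of production paths.  Open/closed targets of 30 / 26 Å
around the native 28 Å give two clearly separated but overlapping states —
the same qualitative situation as a modest redox-dependent expansion.

`synthesize_experiment()` turns an ensemble into an "observed" profile:
the truth is the ensemble-averaged Debye profile of the monomer;
dimer/trimer contaminants (default 3 / 1 wt%, i.e. a 96% monodisperse
sample) are rigid copies of the median-$R_g$ frame displaced along its
principal axis so that the $k$-mer's coordinate $R_g$ equals
$R_{g,1} k^{1/3}$ — the same density-preserving growth law the correction
model assumes, which makes the generator and the correction a consistent
pair; multiplicative Gaussian noise with relative standard deviation
$\sigma(q)/I = 0.01 + 0.05\,q$ matches how SAXS uncertainties grow with
angle, and the $\sigma$ column equals that noise level.

### What the synthetic data does and does not show

The generator reproduces the *statistical structure* of the real problem:
folded domains with hinge flexibility, two states differing mainly in
$D_{a\text{-}a'}$, realistic noise scaling, and mass-weighted low-level
aggregation.  It does not emulate instrument smearing, inter-particle
structure factors, hydration contrast, sequence-specific contact energetics,
or aggregates of irregular geometry.  Passing the closed-loop tests
therefore demonstrates that the pipeline's mathematics and plumbing recover
known ground truth under its own model assumptions — it does not certify
accuracy on any particular real data set.

## Numerical choices and edge cases

* Frames are saved every `save_interval` steps starting after the first
  interval; frame count is `floor(n_steps / save_interval)`.
* A native-contact is counted as formed when $r < r_0 + 2$ Å (the common
  convention for C$\alpha$-level $Q$); the trajectory-mean per-unit $Q$
  stays above 0.8 at 300 K with default parameters while
  $D_{a\text{-}a'}$ fluctuates by 1–3 Å — transient partial openings of an
  edge domain do occur, which is the expected behaviour of a marginally
  stable Gō blob rather than a numerical artifact.
* Coincident beads (r = 0) in any interaction raise an error rather than
  producing infinities; a numerical blow-up during dynamics aborts with the
  step index.
* Superposition uses SVD with explicit reflection correction
  (det = +1 always).
* Dihedral forces skip transiently collinear quadruples (cross-product
  norm below $10^{-10}$) instead of aborting a long run.
* Empty screening selections are reported (`empty-selection` status in the
  pipeline manifest), not errors.
* Problem sizes in the shipped tests and acceptance script — 124-bead toys,
  $10^4$–$10^5$-step trajectories, 120-frame ensembles — were chosen as the
  smallest sizes at which every statistical assertion has comfortable
  margin; all scale factors are plain function arguments.

## Known limitations

* The coarse-grained parameterization is generic (uniform contact depth,
  no sequence-flavoured contact energies or sequence-dependent local
  potentials); it preserves fold stability and hinge flexibility but not
  residue-specific energetics.
* The 0.8 $k_BT$ contact depth leaves small single domains close to their
  melting point; very small toys (≲ 12 beads per domain) are not stable at
  300 K and are only used for algebraic tests, not physics claims.
* Uniform form factors ignore residue contrast; the per-residue mode is a
  crude electron-count proxy, not an atomic form-factor calculation.
* The monomer extraction assumes compact aggregates of known weight
  fractions; it is not a substitute for a full multi-component
  decomposition when aggregation is heavy or irregular.
* The bundled mature ER-60 sequence is a reconstruction of the canonical
  ERp57/PDIA3 mature chain for mass bookkeeping; its computed average mass
  agrees with the published calculated value to within 1 Da, and the
  oxidized-minus-reduced shift (−4.03 Da for two disulfides) is exact by
  construction.
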