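---
title: "A hemiconcerted allosteric model of calmodulin signalling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hemiconcerted allosteric model of calmodulin signalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Calmodulin (CaM) is modelled as two structurally autonomous lobes (N and C),
each carrying two identical calcium-binding sites and each switching between
a closed (T) and an open (R) conformation in a concerted, two-state fashion.
The lobes transition independently of one another — the *hemiconcerted*
assumption — so a CaM molecule occupies one of the classes TT, TR, RT, RR
(first letter: N lobe). Three quantities parameterize each lobe:

* the allosteric constant `L = [T]/[R]` at zero calcium,
* the affinity ratio `c = K_R/K_T < 1` (calcium binds the open lobe more
  tightly),
* the closed-state per-site dissociation constant `K_T`, with a
  conformation-independent association rate `kon`.

Calcium binding does not *gate* opening; it *biases* it. Each bound ion
multiplies the open/closed equilibrium constant by `1/c`, and the kinetic
realization splits this shift symmetrically between the two directed rates:

```
k_TtoR(n) = k0 * c^(-n/2)        k_RtoT(n) = k0 * L * c^(n/2)
```

so opening accelerates *and* closing decelerates as ions bind. Off-rates
follow `koff_T = kon * K_T`, `koff_R = koff_T * c`. With the lumped
occupancy bookkeeping (statistical factors `2 kon` for the first binding and
`2 koff` for release from the doubly occupied lobe — exact for identical
sites), every bind–open–unbind–close cycle closes exactly;
`validate_detailed_balance()` asserts this on the generated network, and the
package computes off-rates from `(kon, K, c)` products rather than rounded
catalogue values precisely so that the cycles close to machine precision.

Binding partners read conformation, not occupancy:

* **CaMKII** and **phospho-CaMKII** bind RR CaM only, with one affinity
  regardless of how many ions are bound, and hold both lobes open while
  bound (a bound-TR species would contradict the binding rule).
* **Calcineurin (CaN)** binds RR CaM only after its B subunit has loaded
  four calcium ions sequentially; the CaM-bound form is the active
  phosphatase.
* **Neurogranin (Ng)** binds CaM whose C lobe is closed (TT and RT), holds
  the C lobe closed, and leaves the N lobe free to transition; its affinity
  is assumed blind to the N-lobe state (`e = 1`).

Calcium binding and release continue on conformation-locked lobes with the
off-rate of the locked conformation. Calcium homeostasis is a constant leak
(3.85e-6 M/s) against a Michaelis–Menten pump (Vmax 1e-4 M/s, Km 2e-6 M),
which fixes basal free calcium at `leak*Km/(Vmax - leak) = 8.0e-8` M
independently of the buffers. A calcium spike is a zero-order injection of
1926 ions over 8 ms into the 1e-15 L compartment (~4.0e-4 M/s while open);
into the equilibrated full model this yields a free-calcium peak of ~0.8e-6
M with a ~30-40 ms half-life, which the single-spike analysis reproduces.

All amounts are molar concentrations in a fixed, well-mixed 1e-15 L
compartment; molecule counts are derived through Avogadro's number only for
reporting (80 uM CaMKII corresponds to ~48,200 monomers).

## Parameters that matter

The reference constants ship in `inst/extdata/reference_params.yaml` and as
the defaults of `cam_params()`, `partner_params()` and `model_config()`.
The asymmetry between the lobes drives everything downstream: the N lobe is
flexible (`LN = 299`) but barely rewarded for opening (`cN = 0.01`), while
the C lobe is rigid (`LC = 195865`) but strongly rewarded (`cC = 5e-5`);
calcium association is 100-fold faster on the N lobe (1.22e10 vs 1.22e8
/M/s) with correspondingly faster release. At spike-train frequencies this
makes the C lobe the low-frequency integrator (its TR window peaks near 20
Hz in the CaM-only model) and the N lobe the high-frequency one.

Partner affinities span five orders of magnitude — Kd 1.2e-6 M (Ng),
3.8e-7 M (CaMKII), 3.26e-9 M (CaN), 2.3e-12 M (phospho-CaMKII) — so the
*order* in which partners capture CaM released during a spike train, and
how hard it is to reclaim, is the core competitive mechanism.

## The CaMKII ring layer

CaMKII subunits trans-autophosphorylate within six-membered rings: an
active (CaM-bound and/or phosphorylated) monomer can only be phosphorylated
if a ring neighbour is also active. For a ring with `k` actives the
probability that a focal active monomer has an active neighbour is
`1 - choose(6-k, 2)/choose(5, 2)` (`ring_neighbor_prob_exact()`), and for
`m` actives placed uniformly over all rings the expectation is a
hypergeometric average of that quantity (`neighbor_prob_expected()`). The
Monte-Carlo construction (`build_neighbor_curve()`: random placements on a
1% active-fraction grid, seed recorded) estimates exactly this expectation,
so the *default* surrogate — the degree-5 polynomial embedded in the rate
law — is fitted to the exact expectation curve at the system's monomer
count instead of to one MC realization: the simulations lose an avoidable
noise source and gain reproducibility, while the MC generator remains
available and is property-tested against the expectation (within 3
standard errors at every grid point for small systems).

Inside the ODE the multiplier is evaluated continuously from the current
species totals (assignment-rule style); the phosphorylation rate of each
CaM-bound, non-phosphorylated monomer is `6.3/s x surrogate(active
fraction)`. Dephosphorylation is a single Henry–Michaelis–Menten flux with
total CaM-bound CaN as the enzyme (kcat 0.8 /s, Km 2e-5 M), applied to the
pooled phosphorylated monomer concentration — free and CaM-bound alike,
since nothing in the biochemistry suggests the phosphosite is shielded
while CaM is bound, and pooling keeps the MM form well defined.

### Bistability of the phosphorylation layer

With this construction the phosphorylation layer is a bistable switch, and
the package's own analyses show a 300-spike 100 Hz train flipping it ON:
during the ~3 s train most CaM binds CaMKII and the per-monomer
phosphorylation rate (~6.3 x 0.6 /s) converts essentially the whole bound
pool; afterwards, monomers that are dephosphorylated while still CaM-bound
are rephosphorylated (~4 /s) faster than they release CaM (1.1 /s), and the
phospho-CaMKII pool (Kd 2.3 pM) sequesters CaM away from CaN, collapsing
the dephosphorylation flux below its basal value. The locked state holds
~14,000 phosphorylated monomers (~30% of the pool) through the 3000 s
recording window, and splitting the train into three bursts changes the
integrated CaMKII activity by only a few percent. Whether the biological
switch behaves this way depends sharply on the effective neighbour
coefficient at intermediate active fractions; a coefficient an order of
magnitude smaller yields the opposite regime (a transient pool that decays
within a minute). Both regimes are reachable through
`model_config(surrogate = ...)`, and the default is the combinatorially
principled curve described above. Readers comparing against sustained
pools of a few hundred monomers should treat that comparison as sensitive
to this layer's calibration.

## Numerical choices

* **Solver.** The network is extremely stiff — conformational rates reach
  6.2e10 /s and the Ng association rate is 1e14 /M/s — and lsoda's
  stiff/non-stiff switching fails mid spike train. All integration uses
  vode with `mf = 22` (BDF, internally generated full Jacobian), default
  `rtol = 1e-8`, `atol = 1e-14` M; the driver restarts the stepper from the
  last accepted state if it stalls.
* **No concentration clamping.** The right-hand side evaluates plain mass
  action even for tiny negative excursions: clamping at zero plants a
  derivative kink exactly where trace species sit, which defeats the BDF
  error test; unclamped mass action is self-correcting (`dy/dt ~ -k y`).
* **Events.** Spike injections are constant zero-order rates within their
  8 ms windows; the integrator is restarted exactly at every window edge,
  so it never steps across a discontinuity. Spike `k` of an `f` Hz train
  starts at `k/f`.
* **Storage grid.** Trajectories are stored adaptively (9 points per
  injection window, ~20 ms spacing between spikes, 1 s along the
  post-train tail after a dense first 10 s); metrics integrate
  trapezoidally on this grid, and refining it changes activated areas by
  <0.1% (tested).
* **Problem sizes.** The shipped analyses use 300-spike protocols with a
  3000 s recording window (extended to 60 s past the last spike for slow
  trains), 5-frequency conformation scans {3, 10, 20, 30, 50} Hz, 8-point
  BCM scans, 10-18 point titration grids, and 10-12 replicate fits; each
  full-model spike-train simulation completes in roughly a second.
* **Equilibration** runs 5000 s and checks the end-state relative
  derivative norm; the tolerance (1e-4) accommodates the sub-picomolar
  basal phospho pool whose intrinsic relaxation time (1/koff ~ 3 h) exceeds
  any practical window. Equilibration carries a ~1e-5 relative solver
  offset on conserved totals, which the conservation tests measure against
  the trajectory's own start.
* **Fitting.** Bounded Levenberg–Marquardt on log10 parameters
  (minpack.lm), with the finite-difference step widened (`epsfcn = 1e-6`)
  so the Jacobian is not swamped by ODE solver noise when the forward model
  re-equilibrates the network. Single-constant fits on noise-free synthetic
  curves recover their generating values to <0.1%; joint (cC, LC) fits on
  noisy replicates reproduce the near-perfect anticorrelation of their
  log-estimates (slope ~ -1.9): the steady-state curves constrain a
  product-like combination of the C lobe's rigidity and its opening reward,
  not the pair.

## The synthetic-data generator

`gen_titration()` / `gen_chelation()` forward-simulate the package's own
steady-state titration (5 uM CaM, 50 uM partner, free calcium on the
x-axis) and stopped-flow chelation protocols (10 mM EGTA into a CaM/Ca
premix; 150 uM quin-2 variant), then add i.i.d. Gaussian noise on the
observable scale, truncated to [0, 1], with the seed recorded in the
dataset. This emulates the *statistical* structure fluorescence-derived
saturation data: it does not emulate instrument artifacts, bleaching,
heteroscedastic noise, or titration-point correlation. Passing the recovery
tests therefore shows the estimation machinery is consistent — not that the
constants are identifiable from any particular laboratory dataset.

Chelator kinetics are not part of the reference parameter set; the defaults
(EGTA kon 1.5e6 /M/s, Kd 70 nM; quin-2 kon 5e8 /M/s, Kd 60 nM) are
literature-typical values exposed through `chelator_spec()`. The quin-2
observable is normalized to the total calcium in the system.

## Design choices at genuinely open points

* **Dephosphorylation substrate**: pooled over free and CaM-bound
  phospho-monomers (see above).
* **CaN's own calcium**: the four B-subunit ions stay loaded while CaN is
  CaM-bound; release requires dissociating from CaM first. Nothing in the
  binding scheme forces this, but the alternative would create unbalanced
  CaM-bound loading chains for a sub-second residence time.
* **Recording window**: 3000 s from stimulation onset, never ending earlier
  than 60 s after the last spike, so slow trains are not truncated
  mid-train and fast trains match the standard window.
* **Autophosphorylation at zero active fraction** is defined as zero (there
  is no active monomer to phosphorylate), keeping the embedded rate law
  continuous at the origin.
* **SBML**: the export writes Level 3 Version 2 with explicit MathML for
  every rate law and a package annotation carrying the solver-facing arrays
  at full precision, so a round-trip reconstructs the network exactly; the
  annotation is what `import_sbml()` trusts, and the reader rejects files
  whose MathML and annotation disagree.

## Known limitations

Single well-mixed compartment: no postsynaptic-density subcompartment, no
CaMKII translocation or clustering, and therefore a global active fraction
where a spatial model would see locally enriched ones. No Ng
phosphorylation by PKC (Ng only binds and releases CaM). The
phosphatase cascade is collapsed into direct CaN action on phospho-CaMKII.
Dodecamers are treated as independent hexamer rings. The phosphorylation
layer's bistability calibration is the dominant structural uncertainty (see
above). LTP/LTD statements reduce to the sign of the BCM value — the
difference of kcat-scaled activated areas — and carry no claim about
downstream synaptic physiology.
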