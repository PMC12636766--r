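---
title: "Simulating protein interaction networks in a near-critical membrane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating protein interaction networks in a near-critical membrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Plasma membranes of animal cells appear to be tuned close to a liquid-liquid
miscibility critical point: below it, lipids demix into coexisting
liquid-ordered (lo) and liquid-disordered (ld) phases; just above it, large
transient domains persist up to a correlation length that diverges at the
critical point. `critppi` asks how this critical solvent shapes the outcome
of protein-protein interaction (PPI) networks embedded in the membrane.

The membrane is an $L \times L$ periodic square lattice. Each lipid site
carries an Ising spin $s_i = \pm 1$ identifying its phase preference
(we use $+1$ for lo, $-1$ for ld). Proteins are disk-shaped inclusions: a
radius-$r$ disk occupies all integer offsets with $dx^2 + dy^2 \le r^2$, and
its boundary sites carry a uniform spin $b = \pm 1$ — the component's domain
preference — that couples to adjacent lipid spins. The total energy is

$$ H = H_\mathrm{mem} + \sum_i H_\mathrm{int}^{(i)}, \qquad
H_\mathrm{mem} = -J \sum_{\langle uv \rangle \in \mathrm{lipid}} s_u s_v,
\qquad
H_\mathrm{int}^{(i)} = -J_\mathrm{int} \sum_{\langle uv \rangle \in
\partial i} b_i \, s_v. $$

Interior disk sites carry no spin and no energy; only the boundary
interacts. Where the boundaries of two distinct disks touch, the pair
contributes $-J_\mathrm{int} \, b_i b_j$ per adjacent boundary pair, so
disks with like preference attract consistently with the domain-mediated
forces the lipids transmit — the Hamiltonian leaves this case open, and we
chose the only sign consistent with those forces.

Temperature enters as the rescaled temperature $\tau = T / T_c$ of the
*bare* membrane, with $T_c = 2J / \ln(1 + \sqrt{2})$ the exact critical
temperature of the square-lattice Ising model (so
$\beta = 1/(\tau \, T_c)$, $k_B = 1$). Cells can move $\tau$ either by
changing temperature or by composition changes that shift $T_c$. The second
control axis is the magnetization $m = \langle s_i \rangle$ — the lo/ld
area-fraction imbalance, moved along tie lines (e.g. by cholesterol loading
or depletion). We realize $m$ as an exact integer composition at
initialization; conserved dynamics preserve it exactly thereafter.

## Dynamics

Lipids evolve by Kawasaki spin exchange: each sweep makes $L^2$ attempts in
which a random site and a random neighbour, if both lipids with unequal
spins, swap with the Metropolis probability $\min(1, e^{-\beta \Delta E})$.
This conserves composition locally (model B), which is what makes $m$ a
meaningful control parameter. Sites are drawn independently at random for
each attempt (random sequential updating); a fresh permutation per sweep
would equally avoid deterministic-update artifacts but costs an extra
$O(L^2)$ shuffle in the innermost loop for no statistical benefit.

Inclusions translate to neighbouring lattice sites. A move is rejected
outright if the translated footprint would overlap another inclusion.
Otherwise lipids on the leading edge are relocated to the vacated
trailing-edge sites through a deterministic mirror mapping (the offset
component along the move axis is negated). Because the mapping is an
involution and disk footprints are reflection-symmetric, the reverse move
is the exact inverse of the forward move, so Metropolis acceptance on the
full local energy change preserves detailed balance. Each inclusion makes
$C$ translation attempts per sweep ($C = 0.1$ by default — proteins diffuse
slower than lipids), interleaved at uniformly random points within the
sweep's lipid attempts.

With reactions disabled, the joint distribution over spins and inclusion
positions is therefore exactly Boltzmann. The package ships an exhaustive
enumeration oracle (`enumerate_boltzmann()`) that verifies this on tiny
systems: the Kawasaki sampler on a $3\times3$ fixed-composition lattice and
the joint position-and-spin ensemble of a $4\times4$ lattice with one
inclusion both match exact enumeration to total-variation distances of a
few times $10^{-2}$ at $10^6$ sweeps.

## Reactions

A network declares component types (radius, copy number, mobility, states
with a boundary preference per state) and contact rules. After the movement
phase of each sweep, every four-adjacent (actor, substrate) pair matching a
rule fires with probability `rate` (default 1): the substrate's state
becomes the rule's product state. The actor never changes. Two scheduling
choices avoid order artifacts, since the underlying physics does not order
simultaneous contacts: contacting pairs and, within a pair, eligible rules
run in randomized order, and a substrate is modified at most once per
sweep.

If the product state carries a different boundary preference
(partition switching, palmitoylation-like), the disk's boundary spins flip
immediately, *without* a Metropolis test. This is deliberate: the reaction
rate does not depend on the configuration of bounding lipids, which is
precisely the detailed-balance violation that lets these networks drive
the spatial configuration out of equilibrium. With static preferences the
state labels are passive, and the package keeps movement and reactions on
two independent RNG streams so that enabling reactions provably leaves the
configurational trajectory bit-identical.

The effective rate of a reaction is its bare rate times the contact
frequency of its two components — and the contact frequency is what the
critical solvent controls. The diagrammatic predictor `sign_predict()`
formalizes this: for each rule, the contact sign is $+1$ if actor and
(pre-reaction) substrate prefer different phases (contact rate rises with
$\tau$ as domains dissolve) and $-1$ if they share a phase; multiplied by
the rule's activity sign ($\pm 1$ for activating/deactivating) it gives the
rule's contribution to $\partial f_A / \partial \tau$. If all rules agree
the common sign is the prediction, otherwise the diagram is indeterminate.

## Analysis layer

`run_scan()` runs seeded replicates across a grid of $\tau$, $m$, or
component radius and reports the steady-state active-target fraction
$f_A$ (mean over post-burn-in records). Activity response curves are
summarized by the generalized logistic fit

$$ f_A(\tau) = \frac{R - L}{2} \tanh\!\left(\frac{\tau - \tau_0}
{2\,\Delta\tau}\right) + \frac{R + L}{2}, $$

fitted by bounded Levenberg-Marquardt least squares
(`minpack.lm::nlsLM`), with asymptotes constrained to $[0, 1]$ for
activity data and Wald confidence intervals from the fit covariance.
$\Delta\tau$ is the growth width — smaller means the network is a sharper
sensor of $\tau$ — and $\tau_0$ the point of steepest activity change.
Starting values come from the data (edge means for the asymptotes, the
steepest finite-difference segment for $\tau_0$); flat data is returned
with equal asymptotes and an `unidentifiable` flag rather than an error.

`cross_correlation()` reports the radially averaged, density-normalized
cross-correlation $g(r) = \langle \rho_A(x)\rho_B(x+r)\rangle /
(\langle\rho_A\rangle\langle\rho_B\rangle)$ between the footprint
indicator fields of two component types, computed by FFT over periodic
displacements; $g \equiv 1$ means no association. The normalization by the
product of mean densities is a choice (the qualitative comparisons it
feeds are invariant to it).

`detect_pockets()` operationalizes the far-from-equilibrium "pocket"
domains that partition-switching networks can form: ordered domains packed
with activated targets and activators but kinetically excluding
inactivators. Because the phenomenon is defined visually in the first
instance, two detectors are reported side by side so that no single
heuristic is load-bearing: a *structural* detector (four-connected ordered
clusters — ordered lipids plus embedded order-preferring inclusions —
containing at least one active target and one activator but no
inactivator, persisting across $\ge 3$ consecutive snapshots with $\ge
50\%$ site overlap) and a *distributional* detector (replicates whose
$f_A$ exceeds the replicate median by more than 5 MADs). All thresholds
are arguments.

## Default study conditions and problem sizes

The default geometry is a $64 \times 64$ lattice with 10 activators, 10
inactivators and 20 two-state targets (about 1% site coverage at radius
0), $J = J_\mathrm{int} = 1$, $C = 0.1$, firing rate 1 per contacting pair
per sweep, and $2 \times 10^5$ sweeps per run with the first half
discarded as burn-in. Copy numbers are a package choice: dilute enough
that inclusions perturb the bare-membrane critical point only slightly,
dense enough that contact statistics converge in a short run. The
bundled YAML networks (`static_partitioning_network.yaml`,
`partition_switching_network.yaml`) encode the two canonical cascades: the
static one (activator prefers ld; inactivator and target prefer lo) and
the partition-switching one (activator and inactivator prefer lo; the
target prefers ld when inactive and lo when active).

The test suite runs the same studies at reduced scale — $3 \times 10^4$
to $1.5 \times 10^5$ sweeps, 3-8 replicates, $L = 48$-$64$ — sizes chosen
so each statistical assertion retains power while the whole suite stays
fast; the full-scale scan lives in `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Rounding of the up-spin count at initialization is half-away-from-zero,
  so $m_\mathrm{target} = 0$ on an odd lipid count biases to $+1$ by half
  a spin rather than truncating downward.
* Metropolis acceptance uses a precomputed $e^{-\beta k}$ table when both
  couplings are small integers (the common case), and falls back to `exp`
  otherwise.
* Inclusion moves recompute the energy over the union of old and new
  footprints before and after the move and revert on rejection; this is
  exact for any radius and avoids bespoke incremental bookkeeping.
* A lattice so crowded that an inclusion cannot be placed after a bounded
  number of uniform draws is reported as an error naming the component,
  before any sweep runs.
* Zero-sweep runs return the initial record only; `burn_in` must leave at
  least one record.
* Reproducibility: one master seed per run; the initializer, the movement
  stream and the reaction stream use seeds derived from it by a counter
  scheme, and scans derive one seed per (value, replicate) cell the same
  way. Identical config and seed give byte-identical results.

## What the synthetic conditions do and do not show

Everything here is synthetic: the membrane is a two-component Ising
caricature of a many-lipid mixture, inclusions are rigid disks with
uniform boundaries, reaction kinetics are single-step contact rules with
no explicit time calibration, and hydrodynamic flows are absent. Passing
tests therefore demonstrate the *mechanism* — domain-mediated contact
rates make network output sensitive to $\tau$ and $m$ near criticality,
more strongly for larger components, and partition-switching rules can
kinetically trap pockets — not quantitative rates for any real signaling
pathway. Mapping to real membranes needs the lattice constant
($\approx 1$ nm), a diffusion-based sweep-to-time calibration, and real
partition coefficients, none of which the package claims.

Two quantitative caveats discovered and characterized by the package's own
validation suite are worth stating plainly:

* **Ensemble constraint at criticality.** At $\tau = 1$ the bare-membrane
  energy per site under *conserved* composition ($m = 0$ fixed) converges
  to about $-1.35 J$ on a $64^2$ lattice, not to the unconstrained Onsager
  value $-\sqrt{2} J \approx -1.414 J$. This is not an equilibration or
  correctness failure: the unconstrained critical ensemble has a broad
  magnetization distribution ($\langle |m| \rangle \sim L^{-1/8} \approx
  0.6$ at $L = 64$), and pinning $m = 0$ removes exactly the partially
  ordered configurations that dominate it. The package's nonconserved
  (Glauber) testing dynamics, which sample the unconstrained ensemble,
  reproduce the Onsager value to about 1% on the same lattice — the
  calibration is right; the conserved ensemble is genuinely different at
  criticality, and converges to the unconstrained one extremely slowly
  with $L$.
* **Slow steady states.** Pocket formation frequency depends on slow
  kinetics; reduced-scale batteries detect the phenomenon's existence
  (the structural detector fires in a substantial fraction of
  partition-switching replicates and never in static-partitioning
  batteries), not its asymptotic rate. In particular, the *distributional*
  signature — replicates more than 5 MADs above the median — requires
  pockets to approach saturation, which happens on $\sim 10^6$-sweep
  timescales; in reduced-scale batteries the best separation we observe
  is about 4.6 MADs.
* **Coverage confounds the size comparison.** Scanning component radius at
  fixed copy numbers changes the inclusion area coverage (1% at $r = 0$ to
  13% at $r = 2$ for the default network on $64^2$), which shifts the
  effective critical temperature upward with radius (fitted inflections
  1.01, 1.10, 1.20) and broadens the largest disks' response. The
  growth-width decrease from $r = 0$ to $r = 1$ is robust; between $r = 1$
  and $r = 2$ the coverage effect dominates at this lattice size and the
  fitted widths are statistically indistinguishable or inverted.
  Disentangling size from coverage cleanly needs lattices several times
  larger.
* **Mobility and steady state.** The translation-attempt rate `C` cannot
  change the equilibrium configurational ensemble of a static-partitioning
  network — it only sets how fast the ensemble is reached. Large-radius
  studies (the composition scans, the radius scans) therefore run at
  `C = 1`: at the default `C = 0.1`, radius-3 inclusion arrangements are
  still relaxing after $3 \times 10^5$ sweeps and transient activities can
  even trend opposite to their steady-state values.

## Known limitations

Disks only (no shapes, no rotations); fixed copy numbers (no
insertion/deletion or complex formation); two-state components are all the
bundled networks exercise, though the schema allows more; no
hydrodynamics; no physical time units. Contact is four-adjacency;
diagonal contact is not counted (the tightest reading of "in contact",
and the same convention as the phase-cluster connectivity used by the
pocket detector).
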