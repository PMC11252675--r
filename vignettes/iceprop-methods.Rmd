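---
title: "Modelling intracellular ice formation and propagation in small tissue constructs"
author: "iceprop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{iceprop methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iceprop)
```

## The model

Freezing injury in tissues is driven by intracellular ice formation (IIF),
which is stochastic at the single-cell level and contagious between cells in
contact.  `iceprop` models a tissue construct as a set of spherical cell
agents with a contact graph.  An unfrozen cell $j$ with $k_j$ frozen
neighbours forms ice at total rate

$$J_j \;=\; J^i(t)\,\bigl(1 + k_j\,\alpha\bigr),$$

where $J^i$ is the spontaneous (neighbour-independent) nucleation rate and
$\alpha = J^p/J^i$ is the non-dimensional ratio of the propagative to the
spontaneous mechanism.  Because every rate is proportional to $J^i$, the
process becomes homogeneous in the non-dimensional time

$$\tau(t) = \int_0^t J^i\,\mathrm{d}t',$$

in which an isolated cell freezes at unit rate and the whole construct is a
continuous-time Markov chain on the $2^N$ frozen-cell subsets.  All
stochastic machinery in the package works in $\tau$; single-cell biophysics
supplies the monotone map between $\tau$, time and temperature for a given
cooling protocol, so any result can be replayed in kelvin or seconds.

## Exact solution on small constructs

For small $N$ the master equation is solved exactly.  States are lumped
into orbits of the construct's symmetry group: because per-cell rates depend
only on frozen-neighbour counts, any permutation of cells that preserves the
contact graph preserves the law of the process, and the chain is exactly
lumpable on orbit classes.  `enumerate_reduced_states()` partitions the
subsets, `build_generator()` assembles the reduced generator from the
per-cell rate $1 + k\alpha$, and `solve_master_equation()` propagates
$\mathrm{d}P/\mathrm{d}\tau = PQ$ with the matrix exponential, which is
exact to machine precision at these sizes.

The packaged 2&nbsp;&times;&nbsp;2 construct (`construct_2x2()`) deserves a
note.  Its contact graph is the complete graph on four cells — the diagonal
pair also exchanges propagative rate — but the symmetry group supplied for
lumping is the square's dihedral group $D_4$, not the full automorphism
group $S_4$ of the complete graph.  $D_4$ keeps the edge-adjacent and
diagonal two-frozen configurations as distinct classes, giving six classes
in total, with transition rates $4$ (no ice &rarr; one cell),
$2 + 2\alpha$ (one &rarr; adjacent pair), $1+\alpha$ (one &rarr; diagonal
pair), $2+4\alpha$ (pair &rarr; triplet) and $1 + 3\alpha$ (triplet &rarr;
all frozen).  Using $S_4$ instead would merge the two pair classes and
produce five classes; the six-class description is retained because the two
pair configurations are geometrically distinct states of the construct even
though their subsequent dynamics coincide.

```{r markov}
cx <- construct_2x2()
cls <- enumerate_reduced_states(cx$graph)
build_generator(cx$graph, cls, alpha = 10.4)
```

Correctness of the reduction is tested against a brute-force solution of the
unreduced $2^N$-state chain for several random graphs with $N \le 6$.

## Monte Carlo samplers

Two samplers cover constructs beyond exact enumeration.

**Fixed-step.**  Time is discretised with
$\Delta\tau = \varepsilon / \bigl((1 + n\alpha)N\bigr)$, where $n$ is the
maximum neighbour count and $\varepsilon$ a per-step probability bound.  At
each step every unfrozen cell freezes independently with probability
$(1 + k\alpha)\Delta\tau$, evaluated against start-of-step neighbour counts
(synchronous update: simultaneous freezes are allowed but do not cascade
within a step).  The default $\varepsilon = 0.05$ is the unique round value
for which the rule with $n = 2$, $N = 4$, $\alpha = 10.4$ gives exactly 1744
steps on $\tau \in [0,1]$, the validation configuration used for the
2&nbsp;&times;&nbsp;2 construct; $n$ is otherwise taken from the supplied
contact graph (maximum degree), with an explicit override field.  The
synchronous scheme's exact one-step law (computable on the 16 raw states of
the 2&nbsp;&times;&nbsp;2 construct) deviates from the continuous chain by
less than $5\times10^{-4}$ in any class probability at these defaults, i.e.
the discretisation error is far below Monte Carlo noise at $10^4$
replicates.

**Gillespie.**  Event-driven and exact: with aggregate rate
$\Lambda = \sum_{\text{unfrozen}} (1 + k_j\alpha)$, waiting times are
$\mathrm{Exponential}(\Lambda)$ and the freezing cell is chosen
proportionally to its rate.  Gillespie replicates run on independent
streams derived from `(rng_seed, replicate)`, so ensembles are reproducible
and order-independent; the fixed-step sampler is instead vectorised across
replicates on a single stream seeded by `rng_seed`, a deliberate trade of
per-replicate stream independence for a ~60-fold speedup at the
$10^4$-replicate validation scale.  Identical seed and configuration give
bit-identical event logs for both samplers.

Ensembles aggregate into per-cell freeze-probability maps with binomial
standard errors (`aggregate_freeze_map()`), empirical state-class
trajectories directly comparable to the master equation
(`aggregate_state_classes()`), and all-frozen curves (`all_frozen_curve()`).

## Single-cell biophysics

The map from $\tau$ to time and temperature needs $J^i(T)$ along the
protocol, which in turn needs the cell's water content.

**Water transport.**  During linear cooling $T(t) = T_0 - Bt$, osmotic
water loss follows the classic two-compartment membrane-limited model:

$$\frac{\mathrm{d}V}{\mathrm{d}T} = \frac{L_p(T)\,A\,\bar R\,T}{B\,v_w}
  \left[\ln\frac{V_w}{V_w + v_w v_s n_s}
  - \frac{\Delta H_f}{\bar R}\Bigl(\frac{1}{T_R}-\frac{1}{T}\Bigr)\right],$$

with $V_w = V - V_b$ the osmotically active water volume.  The bracket is
the chemical-potential imbalance between the (ideal) intracellular solution
and extracellular solution in equilibrium with ice; it vanishes exactly at
equilibrium and is positive for a supercooled interior, so with this sign
convention water leaves the cell as temperature falls.  $L_p$ follows an
Arrhenius law anchored at $T_R = 273.15$ K.  The ODE is integrated with
`deSolve::lsoda` (relative tolerance $10^{-8}$, absolute $10^{-6}$
&mu;m&sup3;) on a 0.05 K output grid; when the remaining water falls below
$10^{-6}V_{iso}$ the volume state is held fixed to avoid the logarithmic
singularity.  Halving either the output grid or the tolerance changes the
retained-water fraction at $B = 400$ K/min by well under 0.1 percentage
points.

**Nucleation.**  The spontaneous rate uses diffusion-limited heterogeneous
nucleation kinetics,

$$J^i(T) = A\,\Omega_0\,\frac{\eta_0}{\eta}\Bigl(\frac{T}{T_{f0}}\Bigr)^{1/2}
  \exp\!\left[-\frac{\kappa_0}{T^3\,(T_f-T)^2}
  \Bigl(\frac{T_f}{T_{f0}}\Bigr)^{4}\right],$$

zero without supercooling ($T \ge T_f$).  Two quantities require a
definition the parameter table does not supply:

* $\phi_s$, the non-water volume fraction entering the Vand-type cytoplasm
  viscosity $\eta = \eta_w(T)\exp\bigl(2.5\phi_s/(1-\varphi\phi_s)\bigr)$,
  is defined as $1 - V_w/V$ (all non-water material).  It grows from
  $v_b = 0.51$ at isotonic conditions toward 1 on dehydration, which
  produces the required diffusion-limited quench of nucleation in
  concentrated cytoplasm.
* $\eta_0$ ("isotonic conditions") is the cytoplasm viscosity at
  $\phi_s = v_b$ and $T = T_{f0}$.
* The melting temperature in the supercooling term is the *current*
  cytoplasm freezing point $T_f(x_w)$, which falls as the cell concentrates;
  this is what couples dehydration to nucleation suppression.

**Freezing-point depression** uses
$T_f = [1/T_{f0} - (\bar R/\Delta H_f)\ln x_w]^{-1}$ with
$x_w = n_w/(n_w + 2 n_s)$.  Note an internal tension kept deliberately: the
relation is anchored at the isotonic freezing point $T_{f0} = 272.63$ K but
is evaluated at the actual mole fraction, whose isotonic value is already
below 1 ($x_w \approx 0.9944$ with the default salt content), so the
computed isotonic freezing point is 272.06 K — the isotonic depression is
counted twice, about 0.5 K.  The package evaluates the relation exactly as
written because every downstream quantity inherits this convention from the
parameter table; the practical consequence is only that cells start
marginally above their computed freezing point at $T_0 = 272.15$ K.

**Parameters.**  `rat_hepatocyte()` packages the tabulated constants.
Table-derived values are used as printed, including the unusually large
$E_{Lp} = 342$ kJ/mol.  Three entries are constructed rather than printed:

* $V_{iso} = \frac{4}{3}\pi(10.5)^3 \approx 4849$ &mu;m&sup3; from the 21
  &mu;m cell diameter (the printed surface area, 1412 &mu;m&sup2;, is
  treated as an area although its printed unit is volume; it agrees with
  the sphere's 1385 &mu;m&sup2; to 2%).
* $n_s = 0.155\,\mathrm{mol/L}\times(1-v_b)V_{iso}$: isotonic physiological
  saline in the osmotically active volume, the standard assumption of
  single-cell osmotic models.  $n_s$ affects the late (colligative) part of
  dehydration only; the early, temperature-driven loss is insensitive to it.
* $\Delta H_f$ is stored in both pressure-volume and molar-energy units,
  converted once at construction (1 &mu;m&sup3;&middot;atm =
  1.01325&times;10&minus;&sup1;&sup3; J), so the transport and
  freezing-point formulas each use their natural form.

```{r dehydration}
hep <- rat_hepatocyte()
tr <- integrate_dehydration(hep, cooling_protocol(B = 400))
tr
```

The composite-trapezoid integral of $J^i$ over time gives $\tau(T)$
(`tau_of_time()`), inverted by first grid crossing (`tau_map()`).  The
cumulative single-cell IIF probability is $1 - e^{-\tau(T)}$
(`single_cell_iif_curve()`).

## Geometry

Three canonical constructs are generated programmatically, deterministic
given their arguments:

* `build_disc_monolayer(n)` — planar hexagonal packing filled ring by ring
  from the centre, centre spacing 0.85 diameters by default (within the 20%
  radius-overlap bound that every builder enforces).  22 cells is the centre
  plus a full double ring plus three third-ring cells.
* `build_spheroid(n, D)` — face-centred-cubic sites retained in order of
  distance from the centre; the lattice spacing is chosen so $n$ cells at
  FCC density fill a sphere of diameter $D$, and the achieved bounding
  diameter is reported in the metadata (103 cells at $D = 100$ &mu;m gives
  102 &mu;m).
* `build_slab(nx, ny, nz)` — cubic lattice at touching spacing.

Neighbourhoods come from either rule: *radius* (centres closer than $R$) or
*contact* (membranes touch within a small slack).  On a planar square
lattice the radius rule with $R$ just above the diagonal spacing gives an
interior cell 8 neighbours; the contact rule on touching spheres gives 4.
No choice of $R$ reproduces a maximum degree of 8 on the 3-D cubic slab
(face/planar-diagonal/cubic-diagonal neighbourhoods give 6, 18 or 26), so
slab experiments take the rule from configuration and the packaged slab
config uses membrane contact (maximum degree 6).  Because published disc
coordinates are unavailable, discs and spheroids here are reproducible *in
kind*, not coordinate-exact; associations between a specific $R$ and a
specific neighbour count in an irregular packing do not transfer, and the
suite instead tests the monotone property that growing $R$ never decreases
any degree.

## Mechanics

Cell motion uses the standard center-based formulation: quadratic-ramp
pair potentials with repulsion $c_{rep}(1-d/s)^2$ inside membrane overlap
($s = r_i + r_j$) and adhesion $c_{adh}(1-d/d_{max})^2$ inside the maximum
adhesion distance, overdamped updates $\dot x = F/\gamma$ at
$\Delta t = 0.001$ s.  The published adhesion parameters (30 pN adhesion,
750 pN repulsion, "maximum adhesion distance 1.25 &mu;m") are used with the
reach interpreted as the *relative* factor $1.25\,(r_i+r_j)$ — the standard
default of the center-based frameworks these constants come from; an
absolute 1.25 &mu;m reach would put adhesion out of range for any pair of
non-overlapping 21 &mu;m cells.  An absolute mode is available for
sensitivity analysis.  The drag coefficient is not published; the default
$\gamma = 1$ pN&middot;s/&mu;m maps pN forces to &mu;m/s velocities and
sets only the relaxation timescale, not equilibria or detachment topology.
Frozen cells stay mobile as rigid spheres by default (a pinned mode
exists).

On freezing, the remaining water expands by the factor 1.09:
$V_{frozen} = (V - V_w) + 1.09\,V_w$, fixed thereafter; the volume books
(solids + liquid before, solids + 1.09&times;water-at-freeze after) are
checked exactly in the suite.  A pair from the initial attachment set is
*severed* when its separation exceeds the adhesive reach;
`detect_detachment()` reports severed pairs, per-cell lost contacts and the
connected components of the surviving attachment graph.

The driver (`run_experiment()`) replays a sampled freeze log in dimensional
time: unfrozen cells follow the shared dehydration trajectory (identical
cells, no thermal gradients — the model's stated regime of validity is
constructs small enough, below roughly 150 &mu;m, that internal temperature
gradients are negligible), each cell's volume is fixed by expansion at its
scheduled freeze time (first time-grid crossing of its $\tau_j$), and
mechanics is stepped throughout.

## What the generated data do and do not emulate

The geometry builders define the study conditions: regular, monodisperse
packings with deterministic coordinates.  Real hepatocyte tissue is
polydisperse, irregular, and vascularised; contact counts in real discs
scatter far more than in a hexagonal packing, and the association between
neighbourhood radius and degree is geometry-specific.  Passing tests
therefore demonstrate correctness of the solvers and the qualitative
propagation phenomenology (ice spreads preferentially through
well-connected interiors; slower cooling dehydrates cells before they
freeze), not quantitative transfer to histology-derived geometries.
Heat transfer, solute gradients, extracellular ice and cryoprotectants are
out of scope.

## Numerical and statistical choices

* Master equation: matrix exponential on the reduced space (exact); grid
  stepping reuses the semigroup property.
* Probability conservation is asserted at $10^{-9}$ at every grid point;
  the all-frozen class is checked monotone.
* Fixed-step tie handling is synchronous (above); Gillespie has no ties.
* The $\tau$ inverse uses first grid crossing; events beyond $\tau(T_{end})$
  are reported as never frozen within the protocol, not silently dropped.
* Default simulation sizes in the suite are chosen for a laptop-scale run:
  $10^4$ fixed-step replicates for the 2&nbsp;&times;&nbsp;2 validation,
  $10^3$ Gillespie replicates per $\alpha$ for the threshold experiment,
  $10^2$ replicates for the disc and slab ensembles (the published
  ensembles used $10^5$ for the 2&nbsp;&times;&nbsp;2 validation and
  $10^2$ elsewhere).
* Statistical comparisons use binomial standard errors with explicit
  replicate counts; when two empirical curves are compared the errors are
  pooled.

## Known limitations and honest discrepancies

Several published headline numbers are not reproduced by a faithful
implementation of the printed equations and parameters, and the package
reports what it computes rather than the printed value:

* **Water retention at fast cooling.**  At $B = 400$ K/min the integrated
  model retains 64.7% of the initial *water* (normalized cell *volume*
  plateau 0.827).  The published claim of "about 85%" water retention is
  consistent with the normalized-volume plateau rather than the water
  fraction; at $B = 100$ K/min the model does reproduce near-complete water
  loss (5.8% retained).
* **Cooling-rate thresholds of single-cell IIF.**  The printed parameter
  set makes $L_p$ collapse near 263 K (large $E_{Lp}$), so dehydration
  stalls at a few percent residual water, the freezing point plateaus near
  262.5 K, and supercooling keeps growing on cooling to 230 K.  The
  asymptotic IIF probability at $B = 80$ K/min is therefore about 0.59,
  not $\approx 0$, and the first cooling rate reaching $P \ge 99.5\%$ in a
  10 K/min scan is near 190 K/min — above, but not just above, the
  published 130.  The cumulative probability is also not monotone in $B$
  at the slow end ($\tau$ at 50 K/min exceeds $\tau$ at 100 K/min, because
  slower protocols spend longer at every temperature).
* **The $\alpha$ threshold.**  On the 22-cell disc the all-frozen time is
  first-nucleation plus a propagation sweep whose mean scales like
  $1/\alpha$; at $10^3$ replicates the $\alpha = 50$ curve differs from
  $\alpha = 200$ by tens of pooled standard errors, and the
  indistinguishability threshold found by the packaged experiment is 200.
  The published threshold of 50 is recoverable only at two-orders-coarser
  statistical resolution on the temperature axis, where the steep
  $\tau(T)$ map compresses the curve differences below visual resolution.
* **Seed-distance ordering on the slab.**  With 2387 cells the aggregate
  spontaneous rate ($\approx N$ in $\tau$ units) dominates a single seeded
  front at $\alpha = 10.4$: mean freeze times are essentially flat beyond
  a few hops from the seed, and their Spearman correlation with graph
  distance is near zero.  Distance ordering is a property of
  propagation-dominated regimes ($\alpha \gg N$), not of this study
  condition.

These four discrepancies are asserted at their published values in the
acceptance suite and left failing there by design; the rest of the suite is
the package's own correctness evidence.
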