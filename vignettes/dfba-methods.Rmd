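---
title: "Methods: batch dFBA with Monod kinetics and isotopomer dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batch dFBA with Monod kinetics and isotopomer dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the modeling assumptions, numerical choices and
design decisions behind `dynafba`, at the level of detail a user needs to
judge what the package's results do and do not show.

## The kinetic layer

The batch model is an unsegregated, unstructured Monod system for growth
on lactate with overflow to pyruvate and acetate and their later reuse.
Its state is `(X, LACT, ACT, PYR)` — biomass in g DCW/L, concentrations
in mM — and its 14 constants are the three maximal growth rates (1/h),
three apparent yields (g DCW/mol), three saturation constants (mM), three
overflow rate constants (L/(h·g DCW)), an endogenous decay rate (1/h) and
a lag time (h). Three structural choices deserve comment.

* **Overflow is first order in both biomass and substrate.** The units
  of the overflow constants (L/(h·g DCW)) force the rate form
  `r = k * X * C`; a biomass-only form would have units 1/h.
* **Overflow debits the parent pool mole-per-mole.** The lactate balance
  subtracts both the growth term `1000 * (mu_L / Y_XL) * X` and the two
  overflow rates; pyruvate likewise loses what becomes acetate. Without
  these debits the large observed overflow fractions (roughly a third of
  lactate uptake to acetate) would violate carbon conservation. The
  factor 1000 converts mol to mmol, since yields are per mole but
  concentrations are mM.
* **The lag gate multiplies every derivative**, not only growth, because
  measured trajectories are flat before growth starts; this includes the
  endogenous-decay term, so the inoculum does not decay during the lag.

Integration uses `lsoda` with a 0.05 h step bound and clipping of states
at zero inside the right-hand side and on output. The step bound plus
clipping prevent spurious negative concentrations near substrate
exhaustion without event handling; with the default tolerances
(rtol 1e-8) the clip is a no-op except within solver noise of zero.

### Fitting

The objective is the sum of squared residuals with each variable divided
by its maximum measured value, so that biomass (< 1 g/L) and metabolites
(> 10 mM) contribute on comparable scales. Minimization runs on
parameters scaled by the initial guess (all O(1)): a Levenberg–Marquardt
pass on the residual vector, then a quasi-Newton (`nlminb`) polish of the
scalar objective. Default bounds are `[0, 10 * guess]` with the lag time
capped at the observation horizon; an optional multi-start flag adds
±20% perturbed restarts. On noise-free hourly data over 34 h all 14
parameters are recovered to relative error below 1e-6 from ±20%
perturbed starts, so the printed-precision constants are comfortably
identifiable at the reference conditions.

Bootstrap uncertainties use case resampling of time points with
replacement, independently per measured variable, refitting from the
point estimate with a capped iteration budget. Duplicate resampled
points enter as sqrt-count weights so the refit residual keeps strictly
increasing sample times. A monitor records the running change of the
standard deviations every 50 replicates; the conventional 1000-replicate
default is retained.

## The flux layer

The stoichiometric container holds the matrix S, bounds, biomass id and
an exchange map for lactate, acetate, pyruvate, O₂ and CO₂. Sign
convention, used everywhere: exchange flux > 0 is secretion, < 0 uptake.
SBML input accepts Level 3 with `fbc` bounds and Level 2 COBRA-dialect
kinetic-law bounds; defaults are `[0, 1000]` (irreversible) and
`[-1000, 1000]` (reversible). Exchange roles and the biomass reaction
resolve by configurable id patterns, since id conventions differ between
reconstructions.

### The dual-objective problem

Each pseudo-steady state solves

maximize `v_bio - w * sum(v_j^2)` subject to `S v = 0`,
`lb <= v <= ub`, and the three kinetically derived exchange fluxes fixed
as equalities.

The sum runs over **all** reactions, exchanges included. Fixed
exchanges are equalities rather than bounds because they are computed
from, not limited by, the kinetics. For `w > 0` the problem is a
strictly concave QP, so the optimum is global and unique; at `w = 0` it
degenerates to the max-growth LP, for which any optimal vertex may be
reported and downstream code must not rely on uniqueness.

Numerically, the equality system (metabolite balances plus fixed
exchanges) is eliminated first: an SVD yields a particular solution and
an orthonormal null-space basis, and the box bounds become inequalities
on the few remaining coordinates. The reduced QP is solved by the
compiled Goldfarb–Idnani active-set method (via `pracma::quadprog`).
Two details matter: flux polytopes routinely contain zero-width faces
(irreversible reactions pinned at zero by the balances), which the
active-set method misreports as infeasibility, so all inequalities are
relaxed by a feasibility tolerance of 1e-9 (configurable in
`dfba_config`); and the max-growth LP is solved by bisection on the
growth rate with strictly convex minimum-norm feasibility probes, which
is slower than a simplex but robust at these sizes and keeps the `w = 0`
path independent of any LP code.

### The bi-level search

The weight grid is `{0}` plus 60 log-spaced points spanning 1e-9 to 1.
The formal range of the weight is zero to one, but because the total
squared flux is numerically large the informative weights are small;
log spacing covers both regimes. Because the optimal growth rate is
non-increasing in `w` (a Pareto frontier, asserted at run time), the
grid argmin of `|mu_monod - mu_FBA(w)|` is found by bisection over grid
indices — identical result to an exhaustive sweep at a fraction of the
QP count. Ties break toward the smaller weight; a kinetic rate above
the unweighted optimum returns the smallest weight with an
"unattainable growth" warning.

Per interval, the kinetic growth rate is the gross `mu_L + mu_A + mu_P`
at the interval midpoint, gated by the lag: endogenous decay is treated
as maintenance outside the FBA biomass flux (a flag selects the net-rate
alternative). Exchange fluxes are exact analytic derivatives of the
kinetic model at the midpoint divided by biomass — no finite
differences. Midpoint evaluation (rather than endpoints) is a package
choice; at five-minute resolution the difference is far below the weight
grid resolution. Infeasible intervals carry the last feasible weight
forward and are flagged; more than 5% failures raises a summary warning.
Halving the interval length changes the time-integrated lactate uptake
by well under 2% on the toy network, so the five-minute default is
effectively converged.

## The toy central-carbon network

`build_toy_model()` is the desk-scale stand-in for a genome-scale
reconstruction: 20 metabolites, 28 reactions — lactate oxidation to
pyruvate and acetyl-CoA, pyruvate/acetate exchange (overflow and reuse),
oxidative TCA cycle, glyoxylate shunt, malic enzyme and pyruvate
carboxylase, a lumped gluconeogenic drain, serine/glycine/C1 synthesis
with a C1-oxidation valve, respiration, maintenance ATPase and a biomass
reaction over eight precursors (≈ 42 mmol C per g DCW).

Its energetics are deliberate. The coupled NADH oxidase carries P/O = 1
(low aerobic respiratory efficiency, as reported for *Shewanella*), an
uncoupled NADH oxidase provides energy spilling, and the biomass
reaction carries a high lumped growth-associated ATP demand
(220 mmol/g DCW). Together these make fast growth flux-expensive
relative to carbon disposal, so the dual-objective growth rate declines
appreciably with `w` — the regime the bi-level search needs. With a low
ATP burden the flux-minimal state would coincide with maximal growth and
the weight would be unidentifiable; this is a property of any network
this small, not of the method.

By construction the network grows on lactate while secreting acetate and
pyruvate, and growth on acetate alone strictly requires glyoxylate-shunt
flux, giving the expected late-phase rise of the malate-synthase to
fumarase flux ratio.

What the toy network does **not** emulate: genome-scale redundancy
(isozymes, alternative routes) and cofactor detail, realistic biomass
composition beyond the five amino-acid precursors, and any regulatory
constraint. Tests passing on it validate the machinery — the
optimization layers, the labeling algebra, parameter recovery — not the
biology of any particular organism; with a genome-scale SBML file
supplied, the identical pipeline runs on it unchanged.

## The isotopomer layer

Atom transitions are plain text (`rxn: mal[abcd] -> pyr[abc] + co2[d]`),
validated as carbon-conserving bijections so every mapping can be
reversed for bidirectional flux. Rotational symmetry (succinate,
fumarate) is encoded as two equally weighted mapping variants per
reaction. Isotopomer states index carbons little-endian (carbon 1 is the
fastest bit), and per-interval distributions solve the flux-weighted
fixed point: each produced metabolite's IDV is the production-weighted
mean of mapped precursor distributions, with joint (Kronecker)
distributions for multi-substrate reactions. Iteration is Gauss–Seidel
to an infinity-norm tolerance of 1e-10; each update renormalizes the
vector sum, since bimolecular terms otherwise amplify floating-point
drift through cycles. Warm starts from the previous interval keep the
per-interval cost low.

**Exchange convention.** A designated reversible pathway with
coefficient `exch` carries a bidirectional flux
`v_exch = exch/(1-exch) * v_ref` added to both directions on top of the
net flux, with a fixed reference scale `v_ref` of 1 mmol/g DCW/h —
the normalized-exchange ("xch01") convention of ¹³C flux analysis. The
alternative of scaling by the pathway's own net flux was rejected: the
flux-minimizing solutions keep the malic-enzyme net flux near zero
through most of the batch, which would make its exchange coefficient
structurally unidentifiable, while substantial label exchange across a
minimal net flux is precisely the phenomenon the coefficient describes.
Fitted coefficients are therefore convention-dependent and comparable
only under the same convention and reference scale.

Extracellular acetate and pyruvate pools follow the kinetic
concentrations; secretion mixes the transient intracellular labeling
into the pool, uptake feeds the pool distribution back. Protein-bound
amino-acid labeling accumulates as
`sum(dX(t) p(t) IDV(t)) / sum(dX(t) p(t))` with `p` the biomass drain
flux of the precursor; harvest snapshots report the cumulative
distribution at the end of the requested interval. Natural ¹³C abundance
is off by default (no correction is applied to the synthetic data the
package generates); a flag adds the 1.07% per-carbon abundance to the
tracer and a binomial convolution to reported MDVs. The amino-acid map
(Ala←pyruvate, Asp←oxaloacetate, Glu←2-oxoglutarate, Ser, Gly) inherits
the precursor backbone unchanged, and the M-57 fragment convention
carries all amino-acid carbons.

### The Monte Carlo cross-check

`mc_label_propagation()` estimates the same stationary distributions by
explicit molecule pools: each sweep resamples every pool from its
producing pathways. Molecules within one chain share ancestry, so a
binomial standard error would understate the sampling error severalfold;
the estimator therefore runs independent replicate chains and reports
the empirical standard error across chains, with each chain averaging
pool fractions over its final sweeps. Comparisons with the fixed point
use one scalar per metabolite (mean labeled-carbon count), which keeps
the number of simultaneous comparisons small enough for a 3-standard-
error bound to be meaningful; entry-level agreement is checked
absolutely (typically within 1e-3 at 1e5 molecules).

### Exchange-coefficient fitting

Fitting minimizes the σ-weighted score `sum(((sim - exp)/sigma)^2)` with
σ = 0.02 (the GC-MS scale error) over `exch` in `[0, 0.995]`: golden-
section search for one coefficient, `nlminb` for several. Asymptotic
confidence intervals come from the numerical curvature of the objective
at the optimum (`2 * s^2 * H^{-1}` with `s^2` the score per degree of
freedom); a flat objective yields the full interval with a
non-identifiability warning. On noise-free synthetic distributions the
malic-enzyme coefficient is recovered to 1e-4 of its generating value.

## Problem sizes in the test suite

Unit tests run the dFBA at half-hour resolution (68 intervals); the
end-to-end suite uses the full 408-interval default, one mid-exponential
interval for the Monte Carlo comparison (1e5 molecules, 200 sweeps,
8 chains), and single fits for the parameter-recovery checks. These
sizes were chosen as the smallest that exercise every phase of the batch
(lag, lactate growth, transition, acetate growth) with headroom on a
single CPU.

## Known limitations

* The static optimization approach ignores intracellular metabolite
  pool dynamics between intervals; the labeling layer inherits the
  pseudo-steady-state assumption per interval.
* There is no feedback from the flux layer to the kinetics — the Monod
  model is solved first and alone. Simultaneous (integrated) kinetic-FBA
  estimation is out of scope.
* The LP-by-bisection max-growth solver reports the minimum-norm optimal
  vertex; degenerate alternative optima at `w = 0` are not enumerated.
* Bootstrap refits reuse the point estimate as the start, which is the
  standard economical choice but can understate multi-modal uncertainty.
* Isotopomer algebra is IDV-level (up to 2⁶ states per metabolite here);
  genome-scale labeling simulation would need EMU-style decomposition,
  which is unnecessary at toy scale and out of scope.
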