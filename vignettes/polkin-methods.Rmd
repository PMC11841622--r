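---
title: "From polarized photon counts to a 24-state transporter model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From polarized photon counts to a 24-state transporter model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polkin)
```

# The measurement and the model

A membrane transporter such as the bacterial arginine/agmatine antiporter
visits four canonical conformations — externally open (Eo), externally
occluded (Ex), internally open (Io) and internally occluded (Ix).  When a
fluorophore is rigidly attached to a marker helix, each conformation gives
the emission dipole a characteristic spatial orientation, described by an
inclination angle theta (from the optical axis) and a rotation angle phi
(in the sample plane).  A polarization microscope splits the emission into
four polarized components, I0, I45, I90 and I135, recorded per camera frame
(10 ms in the default configuration).  `polkin` implements the full chain
of inference from such four-channel photon-count traces to a fully
parameterized conformational-kinetic model and its transport predictions:

1. **Polarimetry** — orientation from intensity ratios, with wobble
   correction (`estimateAngles`, `forwardIntensities`, `toLocalFrame`).
2. **Changepoint detection** — Poisson log-likelihood-ratio tests find the
   frames at which the orientation changes (`detectChangepoints`).
3. **State calling** — shortest-distance clustering of dwell-averaged
   orientations on the unit sphere resolves the conformational states
   (`clusterOrientations`), merges changepoint false positives
   (`mergeSameState`) and tabulates occupancies and transition
   probabilities (`stateStatistics`).
4. **Dwell-time kinetics** — camera-corrected double-exponential fits
   reveal two energetic substates per conformation; closed-form inversion
   yields the 20 apparent rate constants of an 8-state scheme per ligand
   condition; binding-isotherm fits across the concentration series yield
   the 60 rate constants (apo, Arg-bound, Agm-bound) and equilibrium fits
   yield the dissociation constants (`fitDwell`, `invertSerialScheme`,
   `fitRateConstants`, `fitEquilibriumConstants`).
5. **Transport model** — the 24-state scheme (8 apo states plus 8 states
   per ligand branch) with second-order binding edges at the two open
   substates is assembled into a generator; stochastic (Gillespie) and
   deterministic (24 coupled ODEs) simulations predict tracer uptake into
   vesicles, Michaelis-Menten behaviour, and the uniporter-versus-exchanger
   dichotomy (`buildGenerator`, `gillespieTransport`,
   `integrateTransport`, `fmaxExchanger`).

A synthetic-data generator (`makeGroundTruth`, `simulateStatePath`,
`renderTrace`, `makeFluxDataset`) produces microscopy-like and flux-assay
datasets with known parameters so that every stage — and the pipeline end
to end (`runPipeline`) — is testable without access to raw recordings.

# Polarimetry

For an emission dipole at (theta, phi) and order parameter S, the expected
intensities are

$$I_{0,90} = \tfrac{I_{tot}}{4}(1 \pm S\sin\theta\cos 2\phi),\qquad
  I_{45,135} = \tfrac{I_{tot}}{4}(1 \pm S\sin\theta\sin 2\phi).$$

Inversion uses only intensity ratios, so the estimate is insensitive to
brightness changes: phi is half the two-argument arctangent of
(I45-I135, I0-I90), and sin(theta) is the normalized modulation amplitude
divided by S.  Fast restricted rotation of the fluorophore within a
half-cone of angle delta attenuates the modulation; we adopt the standard
wobble-in-cone second-rank factor

$$S(\delta) = \cos\delta\,(1+\cos\delta)/2,$$

with S(0) = 1 and S decreasing monotonically (delta must stay below the
54.7-degree magic angle).  delta is an input measured in a separate
ensemble anisotropy experiment; 27 degrees is typical of a bifunctionally
attached rhodamine.  Instrument-specific channel imperfections are modelled
as per-channel multiplicative gains and additive backgrounds
(`Calibration`), applied before inversion.

Conventions: the dipole is a line, so theta is folded to [0, 90] degrees
and phi to (-90, 90] (the polarized components determine 2 phi).  A dipole
on the optical axis has undefined phi; it is reported as 0 with a
`"degenerate"` flag and excluded from state means.  When noise pushes the
apparent sin(theta) above S, theta is clipped to 90 degrees with a
`"clipped"` flag.  Angles are degrees at every interface and radians
internally.

Because each molecule sits on the coverslip in an arbitrary orientation,
orientations are re-expressed in a molecule-local frame defined by two
reference states: the local x axis is the mean orientation of the first
reference state (its mean phi becomes 0, theta becomes 90) and the local
x-y plane is spanned by the two reference means, with the z sign chosen so
the second reference has positive phi (`toLocalFrame`).  The registration
is exactly invariant to rigid rotations of the input, which is tested as a
property.

An important numerical caveat near theta = 90 degrees: theta is recovered
through an arcsine, whose derivative diverges at 1, so photon noise folds
theta estimates of in-plane dipoles *downward* by several degrees even for
well-averaged events.  Two design choices address this.  First, state
*assignment* is done in the measurement plane
(sin(theta) cos(2 phi), sin(theta) sin(2 phi)), where the photon noise is
isotropic and the folding cannot push an event across a state boundary.
Second, the resolution test for the number of states (below) is guarded by
a bimodality criterion that cannot be fooled by the folded tails.

# Changepoint detection

Transitions are found on the raw integer counts (Poisson statistics hold
for photon counting; gains and backgrounds are corrected only afterwards).
For a candidate split of a segment, each channel contributes

$$LLR = m\ln\frac{m}{\tau} + (N-m)\ln\frac{N-m}{T-\tau} - N\ln\frac{N}{T},$$

with m photons before the split, N in total, and tau, T the corresponding
durations; the score is the sum over the four channels, which rewards the
concurrent, opposite-sign intensity changes that orientation changes
produce.  The detection threshold is the 95th percentile (by default) of
the maximum-over-splits LLR on Monte-Carlo null traces of matched length
and rate — a per-trace false-positive calibration that automatically
accounts for multiple testing across splits.  Thresholds are simulated on
a geometric grid of segment lengths and interpolated in log length; they
depend on the total photon rate only weakly, so they are calibrated on an
even four-way split of the (coarsely bucketed) total rate and cached.

The search is recursive bisection: accept the best split of the whole
trace if above threshold, recurse on both sides, then iterate a refinement
pass (re-locate each changepoint within the interval bracketed by its
neighbours, dropping it if sub-threshold) and a false-negative pass
(re-test every segment), to convergence with at most 10 iterations.  Ties
between equal-LLR splits resolve to the earliest frame.  At 95% confidence
roughly one accepted transition in twenty is a false positive; these are
recognized later, when two consecutive events fall in the same state, and
merged (`mergeSameState`).

A camera integrates: the single frame that straddles a transition contains
a mixture of the two flanking intensities and is often bracketed by two
changepoints.  Such one-frame events between two different states are
absorbed into the preceding event rather than counted as state visits
(`transientFrames = 1`); at the dwell scales of interest (hundreds of
frames) genuine one-frame dwells are vanishingly rare, so the cost of the
rule is negligible while uncorrected transition frames would contaminate
both the transition counts and the bleach-step detector.

Quality control follows standard single-molecule practice
(`filterParticles`): at least 15 events per particle (required for
reliable state identification), signal-to-noise ratio above 5 (SNR is the
background-subtracted mean total intensity over the SD of the total), and
a single terminal photobleach step, detected as a concurrent drop of all
channels to background; any sustained intermediate intensity level between
full signal and background marks a multi-fluorophore particle, which is
excluded.

# State calling

Events are clustered by shortest (chord) distance on the unit sphere,
using k-means with k-means++ seeding and 50 restarts, on events at least 3
frames long (shorter events are labelled afterwards in the measurement
plane as described above).  The number of states is the largest k (up to
6) for which *every* pair of cluster means is resolvable.  A pair is
resolvable when (i) the angular separation of the means exceeds 2.5 times
the pooled angular sigma — the mean of the two clusters' SDs measured
along the inter-mean geodesic — and (ii) the projected one-dimensional
distribution of both clusters along that geodesic shows a genuine density
valley between the means (valley depth below 0.7 of the lower peak).  The
second criterion is the bimodality guard: k-means will happily split one
state into two fragments whose truncated SDs pass a pure 2.5-sigma test,
but fragments of a single distribution never show a valley.  Two clusters
one sigma apart merge; the four-state geometry of the transporter (phi
means near 0, 18, 27 and 40 degrees) resolves cleanly.  States are
labelled C1..C4 by increasing mean phi, matching the local-frame
convention in which C1 defines phi = 0.

Occupancies are time-weighted (dwell-duration weighted), which matches the
equilibrium interpretation of state probabilities; transition
probabilities are exit-conditional, `p[i, j] = n[i, j] / sum_j n[i, j]`,
counted between consecutive events within a trace.

Conformational states are matched to structural states by evaluating all
24 pairings of the four mean orientations against four reference
orientations and minimizing the combined squared chord distance (dipoles
are axes, so each pair is compared up to sign); `matchStructuralStates`
returns the full 24-vector and the best assignment.

# Dwell-time kinetics

**Camera-quantized pmf.** A dwell that starts at a uniformly distributed
phase within a frame and lasts an exponential time with rate lambda spans
k frames with probability

$$P(1) = 1 - \frac{1-e^{-x}}{x},\qquad
  P(k\ge 2) = e^{-kx}\frac{(e^{x}-1)^2}{x},\qquad x=\lambda\,\Delta t .$$

This closed form was derived from the uniform-phase model and is validated
against a large Monte-Carlo discretization oracle in the test suite; it
tends to the geometric law as x tends to 0 and can be renormalized over
k >= kmin when the shortest events are discarded.  Two-component mixtures
weight two such pmfs by f and 1-f.

**Serial scheme.** Each conformation hides two energetic substates: the
entered, communicating substate A (S1..S4) and an occluded cul-de-sac
partner B (S5..S8) reachable only from A.  The dwell in the conformation
is then a two-exponential mixture whose parameters map bijectively to the
underlying rates:

$$k_{out} = f\lambda_1 + (1-f)\lambda_2,\qquad
  k_{ba} = \lambda_1\lambda_2/k_{out},\qquad
  k_{ab} = \lambda_1+\lambda_2-k_{out}-k_{ba},$$

with the directed inter-conformational rates `k[i, j] = kOut * p[i, j]`.
The inversion is exact (it is the inverse of the eigen-solution of the
2x2 dwell generator) and is property-tested over the positive cone.  Any
valid (lambda1 > lambda2 > 0, 0 < f < 1) triple maps to non-negative
rates; f = 1 flags the single-substate boundary.

**Pooling across conditions.** The slow component typically carries only a
few percent of the events, so a single condition's 3,000 events pin its
rate no better than ~25% (the Cramer-Rao bound at these parameters — the
package's estimator reaches it).  The remedy is to pool the whole
concentration series in one likelihood.  Two couplings are provided.
`globalFitDwell` imposes binding isotherms
$(x_0 + x_L[L]/K_{1/2})/(1+[L]/K_{1/2})$ on the mixture parameters tau1,
tau2 and f themselves (each with its own half-saturation constant, since
the fast and slow components report on different substates).
`globalFitSerial` — the coupling used by the pipeline — imposes the
isotherms one level deeper, on the serial-scheme rates k_out, k_ab and
k_ba, and computes each condition's mixture parameters from them through
the exact eigen solution.  The distinction matters: when the underlying
rate constants interpolate as isotherms (which is what the apparent-rate
framework asserts), the eigenvalue-level curves are *not* exactly of
isotherm form, so the tau-level coupling carries a small systematic bias
into the saturating limits, precisely where the dissociation constants
look; the rate-level coupling is exactly correct there.  It also removes
the leverage problem of the apo condition: the zero-concentration rates
are constrained by every low-concentration condition through the model
instead of by a single dataset.  In both fits the likelihood is profiled
over a shared K1/2 on a log grid (the one genuinely non-convex
direction), warm-starting each node, before the per-parameter constants
are released; K1/2 is confined to the sampled concentration range,
outside of which it is not identifiable.

**Rate-constant isotherms.** Apparent rates per condition follow

$${}^{app}k_{ij} = \frac{k_{ij} + {}^{L}k_{ij}\,[L]/K_{1/2}}{1 + [L]/K_{1/2}},$$

fitted per transition by weighted least squares with the arginine and
agmatine series sharing a single apo constant — 20 transitions times
(apo + two bound branches) giving the 60 rate constants.  Weights are
proportional to the source conformation's event count over the squared
rate (approximately relative least squares).  K1/2 is again confined to
the sampled range: a half-saturation below the lowest tested concentration
would let the isotherm chase the apo point in isolation.

**Equilibrium constants.** Stationary probabilities of the eight substates
solve the transposed-generator null space (one balance equation replaced
by normalization, rows equilibrated so disparate rate scales remain
solvable).  Their concentration dependence follows

$$P_i([L]) = \frac{K_{i,1} + {}^{L}K_{i,1}[L]/K_{D1}}
  {\sum_j K_{j,1} + \sum_j {}^{L}K_{j,1}[L]/K_{D1}},$$

with S1 the reference state.  The isotherm depends on LK and KD1 only
through B_i = LK_i/KD1, so the fit is parameterized in (K, B); per-state
dissociation constants follow directly as K_Di = K_i/B_i, which keeps the
practically consequential ones — S6 (external binding) and S7 (internal
binding) for each ligand — well conditioned even when KD1 itself is
weakly determined.  Weights are inverse-variance (multinomial, var
proportional to P).  In the pipeline the P curves entering this fit are
evaluated from the isotherm-smoothed apparent rates; the raw per-condition
probabilities are also reported.

**Model comparison.** Single- versus double-exponential fits are compared
by a nested-model F test on binned Poisson deviances,
$F = ((D_1-D_2)/2)\,/\,(D_2/(n_b-3))$, with bins aggregated from the right
until every bin expects at least five counts.  Null simulations in the
test suite confirm the nominal 5% size; well-separated mixtures at a few
thousand events give p-values far below 1e-15.  Triple-exponential fits
are deliberately out of scope.

# The 24-state transport model

The generator stacks the 8 apo states with 8 states per ligand branch
(two branches: 24 states).  Within each branch the 20 branch-specific rate
constants apply; binding edges exist only at the two open substates — in
sidedness configuration 1, S6 exchanges ligand with the external solution
and S7 with the internal solution; configuration 2 swaps them.  Binding is
a near-diffusion-limited second-order step, kon = 1e7 /M/s by default,
with koff = kon * KD; the resulting off-rates are far faster than the
conformational rates, so binding acts as a rapid equilibrium and kon's
exact value is immaterial.  Rows of the generator sum to zero by
construction and the ODE trajectories stay on the probability simplex to
integrator accuracy.

Two-compartment bookkeeping (`CompartmentSystem`) couples the transporter
to finite substrate pools: releases into and uptakes from each compartment
change its concentration, scaled by the number of transporter copies and
the compartment volume.  The deterministic route integrates the 24 state
probabilities coupled to the concentrations with a stiff solver (lsoda,
rtol 1e-8); per-species mass is conserved to better than 1e-8 relative
(molecules bound to transporters are part of the budget).  The stochastic
route is an exact Gillespie simulation of a single transporter serving its
share of the compartment volumes, with propensities updated after every
binding or release event; averaged over replicates it agrees with the ODE
within the Monte-Carlo envelope, which is asserted in the tests.

The net flux through the transport path can be evaluated at any of its
five serial transitions, e.g.
$^{app}k_{flux} = {}^{L}k_{2,6}P^L_2 - {}^{L}k_{6,2}P^L_6$ for the step
between the bound outward-occluded and outward-open substates; the step
between the two bound communicating conformations sums its three parallel
pathways.  At quasi-steady state all five agree (to ~0.02% in the test
scenario), reflecting the separation between conformational relaxation
and net transport.

Removing the 12 apo inter-conformational transitions (keeping the apo
serial transitions) converts the uniporter into an obligatory 1:1
exchanger (`makeExchanger`): every crossing then requires a bound ligand.
Note that the exchanger's apo occluded pairs {S1, S5} and {S4, S8} become
isolated; the stationary solver detects the reducible chain and falls back
to the long-time limit of a uniform start (uniformized transition matrix,
repeated squaring with row renormalization).  Exchange thermodynamics are
closed-form: with volume ratio rv and initial concentration ratio rc, a
1:1 exchange can accumulate at most

$$F_{max} = \frac{1}{1 + r_v/r_c}$$

of the external tracer inside the vesicles — predetermined by the initial
conditions and independent of every kinetic parameter, which the tests
verify by scaling all rates.  A uniporter instead lets the tracer
equilibrate by volume, F = 1/(1+rv), and its transient peak uptake (the
observable analogue of Fmax) does depend on the kinetics.  Under the
symmetric condition rv follows from the observed maximal uptake as
rv = (1-F)/F.  Random vesicle orientation is modelled by averaging the two
sidedness configurations.  Membrane potential is not modelled.

# The synthetic-data generator

`makeGroundTruth` builds a fully specified model; its defaults define the
study conditions for all end-to-end validation and were chosen once, from
the published qualitative structure and scales:

* **Topology and rate scales** (`"adic-like"`): four conformations, two
  substates each; the four serial forward rates (0.045-0.06 /s) are 5-7x
  slower than the median of the other rates (inter-conformational rates
  0.25-0.6 /s, cul-de-sac returns 0.11-0.14 /s), reproducing the published
  pattern in which those four transitions are the slowest.  Mean
  conformational dwells are then ~1.5 s with slow components of several
  seconds — second-scale events at 10 ms frames, consistent with per-event
  orientation SDs near 4 degrees (see below).
* **Thermodynamic consistency**: each branch satisfies detailed balance
  with respect to per-state equilibrium ratios, and the bound-branch
  ratios follow the thermodynamic cycle LK = K * KD1/KDi.  Consequently
  the apparent rates follow the binding isotherm *exactly* with K1/2 equal
  to the source-state KD, and the substate probabilities follow the
  equilibrium isotherm *exactly* — the estimands of the analysis are
  well-defined truths of the generator, which is what makes end-to-end
  recovery a meaningful test.
* **Dissociation constants**: 50-200 uM, with the consequential external
  (S6) and internal (S7) sites distinct between arginine and agmatine.
* **Orientations**: the published polarization means ((90, 0),
  (88.7, 17.9), (77.4, 27.2), (90, 40.5) degrees); wobble half-cone
  27.03 degrees.
* **Photon budget**: 400 signal photons per frame over 5 background
  photons per channel (SNR ~ 19, within the 5-20 range of the
  instrument); with second-scale dwells this yields the few-degree
  per-event angular noise that makes four states resolvable at 2.5 sigma.
  Faster kinetics at the same photon rate would not support four-state
  resolution — a genuine physical trade-off of the method, not a software
  parameter.
* **Noise model**: pure Poisson shot noise per channel; camera frames
  integrate across transitions (occupancy-weighted mixing within the
  straddling frame); photobleaching is a single complete step at the end
  of the particle's trajectory.  EMCCD excess noise is not modelled.
* **Flux datasets**: deterministic model curves (averaged over the two
  sidedness configurations) times mean-one lognormal sampling noise with a
  chosen coefficient of variation, plus an optional known recovery
  efficiency.

What passing the synthetic tests does *not* show about real data: the
generator has no molecule-to-molecule orientation heterogeneity, no drift,
blinking or multi-fluorophore particles beyond the QC test cases, no EMCCD
excess noise, and the per-condition dynamics are exactly the aggregated
8-state chain the analysis assumes.  Real recordings violate all of these
to some degree; the pipeline's QC and its explicitly calibrated thresholds
are the first line of defence, but recovery accuracy on real data will be
bounded below by these unmodelled effects.

# End-to-end validation and problem sizes

`runPipeline` ties the stages together and is validated by simulating an
adic-like truth over the apo condition plus 12 arginine and 10 agmatine
concentrations (10 uM - 2.5 mM, bracketing all half-saturation constants),
3,000 events per condition in particles of 150 events — event counts at
the upper end of the published per-distribution range.  The committed
check (one fixed seed, runtime a few minutes) requires: exactly four
resolvable states; all 20 apo rate constants within 25%; the four serial
forward rates identified as the slowest; and the four consequential
dissociation constants within a factor of two.

One precision limit deserves an honest statement.  The apo values of the
cul-de-sac return rates are anchored by a single zero-concentration
dataset: its slow-component maximum-likelihood estimate carries ~30%
scatter (and ~+10% small-sample bias) at these event counts — the
Cramer-Rao bound, which we verified the estimator attains — and because a
half-saturation constant below the lowest tested concentration is never
excludable by the data, no amount of pooling across the series can fully
transfer information into the zero-concentration limit.  Replicating the
whole study across independent seeds therefore scatters the
worst-of-twenty apo rate error over roughly 20-60%, dominated by exactly
these return rates, while the majority of the rate constants recover
within ~10-15% and the serial forward rates are identified as the slowest
in essentially every replicate.  The committed fixed-seed check is
deterministic and reproducible; the cross-replicate scatter is a property
of the measurement design (paper-scale event counts with a
five-percent-amplitude slow component), not of the implementation, and
the same limit applies to any analysis of real recordings at these
statistics.

Numerical and degenerate-input choices collected in one place: earliest
frame wins LLR ties; refinement iterations capped at 10; k-means restarts
50; optimizers are bounded quasi-Newton (nlminb) on log-transformed rates
(logit-transformed fractions) with multi-start or profile strategies as
described; dwell fits require 50 events for two components; boundary
(censored) events of each trace are excluded from dwell-duration fits but
kept for transition counts; background-only events are flagged `"dark"`
and excluded from orientation statistics; all-zero intensity input is an
error; stationary solves equilibrate rows and fall back to a uniformized
power method on reducible chains.

# Known limitations

* The apparent-rate/isotherm framework treats each ligand condition as an
  aggregated 8-state Markov chain; it does not maximize a hidden-Markov
  likelihood over raw traces, and missed-event correction is limited to
  the frame-quantization pmf with an optional minimum dwell length.
* The zero-concentration values of the slow (cul-de-sac return) rates are
  information-limited by the single apo dataset (~30% scatter at
  paper-scale event counts; see the end-to-end section); confidence
  intervals on those constants should be obtained by parametric bootstrap
  before any mechanistic weight is placed on them.
* Per-transition half-saturation constants with small dynamic range are
  unidentifiable (they are confined to the sampled concentration range and
  flagged rather than extrapolated).
* theta near 90 degrees is intrinsically ill-determined by polarization
  ratios; the package mitigates but cannot remove this.
* The transport model omits membrane potential and treats pH only through
  alternate parameter sets, mirroring the scope of the measurements it is
  built from.
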