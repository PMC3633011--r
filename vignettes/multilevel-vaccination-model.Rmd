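---
title: "A two-level Petri-net / population model of ErbB2-driven tumour growth and vaccination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-level Petri-net / population model of ErbB2-driven tumour growth and vaccination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncolevel)
```

## The modelling problem

Cancer-stem-cell (CSC) theory describes a tumour as a hierarchy: a small
pool of self-renewing CSCs seeds committed progenitor cells (PCs) that
proliferate rapidly through successive maturation stages and terminally
differentiate into post-mitotic tumour cells (TCs). Therapies that act on
surface receptors — such as antibody vaccination against the ErbB2 (HER2/neu)
oncoantigen in transgenic mammary-carcinoma models — perturb intracellular
signalling, and the population consequences of that perturbation are what an
experimentalist actually observes. `oncolevel` implements a two-level model
of this situation:

1. a **molecular level**: a Petri net of the proliferation signalling
   network (ErbB-family receptor activation, PI3K/Akt, mTOR and TLR2
   cascades), analysed structurally (P-semiflows), behaviourally (CTL model
   checking on the reachability graph) and dynamically (generalized
   mass-action ODEs, with a Gillespie simulator as the stochastic
   counterpart);
2. a **population level**: a linear, homogeneous nine-compartment ODE system
   for CSC, PC1–PC7 and TC counts;
3. a **coupling**: the simulated time courses of three proliferation-pivotal
   proteins — cyclin D, NF-kB and (Akt-phosphorylated) BAD — are turned into
   the time-varying proliferation rates $\omega_{CSC}(t)$ and
   $\omega_{PC}(t)$ of the population model.

In-silico experiments then schedule growth-factor injections and
vaccinations as timed events on the molecular state and read their effect
off the population trajectories.

## The Petri-net layer

A net is the tuple $N = (P, T, I^-, I^+, m_0)$; `petri_net()` stores the
arc multiplicities as dense $|T|\times|P|$ matrices in declared order, so
the incidence matrix $C$ with $c_{t,p} = I^+(t,p) - I^-(t,p)$ and all
downstream analyses are deterministic. The reaction-list grammar
(`parse_reactions()`) maps one reversible reaction to a `_f`/`_b`
transition pair, which keeps the semiflow algebra standard.

**P-semiflows.** A P-semiflow is a non-negative integer place vector $x$
with $xC = 0$; its weighted token sum is invariant under any firing and, in
a biochemical net, identifies where a kind of matter is conserved.
`p_semiflows()` implements Farkas (Fourier–Motzkin) elimination of the
transition columns in exact integer arithmetic — every intermediate row is
re-divided by its gcd, so the doubles that store the rows are never
rounded — followed by support-minimality filtering and canonical ordering
(support size, then support names). The worst case is exponential; a
`max_rows` cap turns pathological inputs into a clear error rather than a
hang. On the five-reaction Pten subnet shipped as `build_pten_subnet()` the
generator returns exactly two minimal semiflows: the Pten-conservation law
(unit coefficients on Pten and its three complexes) and the lipid law
(coefficient 2 on the double-lipid complex):

```{r semiflows}
pten <- build_pten_subnet()
p_semiflows(pten$net)
```

**Reachability and CTL.** `reachability_graph()` explores integer markings
breadth-first with a state cap, and `check_ctl()` labels it by the standard
fixed points (EX direct, EF/EU least, EG greatest; universal operators by
duality). Two choices deserve a note:

* *Deadlock totalization.* CTL path semantics need a total transition
  relation; terminal markings receive a self-loop before the fixed points
  are computed, the conventional choice that makes `EG` on dead states
  well-defined.
* *Atom sugar and fused operators.* A bare place name abbreviates
  `place > 0`, matching how queries are written in practice. Words such as
  `AXG` are rejected as unpaired temporal operators — but only when
  followed by the start of a formula, since `EGF` is a perfectly good
  species name. When a place list is supplied to `parse_ctl()` the species
  reading always wins.

Three reference full-network queries ship (as repaired interpretations;
the renderings they were transcribed from have unbalanced parentheses) in
`inst/extdata/queries_full_network.ctl`. The reachability graph of the full
111-place network at realistic markings is intractable, so the test suite
instantiates the cyclic-Pten steady-state query on the Pten subnet graph
and the growth-factor reachability query on the closed demo net at a small
marking — both hold.

## From net to ODEs, and back down to fewer ODEs

`derive_odes()` applies generalized mass action: transition $t$ with rate
constant $k$ contributes velocity $k \prod_h X_h^{I^-(t,h)}$, signed by the
incidence row. Kinetic orders equal input stoichiometries — marking-
dependent rate functions are out of scope. `reduce_odes()` removes one
equation per minimal semiflow, rewriting the support place with the largest
not-yet-eliminated index (a deterministic choice; the method does not
prescribe one) as a linear combination of the others. Events may break a
conservation constant (an injection adds mass), so the reduced integrator
recomputes the invariant constants from the post-event state at every
restart; reduced and full trajectories agree to $10^{-6}$ relative on the
shipped fixtures and on randomly generated conservative nets.

Integration uses `deSolve::lsoda` (stiff-capable) with defaults
`rtol = 1e-8`, `atol = 1e-10`, restarted at each scheduled event — event
times are known, so no root-finding is needed. Trajectory rows at an event
time hold the post-event state; pre-event values are kept in the
trajectory's `events` table.

`ssa_simulate()` is the stochastic counterpart (Gillespie direct method,
combinatorial propensities: falling factorials over $m!$ for
multiplicity-$m$ inputs) and serves as an independent oracle: as token
counts grow the ensemble mean approaches the ODE solution. At the test
scale (the Pten subnet at a 100-token marking, 200 runs) the ensemble mean
retains the well-known $O(1/V)$ covariance bias of order one SEM, so the
convergence check compares, at each of ten checkpoints, the RMS
standardized deviation across species against 3 — a per-species,
per-checkpoint 3-SEM test at 60 marginal comparisons would reject a correct
simulator about half the time, which is a property of that statistic, not
of the simulator.

## The population level

With $N = (N_{CSC}, N_{PC_1}, \dots, N_{PC_7}, N_{TC})$:

$$
\begin{aligned}
\dot N_{CSC} &= P_{sy}\,\omega_{CSC} N_{CSC}
  + \gamma_{PC}\textstyle\sum_{j=1}^{3} N_{PC_j}
  - (\eta_1 + d_1) N_{CSC}\\
\dot N_{PC_1} &= P_{asy}\,\omega_{CSC} N_{CSC} + \eta_1 N_{CSC}
  - (\omega_{PC} + \gamma_{PC} + \eta_2 + d_2) N_{PC_1}\\
\dot N_{PC_j} &= (2\omega_{PC} + \eta_2) N_{PC_{j-1}}
  - (\omega_{PC} + \eta_2 + d_2) N_{PC_j}
  - [j \le 3]\,\gamma_{PC} N_{PC_j} \qquad j = 2,\dots,6\\
\dot N_{PC_7} &= (2\omega_{PC} + \eta_2) N_{PC_6} - (\eta_3 + d_2) N_{PC_7}\\
\dot N_{TC} &= \eta_3 N_{PC_7} - d_3 N_{TC}
\end{aligned}
$$

Two transcription artifacts of the reference equation set are corrected
(and flagged here): the CSC differentiation flux $\eta_1 N_{CSC}$ enters $PC_1$ with a
*positive* sign — a negative sign would destroy mass and break
non-negativity — and the middle-stage death term is $-d_2 N_{PC_i}$,
consistent with the neighbouring stages. The system is linear and
homogeneous; `population_matrix()` exposes the system matrix, whose
dominant eigenvalue is the asymptotic growth rate (a test oracle).

Parameter defaults are documented placeholders, chosen once: division
probabilities $P_{sy} = P_{asy} = 0.5$ (whether they must sum to one is
left open by the source model; the constructor only enforces
$P_{sy}+P_{asy}\le 1$, leaving room for symmetric differentiation), rates
$\gamma_{PC} = 0.002$, $\eta = (0.005, 0.01, 0.01)$,
$d = (0.005, 0.005, 0.002)$ and baseline $\omega = (0.02, 0.04)$ per unit
time on the model's arbitrary time scale. They give sustained hierarchical
growth on the 0–6000 window used by all experiments. The initial
composition follows the spheroid assay: 15 CSCs per 1000 cells, remainder
terminal. The number of PC stages is 7, but the implementation is
parameterized (`npc`) so that short chains can be tested against closed
forms.

## Coupling and the demo network

`make_rate_function()` builds
$\omega(t) = s \cdot f_1(t) f_2(t) f_3(t)$ from a molecular trajectory:
each factor is the linearly interpolated, endpoint-clamped trajectory of
one target species, normalized to its baseline (value at the first time
point). The BAD factor uses the Akt-phosphorylated (inactive) species
`pBAD` with baseline normalization, so the product *increases* with
proliferative signalling; using active BAD with the reciprocal transform is
a configuration alternative. The scale $s$ (one per population, defaults
0.02 and 0.04 per unit time) maps the dimensionless product to a rate and
is chosen so the unvaccinated model reproduces the constant-rate baseline
growth — the source material states no units for $\omega$.

Because the factors normalize to the first time point, the molecular nets
must start at rest: `equilibrate_net()` relaxes a net to its unstimulated
steady state before coupling. Skipping this step mistakes the autonomous
relaxation transient for a proliferation signal (the product then reaches
~150 × its intended scale and the population equations overflow).

`build_demo_erbb2_net()` is a deliberately small (~35 species) stand-in for
the unavailable 111-place network, with the same five-portion organization:
(A) ligand binding and dimerization for ErbB1/2/3, including the
ligand-independent ErbB2 homodimer of the transgenic model; (B) PI3K
recruitment by active dimers, Pip3 production, and — verbatim — the
five-reaction Pten subnet of `build_pten_subnet()`, then Akt activation; (C) the three targets (BAD
phosphorylation, cyclin D stabilization via GSK-3β inhibition, NF-kB
activation via IKKα); (D) the TSC2/Rheb/mTOR loop; (E) the
TLR2–MyD88–IRAK–TRAF6 cascade converging on NF-kB, with the CSC net
carrying 100 × the PC net's surface TLR2. Its kinetic constants are
repository-defined on the arbitrary time scale and were calibrated once
against the qualitative behaviours below, then frozen; all conclusions
drawn from this net are qualitative.

Three mechanisms in the demo net are worth justifying because the coarse
sketch it follows does not force them:

* *Bound-ligand internalization* (`turnover = TRUE`): free-ligand decay
  alone cannot terminate a response, because ligand sequestered in
  receptor complexes re-binds faster than it decays; without
  internalization the three injection responses merge into a plateau
  instead of three distinct cyclin D peaks.
* *Receptor re-expression*: the transgene expresses ErbB2 constitutively,
  so surface receptor recovers (~1000 time units) after an antibody hit.
  Without re-synthesis a single vaccination silences signalling forever
  and growth never resumes, contradicting the single-vaccination
  experiment.
* *Vaccination scope*: a vaccination event scales **all** membrane species
  containing the target receptor (`receptor_species()`), not only the free
  receptor and homodimer. Scaling only the latter leaves preformed
  dimer–PI3K signalling complexes intact and the vaccination has no
  measurable phenotype; the antibody's functional block acts on the
  receptor wherever it sits on the membrane.

With `turnover = FALSE` the demo net is fully conservative (every place is
covered by a semiflow), which is the configuration used for boundedness
and reachability analyses.

## The in-silico experiments

`preset_schedule()` encodes the four experiment presets on the shared
arbitrary time axis: three growth-factor injections at t = 1500, 2500,
3500 (`fig4`); those plus five ErbB2 vaccinations from t = 1000 every 1000
units (`fig5`); a single ErbB2 vaccination at t = 1500 (`fig7a`); combined
ErbB2 + TLR2 vaccination at t = 1500 (`fig7b`). Injections `add` ligand
(EGF, HRG, and the TLR2 ligand on the CSC net); vaccinations `scale`
receptor species by a retention factor (default 0.1).

The behaviours the acceptance suite verifies on a 0–6000 grid (601 points;
the problem sizes quoted here are the ones the shipped tests use):

* unvaccinated growth shows three cyclin D maxima, each within 600 time
  units after its injection;
* the five-vaccination schedule strictly delays the ten-fold TC expansion
  (in the default calibration it is pushed beyond the simulation window)
  and strictly lowers the final TC count, with
  $\omega_{CSC}^{vacc}(t) \le \omega_{CSC}(t)$ pointwise after the first
  vaccination;
* adding TLR2 vaccination to ErbB2 vaccination leaves the growth-onset
  time unchanged and lowers the final TC count by a limited factor
  (≈ 0.6–0.7), and a TLR2-only vaccination leaves $\omega_{PC}$ untouched
  when PCs carry no TLR2.

## What the synthetic generator does and does not emulate

`random_conservative_net()` plants conservation laws by construction:
chains of stoichiometry-balanced conversions connect each law's support
(making the planted vector the unique minimal semiflow there), and the
remaining reaction budget is rejection-sampled from reactions orthogonal to
every planted law. Planted laws must have pairwise disjoint supports —
overlapping supports would make "the planted vector is recovered" an
ill-posed claim, since only the cone's extreme rays are identifiable.
Rates are log-uniform in $[10^{-2}, 10^2]$ and all randomness flows from
one integer seed. These nets exercise the algebra and the solvers; they do
not emulate pathway topology, parameter realism, or the sloppiness of real
kinetic data, so green property suites certify the machinery, not
biological fidelity.

## Known limitations

* The full 111-place/124-reaction/235-parameter network lives in a
  supplement that is not distributed here; `load_full_network()` accepts it
  once converted to the reaction-list grammar (drop-in paths
  `inst/extdata/full_network_reactions.rxn` / `full_network_params.tsv`),
  and the structural-count checks activate automatically when the files
  are present.
* The time axis is arbitrary; aligning it with calendar time in vivo is an
  acknowledged open problem of the approach, and no tumour-mass/cell-count
  conversion is attempted.
* CTL checking is explicit-state; nets whose reachable state space exceeds
  the cap need external symbolic tools.
* Mass-action kinetics only; no Michaelis–Menten or Hill shortcuts, no
  marking-dependent rates, no tau-leaping or hybrid simulation.
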