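---
title: "Modelling the E. coli lsr quorum-sensing switch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the E. coli lsr quorum-sensing switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsrswitch)
```

## The system

Autoinducer-2 (AI-2) is the interspecies quorum-sensing signal of *E. coli*.
Extracellular AI-2 is imported by the Lsr transporter (encoded by the *lsr*
operon) and by an uncharacterized alternative pathway, phosphorylated by the
kinase LsrK, and the phosphorylated form (AI-2-P) binds and sequesters the
repressor LsrR. LsrR represses both the *lsr*-operon promoter and its own
gene, so sequestration derepresses the operon, boosts import, and closes a
positive feedback loop — the "switch". All scenarios handled here are
*luxS*-null: the cells synthesize no AI-2 of their own and the externally
added dose is the only input.

`lsrswitch` implements three nested topologies of this circuit:

* **`first`** — LsrR is the only repressor of the *lsr* promoter.
* **`reg_no_binding`** — a second repressor, REG, is expressed from the same
  *lsr* promoter and represses it (coefficient $k_4$), but does not interact
  with AI-2-P.
* **`reg_binding`** — additionally, AI-2-P sequesters REG (rate $k_5$), the
  full modified model.

and the four experimental scenarios: the intact (*luxS*-only) network and
the *lsr*-operon, *lsrR* and *lsrK* knockouts (any combination of the three
is accepted).

## The equations

State variables (all µM): Lsr transporter $OP$, REG $G$, LsrR $R$,
phospho-AI-2 $Ap$, unphosphorylated internal AI-2 $U$, external AI-2
$A_{out}$, complexes $C_R$ (LsrR·AI-2-P) and $C_G$ (REG·AI-2-P), and the
reporter protein $Y$. Promoter activity is

$$P(R, G) = k_{op}\,\frac{1}{1+(R/k_1)^{n_{OP}}}\,\frac{1}{1+(G/k_4)^{n_G}},$$

with the $G$ factor dropped in the `first` topology. The full system is

$$
\begin{aligned}
\dot{OP} &= P(R,G) - k_{deg}\,OP \\
\dot{G} &= P(R,G) - k_{deg}\,G - k_5\,G\,Ap \\
\dot{R} &= \frac{k_r}{1+(R/k_2)^{n_R}} - k_{deg}\,R - k_3\,R\,Ap \\
\dot{Ap} &= (k_{imp}\,OP + k_f)\,A_{out} - k_3\,R\,Ap - k_5\,G\,Ap \\
\dot{A}_{out} &= -(k_{imp}\,OP + k_f)\,A_{out} \\
\dot{C}_R &= k_3\,R\,Ap - k_{deg}\,C_R, \qquad
\dot{C}_G = k_5\,G\,Ap - k_{deg}\,C_G \\
\dot{Y} &= P(R,G) - k_{deg}\,Y
\end{aligned}
$$

Initial state is all-zero except $A_{out}(0) = $ dose; the measured output
is $s_{rep}\,Y$ in Miller units.

Modelling assumptions, stated explicitly because several were genuinely
open design choices:

* **REG is lsr-promoter-driven.** $k_{op}$ is the shared operon/regulator
  synthesis rate and REG is interpreted as an operon-encoded AI-2-P
  processor, so $G$ shares the synthesis term $P(R,G)$ and disappears with
  the operon knockout. This is the structural feature that lets the full
  model produce *higher* expression in the operon knockout than in the
  intact network: deleting the operon removes REG repression while the
  alternative import pathway still delivers AI-2-P.
* **Reporter species $Y$.** The β-galactosidase fusion reads out *lsr*
  promoter activity even when the chromosomal operon is deleted, so the
  reporter is a separate species driven by $P(R,G)$ that no knockout
  removes.
* **Decay.** The dilution/decay rate $k_{deg}$ applies to proteins and
  complexes ($OP, G, R, Y, C_R, C_G$); the signal species $Ap$, $U$ and
  $A_{out}$ do not decay. Consequently the pool
  $A_{out}+Ap+U+C_R+C_G$ is non-increasing, and decreases only through
  complex turnover — an invariant the tests assert on every trajectory.
* **Instantaneous phosphorylation.** LsrK kinetics are fast relative to the
  500-min horizon, so imported AI-2 is treated as phosphorylated on arrival;
  the *lsrK* knockout is a structural switch (import is routed to the inert
  pool $U$, $Ap \equiv 0$), not a rate change.
* **Alternative import is first order** in $A_{out}$ with rate constant
  $k_f$ (min⁻¹); likewise $k_{op}$ and $k_r$ act as maximal synthesis rates
  in µM·min⁻¹.
* **REG cooperativity $n_G$** defaults to 1; there is no evidence of
  cooperative REG binding, and the large $k_4$ already encodes weak
  repression.

Knockout transforms: `lsr_operon` zeroes the $OP$ and $G$ synthesis terms
(import reduces to $k_f A_{out}$, and $A_{out}(t) = A_{out}(0)e^{-k_f t}$
exactly — used as a closed-form integrator check); `lsrR` removes $R$ and
its equation; `lsrK` blocks phosphorylation as above, which decouples the
reporter from dose entirely.

## Parameters

Defaults are the best-fit values of the full model; `s_rep` (Miller units
per µM reporter) and `nG` are additions needed to make the reporter scale
and the REG Hill form explicit.

| symbol | meaning | default | units |
|---|---|---|---|
| `k_op` | operon/REG maximal synthesis rate | 7 | µM·min⁻¹ |
| `k_r` | LsrR maximal synthesis rate | 2 | µM·min⁻¹ |
| `k1` | LsrR→operon repression coefficient | 0.2 | µM |
| `k2` | LsrR auto-repression coefficient | 0.1 | µM |
| `k3` | AI-2-P/LsrR binding rate | 0.05 | µM⁻¹·min⁻¹ |
| `k4` | REG→operon repression coefficient | 65 | µM |
| `k5` | AI-2-P/REG binding rate | 1e-4 | µM⁻¹·min⁻¹ |
| `k_f` | alternative import rate | 0.01 | min⁻¹ |
| `k_imp` | Lsr import rate | 0.01 | µM⁻¹·min⁻¹ |
| `nOP`, `nR` | Hill cooperativities | 4, 4 | — |
| `nG` | REG Hill cooperativity | 1 | — |
| `k_deg` | protein decay/dilution | 0.02 | min⁻¹ |
| `s_rep` | reporter calibration | 1 | MU·µM⁻¹ |

Two unit notes. `k_deg` is kept at the printed 0.02 min⁻¹ even though a
30-min division time corresponds to $\ln 2/30 \approx 0.023$; the
difference is immaterial at the fit tolerances but the choice is recorded.
`k_f` is implemented as a first-order rate (min⁻¹) — a per-µM label on a
simple flux out of a single substrate pool is read as typographical.

## Numerics

The system is non-stiff over the admissible parameter ranges (all rates
≤ O(10) min⁻¹, horizon 500 min), so `integrate_timecourse()` uses an
embedded Dormand–Prince 5(4) pair with PI step control (compiled), default
tolerances `rtol = 1e-8`, `atol = 1e-10`. No ODE-solver package is assumed
at runtime. Correctness is established three ways in the test suite: exact
closed forms (pure decay, operon-knockout AI-2 depletion), an independent
fixed-step RK4 oracle with its own hand-written right-hand side
(sup-norm agreement to 1e-4 relative at `dt = 0.01` min), and invariance of
all reported summaries under grid refinement and tolerance tightening.

Summaries: the default output grid is 1-min spacing on [0, 500] min —
experimental sampling was hourly, but a fine grid removes grid artifacts
from peak location. `peak_activity()` is the grid argmax with the earliest
time on ties; `activity_at_fixed_time()` interpolates linearly (the
published single-time comparisons use hour 5).

## Fitting

`fit_model()` minimizes the weighted SSE between model reporter values and
Miller-unit records with a classic Hooke–Jeeves pattern search. Positive
rate/affinity parameters are searched in log coordinates (scale-free
steps); Hill coefficients linearly. Defaults: initial step 25% of the
(transformed) bound range, halving on failed sweeps, termination when all
steps fall below 1e-4 of their initial size or 10⁴ evaluations, 20
Latin-hypercube restarts (log-uniform stratified) after the user-supplied
start. Starts outside the search box are projected onto it. `k_deg` is
fixed by default — decay is set by the division time, not estimated — and
integration failures inside the objective return a flagged 1e12 penalty
rather than aborting the search.

Bounds are declared, not inferred: rates and binding constants
[1e-4, 1e2] in natural units, repression coefficients [1e-2, 1e2] µM, Hill
coefficients [1, 6]. The `k4` default of 65 µM sits within but near the top
of its box; single-parameter recovery from 3× starts (projected to the
bound) still converges to it on noise-free data.

## Topology discrimination

`joint_fit_variants()` fits each topology to pooled multi-scenario data
(one shared parameter vector per topology) and reports raw joint and
per-scenario SSE plus ratios — no information-criterion penalty, because
the topologies are nested and the argument rests on fit quality alone. On
noise-free data generated by the full model across all four scenarios, the
`first` topology cannot reconcile the intact and operon-knockout
amplitudes (its operon knockout always expresses *less* than intact),
`reg_no_binding` captures the amplitudes but leaves the lsrR-knockout
response dose-independent, and `reg_binding` fits everything — the ordering
the SSE table and the qualitative checks both report. A single-scenario
dataset is accepted but flagged non-discriminating: all three topologies
fit any one scenario well.

`qualitative_checks()` encodes the four signatures: S1 intact peaks
strictly increase with dose; S2 the operon-knockout top-dose peak exceeds
the intact one; S3 the lsrR-knockout shows weak but real dose dependence;
S4 the lsrK knockout is flat in dose and low versus intact. Three
thresholds operationalize the verbal criteria and are echoed in every
report: `dep_factor = 1.01` (S3 lower bound — a structurally
dose-independent topology differs from ratio 1 only by integrator
round-off, and a sub-1% effect would be invisible in a β-gal assay),
`flat_factor = 1.1` and `low_factor = 0.2` for S4.

`affinity_ratio_report()` summarizes the balance the fitted constants
imply: k1/k2 within one order of magnitude (LsrR binds both promoters
comparably), k4 > k2 (REG repression weaker than LsrR auto-repression),
k5 < k3 (AI-2-P prefers LsrR over REG).

## Synthetic data

The generator stands in for the wet-lab β-galactosidase assays.
`generate_model_truth()` samples the exact model reporter (optionally with
multiplicative log-normal noise, `ε ~ N(0, log(1+CV²))`, seeded) and is the
basis of all recovery tests. `generate_experiment_like()` emulates the
assay protocol: hourly sampling on [0, 480] min, the 7-dose panel
{0, 1, 2, 5, 10, 20, 40} µM (the experiments spanned 0–40 µM; the exact
dose list is not recorded, so a log-ish ladder is declared), and
per-scenario amplitude calibration. The absolute Miller-unit scale of the
model is unknowable, so each scenario's reporter is rescaled by one factor
making its noise-free top-dose peak hit the published summary exactly —
intact 70 and operon-knockout 200 Miller units; the lsrR (120) and lsrK
(10) targets are shape-preserving placeholders for scenarios without a
printed peak and are never used as quantitative ground truth. The scale
factors are emitted in the dataset's provenance attribute/sidecar so fits
can invert them. Default noise CV is 0.10, a typical bench variability for
this assay.

The rise-then-fall shape of the generated series is produced by the
model's own mechanism — external AI-2 depletion plus protein dilution —
not by an empirical growth envelope. What the generator does **not**
emulate: growth-phase physiology (OD normalization, stationary-phase
metabolic shutdown), day-to-day assay drift, and in vivo AI-2 synthesis. A
green recovery test therefore establishes that the estimation machinery
inverts the model's own data under the stated noise, not that the model is
identified from a real assay.

## Degenerate inputs and edge rules

Repressor concentration 0 gives exactly the maximal promoter rate (no
0⁰ ambiguity); a zero repression coefficient with a positive repressor
concentration is a domain error. Inadmissible parameter sets inside the
optimizer are penalized, outside it they error with every violation named.
Datasets must be non-empty with times in [0, 500] min; the weight column
defaults to 1.

## Limitations

In vivo AI-2 synthesis (LuxS pathway), CRP/glucose catabolite control,
explicit LsrK kinetics and growth dynamics beyond the constant dilution
term are out of scope. The Hooke–Jeeves search is local per start; global
coverage comes only from the Latin-hypercube restarts, and with the small
restart budgets used in the examples the joint-fit SSE values for badly
misspecified topologies are upper bounds, which is the direction that
matters for the discrimination argument.
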