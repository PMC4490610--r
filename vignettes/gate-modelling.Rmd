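---
title: "Steady-state modelling of layered bacterial logic gates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state modelling of layered bacterial logic gates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatestack)
```

## Scope and model

`gatestack` models the steady-state behaviour of transcriptional logic
circuits built from three bacterial primitives: inducible input devices,
the HrpR/HrpS-activated sigma-54 promoter pHrpL as an AND element, and
lambda CI operator sites downstream of a transcription start site as an
elongation-roadblock NOT element. Everything here is steady state: outputs
are endpoint, OD-normalised fluorescence values after a fixed induction
period. No kinetics, no mechanistic activator-DNA binding models and no
stochastic gene expression are attempted; population noise appears only in
the synthetic-data generator.

### Input devices

An input device is a promoter/RBS pair with a Hill transfer function

$$Y = A + \frac{B\,[X]^n}{C^n + [X]^n}$$

with basal output $A$ (au), dynamic range $B$ (au), switch point $C$
(mol/L) and cooperativity $n$. RBS strength enters as one proportional
factor $\alpha$ on $A$ and $B$ jointly. A shared factor is the only form
identifiable from a single calibration measurement, which is precisely the
use case of `rescale_rbs()`: predict a weaker variant's entire curve from
its output at one saturating concentration. Gate composition consumes the
basal-subtracted, range-normalised activation $a(x) = x^n/(C^n+x^n)$.

### Gate composition

* **AND**: $Y = G_0 + G_{max}\,(c/c_{ref})\,s\,a_S(x_a)\,a_R(x_r)$. The
  bilinear product form is the simplest surface consistent with the
  observed behaviour (off when either input is absent, reporter output
  linear in pHrpL copy number $c$, activator dosage saturating). A
  Hill-on-product variant was considered and rejected as
  under-constrained: no intermediate-activation data exist to pin its two
  extra parameters. $s$ is the activator share under competition (below).
* **OR**: the functional architectures (tandem design I and the
  dual-cassette design III) are additive, $Y = Y_a(x_a) + Y_b(x_r)$. The
  additivity assumption is known to overpredict at very high induction,
  where the expression machinery saturates; an optional soft cap
  $Y\,\mathrm{cap}/(Y+\mathrm{cap})$ is provided but off by default, so the
  model's stated domain is low-to-medium induction. Design II — the tandem
  order that puts the AraC-regulated pBAD promoter downstream — is modelled
  as its rhamnose arm alone: unliganded AraC loops pBAD and silences the
  shared transcript, a failure mode the design-rule checker flags
  structurally.
* **NOT / repression**: transmission through an operator-bearing hybrid
  promoter is $f(cl) = \varepsilon + (1-\varepsilon)/(1 + (cl/K_{eff})^h)$
  with repressor level $cl$ in normalised units ($cl_{max}=1$ at full
  driver activation, since absolute repressor concentrations are never
  measured). $K_{eff}$ multiplies $K_r$ by a site-configuration factor:
  250 for a single site (negligible repression without a hard zero), 1 for
  the dual perfect-dyad site, 1 for four sites (their failure is a UTR
  effect, not a repression effect), and a further 5 for sites placed
  distal to the transcription start site, encoding the observation that a
  roadblock far from the start needs more repressor to stall an RNA
  polymerase that has gained momentum.
* **5'-UTR hairpin penalty**: a logistic multiplier
  $u(h) = 1/(1+e^{k(h-h_0)})$ on the hairpin count $h$, with $h_0 = 5$,
  $k = 2$ so that $u(3) \approx 0.98$ (the evolved dual-site operator)
  and $u(7) \approx 0.02$ (the original/quadruple-site region). The count,
  not a folding energy, is the predictor: the biological contrast being
  captured is structural (7 versus 3 consecutive stem-loops), and a
  thermodynamic model would add parameters no available measurement
  constrains.
* **Activator competition**: two pHrpL modules on plasmids with copy
  numbers $c_{low}, c_{high}$ split the HrpRS pool as
  $w_{low} = c_{low}^{\gamma}/(c_{low}^{\gamma}+c_{high}^{\gamma})$.
  $\gamma = 0.6$ is calibrated so the standalone-AND to half-adder-CARRY
  ratio $1/w_{low} = 1+(c_{high}/c_{low})^{\gamma}$ is approximately 7 at
  copies 5 and 100, the observed cost of running the two gates in
  parallel. The half subtractor has a single pHrpL module, so competition
  defaults off there.

Layered predictors chain these factors: NIMPLY is
OR × repression(CI from pBAD) × $u(h)$; XOR (the dual-cassette design IV,
the only quantitative XOR — the failed designs I-III are handled
structurally by the design-rule checker) is
OR × repression(CI from AND) × $u(3)$; the half adder is AND (CARRY,
share $w_{low}$) in parallel with XOR (SUM, CI share $w_{high}$).

### Default calibration

All worked examples and the acceptance computations use one fixed
parameter set: pBAD $(A{=}30, B{=}3000, C{=}1.1{\times}10^{-4}, n{=}2)$,
pRHAB $(A{=}25, B{=}3500, C{=}5{\times}10^{-4}, n{=}1.8)$,
$G_0{=}50$, $G_{max}{=}1000$, $\varepsilon{=}0.02$, $K_r{=}0.15$, $h{=}2$,
$h_0{=}5$, $k{=}2$, $\gamma{=}0.6$, copies 5/100, $cl_{max}{=}1$, logic
inputs $7{\times}10^{-3}$ M arabinose and $2.8{\times}10^{-2}$ M rhamnose.
These are calibrated stand-ins chosen to respect every characterised
behaviour (switch points below the logic inputs, dynamic ranges in the
few-thousand-au range of OD-normalised reporter assays); the study's own
fitted device parameters are not published in recoverable form, so no
claim is made that these equal them.

## Fitting

`fit_hill()` minimises unweighted SSE on OD-normalised output using
Levenberg-Marquardt with box bounds ($A,B \ge 0$; $C$ within a decade of
the observed non-zero concentration range; $n \in (0, 10]$), multi-started
over $n_0 \in \{0.5, 1, 2, 4\}$ with $C_0$ at the geometric median of the
non-zero grid, $A_0 = \min y$, $B_0 = \max y - \min y$; the lowest-SSE
start wins. The unweighted linear-scale objective is the default because
the replicate noise of plate-reader fluorescence is roughly proportional
to signal only above background, and down-weighting the saturated plateau
would degrade $B$; a log-output objective (`objective = "log_sse"`) is
available for data spanning many decades. Flat datasets (range under 3
replicate SDs) short-circuit to a degenerate result ($B \approx 0$)
rather than an unstable fit. On the 17-point grid with 5 % lognormal
noise and 3 replicates, $B$ and $C$ are recovered within 15 % and $n$
within ±0.3 (property-tested over 20 seeds).

## Digital metrics

Outputs at the four conditions (0,0), (A,0), (0,B), (A,B) — this order is
fixed everywhere — yield delta (ON mean minus OFF max), fold change, and
leak, defined as $100\,(\text{worst OFF} - \min)/(\text{ON mean} - \min)$
so that basal output common to all conditions does not count as leak. The
ON/OFF call thresholds at a fixed fraction of the observed per-channel
dynamic range, which makes the call invariant under affine rescaling of
the channel. The fraction defaults to 0.4 rather than the midpoint: an
additive OR gate's single-input output is close to half its both-input
output by construction (the two arms have comparable dynamic ranges), so
a 0.5 threshold sits on top of the single-input level and misclassifies
it, whereas 0.4 classifies every implemented gate correctly at the
default calibration with margin on both sides (the nearest calls are the
OR single-input ON at 46 % of range and the XOR both-input leak at 8 %).
The fraction is exposed (`threshold_frac`) for users with differently
balanced channels.

## Sequence analysis

`count_hairpins()` scans the transcribed region (120 nt window by
default) left to right for perfect inverted repeats with stem ≥ 4 bp and
loop 3-8 nt, taking at each position the longest stem (shortest loop on
ties) and resuming after each accepted hairpin, so calls never overlap.
The scan is deterministic and is verified in the test suite against an
exhaustive $O(L^3)$ enumerator. Two properties deserve note. First, the
set of candidate inverted repeats is exactly strand-symmetric, and the
suite verifies this; the greedy selection, however, is directional, and
on rare sequences (about 0.6 % of random 20-60-mers) the forward and
reverse-complement scans accept different numbers of non-overlapping
hairpins — a known, documented property of greedy interval selection,
irrelevant for the well-separated hairpin arrays the penalty model
consumes. Second, the model deliberately ignores wobble pairs and
mismatched stems; `dyad_symmetry_score()` provides the complementary
site-level view (fraction of self-complementary positions, middle base of
odd sites ignored).

## Design-rule checker

`run_drc()` is a pure function of a cassette-level circuit description:
deterministic ordering by (plasmid, cassette, rule), severity `error` for
demonstrated hard failures (co-resident sigma-54 promoters, four identical
operator sites in one transcript, dual-function regulator downstream in a
tandem pair) and `warning` for risk factors (unevidenced crosstalk, RBS
imbalance above 5-fold, single operator sites, strong RBS on a repressed
stage). Sigma-54 proximity is defined as same-plasmid co-residency — the
demonstrated fix is plasmid separation, and no base-pair distance
threshold is established — with the downstream promoter flagged, since
that is the one switched on. Dual-function regulators are declared in the
schema rather than inferred from sequence, because the behaviour is known
mechanistically per regulator, not computable from the design.

## Synthetic data

The generator emulates: the twofold dilution grid built upward from
8.38e-7 M (16 doublings ending at 2.75e-2 M at 3 significant figures);
multiplicative lognormal replicate noise ($\sigma = \sqrt{\ln(1+cv^2)}$,
default $cv = 0.05$ as a realistic plate-reader figure — the true
replicate noise of the original assays is unknown and never asserted)
plus an additive 2-au background floor; OD600 near 0.5 with 5 % jitter,
with raw fluorescence stored as per-cell output × OD so that
normalisation round-trips; and 10,000-event lognormal flow populations
($\sigma_{log} = 0.4$) whose median equals the model output. What passing
tests on these data do show: the estimators and metrics are correct for
data generated by the stated model. What they do not show: robustness to
growth-dependent effects, inducer toxicity, day effects or non-lognormal
outliers present in real plate-reader and cytometry data.

## Numerical choices and degenerate inputs

Hill evaluation uses the $1/(1+(C/x)^n)$ form (no overflow at large $x$,
exact 0 activation at $x = 0$). Negative concentrations, non-positive
switch points, out-of-range leak floors, unsupported operator counts and
all-equal four-condition outputs raise immediate errors rather than
propagating NaN. OD rows at or below the blank are rejected with an
explicit row listing, never silently dropped. All generators take a seed
and are bitwise reproducible.

## Interfaces and problem sizes

The package follows an analysis-workflow layout: the `analysis/` scripts
are the narrative drivers and the exported functions are the programmatic
interface; file formats are CSV for tables (with JSON metadata sidecars),
JSON for models, designs and reports, FASTA for sequences. The test suite
runs the full property checks at moderate sizes (20 fit seeds on the
17-point grid, 500 random sequences for the hairpin oracle, 10,000-event
flow samples), sizes at which every estimate under test is already
stable.

## Known limitations

Steady state only; the OR additivity model over-predicts at very high
induction unless the cap is enabled; the AND/XOR functional forms are
calibrated phenomenological surfaces, not mechanistic models, and only
XOR design IV is quantitative; the hairpin model has no thermodynamics;
the sigma-54 rule is conservative (any same-plasmid pair); and the
default parameter set is a documented stand-in, so absolute output values
should not be read as predictions for any particular strain.
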