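---
title: "Methods: signal detection, onset modelling and network analysis in tcevigil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal detection, onset modelling and network analysis in tcevigil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcevigil)
```

# Scope and data model

`tcevigil` analyses spontaneous adverse-event reports for T-cell
engagers (TCEs) and CAR-T products. The unit of analysis is the
deduplicated *report*: one primary-suspect drug (resolved to a canonical
id with class and molecular target), a non-empty set of MedDRA-style
preferred terms (PTs), a set of outcome codes (DE/LT/HO/DS/CA/RI/OT,
with `fatal` defined as DE present), demographics that may be missing,
a calendar year, and — where both therapy start and event dates are
recorded at day resolution — a nonnegative onset interval in days.

Spontaneous data carry no exposure denominators: everything the package
computes is a *reporting* association, not an incidence or a causal
effect. That caveat applies to every statistic below.

# Deduplication protocol

Raw quarterly records are cleaned in three audited steps:

1. **Version selection.** Per case id, keep the record with the latest
   receipt date; ties break to the highest primary id. A missing receipt
   date is treated as oldest, so an undated version never displaces a
   dated one.
2. **Content duplicates.** Records identical on a configurable field key
   collapse to the lexicographically smallest primary id. The default
   key — event date, age, sex, weight, country, sorted PT set, sorted
   drug-name set — mirrors common FAERS practice; the field list is an
   argument because no canonical definition exists.
3. **Deletion lists.** Case ids on the quarterly withdrawal list are
   dropped.

The protocol is idempotent, and the audit counts always sum to the
difference between input and output sizes. Unit normalisation happens at
cohort assignment: age codes YR/MON/WK/DY/DEC convert to years and
values outside [0, 120] become missing (implausible entries are common
in raw data); weights in pounds convert to kg; negative onset intervals
(event before start — date-entry errors) become missing rather than
contributing negative times.

# The 2×2 table and its three frameworks

Every disproportionality statistic is computed from the table
a = exposed ∧ event, b = exposed only, c = event only, d = neither.
Counting is at report level: a report with several matching PTs still
contributes one to `a`. (Mention-level counting is a recognised
alternative; report-level is the standard SRS construction and the one
implemented. The choice matters only for multi-PT reports.) The
background cells (c, d) always come from the *non-exposed* reports in
scope, so the three comparison frameworks are obtained purely by
choosing the scope: exposure class versus the whole database background,
or one therapeutic class versus the other by restricting the scope to
their union.

# The eight estimators

For one pair the package reports:

* **ROR** = (a·d)/(b·c), CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`.
* **PRR** = [a/(a+b)]/[c/(c+d)], analogous log-scale Wald CI.
* **χ²** — Yates-corrected Pearson statistic (via `chisq.test`).
* **Fisher** — two-sided exact hypergeometric p (via `fisher.test`).
* **O/E** — a divided by E = (a+b)(a+c)/N, with the exact Poisson
  (Garwood) bounds on a divided by E; the lower bound is 0 when a = 0.
* **BCPNN, normal approximation** — the information component
  IC = log₂ p₁₁/(p₁.p.₁) with the classical closed-form posterior
  moments under marginal Beta(1,1) priors and a joint prior centred on
  independence; IC₀₂₅ = E(IC) − 1.96·√V(IC). The prior constants are
  stated in the code and are validated by agreement with the Monte Carlo
  variant rather than transcribed blindly: the posterior expectation of
  the two variants agrees to 0.1 bits once all cells reach ~20 and the
  margins are not tiny, and the 2.5th percentiles converge in the
  large-count limit. They differ at small counts because the joint
  prior mass differs — that is a property of the two published
  constructions, not an implementation artefact.
* **BCPNN, Monte Carlo** — cell probabilities drawn from
  Dirichlet((1,1,1,1) + counts), IC per draw, median and 2.5th
  percentile reported; 10,000 draws by default and fully seeded, so
  results are bit-reproducible.
* **EBGM** — the DuMouchel gamma-Poisson shrinker. The relative
  reporting rate λ has a two-component gamma mixture prior whose five
  hyperparameters are estimated by maximising the marginal
  negative-binomial mixture likelihood of all pair counts given their
  expectations. EBGM = 2^{E[log₂ λ | a]}; EB05 is the 5th posterior
  percentile.

**Zero cells.** The Haldane–Anscombe +0.5 correction is applied to all
four cells for the ROR/PRR point and interval *only* when a zero cell
exists (flagged in the output); Fisher, O/E and the Bayesian estimators
always use raw counts, which they handle natively.

**Signal thresholds** follow the standard multi-algorithm battery:
ROR₀₂₅ > 1 ∧ a ≥ 3; PRR₀₂₅ ≥ 1 ∧ a ≥ 3; χ² ≥ 4 ∧ PRR ≥ 2 ∧ a ≥ 3;
Fisher p < 0.05; O/E₀₂₅ > 1; IC₀₂₅ > 0 (both variants); EBGM₀₅ ≥ 2.
Flags are recomputable from the stored statistics.

**Drug-specificity ratio.** For an event, the highest per-drug ROR
divided by the second-highest across the cohort. A pair is a
drug-specific signal when the top drug meets the ROR signal criteria,
its ROR exceeds 5 and the ratio exceeds 10; an event reported for only
one drug has an infinite ratio, which counts as specific. The ROR
criteria alone gate this filter — the other seven algorithms inform the
per-pair evidence table but are not part of the specificity definition.

## Numerical choices for the GPS fit

The GPS marginal likelihood has a well-known ridge. The optimiser is
BFGS on unconstrained transforms (log for the four gamma parameters,
logit for the weight) from DuMouchel's classical starting values
(0.2, 0.1, 2, 4, 1/3) plus four jittered restarts (N(0, 0.5²) on the
transformed scale, seeded); the best of the five solutions wins.
Non-finite exploratory evaluations are assigned a large penalty instead
of erroring. EB05 has no closed form and is found by numerical inversion
of the posterior mixture CDF (`uniroot`, tolerance 1e-8, with an upper
bracket doubled until it covers the quantile). On data actually drawn
from a single gamma the two fitted components typically overlap rather
than pushing the weight to a boundary — the fit is then judged by its
predictive behaviour, which the tests compare against the generating
single component.

# Time-to-onset and the Weibull shape parameter

With no censoring in spontaneous reports, the Kaplan-Meier cumulative
incidence reduces to the empirical CDF; medians and IQRs are type-7
quantiles of the raw day values, reported at day resolution. Group
comparisons use the two-sided Wilcoxon rank-sum test (two groups) or
Kruskal-Wallis (more), both tie-corrected.

The Weibull shape α classifies the reporting hazard: the 95% CI entirely
below 1 is called *early-peaking*, spanning 1 *constant-rate*, entirely
above 1 *late-peaking*. CIs are Wald intervals from the observed
information on log-parameters.

**Day-zero handling.** Onset data are day counts, so 0 is a legitimate
value but the Weibull support is positive. Two conventions are
implemented. The default for integer data is the **interval-censored
likelihood**: a recorded day d is the event "onset in [d, d+1)", and
the likelihood term is F(d+1) − F(d). The alternative (`method =
"shift"`) is the half-day convention — 0 becomes 0.5, other values stay
— followed by the continuous MLE via Newton iteration on the profile
shape equation. The interval likelihood is the default because the
continuous fit on day-rounded data is materially biased when the scale
is only a few days: with a generating shape of 0.6–0.7 and scale ~5
days, a third of the mass falls in [0, 1) and collapsing it to one
point inflates the fitted shape by roughly +0.07 to +0.12 — enough to
move an early-peaking signal toward the constant-rate boundary. The
test suite quantifies this: the interval fit keeps the mean absolute
shape error at or below 0.03 at n = 2000 across shapes 0.5–1.5 and its
CI covers the generating shape at the nominal rate, while the shift
convention remains available for sensitivity analysis.

# Co-occurrence network

Within the exposure cohort's reports (class effects are the object of
study, so lifts are computed over TCE reports rather than the whole
database — switchable), candidate PTs are those whose
exposure-versus-background Fisher p, Benjamini-Hochberg adjusted across
all tested PTs, is below 0.05. For a PT pair,
lift = (n_ab/N) / ((n_a/N)(n_b/N)); an undirected edge is admitted when
n_ab ≥ 10 and lift > 2 (strict), weighted by lift, and isolated nodes
are dropped. Louvain community detection runs at resolution 1 with the
node-order randomisation controlled by the seed; the weighted modularity
Q of the returned partition is reported. Within each community,
weighted eigenvector centrality on the community's *induced subgraph*
identifies the hub PT; exact ties break lexicographically so results
are deterministic. The intersection (UpSet-style) table reports exact
subset counts — a report contributes to exactly one subset, the one
equal to its intersection with the AE list — with per-subset outcome
distributions and target breakdowns.

# Cohort statistics

Between-cohort tables use complete-case analysis per variable:
continuous variables as median [Q1–Q3] with the Wilcoxon rank-sum test,
categorical as n (%) on the non-missing denominator with Pearson's χ²,
switching to Fisher's exact test when any expected cell is below 5
("as appropriate" needs an operational rule; this is the textbook one).
The fatal-outcome trend uses the Cochran-Armitage statistic with
consecutive integer year scores and a two-sided p. Univariate
risk-factor ORs (age ≥ 65 vs < 65; indication group vs leukaemia;
target vs CD19; weight ≥ 80 kg vs < 80; concurrent CRS — defined as the
CRS PT in the same report, since report-level data carry no intra-report
timing — vs none) are 2×2 odds ratios with Woolf CIs; zero cells get
the +0.5 correction and are flagged. Multivariable adjustment is
deliberately out of scope: with the missingness patterns of spontaneous
data it would suggest a rigour the data cannot support.

# The synthetic generator: what it emulates, and what it does not

`srsConfig()`/`generateSrs()` produce a database with known structure:

* **Drugs** drawn by marketing-share weight from the bundled roster of
  real TCE/CAR-T products (shares are plausibility weights, not market
  data).
* **Events** per PT as Bernoulli draws from a ~200-term mock vocabulary
  with 27 organ-class groupings. The named clinical-syndrome terms carry
  base probabilities chosen to echo the reporting frequencies typical of
  this drug class (CRS ≈ 17%, pyrexia ≈ 10%, ICANS ≈ 6%, ...); filler
  terms are systematic. The dictionary is synthetic — it mirrors the
  *structure* of a licensed terminology, not its content.
* **Planted signals**: a drug- or class-level odds ratio multiplies the
  base odds of a PT for matching reports.
* **Planted co-occurrence**: for a pair with target lift L, an anchor PT
  is drawn at its base rate p_A and the partner at conditional rate
  L·p_B given the anchor (and the compensating rate otherwise), which
  makes the population lift exactly L. This is exact in expectation only
  for disjoint pairs, so overlapping pairs — or pairs sharing a PT with
  a planted odds ratio — are rejected at validation, and an implied
  conditional probability above 1 is a hard error naming the pair.
  *Blocks* of PTs with a common pairwise lift use a shared latent
  Bernoulli activation instead, with the high/low member probabilities
  solved in closed form from the marginal and the lift target.
* **Onset times** from per-(class, PT) Weibull models, floored to whole
  days (so day 0 is representable, matching the 0–2 day medians typical
  of acute onset); first matching rule wins, with a class default.
* **Fatality** per year, linearly interpolated between configured
  endpoints (defaults 0.143 → 0.235 across 2015–2025), overridden by
  PT-set conditionals applied most-specific-last — which is how a
  severity hierarchy such as CRS < CRS+ICANS < CRS+ICANS+infection is
  planted.
* **Missingness** per field (defaults echo the heavy missingness of
  real demographics: weight ~79%, age ~44%, onset dates ~45%), and
  **duplicate injection** that emits version duplicates and content
  clones the deduplication protocol must remove exactly.

Every report keeps at least one event (empty draws are resampled), and
the ground-truth ledger re-counts the planted 2×2 tables and lifts from
the emitted reports, so "the ledger matches the data" is itself a tested
invariant. Identical config + seed gives identical output.

**What passing tests do and do not show.** The generator draws
conditionally independent events given the planted structure, carries no
reporting biases, no drug-name misspellings, no narrative text, no
secular changes in coding practice, and its demographics are simple
parametric draws. Tests against it validate the *estimators and the
pipeline plumbing* — recovery of planted parameters, calibration under
the null, exact undoing of injected duplicates — not the behaviour of
the methods under real-world reporting artefacts such as stimulated
reporting, duplicate clusters that differ in a key field, or
indication-driven confounding.

# Problem sizes and runtime choices

The bundled validation uses sizes chosen to make Monte Carlo error
negligible relative to the tolerance being checked while keeping the
whole suite in the one-minute range: planted odds-ratio and lift
recovery at n = 100,000 reports; community separation and the fatality
hierarchy at n = 50,000; Weibull recovery at n = 2,000 onsets (100
seeds for the CI-coverage property); trend-test calibration over 2,000
null simulations; oracle equivalence over 1,000 random tables. The
BCPNN MCMC default of 10,000 draws keeps the 2.5th-percentile Monte
Carlo error near 0.01 bits; batch drivers default to 2,000 draws per
pair, which is sufficient for flag stability.

# Interfaces and the pipeline driver

The package is an R library: the analysis surface is its functions, the
configuration-driven `runPipeline()` binds the stages (input →
deduplication → cohort assignment → contingency/signals →
drug-specificity → onset → network → cohort statistics) with
stage-tagged errors, per-stage child seeds derived from the global seed
(stage k uses `seed*10 + k`), and a JSON manifest carrying the seed,
stage counts and threshold echo, so a rerun with the same inputs and
seed is identical. YAML configs are validated against a closed key set —
unknown keys are hard errors, because silently ignored options are how
analyses diverge from their descriptions.

# Known limitations

Reporting associations only; no exposure denominators, no severity
grades, no causal claims. The BCPNN normal and Monte Carlo variants
deliberately implement two different published priors and therefore
differ at small counts. The GPS fit assumes a two-component prior; data
from more heterogeneous mixtures will be summarised, not discovered.
The content-duplicate key is heuristic — near-duplicates differing in
any key field survive. VigiBase-style record-level data are out of
scope; only the internal data model and the FAERS-dialect reader are
provided.
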