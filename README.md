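# tcevigil

Multi-level pharmacovigilance signal detection for T-cell redirecting
therapies (T-cell engagers and CAR-T products) from spontaneous
reporting system (SRS) data, with a fully seeded synthetic SRS generator
so every stage of the pipeline can be validated against planted ground
truth without any external download.

## What it does, and for whom

Drug-safety researchers mining databases such as FAERS face a chain of
methodological steps — report deduplication, cohort assignment,
disproportionality analysis, onset-time modelling, adverse-event
clustering, and cohort statistics — that are usually re-implemented ad
hoc per study. `tcevigil` packages that chain for the T-cell redirecting
therapy setting:

* **Ingestion & deduplication** — reads `$`-delimited FAERS-dialect
  quarterly ASCII tables (DEMO/DRUG/REAC/OUTC/THER/INDI), keeps the
  latest version of each case (by case id, receipt date, primary id),
  collapses content duplicates on a configurable field key, applies
  deletion lists, and resolves primary-suspect drug names against a
  registry of TCE/CAR-T products with brand-name synonyms.
* **Eight-algorithm disproportionality analysis** on 2×2 contingency
  tables `(a, b, c, d)`: reporting odds ratio
  ROR = (a·d)/(b·c) with Wald CI, proportional reporting ratio
  PRR = [a/(a+b)]/[c/(c+d)], Yates-corrected χ², Fisher's exact test,
  observed/expected ratio O/E = a / [(a+b)(a+c)/N] with exact Poisson
  (Garwood) interval, the BCPNN information component
  IC = log₂ p₁₁/(p₁·p·₁) in both its closed-form normal approximation
  and a seeded Dirichlet Monte Carlo variant, and the DuMouchel
  gamma-Poisson shrinker (EBGM with EB05). Standard signal thresholds
  (ROR₀₂₅ > 1 ∧ a ≥ 3; PRR₀₂₅ ≥ 1 ∧ a ≥ 3; χ² ≥ 4 ∧ PRR ≥ 2 ∧ a ≥ 3;
  p < 0.05; O/E₀₂₅ > 1; IC₀₂₅ > 0; EBGM₀₅ ≥ 2) are evaluated per pair,
  and a **drug-specificity ratio** (highest ROR for an event divided by
  the second-highest across the cohort; infinite counts as specific)
  separates molecule-specific toxicities from class effects.
* **Time-to-onset analysis** — Kaplan-Meier/ECDF cumulative incidence,
  Wilcoxon/Kruskal-Wallis group comparison, and Weibull shape-parameter
  fitting by interval-censored maximum likelihood (shape α < 1 ⇒
  early-peaking reporting hazard).
* **Co-occurrence networks** — BH-filtered significant PTs, pairwise
  lift = N·n_ab/(n_a·n_b), edges admitted at n_ab ≥ 10 and lift > 2,
  Louvain communities with weighted modularity, per-community weighted
  eigenvector-centrality hubs, and exact UpSet-style intersection tables
  with outcome breakdowns.
* **Cohort statistics** — complete-case TCE-vs-CAR-T comparison tables
  (Wilcoxon, χ²/Fisher), Cochran-Armitage trend test for the fatal
  proportion over calendar years, and univariate odds-ratio risk-factor
  analysis for ICANS occurrence and ICANS fatality.
* **Synthetic SRS generator** — seeded, with planted drug-event odds
  ratios, pairwise co-occurrence lifts and lift blocks, per-(class, PT)
  Weibull onset models, a per-year fatality trend with PT-conditional
  overrides, configurable missingness, and duplicate injection — plus a
  ground-truth ledger so recovered statistics can be compared to the
  generating parameters.

## Worked example

```r
library(tcevigil)
icans <- "immune effector cell-associated neurotoxicity syndrome"

cfg <- srsConfig(
  n_reports = 20000, seed = 42,
  signals = data.frame(drug = c("talquetamab", "TCE"),
                       pt = c("dry mouth", "infection"),
                       or = c(20, 2)),
  cooc = data.frame(pt_a = "cytokine release syndrome",
                    pt_b = icans, lift = 2.71))
sim <- generateSrs(cfg)

st <- signalTable(reportData(sim), c("talquetamab", "blinatumomab"),
                  c("dry mouth", "pyrexia"), mcmc_draws = 2000, seed = 1)
st[, c("exposure", "event", "a", "ror", "ror_lo", "ror_hi",
       "ebgm", "eb05", "flag_ror", "flag_ebgm")]
#>       exposure     event   a    ror ror_lo ror_hi  ebgm  eb05 flag_ror flag_ebgm
#> 1  talquetamab dry mouth 294 21.683 18.177 25.865 8.636 8.620     TRUE      TRUE
#> 2  talquetamab   pyrexia 116  0.959  0.787  1.168 0.943 0.816    FALSE     FALSE
#> 3 blinatumomab dry mouth  92  0.469  0.375  0.588 0.591 0.503    FALSE     FALSE
#> 4 blinatumomab   pyrexia 574  0.986  0.891  1.092 0.985 0.920    FALSE     FALSE
```

The planted talquetamab–dry-mouth signal (odds ratio 20) is flagged by
both the frequentist ROR (21.7, CI above 1, a ≥ 3) and the shrinkage
estimator (EB05 8.6 ≥ 2); the unplanted pairs stay near 1 and unflagged.
The EBGM sits well below the raw ROR — that is the empirical-Bayes
shrinkage doing its job on a single quarter's worth of evidence.

```r
tce <- reportData(sim)[reportData(sim)$drug_class == "TCE", ]
weibullFit(extractTto(tce, icans))
#> WeibullFit (interval, n=507): shape 0.600 (95% CI 0.554-0.649),
#>   scale 4.66 days -> early-peaking

ft <- fatalTrend(sim@reports)
#> fatal % 2015 -> 2025: 14.7% -> 23.5%, trend p = 4.74e-26
```

The fitted shape parameter recovers the generating early-peaking onset
model (α = 0.63 planted; CI excludes 1), and the Cochran-Armitage test
finds the planted rise in the fatal-outcome proportion.

The full chain — ingestion, dedup, signals, DSR, onset, network, cohort
statistics — runs from one configuration object:

```r
res <- runPipeline(pipelineConfig(
  input = list(mode = "synthetic", config = cfg),
  seed = 42, out_dir = "out"))
```

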