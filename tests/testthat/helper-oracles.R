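# Independent brute-force oracles and fixture builders used across the
# test files. Oracles are written directly from first principles so they
# stay independent of the package code paths they check.

# --- closed-form disproportionality oracles ---------------------------------

o_ror <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) { a <- a + .5; b <- b + .5; c <- c + .5; d <- d + .5 }
  pt <- exp(log(a) + log(d) - log(b) - log(c))
  se <- sqrt(1/a + 1/b + 1/c + 1/d)
  c(pt, pt * exp(-1.96 * se), pt * exp(1.96 * se))
}

o_prr <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) { a <- a + .5; b <- b + .5; c <- c + .5; d <- d + .5 }
  pt <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1/a - 1/(a + b) + 1/c - 1/(c + d))
  c(pt, pt * exp(-1.96 * se), pt * exp(1.96 * se))
}

# textbook Yates formula with the |O-E| <= 0.5 clamp
o_chi2_yates <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(E == 0)) return(NA_real_)
  sum((pmax(abs(m - E) - 0.5, 0))^2 / E)
}

# exhaustive two-sided hypergeometric enumeration
o_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; cs <- a + c; N <- a + b + c + d
  lo <- max(0, r1 + cs - N); hi <- min(r1, cs)
  probs <- dhyper(lo:hi, cs, N - cs, r1)
  p_obs <- dhyper(a, cs, N - cs, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

o_oe <- function(a, b, c, d) {
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  lo <- if (a == 0) 0 else qchisq(0.025, 2 * a) / 2
  hi <- qchisq(0.975, 2 * (a + 1)) / 2
  c(a / E, lo / E, hi / E)
}

# posterior E[log lambda] and 5th percentile for the gamma mixture, by
# numerical integration / fine grid (independent of the digamma route)
o_ebgm <- function(a, E, hp) {
  w1 <- hp@mix_p * dnbinom(a, size = hp@alpha1, prob = hp@beta1 / (hp@beta1 + E))
  w2 <- (1 - hp@mix_p) * dnbinom(a, size = hp@alpha2, prob = hp@beta2 / (hp@beta2 + E))
  Q <- w1 / (w1 + w2)
  f <- function(x) (Q * dgamma(x, hp@alpha1 + a, rate = hp@beta1 + E) +
                      (1 - Q) * dgamma(x, hp@alpha2 + a, rate = hp@beta2 + E))
  elog <- integrate(function(x) log(x) * f(x), 0, Inf, rel.tol = 1e-10)$value
  cdf <- function(x) Q * pgamma(x, hp@alpha1 + a, rate = hp@beta1 + E) +
    (1 - Q) * pgamma(x, hp@alpha2 + a, rate = hp@beta2 + E)
  eb05 <- uniroot(function(x) cdf(x) - 0.05, c(1e-12, 1e6), tol = 1e-10)$root
  c(ebgm = exp(elog), eb05 = eb05)
}

# random small 2x2 tables; strictly positive cells when positive = TRUE
random_tables <- function(n, seed, max_cell = 30, positive = FALSE) {
  set.seed(seed)
  lo <- if (positive) 1 else 0
  t(replicate(n, {
    repeat {
      x <- sample(lo:max_cell, 4, replace = TRUE)
      if (sum(x) > 0 && (x[1] + x[2]) > 0 && (x[1] + x[3]) > 0) return(x)
    }
  }))
}

# --- graph oracles ----------------------------------------------------------

# principal eigenvector of a weighted adjacency matrix, scaled to max 1
o_eigen_centrality <- function(adj) {
  e <- eigen(adj, symmetric = TRUE)
  v <- abs(e$vectors[, 1])
  v / max(v)
}

adj_rand_index <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# --- fixture builders -------------------------------------------------------

tiny_registry <- function() {
  drugs <- data.frame(
    drug_id = c("blinatumomab", "talquetamab", "tisagenlecleucel"),
    class = c("TCE", "TCE", "CART"),
    target = c("CD19", "GPRC5D", "CD19"),
    stringsAsFactors = FALSE)
  drugs$synonyms <- list(c("blinatumomab", "BLINCYTO"),
                         c("talquetamab", "TALVEY"),
                         c("tisagenlecleucel", "KYMRIAH"))
  drugRegistry(drugs)
}

# build a SafetyReportSet from parallel vectors; events as a list
mk_reports <- function(drug_id, events, fatal = FALSE, tto = NA_real_,
                       year = 2020L, age = NA_real_, sex = NA_character_,
                       weight = NA_real_, target = NULL, drug_class = NULL,
                       indication = NA_character_) {
  n <- length(events)
  lookup <- c(blinatumomab = "TCE", talquetamab = "TCE",
              teclistamab = "TCE", tisagenlecleucel = "CART",
              `axicabtagene ciloleucel` = "CART")
  tg <- c(blinatumomab = "CD19", talquetamab = "GPRC5D",
          teclistamab = "BCMA", tisagenlecleucel = "CD19",
          `axicabtagene ciloleucel` = "CD19")
  drug_id <- rep_len(drug_id, n)
  fatal <- rep_len(fatal, n)
  df <- data.frame(
    report_id = sprintf("R%04d", seq_len(n)),
    drug_id = drug_id,
    drug_class = if (is.null(drug_class)) unname(lookup[drug_id])
    else rep_len(drug_class, n),
    target = if (is.null(target)) unname(tg[drug_id]) else rep_len(target, n),
    fatal = fatal,
    age_years = rep_len(age, n), sex = rep_len(sex, n),
    weight_kg = rep_len(weight, n), region = NA_character_,
    reporter = NA_character_,
    indication_group = rep_len(indication, n),
    year = rep_len(as.integer(year), n),
    tto_days = rep_len(tto, n), stringsAsFactors = FALSE)
  df$events <- events
  df$outcomes <- lapply(fatal, function(f) if (f) c("DE") else c("OT"))
  methods::new("SafetyReportSet", reports = df, audit = list())
}

# minimal one-PT generator config for onset-time studies
tto_config <- function(n, shape, scale, seed, class = "TCE",
                       pt = "immune effector cell-associated neurotoxicity syndrome",
                       target = "BCMA", fatality = list(p_start = 0.2, p_end = 0.2)) {
  srsConfig(
    n_reports = n, seed = seed,
    drugs = data.frame(drug_id = "drugA", class = class, target = target,
                       share = 1),
    pts = data.frame(pt = pt, soc = "Nerv", base_p = 1),
    tto = data.frame(class = class, pt = NA, shape = shape, scale = scale),
    fatality = fatality,
    missingness = c(age = 0, sex = 0, weight = 0, region = 0, reporter = 0,
                    indication = 0, dates = 0))
}
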