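# Gamma-Poisson shrinker: simulate counts from a known two-component
# prior, refit, and check the fit dominates the generating parameters in
# likelihood while reproducing the posterior scores of the truth.

sim_gps_cells <- function(n, hp, seed) {
  set.seed(seed)
  E <- exp(runif(n, log(0.5), log(50)))
  comp <- runif(n) < hp$P
  lam <- ifelse(comp, rgamma(n, hp$a1, rate = hp$b1),
                rgamma(n, hp$a2, rate = hp$b2))
  list(a = rpois(n, lam * E), E = E)
}

true_hp <- list(a1 = 0.8, b1 = 2, a2 = 3, b2 = 2.5, P = 0.4)

test_that("GPS fit recovers the generating prior's predictive behaviour", {
  cells <- sim_gps_cells(2000, true_hp, seed = 31)
  fit <- ebgmFit(cells$a, cells$E, seed = 32)
  expect_equal(fit@convergence, 0)
  # the MLE must dominate the generating parameters on the sample
  nll_at <- function(a1, b1, a2, b2, P) {
    l1 <- dnbinom(cells$a, size = a1, prob = b1 / (b1 + cells$E), log = TRUE)
    l2 <- dnbinom(cells$a, size = a2, prob = b2 / (b2 + cells$E), log = TRUE)
    m <- pmax(l1, l2)
    sum(m + log(P * exp(l1 - m) + (1 - P) * exp(l2 - m)))
  }
  ll_true <- nll_at(true_hp$a1, true_hp$b1, true_hp$a2, true_hp$b2, true_hp$P)
  expect_gte(fit@loglik, ll_true - 1e-6)
  # posterior scores under fitted vs generating prior agree closely
  hp_true <- new("GpsHyperparams", alpha1 = true_hp$a1, beta1 = true_hp$b1,
                 alpha2 = true_hp$a2, beta2 = true_hp$b2, mix_p = true_hp$P,
                 loglik = ll_true, convergence = 0)
  test_a <- c(0, 2, 5, 20, 60)
  test_E <- c(1, 1, 2, 5, 6)
  s_fit <- ebgmScore(hyper = fit, a = test_a, E = test_E)
  s_true <- ebgmScore(hyper = hp_true, a = test_a, E = test_E)
  expect_equal(s_fit$ebgm, s_true$ebgm, tolerance = 0.1)
})

test_that("likelihood at the optimum is at least the likelihood at the start", {
  cells <- sim_gps_cells(500, true_hp, seed = 33)
  start <- c(0.2, 0.1, 2, 4, 1/3)
  fit <- ebgmFit(cells$a, cells$E, start = start, seed = 34)
  nll_start <- {
    l1 <- dnbinom(cells$a, size = start[1],
                  prob = start[2] / (start[2] + cells$E), log = TRUE)
    l2 <- dnbinom(cells$a, size = start[3],
                  prob = start[4] / (start[4] + cells$E), log = TRUE)
    m <- pmax(l1, l2)
    sum(m + log(start[5] * exp(l1 - m) + (1 - start[5]) * exp(l2 - m)))
  }
  expect_gte(fit@loglik, nll_start)
})

test_that("single-component data are fit without spurious structure", {
  # data from one gamma: the overparameterised mixture must reproduce the
  # single component's predictive behaviour instead of inventing signal
  set.seed(35)
  E <- exp(runif(800, log(1), log(30)))
  a <- rpois(800, rgamma(800, 2, rate = 2) * E)
  fit <- ebgmFit(a, E, seed = 36)
  prior_mean <- fit@mix_p * fit@alpha1 / fit@beta1 +
    (1 - fit@mix_p) * fit@alpha2 / fit@beta2
  expect_lt(abs(prior_mean - 1), 0.15)
  hp_true <- new("GpsHyperparams", alpha1 = 2, beta1 = 2, alpha2 = 2,
                 beta2 = 2, mix_p = 0.5, loglik = 0, convergence = 0)
  grid_a <- c(0, 2, 5, 20); grid_E <- c(1, 2, 2, 4)
  s_fit <- ebgmScore(hyper = fit, a = grid_a, E = grid_E)
  s_true <- ebgmScore(hyper = hp_true, a = grid_a, E = grid_E)
  expect_equal(s_fit$ebgm, s_true$ebgm, tolerance = 0.1)
})

test_that("EBGM scores agree with numerical-integration oracles", {
  cells <- sim_gps_cells(1000, true_hp, seed = 37)
  fit <- ebgmFit(cells$a, cells$E, seed = 38)
  for (case in list(c(0, 2), c(3, 1), c(15, 2), c(40, 30))) {
    got <- ebgmScore(hyper = fit, a = case[1], E = case[2])
    ref <- o_ebgm(case[1], case[2], fit)
    expect_equal(got$ebgm, unname(ref["ebgm"]), tolerance = 1e-6)
    expect_equal(got$eb05, unname(ref["eb05"]), tolerance = 1e-6)
  }
})

test_that("shrinkage has the right direction and ordering", {
  cells <- sim_gps_cells(1000, true_hp, seed = 39)
  fit <- ebgmFit(cells$a, cells$E, seed = 40)
  # eb05 <= ebgm always
  s <- ebgmScore(hyper = fit, a = c(0, 1, 5, 10, 50, 200),
                 E = c(1, 2, 1, 2, 10, 20))
  expect_true(all(s$eb05 <= s$ebgm + 1e-9))
  # EBGM between 1 and a/E for strong signals (prior pulls toward ~1)
  s2 <- ebgmScore(hyper = fit, a = c(30, 100), E = c(3, 10))
  expect_true(all(s2$ebgm < c(30 / 3, 100 / 10)))
  expect_true(all(s2$ebgm > 1))
  # shrinkage vanishes for very large counts: a/E = 10
  s3 <- ebgmScore(hyper = fit, a = 20000, E = 2000)
  expect_equal(s3$ebgm, 10, tolerance = 0.05)
  # a = 0: pulled to the small-signal region, below 1
  s0 <- ebgmScore(hyper = fit, a = 0, E = 5)
  expect_lt(s0$ebgm, 1)
  expect_lt(s0$eb05, s0$ebgm)
})
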