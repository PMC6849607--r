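test_that("trait containers validate their invariants", {
  expect_error(metabolic_traits(-1, 0.5, 0.3, 0.4), "B0")
  expect_error(metabolic_traits(1, 0.5, 0, 0.4), "K0")
  expect_error(metabolic_traits(1, Inf, 0.3, 0.4), "finite")
  tr <- metabolic_traits(0.8, 0.6, 0.3, 0.4)
  expect_s3_class(tr, "metabolic_traits")
  expect_equal(tr$T_ref_K, 288.15)
})

test_that("realised growth rate composes its Monod and Arrhenius identities", {
  tr <- metabolic_traits(0.8, 0.6, 0.3, 0.4)
  expect_equal(realised_growth_rate(tr, tr$T_ref_K, 0.3), 0.4)  # B0 / 2
  T_K <- celsius_to_kelvin(25)
  mu_max_T <- arrhenius_value(0.8, 0.6, T_K, tr$T_ref_K)
  expect_equal(realised_growth_rate(tr, T_K, 1e9), mu_max_T,
               tolerance = 1e-8)
  expect_equal(realised_growth_rate(tr, T_K, 1),
               oracle_mu(0.8, 0.6, 0.3, 0.4, T_K, 1, tr$T_ref_K),
               tolerance = 1e-15)
})

test_that("identical competitors tie and swapping competitors negates R", {
  a <- metabolic_traits(0.8, 0.6, 0.3, 0.4)
  same <- competitive_advantage_R(a, a, 298.15, 1)
  expect_identical(same$R, 0)
  expect_identical(same$winner, "tie")

  set.seed(42)
  for (i in 1:50) {
    tr <- random_traits(2)
    T_K <- runif(1, 280, 310); S <- runif(1, 0.01, 50)
    fwd <- competitive_advantage_R(tr[[1]], tr[[2]], T_K, S)
    bwd <- competitive_advantage_R(tr[[2]], tr[[1]], T_K, S)
    expect_identical(fwd$R, -bwd$R)
    fi <- competitive_advantage_Rinf(tr[[1]], tr[[2]], T_K)
    bi <- competitive_advantage_Rinf(tr[[2]], tr[[1]], T_K)
    expect_identical(fi$R, -bi$R)
  }
})

test_that("the saturated advantage drops the half-saturation traits and is the S -> Inf limit", {
  a <- metabolic_traits(0.8, 0.6, 0.05, 0.1)
  b <- metabolic_traits(0.8, 0.6, 3.0, 0.9)   # same B0/E_mu, wildly different K
  expect_identical(competitive_advantage_Rinf(a, b, 300)$R, 0)

  at_ref <- competitive_advantage_Rinf(metabolic_traits(0.9, 0.2, 1, 1),
                                       metabolic_traits(0.7, 1.4, 1, 1),
                                       288.15)
  expect_identical(at_ref$winner, "a")  # larger B0 wins at T_ref

  set.seed(7)
  checked <- 0
  while (checked < 50) {
    tr <- lapply(1:2, function(j)
      metabolic_traits(runif(1, 0.1, 2), runif(1, -0.5, 1.5),
                       runif(1, 0.01, 10), runif(1, -0.5, 1.5)))
    T_K <- runif(1, 280, 310)
    K_T <- vapply(tr, function(x)
      arrhenius_value(x$K0, x$E_K, T_K, x$T_ref_K), numeric(1))
    if (any(K_T > 10)) next  # the limit statement presumes K values <= 10
    checked <- checked + 1
    R_S <- competitive_advantage_R(tr[[1]], tr[[2]], T_K, 1e6, t_days = 14)$R
    R_inf <- competitive_advantage_Rinf(tr[[1]], tr[[2]], T_K, t_days = 14)$R
    # relative to the saturated-advantage scale t * mu_max; the two terms
    # can cancel in R_inf itself, which would make a ratio to R_inf ill-posed
    scale <- 14 * max(vapply(tr, function(x)
      arrhenius_value(x$B0, x$E_mu, T_K, x$T_ref_K), numeric(1)))
    expect_lt(abs(R_S - R_inf), 1e-4 * scale)
  }
})

test_that("time linearity holds and the winner is horizon-invariant", {
  set.seed(11)
  tr <- random_traits(2)
  r1 <- competitive_advantage_R(tr[[1]], tr[[2]], 295, 2, t_days = 1)
  r14 <- competitive_advantage_R(tr[[1]], tr[[2]], 295, 2, t_days = 14)
  expect_equal(r14$R, 14 * r1$R, tolerance = 1e-12)
  expect_identical(r14$winner, r1$winner)
})

test_that("|R(S) - R_inf| vanishes as nutrients saturate and decreases beyond both K_S", {
  set.seed(19)
  for (i in 1:20) {
    tr <- random_traits(2)
    T_K <- runif(1, 283, 303)
    K_T <- vapply(tr, function(x)
      arrhenius_value(x$K0, x$E_K, T_K, x$T_ref_K), numeric(1))
    # once S dominates both half-saturations each Monod term is in its
    # saturating regime and the residual nutrient effect decays as 1/S
    S_grid <- max(K_T) * 10^seq(1, 6, length.out = 11)
    R_inf <- competitive_advantage_Rinf(tr[[1]], tr[[2]], T_K)$R
    gap <- vapply(S_grid, function(S)
      abs(competitive_advantage_R(tr[[1]], tr[[2]], T_K, S)$R - R_inf),
      numeric(1))
    expect_true(all(diff(gap[gap > 1e-14]) <= 1e-10))
    expect_lt(gap[length(gap)], 1e-4 * max(abs(R_inf), 1e-6))
  }
})

test_that("the crossing temperature solves the trait trade-off analytically", {
  # equal normalisation constants cross exactly at the reference temperature
  a <- metabolic_traits(0.5, 0.9, 1, 1)
  b <- metabolic_traits(0.5, 0.3, 1, 1)
  expect_equal(crossing_temperature(a, b)$T_K, 288.15, tolerance = 1e-10)

  # B0 ratio e, energy difference -0.5 eV: verified against sign bisection
  a2 <- metabolic_traits(0.5 * exp(1), 0.2, 1, 1)
  b2 <- metabolic_traits(0.5, 0.7, 1, 1)
  cr <- crossing_temperature(a2, b2)
  expect_equal(cr$status, "crossing")
  lo <- 250; hi <- 350
  f <- function(T_K) competitive_advantage_Rinf(a2, b2, T_K)$R
  stopifnot(sign(f(lo)) != sign(f(hi)))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  expect_equal(cr$T_K, (lo + hi) / 2, tolerance = 1e-6)
  expect_equal(cr$T_K, 303.2, tolerance = 1e-3)

  # far above T_ref the species with the larger activation energy wins
  expect_identical(competitive_advantage_Rinf(a2, b2, 400)$winner, "b")

  expect_identical(crossing_temperature(a, a)$status, "degenerate")
  c1 <- metabolic_traits(0.9, 0.5, 1, 1)
  c2 <- metabolic_traits(0.5, 0.5, 1, 1)
  expect_identical(crossing_temperature(c1, c2)$status, "none")
})

test_that("reversal prediction agrees with comparing winners at the two temperatures", {
  # constructed crossing strictly between the probes
  a <- metabolic_traits(0.6, 0.3, 1, 1)
  T_star <- celsius_to_kelvin(20)
  # choose b so that the saturated advantage flips exactly at 20 C
  E_b <- 0.8
  B0_b <- 0.6 * exp((E_b - 0.3) / boltzmann_eV_K *
                      (1 / T_star - 1 / 288.15))
  b <- metabolic_traits(B0_b, E_b, 1, 1)
  expect_equal(crossing_temperature(a, b)$T_K, T_star, tolerance = 1e-9)
  rev <- predict_reversal(a, b, celsius_to_kelvin(15), celsius_to_kelvin(25))
  expect_true(rev$reversal)

  expect_identical(predict_reversal(a, a, 288.15, 298.15)$status,
                   "indeterminate")

  set.seed(101)
  for (i in 1:1000) {
    tr <- random_traits(2)
    T1 <- runif(1, 280, 300); T2 <- T1 + runif(1, 1, 20)
    S <- runif(1, 0.05, 50)
    rv <- predict_reversal(tr[[1]], tr[[2]], T1, T2, S = S)
    w1 <- competitive_advantage_R(tr[[1]], tr[[2]], T1, S)$winner
    w2 <- competitive_advantage_R(tr[[1]], tr[[2]], T2, S)$winner
    expect_identical(rv$reversal, w1 != w2)
  }
})

test_that("the prediction grid covers all pairs antisymmetrically", {
  panel <- sample_species_panel(4, seed = 44)
  grid <- prediction_grid(panel[, c("species", "B0_per_day", "E_mu_eV",
                                    "K0_umol_L", "E_K_eV", "T_ref_C")],
                          temperatures_C = c(15, 25),
                          phosphate_umol_L = c(0.1, 1, 30))
  expect_equal(nrow(grid), choose(4, 2) * 2 * 3)
  expect_true(all(grid$species_a < grid$species_b))
  expect_true(all(grid$winner %in% c("a", "b", "tie")))
  # R matches the pairwise op for a spot-checked row
  row <- grid[7, ]
  pred <- competitive_advantage_R(panel_traits(panel, row$species_a),
                                  panel_traits(panel, row$species_b),
                                  celsius_to_kelvin(row$temperature_C),
                                  row$phosphate_umol_L)
  expect_equal(row$R, pred$R, tolerance = 1e-12)

  rinf <- prediction_grid(panel, temperatures_C = c(15, 25), mode = "Rinf")
  expect_equal(nrow(rinf), choose(4, 2) * 2)
  expect_true(all(is.na(rinf$phosphate_umol_L)))
})

test_that("far below both half-saturations, advantage follows the affinity ratio", {
  set.seed(55)
  for (i in 1:20) {
    a <- metabolic_traits(runif(1, 0.3, 1), runif(1, 0.2, 0.8),
                          runif(1, 0.1, 1), runif(1, 0.2, 0.8))
    b <- metabolic_traits(runif(1, 0.3, 1), runif(1, 0.2, 0.8),
                          runif(1, 0.1, 1), runif(1, 0.2, 0.8))
    T_K <- runif(1, 285, 300)
    KS <- function(tr) arrhenius_value(tr$K0, tr$E_K, T_K, tr$T_ref_K)
    S <- min(KS(a), KS(b)) / 100
    t <- 14
    f <- function(tr) exp(-(tr$E_mu - tr$E_K) / boltzmann_eV_K *
                            (1 / T_K - 1 / tr$T_ref_K))
    approx_R <- S * t * (a$B0 / a$K0 * f(a) - b$B0 / b$K0 * f(b))
    exact_R <- competitive_advantage_R(a, b, T_K, S, t)$R
    # S is 1% of the smaller K_S, so each Monod term is within ~1% of its
    # linear (affinity) approximation; compare on the scale of the terms to
    # stay meaningful when the two species nearly cancel
    scale <- S * t * max(a$B0 / a$K0 * f(a), b$B0 / b$K0 * f(b))
    expect_lt(abs(exact_R - approx_R), 0.03 * scale)
  }
})
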