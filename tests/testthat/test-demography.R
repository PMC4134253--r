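test_that("life-table entries follow the scenario algebra", {
  s <- life_history_scenario(age_first_litter_f = 1,
                             juvenile_survival = 0.50,
                             prop_females_breeding = 0.50)
  lt <- life_table(s)
  expect_equal(lt$mx[1], 0.50 * 1.35 * 3 * 0.5) # 1.0125 daughters/yr
  expect_equal(lt$lx[1], 0.50)
  expect_equal(lt$lx[3], 0.50 * 0.68^2)
  expect_true(all(diff(lt$lx) <= 0))
  expect_equal(nrow(lt), s$max_age)

  lt2 <- life_table(life_history_scenario(age_first_litter_f = 2,
                                          juvenile_survival = 0.3,
                                          prop_females_breeding = 0.35))
  expect_equal(lt2$mx[1], 0) # no breeding before first litter age
  expect_gt(lt2$mx[2], 0)

  lt0 <- life_table(life_history_scenario(prop_females_breeding = 0,
                                          juvenile_survival = 0.5,
                                          age_first_litter_f = 1))
  expect_true(all(lt0$mx == 0))
})

test_that("growth rate falls back to adult survival without recruitment", {
  s <- life_history_scenario(prop_females_breeding = 0,
                             juvenile_survival = 0.5,
                             age_first_litter_f = 1)
  expect_equal(deterministic_growth(life_table(s))$lambda, 0.68)
  s2 <- life_history_scenario(juvenile_survival = 0,
                              prop_females_breeding = 0.5,
                              age_first_litter_f = 1)
  lt2 <- life_table(s2)
  expect_true(all(lt2$lx == 0))
  expect_equal(deterministic_growth(lt2)$lambda, 0.68)
})

test_that("Euler-Lotka root equals the Leslie dominant eigenvalue (1e-8)", {
  set.seed(7)
  for (i in 1:100) {
    s <- random_scenario()
    lt <- life_table(s)
    lam <- deterministic_growth(lt)$lambda
    M <- leslie_matrix(lt)
    expect_equal(lam, power_iteration_lambda(M), tolerance = 1e-8)
    expect_equal(lam, max(Re(eigen(M, only.values = TRUE)$values)),
                 tolerance = 1e-8)
  }
})

test_that("optimistic scenario growth is pinned by the matrix oracle", {
  s <- life_history_scenario(age_first_litter_f = 1,
                             juvenile_survival = 0.50,
                             prop_females_breeding = 0.50)
  lam <- deterministic_growth(life_table(s))$lambda
  expect_gt(lam, 1.1)
  expect_lt(lam, 1.25)
  expect_equal(lam, power_iteration_lambda(leslie_matrix(life_table(s))),
               tolerance = 1e-8)
  # delayed first litter: barely at replacement
  s2 <- life_history_scenario(age_first_litter_f = 2,
                              juvenile_survival = 0.50,
                              prop_females_breeding = 0.50)
  lam2 <- deterministic_growth(life_table(s2))$lambda
  expect_equal(lam2, power_iteration_lambda(leslie_matrix(life_table(s2))),
               tolerance = 1e-8)
  expect_gt(lam2, 0.95)
  expect_lt(lam2, 1.1)
})

test_that("lambda is monotone in survival, breeding and first-litter age", {
  base <- life_history_scenario(age_first_litter_f = 1,
                                juvenile_survival = 0.3,
                                prop_females_breeding = 0.5)
  lam <- function(...) {
    deterministic_growth(life_table(life_history_scenario(...)))$lambda
  }
  sj_grid <- seq(0.05, 0.6, by = 0.05)
  l1 <- sapply(sj_grid, function(v) lam(age_first_litter_f = 1,
                                        juvenile_survival = v,
                                        prop_females_breeding = 0.5))
  expect_true(all(diff(l1) > 0))
  l2 <- sapply(sj_grid, function(v) lam(age_first_litter_f = 2,
                                        juvenile_survival = v,
                                        prop_females_breeding = 0.5))
  expect_true(all(l2 <= l1 + 1e-12))
  expect_lt(lam(age_first_litter_f = 1, juvenile_survival = 0.3,
                prop_females_breeding = 0.35),
            lam(age_first_litter_f = 1, juvenile_survival = 0.3,
                prop_females_breeding = 0.5))
  expect_lt(lam(age_first_litter_f = 1, juvenile_survival = 0.3,
                prop_females_breeding = 0.5, adult_survival_f = 0.6),
            lam(age_first_litter_f = 1, juvenile_survival = 0.3,
                prop_females_breeding = 0.5, adult_survival_f = 0.75))
})

test_that("truncated tables approach the closed-form infinite-age limits", {
  sa <- 0.68
  m <- 0.5 * 1.35 * 3 * 0.5
  sj <- 0.4
  s1 <- life_history_scenario(age_first_litter_f = 1, juvenile_survival = sj,
                              prop_females_breeding = 0.5, max_age = 300)
  expect_equal(deterministic_growth(life_table(s1))$lambda, sa + m * sj,
               tolerance = 1e-6)
  s2 <- life_history_scenario(age_first_litter_f = 2, juvenile_survival = sj,
                              prop_females_breeding = 0.5, max_age = 300)
  lam2_closed <- (sa + sqrt(sa^2 + 4 * m * sj * sa)) / 2
  expect_equal(deterministic_growth(life_table(s2))$lambda, lam2_closed,
               tolerance = 1e-6)
})

test_that("the growth surface behaves like the published sensitivity plot", {
  surf <- lambda_surface(sj_values = seq(0.05, 0.6, by = 0.05))
  # monotone in juvenile survival wherever fecundity is positive (the
  # zero-recruitment fallback lambda = adult survival is a separate branch)
  for (afl in 1:2) {
    sub <- surf[surf$age_first_litter == afl, ]
    expect_true(all(diff(sub$lambda) >= 0))
  }
  wide <- merge(surf[surf$age_first_litter == 1, ],
                surf[surf$age_first_litter == 2, ],
                by = "juvenile_survival")
  expect_true(all(wide$lambda.y <= wide$lambda.x + 1e-12))
  expect_equal(nrow(lambda_surface(sj_values = 0.4, afl_values = 1L)), 1L)
  # replacement threshold for first litter at 1 year (50% breeding)
  thr1 <- lambda_threshold(afl = 1)
  expect_gt(thr1, 0.20)
  expect_lt(thr1, 0.35)
  expect_gt(lambda_threshold(afl = 2), thr1)
})

test_that("generation time is about two years for optimistic scenarios", {
  s <- life_history_scenario(age_first_litter_f = 1,
                             juvenile_survival = 0.50,
                             prop_females_breeding = 0.50)
  gt <- deterministic_growth(life_table(s))$generation_time
  expect_gt(gt, 1.5)
  expect_lt(gt, 3.5)
  s2 <- life_history_scenario(age_first_litter_f = 2,
                              juvenile_survival = 0.50,
                              prop_females_breeding = 0.50)
  expect_gte(deterministic_growth(life_table(s2))$generation_time, 2)
})

test_that("expected-value projection converges to the asymptotic rate", {
  s <- life_history_scenario(age_first_litter_f = 1,
                             juvenile_survival = 0.4,
                             prop_females_breeding = 0.5)
  lam <- deterministic_growth(life_table(s))$lambda
  tr <- expected_trajectory(s, years = 60)
  expect_equal(tr$growth_factor[61], lam, tolerance = 1e-6)
})
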