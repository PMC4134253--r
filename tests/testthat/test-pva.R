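sceaux_opt <- function(...) {
  life_history_scenario(age_first_litter_f = 1, juvenile_survival = 0.50,
                        prop_females_breeding = 0.50, ...)
}

test_that("founders match the requested size, frequencies and determinism", {
  freqs <- sceaux_founder_freqs()
  st <- init_population(sceaux_opt(), freqs, seed = 11)
  pop <- pop_of(st)
  expect_equal(length(pop$age), 120L)
  expect_equal(ncol(pop$geno), 2L * length(freqs))
  expect_false(anyNA(pop$geno))
  expect_true(all(pop$age >= 1 & pop$age <= 8))
  # founder gene diversity close to the construction target
  he0 <- mean(sapply(seq_along(freqs), function(l) {
    a <- c(pop$geno[, 2 * l - 1], pop$geno[, 2 * l])
    1 - sum((tabulate(a) / length(a))^2)
  }))
  expect_equal(he0, gene_diversity(freqs), tolerance = 0.02)
  st2 <- init_population(sceaux_opt(), freqs, seed = 11)
  expect_identical(st, st2)
  # single-allele loci carry no diversity
  mono <- allele_freq_table(list(l1 = c(a = 1), l2 = c(b = 1)))
  stm <- init_population(sceaux_opt(), mono, seed = 1)
  sm <- simulate_pva(sceaux_opt(), freqs = mono, seed = 2, replicates = 3,
                     years = 5)
  expect_true(all(sm$he_trajectory$he_mean == 0))
})

test_that("unnormalized founder frequencies are rejected", {
  bad <- list(l1 = c(a = 0.6, b = 0.6))
  expect_error(init_population(sceaux_opt(), bad, seed = 1), "sum")
  expect_error(allele_freq_table(list(l1 = c(a = -0.2, b = 1.2))),
               "non-negative")
})

test_that("immortal non-breeding populations pass through unchanged, aging", {
  s <- life_history_scenario(
    age_first_litter_f = 1, juvenile_survival = 1,
    prop_females_breeding = 0, adult_survival_f = 1, adult_survival_m = 1,
    adult_survival_f_ev_sd = 0, adult_survival_m_ev_sd = 0,
    juvenile_survival_ev_sd = 0, breeding_ev_sd = 0,
    max_age = 50, carrying_capacity = 10000, initial_n = 10,
    allow_overshoot = TRUE)
  st <- manual_state(sex = rep(1:2, 5), age = rep(2L, 10))
  st2 <- annual_cycle(st, s)
  expect_equal(pop_of(st2)$sex, pop_of(st)$sex)
  expect_equal(pop_of(st2)$age, rep(3L, 10))
  expect_equal(st2$year, 1L)
})

test_that("zero juvenile survival stops recruitment", {
  s <- life_history_scenario(
    age_first_litter_f = 1, juvenile_survival = 0,
    prop_females_breeding = 1, adult_survival_f = 1, adult_survival_m = 1,
    adult_survival_f_ev_sd = 0, adult_survival_m_ev_sd = 0,
    juvenile_survival_ev_sd = 0, breeding_ev_sd = 0,
    max_age = 50, carrying_capacity = 1000, initial_n = 10)
  st <- manual_state(sex = rep(1:2, 5), age = rep(2L, 10))
  set.seed(1)
  st2 <- annual_cycle(st, s)
  expect_equal(length(pop_of(st2)$age), 10L) # adults immortal, no recruits
  expect_true(all(pop_of(st2)$age == 3L))
})

test_that("litters require a sire: all-female populations produce none", {
  s <- life_history_scenario(
    age_first_litter_f = 1, juvenile_survival = 1,
    prop_females_breeding = 1, adult_survival_f = 1, adult_survival_m = 1,
    adult_survival_f_ev_sd = 0, adult_survival_m_ev_sd = 0,
    juvenile_survival_ev_sd = 0, breeding_ev_sd = 0,
    max_age = 50, carrying_capacity = 1000, initial_n = 5)
  st <- manual_state(sex = rep(1L, 5), age = rep(2L, 5))
  set.seed(2)
  st2 <- annual_cycle(st, s)
  expect_equal(length(pop_of(st2)$age), 5L)
})

test_that("summaries are bit-reproducible for identical seeds", {
  s <- sceaux_opt(replicates = 10, years = 8)
  freqs <- two_locus_freqs()
  a <- simulate_pva(s, freqs = freqs, seed = 99)
  b <- simulate_pva(s, freqs = freqs, seed = 99)
  expect_identical(a, b)
  c <- simulate_pva(s, freqs = freqs, seed = 100)
  expect_false(identical(a$stochastic_r_mean, c$stochastic_r_mean))
})

test_that("no mutation: every allele descends from a founder allele", {
  freqs <- two_locus_freqs()
  s <- sceaux_opt(initial_n = 30, carrying_capacity = 30)
  set.seed(5)
  st <- init_population(s, freqs, seed = 5, n = 30)
  founder_alleles <- lapply(1:2, function(l)
    sort(unique(c(pop_of(st)$geno[, 2 * l - 1], pop_of(st)$geno[, 2 * l]))))
  for (t in 1:15) st <- annual_cycle(st, s)
  pop <- pop_of(st)
  expect_gt(length(pop$age), 0)
  for (l in 1:2) {
    now <- unique(c(pop$geno[, 2 * l - 1], pop$geno[, 2 * l]))
    expect_true(all(now %in% founder_alleles[[l]]))
  }
})

test_that("with EV off and a large population r converges to ln(lambda)", {
  s <- life_history_scenario(
    age_first_litter_f = 1, juvenile_survival = 0.3,
    prop_females_breeding = 0.5,
    adult_survival_f_ev_sd = 0, adult_survival_m_ev_sd = 0,
    juvenile_survival_ev_sd = 0, breeding_ev_sd = 0,
    initial_n = 5000, carrying_capacity = 10000000, allow_overshoot = TRUE)
  lam <- deterministic_growth(life_table(s))$lambda
  sm <- simulate_pva(s, seed = 31, replicates = 10, years = 10)
  expect_lt(abs(sm$stochastic_r_mean - log(lam)), 0.02)
})

test_that("closed-population heterozygosity decays like Wright-Fisher drift", {
  freqs <- sceaux_founder_freqs()
  s <- sceaux_opt()
  sm <- simulate_pva(s, freqs = freqs, seed = 13, replicates = 150)
  # He non-increasing in expectation (tolerate tiny MC jitter)
  expect_true(all(diff(sm$he_trajectory$he_mean) < 0.005))
  gt <- deterministic_growth(life_table(s))$generation_time
  ne <- ne_from_he_decay(sm, gt)
  expect_gt(ne, 10)
  expect_lt(ne, 80)
})

test_that("gene flow from an undrifted source raises final heterozygosity", {
  freqs <- sceaux_founder_freqs()
  s <- life_history_scenario(age_first_litter_f = 2,
                             juvenile_survival = 0.2,
                             prop_females_breeding = 0.35)
  closed <- simulate_pva(s, freqs = freqs, seed = 17, replicates = 150)
  open <- simulate_pva(s, plan = immigration_plan(3), freqs = freqs,
                       seed = 17, replicates = 150, ideal_source = TRUE)
  expect_gt(open$he_final_mean, closed$he_final_mean)
})

test_that("extinction risk shrinks as juvenile survival improves", {
  pe <- sapply(c(0.2, 0.3, 0.4, 0.5), function(sj) {
    s <- life_history_scenario(age_first_litter_f = 1,
                               juvenile_survival = sj,
                               prop_females_breeding = 0.35)
    simulate_pva(s, seed = 23, replicates = 200)$extinction_probability
  })
  expect_true(all(diff(pe) < 0.05)) # non-increasing up to MC noise
  expect_gt(pe[1] - pe[4], 0.5)     # and strongly decreasing overall
})

test_that("the scenario-grid summary has the published table's shape", {
  res <- run_scenario_grid(replicates = 4, years = 4, seed = 3)
  expect_equal(nrow(res), 16L)
  expect_true(all(c("stochastic_r", "stochastic_r_sd",
                    "extinction_probability", "he_final", "he_final_sd")
                  %in% names(res)))
  expect_equal(res$age_first_litter, rep(1:2, each = 8))
})
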