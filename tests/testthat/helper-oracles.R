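# Independent oracles and fixture builders used across the suite.

# Dominant eigenvalue of a non-negative matrix by power iteration
# (independent of both the package's bisection root and base eigen()).
power_iteration_lambda <- function(M, iter = 10000, tol = 1e-12) {
  v <- rep(1, nrow(M))
  lam <- 1
  for (i in seq_len(iter)) {
    v2 <- as.vector(M %*% v)
    lam2 <- sqrt(sum(v2^2))
    if (lam2 == 0) return(0)
    v2 <- v2 / lam2
    if (max(abs(v2 - v)) < tol) {
      v <- v2
      lam <- lam2
      break
    }
    v <- v2
    lam <- lam2
  }
  # Rayleigh quotient for the final estimate
  sum(v * (M %*% v)) / sum(v * v)
}

# Brute-force exact Hardy-Weinberg p-value for a biallelic genotype count
# table (n_aa, n_ab, n_bb): enumerate every table with the same allele
# counts directly.
hwe_biallelic_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  tab_prob <- function(ab) {
    aa <- (na - ab) / 2
    bb <- n - aa - ab
    if (aa < 0 || bb < 0 || aa != round(aa)) return(NA_real_)
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(ab) - lfactorial(bb) +
          ab * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  }
  abs_grid <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  probs <- vapply(abs_grid, tab_prob, numeric(1))
  probs <- probs[!is.na(probs)]
  p_obs <- tab_prob(n_ab)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# random valid scenario (positive fecundity) for property tests
random_scenario <- function() {
  afl <- sample(1:2, 1)
  life_history_scenario(
    age_first_litter_f = afl,
    age_first_breeding_m = sample(1:2, 1),
    max_age = sample((afl + 1):12, 1),
    juvenile_survival = runif(1, 0.05, 0.8),
    prop_females_breeding = runif(1, 0.1, 0.9),
    prob_second_litter = runif(1, 0, 0.6),
    adult_survival_f = runif(1, 0.3, 0.9),
    adult_survival_m = runif(1, 0.3, 0.9),
    litter_size_mean = runif(1, 1, 5),
    litter_size_max = 6
  )
}

# small founder table for genetic runs
two_locus_freqs <- function() {
  allele_freq_table(list(
    locA = c(a1 = 0.5, a2 = 0.5),
    locB = c(b1 = 0.7, b2 = 0.2, b3 = 0.1)))
}

# hand-built simulation state (bypasses init_population) for targeted
# annual_cycle tests
manual_state <- function(sex, age, geno = NULL, loci = NULL) {
  structure(list(
    year = 0L,
    residents = structure(list(sex = as.integer(sex), age = as.integer(age),
                               origin = rep(0L, length(sex)), geno = geno,
                               loci = loci),
                          class = "population"),
    source = NULL, n_pre_truncation = NA_integer_),
    class = "pva_state")
}

pop_of <- function(state) state$residents
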