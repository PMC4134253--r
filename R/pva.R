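# Individual-based stochastic simulator.
#
# A population is a column-store: integer vectors sex (1 = F, 2 = M), age
# (completed years at census), origin (0 resident-born, 1 immigrant), and an
# optional integer genotype matrix with two columns per locus (allele ids are
# opaque small integers, coded per locus). The annual cycle is
# breed -> death -> immigrate -> truncate, with ages incremented at year end,
# mirroring the convention of the classical PVA simulators.

new_population <- function(sex, age, origin = rep(0L, length(sex)),
                           geno = NULL, loci = NULL) {
  stopifnot(length(sex) == length(age), length(origin) == length(age))
  structure(list(sex = as.integer(sex), age = as.integer(age),
                 origin = as.integer(origin), geno = geno, loci = loci),
            class = "population")
}

pop_size <- function(pop) length(pop$age)

subset_pop <- function(pop, keep) {
  new_population(pop$sex[keep], pop$age[keep], pop$origin[keep],
                 if (!is.null(pop$geno)) pop$geno[keep, , drop = FALSE],
                 pop$loci)
}

bind_pop <- function(a, b) {
  if (pop_size(a) == 0L) return(b)
  if (pop_size(b) == 0L) return(a)
  new_population(c(a$sex, b$sex), c(a$age, b$age), c(a$origin, b$origin),
                 if (!is.null(a$geno)) rbind(a$geno, b$geno), a$loci)
}

# sample founder genotypes: two independent allele copies per locus
# (Hardy-Weinberg proportions, unrelated founders)
sample_genotypes <- function(n, freqs) {
  loci <- names(freqs)
  geno <- matrix(0L, n, 2L * length(loci))
  for (l in seq_along(loci)) {
    p <- freqs[[l]]
    k <- length(p)
    geno[, 2L * l - 1L] <- sample.int(k, n, replace = TRUE, prob = p)
    geno[, 2L * l] <- sample.int(k, n, replace = TRUE, prob = p)
  }
  geno
}

make_population <- function(n, scenario, freqs = NULL) {
  if (n == 0L)
    return(new_population(integer(0), integer(0),
                          geno = if (!is.null(freqs))
                            matrix(0L, 0, 2L * length(freqs)),
                          loci = names(freqs)))
  sex <- sample(1:2, n, replace = TRUE)
  ages <- sample.int(scenario$max_age, n, replace = TRUE,
                     prob = stable_age_distribution(scenario))
  geno <- if (!is.null(freqs)) sample_genotypes(n, freqs)
  new_population(sex, ages, geno = geno, loci = names(freqs))
}

#' Initialize a simulation state
#'
#' Creates the starting population: `initial_n` individuals with Bernoulli
#' (0.5) sexes, ages drawn from the stable age distribution implied by the
#' scenario's life table, and (when allele frequencies are supplied) diploid
#' multi-locus genotypes drawn as two independent allele copies per locus
#' from the given spectra — i.e. unrelated founders in Hardy-Weinberg
#' proportions, so the expected initial gene diversity equals that of the
#' frequency table.
#'
#' @param scenario A [life_history_scenario()].
#' @param freqs Optional [allele_freq_table()] of founder allele frequencies;
#'   omit for purely demographic runs.
#' @param seed Optional integer seed (set for reproducibility; identical
#'   seeds give identical populations).
#' @param n Number of founders, defaulting to `scenario$initial_n`.
#' @return A list of class `pva_state` with elements `year` (0), `residents`
#'   and `source` (`NULL` until an immigration run installs one).
#' @export
init_population <- function(scenario, freqs = NULL, seed = NULL,
                            n = scenario$initial_n) {
  if (!is.null(freqs)) check_freq_table(freqs)
  if (!is.null(seed)) set.seed(seed)
  structure(list(year = 0L,
                 residents = make_population(n, scenario, freqs),
                 source = NULL, n_pre_truncation = NA_integer_),
            class = "pva_state")
}

# mean and SD -> beta draw via a uniform quantile u; degenerate cases
# collapse to the mean
qbeta_mean_sd <- function(u, mean, sd) {
  if (sd <= 0 || mean <= 0 || mean >= 1) return(mean)
  v <- min(sd^2, 0.95 * mean * (1 - mean)) # feasibility cap
  t <- mean * (1 - mean) / v - 1
  stats::qbeta(u, mean * t, (1 - mean) * t)
}

# Annual environmental draw. By default the four vital rates share one
# annual environmental quantile (concordance of environmental variation in
# survival and reproduction, the convention of the classical PVA
# simulators: a good year is good for every rate); with
# ev_concordance = FALSE each rate gets its own independent draw.
draw_year_rates <- function(sc) {
  conc <- is.null(sc$ev_concordance) || isTRUE(sc$ev_concordance)
  u <- stats::runif(if (conc) 1L else 4L)
  if (conc) u <- rep(u, 4L)
  list(saf = qbeta_mean_sd(u[1], sc$adult_survival_f,
                           sc$adult_survival_f_ev_sd),
       sam = qbeta_mean_sd(u[2], sc$adult_survival_m,
                           sc$adult_survival_m_ev_sd),
       sj  = qbeta_mean_sd(u[3], sc$juvenile_survival,
                           sc$juvenile_survival_ev_sd),
       pb  = qbeta_mean_sd(u[4], sc$prop_females_breeding,
                           sc$breeding_ev_sd))
}

# Mendelian inheritance: one uniformly chosen allele per locus from each
# parent
mendel_offspring <- function(geno, moms, sires) {
  noff <- length(moms)
  L <- ncol(geno) %/% 2L
  out <- matrix(0L, noff, 2L * L)
  for (l in seq_len(L)) {
    mcol <- 2L * l - 1L + (stats::runif(noff) < 0.5)
    pcol <- 2L * l - 1L + (stats::runif(noff) < 0.5)
    out[, 2L * l - 1L] <- geno[cbind(moms, mcol)]
    out[, 2L * l] <- geno[cbind(sires, pcol)]
  }
  out
}

# breeding + mortality for one population (no immigration, no truncation,
# no aging). Returns the survivors including surviving offspring (age 0).
pop_year_step <- function(pop, sc, rates) {
  n <- pop_size(pop)
  if (n == 0L) return(pop)
  off <- NULL
  fem <- which(pop$sex == 1L & pop$age >= sc$age_first_litter_f)
  mal <- which(pop$sex == 2L & pop$age >= sc$age_first_breeding_m)
  if (length(fem) && length(mal) && rates$pb > 0) {
    br <- fem[stats::runif(length(fem)) < rates$pb]
    if (length(br)) {
      litters <- 1L + (stats::runif(length(br)) < sc$prob_second_litter)
      moms <- rep(br, litters)
      sizes <- stats::rbinom(length(moms), sc$litter_size_max,
                             sc$litter_size_mean / sc$litter_size_max)
      keep <- sizes > 0L
      if (any(keep)) {
        moms <- moms[keep]
        sizes <- sizes[keep]
        # polygyny: each litter sired by one male drawn with replacement
        sires <- mal[sample.int(length(mal), length(moms), replace = TRUE)]
        mom_of <- rep(moms, sizes)
        sire_of <- rep(sires, sizes)
        noff <- length(mom_of)
        off <- new_population(
          sex = 1L + (stats::runif(noff) < sc$sex_ratio_birth),
          age = rep(0L, noff),
          origin = rep(0L, noff),
          geno = if (!is.null(pop$geno))
            mendel_offspring(pop$geno, mom_of, sire_of),
          loci = pop$loci)
      }
    }
  }
  # mortality of censused individuals (age/sex-specific, senescence cap)
  p <- ifelse(pop$sex == 1L, rates$saf, rates$sam)
  p[pop$age >= sc$max_age] <- 0
  pop <- subset_pop(pop, stats::runif(n) < p)
  # first-year mortality of the new cohort
  if (!is.null(off)) {
    off <- subset_pop(off, stats::runif(pop_size(off)) < rates$sj)
    pop <- bind_pop(pop, off)
  }
  pop
}

truncate_to_k <- function(pop, k) {
  n <- pop_size(pop)
  if (n <= k) return(pop)
  subset_pop(pop, stats::runif(n) >= (n - k) / n)
}

# default parameterization of the stable source population feeding
# immigration: self-sustaining vital rates at the source's own carrying
# capacity
source_scenario_default <- function(plan) {
  life_history_scenario(age_first_litter_f = 1L, juvenile_survival = 0.5,
                        prop_females_breeding = 0.5,
                        carrying_capacity = plan$source_size,
                        initial_n = plan$source_size)
}

#' Advance a simulation state by one year
#'
#' Applies, in order: (1) environmental draws — each vital rate is drawn for
#' the year from a beta distribution with the scenario mean and its
#' environmental SD, independently per rate and per population; (2) breeding
#' — each female at or above the age at first litter breeds with the year's
#' breeding probability, breeding females add a second litter with the
#' scenario's second-litter probability, litter sizes are
#' Binomial(`litter_size_max`, `litter_size_mean/litter_size_max`), each
#' litter is sired by one male drawn uniformly with replacement (polygyny; no
#' males means no litters), offspring sex is Bernoulli and each offspring
#' inherits one uniformly chosen allele per locus from each parent; (3)
#' mortality — Bernoulli survival with the year's age/sex-specific rates
#' (first-year rate for the new cohort; individuals at the maximum age die);
#' (4) immigration — Poisson arrivals move from the source population
#' (running its own cycle at its own carrying capacity, no immigration) into
#' the residents, drawn uniformly from source individuals in the dispersal
#' age window, capped by availability; (5) carrying-capacity truncation —
#' when N exceeds K every individual is independently removed with
#' probability (N-K)/N; (6) ages and year increment.
#'
#' The pre-truncation resident count is recorded in `n_pre_truncation`; the
#' stochastic growth rate is computed on that count, matching the convention
#' of the classical PVA simulators in which r reflects growth before the
#' ceiling is imposed.
#'
#' @param state A `pva_state` from [init_population()].
#' @param scenario A [life_history_scenario()].
#' @param plan Optional [immigration_plan()]; `NULL` disables immigration.
#' @param source_scenario Scenario for the source population (defaults to a
#'   self-sustaining parameterization at the source's size).
#' @param ideal_source When `TRUE`, immigrants are drawn from an undrifting
#'   idealized pool at the founder allele frequencies instead of the
#'   simulated source (used to isolate drift from source-side drift).
#' @param founder_freqs Allele frequencies for `ideal_source` draws.
#' @return The advanced `pva_state`.
#' @export
annual_cycle <- function(state, scenario, plan = NULL,
                         source_scenario = NULL, ideal_source = FALSE,
                         founder_freqs = NULL) {
  stopifnot(inherits(state, "pva_state"))
  rates <- draw_year_rates(scenario)
  res <- pop_year_step(state$residents, scenario, rates)
  src <- state$source
  migrating <- !is.null(plan) && plan$expected_immigrants_per_year > 0
  if (migrating && !ideal_source) {
    if (is.null(src))
      stop("immigration requested but state has no source population",
           call. = FALSE)
    ssc <- if (is.null(source_scenario)) source_scenario_default(plan)
           else source_scenario
    src <- pop_year_step(src, ssc, draw_year_rates(ssc))
  }
  if (migrating) {
    n_arrive <- stats::rpois(1, plan$expected_immigrants_per_year)
    if (n_arrive > 0) {
      if (ideal_source) {
        if (is.null(founder_freqs))
          stop("ideal_source needs founder_freqs", call. = FALSE)
        imm <- new_population(
          sex = sample(1:2, n_arrive, replace = TRUE),
          age = sample(plan$immigrant_min_age:plan$immigrant_max_age,
                       n_arrive, replace = TRUE),
          origin = rep(1L, n_arrive),
          geno = if (!is.null(res$geno))
            sample_genotypes(n_arrive, founder_freqs),
          loci = res$loci)
        res <- bind_pop(res, imm)
      } else {
        elig <- which(src$age >= plan$immigrant_min_age &
                      src$age <= plan$immigrant_max_age)
        n_take <- min(n_arrive, length(elig))
        if (n_take > 0) {
          pick <- elig[sample.int(length(elig), n_take)]
          imm <- subset_pop(src, pick)
          imm$origin <- rep(1L, n_take)
          src <- subset_pop(src, -pick)
          res <- bind_pop(res, imm)
        }
      }
    }
  }
  n_pre <- pop_size(res)
  res <- truncate_to_k(res, scenario$carrying_capacity)
  if (migrating && !ideal_source)
    src <- truncate_to_k(src, plan$source_size)
  res$age <- res$age + 1L
  if (!is.null(src)) src$age <- src$age + 1L
  structure(list(year = state$year + 1L, residents = res, source = src,
                 n_pre_truncation = n_pre),
            class = "pva_state")
}

# mean gene diversity (plain 1 - sum p^2, drift bookkeeping form) across
# loci of a population's current allele frequencies
gene_diversity_pop <- function(pop) {
  if (is.null(pop$geno) || pop_size(pop) == 0L) return(NA_real_)
  L <- ncol(pop$geno) %/% 2L
  he <- numeric(L)
  for (l in seq_len(L)) {
    a <- c(pop$geno[, 2L * l - 1L], pop$geno[, 2L * l])
    p <- tabulate(a) / length(a)
    he[l] <- 1 - sum(p^2)
  }
  mean(he)
}

is_extinct <- function(pop) {
  !any(pop$sex == 1L) || !any(pop$sex == 2L)
}

#' Run replicated stochastic population projections
#'
#' Runs independent replicates of [annual_cycle()] over the scenario's time
#' horizon and summarizes them: the stochastic growth rate (mean and SD over
#' replicate-years of `ln(N_pre-truncation(t+1)/N(t))`, restricted to years
#' with positive counts and before extinction), the probability of
#' extinction (a replicate is extinct once either sex is absent from the
#' residents; "within the horizon" = first passage), the mean population
#' trajectory, and — when genotypes are tracked — the yearly mean expected
#' heterozygosity (gene diversity, `1 - sum p^2` averaged over loci) across
#' replicates still extant in that year.
#'
#' Each replicate consumes its own RNG substream derived from `seed`, so
#' results are bit-reproducible and independent of replicate order.
#'
#' @param scenario A [life_history_scenario()].
#' @param plan Optional [immigration_plan()].
#' @param freqs Optional [allele_freq_table()] of founder frequencies;
#'   genotypes are tracked iff supplied.
#' @param seed Integer master seed (mandatory: no silent nondeterminism).
#' @param replicates,years Override the scenario's settings (e.g. for quick
#'   checks).
#' @param source_scenario,ideal_source See [annual_cycle()].
#' @return An object of class `pva_summary`; see Details.
#' @details The summary contains `stochastic_r_mean`, `stochastic_r_sd`,
#'   `extinction_probability`, `he_initial_mean`, `he_final_mean`,
#'   `he_final_sd` (final-year statistics over extant replicates only),
#'   `n_trajectory_mean`, `he_trajectory` (data frame of per-year mean/SD of
#'   gene diversity and the number of extant replicates), `replicates`,
#'   `years` and `seed`.
#' @examples
#' s <- life_history_scenario(juvenile_survival = 0.5,
#'                            prop_females_breeding = 0.5,
#'                            replicates = 20, years = 10)
#' simulate_pva(s, seed = 1)
#' @export
simulate_pva <- function(scenario, plan = NULL, freqs = NULL, seed,
                         replicates = scenario$replicates,
                         years = scenario$years,
                         source_scenario = NULL, ideal_source = FALSE) {
  stopifnot(inherits(scenario, "life_history_scenario"))
  if (missing(seed)) stop("an explicit integer seed is required",
                          call. = FALSE)
  if (replicates < 1) stop("replicates must be at least 1", call. = FALSE)
  if (!is.null(freqs)) check_freq_table(freqs)
  track <- !is.null(freqs)
  migrating <- !is.null(plan) && plan$expected_immigrants_per_year > 0
  if (migrating && is.null(source_scenario))
    source_scenario <- source_scenario_default(plan)

  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, replicates)

  r_sum <- 0; r_sumsq <- 0; r_n <- 0L
  n_extinct <- 0L
  n_traj <- matrix(0L, replicates, years + 1L)
  he_traj <- if (track) matrix(NA_real_, replicates, years + 1L)
  extant_at <- matrix(FALSE, replicates, years + 1L)

  for (i in seq_len(replicates)) {
    set.seed(rep_seeds[i])
    res <- make_population(scenario$initial_n, scenario, freqs)
    src <- if (migrating && !ideal_source)
      make_population(plan$source_size, source_scenario, freqs)
    state <- structure(list(year = 0L, residents = res, source = src,
                            n_pre_truncation = NA_integer_),
                       class = "pva_state")
    gone <- is_extinct(res)            # current status
    ever_extinct <- gone               # first-passage extinction flag
    if (ever_extinct) n_extinct <- n_extinct + 1L
    n_traj[i, 1L] <- pop_size(res)
    extant_at[i, 1L] <- !gone
    if (track) he_traj[i, 1L] <- gene_diversity_pop(res)
    for (t in seq_len(years)) {
      gone_prev <- gone
      n_prev <- pop_size(state$residents)
      state <- annual_cycle(state, scenario, plan, source_scenario,
                            ideal_source, freqs)
      n_pre <- state$n_pre_truncation
      if (!gone_prev && n_prev > 0L && n_pre > 0L) {
        r <- log(n_pre / n_prev)
        r_sum <- r_sum + r
        r_sumsq <- r_sumsq + r^2
        r_n <- r_n + 1L
      }
      gone <- is_extinct(state$residents) # immigration may rescue later
      if (gone && !ever_extinct) {
        ever_extinct <- TRUE
        n_extinct <- n_extinct + 1L
      }
      n_traj[i, t + 1L] <- pop_size(state$residents)
      extant_at[i, t + 1L] <- !gone
      if (track && !gone)
        he_traj[i, t + 1L] <- gene_diversity_pop(state$residents)
    }
  }

  he_df <- NULL
  he_init <- he_fin <- he_fin_sd <- NA_real_
  if (track) {
    he_traj[!extant_at] <- NA_real_
    he_df <- data.frame(
      year = 0:years,
      he_mean = apply(he_traj, 2, function(z) mean(z, na.rm = TRUE)),
      he_sd = apply(he_traj, 2, function(z) {
        z <- z[!is.na(z)]
        if (length(z) < 2L) NA_real_ else stats::sd(z)
      }),
      n_extant = colSums(!is.na(he_traj)))
    he_init <- he_df$he_mean[1L]
    he_fin <- he_df$he_mean[years + 1L]
    he_fin_sd <- he_df$he_sd[years + 1L]
  }
  structure(list(
    stochastic_r_mean = if (r_n > 0) r_sum / r_n else NA_real_,
    stochastic_r_sd = if (r_n > 1)
      sqrt((r_sumsq - r_sum^2 / r_n) / (r_n - 1)) else NA_real_,
    extinction_probability = n_extinct / replicates,
    he_initial_mean = he_init,
    he_final_mean = he_fin,
    he_final_sd = he_fin_sd,
    n_trajectory_mean = colMeans(n_traj),
    he_trajectory = he_df,
    replicates = replicates,
    years = years,
    seed = seed),
    class = "pva_summary")
}

#' @export
print.pva_summary <- function(x, ...) {
  cat(sprintf("PVA summary: %d replicates x %d years (seed %s)\n",
              x$replicates, x$years, format(x$seed)))
  cat(sprintf("  stochastic r = %.3f (SD %.3f), P(extinction) = %.3f\n",
              x$stochastic_r_mean, x$stochastic_r_sd,
              x$extinction_probability))
  if (!is.na(x$he_initial_mean))
    cat(sprintf("  He: %.3f initial -> %.3f (SD %.3f) final (extant reps)\n",
                x$he_initial_mean, x$he_final_mean, x$he_final_sd))
  cat(sprintf("  mean N: %.1f initial -> %.1f final\n",
              x$n_trajectory_mean[1],
              x$n_trajectory_mean[length(x$n_trajectory_mean)]))
  invisible(x)
}

#' Summarize the full factorial of uncertain parameters
#'
#' Runs [simulate_pva()] for every scenario of [scenario_grid()] and returns
#' one row per scenario with the stochastic growth rate, its SD, the
#' extinction probability and (when founder frequencies are given) the final
#' expected heterozygosity — the machine-readable analogue of the standard
#' PVA results table.
#'
#' @param replicates,years Simulation effort per scenario.
#' @param seed Master seed; per-scenario seeds are derived from it.
#' @param freqs Optional founder [allele_freq_table()] enabling genetic
#'   tracking.
#' @param grid Scenario list, defaulting to [scenario_grid()].
#' @return Data frame with 5 value columns (`stochastic_r`, `stochastic_r_sd`,
#'   `extinction_probability`, `he_final`, `he_final_sd`) and the three
#'   varied parameters as identifier columns.
#' @export
run_scenario_grid <- function(replicates = 1000L, years = 20L, seed,
                              freqs = NULL, grid = scenario_grid()) {
  if (missing(seed)) stop("an explicit integer seed is required",
                          call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(2147483646L, length(grid))
  rows <- lapply(seq_along(grid), function(i) {
    sc <- grid[[i]]
    sm <- simulate_pva(sc, freqs = freqs, seed = seeds[i],
                       replicates = replicates, years = years)
    data.frame(age_first_litter = sc$age_first_litter_f,
               juvenile_survival = sc$juvenile_survival,
               prop_females_breeding = sc$prop_females_breeding,
               stochastic_r = sm$stochastic_r_mean,
               stochastic_r_sd = sm$stochastic_r_sd,
               extinction_probability = sm$extinction_probability,
               he_final = sm$he_final_mean,
               he_final_sd = sm$he_final_sd)
  })
  do.call(rbind, rows)
}

#' Effective population size from a heterozygosity trajectory
#'
#' Under neutral Wright-Fisher drift expected gene diversity decays by a
#' factor `1 - 1/(2 Ne)` per generation. This fits
#' `ln He_t = ln He_0 + (t / T) ln(1 - 1/(2 Ne))` by least squares on the
#' mean trajectory and inverts for Ne.
#'
#' @param summary A `pva_summary` with a tracked heterozygosity trajectory,
#'   or a data frame with columns `year` and `he_mean`.
#' @param generation_time Generation time T in years (from
#'   [deterministic_growth()]).
#' @return Estimated effective population size (harmonic-mean sense).
#' @export
ne_from_he_decay <- function(summary, generation_time) {
  df <- if (inherits(summary, "pva_summary")) summary$he_trajectory
        else summary
  if (is.null(df)) stop("no heterozygosity trajectory available",
                        call. = FALSE)
  ok <- is.finite(df$he_mean) & df$he_mean > 0
  fit <- stats::lm(log(he_mean) ~ year, data = df[ok, ])
  slope_per_gen <- unname(stats::coef(fit)[2]) * generation_time
  1 / (2 * (1 - exp(slope_per_gen)))
}
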