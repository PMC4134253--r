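#' Female life table implied by a scenario
#'
#' Builds the (birth-pulse, pre-breeding census) female life table. The first
#' censused class is age 1; survivorship to age 1 is juvenile survival and
#' each later year multiplies by adult female survival (no separate subadult
#' rate is modeled). Fecundity per female-year is constant from the age at
#' first litter onward:
#' `m = prop_females_breeding * (1 + prob_second_litter) * litter_size_mean *
#' (1 - sex_ratio_birth)` daughters.
#'
#' @param scenario A [life_history_scenario()].
#' @return A `life_table`: data frame with columns `age`, `lx` (survivorship
#'   from birth to age x) and `mx` (daughters per female of age x per year),
#'   truncated at `max_age`, with the adult female survival kept as an
#'   attribute for the no-recruitment limit of [deterministic_growth()].
#' @examples
#' lt <- life_table(life_history_scenario(juvenile_survival = 0.5,
#'                                        prop_females_breeding = 0.5))
#' lt$mx[1]  # 0.5 * 1.35 * 3 * 0.5 = 1.0125
#' @export
life_table <- function(scenario) {
  stopifnot(inherits(scenario, "life_history_scenario"))
  x <- seq_len(scenario$max_age)
  lx <- scenario$juvenile_survival * scenario$adult_survival_f^(x - 1)
  m <- scenario$prop_females_breeding * (1 + scenario$prob_second_litter) *
    scenario$litter_size_mean * (1 - scenario$sex_ratio_birth)
  mx <- ifelse(x >= scenario$age_first_litter_f, m, 0)
  structure(data.frame(age = x, lx = lx, mx = mx),
            class = c("life_table", "data.frame"),
            adult_survival_f = scenario$adult_survival_f,
            age_first_litter = scenario$age_first_litter_f)
}

#' Leslie (projection) matrix for a female life table
#'
#' With a pre-breeding census the top-row fertilities are `Sj * mx` (a
#' daughter must survive her first year to be censused) and the subdiagonal
#' carries adult survival; its dominant eigenvalue equals the Euler-Lotka
#' root of [deterministic_growth()].
#'
#' @param lt A [life_table()].
#' @return A square numeric matrix, one row/column per censused age class.
#' @export
leslie_matrix <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  A <- nrow(lt)
  sa <- attr(lt, "adult_survival_f")
  sj <- lt$lx[1]
  M <- matrix(0, A, A)
  M[1, ] <- sj * lt$mx
  if (A > 1)
    M[cbind(2:A, 1:(A - 1))] <- sa
  M
}

#' Asymptotic growth rate and generation time
#'
#' Solves the Euler-Lotka equation `sum_x lx * mx * lambda^(-x) = 1` on the
#' truncated age range by bisection on `[1e-6, 5]` to an absolute tolerance
#' of 1e-10 (deterministic; no randomness). When the life table has no
#' recruitment (all `lx * mx = 0`) the population declines by adult survival
#' alone and `lambda` equals the adult female survival rate. Generation time
#' is the mean age of mothers in the stable population,
#' `T = sum(x lx mx lambda^-x) / sum(lx mx lambda^-x)`.
#'
#' @param lt A [life_table()].
#' @return A list of class `deterministic_result` with elements `lambda` and
#'   `generation_time` (`NA` when there is no recruitment).
#' @export
deterministic_growth <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  if (any(!is.finite(lt$lx)) || any(!is.finite(lt$mx)))
    stop("life table contains non-finite entries", call. = FALSE)
  x <- lt$age
  prod_ <- lt$lx * lt$mx
  if (all(prod_ == 0)) {
    lam <- attr(lt, "adult_survival_f")
    return(structure(list(lambda = lam, generation_time = NA_real_),
                     class = "deterministic_result"))
  }
  f <- function(lam) sum(prod_ * lam^(-x)) - 1
  lo <- 1e-6
  hi <- 5
  if (f(hi) > 0) hi <- 50 # extreme fecundities still bracketed
  # f is strictly decreasing in lambda; bisect
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  lam <- (lo + hi) / 2
  w <- prod_ * lam^(-x)
  structure(list(lambda = lam, generation_time = sum(x * w) / sum(w)),
            class = "deterministic_result")
}

#' @export
print.deterministic_result <- function(x, ...) {
  cat(sprintf("lambda = %.6f, generation time = %s yr\n", x$lambda,
              ifelse(is.na(x$generation_time), "NA",
                     sprintf("%.3f", x$generation_time))))
  invisible(x)
}

#' Deterministic growth-rate surface over juvenile survival and age at first
#' litter
#'
#' Evaluates [deterministic_growth()] on a grid, reproducing the standard
#' sensitivity plot of lambda against juvenile survival for each age at
#' first litter.
#'
#' @param base Scenario supplying all other parameters.
#' @param sj_values Grid of juvenile survival probabilities.
#' @param afl_values Grid of ages at first litter (years).
#' @return Data frame with columns `age_first_litter`, `juvenile_survival`,
#'   `lambda`.
#' @export
lambda_surface <- function(base = life_history_scenario(),
                           sj_values = seq(0, 0.6, by = 0.05),
                           afl_values = c(1L, 2L)) {
  if (!length(sj_values) || !length(afl_values))
    stop("empty parameter grid", call. = FALSE)
  grid <- expand.grid(juvenile_survival = sj_values,
                      age_first_litter = afl_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$lambda <- vapply(seq_len(nrow(grid)), function(i) {
    s <- base
    s$juvenile_survival <- grid$juvenile_survival[i]
    s$age_first_litter_f <- grid$age_first_litter[i]
    deterministic_growth(life_table(validate_scenario(s)))$lambda
  }, numeric(1))
  grid[, c("age_first_litter", "juvenile_survival", "lambda")]
}

#' Juvenile survival threshold for population growth
#'
#' Finds the juvenile survival rate at which the deterministic growth rate
#' crosses 1 (population replacement), for a given age at first litter and
#' breeding proportion.
#'
#' @param base Scenario supplying all other parameters.
#' @param afl Age at first litter (years).
#' @param interval Search interval for juvenile survival.
#' @return The critical juvenile survival probability, or `NA` if lambda
#'   never reaches 1 on the interval.
#' @export
lambda_threshold <- function(base = life_history_scenario(), afl = 1L,
                             interval = c(0.01, 0.99)) {
  g <- function(sj) {
    s <- base
    s$juvenile_survival <- sj
    s$age_first_litter_f <- afl
    deterministic_growth(life_table(validate_scenario(s)))$lambda - 1
  }
  if (g(interval[1]) * g(interval[2]) > 0) return(NA_real_)
  stats::uniroot(g, interval, tol = 1e-9)$root
}

#' Expected-value (deterministic) population projection
#'
#' Projects the expected female age-class vector through the Leslie matrix
#' with no stochasticity of any kind; provided for validating the stochastic
#' engine (its yearly growth factor converges to the Euler-Lotka lambda).
#'
#' @param scenario A [life_history_scenario()].
#' @param years Number of projected years.
#' @param n0 Initial total female count, spread over the stable age
#'   distribution.
#' @return Data frame with columns `year`, `n` (expected total females) and
#'   `growth_factor` (`n[t]/n[t-1]`, `NA` for year 0).
#' @export
expected_trajectory <- function(scenario, years = 30L,
                                n0 = scenario$initial_n / 2) {
  lt <- life_table(scenario)
  M <- leslie_matrix(lt)
  v <- stable_age_distribution(scenario) * n0
  n <- numeric(years + 1)
  n[1] <- sum(v)
  for (t in seq_len(years)) {
    v <- as.vector(M %*% v)
    n[t + 1] <- sum(v)
  }
  data.frame(year = 0:years, n = n, growth_factor = c(NA, n[-1] / n[-length(n)]))
}

#' Stable age distribution of censused age classes
#'
#' Proportions `c_x` proportional to `lx * lambda^-x` over ages
#' `1..max_age`; used to initialize simulated populations.
#'
#' @param scenario A [life_history_scenario()].
#' @return Numeric vector of length `max_age` summing to 1.
#' @export
stable_age_distribution <- function(scenario) {
  lt <- life_table(scenario)
  lam <- deterministic_growth(lt)$lambda
  w <- lt$lx * lam^(-lt$age)
  if (sum(w) <= 0) w <- rep(1, nrow(lt)) # degenerate: uniform ages
  w / sum(w)
}
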