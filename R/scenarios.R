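#' Default life-history parameterization for an urban red-squirrel population
#'
#' Returns the baseline vital rates and simulation settings used throughout
#' the package: a polygynous mating system, 35% of breeding females producing
#' a second litter, litters of mean 3 and maximum 6 offspring with a 1:1 birth
#' sex ratio, adult annual survival of 0.68 (environmental SD 0.12) for
#' females and 0.63 (SD 0.13) for males, a carrying capacity and starting size
#' of 120 individuals, and 1000 replicates of 20 simulated years. Parameters
#' for which no field estimate exists (maximum age, male age at first
#' breeding, environmental SDs of juvenile survival and breeding rate) carry
#' literature-typical values and can be overridden in
#' [life_history_scenario()] or a scenario file.
#'
#' @return Named list of default parameter values.
#' @export
sceaux_defaults <- function() {
  list(
    age_first_litter_f      = 1L,
    age_first_breeding_m    = 1L,
    max_age                 = 8L,
    prop_females_breeding   = 0.50,
    prob_second_litter      = 0.35,
    litter_size_mean        = 3,
    litter_size_max         = 6L,
    sex_ratio_birth         = 0.5,
    adult_survival_f        = 0.68,
    adult_survival_f_ev_sd  = 0.12,
    adult_survival_m        = 0.63,
    adult_survival_m_ev_sd  = 0.13,
    juvenile_survival       = 0.50,
    juvenile_survival_ev_sd = 0.10,
    breeding_ev_sd          = 0.10,
    carrying_capacity       = 120L,
    initial_n               = 120L,
    years                   = 20L,
    replicates              = 1000L,
    ev_concordance          = TRUE
  )
}

prob_fields <- c(
  "prop_females_breeding", "prob_second_litter", "sex_ratio_birth",
  "adult_survival_f", "adult_survival_m", "juvenile_survival"
)
sd_fields <- c(
  "adult_survival_f_ev_sd", "adult_survival_m_ev_sd",
  "juvenile_survival_ev_sd", "breeding_ev_sd"
)

validate_scenario <- function(s, allow_overshoot = FALSE) {
  for (f in c(prob_fields, sd_fields, "litter_size_mean", "litter_size_max",
              "age_first_litter_f", "age_first_breeding_m", "max_age",
              "carrying_capacity", "initial_n", "years", "replicates")) {
    v <- s[[f]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || !is.finite(v))
      stop("scenario field '", f, "' must be a single finite number",
           call. = FALSE)
  }
  for (f in prob_fields) {
    if (s[[f]] < 0 || s[[f]] > 1)
      stop("scenario field '", f, "' must be a probability in [0, 1], got ",
           s[[f]], call. = FALSE)
  }
  for (f in sd_fields) {
    if (s[[f]] < 0)
      stop("scenario field '", f, "' must be a non-negative SD", call. = FALSE)
  }
  if (!is.logical(s$ev_concordance) || length(s$ev_concordance) != 1L)
    stop("ev_concordance must be TRUE or FALSE", call. = FALSE)
  if (s$litter_size_mean > s$litter_size_max)
    stop("litter_size_mean must not exceed litter_size_max", call. = FALSE)
  if (s$age_first_litter_f < 1)
    stop("age_first_litter_f must be at least 1 year", call. = FALSE)
  if (s$max_age <= s$age_first_litter_f)
    stop("max_age must exceed age_first_litter_f", call. = FALSE)
  if (s$years < 1 || s$replicates < 1)
    stop("years and replicates must be at least 1", call. = FALSE)
  if (!allow_overshoot && s$initial_n > s$carrying_capacity)
    stop("initial_n exceeds carrying_capacity; pass allow_overshoot = TRUE ",
         "to permit a supersaturated start", call. = FALSE)
  invisible(s)
}

#' Construct a life-history scenario
#'
#' A scenario bundles every parameter of one population-viability run: female
#' age at first litter, juvenile survival, the annual proportion of breeding
#' females, sex- and age-specific adult survival with their environmental
#' (among-year) SDs, litter-size distribution, carrying capacity, starting
#' size and run length. Unspecified fields take the defaults of
#' [sceaux_defaults()].
#'
#' @param ... Named scalar overrides of the default fields.
#' @param allow_overshoot Permit `initial_n > carrying_capacity` (used for
#'   supersaturated starting conditions); otherwise an error.
#' @return An object of class `life_history_scenario` (a validated named list).
#' @examples
#' s <- life_history_scenario(age_first_litter_f = 1,
#'                            juvenile_survival = 0.5,
#'                            prop_females_breeding = 0.5)
#' s$adult_survival_f  # 0.68
#' @export
life_history_scenario <- function(..., allow_overshoot = FALSE) {
  s <- sceaux_defaults()
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(names(dots) == "")))
    stop("all scenario overrides must be named", call. = FALSE)
  unknown <- setdiff(names(dots), names(s))
  if (length(unknown))
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  s[names(dots)] <- dots
  validate_scenario(s, allow_overshoot)
  structure(s, class = "life_history_scenario")
}

#' @export
print.life_history_scenario <- function(x, ...) {
  cat("Life-history scenario\n")
  cat(sprintf("  age at first litter (F): %d yr | juvenile survival: %.2f | breeding females: %.2f\n",
              as.integer(x$age_first_litter_f), x$juvenile_survival,
              x$prop_females_breeding))
  cat(sprintf("  adult survival F/M: %.2f (SD %.2f) / %.2f (SD %.2f); max age %d\n",
              x$adult_survival_f, x$adult_survival_f_ev_sd,
              x$adult_survival_m, x$adult_survival_m_ev_sd,
              as.integer(x$max_age)))
  cat(sprintf("  litters: mean %.1f, max %d; second litter prob %.2f; birth sex ratio %.2f\n",
              x$litter_size_mean, as.integer(x$litter_size_max),
              x$prob_second_litter, x$sex_ratio_birth))
  cat(sprintf("  N0 = %d, K = %d, %d years x %d replicates\n",
              as.integer(x$initial_n), as.integer(x$carrying_capacity),
              as.integer(x$years), as.integer(x$replicates)))
  invisible(x)
}

# keys that a scenario file must provide explicitly (no silent defaulting of
# the parameters the analysis is most sensitive to)
mandatory_scenario_keys <- c("age_first_litter_f", "juvenile_survival",
                             "prop_females_breeding")

#' Load a scenario from a YAML key/value file
#'
#' Reads a flat key/value document, checks that the mandatory keys
#' (`age_first_litter_f`, `juvenile_survival`, `prop_females_breeding`) are
#' present, fills every other field with the documented defaults (each filled
#' default is reported via `message()`), and validates the result.
#'
#' @param path Path to a YAML scenario file.
#' @param text YAML text given directly instead of a file.
#' @param overrides Named list applied on top of the file (command-line style
#'   `key=value` overrides).
#' @param quiet Suppress the filled-default messages.
#' @return A [life_history_scenario()].
#' @seealso [write_scenario()] for the inverse operation.
#' @export
load_scenario <- function(path = NULL, text = NULL, overrides = list(),
                          quiet = FALSE) {
  if (is.null(path) == is.null(text))
    stop("supply exactly one of 'path' or 'text'", call. = FALSE)
  vals <- if (!is.null(path)) {
    if (!file.exists(path)) stop("scenario file not found: ", path,
                                 call. = FALSE)
    yaml::read_yaml(path)
  } else {
    yaml::yaml.load(text)
  }
  if (!is.list(vals) || is.null(names(vals)))
    stop("scenario document must be a flat key/value mapping", call. = FALSE)
  vals[names(overrides)] <- overrides
  missing_keys <- setdiff(mandatory_scenario_keys, names(vals))
  if (length(missing_keys))
    stop("scenario document is missing mandatory key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  defaults <- sceaux_defaults()
  filled <- setdiff(names(defaults), names(vals))
  if (length(filled) && !quiet)
    message("filled defaults: ",
            paste(sprintf("%s=%s", filled,
                          vapply(defaults[filled], format, "")),
                  collapse = ", "))
  do.call(life_history_scenario, vals)
}

#' Serialize a scenario to YAML
#'
#' @param scenario A [life_history_scenario()].
#' @param path Output file; when `NULL` the YAML text is returned instead.
#' @return `path` invisibly, or the YAML string when `path = NULL`.
#' @export
write_scenario <- function(scenario, path = NULL) {
  stopifnot(inherits(scenario, "life_history_scenario"))
  txt <- yaml::as.yaml(unclass(scenario), precision = 15L)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Construct an immigration plan
#'
#' Describes gene flow into the focal population: the expected number of
#' immigrants per year (Poisson arrivals), the age window of dispersers
#' (juveniles and subadults, 1-2 years by default), and the size of the
#' stable source population they are drawn from.
#'
#' @param expected_immigrants_per_year Mean arrivals per year (e.g. 0.2 for
#'   one immigrant every five years, up to 5 per year).
#' @param immigrant_min_age,immigrant_max_age Age window (completed years) of
#'   dispersing individuals.
#' @param source_size Stable size of the simulated source population.
#' @return An object of class `immigration_plan`.
#' @export
immigration_plan <- function(expected_immigrants_per_year = 0,
                             immigrant_min_age = 1L,
                             immigrant_max_age = 2L,
                             source_size = 100L) {
  if (expected_immigrants_per_year < 0)
    stop("expected_immigrants_per_year must be non-negative", call. = FALSE)
  if (immigrant_min_age < 1 || immigrant_min_age > immigrant_max_age)
    stop("need 1 <= immigrant_min_age <= immigrant_max_age", call. = FALSE)
  if (source_size < 1)
    stop("source_size must be positive", call. = FALSE)
  structure(
    list(expected_immigrants_per_year = expected_immigrants_per_year,
         immigrant_min_age = as.integer(immigrant_min_age),
         immigrant_max_age = as.integer(immigrant_max_age),
         source_size = as.integer(source_size)),
    class = "immigration_plan")
}

#' Factorial grid of uncertain demographic parameters
#'
#' Enumerates the 16 scenarios spanned by the parameters for which no field
#' estimate was available: female age at first litter (1 or 2 years),
#' juvenile survival (20-50%) and the proportion of breeding females at high
#' density (35% or 50%). Ordering is age at first litter (slowest), then
#' juvenile survival, then breeding proportion, so the first element is
#' (1 year, 0.20, 0.35). All other fields come from [sceaux_defaults()].
#'
#' @param afl_values,sj_values,breed_values Optional alternative grids.
#' @return A list of [life_history_scenario()] objects.
#' @export
scenario_grid <- function(afl_values = c(1L, 2L),
                          sj_values = c(0.20, 0.30, 0.40, 0.50),
                          breed_values = c(0.35, 0.50)) {
  combos <- expand.grid(breed = breed_values, sj = sj_values,
                        afl = afl_values, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i)
    life_history_scenario(
      age_first_litter_f = as.integer(combos$afl[i]),
      juvenile_survival = combos$sj[i],
      prop_females_breeding = combos$breed[i]))
}
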