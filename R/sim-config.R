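#' Simulation configuration for the two-area warming experiment
#'
#' Builds and validates the configuration object consumed by
#' [generate_temperature_series()], [simulate_population()],
#' [sample_catch()], [simulate_community()] and [run_pipeline()].
#'
#' The defaults describe a Biotest-style whole-ecosystem warming experiment:
#' two enclosed coastal areas ("heated" and "reference"), perch cohorts born
#' 1969--2003, warming onset in 1980 as a +7 degC step in growth-season
#' temperature, and gillnet survey sampling with a female-only ageing
#' programme and length-stratified subsampling in later years.
#'
#' @param year_start first calendar year simulated (first birth cohort).
#' @param year_end last calendar year simulated (last capture year).
#' @param impact_year first calendar year of warming.
#' @param birth_year_end last birth cohort; defaults to `year_end - 2` so the
#'   final cohorts still acquire at least one complete growth year.
#' @param recruits_per_year_per_area number of recruits entering each area
#'   each year.
#' @param reference_temp_mean,reference_temp_trend,reference_temp_sd mean
#'   (degC), linear trend (degC/year) and interannual s.d. (degC) of the
#'   reference-area growth-season temperature.
#' @param warming_form one of `"step"`, `"linear"`, `"asymptotic"`,
#'   `"sigmoid"`, `"none"`; temporal shape of the heated-area temperature
#'   elevation after `impact_year`.
#' @param warming_magnitude asymptotic temperature elevation (degC).
#' @param warming_form_params list of shape parameters: `ramp_years` (linear),
#'   `gamma` (asymptotic/sigmoid), `tau` (sigmoid).
#' @param growth_params list of thermal growth-model parameters, see
#'   [growth_increment()].
#' @param individual_growth_cv lognormal CV of the *persistent* individual
#'   growth multiplier (a fish's lifelong growth potential).
#' @param transient_growth_cv lognormal CV of the *transient* fish-by-year
#'   growth multiplier; individual growth variation is predominantly
#'   year-specific, so conditioning on reaching a size class carries only
#'   weak information about future growth.
#' @param area_year_growth_cv lognormal CV of an area-by-year growth
#'   multiplier representing local environmental variability (food,
#'   density) that is *not* shared between areas; this is the main source
#'   of noise in the paired difference series.
#' @param measurement_sd s.d. (mm) of length measurement error at capture.
#' @param survival annual survival probability used by the truncated
#'   geometric capture-age schedule.
#' @param max_age oldest capture age.
#' @param female_fraction probability that a recruit is female.
#' @param selectivity_params list with `l50` (mm) and `slope` (mm) of the
#'   logistic gillnet selectivity curve.
#' @param stratified_subsample_n maximum number of fish retained per length
#'   bin per area and year once stratified subsampling starts.
#' @param stratification_start_year first capture year with stratified
#'   subsampling.
#' @param stratification_bin_mm width (mm) of the subsampling length bins.
#' @param gradual_effect_mode logical; if `TRUE` a secondary multiplier on
#'   the juvenile growth capacity in the heated area ramps linearly from 1
#'   to `1 + gradual_effect_rho` over `gradual_effect_ramp_years` after
#'   impact, emulating gradually changing biotic conditions or adaptation.
#' @param gradual_effect_rho final proportional increase of juvenile growth
#'   capacity under `gradual_effect_mode`.
#' @param gradual_effect_initial multiplier value at the onset itself; the
#'   default slightly below 1 represents initially unfavourable biotic
#'   conditions that roughly offset the juveniles' immediate thermal gain,
#'   so the net juvenile response emerges gradually.
#' @param gradual_effect_ramp_years ramp length (years) of the gradual mode.
#' @param juvenile_length_max length (mm) below which the gradual multiplier
#'   applies.
#' @param hatch_length_mm length at hatch (mm).
#' @param relation_a,relation_b true power-law body-length/operculum-radius
#'   relation L = a R^b used when synthesising annuli.
#' @param radius_noise_cv lognormal CV of annulus-radius measurement noise.
#' @param community_params list controlling the synthetic community
#'   generator, see [simulate_community()].
#' @param rng_seed integer seed governing all randomness.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(rng_seed = 1)
#' cfg$impact_year
sim_config <- function(year_start = 1969,
                       year_end = 2005,
                       impact_year = 1980,
                       birth_year_end = year_end - 2,
                       recruits_per_year_per_area = 150,
                       reference_temp_mean = 16,
                       reference_temp_trend = 0.02,
                       reference_temp_sd = 0.5,
                       warming_form = "step",
                       warming_magnitude = 7,
                       warming_form_params = list(ramp_years = 24, gamma = 3, tau = 8),
                       growth_params = default_growth_params(),
                       individual_growth_cv = 0.08,
                       transient_growth_cv = 0.15,
                       area_year_growth_cv = 0.015,
                       measurement_sd = 2,
                       survival = 0.70,
                       max_age = 10,
                       female_fraction = 0.5,
                       selectivity_params = list(l50 = 90, slope = 12),
                       stratified_subsample_n = 25,
                       stratification_start_year = 1992,
                       stratification_bin_mm = 25,
                       gradual_effect_mode = FALSE,
                       gradual_effect_rho = 0.32,
                       gradual_effect_initial = 0.96,
                       gradual_effect_ramp_years = 24,
                       juvenile_length_max = 100,
                       hatch_length_mm = 5,
                       relation_a = 12,
                       relation_b = 1.15,
                       radius_noise_cv = 0.03,
                       community_params = default_community_params(),
                       rng_seed = 1L) {
  cfg <- list(
    year_start = as.integer(year_start),
    year_end = as.integer(year_end),
    impact_year = as.integer(impact_year),
    birth_year_end = as.integer(birth_year_end),
    recruits_per_year_per_area = as.integer(recruits_per_year_per_area),
    reference_temp_mean = reference_temp_mean,
    reference_temp_trend = reference_temp_trend,
    reference_temp_sd = reference_temp_sd,
    warming_form = warming_form,
    warming_magnitude = warming_magnitude,
    warming_form_params = warming_form_params,
    growth_params = growth_params,
    individual_growth_cv = individual_growth_cv,
    transient_growth_cv = transient_growth_cv,
    area_year_growth_cv = area_year_growth_cv,
    measurement_sd = measurement_sd,
    survival = survival,
    max_age = as.integer(max_age),
    female_fraction = female_fraction,
    selectivity_params = selectivity_params,
    stratified_subsample_n = as.integer(stratified_subsample_n),
    stratification_start_year = as.integer(stratification_start_year),
    stratification_bin_mm = stratification_bin_mm,
    gradual_effect_mode = isTRUE(gradual_effect_mode),
    gradual_effect_rho = gradual_effect_rho,
    gradual_effect_initial = gradual_effect_initial,
    gradual_effect_ramp_years = gradual_effect_ramp_years,
    juvenile_length_max = juvenile_length_max,
    hatch_length_mm = hatch_length_mm,
    relation_a = relation_a,
    relation_b = relation_b,
    radius_noise_cv = radius_noise_cv,
    community_params = community_params,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default thermal growth-model parameters
#'
#' Parameters of the phenomenological size- and temperature-dependent annual
#' growth increment, see [growth_increment()]. `theta0` anchors the optimum
#' growth temperature of small (<= `l_ref` mm) fish near 30 degC; `theta1`
#' makes the optimum decline with the logarithm of body length so that the
#' optimum of 200 mm fish lies below heated-area growth-season temperature;
#' `w` is the *annual effective* thermal breadth (seasonal integration makes
#' it much broader than an instantaneous physiological curve).
#'
#' @return A list with elements `l_inf`, `k`, `theta0`, `theta1`, `l_ref`, `w`.
#' @export
default_growth_params <- function() {
  list(l_inf = 300, k = 0.233, theta0 = 30, theta1 = 14, l_ref = 70, w = 60)
}

#' Default synthetic community generator parameters
#'
#' @return A list describing species pool, survey design and post-impact
#'   compositional drift used by [simulate_community()].
#' @export
default_community_params <- function() {
  list(
    species = c("perch", "roach", "bream", "whitefish", "ruffe",
                "bleak", "herring", "smelt"),
    base_abundance = c(perch = 40, roach = 35, bream = 8, whitefish = 10,
                       ruffe = 12, bleak = 6, herring = 9, smelt = 7),
    # proportional post-impact abundance shift per species in the heated area
    drift_effect = c(perch = 0.8, roach = 0.6, bream = 0.4, whitefish = -0.8,
                     ruffe = 0.3, bleak = -0.3, herring = -0.6, smelt = -0.9),
    drift_form = "sigmoid",   # "sigmoid", "step" or "none"
    drift_tau = 8, drift_gamma = 2,
    survey_year_start = 1977,
    survey_year_end = 2004,
    month_by_area = c(heated = 10, reference = 8),
    n_stations = c(heated = 3, reference = 4),
    n_nights = 6,
    nets_per_station = 2,
    year_cv = 0.25
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!(cfg$year_start < cfg$impact_year && cfg$impact_year < cfg$year_end))
    stop("require year_start < impact_year < year_end", call. = FALSE)
  if (!cfg$warming_form %in% c("step", "linear", "asymptotic", "sigmoid", "none"))
    stop("unknown warming_form: ", cfg$warming_form, call. = FALSE)
  if (cfg$warming_magnitude < 0) stop("warming_magnitude must be >= 0", call. = FALSE)
  for (nm in c("reference_temp_sd", "individual_growth_cv", "measurement_sd",
               "radius_noise_cv", "area_year_growth_cv", "transient_growth_cv")) {
    if (cfg[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  }
  if (cfg$survival <= 0 || cfg$survival >= 1)
    stop("survival must be in (0, 1)", call. = FALSE)
  if (cfg$female_fraction < 0 || cfg$female_fraction > 1)
    stop("female_fraction must be in [0, 1]", call. = FALSE)
  gp <- cfg$growth_params
  if (!all(c("l_inf", "k", "theta0", "theta1", "l_ref", "w") %in% names(gp)))
    stop("growth_params incomplete", call. = FALSE)
  if (cfg$birth_year_end >= cfg$year_end)
    stop("birth_year_end must be < year_end", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-area warming simulation configuration\n")
  cat(sprintf("  years %d-%d, impact %d, cohorts %d-%d\n",
              x$year_start, x$year_end, x$impact_year,
              x$year_start, x$birth_year_end))
  cat(sprintf("  warming: %s, magnitude %.1f degC\n",
              x$warming_form, x$warming_magnitude))
  cat(sprintf("  recruits/area/year: %d, seed: %d\n",
              x$recruits_per_year_per_area, x$rng_seed))
  invisible(x)
}

# deterministic polynomial rolling hash of an R object (report provenance);
# modulus 2^31 - 1 keeps every intermediate exactly representable as double
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
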