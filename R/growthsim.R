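#' Generate paired heated/reference temperature series
#'
#' The reference area follows `mean + trend * (year - year_start)` plus
#' i.i.d. Gaussian interannual noise. The heated area shares the *same*
#' noise stream and trend (so the paired design's common-variability
#' assumption holds by construction) and adds a warming anomaly
#' `delta_T(year)` that is 0 before `impact_year` and follows
#' `warming_form` afterwards:
#' \describe{
#'   \item{step}{constant `warming_magnitude`}
#'   \item{linear}{ramp from 0 to the magnitude over `ramp_years`}
#'   \item{asymptotic}{`magnitude * s / (s + gamma)`, `s = year - impact_year`}
#'   \item{sigmoid}{`magnitude / (1 + exp(-(s - tau) / gamma))`}
#'   \item{none}{identically 0}
#' }
#'
#' @param config a [sim_config()] object.
#' @return A list with elements `heated` and `reference`, each a data frame
#'   with columns `area`, `year`, `temperature`.
#' @export
#' @examples
#' ts <- generate_temperature_series(sim_config(reference_temp_sd = 0))
#' head(ts$heated)
generate_temperature_series <- function(config) {
  validate_sim_config(config)
  years <- config$year_start:config$year_end
  set.seed(config$rng_seed)
  noise <- stats::rnorm(length(years), 0, config$reference_temp_sd)
  ref <- config$reference_temp_mean +
    config$reference_temp_trend * (years - config$year_start) + noise
  dT <- warming_anomaly(years, config)
  list(
    heated = data.frame(area = "heated", year = years,
                        temperature = ref + dT),
    reference = data.frame(area = "reference", year = years,
                           temperature = ref)
  )
}

# temperature elevation of the heated area by calendar year
warming_anomaly <- function(years, config) {
  s <- years - config$impact_year
  after <- s >= 0
  p <- config$warming_form_params
  M <- config$warming_magnitude
  f <- switch(config$warming_form,
    none = rep(0, length(years)),
    step = as.numeric(after),
    linear = ifelse(after, pmin(s / p$ramp_years, 1), 0),
    asymptotic = ifelse(after, s / (s + p$gamma), 0),
    sigmoid = ifelse(after, 1 / (1 + exp(-(s - p$tau) / p$gamma)), 0),
    stop("unknown warming_form: ", config$warming_form, call. = FALSE)
  )
  M * f
}

# size-dependent optimum growth temperature (degC); clamped at theta0 for
# lengths below l_ref (hatchlings share the small-fish optimum)
t_opt <- function(length_mm, theta0 = 30, theta1 = 14, l_ref = 70) {
  theta0 - theta1 * log(pmax(length_mm, l_ref) / l_ref)
}

#' Annual growth increment from the thermal performance model
#'
#' Phenomenological annual increment
#' `g_max(L) * exp(-((T - T_opt(L)) / w)^2)`, with growth capacity
#' `g_max(L) = k * max(l_inf - L, 0)` and a size-dependent optimum
#' temperature `T_opt(L) = theta0 - theta1 * log(L / l_ref)` (clamped at
#' `theta0` below `l_ref`). The optimum of small fish sits near 30 degC and
#' declines with body size, so moderate warming accelerates juvenile growth
#' while large fish gain little or overshoot their optimum.
#'
#' @param length_mm body length (mm) at the start of the growth year;
#'   vectorised.
#' @param temperature_C growth-season temperature (degC).
#' @param growth_params list as in [default_growth_params()].
#' @param heterogeneity multiplicative individual growth factor (default 1).
#' @return Increment in mm (>= 0), same length as the inputs.
#' @export
#' @examples
#' growth_increment(70, 30, default_growth_params())  # at the optimum
growth_increment <- function(length_mm, temperature_C,
                             growth_params = default_growth_params(),
                             heterogeneity = 1) {
  if (any(length_mm <= 0)) stop("length_mm must be > 0", call. = FALSE)
  gp <- growth_params
  g_max <- gp$k * pmax(gp$l_inf - length_mm, 0)
  topt <- t_opt(length_mm, gp$theta0, gp$theta1, gp$l_ref)
  perf <- exp(-((temperature_C - topt) / gp$w)^2)
  pmax(g_max * perf * heterogeneity, 0)
}

# gradual post-impact multiplier on juvenile growth capacity (heated
# area): ramps linearly from `gradual_effect_initial` (biotic conditions
# at onset, typically ~offsetting the immediate thermal gain) to
# `1 + gradual_effect_rho`
gradual_multiplier <- function(year, length_mm, config) {
  if (!config$gradual_effect_mode) return(rep(1, length(year)))
  s <- pmax(year - config$impact_year, 0)
  ramp <- pmin(s / config$gradual_effect_ramp_years, 1)
  m0 <- config$gradual_effect_initial
  ifelse(length_mm < config$juvenile_length_max,
         m0 + (1 + config$gradual_effect_rho - m0) * ramp, 1)
}

#' Simulate the two-area fish population
#'
#' Each recruit hatches at `hatch_length_mm`, receives a lognormal
#' individual growth multiplier (CV `individual_growth_cv`), a sex, and a
#' capture age drawn from a truncated geometric schedule (annual survival
#' `survival`, maximum age `max_age`, capture years restricted to
#' `(year_start, year_end]`). It then grows one [growth_increment()] per
#' calendar year at its area's temperature; under `gradual_effect_mode` the
#' heated-area juvenile growth capacity additionally ramps up after impact.
#' Capture length is the true length at capture age plus Gaussian
#' measurement noise. Deterministic given the configuration seed.
#'
#' @param config a [sim_config()] object.
#' @param temperatures optional precomputed result of
#'   [generate_temperature_series()].
#' @return An object of class `"fish_population"`: list with data frames
#'   `individuals` (id, area, birth_year, sex, capture_year, capture_age,
#'   capture_length) and `trajectories` (id, area, birth_year, age, length;
#'   true lengths-at-age 0..capture_age), plus the temperature series and
#'   config as attributes.
#' @export
simulate_population <- function(config, temperatures = NULL) {
  validate_sim_config(config)
  if (is.null(temperatures)) temperatures <- generate_temperature_series(config)
  temp_map <- list(
    heated = stats::setNames(temperatures$heated$temperature,
                             temperatures$heated$year),
    reference = stats::setNames(temperatures$reference$temperature,
                                temperatures$reference$year)
  )
  set.seed(config$rng_seed + 1L)
  cohorts <- config$year_start:config$birth_year_end
  n <- config$recruits_per_year_per_area

  # area-by-year environmental growth multiplier (independent between
  # areas; the local variability the paired design is meant to absorb)
  all_years <- config$year_start:config$year_end
  env <- list(
    heated = stats::setNames(
      individual_heterogeneity(length(all_years), config$area_year_growth_cv),
      all_years),
    reference = stats::setNames(
      individual_heterogeneity(length(all_years), config$area_year_growth_cv),
      all_years)
  )
  ind_list <- vector("list", 2L)
  areas <- c("heated", "reference")
  for (ai in seq_along(areas)) {
    area <- areas[ai]
    birth_year <- rep(cohorts, each = n)
    nf <- length(birth_year)
    id <- sprintf("%s%05d", ifelse(area == "heated", "H", "R"), seq_len(nf))
    sex <- ifelse(stats::runif(nf) < config$female_fraction, "F", "M")
    capture_age <- draw_capture_age(birth_year, config)
    het <- individual_heterogeneity(nf, config$individual_growth_cv)
    ind_list[[ai]] <- data.frame(
      id = id, area = area, birth_year = birth_year, sex = sex,
      capture_age = capture_age,
      capture_year = birth_year + capture_age,
      heterogeneity = het,
      stringsAsFactors = FALSE
    )
  }
  individuals <- do.call(rbind, ind_list)

  # grow all fish age by age; temperature looked up per (area, calendar year)
  max_age <- max(individuals$capture_age)
  nf <- nrow(individuals)
  L <- matrix(NA_real_, nrow = nf, ncol = max_age + 1L)
  L[, 1L] <- config$hatch_length_mm
  for (a in 0:(max_age - 1L)) {
    alive <- individuals$capture_age > a
    yr <- individuals$birth_year[alive] + a
    tC <- ifelse(individuals$area[alive] == "heated",
                 temp_map$heated[as.character(yr)],
                 temp_map$reference[as.character(yr)])
    len <- L[alive, a + 1L]
    heated_i <- individuals$area[alive] == "heated"
    mult <- ifelse(heated_i, gradual_multiplier(yr, len, config), 1)
    mult <- mult * ifelse(heated_i, env$heated[as.character(yr)],
                          env$reference[as.character(yr)])
    mult <- mult * individual_heterogeneity(sum(alive),
                                            config$transient_growth_cv)
    inc <- growth_increment(len, tC, config$growth_params,
                            individuals$heterogeneity[alive]) * mult
    L[alive, a + 2L] <- len + pmax(inc, 1e-3)  # floor keeps trajectories strictly increasing
  }

  true_at_capture <- L[cbind(seq_len(nf), individuals$capture_age + 1L)]
  individuals$capture_length <- pmax(
    true_at_capture + stats::rnorm(nf, 0, config$measurement_sd), 1)

  ages <- lapply(individuals$capture_age, function(a) 0:a)
  len_list <- lapply(seq_len(nf), function(i)
    L[i, seq_len(individuals$capture_age[i] + 1L)])
  reps <- individuals$capture_age + 1L
  trajectories <- data.frame(
    id = rep(individuals$id, reps),
    area = rep(individuals$area, reps),
    birth_year = rep(individuals$birth_year, reps),
    age = unlist(ages),
    length = unlist(len_list),
    stringsAsFactors = FALSE
  )

  pop <- list(
    individuals = individuals[, c("id", "area", "birth_year", "sex",
                                  "capture_year", "capture_age",
                                  "capture_length", "heterogeneity")],
    trajectories = trajectories
  )
  attr(pop, "temperatures") <- temperatures
  attr(pop, "config") <- config
  class(pop) <- "fish_population"
  pop
}

# truncated geometric capture age: P(a) proportional to survival^a,
# a = 1..min(max_age, year_end - birth_year)
draw_capture_age <- function(birth_year, config) {
  cap <- pmin(config$max_age, config$year_end - birth_year)
  vapply(cap, function(m) {
    a <- seq_len(m)
    sample(a, 1L, prob = config$survival^a)
  }, integer(1))
}

individual_heterogeneity <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' @export
print.fish_population <- function(x, ...) {
  cat(sprintf("fish_population: %d individuals (%d heated, %d reference), cohorts %d-%d\n",
              nrow(x$individuals),
              sum(x$individuals$area == "heated"),
              sum(x$individuals$area == "reference"),
              min(x$individuals$birth_year), max(x$individuals$birth_year)))
  invisible(x)
}

#' Apply the survey sampling protocol to a simulated population
#'
#' Mirrors the ageing-programme sampling: (i) optional female-only filter;
#' (ii) logistic size-dependent gillnet selectivity on capture length
#' (retention probability `1 / (1 + exp(-(L - l50) / slope))`);
#' (iii) from `stratification_start_year` onwards, at most
#' `stratified_subsample_n` fish per `stratification_bin_mm` length bin per
#' area and capture year. Deterministic given the configuration seed.
#'
#' @param population a `"fish_population"`.
#' @param config a [sim_config()]; defaults to the one stored on the
#'   population.
#' @param female_only keep only females (the ageing programme sexed fish and
#'   aged females throughout).
#' @return A `"fish_population"` restricted to the sampled fish, with a
#'   `"sampling"` attribute recording counts after each filter stage.
#' @export
sample_catch <- function(population, config = attr(population, "config"),
                         female_only = TRUE) {
  stopifnot(inherits(population, "fish_population"))
  ind <- population$individuals
  if (nrow(ind) == 0) {
    warning("empty population, nothing to sample")
    return(population)
  }
  counts <- c(total = nrow(ind))
  set.seed(config$rng_seed + 2L)

  if (female_only) ind <- ind[ind$sex == "F", , drop = FALSE]
  counts <- c(counts, females = nrow(ind))

  sp <- config$selectivity_params
  p_ret <- 1 / (1 + exp(-(ind$capture_length - sp$l50) / sp$slope))
  ind <- ind[stats::runif(nrow(ind)) < p_ret, , drop = FALSE]
  counts <- c(counts, selected = nrow(ind))

  strat <- ind$capture_year >= config$stratification_start_year
  if (any(strat) && is.finite(config$stratified_subsample_n)) {
    bin <- floor(ind$capture_length / config$stratification_bin_mm)
    key <- paste(ind$area, ind$capture_year, bin)
    keep <- rep(TRUE, nrow(ind))
    for (k in unique(key[strat])) {
      idx <- which(key == k & strat)
      if (length(idx) > config$stratified_subsample_n)
        keep[setdiff(idx, sample(idx, config$stratified_subsample_n))] <- FALSE
    }
    ind <- ind[keep, , drop = FALSE]
  }
  counts <- c(counts, subsampled = nrow(ind))

  if (nrow(ind) == 0) warning("sampling filters removed every fish")
  out <- list(
    individuals = ind,
    trajectories = population$trajectories[
      population$trajectories$id %in% ind$id, , drop = FALSE]
  )
  attr(out, "temperatures") <- attr(population, "temperatures")
  attr(out, "config") <- config
  attr(out, "sampling") <- counts
  class(out) <- "fish_population"
  out
}

#' Simulate two-area gillnet survey catch records
#'
#' Generates per-(area, year, station, night, species) count records in the
#' layout expected by [compute_cpue()]: October survey in the heated area,
#' August in the reference area, six nights per survey, a fixed station set
#' per area and a common species pool. Species-specific expected counts are
#' lognormally perturbed per year; in the heated area the composition
#' optionally drifts after `impact_year` (abrupt or sigmoidal), emulating a
#' warming-driven community shift.
#'
#' @param config a [sim_config()]; generator options live in
#'   `config$community_params`.
#' @return Data frame with columns `area`, `year`, `month`, `night`,
#'   `station`, `species`, `count`, `nets`.
#' @export
simulate_community <- function(config) {
  validate_sim_config(config)
  cp <- config$community_params
  set.seed(config$rng_seed + 3L)
  years <- cp$survey_year_start:cp$survey_year_end
  out <- list()
  for (area in c("heated", "reference")) {
    stations <- paste0(substr(area, 1, 1), seq_len(cp$n_stations[[area]]))
    for (y in years) {
      s <- y - config$impact_year
      drift <- if (area == "heated" && s >= 0) {
        switch(cp$drift_form,
               none = 0,
               step = 1,
               sigmoid = 1 / (1 + exp(-(s - cp$drift_tau) / cp$drift_gamma)),
               stop("unknown drift_form: ", cp$drift_form, call. = FALSE))
      } else 0
      lambda_sp <- cp$base_abundance * pmax(1 + cp$drift_effect * drift, 0.02)
      year_eff <- individual_heterogeneity(length(cp$species), cp$year_cv)
      grid <- expand.grid(station = stations, night = seq_len(cp$n_nights),
                          species = cp$species, stringsAsFactors = FALSE)
      lam <- lambda_sp[grid$species] * year_eff[match(grid$species, cp$species)] /
        (cp$n_stations[[area]])
      out[[length(out) + 1L]] <- data.frame(
        area = area, year = y, month = cp$month_by_area[[area]],
        night = grid$night, station = grid$station, species = grid$species,
        count = stats::rpois(nrow(grid), lam),
        nets = cp$nets_per_station,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Write population tables as delimited text
#'
#' Writes `individuals.tsv`, `trajectories.tsv` and `temperatures.tsv` with
#' a `#schema:` header line each, plus `metadata.tsv` carrying the seed and
#' config hash.
#'
#' @param population a `"fish_population"`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "fish_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(population, "config")
  temps <- attr(population, "temperatures")
  files <- c(
    write_table_schema(population$individuals, file.path(dir, "individuals.tsv"),
                       "individuals v1"),
    write_table_schema(population$trajectories, file.path(dir, "trajectories.tsv"),
                       "trajectories v1"),
    write_table_schema(rbind(temps$heated, temps$reference),
                       file.path(dir, "temperatures.tsv"), "temperatures v1"),
    write_table_schema(
      data.frame(key = c("rng_seed", "config_hash"),
                 value = c(cfg$rng_seed, config_hash(cfg))),
      file.path(dir, "metadata.tsv"), "metadata v1")
  )
  invisible(files)
}

write_table_schema <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#schema: ", schema), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read a delimited table written with a schema header
#'
#' @param path file path.
#' @return Data frame; the schema line is stored in attribute `"schema"`.
#' @export
read_table_schema <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  attr(df, "schema") <- sub("^#schema: ", "", first)
  df
}
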