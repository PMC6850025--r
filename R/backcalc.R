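#' Synthesise operculum annuli from a growth trajectory
#'
#' Inverse model for the synthetic-data path: given true lengths-at-age and
#' a body-length/operculum-radius power relation `L = a * R^b`, the radius
#' of the winter ring laid down at age `i` is
#' `R_i = (L_i / a)^(1/b) * lognormal noise`, re-sorted to be monotone. The
#' capture radius derives from capture length the same way (noise-free) and
#' is floored at the largest annulus radius.
#'
#' @param lengths_at_age numeric vector of lengths (mm) at ages `0..A`;
#'   element 1 is the hatch length, which leaves no ring. Must be strictly
#'   increasing.
#' @param capture_length measured length at capture (mm).
#' @param relation list or `"length_radius_relation"` with elements `a`, `b`.
#' @param radius_noise_cv lognormal CV of ring-radius measurement noise.
#' @return A list of class `"operculum_record"` with elements `annuli_radii`
#'   (radii at ages `1..A`), `capture_radius`, `capture_length`.
#' @export
#' @examples
#' rec <- synthesize_annuli(c(5, 70, 120), 150, list(a = 1, b = 1), 0)
#' rec$annuli_radii  # equals the lengths at ages 1..2
synthesize_annuli <- function(lengths_at_age, capture_length, relation,
                              radius_noise_cv = 0) {
  if (any(diff(lengths_at_age) <= 0))
    stop("trajectory must be strictly increasing", call. = FALSE)
  stopifnot(relation$a > 0, relation$b > 0, capture_length > 0)
  ring_lengths <- lengths_at_age[-1L]  # hatch leaves no winter ring
  radii <- (ring_lengths / relation$a)^(1 / relation$b)
  if (radius_noise_cv > 0) {
    sdlog <- sqrt(log(1 + radius_noise_cv^2))
    radii <- radii * stats::rlnorm(length(radii), -sdlog^2 / 2, sdlog)
    radii <- sort(radii)
  }
  r_c <- (capture_length / relation$a)^(1 / relation$b)
  if (length(radii)) r_c <- max(r_c, radii[length(radii)])
  structure(list(annuli_radii = radii, capture_radius = r_c,
                 capture_length = capture_length),
            class = "operculum_record")
}

#' Fit the body-length/operculum-radius power relation
#'
#' Ordinary least squares of `log(L_c)` on `log(R_c)` across fish:
#' `L = a * R^b` with `a = exp(intercept)`, `b = slope`.
#'
#' @param capture_length,capture_radius positive vectors (one entry per
#'   fish, length >= 3).
#' @return A list of class `"length_radius_relation"`: `a`, `b`, `n`,
#'   `sigma_log` (residual s.d. on the log scale).
#' @export
fit_length_radius <- function(capture_length, capture_radius) {
  ok <- is.finite(capture_length) & is.finite(capture_radius) &
    capture_length > 0 & capture_radius > 0
  if (sum(ok) < 3) stop("need at least 3 positive (L, R) pairs", call. = FALSE)
  x <- log(capture_radius[ok]); y <- log(capture_length[ok])
  if (stats::var(x) < 1e-12)
    stop("singular fit: all capture radii (effectively) equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[2])
  if (abs(b) < 1e-8)
    warning("estimated exponent b is ~0: lengths do not scale with radius")
  structure(list(a = exp(unname(stats::coef(fit)[1])), b = b,
                 n = sum(ok), sigma_log = stats::sigma(fit)),
            class = "length_radius_relation")
}

#' @export
print.length_radius_relation <- function(x, ...) {
  cat(sprintf("length-radius power relation: L = %.4g * R^%.4g (n = %d, log-sd = %.3g)\n",
              x$a, x$b, x$n, x$sigma_log))
  invisible(x)
}

#' Back-calculate lengths-at-age under the body proportional hypothesis
#'
#' With the power form of the length-radius relation, the body proportional
#' hypothesis (the ratio of body length to the length expected from the
#' structure radius is maintained through life) gives
#' `L_i = L_c * (R_i / R_c)^b`; the coefficient `a` cancels.
#'
#' @param record an `"operculum_record"` (or list with `annuli_radii`,
#'   `capture_radius`, `capture_length`).
#' @param relation a `"length_radius_relation"` (only `b` is used).
#' @param hatch_floor optional minimum length (mm) applied to the output.
#' @return Numeric vector of back-calculated lengths at ages `1..A`.
#' @export
#' @examples
#' rec <- list(annuli_radii = c(2, 4), capture_radius = 8, capture_length = 200)
#' backcalculate_lengths(rec, list(a = 1, b = 1))  # 50, 100
backcalculate_lengths <- function(record, relation, hatch_floor = NULL) {
  r <- record$annuli_radii
  if (any(r > record$capture_radius + 1e-12))
    stop("annulus radius exceeds capture radius", call. = FALSE)
  if (any(diff(r) <= 0)) stop("annuli radii must be strictly increasing",
                              call. = FALSE)
  L <- record$capture_length * (r / record$capture_radius)^relation$b
  if (!is.null(hatch_floor)) L <- pmax(L, hatch_floor)
  L
}

#' Synthesise an annuli table for a whole sampled population
#'
#' Applies [synthesize_annuli()] to every fish, using the true relation in
#' the configuration. Radius noise uses the configuration seed.
#'
#' @param population a `"fish_population"` (typically after
#'   [sample_catch()]).
#' @param config a [sim_config()]; defaults to the one stored on the
#'   population.
#' @return A list with `annuli` (data frame: id, age, radius) and
#'   `captures` (data frame: id, area, capture_radius, capture_length).
#' @export
synthesize_annuli_table <- function(population,
                                    config = attr(population, "config")) {
  stopifnot(inherits(population, "fish_population"))
  set.seed(config$rng_seed + 4L)
  relation <- list(a = config$relation_a, b = config$relation_b)
  ind <- population$individuals
  traj <- population$trajectories
  traj <- traj[order(traj$id, traj$age), ]
  rings <- traj[traj$age >= 1L, , drop = FALSE]  # hatch leaves no ring

  radius <- (rings$length / relation$a)^(1 / relation$b)
  if (config$radius_noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$radius_noise_cv^2))
    radius <- radius * stats::rlnorm(length(radius), -sdlog^2 / 2, sdlog)
    # re-sort within fish: rows are age-ordered per id
    radius <- stats::ave(radius, rings$id, FUN = sort)
  }

  r_c <- (ind$capture_length / relation$a)^(1 / relation$b)
  r_max <- tapply(radius, rings$id, max)
  r_c <- pmax(r_c, as.numeric(r_max[ind$id]))

  list(
    annuli = data.frame(id = rings$id, age = rings$age, radius = radius,
                        stringsAsFactors = FALSE),
    captures = data.frame(id = ind$id, area = ind$area,
                          capture_radius = r_c,
                          capture_length = ind$capture_length,
                          stringsAsFactors = FALSE)
  )
}

#' Back-calculate a whole annuli table
#'
#' Fits the length-radius relation from the capture pairs (per area by
#' default, pooled optionally) and back-calculates every fish's
#' lengths-at-age. The hatch length is appended as the age-0 length of every
#' fish, as assumed in first-year growth calculations.
#'
#' @param annuli_table result of [synthesize_annuli_table()] (or equivalent
#'   real tables with the same columns).
#' @param individuals data frame with id, area, birth_year, capture_year
#'   (e.g. `population$individuals`).
#' @param per_area fit the relation separately per area (default) or pooled.
#' @param hatch_length_mm assumed length at hatch, appended at age 0.
#' @return A list with `lengths` (data frame: id, area, birth_year,
#'   capture_year, age, length) and `relations` (list of fitted relations
#'   keyed by area or `"pooled"`).
#' @export
backcalculate_population <- function(annuli_table, individuals,
                                     per_area = TRUE, hatch_length_mm = 5) {
  cap <- annuli_table$captures
  groups <- if (per_area) split(cap, cap$area) else list(pooled = cap)
  relations <- lapply(groups, function(g)
    fit_length_radius(g$capture_length, g$capture_radius))

  ann <- annuli_table$annuli
  idx <- match(ann$id, cap$id)
  area <- cap$area[idx]
  b <- if (per_area) {
    vapply(relations, function(r) r$b, numeric(1))[area]
  } else rep(relations$pooled$b, nrow(ann))
  L <- cap$capture_length[idx] * (ann$radius / cap$capture_radius[idx])^b

  meta <- individuals[match(ann$id, individuals$id), ]
  lengths <- data.frame(id = ann$id, area = area,
                        birth_year = meta$birth_year,
                        capture_year = meta$capture_year,
                        age = ann$age, length = L,
                        stringsAsFactors = FALSE)
  # age-0 hatch length for every fish
  ind <- individuals[individuals$id %in% cap$id, ]
  hatch <- data.frame(id = ind$id, area = ind$area,
                      birth_year = ind$birth_year,
                      capture_year = ind$capture_year,
                      age = 0L, length = hatch_length_mm,
                      stringsAsFactors = FALSE)
  lengths <- rbind(hatch, lengths)
  lengths <- lengths[order(lengths$id, lengths$age), ]
  rownames(lengths) <- NULL
  list(lengths = lengths, relations = relations)
}
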