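#' Length-specific annual growth
#'
#' `G_L = (L_{t+1} - L_t) / L_t`, the relative length increment over one
#' growth year. Scale-invariant: multiplying both lengths by a positive
#' constant leaves it unchanged.
#'
#' @param l_t length at the start of the growth year (mm), > 0; vectorised.
#' @param l_t1 length one year later (mm).
#' @return Numeric vector of growth rates; a warning is raised if any input
#'   pair decreases.
#' @export
#' @examples
#' length_specific_growth(100, 150)  # 0.5
#' length_specific_growth(5, 70)     # 13: first-year growth from hatch
length_specific_growth <- function(l_t, l_t1) {
  if (any(l_t <= 0)) stop("l_t must be > 0", call. = FALSE)
  g <- (l_t1 - l_t) / l_t
  if (any(g < 0)) warning("negative growth: input lengths decrease")
  g
}

#' Size-class specification for age-specific growth analysis
#'
#' Discrete, non-overlapping length windows, one per age, so that
#' size-dependent growth rates are compared among fish with a common growth
#' history. The defaults are the analysis windows for the study system:
#' newborns start at 5 mm (everyone qualifies), 1-year-olds 65--75 mm,
#' 2-year-olds 110--130 mm, 3-year-olds 140--160 mm. Intervals are closed
#' on both ends. Cells (area x year) with fewer than `n_min` fish are
#' dropped.
#'
#' @param classes named list mapping age (as character) to `c(lower, upper)`
#'   in mm.
#' @param n_min minimum fish per (area, year) cell.
#' @param hatch_length_mm conventional age-0 length.
#' @return A list of class `"size_class_spec"`.
#' @export
size_class_spec <- function(classes = list(`1` = c(65, 75),
                                           `2` = c(110, 130),
                                           `3` = c(140, 160)),
                            n_min = 4,
                            hatch_length_mm = 5) {
  for (cl in classes) {
    if (length(cl) != 2 || cl[1] >= cl[2])
      stop("each size class must be c(lower, upper) with lower < upper",
           call. = FALSE)
  }
  ages <- sort(as.integer(names(classes)))
  for (i in seq_along(ages)[-1]) {
    lo <- classes[[as.character(ages[i])]][1]
    hi_prev <- classes[[as.character(ages[i - 1])]][2]
    if (lo <= hi_prev)
      stop("size classes of successive ages must not overlap", call. = FALSE)
  }
  structure(list(classes = classes, n_min = n_min,
                 hatch_length_mm = hatch_length_mm),
            class = "size_class_spec")
}

#' Select fish belonging to one age's size class
#'
#' Keeps records whose back-calculated length at `age` falls inside the
#' class window (closed interval; age 0 means all fish, which start at the
#' hatch length by convention), then drops every (area, year) cell with
#' fewer than `n_min` fish, where the year is the calendar year of the
#' growth increment starting at that age (`birth_year + age`).
#'
#' @param lengths back-calculated length table (id, area, birth_year,
#'   capture_year, age, length), e.g. from [backcalculate_population()].
#' @param age integer age class.
#' @param spec a [size_class_spec()].
#' @return Subset of `lengths` at the stated age with a `year` column
#'   appended.
#' @export
select_size_class <- function(lengths, age, spec = size_class_spec()) {
  sel <- lengths[lengths$age == age, , drop = FALSE]
  if (age > 0) {
    win <- spec$classes[[as.character(age)]]
    if (is.null(win)) stop("no size class defined for age ", age, call. = FALSE)
    sel <- sel[sel$length >= win[1] & sel$length <= win[2], , drop = FALSE]
  }
  sel$year <- sel$birth_year + age
  cell <- paste(sel$area, sel$year)
  n_cell <- table(cell)
  sel <- sel[n_cell[cell] >= spec$n_min, , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Build an annual response series per area
#'
#' Two response families:
#' \describe{
#'   \item{`size_at_age_k`}{mean back-calculated length at age `k`, assigned
#'     to the calendar year the fish reached that age
#'     (`birth_year + k`).}
#'   \item{`growth_ageclass_k`}{mean length-specific growth `G_L` over the
#'     increment from age `k` to `k + 1`, restricted to the age-`k` size
#'     class, assigned to the calendar year the increment started
#'     (`birth_year + k`).}
#' }
#' Growth increments belonging to a fish's capture calendar year are
#' excluded (growth in the survey year is incomplete), cohorts with fewer
#' than `min_cohort_n` individuals in an area are excluded, and cells with
#' fewer than `n_min` fish are dropped.
#'
#' @param lengths back-calculated length table, see [select_size_class()].
#' @param response string, `"size_at_age_<k>"` or `"growth_ageclass_<k>"`.
#' @param spec a [size_class_spec()].
#' @param min_cohort_n minimum individuals per (area, birth year) cohort.
#' @return A data frame of class `"annual_response_series"` with columns
#'   `area`, `year`, `mean`, `n` and attribute `"response"`.
#' @export
build_response_series <- function(lengths, response,
                                  spec = size_class_spec(),
                                  min_cohort_n = 3) {
  parsed <- parse_response(response)
  lengths <- drop_small_cohorts(lengths, min_cohort_n)

  if (parsed$type == "size_at_age") {
    sel <- lengths[lengths$age == parsed$age, , drop = FALSE]
    sel$year <- sel$birth_year + parsed$age
    sel$value <- sel$length
  } else {
    sel <- select_size_class(lengths, parsed$age, spec)
    nxt <- lengths[lengths$age == parsed$age + 1L,
                   c("id", "length"), drop = FALSE]
    idx <- match(sel$id, nxt$id)
    sel$next_length <- nxt$length[idx]
    sel <- sel[!is.na(sel$next_length), , drop = FALSE]
    # growth during the survey year is not assessed
    sel <- sel[sel$year < sel$capture_year, , drop = FALSE]
    sel$value <- length_specific_growth(sel$length, sel$next_length)
  }

  agg <- aggregate_mean_n(sel$value, sel$area, sel$year)
  agg <- agg[agg$n >= spec$n_min, , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "response") <- response
  class(agg) <- c("annual_response_series", "data.frame")
  agg
}

parse_response <- function(response) {
  m <- regmatches(response,
                  regexec("^(size_at_age|growth_ageclass)_([0-9]+)$", response))[[1]]
  if (length(m) != 3)
    stop("unknown response: ", response,
         " (expected size_at_age_<k> or growth_ageclass_<k>)", call. = FALSE)
  list(type = m[2], age = as.integer(m[3]))
}

drop_small_cohorts <- function(lengths, min_cohort_n) {
  if (min_cohort_n <= 1) return(lengths)
  ids <- unique(lengths[, c("id", "area", "birth_year")])
  n_cohort <- table(paste(ids$area, ids$birth_year))
  key <- paste(lengths$area, lengths$birth_year)
  lengths[n_cohort[key] >= min_cohort_n, , drop = FALSE]
}

aggregate_mean_n <- function(value, area, year) {
  key <- paste(area, year, sep = "\r")
  means <- tapply(value, key, mean)
  ns <- tapply(value, key, length)
  parts <- strsplit(names(means), "\r", fixed = TRUE)
  out <- data.frame(
    area = vapply(parts, `[`, "", 1L),
    year = as.integer(vapply(parts, `[`, "", 2L)),
    mean = as.numeric(means),
    n = as.integer(ns),
    stringsAsFactors = FALSE
  )
  out[order(out$area, out$year), ]
}

#' Heated-minus-reference difference series
#'
#' The unit BACIPS operates on: for every year present in both areas,
#' `delta = heated mean - reference mean`, flagged before/after with
#' `after = (year >= impact_year)`.
#'
#' @param heated,reference `"annual_response_series"` (or data frames with
#'   `area`, `year`, `mean`, `n`) for the two areas; alternatively pass a
#'   single series containing both areas as `heated` and omit `reference`.
#' @param impact_year first year of impact.
#' @param min_before,min_after minimum number of shared years required on
#'   each side of the impact.
#' @return A data frame of class `"difference_series"` with columns `year`,
#'   `delta`, `after` and attributes `"response"` and `"impact_year"`.
#' @export
difference_series <- function(heated, reference = NULL, impact_year,
                              min_before = 2, min_after = 2) {
  if (is.null(reference)) {
    reference <- heated[heated$area == "reference", , drop = FALSE]
    heated <- heated[heated$area == "heated", , drop = FALSE]
  }
  common <- intersect(heated$year, reference$year)
  common <- sort(common)
  after <- common >= impact_year
  if (sum(!after) < min_before || sum(after) < min_after) {
    deficient <- if (sum(!after) < min_before) "before" else "after"
    stop(sprintf(
      "insufficient overlap in the %s-impact period: %d before / %d after shared years",
      deficient, sum(!after), sum(after)), call. = FALSE)
  }
  d <- data.frame(
    year = common,
    delta = heated$mean[match(common, heated$year)] -
      reference$mean[match(common, reference$year)],
    after = after
  )
  attr(d, "response") <- attr(heated, "response")
  attr(d, "impact_year") <- impact_year
  class(d) <- c("difference_series", "data.frame")
  d
}

#' @export
print.difference_series <- function(x, ...) {
  cat(sprintf("difference series%s: %d before / %d after years (impact %s)\n",
              if (!is.null(attr(x, "response")))
                paste0(" [", attr(x, "response"), "]") else "",
              sum(!x$after), sum(x$after), attr(x, "impact_year")))
  print.data.frame(x, ...)
  invisible(x)
}
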