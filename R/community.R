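#' Build a species-by-(area, year) CPUE matrix from catch records
#'
#' Catch per unit effort is total catch divided by total net-nights after
#' filtering: only the first fishing night actually sampled per area and
#' year, an area-specific survey month, an optional station inclusion list,
#' an optional excluded-species list, and optional removal of disturbed
#' samplings. Species not caught in both areas are dropped (compositions
#' must be comparable across areas).
#'
#' @param catch data frame with columns `area`, `year`, `month`, `night`,
#'   `station`, `species`, `count`, `nets` (one row per station-night and
#'   species; `nets` is the number of nets fished that station-night).
#' @param month_by_area named vector mapping area to survey month; `NULL`
#'   keeps all months.
#' @param first_night_only use only the first (minimum-index) night fished
#'   per area and year.
#' @param stations optional character vector of stations to include.
#' @param exclude_species optional character vector of species to drop
#'   before CPUE computation (e.g. taxa not sampled representatively).
#' @param disturbed optional data frame with columns `area`, `year`,
#'   `station`, `night` naming samplings to exclude.
#' @return An object of class `"community_matrix"`: numeric matrix with one
#'   row per `area:year` and one column per retained species, with
#'   attributes `meta` (data frame area, year, effort) and
#'   `dropped_species`.
#' @export
compute_cpue <- function(catch,
                         month_by_area = c(heated = 10, reference = 8),
                         first_night_only = TRUE,
                         stations = NULL,
                         exclude_species = NULL,
                         disturbed = NULL) {
  req <- c("area", "year", "month", "night", "station", "species", "count", "nets")
  stopifnot(all(req %in% names(catch)))
  if (!is.null(month_by_area))
    catch <- catch[catch$month == month_by_area[catch$area], , drop = FALSE]
  if (!is.null(stations))
    catch <- catch[catch$station %in% stations, , drop = FALSE]
  if (!is.null(exclude_species))
    catch <- catch[!catch$species %in% exclude_species, , drop = FALSE]
  if (!is.null(disturbed)) {
    bad <- paste(disturbed$area, disturbed$year, disturbed$station,
                 disturbed$night)
    catch <- catch[!paste(catch$area, catch$year, catch$station,
                          catch$night) %in% bad, , drop = FALSE]
  }
  if (first_night_only) {
    first <- stats::aggregate(night ~ area + year, data = catch, FUN = min)
    key <- paste(catch$area, catch$year)
    fkey <- paste(first$area, first$year)
    catch <- catch[catch$night == first$night[match(key, fkey)], , drop = FALSE]
  }
  if (nrow(catch) == 0) stop("no catch records left after filtering", call. = FALSE)

  # effort: net-nights per (area, year) over distinct station-nights
  sn <- unique(catch[, c("area", "year", "station", "night", "nets")])
  effort <- stats::aggregate(nets ~ area + year, data = sn, FUN = sum)
  if (any(effort$nets <= 0)) {
    bad <- effort[effort$nets <= 0, ]
    stop("zero effort after filters for ",
         paste(bad$area, bad$year, collapse = ", "), call. = FALSE)
  }

  totals <- stats::aggregate(count ~ area + year + species, data = catch,
                             FUN = sum)
  totals$effort <- effort$nets[match(paste(totals$area, totals$year),
                                     paste(effort$area, effort$year))]
  totals$cpue <- totals$count / totals$effort

  species <- sort(unique(totals$species))
  rows <- unique(totals[, c("area", "year")])
  rows <- rows[order(rows$area, rows$year), ]
  mat <- matrix(0, nrow(rows), length(species),
                dimnames = list(paste(rows$area, rows$year, sep = ":"), species))
  mat[cbind(match(paste(totals$area, totals$year, sep = ":"),
                  rownames(mat)),
            match(totals$species, species))] <- totals$cpue

  # keep only species caught in both areas
  by_area <- rowsum(mat, rows$area)
  present_both <- colnames(mat)[apply(by_area > 0, 2, all)]
  dropped <- setdiff(colnames(mat), present_both)
  mat <- mat[, present_both, drop = FALSE]

  attr(mat, "meta") <- data.frame(area = rows$area, year = rows$year,
                                  effort = effort$nets[
                                    match(paste(rows$area, rows$year),
                                          paste(effort$area, effort$year))],
                                  stringsAsFactors = FALSE)
  attr(mat, "dropped_species") <- dropped
  class(mat) <- c("community_matrix", class(mat))
  mat
}

#' Chord distance matrix
#'
#' Euclidean distance between unit-normalised abundance vectors:
#' `d(x, y) = ||x/||x|| - y/||y||||`. Scale-invariant per row and bounded
#' by `sqrt(2)` for non-negative abundances.
#'
#' @param mat abundance matrix, rows = sites (here area:year), columns =
#'   species.
#' @return A [stats::dist] object.
#' @export
#' @examples
#' chord_distance_matrix(rbind(c(1, 0), c(0, 1)))  # sqrt(2)
chord_distance_matrix <- function(mat) {
  mat <- as.matrix(mat)
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0))
    stop("all-zero row(s): ", paste(rownames(mat)[norms == 0], collapse = ", "),
         "; chord normalisation undefined", call. = FALSE)
  stats::dist(mat / norms)
}

#' Principal coordinates analysis
#'
#' Classical metric MDS: Gower double-centering of `-D^2 / 2` and
#' eigendecomposition (via [stats::cmdscale()]); coordinates are
#' eigenvectors scaled by the square root of their eigenvalues. Negative
#' eigenvalues are reported, not dropped silently. Each axis' proportion of
#' variation is its eigenvalue over the sum of positive eigenvalues.
#'
#' To remove the eigenvector sign ambiguity, axis orientation can be fixed
#' against the abundance matrix: each axis is flipped, if needed, so that
#' the most abundant species' association (correlation of its abundances
#' with the axis scores) is non-negative.
#'
#' @param d a [stats::dist] object or symmetric zero-diagonal matrix.
#' @param abundances optional matrix (same row order as `d`) used for the
#'   orientation rule.
#' @return An object of class `"pcoa_result"`: `scores` (rows x axes),
#'   `eigenvalues` (all, descending), `proportion` (per retained positive
#'   axis), `negative_eigenvalues`.
#' @export
pcoa <- function(d, abundances = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 sites", call. = FALSE)
  cs <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = n - 1, eig = TRUE))
  eig <- cs$eig
  pos <- eig > 1e-9 * max(abs(eig))
  scores <- cs$points
  keep <- seq_len(min(ncol(scores), sum(pos)))
  scores <- scores[, keep, drop = FALSE]
  colnames(scores) <- paste0("PCO", seq_len(ncol(scores)))
  rownames(scores) <- rownames(dm)

  if (!is.null(abundances)) {
    ab <- as.matrix(abundances)
    dominant <- which.max(colSums(ab))
    for (j in seq_len(ncol(scores))) {
      r <- suppressWarnings(stats::cor(ab[, dominant], scores[, j]))
      if (is.finite(r) && r < 0) scores[, j] <- -scores[, j]
    }
  }

  structure(list(
    scores = scores,
    eigenvalues = eig,
    proportion = eig[pos][seq_len(ncol(scores))] / sum(eig[pos]),
    negative_eigenvalues = eig[eig < 0]
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d sites, %d positive axes\n",
              nrow(x$scores), ncol(x$scores)))
  cat("proportion of variation:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$proportion, 4)),
             collapse = ", "), "\n")
  if (length(x$negative_eigenvalues))
    cat(sprintf("note: %d negative eigenvalue(s), min %.3g\n",
                length(x$negative_eigenvalues), min(x$negative_eigenvalues)))
  invisible(x)
}

#' Difference series of PCoA axis scores between areas
#'
#' Extracts per-year site scores of one ordination axis for each area
#' (rows named `area:year`) and forms the heated-minus-reference
#' difference series for BACIPS analysis. The axis sign is whatever the
#' orientation rule fixed; flipping it negates the series but leaves
#' model choice unchanged.
#'
#' @param result a `"pcoa_result"` whose score rows are named
#'   `area:year`.
#' @param axis axis number.
#' @param impact_year first impact year.
#' @return A `"difference_series"`.
#' @export
axis_difference_series <- function(result, axis, impact_year) {
  scores <- result$scores
  if (axis > ncol(scores)) stop("axis ", axis, " not available", call. = FALSE)
  parts <- strsplit(rownames(scores), ":", fixed = TRUE)
  area <- vapply(parts, `[`, "", 1L)
  year <- as.integer(vapply(parts, `[`, "", 2L))
  sc <- scores[, axis]
  mk <- function(a) {
    d <- data.frame(area = a, year = year[area == a], mean = sc[area == a],
                    n = 1L, stringsAsFactors = FALSE)
    attr(d, "response") <- paste0("PCO", axis)
    d
  }
  difference_series(mk("heated"), mk("reference"), impact_year)
}
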