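test_that("CPUE construction filters and divides by effort", {
  toy <- expand.grid(night = 1:2, station = c("s1", "s2"),
                     species = c("perch", "roach"),
                     stringsAsFactors = FALSE)
  toy$area <- "heated"; toy$year <- 1990; toy$month <- 10; toy$nets <- 1
  toy$count <- c(20, 9, 10, 7, 4, 1, 6, 3)  # night1: perch 30, roach 10
  cm <- compute_cpue(toy, month_by_area = c(heated = 10))
  # 30 perch over 2 nets, 1 night
  expect_equal(unname(cm["heated:1990", "perch"]), 15)
  expect_equal(unname(cm["heated:1990", "roach"]), 5)

  # second-night records never contribute
  toy2 <- toy; toy2$count[toy2$night == 2] <- 1e6
  expect_equal(as.numeric(compute_cpue(toy2, month_by_area = c(heated = 10))),
               as.numeric(cm))

  # hand-computed oracle on a mixed two-area table
  mixed <- rbind(
    data.frame(area = "heated", year = 1990, month = 10, night = 1,
               station = "h1", species = c("perch", "roach"), count = c(8, 4),
               nets = 2),
    data.frame(area = "reference", year = 1990, month = 8, night = 1,
               station = c("r1", "r2"), species = "perch", count = c(3, 6),
               nets = c(2, 1)),
    data.frame(area = "reference", year = 1990, month = 8, night = 1,
               station = "r1", species = "roach", count = 12, nets = 2)
  )
  cm2 <- compute_cpue(mixed)
  expect_equal(unname(cm2["heated:1990", "perch"]), 8 / 2)
  expect_equal(unname(cm2["reference:1990", "perch"]), (3 + 6) / 3)
  expect_equal(unname(cm2["reference:1990", "roach"]), 12 / 3)

  # species absent from one area are dropped
  one_sided <- rbind(mixed,
                     data.frame(area = "heated", year = 1990, month = 10,
                                night = 1, station = "h1", species = "smelt",
                                count = 5, nets = 2))
  cm3 <- compute_cpue(one_sided)
  expect_false("smelt" %in% colnames(cm3))
  expect_true("smelt" %in% attr(cm3, "dropped_species"))

  # disturbed samplings are excluded
  dist_cm <- compute_cpue(mixed, disturbed = data.frame(
    area = "reference", year = 1990, station = "r2", night = 1))
  expect_equal(unname(dist_cm["reference:1990", "perch"]), 3 / 2)
})

test_that("chord distance matches hand values and its bounds", {
  m <- rbind(a = c(2, 2), b = c(5, 5), c = c(1, 0), d = c(0, 1), e = c(1, 1))
  D <- as.matrix(chord_distance_matrix(m))
  expect_equal(D["a", "b"], 0)                        # proportional rows
  expect_equal(D["c", "d"], sqrt(2))                  # orthogonal maximum
  expect_equal(D["c", "e"], sqrt(2 - sqrt(2)), tolerance = 1e-10)  # 0.76537

  expect_error(chord_distance_matrix(rbind(c(1, 1), c(0, 0))), "all-zero")

  # random compositions: bounded by sqrt(2), invariant to row scaling
  set.seed(8)
  for (i in 1:25) {
    x <- matrix(rexp(40 * 6), 40, 6)
    D1 <- chord_distance_matrix(x)
    expect_true(all(D1 >= -1e-12 & D1 <= sqrt(2) + 1e-12))
    D2 <- chord_distance_matrix(x * runif(40, 0.1, 10))
    expect_equal(as.numeric(D1), as.numeric(D2), tolerance = 1e-10)
  }
})

test_that("PCoA round-trips Euclidean configurations", {
  set.seed(14)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  rownames(pts) <- paste0("p", 1:8)
  D <- dist(pts)
  res <- pcoa(D)
  # recovered coordinates reproduce the distances
  expect_lt(max(abs(as.matrix(dist(res$scores)) - as.matrix(D))), 1e-9)
  # proportions ordered, non-negative, sum to <= 1
  expect_true(all(diff(res$proportion) <= 1e-12))
  expect_true(all(res$proportion >= 0))
  expect_lte(sum(res$proportion), 1 + 1e-12)

  # collinear points: a single axis carries all variation
  line <- cbind(c(0, 1, 2, 5), 0)
  res_line <- pcoa(dist(line))
  expect_equal(res_line$proportion[1], 1, tolerance = 1e-9)
})

test_that("PCoA agrees with independent implementations", {
  set.seed(15)
  m <- matrix(rexp(7 * 5), 7, 5)
  rownames(m) <- paste0("s", 1:7)
  norm <- m / sqrt(rowSums(m^2))
  res <- pcoa(dist(norm))
  # equals PCA scores of the normalised rows up to sign
  pc <- prcomp(norm, center = TRUE, scale. = FALSE)
  for (j in 1:2) {
    expect_equal(abs(as.numeric(res$scores[, j])),
                 abs(as.numeric(pc$x[, j])), tolerance = 1e-8)
  }
  ap <- ape::pcoa(dist(norm))
  for (j in 1:2) {
    expect_equal(abs(as.numeric(res$scores[, j])),
                 abs(as.numeric(ap$vectors[, j])), tolerance = 1e-8)
  }
  expect_equal(res$proportion[1:2],
               unname(ap$values$Relative_eig[1:2]), tolerance = 1e-8)
})

test_that("chord distances embed without meaningful negative eigenvalues", {
  set.seed(16)
  for (i in 1:10) {
    comp <- matrix(rexp(12 * 8), 12, 8)
    res <- pcoa(chord_distance_matrix(comp))
    if (length(res$negative_eigenvalues))
      expect_gt(min(res$negative_eigenvalues), -1e-9)
  }
})

test_that("axis difference series respond to compositional drift and sign flips", {
  cfg <- small_config()
  rec <- simulate_community(cfg)
  cm <- compute_cpue(rec, month_by_area = cfg$community_params$month_by_area)
  ord <- pcoa(chord_distance_matrix(cm), abundances = cm)
  d1 <- axis_difference_series(ord, 1, cfg$impact_year)
  # drift on: post-impact divergence exceeds pre-impact scatter
  expect_gt(mean(abs(d1$delta[d1$after & d1$year > cfg$impact_year + 10])),
            mean(abs(d1$delta[!d1$after])))

  # axis flip negates the series but not the model choice
  ord_f <- ord
  ord_f$scores[, 1] <- -ord_f$scores[, 1]
  d1f <- axis_difference_series(ord_f, 1, cfg$impact_year)
  expect_equal(d1f$delta, -d1$delta)
  expect_equal(compare_models(d1)$best, compare_models(d1f)$best)

  # identical community trajectories: zero differences
  even <- expand.grid(night = 1, station = "s1",
                      species = c("perch", "roach"), year = 1975:1985,
                      stringsAsFactors = FALSE)
  even$count <- ifelse(even$species == "perch", 10, 5) + even$year %% 3
  both <- rbind(transform(even, area = "heated", month = 10, nets = 2),
                transform(even, area = "reference", month = 8, nets = 2))
  cm0 <- compute_cpue(both)
  d0 <- axis_difference_series(pcoa(chord_distance_matrix(cm0),
                                    abundances = cm0), 1, 1980)
  expect_lt(max(abs(d0$delta)), 1e-9)
})

test_that("orientation rule gives the dominant species a non-negative loading", {
  cfg <- small_config()
  cm <- compute_cpue(simulate_community(cfg),
                     month_by_area = cfg$community_params$month_by_area)
  ord <- pcoa(chord_distance_matrix(cm), abundances = cm)
  dominant <- which.max(colSums(cm))
  for (j in 1:2) {
    r <- cor(cm[, dominant], ord$scores[, j])
    if (is.finite(r)) expect_gte(r, 0)
  }
})
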