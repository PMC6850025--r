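test_that("length-specific growth is the relative increment and scale-invariant", {
  expect_equal(length_specific_growth(100, 150), 0.5)
  expect_equal(length_specific_growth(80, 80), 0)
  expect_equal(length_specific_growth(5, 70), 13)  # first year from hatch
  expect_error(length_specific_growth(0, 10), "l_t")
  expect_warning(g <- length_specific_growth(100, 90), "decrease")
  expect_equal(g, -0.1)

  set.seed(1)
  l1 <- runif(50, 10, 100); l2 <- l1 + runif(50, 0, 60)
  for (c_ in c(0.5, 3)) {
    expect_equal(length_specific_growth(c_ * l1, c_ * l2),
                 length_specific_growth(l1, l2))
  }
})

test_that("size-class selection uses closed intervals and the minimum cell size", {
  lengths <- data.frame(
    id = sprintf("f%02d", 1:10),
    area = rep(c("heated", "reference"), each = 5),
    birth_year = 1990,
    capture_year = 1996,
    age = 1L,
    length = c(65, 70, 75, 75.0001, 64.9999, 70, 71, 72, 73, 74)
  )
  spec <- size_class_spec(n_min = 1)
  sel <- select_size_class(lengths, 1, spec)
  # boundaries 65 and 75 retained, values just outside dropped
  expect_setequal(sel$id, c("f01", "f02", "f03", "f06", "f07", "f08", "f09", "f10"))
  expect_true(all(sel$year == 1991))

  # cells below n_min vanish entirely
  spec4 <- size_class_spec(n_min = 4)
  sel4 <- select_size_class(lengths, 1, spec4)
  expect_true(all(sel4$area == "reference"))  # heated cell has n = 3

  # age 0 keeps everyone (newborns all start at hatch length)
  l0 <- data.frame(id = c("a", "b"), area = "heated", birth_year = 1990,
                   capture_year = 1995, age = 0L, length = 5)
  expect_equal(nrow(select_size_class(l0, 0, size_class_spec(n_min = 1))), 2)

  # overlapping class definitions are rejected
  expect_error(size_class_spec(classes = list(`1` = c(65, 120),
                                              `2` = c(110, 130))),
               "overlap")
})

test_that("response aggregation matches a brute-force group-by oracle", {
  set.seed(33)
  n <- 400
  lengths <- data.frame(
    id = sprintf("f%03d", 1:n),
    area = sample(c("heated", "reference"), n, TRUE),
    birth_year = sample(1980:1990, n, TRUE),
    age = 2L,
    length = runif(n, 100, 140)
  )
  lengths$capture_year <- lengths$birth_year + sample(3:6, n, TRUE)
  spec <- size_class_spec(classes = list(`2` = c(100, 140)), n_min = 1)
  out <- build_response_series(lengths, "size_at_age_2", spec,
                               min_cohort_n = 1)
  oracle <- oracle_group_mean(lengths$length, lengths$area,
                              lengths$birth_year + 2L)
  expect_equal(out$mean, oracle$mean)
  expect_equal(out$n, oracle$n)
  # filtering can only shrink cells
  out4 <- build_response_series(lengths, "size_at_age_2",
                                size_class_spec(classes = list(`2` = c(100, 140)),
                                                n_min = 4),
                                min_cohort_n = 1)
  m <- merge(out4, out, by = c("area", "year"))
  expect_true(all(m$n.x <= m$n.y))
})

test_that("growth responses exclude the capture-year increment", {
  # two fish: one caught the year after its increment, one caught in the
  # increment year itself
  lengths <- data.frame(
    id = rep(c("keep", "drop", "pad1", "pad2", "pad3"), each = 2),
    area = "heated",
    birth_year = 1990,
    capture_year = c(1993, 1993, 1991, 1991, 1993, 1993, 1993, 1993, 1993, 1993),
    age = rep(c(0L, 1L), 5),
    length = rep(c(5, 70), 5)
  )
  spec <- size_class_spec(n_min = 1)
  out <- build_response_series(lengths, "growth_ageclass_0", spec,
                               min_cohort_n = 1)
  # increment year is 1990 for all; fish "drop" caught 1991 still counts,
  # a fish captured in 1990 itself would not: construct that case
  expect_equal(out$n, 5L)

  lengths$capture_year[lengths$id == "drop"] <- 1990
  out2 <- build_response_series(lengths, "growth_ageclass_0", spec,
                                min_cohort_n = 1)
  expect_equal(out2$n, 4L)
  expect_equal(out2$mean, 13)  # (70 - 5) / 5
})

test_that("cohorts below the minimum size are excluded", {
  lengths <- data.frame(
    id = c("a", "b", "c", "x", "y"),
    area = "heated",
    birth_year = c(1990, 1990, 1990, 1991, 1991),
    capture_year = 1997,
    age = 1L,
    length = 70
  )
  out <- build_response_series(lengths, "size_at_age_1",
                               size_class_spec(n_min = 1), min_cohort_n = 3)
  expect_equal(out$year, 1991)  # the 1991 cohort (n = 2) is gone
})

test_that("difference series subtracts reference from heated on shared years", {
  mk <- function(area, years, means) {
    data.frame(area = area, year = years, mean = means, n = 10L)
  }
  h <- mk("heated", 1976:1985, rep(10, 10))
  r <- mk("reference", 1976:1985, rep(10, 10))
  d0 <- difference_series(h, r, impact_year = 1980)
  expect_true(all(d0$delta == 0))
  expect_equal(d0$after, d0$year >= 1980)

  r2 <- mk("reference", 1976:1985, rep(7, 10))
  expect_true(all(difference_series(h, r2, 1980)$delta == 3))

  # arbitrary small tables match hand subtraction on the year intersection
  h3 <- mk("heated", c(1977, 1978, 1981, 1983), c(1, 2, 8, 9))
  r3 <- mk("reference", c(1978, 1979, 1981, 1983), c(5, 5, 3, 4))
  d3 <- difference_series(h3, r3, 1980, min_before = 1)
  expect_equal(d3$year, c(1978, 1981, 1983))
  expect_equal(d3$delta, c(2 - 5, 8 - 3, 9 - 4))

  # insufficient overlap errors name the deficient period
  expect_error(difference_series(mk("heated", 1979:1985, 1:7),
                                 mk("reference", 1979:1985, 1:7), 1980),
               "before")
  expect_error(difference_series(mk("heated", 1970:1980, 1:11),
                                 mk("reference", 1970:1980, 1:11), 1980),
               "after")
})
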