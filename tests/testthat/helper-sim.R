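# small configurations used across tests; kept deterministic
small_config <- function(...) {
  sim_config(recruits_per_year_per_area = 30, rng_seed = 42, ...)
}

noiseless_config <- function(...) {
  args <- utils::modifyList(list(recruits_per_year_per_area = 10,
                                 reference_temp_sd = 0,
                                 individual_growth_cv = 0,
                                 transient_growth_cv = 0,
                                 area_year_growth_cv = 0,
                                 measurement_sd = 0,
                                 radius_noise_cv = 0,
                                 rng_seed = 42), list(...))
  do.call(sim_config, args)
}

# brute-force group-by mean/count oracle used against the package aggregation
oracle_group_mean <- function(value, area, year) {
  keys <- unique(data.frame(area = area, year = year))
  keys <- keys[order(keys$area, keys$year), ]
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- area == keys$area[i] & year == keys$year[i]
    data.frame(area = keys$area[i], year = keys$year[i],
               mean = mean(value[sel]), n = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

# hand-rolled simple linear regression (slope, its p-value, F, r2)
oracle_ols <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  s2 <- sum(res^2) / (n - 2)
  se_b <- sqrt(s2 / sum((x - mean(x))^2))
  t <- b / se_b
  list(slope = b, intercept = a,
       p = 2 * pt(abs(t), n - 2, lower.tail = FALSE),
       f = t^2,
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}
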