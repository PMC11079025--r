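# scenario generator: determinism, field statistics, planted structure

test_that("gen_gaussian_field: degenerate cases, determinism, moments", {
  cf <- gen_gaussian_field(c(10, 10), 0, mean = 4, sd = 0, seed = 1)
  expect_true(all(cf$values == 4))
  a <- gen_gaussian_field(c(20, 20), 5, mean = 1, sd = 2, seed = 9)
  b <- gen_gaussian_field(c(20, 20), 5, mean = 1, sd = 2, seed = 9)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, gen_gaussian_field(c(20, 20), 5, 1, 2, seed = 10)$values))

  # iid case: sample moments within 3 standard errors
  f <- gen_gaussian_field(c(100, 100), 0, mean = 10, sd = 3, seed = 2)
  n <- 1e4
  expect_lt(abs(mean(f$values) - 10), 3 * 3 / sqrt(n))
  expect_lt(abs(sd(f$values) - 3), 3 * 3 / sqrt(2 * n))

  # autocorrelation raises neighbour similarity
  rough <- gen_gaussian_field(c(60, 60), 0, 0, 1, seed = 3)
  smooth <- gen_gaussian_field(c(60, 60), 8, 0, 1, seed = 3)
  lag_cor <- function(m) cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)]))
  expect_gt(lag_cor(smooth$values), 0.8)
  expect_lt(abs(lag_cor(rough$values)), 0.1)

  expect_error(gen_gaussian_field(c(5, 5), 0, 0, sd = -1), "non-negative")
})

test_that("gen_trend_stack plants exact noiseless slopes", {
  ts <- gen_trend_stack(c(8, 8), n_years = 12, degraded_fraction = 0.25,
                        slope = -0.002, noise_sd = 0, seed = 5)
  expect_equal(sum(ts$mask$values), round(0.25 * 64))
  tr <- trend_raster(ts$stack)
  deg <- ts$mask$values == 1
  expect_equal(max(abs(tr$slope$values[deg] + 0.002)), 0)
  expect_error(gen_trend_stack(c(4, 4), 12, 1.5, -1, 0), "fraction")
  expect_error(gen_trend_stack(c(4, 4), 2, 0.5, -1, 0), "n_years")
})

test_that("land-use fractions and zone partition behave as configured", {
  cfg <- scenario_config(shape = c(50, 50), seed = 21,
                         frac_agricultural = 0.6, frac_arable = 0.3,
                         n_zones = 5)
  lz <- gen_landuse_and_zones(cfg)
  ag <- stratum_mask(lz$land, "agricultural")
  ar <- stratum_mask(lz$land, "arable")
  expect_lt(abs(mean(ag$values) - 0.6), 0.02)
  expect_lt(abs(mean(ar$values) - 0.3), 0.02)
  # arable subset of agricultural
  expect_true(all(ag$values[ar$values == 1] == 1))
  # zones partition the domain
  zv <- lz$zones$zones$values
  expect_false(anyNA(zv))
  expect_setequal(unique(as.vector(zv)), 1:5)
  expect_equal(area_km2(grid_like(lz$zones$zones, as.numeric(zv %in% 1:5),
                                  nodata = 255)),
               50 * 50 * 0.25)
  # one incomplete zone planted
  expect_true(any(lz$zones$completeness < 12))

  # extreme fractions
  cfg1 <- scenario_config(shape = c(20, 20), seed = 1,
                          frac_agricultural = 1, frac_arable = 0,
                          n_zones = 2)
  lz1 <- gen_landuse_and_zones(cfg1)
  expect_true(all(stratum_mask(lz1$land, "agricultural")$values == 1))
  expect_equal(sum(stratum_mask(lz1$land, "arable")$values), 0)
})

test_that("scenario generation is fully deterministic in the seed", {
  s1 <- gen_process_inputs(scenario_config(shape = c(24, 24), seed = 33))
  s2 <- gen_process_inputs(scenario_config(shape = c(24, 24), seed = 33))
  expect_identical(s1$truth$lmi$values, s2$truth$lmi$values)
  expect_identical(s1$inputs$WaE$values, s2$inputs$WaE$values)
  expect_identical(s1$inputs$SOCL$values, s2$inputs$SOCL$values)
  expect_identical(s1$inputs$SPHM$Hg$values, s2$inputs$SPHM$Hg$values)
  s3 <- gen_process_inputs(scenario_config(shape = c(24, 24), seed = 34))
  expect_false(identical(s1$inputs$WaE$values, s3$inputs$WaE$values))
})

test_that("null and saturated scenarios force the LMI", {
  null_cfg <- scenario_config(shape = c(16, 16), seed = 3,
                              critical_fractions = c(A = 0),
                              default_fraction = 0, n_zones = 2)
  scn <- gen_process_inputs(null_cfg)
  stack <- build_critical_stack(scn$inputs)
  lmi <- compute_lmi(stack$masks, scn$land, "agricultural")
  expect_true(all(lmi$counts$values[!is.na(lmi$counts$values)] == 0))

  five <- stats::setNames(c(rep(1, 5), rep(0, 7)),
                          registry_process_ids(default_registry()))
  cfg5 <- scenario_config(shape = c(16, 16), seed = 4,
                          critical_fractions = five,
                          default_fraction = 0, n_zones = 2)
  scn5 <- gen_process_inputs(cfg5)
  stack5 <- build_critical_stack(scn5$inputs)
  lmi5 <- compute_lmi(stack5$masks, scn5$land, "agricultural")
  v <- lmi5$counts$values
  expect_true(all(v[!is.na(v)] == 5))
})

test_that("ground truth LMI is the sum of planted masks", {
  scn <- small_scenario()
  s <- matrix(0, 32, 32)
  for (m in scn$truth$masks) {
    ok <- !is.na(m$values)
    s[ok] <- s[ok] + m$values[ok]
  }
  expect_identical(scn$truth$lmi$values, s)
})

test_that("boundary-stress values classify Non-critical", {
  reg <- default_registry()
  cases <- boundary_stress_cases(reg)
  expect_gt(nrow(cases), 15)  # every strict scalar is covered
  for (i in seq_len(nrow(cases))) {
    res <- evaluate_process(reg[[cases$process_id[i]]],
                            lapply(cases$columns[[i]], identity))
    expect_equal(unname(res), 0,
                 label = paste("boundary case", cases$scalar_id[i]))
  }
})

test_that("scenario round-trips through the GeoTIFF directory format", {
  scn <- gen_process_inputs(scenario_config(shape = c(12, 12), seed = 8,
                                            n_zones = 2))
  dir <- withr::local_tempdir()
  write_scenario(scn, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_scenario(dir)
  stack_a <- build_critical_stack(scn$inputs)
  stack_b <- build_critical_stack(back$inputs)
  for (pid in names(stack_a$masks))
    expect_identical(stack_b$masks[[pid]]$values,
                     stack_a$masks[[pid]]$values)
  expect_identical(back$zones$completeness, scn$zones$completeness)
})
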