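# threshold perturbation, label simulation and the RF probability model

small_unc_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scn <- small_scenario()
      stack <- build_critical_stack(scn$inputs)
      lmi <- compute_lmi(stack$masks, scn$land, "agricultural")
      im <- build_input_matrix(stack, lmi, sample_n = 600, seed = 2)
      cache <<- list(scn = scn, stack = stack, lmi = lmi, im = im)
    }
    cache
  }
})

test_that("sample_thresholds follows the stated law and is seeded", {
  s0 <- sample_thresholds(n_sims = 5, sd_fraction = 0, seed = 1)
  base <- attr(s0, "baseline")
  for (j in seq_len(ncol(s0)))
    expect_true(all(s0[, j] == base[j]))

  a <- sample_thresholds(n_sims = 100, seed = 7)
  b <- sample_thresholds(n_sims = 100, seed = 7)
  expect_identical(a, b)

  # empirical sd of draws for t0 = 2 within 3 SE of 0.2
  big <- sample_thresholds(n_sims = 10000, sd_fraction = 0.1, seed = 3)
  sdest <- sd(big[, "WaE_gt"])
  se <- 0.2 / sqrt(2 * (10000 - 1))
  expect_lt(abs(sdest - 0.2), 3 * se)
  expect_lt(abs(mean(big[, "WaE_gt"]) - 2), 3 * 0.2 / sqrt(10000))

  expect_error(sample_thresholds(n_sims = 0), "n_sims")
  expect_error(sample_thresholds(n_sims = 5, sd_fraction = -1),
               "sd_fraction")
})

test_that("simulate_lmi_labels collapses to baseline at sd 0", {
  su <- small_unc_setup()
  s0 <- sample_thresholds(n_sims = 3, sd_fraction = 0, seed = 1)
  sim <- simulate_lmi_labels(su$im, s0)
  hit <- vapply(seq_len(nrow(su$im$matrix)), function(r)
    unname(sim$freq[r, as.character(su$im$baseline_class[r])]), numeric(1))
  expect_true(all(hit == 1))
  expect_true(all(sim$entropy == 0))
  expect_true(all(abs(rowSums(sim$freq) - 1) < 1e-12))
})

test_that("a hand-computed micro-example reproduces the row sums", {
  # three processes (WaE, SS, SA), two hand-set threshold draws
  im <- structure(list(
    matrix = cbind(WaE = c(2.5, 1.5, 3.0), SS = c(55, 45, 40),
                   SA = c(5.0, 6.0, 5.6)),
    baseline_count = c(3, 0, 1), baseline_class = c(3, 0, 1),
    pixel_idx = 1:3, stratum_pixels = 3,
    process_ids = c("WaE", "SS", "SA")), class = "lmdi_input_matrix")
  draws <- rbind(c(WaE_gt = 2.6, SS_gt = 50, SA_lt = 5.5),
                 c(WaE_gt = 1.0, SS_gt = 42, SA_lt = 5.1))
  sim <- simulate_lmi_labels(im, draws)
  # draw 1: row1 = (0,1,1)=2, row2 = (0,0,0)=0, row3 = (1,0,0)=1
  # draw 2: row1 = (1,1,1)=3, row2 = (1,1,0)=2, row3 = (1,0,0)=1
  expect_equal(sim$draw_class_counts[1, ], c(`0` = 1L, `1` = 1L, `2` = 1L,
                                             `3` = 0L, `4` = 0L, `5` = 0L))
  expect_equal(unname(sim$freq[1, ]), c(0, 0, 0.5, 0.5, 0, 0))
  expect_equal(unname(sim$freq[2, ]), c(0.5, 0, 0.5, 0, 0, 0))
  expect_equal(unname(sim$freq[3, ]), c(0, 1, 0, 0, 0, 0))
})

test_that("far-from-threshold rows have degenerate label distributions", {
  # every value >= 10 sd from its threshold -> all draws agree
  im <- structure(list(
    matrix = cbind(WaE = c(10, 0.1), SS = c(99, 1), SA = c(2, 9)),
    baseline_count = c(3, 0), baseline_class = c(3, 0),
    pixel_idx = 1:2, stratum_pixels = 2,
    process_ids = c("WaE", "SS", "SA")), class = "lmdi_input_matrix")
  draws <- sample_thresholds(n_sims = 300, sd_fraction = 0.1, seed = 5)
  draws <- draws[, c("WaE_gt", "SS_gt", "SA_lt")]
  sim <- simulate_lmi_labels(im, draws)
  expect_equal(unname(sim$freq[1, "3"]), 1)
  expect_equal(unname(sim$freq[2, "0"]), 1)
  expect_true(all(sim$entropy == 0))
})

test_that("boundary-hugging rows carry higher label entropy", {
  set.seed(8)
  n <- 150
  hug <- cbind(WaE = rnorm(n, 2, 0.05), SS = rnorm(n, 50, 1),
               SA = rnorm(n, 5.5, 0.05))
  far <- cbind(WaE = runif(n, 8, 10), SS = runif(n, 90, 99),
               SA = runif(n, 1, 2))
  mk_im <- function(M) {
    counts <- (M[, 1] > 2) + (M[, 2] > 50) + (M[, 3] < 5.5)
    structure(list(matrix = M, baseline_count = counts,
                   baseline_class = pmin(counts, 5),
                   pixel_idx = seq_len(nrow(M)), stratum_pixels = nrow(M),
                   process_ids = c("WaE", "SS", "SA")),
              class = "lmdi_input_matrix")
  }
  draws <- sample_thresholds(n_sims = 400, sd_fraction = 0.1, seed = 9)
  draws <- draws[, c("WaE_gt", "SS_gt", "SA_lt")]
  e_hug <- mean(simulate_lmi_labels(mk_im(hug), draws)$entropy)
  e_far <- mean(simulate_lmi_labels(mk_im(far), draws)$entropy)
  expect_gt(e_hug, e_far)
  expect_equal(e_far, 0)
})

test_that("RF probabilities normalise and recover planted sensitivity", {
  su <- small_unc_setup()
  draws <- sample_thresholds(n_sims = 150, sd_fraction = 0.1, seed = 11)
  rf <- fit_rf_uncertainty(su$im, draws, n_trees = 60, reps = 2, seed = 12)
  expect_true(all(abs(rowSums(rf$prob) - 1) < 1e-9))
  expect_true(all(rf$prob >= 0 & rf$prob <= 1))
  expect_length(rf$importance, ncol(su$im$matrix))
  expect_gte(rf$oob_error, 0)

  # planted sensitivity: only WaE hugs its threshold
  set.seed(13)
  n <- 500
  M <- cbind(WaE = rnorm(n, 2, 0.15), SS = runif(n, 80, 99),
             SA = runif(n, 7, 9))
  counts <- (M[, 1] > 2) + (M[, 2] > 50) + 0
  im <- structure(list(matrix = M, baseline_count = counts,
                       baseline_class = pmin(counts, 5),
                       pixel_idx = 1:n, stratum_pixels = n,
                       process_ids = c("WaE", "SS", "SA")),
                  class = "lmdi_input_matrix")
  d2 <- sample_thresholds(n_sims = 100, sd_fraction = 0.1, seed = 14)
  d2 <- d2[, c("WaE_gt", "SS_gt", "SA_lt")]
  rf2 <- fit_rf_uncertainty(im, d2, n_trees = 80, reps = 3, seed = 15)
  expect_equal(names(which.max(rf2$importance)), "WaE")

  # single-class labels warn and give degenerate probabilities
  im1 <- im
  im1$matrix[, "WaE"] <- 10   # everything class 2
  im1$baseline_count <- rep(2, n); im1$baseline_class <- rep(2, n)
  d0 <- sample_thresholds(n_sims = 5, sd_fraction = 0, seed = 1)
  d0 <- d0[, c("WaE_gt", "SS_gt", "SA_lt")]
  expect_warning(rf1 <- fit_rf_uncertainty(im1, d0, n_trees = 10, reps = 1,
                                           seed = 1), "single-class")
  expect_equal(unname(rf1$prob[1, "2"]), 1)
  expect_equal(rf1$oob_error, 0)
})

test_that("class-area ranges cover the baseline and sum to the stratum", {
  su <- small_unc_setup()
  draws <- sample_thresholds(n_sims = 200, sd_fraction = 0.1, seed = 21)
  sim <- simulate_lmi_labels(su$im, draws)
  rf <- fit_rf_uncertainty(su$im, draws, n_trees = 60, reps = 2, seed = 22)
  rng <- class_area_error_ranges(rf, sim, cell_size_m = 500)
  stratum_area <- su$im$stratum_pixels * 0.25
  expect_equal(sum(rng$baseline_km2), stratum_area)
  expect_equal(sum(rng$expected_km2), stratum_area, tolerance = 1e-9)
  expect_true(all(rng$lo_km2 <= rng$hi_km2))
  expect_true(all(rng$baseline_km2 >= rng$lo_km2 - 1e-9 &
                    rng$baseline_km2 <= rng$hi_km2 + 1e-9))

  # degenerate probabilities -> zero-width ranges at baseline areas
  d0 <- sample_thresholds(n_sims = 5, sd_fraction = 0, seed = 1)
  sim0 <- simulate_lmi_labels(su$im, d0)
  counts0 <- vapply(0:5, function(k)
    sum(su$im$baseline_class == k), numeric(1))
  expect_true(all(apply(sim0$draw_class_counts, 1,
                        function(r) all(r == counts0))))
})

test_that("uncertainty grids place probabilities at sampled pixels", {
  su <- small_unc_setup()
  draws <- sample_thresholds(n_sims = 50, sd_fraction = 0.1, seed = 31)
  rf <- fit_rf_uncertainty(su$im, draws, n_trees = 30, reps = 1, seed = 32)
  gg <- uncertainty_grids(rf, su$lmi$counts)
  p0 <- gg$prob[["0"]]$values
  expect_equal(sum(!is.na(p0)), length(su$im$pixel_idx))
  expect_equal(p0[su$im$pixel_idx[5]], unname(rf$prob[5, 1]))
  expect_equal(gg$predicted$values[su$im$pixel_idx[7]],
               rf$predicted_class[7])
})
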