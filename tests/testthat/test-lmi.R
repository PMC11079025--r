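# LMI computation, classing, zonal reporting, natural breaks

mk_land_all <- function(nr, nc) {
  # everything arable -> both strata cover the full domain
  land_mask(grid_create(matrix(211, nr, nc), nodata = 255))
}

test_that("compute_lmi equals the per-pixel loop oracle", {
  set.seed(2)
  masks <- lapply(1:12, function(i) rand_mask(16, 16, 0.4, seed = i))
  names(masks) <- registry_process_ids(default_registry())
  land <- mk_land_all(16, 16)
  lmi <- compute_lmi(masks, land, "agricultural")
  oracle <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16)
    for (m in masks) oracle[i, j] <- oracle[i, j] + m$values[i, j]
  expect_identical(lmi$counts$values, oracle)
  expect_true(all(lmi$n_layers$values == 12))

  expect_error(compute_lmi(list(), land), "no critical masks")
})

test_that("nodata layers are skipped with completeness recorded", {
  masks <- lapply(1:3, function(i) rand_mask(8, 8, 0.5, seed = i))
  names(masks) <- c("WaE", "SS", "A")
  masks$SS$values[1, 1] <- NA
  land <- mk_land_all(8, 8)
  lmi <- compute_lmi(masks, land)
  expect_equal(lmi$n_layers$values[1, 1], 2)
  expect_equal(lmi$counts$values[1, 1],
               masks$WaE$values[1, 1] + masks$A$values[1, 1])
})

test_that("classify_lmi maps counts to the five classes", {
  counts <- grid_create(matrix(c(0, 1, 4, 5, 7, 12), 2, 3), nodata = 255)
  lmi <- structure(list(counts = counts), class = "lmdi_index")
  cls <- classify_lmi(lmi)
  expect_equal(as.vector(cls$values), c(0, 1, 4, 5, 5, 5))
  bad <- structure(list(counts = grid_create(matrix(-1, 1, 1))),
                   class = "lmdi_index")
  expect_error(classify_lmi(bad), "negative")
})

test_that("zonal report conserves areas and percentages", {
  scn <- small_scenario()
  stack <- build_critical_stack(scn$inputs)
  for (stratum in c("agricultural", "arable")) {
    lmi <- compute_lmi(stack$masks, scn$land, stratum)
    cls <- classify_lmi(lmi)
    rep <- zonal_stats(cls, lmi, scn$zones, scn$land, stratum = stratum)
    sm <- stratum_mask(scn$land, stratum)
    for (z in unique(rep$zone)) {
      rows <- rep[rep$zone == z, ]
      if (z == "ALL") {
        keep <- names(which(scn$zones$completeness == 12))
        sel <- sm$values == 1 &
          scn$zones$zones$values %in% as.integer(keep)
      } else {
        sel <- sm$values == 1 & scn$zones$zones$values == as.integer(z)
      }
      sel[is.na(sel)] <- FALSE
      expect_equal(sum(rows$area_km2), sum(sel) * 0.25)
      if (sum(sel) > 0)
        expect_lt(abs(sum(rows$percent) - 100), 1e-9)
    }
    # incomplete zone flagged and excluded from ALL
    inc <- names(which(scn$zones$completeness < 12))
    expect_true(all(rep$incomplete[rep$zone %in% inc]))
    expect_false(any(rep$incomplete[rep$zone == "ALL"]))
  }
})

test_that("two equal-area zones with classes 1 and 3 average to 2", {
  nr <- 10; nc <- 10
  m1 <- grid_create(matrix(c(rep(1, 50), rep(0, 50)), nr, nc), nodata = 255)
  m3a <- grid_create(matrix(c(rep(0, 50), rep(1, 50)), nr, nc), nodata = 255)
  masks <- list(WaE = m1, SS = m3a, SA = m3a, A = m3a)
  # left half: only WaE critical (count 1); right half: 3 criticals
  land <- mk_land_all(nr, nc)
  zones <- zone_partition(grid_create(
    matrix(c(rep(1, 50), rep(2, 50)), nr, nc), nodata = 255))
  lmi <- compute_lmi(masks, land, "agricultural")
  cls <- classify_lmi(lmi)
  rep <- zonal_stats(cls, lmi, zones, land)
  all_rows <- rep[rep$zone == "ALL", ]
  expect_equal(unique(all_rows$mean_processes), 2)
  expect_equal(all_rows$percent[all_rows$class == 1], 50)
  expect_equal(all_rows$percent[all_rows$class == 3], 50)
})

test_that("arable LMI equals agricultural LMI on arable pixels", {
  scn <- small_scenario()
  stack <- build_critical_stack(scn$inputs)
  ag <- compute_lmi(stack$masks, scn$land, "agricultural")
  ar <- compute_lmi(stack$masks, scn$land, "arable")
  sel <- !is.na(ar$counts$values)
  expect_identical(ar$counts$values[sel], ag$counts$values[sel])
})

test_that("adding an all-zero mask never changes the LMI", {
  scn <- small_scenario()
  stack <- build_critical_stack(scn$inputs)
  lmi <- compute_lmi(stack$masks, scn$land, "agricultural")
  zero <- grid_like(stack$masks[[1]],
                    matrix(0, 32, 32), nodata = 255)
  lmi2 <- compute_lmi(c(stack$masks, list(EXTRA = zero)), scn$land,
                      "agricultural")
  expect_identical(lmi2$counts$values, lmi$counts$values)
})

test_that("lmi_histogram tallies exactly and reports the 1..5 share", {
  counts <- grid_create(matrix(c(0, 0, 1, 2, 2, 2, 5, 6, NA), 3, 3),
                        nodata = 255)
  lmi <- structure(list(counts = counts), class = "lmdi_index")
  h <- lmi_histogram(lmi)
  expect_equal(sum(h$counts), 8)            # valid pixels only
  expect_equal(unname(h$counts[c("0", "2", "6")]), c(2, 3, 1))
  expect_equal(h$share_1_5, 5 / 6)          # of the 6 nonzero pixels
  expect_equal(h$mean, mean(c(0, 0, 1, 2, 2, 2, 5, 6)))

  # tally oracle on a random stack
  set.seed(6)
  v <- matrix(sample(0:9, 400, TRUE), 20, 20)
  lm2 <- structure(list(counts = grid_create(v, nodata = 255)),
                   class = "lmdi_index")
  h2 <- lmi_histogram(lm2)
  for (k in 0:9) expect_equal(unname(h2$counts[as.character(k)]),
                              sum(v == k))
})

test_that("natural breaks match the exhaustive-partition oracle", {
  expect_equal(natural_breaks(c(1, 1, 1, 9, 9, 9), 2), 1)
  # k = number of distinct values -> every value its own class
  b <- natural_breaks(c(2, 5, 8), 3)
  expect_equal(b, c(2, 5))
  # achieved within-class SSD equals the exhaustive-partition minimum
  # (breaks themselves can tie; the criterion value cannot)
  ssd_of_breaks <- function(x, breaks) {
    xs <- sort(x)
    grp <- findInterval(xs, breaks + 1e-12) + 1
    sum(vapply(split(xs, grp), function(v) sum((v - mean(v))^2), 0))
  }
  set.seed(44)
  for (rep in 1:5) {
    x <- round(runif(12, 0, 100))
    if (length(unique(x)) < 5) next
    got <- natural_breaks(x, 3)
    oracle <- jenks_exhaustive(x, 3)
    expect_equal(ssd_of_breaks(x, got), oracle$ssd, tolerance = 1e-9)
  }
  expect_error(natural_breaks(c(1, 1, 2), 3), "distinct")
})
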