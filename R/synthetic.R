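#' Synthetic degradation scenarios with known ground truth
#'
#' Generates all twelve process inputs (including annual trend stacks,
#' climatologies, the nine metal layers and the four nutrient layers), a
#' CORINE-like land-use mask and a zone partition, such that applying the
#' rule registry reproduces a planted Critical mask per process exactly.
#' Raw values are drawn on the correct side of each threshold with a margin
#' of at least 5% of the threshold magnitude, so recovery is unambiguous; a
#' separate boundary-stress generator places values exactly at the strict
#' thresholds to pin down the inequality convention.
#'
#' @name synthetic_data
NULL

#' Scenario configuration
#'
#' Defaults describe a plausible desk-scale world: a 64 x 64 equal-area
#' plane of 500 m cells, moderately autocorrelated process fields, a 20%
#' planted Critical fraction per process (25% for aridity), annual stacks
#' matching the real analysis windows (SOCL 15, NDVI 16, GTD 10 years)
#' with planted declines five times the criticality slope cut-off, 70%
#' agricultural cover of which arable makes up 40% of the domain, and four
#' Voronoi zones of which one integrates only 9 of the 12 layers (the
#' acidification, compaction and heavy-metal layers are withheld there).
#'
#' @param shape c(rows, cols).
#' @param cell_size_m cell edge, metres.
#' @param seed integer; fully determines all outputs.
#' @param critical_fractions named vector of planted Critical fractions per
#'   process id (missing names fall back to `default_fraction`).
#' @param default_fraction planted fraction where not specified.
#' @param margin threshold margin: raw values stay at least
#'   `margin * |threshold|` away from every cut-off (default 0.05; use
#'   0.10 or more for a well-separated scenario).
#' @param correlation_length field autocorrelation length in cells.
#' @param n_years named vector of stack lengths for SOCL, VD, GD.
#' @param trend_slope_factor planted decline = factor x slope threshold.
#' @param trend_noise_frac stack noise sd as a fraction of |planted slope|.
#' @param frac_agricultural fraction of the domain that is agricultural.
#' @param frac_arable fraction of the domain that is arable (subset).
#' @param n_zones number of Voronoi zones.
#' @param incomplete_zone plant one zone with only 9 layers when
#'   `n_zones >= 3` (default TRUE, matching the reporting situation of
#'   countries lacking three layers).
#' @param planted_class_proportions optional numeric vector of length 6
#'   (classes 0..5) summing to 1: plant exact LMI class shares over the
#'   agricultural stratum instead of per-process fractions.
#' @export
scenario_config <- function(shape = c(64, 64), cell_size_m = 500, seed = 42,
                            critical_fractions = c(A = 0.25),
                            default_fraction = 0.2, margin = 0.05,
                            correlation_length = 6,
                            n_years = c(SOCL = 15, VD = 16, GD = 10),
                            trend_slope_factor = 5,
                            trend_noise_frac = 0.02,
                            frac_agricultural = 0.7, frac_arable = 0.4,
                            n_zones = 4, incomplete_zone = TRUE,
                            planted_class_proportions = NULL) {
  stopifnot(frac_agricultural >= 0, frac_agricultural <= 1,
            frac_arable >= 0, frac_arable <= frac_agricultural,
            all(n_years >= 10), n_zones >= 1)
  if (!is.null(planted_class_proportions)) {
    stopifnot(length(planted_class_proportions) == 6,
              abs(sum(planted_class_proportions) - 1) < 1e-9,
              all(planted_class_proportions >= 0))
  }
  pids <- registry_process_ids(default_registry())
  fr <- stats::setNames(rep(default_fraction, length(pids)), pids)
  fr[names(critical_fractions)] <- critical_fractions
  if (any(fr < 0 | fr > 1)) stop("critical fractions must lie in [0, 1]")
  if (margin <= 0 || margin >= 0.5) stop("margin must lie in (0, 0.5)")
  structure(list(shape = shape, cell_size_m = cell_size_m, seed = seed,
                 critical_fractions = fr, margin = margin,
                 correlation_length = correlation_length,
                 n_years = n_years, trend_slope_factor = trend_slope_factor,
                 trend_noise_frac = trend_noise_frac,
                 frac_agricultural = frac_agricultural,
                 frac_arable = frac_arable, n_zones = n_zones,
                 incomplete_zone = incomplete_zone,
                 planted_class_proportions = planted_class_proportions),
            class = "lmdi_scenario_config")
}

#' Seeded spatially autocorrelated Gaussian field
#'
#' White noise smoothed with a periodic Gaussian kernel of the requested
#' correlation length (FFT convolution), then rescaled to the target mean
#' and standard deviation. `correlation_length = 0` yields i.i.d. noise;
#' `sd = 0` yields a constant field.
#'
#' @param shape c(rows, cols).
#' @param correlation_length kernel scale in cells (>= 0).
#' @param mean,sd target first moments (`sd >= 0`).
#' @param seed integer seed.
#' @param cell_size_m cell edge for the returned grid.
#' @return a [grid_create()] grid.
#' @export
gen_gaussian_field <- function(shape, correlation_length = 0, mean = 0,
                               sd = 1, seed = 1, cell_size_m = 500) {
  if (sd < 0) stop("sd must be non-negative")
  if (correlation_length < 0) stop("correlation_length must be >= 0")
  nr <- shape[1]; nc <- shape[2]
  if (sd == 0) return(grid_create(matrix(mean, nr, nc),
                                  cell_size = cell_size_m))
  set.seed(seed)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (correlation_length > 0) {
    dx <- pmin(0:(nc - 1), nc - 0:(nc - 1))
    dy <- pmin(0:(nr - 1), nr - 0:(nr - 1))
    kern <- exp(-outer(dy^2, dx^2, "+") / (2 * correlation_length^2))
    f <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE))
    z <- (f - base::mean(f)) / stats::sd(f)
  }
  grid_create(mean + sd * z, cell_size = cell_size_m)
}

#' Planted annual trend stack
#'
#' Degraded pixels follow value_t = intercept + slope * t + Normal(0,
#' noise_sd); the rest have slope zero. The degraded set is drawn from an
#' autocorrelated field when `correlation_length > 0`.
#'
#' @param shape c(rows, cols). @param n_years stack length (>= 3).
#' @param degraded_fraction fraction of pixels with the planted decline.
#' @param slope planted slope (units per year).
#' @param noise_sd observation noise standard deviation.
#' @param seed integer seed. @param intercept base level at year 1.
#' @param correlation_length autocorrelation of the degraded-set field.
#' @param cell_size_m cell edge.
#' @return list: `stack` (multi-band grid) and `mask` (0/1 degraded grid).
#' @export
gen_trend_stack <- function(shape, n_years, degraded_fraction, slope,
                            noise_sd, seed = 1, intercept = 1,
                            correlation_length = 0, cell_size_m = 500) {
  if (n_years < 3) stop("n_years must be >= 3")
  if (degraded_fraction < 0 || degraded_fraction > 1)
    stop("degraded_fraction must lie in [0, 1]")
  nr <- shape[1]; nc <- shape[2]
  npx <- nr * nc
  mask <- .planted_mask(shape, degraded_fraction, correlation_length,
                        seed = seed * 13 + 1)
  set.seed(seed)
  arr <- array(NA_real_, c(nr, nc, n_years))
  sl <- ifelse(mask == 1, slope, 0)
  for (t in seq_len(n_years)) {
    eps <- if (noise_sd > 0) matrix(stats::rnorm(npx, 0, noise_sd), nr, nc)
           else 0
    arr[, , t] <- intercept + sl * (t - 1) + eps
  }
  list(stack = grid_create(arr, cell_size = cell_size_m),
       mask = grid_create(mask, cell_size = cell_size_m, nodata = 255))
}

# 0/1 matrix with an exact planted count, optionally autocorrelated
.planted_mask <- function(shape, fraction, correlation_length, seed) {
  nr <- shape[1]; nc <- shape[2]
  n1 <- round(fraction * nr * nc)
  f <- gen_gaussian_field(shape, correlation_length, 0, 1, seed)
  ord <- order(f$values, decreasing = TRUE)
  m <- matrix(0, nr, nc)
  if (n1 > 0) m[ord[seq_len(n1)]] <- 1
  m
}

#' Land-use mask and zone partition generator
#'
#' Zones are a seeded Voronoi partition of the lattice. The agricultural
#' stratum is the top `frac_agricultural` share of a smooth suitability
#' field (so it is spatially coherent), and the arable subset the top
#' `frac_arable` share; both shares are exact by rank selection. Arable
#' pixels draw codes 211/212/213, other agricultural pixels the remaining
#' CORINE-like agricultural codes, non-agricultural land 311. When
#' `n_zones >= 3` and `incomplete_zone` is set, the last zone is flagged as
#' integrating only 9 of the 12 layers.
#'
#' @param config a [scenario_config()].
#' @return list: `land` ([land_mask()]) and `zones` ([zone_partition()]).
#' @export
gen_landuse_and_zones <- function(config) {
  nr <- config$shape[1]; nc <- config$shape[2]
  set.seed(config$seed * 7 + 3)
  cx <- stats::runif(config$n_zones, 0.5, nc + 0.5)
  cy <- stats::runif(config$n_zones, 0.5, nr + 0.5)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  colsm <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  best <- matrix(1, nr, nc); bestd <- (rows - cy[1])^2 + (colsm - cx[1])^2
  if (config$n_zones > 1) for (z in 2:config$n_zones) {
    d <- (rows - cy[z])^2 + (colsm - cx[z])^2
    upd <- d < bestd
    best[upd] <- z; bestd[upd] <- d[upd]
  }
  zones_g <- grid_create(best, cell_size = config$cell_size_m, nodata = 255)
  comp <- stats::setNames(rep(12L, config$n_zones),
                          seq_len(config$n_zones))
  if (config$incomplete_zone && config$n_zones >= 3)
    comp[[as.character(config$n_zones)]] <- 9L

  suit <- gen_gaussian_field(config$shape, config$correlation_length, 0, 1,
                             config$seed * 7 + 4)
  npx <- nr * nc
  n_ag <- round(config$frac_agricultural * npx)
  n_ar <- round(config$frac_arable * npx)
  ord <- order(suit$values, decreasing = TRUE)
  codes <- matrix(311, nr, nc)
  arable_codes <- c(211, 212, 213)
  other_ag <- c(221, 222, 223, 231, 241, 242, 243, 244)
  set.seed(config$seed * 7 + 5)
  if (n_ar > 0) codes[ord[seq_len(n_ar)]] <-
      sample(arable_codes, n_ar, replace = TRUE)
  if (n_ag > n_ar) codes[ord[(n_ar + 1):n_ag]] <-
      sample(other_ag, n_ag - n_ar, replace = TRUE)
  land <- land_mask(grid_create(codes, cell_size = config$cell_size_m,
                                nodata = 255))
  list(land = land, zones = zone_partition(zones_g, comp))
}

# uniform draws in [lo, hi] shaped like the planted mask selector
.fill <- function(n, lo, hi) stats::runif(n, lo, hi)

# margin convention: for a margin m, the critical side of a "greater" rule
# starts at t + m*|t| and the safe side stops at t - m*|t| (mirrored for
# "less" rules), so threshold comparisons are never decided within m*|t|
# of the cut-off.
.gt_crit <- function(n, t, m) .fill(n, t + m * abs(t), t + 2 * abs(t))
.gt_safe <- function(n, t, m, lo = 0) .fill(n, lo, t - m * abs(t))
.lt_crit <- function(n, t, m, lo) .fill(n, lo, t - m * abs(t))
.lt_safe <- function(n, t, m, hi) .fill(n, t + m * abs(t), hi)

#' Generate all twelve process inputs plus ground truth
#'
#' For every process, raw values are drawn so that the rule registry
#' reproduces the planted Critical mask exactly. In the incomplete zone
#' (if any) the acidification, compaction and heavy-metal inputs are
#' nodata. With `planted_class_proportions` set, exact LMI class shares
#' are planted over the agricultural stratum by largest-remainder
#' allocation and per-pixel process sets are drawn to match.
#'
#' @param config a [scenario_config()].
#' @param registry rule registry (thresholds define the margins).
#' @return list of class `lmdi_scenario`: `inputs` (manifest for
#'   [build_critical_stack()]), `land`, `zones`, `truth` (list:
#'   `masks` per process, `lmi` grid, `class_proportions` over the
#'   agricultural stratum), `config`.
#' @export
gen_process_inputs <- function(config, registry = default_registry()) {
  nr <- config$shape[1]; nc <- config$shape[2]
  npx <- nr * nc
  lz <- gen_landuse_and_zones(config)
  withheld <- c("SA", "SC", "SPHM")
  inc_zone <- if (config$incomplete_zone && config$n_zones >= 3)
    config$n_zones else NA_integer_
  unavailable <- if (!is.na(inc_zone)) lz$zones$zones$values == inc_zone
                 else matrix(FALSE, nr, nc)

  pids <- registry_process_ids(registry)
  avail <- lapply(stats::setNames(pids, pids), function(p)
    if (p %in% withheld) !unavailable else matrix(TRUE, nr, nc))

  if (is.null(config$planted_class_proportions)) {
    masks <- list()
    for (i in seq_along(pids)) {
      p <- pids[i]
      m <- .planted_mask(config$shape, config$critical_fractions[[p]],
                         config$correlation_length,
                         seed = config$seed * 101 + i)
      m[!avail[[p]]] <- NA_real_
      masks[[p]] <- m
    }
  } else {
    masks <- .plant_class_masks(config, lz, avail, pids)
  }

  inputs <- list()
  set.seed(config$seed * 1009 + 7)
  simple <- function(p, crit_fun, safe_fun) {
    m <- masks[[p]]
    v <- matrix(NA_real_, nr, nc)
    i1 <- which(!is.na(m) & m == 1); i0 <- which(!is.na(m) & m == 0)
    v[i1] <- crit_fun(length(i1)); v[i0] <- safe_fun(length(i0))
    grid_create(v, cell_size = config$cell_size_m)
  }
  mg <- config$margin
  inputs$WaE <- simple("WaE", function(n) .gt_crit(n, 2, mg),
                       function(n) .gt_safe(n, 2, mg))
  inputs$WiE <- simple("WiE", function(n) .gt_crit(n, 2, mg),
                       function(n) .gt_safe(n, 2, mg))
  inputs$SS  <- simple("SS", function(n) .fill(n, 50 * (1 + mg), 100),
                       function(n) .gt_safe(n, 50, mg))
  inputs$SA  <- simple("SA", function(n) .lt_crit(n, 5.5, mg, 3.5),
                       function(n) .lt_safe(n, 5.5, mg, 8.5))
  inputs$SC  <- simple("SC", function(n) sample(4:5, n, replace = TRUE),
                       function(n) sample(1:3, n, replace = TRUE))
  inputs$SPP <- simple("SPP", function(n) .fill(n, 3 * (1 + mg), 5),
                       function(n) .gt_safe(n, 3, mg))

  # nutrient composite: each critical pixel fires one random sub-condition
  {
    m <- masks[["SNI"]]
    ns <- matrix(NA_real_, nr, nc); nu <- ns; pa <- ns; pb <- ns
    i1 <- which(!is.na(m) & m == 1); i0 <- which(!is.na(m) & m == 0)
    safe_n <- function(n) .gt_safe(n, 50, mg)
    safe_u <- function(n) .fill(n, 0.2, 0.9 * (1 - mg))
    safe_p <- function(n) .fill(n, 25 * (1 + mg), 50 * (1 - mg))
    any_b  <- function(n) .fill(n, -5, 5)
    ns[i0] <- safe_n(length(i0)); nu[i0] <- safe_u(length(i0))
    pa[i0] <- safe_p(length(i0)); pb[i0] <- any_b(length(i0))
    which_cond <- sample(4, length(i1), replace = TRUE)
    for (k in 1:4) {
      ii <- i1[which_cond == k]; n <- length(ii)
      if (n == 0) next
      ns[ii] <- if (k == 1) .gt_crit(n, 50, mg) else safe_n(n)
      nu[ii] <- if (k == 2) .fill(n, 0.9 * (1 + mg), 1.5) else safe_u(n)
      pa[ii] <- if (k == 3) .fill(n, 50 * (1 + mg), 100)
                else if (k == 4) .fill(n, 0, 25 * (1 - mg)) else safe_p(n)
      pb[ii] <- if (k == 3) .fill(n, 0.5, 10)
                else if (k == 4) .fill(n, -10, -0.5) else any_b(n)
    }
    gmk <- function(v) grid_create(v, cell_size = config$cell_size_m)
    inputs$SNI <- list(n_surplus = gmk(ns), nue = gmk(nu),
                       p_avail = gmk(pa), p_budget = gmk(pb))
  }

  # metal union: one random metal exceeds per critical pixel
  {
    m <- masks[["SPHM"]]
    thr <- c(As = 5, Cd = 1, Cr = 100, Co = 20, Pb = 60, Sb = 2, Ni = 50,
             Cu = 100, Hg = 0.5)
    vals <- lapply(thr, function(t) matrix(NA_real_, nr, nc))
    i1 <- which(!is.na(m) & m == 1); i0 <- which(!is.na(m) & m == 0)
    hot <- sample(length(thr), length(i1), replace = TRUE)
    for (j in seq_along(thr)) {
      t <- thr[[j]]
      vals[[j]][i0] <- .fill(length(i0), 0.2 * t, (1 - mg) * t)
      cold <- i1[hot != j]; hh <- i1[hot == j]
      vals[[j]][cold] <- .fill(length(cold), 0.2 * t, (1 - mg) * t)
      vals[[j]][hh] <- .fill(length(hh), (1 + mg) * t, 2 * t)
    }
    inputs$SPHM <- lapply(vals, function(v)
      grid_create(v, cell_size = config$cell_size_m))
  }

  # aridity: AI planted inside/outside the dryland-critical band
  {
    m <- masks[["A"]]
    ai <- matrix(NA_real_, nr, nc)
    i1 <- which(!is.na(m) & m == 1); i0 <- which(!is.na(m) & m == 0)
    ai[i1] <- .fill(length(i1), 0.03 * (1 + mg), 0.65 * (1 - mg))
    humid <- stats::runif(length(i0)) < 0.9
    ai[i0[humid]] <- .fill(sum(humid), 0.65 * (1 + mg), 1.5)
    ai[i0[!humid]] <- .fill(sum(!humid), 0.005, 0.03 * (1 - mg))
    pet <- matrix(.fill(npx, 800, 1200), nr, nc)
    gmk <- function(v) grid_create(v, cell_size = config$cell_size_m)
    inputs$A <- list(P = gmk(ai * pet), PET = gmk(pet))
  }

  # trend processes: planted decline at factor x the slope cut-off
  slope_thr <- c(SOCL = -0.1, VD = -0.001, GD = -0.001)
  intercepts <- c(SOCL = 50, VD = 0.6, GD = 5)
  for (p in names(slope_thr)) {
    m <- masks[[p]]
    slope <- config$trend_slope_factor * slope_thr[[p]]
    noise <- config$trend_noise_frac * abs(slope)
    ny <- config$n_years[[p]]
    set.seed(config$seed * 331 + match(p, names(slope_thr)))
    arr <- array(NA_real_, c(nr, nc, ny))
    sl <- ifelse(!is.na(m) & m == 1, slope, 0)
    for (t in seq_len(ny))
      arr[, , t] <- intercepts[[p]] + sl * (t - 1) +
        matrix(stats::rnorm(npx, 0, noise), nr, nc)
    inputs[[p]] <- grid_create(arr, cell_size = config$cell_size_m)
  }

  inputs <- inputs[pids]

  mask_grids <- lapply(masks, function(m)
    grid_create(m, cell_size = config$cell_size_m, nodata = 255))
  true_lmi <- matrix(0, nr, nc)
  for (m in masks) {
    ok <- !is.na(m)
    true_lmi[ok] <- true_lmi[ok] + m[ok]
  }
  ag <- stratum_mask(lz$land, "agricultural")$values == 1
  cls <- pmin(true_lmi, 5)
  props <- vapply(0:5, function(k) mean(cls[ag] == k), numeric(1))
  names(props) <- 0:5
  structure(list(inputs = inputs, land = lz$land, zones = lz$zones,
                 truth = list(
                   masks = mask_grids[pids],
                   lmi = grid_create(true_lmi,
                                     cell_size = config$cell_size_m,
                                     nodata = 255),
                   class_proportions = props),
                 config = config),
            class = "lmdi_scenario")
}

# exact LMI class planting over the agricultural stratum
.plant_class_masks <- function(config, lz, avail, pids) {
  nr <- config$shape[1]; nc <- config$shape[2]
  npx <- nr * nc
  ag <- stratum_mask(lz$land, "agricultural")$values == 1
  idx_ag <- which(ag); idx_out <- which(!ag)
  props <- config$planted_class_proportions
  n_ag <- length(idx_ag)
  base <- floor(props * n_ag)
  rem <- n_ag - sum(base)
  if (rem > 0) {
    frac <- props * n_ag - base
    base[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      base[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  set.seed(config$seed * 557 + 11)
  cls_ag <- sample(rep(0:5, times = base))
  counts <- matrix(0L, nr, nc)
  counts[idx_ag] <- ifelse(cls_ag == 5,
                           5L + as.integer(stats::runif(n_ag) < 0.4),
                           cls_ag)[seq_len(n_ag)]
  counts[idx_out] <- sample(0:3, length(idx_out), replace = TRUE)
  avail_mat <- vapply(pids, function(p) as.vector(avail[[p]]),
                      logical(npx))
  masks <- lapply(stats::setNames(pids, pids), function(p) {
    m <- matrix(0, nr, nc)
    m[!avail[[p]]] <- NA_real_
    m
  })
  for (i in seq_len(npx)) {
    k <- counts[i]
    if (k == 0L) next
    ok <- which(avail_mat[i, ])
    if (k > length(ok)) k <- length(ok)
    pick <- if (length(ok) == 1L) ok else sample(ok, k)
    for (j in pick) masks[[pids[j]]][i] <- 1
  }
  masks
}

#' Boundary-stress cases for the strict-inequality convention
#'
#' One case per strict scalar threshold: the raw value sits exactly at the
#' printed cut-off, all other inputs of the process are safe, and the
#' expected criticality is 0. Non-strict cut-offs (the MK p <= 0.1
#' significance level and the lower dryland bound AI >= 0.03) are excluded
#' by design: they are not strict-inequality thresholds.
#'
#' @param registry rule registry.
#' @return data.frame: `process_id`, `scalar_id`, plus a list-column
#'   `columns` of named input values for [evaluate_process()].
#' @export
boundary_stress_cases <- function(registry = default_registry()) {
  safe_cols <- list(
    WaE = 1, WiE = 1, SOCL_slope = 0, SOCL_p = 0.5, SS = 10, SA = 7,
    SC_code = 2, N_surplus = 10, NUE = 0.5, P_avail = 35, P_budget = 1,
    SPP_rs = 1, As = 1, Cd = 0.2, Cr = 20, Co = 5, Pb = 10, Sb = 0.5,
    Ni = 10, Cu = 20, Hg = 0.1, VD_slope = 0, VD_p = 0.5, GD_slope = 0,
    GD_p = 0.5, AI = 1)
  sc <- registry_scalars(registry)
  strict <- sc[sc$op %in% c(">", "<"), , drop = FALSE]
  cases <- lapply(seq_len(nrow(strict)), function(i) {
    cols <- safe_cols
    cols[[strict$column[i]]] <- strict$t0[i]
    # significance must hold so only the boundary scalar decides
    if (strict$process_id[i] == "SOCL") cols$SOCL_p <- 0.01
    if (strict$process_id[i] == "VD") cols$VD_p <- 0.01
    if (strict$process_id[i] == "GD") cols$GD_p <- 0.01
    # P budget boundary cases need the paired availability condition armed
    if (strict$scalar_id[i] == "P_budget_gt") cols$P_avail <- 60
    if (strict$scalar_id[i] == "P_budget_lt") cols$P_avail <- 10
    # P availability boundaries need a budget that would allow firing
    if (strict$scalar_id[i] == "P_avail_gt") cols$P_budget <- 1
    if (strict$scalar_id[i] == "P_avail_lt") cols$P_budget <- -1
    # AI boundary needs the non-strict lower bound satisfied
    if (strict$scalar_id[i] == "AI_lt") cols$AI <- strict$t0[i]
    cols
  })
  data.frame(process_id = strict$process_id, scalar_id = strict$scalar_id,
             columns = I(cases), stringsAsFactors = FALSE)
}

#' Write a scenario to a directory of GeoTIFFs plus a manifest
#'
#' @param scenario an `lmdi_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; layout: one GeoTIFF per input layer (stacks
#'   multi-band), ground-truth masks under `truth/`, land-use and zone
#'   rasters, and `manifest.json` mapping process ids to files, units and
#'   rule kinds.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  reg <- default_registry()
  manifest <- list()
  wr <- function(g, name, datatype = "FLT8S") {
    write_raster(g, file.path(dir, name), datatype)
    name
  }
  for (pid in names(scenario$inputs)) {
    inp <- scenario$inputs[[pid]]
    proc <- reg[[pid]]
    entry <- list(kind = proc$kind, unit = proc$unit)
    if (inherits(inp, "lmdi_grid")) {
      entry$files <- wr(inp, paste0(pid, ".tif"))
    } else {
      entry$files <- vapply(names(inp), function(nm)
        wr(inp[[nm]], paste0(pid, "_", nm, ".tif")), character(1))
    }
    manifest[[pid]] <- entry
  }
  write_raster(scenario$land$codes, file.path(dir, "landuse.tif"), "INT4S")
  write_raster(scenario$zones$zones, file.path(dir, "zones.tif"), "INT4S")
  for (pid in names(scenario$truth$masks))
    write_raster(scenario$truth$masks[[pid]],
                 file.path(dir, "truth", paste0(pid, "_mask.tif")), "INT1U")
  write_raster(scenario$truth$lmi, file.path(dir, "truth", "lmi.tif"),
               "INT1U")
  jsonlite::write_json(
    list(processes = manifest,
         landuse = "landuse.tif", zones = "zones.tif",
         completeness = as.list(scenario$zones$completeness),
         agricultural_codes = scenario$land$agricultural_codes,
         arable_codes = scenario$land$arable_codes,
         class_proportions = scenario$truth$class_proportions,
         seed = scenario$config$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scenario directory written by [write_scenario()]
#' @param dir scenario directory.
#' @return list with `inputs`, `land`, `zones` ready for the pipeline.
#' @export
read_scenario <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("scenario manifest not found: ", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  inputs <- list()
  for (pid in names(man$processes)) {
    entry <- man$processes[[pid]]
    files <- entry$files
    if (length(files) == 1L && !nzchar(names(files)[1] %||% "")) {
      inputs[[pid]] <- read_raster(file.path(dir, files))
    } else {
      nms <- sub("\\.tif$", "", sub(paste0("^", pid, "_"), "", files))
      inputs[[pid]] <- stats::setNames(
        lapply(files, function(f) read_raster(file.path(dir, f))), nms)
    }
  }
  land <- land_mask(read_raster(file.path(dir, "landuse.tif")),
                    agricultural_codes = man$agricultural_codes,
                    arable_codes = man$arable_codes)
  comp <- unlist(man$completeness)
  zones <- zone_partition(read_raster(file.path(dir, "zones.tif")),
                          stats::setNames(as.integer(comp), names(comp)))
  list(inputs = inputs, land = land, zones = zones)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
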