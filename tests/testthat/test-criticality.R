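# rule registry and Critical/Non-critical classification

reg <- default_registry()

test_that("registry covers the twelve processes with documented thresholds", {
  expect_identical(registry_process_ids(reg),
                   c("WaE", "WiE", "SOCL", "SS", "SA", "SC", "SNI", "SPP",
                     "SPHM", "VD", "GD", "A"))
  sc <- registry_scalars(reg)
  expect_false(anyDuplicated(sc$scalar_id) > 0)
  # spot-check the documented cut-offs through the table, not the code
  get <- function(id) sc[sc$scalar_id == id, ]
  expect_equal(get("WaE_gt")$t0, 2)
  expect_equal(get("SA_lt")$t0, 5.5)
  expect_equal(get("Hg_gt")$t0, 0.5)
  expect_equal(get("AI_lt")$t0, 0.65)
  expect_equal(get("VD_slope_lt")$t0, -0.001)
  expect_identical(get("VD_p_le")$op, "<=")
})

test_that("simple thresholds are strict and match a per-pixel loop oracle", {
  g <- tiny_grid(matrix(c(3.5, 2, 1.9, 2.0001), 2, 2))
  m <- classify_simple_threshold(g, reg[["WaE"]])
  expect_equal(as.vector(m$values), c(1, 0, 0, 1))

  ph <- tiny_grid(matrix(c(5.5, 5.4999, 7, 3), 2, 2))
  mp <- classify_simple_threshold(ph, reg[["SA"]])
  expect_equal(as.vector(mp$values), c(0, 1, 0, 1))  # pH 5.5 boundary -> 0

  set.seed(1)
  rg <- tiny_grid(matrix(runif(400, 0, 5), 20, 20))
  mm <- classify_simple_threshold(rg, reg[["WaE"]])
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    oracle[i, j] <- as.numeric(rg$values[i, j] > 2)
  expect_identical(mm$values, oracle)
})

test_that("class membership: compaction codes and pesticide risk classes", {
  codes <- tiny_grid(matrix(c(1, 3, 4, 5, 2, NA), 2, 3))
  m <- classify_class_membership(codes, critical_codes = c(4, 5))
  expect_equal(as.vector(m$values), c(0, 0, 1, 1, 0, NA))
  expect_error(classify_class_membership(tiny_grid(matrix(9, 1, 1)),
                                         critical_codes = c(4, 5)),
               "unknown class code")
  # risk score 3.2 maps to class high -> critical under the registry rule
  expect_equal(risk_score_to_class(3.2), 4)
  rs <- tiny_grid(matrix(c(3.2, 3, 4.5, 0.5), 2, 2))
  mrs <- classify_simple_threshold(rs, reg[["SPP"]])
  expect_equal(as.vector(mrs$values), c(1, 0, 1, 0))  # RS 3 boundary -> 0
})

test_that("nutrient imbalance composite honours the four-way rule", {
  gm <- function(x) tiny_grid(matrix(x, 1, 4))
  ns <- gm(c(80, 10, 40, 40)); nue <- gm(c(0.5, 0.95, 0.8, 0.8))
  pa <- gm(c(30, 30, 30, 60)); pb <- gm(c(5, 5, 5, 5))
  m <- classify_nutrient_imbalance(ns, nue, pa, pb)
  # 1: N surplus; 2: NUE deficit; 3: nothing; 4: P surplus
  expect_equal(as.vector(m$values), c(1, 1, 0, 1))
  cl <- attr(m, "classes")
  expect_equal(as.vector(cl$n_surplus$values), c(1, 0, 0, 0))
  expect_equal(as.vector(cl$p_surplus$values), c(0, 0, 0, 1))
  # P deficit requires BOTH low P and negative budget
  m2 <- classify_nutrient_imbalance(gm(rep(10, 4)), gm(rep(0.5, 4)),
                                    gm(c(20, 20, 30, 20)),
                                    gm(c(-1, 1, -1, 0)))
  expect_equal(as.vector(m2$values), c(1, 0, 0, 0))
  expect_error(classify_nutrient_imbalance(ns, gm(rep(-0.1, 4)), pa, pb),
               "non-negative")
})

test_that("heavy-metal union equals the per-pixel OR oracle", {
  thr <- c(As = 5, Cd = 1, Cr = 100, Co = 20, Pb = 60, Sb = 2, Ni = 50,
           Cu = 100, Hg = 0.5)
  set.seed(8)
  metals <- lapply(thr, function(t)
    tiny_grid(matrix(runif(100, 0, 1.6 * t), 10, 10)))
  m <- classify_heavy_metals(metals)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    oracle[i, j] <- as.numeric(any(vapply(names(thr), function(nm)
      metals[[nm]]$values[i, j] > thr[[nm]], logical(1))))
  expect_identical(m$values, oracle)

  # single exceedance drives the union; all-below -> 0
  low <- lapply(thr, function(t) tiny_grid(matrix(0.5 * t, 2, 2)))
  expect_true(all(classify_heavy_metals(low)$values == 0))
  hot <- low; hot$Cd <- tiny_grid(matrix(1.5, 2, 2))
  expect_true(all(classify_heavy_metals(hot)$values == 1))

  expect_error(classify_heavy_metals(low[1:5]), "all nine")

  # nodata policy: valid exceedance certifies 1; missing metal blocks 0
  na_cd <- low
  na_cd$Cd$values[1, 1] <- NA
  res <- classify_heavy_metals(na_cd)
  expect_true(is.na(res$values[1, 1]))
  expect_true(all(res$values[-1] == 0))
  hot_na <- hot; hot_na$As$values[1, 1] <- NA
  expect_equal(classify_heavy_metals(hot_na)$values[1, 1], 1)
})

test_that("aridity: AI ratio, dryland classes and criticality band", {
  P <- tiny_grid(matrix(c(300, 650, 20, 700, 100, 550), 2, 3))
  PET <- tiny_grid(matrix(1000, 2, 3))
  ar <- compute_aridity(P, PET)
  expect_equal(as.vector(ar$ai$values),
               c(0.3, 0.65, 0.02, 0.7, 0.1, 0.55))
  # classes: semi-arid, humid (boundary, strict <), hyper-arid, humid,
  # arid, dry sub-humid
  expect_equal(as.vector(ar$class$values), c(3, 5, 1, 5, 2, 4))
  expect_equal(as.vector(ar$mask$values), c(1, 0, 0, 0, 1, 1))

  bad <- tiny_grid(matrix(c(1000, 0), 1, 2))
  expect_warning(res <- compute_aridity(tiny_grid(matrix(500, 1, 2)), bad),
                 "PET")
  expect_true(is.na(res$ai$values[1, 2]))
})

test_that("trend-process criticality needs both slope and significance", {
  sl <- tiny_grid(matrix(c(-0.002, -0.002, -0.0005, -0.002), 2, 2))
  p <- tiny_grid(matrix(c(0.04, 0.2, 0.01, 0.1), 2, 2))
  m <- classify_trend_process(sl, p, slope_threshold = -0.001)
  # p = 0.1 exactly is significant (non-strict <=)
  expect_equal(as.vector(m$values), c(1, 0, 0, 1))
  expect_error(classify_trend_process(sl, p, slope_threshold = 0.001),
               "negative")
})

test_that("build_critical_stack recovers planted masks and tracks missing", {
  scn <- small_scenario()
  stack <- build_critical_stack(scn$inputs)
  expect_identical(names(stack$masks), registry_process_ids(reg))
  expect_length(stack$missing, 0)
  for (pid in names(stack$masks))
    expect_identical(stack$masks[[pid]]$values,
                     scn$truth$masks[[pid]]$values)

  sub <- build_critical_stack(scn$inputs[c("WaE", "SS", "A")])
  expect_length(sub$masks, 3)
  expect_setequal(sub$missing,
                  setdiff(registry_process_ids(reg), c("WaE", "SS", "A")))
  expect_error(build_critical_stack(list()), "empty")
  expect_error(build_critical_stack(list(XX = tiny_grid(matrix(1, 2, 2)))),
               "unknown process")
})

test_that("rules are monotone under perturbation toward criticality", {
  set.seed(12)
  sc <- registry_scalars(reg)
  for (k in 1:50) {
    row <- sc[sample(nrow(sc), 1), ]
    v <- row$t0 + rnorm(1, 0, max(abs(row$t0), 0.1))
    cols <- list(v); names(cols) <- row$column
    proc <- reg[[row$process_id]]
    if (length(proc$scalars) > 1) next  # single-scalar rules suffice here
    base <- evaluate_process(proc, cols)
    dirn <- if (row$op %in% c(">", ">=")) 1 else -1
    cols[[row$column]] <- v + dirn * abs(rnorm(1)) * max(abs(row$t0), 0.1)
    moved <- evaluate_process(proc, cols)
    expect_gte(moved, base)
  }
})
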