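#' Criticality rule registry
#'
#' Each of the twelve land-degradation processes carries one documented rule
#' that maps its raw metric to Critical (1) / Non-critical (0). The registry
#' is data, not code: every scalar cut-off is listed with its comparison
#' operator so that the uncertainty module can perturb thresholds without
#' touching the classification logic. Scalar comparisons printed as ">" or
#' "<" are strict (boundary values are Non-critical); the Mann-Kendall
#' significance cut-off is non-strict (p <= 0.1) and the lower dryland bound
#' is non-strict (AI >= 0.03 keeps arid land critical, hyper-arid is not).
#'
#' Canonical process order and abbreviations: WaE (water erosion), WiE (wind
#' erosion), SOCL (soil organic carbon loss), SS (soil salinization), SA
#' (soil acidification), SC (soil compaction), SNI (soil nutrient
#' imbalances), SPP (soil pollution via pesticides), SPHM (soil pollution
#' via heavy metals), VD (vegetation degradation), GD (groundwater decline),
#' A (aridity).
#'
#' Composite rules: SNI is critical when N surplus > 50 kg/ha OR nitrogen
#' use efficiency > 0.9 OR (available P > 50 mg/kg AND positive P budget)
#' OR (available P < 25 mg/kg AND negative P budget). SPHM is the union of
#' nine per-metal exceedances. Aridity is critical on dry sub-humid,
#' semi-arid and arid land (0.03 <= AI < 0.65); hyper-arid is excluded.
#' Trend processes (SOCL, VD, GD) require a Sen's slope below the cut-off
#' AND a two-sided Mann-Kendall p-value <= 0.1. Compaction susceptibility
#' and pesticide risk are ordinal: codes 1..5 (very low .. very high) with
#' High and Very High critical, expressed as a scalar cut at 3.5 (codes) or
#' a risk score > 3.
#'
#' @return An object of class `lmdi_registry`: an ordered list of process
#'   definitions, each with `id`, `name`, `kind`, `unit`, `scalars` (list of
#'   `scalar_id`, `column`, `t0`, `op`) and `combine` (how scalar booleans
#'   merge into process criticality).
#' @export
default_registry <- function() {
  sc <- function(id, column, t0, op) list(scalar_id = id, column = column,
                                          t0 = t0, op = op)
  procs <- list(
    list(id = "WaE", name = "Water erosion", kind = "simple_threshold",
         unit = "t ha-1 yr-1",
         scalars = list(sc("WaE_gt", "WaE", 2, ">")), combine = "and"),
    list(id = "WiE", name = "Wind erosion", kind = "simple_threshold",
         unit = "t ha-1 yr-1",
         scalars = list(sc("WiE_gt", "WiE", 2, ">")), combine = "and"),
    list(id = "SOCL", name = "Soil organic carbon loss", kind = "trend",
         unit = "t C km-2 yr-1",
         scalars = list(sc("SOCL_slope_lt", "SOCL_slope", -0.1, "<"),
                        sc("SOCL_p_le", "SOCL_p", 0.1, "<=")),
         combine = "and"),
    list(id = "SS", name = "Soil salinization", kind = "simple_threshold",
         unit = "% saline/sodic",
         scalars = list(sc("SS_gt", "SS", 50, ">")), combine = "and"),
    list(id = "SA", name = "Soil acidification", kind = "simple_threshold",
         unit = "pH",
         scalars = list(sc("SA_lt", "SA", 5.5, "<")), combine = "and"),
    list(id = "SC", name = "Soil compaction", kind = "class_membership",
         unit = "susceptibility class 1-5",
         scalars = list(sc("SC_gt", "SC_code", 3.5, ">")), combine = "and"),
    list(id = "SNI", name = "Soil nutrient imbalances",
         kind = "nutrient_composite", unit = "kg/ha (N), mg/kg (P)",
         scalars = list(sc("N_surplus_gt", "N_surplus", 50, ">"),
                        sc("NUE_gt", "NUE", 0.9, ">"),
                        sc("P_avail_gt", "P_avail", 50, ">"),
                        sc("P_avail_lt", "P_avail", 25, "<"),
                        sc("P_budget_gt", "P_budget", 0, ">"),
                        sc("P_budget_lt", "P_budget", 0, "<")),
         combine = "nutrient"),
    list(id = "SPP", name = "Soil pollution via pesticides",
         kind = "class_membership", unit = "risk score",
         scalars = list(sc("SPP_gt", "SPP_rs", 3, ">")), combine = "and"),
    list(id = "SPHM", name = "Soil pollution via heavy metals",
         kind = "metal_union", unit = "mg/kg",
         scalars = list(sc("As_gt", "As", 5, ">"),
                        sc("Cd_gt", "Cd", 1, ">"),
                        sc("Cr_gt", "Cr", 100, ">"),
                        sc("Co_gt", "Co", 20, ">"),
                        sc("Pb_gt", "Pb", 60, ">"),
                        sc("Sb_gt", "Sb", 2, ">"),
                        sc("Ni_gt", "Ni", 50, ">"),
                        sc("Cu_gt", "Cu", 100, ">"),
                        sc("Hg_gt", "Hg", 0.5, ">")),
         combine = "or"),
    list(id = "VD", name = "Vegetation degradation", kind = "trend",
         unit = "NDVI units yr-1",
         scalars = list(sc("VD_slope_lt", "VD_slope", -0.001, "<"),
                        sc("VD_p_le", "VD_p", 0.1, "<=")),
         combine = "and"),
    list(id = "GD", name = "Groundwater decline", kind = "trend",
         unit = "m yr-1 (GTD)",
         scalars = list(sc("GD_slope_lt", "GD_slope", -0.001, "<"),
                        sc("GD_p_le", "GD_p", 0.1, "<=")),
         combine = "and"),
    list(id = "A", name = "Aridity", kind = "aridity", unit = "AI mm/mm",
         scalars = list(sc("AI_lt", "AI", 0.65, "<"),
                        sc("AI_ge", "AI", 0.03, ">=")),
         combine = "and"))
  names(procs) <- vapply(procs, function(p) p$id, character(1))
  structure(procs, class = "lmdi_registry")
}

#' Canonical process order of a registry
#' @param registry an `lmdi_registry`.
#' @export
registry_process_ids <- function(registry) names(registry)

#' Flat table of every scalar threshold in a registry
#'
#' One row per scalar cut-off, giving its owning process, the input-matrix
#' column it compares, the baseline threshold `t0` and the comparison
#' operator. This is the object the Monte-Carlo perturbation draws against.
#'
#' @param registry an `lmdi_registry`.
#' @return data.frame with columns `scalar_id`, `process_id`, `column`,
#'   `t0`, `op`.
#' @export
registry_scalars <- function(registry) {
  rows <- do.call(rbind, lapply(registry, function(p) {
    do.call(rbind, lapply(p$scalars, function(s)
      data.frame(scalar_id = s$scalar_id, process_id = p$id,
                 column = s$column, t0 = s$t0, op = s$op,
                 stringsAsFactors = FALSE)))
  }))
  rownames(rows) <- NULL
  rows
}

.compare_op <- function(values, op, threshold) {
  switch(op,
         ">"  = values >  threshold,
         "<"  = values <  threshold,
         ">=" = values >= threshold,
         "<=" = values <= threshold,
         stop("unknown operator: ", op))
}

#' Evaluate one process rule on column vectors
#'
#' Core evaluator shared by the baseline classification and the
#' threshold-perturbation simulation. `columns` is a named list (or named
#' matrix columns) of raw values; `thresholds` optionally overrides scalar
#' baselines by `scalar_id`.
#'
#' Missing-value policy for OR-composites (metal union, nutrient rule): a
#' pixel is Critical as soon as one computable branch fires; it is
#' Non-critical only when every branch is computable and false; otherwise it
#' is nodata (a missing input could still certify criticality but its
#' absence cannot certify safety).
#'
#' @param process one element of a registry.
#' @param columns named list of numeric vectors (one per input column).
#' @param thresholds optional named numeric vector keyed by `scalar_id`.
#' @return numeric vector of 1/0/NA.
#' @export
evaluate_process <- function(process, columns, thresholds = NULL) {
  sv <- lapply(process$scalars, function(s) {
    t0 <- if (!is.null(thresholds) && s$scalar_id %in% names(thresholds))
      thresholds[[s$scalar_id]] else s$t0
    col <- columns[[s$column]]
    if (is.null(col)) stop("missing input column: ", s$column,
                           " for process ", process$id)
    .compare_op(col, s$op, t0)
  })
  names(sv) <- vapply(process$scalars, function(s) s$scalar_id, character(1))
  or_merge <- function(conds) {
    any_true <- Reduce(function(a, b) {
      a[is.na(a)] <- FALSE; b[is.na(b)] <- FALSE; a | b
    }, conds)
    all_false <- Reduce(`&`, lapply(conds, function(x) !is.na(x) & !x))
    out <- rep(NA_real_, length(any_true))
    out[any_true] <- 1
    out[!any_true & all_false] <- 0
    out
  }
  if (process$combine == "and") {
    res <- Reduce(`&`, sv)
    return(as.numeric(res))
  }
  if (process$combine == "or") return(or_merge(sv))
  if (process$combine == "nutrient") {
    conds <- list(
      sv[["N_surplus_gt"]],
      sv[["NUE_gt"]],
      sv[["P_avail_gt"]] & sv[["P_budget_gt"]],
      sv[["P_avail_lt"]] & sv[["P_budget_lt"]])
    return(or_merge(conds))
  }
  stop("unknown combine mode: ", process$combine)
}

#' Binarize a continuous layer against a simple threshold rule
#'
#' @param values a [grid_create()] grid in the rule's units.
#' @param process a registry entry of kind `simple_threshold` (or any
#'   single-scalar rule).
#' @return A 0/1/NA grid (nodata sentinel 255).
#' @export
classify_simple_threshold <- function(values, process) {
  if (length(process$scalars) != 1L)
    stop("classify_simple_threshold expects a single-scalar rule")
  cols <- list(as.vector(values$values))
  names(cols) <- process$scalars[[1]]$column
  out <- evaluate_process(process, cols)
  grid_like(values, matrix(out, nrow(values$values), ncol(values$values)),
            nodata = 255)
}

#' Binarize a categorical layer by critical class membership
#'
#' @param codes grid of integer class codes.
#' @param critical_codes codes deemed Critical (e.g. High/Very High).
#' @param known_codes full set of legal codes; anything else errors.
#' @export
classify_class_membership <- function(codes, critical_codes,
                                      known_codes = 1:5) {
  v <- codes$values
  bad <- !is.na(v) & !(v %in% known_codes)
  if (any(bad)) stop("unknown class code(s): ",
                     paste(unique(v[bad]), collapse = ", "))
  out <- ifelse(is.na(v), NA_real_, as.numeric(v %in% critical_codes))
  grid_like(codes, out, nodata = 255)
}

#' Map a pesticide risk score to its ordinal risk class
#'
#' Classes: 1 very low (RS <= 1), 2 low (1 < RS <= 2), 3 moderate
#' (2 < RS <= 3), 4 high (3 < RS <= 4), 5 very high (RS > 4). Only the
#' high/very-high boundaries are documented upstream; the lower bins are a
#' package convention and never affect criticality.
#'
#' @param rs numeric risk scores.
#' @export
risk_score_to_class <- function(rs) {
  ifelse(is.na(rs), NA_real_, pmin(pmax(ceiling(rs), 1), 5))
}

#' Nutrient-imbalance criticality from the four N/P inputs
#'
#' Critical when N surplus > 50 kg/ha, or NUE > 0.9, or P surplus
#' (available P > 50 mg/kg with positive budget), or P deficit (available
#' P < 25 mg/kg with negative budget). The four sub-conditions are attached
#' as attribute `"classes"` (a list of 0/1 grids) since the upstream
#' construction merges four classes into one layer.
#'
#' @param n_surplus grid, kg/ha. @param nue grid, dimensionless ratio >= 0.
#' @param p_avail grid, mg/kg. @param p_budget grid, budget sign carrier.
#' @param registry registry supplying the thresholds.
#' @export
classify_nutrient_imbalance <- function(n_surplus, nue, p_avail, p_budget,
                                        registry = default_registry()) {
  grid_check_aligned(n_surplus, nue, p_avail, p_budget)
  if (any(nue$values < 0, na.rm = TRUE))
    stop("NUE must be non-negative")
  proc <- registry[["SNI"]]
  cols <- list(N_surplus = as.vector(n_surplus$values),
               NUE = as.vector(nue$values),
               P_avail = as.vector(p_avail$values),
               P_budget = as.vector(p_budget$values))
  out <- evaluate_process(proc, cols)
  d <- dim(n_surplus$values)
  res <- grid_like(n_surplus, matrix(out, d[1], d[2]), nodata = 255)
  sub <- list(
    n_surplus = as.numeric(cols$N_surplus > 50),
    n_deficit = as.numeric(cols$NUE > 0.9),
    p_surplus = as.numeric(cols$P_avail > 50 & cols$P_budget > 0),
    p_deficit = as.numeric(cols$P_avail < 25 & cols$P_budget < 0))
  attr(res, "classes") <- lapply(sub, function(x)
    grid_like(n_surplus, matrix(x, d[1], d[2]), nodata = 255))
  res
}

#' Heavy-metal pollution criticality (nine-threshold union)
#'
#' Critical where any metal concentration exceeds its safe limit:
#' As > 5, Cd > 1, Cr > 100, Co > 20, Pb > 60, Sb > 2, Ni > 50, Cu > 100,
#' Hg > 0.5 (mg/kg). Nodata policy: one valid exceedance is enough for
#' Critical; Non-critical requires all nine valid and below.
#'
#' @param metals named list of nine grids (`As`, `Cd`, `Cr`, `Co`, `Pb`,
#'   `Sb`, `Ni`, `Cu`, `Hg`).
#' @param registry registry supplying thresholds.
#' @param allow_subset permit fewer than nine metals (explicit opt-in).
#' @export
classify_heavy_metals <- function(metals, registry = default_registry(),
                                  allow_subset = FALSE) {
  proc <- registry[["SPHM"]]
  want <- vapply(proc$scalars, function(s) s$column, character(1))
  if (!allow_subset && !all(want %in% names(metals)))
    stop("need all nine metal grids: missing ",
         paste(setdiff(want, names(metals)), collapse = ", "))
  use <- intersect(want, names(metals))
  if (length(use) == 0L) stop("no metal grids supplied")
  grid_check_aligned(metals[use])
  sub <- proc
  sub$scalars <- proc$scalars[match(use, want)]
  cols <- lapply(metals[use], function(g) as.vector(g$values))
  out <- evaluate_process(sub, cols)
  ref <- metals[[use[1]]]
  grid_like(ref, matrix(out, nrow(ref$values), ncol(ref$values)),
            nodata = 255)
}

#' Aridity index, dryland classes and aridity criticality
#'
#' AI = P / PET (mm/mm). Dryland classes: hyper-arid (< 0.03), arid
#' (0.03-0.2), semi-arid (0.2-0.5), dry sub-humid (0.5-0.65), humid
#' (>= 0.65). The criticality layer covers dry sub-humid, semi-arid and
#' arid land only: 0.03 <= AI < 0.65.
#'
#' @param P precipitation climatology grid (mm).
#' @param PET potential evapotranspiration climatology grid (mm).
#' @param registry registry supplying the AI cut-offs.
#' @return list with `ai` grid, `class` grid (codes 1 hyper-arid .. 5
#'   humid) and `mask` criticality grid.
#' @export
compute_aridity <- function(P, PET, registry = default_registry()) {
  grid_check_aligned(P, PET)
  pet <- PET$values
  n_bad <- sum(!is.na(pet) & pet <= 0)
  if (n_bad > 0)
    warning(n_bad, " pixel(s) with PET <= 0 set to nodata")
  pet[!is.na(pet) & pet <= 0] <- NA_real_
  ai <- P$values / pet
  cls <- ifelse(is.na(ai), NA_real_,
         ifelse(ai < 0.03, 1,
         ifelse(ai < 0.2, 2,
         ifelse(ai < 0.5, 3,
         ifelse(ai < 0.65, 4, 5)))))
  proc <- registry[["A"]]
  mask <- evaluate_process(proc, list(AI = as.vector(ai)))
  d <- dim(ai)
  list(ai = grid_like(P, ai),
       class = grid_like(P, cls, nodata = 255),
       mask = grid_like(P, matrix(mask, d[1], d[2]), nodata = 255))
}

#' Trend-process criticality from slope and significance grids
#'
#' Critical where Sen's slope < `slope_threshold` and the two-sided
#' Mann-Kendall p-value <= `p_threshold`.
#'
#' @param slope Sen's slope grid (units per year).
#' @param p MK p-value grid.
#' @param slope_threshold negative cut-off (e.g. -0.001).
#' @param p_threshold significance level (default 0.1, non-strict).
#' @export
classify_trend_process <- function(slope, p, slope_threshold,
                                   p_threshold = 0.1) {
  grid_check_aligned(slope, p)
  if (slope_threshold >= 0)
    stop("slope_threshold must be negative (decline rule)")
  out <- as.numeric(slope$values < slope_threshold & p$values <= p_threshold)
  grid_like(slope, out, nodata = 255)
}

#' Expand a process-input manifest into flat input columns
#'
#' Turns the heterogeneous raw inputs (single grids, annual stacks,
#' composite input lists) into the named column grids the registry's scalar
#' rules compare against: trend stacks become Sen-slope and p columns,
#' P/PET become an AI column, composites contribute one column each.
#'
#' @param inputs named list keyed by process id; see [build_critical_stack()].
#' @param registry an `lmdi_registry`.
#' @param min_frac gap tolerance forwarded to [trend_raster()].
#' @return named list of single-band grids, one per registry column.
#' @export
process_columns <- function(inputs, registry = default_registry(),
                            min_frac = 0.7) {
  cols <- list()
  for (pid in intersect(registry_process_ids(registry), names(inputs))) {
    proc <- registry[[pid]]
    inp <- inputs[[pid]]
    if (proc$kind == "trend") {
      if (inherits(inp, "lmdi_grid")) {
        tr <- trend_raster(inp, min_frac = min_frac)
      } else if (is.list(inp) && all(c("slope", "p") %in% names(inp))) {
        tr <- inp
      } else stop("trend process ", pid,
                  " needs a multi-band stack or slope/p grids")
      cols[[paste0(pid, "_slope")]] <- tr$slope
      cols[[paste0(pid, "_p")]] <- tr$p
    } else if (proc$kind == "aridity") {
      ar <- compute_aridity(inp$P, inp$PET, registry)
      cols[["AI"]] <- ar$ai
    } else if (proc$kind == "nutrient_composite") {
      cols[["N_surplus"]] <- inp$n_surplus
      cols[["NUE"]] <- inp$nue
      cols[["P_avail"]] <- inp$p_avail
      cols[["P_budget"]] <- inp$p_budget
    } else if (proc$kind == "metal_union") {
      for (m in names(inp)) cols[[m]] <- inp[[m]]
    } else {
      want <- proc$scalars[[1]]$column
      cols[[want]] <- inp
    }
  }
  cols
}

#' Build the ordered Critical/Non-critical layer stack
#'
#' Applies the full rule registry to a manifest of raw process inputs and
#' returns one binary mask per available process in canonical order.
#' Processes absent from the manifest are recorded, not silently dropped;
#' zones integrating only 9-11 of the 12 layers are handled downstream.
#'
#' @param inputs named list keyed by process id. Values: a grid for simple
#'   rules; a multi-band stack (or `list(slope=, p=)`) for SOCL/VD/GD;
#'   `list(n_surplus=, nue=, p_avail=, p_budget=)` for SNI; a named list of
#'   nine metal grids for SPHM; `list(P=, PET=)` for A.
#' @param registry an `lmdi_registry`.
#' @param min_frac trend gap tolerance.
#' @return list with `masks` (named list of 0/1/NA grids in canonical
#'   order), `missing` (character vector of absent process ids) and
#'   `columns` (the flat input columns, reused by the uncertainty module).
#' @export
build_critical_stack <- function(inputs, registry = default_registry(),
                                 min_frac = 0.7) {
  if (length(inputs) == 0L) stop("empty input manifest")
  if (anyDuplicated(names(inputs)))
    stop("duplicate process ids in manifest")
  unknown <- setdiff(names(inputs), registry_process_ids(registry))
  if (length(unknown)) stop("unknown process id(s): ",
                            paste(unknown, collapse = ", "))
  cols <- process_columns(inputs, registry, min_frac)
  ref <- cols[[1]]
  grid_check_aligned(cols)
  flat <- lapply(cols, function(g) as.vector(g$values))
  avail <- intersect(registry_process_ids(registry), names(inputs))
  masks <- list()
  for (pid in avail) {
    out <- evaluate_process(registry[[pid]], flat)
    masks[[pid]] <- grid_like(ref, matrix(out, nrow(ref$values),
                                          ncol(ref$values)), nodata = 255)
  }
  list(masks = masks,
       missing = setdiff(registry_process_ids(registry), avail),
       columns = cols)
}
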