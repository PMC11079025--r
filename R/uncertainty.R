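#' Threshold-perturbation uncertainty of the LMI classification
#'
#' The criticality cut-offs are judgement calls, so their effect on the LMI
#' map is quantified by Monte Carlo: every scalar threshold t0 in the
#' registry is redrawn n times from Normal(t0, |t0|/10), the stacked input
#' matrix is re-binarized under each draw, row sums give perturbed LMI
#' values, and a Random-Forest classifier trained on the original inputs
#' against the perturbed labels yields per-pixel class probabilities, an
#' out-of-bag error and per-input importances (the sensitivity ranking).
#' Reference settings are 20,000 draws, 1000 trees and 20 repetitions;
#' desk-scale defaults (2,000 draws, 200 trees, 5 repetitions) keep the
#' test suite fast.
#'
#' @name uncertainty
NULL

#' Draw perturbed threshold samples
#'
#' @param registry rule registry.
#' @param n_sims number of draws (reference value 20,000).
#' @param sd_fraction standard deviation as a fraction of |t0| (default
#'   0.1, i.e. one-tenth of the threshold).
#' @param seed integer seed.
#' @return numeric matrix `n_sims` x n_scalars, columns named by
#'   `scalar_id`; attribute `baseline` carries the t0 vector.
#' @export
sample_thresholds <- function(registry = default_registry(), n_sims,
                              sd_fraction = 0.1, seed = 1) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  if (sd_fraction < 0) stop("sd_fraction must be >= 0")
  sc <- registry_scalars(registry)
  set.seed(seed)
  draws <- vapply(seq_len(nrow(sc)), function(j)
    stats::rnorm(n_sims, sc$t0[j], abs(sc$t0[j]) * sd_fraction),
    numeric(n_sims))
  if (n_sims == 1L) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- sc$scalar_id
  attr(draws, "baseline") <- stats::setNames(sc$t0, sc$scalar_id)
  draws
}

#' Stack the raw inputs of sampled pixels into a single matrix
#'
#' @param stack result of [build_critical_stack()] (supplies the flat input
#'   columns).
#' @param lmi `lmdi_index` for the stratum under study (baseline labels).
#' @param sample_n cap on the number of pixel rows (default 100,000); rows
#'   are drawn without replacement, seeded. Rows with any missing input are
#'   dropped.
#' @param seed integer seed for the subsample.
#' @return list of class `lmdi_input_matrix`: `matrix` (rows x columns),
#'   `baseline_count`, `baseline_class`, `pixel_idx` (positions in the
#'   grid), `stratum_pixels` (total valid stratum pixel count),
#'   `process_ids` (available processes).
#' @export
build_input_matrix <- function(stack, lmi, sample_n = 1e5, seed = 1) {
  cols <- stack$columns
  M <- vapply(cols, function(g) as.vector(g$values),
              numeric(length(cols[[1]]$values)))
  counts <- as.vector(lmi$counts$values)
  ok <- !is.na(counts) & stats::complete.cases(M)
  idx <- which(ok)
  if (length(idx) == 0L) stop("no complete stratum pixels to sample")
  set.seed(seed)
  if (length(idx) > sample_n) idx <- sort(sample(idx, sample_n))
  structure(list(matrix = M[idx, , drop = FALSE],
                 baseline_count = counts[idx],
                 baseline_class = pmin(counts[idx], 5),
                 pixel_idx = idx,
                 stratum_pixels = sum(!is.na(counts)),
                 process_ids = names(stack$masks)),
            class = "lmdi_input_matrix")
}

# labels (classes 0..5) of every row under one threshold draw
.labels_for_draw <- function(im, registry, thresholds) {
  cols <- lapply(seq_len(ncol(im$matrix)), function(j) im$matrix[, j])
  names(cols) <- colnames(im$matrix)
  total <- numeric(nrow(im$matrix))
  for (pid in im$process_ids) {
    v <- evaluate_process(registry[[pid]], cols, thresholds)
    v[is.na(v)] <- 0   # rows are complete; NA can only arise from
    total <- total + v # or-composites whose branches are all false-ish
  }
  pmin(total, 5)
}

#' Re-classify the input matrix under every threshold draw
#'
#' @param im `lmdi_input_matrix`.
#' @param samples draw matrix from [sample_thresholds()].
#' @param registry rule registry.
#' @return list of class `lmdi_simulation`: `freq` (rows x 6 empirical
#'   class frequencies over draws), `entropy` (per-row Shannon entropy of
#'   `freq`, nats), `draw_class_counts` (n_sims x 6 pixel tallies per
#'   draw), `n_sims`.
#' @export
simulate_lmi_labels <- function(im, samples,
                                registry = default_registry()) {
  if (any(!is.finite(im$matrix))) stop("non-finite input matrix entries")
  n <- nrow(im$matrix)
  n_sims <- nrow(samples)
  freq <- matrix(0, n, 6)
  draw_counts <- matrix(0L, n_sims, 6)
  for (s in seq_len(n_sims)) {
    lab <- .labels_for_draw(im, registry, samples[s, ])
    for (k in 0:5) {
      sel <- lab == k
      freq[sel, k + 1] <- freq[sel, k + 1] + 1
      draw_counts[s, k + 1] <- sum(sel)
    }
  }
  freq <- freq / n_sims
  ent <- -rowSums(ifelse(freq > 0, freq * log(freq), 0))
  colnames(freq) <- colnames(draw_counts) <- 0:5
  structure(list(freq = freq, entropy = ent,
                 draw_class_counts = draw_counts, n_sims = n_sims),
            class = "lmdi_simulation")
}

#' Random-Forest class-probability model of threshold uncertainty
#'
#' Trains a forest on the original input values as covariates against
#' perturbed LMI class labels (one randomly chosen draw per repetition;
#' `target = "baseline"` trains on the unperturbed labels instead).
#' Probabilities, out-of-bag error and impurity importances are averaged
#' over repetitions.
#'
#' @param im `lmdi_input_matrix`.
#' @param samples draw matrix from [sample_thresholds()].
#' @param registry rule registry.
#' @param n_trees trees per forest (reference 1000; desk-scale 200).
#' @param reps repetitions (reference 20; desk-scale 5).
#' @param seed integer seed.
#' @param target `"perturbed"` or `"baseline"` labels.
#' @param mtry features per split (default floor(sqrt(p))).
#' @param min_node minimum terminal node size (1, the standard
#'   classification default; larger values prune the trees).
#' @return list of class `lmdi_uncertainty`: `prob` (rows x 6 averaged
#'   class probabilities), `predicted_class` (modal class per row),
#'   `oob_error`, `importance` (named by input column), `reps`, `im`.
#' @export
fit_rf_uncertainty <- function(im, samples, registry = default_registry(),
                               n_trees = 1000, reps = 20, seed = 1,
                               target = c("perturbed", "baseline"),
                               mtry = NULL, min_node = 1) {
  target <- match.arg(target)
  X <- im$matrix
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  set.seed(seed)
  draw_ids <- sample(nrow(samples), reps, replace = reps > nrow(samples))
  prob <- matrix(0, nrow(X), 6)
  oob <- numeric(reps)
  imp <- matrix(0, reps, p)
  single_class_seen <- FALSE
  for (r in seq_len(reps)) {
    y <- if (target == "perturbed")
      .labels_for_draw(im, registry, samples[draw_ids[r], ])
    else im$baseline_class
    if (length(unique(y)) < 2L) {
      single_class_seen <- TRUE
      prob[, unique(y) + 1] <- prob[, unique(y) + 1] + 1
      oob[r] <- 0
      next
    }
    fit <- .rf_fit_predict(X, as.integer(y), 6L, X, as.integer(n_trees),
                           as.integer(mtry), as.integer(min_node), 0L,
                           seed * 1000 + r)
    prob <- prob + fit$prob
    oob[r] <- fit$oob_error
    imp[r, ] <- fit$importance
  }
  if (single_class_seen)
    warning("single-class labels in at least one repetition: ",
            "probabilities are degenerate there, OOB error 0")
  prob <- prob / reps
  colnames(prob) <- 0:5
  structure(list(prob = prob,
                 predicted_class = max.col(prob) - 1L,
                 oob_error = mean(oob),
                 importance = stats::setNames(colMeans(imp), colnames(X)),
                 reps = reps, im = im),
            class = "lmdi_uncertainty")
}

#' Per-class probability and predicted-class grids
#'
#' Maps the sampled-row probabilities back onto the analysis grid
#' (unsampled pixels stay nodata).
#'
#' @param unc `lmdi_uncertainty`.
#' @param template any grid on the analysis geometry.
#' @return list: `prob` (list of 6 grids, classes 0..5) and `predicted`
#'   (class-code grid).
#' @export
uncertainty_grids <- function(unc, template) {
  d <- dim(template$values)[1:2]
  mk <- function(vals) {
    v <- rep(NA_real_, prod(d))
    v[unc$im$pixel_idx] <- vals
    grid_like(template, matrix(v, d[1], d[2]), nodata = -1)
  }
  list(prob = lapply(stats::setNames(1:6, 0:5), function(k)
         mk(unc$prob[, k])),
       predicted = mk(unc$predicted_class))
}

#' Class-area error ranges from the uncertainty analysis
#'
#' For each LMI class: the baseline area, the expected area under the
#' Random-Forest class probabilities (sum of per-pixel probabilities scaled
#' to the stratum), and the min-max envelope of the class area across the
#' Monte-Carlo threshold draws. The unperturbed threshold set is included
#' in the envelope as the ensemble's zero-perturbation member, so an
#' "area +/- error" report always brackets the baseline area (threshold
#' perturbation can shift class areas asymmetrically when raw-value density
#' differs on the two sides of a cut-off, which would otherwise let the
#' envelope exclude the baseline). Both constructions are labelled in the
#' output since the reporting convention leaves the range construction
#' open.
#'
#' @param unc `lmdi_uncertainty`.
#' @param sim `lmdi_simulation` on the same input matrix.
#' @param cell_size_m analysis cell size in metres.
#' @return data.frame: `class`, `baseline_km2`, `expected_km2`,
#'   `lo_km2`, `hi_km2` (draw envelope), `method` metadata column.
#' @export
class_area_error_ranges <- function(unc, sim, cell_size_m = 500) {
  im <- unc$im
  n <- nrow(im$matrix)
  scale <- im$stratum_pixels / n            # sample -> stratum inflation
  cellkm2 <- (cell_size_m / 1000)^2
  base <- vapply(0:5, function(k) sum(im$baseline_class == k), numeric(1))
  expected <- colSums(unc$prob) * scale * cellkm2
  ensemble <- rbind(sim$draw_class_counts, base)
  lo <- apply(ensemble, 2, min) * scale * cellkm2
  hi <- apply(ensemble, 2, max) * scale * cellkm2
  data.frame(class = 0:5,
             baseline_km2 = base * scale * cellkm2,
             expected_km2 = as.numeric(expected),
             lo_km2 = as.numeric(lo), hi_km2 = as.numeric(hi),
             method = "expected=RF probabilities; range=min-max over draws + baseline",
             stringsAsFactors = FALSE)
}
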