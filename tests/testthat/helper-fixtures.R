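# Shared fixtures: everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# small deterministic grid of given values
tiny_grid <- function(values, nr = NULL, nc = NULL, cell = 500, nodata = -9999) {
  if (is.null(nr)) nr <- nrow(values)
  if (!is.matrix(values)) values <- matrix(values, nr, nc)
  grid_create(values, cell_size = cell, nodata = nodata)
}

# random binary mask grid
rand_mask <- function(nr, nc, p = 0.5, seed = 1, cell = 500) {
  set.seed(seed)
  tiny_grid(matrix(rbinom(nr * nc, 1, p), nr, nc), cell = cell, nodata = 255)
}

# a small full scenario reused by several files (cached per session)
small_scenario <- local({
  cache <- new.env()
  function(seed = 17, shape = c(32, 32), ...) {
    key <- paste(seed, paste(shape, collapse = "x"), ...)
    if (is.null(cache[[key]]))
      cache[[key]] <- gen_process_inputs(
        scenario_config(shape = shape, seed = seed, ...))
    cache[[key]]
  }
})

# exact MK p-value by exhaustive permutation (oracle, n <= 8):
# two-sided p = P(|S_perm| >= |S_obs|) over all orderings of the values
mk_exact_p <- function(x) {
  n <- length(x)
  stopifnot(n <= 8)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  s_of <- function(v) {
    d <- outer(v, v, "-")
    sum(sign(d[lower.tri(d)]))
  }
  s_obs <- s_of(x)
  ss <- vapply(perms(x), s_of, numeric(1))
  mean(abs(ss) >= abs(s_obs))
}

# brute-force Jenks: best k-partition of sorted values by enumeration
jenks_exhaustive <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf; best_cuts <- NULL
  cut_sets <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(cut_sets))) {
    cuts <- cut_sets[, j]
    bounds <- c(0, cuts, n)
    tot <- 0
    for (i in seq_len(k)) tot <- tot + ssd(x[(bounds[i] + 1):bounds[i + 1]])
    if (tot < best - 1e-12) { best <- tot; best_cuts <- cuts }
  }
  list(breaks = x[best_cuts], ssd = best)
}
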