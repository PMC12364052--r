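#' Summary statistics of a germinal-center sample
#'
#' Five pooled empirical distributions over a collection of sampled GCs:
#' * `abundance`: copies per distinct sampled sequence (within each GC);
#' * `affinity`: sampled-leaf affinities;
#' * `n_mutations`: nucleotide differences of each sampled sequence from
#'   the naive sequence;
#' * `root_to_tip`: mutation events accumulated along each sampled leaf's
#'   lineage (root-to-tip divergence in substitution events);
#' * `leaves_per_gc`: sampled leaves per GC.
#'
#' @param sample A `gc_sample` (from [simulate_gcs()]) or a list of
#'   [run_gc()] results.
#' @return An object of class `gc_summary_stats` (a named list of numeric
#'   vectors).
#' @export
summary_statistics <- function(sample) {
  if (inherits(sample, "simulated_gc")) sample <- list(sample)
  if (!length(sample)) stop("empty GC sample")
  stopifnot(all(vapply(sample, inherits, logical(1), "simulated_gc")))
  abund <- unlist(lapply(sample, function(s)
    as.integer(table(unname(s$sequences)))))
  structure(list(
    abundance = abund,
    affinity = unlist(lapply(sample, function(s)
      s$tree$affinity[seq_len(s$tree$n_tip)])),
    n_mutations = unlist(lapply(sample, function(s) s$n_mutations)),
    root_to_tip = unlist(lapply(sample, function(s) s$path_mutations)),
    leaves_per_gc = vapply(sample, function(s) s$tree$n_tip, numeric(1))),
    class = "gc_summary_stats")
}

#' @export
print.gc_summary_stats <- function(x, ...) {
  cat("<gc_summary_stats>\n")
  for (nm in names(x))
    cat(sprintf("  %-14s n=%5d  mean=%8.3g  sd=%8.3g\n", nm,
                length(x[[nm]]), mean(x[[nm]]), sd(x[[nm]])))
  invisible(x)
}

#' 1-Wasserstein distance between two empirical samples
#'
#' The area between the two empirical CDFs.
#'
#' @param x,y Numeric samples.
#' @return Non-negative scalar.
#' @export
wasserstein1 <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  z <- sort(unique(c(x, y)))
  if (length(z) == 1L) return(0)
  Fx <- ecdf_at(x, z); Fy <- ecdf_at(y, z)
  sum(abs(Fx - Fy)[-length(z)] * diff(z))
}

ecdf_at <- function(x, z) {
  findInterval(z, sort(x)) / length(x)
}

#' Distance between two summary-statistic sets
#'
#' Mean, over the five statistics, of the 1-Wasserstein distance between
#' the pooled empirical distributions, each statistic first divided by its
#' pooled standard deviation across both samples (so statistics on
#' different scales contribute comparably). A statistic with zero pooled
#' variance is skipped with a warning. Symmetric, zero on identical inputs;
#' the per-statistic scaling means the triangle inequality is not
#' guaranteed.
#'
#' @param a,b [summary_statistics()] results.
#' @return Non-negative scalar distance.
#' @export
stats_distance <- function(a, b) {
  stopifnot(inherits(a, "gc_summary_stats"), inherits(b, "gc_summary_stats"))
  vals <- numeric(0)
  for (nm in names(a)) {
    s <- sd(c(a[[nm]], b[[nm]]))
    if (!is.finite(s) || s == 0) {
      warning("statistic '", nm, "' has zero pooled variance; skipped")
      next
    }
    vals <- c(vals, wasserstein1(a[[nm]] / s, b[[nm]] / s))
  }
  if (!length(vals)) stop("no statistic with positive variance")
  mean(vals)
}

#' Medoid response curve
#'
#' Among a set of predicted response curves, picks the member minimizing
#' the sum over all other curves of the sum of squared pointwise
#' differences on a uniform affinity grid over `domain` (first index wins
#' ties). The medoid is always a member of the set, never an average.
#'
#' @param curves A list of [response_params()], or a data frame with
#'   columns `xc, xh, yc, yh` (one curve per row).
#' @param domain Affinity interval, default `c(-2.5, 3)`.
#' @param n Grid size (default 512).
#' @return List with `index` and `params` (a [response_params()]).
#' @export
medoid_curve <- function(curves, domain = c(-2.5, 3), n = 512L) {
  if (is.data.frame(curves))
    curves <- lapply(seq_len(nrow(curves)), function(i)
      response_params(curves$xc[i], curves$xh[i], curves$yc[i],
                      curves$yh[i]))
  if (!length(curves)) stop("empty curve list")
  stopifnot(all(vapply(curves, inherits, logical(1), "response_params")))
  C <- vapply(curves, response_curve_on_grid, numeric(n), domain = domain,
              n = n)
  G <- crossprod(C) # k x k of inner products
  sq <- diag(G)
  D <- outer(sq, sq, "+") - 2 * G # pairwise sums of squared differences
  tot <- rowSums(D)
  i <- which.min(tot)
  list(index = i, params = curves[[i]])
}

#' The 3-D non-sigmoid scan grid
#'
#' @param capacity,init_population,death_rate Grid values; defaults are the
#'   4 x 3 x 4 = 48-point scan: capacities (500, 750, 1000, 2000), initial
#'   populations (8, 32, 128), death rates (0.05, 0.1, 0.2, 0.4).
#' @return Data frame of grid points.
#' @export
nonsigmoid_grid <- function(capacity = c(500, 750, 1000, 2000),
                            init_population = c(8L, 32L, 128L),
                            death_rate = c(0.05, 0.1, 0.2, 0.4)) {
  expand.grid(capacity = capacity, init_population = init_population,
              death_rate = death_rate, KEEP.OUT.ATTRS = FALSE)
}

#' Scan non-sigmoid parameters by summary-statistic matching
#'
#' For every grid point (carrying capacity, initial population, death
#' rate): predict per-GC sigmoid parameters on the target trees with the
#' grid values as auxiliary inputs, take the medoid curve, simulate a mimic
#' sample with (medoid sigmoid + grid non-sigmoid) parameters, and measure
#' the summary-statistic distance to the target sample. The grid point with
#' the smallest distance carries the best inferred values.
#'
#' @param target A `gc_sample` whose parameters are sought.
#' @param model A trained `gcnn` with a stored scaler and aux inputs.
#' @param grid Data frame with columns `capacity`, `init_population`,
#'   `death_rate` (default [nonsigmoid_grid()]).
#' @param base_config A [gc_config()] providing everything else for the
#'   mimic simulations (naive sequence, DMS, SHM model, sampling time,
#'   sample-size range, multiplier).
#' @param n_sim Mimic GCs per grid point (120 at full budget; reduce for
#'   quick scans).
#' @param verbose Progress messages?
#' @return A `gc_scan`: the grid with `distance`, `rank`, and the medoid
#'   sigmoid parameters per point; attribute `"best"` is the top-ranked
#'   row.
#' @export
scan_nonsigmoid <- function(target, model, grid = nonsigmoid_grid(),
                            base_config, n_sim = 120L, verbose = FALSE) {
  stopifnot(inherits(model, "gcnn"), model$trained, model$aux_inputs,
            inherits(base_config, "gc_config"))
  if (!all(c("capacity", "init_population", "death_rate") %in% names(grid)))
    stop("grid needs capacity, init_population, death_rate columns")
  enc <- lapply(target, function(s) encode_tree(scale_tree(s$tree),
                                                model$arch$width))
  target_stats <- summary_statistics(target)
  k <- length(enc)
  res <- grid
  res$distance <- NA_real_
  res$xc <- res$xh <- res$yc <- res$yh <- NA_real_
  # per-point seeds derived from the point's values (not its position), so
  # the ranking is invariant to grid ordering
  base_seed <- sample.int(.Machine$integer.max, 1L)
  point_seed <- function(i) {
    v <- as.numeric(grid[i, c("capacity", "init_population", "death_rate")])
    (base_seed + as.integer(sum(v * c(7, 7919, 104729)) %% 1e9)) %% 2147483647L
  }
  for (i in seq_len(nrow(grid))) {
    auxraw <- matrix(rep(as.numeric(grid[i, c("capacity", "init_population",
                                              "death_rate")]), each = k),
                     nrow = 3L, byrow = TRUE)
    pred <- predict(model, enc, aux = auxraw)
    med <- medoid_curve(pred, domain = model$domain)
    res[i, c("xc", "xh", "yc", "yh")] <-
      unlist(med$params[c("xc", "xh", "yc", "yh")])
    d <- tryCatch({
      cfg <- base_config
      cfg$response <- med$params
      cfg$capacity <- grid$capacity[i]
      cfg$init_population <- as.integer(grid$init_population[i])
      cfg$death_rate_functional <- grid$death_rate[i]
      set.seed(point_seed(i))
      mimic <- simulate_gcs(cfg, n_sim)
      suppressWarnings(
        stats_distance(target_stats, summary_statistics(mimic)))
    }, error = function(e) Inf)
    res$distance[i] <- d
    if (verbose)
      message(sprintf("grid %2d/%d: N0=%g init=%g mu=%g -> %.4f", i,
                      nrow(grid), grid$capacity[i], grid$init_population[i],
                      grid$death_rate[i], d))
  }
  res$rank <- rank(res$distance, ties.method = "first")
  res <- res[, c("capacity", "init_population", "death_rate", "distance",
                 "rank", "xc", "xh", "yc", "yh")]
  structure(tibble::as_tibble(res), class = c("gc_scan", class(tibble::tibble())),
            best = res[res$rank == 1L, ])
}

#' @export
print.gc_scan <- function(x, ...) {
  best <- attr(x, "best")
  cat(sprintf(
    "<gc_scan> %d grid points; best: capacity=%g, init=%g, death=%g (distance %.4f)\n",
    nrow(x), best$capacity, best$init_population, best$death_rate,
    best$distance))
  NextMethod()
}
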