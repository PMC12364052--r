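#' Germinal-center simulation configuration
#'
#' Bundles everything one simulated GC needs: the naive sequence, the DMS
#' affinity map, the 5-mer mutation model, the sigmoid response parameters,
#' and the population-dynamics settings. Defaults are the data-mimic
#' operating point: carrying capacity 500 with birth-rate modulation,
#' initial population 128, sampling at 20 days with 60-95 sequences,
#' functional death rate 0.2/day, stop-codon death rate 10/day, mutability
#' multiplier 0.5, and sigmoid (xc, xh, yc, yh) = (1.6, 2, 18.2, 0.4).
#'
#' @param naive_seq In-frame functional nucleotide string.
#' @param dms A [dms_table()].
#' @param shm A [mutation_model()].
#' @param response A [response_params()].
#' @param capacity Carrying capacity N0 (cells).
#' @param capacity_method One of `"birth"` (logistic modulation of birth
#'   rates, the default used for all headline dynamics), `"death"`, or
#'   `"hard"` (kill a random cell on overflow).
#' @param init_population Cells present at time 0 (created by zero-time
#'   binary expansion of the naive cell).
#' @param t_sample Sampling time T (days).
#' @param sample_size Either a single integer or an inclusive integer range
#'   `c(lo, hi)` from which each GC's sample size is drawn uniformly.
#' @param death_rate_functional,death_rate_stops Death rates (1/day) for
#'   functional and stop-codon-bearing cells.
#' @param mutability_multiplier Global SHM rate multiplier (overrides the
#'   model's stored multiplier).
#' @param min_viable Minimum living cells required at `t_sample` (otherwise
#'   the run is discarded and retried).
#' @param max_tries Retry budget before failing loudly.
#' @param zero_birth_nonfunctional If `TRUE`, nonfunctional cells get birth
#'   rate 0 instead of the response-function rate at their frozen affinity.
#' @return An object of class `gc_config`.
#' @export
gc_config <- function(naive_seq, dms, shm,
                      response = response_params(1.6, 2, 18.2, 0.4),
                      capacity = 500, capacity_method = c("birth", "death", "hard"),
                      init_population = 128L, t_sample = 20,
                      sample_size = c(60L, 95L),
                      death_rate_functional = 0.2, death_rate_stops = 10,
                      mutability_multiplier = 0.5,
                      min_viable = 10L, max_tries = 1000L,
                      zero_birth_nonfunctional = FALSE) {
  capacity_method <- match.arg(capacity_method)
  stopifnot(inherits(dms, "dms_table"), inherits(shm, "mutation_model"),
            inherits(response, "response_params"))
  naive_seq <- validate_nt(naive_seq)
  if (is_nonfunctional(naive_seq)) stop("naive sequence must be functional")
  if (capacity < init_population || init_population < 1L)
    stop("need capacity >= init_population >= 1")
  if (t_sample <= 0) stop("t_sample must be > 0")
  if (length(sample_size) == 1L) sample_size <- rep(sample_size, 2L)
  if (any(sample_size < 1L) || sample_size[1] > sample_size[2])
    stop("sample_size must be a positive integer or c(lo, hi) range")
  structure(list(
    naive_seq = naive_seq, dms = dms, shm = shm, response = response,
    capacity = capacity, capacity_method = capacity_method,
    init_population = as.integer(init_population), t_sample = t_sample,
    sample_size = as.integer(sample_size),
    death_rate_functional = death_rate_functional,
    death_rate_stops = death_rate_stops,
    mutability_multiplier = mutability_multiplier,
    min_viable = as.integer(min_viable), max_tries = as.integer(max_tries),
    zero_birth_nonfunctional = isTRUE(zero_birth_nonfunctional)),
    class = "gc_config")
}

#' @export
print.gc_config <- function(x, ...) {
  cat(sprintf(
    "<gc_config> N0=%g (%s), init=%d, T=%g d, sample %d-%d, mu_f=%g, mu_s=%g, mult=%g\n",
    x$capacity, x$capacity_method, x$init_population, x$t_sample,
    x$sample_size[1], x$sample_size[2], x$death_rate_functional,
    x$death_rate_stops, x$mutability_multiplier))
  print(x$response)
  invisible(x)
}

codon_aa_lookup <- function() {
  if (is.null(.cache$codon_aa)) {
    map <- get_codon_map()
    idx <- match(map, AA20)
    idx[is.na(idx)] <- 0L # stops
    .cache$codon_aa <- as.integer(idx - 1L)
  }
  .cache$codon_aa
}

shm_for_cpp <- function(model) {
  bt <- model$boundary
  list(full = model$mutability, L2 = bt$L2$mut, L1 = bt$L1$mut,
       R1 = bt$R1$mut, R2 = bt$R2$mut,
       s_full = model$substitution, s_L2 = bt$L2$sub, s_L1 = bt$L1$sub,
       s_R1 = bt$R1$sub, s_R2 = bt$R2$sub)
}

cap_method_code <- function(method) {
  match(method, c("birth", "death", "hard")) - 1L
}

#' Simulate one germinal center
#'
#' Runs the birth-death-mutation process to `t_sample`, retrying (up to
#' `max_tries`) whenever the population goes extinct or has fewer than
#' `min_viable` living cells at sampling time, then samples cells uniformly
#' without replacement and returns the induced sampled tree (sampled leaves
#' plus their ancestors, unifurcations collapsed) with per-node times and
#' affinities.
#'
#' @param config A [gc_config()].
#' @param record_truth Keep the full event tree (all nodes ever created)?
#' @param record_trajectory Keep the (time, living-cell-count) trace?
#' @return An object of class `simulated_gc`: `tree` (an
#'   [annotated_tree()]), `sequences` (sampled leaf sequences, named by tip
#'   label), `n_mutations` (leaf Hamming distances to naive),
#'   `path_mutations` (mutation events on each leaf's root path), `living`
#'   (data frame snapshot of the final population), `params`, `config`,
#'   `n_tries`, and optionally `truth` / `trajectory`.
#' @export
run_gc <- function(config, record_truth = FALSE, record_trajectory = FALSE) {
  stopifnot(inherits(config, "gc_config"))
  k <- if (config$sample_size[1] == config$sample_size[2])
    config$sample_size[1]
  else sample(config$sample_size[1]:config$sample_size[2], 1L)
  res <- sim_gc_cpp(
    naive = seq_to_int(config$naive_seq),
    codon_aa = codon_aa_lookup(),
    dms_eff = config$dms$effects,
    shm_model = shm_for_cpp(config$shm),
    multiplier = config$mutability_multiplier,
    resp = unlist(config$response[c("xc", "xh", "yc", "yh")]),
    N0 = config$capacity,
    cap_method = cap_method_code(config$capacity_method),
    init_pop = config$init_population, T = config$t_sample,
    mu_f = config$death_rate_functional, mu_s = config$death_rate_stops,
    min_viable = config$min_viable, max_tries = config$max_tries,
    sample_size = k,
    zero_birth_nonfunc = config$zero_birth_nonfunctional,
    record_truth = record_truth, record_trajectory = record_trajectory)
  tr <- res$tree
  if (length(tr$edge_from) < 1L)
    stop("degenerate sampled tree (no edges); increase sample size or events")
  tree <- annotated_tree(cbind(tr$edge_from, tr$edge_to), tr$edge_length,
                         tr$n_tip, tr$node_affinity,
                         node_time = tr$node_time)
  seqs <- setNames(as.character(res$sequences), tree$tip_label)
  out <- structure(list(
    tree = tree, sequences = seqs,
    n_mutations = as.integer(res$n_mutations),
    path_mutations = as.integer(res$path_mutations),
    living = data.frame(affinity = res$living_affinity,
                        lambda = res$living_lambda, mu = res$living_mu,
                        functional = res$living_functional),
    params = config$response, config = config,
    n_tries = res$n_tries), class = "simulated_gc")
  if (record_trajectory) out$trajectory <- res$trajectory
  if (record_truth)
    out$truth <- parent_to_tree(res$truth$parent, res$truth$time,
                                res$truth$affinity)
  out
}

#' @export
print.simulated_gc <- function(x, ...) {
  cat(sprintf(
    "<simulated_gc> %d sampled leaves (of %d living at T=%g d), %d tries, mean leaf affinity %.3g\n",
    x$tree$n_tip, nrow(x$living), x$config$t_sample, x$n_tries,
    mean(x$tree$affinity[seq_len(x$tree$n_tip)])))
  invisible(x)
}

#' Simulate a sample of germinal centers
#'
#' @param config A [gc_config()] shared by all GCs (each GC redraws its
#'   sample size from the configured range).
#' @param n_gcs Number of GCs.
#' @param ... Passed to [run_gc()].
#' @return A list of [run_gc()] results with class `gc_sample`.
#' @export
simulate_gcs <- function(config, n_gcs, ...) {
  out <- lapply(seq_len(n_gcs), function(i) run_gc(config, ...))
  structure(out, class = "gc_sample", config = config)
}

#' Carrying-capacity modulation factor
#'
#' `m = (sum(mu) / sum(lambda))^(N / N0)` under birth modulation (all
#' per-cell birth rates are multiplied by `m`, driving the process to
#' criticality at `N = N0`); the reciprocal base under death modulation;
#' and 1 under the hard method (which instead kills a random cell whenever a
#' birth exceeds the capacity).
#'
#' @param lambda Per-cell intrinsic birth rates of the living population.
#' @param mu Per-cell death rates.
#' @param capacity Carrying capacity N0.
#' @param method `"birth"`, `"death"`, or `"hard"`.
#' @return The dimensionless factor `m`.
#' @export
capacity_factor <- function(lambda, mu, capacity,
                            method = c("birth", "death", "hard")) {
  method <- match.arg(method)
  N <- length(lambda)
  stopifnot(N >= 1L, length(mu) == N, capacity > 0)
  if (method == "hard") return(1)
  num <- if (method == "birth") sum(mu) else sum(lambda)
  den <- if (method == "birth") sum(lambda) else sum(mu)
  if (den <= 0) stop("capacity_factor: zero denominator rate sum")
  (num / den)^(N / capacity)
}

#' Effective (net) birth rate
#'
#' `m * lambda_i - mu_i`: the intrinsic response-function birth rate scaled
#' by the current capacity modulation, minus the cell's death rate. At
#' carrying capacity the population mean of this quantity is 0 (the process
#' is critical there).
#'
#' @inheritParams capacity_factor
#' @return Numeric vector of per-cell net rates (1/day).
#' @export
effective_birth_rate <- function(lambda, mu, capacity,
                                 method = c("birth", "death", "hard")) {
  m <- capacity_factor(lambda, mu, capacity, method)
  m * lambda - mu
}

#' Effective birth rates of a simulated GC's final population
#'
#' @param sim A [run_gc()] result.
#' @return Data frame with `affinity`, `effective_rate`, and `intrinsic_rate`
#'   for every cell living at sampling time.
#' @export
effective_birth_rates <- function(sim) {
  stopifnot(inherits(sim, "simulated_gc"))
  eff <- effective_birth_rate(sim$living$lambda, sim$living$mu,
                              sim$config$capacity,
                              sim$config$capacity_method)
  data.frame(affinity = sim$living$affinity, effective_rate = eff,
             intrinsic_rate = sim$living$lambda)
}

#' Initial population by zero-time binary expansion
#'
#' The naive cell splits repeatedly (one cell at a time, oldest first) with
#' no mutation and no time passage until `n_init` identical cells exist.
#'
#' @param naive_seq Naive nucleotide sequence.
#' @param n_init Number of initial cells (>= 1; need not be a power of 2).
#' @return A `gc_state` list: `cells` (data frame with `id`, `sequence`,
#'   `affinity`, `functional`, `birth_time`, `parent`), `tree_parent`
#'   (0-based parent array over all nodes, -1 for the root), and `time`.
#' @export
initialize_population <- function(naive_seq, n_init) {
  naive_seq <- validate_nt(naive_seq)
  stopifnot(n_init >= 1L)
  parent <- c(-1L)
  cells <- 0L # node ids (0-based) of living cells
  split_at <- 1L
  while (length(cells) < n_init) {
    v <- cells[split_at]
    parent <- c(parent, v, v)
    c1 <- length(parent) - 2L; c2 <- length(parent) - 1L
    cells[split_at] <- c1
    cells <- c(cells, c2)
    split_at <- split_at + 1L
  }
  list(cells = data.frame(
         id = cells, sequence = naive_seq, affinity = 0, functional = TRUE,
         birth_time = 0, parent = parent[cells + 1L]),
       tree_parent = parent, time = 0)
}

#' Draw the next event for a small explicit population
#'
#' Reference-path event draw used to validate the simulation core: given the
#' living cells' affinities and sequences, draws the next
#' (event type, cell, waiting time) either by per-cell first-reaction
#' competition (independent exponential clocks for every cell-event pair,
#' minimum wins) or by the direct construction (one total-rate exponential
#' plus a categorical draw). The two are distribution-identical.
#'
#' @param cells Data frame with columns `sequence`, `affinity`, `functional`.
#' @param config A [gc_config()] supplying rates and the capacity rule.
#' @param method `"first-reaction"` or `"direct"`.
#' @return List with `type` (`"birth"`, `"death"`, `"mutation"`), `cell`
#'   (row index), and `wait` (days).
#' @export
draw_event <- function(cells, config, method = c("first-reaction", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "gc_config"), nrow(cells) >= 1L)
  lam <- sigmoid_response(cells$affinity, config$response)
  if (config$zero_birth_nonfunctional) lam[!cells$functional] <- 0
  mu <- ifelse(cells$functional, config$death_rate_functional,
               config$death_rate_stops)
  mut <- config$mutability_multiplier *
    vapply(cells$sequence, function(s) sum(position_mutability(s, config$shm)),
           numeric(1))
  m <- capacity_factor(lam, mu, config$capacity, config$capacity_method)
  if (config$capacity_method == "birth") lam <- m * lam
  if (config$capacity_method == "death") mu <- m * mu
  rates <- cbind(birth = lam, death = mu, mutation = mut)
  if (all(rates <= 0)) stop("all event rates are zero")
  if (method == "first-reaction") {
    waits <- matrix(Inf, nrow(rates), 3L)
    pos <- rates > 0
    waits[pos] <- rexp(sum(pos), rate = rates[pos])
    j <- which.min(waits)
    cell <- (j - 1L) %% nrow(rates) + 1L
    type <- colnames(rates)[(j - 1L) %/% nrow(rates) + 1L]
    list(type = type, cell = cell, wait = min(waits))
  } else {
    R <- sum(rates)
    wait <- rexp(1L, rate = R)
    j <- sample.int(length(rates), 1L, prob = as.vector(rates))
    cell <- (j - 1L) %% nrow(rates) + 1L
    type <- colnames(rates)[(j - 1L) %/% nrow(rates) + 1L]
    list(type = type, cell = cell, wait = wait)
  }
}
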