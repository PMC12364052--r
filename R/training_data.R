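#' Simulate and encode a network training set
#'
#' Each germinal center gets its own parameter draw: sigmoid parameters from
#' [sample_response_params()] under the naive-rate constraint, and the
#' non-sigmoid parameters uniformly from their training ranges (carrying
#' capacity \[500, 2000\], sampling time \[10, 35\] days, initial population
#' \[8, 128\], functional death rate \[0.05, 0.5\], sample size \[50, 130\],
#' mutability multiplier 0.68). Runs whose population dies out are retried;
#' a parameter set that keeps failing is redrawn, so the emitted set is
#' conditioned on viability, exactly as a discard-and-retry pipeline
#' produces.
#'
#' @param n_gcs Number of GCs to simulate.
#' @param naive_seq,dms,shm Shared inputs (see [gc_config()]).
#' @param bounds Sigmoid [param_bounds()].
#' @param capacity,t_sample,init_population,death_rate,sample_size Ranges
#'   `c(lo, hi)` for the non-sigmoid draws.
#' @param mutability_multiplier SHM multiplier (default 0.68).
#' @param width Encoding width (default 200).
#' @param tries_per_set [run_gc()] retries before redrawing parameters.
#' @param verbose Report progress every 500 GCs?
#' @return A `gc_training_set`: `encodings` (list of [encode_tree()]
#'   matrices of unit-depth-scaled sampled trees), `truth` (4 x n matrix of
#'   sigmoid parameters), `aux` (n x 3 matrix: capacity, init population,
#'   death rate), and `meta` (per-GC data frame).
#' @export
make_training_set <- function(n_gcs, naive_seq, dms, shm,
                              bounds = param_bounds(),
                              capacity = c(500, 2000), t_sample = c(10, 35),
                              init_population = c(8L, 128L),
                              death_rate = c(0.05, 0.5),
                              sample_size = c(50L, 130L),
                              mutability_multiplier = 0.68, width = 200L,
                              tries_per_set = 10L, verbose = FALSE) {
  encodings <- vector("list", n_gcs)
  truth <- matrix(NA_real_, 4L, n_gcs,
                  dimnames = list(c("xc", "xh", "yc", "yh"), NULL))
  aux <- matrix(NA_real_, n_gcs, 3L,
                dimnames = list(NULL, c("capacity", "init_population",
                                        "death_rate")))
  meta <- vector("list", n_gcs)
  for (i in seq_len(n_gcs)) {
    sim <- NULL
    for (attempt in 1:50) {
      p <- sample_response_params(bounds)
      N0 <- runif(1L, capacity[1], capacity[2])
      ip <- sample(init_population[1]:init_population[2], 1L)
      Tt <- runif(1L, t_sample[1], t_sample[2])
      mu <- runif(1L, death_rate[1], death_rate[2])
      cfg <- gc_config(naive_seq, dms, shm, response = p,
                       capacity = N0, init_population = ip, t_sample = Tt,
                       sample_size = sample_size,
                       death_rate_functional = mu,
                       mutability_multiplier = mutability_multiplier,
                       max_tries = tries_per_set)
      sim <- tryCatch(run_gc(cfg), error = function(e) NULL)
      if (!is.null(sim)) break
    }
    if (is.null(sim))
      stop("could not generate a viable GC after 50 parameter redraws")
    encodings[[i]] <- encode_tree(scale_tree(sim$tree), width)
    truth[, i] <- unlist(p[c("xc", "xh", "yc", "yh")])
    aux[i, ] <- c(N0, ip, mu)
    meta[[i]] <- data.frame(capacity = N0, init_population = ip,
                            t_sample = Tt, death_rate = mu,
                            n_sampled = sim$tree$n_tip,
                            n_living = nrow(sim$living),
                            xc = p$xc, xh = p$xh, yc = p$yc, yh = p$yh)
    if (verbose && i %% 500L == 0L)
      message("simulated ", i, " / ", n_gcs, " GCs")
  }
  structure(list(encodings = encodings, truth = truth, aux = aux,
                 meta = do.call(rbind, meta), width = as.integer(width)),
            class = "gc_training_set")
}

#' @export
print.gc_training_set <- function(x, ...) {
  cat(sprintf("<gc_training_set> %d encoded GCs (width %d)\n",
              length(x$encodings), x$width))
  invisible(x)
}

#' Standardize a training set and assemble network inputs
#'
#' Fits the feature scaler on the whole set, standardizes encodings and
#' auxiliary values, and flattens the encodings into the
#' `(4 * width) x n` input matrix the network consumes.
#'
#' @param ts A [make_training_set()] result.
#' @return A list of class `gc_training_data`: `X`, `truth`, `aux`
#'   (`3 x n`, standardized), and `scaler`.
#' @export
prepare_training_data <- function(ts) {
  stopifnot(inherits(ts, "gc_training_set"))
  std <- standardize_features(ts$encodings, ts$aux)
  X <- vapply(std$encodings, as.vector, numeric(4L * ts$width))
  structure(list(X = X, truth = ts$truth, aux = t(std$aux),
                 scaler = std$scaler), class = "gc_training_data")
}

#' Fit the sigmoid (or per-bin) response model to a training set
#'
#' Convenience wrapper: standardizes, builds the network, trains it, and
#' stores the scaler with the model.
#'
#' @param ts A [make_training_set()] result.
#' @param cfg A [train_config()].
#' @param per_bin Train the per-bin variant instead of the sigmoid model?
#' @param aux_inputs Feed non-sigmoid values into the dense stack?
#' @param verbose Print per-epoch losses?
#' @return A trained `gcnn` with attribute `data` (the prepared
#'   `gc_training_data`).
#' @export
fit_response_model <- function(ts, cfg = train_config(), per_bin = FALSE,
                               aux_inputs = TRUE, verbose = FALSE) {
  data <- prepare_training_data(ts)
  net <- build_network(width = ts$width, aux_inputs = aux_inputs,
                       per_bin = per_bin)
  net <- train_network(net, data$X, data$truth,
                       if (aux_inputs) data$aux, cfg = cfg,
                       scaler = data$scaler, verbose = verbose)
  attr(net, "data") <- data
  net
}

#' Mean curve-difference loss of a model on a subset of trees
#'
#' @param net A trained `gcnn`.
#' @param data A [prepare_training_data()] result.
#' @param subset Tree indices (default the model's held-out test split).
#' @return Mean single-GC curve-difference loss.
#' @export
mean_curve_loss <- function(net, data, subset = net$splits$test) {
  stopifnot(inherits(net, "gcnn"), net$trained)
  pred <- predict(net, data$X[, subset, drop = FALSE],
                  aux = if (net$aux_inputs) data$aux[, subset, drop = FALSE])
  truth <- data$truth[, subset, drop = FALSE]
  if (net$per_bin) {
    mean(vapply(seq_along(subset), function(i) {
      ft <- sigmoid_curves(truth[, i, drop = FALSE], net$bin_centers)
      w <- trapezoid_weights(length(net$bin_centers), range(net$bin_centers))
      sum(w * abs(ft - pred[i, ])) / sum(w * ft)
    }, numeric(1)))
  } else {
    mean(vapply(seq_along(subset), function(i) {
      curve_difference_loss(
        response_params(truth["xc", i], truth["xh", i], truth["yc", i],
                        truth["yh", i]),
        response_params(pred$xc[i], pred$xh[i], pred$yc[i], pred$yh[i]))
    }, numeric(1)))
  }
}
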