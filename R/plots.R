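#' Plot predicted response curves
#'
#' Draws each predicted sigmoid response curve, optionally highlighting the
#' medoid and overlaying a true curve.
#'
#' @param pred Data frame with columns `xc, xh, yc, yh` (one curve per GC).
#' @param truth Optional [response_params()] to overlay.
#' @param medoid Show the medoid curve? (default TRUE)
#' @param domain Affinity interval, default `c(-2.5, 3)`.
#' @return A ggplot object.
#' @export
plot_response_curves <- function(pred, truth = NULL, medoid = TRUE,
                                 domain = c(-2.5, 3)) {
  g <- seq(domain[1], domain[2], length.out = 200L)
  long <- do.call(rbind, lapply(seq_len(nrow(pred)), function(i) {
    p <- response_params(pred$xc[i], pred$xh[i], pred$yc[i], pred$yh[i])
    data.frame(gc = i, affinity = g, rate = sigmoid_response(g, p))
  }))
  pl <- ggplot2::ggplot(long, ggplot2::aes(.data$affinity, .data$rate,
                                           group = .data$gc)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3, colour = "grey40") +
    ggplot2::labs(x = "affinity  -log10(KD / KD_naive)",
                  y = "intrinsic birth rate (1/day)") +
    ggplot2::theme_minimal()
  if (medoid && nrow(pred) > 1L) {
    med <- medoid_curve(pred, domain = domain)
    md <- data.frame(affinity = g,
                     rate = sigmoid_response(g, med$params))
    pl <- pl + ggplot2::geom_line(
      data = md, ggplot2::aes(.data$affinity, .data$rate),
      inherit.aes = FALSE, colour = "darkorange", linewidth = 1)
  }
  if (!is.null(truth)) {
    td <- data.frame(affinity = g, rate = sigmoid_response(g, truth))
    pl <- pl + ggplot2::geom_line(
      data = td, ggplot2::aes(.data$affinity, .data$rate),
      inherit.aes = FALSE, colour = "forestgreen", linewidth = 1,
      linetype = "dashed")
  }
  pl
}

#' Plot a simulated GC's population trajectory
#'
#' Requires `run_gc(..., record_trajectory = TRUE)`. The carrying capacity
#' is shown as a dashed line.
#'
#' @param sim A [run_gc()] result with a recorded trajectory.
#' @return A ggplot object.
#' @export
plot_population <- function(sim) {
  stopifnot(inherits(sim, "simulated_gc"))
  if (is.null(sim$trajectory))
    stop("run_gc must be called with record_trajectory = TRUE")
  ggplot2::ggplot(sim$trajectory, ggplot2::aes(.data$time, .data$n)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = sim$config$capacity,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time (days)", y = "living cells") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot training history
#'
#' @param object A trained `gcnn`.
#' @param ... Unused.
#' @return A ggplot of train and validation loss per epoch.
#' @export
autoplot.gcnn <- function(object, ...) {
  stopifnot(object$trained)
  h <- object$history
  long <- rbind(data.frame(epoch = h$epoch, loss = h$train_loss,
                           split = "train"),
                data.frame(epoch = h$epoch, loss = h$val_loss,
                           split = "validation"))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "curve-difference loss") +
    ggplot2::theme_minimal()
}

#' Plot scan distances over the non-sigmoid grid
#'
#' @param object A `gc_scan` result.
#' @param ... Unused.
#' @return A ggplot faceted by death rate.
#' @export
autoplot.gc_scan <- function(object, ...) {
  df <- as.data.frame(object)
  df$init_population <- factor(df$init_population)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$capacity),
                                   .data$distance,
                                   colour = .data$init_population,
                                   group = .data$init_population)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~death_rate, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "carrying capacity",
                  y = "summary-statistic distance") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL

#' Tidy a trained model's history
#'
#' @param x A trained `gcnn`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.gcnn <- function(x, ...) {
  stopifnot(x$trained)
  tibble::as_tibble(x$history)
}

#' One-row model summary
#'
#' @param x A trained `gcnn`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, epochs, final train and
#'   validation loss.
#' @export
glance.gcnn <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_parameters = sum(network_param_counts(x)$n_params),
    epochs = if (is.null(h)) 0L else nrow(h),
    train_loss = if (is.null(h)) NA_real_ else h$train_loss[nrow(h)],
    val_loss = if (is.null(h)) NA_real_ else h$val_loss[nrow(h)],
    per_bin = x$per_bin)
}

#' Tidy a non-sigmoid scan
#'
#' @param x A `gc_scan`.
#' @param ... Unused.
#' @return The scan tibble ordered by rank.
#' @export
tidy.gc_scan <- function(x, ...) {
  tibble::as_tibble(x[order(x$rank), ])
}

#' One-row scan summary (the best grid point)
#'
#' @param x A `gc_scan`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.gc_scan <- function(x, ...) {
  tibble::as_tibble(attr(x, "best"))
}
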