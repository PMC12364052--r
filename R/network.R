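#' Clip bounds applied to network outputs
#'
#' Hard clamp applied to the predicted sigmoid parameters during training
#' and prediction; somewhat wider than the simulation bounds:
#' `xc` in \[0.001, 3.5\], `xh` in \[-1.5, 5\], `yc` in \[0.1, 65\],
#' `yh` in \[0, 10\].
#'
#' @return A 4 x 2 matrix of (min, max) rows named by parameter.
#' @export
clip_bounds <- function() {
  matrix(c(0.001, 3.5, -1.5, 5, 0.1, 65, 0, 10), nrow = 4L, byrow = TRUE,
         dimnames = list(c("xc", "xh", "yc", "yh"), c("min", "max")))
}

#' Clamp raw network outputs to the clip bounds
#'
#' @param raw Numeric matrix, outputs x observations (or a vector for one
#'   observation).
#' @param bounds Matrix of (min, max) rows, one per output; default
#'   [clip_bounds()].
#' @return Clamped values, same shape. Gradients are passed straight
#'   through during training.
#' @export
clip_params <- function(raw, bounds = clip_bounds()) {
  v <- is.null(dim(raw))
  raw <- as.matrix(raw)
  out <- pmin(pmax(raw, bounds[, 1]), bounds[, 2])
  if (v) drop(out) else out
}

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}
# derivative computed from the activation: 1 where x >= 0, act + 1 below
elu_prime_act <- function(a) {
  d <- a + 1
  d[d > 1] <- 1
  d
}

glorot <- function(nout, nin) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nout * nin, -lim, lim), nout, nin)
}

#' Build the tree-encoding convolutional network
#'
#' The fixed architecture: two 1D convolutions (25 filters, kernel 4), max
#' pooling (size 2, stride 2), a third convolution (40 filters, kernel 4),
#' global average pooling, then dense layers of 48, 32, 16, 8 units and a
#' linear output layer. All hidden activations are ELU; convolutions use
#' valid padding. When `aux_inputs` is `TRUE`, the standardized non-sigmoid
#' parameter values (carrying capacity, initial population, death rate) are
#' concatenated onto the pooled features entering the first dense layer.
#'
#' @param width Encoding width (columns), default 200.
#' @param channels Encoding rows, default 4.
#' @param output_dim 4 for the sigmoid model; the number of affinity bins
#'   for the per-bin model.
#' @param aux_inputs Inject non-sigmoid values into the first dense layer?
#' @param n_aux Number of auxiliary inputs (default 3).
#' @param per_bin Is this the per-bin variant (outputs are response values
#'   at bin centres rather than sigmoid parameters)?
#' @param clip Clip bounds matrix (`output_dim` x 2); default
#'   [clip_bounds()] for the sigmoid model, `[0, 75]` per bin otherwise.
#' @param domain Affinity domain used by the loss, default `c(-2.5, 3)`.
#' @return An object of class `gcnn` (untrained).
#' @export
build_network <- function(width = 200L, channels = 4L, output_dim = 4L,
                          aux_inputs = TRUE, n_aux = 3L, per_bin = FALSE,
                          clip = NULL, domain = c(-2.5, 3)) {
  if (per_bin && output_dim == 4L) output_dim <- 12L
  if (is.null(clip))
    clip <- if (per_bin)
      matrix(c(0, 75), output_dim, 2L, byrow = TRUE) else clip_bounds()
  if (nrow(clip) != output_dim) stop("clip bounds must match output_dim")
  if (any(clip[, 1] >= clip[, 2])) stop("clip lower bounds must be < upper")
  w1 <- width - 3L; w2 <- w1 - 3L
  if (w2 %% 2L != 0L) stop("width must leave an even length for pooling")
  wp <- w2 %/% 2L; w3 <- wp - 3L
  if (w3 < 1L) stop("width too small for the architecture")
  naux <- if (aux_inputs) as.integer(n_aux) else 0L
  params <- list(
    conv1 = list(W = glorot(25L, channels * 4L), b = numeric(25L)),
    conv2 = list(W = glorot(25L, 25L * 4L), b = numeric(25L)),
    conv3 = list(W = glorot(40L, 25L * 4L), b = numeric(40L)),
    dense1 = list(W = glorot(48L, 40L + naux), b = numeric(48L)),
    dense2 = list(W = glorot(32L, 48L), b = numeric(32L)),
    dense3 = list(W = glorot(16L, 32L), b = numeric(16L)),
    dense4 = list(W = glorot(8L, 16L), b = numeric(8L)),
    output = list(W = glorot(output_dim, 8L), b = numeric(output_dim)))
  structure(list(
    params = params, ema = params,
    arch = list(width = as.integer(width), channels = as.integer(channels),
                w1 = w1, w2 = w2, wp = wp, w3 = w3, n_aux = naux,
                output_dim = as.integer(output_dim)),
    aux_inputs = aux_inputs && n_aux > 0L, per_bin = per_bin, clip = clip,
    domain = domain,
    bin_centers = if (per_bin)
      seq(domain[1], domain[2], length.out = 2L * output_dim + 1L)[seq(2L, 2L * output_dim, 2L)],
    trained = FALSE, history = NULL, scaler = NULL), class = "gcnn")
}

#' @export
print.gcnn <- function(x, ...) {
  pc <- network_param_counts(x)
  cat(sprintf("<gcnn> %s model, %d outputs, aux inputs %s, %d parameters%s\n",
              if (x$per_bin) "per-bin" else "sigmoid", x$arch$output_dim,
              if (x$aux_inputs) "on" else "off", sum(pc$n_params),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Per-layer parameter counts
#'
#' @param net A [build_network()] model.
#' @return Data frame with one row per parameterized layer, in
#'   architecture order, giving the number of trainable parameters.
#' @export
network_param_counts <- function(net) {
  stopifnot(inherits(net, "gcnn"))
  n <- vapply(net$params, function(l) length(l$W) + length(l$b), numeric(1))
  data.frame(layer = names(net$params),
             type = c(rep("conv", 3L), rep("dense", 5L)),
             n_params = as.integer(n), row.names = NULL)
}

# index caches ----------------------------------------------------------

im2col_index <- function(channels, width, kernel) {
  wout <- width - kernel + 1L
  key <- paste0("i", channels, "_", width, "_", kernel)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- as.vector(outer(seq_len(channels * kernel),
                                     (seq_len(wout) - 1L) * channels, "+"))
  }
  .cache[[key]]
}

pool_index <- function(width, batch) {
  key <- paste0("p", width, "_", batch)
  if (is.null(.cache[[key]])) {
    base <- rep((seq_len(batch) - 1L) * width, each = width %/% 2L)
    .cache[[key]] <- list(odd = base + seq(1L, width - 1L, 2L),
                          even = base + seq(2L, width, 2L))
  }
  .cache[[key]]
}

im2col <- function(Xm, channels, width, kernel) {
  iv <- im2col_index(channels, width, kernel)
  out <- Xm[iv, , drop = FALSE]
  dim(out) <- c(channels * kernel, length(iv) %/% (channels * kernel) * ncol(Xm))
  out
}

col2im <- function(dXcol, channels, width, kernel, batch) {
  wout <- width - kernel + 1L
  dXm <- matrix(0, channels * width, batch)
  for (k in seq_len(kernel)) {
    blk <- dXcol[(k - 1L) * channels + seq_len(channels), , drop = FALSE]
    dim(blk) <- c(channels * wout, batch)
    rows <- (k - 1L) * channels + seq_len(channels * wout)
    dXm[rows, ] <- dXm[rows, ] + blk
  }
  dXm
}

# forward pass; X is (channels*width) x batch in channel-fastest layout
# (as.vector of a channels x width matrix); aux is n_aux x batch or NULL
nn_forward <- function(net, X, aux = NULL, params = net$params,
                       keep_cache = FALSE) {
  a <- net$arch
  B <- ncol(X)
  c1 <- im2col(X, a$channels, a$width, 4L)
  A1 <- elu(params$conv1$W %*% c1 + params$conv1$b)
  X1 <- A1
  dim(X1) <- c(25L * a$w1, B)
  c2 <- im2col(X1, 25L, a$w1, 4L)
  A2 <- elu(params$conv2$W %*% c2 + params$conv2$b) # 25 x (w2*B)
  pi <- pool_index(a$w2, B)
  Ao <- A2[, pi$odd, drop = FALSE]; Ae <- A2[, pi$even, drop = FALSE]
  mask <- Ao >= Ae
  P <- pmax(Ao, Ae) # 25 x (wp*B)
  Xp <- P
  dim(Xp) <- c(25L * a$wp, B)
  c3 <- im2col(Xp, 25L, a$wp, 4L)
  A3 <- elu(params$conv3$W %*% c3 + params$conv3$b) # 40 x (w3*B)
  arr <- A3
  dim(arr) <- c(40L, a$w3, B)
  G <- colMeans(aperm(arr, c(2L, 1L, 3L))) # 40 x B
  D0 <- if (net$aux_inputs) {
    if (is.null(aux)) stop("model expects auxiliary (non-sigmoid) inputs")
    rbind(G, aux)
  } else G
  A4 <- elu(params$dense1$W %*% D0 + params$dense1$b)
  A5 <- elu(params$dense2$W %*% A4 + params$dense2$b)
  A6 <- elu(params$dense3$W %*% A5 + params$dense3$b)
  A7 <- elu(params$dense4$W %*% A6 + params$dense4$b)
  raw <- params$output$W %*% A7 + params$output$b
  out <- list(raw = raw, clipped = clip_params(raw, net$clip))
  if (keep_cache)
    out$cache <- list(X = X, c1 = c1, A1 = A1, c2 = c2, A2 = A2,
                      mask = mask, c3 = c3, A3 = A3, G = G,
                      D0 = D0, A4 = A4, A5 = A5, A6 = A6, A7 = A7, B = B)
  out
}

# backward pass from d(loss)/d(raw outputs); returns gradients shaped like
# net$params
nn_backward <- function(net, params, cache, draw) {
  a <- net$arch
  B <- cache$B
  g <- list()
  dZ <- draw # output layer is linear; clip is straight-through
  g$output <- list(W = tcrossprod(dZ, cache$A7), b = rowSums(dZ))
  dZ <- crossprod(params$output$W, dZ) * elu_prime_act(cache$A7)
  g$dense4 <- list(W = tcrossprod(dZ, cache$A6), b = rowSums(dZ))
  dZ <- crossprod(params$dense4$W, dZ) * elu_prime_act(cache$A6)
  g$dense3 <- list(W = tcrossprod(dZ, cache$A5), b = rowSums(dZ))
  dZ <- crossprod(params$dense3$W, dZ) * elu_prime_act(cache$A5)
  g$dense2 <- list(W = tcrossprod(dZ, cache$A4), b = rowSums(dZ))
  dZ <- crossprod(params$dense2$W, dZ) * elu_prime_act(cache$A4)
  g$dense1 <- list(W = tcrossprod(dZ, cache$D0), b = rowSums(dZ))
  dD0 <- crossprod(params$dense1$W, dZ)
  dG <- dD0[seq_len(40L), , drop = FALSE]
  # undo global average pooling
  dZ3 <- dG[, rep(seq_len(B), each = a$w3), drop = FALSE] *
    (elu_prime_act(cache$A3) / a$w3)
  g$conv3 <- list(W = tcrossprod(dZ3, cache$c3), b = rowSums(dZ3))
  dc3 <- crossprod(params$conv3$W, dZ3)
  dP <- col2im(dc3, 25L, a$wp, 4L, B)
  dim(dP) <- c(25L, a$wp * B)
  pi <- pool_index(a$w2, B)
  dA2 <- matrix(0, 25L, a$w2 * B)
  dA2[, pi$odd] <- dP * cache$mask
  dA2[, pi$even] <- dP * (1 - cache$mask)
  dZ2 <- dA2 * elu_prime_act(cache$A2)
  g$conv2 <- list(W = tcrossprod(dZ2, cache$c2), b = rowSums(dZ2))
  dc2 <- crossprod(params$conv2$W, dZ2)
  dZ1 <- col2im(dc2, 25L, a$w1, 4L, B)
  dim(dZ1) <- c(25L, a$w1 * B)
  dZ1 <- dZ1 * elu_prime_act(cache$A1)
  g$conv1 <- list(W = tcrossprod(dZ1, cache$c1), b = rowSums(dZ1))
  g[names(net$params)]
}

# loss machinery --------------------------------------------------------

trapezoid_weights <- function(n, domain) {
  h <- (domain[2] - domain[1]) / (n - 1L)
  w <- rep(h, n); w[c(1L, n)] <- h / 2
  w
}

# curves for a 4 x B matrix of sigmoid parameters on grid g: returns n x B
sigmoid_curves <- function(P, g) {
  # rows: 1 = xc, 2 = xh, 3 = yc, 4 = yh
  S <- stats::plogis(outer(g, P[2L, ], "-") * rep(P[1L, ], each = length(g)))
  sweep(S, 2L, P[3L, ], "*") + rep(P[4L, ], each = length(g))
}

#' Curve-difference loss
#'
#' The area between the true and predicted response curves divided by the
#' area under the true curve, both measured by trapezoidal quadrature on a
#' uniform affinity grid over `domain` (default `[-2.5, 3]`). Zero iff the
#' curves agree on the grid; equals 1 against the zero curve.
#'
#' @param true_curve,predicted_curve Either [response_params()] objects or
#'   numeric vectors of equal length giving curve values on the uniform
#'   grid.
#' @param domain Affinity interval, default `c(-2.5, 3)`.
#' @param n Grid size when evaluating [response_params()] inputs (default
#'   512).
#' @return Non-negative scalar loss.
#' @export
curve_difference_loss <- function(true_curve, predicted_curve,
                                  domain = c(-2.5, 3), n = 512L) {
  as_curve <- function(x) {
    if (inherits(x, "response_params")) response_curve_on_grid(x, domain, n)
    else as.numeric(x)
  }
  ft <- as_curve(true_curve); fp <- as_curve(predicted_curve)
  if (length(ft) != length(fp))
    stop("curves must be evaluated on the same grid")
  w <- trapezoid_weights(length(ft), domain)
  denom <- sum(w * ft)
  if (denom <= 0) stop("true curve has non-positive area on the domain")
  sum(w * abs(ft - fp)) / denom
}

# batched loss + gradient wrt predicted parameter matrix (4 x B, clipped).
# truth is 4 x B of true sigmoid parameters.
curve_loss_batch <- function(P_pred, P_true, domain, n = 512L,
                             grad = TRUE) {
  g <- seq(domain[1], domain[2], length.out = n)
  w <- trapezoid_weights(n, domain)
  ft <- sigmoid_curves(P_true, g)
  S <- stats::plogis(outer(g, P_pred[2L, ], "-") *
                       rep(P_pred[1L, ], each = n))
  fp <- sweep(S, 2L, P_pred[3L, ], "*") + rep(P_pred[4L, ], each = n)
  atrue <- colSums(w * ft)
  loss <- colSums(w * abs(ft - fp)) / atrue
  out <- list(loss = loss)
  if (grad) {
    dLdf <- (w * sign(fp - ft)) / rep(atrue, each = n) # n x B
    Sp <- S * (1 - S)
    yc <- rep(P_pred[3L, ], each = n)
    xc <- rep(P_pred[1L, ], each = n)
    xdiff <- outer(g, P_pred[2L, ], "-")
    out$grad <- rbind(
      xc = colSums(dLdf * yc * Sp * xdiff),
      xh = colSums(dLdf * (-yc * Sp * xc)),
      yc = colSums(dLdf * S),
      yh = colSums(dLdf))
  }
  out
}

# per-bin variant: outputs ARE curve values at bin centres; truth curve
# evaluated at the same centres; coarse trapezoid over the bin-centre grid
bin_loss_batch <- function(F_pred, P_true, centers, grad = TRUE) {
  n <- length(centers)
  dom <- range(centers)
  w <- trapezoid_weights(n, dom)
  ft <- sigmoid_curves(P_true, centers)
  atrue <- colSums(w * ft)
  loss <- colSums(w * abs(ft - F_pred)) / atrue
  out <- list(loss = loss)
  if (grad) out$grad <- (w * sign(F_pred - ft)) / rep(atrue, each = n)
  out
}

# optimizer --------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_step <- function(params, grads, state, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  for (l in names(params)) for (p in names(params[[l]])) {
    gr <- grads[[l]][[p]]
    state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * gr
    state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * gr^2
    mhat <- state$m[[l]][[p]] / (1 - beta1^step)
    vhat <- state$v[[l]][[p]] / (1 - beta2^step)
    params[[l]][[p]] <- params[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' Adam with learning rate 0.01, exponential-moving-average weight momentum
#' 0.99 (EMA weights are used for validation and prediction), batch size 32,
#' 35 epochs, no dropout; 20% of the data is held out as a test split and
#' 10% of the remainder as a validation split.
#'
#' @param learning_rate,ema_momentum,batch_size,epochs,test_frac,val_frac
#'   Scalars as described.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, ema_momentum = 0.99,
                         batch_size = 32L, epochs = 35L, test_frac = 0.2,
                         val_frac = 0.1) {
  stopifnot(test_frac > 0, test_frac < 1, val_frac > 0, val_frac < 1,
            epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(learning_rate = learning_rate, ema_momentum = ema_momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), test_frac = test_frac,
                 val_frac = val_frac), class = "train_config")
}

#' Train the network on an encoded training set
#'
#' Minimizes the mean curve-difference loss between true and predicted
#' response curves. The input encodings and auxiliary values must already be
#' standardized (see [standardize_features()]); attach the scaler so that
#' prediction can reuse it.
#'
#' @param net A [build_network()] model.
#' @param X Numeric matrix `(channels * width) x n`: each column an encoded
#'   tree flattened column-major (`as.vector` of the 4 x W matrix).
#' @param truth 4 x n matrix (rows xc, xh, yc, yh) of true sigmoid
#'   parameters.
#' @param aux `n_aux x n` matrix of standardized non-sigmoid values, or
#'   NULL.
#' @param cfg A [train_config()].
#' @param scaler Optional `tree_scaler` stored with the model.
#' @param verbose Print per-epoch losses?
#' @return The trained `gcnn`, with `history` (per-epoch train/validation
#'   loss data frame) and `splits` (index vectors).
#' @export
train_network <- function(net, X, truth, aux = NULL, cfg = train_config(),
                          scaler = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "gcnn"), inherits(cfg, "train_config"))
  n <- ncol(X)
  if (ncol(truth) != n) stop("truth must have one column per tree")
  if (net$aux_inputs && (is.null(aux) || ncol(aux) != n))
    stop("model expects auxiliary inputs for every tree")
  idx <- sample.int(n)
  n_test <- floor(cfg$test_frac * n)
  test_idx <- idx[seq_len(n_test)]
  rest <- idx[-seq_len(n_test)]
  n_val <- floor(cfg$val_frac * length(rest))
  val_idx <- rest[seq_len(n_val)]
  train_idx <- rest[-seq_len(n_val)]
  if (length(train_idx) < cfg$batch_size)
    stop("too few training trees for one batch")
  params <- net$params
  ema <- params
  state <- list(m = adam_init(params), v = adam_init(params))
  mom <- cfg$ema_momentum
  step <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  eval_loss <- function(p, ix) {
    tot <- 0
    for (s in split(ix, ceiling(seq_along(ix) / 256L))) {
      fw <- nn_forward(net, X[, s, drop = FALSE],
                       if (net$aux_inputs) aux[, s, drop = FALSE],
                       params = p)
      lb <- if (net$per_bin)
        bin_loss_batch(fw$clipped, truth[, s, drop = FALSE],
                       net$bin_centers, grad = FALSE)
      else curve_loss_batch(fw$clipped, truth[, s, drop = FALSE],
                            net$domain, grad = FALSE)
      tot <- tot + sum(lb$loss)
    }
    tot / length(ix)
  }
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0; ep_n <- 0L
    for (s in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      fw <- nn_forward(net, X[, s, drop = FALSE],
                       if (net$aux_inputs) aux[, s, drop = FALSE],
                       params = params, keep_cache = TRUE)
      lb <- if (net$per_bin)
        bin_loss_batch(fw$clipped, truth[, s, drop = FALSE],
                       net$bin_centers)
      else curve_loss_batch(fw$clipped, truth[, s, drop = FALSE],
                            net$domain)
      if (any(!is.finite(lb$loss)))
        stop("training diverged: non-finite loss at epoch ", ep)
      ep_loss <- ep_loss + sum(lb$loss); ep_n <- ep_n + length(s)
      draw <- lb$grad / length(s) # mean loss over the batch
      grads <- nn_backward(net, params, fw$cache, draw)
      step <- step + 1L
      upd <- adam_step(params, grads, state, cfg$learning_rate, step)
      params <- upd$params; state <- upd$state
      for (l in names(params)) for (p in names(params[[l]]))
        ema[[l]][[p]] <- mom * ema[[l]][[p]] + (1 - mom) * params[[l]][[p]]
    }
    vl <- eval_loss(ema, val_idx)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %2d  train %.4f  val %.4f", ep,
                      ep_loss / ep_n, vl))
  }
  net$params <- params
  net$ema <- ema
  net$trained <- TRUE
  net$history <- hist
  net$scaler <- scaler
  net$splits <- list(train = train_idx, val = val_idx, test = test_idx)
  net
}

#' Predict response parameters for encoded trees
#'
#' Uses the EMA weights. Outputs are clamped to the clip bounds; for the
#' per-bin model the outputs are response values at the bin centres.
#'
#' @param object A trained `gcnn`.
#' @param X `(channels * width) x n` standardized encoding matrix, or a list
#'   of raw [encode_tree()] matrices (standardized with the stored scaler).
#' @param aux `n_aux x n` matrix of auxiliary values. If a stored scaler is
#'   used, pass RAW auxiliary values (they are standardized alongside).
#' @param ... Unused.
#' @return For the sigmoid model, a data frame with columns `xc, xh, yc,
#'   yh` (one row per tree); for the per-bin model a matrix `n x n_bins`.
#' @export
predict.gcnn <- function(object, X, aux = NULL, ...) {
  net <- object
  if (is.list(X) && !is.matrix(X)) {
    if (is.null(net$scaler))
      stop("raw encodings given but the model has no stored scaler")
    std <- apply_tree_scaler(net$scaler, X,
                             if (!is.null(aux)) t(aux))
    X <- vapply(std$encodings, as.vector,
                numeric(net$arch$channels * net$arch$width))
    if (!is.null(aux)) aux <- t(std$aux)
  }
  out <- matrix(NA_real_, net$arch$output_dim, ncol(X))
  for (s in split(seq_len(ncol(X)), ceiling(seq_len(ncol(X)) / 256L))) {
    fw <- nn_forward(net, X[, s, drop = FALSE],
                     if (net$aux_inputs) aux[, s, drop = FALSE],
                     params = net$ema)
    out[, s] <- fw$clipped
  }
  if (net$per_bin) return(t(out))
  res <- as.data.frame(t(out))
  names(res) <- c("xc", "xh", "yc", "yh")
  res
}
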