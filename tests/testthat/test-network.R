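test_that("layer parameter counts match the published architecture", {
  net <- withr::with_seed(61, build_network(aux_inputs = FALSE))
  pc <- network_param_counts(net)
  # conv2, conv3, dense 48/32/16/8 (aux inputs disabled)
  expect_equal(pc$n_params[pc$layer == "conv2"], 2525L)
  expect_equal(pc$n_params[pc$layer == "conv3"], 4040L)
  expect_equal(pc$n_params[pc$layer == "dense1"], 1968L)
  expect_equal(pc$n_params[pc$layer == "dense2"], 1568L)
  expect_equal(pc$n_params[pc$layer == "dense3"], 528L)
  expect_equal(pc$n_params[pc$layer == "dense4"], 136L)
  # with auxiliary inputs the first dense layer widens by 3 inputs
  net_aux <- withr::with_seed(61, build_network(aux_inputs = TRUE))
  pc_aux <- network_param_counts(net_aux)
  expect_equal(pc_aux$n_params[pc_aux$layer == "dense1"], 48L * 44L)
})

test_that("curve-difference loss matches its analytic oracles", {
  n <- 301L
  expect_equal(curve_difference_loss(rep(2, n), rep(2, n)), 0)
  expect_equal(curve_difference_loss(rep(2, n), rep(1, n)), 0.5)
  expect_equal(curve_difference_loss(rep(2, n), rep(0, n)), 1)
  p <- response_params(1.6, 2, 18.2, 0.4)
  expect_equal(curve_difference_loss(p, p), 0)
  expect_error(curve_difference_loss(rep(0, n), rep(1, n)), "area")
  # non-negative, and positive whenever curves differ on the grid
  withr::with_seed(62, {
    for (i in 1:10) {
      a <- sample_response_params(); b <- sample_response_params()
      l <- curve_difference_loss(a, b)
      expect_gte(l, 0)
      if (!isTRUE(all.equal(response_curve_on_grid(a),
                            response_curve_on_grid(b))))
        expect_gt(l, 0)
    }
  })
})

test_that("output clipping clamps to the published bounds", {
  raw <- c(xc = 1, xh = 0.3, yc = 20, yh = 5)
  expect_equal(clip_params(raw), raw, ignore_attr = TRUE)
  expect_equal(unname(clip_params(c(-1, 0, 20, 0.2))[1]), 0.001)
  expect_equal(unname(clip_params(c(1, 0, 20, 20))[4]), 10)
  expect_equal(unname(clip_params(c(1, -7, 100, 0.2))[2:3]), c(-1.5, 65))
})

test_that("backpropagation matches central finite differences", {
  net <- withr::with_seed(63, build_network(aux_inputs = TRUE))
  net$params$output$b <- c(1, 1, 5, 1) # keep raw outputs off the clip edges
  withr::with_seed(64, {
    X <- matrix(rnorm(800 * 5), 800, 5)
    aux <- matrix(rnorm(15), 3, 5)
  })
  truth <- matrix(rep(c(1.6, 2, 18.2, 0.4), 5), 4)
  f <- function(p) {
    fw <- gcresponse:::nn_forward(net, X, aux, params = p)
    mean(gcresponse:::curve_loss_batch(fw$clipped, truth, net$domain,
                                       grad = FALSE)$loss)
  }
  fw <- gcresponse:::nn_forward(net, X, aux, keep_cache = TRUE)
  lb <- gcresponse:::curve_loss_batch(fw$clipped, truth, net$domain)
  gr <- gcresponse:::nn_backward(net, net$params, fw$cache, lb$grad / 5)
  h <- 1e-5
  withr::with_seed(65, {
    for (ly in names(net$params)) {
      for (i in sample(length(net$params[[ly]]$W), 2)) {
        pp <- net$params
        pp[[ly]]$W[i] <- pp[[ly]]$W[i] + h; f1 <- f(pp)
        pp[[ly]]$W[i] <- pp[[ly]]$W[i] - 2 * h; f2 <- f(pp)
        num <- (f1 - f2) / (2 * h)
        expect_equal(gr[[ly]]$W[i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("training reduces the loss on a learnable synthetic problem", {
  # encode the true parameters directly into the input channels (plus
  # noise): any functioning optimizer must beat its starting loss
  for (seed in c(71, 72)) {
    withr::with_seed(seed, {
      n <- 256L
      truth <- rbind(xc = runif(n, 0.2, 2), xh = runif(n, -0.5, 3),
                     yc = runif(n, 0.5, 35), yh = runif(n, 0, 0.6))
      base <- matrix(rnorm(800 * n, sd = 0.1), 800, n)
      for (k in 1:4) base[seq(k, 400, by = 4), ] <-
          base[seq(k, 400, by = 4), ] + scale(truth[k, ])[, 1]
      net <- build_network(aux_inputs = FALSE)
      net <- train_network(net, base, truth,
                           cfg = train_config(epochs = 6))
      h <- net$history
      expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
      expect_true(all(is.finite(h$val_loss)))
      expect_named(h, c("epoch", "train_loss", "val_loss"))
    })
  }
})

test_that("prediction is deterministic, clipped, and aux-sensitive", {
  net <- withr::with_seed(73, build_network(aux_inputs = TRUE))
  withr::with_seed(74, {
    X <- matrix(rnorm(800 * 4), 800, 4)
    aux <- matrix(rnorm(12), 3, 4)
  })
  p1 <- predict(net, X, aux = aux)
  p2 <- predict(net, X, aux = aux)
  expect_identical(p1, p2)
  cb <- clip_bounds()
  for (j in 1:4) {
    expect_true(all(p1[[j]] >= cb[j, 1] & p1[[j]] <= cb[j, 2]))
  }
  # the auxiliary path must be live: different aux, different outputs
  p3 <- predict(net, X, aux = aux + 1)
  expect_false(isTRUE(all.equal(p1, p3)))
  expect_error(predict(net, X), "auxiliary")
})

test_that("the per-bin variant trains with the same plumbing", {
  withr::with_seed(75, {
    n <- 128L
    truth <- rbind(runif(n, 0.2, 2), runif(n, -0.5, 3),
                   runif(n, 0.5, 35), runif(n, 0, 0.6))
    X <- matrix(rnorm(800 * n, sd = 0.3), 800, n)
    net <- build_network(aux_inputs = FALSE, per_bin = TRUE)
    expect_equal(net$arch$output_dim, 12L)
    expect_length(net$bin_centers, 12L)
    net <- train_network(net, X, truth, cfg = train_config(epochs = 2))
    pred <- predict(net, X[, 1:5])
    expect_equal(dim(pred), c(5L, 12L))
    expect_true(all(pred >= 0 & pred <= 75))
  })
})

test_that("models survive a directory round trip", {
  net <- withr::with_seed(76, build_network(aux_inputs = TRUE))
  net$trained <- TRUE
  net$history <- data.frame(epoch = 1L, train_loss = 0.5, val_loss = 0.6)
  withr::with_seed(77, {
    X <- matrix(rnorm(800 * 3), 800, 3); aux <- matrix(rnorm(9), 3, 3)
  })
  dir <- withr::local_tempdir()
  write_gcnn(net, dir)
  net2 <- read_gcnn(dir)
  expect_equal(predict(net2, X, aux = aux), predict(net, X, aux = aux),
               tolerance = 1e-12)
})
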