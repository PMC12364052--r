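test_that("ladderization sorts by time, then ancestor time, then affinity", {
  tr <- hand_tree()
  ord <- ladderize_order(tr)
  # leaf times: t1 = 3, t2 = 2, t3 = 4 -> cherry (t2 before t1), then t3;
  # the n5 subtree (time 1) precedes t3 (time 4) at the root
  expect_equal(as.integer(ord), c(2L, 1L, 3L))
  # ultrametric cherry with equal leaf times and parents: affinity decides
  cherry <- annotated_tree(
    edge = rbind(c(3L, 1L), c(3L, 2L)), edge_length = c(2, 2), n_tip = 2L,
    affinity = c(0.9, -0.3, 0))
  expect_equal(as.integer(ladderize_order(cherry)), c(2L, 1L))
})

test_that("full-key ties raise the tie error unless explicitly kept", {
  tied <- annotated_tree(
    edge = rbind(c(3L, 1L), c(3L, 2L)), edge_length = c(2, 2), n_tip = 2L,
    affinity = c(0.5, 0.5, 0))
  expect_error(ladderize_order(tied), "tie between nodes")
  expect_silent(ladderize_order(tied, on_tie = "keep"))
  # identical-subtree ties leave the encoding unchanged either way
  e <- encode_tree(tied, width = 4L)
  expect_equal(e[, 1], e[, 2])
})

test_that("trees are scaled to mean unit leaf depth", {
  tr <- hand_tree() # leaf depths 3, 2, 4 -> mean 3
  sc <- scale_tree(tr)
  expect_equal(mean(sc$node_time[1:3]), 1, tolerance = 1e-9)
  expect_equal(sort(sc$node_time[1:3]), c(2, 3, 4) / 3)
  expect_identical(sc$affinity, tr$affinity)
  # already unit depth: unchanged
  expect_equal(scale_tree(sc), sc)
  # uniform depth 2: all branch lengths halved
  cherry <- annotated_tree(rbind(c(3L, 1L), c(3L, 2L)), c(2, 2), 2L,
                           c(1, 0, 0))
  expect_equal(scale_tree(cherry)$edge_length, c(1, 1))
  # mixed depths 1 and 3
  mix <- annotated_tree(rbind(c(3L, 1L), c(3L, 2L)), c(1, 3), 2L,
                        c(1, 0, 0))
  expect_equal(sort(scale_tree(mix)$node_time[1:2]), c(0.5, 1.5))
  degenerate <- annotated_tree(rbind(c(3L, 1L), c(3L, 2L)), c(0, 0), 2L,
                               c(1, 0, 0))
  expect_error(scale_tree(degenerate), "zero")
})

test_that("CBLV columns carry heights and affinities along the ladder", {
  # single leaf under the root
  single <- annotated_tree(matrix(c(2L, 1L), 1), 1.5, 1L, c(0.7, 0.1))
  e <- encode_tree(single, width = 5L)
  expect_equal(e[, 1], c(1.5, 0, 0.7, 0.1))
  expect_true(all(e[, 2:5] == 0))
  # hand tree: ladder order t2, t1, t3 with attachments n5, n5, root
  tr <- hand_tree()
  e <- encode_tree(tr, width = 6L)
  expect_equal(e[, 1], c(2, 0, 2, 0))    # t2: height 2 (time), root attach
  expect_equal(e[, 2], c(3, 1, 1, 0.5))  # t1 attaches at n5 (time 1)
  expect_equal(e[, 3], c(4, 0, -1, 0))   # t3 attaches at the root
  expect_true(all(e[, 4:6] == 0))
  expect_error(encode_tree(tr, width = 2L), "tips")
})

test_that("encoding is canonical under child-order permutations", {
  cfg <- small_config()
  sims <- withr::with_seed(51, lapply(1:8, function(i) run_gc(cfg)))
  mats <- lapply(sims, function(s) encode_tree(scale_tree(s$tree)))
  for (s in sims) {
    tr <- s$tree
    # reverse the order of all edges (and thereby children order)
    perm <- tr
    ix <- rev(seq_len(nrow(tr$edge)))
    perm$edge <- tr$edge[ix, , drop = FALSE]
    perm$edge_length <- tr$edge_length[ix]
    expect_equal(encode_tree(scale_tree(perm)),
                 encode_tree(scale_tree(tr)))
  }
  # distinct trees give distinct matrices
  keys <- vapply(mats, function(m) paste(m, collapse = ","), character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("feature standardization centres, scales, inverts, and errors", {
  cfg <- small_config()
  sims <- withr::with_seed(52, lapply(1:6, function(i) run_gc(cfg)))
  enc <- lapply(sims, function(s) encode_tree(scale_tree(s$tree)))
  aux <- cbind(capacity = runif(6, 500, 2000),
               init_population = sample(8:128, 6),
               death_rate = runif(6, 0.05, 0.5))
  std <- standardize_features(enc, aux)
  hs <- unlist(lapply(std$encodings, function(e)
    e[1:2, seq_len(attr(e, "n_tip"))]))
  as <- unlist(lapply(std$encodings, function(e)
    e[3:4, seq_len(attr(e, "n_tip"))]))
  expect_equal(mean(hs), 0, tolerance = 1e-6)
  expect_equal(sd(hs), 1, tolerance = 1e-6)
  expect_equal(mean(as), 0, tolerance = 1e-6)
  expect_equal(sd(as), 1, tolerance = 1e-6)
  expect_equal(unname(colMeans(std$aux)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(std$aux, 2, sd)), rep(1, 3), tolerance = 1e-9)
  # padding stays exactly zero
  for (e in std$encodings) {
    n <- attr(e, "n_tip")
    if (n < ncol(e)) expect_true(all(e[, (n + 1):ncol(e)] == 0))
  }
  # inverse transform restores the originals
  back <- apply_tree_scaler(std$scaler, std$encodings, std$aux,
                            inverse = TRUE)
  expect_equal(back$encodings[[1]][, seq_len(attr(enc[[1]], "n_tip"))],
               enc[[1]][, seq_len(attr(enc[[1]], "n_tip"))],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(back$aux), unname(aux), tolerance = 1e-9)
  # zero-variance auxiliary feature is named in the error
  aux0 <- aux; aux0[, "death_rate"] <- 0.2
  expect_error(fit_tree_scaler(enc, aux0), "death_rate")
})

test_that("scaler JSON survives a round trip", {
  cfg <- small_config()
  sims <- withr::with_seed(53, lapply(1:3, function(i) run_gc(cfg)))
  enc <- lapply(sims, function(s) encode_tree(scale_tree(s$tree)))
  sc <- fit_tree_scaler(enc)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_scaler(sc, path)
  sc2 <- read_tree_scaler(path)
  expect_equal(sc2$h_mean, sc$h_mean)
  expect_equal(sc2$a_sd, sc$a_sd)
})
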