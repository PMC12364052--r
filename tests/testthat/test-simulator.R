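test_that("zero-time binary expansion yields the requested population", {
  fx <- fixture_inputs()
  st1 <- initialize_population(fx$naive, 1)
  expect_equal(nrow(st1$cells), 1L)
  st8 <- initialize_population(fx$naive, 8)
  expect_equal(nrow(st8$cells), 8L)
  internal <- sum(!(seq_along(st8$tree_parent) - 1L) %in% st8$cells$id)
  expect_equal(internal, 7L) # 7 split events for 8 cells
  expect_true(all(st8$cells$sequence == fx$naive))
  expect_true(all(st8$cells$birth_time == 0))
  st5 <- initialize_population(fx$naive, 5) # non-power-of-two
  expect_equal(nrow(st5$cells), 5L)
})

test_that("capacity factor follows the logistic-modulation formula", {
  # equal total rates: no modulation at any population size
  expect_equal(capacity_factor(rep(2, 7), rep(2, 7), 10), 1)
  # sum(mu) = 2, sum(lambda) = 8, N = N0/2 -> (1/4)^(1/2)
  expect_equal(capacity_factor(rep(8 / 50, 50), rep(2 / 50, 50), 100), 0.5)
  # tiny population relative to capacity: exponent near zero, m near one
  expect_equal(capacity_factor(8, 2, 1e6), 1, tolerance = 1e-4)
  # death modulation inverts the base
  expect_equal(capacity_factor(rep(8 / 50, 50), rep(2 / 50, 50), 50,
                               method = "death"), 4)
  expect_equal(capacity_factor(1, 5, 100, method = "hard"), 1)
  expect_error(capacity_factor(rep(0, 3), rep(1, 3), 10), "denominator")
})

test_that("effective birth rate is m*lambda - mu with its identities", {
  expect_equal(effective_birth_rate(1.2, 0.2, 100, method = "hard"), 1)
  expect_equal(effective_birth_rate(3, 0, 100, method = "hard"), 3)
  # at carrying capacity the population-average net rate is exactly zero
  withr::with_seed(41, {
    lam <- runif(80, 0.5, 10); mu <- runif(80, 0.05, 0.5)
  })
  expect_equal(mean(effective_birth_rate(lam, mu, capacity = 80)), 0,
               tolerance = 1e-12)
})

test_that("first-reaction and direct event draws agree with exact rates", {
  cfg <- small_config(capacity_method = "hard") # m = 1: pure rates
  cells <- data.frame(sequence = fixture_inputs()$naive,
                      affinity = c(0, 1.5, 3), functional = c(TRUE, TRUE, FALSE))
  lam <- sigmoid_response(cells$affinity, cfg$response)
  mu <- ifelse(cells$functional, 0.2, 10)
  mut <- cfg$mutability_multiplier *
    sapply(cells$sequence, function(s)
      sum(gcresponse:::position_mutability(s, cfg$shm)))
  rates <- c(lam, mu, unname(mut))
  n <- 4000
  draw_tab <- function(method) {
    keys <- withr::with_seed(42 + (method == "direct"), {
      replicate(n, {
        ev <- draw_event(cells, cfg, method)
        paste0(ev$type, ev$cell)
      })
    })
    lv <- paste0(rep(c("birth", "death", "mutation"), each = 3), 1:3)
    table(factor(keys, levels = lv))
  }
  t_fr <- draw_tab("first-reaction")
  t_di <- draw_tab("direct")
  expected <- rates / sum(rates)
  expect_gt(chisq.test(t_fr, p = expected)$p.value, 0.001)
  expect_gt(chisq.test(t_di, p = expected)$p.value, 0.001)
  # the two constructions agree with each other
  expect_gt(chisq.test(rbind(t_fr, t_di))$p.value, 0.001)
})

test_that("waiting times are exponential with the total rate", {
  cfg <- small_config(capacity_method = "hard")
  cells <- data.frame(sequence = fixture_inputs()$naive, affinity = 1,
                      functional = TRUE)
  lam <- sigmoid_response(1, cfg$response)
  mut <- cfg$mutability_multiplier *
    sum(gcresponse:::position_mutability(cells$sequence, cfg$shm))
  R <- lam + 0.2 + mut
  waits <- withr::with_seed(43, {
    replicate(2000, draw_event(cells, cfg, "first-reaction")$wait)
  })
  se <- sd(waits) / sqrt(length(waits))
  expect_lt(abs(mean(waits) - 1 / R), 3 * se)
})

test_that("a frozen configuration keeps the population constant", {
  # birth modulation with all death rates zero drives m to zero and the
  # multiplier is zero: no events can fire, so the initial naive cells are
  # returned unchanged at sampling time
  fx <- fixture_inputs()
  cfg <- gc_config(fx$naive, fx$dms, fx$shm,
                   capacity = 64, init_population = 16L, t_sample = 5,
                   sample_size = 16L, death_rate_functional = 0,
                   mutability_multiplier = 0, min_viable = 10L)
  sim <- run_gc(cfg)
  expect_equal(nrow(sim$living), 16L)
  expect_equal(sim$tree$n_tip, 16L)
  expect_true(all(sim$sequences == fx$naive))
  expect_true(all(sim$n_mutations == 0L))
})

test_that("hard capacity enforcement never exceeds N0", {
  fx <- fixture_inputs()
  cfg <- gc_config(fx$naive, fx$dms, fx$shm, capacity = 60,
                   capacity_method = "hard", init_population = 16L,
                   t_sample = 8, sample_size = c(20L, 30L))
  sim <- withr::with_seed(44, run_gc(cfg, record_trajectory = TRUE))
  expect_lte(max(sim$trajectory$n), 60)
})

test_that("death-modulated capacity also regulates the population", {
  fx <- fixture_inputs()
  cfg <- gc_config(fx$naive, fx$dms, fx$shm, capacity = 120,
                   capacity_method = "death", init_population = 32L,
                   t_sample = 12, sample_size = c(20L, 30L))
  sim <- withr::with_seed(48, run_gc(cfg, record_trajectory = TRUE))
  n2 <- sim$trajectory$n[sim$trajectory$time > 6]
  # bounded: no sustained blow-up past capacity, no extinction
  expect_lt(mean(n2), 2 * cfg$capacity)
  expect_gt(min(n2), 0)
})

test_that("simulated GCs are reproducible and structurally sound", {
  cfg <- small_config()
  s1 <- withr::with_seed(45, run_gc(cfg, record_truth = TRUE))
  s2 <- withr::with_seed(45, run_gc(cfg, record_truth = TRUE))
  expect_identical(s1$tree, s2$tree)
  expect_identical(s1$sequences, s2$sequences)
  # sampled-tree times are non-decreasing root -> leaf
  expect_true(all(s1$tree$edge_length >= 0))
  tips <- seq_len(s1$tree$n_tip)
  expect_equal(unname(s1$tree$node_time[tips]), rep(8, length(tips)))
  # truth tree: birth/split nodes are binary
  kids <- table(s1$truth$edge[, 1])
  expect_true(all(kids <= 2))
  # living snapshot is consistent with the response function
  lam <- sigmoid_response(s1$living$affinity, cfg$response)
  expect_equal(s1$living$lambda, lam, tolerance = 1e-9)
  expect_true(all(s1$living$mu[s1$living$functional] == 0.2))
  expect_true(all(s1$living$mu[!s1$living$functional] == 10))
})

test_that("non-viable parameter sets exhaust the retry budget loudly", {
  fx <- fixture_inputs()
  doomed <- gc_config(fx$naive, fx$dms, fx$shm,
                      response = response_params(0.5, 3, 0.6, 0),
                      capacity = 200, init_population = 4L, t_sample = 10,
                      sample_size = 10L, death_rate_functional = 0.5,
                      min_viable = 10L, max_tries = 5L)
  expect_error(withr::with_seed(46, run_gc(doomed)), "retry budget")
})

test_that("population regulation holds the plateau near capacity", {
  # long enough past the initial growth phase for the plateau to dominate
  # the second-half average
  fx <- fixture_inputs()
  cfg <- gc_config(fx$naive, fx$dms, fx$shm, capacity = 150,
                   init_population = 32L, t_sample = 14,
                   sample_size = c(20L, 30L))
  sims <- withr::with_seed(47, lapply(1:3, function(i)
    run_gc(cfg, record_trajectory = TRUE)))
  plateau <- sapply(sims, function(s)
    mean(s$trajectory$n[s$trajectory$time > cfg$t_sample / 2]))
  expect_true(all(abs(plateau - cfg$capacity) / cfg$capacity < 0.25))
})
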