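# Shared synthetic inputs, built once per test run. Everything is generated
# in code under a fixed seed; no binary fixtures.

fixture_env <- new.env(parent = emptyenv())

fixture_inputs <- function() {
  if (is.null(fixture_env$naive)) {
    withr::with_seed(424242, {
      fixture_env$naive <- synth_naive_seq(100)
      fixture_env$dms <- synth_dms(fixture_env$naive)
      fixture_env$shm <- synth_shm_model()
    })
  }
  fixture_env
}

# small, fast GC configuration used by most simulator-level tests
small_config <- function(...) {
  fx <- fixture_inputs()
  gc_config(fx$naive, fx$dms, fx$shm,
            capacity = 150, init_population = 16L, t_sample = 8,
            sample_size = c(20L, 30L), ...)
}

# data-mimic configuration (full-size defaults)
mimic_config <- function(...) {
  fx <- fixture_inputs()
  gc_config(fx$naive, fx$dms, fx$shm, ...)
}

# a small annotated tree built by hand:
#        root(t=0, a=0)
#        /            \
#   n5(t=1, a=0.5)     t3 (t=4, a=-1)
#    /      \
# t1(t=3,a=1)  t2(t=2,a=2)
hand_tree <- function() {
  annotated_tree(
    edge = rbind(c(4L, 5L), c(5L, 1L), c(5L, 2L), c(4L, 3L)),
    edge_length = c(1, 2, 1, 4),
    n_tip = 3L,
    affinity = c(1, 2, -1, 0, 0.5))
}

# uniform mutation model: every motif has the same mutability r and a
# uniform substitution distribution over the three alternative bases
uniform_shm <- function(r = 0.001, multiplier = 1) {
  centre <- (seq_len(1024L) - 1L) %/% 16L %% 4L + 1L
  sub <- matrix(1 / 3, 1024L, 4L)
  sub[cbind(seq_len(1024L), centre)] <- 0
  mutation_model(rep(r, 1024L), sub, multiplier = multiplier)
}
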