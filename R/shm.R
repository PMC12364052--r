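#' 5-mer context-sensitive somatic hypermutation model
#'
#' Holds, for each of the 4^5 = 1024 nucleotide 5-mers, a relative mutability
#' of the centre base and a substitution distribution over the three
#' alternative bases, plus a global rate multiplier (the "mutability
#' multiplier": 0.68 for training simulations, 0.5 for the data-mimic
#' setting). Motifs are ordered lexicographically over `ACGT` (first base
#' slowest).
#'
#' @param mutability Numeric vector of length 1024, non-negative.
#' @param substitution 1024 x 4 numeric matrix; row `i` is the probability of
#'   mutating the centre base of motif `i` to `A`, `C`, `G`, `T`. The centre
#'   base's own column must be 0 and each row must sum to 1.
#' @param multiplier Global scale applied to per-sequence mutability (1/day
#'   per mutability unit).
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(mutability, substitution, multiplier = 1) {
  mutability <- as.numeric(mutability)
  substitution <- as.matrix(substitution)
  if (length(mutability) != 1024L)
    stop("mutability must have length 1024 (one entry per 5-mer)")
  if (any(!is.finite(mutability)) || any(mutability < 0))
    stop("mutabilities must be finite and >= 0")
  if (!identical(dim(substitution), c(1024L, 4L)))
    stop("substitution must be a 1024 x 4 matrix")
  centre <- (seq_len(1024L) - 1L) %/% 16L %% 4L + 1L
  if (any(abs(substitution[cbind(seq_len(1024L), centre)]) > 1e-12))
    stop("substitution probability of the centre base must be 0")
  if (any(abs(rowSums(substitution) - 1) > 1e-9))
    stop("substitution rows must sum to 1")
  colnames(substitution) <- NUC
  m <- structure(list(mutability = mutability, substitution = substitution,
                      multiplier = multiplier),
                 class = "mutation_model")
  m$boundary <- boundary_tables(m)
  m
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf("<mutation_model> 1024 motifs, multiplier %.3g, mean mutability %.3g\n",
              x$multiplier, mean(x$mutability)))
  invisible(x)
}

# Precomputed N-padded boundary motif tables: mutability (and substitution
# rows) averaged over all full motifs consistent with the observed bases.
# Motif index (0-based) = b1*256 + b2*64 + b3*16 + b4*4 + b5, so the last
# base cycles fastest.
boundary_tables <- function(m) {
  mu <- m$mutability
  sub <- m$substitution
  red <- function(v, nrowm, use_rows) {
    if (use_rows) rowMeans(matrix(v, nrow = nrowm)) else
      colMeans(matrix(v, nrow = nrowm))
  }
  avg <- function(nrowm, use_rows) {
    list(mut = red(mu, nrowm, use_rows),
         sub = apply(sub, 2L, red, nrowm = nrowm, use_rows = use_rows))
  }
  list(
    # position 1: NN c r1 r2 -> average over the two leading bases
    L2 = avg(64L, use_rows = TRUE),
    # position 2: N l1 c r1 r2 -> average over the leading base
    L1 = avg(256L, use_rows = TRUE),
    # position L-1: l2 l1 c r1 N -> average over the trailing base
    R1 = avg(4L, use_rows = FALSE),
    # position L: l2 l1 c NN -> average over the two trailing bases
    R2 = avg(16L, use_rows = FALSE)
  )
}

seq_to_int <- function(seq) {
  v <- match(strsplit(validate_nt(seq), "")[[1]], NUC) - 1L
  v
}

# Per-position relative mutability (multiplier NOT applied) plus, for each
# position, the substitution distribution row.
position_mutability <- function(seq, model, with_sub = FALSE) {
  stopifnot(inherits(model, "mutation_model"))
  b <- seq_to_int(seq)
  L <- length(b)
  if (L < 5L) stop("sequence must have length >= 5 for a full 5-mer motif")
  out <- numeric(L)
  i <- 3:(L - 2L)
  full_idx <- b[i - 2L] * 256L + b[i - 1L] * 64L + b[i] * 16L +
    b[i + 1L] * 4L + b[i + 2L] + 1L
  out[i] <- model$mutability[full_idx]
  bt <- model$boundary
  i1 <- b[1L] * 16L + b[2L] * 4L + b[3L] + 1L
  i2 <- b[1L] * 64L + b[2L] * 16L + b[3L] * 4L + b[4L] + 1L
  iR1 <- b[L - 3L] * 64L + b[L - 2L] * 16L + b[L - 1L] * 4L + b[L] + 1L
  iR2 <- b[L - 2L] * 16L + b[L - 1L] * 4L + b[L] + 1L
  out[1L] <- bt$L2$mut[i1]
  out[2L] <- bt$L1$mut[i2]
  out[L - 1L] <- bt$R1$mut[iR1]
  out[L] <- bt$R2$mut[iR2]
  if (!with_sub) return(out)
  subrow <- function(pos) {
    if (pos == 1L) bt$L2$sub[i1, ]
    else if (pos == 2L) bt$L1$sub[i2, ]
    else if (pos == L - 1L) bt$R1$sub[iR1, ]
    else if (pos == L) bt$R2$sub[iR2, ]
    else model$substitution[b[pos - 2L] * 256L + b[pos - 1L] * 64L +
                            b[pos] * 16L + b[pos + 1L] * 4L + b[pos + 2L] + 1L, ]
  }
  list(mutability = out, subrow = subrow)
}

#' Total mutability of a sequence
#'
#' The per-day mutation rate of a whole sequence: the global multiplier times
#' the sum over positions of the centred 5-mer mutability. Boundary positions
#' (the first and last two) use N-padded motifs whose mutability is the mean
#' over all full motifs matching the observed bases.
#'
#' @param seq Nucleotide string (length >= 5).
#' @param model A [mutation_model()].
#' @return Rate, 1/day.
#' @export
sequence_mutability <- function(seq, model) {
  model$multiplier * sum(position_mutability(seq, model))
}

#' Draw one somatic hypermutation
#'
#' Samples a position proportionally to per-position mutability, then a new
#' base from that position's 5-mer substitution distribution. The new base
#' always differs from the old.
#'
#' @param seq Nucleotide string (length >= 5).
#' @param model A [mutation_model()].
#' @return A list with `position` (1-based), `new_base`, and `sequence` (the
#'   mutated string).
#' @export
draw_mutation <- function(seq, model) {
  pm <- position_mutability(seq, model, with_sub = TRUE)
  tot <- sum(pm$mutability)
  if (tot <= 0) stop("all-zero mutability: no mutation can be drawn")
  pos <- sample.int(length(pm$mutability), 1L, prob = pm$mutability)
  pr <- pm$subrow(pos)
  new_base <- sample(NUC, 1L, prob = pr)
  out <- seq
  substr(out, pos, pos) <- new_base
  list(position = pos, new_base = new_base, sequence = out)
}

#' Synthesize a 5-mer mutation model
#'
#' Log-normal relative mutabilities (heavy-tailed hot/cold spots, as in
#' published SHM models) and Dirichlet(1,1,1) substitution rows over the
#' three alternative bases. The mutabilities are scaled so that a sequence of
#' `ref_length` bases has total mutability `ref_length * mean_rate_per_site`
#' per day at multiplier 1 -- 1/day for a 300 nt BCR at the default, so that
#' data-mimic samples (multiplier 0.5, 20 days) accumulate about 6 observed
#' mutations per sequence, the level seen in extracted-GC data.
#'
#' @param mean_rate_per_site Mean per-site mutation rate (1/day) at
#'   multiplier 1 (default `1/300`).
#' @param sdlog Log-scale spread of motif mutabilities (default 1).
#' @param multiplier Global mutability multiplier stored in the model
#'   (default 1; simulations override per configuration).
#' @return A [mutation_model()]. Deterministic given the RNG state.
#' @export
synth_shm_model <- function(mean_rate_per_site = 1 / 300, sdlog = 1,
                            multiplier = 1) {
  stopifnot(mean_rate_per_site > 0, sdlog > 0)
  mu <- rlnorm(1024L, meanlog = log(mean_rate_per_site) - sdlog^2 / 2,
               sdlog = sdlog)
  g <- matrix(rgamma(1024L * 4L, shape = 1), 1024L, 4L)
  centre <- (seq_len(1024L) - 1L) %/% 16L %% 4L + 1L
  g[cbind(seq_len(1024L), centre)] <- 0
  sub <- g / rowSums(g)
  mutation_model(mu, sub, multiplier = multiplier)
}

motif_strings <- function() {
  g <- expand.grid(NUC, NUC, NUC, NUC, NUC, stringsAsFactors = FALSE)
  apply(g[, 5:1], 1L, paste0, collapse = "")
}

#' Read / write a 5-mer mutation model as CSV
#'
#' S5F-style layout: columns `motif`, `mutability`, `p_to_A`, `p_to_C`,
#' `p_to_G`, `p_to_T`, with the centre-base probability 0. The multiplier is
#' recorded as a header comment.
#'
#' @param model A [mutation_model()].
#' @param path File path.
#' @return `read_shm_csv` returns a [mutation_model()]; `write_shm_csv`
#'   returns `path` invisibly.
#' @export
write_shm_csv <- function(model, path) {
  stopifnot(inherits(model, "mutation_model"))
  df <- data.frame(motif = motif_strings(),
                   mutability = signif(model$mutability, 7),
                   p_to_A = signif(model$substitution[, 1], 7),
                   p_to_C = signif(model$substitution[, 2], 7),
                   p_to_G = signif(model$substitution[, 3], 7),
                   p_to_T = signif(model$substitution[, 4], 7))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# multiplier=", format(model$multiplier, digits = 15)), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shm_csv
#' @export
read_shm_csv <- function(path) {
  first <- readLines(path, n = 1L)
  mult <- if (startsWith(first, "# multiplier="))
    as.numeric(sub("^# multiplier=", "", first)) else 1
  df <- read.csv(path, comment.char = "#")
  ord <- match(motif_strings(), df$motif)
  if (anyNA(ord)) stop("SHM CSV must contain all 1024 5-mer motifs")
  df <- df[ord, ]
  sub <- cbind(df$p_to_A, df$p_to_C, df$p_to_G, df$p_to_T)
  rs <- rowSums(sub)
  if (any(abs(rs - 1) > 1e-3))
    stop("substitution rows must sum to 1")
  sub <- sub / rs # absorb CSV rounding
  mutation_model(df$mutability, sub, multiplier = mult)
}
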