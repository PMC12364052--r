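#' Affinity relative to the naive antibody
#'
#' Affinity is measured as `x = -log10(KD / KD_naive)`, i.e. the number of
#' orders of magnitude by which a variant's dissociation constant improves on
#' the naive antibody's (KD_naive ~ 40 nM for the system this package
#' emulates). Larger `x` means stronger binding; the naive sequence sits at
#' `x = 0`.
#'
#' @param kd Dissociation constant of the variant (molar), positive.
#' @param kd_naive Dissociation constant of the naive antibody (molar),
#'   positive.
#' @return Dimensionless affinity `x`.
#' @examples
#' affinity_from_kd(1e-10, 4e-8) # ~2.6
#' affinity_from_kd(1e-6, 4e-8)  # ~-1.4
#' @export
affinity_from_kd <- function(kd, kd_naive) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("kd must be positive and finite")
  if (any(!is.finite(kd_naive)) || any(kd_naive <= 0))
    stop("kd_naive must be positive and finite")
  -log10(kd / kd_naive)
}

#' Recover KD from an affinity value
#'
#' Inverse of [affinity_from_kd()]: `kd = kd_naive * 10^(-x)`.
#'
#' @param x Affinity.
#' @param kd_naive Naive dissociation constant (molar).
#' @return KD in molar.
#' @export
kd_from_affinity <- function(x, kd_naive) {
  kd_naive * 10^(-x)
}

#' Deep-mutational-scan affinity table
#'
#' A `dms_table` holds the per-site, per-amino-acid affinity effects of a
#' deep mutational scan on the naive antibody, on the `-log10(KD/KD_naive)`
#' scale. Effects of multi-mutants combine additively (no epistasis). Sites
#' are 1-based over the translated naive protein; the naive residue at every
#' site has effect exactly 0.
#'
#' @param naive_protein Amino-acid string of the naive antibody.
#' @param effects Numeric matrix, `nchar(naive_protein)` rows by 20 columns
#'   (columns in the fixed order `ACDEFGHIKLMNPQRSTVWY`), giving the affinity
#'   change of substituting each amino acid at each site. Entries for the
#'   naive residue must be 0.
#' @return An object of class `dms_table`.
#' @export
dms_table <- function(naive_protein, effects) {
  stopifnot(is.character(naive_protein), length(naive_protein) == 1L)
  naive_aa <- strsplit(naive_protein, "")[[1]]
  L <- length(naive_aa)
  if (!all(naive_aa %in% AA20))
    stop("naive protein contains non-standard residues (is it functional?)")
  effects <- as.matrix(effects)
  if (!identical(dim(effects), c(L, 20L)))
    stop("effects must be a ", L, " x 20 matrix")
  if (any(!is.finite(effects)))
    stop("all DMS effects must be finite")
  colnames(effects) <- AA20
  naive_idx <- match(naive_aa, AA20)
  naive_eff <- effects[cbind(seq_len(L), naive_idx)]
  if (any(abs(naive_eff) > 1e-12))
    stop("effect of the naive residue must be 0 at every site")
  structure(list(naive_protein = naive_protein, effects = effects),
            class = "dms_table")
}

#' @export
print.dms_table <- function(x, ...) {
  cat("<dms_table> ", nchar(x$naive_protein), " sites x 20 amino acids\n",
      "  effect range: [", round(min(x$effects), 3), ", ",
      round(max(x$effects), 3), "]\n", sep = "")
  invisible(x)
}

#' Affinity of a nucleotide sequence under an additive DMS map
#'
#' Translates `seq` and the naive sequence and sums the tabulated DMS effect
#' of every amino-acid difference. Synonymous changes contribute 0; stop
#' codons are not scored here (see [is_nonfunctional()]); positions where the
#' mutant residue is a stop are skipped so that the caller can apply the
#' nonfunctional death-rate rule instead.
#'
#' @param seq,naive_seq In-frame nucleotide strings of equal length.
#' @param dms A [dms_table()].
#' @return Affinity (dimensionless).
#' @export
affinity_of_sequence <- function(seq, naive_seq, dms) {
  stopifnot(inherits(dms, "dms_table"))
  seq <- validate_nt(seq); naive_seq <- validate_nt(naive_seq)
  if (nchar(seq) != nchar(naive_seq))
    stop("sequence length (", nchar(seq), ") != naive length (",
         nchar(naive_seq), ")")
  aa <- strsplit(translate_nt(seq), "")[[1]]
  naive_aa <- strsplit(translate_nt(naive_seq), "")[[1]]
  if (!identical(naive_aa, strsplit(dms$naive_protein, "")[[1]]))
    stop("naive sequence does not translate to the DMS table's naive protein")
  diff <- which(aa != naive_aa & aa != "*")
  if (!length(diff)) return(0)
  col <- match(aa[diff], AA20)
  if (anyNA(col))
    stop("mutant residue absent from DMS table at site(s) ",
         paste(diff[is.na(col)], collapse = ", "))
  sum(dms$effects[cbind(diff, col)])
}

#' Does a sequence contain a stop codon?
#'
#' @param seq In-frame nucleotide string (length divisible by 3).
#' @return `TRUE` if the translation contains a stop codon.
#' @export
is_nonfunctional <- function(seq) {
  grepl("*", translate_nt(seq), fixed = TRUE)
}

#' Synthesize a DMS affinity table
#'
#' Generates a complete synthetic deep-mutational-scan table over all sites
#' and the 19 non-naive amino acids, emulating the shape of real antibody
#' DMS data: most substitutions are deleterious (drawn from a gamma-shaped
#' left tail) with a small fraction beneficial, so that additive multi-mutant
#' affinities can span roughly -37 to +3 as seen in sampled sequences.
#'
#' @param naive_seq In-frame, functional naive nucleotide sequence.
#' @param frac_beneficial Fraction of non-naive substitutions with a positive
#'   effect (default 0.05).
#' @param effect_scale Scale (affinity units) of the deleterious effect
#'   distribution (default 1).
#' @param beneficial_scale Scale of the beneficial tail (default 0.3,
#'   calibrated so that data-mimic samples under selection reproduce the
#'   observed affinity spread: mean near -0.3, maximum near +3).
#' @return A [dms_table()]. Deterministic given the RNG state (`set.seed()`).
#' @export
synth_dms <- function(naive_seq, frac_beneficial = 0.05, effect_scale = 1,
                      beneficial_scale = 0.3) {
  if (frac_beneficial < 0 || frac_beneficial > 1)
    stop("frac_beneficial must be in [0, 1]")
  if (effect_scale <= 0 || beneficial_scale <= 0)
    stop("effect scales must be positive")
  naive_seq <- validate_nt(naive_seq)
  if (is_nonfunctional(naive_seq))
    stop("naive sequence must be functional (no stop codons)")
  prot <- translate_nt(naive_seq)
  naive_aa <- strsplit(prot, "")[[1]]
  L <- length(naive_aa)
  n <- L * 20L
  ben <- matrix(runif(n) < frac_beneficial, L, 20L)
  mag_del <- matrix(rgamma(n, shape = 1.2, scale = effect_scale), L, 20L)
  mag_ben <- matrix(rgamma(n, shape = 1.0, scale = beneficial_scale), L, 20L)
  eff <- ifelse(ben, mag_ben, -mag_del)
  eff[cbind(seq_len(L), match(naive_aa, AA20))] <- 0
  dms_table(prot, eff)
}

#' Generate a synthetic naive antibody nucleotide sequence
#'
#' Draws a random in-frame coding sequence with no stop codons, standing in
#' for the naive BCR sequence that seeds every simulated germinal center.
#'
#' @param n_codons Number of codons (default 100).
#' @return A nucleotide string of length `3 * n_codons`.
#' @export
synth_naive_seq <- function(n_codons = 100L) {
  stopifnot(n_codons >= 2L)
  map <- get_codon_map()
  ok <- names(map)[map != "*"]
  paste0(sample(ok, n_codons, replace = TRUE), collapse = "")
}

#' Read / write a DMS table as CSV
#'
#' Long format with columns `site` (1-based), `aa` (single letter),
#' `delta_affinity` (float); the naive residue rows carry 0. A header comment
#' line records the naive protein.
#'
#' @param dms A [dms_table()].
#' @param path File path.
#' @return `read_dms_csv` returns a [dms_table()]; `write_dms_csv` returns
#'   `path` invisibly.
#' @export
write_dms_csv <- function(dms, path) {
  stopifnot(inherits(dms, "dms_table"))
  L <- nchar(dms$naive_protein)
  df <- data.frame(site = rep(seq_len(L), each = 20L),
                   aa = rep(AA20, L),
                   delta_affinity = signif(as.vector(t(dms$effects)), 7))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# naive_protein=", dms$naive_protein), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dms_csv
#' @export
read_dms_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# naive_protein="))
    stop("missing '# naive_protein=' header in ", path)
  prot <- sub("^# naive_protein=", "", first)
  df <- read.csv(path, comment.char = "#")
  need <- c("site", "aa", "delta_affinity")
  if (!all(need %in% names(df)))
    stop("DMS CSV must have columns: ", paste(need, collapse = ", "))
  L <- nchar(prot)
  eff <- matrix(NA_real_, L, 20L, dimnames = list(NULL, AA20))
  eff[cbind(df$site, match(df$aa, AA20))] <- df$delta_affinity
  if (anyNA(eff))
    stop("incomplete DMS table: every (site, amino acid) pair is required")
  dms_table(prot, eff)
}
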