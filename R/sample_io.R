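#' Write / read a simulated GC sample as plain-text files
#'
#' Each GC gets a Newick file (`gc0001.nwk`, with time and affinity node
#' comments) and a FASTA of its sampled sequences (`gc0001.fasta`); the
#' directory also holds `manifest.csv` (per-GC truth parameters) and
#' `leaf_stats.csv` (per-leaf mutation counts, so summary statistics can be
#' recomputed from disk).
#'
#' @param sample A `gc_sample` from [simulate_gcs()].
#' @param dir Output directory.
#' @export
write_gc_sample <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); leaves <- list()
  for (i in seq_along(sample)) {
    s <- sample[[i]]
    stem <- sprintf("gc%04d", i)
    write_annotated_newick(s$tree, file.path(dir, paste0(stem, ".nwk")))
    write_fasta(s$sequences, file.path(dir, paste0(stem, ".fasta")))
    p <- s$params
    rows[[i]] <- data.frame(gc = stem, xc = p$xc, xh = p$xh, yc = p$yc,
                            yh = p$yh, capacity = s$config$capacity,
                            init_population = s$config$init_population,
                            t_sample = s$config$t_sample,
                            death_rate = s$config$death_rate_functional,
                            n_tip = s$tree$n_tip)
    leaves[[i]] <- data.frame(gc = stem, tip = names(s$sequences),
                              n_mutations = s$n_mutations,
                              path_mutations = s$path_mutations)
  }
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, leaves), file.path(dir, "leaf_stats.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_gc_sample
#' @return `read_gc_sample`: a `gc_sample` list whose elements carry the
#'   tree, sequences and per-leaf mutation counts (sufficient for encoding
#'   and summary statistics; the living-population snapshot is not stored
#'   on disk).
#' @export
read_gc_sample <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"))
  leaf <- read.csv(file.path(dir, "leaf_stats.csv"))
  out <- lapply(seq_len(nrow(man)), function(i) {
    stem <- man$gc[i]
    tree <- read_annotated_newick(file.path(dir, paste0(stem, ".nwk")))
    seqs <- read_fasta(file.path(dir, paste0(stem, ".fasta")))
    seqs <- seqs[tree$tip_label]
    ls <- leaf[leaf$gc == stem, ]
    ls <- ls[match(tree$tip_label, ls$tip), ]
    structure(list(
      tree = tree, sequences = seqs,
      n_mutations = ls$n_mutations, path_mutations = ls$path_mutations,
      living = NULL,
      params = response_params(man$xc[i], man$xh[i], man$yc[i], man$yh[i]),
      config = list(capacity = man$capacity[i],
                    init_population = man$init_population[i],
                    t_sample = man$t_sample[i],
                    death_rate_functional = man$death_rate[i]),
      n_tries = NA_integer_), class = "simulated_gc")
  })
  structure(out, class = "gc_sample")
}
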