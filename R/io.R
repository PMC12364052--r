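#' Read / write FASTA
#'
#' Thin wrappers over Biostrings with the conventions used throughout:
#' named character vectors in, named character vectors out, deterministic
#' record order, duplicate ids rejected.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: a named character vector (possibly empty).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- setNames(as.character(set), names(set))
  if (anyDuplicated(names(out)))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Keys mirror the simulation parameter table: `naive_fasta`, `dms_csv`,
#' `shm_csv` (paths, resolved relative to the YAML file), the sigmoid
#' parameters `xscale`, `xshift`, `yscale`, `yshift` (values or
#' `[lo, hi]` bounds plus `naive_birth_rate` bounds), and the non-sigmoid
#' settings `carrying_capacity`, `capacity_method`, `initial_population`,
#' `time_to_sampling`, `seqs_per_gc`, `death_rate_functional`,
#' `death_rate_stops`, `mutability_multiplier`.
#'
#' @param path YAML file path.
#' @return A list with a [gc_config()] under `$config` (when all sigmoid
#'   values are scalars) or [param_bounds()] under `$bounds` (when they are
#'   ranges), plus the raw values.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  naive <- unname(read_fasta(resolve(raw$naive_fasta))[1])
  dms <- read_dms_csv(resolve(raw$dms_csv))
  shm <- read_shm_csv(resolve(raw$shm_csv))
  sig <- raw[c("xscale", "xshift", "yscale", "yshift")]
  scalar <- all(lengths(sig) == 1L)
  out <- list(raw = raw, naive_seq = naive, dms = dms, shm = shm)
  get <- function(key, default) raw[[key]] %||% default
  if (scalar) {
    out$config <- gc_config(
      naive, dms, shm,
      response = response_params(sig$xscale, sig$xshift, sig$yscale,
                                 sig$yshift),
      capacity = get("carrying_capacity", 500),
      capacity_method = get("capacity_method", "birth"),
      init_population = get("initial_population", 128L),
      t_sample = get("time_to_sampling", 20),
      sample_size = get("seqs_per_gc", c(60L, 95L)),
      death_rate_functional = get("death_rate_functional", 0.2),
      death_rate_stops = get("death_rate_stops", 10),
      mutability_multiplier = get("mutability_multiplier", 0.5))
  } else {
    out$bounds <- param_bounds(
      xc = unlist(sig$xscale), xh = unlist(sig$xshift),
      yc = unlist(sig$yscale), yh = unlist(sig$yshift),
      lambda0 = unlist(get("naive_birth_rate", c(0.1, 15))))
    out$ranges <- list(
      capacity = unlist(get("carrying_capacity", c(500, 2000))),
      t_sample = unlist(get("time_to_sampling", c(10, 35))),
      init_population = unlist(get("initial_population", c(8L, 128L))),
      death_rate = unlist(get("death_rate_functional", c(0.05, 0.5))),
      sample_size = unlist(get("seqs_per_gc", c(50L, 130L))),
      mutability_multiplier = get("mutability_multiplier", 0.68))
  }
  out
}

#' Write a provenance stamp next to pipeline outputs
#'
#' Records the resolved settings, the seed, the package version, and a hash
#' of the settings, so every output directory is self-describing.
#'
#' @param dir Output directory (created if needed).
#' @param settings List of resolved settings.
#' @param seed The root RNG seed of the invocation.
#' @export
write_provenance <- function(dir, settings, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(
    package = "gcresponse",
    version = as.character(utils::packageVersion("gcresponse")),
    seed = seed,
    config_hash = rlang::hash(settings),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    settings = settings)
  jsonlite::write_json(stamp, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(file.path(dir, "provenance.json"))
}

#' Save / load a trained model directory
#'
#' The directory holds `weights.json` (current and EMA weights),
#' `config.json` (architecture, clip bounds, domain), and `scaler.json`.
#'
#' @param net A trained `gcnn`.
#' @param dir Model directory.
#' @export
write_gcnn <- function(net, dir) {
  stopifnot(inherits(net, "gcnn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- function(ps) lapply(ps, function(l)
    list(W = list(dim = dim(l$W), data = as.vector(l$W)), b = l$b))
  jsonlite::write_json(
    list(params = flat(net$params), ema = flat(net$ema)),
    file.path(dir, "weights.json"), auto_unbox = FALSE, digits = NA)
  jsonlite::write_json(
    list(arch = net$arch, aux_inputs = net$aux_inputs,
         per_bin = net$per_bin, clip = as.vector(net$clip),
         domain = net$domain, trained = net$trained,
         history = net$history),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(net$scaler))
    write_tree_scaler(net$scaler, file.path(dir, "scaler.json"))
  invisible(dir)
}

#' @rdname write_gcnn
#' @export
read_gcnn <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  net <- build_network(width = cfg$arch$width, channels = cfg$arch$channels,
                       output_dim = cfg$arch$output_dim,
                       aux_inputs = cfg$aux_inputs, n_aux = cfg$arch$n_aux,
                       per_bin = cfg$per_bin,
                       clip = matrix(cfg$clip, ncol = 2L),
                       domain = cfg$domain)
  w <- jsonlite::read_json(file.path(dir, "weights.json"),
                           simplifyVector = TRUE)
  unflat <- function(ps) lapply(ps, function(l)
    list(W = matrix(l$W$data, l$W$dim[1], l$W$dim[2]), b = l$b))
  net$params <- unflat(w$params)
  net$ema <- unflat(w$ema)
  net$trained <- isTRUE(cfg$trained)
  net$history <- cfg$history
  scp <- file.path(dir, "scaler.json")
  if (file.exists(scp)) net$scaler <- read_tree_scaler(scp)
  net
}
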