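# End-to-end orchestration: validated run configuration, staged execution
# (ensemble -> contacts -> MFCC -> hot spots -> peptides), reproducible
# manifest.

CONFIG_KEYS <- list(
  top = c("input", "seed", "outdir", "groups", "criteria", "backend",
          "cutoff", "water_shell", "regions", "ensemble", "peptides"),
  groups = c("a", "b"),
  criteria = c("hbond_ha_max", "hbond_da_max", "hydrophobic_min",
               "hydrophobic_max", "salt_bridge_max"),
  backend = c("kind", "dielectric", "table", "dir", "format"),
  ensemble = c("enabled", "kmin", "kmax", "reduce"),
  peptides = c("regions", "cyclize", "mutations"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file containing one) with keys
#' `input` (PDB path), `outdir`, `seed`, `groups` (`a`, `b`: chain id
#' vectors), and optional `criteria` (contact thresholds), `backend`,
#' `cutoff` (pair threshold, default 8), `water_shell`, `regions` (named
#' list `name: [chain, start, end]`), `ensemble`
#' (`enabled`/`kmin`/`kmax`/`reduce`) and `peptides`
#' (`regions`/`cyclize`/`mutations`).  Unknown keys anywhere are rejected
#' before any stage runs.
#'
#' @param config named list or YAML path.
#' @return The validated configuration (class `run_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, CONFIG_KEYS$top, "top level")
  for (sec in c("groups", "criteria", "backend", "ensemble", "peptides"))
    if (!is.null(config[[sec]]))
      check_keys(config[[sec]], CONFIG_KEYS[[sec]], sec)
  if (is.null(config$input)) stop("config lacks 'input'")
  if (is.null(config$outdir)) stop("config lacks 'outdir'")
  if (is.null(config$groups$a) || is.null(config$groups$b))
    stop("config needs groups$a and groups$b chain sets")
  if (length(intersect(config$groups$a, config$groups$b)))
    stop("chain groups overlap")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$cutoff)) config$cutoff <- 8.0
  structure(config, class = "run_config")
}

config_criteria <- function(config) {
  do.call(contact_criteria, config$criteria %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_regions <- function(config) {
  if (is.null(config$regions)) return(cdr_regions())
  lapply(names(config$regions), function(nm) {
    r <- config$regions[[nm]]
    region_def(nm, as.character(r[[1]]),
               list(c(as.integer(r[[2]]), as.integer(r[[3]]))))
  })
}

#' Run the full interface-decomposition pipeline
#'
#' Stages, in order: read the (possibly multi-model) input structure;
#' optionally select representative conformations (featurization + Gaussian
#' mixture + silhouette); detect interface contacts on every conformation
#' and summarize their conservation; decompose the first (or representative)
#' conformation's interface into MFCC pair energies; aggregate hot spots per
#' residue and region; extract and characterize mimetic peptides from the
#' configured regions.  Every output file is listed in a JSON manifest with
#' its MD5 hash, the seed and the package version; rerunning an identical
#' configuration reproduces identical hashes.
#'
#' @param config named list, YAML path, or `run_config`.
#' @return The manifest, invisibly (list).
#' @export
run_all <- function(config) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  message("stage input: reading ", config$input)
  models <- read_pdb(config$input,
                     keep_waters = !is.null(config$water_shell))
  criteria <- config_criteria(config)
  ga <- as.character(config$groups$a); gb <- as.character(config$groups$b)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  energy_model <- 1L
  ens_info <- NULL
  if (isTRUE(config$ensemble$enabled) && length(models) >= 4L) {
    message("stage ensemble: ", length(models), " conformations")
    traj <- as_trajectory(models)
    feats <- featurize(traj)
    kmax <- config$ensemble$kmax %||% 10L
    kmin <- config$ensemble$kmin %||% 2L
    em <- select_representatives(feats, k_range = kmin:kmax,
                                 reduce = isTRUE(config$ensemble$reduce),
                                 seed = config$seed)
    ens_info <- list(n_clusters = em$n_clusters,
                     representatives = em$representatives)
    energy_model <- em$representatives[1]
    emit(data.frame(frame = seq_along(em$labels), cluster = em$labels),
         "ensemble_clusters.csv")
  }

  message("stage contacts: scanning ", length(models), " conformation(s)")
  clists <- lapply(models, function(m) {
    rbind(detect_hbonds(m, ga, gb, criteria, mode = "heavy_only"),
          detect_hydrophobic(m, ga, gb, criteria),
          detect_salt_bridges(m, ga, gb, criteria))
  })
  emit(clists[[energy_model]], "contacts.csv")
  cons <- conservation(clists)
  emit(cons$counts, "contact_conservation.csv")

  message("stage mfcc: interface energies (model ", energy_model, ")")
  bk <- config$backend %||% list()
  backend <- backend_config(kind = bk$kind %||% "classical",
                            dielectric = bk$dielectric %||% 40,
                            table = bk$table, dir = bk$dir,
                            format = bk$format %||% "pdb")
  recs <- interface_energies(models[[energy_model]], ga, gb, backend,
                             cutoff = config$cutoff,
                             water_shell = config$water_shell)
  emit(as.data.frame(recs), "energies.csv")

  message("stage hotspots")
  regions <- config_regions(config)
  report <- hotspot_report(recs, regions, side = "a")
  hs_path <- file.path(outdir, "hotspots.json")
  write_hotspot_report(report, hs_path)
  files <- c(files, hs_path)

  pep_rows <- NULL
  if (!is.null(config$peptides)) {
    message("stage peptides")
    wanted <- config$peptides$regions %||%
      vapply(regions, function(r) r$name, "")
    peps <- list()
    for (nm in wanted) {
      reg <- regions[[match(nm, vapply(regions, function(r) r$name, ""))]]
      if (is.null(reg)) stop("peptide region not defined: ", nm)
      p <- extract_segment(models[[energy_model]], reg)
      for (mu in config$peptides$mutations %||% list())
        if (identical(mu$region, nm))
          p <- mutate_peptide(p, mu$position, mu$to)
      peps <- c(peps, list(p))
      if (isTRUE(config$peptides$cyclize)) peps <- c(peps, list(cyclize(p)))
    }
    pep_rows <- design_report(peps)
    emit(pep_rows, "peptides.csv")
  }

  manifest <- list(
    package = "epitopedecomp",
    version = as.character(utils::packageVersion("epitopedecomp")),
    seed = config$seed,
    input = config$input,
    input_md5 = unname(tools::md5sum(config$input)),
    n_models = length(models),
    ensemble = ens_info,
    total_energy = attr(recs, "total"),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
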