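#' Load a configuration file
#'
#' Reads a YAML or JSON configuration and builds a validated [bsm_config()].
#' The file may contain any of the scalar arguments of [bsm_config()] at the
#' top level plus optional `hippo` and `bell` sections whose entries are
#' passed to [hippo_params()] and [bell_params()]. Unknown keys are rejected
#' with an error naming the key; all constraints are enforced by the
#' constructors. An empty file yields the full default configuration.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @return A [bsm_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a mapping", call. = FALSE)
  config_from_list(raw)
}

config_from_list <- function(raw) {
  top_args <- setdiff(names(formals(bsm_config)), c("hippo", "bell"))
  unknown <- setdiff(names(raw), c(top_args, "hippo", "bell"))
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  hippo_args <- raw$hippo %||% list()
  bad <- setdiff(names(hippo_args), names(formals(hippo_params)))
  if (length(bad) > 0)
    stop(sprintf("unknown hippo key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (!is.null(hippo_args$prod))
    hippo_args$prod <- unlist(modifyList(
      as.list(formals(hippo_params)$prod)[-1], as.list(hippo_args$prod)))
  if (!is.null(hippo_args$deg))
    hippo_args$deg <- unlist(modifyList(
      as.list(formals(hippo_params)$deg)[-1], as.list(hippo_args$deg)))
  bell_args <- raw$bell %||% list()
  bad <- setdiff(names(bell_args), names(formals(bell_params)))
  if (length(bad) > 0)
    stop(sprintf("unknown bell key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (!is.null(bell_args$jub_K)) bell_args$jub_K <- unlist(bell_args$jub_K)
  args <- raw[intersect(names(raw), top_args)]
  args$hippo <- do.call(hippo_params, hippo_args)
  args$bell <- do.call(bell_params, bell_args)
  do.call(bsm_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical checksum of a configuration
#'
#' MD5 of the canonicalized (recursively name-sorted) JSON serialization of
#' the configuration; insensitive to key order, stable across sessions.
#'
#' @param config A [bsm_config()].
#' @return Hex checksum string.
#' @export
config_checksum <- function(config) {
  canonical <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canonical)
      if (!is.null(names(x))) x[order(names(x))] else x
    } else x
  }
  js <- jsonlite::toJSON(canonical(unclass(config)), digits = NA,
                         auto_unbox = TRUE, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Write a scan result with a run manifest
#'
#' Writes the tidy result table as an RFC-4180-style CSV (UTF-8, header row,
#' one record per row) plus a JSON run manifest carrying the experiment id,
#' the canonical configuration checksum, package version, file list and
#' timestamp. A write/read round trip reproduces the table.
#'
#' @param result A data frame (e.g. from the experiment drivers).
#' @param dir Output directory (created if needed).
#' @param experiment Experiment identifier used in file names.
#' @param config Optional [bsm_config()] recorded in the manifest.
#' @return Invisibly, a list with `files` (paths written) and `manifest`.
#' @export
write_results <- function(result, dir, experiment = "experiment",
                          config = NULL) {
  stopifnot(is.data.frame(result))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory: %s", dir), call. = FALSE)
  csv <- file.path(dir, paste0(experiment, ".csv"))
  utils::write.csv(result, csv, row.names = FALSE)
  manifest <- list(
    experiment = experiment,
    config_checksum = if (is.null(config)) NA else config_checksum(config),
    package_version = as.character(utils::packageVersion("hippomech")),
    n_records = nrow(result),
    columns = names(result),
    files = basename(csv),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  mf <- file.path(dir, paste0(experiment, "-manifest.json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(files = c(csv, mf), manifest = manifest))
}

#' Read back a result CSV
#'
#' @param path CSV path written by [write_results()].
#' @return Data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Experiment presets
#'
#' Registry tying the canonical experiment names to configuration templates
#' with the published settings pre-filled: `fig4` (Fat-production scan),
#' `fig10` (single-junction force sweep), `fig11` (Vinculin dependence of
#' the crossovers), `fig13` (mechanical swelling/stretch demo), `fig15`
#' (tension by alpha-catenin grid), `fig16`/`fig17` (centre-cell
#' alpha-catenin perturbation at boundary level 30 molecules/node under
#' -100/+100 pN and 800/100 pN), `fig18` (growth on/off comparison), `fig19`
#' (Jub-production scan, boundary 250 nM/min, 800 pN).
#'
#' @param name Preset name.
#' @return List with `name`, `experiment` (driver to use), `config` (a
#'   [bsm_config()]) and `args` (driver arguments).
#' @export
experiment_preset <- function(name = c("fig4", "fig10", "fig11", "fig13",
                                       "fig15", "fig16", "fig17", "fig18",
                                       "fig19")) {
  name <- match.arg(name)
  base <- switch(
    name,
    fig4 = list(experiment = "fat_production_scan", config = bsm_config(),
                args = list(fat_production_range = seq(0.3, 3,
                                                       length.out = 9))),
    fig10 = list(experiment = "single_junction", config = bsm_config(),
                 args = list(force_grid = seq(0, 15, by = 0.05))),
    fig11 = list(experiment = "crossover_vinculin", config = bsm_config(),
                 args = list(vinculin_grid = seq(0, 10, by = 2))),
    fig13 = list(experiment = "mech_demo", config = bsm_config(),
                 args = list(area_scale = 1.5,
                             forces = c(0, 800, -100))),
    fig15 = list(experiment = "tension_catenin_heatmap",
                 config = bsm_config(),
                 args = list(tension_grid = seq(200, 1000, length.out = 10),
                             catenin_grid = seq(5, 100, length.out = 10))),
    fig16 = list(experiment = "center_perturbation",
                 config = growth_experiment_config(),
                 args = list(boundary_catenin = 30,
                             boundary_forces = c(-100, 100))),
    fig17 = list(experiment = "differential_response_scan",
                 config = growth_experiment_config(),
                 args = list(boundary_catenin = 30,
                             boundary_forces = c(800, 100))),
    fig18 = list(experiment = "growth_comparison",
                 config = growth_experiment_config(),
                 args = list(boundary_catenin = 30,
                             boundary_forces = c(800, 100))),
    fig19 = list(experiment = "jub_production_scan",
                 config = growth_experiment_config(),
                 args = list(boundary_jub = 250, boundary_force = 800)))
  c(list(name = name), base)
}

#' Run an experiment preset
#'
#' Executes the driver behind a preset, optionally at reduced problem size
#' (shorter coupled horizon, coarser sweep) and writes the tidy results.
#'
#' @param name Preset name (see [experiment_preset()]).
#' @param dir Optional output directory passed to [write_results()].
#' @param reduced Use a reduced sweep/horizon.
#' @return The result data frame (invisibly when `dir` is given).
#' @export
run_preset <- function(name, dir = NULL, reduced = FALSE) {
  pr <- experiment_preset(name)
  cfg <- pr$config
  if (reduced) {
    cfg$horizon <- 20
    cfg$dt_couple <- 1
  }
  res <- switch(
    pr$experiment,
    fat_production_scan = fat_production_scan(
      cfg$hippo, pr$args$fat_production_range),
    single_junction = {
      fg <- pr$args$force_grid
      if (reduced) fg <- seq(0, 15, by = 0.5)
      do.call(rbind, lapply(fg, function(f) {
        occ <- equilibrium_occupancy(f, cfg$bell, cfg$vinculin)
        bj <- bound_jub(f, cfg$bell, cfg$vinculin,
                        jub_pool = cfg$bell$n_cat)
        data.frame(force = f, C1 = occ[1], C2 = occ[2], C3 = occ[3],
                   bound_jub = bj[["bound"]], free_jub = bj[["free"]])
      }))
    },
    crossover_vinculin = {
      vg <- pr$args$vinculin_grid
      do.call(rbind, lapply(vg, function(v) data.frame(
        vinculin = v,
        c1c2 = crossover_force("C1C2", cfg$bell, V = v),
        c2c3 = crossover_force("C2C3", cfg$bell, V = v))))
    },
    mech_demo = {
      do.call(rbind, lapply(pr$args$forces, function(bf) {
        net <- build_hex_patch(cfg$edge_length, cfg$KN, cfg$KT, cfg$Xi,
                               cfg$FA_belt, cfg$FA_transverse)
        net <- apply_swelling(net, 1, pr$args$area_scale)
        rel <- integrate_network(net, imposed = bf, horizon = 300)
        areas <- cell_areas(rel)
        data.frame(boundary_force = bf, cell = 1:7, area = areas,
                   side_cv = vapply(1:7, function(ci) {
                     s <- cell_side_lengths(rel, ci)
                     stats::sd(s) / mean(s)
                   }, numeric(1)))
      }))
    },
    tension_catenin_heatmap = {
      tg <- pr$args$tension_grid; cg <- pr$args$catenin_grid
      if (reduced) {
        tg <- seq(200, 1000, length.out = 4)
        cg <- seq(5, 100, length.out = 4)
      }
      tension_catenin_heatmap(cfg, tg, cg)
    },
    center_perturbation = center_perturbation(
      cfg, if (reduced) c(20, 30, 40) else seq(20, 40, by = 5),
      pr$args$boundary_catenin, pr$args$boundary_forces),
    differential_response_scan = differential_response_scan(
      cfg, if (reduced) c(20, 30, 40) else seq(20, 40, by = 5),
      pr$args$boundary_catenin, pr$args$boundary_forces),
    growth_comparison = {
      rng <- if (reduced) c(20, 30, 40) else seq(20, 40, by = 5)
      on <- center_perturbation(cfg, rng, pr$args$boundary_catenin,
                                pr$args$boundary_forces)
      cfg_off <- cfg; cfg_off$growth_enabled <- FALSE
      off <- center_perturbation(cfg_off, rng, pr$args$boundary_catenin,
                                 pr$args$boundary_forces)
      on$growth <- "on"; off$growth <- "off"
      rbind(on, off)
    },
    jub_production_scan = jub_production_scan(
      cfg, if (reduced) c(50, 250, 450) else seq(50, 450, by = 100),
      pr$args$boundary_jub, pr$args$boundary_force))
  if (!is.null(dir)) {
    write_results(res, dir, pr$name, cfg)
    return(invisible(res))
  }
  res
}
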