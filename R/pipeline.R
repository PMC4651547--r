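#' Read and validate a pipeline configuration
#'
#' YAML with top-level sections `structure` (either `path`/`format` with
#' optional `cterm_sequence`, `termini`, `hetero_charges`, `selections`, or
#' `synthetic` describing a generator), `surface` ([surface_spec()] fields),
#' `scan` ([scan_config()] fields), optional `field` ([field_spec()]
#' fields), `outputs` (`dir`), `seed` and `log_level`.  Unknown keys at any
#' of these levels are rejected before any computation.
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("structure", "surface", "scan", "field", "outputs",
                    "seed", "log_level"), "top level")
  if (is.null(cfg$structure)) stop("config needs a 'structure' section")
  check_keys(cfg$structure,
             c("path", "format", "synthetic", "cterm_sequence", "termini",
               "hetero_charges", "selections"), "structure")
  if (!is.null(cfg$structure$synthetic))
    check_keys(cfg$structure$synthetic,
               c("kind", "n_atoms", "radius", "cap_half_angle",
                 "cap_charge", "q", "separation"), "structure.synthetic")
  check_keys(cfg$surface,
             c("nx", "ny", "thiol_spacing", "protonation_fraction",
               "headgroup_charge_protonated", "seed", "gold_layers"),
             "surface")
  check_keys(cfg$scan,
             c("theta_step", "psi_step", "gap", "dielectric", "cutoff",
               "k_minima", "basin_separation"), "scan")
  check_keys(cfg$field,
             c("field_z", "pzc", "applied_potential", "weight"), "field")
  check_keys(cfg$outputs, c("dir", "formats"), "outputs")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$log_level <- cfg$log_level %||% "info"
  attr(cfg, "config_path") <- path
  class(cfg) <- "pipeline_config"
  cfg
}

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible(TRUE))
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Run the full orientation-screening pipeline
#'
#' Stages, in order: load (or generate) and parameterize the protein, build
#' the SAM-coated slab, scan the (theta, psi) grid, select the favourable
#' orientations, compute per-pose observables (dipole magnitude and angle
#' to the surface normal, surface distances for every named selection),
#' optionally re-rank under the interfacial field, and write the landscape
#' (CSV + JSON), the selected poses (multi-MODEL PDB) and the run report
#' (JSON).  Identical config + seed gives bit-identical outputs (no
#' timestamps are embedded).
#'
#' @param config a [read_pipeline_config()] result, or a path to a YAML
#'   config.
#' @return the run report (class `run_report`), invisibly written to
#'   `outputs/report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_info <- function(...) {
    if (!identical(config$log_level, "quiet")) message("[samscan] ", ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  protein <- stage("structure", {
    sc <- config$structure
    if (!is.null(sc$synthetic)) {
      syn <- sc$synthetic
      m <- switch(syn$kind %||% "patchy_sphere",
                  patchy_sphere = make_patchy_sphere(
                    n_atoms = syn$n_atoms %||% 200L,
                    radius = syn$radius %||% 15,
                    cap_half_angle = syn$cap_half_angle %||% 60,
                    cap_charge = syn$cap_charge %||% -1,
                    seed = config$seed),
                  dumbbell = make_dumbbell(q = syn$q %||% 0.5,
                                           separation = syn$separation %||% 2),
                  stop("unknown synthetic kind: ", syn$kind))
      m
    } else {
      m <- read_structure(sc$path, format = sc$format %||% "auto")
      if (!is.null(sc$cterm_sequence))
        m <- append_cterm_helix(m, sc$cterm_sequence)
      hc <- if (!is.null(sc$hetero_charges))
        do.call(rbind, lapply(sc$hetero_charges, as.data.frame))
      m <- parameterize(m, termini = sc$termini %||% "charged",
                        hetero_charges = hc)
      if (!is.null(sc$selections))
        for (lab in names(sc$selections))
          m$selections[[lab]] <-
            which(m$atoms$atom_name %in% sc$selections[[lab]])
      m
    }
  })
  par_info <- attr(protein, "parameterization") %||% list(n_defaulted = 0L)
  log_info("structure: ", n_atoms(protein), " atoms, net charge ",
           sprintf("%+.2f", protein$net_charge), " e (",
           par_info$n_defaulted, " default-parameterized)")

  surface <- stage("surface", {
    sspec <- do.call(surface_spec, c(config$surface %||% list(),
                                     list()))
    build_sam_surface(sspec)
  })
  log_info("surface: ", length(surface$protonated_indices), "/",
           surface$spec$nx * surface$spec$ny, " chains protonated, net ",
           sprintf("%+.1f", surface$net_charge), " e")

  scfg <- stage("scan-config", do.call(scan_config, config$scan %||% list()))
  landscape <- stage("scan", scan_orientations(protein, surface, scfg))
  log_info("landscape: ", length(landscape$theta_values), " x ",
           length(landscape$psi_values), " orientations, min ",
           sprintf("%.2f", min(landscape$energies)), " kcal/mol")

  ranked <- landscape
  if (!is.null(config$field)) {
    fs <- do.call(field_spec, config$field)
    dip <- scan_dipoles(protein, landscape)
    ranked <- stage("field-rerank", field_rerank(landscape, dip, fs))
  }

  poses <- stage("select", select_minima(ranked))
  posed_models <- list()
  pose_rows <- lapply(poses, function(p) {
    m <- rotate_model(protein, p$theta, p$psi)
    m <- suppressWarnings(place_above(m, surface, scfg$gap))
    posed_models[[length(posed_models) + 1L]] <<- m
    dr <- dipole_moment(m)
    dists <- lapply(names(m$selections), function(lab)
      surface_distance(m, lab, surface))
    names(dists) <- names(m$selections)
    c(list(theta = p$theta, psi = p$psi, energy = p$energy,
           dipole_debye = dr$magnitude,
           dipole_angle_to_normal_deg = dr$angle_to_normal),
      if (length(dists)) list(surface_distances = dists))
  })

  outdir <- config$outputs$dir %||% "samscan_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_landscape_csv(landscape, file.path(outdir, "landscape.csv"))
  write_landscape_json(landscape, file.path(outdir, "landscape.json"))
  write_structure(posed_models, file.path(outdir, "poses.pdb"))

  cfg_path <- attr(config, "config_path")
  report <- structure(list(
    landscape = list(min_energy = min(landscape$energies),
                     max_energy = max(landscape$energies),
                     mean_energy = mean(landscape$energies),
                     n_orientations = length(landscape$energies)),
    poses = pose_rows,
    warnings = list(
      n_default_parameterized = par_info$n_defaulted,
      footprint_overhang =
        max(apply(coords(protein), 2, function(v) diff(range(v)))[1:2]) >
        min(surface$extent_x, surface$extent_y)),
    provenance = list(
      package_version = as.character(utils::packageVersion("samscan")),
      seed = config$seed,
      config_md5 = if (!is.null(cfg_path) && file.exists(cfg_path))
        unname(tools::md5sum(cfg_path)) else NA,
      config = unclass(config))),
    class = "run_report")
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_info("report written to ", file.path(outdir, "report.json"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: %d orientations, E_min %.2f kcal/mol, %d poses>\n",
              x$landscape$n_orientations, x$landscape$min_energy,
              length(x$poses)))
  for (p in x$poses)
    cat(sprintf("  pose theta %g psi %g: E %.2f kcal/mol, |mu| %.2f D\n",
                p$theta, p$psi, p$energy, p$dipole_debye))
  invisible(x)
}
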