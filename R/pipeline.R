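#' Pipeline configuration
#'
#' Builds the fully resolved configuration for [run_pipeline()]. Every
#' parameter has an explicit recorded default; the resolved configuration is
#' written alongside the outputs so each run is reproducible from its own
#' provenance. Fields mirror the pipeline stages: synthetic input (or sample
#' CSV path), validity filter, density grid, ridge detection, path
#' extraction and umbrella windows.
#'
#' @param output_dir output directory.
#' @param input_csv optional path to an ion-sample CSV; when NULL the synth
#'   stage generates a tube cloud from `synth`.
#' @param species ion species label.
#' @param z_min,z_max,min_dwell validity-filter slab (Angstrom) and dwell
#'   threshold (ps); the filter applies only to trajectory input.
#' @param voxel,smoothing density grid voxel edge and Gaussian smoothing
#'   sigma, Angstrom.
#' @param gamma,scales,rel_threshold,aniso ridge-detection parameters.
#' @param k,smoothing_span path-extraction parameters.
#' @param z_hi,z_lo,spacing,ext_hi,ext_lo umbrella-window parameters
#'   (Angstrom); set `ext_hi`/`ext_lo` to NULL to skip extensions.
#' @param seed integer seed for the synth stage.
#' @param synth list describing the synthetic cloud: `curve` (a
#'   [curve_segment()]-style object or NULL), `sigma`, `n`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(output_dir,
                       input_csv = NULL,
                       species = "Na",
                       z_min = -5, z_max = 20, min_dwell = 1000,
                       voxel = 0.5, smoothing = 1.0,
                       gamma = 0.75, scales = default_ridge_scales(),
                       rel_threshold = 0.1, aniso = 2,
                       k = 8, smoothing_span = 7,
                       z_hi = 17.5, z_lo = 5.5, spacing = 1,
                       ext_hi = 22.5, ext_lo = 18.5,
                       seed = 1L,
                       synth = list(curve = NULL, sigma = 1.0, n = 50000)) {
  cfg <- list(output_dir = output_dir, input_csv = input_csv,
              species = species, z_min = z_min, z_max = z_max,
              min_dwell = min_dwell, voxel = voxel, smoothing = smoothing,
              gamma = gamma, scales = scales, rel_threshold = rel_threshold,
              aniso = aniso, k = k, smoothing_span = smoothing_span,
              z_hi = z_hi, z_lo = z_lo, spacing = spacing,
              ext_hi = ext_hi, ext_lo = ext_lo, seed = as.integer(seed),
              synth = synth)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a configuration list.
#' @export
validate_config <- function(cfg) {
  need <- c("output_dir", "species", "z_min", "z_max", "min_dwell", "voxel",
            "smoothing", "gamma", "scales", "rel_threshold", "aniso", "k",
            "smoothing_span", "z_hi", "z_lo", "spacing", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing field(s): ",
                         paste(miss, collapse = ", "))
  if (cfg$z_min >= cfg$z_max) stop("invalid config: z_min must be < z_max")
  if (cfg$voxel <= 0) stop("invalid config: voxel must be positive")
  if (cfg$smoothing < 0) stop("invalid config: smoothing must be >= 0")
  if (cfg$rel_threshold < 0 || cfg$rel_threshold >= 1) {
    stop("invalid config: rel_threshold must be in [0, 1)")
  }
  invisible(TRUE)
}

# serializable form of a config (curves expanded to their parameters)
.config_json <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$synth$curve)) {
    cv <- out$synth$curve
    out$synth$curve <- c(list(kind = cv$kind), cv$params)
  }
  out
}

#' Read a resolved configuration back from its JSON form
#'
#' Counterpart of the `config.json` written by [run_pipeline()]; the
#' round-tripped configuration validates and reproduces the run.
#'
#' @param file path to a config JSON.
#' @return a [run_config()] object.
#' @export
read_run_config <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!is.null(j$synth$curve) && length(j$synth$curve)) {
    cv <- j$synth$curve
    j$synth$curve <- switch(cv$kind,
      segment = curve_segment(cv$from, cv$to),
      helix = curve_helix(cv$radius, cv$pitch, cv$turns,
                          center = cv$center, axis = cv$axis,
                          phase = cv$phase),
      polyline = curve_polyline(cv$vertices),
      stop("unknown curve kind in config: ", cv$kind))
  } else {
    j$synth$curve <- NULL
  }
  args <- j[intersect(names(j), names(formals(run_config)))]
  do.call(run_config, args)
}

#' Run the full detection pipeline
#'
#' Executes the stages synth (or CSV load) -> density -> ridges -> path ->
#' windows in dependency order, writing each product (sample CSV, MRC map,
#' ridge CSV/PDB, path CSV/PDB, window CSV/JSON), the resolved
#' configuration, and a manifest listing every output with an md5 checksum.
#' Rerunning with an identical configuration and seed reproduces the
#' checksums of all deterministic outputs. A stage failure aborts with the
#' failing stage named; outputs of completed stages are retained and the
#' manifest marks the run as partial.
#'
#' @param cfg a [run_config()].
#' @param stages subset of `c("synth", "density", "ridges", "path",
#'   "windows")` to run (dependencies must be satisfied by earlier runs'
#'   in-memory results; default all).
#' @return the manifest: list with `outputs` (file, md5), `config`, `log`.
#' @export
run_pipeline <- function(cfg, stages = c("synth", "density", "ridges",
                                         "path", "windows")) {
  validate_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  add_output <- function(f) outputs[[length(outputs) + 1]] <<- f
  run_stage <- function(name, expr) {
    note("[%s] starting", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  p <- function(f) file.path(cfg$output_dir, f)

  samples <- NULL
  if ("synth" %in% stages) {
    samples <- run_stage("synth", {
      if (!is.null(cfg$input_csv)) {
        note("[synth] loading samples from %s", cfg$input_csv)
        read_samples_csv(cfg$input_csv)
      } else {
        curve <- cfg$synth$curve
        if (is.null(curve)) curve <- curve_segment(c(0, 0, -5), c(0, 0, 25))
        note("[synth] tube cloud: sigma=%g A, n=%d, seed=%d",
             cfg$synth$sigma, as.integer(cfg$synth$n), cfg$seed)
        s <- sample_tube_cloud(curve, cfg$synth$sigma, cfg$synth$n,
                               seed = cfg$seed, species = cfg$species)
        write_samples_csv(s, p("samples.csv"))
        add_output(p("samples.csv"))
        s
      }
    })
  }
  map <- NULL
  if ("density" %in% stages) {
    map <- run_stage("density", {
      note("[density] voxel=%g A, smoothing=%g A", cfg$voxel, cfg$smoothing)
      m <- build_density_map(samples, cfg$voxel, cfg$smoothing)
      write_mrc(m, p("density.mrc"))
      add_output(p("density.mrc"))
      m
    })
  }
  ridge <- NULL
  if ("ridges" %in% stages) {
    ridge <- run_stage("ridges", {
      note("[ridges] gamma=%g, %d scales, rel_threshold=%g",
           cfg$gamma, length(cfg$scales), cfg$rel_threshold)
      ss <- build_scale_space(map, cfg$scales)
      r <- detect_ridge_points(ss, gamma = cfg$gamma,
                               rel_threshold = cfg$rel_threshold,
                               aniso = cfg$aniso)
      write_ridge_csv(r, p("ridge_points.csv"))
      write_pdb_pseudo(r, p("ridge_points.pdb"))
      add_output(p("ridge_points.csv")); add_output(p("ridge_points.pdb"))
      r
    })
  }
  path <- NULL
  if ("path" %in% stages) {
    path <- run_stage("path", {
      note("[path] k=%d, smoothing_span=%d", cfg$k, cfg$smoothing_span)
      g <- build_neighbor_graph(ridge, k = cfg$k)
      pp <- extract_principal_curve(g, ridge,
                                    smoothing_span = cfg$smoothing_span)
      write_path_csv(pp, p("path.csv"))
      write_pdb_pseudo(pp, p("path.pdb"))
      add_output(p("path.csv")); add_output(p("path.pdb"))
      pp
    })
  }
  windows <- NULL
  if ("windows" %in% stages) {
    windows <- run_stage("windows", {
      note("[windows] Z %g..%g A @ %g A, extension %s..%s A",
           cfg$z_hi, cfg$z_lo, cfg$spacing,
           format(cfg$ext_hi), format(cfg$ext_lo))
      w <- make_umbrella_windows(path, cfg$z_hi, cfg$z_lo, cfg$spacing,
                                 cfg$ext_hi, cfg$ext_lo)
      write_windows_csv(w, p("windows.csv"))
      write_windows_json(w, path, p("windows.json"))
      add_output(p("windows.csv")); add_output(p("windows.json"))
      w
    })
  }
  jsonlite::write_json(.config_json(cfg), p("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  add_output(p("config.json"))
  files <- unlist(outputs)
  manifest <- list(
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE),
    config = .config_json(cfg),
    log = log,
    results = list(samples = samples, map = map, ridge = ridge,
                   path = path, windows = windows))
  writeLines(jsonlite::toJSON(manifest[c("outputs", "log")],
                              auto_unbox = TRUE, pretty = TRUE,
                              dataframe = "rows"),
             p("manifest.json"))
  invisible(manifest)
}
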