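#' Pipeline configuration
#'
#' Builds (and validates) the single configuration object that drives
#' [run_pipeline()]. Every under-determined analysis parameter (bin width,
#' plateau edge, ACF cutoff rule, region edges, regime margin) surfaces
#' here with its documented default, so a run is fully auditable from its
#' config plus the written log.
#'
#' @param window_glob Glob matching the umbrella-window XVG files.
#' @param force_glob Glob matching the restraint-force XVG files (optional;
#'   without it the diffusion/permeability stages are skipped unless
#'   `diffusion_constant` is given).
#' @param temperature K.
#' @param bin_width WHAM bin width, nm.
#' @param z_bulk Bulk plateau edge, nm.
#' @param reference Primary reference convention for the written PMF.
#' @param bounds Integration bounds, nm (NULL: full overlap).
#' @param region_edges Resistance-decomposition edges, nm.
#' @param margin Regime margin, kJ/mol.
#' @param diffusion_constant Optional flat D (nm^2/ps) used when no force
#'   files are given.
#' @param outdir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_glob, force_glob = NULL,
                            temperature = 298.15, bin_width = 0.01,
                            z_bulk = 3.5, reference = "bulk_water",
                            bounds = NULL, region_edges = c(-1, 1),
                            margin = 2, diffusion_constant = NULL,
                            outdir = ".") {
  cfg <- list(window_glob = window_glob, force_glob = force_glob,
              temperature = temperature, bin_width = bin_width,
              z_bulk = z_bulk, reference = reference, bounds = bounds,
              region_edges = region_edges, margin = margin,
              diffusion_constant = diffusion_constant, outdir = outdir)
  if (is.null(cfg$window_glob)) stop("window_glob is required")
  if (cfg$bin_width <= 0) stop("bin_width must be > 0")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose keys match the [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, raw[intersect(names(raw), known)])
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full permeability pipeline
#'
#' Orchestrates WHAM solution of the umbrella windows, split-half
#' uncertainties, re-referencing, barrier extraction, the local diffusion
#' profile from the force series, and permeability under both the
#' bulk-water and global-minimum reference conventions, writing all outputs
#' to `config$outdir`:
#' `pmf_profile.tsv`, `diffusion_profile.tsv`, `resistance_profile.tsv`,
#' `permeability.json` and a `run_log.txt` recording every default actually
#' used. Any stage failure aborts with the stage name and cause.
#'
#' @param config A [pipeline_config()], or the path of a JSON config file.
#' @return Invisibly, a result bundle: `profile`, `barriers`, `diffusion`,
#'   `perm_water`, `perm_min`, `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("temperature_K = %g", config$temperature),
                 sprintf("bin_width_nm = %g", config$bin_width),
                 sprintf("z_bulk_nm = %g", config$z_bulk),
                 sprintf("region_edges_nm = %s", paste(config$region_edges, collapse = ", ")),
                 sprintf("regime_margin_kJmol = %g", config$margin),
                 "acf_cutoff_rule = first_zero")

  windows <- stage("read_windows", {
    files <- Sys.glob(config$window_glob)
    if (length(files) == 0L) stop("no window files match ", config$window_glob)
    lapply(sort(files), read_window_xvg)
  })
  log_lines <- c(log_lines, sprintf("n_windows = %d", length(windows)))

  profile <- stage("pmf", wham_solve(windows, temperature = config$temperature,
                                     bin_width = config$bin_width))
  err <- stage("pmf_uncertainty",
               split_half_uncertainty(windows, temperature = config$temperature,
                                      bin_width = config$bin_width))
  profile$uncertainty <- stats::approx(err$z, err$values, xout = profile$z, rule = 2)$y
  profile <- stage("set_reference",
                   set_reference(profile, config$reference, z_bulk = config$z_bulk))
  barriers <- stage("barriers", extract_barriers(profile, z_bulk = config$z_bulk))

  dprof <- NULL
  if (!is.null(config$force_glob)) {
    dprof <- stage("diffusion", {
      files <- Sys.glob(config$force_glob)
      if (length(files) == 0L) stop("no force files match ", config$force_glob)
      diffusion_profile(lapply(sort(files), read_force_xvg),
                        temperature = config$temperature)
    })
  } else if (!is.null(config$diffusion_constant)) {
    dprof <- config$diffusion_constant
    log_lines <- c(log_lines, sprintf("flat_diffusion_nm2_per_ps = %g", dprof))
  } else {
    stop("pipeline stage 'diffusion' failed: no force files and no diffusion_constant",
         call. = FALSE)
  }

  perm_w <- stage("permeability_water",
                  permeability(profile, dprof, bounds = config$bounds,
                               reference = "bulk_water", z_bulk = config$z_bulk,
                               region_edges = config$region_edges,
                               margin = config$margin))
  perm_m <- stage("permeability_minimum",
                  permeability(profile, dprof, bounds = config$bounds,
                               reference = "global_minimum", z_bulk = config$z_bulk,
                               region_edges = config$region_edges,
                               margin = config$margin))

  files <- character(0)
  out <- function(name) file.path(config$outdir, name)
  stage("write_outputs", {
    write_profile(profile, out("pmf_profile.tsv"))
    files <<- c(files, out("pmf_profile.tsv"))
    if (inherits(dprof, "depth_profile")) {
      df <- data.frame(z_nm = fmt_g17(dprof$z),
                       D_nm2_per_ps = fmt_g17(dprof$values),
                       D_cm2_per_s = fmt_g17(dprof$values * 1e-2),
                       cutoff_ps = fmt_g17(dprof$meta$cutoff_ps))
      utils::write.table(df, out("diffusion_profile.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <<- c(files, out("diffusion_profile.tsv"))
    }
    rho <- perm_w$resistance
    cum_on_rho <- stats::approx(perm_w$cumulative$z, perm_w$cumulative$values,
                                xout = rho$z, rule = 2)$y
    rdf <- data.frame(z_nm = fmt_g17(rho$z),
                      rho_ps_per_nm2 = fmt_g17(rho$values),
                      cumR_ps_per_nm = fmt_g17(cum_on_rho))
    utils::write.table(rdf, out("resistance_profile.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <<- c(files, out("resistance_profile.tsv"))

    perm_json <- list(
      bulk_water = list(P_cm_per_s = perm_w$P_cm_per_s,
                        R_total_ps_per_nm = perm_w$R_total_ps_per_nm,
                        regime = perm_w$regime,
                        region_fractions = as.list(perm_w$decomposition$fractions)),
      global_minimum = list(P_cm_per_s = perm_m$P_cm_per_s,
                            R_total_ps_per_nm = perm_m$R_total_ps_per_nm,
                            regime = perm_m$regime,
                            region_fractions = as.list(perm_m$decomposition$fractions),
                            notes = perm_m$notes),
      barriers = list(z_eq_nm = barriers$z_eq,
                      dG_desorption_kJmol = barriers$dG_desorption,
                      dG_translocation_kJmol = barriers$dG_translocation,
                      degenerate = barriers$degenerate),
      integration_bounds_nm = perm_w$integration_bounds
    )
    jsonlite::write_json(perm_json, out("permeability.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, out("permeability.json"))
    writeLines(log_lines, out("run_log.txt"))
    files <<- c(files, out("run_log.txt"))
  })

  invisible(list(profile = profile, barriers = barriers, diffusion = dprof,
                 perm_water = perm_w, perm_min = perm_m, files = files))
}
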