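#' Read a two-column time series in XVG dialect
#'
#' Lines beginning with `#` or `@` are comments; `# key = value` comment
#' lines are parsed into metadata. Data lines hold two whitespace-separated
#' numbers (time in ps, value). Times must be strictly increasing and
#' uniformly spaced (relative tolerance 1e-6 on the step).
#'
#' @param path File path.
#' @return A list with `dt` (ps), `time`, `values`, and `metadata`
#'   (named character vector).
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*[#@]", lines) | !nzchar(trimws(lines))
  meta <- character(0)
  hk <- regmatches(lines, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(\\S+)", lines))
  for (m in hk) if (length(m) == 3L) meta[m[2]] <- m[3]
  data_idx <- which(!is_comment)
  if (length(data_idx) == 0L) stop("no data rows in ", path)
  fields <- strsplit(trimws(lines[data_idx]), "\\s+")
  bad_n <- which(lengths(fields) != 2L)
  if (length(bad_n) > 0L)
    stop(sprintf("line %d of %s: expected two columns", data_idx[bad_n[1]], path))
  vals <- suppressWarnings(vapply(fields, function(f) as.numeric(f), numeric(2)))
  bad <- which(colSums(is.na(vals)) > 0)
  if (length(bad) > 0L)
    stop(sprintf("line %d of %s: non-numeric field", data_idx[bad[1]], path))
  tt <- vals[1, ]
  vv <- vals[2, ]
  if (length(tt) >= 2L) {
    d <- diff(tt)
    if (any(d <= 0)) stop("times are not strictly increasing in ", path)
    dt <- stats::median(d)
    if (max(abs(d - dt)) > 1e-6 * max(dt, .Machine$double.eps))
      stop("non-uniform time step in ", path)
  } else dt <- NA_real_
  list(dt = dt, time = tt, values = vv, metadata = meta)
}

write_xvg <- function(time, values, path, meta = list(), title = "", ylab = "") {
  head <- c(
    vapply(names(meta), function(k) sprintf("# %s = %s", k, fmt_g17(as.numeric(meta[[k]]))),
           character(1)),
    sprintf('@    title "%s"', title),
    '@    xaxis label "Time (ps)"',
    sprintf('@    yaxis label "%s"', ylab)
  )
  body <- paste(fmt_g17(time), fmt_g17(values))
  writeLines(c(head, body), path)
  invisible(path)
}

#' Write an umbrella window as an XVG-dialect file
#'
#' Header records `z0`, `k`, `dt` and the generating seed (if known); the
#' body is (time ps, reaction coordinate nm).
#'
#' @param window An [umbrella_window()].
#' @param path Output file; conventionally `window_<z0>.xvg`.
#' @export
write_window_xvg <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  meta <- list(z0 = window$z0, k = window$k, dt = window$dt)
  if (!is.null(window$seed)) meta$seed <- window$seed
  tt <- (seq_along(window$samples) - 1) * window$dt
  write_xvg(tt, window$samples, path, meta,
            title = "Umbrella window reaction coordinate", ylab = "z (nm)")
}

#' Write a restraint-force series as an XVG-dialect file
#'
#' @param series A [force_series()].
#' @param path Output file; conventionally `force_<z0>.xvg`.
#' @export
write_force_xvg <- function(series, path) {
  stopifnot(inherits(series, "force_series"))
  meta <- list(z0 = series$z0, dt = series$dt)
  if (!is.null(series$seed)) meta$seed <- series$seed
  tt <- (seq_along(series$force) - 1) * series$dt
  write_xvg(tt, series$force, path, meta,
            title = "Restraint force", ylab = "F (kJ/mol/nm)")
}

#' Read an umbrella window written by [write_window_xvg()]
#' @param path File path; the `z0` and `k` header keys are required.
#' @return An [umbrella_window()].
#' @export
read_window_xvg <- function(path) {
  ts <- read_timeseries(path)
  if (!all(c("z0", "k") %in% names(ts$metadata)))
    stop("window file ", path, " lacks z0/k header metadata")
  dt <- if (!is.na(ts$dt)) ts$dt else as.numeric(ts$metadata["dt"])
  umbrella_window(z0 = as.numeric(ts$metadata["z0"]),
                  k = as.numeric(ts$metadata["k"]),
                  samples = ts$values, dt = dt)
}

#' Read a force series written by [write_force_xvg()]
#' @param path File path; the `z0` header key is required.
#' @return A [force_series()].
#' @export
read_force_xvg <- function(path) {
  ts <- read_timeseries(path)
  if (!("z0" %in% names(ts$metadata)))
    stop("force file ", path, " lacks z0 header metadata")
  dt <- if (!is.na(ts$dt)) ts$dt else as.numeric(ts$metadata["dt"])
  force_series(z0 = as.numeric(ts$metadata["z0"]), dt = dt, force = ts$values)
}

#' Write a window set (and optional force set) to a directory
#'
#' Files are named `window_<z0>.xvg` / `force_<z0>.xvg` with z0 printed at
#' three decimals.
#'
#' @param windows List of [umbrella_window()].
#' @param dir Output directory (created if missing).
#' @param forces Optional list of [force_series()].
#' @return Character vector of the written paths, invisibly.
#' @export
write_window_set <- function(windows, dir, forces = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (w in windows) {
    p <- file.path(dir, sprintf("window_%.3f.xvg", w$z0))
    write_window_xvg(w, p)
    paths <- c(paths, p)
  }
  for (f in forces %||% list()) {
    p <- file.path(dir, sprintf("force_%.3f.xvg", f$z0))
    write_force_xvg(f, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a profile to TSV
#'
#' Free-energy profiles get columns `z_nm`, `G_kJmol`, `err_kJmol`; depth
#' profiles get `z_nm` plus a quantity-named value column. A commented header
#' records units, the reference convention and the temperature. Values are
#' printed with 17 significant digits so that [read_profile()] round-trips
#' them bit-exactly.
#'
#' @param profile A [free_energy_profile()] or [depth_profile()].
#' @param path Output file.
#' @export
write_profile <- function(profile, path) {
  if (inherits(profile, "free_energy_profile")) {
    if (length(profile$z) == 0L) stop("refusing to write an empty profile")
    hdr <- c("# type = free_energy_profile",
             paste0("# reference = ", profile$reference),
             paste0("# temperature_K = ", fmt_g17(profile$temperature)),
             "# columns: z_nm\tG_kJmol\terr_kJmol")
    err <- profile$uncertainty %||% rep(NA_real_, length(profile$z))
    body <- paste(fmt_g17(profile$z), fmt_g17(profile$G),
                  ifelse(is.na(err), "NA", fmt_g17(err)), sep = "\t")
  } else if (inherits(profile, "depth_profile")) {
    if (length(profile$z) == 0L) stop("refusing to write an empty profile")
    hdr <- c("# type = depth_profile",
             paste0("# quantity = ", profile$quantity),
             paste0("# columns: z_nm\t", profile$quantity))
    body <- paste(fmt_g17(profile$z), fmt_g17(profile$values), sep = "\t")
  } else stop("profile must be a free_energy_profile or depth_profile")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a profile written by [write_profile()]
#' @param path File path.
#' @return The reconstructed profile object.
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get_key <- function(key) {
    m <- regmatches(hdr, regexec(paste0("^#\\s*", key, "\\s*=\\s*(.+)$"), hdr))
    hit <- Filter(function(x) length(x) == 2L, m)
    if (length(hit) == 0L) return(NA_character_)
    trimws(hit[[1]][2])
  }
  type <- get_key("type")
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (identical(type, "free_energy_profile")) {
    z <- as.numeric(vapply(fields, `[`, "", 1))
    g <- as.numeric(vapply(fields, `[`, "", 2))
    e <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
    if (all(is.na(e))) e <- NULL
    free_energy_profile(z, g, reference = get_key("reference"),
                        temperature = as.numeric(get_key("temperature_K")),
                        uncertainty = e)
  } else if (identical(type, "depth_profile")) {
    z <- as.numeric(vapply(fields, `[`, "", 1))
    v <- as.numeric(vapply(fields, `[`, "", 2))
    depth_profile(z, v, quantity = get_key("quantity"))
  } else stop("unrecognized profile file: ", path)
}
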