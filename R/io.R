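# Plain-text readers and writers for the package's file dialects:
# delimited numeric tables with '#' comments and an optional header line,
# and structured key-value (YAML) experiment descriptors, run
# configurations and reports.

# Parse a whitespace/comma-delimited numeric table. Returns a data frame;
# malformed rows are reported with their 1-based line numbers in `path`.
.read_numeric_table <- function(path, col_names, optional_last = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no data lines in ", path)

  split_row <- function(s) strsplit(trimws(s), "[,;\t ]+")[[1]]
  n_req <- length(col_names) - optional_last

  # optional header: first non-comment line whose fields are not numeric
  first <- split_row(lines[idx[1]])
  if (all(is.na(suppressWarnings(as.numeric(first))))) idx <- idx[-1]
  if (!length(idx)) stop("no data rows in ", path)

  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    f <- split_row(lines[idx[j]])
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < n_req || length(v) > length(col_names) ||
        any(is.na(v)))
      stop(sprintf("%s: malformed row at line %d: '%s'",
                   path, idx[j], lines[idx[j]]))
    rows[[j]] <- c(v, rep(NA_real_, length(col_names) - length(v)))
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- col_names
  out
}

.write_table <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write correlogram files
#'
#' Two-column delimited text (`lag_us`, `g2`), `#` comments, optional
#' header line; the writer emits the same dialect, so write/read
#' round-trips are exact to the printed precision (17 significant
#' digits).
#'
#' @param path File path.
#' @return `read_correlogram` returns a [correlogram()];
#'   `write_correlogram` returns `path` invisibly.
#' @export
read_correlogram <- function(path) {
  df <- .read_numeric_table(path, c("lag_us", "g2"))
  tryCatch(correlogram(df$lag_us, df$g2),
           error = function(e) {
             if (any(diff(df$lag_us) <= 0)) {
               bad <- which(diff(df$lag_us) <= 0)[1] + 1L
               stop(sprintf("%s: lag column not strictly increasing at data row %d",
                            path, bad))
             }
             stop(path, ": ", conditionMessage(e))
           })
}

#' @rdname read_correlogram
#' @param c A [correlogram()].
#' @export
write_correlogram <- function(c, path) {
  stopifnot(inherits(c, "correlogram"))
  df <- data.frame(lag_us = format(c$lag_us, digits = 17),
                   g2 = format(c$g2, digits = 17))
  .write_table(df, path, "correlogram: lag time (us), g2(t)")
}

#' Read and write emission-spectrum files
#'
#' Two-column delimited text (`wavelength_nm`, `intensity`) with `#`
#' comments; the excitation wavelength lives in a header comment
#' `# excitation_nm: <value>` or is supplied explicitly (an explicit
#' value wins).
#'
#' @param path File path.
#' @param excitation_nm Excitation wavelength (nm); required if the file
#'   has no `excitation_nm` header comment.
#' @return `read_spectrum` returns an [emission_spectrum()].
#' @export
read_spectrum <- function(path, excitation_nm = NULL) {
  if (is.null(excitation_nm)) {
    lines <- readLines(path, warn = FALSE)
    m <- regmatches(lines,
                    regexpr("^#\\s*excitation_nm\\s*[:=]\\s*[0-9.eE+-]+",
                            lines))
    if (length(m))
      excitation_nm <- as.numeric(sub(".*[:=]\\s*", "", m[1]))
  }
  if (is.null(excitation_nm) || is.na(excitation_nm))
    stop(path, ": excitation wavelength not found; pass 'excitation_nm' ",
         "or add a '# excitation_nm: <value>' header comment")
  df <- .read_numeric_table(path, c("wavelength_nm", "intensity"))
  tryCatch(emission_spectrum(df$wavelength_nm, df$intensity, excitation_nm),
           error = function(e) stop(path, ": ", conditionMessage(e)))
}

#' @rdname read_spectrum
#' @param spec An [emission_spectrum()].
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "emission_spectrum"))
  df <- data.frame(wavelength_nm = format(spec$wavelength_nm, digits = 17),
                   intensity = format(spec$intensity, digits = 17))
  .write_table(df, path,
               sprintf("excitation_nm: %.17g", attr(spec, "excitation_nm")))
}

#' Read and write Stewart standards files
#'
#' Delimited text with columns `conc_mg_ml`, `absorbance` and optional
#' `se`, `#` comments, optional header.
#'
#' @param path File path.
#' @return `read_standards` returns a data frame ready for
#'   [fit_calibration()].
#' @export
read_standards <- function(path) {
  df <- .read_numeric_table(path, c("conc_mg_ml", "absorbance", "se"),
                            optional_last = 1L)
  if (all(is.na(df$se))) df$se <- NULL
  df
}

#' @rdname read_standards
#' @param standards Data frame with `conc_mg_ml`, `absorbance` and
#'   optionally `se`.
#' @export
write_standards <- function(standards, path) {
  .write_table(standards, path,
               "Stewart standards: concentration (mg/mL), absorbance @485nm, SE")
}

#' Read and write experiment descriptor files
#'
#' Structured key-value (YAML) text describing one two-extrusion
#' experiment: scalar keys `m0_mg`, `v1_ml`, `vt_ml` (and optional
#' `v2_ml`), `d1`, `d2`, and intensity readings as replicate lists
#' `intensities_i`, `intensities_ii` (plus optional `buffer`); scalar
#' intensities with `se_i1`/`se_i2` are also accepted. Unknown keys are
#' rejected.
#'
#' @param path File path.
#' @return `read_experiment` returns an [extrusion_pair()].
#' @export
read_experiment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- yaml::read_yaml(path)
  known <- c("m0_mg", "v1_ml", "v2_ml", "vt_ml", "d1", "d2",
             "intensities_i", "intensities_ii", "buffer",
             "se_i1", "se_i2", "se_buffer", "se_m0", "se_v1", "se_vt")
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop(path, ": unknown keys in experiment descriptor: ",
         paste(extra, collapse = ", "))
  req <- c("m0_mg", "v1_ml", "vt_ml", "d1", "d2",
           "intensities_i", "intensities_ii")
  missing <- setdiff(req, names(x))
  if (length(missing))
    stop(path, ": missing required keys: ", paste(missing, collapse = ", "))
  extrusion_pair(m0 = x$m0_mg, v1 = x$v1_ml, vt = x$vt_ml,
                 d1 = x$d1, d2 = x$d2,
                 i1 = unlist(x$intensities_i),
                 i2 = unlist(x$intensities_ii),
                 se_i1 = x$se_i1 %||% NA, se_i2 = x$se_i2 %||% NA,
                 v2 = x$v2_ml,
                 buffer = if (!is.null(x$buffer)) unlist(x$buffer),
                 se_buffer = x$se_buffer %||% 0,
                 se_m0 = x$se_m0 %||% 0, se_v1 = x$se_v1 %||% 0,
                 se_vt = x$se_vt %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_experiment
#' @param pair An [extrusion_pair()].
#' @export
write_experiment <- function(pair, path) {
  stopifnot(inherits(pair, "extrusion_pair"))
  x <- list(m0_mg = pair$m0, v1_ml = pair$v1, vt_ml = pair$vt,
            d1 = pair$d1, d2 = pair$d2,
            intensities_i = pair$i1, intensities_ii = pair$i2,
            se_i1 = pair$se_i1, se_i2 = pair$se_i2)
  if (!is.null(pair$v2)) x$v2_ml <- pair$v2
  if (pair$se_m0 > 0) x$se_m0 <- pair$se_m0
  if (pair$se_v1 > 0) x$se_v1 <- pair$se_v1
  if (pair$se_vt > 0) x$se_vt <- pair$se_vt
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read and write run-configuration files
#'
#' Structured key-value (YAML) text holding optical settings and analysis
#' options. Recognized keys: `wavelength_nm`, `angle_deg`,
#' `refractive_index`, `temperature_K`, `viscosity_mPas` (optical);
#' `cumulants_order`, `contin_grid_size`, `contin_lambda`,
#' `peak_window_nm` (analysis); `seed`. Unknown keys are rejected with a
#' message naming them; missing keys take the package defaults.
#'
#' @param path File path.
#' @return `read_run_config` returns a list with elements `optical` (an
#'   [optical_config()]) and the analysis options.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- yaml::read_yaml(path)
  if (is.null(x)) x <- list()
  known <- c("wavelength_nm", "angle_deg", "refractive_index",
             "temperature_K", "viscosity_mPas", "cumulants_order",
             "contin_grid_size", "contin_lambda", "peak_window_nm", "seed")
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop(path, ": unknown configuration keys: ",
         paste(extra, collapse = ", "))
  defaults <- formals(optical_config)
  cfg <- optical_config(
    wavelength_nm = x$wavelength_nm %||% eval(defaults$wavelength_nm),
    angle_deg = x$angle_deg %||% eval(defaults$angle_deg),
    refractive_index = x$refractive_index %||% eval(defaults$refractive_index),
    temperature_K = x$temperature_K %||% eval(defaults$temperature_K),
    viscosity_mPas = x$viscosity_mPas %||% eval(defaults$viscosity_mPas))
  list(optical = cfg,
       cumulants_order = x$cumulants_order %||% 2,
       contin_grid_size = x$contin_grid_size %||% 80,
       contin_lambda = x$contin_lambda %||% "auto",
       peak_window_nm = x$peak_window_nm %||% 5,
       seed = x$seed)
}

#' @rdname read_run_config
#' @param config A list as returned by [read_run_config()].
#' @export
write_run_config <- function(config, path) {
  cfg <- config$optical
  x <- list(wavelength_nm = cfg$wavelength_nm, angle_deg = cfg$angle_deg,
            refractive_index = cfg$refractive_index,
            temperature_K = cfg$temperature_K,
            viscosity_mPas = cfg$viscosity_mPas,
            cumulants_order = config$cumulants_order,
            contin_grid_size = config$contin_grid_size,
            contin_lambda = config$contin_lambda,
            peak_window_nm = config$peak_window_nm)
  if (!is.null(config$seed)) x$seed <- config$seed
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}
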