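#' Read a SAXS curve from multi-column ASCII text
#'
#' Parses whitespace- or comma-separated columns `q` (inverse Angstrom),
#' `I` (cm^-1) and optionally `dI` (cm^-1). Lines starting with `#` are
#' comments; header comments of the form `# key: value` with keys
#' `sample_id`, `concentration_wtpct` or `temperature_K` populate the
#' curve metadata (explicit arguments win). Malformed rows and
#' non-increasing q are reported with their line numbers.
#'
#' @param path Input file.
#' @param sample_id,concentration,temperature Metadata overrides.
#' @return A [saxs_curve()].
#' @export
read_saxs_curve <- function(path, sample_id = NULL, concentration = NULL,
                            temperature = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  hdr <- grep("^\\s*#", lines, value = TRUE)
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  is_data <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(is_data)
  if (!length(rows)) stop("no data rows in ", path, call. = FALSE)
  parsed <- lapply(rows, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || any(is.na(vals)))
      stop("malformed data row at line ", i, " of ", path, ": '",
           lines[i], "'", call. = FALSE)
    vals
  })
  ncol <- unique(vapply(parsed, length, integer(1)))
  if (length(ncol) != 1)
    stop("inconsistent column counts in ", path, call. = FALSE)
  mat <- do.call(rbind, parsed)
  q <- mat[, 1]
  bad <- which(diff(q) <= 0)
  if (length(bad))
    stop("non-increasing q at line ", rows[bad[1] + 1], " of ", path,
         call. = FALSE)
  saxs_curve(
    q = q, intensity = mat[, 2],
    uncertainty = if (ncol >= 3) mat[, 3] else NULL,
    sample_id = sample_id %||% meta$sample_id %||% basename(path),
    concentration = concentration %||%
      (if (!is.null(meta$concentration_wtpct)) as.numeric(meta$concentration_wtpct) else NA_real_),
    temperature = temperature %||%
      (if (!is.null(meta$temperature_K)) as.numeric(meta$temperature_K) else 293))
}

#' Write a SAXS curve as ASCII text
#'
#' Inverse of [read_saxs_curve()]: metadata as `# key: value` comments,
#' then `q I [dI]` columns at full double precision (the write/read round
#' trip is value-identical).
#'
#' @param curve A [saxs_curve()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_saxs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  hdr <- c(sprintf("# sample_id: %s", attr(curve, "sample_id")),
           sprintf("# concentration_wtpct: %.17g", attr(curve, "concentration")),
           sprintf("# temperature_K: %.17g", attr(curve, "temperature")),
           "# columns: q_invA I_cm1 dI_cm1")
  has_u <- all(is.finite(curve$uncertainty))
  body <- if (has_u)
    sprintf("%.17g %.17g %.17g", curve$q, curve$intensity, curve$uncertainty)
  else sprintf("%.17g %.17g", curve$q, curve$intensity)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an isotherm (tension or conductivity) series from CSV
#'
#' Expects comment headers `# kind: tension|conductivity` and optionally
#' `# temperature_K: ...`, then a CSV table with columns `concentration`
#' and `value`.
#'
#' @param path Input file.
#' @param kind,temperature Overrides of the header metadata.
#' @return An [isotherm_series()].
#' @export
read_isotherm <- function(path, kind = NULL, temperature = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  for (h in grep("^\\s*#", lines, value = TRUE)) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  df <- utils::read.csv(text = lines[!grepl("^\\s*#", lines)])
  if (!all(c("concentration", "value") %in% names(df)))
    stop("isotherm CSV needs `concentration` and `value` columns", call. = FALSE)
  isotherm_series(df$concentration, df$value,
                  kind = kind %||% meta$kind %||% "tension",
                  temperature = temperature %||%
                    (if (!is.null(meta$temperature_K)) as.numeric(meta$temperature_K) else 293))
}

#' Write an isotherm series as CSV
#'
#' @param series An [isotherm_series()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(series, path) {
  stopifnot(inherits(series, "isotherm_series"))
  hdr <- c(sprintf("# kind: %s", attr(series, "kind")),
           sprintf("# temperature_K: %.17g", attr(series, "temperature")),
           "concentration,value")
  writeLines(c(hdr, sprintf("%.17g,%.17g", series$concentration, series$value)),
             path)
  invisible(path)
}
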