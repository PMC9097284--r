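#' Read a COLVAR-style time series
#'
#' Parses PLUMED-COLVAR-style text: a `#! FIELDS time <name> ...` header
#' followed by whitespace-separated numeric rows. Comment lines are
#' ignored; blocks with repeated time stamps (simulation restarts) are
#' deduplicated keeping the last occurrence; after deduplication the time
#' column must be strictly increasing and uniformly spaced.
#'
#' @param path file path
#' @param column name of the coordinate column (default: the first
#'   non-time field)
#' @return a [coord_series()]
#' @export
read_colvar <- function(path, column = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  if (length(hdr) == 0) stop("no '#! FIELDS' header found in ", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", hdr[1]), "\\s+")[[1]]
  it <- which(fields == "time")
  if (length(it) != 1) stop("COLVAR header must name a 'time' field")
  if (is.null(column)) {
    ic <- setdiff(seq_along(fields), it)[1]
    if (is.na(ic)) stop("COLVAR header has no coordinate column")
  } else {
    ic <- which(fields == column)
    if (length(ic) != 1) stop("column '", column, "' not found in header")
  }
  data <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(data) == 0) stop("no data rows in ", path)
  mat <- do.call(rbind, lapply(strsplit(trimws(data), "\\s+"), function(p) {
    v <- suppressWarnings(as.numeric(p))
    if (any(is.na(v))) stop("malformed numeric row in ", path)
    v[c(it, ic)]
  }))
  keep <- !duplicated(mat[, 1], fromLast = TRUE)
  tm <- mat[keep, 1]
  s <- mat[keep, 2]
  if (any(diff(tm) <= 0)) stop("time not strictly increasing after dedup")
  if (length(tm) >= 2 && !is_uniform(tm, 1e-5)) {
    stop("time stamps are not uniformly spaced")
  }
  dt <- if (length(tm) >= 2) (tm[length(tm)] - tm[1]) / (length(tm) - 1) else 1
  coord_series(s, dt = dt, t0 = tm[1])
}

#' Write a coordination series as COLVAR-style text
#'
#' @param series a [coord_series()]
#' @param path output path
#' @param name coordinate field name (default "s")
#' @return `path`, invisibly
#' @export
write_colvar <- function(series, path, name = "s") {
  stopifnot(inherits(series, "coord_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#! FIELDS time %s", name), con)
  writeLines(sprintf("%.17g %.17g", series_times(series), series$values), con)
  invisible(path)
}

#' Read / write free-energy profile TSV
#'
#' Tab-separated columns `s`, `F_kJ_per_mol`, with the temperature in a
#' `# temperature_K:` comment line. Profiles on a non-uniform grid are
#' re-gridded onto a uniform grid by linear interpolation, with a warning.
#'
#' @param path file path
#' @param temperature temperature used if the file carries none, K
#' @return an [fe_profile()]
#' @export
read_profile_tsv <- function(path, temperature = 300) {
  lines <- readLines(path, warn = FALSE)
  tl <- grep("^#\\s*temperature_K:", lines, value = TRUE)
  if (length(tl) > 0) {
    temperature <- as.numeric(sub("^#\\s*temperature_K:\\s*", "", tl[1]))
  }
  df <- read_numeric_tsv(path, c("s", "F_kJ_per_mol"))
  s <- df$s
  F <- df$F_kJ_per_mol
  if (!is_uniform(s)) {
    warning("non-uniform profile grid; re-gridding by linear interpolation")
    gu <- seq(min(s), max(s), length.out = length(s))
    F <- approx(s, F, xout = gu)$y
    s <- gu
  }
  fe_profile(s, F, temperature = temperature, normalize = FALSE)
}

#' @rdname read_profile_tsv
#' @param profile an [fe_profile()]
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "fe_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_K: %.17g", profile$temperature), con)
  writeLines("s\tF_kJ_per_mol", con)
  writeLines(sprintf("%.17g\t%.17g", profile$s, profile$F), con)
  invisible(path)
}

#' Read / write diffusion profile TSV
#'
#' Tab-separated columns `s`, `D_ps_inv`, `dD_ps_inv`.
#'
#' @param path file path
#' @return a [diffusion_profile()]
#' @export
read_diffusion_tsv <- function(path) {
  df <- read_numeric_tsv(path, c("s", "D_ps_inv"))
  dD <- if (!is.null(df$dD_ps_inv)) df$dD_ps_inv else 0
  diffusion_profile(df$s, df$D_ps_inv, dD)
}

#' @rdname read_diffusion_tsv
#' @param D a [diffusion_profile()]
#' @export
write_diffusion_tsv <- function(D, path) {
  stopifnot(inherits(D, "diffusion_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("s\tD_ps_inv\tdD_ps_inv", con)
  writeLines(sprintf("%.17g\t%.17g\t%.17g", D$s, D$D, D$dD), con)
  invisible(path)
}

# strict numeric TSV reader with line-numbered errors
read_numeric_tsv <- function(path, required) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(body) < 2) stop("no data in ", path)
  header <- strsplit(trimws(lines[body[1]]), "\t|\\s+")[[1]]
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  rows <- lapply(body[-1], function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                              "\t|\\s+")[[1]]))
    if (any(is.na(v)) || length(v) != length(header)) {
      stop("malformed numeric data at line ", i, " of ", path)
    }
    v
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- header
  df
}

#' Write / read a state partition as JSON
#'
#' @param partition a [state_partition()]
#' @param path file path
#' @return `path` invisibly (write); a [state_partition()] (read)
#' @export
write_partition_json <- function(partition, path) {
  stopifnot(inherits(partition, "state_partition"))
  jsonlite::write_json(
    lapply(seq_len(nrow(partition)), function(i) {
      list(label = partition$label[i], left = partition$left[i],
           min = partition$min[i], right = partition$right[i])
    }),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partition_json
#' @export
read_partition_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  state_partition(x$label, x$left, x$min, x$right)
}

#' Write a results list as JSON with provenance
#'
#' Embeds the run configuration (if given) and the package version so every
#' result file records how it was produced.
#'
#' @param results named list
#' @param path file path
#' @param config optional configuration list to embed
#' @return `path`, invisibly
#' @export
write_results_json <- function(results, path, config = NULL) {
  payload <- list(package = "hydrokin",
                  version = as.character(packageVersion("hydrokin")),
                  config = config, results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
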