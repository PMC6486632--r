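velocity_table_header <- c("series_id", "inhibitor_name",
                           "inhibitor_conc_uM", "substrate_name",
                           "substrate_conc_uM", "replicate", "velocity")

#' Read a velocity table from CSV
#'
#' Reads the canonical comma-separated velocity schema (UTF-8, decimal
#' point) with header exactly
#' `series_id,inhibitor_name,inhibitor_conc_uM,substrate_name,substrate_conc_uM,replicate,velocity`
#' and returns the series grouped by inhibitor concentration. A missing or
#' misnamed column raises a schema error naming the column; a non-numeric
#' cell raises an error with its row number.
#'
#' @param path Path to the CSV file.
#' @return A named list of per-series data frames (one per inhibitor
#'   concentration, ascending), each carrying the full schema columns. An
#'   empty file with a valid header yields an empty list.
#' @export
read_velocity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(velocity_table_header, names(raw))
  if (length(missing))
    stop("velocity table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  raw <- raw[velocity_table_header]
  for (col in c("inhibitor_conc_uM", "substrate_conc_uM", "replicate",
                "velocity")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column `%s`, data row %d: \"%s\"",
                   col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    raw[[col]] <- num
  }
  if (any(raw$inhibitor_conc_uM < 0) || any(raw$substrate_conc_uM < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (nrow(raw) == 0L) return(list())
  sp <- split(raw, raw$inhibitor_conc_uM)
  sp[order(as.numeric(names(sp)))]
}

#' Write a velocity table to CSV
#'
#' Writes the canonical schema deterministically (no quoting of numerics,
#' no row names), so that identical tables produce byte-identical files
#' and a read/write cycle of a canonical file is the identity.
#'
#' @param tab A velocity table data frame or list of per-series frames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_velocity_table <- function(tab, path) {
  tab <- as_velocity_table(tab)
  stopifnot(all(velocity_table_header %in% names(tab)))
  utils::write.csv(tab[velocity_table_header], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a key-value run configuration file
#'
#' Minimal `key = value` format, one pair per line; `#` starts a comment.
#' Values that parse as numbers are returned numeric; comma-separated
#' values become vectors.
#'
#' @param path Path to the configuration file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed configuration line: ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

# canonical hash of a configuration-like list, for provenance blocks
config_hash <- function(x) {
  canon <- paste(names(x),
                 vapply(x, function(v) paste(format(v, digits = 15),
                                             collapse = ","),
                        character(1)),
                 sep = "=", collapse = ";")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}

#' Provenance block for machine-readable outputs
#'
#' Every run record written by the package carries the package version, a
#' hash of the configuration that produced it, and the seed used, so that
#' any output file can be traced back to a reproducible invocation.
#'
#' @param config Named list describing the run.
#' @param seed Seed used, or `NA`.
#' @return Named list with `package`, `version`, `config_hash`, `seed`.
#' @export
provenance_block <- function(config = list(), seed = NA) {
  list(package = "rnakin",
       version = as.character(utils::packageVersion("rnakin")),
       config_hash = config_hash(config),
       seed = seed)
}

#' Write a fit result as JSON
#'
#' Serialises a [fit_result()] (estimates, standard errors, bootstrap
#' intervals when present, RSS, convergence flag and recorded warnings)
#' together with a provenance block.
#'
#' @param fit A [fit_result()].
#' @param path Output path.
#' @param config Named list describing the run (hashed into provenance).
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, config = list()) {
  stopifnot(inherits(fit, "fit_result"))
  obj <- list(model = fit$model,
              estimates = as.list(fit$estimates),
              std_errors = as.list(fit$se),
              rss = fit$rss, n = fit$n,
              converged = fit$converged,
              warnings = fit$warnings,
              provenance = provenance_block(config, fit$seed))
  if (!is.null(fit$boot))
    obj$bootstrap <- list(level = fit$boot$level,
                          n_resamples = fit$boot$n_resamples,
                          n_failed = fit$boot$n_failed,
                          ci_lower = as.list(stats::setNames(
                            fit$boot$ci["lower", ], colnames(fit$boot$ci))),
                          ci_upper = as.list(stats::setNames(
                            fit$boot$ci["upper", ], colnames(fit$boot$ci))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
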