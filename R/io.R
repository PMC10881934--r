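# CSV interchange formats and report artifacts.
#
# All files are comma-separated UTF-8 with a header row and `.` decimal
# separator. Times are always hours; FIA is dimensionless.

#' Read time-activity curves from CSV
#'
#' Expects columns `curve_id, t_h, fia` (extra columns, e.g. `model_kind`
#' and `noisy` as written by [write_tac_csv()], are ignored). Rows are
#' grouped by `curve_id` and sorted by time; every curve must satisfy the
#' [tac_points()] invariants.
#'
#' @param path CSV file path.
#' @return Named list of [tac_points()], one per `curve_id`.
#' @export
read_tac_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("curve_id", "t_h", "fia")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("t_h", "fia")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      stop("non-numeric ", col, " in ", path, " at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    df[[col]] <- vals
  }
  if (any(df$fia <= 0)) {
    stop("non-positive FIA in ", path, " at data row(s) ",
         paste(utils::head(which(df$fia <= 0), 5), collapse = ", "),
         call. = FALSE)
  }
  curves <- lapply(split(df, factor(df$curve_id,
                                    levels = unique(df$curve_id))),
                   function(grp) {
    grp <- grp[order(grp$t_h), ]
    if (any(duplicated(grp$t_h))) {
      stop("duplicated times for curve ", grp$curve_id[1], " in ", path,
           call. = FALSE)
    }
    tac_points(grp$t_h, grp$fia, noisy = isTRUE(grp$noisy[1]))
  })
  curves
}

#' Write a synthetic dataset to CSV
#'
#' One row per point, columns `curve_id, model_kind, t_h, fia, noisy`; the
#' companion truth-parameter table is written by pairing with
#' [truth_parameters()] and [utils::write.csv()].
#'
#' @param dataset A [generate_dataset()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tac_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a benchmark report to a directory
#'
#' Emits `delta_tau_summary.csv`, `ca_vs_n.csv` (when the report carries
#' accuracies) and `config.json` (the full configuration echo, seeds
#' included, sufficient to regenerate the report).
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$delta_summary,
                   file.path(dir, "delta_tau_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(report$ca)) {
    utils::write.csv(report$ca, file.path(dir, "ca_vs_n.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  cfg <- report$config
  cfg$ml2 <- unclass(cfg$ml2)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
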