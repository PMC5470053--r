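#' Read a two-group marker sample from a delimited file
#'
#' Reads a CSV or TSV file (extension-detected, header required), extracts
#' the marker and status columns, maps the status to 0/1, and drops rows
#' with missing values (reporting how many were dropped).
#'
#' @param path file path; `.tsv`/`.txt` are read as tab-separated,
#'   anything else as comma-separated.
#' @param score_col,label_col column names.
#' @param positive for factor/character status columns, the level coding
#'   disease.
#' @return A data frame with columns `score` (numeric) and `status`
#'   (integer 0/1).
#' @export
read_sample <- function(path, score_col, label_col, positive = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c(score_col, label_col))
    if (!col %in% names(df)) stop("column not found: ", col, call. = FALSE)
  score <- df[[score_col]]
  if (!is.numeric(score))
    stop("score column '", score_col, "' is not numeric", call. = FALSE)
  keep <- !is.na(score) & !is.na(df[[label_col]])
  if (any(!keep))
    message(sum(!keep), " row(s) with missing values dropped")
  data.frame(score = score[keep],
             status = coerce_labels(df[[label_col]][keep], positive))
}

#' Packaged published coordinate tables
#'
#' Returns one of the coordinate tables shipped with the package: the
#' 17-row artificial-data illustration (`"table2"`, AUC 0.918) and the
#' heart-failure mortality candidate lists for pulse pressure
#' (`"table9_pp"`, AUC 0.892), left-ventricular ejection fraction
#' (`"table9_lvef"`, AUC 0.809), plasma sodium (`"table9_sodium"`,
#' AUC 0.777) and heart rate (`"table9_hr"`, AUC 0.647).  The heart-failure
#' tables carry the study group sizes (43 deceased, 117 alive) so the
#' minimum P value criterion can reconstruct the 2x2 counts.  Sensitivity
#' and specificity are stored as proportions.
#'
#' @param name fixture name.
#' @return A `"rocut_roc"` object (see [roc_from_coords()]).
#' @examples
#' cp_iu(load_fixture("table2"))
#' @export
load_fixture <- function(name = c("table2", "table9_pp", "table9_lvef",
                                  "table9_sodium", "table9_hr")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "rocut",
                      mustWork = TRUE)
  meta <- parse_meta(readLines(path, n = 1L))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  roc_from_coords(df$cutpoint, df$se, df$sp, auc = meta$auc,
                  n1 = meta$n1, n0 = meta$n0,
                  direction = if (identical(meta$direction, "gt")) "gt"
                              else "lt")
}

parse_meta <- function(line) {
  stopifnot(startsWith(line, "#"))
  fields <- strsplit(trimws(sub("^#", "", line)), "[[:space:]]+")[[1]]
  kv <- strsplit(fields, "=")
  out <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  for (k in c("auc", "n1", "n0"))
    if (!is.null(out[[k]])) out[[k]] <- as.numeric(out[[k]])
  out
}

#' Write a result object to JSON or TSV
#'
#' Serializes a criterion selection, a bootstrap summary, or a simulation
#' report.  Numeric fields are written at full double precision (17
#' significant digits in TSV; maximal precision in JSON), so reading the
#' file back reproduces them to machine accuracy.
#'
#' @param x a `"rocut_cut"`, `"rocut_boot"`, `"rocut_sim"` or plain data
#'   frame / named list.
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  flat <- flatten_report(x)
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  } else {
    df <- if (is.data.frame(flat)) flat else as.data.frame(flat)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

flatten_report <- function(x) {
  if (inherits(x, "rocut_cut"))
    return(list(method = x$method, cutpoint = x$cutpoint, se = x$se,
                sp = x$sp, criterion_value = x$criterion_value,
                ties = x$ties))
  if (inherits(x, "rocut_boot"))
    return(list(method = x$method, estimate = x$estimate, sd_b = x$sd_b,
                ci_low = x$ci_low, ci_high = x$ci_high, b = x$b))
  if (inherits(x, "rocut_sim")) {
    out <- as.data.frame(x)
    return(out)
  }
  x
}
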