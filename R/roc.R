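#' Empirical ROC coordinates for a two-group sample
#'
#' Builds the empirical ROC curve of a continuous marker against a binary
#' disease status.  Candidate cut-points are the unique observed marker
#' values.  With `direction = "gt"` a subject is called positive when the
#' marker strictly exceeds the cut-point, so at cut-point `c`
#' `se(c) = P(X > c | D = 1)` and `sp(c) = P(X <= c | D = 0)`.  With
#' `direction = "lt"` the comparison is reversed (`X < c` is a positive
#' call).  `direction = "auto"` starts from `"gt"` and flips when the
#' resulting AUC falls below 0.5, so markers that decrease with disease are
#' handled transparently.
#'
#' The AUC is the Mann-Whitney statistic (concordant pairs plus half the
#' tied pairs, over all case/control pairs), which equals the trapezoidal
#' area under the empirical curve.
#'
#' @param scores numeric vector of marker values.
#' @param labels disease status: a 0/1 numeric vector, a logical vector, or
#'   a two-level factor/character vector (see `positive`).
#' @param direction `"auto"`, `"gt"` (greater values indicate disease) or
#'   `"lt"`.
#' @param positive for factor/character labels, the level coding disease.
#' @return An object of class `"rocut_roc"`: a list with `thresholds`
#'   (increasing), `se`, `sp`, group sizes `n1`/`n0`, `auc`, `direction`,
#'   a `flipped` flag (TRUE when `"auto"` reversed the comparison), and the
#'   per-threshold counts `s` (negative-call controls) and `v`
#'   (positive-call cases) used by the minimum P value criterion.
#' @seealso [select_cutpoint()], [roc_table()], [roc_from_coords()]
#' @examples
#' roc <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' roc$auc
#' @export
roc_curve <- function(scores, labels, direction = c("auto", "gt", "lt"),
                      positive = NULL) {
  direction <- match.arg(direction)
  labels <- coerce_labels(labels, positive)
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have the same length", call. = FALSE)
  if (anyNA(scores) || anyNA(labels))
    stop("missing values in scores or labels; drop them first", call. = FALSE)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  if (length(unique(scores)) < 2L)
    stop("degenerate data: all marker values identical", call. = FALSE)

  x1 <- scores[labels == 1L]
  x0 <- scores[labels == 0L]

  flipped <- FALSE
  if (direction == "auto") {
    direction <- "gt"
    if (mw_auc(x1, x0) < 0.5) {
      direction <- "lt"
      flipped <- TRUE
    }
  }
  if (direction == "lt") {
    core <- roc_core(-x1, -x0)
    core$th <- rev(-core$th)
    core$se <- rev(core$se)
    core$sp <- rev(core$sp)
    core$s <- rev(core$s)
    core$v <- rev(core$v)
  } else {
    core <- roc_core(x1, x0)
  }

  structure(
    list(thresholds = core$th, se = core$se, sp = core$sp,
         n1 = core$n1, n0 = core$n0, auc = core$auc,
         direction = direction, flipped = flipped,
         s = core$s, v = core$v),
    class = "rocut_roc")
}

# Fast shared kernel: positivity is x > threshold.
# Returns counts s = #{controls <= t} and v = #{cases > t} alongside se/sp.
roc_core <- function(x1, x0) {
  th <- sort(unique(c(x1, x0)))
  n1 <- length(x1)
  n0 <- length(x0)
  c1 <- findInterval(th, sort(x1))
  c0 <- findInterval(th, sort(x0))
  list(th = th, se = 1 - c1 / n1, sp = c0 / n0,
       s = c0, v = n1 - c1, n1 = n1, n0 = n0, auc = mw_auc(x1, x0))
}

# Mann-Whitney AUC with tie correction, via midranks.
mw_auc <- function(x1, x0) {
  n1 <- length(x1)
  n0 <- length(x0)
  r <- rank(c(x0, x1))
  (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' ROC coordinates from a printed coordinate table
#'
#' Wraps an already-computed list of (cut-point, sensitivity, specificity)
#' coordinates -- e.g. candidates printed in a publication -- as a ROC
#' object so that every selection criterion can be applied to it directly.
#' When group sizes are supplied, the 2x2 counts needed by the minimum
#' P value criterion are reconstructed by rounding `se * n1` and `sp * n0`.
#'
#' @param cutpoints,se,sp numeric vectors of equal length; `se`/`sp` as
#'   proportions in `[0, 1]`.
#' @param auc the AUC associated with the full curve (required by the Index
#'   of Union criterion).
#' @param n1,n0 optional diseased / nondiseased group sizes.
#' @param direction which comparison generated the coordinates (metadata
#'   only; the criteria operate purely on the coordinates).
#' @return A `"rocut_roc"` object.
#' @examples
#' roc <- roc_from_coords(c(1, 2), se = c(0.9, 0.6), sp = c(0.5, 0.95),
#'                        auc = 0.8)
#' cp_iu(roc)
#' @export
roc_from_coords <- function(cutpoints, se, sp, auc = NULL,
                            n1 = NULL, n0 = NULL,
                            direction = c("gt", "lt")) {
  direction <- match.arg(direction)
  if (length(cutpoints) == 0L)
    stop("empty coordinate table", call. = FALSE)
  if (length(se) != length(cutpoints) || length(sp) != length(cutpoints))
    stop("'cutpoints', 'se' and 'sp' must have equal length", call. = FALSE)
  if (anyDuplicated(cutpoints))
    stop("cut-points must be unique", call. = FALSE)
  if (any(se < 0 | se > 1) || any(sp < 0 | sp > 1))
    stop("'se' and 'sp' must lie in [0, 1]", call. = FALSE)
  if (!is.null(auc) && (auc < 0 || auc > 1))
    stop("'auc' must lie in [0, 1]", call. = FALSE)
  cutpoints <- as.numeric(cutpoints)
  se <- as.numeric(se)
  sp <- as.numeric(sp)
  o <- order(cutpoints)
  s <- v <- NULL
  if (!is.null(n1) && !is.null(n0)) {
    s <- as.integer(round(sp[o] * n0))
    v <- as.integer(round(se[o] * n1))
  }
  structure(
    list(thresholds = cutpoints[o], se = se[o], sp = sp[o],
         n1 = n1, n0 = n0, auc = auc, direction = direction,
         flipped = FALSE, s = s, v = v),
    class = "rocut_roc")
}

#' 2x2 contingency table at a cut-point
#'
#' Returns the four cell counts of the disease-by-dichotomized-marker table
#' at candidate cut-point `c`: `s` and `r` are the negative- and
#' positive-call counts among nondiseased, `u` and `v` among diseased.  For
#' `direction = "gt"` a positive call is `X > c`.
#'
#' @param roc a `"rocut_roc"` object carrying counts (built from a sample,
#'   or from coordinates with `n1`/`n0` supplied).
#' @param c a value in `roc$thresholds`.
#' @return Named integer vector with elements `s`, `r`, `u`, `v`.
#' @export
roc_table <- function(roc, c) {
  stopifnot(inherits(roc, "rocut_roc"))
  if (is.null(roc$s))
    stop("no counts available: supply 'n1' and 'n0'", call. = FALSE)
  i <- match(c, roc$thresholds)
  if (is.na(i))
    stop("'c' is not a candidate threshold", call. = FALSE)
  s <- roc$s[i]
  v <- roc$v[i]
  c(s = s, r = roc$n0 - s, u = roc$n1 - v, v = v)
}

#' @export
print.rocut_roc <- function(x, ...) {
  cat("Empirical ROC curve\n")
  cat(sprintf("  thresholds: %d candidate cut-points\n", length(x$thresholds)))
  if (!is.null(x$n1))
    cat(sprintf("  groups: n1 = %d diseased, n0 = %d nondiseased\n",
                x$n1, x$n0))
  if (!is.null(x$auc)) cat(sprintf("  AUC: %.4f\n", x$auc))
  cat(sprintf("  direction: %s%s\n", x$direction,
              if (isTRUE(x$flipped)) " (auto-flipped)" else ""))
  invisible(x)
}

# Map labels to integer 0/1.
coerce_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stop("numeric labels must contain only 0 and 1", call. = FALSE)
    return(as.integer(labels))
  }
  lv <- unique(as.character(labels))
  lv <- lv[!is.na(lv)]
  if (length(lv) > 2L)
    stop("label column has more than two categories", call. = FALSE)
  if (is.null(positive)) {
    if (setequal(lv, c("0", "1"))) positive <- "1"
    else stop("supply 'positive' to identify the diseased level",
              call. = FALSE)
  }
  if (!positive %in% lv)
    stop("'positive' is not a label level", call. = FALSE)
  as.integer(as.character(labels) == positive)
}
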