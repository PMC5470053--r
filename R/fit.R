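#' Fit optimal ROC cut-points to a two-group sample
#'
#' The main entry point of the package.  Builds the empirical ROC curve of
#' a marker against a binary status and selects the optimal cut-point under
#' each requested criterion: the Index of Union (`"iu"`), the Youden index
#' (`"youden"`), the point closest to the (0,1) corner (`"er"`), the
#' concordance probability (`"cz"`), and the minimum P value approach
#' (`"minp"`).  Optionally attaches stratified bootstrap percentile
#' confidence intervals for every selected cut-point.
#'
#' @param formula a formula of the form `score ~ status`.
#' @param data a data frame containing the variables of `formula`.
#' @param methods criteria to apply (any subset of the five, in any order).
#' @param direction `"auto"` (default), `"gt"` or `"lt"`; see [roc_curve()].
#' @param positive for factor/character status, the level coding disease.
#' @param boot number of bootstrap resamples per method (0 = none).
#' @param seed integer seed for the bootstrap.
#' @param stratified stratify bootstrap resampling by group (default TRUE).
#' @return An object of class `"rocut"`, a list with the fitted `roc`
#'   curve, a named list `results` of `"rocut_cut"` selections, an optional
#'   named list `boot` of `"rocut_boot"` summaries, and the matched call.
#'   Supports `print()`, `summary()`, `coef()` (named vector of
#'   cut-points), `predict()` (dichotomize new marker values) and `plot()`
#'   (ROC curve with the selected points).
#' @examples
#' d <- generate_sample(dist_spec("normal", c(1.68, 1), c(0, 1)),
#'                      50, 50, seed = 42)
#' fit <- rocut(score ~ status, d)
#' coef(fit)
#' @export
rocut <- function(formula, data,
                  methods = c("minp", "youden", "cz", "er", "iu"),
                  direction = c("auto", "gt", "lt"), positive = NULL,
                  boot = 0L, seed = NULL, stratified = TRUE) {
  direction <- match.arg(direction)
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L)
    stop("'formula' must have the form score ~ status", call. = FALSE)
  scores <- mf[[1L]]
  if (!is.numeric(scores))
    stop("the marker (left-hand side) must be numeric", call. = FALSE)
  labels <- coerce_labels(mf[[2L]], positive)
  methods <- vapply(methods, canon_method, character(1), USE.NAMES = FALSE)

  roc <- roc_curve(scores, labels, direction)
  results <- lapply(methods, function(m) select_cutpoint(roc, m))
  names(results) <- methods

  boots <- NULL
  if (boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    boots <- lapply(methods, function(m) {
      bootstrap_cutpoint(scores, labels, m, b = boot,
                         stratified = stratified,
                         direction = roc$direction)
    })
    names(boots) <- methods
  }

  structure(list(call = match.call(), roc = roc, methods = methods,
                 results = results, boot = boots,
                 marker = deparse(formula[[2L]])),
            class = "rocut")
}

#' @export
print.rocut <- function(x, ...) {
  cat("Optimal ROC cut-points\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat(sprintf("AUC = %.4f (n1 = %d, n0 = %d, direction = %s)\n\n",
              x$roc$auc, x$roc$n1, x$roc$n0, x$roc$direction))
  print(summary_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}

summary_table <- function(x) {
  tab <- data.frame(
    method = vapply(x$results, function(r) method_label(r$method), ""),
    cutpoint = vapply(x$results, `[[`, 0, "cutpoint"),
    se = vapply(x$results, `[[`, 0, "se"),
    sp = vapply(x$results, `[[`, 0, "sp"),
    criterion = vapply(x$results, `[[`, 0, "criterion_value"),
    row.names = NULL)
  if (!is.null(x$boot)) {
    tab$sd_b <- vapply(x$boot, `[[`, 0, "sd_b")
    tab$ci_low <- vapply(x$boot, `[[`, 0, "ci_low")
    tab$ci_high <- vapply(x$boot, `[[`, 0, "ci_high")
  }
  tab
}

#' @export
summary.rocut <- function(object, ...) {
  out <- summary_table(object)
  attr(out, "auc") <- object$roc$auc
  attr(out, "n") <- c(n1 = object$roc$n1, n0 = object$roc$n0)
  class(out) <- c("summary.rocut", "data.frame")
  out
}

#' @export
print.summary.rocut <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("AUC = %.4f, n1 = %d, n0 = %d\n",
              attr(x, "auc"), n["n1"], n["n0"]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.rocut <- function(object, ...) {
  vapply(object$results, `[[`, 0, "cutpoint")
}

#' Classify new marker values at a fitted cut-point
#'
#' @param object a fitted [rocut()] object.
#' @param newdata numeric vector of marker values (or a data frame
#'   containing the marker column used in the fit).
#' @param method which criterion's cut-point to use; defaults to the first
#'   fitted one.
#' @param ... unused.
#' @return Integer vector, 1 for a positive (diseased) call, 0 otherwise.
#' @export
predict.rocut <- function(object, newdata, method = object$methods[1L],
                          ...) {
  method <- canon_method(method)
  if (is.data.frame(newdata)) {
    if (!object$marker %in% names(newdata))
      stop("'newdata' lacks the marker column ", object$marker,
           call. = FALSE)
    newdata <- newdata[[object$marker]]
  }
  cut <- object$results[[method]]$cutpoint
  if (is.null(cut)) stop("method not fitted: ", method, call. = FALSE)
  if (object$roc$direction == "gt") as.integer(newdata > cut)
  else as.integer(newdata < cut)
}

#' Plot the fitted ROC curve and selected cut-points
#'
#' Draws the empirical ROC curve in (1 - specificity, sensitivity) space
#' with the chance diagonal and marks the cut-point selected by each
#' fitted criterion.
#'
#' @param x a fitted [rocut()] object.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.rocut <- function(x, ...) {
  roc <- x$roc
  o <- order(1 - roc$sp, roc$se)
  fpr <- c(0, (1 - roc$sp)[o], 1)
  tpr <- c(0, roc$se[o], 1)
  graphics::plot(fpr, tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  cols <- seq_along(x$results) + 1L
  for (i in seq_along(x$results)) {
    r <- x$results[[i]]
    graphics::points(1 - r$sp, r$se, pch = 19, col = cols[i])
  }
  graphics::legend("bottomright", bty = "n", pch = 19, col = cols,
                   legend = sprintf("%s: %g",
                                    vapply(x$results, function(r)
                                      method_label(r$method), ""),
                                    vapply(x$results, `[[`, 0, "cutpoint")))
  invisible(x)
}
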