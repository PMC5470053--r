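#' Optimal cut-point selection criteria
#'
#' Each function scans the candidate cut-points of a ROC object and selects
#' the optimum of its objective:
#'
#' * `cp_youden()`: maximizes the Youden index `J(c) = Se(c) + Sp(c) - 1`.
#' * `cp_closest01()`: minimizes the Euclidean distance
#'   `ER(c) = sqrt((1 - Se(c))^2 + (1 - Sp(c))^2)` from the ROC point to the
#'   (0,1) corner.
#' * `cp_concordance()`: maximizes the concordance probability
#'   `CZ(c) = Se(c) * Sp(c)`.
#' * `cp_minp()`: maximizes the Pearson chi-square of the 2x2 table formed
#'   by dichotomizing the marker at `c` against disease status,
#'   `N (sv - ur)^2 / ((s + r)(u + v)(s + u)(r + v))`.  Thresholds whose
#'   table has an empty margin are skipped (the statistic is undefined
#'   there).
#' * `cp_iu()`: minimizes the Index of Union
#'   `IU(c) = |Se(c) - AUC| + |Sp(c) - AUC|`; among cut-points tied on
#'   `IU` the one with the smallest `|Se(c) - Sp(c)|` is returned.
#'
#' Objective ties are detected at tolerance `1e-9`; after any secondary
#' rule, remaining ties are broken by the smallest cut-point, so results
#' are deterministic.  All cut-points tied on the primary objective are
#' reported in the `ties` field, and the full objective profile is kept so
#' nearby alternatives can be inspected.
#'
#' @param roc a `"rocut_roc"` object from [roc_curve()] or
#'   [roc_from_coords()].
#' @param auc the AUC used by the Index of Union; defaults to the AUC
#'   stored in `roc`.
#' @return An object of class `"rocut_cut"`: a list with `method`,
#'   `cutpoint`, `se`, `sp`, `criterion_value`, `ties`, and a `profile`
#'   data frame of the objective over all candidates.
#' @examples
#' roc <- roc_curve(c(1, 2, 3, 4, 5), c(0, 0, 1, 0, 1))
#' cp_youden(roc)
#' @name criteria
NULL

#' @rdname criteria
#' @export
cp_youden <- function(roc) {
  stopifnot(inherits(roc, "rocut_roc"))
  pick_best(roc, "youden", roc$se + roc$sp - 1, maximize = TRUE)
}

#' @rdname criteria
#' @export
cp_closest01 <- function(roc) {
  stopifnot(inherits(roc, "rocut_roc"))
  pick_best(roc, "er", sqrt((1 - roc$se)^2 + (1 - roc$sp)^2),
            maximize = FALSE)
}

#' @rdname criteria
#' @export
cp_concordance <- function(roc) {
  stopifnot(inherits(roc, "rocut_roc"))
  pick_best(roc, "cz", roc$se * roc$sp, maximize = TRUE)
}

#' @rdname criteria
#' @export
cp_minp <- function(roc) {
  stopifnot(inherits(roc, "rocut_roc"))
  chi <- chisq_profile(roc)
  if (all(is.na(chi)))
    stop("no threshold yields a 2x2 table with positive margins",
         call. = FALSE)
  pick_best(roc, "minp", chi, maximize = TRUE)
}

#' @rdname criteria
#' @export
cp_iu <- function(roc, auc = roc$auc) {
  stopifnot(inherits(roc, "rocut_roc"))
  if (is.null(auc))
    stop("an AUC value is required for the Index of Union", call. = FALSE)
  if (auc < 0 || auc > 1) stop("'auc' must lie in [0, 1]", call. = FALSE)
  iu <- abs(roc$se - auc) + abs(roc$sp - auc)
  tie <- which(iu <= min(iu) + 1e-9)
  d <- abs(roc$se[tie] - roc$sp[tie])
  sel <- tie[d <= min(d) + 1e-9][1L]
  new_cut(roc, "iu", sel, iu[sel], ties = roc$thresholds[tie], profile = iu)
}

#' Select a cut-point by name
#'
#' Dispatch wrapper over the five criteria.  Method names follow the
#' field's shorthand: `"youden"`, `"er"` (closest to (0,1)), `"cz"`
#' (concordance probability), `"minp"`, `"iu"` (Index of Union); the long
#' aliases `"closest_01"`, `"concordance"`, `"min_p"` and
#' `"index_of_union"` are also accepted.
#'
#' @param roc a `"rocut_roc"` object.
#' @param method criterion name.
#' @return A `"rocut_cut"` object.
#' @export
select_cutpoint <- function(roc, method) {
  switch(canon_method(method),
         youden = cp_youden(roc),
         er = cp_closest01(roc),
         cz = cp_concordance(roc),
         minp = cp_minp(roc),
         iu = cp_iu(roc))
}

canon_method <- function(method) {
  stopifnot(is.character(method), length(method) == 1L)
  key <- c(youden = "youden",
           er = "er", closest_01 = "er",
           cz = "cz", concordance = "cz",
           minp = "minp", min_p = "minp",
           iu = "iu", index_of_union = "iu")
  m <- unname(key[tolower(method)])
  if (is.na(m)) stop("unknown method: ", method, call. = FALSE)
  m
}

rocut_methods <- c("minp", "youden", "cz", "er", "iu")

method_label <- function(m) {
  c(minp = "Minimum P value", youden = "Youden index",
    cz = "Concordance probability", er = "Closest to (0,1)",
    iu = "Index of Union")[m]
}

# chi-square profile over thresholds; NA where a column margin is empty
chisq_profile <- function(roc) {
  if (is.null(roc$s))
    stop("minimum P value needs 2x2 counts: build the ROC from a sample ",
         "or supply 'n1' and 'n0' to roc_from_coords()", call. = FALSE)
  s <- as.numeric(roc$s)
  v <- as.numeric(roc$v)
  n1 <- roc$n1
  n0 <- roc$n0
  u <- n1 - v
  r <- n0 - s
  m0 <- s + u
  m1 <- r + v
  N <- n1 + n0
  chi <- N * (s * v - u * r)^2 / (n0 * n1 * m0 * m1)
  chi[m0 == 0 | m1 == 0] <- NA_real_
  chi
}

pick_best <- function(roc, method, obj, maximize) {
  o <- if (maximize) obj else -obj
  best <- max(o, na.rm = TRUE)
  tie <- which(!is.na(o) & o >= best - 1e-9)
  new_cut(roc, method, tie[1L], obj[tie[1L]],
          ties = roc$thresholds[tie], profile = obj)
}

new_cut <- function(roc, method, index, value, ties, profile) {
  structure(
    list(method = method, cutpoint = roc$thresholds[index],
         se = roc$se[index], sp = roc$sp[index],
         criterion_value = value, ties = ties,
         profile = data.frame(cutpoint = roc$thresholds, value = profile)),
    class = "rocut_cut")
}

#' @export
print.rocut_cut <- function(x, ...) {
  cat(sprintf("%s cut-point: %g  (Se = %.3f, Sp = %.3f)\n",
              method_label(x$method), x$cutpoint, x$se, x$sp))
  cat(sprintf("  criterion value: %.6g\n", x$criterion_value))
  if (length(x$ties) > 1L)
    cat("  tied candidates:", paste(format(x$ties), collapse = ", "), "\n")
  invisible(x)
}
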