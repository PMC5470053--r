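#' Bootstrap standard deviation and percentile CI for a cut-point
#'
#' Draws `b` bootstrap resamples of the sample, re-estimates the cut-point
#' on each, and summarizes the bootstrap distribution by its standard
#' deviation and the basic percentile 95% confidence interval (the 2.5 and
#' 97.5 empirical percentiles, linear interpolation between order
#' statistics).
#'
#' By default resampling is stratified: the diseased and nondiseased groups
#' are resampled independently so group sizes -- design constants in a
#' case-control study -- are preserved and the prevalence seen by the
#' minimum P value criterion is not randomized.  Set `stratified = FALSE`
#' to resample the pooled sample instead.
#'
#' A resample in which one group is empty or all marker values coincide
#' cannot produce a ROC curve; such resamples are redrawn, up to 1000
#' retries in total.
#'
#' @param scores,labels the sample (labels as in [roc_curve()]).
#' @param method criterion name.
#' @param b number of bootstrap resamples (at least 2).
#' @param seed optional integer seed; results are reproducible given the
#'   seed.
#' @param stratified resample within groups (default) or pooled.
#' @param direction passed to [roc_curve()].
#' @param positive passed to [roc_curve()].
#' @return An object of class `"rocut_boot"`: list with `estimate` (the
#'   cut-point on the original sample), `sd_b`, `ci_low`, `ci_high`, `b`,
#'   `seed`, `method`, and the vector of bootstrap `estimates`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(40), rnorm(40, 2))
#' g <- rep(0:1, each = 40)
#' bootstrap_cutpoint(x, g, "iu", b = 50, seed = 7)
#' @export
bootstrap_cutpoint <- function(scores, labels, method, b = 200L,
                               seed = NULL, stratified = TRUE,
                               direction = c("auto", "gt", "lt"),
                               positive = NULL) {
  direction <- match.arg(direction)
  method <- canon_method(method)
  if (b < 2L) stop("'b' must be at least 2", call. = FALSE)
  labels <- coerce_labels(labels, positive)
  roc <- roc_curve(scores, labels, direction)
  estimate <- select_cutpoint(roc, method)$cutpoint

  if (!is.null(seed)) set.seed(seed)
  x1 <- scores[labels == 1L]
  x0 <- scores[labels == 0L]
  est <- boot_estimates(x1, x0, method, b, stratified,
                        flip = roc$direction == "lt")[, 1L]

  ci <- unname(stats::quantile(est, c(0.025, 0.975), type = 7))
  structure(
    list(estimate = estimate, sd_b = stats::sd(est),
         ci_low = ci[1], ci_high = ci[2], b = as.integer(b),
         seed = seed, method = method, estimates = est),
    class = "rocut_boot")
}

# Shared resamples across methods: returns a b x length(methods) matrix of
# cut-point estimates.  `flip = TRUE` runs the reversed-direction ("lt")
# convention by negating scores and negating the estimates back.
boot_estimates <- function(x1, x0, methods, b, stratified = TRUE,
                           flip = FALSE) {
  n1 <- length(x1)
  n0 <- length(x0)
  if (flip) {
    x1 <- -x1
    x0 <- -x0
  }
  out <- matrix(NA_real_, b, length(methods),
                dimnames = list(NULL, methods))
  retries <- 0L
  for (i in seq_len(b)) {
    repeat {
      if (stratified) {
        b1 <- x1[sample.int(n1, n1, replace = TRUE)]
        b0 <- x0[sample.int(n0, n0, replace = TRUE)]
      } else {
        pool <- c(x1, x0)
        lab <- rep(c(1L, 0L), c(n1, n0))
        idx <- sample.int(n1 + n0, n1 + n0, replace = TRUE)
        b1 <- pool[idx][lab[idx] == 1L]
        b0 <- pool[idx][lab[idx] == 0L]
      }
      ok <- length(b1) > 0L && length(b0) > 0L &&
        length(unique(c(b1, b0))) > 1L
      if (ok) break
      retries <- retries + 1L
      if (retries > 1000L)
        stop("too many degenerate bootstrap resamples", call. = FALSE)
    }
    out[i, ] <- estimate_all(b1, b0, methods)
  }
  if (flip) -out else out
}

# Fast all-methods estimation on raw group samples ("gt" convention).
estimate_all <- function(x1, x0, methods) {
  k <- roc_core(x1, x0)
  th <- k$th
  se <- k$se
  sp <- k$sp
  out <- numeric(length(methods))
  for (j in seq_along(methods)) {
    out[j] <- switch(methods[j],
      youden = arg_best(th, se + sp - 1),
      er = arg_best(th, -sqrt((1 - se)^2 + (1 - sp)^2)),
      cz = arg_best(th, se * sp),
      minp = {
        s <- k$s
        v <- k$v
        u <- k$n1 - v
        r <- k$n0 - s
        m0 <- s + u
        m1 <- r + v
        chi <- (k$n1 + k$n0) * (s * v - u * r)^2 / (k$n0 * k$n1 * m0 * m1)
        chi[m0 == 0 | m1 == 0] <- NA_real_
        arg_best(th, chi)
      },
      iu = {
        iu <- abs(se - k$auc) + abs(sp - k$auc)
        tie <- which(iu <= min(iu) + 1e-9)
        d <- abs(se[tie] - sp[tie])
        th[tie[d <= min(d) + 1e-9][1L]]
      })
  }
  out
}

arg_best <- function(th, obj) {
  th[which(!is.na(obj) & obj >= max(obj, na.rm = TRUE) - 1e-9)[1L]]
}

#' @export
print.rocut_boot <- function(x, ...) {
  cat(sprintf("Bootstrap (%d resamples) for the %s cut-point\n",
              x$b, method_label(x$method)))
  cat(sprintf("  estimate: %g\n  SD_B: %.4f\n  95%% percentile CI: [%g, %g]\n",
              x$estimate, x$sd_b, x$ci_low, x$ci_high))
  invisible(x)
}
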