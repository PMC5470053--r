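#' Generate a two-group sample from a parametric biomarker model
#'
#' Draws `n1` diseased and `n0` nondiseased marker values from the model's
#' group distributions.
#'
#' @param spec a [dist_spec()] object.
#' @param n1,n0 group sizes.
#' @param seed optional integer seed.
#' @return A data frame with columns `score` and `status` (1 diseased,
#'   0 nondiseased), diseased rows first.
#' @examples
#' d <- generate_sample(dist_spec("normal", c(1, 1), c(0, 1)), 20, 20, seed = 1)
#' table(d$status)
#' @export
generate_sample <- function(spec, n1, n0, seed = NULL) {
  stopifnot(inherits(spec, "rocut_dist"), n1 >= 1, n0 >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(score = c(rdist(spec, "diseased", n1),
                       rdist(spec, "nondiseased", n0)),
             status = rep(c(1L, 0L), c(n1, n0)))
}

rdist <- function(spec, group, n) {
  p <- spec[[group]]
  if (spec$family == "normal") stats::rnorm(n, p[1], p[2])
  else stats::rgamma(n, shape = p[1], scale = p[2])
}

#' Monte-Carlo evaluation of the cut-point estimators
#'
#' Repeatedly generates samples from a parametric scenario, estimates each
#' criterion's cut-point on every replicate, and summarizes estimator
#' performance against the population truth: relative bias
#' `E[(chat - c) / c]` and mean squared error `E[(chat - c)^2]`.  With
#' `bootstrap_b > 0`, each replicate additionally gets a stratified
#' bootstrap, and the report gains the mean bootstrap standard deviation,
#' the empirical coverage of the 95% percentile interval, and the mean
#' interval length.
#'
#' Replicates use independent RNG substreams (L'Ecuyer-CMRG, advanced with
#' [parallel::nextRNGStream()]) derived from `seed`, so a scenario is
#' reproducible and replicate `i` does not depend on how much randomness
#' earlier replicates consumed.  A degenerate replicate (all marker values
#' equal) is regenerated from the next substream and counted.
#'
#' Population truths default to [true_cutpoint()] per method (only the
#' minimum P value truth depends on prevalence, taken as
#' `n1 / (n1 + n0)` unless the spec says otherwise).  Supply
#' `true_cutpoints` (named by method) to override, e.g. to use rounded
#' published values.
#'
#' @param spec a [dist_spec()] object.  Its `prevalence` is overridden by
#'   `n1 / (n1 + n0)` for the minimum P value truth when left at the
#'   default 0.5 and the design is unbalanced.
#' @param n1,n0 group sizes per replicate.
#' @param reps number of Monte-Carlo replicates.
#' @param methods criteria to evaluate.
#' @param bootstrap_b bootstrap resamples per replicate (0 = no bootstrap).
#' @param seed integer seed for the scenario.
#' @param true_cutpoints optional named numeric vector of truths.
#' @return An object of class `"rocut_sim"`: a data frame with one row per
#'   method (`true_cutpoint`, `relative_bias`, `mse`, and, when
#'   bootstrapped, `sd_b_mean`, `coverage`, `mean_ci_length`).  The matrix
#'   of replicate estimates is kept in `attr(, "estimates")` for audit.
#' @examples
#' spec <- dist_spec("normal", c(1.68, 1), c(0, 1))
#' run_scenario(spec, 50, 50, reps = 20, methods = c("youden", "iu"), seed = 1)
#' @export
run_scenario <- function(spec, n1, n0, reps = 1000L,
                         methods = c("minp", "youden", "cz", "er", "iu"),
                         bootstrap_b = 0L, seed = NULL,
                         true_cutpoints = NULL) {
  stopifnot(inherits(spec, "rocut_dist"), reps >= 1)
  methods <- vapply(methods, canon_method, character(1), USE.NAMES = FALSE)

  truth_spec <- spec
  if (spec$prevalence == 0.5 && n1 != n0)
    truth_spec$prevalence <- n1 / (n1 + n0)
  truths <- vapply(methods, function(m) {
    if (!is.null(true_cutpoints) && m %in% names(true_cutpoints))
      true_cutpoints[[m]]
    else true_cutpoint(truth_spec, m)
  }, numeric(1))

  est <- matrix(NA_real_, reps, length(methods),
                dimnames = list(NULL, methods))
  if (bootstrap_b > 0) {
    if (bootstrap_b < 2) stop("'bootstrap_b' must be >= 2", call. = FALSE)
    sd_b <- len <- est
    cover <- matrix(NA, reps, length(methods),
                    dimnames = list(NULL, methods))
  }

  streams <- rng_substreams(seed)
  on.exit(streams$restore(), add = TRUE)
  n_degen <- 0L
  for (i in seq_len(reps)) {
    repeat {
      streams$activate()
      x1 <- rdist(spec, "diseased", n1)
      x0 <- rdist(spec, "nondiseased", n0)
      if (length(unique(c(x1, x0))) > 1L) break
      n_degen <- n_degen + 1L
    }
    est[i, ] <- estimate_all(x1, x0, methods)
    if (bootstrap_b > 0) {
      bm <- boot_estimates(x1, x0, methods, bootstrap_b)
      sd_b[i, ] <- apply(bm, 2, stats::sd)
      ci <- apply(bm, 2, stats::quantile, probs = c(0.025, 0.975), type = 7)
      cover[i, ] <- ci[1, ] <= truths & truths <= ci[2, ]
      len[i, ] <- ci[2, ] - ci[1, ]
    }
  }

  report <- data.frame(
    method = methods,
    true_cutpoint = truths,
    relative_bias = colMeans(sweep(est, 2, truths) ) / truths,
    mse = colMeans(sweep(est, 2, truths)^2),
    row.names = NULL)
  if (bootstrap_b > 0) {
    report$sd_b_mean <- colMeans(sd_b)
    report$coverage <- colMeans(cover)
    report$mean_ci_length <- colMeans(len)
  }
  structure(report, class = c("rocut_sim", "data.frame"),
            estimates = est, spec = spec, n1 = n1, n0 = n0, reps = reps,
            bootstrap_b = bootstrap_b, seed = seed,
            n_degenerate = n_degen)
}

#' @export
print.rocut_sim <- function(x, digits = 4, ...) {
  cat(sprintf("Monte-Carlo scenario: %s model, n1 = %d, n0 = %d, %d replicates\n",
              attr(x, "spec")$family, attr(x, "n1"), attr(x, "n0"),
              attr(x, "reps")))
  if (attr(x, "bootstrap_b") > 0)
    cat(sprintf("  bootstrap: %d resamples per replicate\n",
                attr(x, "bootstrap_b")))
  if (attr(x, "n_degenerate") > 0)
    cat(sprintf("  degenerate replicates regenerated: %d\n",
                attr(x, "n_degenerate")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

# Per-replicate RNG substreams.  activate() installs the next stream as the
# global RNG state; restore() puts the caller's RNG back.
rng_substreams <- function(seed) {
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  old_kind <- RNGkind()
  if (is.null(seed)) seed <- stats::runif(1, 0, .Machine$integer.max)
  seed <- as.integer(abs(as.numeric(seed)) %% .Machine$integer.max)
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", globalenv())
  list(
    activate = function() {
      assign(".Random.seed", stream, envir = globalenv())
      stream <<- parallel::nextRNGStream(stream)
      invisible(NULL)
    },
    restore = function() {
      RNGkind(old_kind[1], old_kind[2], old_kind[3])
      if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv())
      invisible(NULL)
    })
}

#' Twofold cross-validation of the selected cut-point
#'
#' Checks the stability of each criterion's cut-point by a twofold
#' cross-validation round: (1) generate a sample and estimate the cut-point
#' on the full data; (2) split it into two halves, stratified by group;
#' (3) estimate the cut-point on subset I; (4) re-label every observation
#' of subset II by dichotomizing its marker at that cut-point (the
#' predicted class becomes the group label); (5) re-estimate the cut-point
#' on the re-labeled subset II; (6) re-label subset I with it likewise;
#' (7) estimate the cut-point on the two re-labeled halves combined; and
#' (8) report the difference between the full-data cut-point and this final
#' cut-point.  A stable criterion yields differences centered at zero.
#'
#' @param spec a [dist_spec()] object.
#' @param n1,n0 group sizes (odd sizes put the extra observation in
#'   subset II).
#' @param methods criteria to evaluate.
#' @param reps number of independent rounds.
#' @param seed integer seed (substreams as in [run_scenario()]).
#' @return A `reps` x `length(methods)` matrix of differences (full-data
#'   cut-point minus post-cross-validation cut-point).  A round in which a
#'   re-labeled half is degenerate yields `NA` for that method.
#' @examples
#' spec <- dist_spec("normal", c(1.05, 1), c(0, 1))
#' cross_validate(spec, 50, 50, methods = "iu", reps = 3, seed = 1)
#' @export
cross_validate <- function(spec, n1, n0,
                           methods = c("minp", "youden", "cz", "er", "iu"),
                           reps = 1L, seed = NULL) {
  stopifnot(inherits(spec, "rocut_dist"), n1 >= 2, n0 >= 2)
  methods <- vapply(methods, canon_method, character(1), USE.NAMES = FALSE)
  out <- matrix(NA_real_, reps, length(methods),
                dimnames = list(NULL, methods))
  streams <- rng_substreams(seed)
  on.exit(streams$restore(), add = TRUE)
  for (i in seq_len(reps)) {
    streams$activate()
    x1 <- rdist(spec, "diseased", n1)
    x0 <- rdist(spec, "nondiseased", n0)
    i1 <- sample.int(n1, n1 %/% 2L)
    i0 <- sample.int(n0, n0 %/% 2L)
    full <- estimate_all(x1, x0, methods)
    for (j in seq_along(methods)) {
      out[i, j] <- full[j] - cv_round(x1, x0, i1, i0, methods[j])
    }
  }
  out
}

# One cross-validation pass for one method; positive call is score > cut.
cv_round <- function(x1, x0, i1, i0, method) {
  cut1 <- estimate_all(x1[i1], x0[i0], method)
  zb <- c(x1[-i1], x0[-i0])
  pos_b <- zb > cut1
  if (all(pos_b) || !any(pos_b) || length(unique(zb)) < 2L)
    return(NA_real_)
  cut2 <- estimate_all(zb[pos_b], zb[!pos_b], method)
  za <- c(x1[i1], x0[i0])
  pos_a <- za > cut2
  cases <- c(zb[pos_b], za[pos_a])
  controls <- c(zb[!pos_b], za[!pos_a])
  if (length(cases) == 0L || length(controls) == 0L ||
      length(unique(c(cases, controls))) < 2L)
    return(NA_real_)
  estimate_all(cases, controls, method)
}
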