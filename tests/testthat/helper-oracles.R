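# Independent brute-force oracles: recompute everything from raw data by
# direct enumeration, sharing no code with the package internals.

oracle_se_sp <- function(x1, x0, c) {
  c(se = mean(x1 > c), sp = mean(x0 <= c))
}

# trapezoidal area under the empirical ROC, endpoints appended
oracle_trap_auc <- function(x1, x0) {
  th <- sort(unique(c(x1, x0)))
  pts <- t(vapply(th, function(c) {
    ss <- oracle_se_sp(x1, x0, c)
    c(fpr = 1 - ss["sp"], tpr = ss["se"])
  }, c(fpr = 0, tpr = 0)))
  pts <- rbind(c(1, 1), pts, c(0, 0))
  o <- order(pts[, 1], pts[, 2])
  x <- pts[o, 1]
  y <- pts[o, 2]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

oracle_mw_auc <- function(x1, x0) {
  s <- 0
  for (a in x1) for (b in x0)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(x1) * length(x0))
}

oracle_chisq <- function(s, r, u, v) {
  N <- s + r + u + v
  N * (s * v - u * r)^2 / ((s + r) * (u + v) * (s + u) * (r + v))
}

# Eq.(3)-style chi-square from classification probabilities
oracle_chisq_probs <- function(se, sp, n1, n0) {
  N <- n1 + n0
  pos <- (n1 * se + n0 * (1 - sp)) / N  # marginal positive-call rate
  (se + sp - 1)^2 / (pos * (1 - pos) * (1 / n1 + 1 / n0))
}

# exhaustive scan of a criterion over all observed thresholds
oracle_cutpoint <- function(x1, x0, method) {
  th <- sort(unique(c(x1, x0)))
  se <- vapply(th, function(c) mean(x1 > c), 0)
  sp <- vapply(th, function(c) mean(x0 <= c), 0)
  n1 <- length(x1)
  n0 <- length(x0)
  obj <- switch(method,
    youden = se + sp - 1,
    er = -sqrt((1 - se)^2 + (1 - sp)^2),
    cz = se * sp,
    minp = vapply(seq_along(th), function(i) {
      s <- sum(x0 <= th[i]); r <- n0 - s
      u <- sum(x1 <= th[i]); v <- n1 - u
      if (s + u == 0 || r + v == 0) return(NA_real_)
      oracle_chisq(s, r, u, v)
    }, 0),
    iu = {
      auc <- oracle_mw_auc(x1, x0)
      -(abs(se - auc) + abs(sp - auc))
    })
  best <- which(!is.na(obj) & obj >= max(obj, na.rm = TRUE) - 1e-9)
  if (method == "iu") {
    d <- abs(se[best] - sp[best])
    best <- best[d <= min(d) + 1e-9]
  }
  th[best[1]]
}

random_sample <- function(n1 = NULL, n0 = NULL, ties = FALSE) {
  if (is.null(n1)) n1 <- sample(5:30, 1)
  if (is.null(n0)) n0 <- sample(5:30, 1)
  mu <- stats::runif(1, 0.2, 2.5)
  x1 <- stats::rnorm(n1, mu)
  x0 <- stats::rnorm(n0)
  if (ties) {
    x1 <- round(x1, 1)
    x0 <- round(x0, 1)
  }
  list(x1 = x1, x0 = x0,
       scores = c(x1, x0), labels = rep(c(1L, 0L), c(n1, n0)))
}

# published coordinate lists, kept inline as the reference copy that the
# packaged fixtures are checked against
ref_table2 <- data.frame(
  cutpoint = c(3.095, 2.986, 2.727, 2.527, 2.478, 2.416, 2.331, 2.284,
               2.262, 2.243, 2.191, 2.079, 1.985, 1.944, 1.897, 1.836,
               1.741),
  se = c(rep(0.92, 13), 0.88, 0.84, 0.80, 0.76),
  sp = c(0.44, 0.48, 0.52, 0.56, 0.60, 0.64, 0.68, 0.72, 0.76, 0.80,
         0.84, 0.88, rep(0.92, 5)))

ref_table9 <- list(
  table9_pp = list(auc = 0.892, coords = data.frame(
    cutpoint = c(24, 27, 30, 34, 37),
    se = c(0.535, 0.814, 0.837, 0.837, 1.000),
    sp = c(0.983, 0.797, 0.797, 0.771, 0.390))),
  table9_lvef = list(auc = 0.809, coords = data.frame(
    cutpoint = c(0.272, 0.282, 0.290, 0.295, 0.303),
    se = c(0.651, 0.674, 0.698, 0.767, 0.814),
    sp = c(0.814, 0.763, 0.754, 0.695, 0.610))),
  table9_sodium = list(auc = 0.777, coords = data.frame(
    cutpoint = c(133, 134, 135, 136, 137),
    se = c(0.535, 0.605, 0.721, 0.814, 0.930),
    sp = c(0.822, 0.763, 0.669, 0.576, 0.483))),
  table9_hr = list(auc = 0.647, coords = data.frame(
    cutpoint = c(84, 85, 86, 87),
    se = c(0.674, 0.628, 0.581, 0.512),
    sp = c(0.534, 0.585, 0.619, 0.686))))
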