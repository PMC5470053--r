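test_that("every criterion matches an exhaustive-scan oracle on random samples", {
  set.seed(1234)
  for (i in 1:200) {
    sm <- random_sample(ties = i %% 3 == 0)
    roc <- roc_curve(sm$scores, sm$labels, direction = "gt")
    for (m in c("youden", "er", "cz", "minp", "iu")) {
      expect_equal(select_cutpoint(roc, m)$cutpoint,
                   oracle_cutpoint(sm$x1, sm$x0, m),
                   info = paste(m, "sample", i))
    }
  }
})

test_that("the artificial-data coordinate list is resolved as published", {
  roc <- load_fixture("table2")
  iu <- cp_iu(roc)
  expect_equal(iu$cutpoint, 1.985)
  expect_equal(c(iu$se, iu$sp), c(0.92, 0.92))
  expect_equal(iu$criterion_value, abs(0.92 - 0.918) * 2, tolerance = 1e-12)
  yo <- cp_youden(roc)
  expect_equal(yo$cutpoint, 1.985)
  expect_equal(yo$criterion_value, 0.84, tolerance = 1e-12)
  cz <- cp_concordance(roc)
  expect_equal(cz$cutpoint, 1.985)
  expect_equal(cz$criterion_value, 0.8464, tolerance = 1e-12)
})

test_that("heart-failure candidate lists reproduce the published selections", {
  expect_equal(cp_youden(load_fixture("table9_pp"))$cutpoint, 30)
  expect_equal(cp_closest01(load_fixture("table9_pp"))$cutpoint, 30)
  expect_equal(cp_concordance(load_fixture("table9_pp"))$cutpoint, 30)
  expect_equal(cp_minp(load_fixture("table9_pp"))$cutpoint, 24)
  lv <- cp_closest01(load_fixture("table9_lvef"))
  expect_equal(lv$cutpoint, 0.295)
  expect_equal(c(lv$se, lv$sp), c(0.767, 0.695))
  iu_lv <- cp_iu(load_fixture("table9_lvef"))
  expect_equal(iu_lv$cutpoint, 0.295)
  expect_equal(iu_lv$criterion_value,
               abs(0.767 - 0.809) + abs(0.695 - 0.809), tolerance = 1e-12)
})

test_that("minimum P value chi-square matches the closed form and Pearson's test", {
  expect_equal(oracle_chisq(115, 2, 20, 23), 63.94511, tolerance = 1e-6)
  ref <- suppressWarnings(stats::chisq.test(
    matrix(c(115, 2, 20, 23), 2, byrow = TRUE), correct = FALSE))
  expect_equal(oracle_chisq(115, 2, 20, 23), unname(ref$statistic),
               tolerance = 1e-10)
  mp <- cp_minp(load_fixture("table9_pp"))
  expect_equal(mp$cutpoint, 24)
  expect_equal(mp$criterion_value, oracle_chisq(115, 2, 20, 23),
               tolerance = 1e-10)
  # equal cells: statistic is zero
  expect_equal(oracle_chisq(5, 5, 5, 5), 0)
})

test_that("count and probability forms of the chi-square agree at every threshold", {
  set.seed(88)
  for (i in 1:25) {
    sm <- random_sample(ties = TRUE)
    roc <- roc_curve(sm$scores, sm$labels, direction = "gt")
    for (j in seq_along(roc$thresholds)) {
      tab <- roc_table(roc, roc$thresholds[j])
      if (tab["s"] + tab["u"] == 0 || tab["r"] + tab["v"] == 0) next
      expect_equal(oracle_chisq(tab["s"], tab["r"], tab["u"], tab["v"]),
                   oracle_chisq_probs(roc$se[j], roc$sp[j], roc$n1, roc$n0),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("IU applies the |Se - Sp| rule among tied minimizers", {
  roc <- roc_from_coords(
    c(1, 2, 3), se = c(0.95, 0.85, 0.80), sp = c(0.65, 0.75, 0.80),
    auc = 0.8)
  # IU values: 0.30, 0.10, 0.00 -> unique minimum
  expect_equal(cp_iu(roc)$cutpoint, 3)
  roc <- roc_from_coords(
    c(1, 2), se = c(0.75, 0.70), sp = c(0.65, 0.70), auc = 0.8)
  # both have IU = 0.2; the second is more balanced
  iu <- cp_iu(roc)
  expect_equal(iu$cutpoint, 2)
  expect_equal(sort(iu$ties), c(1, 2))
  # exact tie on both rules: smallest cut-point wins
  roc <- roc_from_coords(
    c(1, 2), se = c(0.85, 0.85), sp = c(0.75, 0.75), auc = 0.8)
  expect_equal(cp_iu(roc)$cutpoint, 1)
})

test_that("a point with Se = Sp = AUC attains IU = 0 and is selected", {
  roc <- roc_from_coords(c(1, 2, 3), se = c(0.9, 0.8, 0.6),
                         sp = c(0.6, 0.8, 0.9), auc = 0.8)
  iu <- cp_iu(roc)
  expect_equal(iu$cutpoint, 2)
  expect_equal(iu$criterion_value, 0)
})

test_that("the IU minimizer is at least as balanced as the Youden point on average", {
  set.seed(31)
  diff_iu <- diff_j <- numeric(0)
  for (i in 1:150) {
    sm <- random_sample()
    roc <- roc_curve(sm$scores, sm$labels, direction = "gt")
    if (!(any(roc$se > roc$sp) && any(roc$se < roc$sp))) next
    iu <- cp_iu(roc)
    yo <- cp_youden(roc)
    diff_iu <- c(diff_iu, abs(iu$se - iu$sp))
    diff_j <- c(diff_j, abs(yo$se - yo$sp))
  }
  # IU is more balanced in the vast majority of samples and on average
  expect_lt(mean(diff_iu), mean(diff_j))
  expect_gt(mean(diff_iu <= diff_j + 1e-9), 0.95)
})

test_that("concordance value obeys the AM-GM bound at its optimum", {
  set.seed(77)
  for (i in 1:30) {
    sm <- random_sample()
    cz <- cp_concordance(roc_curve(sm$scores, sm$labels, direction = "gt"))
    expect_lte(cz$criterion_value, ((cz$se + cz$sp) / 2)^2 + 1e-12)
  }
})

test_that("selection dispatch honors aliases and rejects unknown names", {
  roc <- load_fixture("table9_pp")
  expect_equal(select_cutpoint(roc, "youden")$cutpoint,
               cp_youden(roc)$cutpoint)
  expect_equal(select_cutpoint(roc, "index_of_union")$cutpoint,
               cp_iu(roc)$cutpoint)
  expect_equal(select_cutpoint(roc, "closest_01")$cutpoint,
               cp_closest01(roc)$cutpoint)
  expect_error(select_cutpoint(roc, "foo"), "unknown method")
})

test_that("criterion value is the objective recomputed at the selected point", {
  set.seed(15)
  sm <- random_sample(20, 20)
  roc <- roc_curve(sm$scores, sm$labels, direction = "gt")
  yo <- cp_youden(roc)
  expect_equal(yo$criterion_value, yo$se + yo$sp - 1, tolerance = 1e-12)
  er <- cp_closest01(roc)
  expect_equal(er$criterion_value,
               sqrt((1 - er$se)^2 + (1 - er$sp)^2), tolerance = 1e-12)
  cz <- cp_concordance(roc)
  expect_equal(cz$criterion_value, cz$se * cz$sp, tolerance = 1e-12)
  iu <- cp_iu(roc)
  expect_equal(iu$criterion_value,
               abs(iu$se - roc$auc) + abs(iu$sp - roc$auc), tolerance = 1e-12)
})
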