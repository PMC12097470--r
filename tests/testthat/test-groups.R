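test_that("Mann-Whitney exact branch matches full enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(mw_enum_oracle(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # random small samples: implementation vs enumeration oracle
  set.seed(51)
  for (k in 1:10) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(mann_whitney_u(a, b)$p, mw_enum_oracle(a, b),
                 tolerance = 1e-10)
  }
})

test_that("Mann-Whitney is symmetric, sane on identical samples, errors on empty", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(mann_whitney_u(a, c(0.3, 1.8, 4.4))$p,
               mann_whitney_u(c(0.3, 1.8, 4.4), a)$p)
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p, 0.99)
  expect_error(mann_whitney_u(numeric(0), a), "non-empty")
})

test_that("exact and normal-approximation branches agree for moderate n", {
  set.seed(52)
  for (k in 1:10) {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    p_exact <- wilcox.test(a, b, exact = TRUE)$p.value
    p_norm <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
})

test_that("Bonferroni flags compare p against alpha/m", {
  expect_equal(bonferroni(c(0.01, 0.04), alpha = 0.05, m = 4),
               c(TRUE, FALSE))
  expect_equal(bonferroni(0.03, alpha = 0.05, m = 1), TRUE)
  expect_equal(bonferroni(rep(1, 5), alpha = 0.05), rep(FALSE, 5))
  expect_error(bonferroni(0.5, alpha = 2), "alpha")
})

test_that("JS divergence hits its bounds and is symmetric", {
  set.seed(53)
  x <- runif(200, 0, 1)
  expect_equal(js_divergence(x, x, c(0, 1)), 0, tolerance = 1e-9)
  a <- runif(200, 0, 0.4)
  b <- runif(200, 0.6, 1)
  expect_equal(js_divergence(a, b, c(0, 1)), 1, tolerance = 1e-6)
  y <- runif(150, 0.2, 0.9)
  expect_equal(js_divergence(x, y, c(0, 1)), js_divergence(y, x, c(0, 1)))
  j <- js_divergence(x, y, c(0, 1))
  expect_gte(j, 0); expect_lte(j, 1)
  expect_error(js_divergence(x, y, c(1, 1)), "degenerate")
})

test_that("divergence ranking puts the one manipulated parameter first", {
  # two artificial groups of fit results that differ only in theta_e
  mk_fit <- function(theta, id) {
    p <- unclass(nmm_params())
    p["theta_e"] <- theta
    structure(list(repeat_id = id,
                   pareto_params = matrix(p, nrow = 1,
                                          dimnames = list(NULL, names(p))),
                   pareto_objectives = matrix(c(1, 1), 1,
                                              dimnames = list(NULL, c("f_spec", "f_hvg"))),
                   best = list(params = structure(p, class = "nmm_params"),
                               objectives = c(f_spec = 1, f_hvg = 1)),
                   seed = id, trace = NULL), class = "fit_result")
  }
  set.seed(54)
  ga <- lapply(1:12, function(i) mk_fit(-60 + rnorm(1, 0, 0.2), i))
  gb <- lapply(1:12, function(i) mk_fit(-56 + rnorm(1, 0, 0.2), i))
  rk <- rank_parameters_by_divergence(ga, gb)
  expect_equal(nrow(rk), sum(nmm_bounds()$searched))
  expect_equal(rk$param[1], "theta_e")
  # rank-1 identity is robust to bin count
  for (nb in c(10, 40)) {
    expect_equal(rank_parameters_by_divergence(ga, gb, bins = nb)$param[1],
                 "theta_e")
  }
  # identical groups: every JSD at the sampling-noise floor, estimated by
  # a within-group split-half
  rk0 <- rank_parameters_by_divergence(ga[1:6], ga[7:12])
  floor_jsd <- js_divergence(
    vapply(ga[1:6], function(f) f$best$params[["theta_e"]], 0),
    vapply(ga[7:12], function(f) f$best$params[["theta_e"]], 0),
    c(-65, -52))
  expect_lte(max(rk0$jsd), max(floor_jsd, rk0$jsd[rk0$param == "theta_e"]) + 1e-9)
  expect_error(rank_parameters_by_divergence(list(), gb), "at least one")
})

test_that("compare_groups tests each property against control pairwise", {
  set.seed(55)
  summ <- data.frame(
    subject_id = sprintf("s%02d", 1:12),
    group = rep(c("control", "patient_no_seizure", "patient_seizure"),
                each = 4),
    mean_Q_e = c(rnorm(4, 5), rnorm(4, 9), rnorm(4, 12)),
    stringsAsFactors = FALSE)
  cmp <- compare_groups(summ, properties = "mean_Q_e")
  expect_equal(nrow(cmp), 3)  # one per patient grouping vs control
  expect_true(all(cmp$direction == 1))
  expect_equal(cmp$significant, cmp$p < 0.05 / 1)
  expect_error(compare_groups(summ[summ$group == "control", ],
                              properties = "mean_Q_e"), "two groups")
})

test_that("identical group distributions are rarely flagged significant", {
  # type-I control of the comparison machinery at alpha = 0.05
  set.seed(56)
  hits <- 0
  for (k in 1:60) {
    summ <- data.frame(
      subject_id = sprintf("s%02d", 1:12),
      group = rep(c("control", "patient_no_seizure", "patient_seizure"),
                  each = 4),
      mean_Q_e = rnorm(12, 8), stringsAsFactors = FALSE)
    cmp <- compare_groups(summ, properties = "mean_Q_e")
    if (any(cmp$significant)) hits <- hits + 1
  }
  # 3 pairwise tests at alpha = 0.05 each: expect few flagged cohorts
  expect_lte(hits / 60, 0.25)
})
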