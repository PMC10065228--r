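test_that("the Pearson 2x2 statistic matches its closed form and reference", {
  r <- chi2_2x2(30, 70, 10, 90)
  expect_equal(r$statistic, 12.5, tolerance = 1e-12)
  expect_equal(r$p_value, 4.069520174e-4, tolerance = 1e-8)

  r0 <- chi2_2x2(25, 75, 25, 75)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  rd <- chi2_2x2(0, 0, 10, 90)
  expect_true(rd$degenerate)
  expect_equal(rd$p_value, 1)

  set.seed(101)
  for (i in 1:500) {
    tb <- matrix(rpois(4, 40) + 1, 2)
    ref <- suppressWarnings(chisq.test(tb, correct = FALSE))
    got <- chi2_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

rand_matrices <- function(n_feat, n_case, n_ctrl, n_sets, p_case, p_ctrl, seed) {
  set.seed(seed)
  cm <- matrix(rbinom(n_case * n_feat, 1, p_case), n_case,
               dimnames = list(NULL, paste0("f", seq_len(n_feat))))
  ctrl <- lapply(seq_len(n_sets), function(k) {
    matrix(rbinom(n_ctrl * n_feat, 1, p_ctrl), n_ctrl,
           dimnames = list(NULL, paste0("f", seq_len(n_feat))))
  })
  list(case = cm, ctrl = ctrl)
}

test_that("stability screening counts, flags and directions behave", {
  cfg <- selection_config(n_cohorts = 20, stability_fraction = 0.9)

  # identical distributions: nothing passes
  m <- rand_matrices(10, 50, 50, 20, 0.3, 0.3, seed = 1)
  same <- stability_screen(m$case, lapply(m$ctrl, function(x) m$case), cfg)
  expect_equal(sum(same$n_pass), 0)

  # total separation passes every cohort with direction +1
  cm <- matrix(1L, 25, 1, dimnames = list(NULL, "f1"))
  ctrl <- replicate(20, matrix(0L, 25, 1, dimnames = list(NULL, "f1")),
                    simplify = FALSE)
  r <- stability_screen(cm, ctrl, cfg)
  expect_equal(r$n_pass, 20)
  expect_true(r$pass)
  expect_equal(r$direction, 1L)

  # control-enriched features carry direction -1, not removal
  r2 <- stability_screen(1L - cm, lapply(ctrl, function(x) 1L - x), cfg)
  expect_equal(r2$direction, -1L)
  expect_true(r2$pass)

  bad <- m$ctrl
  colnames(bad[[3]]) <- paste0("g", 1:10)
  expect_error(stability_screen(m$case, bad, cfg), "feature index")
  expect_error(stability_screen(m$case, m$ctrl[1:5], cfg), "control matrices")
})

test_that("selection is monotone in the stability threshold and alpha", {
  m <- rand_matrices(30, 60, 60, 20, 0.35, 0.2, seed = 7)
  sel_at <- function(frac, alpha) {
    cfg <- selection_config(alpha = alpha, n_cohorts = 20,
                            stability_fraction = frac)
    r <- stability_screen(m$case, m$ctrl, cfg)
    r$feature_key[r$pass]
  }
  for (fr in c(0.5, 0.75, 0.9)) {
    expect_true(all(sel_at(0.95, 0.01) %in% sel_at(fr, 0.01)))
  }
  expect_true(all(sel_at(0.75, 0.001) %in% sel_at(0.75, 0.01)))
})

test_that("the global null keeps per-feature pass rates at the analytic tail", {
  m <- rand_matrices(40, 60, 60, 20, 0.3, 0.3, seed = 17)
  cfg <- selection_config(n_cohorts = 20, stability_fraction = 0.9)
  r <- stability_screen(m$case, m$ctrl, cfg)
  # expected features passing under independent tests is vanishingly small;
  # the shared case margin correlates the tests but the event still requires
  # a ~4.5-sigma case-frequency excursion
  tail_bound <- pbinom(ceiling(0.9 * 20) - 1, 20, 0.01, lower.tail = FALSE)
  expect_lt(tail_bound * 40, 0.01)
  expect_lte(sum(r$pass), 1)

  # planted signal at study-like penetrance is selected
  sig <- rand_matrices(1, 175, 175, 20, 0.6, 0.05, seed = 19)
  rs <- stability_screen(sig$case, sig$ctrl, cfg)
  expect_true(rs$pass)
})

test_that("logistic filtering retains true effects and handles collinearity", {
  set.seed(23)
  n <- 400
  x1 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 2 * x1))
  x <- cbind(strong = x1, noise = rbinom(n, 1, 0.3), dup = x1)
  r <- lr_filter(x, y, selection_config())
  expect_true(r$retained[r$feature_key == "strong"])
  expect_false(r$retained[r$feature_key == "noise"])
  expect_equal(r$flag[r$feature_key == "dup"], "duplicate")
  expect_equal(sum(r$feature_key %in% c("strong", "dup") & r$retained), 1)
})

test_that("Wald p-values match an independent Newton-Raphson fit", {
  set.seed(29)
  n <- 500
  x <- matrix(rbinom(n * 5, 1, 0.35), n,
              dimnames = list(NULL, paste0("v", 1:5)))
  eta <- -0.5 + x %*% c(1.2, -0.8, 0.4, 0, 0.1)
  y <- rbinom(n, 1, plogis(eta))
  r <- lr_filter(x, y, selection_config())
  o <- oracle_logistic(x, y)
  expect_equal(r$estimate, unname(o$coef), tolerance = 1e-6)
  expect_equal(r$p_value, unname(o$p), tolerance = 1e-6)
})

test_that("separated features are flagged and retained, not dropped", {
  y <- rep(c(1, 0), each = 30)
  x <- cbind(sep = y, other = rbinom(60, 1, 0.5))
  expect_warning(r <- lr_filter(x, y, selection_config()), "ridge")
  expect_equal(r$flag[r$feature_key == "sep"], "separation")
  expect_true(r$retained[r$feature_key == "sep"])
})

test_that("PCA satisfies its geometric contracts", {
  # single varying feature: first loading is that axis with share 1
  x <- cbind(a = c(0, 1, 0, 1, 1, 0), b = 1)
  expect_error(fit_pca(cbind(a = rep(1, 5), b = rep(0, 5))), "constant")
  p1 <- suppressWarnings(fit_pca(x, var_target = 0.8))
  expect_equal(abs(p1$rotation[, 1]), c(a = 1, b = 0))
  expect_equal(p1$var_share[1], 1)

  # projecting the training mean gives an all-zero score vector
  set.seed(37)
  xr <- matrix(rbinom(50 * 8, 1, 0.4), 50,
               dimnames = list(NULL, paste0("f", 1:8)))
  pm <- fit_pca(xr)
  mu <- matrix(colMeans(xr), 1, dimnames = list(NULL, colnames(xr)))
  expect_equal(max(abs(project_scores(pm, mu))), 0, tolerance = 1e-10)

  # eigen-decomposition oracle on the covariance matrix
  ev <- eigen(stats::cov(xr), symmetric = TRUE)$values
  expect_equal(pm$sdev^2, ev[seq_along(pm$sdev)], tolerance = 1e-8)
  expect_equal(pm$var_share, ev / sum(ev), tolerance = 1e-8)

  # orthonormal loadings and exact reconstruction from all components
  expect_equal(crossprod(pm$rotation), diag(ncol(xr)), tolerance = 1e-8,
               ignore_attr = TRUE)
  centred <- sweep(xr, 2, pm$center)
  scores_all <- centred %*% pm$rotation
  expect_equal(scores_all %*% t(pm$rotation), centred, tolerance = 1e-8,
               ignore_attr = TRUE)

  # retained components are the smallest set explaining >= the target
  cum <- cumsum(pm$var_share)
  expect_gte(cum[pm$k], 0.8)
  if (pm$k > 1) expect_lt(cum[pm$k - 1], 0.8)

  expect_error(fit_pca(xr[, 1, drop = FALSE]), "2 features")
  expect_error(fit_pca(xr[1:2, ]), "3 rows")
})

test_that("projection aligns columns by name, zero-filling missing features", {
  set.seed(41)
  xr <- matrix(rbinom(30 * 4, 1, 0.5), 30,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  pm <- fit_pca(xr)
  new <- matrix(c(1, 0, 1), 1, dimnames = list(NULL, c("b", "d", "zz")))
  full <- matrix(0, 1, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  full[, "b"] <- 1
  expect_equal(project_scores(pm, new), project_scores(pm, full))
})
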