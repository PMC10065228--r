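sim_scores <- function(n, k = 2, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * k), n, k, dimnames = list(NULL, LETTERS[seq_len(k)]))
}

test_that("perfectly separable data yields a depth-1 tree with zero error", {
  sc <- matrix(c(1:10 / 10, 2 + 1:10 / 10), ncol = 1,
               dimnames = list(NULL, "A"))
  y <- rep(c("NON_AS", "AS"), each = 10)
  tr <- fit_tree(sc, y, tree_config(min_leaf = 5, min_split = 10))
  expect_equal(tr$root$type, "split")
  expect_equal(tr$root$left$type, "leaf")
  expect_equal(tr$root$right$type, "leaf")
  expect_equal(predict_tree(tr, sc)$label, y)
})

test_that("single-class input gives a constant depth-0 tree", {
  sc <- sim_scores(30)
  tr <- fit_tree(sc, rep("AS", 30), tree_config())
  expect_equal(tr$root$type, "leaf")
  expect_equal(tr$root$label, "AS")
  expect_equal(unique(predict_tree(tr, sim_scores(5, seed = 2))$label), "AS")
})

test_that("greedy splits equal the exhaustive-search impurity minimiser", {
  for (seed in 1:3) {
    sc <- sim_scores(200, k = 2, seed = seed)
    y <- (sc[, 1] + 0.5 * sc[, 2] + rnorm(200, sd = 0.7)) > 0
    cfg <- tree_config(max_depth = 2, min_leaf = 10, min_split = 20)
    tr <- fit_tree(sc, ifelse(y, "AS", "NON_AS"), cfg)
    o <- oracle_split(sc, y, 10)
    expect_equal(tr$root$comp, o$comp)
    expect_equal(tr$root$threshold, o$threshold, tolerance = 1e-12)
    # and each child's split, where the child splits further
    for (side in c("left", "right")) {
      node <- tr$root[[side]]
      if (node$type != "split") next
      in_side <- if (side == "left") sc[, tr$root$comp] <= tr$root$threshold
        else sc[, tr$root$comp] > tr$root$threshold
      oc <- oracle_split(sc[in_side, , drop = FALSE], y[in_side], 10)
      expect_equal(node$comp, oc$comp)
      expect_equal(node$threshold, oc$threshold, tolerance = 1e-12)
    }
  }
})

test_that("tree induction respects its depth and leaf-size limits", {
  sc <- sim_scores(300, k = 3, seed = 9)
  y <- ifelse(rowSums(sc) + rnorm(300) > 0, "AS", "NON_AS")
  cfg <- tree_config(max_depth = 3, min_leaf = 10, min_split = 20)
  tr <- fit_tree(sc, y, cfg)
  lv <- tree_leaves(tr)
  expect_true(all(lv$n >= 10))
  depth <- function(node) if (node$type == "leaf") 0 else
    1 + max(depth(node$left), depth(node$right))
  expect_lte(depth(tr$root), 3)
  # leaf ids are sequential with the requested prefix
  expect_equal(sort(lv$id), sort(paste0("M", seq_len(nrow(lv)))))
})

test_that("candidate fitting is per control cohort and deterministic", {
  case_sc <- sim_scores(60, seed = 11) + 0.8
  ctrl <- lapply(1:10, function(k) sim_scores(60, seed = 100 + k))
  cands <- fit_candidates(case_sc, ctrl, tree_config())
  expect_length(cands, 10)
  expect_error(fit_candidates(case_sc, ctrl, tree_config(), n_cohorts = 20),
               "20")

  same <- fit_candidates(case_sc, list(ctrl[[1]], ctrl[[1]]), tree_config())
  expect_identical(same[[1]], same[[2]])

  # each tree reproduces its own training-pair predictions on replay
  for (k in c(1, 5)) {
    sc <- rbind(case_sc, ctrl[[k]])
    p1 <- predict_tree(cands[[k]], sc)
    p2 <- predict_tree(cands[[k]], sc)
    expect_identical(p1, p2)
  }
})

test_that("model selection maximises mean F with index tie-breaking", {
  case_sc <- sim_scores(50, seed = 13) + 1.2
  ctrl <- lapply(1:8, function(k) sim_scores(50, seed = 200 + k))
  cands <- fit_candidates(case_sc, ctrl, tree_config())
  pick <- select_best(cands, case_sc, ctrl)

  # replay oracle: recompute every (candidate, pairing) F from scratch
  fmat <- attr(pick$report, "f_matrix")
  for (m in seq_along(cands)) {
    for (k in seq_along(ctrl)) {
      sc <- rbind(case_sc, ctrl[[k]])
      truth <- c(rep("AS", 50), rep("NON_AS", 50))
      pred <- predict_tree(cands[[m]], sc)$label
      tp <- sum(pred == "AS" & truth == "AS")
      fp <- sum(pred == "AS" & truth == "NON_AS")
      fn <- sum(pred == "NON_AS" & truth == "AS")
      sens <- tp / (tp + fn)
      ppv <- if (tp + fp > 0) tp / (tp + fp) else NA
      f <- if (is.na(ppv) || sens + ppv == 0) 0 else 2 * sens * ppv / (sens + ppv)
      expect_equal(fmat[m, k], f, tolerance = 1e-12)
    }
  }
  expect_equal(pick$best, which.max(rowMeans(fmat)))
  expect_equal(pick$report$mean_f[pick$best], max(rowMeans(fmat)))

  # identical candidates: ties break to the lowest index
  twin <- select_best(list(cands[[1]], cands[[1]]), case_sc, ctrl)
  expect_equal(twin$best, 1)
})

test_that("prediction equals a manual trace through the stored tree", {
  sc <- sim_scores(300, k = 3, seed = 17)
  y <- ifelse(sc[, 1] - sc[, 3] + rnorm(300, sd = 0.5) > 0, "AS", "NON_AS")
  tr <- fit_tree(sc, y, tree_config(max_depth = 3))
  new <- sim_scores(1000, k = 3, seed = 18)
  got <- predict_tree(tr, new)
  for (i in sample(1000, 50)) {
    o <- oracle_traverse(tr, new[i, ])
    expect_equal(got$label[i], unname(o["label"]))
    expect_equal(got$leaf[i], unname(o["leaf"]))
  }
})

fit_small_pctree <- function(seed = 51) {
  set.seed(seed)
  n_feat <- 8
  feats <- paste0("f", seq_len(n_feat))
  p_case <- c(0.7, 0.65, 0.6, rep(0.25, 5))
  p_ctrl <- c(0.15, 0.2, 0.2, rep(0.25, 5))
  cm <- sapply(seq_len(n_feat), function(j) rbinom(80, 1, p_case[j]))
  colnames(cm) <- feats
  ctrl <- lapply(1:10, function(k) {
    m <- sapply(seq_len(n_feat), function(j) rbinom(80, 1, p_ctrl[j]))
    colnames(m) <- feats
    m
  })
  fit_pctree(cm, ctrl,
             selection = selection_config(n_cohorts = 10,
                                          stability_fraction = 0.9),
             tree = tree_config(max_depth = 2, min_leaf = 10))
}

test_that("the fitted model pipeline predicts with column alignment", {
  m <- fit_small_pctree()
  expect_s3_class(m, "pctree")
  expect_true(all(c("f1", "f2", "f3") %in% m$features))

  new <- matrix(1, 1, 3, dimnames = list("p1", c("f1", "f2", "f3")))
  extra <- cbind(new, matrix(1, 1, 1, dimnames = list("p1", "unknown")))
  full <- matrix(0, 1, length(m$features), dimnames = list("p1", m$features))
  full[, intersect(c("f1", "f2", "f3"), m$features)] <- 1
  expect_equal(predict(m, new), predict(m, full))
  expect_equal(predict(m, extra), predict(m, full))
  expect_equal(nrow(predict(m, full[0, , drop = FALSE])), 0)

  p <- predict(m, full)
  expect_equal(p$label, "AS")
})

test_that("serialised models round-trip with identical predictions", {
  m <- fit_small_pctree(seed = 53)
  path <- withr::local_tempfile(fileext = ".txt")
  write_pctree(m, path)
  back <- read_pctree(path)
  set.seed(55)
  new <- matrix(rbinom(50 * length(m$features), 1, 0.4), 50,
                dimnames = list(NULL, m$features))
  expect_equal(predict(back, new), predict(m, new))
  expect_equal(back$pc_model$center, m$pc_model$center)
})
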