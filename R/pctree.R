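# Decision trees on principal-component scores. One candidate tree is fitted
# per matched control cohort (cases vs control set k) and the final model is
# the candidate with the highest average F value across all 100 pairings.
# Tree induction is greedy axis-aligned CART with Gini impurity and fully
# deterministic tie-breaking (lowest component index, then lowest threshold),
# so identical inputs always give identical trees.

#' Tree induction configuration
#'
#' @param max_depth maximum tree depth (root = depth 0; default 3, matching
#'   the published trees' 2-3 level shape).
#' @param min_leaf minimum participants in a leaf (default 10).
#' @param min_split minimum participants required to attempt a split.
#' @return list of class `tree_config`.
#' @export
tree_config <- function(max_depth = 3, min_leaf = 10, min_split = 20) {
  if (max_depth < 0 || min_leaf < 1 || min_split < 2) {
    stop("invalid tree configuration", call. = FALSE)
  }
  structure(list(max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf),
                 min_split = as.integer(min_split)),
            class = "tree_config")
}

gini <- function(n_as, n) {
  p <- n_as / n
  1 - p^2 - (1 - p)^2
}

# Best axis-aligned split of y (logical: AS) over the score columns.
# Returns NULL when no split satisfies the constraints or reduces impurity.
best_split <- function(scores, y, min_leaf) {
  n <- length(y)
  parent <- gini(sum(y), n) * n
  best <- NULL
  for (j in seq_len(ncol(scores))) {
    v <- scores[, j]
    o <- order(v)
    vs <- v[o]; ys <- y[o]
    cut_ok <- which(diff(vs) > 0)                 # split between distinct values
    cut_ok <- cut_ok[cut_ok >= min_leaf & (n - cut_ok) >= min_leaf]
    if (!length(cut_ok)) next
    cum_as <- cumsum(ys)
    nl <- cut_ok
    al <- cum_as[cut_ok]
    ar <- sum(ys) - al
    nr <- n - nl
    imp <- gini(al, nl) * nl + gini(ar, nr) * nr  # weighted child impurity * n
    ord2 <- order(imp, vs[cut_ok])                # tie: lowest threshold
    i <- ord2[1]
    if (imp[i] < parent - 1e-12 &&
        (is.null(best) || imp[i] < best$imp - 1e-12)) {
      best <- list(comp = j, threshold = (vs[cut_ok[i]] + vs[cut_ok[i] + 1]) / 2,
                   imp = imp[i])
    }
  }
  best
}

#' Fit a decision tree on principal-component scores
#'
#' Greedy CART-style binary tree: each internal node tests one component
#' against a threshold (`<=` goes left). Leaves carry a predicted label
#' (`AS` if the training case fraction exceeds 0.5, `NON_AS` otherwise,
#' ties to `NON_AS`), an id (`M1`, `M2`, ... under the default prefix), and
#' the leaf's training composition, whose case fraction doubles as a
#' continuous risk score for ROC analysis.
#'
#' @param scores numeric matrix of component scores.
#' @param labels vector of `"AS"`/`"NON_AS"` (or logical: case).
#' @param cfg a [tree_config()].
#' @param leaf_prefix prefix for leaf ids (`"M"` male-style, `"F"`
#'   female-style).
#' @return object of class `pc_tree`.
#' @export
fit_tree <- function(scores, labels, cfg = tree_config(), leaf_prefix = "M") {
  scores <- as.matrix(scores)
  y <- if (is.logical(labels)) labels else as.character(labels) == "AS"
  stopifnot(nrow(scores) == length(y))

  build <- function(idx, depth) {
    n <- length(idx)
    n_as <- sum(y[idx])
    make_leaf <- function() {
      list(type = "leaf", label = if (n_as / n > 0.5) "AS" else "NON_AS",
           n = n, n_as = n_as, case_frac = n_as / n)
    }
    if (depth >= cfg$max_depth || n < cfg$min_split || n_as == 0 || n_as == n) {
      return(make_leaf())
    }
    sp <- best_split(scores[idx, , drop = FALSE], y[idx], cfg$min_leaf)
    if (is.null(sp)) return(make_leaf())
    left <- idx[scores[idx, sp$comp] <= sp$threshold]
    right <- idx[scores[idx, sp$comp] > sp$threshold]
    list(type = "split", comp = sp$comp, threshold = sp$threshold,
         left = build(left, depth + 1), right = build(right, depth + 1))
  }
  root <- build(seq_along(y), 0)

  leaf_counter <- 0L
  number <- function(node) {
    if (node$type == "leaf") {
      leaf_counter <<- leaf_counter + 1L
      node$id <- paste0(leaf_prefix, leaf_counter)
    } else {
      node$left <- number(node$left)
      node$right <- number(node$right)
    }
    node
  }
  root <- number(root)
  structure(list(root = root, n_components = ncol(scores),
                 component_names = colnames(scores), config = cfg,
                 leaf_prefix = leaf_prefix),
            class = "pc_tree")
}

#' Predict labels and leaf assignments from a fitted tree
#'
#' @param tree a `pc_tree`.
#' @param scores numeric score matrix.
#' @return data.frame (label, leaf, score) where `score` is the training
#'   case fraction of the assigned leaf.
#' @export
predict_tree <- function(tree, scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  label <- character(n); leaf <- character(n); score <- numeric(n)
  walk <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$type == "leaf") {
      label[idx] <<- node$label
      leaf[idx] <<- node$id
      score[idx] <<- node$case_frac
      return(invisible())
    }
    go_left <- scores[idx, node$comp] <= node$threshold
    walk(node$left, idx[go_left])
    walk(node$right, idx[!go_left])
  }
  walk(tree$root, seq_len(n))
  data.frame(label = label, leaf = leaf, score = score,
             row.names = rownames(scores), stringsAsFactors = FALSE)
}

#' Leaf summary of a fitted tree
#'
#' @param tree a `pc_tree`.
#' @return data.frame (id, label, n, n_as, case_frac, path) — the exportable
#'   subgroup table behind the published M1-M4 / F1-F6 narratives.
#' @export
tree_leaves <- function(tree) {
  rows <- list()
  walk <- function(node, path) {
    if (node$type == "leaf") {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = node$id, label = node$label, n = node$n, n_as = node$n_as,
        case_frac = node$case_frac, path = path, stringsAsFactors = FALSE)
    } else {
      cn <- (tree$component_names %||% LETTERS)[node$comp]
      sep <- if (nzchar(path)) " & " else ""
      walk(node$left, paste0(path, sep, cn, " <= ", signif(node$threshold, 4)))
      walk(node$right, paste0(path, sep, cn, " > ", signif(node$threshold, 4)))
    }
  }
  walk(tree$root, "")
  do.call(rbind, rows)
}

#' @export
print.pc_tree <- function(x, ...) {
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s%s: %s (n=%d, case fraction %.2f)\n", pad, node$id,
                  node$label, node$n, node$case_frac))
    } else {
      cn <- (x$component_names %||% LETTERS)[node$comp]
      cat(sprintf("%sif %s <= %.4g:\n", pad, cn, node$threshold))
      walk(node$left, indent + 1)
      cat(sprintf("%selse (%s > %.4g):\n", pad, cn, node$threshold))
      walk(node$right, indent + 1)
    }
  }
  cat("Decision tree on principal-component scores\n")
  walk(x$root, 0)
  invisible(x)
}

#' Fit one candidate tree per matched control cohort
#'
#' @param case_scores score matrix for the cases.
#' @param control_score_sets list of score matrices, one per control set.
#' @param cfg a [tree_config()].
#' @param n_cohorts expected number of control sets (defaults to the number
#'   supplied; fewer than this is an error).
#' @param leaf_prefix leaf id prefix.
#' @return list of `pc_tree` candidates.
#' @export
fit_candidates <- function(case_scores, control_score_sets,
                           cfg = tree_config(),
                           n_cohorts = length(control_score_sets),
                           leaf_prefix = "M") {
  if (length(control_score_sets) < n_cohorts) {
    stop(sprintf("need %d control score sets, got %d", n_cohorts,
                 length(control_score_sets)), call. = FALSE)
  }
  lapply(control_score_sets[seq_len(n_cohorts)], function(cs) {
    fit_tree(rbind(case_scores, cs),
             c(rep("AS", nrow(case_scores)), rep("NON_AS", nrow(cs))),
             cfg, leaf_prefix)
  })
}

#' Select the candidate tree with the highest average F value
#'
#' Every candidate is evaluated against all matched pairings (cases vs each
#' control set); the F value (harmonic mean of sensitivity and positive
#' predictive value) is computed per pairing and the winner maximises the
#' mean. Exact ties break to the lowest candidate index. A pairing where F
#' is undefined (no predicted positives) contributes 0.
#'
#' @param candidates list of `pc_tree` (from [fit_candidates()]).
#' @param case_scores score matrix for the cases.
#' @param control_score_sets list of control score matrices.
#' @return list with `model` (the winning `pc_tree`), `report` (data.frame
#'   candidate, mean_f, rank; the per-pairing F matrix as attribute
#'   `f_matrix`), and `best` (winning index).
#' @export
select_best <- function(candidates, case_scores, control_score_sets) {
  n_case <- nrow(case_scores)
  truth <- c(rep("AS", n_case), rep("NON_AS", nrow(control_score_sets[[1]])))
  fmat <- matrix(NA_real_, length(candidates), length(control_score_sets))
  for (k in seq_along(control_score_sets)) {
    sc <- rbind(case_scores, control_score_sets[[k]])
    for (m in seq_along(candidates)) {
      pred <- predict_tree(candidates[[m]], sc)$label
      cm <- confusion(pred, truth)
      f <- metrics(cm)$f_value
      fmat[m, k] <- if (is.na(f)) 0 else f / 100
    }
  }
  mean_f <- rowMeans(fmat)
  best <- which.max(mean_f)
  report <- data.frame(candidate = seq_along(candidates), mean_f = mean_f,
                       rank = rank(-mean_f, ties.method = "first"))
  attr(report, "f_matrix") <- fmat
  list(model = candidates[[best]], report = report, best = best)
}

#' Fit the full PC-tree prediction model
#'
#' The modelling front door: chi-squared stability screening of the binary
#' features against all matched control sets, logistic-regression filtering,
#' principal component analysis of the survivors, one candidate decision
#' tree per control cohort, and selection of the candidate with the highest
#' average F value.
#'
#' PCA (and the logistic filter) are fitted on the cases plus control set 1
#' by default; `pca_pooled = TRUE` pools all control sets instead.
#'
#' @param case_matrix binary feature matrix for cases (training split).
#' @param control_matrices list of binary feature matrices, one per control
#'   set, sharing `case_matrix`'s columns.
#' @param selection a [selection_config()].
#' @param tree a [tree_config()].
#' @param leaf_prefix leaf id prefix (`"M"`/`"F"`).
#' @param pca_pooled fit PCA on cases + all control sets instead of cases +
#'   set 1.
#' @return object of class `pctree` with components `stability`, `lr`,
#'   `features` (retained keys), `pc_model`, `tree`, `selection_report`,
#'   `n_candidates`.
#' @export
fit_pctree <- function(case_matrix, control_matrices,
                       selection = selection_config(),
                       tree = tree_config(),
                       leaf_prefix = "M",
                       pca_pooled = FALSE) {
  stab <- stability_screen(case_matrix, control_matrices, selection)
  sel <- stab$feature_key[stab$pass]
  if (!length(sel)) {
    stop("no features passed the stability screen; nothing to model",
         call. = FALSE)
  }
  ref_ctrl <- if (pca_pooled) do.call(rbind, control_matrices) else control_matrices[[1]]
  x_lr <- rbind(case_matrix[, sel, drop = FALSE],
                ref_ctrl[, sel, drop = FALSE])
  y_lr <- c(rep(1, nrow(case_matrix)), rep(0, nrow(ref_ctrl)))
  lr <- lr_filter(x_lr, y_lr, selection)
  retained <- lr$feature_key[lr$retained]
  if (length(retained) < 2) {
    stop("fewer than 2 features survived the logistic filter; PCA needs >= 2",
         call. = FALSE)
  }
  pcm <- fit_pca(x_lr[, retained, drop = FALSE], selection$pca_var)
  case_scores <- project_scores(pcm, case_matrix[, retained, drop = FALSE])
  control_scores <- lapply(control_matrices, function(m) {
    project_scores(pcm, m[, retained, drop = FALSE])
  })
  cands <- fit_candidates(case_scores, control_scores, tree,
                          n_cohorts = selection$n_cohorts,
                          leaf_prefix = leaf_prefix)
  pick <- select_best(cands, case_scores, control_scores)
  structure(list(stability = stab, lr = lr, features = retained,
                 pc_model = pcm, tree = pick$model,
                 selection_report = pick$report, best = pick$best,
                 n_candidates = length(cands),
                 selection_config = selection, tree_config = tree),
            class = "pctree")
}

#' @export
print.pctree <- function(x, ...) {
  cat("PC-tree prediction model\n")
  cat(sprintf("  stability screen: %d / %d features passed\n",
              sum(x$stability$pass), nrow(x$stability)))
  cat(sprintf("  logistic filter:  %d features retained\n", length(x$features)))
  cat(sprintf("  PCA:              %d components (%.1f%% variance)\n",
              x$pc_model$k, 100 * sum(x$pc_model$var_share[seq_len(x$pc_model$k)])))
  cat(sprintf("  selected tree:    candidate %d of %d, mean F = %.3f\n",
              x$best, x$n_candidates,
              x$selection_report$mean_f[x$best]))
  invisible(x)
}

#' @export
summary.pctree <- function(object, ...) {
  print(object)
  cat("\nRetained features:\n")
  print(object$lr[object$lr$retained, c("feature_key", "estimate", "p_value")],
        row.names = FALSE)
  cat("\n")
  print(object$pc_model)
  cat("\n")
  print(object$tree)
  cat("\nLeaf subgroups:\n")
  print(tree_leaves(object$tree), row.names = FALSE)
  invisible(object)
}

#' Predict from a fitted PC-tree model
#'
#' Raw binary features are projected through the stored PC loadings and
#' routed through the selected tree. Columns are aligned by feature key:
#' unseen columns are ignored and missing ones treated as absent (0).
#'
#' @param object a `pctree`.
#' @param newdata binary feature matrix (`feature_matrix` or plain matrix).
#' @param ... unused.
#' @return data.frame (label, leaf, score) per row of `newdata`.
#' @export
predict.pctree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!nrow(newdata)) {
    return(data.frame(label = character(0), leaf = character(0),
                      score = numeric(0)))
  }
  sc <- project_scores(object$pc_model, newdata)
  predict_tree(object$tree, sc)
}

#' Plot the selected decision tree
#'
#' Base-graphics sketch of the tree: internal nodes show the component and
#' threshold, leaves their id, label and training case fraction.
#'
#' @param x a `pctree` or `pc_tree`.
#' @param ... unused.
#' @export
plot.pctree <- function(x, ...) plot(x$tree, ...)

#' @export
plot.pc_tree <- function(x, ...) {
  depth_of <- function(node) {
    if (node$type == "leaf") 0L else 1L + max(depth_of(node$left), depth_of(node$right))
  }
  d <- depth_of(x$root)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(-0.05, 1.05))
  draw <- function(node, xlo, xhi, y) {
    xm <- (xlo + xhi) / 2
    if (node$type == "leaf") {
      graphics::rect(xm - 0.06, y - 0.04, xm + 0.06, y + 0.04,
                     col = if (node$label == "AS") "#d95f5f" else "#7fa8d9")
      graphics::text(xm, y, sprintf("%s\n%s\n%.2f", node$id, node$label,
                                    node$case_frac), cex = 0.7)
    } else {
      cn <- (x$component_names %||% LETTERS)[node$comp]
      ynext <- y - 1 / max(d, 1)
      xl <- (xlo + xm) / 2; xr <- (xm + xhi) / 2
      graphics::segments(xm, y - 0.04, c(xl, xr), ynext + 0.04)
      graphics::text(xm, y, sprintf("%s <= %.3g", cn, node$threshold), cex = 0.8)
      draw(node$left, xlo, xm, ynext)
      draw(node$right, xm, xhi, ynext)
    }
  }
  draw(x$root, 0, 1, 1)
  graphics::title("Decision tree on principal-component scores")
  invisible(x)
}
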