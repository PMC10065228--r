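# Three-stage feature reduction: chi-squared stability screening against the
# 100 matched control sets, multivariable logistic-regression filtering, and
# principal component analysis of the surviving binary features.

#' Feature-selection configuration
#'
#' @param alpha per-test chi-squared significance level (default 0.01).
#' @param stability_fraction fraction of the `n_cohorts` tests a feature must
#'   pass: 0.90 for the male stratum; 0.75 was used for the smaller (hence
#'   lower-powered) female stratum. A property of the data, not of sex, so a
#'   plain config value.
#' @param n_cohorts number of matched control sets tested against (100).
#' @param lr_alpha Wald significance level to remain in the logistic model.
#' @param pca_var retained components are the smallest set explaining at
#'   least this share of variance (default 0.8).
#' @param lr_mode `"multivariable"` (one joint model, the default reading of
#'   "to remain in the logistic regression model") or `"univariable"`
#'   (per-feature fits).
#' @param seed integer seed.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(alpha = 0.01, stability_fraction = 0.90,
                             n_cohorts = 100, lr_alpha = 0.01,
                             pca_var = 0.8,
                             lr_mode = c("multivariable", "univariable"),
                             seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (stability_fraction <= 0 || stability_fraction > 1) {
    stop("`stability_fraction` must be in (0, 1]", call. = FALSE)
  }
  structure(list(alpha = alpha, stability_fraction = stability_fraction,
                 n_cohorts = as.integer(n_cohorts), lr_alpha = lr_alpha,
                 pca_var = pca_var, lr_mode = match.arg(lr_mode),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Uncorrected Pearson statistic with 1 degree of freedom, vectorised over
#' tables. A zero margin makes the table degenerate: the statistic is 0, the
#' p-value 1 and the `degenerate` flag set. Tables with a minimum expected
#' count below 5 are flagged (`low_expected`) but still tested.
#'
#' @param a,b,c,d cell counts: `a` cases with the flag, `b` cases without,
#'   `c` controls with, `d` controls without.
#' @return data.frame (statistic, p_value, degenerate, low_expected).
#' @export
chi2_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0", call. = FALSE)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  degen <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  stat <- ifelse(degen, 0, n * (a * d - b * c)^2 /
                   ifelse(degen, 1, r1 * r2 * c1 * c2))
  p <- ifelse(degen, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  min_exp <- ifelse(degen, 0, pmin(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n)
  data.frame(statistic = stat, p_value = p, degenerate = degen,
             low_expected = !degen & min_exp < 5)
}

#' Chi-squared stability screen over matched control sets
#'
#' Every feature is cross-tabulated against each of the `n_cohorts` control
#' sets (cases with/without the flag vs that set's controls with/without)
#' and a feature passes if it reaches `p < alpha` in at least
#' `stability_fraction * n_cohorts` of the tests. The direction of
#' association is kept: features more frequent in controls than cases carry
#' direction -1 rather than being discarded.
#'
#' @param case_matrix binary matrix, cases x features.
#' @param control_matrices list of `n_cohorts` binary matrices sharing the
#'   feature columns (one per control set).
#' @param cfg a [selection_config()].
#' @return data.frame of class `stability_result`: feature_key, n_pass,
#'   direction, pass.
#' @export
stability_screen <- function(case_matrix, control_matrices,
                             cfg = selection_config()) {
  if (length(control_matrices) != cfg$n_cohorts) {
    stop(sprintf("expected %d control matrices, got %d", cfg$n_cohorts,
                 length(control_matrices)), call. = FALSE)
  }
  feats <- colnames(case_matrix)
  for (m in control_matrices) {
    if (!identical(colnames(m), feats)) {
      stop("control matrices must share the case matrix's feature index",
           call. = FALSE)
    }
  }
  n_case <- nrow(case_matrix)
  a <- colSums(case_matrix)
  b <- n_case - a
  n_pass <- integer(length(feats))
  ctrl_prop <- numeric(length(feats))
  for (m in control_matrices) {
    cc <- colSums(m)
    res <- chi2_2x2(a, b, cc, nrow(m) - cc)
    n_pass <- n_pass + (res$p_value < cfg$alpha)
    ctrl_prop <- ctrl_prop + cc / nrow(m)
  }
  ctrl_prop <- ctrl_prop / length(control_matrices)
  out <- data.frame(
    feature_key = feats,
    n_pass = n_pass,
    direction = ifelse(a / n_case >= ctrl_prop, 1L, -1L),
    pass = n_pass >= cfg$stability_fraction * cfg$n_cohorts,
    stringsAsFactors = FALSE
  )
  class(out) <- c("stability_result", "data.frame")
  attr(out, "config") <- cfg
  out
}

# Ridge-penalised logistic fit by IRLS; covariance approximated by the
# penalised information inverse. Used only when the unpenalised fit fails to
# converge or separates.
ridge_logistic <- function(x, y, lambda = 1e-2, maxit = 100, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(x))), ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-10)
  V <- solve(crossprod(X * w, X) + pen)
  list(coef = beta[-1], se = sqrt(diag(V))[-1])
}

#' Logistic-regression filter
#'
#' Fits a logistic model of case status on the stability-selected features
#' and retains those with Wald `p < lr_alpha`. Perfectly collinear
#' (duplicated or constant) columns are deduplicated first. Non-convergence
#' triggers a ridge-stabilised refit with a warning; features showing
#' complete separation are flagged and retained rather than silently
#' dropped.
#'
#' @param x binary matrix (participants x selected features).
#' @param y outcome: logical, 0/1, or labels `"AS"`/`"NON_AS"`.
#' @param cfg a [selection_config()].
#' @return data.frame of class `lr_result`: feature_key, estimate, p_value,
#'   retained, flag (`""`, `"duplicate"`, `"constant"`, `"separation"`).
#' @export
lr_filter <- function(x, y, cfg = selection_config()) {
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "AS"
  y <- as.numeric(y)
  feats <- colnames(x)
  flag <- setNames(rep("", length(feats)), feats)
  keep <- rep(TRUE, length(feats))

  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  flag[const] <- "constant"; keep[const] <- FALSE
  dup <- duplicated(t(x)) & !const
  flag[dup & keep] <- "duplicate"; keep[dup] <- FALSE

  est <- p <- setNames(rep(NA_real_, length(feats)), feats)
  xk <- x[, keep, drop = FALSE]
  if (ncol(xk)) {
    fit_one <- function(xx) {
      df <- data.frame(y = y, xx)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      sm <- summary(fit)$coefficients
      co <- stats::coef(fit)[-1]
      # aliased coefficients are absent from the summary table; align by name
      se <- sm[match(names(co), rownames(sm)), 2]
      pw <- sm[match(names(co), rownames(sm)), 4]
      bad <- !fit$converged | any(abs(co) > 15, na.rm = TRUE) |
        any(se > 100, na.rm = TRUE) | any(is.na(co))
      if (bad) {
        warning("logistic fit unstable (separation or non-convergence); ",
                "using ridge-stabilised refit", call. = FALSE)
        rg <- ridge_logistic(as.matrix(xx), y)
        co2 <- rg$coef; se2 <- rg$se
        sep <- is.na(co) | abs(co) > 15 | se > 100
        list(est = co2, p = 2 * stats::pnorm(-abs(co2 / se2)), sep = sep)
      } else {
        list(est = co, p = pw, sep = rep(FALSE, length(co)))
      }
    }
    if (cfg$lr_mode == "multivariable") {
      r <- fit_one(xk)
      est[keep] <- r$est; p[keep] <- r$p
      flag[keep][r$sep] <- "separation"
    } else {
      for (j in seq_len(ncol(xk))) {
        r <- fit_one(xk[, j, drop = FALSE])
        fk <- colnames(xk)[j]
        est[fk] <- r$est; p[fk] <- r$p
        if (r$sep[1]) flag[fk] <- "separation"
      }
    }
  }
  out <- data.frame(
    feature_key = feats,
    estimate = est,
    p_value = p,
    retained = (flag == "" & !is.na(p) & p < cfg$lr_alpha) | flag == "separation",
    flag = flag,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("lr_result", "data.frame")
  out
}

#' Principal component analysis of the retained binary features
#'
#' Mean-centred, unscaled PCA (the features are all on the same 0/1 scale,
#' so variance scaling would inflate rare codes). Retains the smallest
#' number of leading components explaining at least `var_target` of the
#' variance; retained components are named A, B, C, ... as in the fitted
#' decision trees.
#'
#' @param x binary matrix (participants x features).
#' @param var_target explained-variance share to retain (default 0.8).
#' @return list of class `pc_model`: center, rotation (all components,
#'   orthonormal), sdev, var_share, k (retained count), features.
#' @export
fit_pca <- function(x, var_target = 0.8) {
  if (ncol(x) < 2) stop("PCA needs at least 2 features", call. = FALSE)
  if (nrow(x) < 3) stop("PCA needs at least 3 rows", call. = FALSE)
  v <- apply(x, 2, stats::var)
  if (all(v == 0)) stop("constant matrix: no variance to decompose", call. = FALSE)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  share <- pr$sdev^2 / sum(pr$sdev^2)
  k <- which(cumsum(share) >= var_target)[1]
  if (is.na(k)) k <- length(share)
  structure(list(center = pr$center, rotation = pr$rotation, sdev = pr$sdev,
                 var_share = share, k = as.integer(k),
                 features = colnames(x)),
            class = "pc_model")
}

#' Project a binary feature matrix onto retained principal components
#'
#' Columns are aligned to the model's feature dictionary: missing features
#' are treated as 0 (absent code), unknown columns are ignored.
#'
#' @param pcm a `pc_model`.
#' @param x binary matrix.
#' @param components which components to return (default the retained `k`).
#' @return numeric score matrix with components named A, B, C, ...
#' @export
project_scores <- function(pcm, x, components = seq_len(pcm$k)) {
  aligned <- matrix(0, nrow(x), length(pcm$features),
                    dimnames = list(rownames(x), pcm$features))
  common <- intersect(colnames(x), pcm$features)
  aligned[, common] <- as.matrix(x[, common, drop = FALSE])
  sc <- sweep(aligned, 2, pcm$center) %*% pcm$rotation[, components, drop = FALSE]
  colnames(sc) <- make.unique(LETTERS[(components - 1L) %% 26L + 1L])
  sc
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("Principal component model: %d features, %d retained components\n",
              length(x$features), x$k))
  cat("  explained variance:",
      paste(sprintf("%s=%.1f%%", LETTERS[seq_len(min(x$k, 26))],
                    100 * x$var_share[seq_len(x$k)]), collapse = ", "), "\n")
  invisible(x)
}

#' Write the selection report
#'
#' Combines the stability and logistic-regression stages into one CSV
#' (feature_key, n_pass, direction, lr_p, retained).
#'
#' @param stability a `stability_result`.
#' @param lr an `lr_result` (may cover a subset of features).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(stability, lr, path) {
  rep <- merge(as.data.frame(stability),
               as.data.frame(lr)[, c("feature_key", "p_value", "retained", "flag")],
               by = "feature_key", all.x = TRUE)
  names(rep)[names(rep) == "p_value"] <- "lr_p"
  rep$retained[is.na(rep$retained)] <- FALSE
  utils::write.csv(rep, path, row.names = FALSE)
  invisible(path)
}
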