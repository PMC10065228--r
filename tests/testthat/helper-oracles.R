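# Independent oracles used by the test suite. Each deliberately avoids the
# package's own code path for the quantity it checks.

# Newton-Raphson logistic regression with Wald p-values (no glm).
oracle_logistic <- function(x, y, maxit = 200, tol = 1e-12) {
  X <- cbind(1, as.matrix(x))
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    mu <- 1 / (1 + exp(-drop(X %*% beta)))
    w <- mu * (1 - mu)
    H <- crossprod(X * w, X)
    step <- solve(H, crossprod(X, y - mu))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- 1 / (1 + exp(-drop(X %*% beta)))
  V <- solve(crossprod(X * (mu * (1 - mu)), X))
  se <- sqrt(diag(V))
  z <- beta / se
  list(coef = beta[-1], se = se[-1], p = (2 * pnorm(-abs(z)))[-1])
}

# Exhaustive-search Gini split: every midpoint of every component.
oracle_split <- function(scores, y, min_leaf) {
  g <- function(nas, n) if (n == 0) 0 else { p <- nas / n; 1 - p^2 - (1 - p)^2 }
  n <- length(y)
  best <- NULL
  for (j in seq_len(ncol(scores))) {
    v <- sort(unique(scores[, j]))
    if (length(v) < 2) next
    for (thr in (head(v, -1) + tail(v, -1)) / 2) {
      l <- scores[, j] <= thr
      if (sum(l) < min_leaf || sum(!l) < min_leaf) next
      imp <- g(sum(y & l), sum(l)) * sum(l) + g(sum(y & !l), sum(!l)) * sum(!l)
      if (is.null(best) || imp < best$imp - 1e-12) {
        best <- list(comp = j, threshold = thr, imp = imp)
      }
    }
  }
  best
}

# AUC as the Mann-Whitney U statistic with rank-averaged ties.
oracle_auc <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Manual single-row trace through a pc_tree.
oracle_traverse <- function(tree, row) {
  node <- tree$root
  while (node$type != "leaf") {
    node <- if (row[node$comp] <= node$threshold) node$left else node$right
  }
  c(label = node$label, leaf = node$id)
}

# Brute-force per-patient per-key scan that recomputes a feature matrix from
# first principles (age-band scheme).
oracle_features_age_band <- function(events, part, patients, age_bands,
                                     levels, aggmap) {
  keys <- list(); cells <- list()
  band_lab <- paste0("age", head(age_bands, -1), "_", tail(age_bands, -1))
  for (r in seq_len(nrow(part))) {
    pid <- part$patient_id[r]; idx <- part$index_date[r]
    wob <- patients$week_of_birth[patients$patient_id == pid]
    pe <- events[events$patient_id == pid & events$event_date < idx, ]
    for (i in seq_len(nrow(pe))) {
      age <- as.numeric(pe$event_date[i] - (wob + 3.5)) / 365.25
      b <- findInterval(age, age_bands)
      if (b < 1 || b >= length(age_bands)) next
      for (L in levels) {
        eff <- min(L, nchar(pe$code[i]))
        key <- paste(substr(pe$code[i], 1, eff), paste0("L", eff),
                     pe$source[i], band_lab[b], sep = "|")
        cells[[length(cells) + 1L]] <- c(paste0(pid, "@", idx), key)
      }
      for (g in names(aggmap)) {
        if (any(startsWith(pe$code[i], aggmap[[g]]))) {
          key <- paste(g, "AGG", pe$source[i], band_lab[b], sep = "|")
          cells[[length(cells) + 1L]] <- c(paste0(pid, "@", idx), key)
        }
      }
    }
  }
  if (!length(cells)) return(NULL)
  unique(do.call(rbind, cells))
}

# A small single-sex population used by several files.
small_pop <- function(n_cases = 20, ratio = 10, seed = 42, ...) {
  generate_population(
    synth_config(n_cases = n_cases, controls_per_case = ratio,
                 population_size = n_cases * 40, seed = seed, ...),
    list(male_signatures())
  )
}
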