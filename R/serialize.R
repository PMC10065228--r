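# Human-readable model serialization: feature dictionary, PC centering and
# loadings, and the tree node list, in one plain-text file.

flatten_tree <- function(node, acc = list()) {
  i <- length(acc) + 1L
  acc[[i]] <- ""  # reserve the slot; filled once children are numbered
  if (node$type == "leaf") {
    acc[[i]] <- sprintf("node %d leaf %s %s %.17g %d %d", i, node$id,
                        node$label, node$case_frac, node$n, node$n_as)
  } else {
    left_i <- length(acc) + 1L
    acc <- flatten_tree(node$left, acc)
    right_i <- length(acc) + 1L
    acc <- flatten_tree(node$right, acc)
    acc[[i]] <- sprintf("node %d split %d %.17g %d %d", i, node$comp,
                        node$threshold, left_i, right_i)
  }
  acc
}

#' Write a fitted PC-tree model as structured text
#'
#' Serialises everything [predict.pctree()] needs: retained feature keys,
#' PC centering vector and retained loading columns, explained-variance
#' shares, and the tree as a numbered node list.
#'
#' @param model a `pctree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pctree <- function(model, path) {
  pcm <- model$pc_model
  k <- pcm$k
  rot <- pcm$rotation[, seq_len(k), drop = FALSE]
  lines <- c(
    "aspredict pctree v1",
    paste("leaf_prefix", model$tree$leaf_prefix),
    paste("components", k),
    paste("features", length(pcm$features)),
    pcm$features,
    "center",
    paste(sprintf("%.17g", pcm$center), collapse = " "),
    "var_share",
    paste(sprintf("%.17g", pcm$var_share[seq_len(k)]), collapse = " "),
    "loadings",
    apply(rot, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
    "tree",
    unlist(flatten_tree(model$tree$root))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a model written by [write_pctree()]
#'
#' @param path file path.
#' @return a `pctree` holding the prediction components (selection-stage
#'   diagnostics are not serialised).
#' @export
read_pctree <- function(path) {
  x <- readLines(path)
  if (x[1] != "aspredict pctree v1") stop("not an aspredict model file", call. = FALSE)
  leaf_prefix <- strsplit(x[2], " ")[[1]][2]
  k <- as.integer(strsplit(x[3], " ")[[1]][2])
  nf <- as.integer(strsplit(x[4], " ")[[1]][2])
  feats <- x[5:(4 + nf)]
  i <- 4 + nf
  stopifnot(x[i + 1] == "center")
  center <- as.numeric(strsplit(x[i + 2], " ")[[1]])
  stopifnot(x[i + 3] == "var_share")
  var_share <- as.numeric(strsplit(x[i + 4], " ")[[1]])
  stopifnot(x[i + 5] == "loadings")
  rot <- t(vapply(x[(i + 6):(i + 5 + nf)],
                  function(l) as.numeric(strsplit(l, " ")[[1]]), numeric(k)))
  dimnames(rot) <- list(feats, paste0("PC", seq_len(k)))
  stopifnot(x[i + 6 + nf] == "tree")
  node_lines <- x[(i + 7 + nf):length(x)]
  toks <- strsplit(node_lines, " ")
  build <- function(i) {
    t <- toks[[i]]
    if (t[3] == "leaf") {
      list(type = "leaf", id = t[4], label = t[5],
           case_frac = as.numeric(t[6]), n = as.integer(t[7]),
           n_as = as.integer(t[8]))
    } else {
      list(type = "split", comp = as.integer(t[4]),
           threshold = as.numeric(t[5]),
           left = build(as.integer(t[6])), right = build(as.integer(t[7])))
    }
  }
  pcm <- structure(list(center = stats::setNames(center, feats), rotation = rot,
                        sdev = sqrt(var_share), var_share = var_share,
                        k = k, features = feats),
                   class = "pc_model")
  tree <- structure(list(root = build(1L), n_components = k,
                         component_names = LETTERS[seq_len(k)],
                         config = NULL, leaf_prefix = leaf_prefix),
                    class = "pc_tree")
  structure(list(pc_model = pcm, tree = tree, features = feats),
            class = "pctree")
}
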