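# Feature construction: binary, time-sliced, multi-level code presence
# flags. Frequency is deliberately collapsed to presence so that heavily
# repeated codes (prescriptions, procedures) do not outweigh one-off
# diagnosis codes.

#' Truncate a code to a hierarchy level
#'
#' Hierarchical clinical codes encode specificity by length; the first
#' `level` characters give the concept at that level. Levels at or beyond
#' the code length return the full code.
#'
#' @param code character vector of codes.
#' @param level prefix length (>= 1).
#' @return character vector of prefixes.
#' @export
truncate_code <- function(code, level) {
  if (any(level < 1)) stop("`level` must be >= 1", call. = FALSE)
  substr(code, 1L, level)
}

#' Default concept aggregation map
#'
#' Groups of code prefixes collapsed into single concept flags, e.g. all
#' specific pain codes into one "pain present" flag. A code may belong to
#' several groups.
#'
#' @return named list: group name -> character vector of code prefixes.
#' @export
default_aggmap <- function() {
  list(
    pain = c("N142", "N143", "16C", "N06"),
    nsaid = "j61",
    analgesic = c("j81", "j61"),
    blood_test = "44F"
  )
}

window_labels <- function(scheme, age_bands, n_year_slices) {
  if (scheme == "age_band") {
    paste0("age", age_bands[-length(age_bands)], "_", age_bands[-1])
  } else {
    paste0("year_", seq_len(n_year_slices))
  }
}

#' Build the binary feature matrix
#'
#' One row per (patient, index date) participant slot, one column per
#' (concept, level, source, window) with at least one supporting event in at
#' least `min_count` participants. Events on or after the index date are
#' excluded. Two window schemes are supported: 5-year age bands anchored at
#' the week-of-birth midpoint (half-open, `[lo, hi)`), or per-year slices
#' counting back from the index date (`year_1` = the year immediately
#' preceding it).
#'
#' @param events event table.
#' @param cohort data.frame with at least `patient_id` and `index_date`
#'   (e.g. a `matched_cohort` or a subset of one). Duplicate
#'   (patient, index) combinations are collapsed.
#' @param patients patient table (for week of birth).
#' @param scheme `"age_band"` or `"pre_index_year"`.
#' @param age_bands band boundaries in years (default 15,20,25,30,35).
#' @param n_year_slices number of pre-index one-year slices (default 3).
#' @param levels code-truncation levels to expand (default 1:5; levels beyond
#'   a code's length collapse to the full code and are deduplicated).
#' @param aggmap aggregation map as from [default_aggmap()], or `NULL`.
#' @param min_count columns present in fewer participants are dropped
#'   (default 5; avoids degenerate chi-squared tables).
#' @return integer matrix of class `feature_matrix` with 0/1 cells, row names
#'   `"<patient_id>@<index_date>"`, and attributes `dictionary` (feature_key,
#'   concept, level, source, window) and `participants`.
#' @export
build_features <- function(events, cohort, patients,
                           scheme = c("age_band", "pre_index_year"),
                           age_bands = c(15, 20, 25, 30, 35),
                           n_year_slices = 3,
                           levels = 1:5,
                           aggmap = default_aggmap(),
                           min_count = 5) {
  scheme <- match.arg(scheme)
  part <- unique(as.data.frame(cohort)[, c("patient_id", "index_date")])
  if (any(is.na(part$index_date))) {
    stop("every participant needs an index date", call. = FALSE)
  }
  part$row_key <- paste0(part$patient_id, "@", part$index_date)
  part <- part[order(part$row_key), ]
  n_rows <- nrow(part)

  empty <- function() {
    m <- matrix(0L, n_rows, 0, dimnames = list(part$row_key, character(0)))
    attr(m, "dictionary") <- data.frame(feature_key = character(0),
                                        concept = character(0),
                                        level = character(0),
                                        source = character(0),
                                        window = character(0))
    attr(m, "participants") <- part
    class(m) <- c("feature_matrix", class(m))
    m
  }
  if (!nrow(events)) return(empty())

  ev <- events[events$patient_id %in% part$patient_id, ]
  ev <- merge(ev, part, by = "patient_id")
  ev <- ev[ev$event_date < ev$index_date, ]          # pre-index only
  if (!nrow(ev)) return(empty())

  if (scheme == "age_band") {
    wob <- patients$week_of_birth[match(ev$patient_id, patients$patient_id)]
    age <- age_at(ev$event_date, wob)
    band <- findInterval(age, age_bands)
    keep <- band >= 1 & band < length(age_bands)
    ev <- ev[keep, ]
    ev$window <- window_labels(scheme, age_bands, n_year_slices)[band[keep]]
  } else {
    back <- as.numeric(ev$index_date - ev$event_date)
    slice <- ceiling(back / DAYS_PER_YEAR)
    keep <- slice >= 1 & slice <= n_year_slices
    ev <- ev[keep, ]
    ev$window <- paste0("year_", slice[keep])
  }
  if (!nrow(ev)) return(empty())

  pieces <- list()
  nc <- nchar(ev$code)
  for (L in sort(unique(levels))) {
    eff <- pmin(L, nc)  # saturated levels relabel to the code's own length
    pieces[[length(pieces) + 1L]] <- data.frame(
      row_key = ev$row_key,
      concept = truncate_code(ev$code, eff),
      level = paste0("L", eff),
      source = ev$source,
      window = ev$window,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(aggmap) && length(aggmap)) {
    for (g in names(aggmap)) {
      hit <- code_matches(ev$code, aggmap[[g]])
      if (!any(hit)) next
      sub <- ev[hit, ]
      pieces[[length(pieces) + 1L]] <- data.frame(
        row_key = sub$row_key, concept = g, level = "AGG",
        source = sub$source, window = sub$window, stringsAsFactors = FALSE
      )
    }
  }
  trip <- unique(do.call(rbind, pieces))
  trip$feature_key <- paste(trip$concept, trip$level, trip$source, trip$window,
                            sep = "|")
  dict <- unique(trip[, c("feature_key", "concept", "level", "source", "window")])
  dict <- dict[order(dict$feature_key), ]
  ri <- match(trip$row_key, part$row_key)
  ci <- match(trip$feature_key, dict$feature_key)
  m <- matrix(0L, n_rows, nrow(dict),
              dimnames = list(part$row_key, dict$feature_key))
  m[cbind(ri, ci)] <- 1L

  keep_col <- colSums(m) >= min_count
  m <- m[, keep_col, drop = FALSE]
  dict <- dict[keep_col, ]
  rownames(dict) <- NULL
  attr(m, "dictionary") <- dict
  attr(m, "participants") <- part
  class(m) <- c("feature_matrix", class(m))
  m
}

#' Feature dictionary of a feature matrix
#' @param fm a `feature_matrix`.
#' @return data.frame (feature_key, concept, level, source, window).
#' @export
feature_dictionary <- function(fm) attr(fm, "dictionary")

#' Extract participant rows from a feature matrix
#'
#' Rows are keyed by `"<patient_id>@<index_date>"`; this returns the rows for
#' a cohort subset (e.g. one control set), in the subset's order.
#'
#' @param fm a `feature_matrix`.
#' @param cohort data.frame with `patient_id` and `index_date`.
#' @return plain integer matrix of the requested rows.
#' @export
feature_rows <- function(fm, cohort) {
  keys <- paste0(cohort$patient_id, "@", cohort$index_date)
  miss <- setdiff(keys, rownames(fm))
  if (length(miss)) {
    stop("participants missing from feature matrix: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  out <- fm[keys, , drop = FALSE]
  attr(out, "dictionary") <- NULL
  attr(out, "participants") <- NULL
  class(out) <- "matrix"
  out <- unclass(out)
  dimnames(out) <- list(keys, colnames(fm))
  out
}

#' Write / read a feature matrix as sparse triplets
#'
#' `features.csv` holds (row_key, feature_key, 1) triplets,
#' `feature_dictionary.csv` the column metadata and `participants.csv` the
#' row metadata; [read_features()] round-trips them.
#'
#' @param fm a `feature_matrix`.
#' @param dir output directory.
#' @return `dir` (write) or the reconstructed `feature_matrix` (read).
#' @export
write_features <- function(fm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(fm == 1L, arr.ind = TRUE)
  trip <- data.frame(row_key = rownames(fm)[idx[, 1]],
                     feature_key = colnames(fm)[idx[, 2]],
                     value = 1L)
  utils::write.csv(trip, file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(feature_dictionary(fm),
                   file.path(dir, "feature_dictionary.csv"), row.names = FALSE)
  utils::write.csv(attr(fm, "participants"),
                   file.path(dir, "participants.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_features
#' @export
read_features <- function(dir) {
  trip <- utils::read.csv(file.path(dir, "features.csv"), stringsAsFactors = FALSE)
  dict <- utils::read.csv(file.path(dir, "feature_dictionary.csv"),
                          stringsAsFactors = FALSE, colClasses = "character")
  part <- utils::read.csv(file.path(dir, "participants.csv"),
                          stringsAsFactors = FALSE)
  part$index_date <- as.Date(part$index_date)
  m <- matrix(0L, nrow(part), nrow(dict),
              dimnames = list(part$row_key, dict$feature_key))
  if (nrow(trip)) {
    m[cbind(match(trip$row_key, part$row_key),
            match(trip$feature_key, dict$feature_key))] <- 1L
  }
  attr(m, "dictionary") <- dict
  attr(m, "participants") <- part
  class(m) <- c("feature_matrix", class(m))
  m
}
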