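# Cohort assembly: concatenated replicate movies, line x feature matrices,
# and hierarchical clustering of experimental lines.

#' Concatenate replicate movies into a cohort table
#'
#' Unions per-movie kinematics tables, namespacing track ids by movie id so
#' that `(movie_id, track_id)` is unique, and attaching line/treatment
#' metadata to every row.
#'
#' @param tables named list of kinematics tables (one per movie; names are
#'   movie ids) as produced by [compute_kinematics()] /
#'   [add_coordination()].
#' @param metadata data frame with `movie_id`, `line` and optionally
#'   `treatment`; one row per movie.
#' @return a `cohort_table` data frame (rows carry `movie_id`, `line`,
#'   `treatment`, namespaced `track_id`, `frame` and all kinematics
#'   columns), with a `counts` attribute of per-movie row counts.
#' @export
concatenate_cohort <- function(tables, metadata) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("tables must be a named list (names = movie ids)")
  }
  if (anyDuplicated(names(tables))) stop("duplicate movie id")
  if (anyDuplicated(metadata$movie_id)) stop("duplicate movie id in metadata")
  miss <- setdiff(names(tables), metadata$movie_id)
  if (length(miss) > 0) stop("metadata missing movie ids: ",
                             paste(miss, collapse = ", "))
  need <- c("track_id", "frame", "t_h")
  ref_cols <- names(tables[[1]])
  rows <- lapply(names(tables), function(mid) {
    tb <- tables[[mid]]
    missing_cols <- setdiff(need, names(tb))
    if (length(missing_cols) > 0) {
      stop("movie ", mid, " is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    mismatch <- setdiff(ref_cols, names(tb))
    if (length(mismatch) > 0) {
      stop("schema mismatch in movie ", mid, ": missing column(s) ",
           paste(mismatch, collapse = ", "))
    }
    md <- metadata[metadata$movie_id == mid, ]
    data.frame(movie_id = mid, line = md$line,
               treatment = md$treatment %||% NA_character_,
               track_id = paste(mid, tb$track_id, sep = ":"),
               tb[, setdiff(ref_cols, "track_id"), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- vapply(rows, nrow, 1L)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Line x feature aggregate matrix
#'
#' Per line, the mean of each morphokinetic parameter over all cell-frame
#' samples in the time window (sample-weighted pooling of replicate movies),
#' plus a z-scored copy (mean 0, sd 1 per column over lines). A parameter is
#' dropped for all lines when any line has fewer than `min_samples` finite
#' samples for it.
#'
#' @param cohort a `cohort_table`.
#' @param parameters character vector of parameter columns.
#' @param window numeric length-2 time window in hours (inclusive), or
#'   `NULL` for all times.
#' @param min_samples minimum finite samples per line per parameter.
#' @return list of class `line_feature_matrix` with `values` (lines x
#'   parameters), `z` (z-scored; zero-variance columns dropped with a
#'   warning), `n` (sample counts) and `dropped` parameter names.
#' @export
line_feature_matrix <- function(cohort, parameters, window = NULL,
                                min_samples = 10L) {
  bad <- setdiff(parameters, names(cohort))
  if (length(bad) > 0) stop("unknown parameter(s): ",
                            paste(bad, collapse = ", "))
  d <- cohort
  if (!is.null(window)) {
    d <- d[d$t_h >= window[1] & d$t_h <= window[2], ]
    if (nrow(d) == 0) stop("empty time window")
  }
  lines <- sort(unique(as.character(d$line)))
  vals <- matrix(NA_real_, length(lines), length(parameters),
                 dimnames = list(lines, parameters))
  ns <- vals
  for (i in seq_along(lines)) {
    di <- d[d$line == lines[i], ]
    for (j in seq_along(parameters)) {
      x <- di[[parameters[j]]]
      x <- x[is.finite(x)]
      ns[i, j] <- length(x)
      if (length(x) > 0) vals[i, j] <- mean(x)
    }
  }
  dropped <- parameters[apply(ns, 2, min) < min_samples]
  keep <- setdiff(parameters, dropped)
  vals <- vals[, keep, drop = FALSE]
  ns <- ns[, keep, drop = FALSE]
  z <- zscore_columns(vals)
  structure(list(values = vals, z = z$z, n = ns,
                 dropped = c(dropped, z$dropped)),
            class = "line_feature_matrix")
}

# z-score columns over rows; drop zero-variance columns with a warning
zscore_columns <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  zero <- sdv < 1e-12 | !is.finite(sdv)
  if (any(zero)) {
    warning("dropping zero-variance column(s) before z-scoring: ",
            paste(colnames(m)[zero], collapse = ", "))
  }
  keep <- which(!zero)
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  list(z = z, dropped = colnames(m)[zero])
}

#' @export
print.line_feature_matrix <- function(x, ...) {
  cat(sprintf("<line_feature_matrix> %d lines x %d parameters\n",
              nrow(x$values), ncol(x$values)))
  print(round(x$values, 3))
  invisible(x)
}

#' Hierarchical clustering of lines by morphokinetic profile
#'
#' Agglomerative clustering of the z-scored line x feature matrix
#' (Euclidean distance, average linkage by default), with a deterministic
#' leaf order (ties broken by line label) and cophenetic distances.
#'
#' @param lfm a [line_feature_matrix()] (or a plain numeric matrix, taken as
#'   already z-scored).
#' @param distance distance measure for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @return list of class `line_clustering` with `hclust`, `leaf_order`
#'   (labels), `cophenetic` (dist), `distance`, `linkage`.
#' @export
cluster_lines <- function(lfm, distance = "euclidean", linkage = "average") {
  z <- if (inherits(lfm, "line_feature_matrix")) lfm$z else lfm
  if (nrow(z) < 2) stop("need at least 2 lines to cluster")
  z <- z[order(rownames(z)), , drop = FALSE]  # label order => determinism
  hc <- hclust(dist(z, method = distance), method = linkage)
  structure(list(hclust = hc, leaf_order = hc$labels[hc$order],
                 cophenetic = cophenetic(hc),
                 distance = distance, linkage = linkage),
            class = "line_clustering")
}

#' @export
print.line_clustering <- function(x, ...) {
  cat("<line_clustering> leaf order:",
      paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' Cut a line clustering into k groups
#'
#' @param clustering a `line_clustering`.
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cut_lines <- function(clustering, k = 2L) {
  cutree(clustering$hclust, k = k)
}

#' Rand index between two partitions
#'
#' @param a,b partition label vectors of equal length.
#' @return the (unadjusted) Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  pairs <- utils::combn(n, 2)
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(sa == sb)
}

#' Export a line clustering as a Newick tree
#'
#' @param clustering a `line_clustering`.
#' @param path output file path.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Clustergram heat map of a line feature matrix
#'
#' Draws the z-scored matrix with row/column dendrograms (requires the
#' pheatmap package).
#'
#' @param lfm a [line_feature_matrix()].
#' @param filename optional PNG path.
#' @param ... passed to [pheatmap::pheatmap()].
#' @export
plot_clustergram <- function(lfm, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_clustergram requires the pheatmap package")
  }
  pheatmap::pheatmap(lfm$z, clustering_method = "average",
                     filename = filename, ...)
}
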