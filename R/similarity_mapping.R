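# Portrait similarity: Pearson correlations between individuals'
# portrait vectors, a minimum spanning tree on 1 - r, and zoom-in
# retraining on sample subsets.

#' Pearson correlation matrix between portraits
#'
#' Correlations are computed between the flattened grid vectors
#' (meta-SNP level, length K), not raw SNP vectors.
#'
#' @param portraits list of [portrait]s (>= 2, common shape).
#' @return An M x M `similarity_matrix` (symmetric, unit diagonal) with
#'   subjects as dimnames. A constant (zero-variance) portrait is an
#'   error naming the individual.
#' @export
correlation_matrix <- function(portraits) {
  stopifnot(length(portraits) >= 2)
  dims <- vapply(portraits, function(p) dim(p$grid), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("portraits have mismatching grid shapes")
  vecs <- vapply(portraits, function(p) as.vector(p$grid),
                 numeric(length(portraits[[1]]$grid)))
  subjects <- vapply(portraits, `[[`, "", "subject")
  sds <- apply(vecs, 2, stats::sd)
  if (any(sds == 0))
    stop("constant portrait (zero variance) for: ",
         paste(subjects[sds == 0], collapse = ", "))
  r <- stats::cor(vecs)
  dimnames(r) <- list(subjects, subjects)
  structure(r, class = c("similarity_matrix", "matrix"))
}

#' Minimum spanning tree of individuals
#'
#' Kruskal's algorithm on edge weights `1 - r`; among equal-weight edges
#' the lexicographically first node pair wins, making the tree
#' deterministic.
#'
#' @param sim a `similarity_matrix` (or any symmetric correlation
#'   matrix with dimnames).
#' @return An object of class `mst_tree`: `nodes` (character vector),
#'   `edges` (data.frame from, to, weight) with exactly M - 1 rows, and
#'   `total_weight`.
#' @export
build_mst <- function(sim) {
  r <- unclass(as.matrix(sim))
  m <- nrow(r)
  stopifnot(m >= 2, ncol(r) == m)
  ids <- rownames(r)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  w <- 1 - r
  if (!all(is.finite(w[upper.tri(w)])))
    stop("non-finite edge weight in the similarity matrix")
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  ed <- data.frame(i = pairs[, 1], j = pairs[, 2],
                   weight = w[pairs])
  ed <- ed[order(ed$weight, ed$i, ed$j), , drop = FALSE]
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(nrow(ed))
  n_edges <- 0L
  for (k in seq_len(nrow(ed))) {
    ri <- find(ed$i[k]); rj <- find(ed$j[k])
    if (ri != rj) {
      parent[ri] <- rj
      keep[k] <- TRUE
      n_edges <- n_edges + 1L
      if (n_edges == m - 1L) break
    }
  }
  ed <- ed[keep, , drop = FALSE]
  edges <- data.frame(from = ids[ed$i], to = ids[ed$j],
                      weight = ed$weight, stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = ids, edges = edges,
                 total_weight = sum(edges$weight)),
            class = "mst_tree")
}

#' @export
print.mst_tree <- function(x, ...) {
  cat(sprintf("mst_tree: %d nodes, %d edges, total weight %.4f\n",
              length(x$nodes), nrow(x$edges), x$total_weight))
  invisible(x)
}

#' Write the MST edge list
#'
#' @param tree an `mst_tree`; @param path output file.
#' @return `path`, invisibly (tab-separated from, to, weight).
#' @export
write_mst <- function(tree, path) {
  utils::write.table(tree$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Render the MST as a 2D layout
#'
#' Simple force-free layout: classical multidimensional scaling of the
#' tree's path distances; nodes colored by an optional label vector.
#'
#' @param tree an `mst_tree`; @param path output PNG.
#' @param labels optional named vector node -> group label for coloring.
#' @return `path`, invisibly.
#' @export
render_mst <- function(tree, path, labels = NULL) {
  m <- length(tree$nodes)
  idx <- stats::setNames(seq_len(m), tree$nodes)
  d <- matrix(Inf, m, m); diag(d) <- 0
  for (k in seq_len(nrow(tree$edges))) {
    i <- idx[tree$edges$from[k]]; j <- idx[tree$edges$to[k]]
    d[i, j] <- d[j, i] <- tree$edges$weight[k]
  }
  for (k in seq_len(m))                      # Floyd-Warshall on the tree
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  xy <- stats::cmdscale(d, k = 2)
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  col <- "grey30"
  if (!is.null(labels)) {
    grp <- factor(labels[tree$nodes])
    col <- grDevices::hcl.colors(nlevels(grp), "Dark 3")[as.integer(grp)]
  }
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "")
  for (k in seq_len(nrow(tree$edges)))
    graphics::segments(xy[idx[tree$edges$from[k]], 1],
                       xy[idx[tree$edges$from[k]], 2],
                       xy[idx[tree$edges$to[k]], 1],
                       xy[idx[tree$edges$to[k]], 2], col = "grey70")
  graphics::points(xy, pch = 19, col = col, cex = 1.2)
  invisible(path)
}

#' Zoom-in retraining on a sample subset
#'
#' Restricts the allele matrix to the given samples, re-centralizes the
#' profiles on the subset, trains a fresh SOM with the same pipeline, and
#' recomputes portraits, the group summary map and spots on the new
#' model. The globally filtered SNP set is reused; set
#' `refilter_maf` to re-apply the MAF filter within the subset.
#'
#' @param matrix an [allele_matrix].
#' @param samples subset of sample IDs (>= 2).
#' @param config a [som_config].
#' @param group_by grouping column for mean portraits.
#' @param threshold_quantile,min_units segmentation settings.
#' @param refilter_maf if not `NULL`, a MAF threshold re-applied within
#'   the subset before training.
#' @return list with `matrix` (the subset), `model`, `portraits`
#'   (individual), `mean_portraits`, `summary`, `spots`.
#' @export
zoom_in <- function(matrix, samples, config = som_config(),
                    group_by = "population",
                    threshold_quantile = 0.90, min_units = 5L,
                    refilter_maf = NULL) {
  stopifnot(inherits(matrix, "allele_matrix"))
  if (length(samples) < 2L)
    stop("zoom-in needs at least two samples")
  j <- match(samples, matrix$sample_meta$sample_id)
  if (anyNA(j))
    stop("unknown sample(s): ",
         paste(samples[is.na(j)], collapse = ", "))
  sub <- allele_matrix(matrix$scores[, j, drop = FALSE],
                       matrix$snp_meta,
                       matrix$sample_meta[j, , drop = FALSE])
  if (!is.null(refilter_maf)) sub <- filter_by_maf(sub, refilter_maf)
  model <- som_fit(sub, config)
  prts <- all_portraits(model, sub)
  mps <- group_portraits(model, sub, group_by)
  sm <- summary_map(mps)
  spots <- segment_spots(sm, model, threshold_quantile, min_units)
  list(matrix = sub, model = model, portraits = prts,
       mean_portraits = mps, summary = sm, spots = spots)
}
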