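# Minor-allelic spot segmentation on the summary map and disease-term
# enrichment per spot.

#' Summary map over group mean portraits
#'
#' Element-wise maximum across the group mean portraits: a unit is "hot"
#' if it is minor-allele enriched in at least one group.
#'
#' @param mean_portraits list of [portrait]s with common shape.
#' @return An object of class `summary_map` (fields `grid`, `groups`).
#' @export
summary_map <- function(mean_portraits) {
  stopifnot(length(mean_portraits) >= 1)
  dims <- vapply(mean_portraits, function(p) dim(p$grid), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("portraits have mismatching grid shapes")
  grid <- Reduce(pmax, lapply(mean_portraits, `[[`, "grid"))
  structure(list(grid = grid,
                 groups = vapply(mean_portraits, `[[`, "",
                                 "subject")),
            class = "summary_map")
}

#' @export
print.summary_map <- function(x, ...) {
  cat(sprintf("summary_map: %d x %d over %d groups, max %.3f\n",
              nrow(x$grid), ncol(x$grid), length(x$groups),
              max(x$grid)))
  invisible(x)
}

# 8-connected component labeling of a logical matrix (BFS flood fill)
.label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  idx <- which(fg)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1L || rr > nr || c2 < 1L || c2 > nc) next
        lin <- (c2 - 1L) * nr + rr
        if (fg[lin] && lab[lin] == 0L) {
          lab[lin] <- nextlab
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# spot labels A, B, ..., Z, AA, AB, ...
.spot_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(n)]
}

#' Segment minor-allelic spots on the summary map
#'
#' Units with summary value strictly above the given quantile of the map
#' form the foreground; 8-connected components with at least `min_units`
#' units become spots, labeled A, B, ... in decreasing peak value.
#' Member SNPs are gathered from the model's unit assignment; a component
#' whose units hold no SNPs is dropped.
#'
#' @param map a [summary_map].
#' @param model the `som_model` that produced the portraits.
#' @param threshold_quantile foreground quantile in (0, 1); default 0.90.
#' @param min_units minimum spot size in units; default 5.
#' @return An object of class `spot_set`: list of spots (each with
#'   `label`, `units` as a 2-column coordinate matrix, `unit_idx`
#'   row-major unit indices, `snp_ids`, `peak`), plus the threshold used.
#'   A map with no unit above the threshold yields an empty set with a
#'   warning.
#' @export
segment_spots <- function(map, model, threshold_quantile = 0.90,
                          min_units = 5L) {
  stopifnot(inherits(map, "summary_map"), inherits(model, "som_model"),
            threshold_quantile > 0, threshold_quantile < 1,
            min_units >= 1L)
  if (!identical(dim(map$grid),
                 c(model$config$rows, model$config$cols)))
    stop("summary map shape does not match the model grid")
  thr <- stats::quantile(map$grid, threshold_quantile, names = FALSE)
  fg <- map$grid > thr
  if (!any(fg)) {
    warning("no unit above the threshold quantile; empty spot set")
    return(structure(list(spots = list(), threshold = thr,
                          quantile = threshold_quantile,
                          dims = dim(map$grid)),
                     class = "spot_set"))
  }
  lab <- .label_components(fg)
  snp_ids <- if (is.null(model$snp_ids))
    as.character(seq_along(model$assignment)) else model$snp_ids
  cols <- model$config$cols
  spots <- list()
  for (l in seq_len(max(lab))) {
    cells <- which(lab == l, arr.ind = TRUE)
    if (nrow(cells) < min_units) next
    units <- (cells[, 1] - 1L) * cols + cells[, 2]   # row-major unit idx
    members <- snp_ids[model$assignment %in% units]
    if (!length(members)) next
    spots[[length(spots) + 1L]] <- list(
      units = cells, unit_idx = sort(units), snp_ids = members,
      peak = max(map$grid[cells]))
  }
  if (length(spots)) {
    ord <- order(vapply(spots, `[[`, 0, "peak"), decreasing = TRUE)
    spots <- spots[ord]
    labs <- .spot_labels(length(spots))
    for (i in seq_along(spots)) spots[[i]]$label <- labs[i]
  }
  structure(list(spots = spots, threshold = thr,
                 quantile = threshold_quantile, dims = dim(map$grid)),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot_set: %d spot(s), threshold %.3f (q%.2f)\n",
              length(x$spots), x$threshold, x$quantile))
  for (s in x$spots)
    cat(sprintf("  %s: %d units, %d SNPs, peak %.3f\n", s$label,
                nrow(s$units), length(s$snp_ids), s$peak))
  invisible(x)
}

#' Allele-score profile of a spot
#'
#' @param spot one element of a `spot_set` (`$spots[[i]]`).
#' @param matrix the [allele_matrix].
#' @param grouping named vector mapping sample IDs to group labels, or a
#'   metadata column name (`"population"`/`"region"`).
#' @return list with `sample_profile` (mean member-SNP score per
#'   individual) and `group_profile` (mean of sample profiles per group).
#' @export
spot_profile <- function(spot, matrix, grouping = "population") {
  stopifnot(inherits(matrix, "allele_matrix"))
  rows <- match(spot$snp_ids, matrix$snp_meta$snp_id)
  if (anyNA(rows)) stop("spot member SNP(s) absent from the matrix")
  sample_profile <- colMeans(matrix$scores[rows, , drop = FALSE])
  if (is.character(grouping) && length(grouping) == 1L) {
    stopifnot(grouping %in% names(matrix$sample_meta))
    grp <- matrix$sample_meta[[grouping]]
  } else {
    grp <- unname(grouping[matrix$sample_meta$sample_id])
  }
  group_profile <- c(tapply(sample_profile, grp, mean))
  list(sample_profile = sample_profile,
       group_profile = group_profile)
}

# one-sided (greater) Fisher p for table [a, b; c, d]:
# P(X >= a), X hypergeometric with margins (a+c annotated, b+d other,
# draw a+b).
.fisher_greater <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Disease-term enrichment of spots
#'
#' For each (spot, term) pair a one-sided Fisher's exact test
#' (alternative "greater") on the 2x2 table of in/out-spot versus
#' annotated/other SNPs, asking whether the spot holds more SNPs of the
#' term than expected if SNPs were distributed at random among the spots.
#' The universe is the set of SNPs clustered on the map. A SNP counts
#' once per term regardless of how many sources reported it. Terms with
#' no annotated SNP in the universe are skipped.
#'
#' @param spots a `spot_set`.
#' @param catalog an [association_catalog] (level-3 mapped if desired;
#'   see [map_catalog_to_level3]), or a data.frame with columns `snp_id`,
#'   `term`.
#' @param universe character vector of all clustered SNP IDs.
#' @return data.frame with one row per (spot, term): contingency counts,
#'   `p_value` (raw, the primary column) and `p_adjust`
#'   (Benjamini-Hochberg over all reported tests), sorted by spot then
#'   ascending p.
#' @export
enrich_terms <- function(spots, catalog, universe) {
  stopifnot(inherits(spots, "spot_set"))
  ann <- if (is.data.frame(catalog)) catalog else
    catalog_annotation(catalog)
  stopifnot(all(c("snp_id", "term") %in% names(ann)))
  universe <- unique(universe)
  n_u <- length(universe)
  ann <- unique(ann[ann$snp_id %in% universe, c("snp_id", "term")])
  term_snps <- split(ann$snp_id, ann$term)
  out <- list()
  for (s in spots$spots) {
    in_spot <- unique(intersect(s$snp_ids, universe))
    n_spot <- length(in_spot)
    for (t in names(term_snps)) {
      snps_t <- term_snps[[t]]
      a <- length(intersect(in_spot, snps_t))
      b <- n_spot - a
      c_ <- length(snps_t) - a
      d <- n_u - a - b - c_
      out[[length(out) + 1L]] <- data.frame(
        spot = s$label, term = t,
        n_spot_annotated = a, n_spot_other = b,
        n_out_annotated = c_, n_out_other = d,
        p_value = .fisher_greater(a, b, c_, d),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(spot = character(0), term = character(0),
                      n_spot_annotated = integer(0),
                      n_spot_other = integer(0),
                      n_out_annotated = integer(0),
                      n_out_other = integer(0),
                      p_value = numeric(0), p_adjust = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$spot, res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Background distribution of disease terms over the clustered SNPs
#'
#' @param catalog an [association_catalog] or `snp_id`/`term` data.frame.
#' @param universe character vector of clustered SNP IDs.
#' @return Named integer vector: per term, the number of universe SNPs
#'   annotated with it (each SNP counted once per term).
#' @export
background_distribution <- function(catalog, universe) {
  ann <- if (is.data.frame(catalog)) catalog else
    catalog_annotation(catalog)
  universe <- unique(universe)
  ann <- unique(ann[ann$snp_id %in% universe, c("snp_id", "term")])
  counts <- table(ann$term)
  stats::setNames(as.integer(counts), names(counts))
}

#' Tab-separated spot report
#'
#' One row per spot: label, unit and SNP counts, peak value, and the top
#' enriched terms with raw and BH-adjusted p-values.
#'
#' @param spots a `spot_set`; @param enrichment result of [enrich_terms].
#' @param path output file; @param top_n terms per spot.
#' @return The report data.frame, invisibly; written to `path` if given.
#' @export
spot_report <- function(spots, enrichment, path = NULL, top_n = 3L) {
  rows <- lapply(spots$spots, function(s) {
    e <- enrichment[enrichment$spot == s$label, , drop = FALSE]
    e <- utils::head(e[order(e$p_value), , drop = FALSE], top_n)
    data.frame(spot = s$label, n_units = nrow(s$units),
               n_snps = length(s$snp_ids), peak = s$peak,
               top_terms = paste(sprintf("%s (p=%.3g, BH=%.3g)",
                                         e$term, e$p_value,
                                         e$p_adjust),
                                 collapse = "; "),
               stringsAsFactors = FALSE)
  })
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spot = character(0), n_units = integer(0),
               n_snps = integer(0), peak = numeric(0),
               top_terms = character(0), stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(rep, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(rep)
}

#' SNP-to-spot membership table
#'
#' @param spots a `spot_set`.
#' @return data.frame with columns `snp_id`, `spot`.
#' @export
spot_membership <- function(spots) {
  rows <- lapply(spots$spots, function(s)
    data.frame(snp_id = s$snp_ids, spot = s$label,
               stringsAsFactors = FALSE))
  if (!length(rows))
    return(data.frame(snp_id = character(0), spot = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Render the summary map with spot outlines and letters
#'
#' @param map a [summary_map]; @param spots its `spot_set`.
#' @param path output PNG; @param pixel_size pixels per unit.
#' @return `path`, invisibly.
#' @export
render_summary_map <- function(map, spots, path, pixel_size = 8L) {
  cm <- ternary_colormap()
  nr <- nrow(map$grid); nc <- ncol(map$grid)
  grDevices::png(path, width = nc * pixel_size,
                 height = nr * pixel_size)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  z <- pmin(pmax(t(map$grid[nr:1, , drop = FALSE]), 0), 2)
  graphics::image(z, breaks = cm$breaks, col = cm$colors,
                  axes = FALSE, useRaster = TRUE)
  for (s in spots$spots) {
    cx <- (mean(s$units[, 2]) - 1) / max(1, nc - 1)
    cy <- (nr - mean(s$units[, 1])) / max(1, nr - 1)
    graphics::text(cx, cy, s$label, col = "white", cex = 1.4,
                   font = 2)
  }
  invisible(path)
}
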