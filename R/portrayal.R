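# SNP portraits: grid images of per-unit mean allele scores.
#
# Portraits are drawn on the raw 0-2 allele-score scale (not the centered
# training scale), so red literally means minor-allele enrichment.

#' Construct a portrait
#'
#' @param grid numeric matrix (map rows x cols) of unit values.
#' @param subject individual ID or group label.
#' @param kind `"individual"`, `"mean"` or `"difference"`.
#' @return An object of class `portrait`.
#' @export
portrait <- function(grid, subject,
                     kind = c("individual", "mean", "difference")) {
  kind <- match.arg(kind)
  grid <- as.matrix(grid)
  lo <- if (kind == "difference") -2 else 0
  if (length(grid) && (min(grid) < lo - 1e-9 || max(grid) > 2 + 1e-9))
    stop("portrait values out of [", lo, ", 2]")
  structure(list(grid = grid, subject = subject, kind = kind),
            class = "portrait")
}

#' @export
print.portrait <- function(x, ...) {
  cat(sprintf("portrait (%s) of %s: %d x %d, values [%.2f, %.2f]\n",
              x$kind, x$subject, nrow(x$grid), ncol(x$grid),
              min(x$grid), max(x$grid)))
  invisible(x)
}

# iterative 8-neighbor mean fill of NA cells (units with no member SNPs)
.fill_empty <- function(grid) {
  if (!anyNA(grid)) return(grid)
  nr <- nrow(grid); nc <- ncol(grid)
  while (anyNA(grid)) {
    nas <- which(is.na(grid), arr.ind = TRUE)
    filled <- grid
    progressed <- FALSE
    for (i in seq_len(nrow(nas))) {
      r <- nas[i, 1]; cc <- nas[i, 2]
      rs <- max(1, r - 1):min(nr, r + 1)
      cs <- max(1, cc - 1):min(nc, cc + 1)
      nb <- grid[rs, cs]
      if (!all(is.na(nb))) {
        filled[r, cc] <- mean(nb, na.rm = TRUE)
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cannot fill an all-empty map")
    grid <- filled
  }
  grid
}

#' Portrait of one individual
#'
#' Each unit takes the mean raw allele score (0-2 scale) of its member
#' SNPs for that individual; units without member SNPs are filled by the
#' iterated mean of their 8-neighbors.
#'
#' @param model a `som_model` fitted with [som_fit] on `matrix`.
#' @param matrix the [allele_matrix] the model was trained on.
#' @param sample sample identifier (column of the matrix).
#' @return A [portrait] of kind `"individual"`.
#' @export
individual_portrait <- function(model, matrix, sample) {
  stopifnot(inherits(model, "som_model"),
            inherits(matrix, "allele_matrix"))
  j <- match(sample, matrix$sample_meta$sample_id)
  if (is.na(j)) stop("unknown sample: ", sample)
  if (length(model$assignment) != nrow(matrix$scores))
    stop("model was not trained on this matrix")
  col <- as.numeric(matrix$scores[, j])
  k <- model$config$rows * model$config$cols
  sums <- rep(NA_real_, k)
  agg <- rowsum(col, group = model$assignment, reorder = TRUE)
  cnt <- tabulate(model$assignment, nbins = k)
  units <- as.integer(rownames(agg))
  sums[units] <- agg[, 1] / cnt[units]
  grid <- matrix(sums, nrow = model$config$rows,
                 ncol = model$config$cols, byrow = TRUE)
  portrait(.fill_empty(grid), subject = sample, kind = "individual")
}

#' Portraits of every individual
#'
#' @param model a `som_model`; @param matrix its [allele_matrix].
#' @return Named list of [portrait]s, one per sample.
#' @export
all_portraits <- function(model, matrix) {
  ids <- matrix$sample_meta$sample_id
  stats::setNames(lapply(ids, function(s)
    individual_portrait(model, matrix, s)), ids)
}

#' Mean portrait of a group
#'
#' @param portraits list of [portrait]s with a common grid shape.
#' @param subject group label for the result.
#' @return A [portrait] of kind `"mean"` (element-wise arithmetic mean).
#' @export
mean_portrait <- function(portraits, subject = "mean") {
  stopifnot(length(portraits) >= 1)
  dims <- vapply(portraits, function(p) dim(p$grid), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("portraits have mismatching grid shapes")
  acc <- Reduce(`+`, lapply(portraits, `[[`, "grid"))
  portrait(acc / length(portraits), subject = subject, kind = "mean")
}

#' Difference of two portraits
#'
#' @param a,b [portrait]s of the same shape.
#' @return A [portrait] of kind `"difference"` holding `a - b`
#'   (element-wise, bounded in `[-2, 2]`).
#' @export
difference_portrait <- function(a, b) {
  stopifnot(inherits(a, "portrait"), inherits(b, "portrait"))
  if (!identical(dim(a$grid), dim(b$grid)))
    stop("portraits have mismatching grid shapes")
  portrait(a$grid - b$grid,
           subject = paste0(a$subject, " - ", b$subject),
           kind = "difference")
}

#' Group mean portraits
#'
#' @param model a `som_model`; @param matrix its [allele_matrix].
#' @param group_by grouping column of the sample metadata
#'   (`"population"` or `"region"`).
#' @return Named list of mean [portrait]s, one per group level.
#' @export
group_portraits <- function(model, matrix, group_by = "population") {
  stopifnot(group_by %in% names(matrix$sample_meta))
  ind <- all_portraits(model, matrix)
  groups <- split(matrix$sample_meta$sample_id,
                  matrix$sample_meta[[group_by]])
  stats::setNames(lapply(names(groups), function(g)
    mean_portrait(ind[groups[[g]]], subject = g)), names(groups))
}

#' Ternary color map for allele-score portraits
#'
#' Scores in `[0, 2]` are split into a major-allele (blue), heterozygous
#' (green) and minor-allele (red) band, with intensity graded within each
#' band. Default cut points at 2/3 and 4/3 partition the range into equal
#' thirds.
#'
#' @param cuts two strictly increasing cut points inside (0, 2).
#' @param n number of color steps.
#' @return An object of class `color_map`: `breaks` and `colors` usable
#'   with [graphics::image], plus the cut points.
#' @export
ternary_colormap <- function(cuts = c(2 / 3, 4 / 3), n = 120L) {
  stopifnot(length(cuts) == 2, cuts[1] > 0, cuts[2] < 2,
            cuts[1] < cuts[2])
  breaks <- seq(0, 2, length.out = n + 1L)
  mid <- (breaks[-1L] + breaks[-(n + 1L)]) / 2
  band <- findInterval(mid, cuts) + 1L       # 1 blue, 2 green, 3 red
  blue <- grDevices::colorRampPalette(c("#08306B", "#9ECAE1"))
  green <- grDevices::colorRampPalette(c("#A1D99B", "#00441B", "#A1D99B"))
  red <- grDevices::colorRampPalette(c("#FCBBA1", "#67000D"))
  cols <- character(n)
  for (b in 1:3) {
    idx <- which(band == b)
    if (!length(idx)) next
    pal <- switch(b, blue, green, red)
    cols[idx] <- pal(length(idx))
  }
  structure(list(breaks = breaks, colors = cols, cuts = cuts,
                 diverging = FALSE),
            class = "color_map")
}

#' Symmetric diverging color map for difference portraits
#'
#' @param limit absolute value mapped to the strongest color (default 2).
#' @param n number of color steps.
#' @return A `color_map` over `[-limit, limit]`, blue-white-red.
#' @export
diverging_colormap <- function(limit = 2, n = 120L) {
  breaks <- seq(-limit, limit, length.out = n + 1L)
  cols <- grDevices::colorRampPalette(
    c("#08306B", "#F7F7F7", "#67000D"))(n)
  structure(list(breaks = breaks, colors = cols, cuts = numeric(0),
                 diverging = TRUE),
            class = "color_map")
}

#' Classify scores into the ternary bands
#'
#' @param values numeric scores in `[0, 2]`.
#' @param colormap a ternary `color_map`.
#' @return factor with levels `major`, `heterozygous`, `minor`.
#' @export
score_band <- function(values, colormap = ternary_colormap()) {
  band <- findInterval(values, colormap$cuts) + 1L
  factor(c("major", "heterozygous", "minor")[band],
         levels = c("major", "heterozygous", "minor"))
}

#' Render a portrait to a PNG image
#'
#' Pure function of (grid, colormap): identical inputs yield identical
#' image bytes. Individual/mean portraits default to the ternary map
#' (score 0 blue, 1 green, 2 red); difference portraits to the symmetric
#' diverging map.
#'
#' @param p a [portrait].
#' @param path output PNG path.
#' @param colormap a `color_map`; default chosen by portrait kind.
#' @param pixel_size pixels per grid unit.
#' @return `path`, invisibly.
#' @export
render_portrait <- function(p, path, colormap = NULL, pixel_size = 6L) {
  stopifnot(inherits(p, "portrait"))
  if (is.null(colormap))
    colormap <- if (p$kind == "difference") diverging_colormap()
                else ternary_colormap()
  nr <- nrow(p$grid); nc <- ncol(p$grid)
  grDevices::png(path, width = nc * pixel_size, height = nr * pixel_size)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  z <- pmin(pmax(t(p$grid[nr:1, , drop = FALSE]),
                 colormap$breaks[1]),
            colormap$breaks[length(colormap$breaks)])
  graphics::image(z, breaks = colormap$breaks, col = colormap$colors,
                  axes = FALSE, useRaster = TRUE)
  invisible(path)
}

#' Export a portrait grid as a tab-separated matrix
#'
#' @param p a [portrait]; @param path output file.
#' @return `path`, invisibly.
#' @export
write_portrait <- function(p, path) {
  utils::write.table(p$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
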