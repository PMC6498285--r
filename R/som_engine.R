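# Batch self-organizing map over centered SNP profiles.
#
# Each SNP is a data point (its profile = allele scores across
# individuals); the map's K = rows * cols prototypes are "meta-SNP"
# profiles. Training is batch SOM: per epoch all SNPs are assigned to
# their best-matching unit (BMU), then every prototype is replaced by the
# Gaussian-neighborhood-weighted mean of the assigned profiles. Batch
# training plus linear initialization makes the whole fit deterministic.

#' SOM configuration
#'
#' @param rows,cols grid dimensions; the default 55 x 55 gives
#'   K = 3,025 meta-SNP prototypes.
#' @param epochs training sweeps (default 100).
#' @param radius_start,radius_end Gaussian neighborhood radius in grid
#'   units, decayed linearly from start (default `max(rows, cols) / 2`) to
#'   end (default 1) over the epochs.
#' @param init `"linear"` (deterministic: prototypes laid out along the
#'   two leading principal directions of the data) or `"random"`
#'   (prototypes drawn from the data rows; requires `seed`).
#' @param seed RNG seed for `init = "random"`; ignored otherwise.
#' @return An object of class `som_config`.
#' @export
som_config <- function(rows = 55L, cols = 55L, epochs = 100L,
                       radius_start = max(rows, cols) / 2,
                       radius_end = 1,
                       init = c("linear", "random"), seed = NULL) {
  init <- match.arg(init)
  rows <- as.integer(rows); cols <- as.integer(cols)
  epochs <- as.integer(epochs)
  if (rows < 2L || cols < 2L) stop("grid must be at least 2 x 2")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (!(radius_start >= radius_end) || !(radius_end > 0))
    stop("need radius_start >= radius_end > 0")
  structure(list(rows = rows, cols = cols, epochs = epochs,
                 radius_start = radius_start, radius_end = radius_end,
                 init = init, seed = seed),
            class = "som_config")
}

#' Centralize SNP profiles
#'
#' Subtracts each SNP's mean allele score across individuals (feature
#' centralization); the means are retained so raw scores can be
#' reconstructed and portraits drawn on the original 0-2 scale.
#'
#' @param matrix an [allele_matrix], or a plain numeric matrix of profiles
#'   (rows = SNPs).
#' @return list with `centered` (numeric matrix, row means 0) and `means`
#'   (per-SNP mean).
#' @export
centralize <- function(matrix) {
  x <- if (inherits(matrix, "allele_matrix")) matrix$scores else matrix
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!nrow(x)) stop("empty profile matrix")
  mns <- rowMeans(x)
  list(centered = x - mns, means = mns)
}

# unit u (1-based, row-major: u = (r-1)*cols + c) -> grid coordinates
.grid_coords <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

# squared Euclidean distances between all rows of x and all rows of p
.cross_dist2 <- function(x, p) {
  d2 <- matrix(rowSums(x^2), nrow(x), nrow(p)) +
    matrix(rowSums(p^2), nrow(x), nrow(p), byrow = TRUE) -
    2 * tcrossprod(x, p)
  d2[d2 < 0] <- 0
  d2
}

.init_prototypes <- function(x, config) {
  k <- config$rows * config$cols
  m <- ncol(x)
  if (config$init == "random") {
    if (is.null(config$seed))
      stop("random initialization requires a seed")
    set.seed(config$seed)
    idx <- sample.int(nrow(x), k, replace = TRUE)
    return(x[idx, , drop = FALSE] +
             matrix(stats::rnorm(k * m, sd = 1e-4), k, m))
  }
  # linear: span the two leading principal directions of the data
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  nv <- min(2L, nrow(x), m)
  sv <- svd(xc, nu = 0, nv = nv)
  denom <- sqrt(max(1, nrow(x) - 1))
  s1 <- sv$d[1] / denom
  v1 <- sv$v[, 1]
  if (nv >= 2L && length(sv$d) >= 2L) {
    s2 <- sv$d[2] / denom
    v2 <- sv$v[, 2]
  } else {
    s2 <- 0
    v2 <- numeric(m)
  }
  a <- if (config$cols > 1L) seq(-2, 2, length.out = config$cols) else 0
  b <- if (config$rows > 1L) seq(-2, 2, length.out = config$rows) else 0
  coords <- .grid_coords(config$rows, config$cols)
  outer(rep(1, nrow(coords)), mu) +
    outer(a[coords[, "col"]] * s1, v1) +
    outer(b[coords[, "row"]] * s2, v2)
}

#' Train a batch self-organizing map on centered SNP profiles
#'
#' Each epoch assigns every profile to its nearest prototype (Euclidean;
#' ties to the lowest unit index) and then replaces each prototype with
#' the neighborhood-kernel-weighted mean of the assigned profiles. The
#' Gaussian kernel acts on Euclidean distance in grid coordinates with a
#' linearly decaying radius. A final assignment pass guarantees the stored
#' mapping is nearest-prototype.
#'
#' @param centered numeric matrix of centered profiles (rows = SNPs), as
#'   produced by [centralize]; at least 2 columns (individuals).
#' @param config a [som_config].
#' @return An object of class `som_model`: `config`, `prototypes`
#'   (K x M), `assignment` (SNP row -> unit index, 1-based), `coords`
#'   (K x 2 grid coordinates), `unit_members` (list unit -> SNP rows),
#'   `qe` (per-epoch mean quantization error), and the input dimnames.
#' @export
train_som <- function(centered, config = som_config()) {
  stopifnot(inherits(config, "som_config"))
  x <- as.matrix(centered)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L) stop("need at least one SNP profile")
  if (ncol(x) < 2L) stop("need at least two individuals")
  if (!all(is.finite(x))) stop("profiles contain non-finite values")
  k <- config$rows * config$cols
  coords <- .grid_coords(config$rows, config$cols)
  gd2 <- .cross_dist2(coords, coords)      # squared grid distances, K x K
  p <- .init_prototypes(x, config)
  n <- nrow(x)
  qe <- numeric(config$epochs)
  radius <- if (config$epochs > 1L)
    seq(config$radius_start, config$radius_end,
        length.out = config$epochs)
  else config$radius_end
  bmu <- integer(n)
  for (e in seq_len(config$epochs)) {
    d2 <- .cross_dist2(x, p)
    bmu <- max.col(-d2, ties.method = "first")
    qe[e] <- mean(sqrt(d2[cbind(seq_len(n), bmu)]))
    h <- exp(-gd2 / (2 * radius[e]^2))
    cnt <- tabulate(bmu, nbins = k)
    s <- matrix(0, k, ncol(x))
    rs <- rowsum(x, group = bmu, reorder = TRUE)
    s[as.integer(rownames(rs)), ] <- rs
    p <- (h %*% s) / as.vector(h %*% cnt)
  }
  d2 <- .cross_dist2(x, p)
  bmu <- max.col(-d2, ties.method = "first")
  qe_final <- mean(sqrt(d2[cbind(seq_len(n), bmu)]))
  members <- split(seq_len(n), factor(bmu, levels = seq_len(k)))
  structure(list(config = config, prototypes = p, assignment = bmu,
                 coords = coords, unit_members = unname(members),
                 qe = qe, qe_final = qe_final,
                 snp_ids = rownames(x), sample_ids = colnames(x),
                 snp_means = NULL),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf(
    "som_model: %d x %d grid (K = %d), %d SNPs x %d individuals, QE %.4f\n",
    x$config$rows, x$config$cols, nrow(x$prototypes),
    length(x$assignment), ncol(x$prototypes), x$qe_final))
  invisible(x)
}

#' Fit a SOM to an allele matrix
#'
#' Convenience wrapper: centralizes the profiles, trains the map, and
#' stores the per-SNP means and identifiers needed for portrayal.
#'
#' @param matrix an [allele_matrix].
#' @param config a [som_config].
#' @return A `som_model` carrying `snp_means`, `snp_ids` and `sample_ids`.
#' @export
som_fit <- function(matrix, config = som_config()) {
  stopifnot(inherits(matrix, "allele_matrix"))
  cz <- centralize(matrix)
  model <- train_som(cz$centered, config)
  model$snp_means <- cz$means
  model$snp_ids <- matrix$snp_meta$snp_id
  model$sample_ids <- matrix$sample_meta$sample_id
  model
}

#' Best-matching unit of a profile
#'
#' @param profile centered profile vector (length = number of
#'   individuals the model was trained on).
#' @param model a `som_model`.
#' @return The 1-based index of the prototype at minimal Euclidean
#'   distance; ties broken towards the lowest unit index.
#' @export
assign_bmu <- function(profile, model) {
  stopifnot(inherits(model, "som_model"))
  if (length(profile) != ncol(model$prototypes))
    stop("profile length ", length(profile),
         " does not match prototype length ", ncol(model$prototypes))
  d2 <- colSums((t(model$prototypes) - as.numeric(profile))^2)
  which.min(d2)
}

#' Export a SOM model as portable text files
#'
#' Writes `config.json`, `prototypes.tsv`, `assignment.tsv` (snp_id,
#' unit_id), `means.tsv` and `qe.tsv` into a directory; [read_som]
#' restores the model.
#'
#' @param model a `som_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_som <- function(model, dir) {
  stopifnot(inherits(model, "som_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  data.table::fwrite(data.table::as.data.table(model$prototypes),
                     file.path(dir, "prototypes.tsv"), sep = "\t")
  snp_ids <- if (is.null(model$snp_ids))
    as.character(seq_along(model$assignment)) else model$snp_ids
  data.table::fwrite(
    data.frame(snp_id = snp_ids, unit_id = model$assignment),
    file.path(dir, "assignment.tsv"), sep = "\t")
  means <- if (is.null(model$snp_means))
    rep(NA_real_, length(model$assignment)) else model$snp_means
  data.table::fwrite(data.frame(snp_id = snp_ids, mean = means),
                     file.path(dir, "means.tsv"), sep = "\t")
  data.table::fwrite(
    data.frame(epoch = seq_along(model$qe), qe = model$qe),
    file.path(dir, "qe.tsv"), sep = "\t")
  invisible(dir)
}

#' Restore a SOM model written by [write_som]
#'
#' @param dir directory written by [write_som].
#' @return A `som_model` (without `sample_ids`, which live with the
#'   allele matrix).
#' @export
read_som <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- som_config(cfg$rows, cfg$cols, cfg$epochs, cfg$radius_start,
                       cfg$radius_end, cfg$init,
                       seed = if (is.null(cfg$seed)) NULL else cfg$seed)
  p <- as.matrix(data.table::fread(file.path(dir, "prototypes.tsv")))
  dimnames(p) <- NULL
  asg <- data.table::fread(file.path(dir, "assignment.tsv"),
                           data.table = FALSE)
  means <- data.table::fread(file.path(dir, "means.tsv"),
                             data.table = FALSE)
  qe <- data.table::fread(file.path(dir, "qe.tsv"),
                          data.table = FALSE)$qe
  k <- config$rows * config$cols
  members <- split(seq_len(nrow(asg)),
                   factor(asg$unit_id, levels = seq_len(k)))
  structure(list(config = config, prototypes = p,
                 assignment = asg$unit_id,
                 coords = .grid_coords(config$rows, config$cols),
                 unit_members = unname(members), qe = qe,
                 qe_final = qe[length(qe)],
                 snp_ids = asg$snp_id, sample_ids = NULL,
                 snp_means = stats::setNames(means$mean, means$snp_id)),
            class = "som_model")
}
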