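# SNP-disease association catalogs and ontology level mapping.

#' Load SNP-disease association tables
#'
#' Each file is tab-separated with required columns `snp_id` and
#' `disease_term_id`, optional `gene` and `source`. Files are unioned and
#' exact duplicate (snp_id, disease_term_id) pairs removed, keeping the
#' first occurrence; per-source record counts are kept as an attribute.
#'
#' @param paths character vector of file paths.
#' @return An object of class `association_catalog`: a list with `records`
#'   (data.frame snp_id, disease_term_id, gene, source) and, after
#'   [map_catalog_to_level3], a `level3` expansion.
#' @export
load_associations <- function(paths) {
  stopifnot(length(paths) >= 1)
  pieces <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("association file not found: ", p)
    df <- utils::read.delim(p, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (nrow(df) == 0L)
      return(data.frame(snp_id = character(0),
                        disease_term_id = character(0),
                        gene = character(0), source = character(0),
                        stringsAsFactors = FALSE))
    for (col in c("snp_id", "disease_term_id"))
      if (!col %in% names(df))
        stop("association file ", p, " lacks required column '", col, "'")
    if (!"gene" %in% names(df)) df$gene <- NA_character_
    if (!"source" %in% names(df)) df$source <- basename(p)
    df[, c("snp_id", "disease_term_id", "gene", "source")]
  })
  rec <- do.call(rbind, pieces)
  per_source <- table(rec$source)
  dup <- duplicated(rec[, c("snp_id", "disease_term_id")])
  rec <- rec[!dup, , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec, level3 = NULL),
            class = "association_catalog",
            per_source = as.list(per_source),
            n_duplicates_removed = sum(dup))
}

#' Build an association catalog from a data frame
#'
#' @param records data.frame with columns `snp_id`, `disease_term_id` and
#'   optionally `gene`, `source`.
#' @return An `association_catalog`.
#' @export
association_catalog <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("snp_id", "disease_term_id") %in% names(records)))
  if (!"gene" %in% names(records)) records$gene <- NA_character_
  if (!"source" %in% names(records)) records$source <- "user"
  dup <- duplicated(records[, c("snp_id", "disease_term_id")])
  records <- records[!dup, c("snp_id", "disease_term_id", "gene", "source")]
  rownames(records) <- NULL
  structure(list(records = records, level3 = NULL),
            class = "association_catalog")
}

#' @export
print.association_catalog <- function(x, ...) {
  cat(sprintf("association_catalog: %d records, %d SNPs, %d terms%s\n",
              nrow(x$records), length(unique(x$records$snp_id)),
              length(unique(x$records$disease_term_id)),
              if (is.null(x$level3)) "" else " (level-3 mapped)"))
  invisible(x)
}

#' SNP identifiers covered by a catalog
#' @param catalog an `association_catalog`.
#' @return character vector of unique SNP IDs.
#' @export
catalog_snps <- function(catalog) {
  stopifnot(inherits(catalog, "association_catalog"))
  unique(catalog$records$snp_id)
}

#' Read an ontology from an OBO flat file
#'
#' Parses `[Term]` stanzas for `id`, `name` and `is_a` lines only
#' (OBO 1.2/1.4); obsolete terms are skipped. The root is the unique term
#' without parents unless given explicitly.
#'
#' @param path OBO file.
#' @param root optional root term identifier.
#' @return An object of class `ontology_graph`: `terms` (data.frame id,
#'   name), `parents` (named list child -> parent ids), `root`, and after
#'   [compute_depths] a named `depth` vector (NA = unreachable from root).
#' @export
read_obo <- function(path, root = NULL) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); names_ <- character(0)
  parents <- list()
  cur <- NULL; cur_name <- NA_character_; cur_parents <- character(0)
  cur_obsolete <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !cur_obsolete) {
      ids[[length(ids) + 1L]] <<- cur
      names_[[length(names_) + 1L]] <<- cur_name
      parents[[cur]] <<- cur_parents
    }
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)            # strip OBO comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE
      cur <- NULL; cur_name <- NA_character_
      cur_parents <- character(0); cur_obsolete <- FALSE
    } else if (grepl("^\\[", ln)) {      # other stanza types
      flush(); in_term <- FALSE; cur <- NULL
    } else if (in_term) {
      if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
      else if (startsWith(ln, "name:"))
        cur_name <- trimws(sub("^name:", "", ln))
      else if (startsWith(ln, "is_a:")) {
        p <- trimws(sub("^is_a:", "", ln))
        p <- strsplit(p, "\\s+")[[1]]
        if (length(p) && nzchar(p[1]))
          cur_parents <- c(cur_parents, p[1])
      } else if (ln == "is_obsolete: true") cur_obsolete <- TRUE
    }
  }
  flush()
  ontology_graph(data.frame(id = ids, name = names_,
                            stringsAsFactors = FALSE),
                 parents, root = root)
}

#' Construct an ontology graph
#'
#' @param terms data.frame with columns `id`, `name`.
#' @param parents named list mapping each term id to its parent ids
#'   (`is_a` edges child -> parent).
#' @param root optional root identifier; defaults to the unique term with
#'   no parents.
#' @return An `ontology_graph` (depths not yet computed).
#' @export
ontology_graph <- function(terms, parents, root = NULL) {
  stopifnot(is.data.frame(terms), all(c("id", "name") %in% names(terms)))
  if (anyDuplicated(terms$id)) stop("duplicate term identifiers")
  parents <- parents[intersect(names(parents), terms$id)]
  if (is.null(root)) {
    rootless <- terms$id[vapply(terms$id, function(t)
      length(parents[[t]]) == 0L, logical(1))]
    if (length(rootless) != 1L)
      stop("root is ambiguous (", length(rootless),
           " parentless terms); pass `root` explicitly")
    root <- rootless
  }
  if (!root %in% terms$id) stop("root term not present: ", root)
  structure(list(terms = terms, parents = parents, root = root,
                 depth = NULL),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, root %s%s\n", nrow(x$terms),
              x$root,
              if (is.null(x$depth)) "" else
                sprintf(", max depth %d",
                        max(x$depth, na.rm = TRUE))))
  invisible(x)
}

#' Compute term depths by breadth-first search from the root
#'
#' Depth is the minimum number of `is_a` edges from the root (root depth
#' 0); multiple parents are allowed. A cycle among the `is_a` edges is an
#' error reporting one offending cycle; terms unreachable from the root
#' keep depth `NA` and are treated as unmapped downstream.
#'
#' @param graph an [ontology_graph].
#' @return The graph with its `depth` vector filled in.
#' @export
compute_depths <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  ids <- graph$terms$id
  children <- vector("list", length(ids))
  names(children) <- ids
  for (child in names(graph$parents))
    for (p in graph$parents[[child]])
      if (p %in% ids) children[[p]] <- c(children[[p]], child)
  cyc <- .find_cycle(graph$parents, ids)
  if (!is.null(cyc))
    stop("ontology is_a edges contain a cycle: ",
         paste(cyc, collapse = " -> "))
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  depth[graph$root] <- 0L
  frontier <- graph$root
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- d
    frontier <- nxt
  }
  graph$depth <- depth
  graph
}

# Depth-first cycle detection over child -> parent edges; returns one
# cycle as a vector of term ids, or NULL.
.find_cycle <- function(parents, ids) {
  state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new 1 open 2 done
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    state[v] <<- 1L
    path <<- c(path, v)
    for (p in parents[[v]]) {
      if (!p %in% ids) next
      if (state[p] == 1L) {
        i <- match(p, path)
        found <<- c(path[i:length(path)], p)
        return()
      }
      if (state[p] == 0L) visit(p)
      if (!is.null(found)) return()
    }
    state[v] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in ids) if (state[v] == 0L) visit(v)
  found
}

#' Map a disease term to the level-3 analysis vocabulary
#'
#' Terms at depth 3 map to themselves; deeper terms map to all of their
#' depth-3 ancestors (several under multiple parentage); terms shallower
#' than depth 3 map to themselves and are flagged `shallow`; unknown or
#' root-unreachable terms return an empty set flagged `unmapped`.
#'
#' @param term a disease term identifier.
#' @param graph an [ontology_graph] with depths computed.
#' @return Character vector of level-3 term ids, with logical attributes
#'   `shallow` and `unmapped`.
#' @export
map_to_level3 <- function(term, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (is.null(graph$depth)) stop("run compute_depths() first")
  d <- graph$depth[term]
  if (is.na(match(term, names(graph$depth))) || is.na(d))
    return(structure(character(0), shallow = FALSE, unmapped = TRUE))
  if (d <= 3L)
    return(structure(term, shallow = unname(d < 3L), unmapped = FALSE))
  anc <- character(0)
  frontier <- term
  seen <- character(0)
  while (length(frontier)) {
    ps <- unique(unlist(graph$parents[frontier], use.names = FALSE))
    ps <- setdiff(ps, seen)
    seen <- c(seen, ps)
    anc <- c(anc, ps[!is.na(graph$depth[ps]) & graph$depth[ps] == 3L])
    frontier <- ps[is.na(graph$depth[ps]) | graph$depth[ps] > 3L]
  }
  structure(unique(anc), shallow = FALSE, unmapped = FALSE)
}

#' Expand a catalog to the level-3 vocabulary
#'
#' Every record is mapped through [map_to_level3]; records whose term has
#' several level-3 ancestors contribute to each of them. Record counts are
#' conserved: records in = mapped records (possibly expanded) + unmapped.
#'
#' @param catalog an [association_catalog].
#' @param graph an [ontology_graph] with depths computed.
#' @return The catalog with a `level3` data.frame (snp_id, level3_term,
#'   gene, source, shallow) and an `unmapped` data.frame attached.
#' @export
map_catalog_to_level3 <- function(catalog, graph) {
  stopifnot(inherits(catalog, "association_catalog"))
  terms <- unique(catalog$records$disease_term_id)
  maps <- lapply(terms, map_to_level3, graph = graph)
  names(maps) <- terms
  rec <- catalog$records
  out <- vector("list", nrow(rec))
  unmapped <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    m <- maps[[rec$disease_term_id[i]]]
    if (length(m) == 0L) { unmapped[i] <- TRUE; next }
    out[[i]] <- data.frame(snp_id = rec$snp_id[i], level3_term = m,
                           gene = rec$gene[i], source = rec$source[i],
                           shallow = attr(m, "shallow"),
                           stringsAsFactors = FALSE)
  }
  lvl3 <- do.call(rbind, out[!unmapped])
  if (is.null(lvl3))
    lvl3 <- data.frame(snp_id = character(0), level3_term = character(0),
                       gene = character(0), source = character(0),
                       shallow = logical(0), stringsAsFactors = FALSE)
  lvl3 <- lvl3[!duplicated(lvl3[, c("snp_id", "level3_term")]), ,
               drop = FALSE]
  rownames(lvl3) <- NULL
  catalog$level3 <- lvl3
  catalog$unmapped <- rec[unmapped, , drop = FALSE]
  catalog
}

#' SNP annotation table for enrichment
#'
#' Returns the (snp_id, term) pairs used by [enrich_terms] and
#' [background_distribution]: the level-3 expansion when available,
#' otherwise the raw disease terms.
#'
#' @param catalog an [association_catalog].
#' @return data.frame with columns `snp_id`, `term`.
#' @export
catalog_annotation <- function(catalog) {
  stopifnot(inherits(catalog, "association_catalog"))
  if (!is.null(catalog$level3))
    data.frame(snp_id = catalog$level3$snp_id,
               term = catalog$level3$level3_term,
               stringsAsFactors = FALSE)
  else
    data.frame(snp_id = catalog$records$snp_id,
               term = catalog$records$disease_term_id,
               stringsAsFactors = FALSE)
}
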