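# Canonical gene-symbol normalization used whenever map identifiers are
# matched against expression tables: trim whitespace, fold case.
norm_sym <- function(x) toupper(trimws(as.character(x)))

#' Construct a molecular interaction map
#'
#' A molecular interaction map (MIM) is a signed directed graph whose nodes
#' are either molecular species (`node_class = "gene"`) or phenotype readout
#' nodes (`node_class = "phenotype"`). Edges carry a sign: `+1` for
#' activation, `-1` for inhibition. Phenotype nodes are readouts, never
#' regulators: any edge leaving a phenotype node is dropped with a warning.
#'
#' @param nodes data.frame with columns `id`, `label`, `node_class`
#'   (`"gene"` or `"phenotype"`; anything else is collapsed to `"gene"`),
#'   `submaps` (list-column of character vectors, or a semicolon-delimited
#'   character column) and `phase` (character or `NA`).
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (`+1` or `-1`).
#' @return An object of class `mim` with validated `nodes` and `edges`
#'   data.frames.
#' @examples
#' nodes <- data.frame(id = c("A", "B", "P"), label = c("A", "B", "P"),
#'                     node_class = c("gene", "gene", "phenotype"),
#'                     submaps = I(list("initiation", character(), character())),
#'                     phase = c(NA, NA, "initiation"))
#' edges <- data.frame(source = c("A", "B"), target = c("B", "P"),
#'                     sign = c(1L, -1L))
#' m <- mim(nodes, edges)
#' @export
mim <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (is.null(nodes$label)) nodes$label <- nodes$id
  nodes$label <- as.character(nodes$label)
  if (is.null(nodes$node_class)) nodes$node_class <- "gene"
  nodes$node_class <- as.character(nodes$node_class)
  # non-phenotype species (metabolites, miRNAs, ...) are treated uniformly
  other <- !(nodes$node_class %in% c("gene", "phenotype"))
  if (any(other)) nodes$node_class[other] <- "gene"
  if (is.null(nodes$phase)) nodes$phase <- NA_character_
  nodes$phase <- as.character(nodes$phase)
  if (is.null(nodes$submaps)) nodes$submaps <- I(rep(list(character()), nrow(nodes)))
  if (!is.list(nodes$submaps))
    nodes$submaps <- I(strsplit(ifelse(is.na(nodes$submaps), "", nodes$submaps), ";",
                                fixed = TRUE))
  nodes$submaps <- I(lapply(nodes$submaps, function(s) unique(trimws(s[nzchar(s)]))))

  if (nrow(edges) == 0) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer())
  } else {
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    if (!all(edges$sign %in% c(-1L, 1L)))
      stop("edge signs must be +1 or -1")
    edges$sign <- as.integer(edges$sign)
    missing <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing))
      stop("edge endpoint(s) not in node table: ",
           paste(missing, collapse = ", "))
    key <- paste(edges$source, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- duplicated(key)
      agree <- !any(tapply(edges$sign, key, function(s) length(unique(s)) > 1))
      if (!agree)
        stop("conflicting signs for duplicated edge(s): ",
             paste(unique(sub("\r", " -> ", key[dup])), collapse = ", "))
      warning("dropping ", sum(dup), " duplicated edge(s)")
      edges <- edges[!dup, , drop = FALSE]
    }
    phen <- nodes$id[nodes$node_class == "phenotype"]
    out_of_phen <- edges$source %in% phen
    if (any(out_of_phen)) {
      warning("dropping ", sum(out_of_phen),
              " edge(s) leaving phenotype node(s); phenotypes are sinks")
      edges <- edges[!out_of_phen, , drop = FALSE]
    }
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "mim")
}

#' @export
print.mim <- function(x, ...) {
  n_gene <- sum(x$nodes$node_class == "gene")
  n_phen <- sum(x$nodes$node_class == "phenotype")
  cat("Molecular interaction map:", n_gene, "genes,", n_phen,
      "phenotypes,", nrow(x$edges), "signed edges\n")
  invisible(x)
}

#' Read a molecular interaction map from SIF + node attribute files
#'
#' The edge file is a headerless 3-column TSV in SIF dialect:
#' `source<TAB>interaction<TAB>target` with interaction words `activates`
#' (sign +1) or `inhibits` (sign -1). The node attribute file is a TSV with
#' header columns `id`, `label`, `node_class`, `submaps` (semicolon-joined)
#' and `phase`. Nodes appearing only in the edge file are added as
#' gene-class nodes with a warning.
#'
#' @param edge_file path to the SIF edge list.
#' @param node_attr_file path to the node attribute table.
#' @return A [mim] object.
#' @export
read_mim <- function(edge_file, node_attr_file) {
  attrs <- utils::read.delim(node_attr_file, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  need <- c("id", "label", "node_class", "submaps", "phase")
  miss <- setdiff(need, names(attrs))
  if (length(miss))
    stop("node attribute file lacks column(s): ", paste(miss, collapse = ", "))
  attrs$phase[!nzchar(attrs$phase)] <- NA_character_

  lines <- readLines(edge_file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 3L)
    if (length(bad))
      stop("malformed SIF line ", bad[1], ": expected 3 tab-separated fields")
    src <- vapply(parts, `[[`, "", 1L)
    verb <- vapply(parts, `[[`, "", 2L)
    tgt <- vapply(parts, `[[`, "", 3L)
    unknown <- !(verb %in% c("activates", "inhibits"))
    if (any(unknown))
      stop("unsupported interaction word(s) at line ",
           which(unknown)[1], ": '", verb[which(unknown)[1]],
           "' (expected 'activates' or 'inhibits')")
    edges <- data.frame(source = src, target = tgt,
                        sign = ifelse(verb == "activates", 1L, -1L))
  } else {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer())
  }
  orphan <- setdiff(c(edges$source, edges$target), attrs$id)
  if (length(orphan)) {
    warning(length(orphan),
            " node(s) present only in the edge file; added as gene-class: ",
            paste(utils::head(orphan, 5), collapse = ", "),
            if (length(orphan) > 5) ", ..." else "")
    attrs <- rbind(attrs,
                   data.frame(id = orphan, label = orphan, node_class = "gene",
                              submaps = "", phase = NA_character_))
  }
  mim(attrs, edges)
}

#' Write a molecular interaction map to SIF + node attribute files
#'
#' Inverse of [read_mim()]; `read_mim(write_mim(map))` reproduces the node
#' and edge sets exactly.
#'
#' @param map a [mim] object.
#' @param edge_file,node_attr_file output paths.
#' @return `map`, invisibly.
#' @export
write_mim <- function(map, edge_file, node_attr_file) {
  stopifnot(inherits(map, "mim"))
  verb <- ifelse(map$edges$sign == 1L, "activates", "inhibits")
  lines <- paste(map$edges$source, verb, map$edges$target, sep = "\t")
  writeLines(lines, edge_file)
  attrs <- data.frame(
    id = map$nodes$id,
    label = map$nodes$label,
    node_class = map$nodes$node_class,
    submaps = vapply(map$nodes$submaps, paste, "", collapse = ";"),
    phase = ifelse(is.na(map$nodes$phase), "", map$nodes$phase))
  utils::write.table(attrs, node_attr_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(map)
}

#' Convert a map to an igraph object
#'
#' @param map a [mim] object.
#' @return A directed `igraph` graph with vertex attributes `label`,
#'   `node_class`, `phase` and edge attribute `sign`.
#' @export
as_igraph <- function(map) {
  stopifnot(inherits(map, "mim"))
  g <- igraph::graph_from_data_frame(
    map$edges, directed = TRUE,
    vertices = data.frame(name = map$nodes$id, label = map$nodes$label,
                          node_class = map$nodes$node_class,
                          phase = ifelse(is.na(map$nodes$phase), "",
                                         map$nodes$phase)))
  g
}

#' Export a map as GraphML (e.g. for Cytoscape)
#'
#' @param map a [mim] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mim_graphml <- function(map, path) {
  igraph::write_graph(as_igraph(map), path, format = "graphml")
  invisible(path)
}

#' Gene nodes belonging to a set of submaps
#'
#' @param map a [mim] object.
#' @param submap_names character vector of submap names; genes whose submap
#'   annotation intersects this set are returned. Unknown names contribute
#'   nothing (with a warning).
#' @return Character vector of gene node ids.
#' @export
submap_genes <- function(map, submap_names) {
  stopifnot(inherits(map, "mim"), length(submap_names) >= 1)
  submap_names <- as.character(submap_names)
  known <- unique(unlist(map$nodes$submaps))
  unknown <- setdiff(submap_names, known)
  if (length(unknown))
    warning("unknown submap name(s): ", paste(unknown, collapse = ", "))
  hit <- vapply(map$nodes$submaps,
                function(s) length(intersect(s, submap_names)) > 0, TRUE)
  map$nodes$id[hit & map$nodes$node_class == "gene"]
}

# In-adjacency list: for each node id, a data.frame of incoming edges
# (source, sign). Used by BFS/DFS helpers below.
in_adjacency <- function(map) {
  split(map$edges[c("source", "sign")], factor(map$edges$target,
                                               levels = map$nodes$id))
}

out_adjacency <- function(map) {
  split(map$edges[c("target", "sign")], factor(map$edges$source,
                                               levels = map$nodes$id))
}

# Shortest admissible upstream distances: BFS over reversed edges from
# `target`, expanding only through gene-class nodes, so every counted path
# is phenotype-free apart from `target` itself. Returns a named integer
# vector of distances (in edges) for gene nodes within `max_depth`.
upstream_distances <- function(map, target, max_depth) {
  stopifnot(max_depth >= 1)
  is_gene <- stats::setNames(map$nodes$node_class == "gene", map$nodes$id)
  adj <- in_adjacency(map)
  dist <- stats::setNames(integer(0), character(0))
  frontier <- target
  d <- 0L
  seen <- target
  while (length(frontier) && d < max_depth) {
    d <- d + 1L
    nxt <- unique(unlist(lapply(adj[frontier], function(e) e$source)))
    nxt <- setdiff(nxt[!is.na(nxt)], seen)
    nxt <- nxt[is_gene[nxt]]
    if (!length(nxt)) break
    dist[nxt] <- d
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  dist
}

#' Upstream gene universe of a phenotype
#'
#' All gene nodes with a directed path to `phenotype_id` of length at most
#' `max_depth` edges that does not pass through any other phenotype node.
#'
#' @param map a [mim] object.
#' @param phenotype_id id of a phenotype-class node.
#' @param max_depth maximum path length in edges (>= 1).
#' @return Character vector of gene ids, ordered by increasing distance.
#' @export
upstream_gene_universe <- function(map, phenotype_id, max_depth) {
  stopifnot(inherits(map, "mim"))
  cls <- map$nodes$node_class[match(phenotype_id, map$nodes$id)]
  if (is.na(cls) || cls != "phenotype")
    stop("'", phenotype_id, "' is not a phenotype node")
  names(sort(upstream_distances(map, phenotype_id, max_depth)))
}

#' Phenotype ids of a map
#' @param map a [mim] object.
#' @return Character vector of phenotype node ids.
#' @export
phenotype_ids <- function(map) {
  map$nodes$id[map$nodes$node_class == "phenotype"]
}

#' Gene ids of a map
#' @param map a [mim] object.
#' @return Character vector of gene node ids.
#' @export
gene_ids <- function(map) {
  map$nodes$id[map$nodes$node_class == "gene"]
}

#' Phase annotation of phenotype nodes
#' @param map a [mim] object.
#' @return data.frame with columns `phenotype` and `phase` (`"unassigned"`
#'   where no phase is recorded).
#' @export
phase_annotation <- function(map) {
  keep <- map$nodes$node_class == "phenotype"
  data.frame(phenotype = map$nodes$id[keep],
             phase = ifelse(is.na(map$nodes$phase[keep]), "unassigned",
                            map$nodes$phase[keep]))
}
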