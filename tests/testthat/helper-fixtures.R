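# Fixture builders and independent oracles used across the suite.

# Minimal map: gene chain/branches feeding one phenotype.
fixture_nodes <- function(ids, classes, submaps = NULL, phases = NULL) {
  data.frame(id = ids, label = ids, node_class = classes,
             submaps = if (is.null(submaps)) I(rep(list(character()),
                                                   length(ids)))
               else I(submaps),
             phase = if (is.null(phases)) NA_character_ else phases)
}

fixture_edges <- function(...) {
  rows <- list(...)
  data.frame(source = vapply(rows, `[[`, "", 1),
             target = vapply(rows, `[[`, "", 2),
             sign = as.integer(vapply(rows, `[[`, "", 3)))
}

# Random signed digraph with `n_genes` genes and one phenotype sink that a
# random gene subset feeds into.
random_mim <- function(n_genes, p_edge, seed) {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(n_genes))
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
  pairs$sign <- ifelse(runif(nrow(pairs)) < 0.4, -1L, 1L)
  feeders <- sample(genes, max(1, round(n_genes / 3)))
  edges <- rbind(pairs,
                 data.frame(source = feeders, target = "PH",
                            sign = sample(c(-1L, 1L), length(feeders),
                                          replace = TRUE)))
  mim(fixture_nodes(c(genes, "PH"), c(rep("gene", n_genes), "phenotype")),
      edges)
}

# Oracle for the influence score: exhaustive simple-path enumeration via
# igraph on the subgraph of gene nodes plus the target phenotype, summing
# sign-product * alpha^(len - 1). Independent of the package's DFS.
oracle_influence <- function(map, gene_id, phenotype_id, alpha, max_depth) {
  keep <- map$nodes$id[map$nodes$node_class == "gene"]
  keep <- union(keep, phenotype_id)
  e <- map$edges[map$edges$source %in% keep & map$edges$target %in% keep, ]
  g <- igraph::graph_from_data_frame(
    e, directed = TRUE, vertices = data.frame(name = keep))
  if (!(gene_id %in% keep)) return(0)
  paths <- igraph::all_simple_paths(g, from = gene_id, to = phenotype_id,
                                    mode = "out", cutoff = max_depth)
  if (!length(paths)) return(0)
  sum(vapply(paths, function(p) {
    ids <- names(p)
    len <- length(ids) - 1
    s <- 1
    for (k in seq_len(len)) {
      s <- s * e$sign[e$source == ids[k] & e$target == ids[k + 1]]
    }
    s * alpha^(len - 1)
  }, 0))
}

# Oracle for triplet feedback loops: brute force over ordered node triples.
oracle_3cycles <- function(map, universe) {
  e <- map$edges[map$edges$source %in% universe &
                   map$edges$target %in% universe &
                   map$edges$source != map$edges$target, ]
  has <- function(a, b) any(e$source == a & e$target == b)
  found <- character()
  for (a in universe) for (b in universe) for (cc in universe) {
    if (a == b || b == cc || a == cc) next
    if (a != min(a, b, cc)) next
    if (has(a, b) && has(b, cc) && has(cc, a))
      found <- c(found, paste(a, b, cc, sep = ">"))
  }
  sort(found)
}

# Small DE table builder.
deg_rows <- function(contrast, time_h, gene, log2FC, padj,
                     base_mean = 100) {
  data.frame(contrast = contrast, time_h = time_h, gene = gene,
             log2FC = log2FC, padj = padj, base_mean = base_mean)
}
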