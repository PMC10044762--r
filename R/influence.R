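#' Propagation parameters
#'
#' Parameters of the attenuated signed-path propagation used for influence
#' and upstream-enrichment scores. `alpha` is the per-step attenuation
#' applied beyond the first edge of a path; `max_depth` caps path length.
#'
#' @param alpha attenuation factor in (0, 1]; default 0.5.
#' @param max_depth maximum path length in edges (>= 1); default 5.
#' @return A list of class `influence_params`.
#' @export
influence_params <- function(alpha = 0.5, max_depth = 5L) {
  stopifnot(alpha > 0, alpha <= 1, max_depth >= 1)
  structure(list(alpha = alpha, max_depth = as.integer(max_depth)),
            class = "influence_params")
}

#' Signed influence of a gene on a phenotype
#'
#' Sum over simple directed paths `q` from `gene_id` to `phenotype_id` of
#' length at most `max_depth` edges, not passing through any other phenotype
#' node, of `sgn(q) * alpha^(len(q) - 1)`, where `sgn(q)` is the product of
#' edge signs along the path. A direct edge contributes exactly its sign;
#' no path gives 0.
#'
#' @param map a [mim] object.
#' @param gene_id,phenotype_id node ids.
#' @param params an [influence_params()] object.
#' @return A single numeric influence score.
#' @export
influence_score <- function(map, gene_id, phenotype_id,
                            params = influence_params()) {
  stopifnot(inherits(map, "mim"))
  if (!(gene_id %in% map$nodes$id)) stop("unknown gene id: ", gene_id)
  if (!(phenotype_id %in% map$nodes$id))
    stop("unknown phenotype id: ", phenotype_id)
  is_gene <- setNames(map$nodes$node_class == "gene", map$nodes$id)
  adj <- out_adjacency(map)
  alpha <- params$alpha
  max_depth <- params$max_depth
  total <- 0
  # Forward depth-first enumeration of simple paths; intermediates must be
  # gene-class so phenotype nodes never act as conduits.
  visit <- function(v, depth, signprod, visited) {
    e <- adj[[v]]
    if (is.null(e) || nrow(e) == 0) return()
    for (k in seq_len(nrow(e))) {
      t <- e$target[k]
      s <- signprod * e$sign[k]
      if (t == phenotype_id) {
        total <<- total + s * alpha^depth
      } else if (depth + 1L < max_depth && is_gene[t] && !(t %in% visited)) {
        visit(t, depth + 1L, s, c(visited, t))
      }
    }
  }
  visit(gene_id, 0L, 1, gene_id)
  total
}

#' Influence matrix over phenotype upstream universes
#'
#' Computes the signed influence score of every upstream gene on every
#' requested phenotype by a single backward depth-first traversal per
#' phenotype: each simple reverse path of `d` edges from the phenotype to a
#' gene contributes `sign-product * alpha^(d-1)` to that gene's entry.
#' Genes outside a phenotype's upstream universe get an exact 0.
#'
#' @param map a [mim] object.
#' @param phenotypes phenotype ids; default all phenotype nodes.
#' @param params an [influence_params()] object.
#' @return An object of class `influence_matrix`: a list with `I` (gene x
#'   phenotype numeric matrix over all gene nodes) and `params`.
#' @export
influence_matrix <- function(map, phenotypes = NULL,
                             params = influence_params()) {
  stopifnot(inherits(map, "mim"))
  if (is.null(phenotypes)) phenotypes <- phenotype_ids(map)
  cls <- map$nodes$node_class[match(phenotypes, map$nodes$id)]
  if (any(is.na(cls) | cls != "phenotype"))
    stop("non-phenotype id(s): ",
         paste(phenotypes[is.na(cls) | cls != "phenotype"], collapse = ", "))
  genes <- gene_ids(map)
  I <- matrix(0, nrow = length(genes), ncol = length(phenotypes),
              dimnames = list(genes, phenotypes))
  is_gene <- setNames(map$nodes$node_class == "gene", map$nodes$id)
  adj <- in_adjacency(map)
  alpha <- params$alpha
  max_depth <- params$max_depth
  for (p in phenotypes) {
    col <- setNames(numeric(length(genes)), genes)
    visit <- function(v, depth, signprod, visited) {
      e <- adj[[v]]
      if (is.null(e) || nrow(e) == 0) return()
      for (k in seq_len(nrow(e))) {
        s0 <- e$source[k]
        if (!is_gene[s0] || s0 %in% visited) next
        contrib <- signprod * e$sign[k]
        col[s0] <<- col[s0] + contrib * alpha^depth
        if (depth + 1L < max_depth)
          visit(s0, depth + 1L, contrib, c(visited, s0))
      }
    }
    visit(p, 0L, 1, p)
    I[, p] <- col
  }
  structure(list(I = I, params = params), class = "influence_matrix")
}

#' @export
print.influence_matrix <- function(x, ...) {
  nz <- sum(x$I != 0)
  cat("Influence matrix:", nrow(x$I), "genes x", ncol(x$I),
      "phenotypes;", nz, "nonzero entries (alpha =", x$params$alpha,
      ", max_depth =", x$params$max_depth, ")\n")
  invisible(x)
}

#' Upstream enrichment score of a gene
#'
#' Attenuated average of significant upstream genes' absolute fold changes:
#' `ES(i) = sum_g |log2FC_g| * alpha^(d(g,i) - 1) / |U_D(i)|` over upstream
#' genes `g` with `padj < tau`, where `d(g, i)` is the shortest
#' phenotype-free path length from `g` to `i` and `U_D(i)` the upstream gene
#' universe of `i` within `max_depth`. Returns 0 when the universe is empty.
#' The score depends on `|log2FC|` only, never on its sign.
#'
#' @param map a [mim] object.
#' @param gene_id a gene node id.
#' @param deg_at_time data.frame with columns `gene`, `log2FC`, `padj` for
#'   one contrast and time point.
#' @param params an [influence_params()] object.
#' @param tau adjusted-p significance threshold; default 0.05.
#' @return A single numeric enrichment score.
#' @export
upstream_enrichment <- function(map, gene_id, deg_at_time,
                                params = influence_params(), tau = 0.05) {
  stopifnot(inherits(map, "mim"))
  if (!(gene_id %in% map$nodes$id)) stop("unknown gene id: ", gene_id)
  dist <- upstream_distances(map, gene_id, params$max_depth)
  if (!length(dist)) return(0)
  sig <- deg_at_time[!is.na(deg_at_time$padj) & deg_at_time$padj < tau, ,
                     drop = FALSE]
  if (!nrow(sig)) return(0)
  idx <- match(norm_sym(names(dist)), norm_sym(sig$gene))
  hit <- !is.na(idx)
  if (!any(hit)) return(0)
  sum(abs(sig$log2FC[idx[hit]]) * params$alpha^(dist[hit] - 1)) / length(dist)
}

#' Upstream enrichment scores for several genes
#'
#' Vectorized wrapper around [upstream_enrichment()].
#'
#' @inheritParams upstream_enrichment
#' @param gene_ids character vector of gene node ids.
#' @return Named numeric vector of enrichment scores.
#' @export
enrichment_scores <- function(map, gene_ids, deg_at_time,
                              params = influence_params(), tau = 0.05) {
  vapply(gene_ids, upstream_enrichment, 0, map = map,
         deg_at_time = deg_at_time, params = params, tau = tau)
}

#' Export an influence matrix as a long-format table
#'
#' @param infl an [influence_matrix()] object.
#' @param drop_zero drop zero entries; default TRUE.
#' @return data.frame with columns `gene`, `phenotype`, `influence`.
#' @export
influence_table <- function(infl, drop_zero = TRUE) {
  stopifnot(inherits(infl, "influence_matrix"))
  df <- data.frame(gene = rep(rownames(infl$I), ncol(infl$I)),
                   phenotype = rep(colnames(infl$I), each = nrow(infl$I)),
                   influence = as.vector(infl$I))
  if (drop_zero) df <- df[df$influence != 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}
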