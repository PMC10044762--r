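#' Enumerate gene-triplet feedback loops upstream of a phenotype
#'
#' Finds every directed simple 3-cycle among the genes of
#' `upstream_gene_universe(phenotype_id, max_depth)`. The two orientations
#' of a triangle (a->b->c->a and a->c->b->a) are distinct edge sets and
#' reported as distinct motifs; self-loops never participate. Each motif
#' carries three raw features: `F_I`, the summed influence of its members
#' on the phenotype; `F_ES`, the summed upstream enrichment scores; and
#' `F_FC`, the summed |log2FC| of its members (missing genes contribute 0).
#' When `max_candidates` is set, motifs are kept in descending `F_I` order
#' (ties broken by the lexicographic node-id key) up to the cap.
#'
#' @param map a [mim] object.
#' @param phenotype_id target phenotype node id.
#' @param infl an [influence_matrix()] covering `phenotype_id`.
#' @param deg_at_time data.frame (`gene`, `log2FC`, `padj`) for the
#'   analysis time point; NULL sets `F_ES` and `F_FC` to 0.
#' @param params an [influence_params()] object (depth for the universe).
#' @param tau adjusted-p threshold for the enrichment term; default 0.05.
#' @param max_candidates optional cap on the candidate population.
#' @return An object of class `motif_set`: data.frame with columns
#'   `motif_id`, `n1`, `n2`, `n3` (cycle order), `F_I`, `F_ES`, `F_FC`,
#'   carrying the motif edge list as attribute `edges`.
#' @export
enumerate_motifs <- function(map, phenotype_id, infl, deg_at_time = NULL,
                             params = influence_params(), tau = 0.05,
                             max_candidates = NULL) {
  stopifnot(inherits(map, "mim"), inherits(infl, "influence_matrix"))
  universe <- upstream_gene_universe(map, phenotype_id, params$max_depth)
  empty <- data.frame(motif_id = character(), n1 = character(),
                      n2 = character(), n3 = character(),
                      F_I = numeric(), F_ES = numeric(), F_FC = numeric())
  if (length(universe) < 3)
    return(structure(empty, class = c("motif_set", "data.frame"),
                     phenotype = phenotype_id))
  e <- map$edges[map$edges$source %in% universe &
                   map$edges$target %in% universe &
                   map$edges$source != map$edges$target, , drop = FALSE]
  if (!nrow(e))
    return(structure(empty, class = c("motif_set", "data.frame"),
                     phenotype = phenotype_id))
  # adjacency lookup among universe genes
  adj <- split(e$target, factor(e$source, levels = universe))
  has_edge <- function(a, b) b %in% adj[[a]]
  motifs <- list()
  for (i in seq_len(nrow(e))) {
    a <- e$source[i]; b <- e$target[i]
    for (cc in adj[[b]]) {
      if (cc == a) next
      if (has_edge(cc, a) && a == min(a, b, cc)) {
        # canonical start = lexicographically smallest node; counts each
        # directed cycle's edge set exactly once
        motifs[[length(motifs) + 1L]] <- c(a, b, cc)
      }
    }
  }
  if (!length(motifs))
    return(structure(empty, class = c("motif_set", "data.frame"),
                     phenotype = phenotype_id))
  n1 <- vapply(motifs, `[[`, "", 1L)
  n2 <- vapply(motifs, `[[`, "", 2L)
  n3 <- vapply(motifs, `[[`, "", 3L)
  motif_id <- paste(n1, n2, n3, sep = ">")

  Icol <- infl$I[, phenotype_id]
  F_I <- Icol[n1] + Icol[n2] + Icol[n3]
  if (!is.null(deg_at_time)) {
    genes <- unique(c(n1, n2, n3))
    es <- enrichment_scores(map, genes, deg_at_time, params, tau)
    fc <- setNames(rep(0, length(genes)), genes)
    idx <- match(norm_sym(genes), norm_sym(deg_at_time$gene))
    fc[!is.na(idx)] <- abs(deg_at_time$log2FC[idx[!is.na(idx)]])
    F_ES <- es[n1] + es[n2] + es[n3]
    F_FC <- fc[n1] + fc[n2] + fc[n3]
  } else {
    F_ES <- F_FC <- rep(0, length(motifs))
  }
  out <- data.frame(motif_id = motif_id, n1 = n1, n2 = n2, n3 = n3,
                    F_I = unname(F_I), F_ES = unname(F_ES),
                    F_FC = unname(F_FC))
  ord <- order(-out$F_I, out$motif_id)
  out <- out[ord, , drop = FALSE]
  if (!is.null(max_candidates) && nrow(out) > max_candidates)
    out <- out[seq_len(max_candidates), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("motif_set", "data.frame"),
            phenotype = phenotype_id)
}

# Edge list (source, target, sign) of one motif row's 3-cycle.
motif_edges <- function(map, n1, n2, n3) {
  want <- rbind(c(n1, n2), c(n2, n3), c(n3, n1))
  idx <- match(paste(want[, 1], want[, 2]),
               paste(map$edges$source, map$edges$target))
  map$edges[idx, , drop = FALSE]
}

#' Min-max normalize motif features
#'
#' Each feature is scaled to [0, 1] by min-max over the candidate motif
#' population; a feature constant across the population maps to 0.5 for
#' every motif by convention. Adds columns `f_I`, `f_ES`, `f_FC`.
#'
#' @param motifs a [enumerate_motifs()] result with >= 1 motif.
#' @return The motif set with normalized feature columns appended.
#' @export
normalize_features <- function(motifs) {
  if (!nrow(motifs)) stop("cannot normalize an empty motif set")
  mm <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) rep(0.5, length(x)) else (x - r[1]) / (r[2] - r[1])
  }
  motifs$f_I <- mm(motifs$F_I)
  motifs$f_ES <- mm(motifs$F_ES)
  motifs$f_FC <- mm(motifs$F_FC)
  motifs
}

#' The 27 weighting scenarios
#'
#' Full grid of weight triples `(w1, w2, w3)` with each weight in
#' {0.33, 0.66, 1.0}.
#'
#' @return data.frame with columns `w1`, `w2`, `w3` (27 rows).
#' @export
weight_scenarios <- function() {
  w <- c(0.33, 0.66, 1.0)
  g <- expand.grid(w1 = w, w2 = w, w3 = w, KEEP.OUT.ATTRS = FALSE)
  g[order(g$w1, g$w2, g$w3), , drop = FALSE]
}

#' Score motifs under one weighting scenario
#'
#' Weighted sum of the normalized features:
#' `S = w1 * f_I + w2 * f_ES + w3 * f_FC`.
#'
#' @param motifs a [normalize_features()] result.
#' @param weights numeric length-3 vector `(w1, w2, w3)`.
#' @return Numeric vector of scores, one per motif.
#' @export
score_motifs <- function(motifs, weights) {
  stopifnot(length(weights) == 3,
            all(c("f_I", "f_ES", "f_FC") %in% names(motifs)))
  weights[1] * motifs$f_I + weights[2] * motifs$f_ES + weights[3] * motifs$f_FC
}

#' @rdname score_motifs
#' @param features numeric length-3 vector of normalized features for a
#'   single motif.
#' @return `score_motif`: a single numeric score.
#' @export
score_motif <- function(features, weights) {
  stopifnot(length(features) == 3, length(weights) == 3)
  sum(weights * features)
}

#' Pareto selection of top motifs across weighting scenarios
#'
#' For each of the 27 weighting scenarios, the `top_m` motifs by score are
#' taken (ties broken deterministically by the lexicographic motif id);
#' the selection is the union over scenarios. A motif that excels under at
#' least one feature weighting therefore survives, yielding a Pareto-style
#' set of non-dominated high-feature motifs.
#'
#' @param motifs a [normalize_features()] result.
#' @param top_m motifs kept per scenario; default 5. Fewer motifs than
#'   `top_m` selects all.
#' @return The selected subset of `motifs`, with columns `best_S` (highest
#'   score across scenarios) and `n_scenarios` (scenarios selecting it),
#'   ordered by descending `best_S`.
#' @export
pareto_select <- function(motifs, top_m = 5) {
  stopifnot(nrow(motifs) >= 1)
  sc <- weight_scenarios()
  sel <- character()
  best <- setNames(rep(-Inf, nrow(motifs)), motifs$motif_id)
  hits <- setNames(integer(nrow(motifs)), motifs$motif_id)
  for (j in seq_len(nrow(sc))) {
    S <- score_motifs(motifs, unlist(sc[j, ]))
    best <- pmax(best, setNames(S, motifs$motif_id))
    ord <- order(-S, motifs$motif_id)
    take <- ord[seq_len(min(top_m, length(ord)))]
    ids <- motifs$motif_id[take]
    hits[ids] <- hits[ids] + 1L
    sel <- union(sel, ids)
  }
  out <- motifs[motifs$motif_id %in% sel, , drop = FALSE]
  out$best_S <- unname(best[out$motif_id])
  out$n_scenarios <- unname(hits[out$motif_id])
  out <- out[order(-out$best_S, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge selected motifs into a core regulatory network
#'
#' Union of the selected motifs' nodes and 3-cycle edges, with each node
#' annotated `up`, `down` or `none` from the overlay's significant log2FC
#' at the analysis time point.
#'
#' @param map a [mim] object.
#' @param selected a [pareto_select()] result (non-empty).
#' @param phenotype_id the phenotype the CRN explains.
#' @param ov an [overlay()] result; annotation uses the overlay rows at
#'   `time_h` (default: all rows).
#' @param time_h optional time point for the annotation.
#' @return An object of class `crn`: list with `phenotype`, `nodes`
#'   (data.frame `id`, `direction`), `edges` (data.frame `source`,
#'   `target`, `sign`) and the selected `motifs`.
#' @export
build_crn <- function(map, selected, phenotype_id, ov, time_h = NULL) {
  if (!nrow(selected))
    stop("empty motif selection; relax max_candidates or top_m")
  nodes <- unique(c(selected$n1, selected$n2, selected$n3))
  edges <- unique(do.call(rbind, lapply(seq_len(nrow(selected)), function(i)
    motif_edges(map, selected$n1[i], selected$n2[i], selected$n3[i]))))
  rownames(edges) <- NULL
  ann <- ov
  if (!is.null(time_h)) ann <- ann[ann$time_h == time_h, , drop = FALSE]
  idx <- match(norm_sym(nodes), norm_sym(ann$gene))
  direction <- rep("none", length(nodes))
  hit <- !is.na(idx)
  direction[hit] <- ifelse(ann$log2FC[idx[hit]] > 0, "up", "down")
  structure(list(phenotype = phenotype_id,
                 nodes = data.frame(id = nodes, direction = direction),
                 edges = edges,
                 motifs = selected),
            class = "crn")
}

#' @export
print.crn <- function(x, ...) {
  cat("Core regulatory network for phenotype '", x$phenotype, "': ",
      nrow(x$nodes), " genes, ", nrow(x$edges), " edges from ",
      nrow(x$motifs), " motifs\n", sep = "")
  invisible(x)
}

#' Export a core regulatory network as GraphML
#'
#' @param crn a [build_crn()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crn_graphml <- function(crn, path) {
  g <- igraph::graph_from_data_frame(
    crn$edges, directed = TRUE,
    vertices = data.frame(name = crn$nodes$id,
                          direction = crn$nodes$direction))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' One-call CRN extraction for a phenotype
#'
#' Convenience wrapper: enumerate motifs, normalize features, Pareto-select
#' and merge, for one contrast and time point.
#'
#' @inheritParams enumerate_motifs
#' @param ov an [overlay()] result for the contrast.
#' @param time_h analysis time point.
#' @param top_m motifs per scenario; default 5.
#' @return A `crn` object, or NULL (with a message) when no feedback loop
#'   exists upstream of the phenotype.
#' @export
extract_crn <- function(map, phenotype_id, infl, ov, time_h,
                        params = influence_params(), tau = 0.05,
                        top_m = 5, max_candidates = 20000) {
  meas <- attr(ov, "measured")
  deg_at_time <- meas[meas$time_h == time_h, , drop = FALSE]
  motifs <- enumerate_motifs(map, phenotype_id, infl, deg_at_time,
                             params = params, tau = tau,
                             max_candidates = max_candidates)
  if (!nrow(motifs)) {
    message("no gene-triplet feedback loops upstream of '", phenotype_id, "'")
    return(NULL)
  }
  selected <- pareto_select(normalize_features(motifs), top_m = top_m)
  build_crn(map, selected, phenotype_id, ov, time_h = time_h)
}
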