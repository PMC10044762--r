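#' Overlay a DE table onto a molecular interaction map
#'
#' Per time point, genes significant at `padj < tau` are intersected with
#' the map's gene nodes (case-insensitive symbol matching after trimming);
#' optionally the map side is restricted to a set of submaps. The count of
#' significant genes not found in the map is recorded per time point, and
#' the full set of measured mapped genes (any padj) is kept alongside for
#' permutation nulls.
#'
#' @param map a [mim] object.
#' @param deg long-format DE table (`contrast`, `time_h`, `gene`, `log2FC`,
#'   `padj`).
#' @param contrast contrast label to overlay.
#' @param tau adjusted-p threshold; default 0.05.
#' @param submap_filter optional character vector of submap names passed to
#'   [submap_genes()].
#' @return An object of class `overlay_set`: a data.frame (`contrast`,
#'   `time_h`, `gene` (map id), `log2FC`, `padj`) of significant mapped
#'   genes, with attributes `unmapped` (per-time counts of significant
#'   genes absent from the map) and `measured` (all measured mapped genes).
#' @export
overlay <- function(map, deg, contrast, tau = 0.05, submap_filter = NULL) {
  stopifnot(inherits(map, "mim"))
  d <- deg[deg$contrast == contrast & !is.na(deg$log2FC), , drop = FALSE]
  if (!nrow(d)) stop("no time points in DE table for contrast '", contrast, "'")
  universe <- if (is.null(submap_filter)) gene_ids(map)
              else submap_genes(map, submap_filter)
  idx <- match(norm_sym(d$gene), norm_sym(universe))
  mapped <- !is.na(idx)
  sig <- !is.na(d$padj) & d$padj < tau

  meas <- data.frame(contrast = d$contrast[mapped], time_h = d$time_h[mapped],
                     gene = universe[idx[mapped]],
                     log2FC = d$log2FC[mapped], padj = d$padj[mapped])
  res <- data.frame(contrast = d$contrast[mapped & sig],
                    time_h = d$time_h[mapped & sig],
                    gene = universe[idx[mapped & sig]],
                    log2FC = d$log2FC[mapped & sig],
                    padj = d$padj[mapped & sig])
  unmapped <- tapply(!mapped & sig, d$time_h, sum)
  n_un <- sum(!mapped & sig)
  if (n_un > 0)
    message(n_un, " significant gene record(s) not matched to map genes")
  rownames(res) <- NULL
  structure(res, class = c("overlay_set", "data.frame"),
            unmapped = unmapped, measured = meas, tau = tau)
}

#' Unique / common / opposite-direction split of two overlays
#'
#' A gene is unique to contrast A when it is significant at any time point
#' in A and at none in B; common when significant in both (not necessarily
#' at the same time). A common gene is in the opposite-direction subset
#' when at some shared time point both contrasts are significant with
#' opposite log2FC signs, or — when no significant time point is shared —
#' when the two contrasts' maximum-|log2FC| significant estimates disagree
#' in sign.
#'
#' @param overlays_A,overlays_B [overlay()] results from the same map.
#' @return An object of class `venn_split`: list with character-vector
#'   elements `unique_A`, `unique_B`, `common`, `opposite` and counts.
#' @export
venn_split <- function(overlays_A, overlays_B) {
  if (!nrow(overlays_A) && !nrow(overlays_B))
    warning("both overlays are empty")
  genes_A <- unique(overlays_A$gene)
  genes_B <- unique(overlays_B$gene)
  common <- intersect(genes_A, genes_B)
  opposite <- character()
  for (g in common) {
    a <- overlays_A[overlays_A$gene == g, , drop = FALSE]
    b <- overlays_B[overlays_B$gene == g, , drop = FALSE]
    shared <- intersect(a$time_h, b$time_h)
    if (length(shared)) {
      sa <- sign(a$log2FC[match(shared, a$time_h)])
      sb <- sign(b$log2FC[match(shared, b$time_h)])
      if (any(sa != sb)) opposite <- c(opposite, g)
    } else {
      sa <- sign(a$log2FC[which.max(abs(a$log2FC))])
      sb <- sign(b$log2FC[which.max(abs(b$log2FC))])
      if (sa != sb) opposite <- c(opposite, g)
    }
  }
  structure(list(unique_A = sort(setdiff(genes_A, genes_B)),
                 unique_B = sort(setdiff(genes_B, genes_A)),
                 common = sort(common),
                 opposite = sort(opposite)),
            class = "venn_split")
}

#' @export
print.venn_split <- function(x, ...) {
  cat("Venn split: unique_A =", length(x$unique_A),
      "| unique_B =", length(x$unique_B),
      "| common =", length(x$common),
      "| opposite =", length(x$opposite),
      sprintf("(%.1f%% of common)\n", opposite_fraction(x)))
  invisible(x)
}

#' Fraction of common DEGs regulated in opposite directions
#'
#' @param x a `venn_split` object, or the number of common genes when
#'   `opposite` is given as a count.
#' @param opposite number of opposite-direction genes (when `x` is the
#'   common count).
#' @return Percentage (0-100) of common genes in the opposite subset; 0
#'   when there are no common genes.
#' @examples
#' opposite_fraction(148, 62)  # 41.89189
#' @export
opposite_fraction <- function(x, opposite = NULL) {
  if (inherits(x, "venn_split")) {
    n_common <- length(x$common)
    n_opp <- length(x$opposite)
  } else {
    stopifnot(is.numeric(x), is.numeric(opposite), opposite <= x)
    n_common <- x
    n_opp <- opposite
  }
  if (n_common == 0) return(0)
  100 * n_opp / n_common
}

#' Write a Venn split summary as JSON
#'
#' @param vs a `venn_split` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_venn_json <- function(vs, path) {
  stopifnot(inherits(vs, "venn_split"))
  obj <- list(
    counts = list(unique_A = length(vs$unique_A),
                  unique_B = length(vs$unique_B),
                  common = length(vs$common),
                  opposite = length(vs$opposite),
                  opposite_pct_of_common = opposite_fraction(vs)),
    genes = list(unique_A = vs$unique_A, unique_B = vs$unique_B,
                 common = vs$common, opposite = vs$opposite),
    opposite_rule = "shared-significant-time sign conflict, else sign of max-|log2FC| significant estimate")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Late-induction filter on base mean counts
#'
#' Genes significant and upregulated at the focal time point whose
#' `base_mean` at that time strictly exceeds its `base_mean` at every
#' earlier measured time point. Distinguishes genuine late induction from
#' fold changes driven by dropping control expression. Genes missing a
#' `base_mean` at an earlier time point are excluded with a warning.
#'
#' @param deg long-format DE table including `base_mean`.
#' @param contrast contrast label.
#' @param focal_time focal time in hours; default 120.
#' @param tau adjusted-p threshold; default 0.05.
#' @return Character vector of gene ids passing the filter.
#' @export
induction_filter <- function(deg, contrast, focal_time = 120, tau = 0.05) {
  d <- deg[deg$contrast == contrast, , drop = FALSE]
  times <- sort(unique(d$time_h))
  if (!(focal_time %in% times)) stop("focal time ", focal_time, " not present")
  earlier <- times[times < focal_time]
  if (!length(earlier)) stop("no time point earlier than ", focal_time)
  focal <- d[d$time_h == focal_time & !is.na(d$padj) &
               d$padj < tau & d$log2FC > 0, , drop = FALSE]
  keep <- character()
  dropped <- 0L
  for (i in seq_len(nrow(focal))) {
    g <- focal$gene[i]
    bm <- d$base_mean[d$time_h %in% earlier & d$gene == g]
    if (length(bm) < length(earlier) || anyNA(bm)) {
      dropped <- dropped + 1L
      next
    }
    if (all(focal$base_mean[i] > bm)) keep <- c(keep, g)
  }
  if (dropped > 0)
    warning(dropped, " gene(s) lacked base_mean at earlier time point(s); excluded")
  sort(keep)
}
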