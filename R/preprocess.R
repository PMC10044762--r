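#' Median-of-ratios size factors
#'
#' Library-size normalization factors via the median-of-ratios estimator:
#' for each sample j, the factor is the median over genes g of
#' `count[g, j] / geometric_mean_over_samples(count[g, ])`, computed over
#' genes with strictly positive counts in every sample.
#'
#' @param counts non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param pseudocount value added to all counts before estimation; default
#'   0. Set a small positive value when no gene is positive in all samples.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts) + pseudocount
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has positive counts in every sample; ",
         "consider the 'pseudocount' fallback argument")
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  apply(logc, 2, function(x) exp(median(x - loggeo)))
}

#' Normalize a count matrix by size factors
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample size factors; default [size_factors()].
#' @return Matrix of normalized counts (`counts[, j] / factors[j]`).
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(factors), all(factors > 0))
  sweep(counts, 2, factors, "/")
}

#' PCA-based outlier screening of RNA-seq samples
#'
#' Within each (contrast, group, time) stratum: counts are normalized,
#' log2(x + 1) transformed, gene-centered, and projected onto the top two
#' principal components. A sample is flagged when its Euclidean distance
#' from the stratum centroid in the PC1-PC2 plane exceeds
#' `median + threshold_mads * MAD` of the stratum's distances. Strata with
#' fewer than 4 samples are skipped with a warning.
#'
#' @param counts genes x samples count matrix.
#' @param metadata data.frame with columns `sample`, `contrast`, `group`,
#'   `time_h`, `replicate`; every column of `counts` must appear in
#'   `metadata$sample`.
#' @param threshold_mads MAD multiplier for the flag threshold; default 3.
#' @return data.frame with columns `sample`, `contrast`, `group`, `time_h`,
#'   `distance`, `flagged`; one row per screened sample.
#' @export
pca_outliers <- function(counts, metadata, threshold_mads = 3) {
  counts <- as.matrix(counts)
  stopifnot(all(colnames(counts) %in% metadata$sample))
  norm <- normalize_counts(counts, size_factors(counts, pseudocount =
    if (any(rowSums(counts > 0) == ncol(counts))) 0 else 0.5))
  lg <- log2(norm + 1)
  md <- metadata[match(colnames(counts), metadata$sample), , drop = FALSE]
  strata <- interaction(md$contrast, md$group, md$time_h, drop = TRUE)
  out <- NULL
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 4) {
      warning("stratum '", s, "' has fewer than 4 samples; skipped")
      next
    }
    x <- lg[, idx, drop = FALSE]
    x <- x[apply(x, 1, sd) > 0, , drop = FALSE]
    # samples as observations, genes as (centered) variables
    pc <- prcomp(t(x), center = TRUE, scale. = FALSE, rank. = 2)
    sc <- pc$x
    if (ncol(sc) < 2) sc <- cbind(sc, 0)
    ctr <- colMeans(sc)
    d <- sqrt(rowSums(sweep(sc, 2, ctr)^2))
    cut <- median(d) + threshold_mads * mad(d)
    out <- rbind(out, data.frame(
      sample = colnames(counts)[idx],
      contrast = md$contrast[idx], group = md$group[idx],
      time_h = md$time_h[idx],
      distance = unname(d), flagged = unname(d > cut)))
  }
  if (is.null(out))
    out <- data.frame(sample = character(), contrast = character(),
                      group = character(), time_h = numeric(),
                      distance = numeric(), flagged = logical())
  rownames(out) <- NULL
  out
}

#' Simple differential expression stand-in
#'
#' A deliberately simple two-group test used when externally computed DE
#' tables (e.g. from a negative-binomial GLM pipeline) are not supplied:
#' log2 fold change is the difference of group means of
#' `log2(normalized + 0.5)`, the p-value comes from a Welch t-test on the
#' same values, and adjustment is Benjamini-Hochberg across genes within
#' the (contrast, time) stratum. `base_mean` is the mean normalized count
#' across both groups' samples at that time. Genes with identical values in
#' both groups (including all-zero genes) get p = 1 by convention.
#'
#' @param counts genes x samples count matrix.
#' @param metadata sample metadata as in [pca_outliers()].
#' @param contrast contrast label selecting samples.
#' @param time_h time point in hours; both groups need >= 2 samples.
#' @param exclude_samples sample ids to drop (e.g. flagged outliers).
#' @return data.frame with columns `contrast`, `time_h`, `gene`, `log2FC`
#'   (treatment minus control), `padj`, `base_mean`.
#' @export
simple_de <- function(counts, metadata, contrast, time_h,
                      exclude_samples = character()) {
  counts <- as.matrix(counts)
  md <- metadata[metadata$contrast == contrast &
                   metadata$time_h == time_h &
                   !(metadata$sample %in% exclude_samples), , drop = FALSE]
  trt <- md$sample[md$group == "treatment"]
  ctl <- md$sample[md$group == "control"]
  if (length(trt) < 2 || length(ctl) < 2)
    stop("need >= 2 samples per group at time ", time_h,
         " for contrast '", contrast, "'")
  keep <- c(trt, ctl)
  sub <- counts[, keep, drop = FALSE]
  norm <- normalize_counts(sub, size_factors(sub, pseudocount =
    if (any(rowSums(sub > 0) == ncol(sub))) 0 else 0.5))
  lg <- log2(norm + 0.5)
  a <- lg[, trt, drop = FALSE]
  b <- lg[, ctl, drop = FALSE]
  log2fc <- rowMeans(a) - rowMeans(b)
  p <- vapply(seq_len(nrow(lg)), function(i) {
    xi <- a[i, ]; yi <- b[i, ]
    if (sd(c(xi, yi)) == 0 || (sd(xi) == 0 && sd(yi) == 0)) return(1)
    t.test(xi, yi)$p.value
  }, 0)
  data.frame(contrast = contrast, time_h = time_h,
             gene = rownames(counts),
             log2FC = unname(log2fc),
             padj = p.adjust(p, method = "BH"),
             base_mean = unname(rowMeans(norm)),
             row.names = NULL)
}

#' Differential expression across all time points of a contrast
#'
#' Runs [simple_de()] at every time point of `contrast` present in
#' `metadata` and binds the results into one long DE table.
#'
#' @inheritParams simple_de
#' @return Long-format data.frame (one row per gene and time point).
#' @export
simple_de_all <- function(counts, metadata, contrast,
                          exclude_samples = character()) {
  times <- sort(unique(metadata$time_h[metadata$contrast == contrast]))
  if (!length(times)) stop("no samples for contrast '", contrast, "'")
  do.call(rbind, lapply(times, function(t)
    simple_de(counts, metadata, contrast, t,
              exclude_samples = exclude_samples)))
}

#' Read / write long-format DE tables
#'
#' DE tables are TSVs with columns `contrast`, `time_h`, `gene`, `log2FC`,
#' `padj`, `base_mean`; externally computed tables (e.g. DESeq2 output
#' reshaped to this layout) are first-class pipeline input.
#'
#' @param path file path.
#' @return `read_deg_table`: the DE data.frame.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("contrast", "time_h", "gene", "log2FC", "padj", "base_mean")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DE table lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_deg_table
#' @param deg DE data.frame to write.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
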