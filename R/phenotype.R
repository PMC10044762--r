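#' Phenotype activity scores from a DEG overlay
#'
#' For each (contrast, time) the raw activity of phenotype p is the
#' influence-weighted fold-change sum over significant mapped genes,
#' `A_p = sum_g I[g, p] * log2FC_g`. Within each (contrast, time) raw
#' scores are normalized to `A_p / max_q |A_q|`, so values lie in [-1, 1]
#' and at least one phenotype attains |1| whenever any activity is nonzero
#' (an all-zero time point stays all-zero). Normalized values support
#' within-phenotype comparison across time; comparing magnitudes across
#' phenotypes is not meaningful.
#'
#' @param map a [mim] object.
#' @param infl an [influence_matrix()] over the phenotypes of interest.
#' @param ov an [overlay()] result.
#' @return data.frame with columns `contrast`, `time_h`, `phenotype`,
#'   `A` (raw), `A_norm`, and `empty_universe` flagging phenotypes with no
#'   upstream influence entries.
#' @export
phenotype_scores <- function(map, infl, ov) {
  stopifnot(inherits(map, "mim"), inherits(infl, "influence_matrix"))
  I <- infl$I
  empty <- colSums(I != 0) == 0
  groups <- unique(ov[c("contrast", "time_h")])
  out <- data.frame(contrast = character(), time_h = numeric(),
                    phenotype = character(), A = numeric(),
                    A_norm = numeric(), empty_universe = logical())
  for (k in seq_len(nrow(groups))) {
    rows <- ov$contrast == groups$contrast[k] & ov$time_h == groups$time_h[k]
    g <- ov$gene[rows]
    fc <- ov$log2FC[rows]
    idx <- match(norm_sym(g), norm_sym(rownames(I)))
    ok <- !is.na(idx)
    A <- if (any(ok)) as.vector(crossprod(I[idx[ok], , drop = FALSE], fc[ok]))
         else numeric(ncol(I))
    mx <- max(abs(A))
    out <- rbind(out, data.frame(
      contrast = groups$contrast[k], time_h = groups$time_h[k],
      phenotype = colnames(I), A = A,
      A_norm = if (mx > 0) A / mx else A,
      empty_universe = unname(empty)))
  }
  rownames(out) <- NULL
  out
}

#' Permutation significance of phenotype activities
#'
#' Builds a null by shuffling the (log2FC, padj) tuples across all measured
#' mapped genes of each (contrast, time); significance resolves against the
#' shuffled padj, so each permutation re-selects its own "significant" set
#' of the same size. The p-value uses add-one smoothing:
#' `p = (1 + #{|A_p^perm| >= |A_p|}) / (1 + n_perm)`. An empty overlay
#' yields p = 1 for every phenotype. Fully seed-reproducible.
#'
#' @inheritParams phenotype_scores
#' @param n_perm number of permutations (>= 100); default 1000.
#' @param seed integer RNG seed.
#' @param tau adjusted-p threshold applied to permuted tables; defaults to
#'   the overlay's own threshold.
#' @return The [phenotype_scores()] data.frame with an extra `p_perm`
#'   column.
#' @export
phenotype_permutation_test <- function(map, infl, ov, n_perm = 1000,
                                       seed = 1L, tau = NULL) {
  stopifnot(n_perm >= 100)
  if (is.null(tau)) tau <- attr(ov, "tau")
  if (is.null(tau)) tau <- 0.05
  meas <- attr(ov, "measured")
  obs <- phenotype_scores(map, infl, ov)
  if (!nrow(obs) && !is.null(meas) && nrow(meas)) {
    # no significant gene anywhere: all activities 0, p = 1
    groups <- unique(meas[c("contrast", "time_h")])
    obs <- do.call(rbind, lapply(seq_len(nrow(groups)), function(k)
      data.frame(contrast = groups$contrast[k], time_h = groups$time_h[k],
                 phenotype = colnames(infl$I), A = 0, A_norm = 0,
                 empty_universe = unname(colSums(infl$I != 0) == 0))))
  }
  obs$p_perm <- rep(1, nrow(obs))
  if (is.null(meas) || !nrow(meas) || !nrow(obs) || !nrow(ov)) return(obs)
  I <- infl$I
  set.seed(seed)
  groups <- unique(obs[c("contrast", "time_h")])
  for (k in seq_len(nrow(groups))) {
    m <- meas[meas$contrast == groups$contrast[k] &
                meas$time_h == groups$time_h[k], , drop = FALSE]
    orow <- obs$contrast == groups$contrast[k] & obs$time_h == groups$time_h[k]
    if (!nrow(m)) next
    idx <- match(norm_sym(m$gene), norm_sym(rownames(I)))
    ok <- !is.na(idx)
    if (!any(ok)) next
    Isub <- I[idx[ok], , drop = FALSE]
    fc <- m$log2FC[ok]
    padj <- m$padj[ok]
    A_obs <- abs(obs$A[orow])
    exceed <- numeric(length(A_obs))
    n <- length(fc)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      sig <- !is.na(padj[perm]) & padj[perm] < tau
      A_b <- if (any(sig))
        abs(as.vector(crossprod(Isub[sig, , drop = FALSE], fc[perm][sig])))
      else numeric(ncol(I))
      exceed <- exceed + (A_b >= A_obs)
    }
    obs$p_perm[orow] <- (1 + exceed) / (1 + n_perm)
  }
  obs
}

#' Long-format table of phenotype activities grouped by phase
#'
#' Arranges activities for radial ("phase wheel") plotting: rows ordered by
#' phase, phenotype, then time, one row per computed activity (missing time
#' points are simply absent). Phenotypes without a phase label are grouped
#' under `"unassigned"`.
#'
#' @param activities output of [phenotype_scores()] or
#'   [phenotype_permutation_test()].
#' @param phases a [phase_annotation()] data.frame (`phenotype`, `phase`).
#' @return data.frame with columns `phase`, `phenotype`, `contrast`,
#'   `time_h`, `A_norm` and (when present) `p_perm`.
#' @export
phase_wheel_export <- function(activities, phases) {
  ph <- phases$phase[match(activities$phenotype, phases$phenotype)]
  ph[is.na(ph)] <- "unassigned"
  out <- data.frame(phase = ph,
                    phenotype = activities$phenotype,
                    contrast = activities$contrast,
                    time_h = activities$time_h,
                    A_norm = activities$A_norm)
  if (!is.null(activities$p_perm)) out$p_perm <- activities$p_perm
  out <- out[order(out$phase, out$phenotype, out$contrast, out$time_h), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
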