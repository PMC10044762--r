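#' Read a marker panel from a GMT file
#'
#' Standard GMT: one tab-separated line per gene set —
#' `name<TAB>description<TAB>member1<TAB>member2...`. Set names key the
#' panel; markers shared between cell types are permitted but reported.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (class `marker_panel`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  panel <- list()
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < 3)
      stop("GMT line ", i, ": expected >= 3 tab-separated fields")
    members <- unique(trimws(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members))
      stop("GMT line ", i, ": gene set '", f[1], "' has no members")
    panel[[f[1]]] <- members
  }
  if (anyDuplicated(names(panel)))
    stop("duplicate gene set name(s) in GMT")
  shared <- table(unlist(panel))
  shared <- names(shared)[shared > 1]
  if (length(shared))
    message(length(shared), " marker(s) shared between cell types: ",
            paste(head(shared, 5), collapse = ", "),
            if (length(shared) > 5) ", ..." else "")
  structure(panel, class = "marker_panel")
}

#' Write a marker panel to a GMT file
#'
#' @param panel named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(panel, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(panel))
  lines <- vapply(seq_along(panel), function(i)
    paste(c(names(panel)[i], descriptions[i], panel[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Immune cell-type composition scores from marker fold changes
#'
#' For each (time point, cell type): markers significant at `padj < tau`
#' are selected; with none the status is `no_significant_markers`; when the
#' significant markers' log2FC values mix signs the cell type is excluded
#' as `opposing_markers`; otherwise the score is the arithmetic mean of the
#' significant markers' log2FC, read as the shift in that cell population.
#' Non-significant markers never enter the average. Cell types with zero
#' measured markers get `no_significant_markers` with a warning.
#'
#' @param panel a [read_gmt()] marker panel (cell type -> marker genes).
#' @param deg long-format DE table.
#' @param contrast contrast label.
#' @param tau adjusted-p threshold; default 0.05.
#' @return data.frame with columns `contrast`, `time_h`, `cell_type`,
#'   `score` (NA unless status is `scored`), `status`, `n_markers_used`.
#' @export
cell_scores <- function(panel, deg, contrast, tau = 0.05) {
  d <- deg[deg$contrast == contrast, , drop = FALSE]
  if (!nrow(d)) stop("no rows for contrast '", contrast, "'")
  times <- sort(unique(d$time_h))
  measured <- unique(norm_sym(d$gene))
  out <- NULL
  for (ct in names(panel)) {
    markers <- norm_sym(panel[[ct]])
    if (!any(markers %in% measured))
      warning("cell type '", ct, "' has no measured markers")
    for (t in times) {
      dt <- d[d$time_h == t, , drop = FALSE]
      m <- dt[norm_sym(dt$gene) %in% markers & !is.na(dt$padj) &
                dt$padj < tau, , drop = FALSE]
      if (!nrow(m)) {
        status <- "no_significant_markers"; score <- NA_real_; n <- 0L
      } else if (length(unique(sign(m$log2FC))) > 1) {
        status <- "opposing_markers"; score <- NA_real_; n <- nrow(m)
      } else {
        status <- "scored"; score <- mean(m$log2FC); n <- nrow(m)
      }
      out <- rbind(out, data.frame(contrast = contrast, time_h = t,
                                   cell_type = ct, score = score,
                                   status = status, n_markers_used = n))
    }
  }
  rownames(out) <- NULL
  out
}
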