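#' In-silico perturbation of map genes
#'
#' Each perturbed gene is assigned +1 (forced up) or -1 (forced down); the
#' predicted level of phenotype p is the linear superposition
#' `L_p = sum_g I[g, p] * v_g` over the influence matrix, normalized per
#' run to `L_p / max_q |L_q|`. Linearity makes the prediction exactly
#' antisymmetric under flipping all assignments and additive over disjoint
#' perturbation sets; it is a static readout, not a dynamic simulation.
#'
#' @param map a [mim] object.
#' @param infl an [influence_matrix()] object.
#' @param spec named numeric vector of +1/-1 assignments, names are gene
#'   ids (case-insensitive). Genes absent from the influence universe
#'   contribute 0 with a warning.
#' @return data.frame with columns `phenotype`, `L` (raw level), `L_norm`,
#'   `direction` (`"up"`, `"down"` or `"none"`).
#' @export
perturb <- function(map, infl, spec) {
  stopifnot(inherits(map, "mim"), inherits(infl, "influence_matrix"),
            length(spec) >= 1, !is.null(names(spec)))
  if (!all(spec %in% c(-1, 1)))
    stop("perturbation values must be +1 or -1")
  unknown <- setdiff(norm_sym(names(spec)), norm_sym(map$nodes$id))
  if (length(unknown))
    stop("perturbed gene(s) not in map: ", paste(unknown, collapse = ", "))
  I <- infl$I
  idx <- match(norm_sym(names(spec)), norm_sym(rownames(I)))
  if (anyNA(idx)) {
    warning("gene(s) outside the influence universe contribute 0: ",
            paste(names(spec)[is.na(idx)], collapse = ", "))
  }
  ok <- !is.na(idx)
  L <- if (any(ok))
    as.vector(crossprod(I[idx[ok], , drop = FALSE], unname(spec[ok])))
  else numeric(ncol(I))
  mx <- max(abs(L))
  data.frame(phenotype = colnames(I), L = L,
             L_norm = if (mx > 0) L / mx else L,
             direction = c("down", "none", "up")[sign(L) + 2],
             row.names = NULL)
}

#' Phase-grouped perturbation report
#'
#' @param levels output of [perturb()].
#' @param phases a [phase_annotation()] data.frame.
#' @return data.frame (`phase`, `phenotype`, `L`, `L_norm`, `direction`)
#'   ordered by phase then phenotype; unphased phenotypes fall under
#'   `"unassigned"`.
#' @export
perturbation_report <- function(levels, phases) {
  ph <- phases$phase[match(levels$phenotype, phases$phenotype)]
  ph[is.na(ph)] <- "unassigned"
  out <- cbind(data.frame(phase = ph), levels)
  out <- out[order(out$phase, out$phenotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}
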