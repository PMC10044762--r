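#' Configuration for the synthetic study generator
#'
#' Defines the conditions the generators emulate: a signed scale-free-like
#' gene network with phenotype sink nodes and planted 3-gene feedback
#' loops; negative-binomial counts over two groups, seven time points and
#' seven replicates with log-normal library-size variation, planted DE
#' genes and optional planted outlier samples; and a 13-cell-type marker
#' panel with planted coherent shifts. Defaults mirror a two-arm murine
#' wound time course (7 animals per group, time points 12-192 h).
#'
#' @param n_genes number of gene nodes in the map; default 60.
#' @param n_phenotypes number of phenotype sink nodes; default 4, one per
#'   inflammation phase.
#' @param edges_per_gene expected background out-degree; default 1.6.
#' @param inhibition_frac fraction of inhibiting background edges; 0.3.
#' @param n_planted_motifs planted 3-gene feedback loops wired to the
#'   first phenotype; default 1.
#' @param module_size direct regulators planted per phenotype; default 10.
#' @param module_log2fc |log2FC| planted on module genes; default 3.
#' @param motif_log2fc |log2FC| planted on motif genes (kept above the
#'   module level so motif members sit in the top |FC| decile); default 4.
#' @param phenotype_directions `"up"`/`"down"` per phenotype; default
#'   alternating starting with `"up"`.
#' @param nb_dispersion negative-binomial dispersion; default 0.05.
#' @param libsize_sdlog log-normal sd of library-size factors; 0.15.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of gene
#'   baseline means; defaults log(100) and 1.
#' @param n_replicates samples per group and time; default 7.
#' @param time_points sampling times in hours; default
#'   c(12, 24, 36, 72, 96, 120, 192).
#' @param de_time time point carrying the planted effects; default 120.
#' @param outlier optional list(`group`, `time_h`, `replicate`, `factor`,
#'   `gene_frac`) describing a planted distorted sample.
#' @param n_cell_types,markers_per_type marker panel shape; defaults 13
#'   and 7 (91 markers).
#' @param marker_shift planted log2FC on shifted cell types; default 1.5.
#' @param n_shifted_cell_types cell types receiving the shift; default 1.
#' @param seed mandatory integer seed; generators are fully deterministic
#'   given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 60, n_phenotypes = 4, edges_per_gene = 1.6,
                       inhibition_frac = 0.3, n_planted_motifs = 1,
                       module_size = 10, module_log2fc = 3,
                       motif_log2fc = 4, phenotype_directions = NULL,
                       nb_dispersion = 0.05, libsize_sdlog = 0.15,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       n_replicates = 7,
                       time_points = c(12, 24, 36, 72, 96, 120, 192),
                       de_time = 120, outlier = NULL,
                       n_cell_types = 13, markers_per_type = 7,
                       marker_shift = 1.5, n_shifted_cell_types = 1,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (is.null(phenotype_directions))
    phenotype_directions <- rep(c("up", "down"), length.out = n_phenotypes)
  stopifnot(n_genes >= 1, n_phenotypes >= 1,
            inhibition_frac >= 0, inhibition_frac <= 1,
            length(phenotype_directions) == n_phenotypes,
            all(phenotype_directions %in% c("up", "down")),
            n_replicates >= 2, de_time %in% time_points,
            module_size * n_phenotypes + 3 * n_planted_motifs <= n_genes)
  structure(as.list(environment()), class = "sim_config")
}

phase_names <- c("initiation", "transition", "resolution", "homeostasis")

#' Generate a synthetic molecular interaction map with planted structure
#'
#' Builds a signed directed gene network with preferential-attachment-like
#' in-degree, phenotype sink nodes wired to disjoint planted regulator
#' modules (activating edges; the module's direction is carried by the
#' planted fold changes), and planted 3-gene activating feedback loops
#' whose members are additionally wired straight to the first phenotype.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `map` (a [mim] object) and `truth`: planted
#'   `motifs` (list of node triples), `focal_phenotype`, `modules`
#'   (data.frame `phenotype`, `gene`, `direction`) and `de` (data.frame
#'   `gene`, `time_h`, `log2fc`).
#' @export
make_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("g%03d", seq_len(config$n_genes))
  phens <- sprintf("P%d", seq_len(config$n_phenotypes))
  n_bg <- round(config$edges_per_gene * config$n_genes)
  indeg <- setNames(rep(0, config$n_genes), genes)
  src <- character(n_bg); tgt <- character(n_bg)
  for (i in seq_len(n_bg)) {
    s <- sample(genes, 1)
    t <- sample(setdiff(genes, s), 1, prob = (indeg[setdiff(genes, s)] + 1))
    src[i] <- s; tgt[i] <- t
    indeg[t] <- indeg[t] + 1
  }
  sign <- ifelse(runif(n_bg) < config$inhibition_frac, -1L, 1L)
  edges <- data.frame(source = src, target = tgt, sign = sign)

  pool <- genes
  motifs <- list()
  if (config$n_planted_motifs > 0) {
    for (m in seq_len(config$n_planted_motifs)) {
      trio <- sample(pool, 3)
      pool <- setdiff(pool, trio)
      motifs[[m]] <- trio
      edges <- rbind(edges, data.frame(
        source = trio, target = trio[c(2, 3, 1)], sign = 1L))
      edges <- rbind(edges, data.frame(
        source = trio, target = phens[1], sign = 1L))
    }
  }
  modules <- NULL
  for (k in seq_along(phens)) {
    mod <- sample(pool, config$module_size)
    pool <- setdiff(pool, mod)
    edges <- rbind(edges, data.frame(source = mod, target = phens[k],
                                     sign = 1L))
    modules <- rbind(modules, data.frame(
      phenotype = phens[k], gene = mod,
      direction = config$phenotype_directions[k]))
  }
  # planted edges were appended last and win over background duplicates
  key <- paste(edges$source, edges$target)
  edges <- edges[!duplicated(key, fromLast = TRUE), , drop = FALSE]

  nodes <- data.frame(
    id = c(genes, phens),
    label = c(genes, phens),
    node_class = c(rep("gene", length(genes)),
                   rep("phenotype", length(phens))),
    submaps = I(c(as.list(sample(phase_names, length(genes), replace = TRUE)),
                  rep(list(character()), length(phens)))),
    phase = c(rep(NA_character_, length(genes)),
              rep(phase_names, length.out = length(phens))))
  map <- suppressWarnings(mim(nodes, edges))

  de <- rbind(
    data.frame(gene = modules$gene, time_h = config$de_time,
               log2fc = ifelse(modules$direction == "up", 1, -1) *
                 config$module_log2fc),
    if (length(motifs))
      data.frame(gene = unlist(motifs), time_h = config$de_time,
                 log2fc = config$motif_log2fc))
  list(map = map,
       truth = list(motifs = motifs, focal_phenotype = phens[1],
                    modules = modules, de = de))
}

#' Generate a synthetic marker panel with planted shifts
#'
#' @param config a [sim_config()] object.
#' @param genes optional pool of gene ids to draw markers from; by default
#'   dedicated marker gene ids are synthesized outside the map. An error
#'   is raised when the pool is too small.
#' @return list with `panel` (a `marker_panel`) and `truth` (data.frame
#'   `cell_type`, `gene`, `time_h`, `log2fc` of planted shifts; empty when
#'   none planted).
#' @export
make_marker_panel <- function(config, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_needed <- config$n_cell_types * config$markers_per_type
  cts <- sprintf("ct%02d", seq_len(config$n_cell_types))
  if (is.null(genes)) {
    members <- sprintf("mk%03d", seq_len(n_needed))
  } else {
    if (length(genes) < n_needed)
      stop("marker pool has ", length(genes), " genes; need ", n_needed)
    members <- sample(genes, n_needed)
  }
  panel <- structure(split(members, rep(cts, each = config$markers_per_type)),
                     class = "marker_panel")
  shifted <- cts[seq_len(min(config$n_shifted_cell_types, length(cts)))]
  truth <- if (length(shifted) && config$marker_shift != 0) {
    data.frame(cell_type = rep(shifted, each = config$markers_per_type),
               gene = unlist(panel[shifted], use.names = FALSE),
               time_h = config$de_time,
               log2fc = config$marker_shift)
  } else {
    data.frame(cell_type = character(), gene = character(),
               time_h = numeric(), log2fc = numeric())
  }
  list(panel = panel, truth = truth)
}

#' Generate negative-binomial counts with planted effects
#'
#' Counts follow `NB(mu = baseline * libsize * 2^fc, size = 1/dispersion)`
#' where `fc` is the planted log2 fold change for treatment samples at the
#' planted time (0 otherwise). A planted outlier sample, when configured,
#' has a fraction of its genes multiplied by a distortion factor.
#'
#' @param config a [sim_config()] object.
#' @param genes character vector of gene ids to simulate.
#' @param truth_de data.frame (`gene`, `time_h`, `log2fc`) of planted
#'   effects, e.g. from [make_map()] and [make_marker_panel()].
#' @return list with `counts` (integer matrix genes x samples),
#'   `metadata` (data.frame `sample`, `contrast`, `group`, `time_h`,
#'   `replicate`) and `truth_de`.
#' @export
make_counts <- function(config, genes, truth_de = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  md <- expand.grid(replicate = seq_len(config$n_replicates),
                    group = c("treatment", "control"),
                    time_h = config$time_points,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  md$contrast <- "trt_vs_ctl"
  md$sample <- sprintf("%s_%gh_r%d", substr(md$group, 1, 3), md$time_h,
                       md$replicate)
  baseline <- rlnorm(length(genes), config$baseline_meanlog,
                     config$baseline_sdlog)
  libsize <- rlnorm(nrow(md), 0, config$libsize_sdlog)
  counts <- matrix(0L, nrow = length(genes), ncol = nrow(md),
                   dimnames = list(genes, md$sample))
  for (j in seq_len(nrow(md))) {
    fc <- rep(0, length(genes))
    if (!is.null(truth_de) && md$group[j] == "treatment") {
      rows <- truth_de$time_h == md$time_h[j]
      idx <- match(truth_de$gene[rows], genes)
      fc[idx[!is.na(idx)]] <- truth_de$log2fc[rows][!is.na(idx)]
    }
    mu <- baseline * libsize[j] * 2^fc
    counts[, j] <- rnbinom(length(genes), mu = mu,
                           size = 1 / config$nb_dispersion)
  }
  if (!is.null(config$outlier)) {
    o <- config$outlier
    hit <- which(md$group == o$group & md$time_h == o$time_h &
                   md$replicate == o$replicate)
    if (length(hit) != 1) stop("outlier spec matches ", length(hit),
                               " samples")
    gsel <- sample(length(genes), round(o$gene_frac * length(genes)))
    counts[gsel, hit] <- as.integer(round(counts[gsel, hit] * o$factor))
  }
  list(counts = counts,
       metadata = md[c("sample", "contrast", "group", "time_h", "replicate")],
       truth_de = truth_de)
}

#' Generate a complete synthetic study
#'
#' Composes [make_map()], [make_marker_panel()] and [make_counts()] into
#' one deterministic bundle: map + planted truth, marker panel, and counts
#' over the union of map genes and marker genes.
#'
#' @param config a [sim_config()] object.
#' @return list with `map`, `truth`, `panel`, `panel_truth`, `counts`,
#'   `metadata` and the combined `truth_de` table.
#' @export
simulate_study <- function(config) {
  mp <- make_map(config)
  pn <- make_marker_panel(config)
  truth_de <- rbind(mp$truth$de,
                    pn$truth[c("gene", "time_h", "log2fc")])
  genes <- c(gene_ids(mp$map), unlist(pn$panel, use.names = FALSE))
  cs <- make_counts(config, genes, truth_de)
  list(map = mp$map, truth = mp$truth, panel = pn$panel,
       panel_truth = pn$truth, counts = cs$counts,
       metadata = cs$metadata, truth_de = truth_de)
}
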