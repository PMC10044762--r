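tri_map <- function(edges) {
  ids <- unique(c(edges$source, edges$target, "P"))
  mim(fixture_nodes(ids, ifelse(ids == "P", "phenotype", "gene")), edges)
}

test_that("triplet feedback loops are enumerated once per orientation", {
  # a->b->c->a wired to P
  e <- fixture_edges(c("a", "b", "1"), c("b", "c", "1"), c("c", "a", "1"),
                     c("a", "P", "1"))
  m <- tri_map(e)
  infl <- influence_matrix(m)
  mo <- enumerate_motifs(m, "P", infl)
  expect_equal(nrow(mo), 1)
  expect_equal(mo$motif_id, "a>b>c")
  # reverse triangle on the same nodes is a distinct motif
  e2 <- rbind(e, fixture_edges(c("b", "a", "1"), c("c", "b", "1"),
                               c("a", "c", "1")))
  mo2 <- enumerate_motifs(tri_map(e2), "P", influence_matrix(tri_map(e2)))
  expect_setequal(mo2$motif_id, c("a>b>c", "a>c>b"))
  # acyclic graph -> none
  e3 <- fixture_edges(c("a", "b", "1"), c("b", "c", "1"), c("c", "P", "1"))
  expect_equal(nrow(enumerate_motifs(tri_map(e3), "P",
                                     influence_matrix(tri_map(e3)))), 0)
})

test_that("enumeration matches the brute-force cycle oracle on random graphs", {
  for (seed in 1:20) {
    m <- random_mim(6, 0.3, seed = seed + 400)
    infl <- influence_matrix(m)
    mo <- enumerate_motifs(m, "PH", infl)
    universe <- upstream_gene_universe(m, "PH", 5)
    expect_setequal(mo$motif_id, oracle_3cycles(m, universe))
  }
})

test_that("self-loops never enter motif cycles", {
  e <- fixture_edges(c("a", "a", "1"), c("a", "b", "1"), c("b", "c", "1"),
                     c("c", "a", "1"), c("a", "P", "1"))
  m <- tri_map(e)
  mo <- enumerate_motifs(m, "P", influence_matrix(m))
  expect_equal(mo$motif_id, "a>b>c")
})

test_that("feature normalization is min-max with the constant convention", {
  mo <- data.frame(motif_id = c("x", "y", "z"), n1 = "a", n2 = "b", n3 = "c",
                   F_I = c(0, 5, 10), F_ES = c(1, 1, 1), F_FC = c(2, 4, 3))
  nf <- normalize_features(mo)
  expect_equal(nf$f_I, c(0, 0.5, 1))
  expect_equal(nf$f_ES, c(0.5, 0.5, 0.5))  # constant feature
  expect_equal(order(nf$f_FC), order(mo$F_FC))
  expect_true(all(nf$f_FC >= 0 & nf$f_FC <= 1))
  # single motif -> all 0.5
  expect_equal(unlist(normalize_features(mo[1, ])[c("f_I", "f_ES", "f_FC")]),
               c(f_I = 0.5, f_ES = 0.5, f_FC = 0.5))
  expect_error(normalize_features(mo[0, ]), "empty")
})

test_that("motif scores reproduce hand-computed weighted sums", {
  expect_equal(score_motif(c(1, 1, 1), c(1, 1, 1)), 3.0)
  expect_equal(score_motif(c(1, 0, 0), c(0.33, 0.66, 1.0)), 0.33)
  expect_equal(score_motif(c(0.5, 0.4, 0.9), c(0.66, 0.33, 1.0)), 1.362)
})

test_that("scoring is linear in the features for every scenario", {
  set.seed(77)
  sc <- weight_scenarios()
  expect_equal(nrow(sc), 27)
  expect_equal(nrow(unique(sc)), 27)
  for (rep in 1:20) {
    fa <- runif(3); fb <- runif(3)
    j <- unlist(sc[sample(27, 1), ])
    expect_equal(score_motif((fa + fb) / 2, j),
                 (score_motif(fa, j) + score_motif(fb, j)) / 2)
  }
})

test_that("dominating motifs are always co-selected with dominated ones", {
  for (seed in 1:100) {
    set.seed(seed + 900)
    n <- sample(5:25, 1)
    mo <- data.frame(motif_id = sprintf("m%02d", 1:n),
                     n1 = "a", n2 = "b", n3 = "c",
                     F_I = runif(n), F_ES = runif(n), F_FC = runif(n))
    nf <- normalize_features(mo)
    top_m <- sample(1:4, 1)
    sel <- pareto_select(nf, top_m = top_m)$motif_id
    dominates <- function(i, j)
      all(c(nf$f_I[i] >= nf$f_I[j], nf$f_ES[i] >= nf$f_ES[j],
            nf$f_FC[i] >= nf$f_FC[j])) &&
      any(c(nf$f_I[i] > nf$f_I[j], nf$f_ES[i] > nf$f_ES[j],
            nf$f_FC[i] > nf$f_FC[j]))
    for (j in which(nf$motif_id %in% sel)) {
      for (i in seq_len(n)) {
        if (i != j && dominates(i, j))
          expect_true(nf$motif_id[i] %in% sel)
      }
    }
  }
})

test_that("specialist motifs each enter the Pareto union", {
  mo <- data.frame(motif_id = c("ifirst", "fcfirst"), n1 = c("a", "d"),
                   n2 = c("b", "e"), n3 = c("c", "f"),
                   F_I = c(1, 0), F_ES = c(0, 0), F_FC = c(0, 1))
  nf <- normalize_features(mo)
  sel <- pareto_select(nf, top_m = 1)
  expect_setequal(sel$motif_id, c("ifirst", "fcfirst"))
  # a motif dominating everywhere is selected by all 27 scenarios
  mo2 <- rbind(mo, data.frame(motif_id = "boss", n1 = "g", n2 = "h",
                              n3 = "i", F_I = 2, F_ES = 2, F_FC = 2))
  sel2 <- pareto_select(normalize_features(mo2), top_m = 1)
  expect_equal(sel2$motif_id, "boss")
  expect_equal(sel2$n_scenarios, 27)
})

test_that("selection handles fewer motifs than top_m", {
  mo <- normalize_features(
    data.frame(motif_id = "only", n1 = "a", n2 = "b", n3 = "c",
               F_I = 1, F_ES = 1, F_FC = 1))
  expect_equal(nrow(pareto_select(mo, top_m = 5)), 1)
})

test_that("motifs merge into an annotated core regulatory network", {
  # two triangles sharing node c: a,b,c and c,d,e
  e <- fixture_edges(c("a", "b", "1"), c("b", "c", "1"), c("c", "a", "1"),
                     c("c", "d", "1"), c("d", "e", "1"), c("e", "c", "-1"),
                     c("a", "P", "1"), c("d", "P", "1"))
  m <- tri_map(e)
  infl <- influence_matrix(m)
  deg <- deg_rows("c", 120, c("a", "b", "c", "d", "e"),
                  c(2, -1, 1.5, 3, -0.5), c(0.01, 0.01, 0.2, 0.01, 0.01))
  ov <- overlay(m, deg, "c")
  meas <- attr(ov, "measured")
  mo <- enumerate_motifs(m, "P", infl, meas[meas$time_h == 120, ])
  expect_equal(nrow(mo), 2)
  crn <- build_crn(m, pareto_select(normalize_features(mo)), "P", ov,
                   time_h = 120)
  expect_equal(nrow(crn$nodes), 5)
  expect_equal(nrow(crn$edges), 6)
  ann <- setNames(crn$nodes$direction, crn$nodes$id)
  expect_equal(ann[["a"]], "up")
  expect_equal(ann[["b"]], "down")
  expect_equal(ann[["c"]], "none")  # not significant
  f <- tempfile(fileext = ".graphml")
  write_crn_graphml(crn, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), 5)
  expect_error(build_crn(m, mo[0, ], "P", ov), "empty")
})

test_that("the planted feedback loop is recovered on the synthetic benchmark", {
  cfg <- sim_config(seed = 7, time_points = 120)
  st <- simulate_study(cfg)
  infl <- influence_matrix(st$map)
  deg <- simple_de(st$counts, st$metadata, "trt_vs_ctl", 120)
  ov <- suppressMessages(overlay(st$map, deg, "trt_vs_ctl"))
  crn <- extract_crn(st$map, st$truth$focal_phenotype, infl, ov, 120)
  planted <- paste(sort(st$truth$motifs[[1]]), collapse = "|")
  got <- vapply(seq_len(nrow(crn$motifs)), function(i)
    paste(sort(c(crn$motifs$n1[i], crn$motifs$n2[i], crn$motifs$n3[i])),
          collapse = "|"), "")
  expect_true(planted %in% got)
})
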