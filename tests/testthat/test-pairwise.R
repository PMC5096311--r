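test_that("the most informative common ancestor is found from tables alone", {
  tab <- fixture_tables()
  m <- mica("GO:0043227", "GO:0043227", tab)
  expect_equal(m$term, "GO:0043227")
  expect_equal(m$ic, unname(tab$ic["GO:0043227"]))
  # gA -> 43227, gB -> 5622, gC -> root: the only shared ancestor is the root
  m2 <- mica("GO:0043227", "GO:0005622", tab)
  expect_equal(m2$term, "GO:0005575")
  expect_identical(m2$ic, 0)
  expect_error(mica("GO:0000001", "GO:0005622", tab), "unknown term")
  # brute-force scan over the full ancestor intersection on random instances
  for (seed in 1:5) {
    inst <- random_instance(seed, n_terms = 25, n_genes = 20)
    tab_r <- build_tables(inst$dag, inst$ann)
    annotated <- names(tab_r$ic)
    for (k in 1:5) {
      ts <- sample(annotated, 2, replace = TRUE)
      got <- mica(ts[1], ts[2], tab_r)
      common <- intersect(dfs_ancestors(inst$dag, ts[1]),
                          dfs_ancestors(inst$dag, ts[2]))
      ics <- tab_r$ic[common]
      expect_equal(got$ic, max(ics))
      expect_equal(got$term, sort(common[ics == max(ics)])[1])
    }
  }
})

test_that("Resnik is the MICA information content", {
  tab <- fixture_tables()
  expect_equal(sim_resnik("GO:0043227", "GO:0043227", tab),
               unname(tab$ic["GO:0043227"]))
  expect_identical(sim_resnik("GO:0043227", "GO:0005622", tab), 0)
  expect_gte(sim_resnik("GO:0043227", "GO:0005575", tab), 0)
})

test_that("Lin scores self-similarity 1 and root-only overlap 0", {
  tab <- fixture_tables()
  expect_identical(sim_lin("GO:0043227", "GO:0043227", tab), 1)
  # self-similarity is 1 even for the zero-IC root
  expect_identical(sim_lin("GO:0005575", "GO:0005575", tab), 1)
  expect_identical(sim_lin("GO:0043227", "GO:0005622", tab), 0)
})

test_that("Jiang-Conrath follows the distance form, optionally clamped", {
  tab <- fixture_tables()
  expect_identical(sim_jiang("GO:0043227", "GO:0043227", tab), 1)
  ic1 <- unname(tab$ic["GO:0043227"]); ic2 <- unname(tab$ic["GO:0005622"])
  expect_equal(sim_jiang("GO:0043227", "GO:0005622", tab),
               1 - (ic1 + ic2))
  # two deep terms sharing only the root go negative unless clamped
  unclamped <- sim_jiang("GO:0043227", "GO:0005622", tab)
  expect_lt(unclamped, 0)
  expect_identical(sim_jiang("GO:0043227", "GO:0005622", tab, clamp = TRUE), 0)
})

test_that("Pekar-Staab uses the deepest common ancestor in both variants", {
  tab <- fixture_tables()
  # shared ancestor is the root (depth 0)
  expect_identical(sim_pekar("GO:0043227", "GO:0005622", tab), 0)
  # deepest common ancestor of (43231, 5622) is 5622 itself at depth 2
  expect_equal(sim_pekar("GO:0043231", "GO:0005622", tab), 2 / (2 + 4 + 2))
  # classic variant: distances measured to the common ancestor
  expect_identical(sim_pekar("GO:0043227", "GO:0043227", tab,
                             variant = "classic"), 1)
  expect_equal(sim_pekar("GO:0043231", "GO:0005622", tab, variant = "classic"),
               2 / (2 + 0 + 2))
  # degenerate root/root comparison scores 0 in both variants
  expect_identical(sim_pekar("GO:0005575", "GO:0005575", tab), 0)
  expect_identical(sim_pekar("GO:0005575", "GO:0005575", tab,
                             variant = "classic"), 0)
})

test_that("Wang similarity reproduces the worked example", {
  tab <- fixture_tables()
  expect_equal(sim_wang("GO:0043227", "GO:0005622", tab),
               1.12 / (2.44 + 2.08), tolerance = 1e-12)
  expect_identical(sim_wang("GO:0043227", "GO:0043227", tab), 1)
  expect_error(sim_wang("GO:0000001", "GO:0005622", tab), "S-value record")
})

test_that("combination rules reduce a term-similarity matrix correctly", {
  expect_identical(combine_scores(matrix(0.4), "max"), 0.4)
  expect_identical(combine_scores(matrix(0.4), "avg"), 0.4)
  expect_identical(combine_scores(matrix(0.4), "bma"), 0.4)
  m <- diag(2)
  expect_identical(combine_scores(m, "max"), 1)
  expect_identical(combine_scores(m, "avg"), 0.5)
  expect_identical(combine_scores(m, "bma"), 1)
  expect_error(combine_scores(matrix(numeric(0), 0, 0), "max"), "empty")
  # independent formula recomputation on random matrices
  for (seed in 1:5) {
    m <- with_seed_local(seed, matrix(stats::runif(12), 3, 4))
    expect_equal(combine_scores(m, "max"), max(as.vector(m)))
    expect_equal(combine_scores(m, "avg"), sum(m) / 12)
    rmax <- c(max(m[1, ]), max(m[2, ]), max(m[3, ]))
    cmax <- c(max(m[, 1]), max(m[, 2]), max(m[, 3]), max(m[, 4]))
    expect_equal(combine_scores(m, "bma"), (sum(rmax) + sum(cmax)) / 7)
  }
})

test_that("gene similarity is built over direct annotation sets", {
  tab <- fixture_tables()
  # identical single-term annotations: similarity 1 under Lin/Jiang/Wang
  ann <- annotation_set(
    data.frame(gene = c("x1", "x2"), term = "GO:0043227"), namespace = "CC")
  for (measure in c("lin", "jiang", "wang")) {
    expect_identical(gene_sim("x1", "x2", tab, measure, annset = ann), 1)
  }
  # the 1x1 case: all rules coincide with the worked-example value
  for (rule in c("max", "avg", "bma")) {
    expect_equal(gene_sim("gA", "gB", tab, "wang", rule = rule),
                 1.12 / 4.52, tolerance = 1e-12)
  }
  expect_error(gene_sim("gA", "nosuch", tab, "wang"), "no annotation")
})

test_that("every measure and rule is symmetric with the documented range", {
  for (seed in 6:10) {
    inst <- random_instance(seed, n_terms = 20, n_genes = 10)
    tab <- build_tables(inst$dag, inst$ann)
    annotated <- names(tab$ic)
    pairs <- with_seed_local(seed, replicate(4, sample(annotated, 2), simplify = FALSE))
    for (p in pairs) {
      for (measure in c("resnik", "lin", "jiang", "pekar", "wang")) {
        a <- term_sim(p[1], p[2], tab, measure)
        b <- term_sim(p[2], p[1], tab, measure)
        expect_equal(a, b, tolerance = 1e-15)
        if (measure %in% c("lin", "wang")) {
          expect_gte(a, 0); expect_lte(a, 1)
        }
        if (measure == "resnik") expect_gte(a, 0)
        if (measure == "jiang") expect_lte(a, 1)
        if (measure == "pekar") {
          expect_gte(a, 0); expect_lt(a, 1)
        }
      }
      cl <- term_sim(p[1], p[2], tab, "pekar", pekar_variant = "classic")
      expect_equal(cl, term_sim(p[2], p[1], tab, "pekar",
                                pekar_variant = "classic"), tolerance = 1e-15)
    }
    genes <- with_seed_local(seed + 100, sample(names(tab$gene_direct), 4))
    for (measure in c("wang", "lin")) {
      for (rule in c("max", "avg", "bma")) {
        expect_equal(gene_sim(genes[1], genes[2], tab, measure, rule = rule),
                     gene_sim(genes[2], genes[1], tab, measure, rule = rule),
                     tolerance = 1e-15)
      }
    }
  }
})

test_that("queries run from tables alone after the graph is discarded", {
  inst <- random_instance(42, n_terms = 15, n_genes = 6)
  tab <- build_tables(inst$dag, inst$ann)
  annotated <- names(tab$ic)
  rm(list = "inst")
  expect_no_error({
    term_sim(annotated[1], annotated[2], tab, "wang")
    term_sim(annotated[1], annotated[2], tab, "resnik")
    gene_sim(names(tab$gene_direct)[1], names(tab$gene_direct)[2], tab, "lin")
    sim_ui(names(tab$gene_closure)[1], names(tab$gene_closure)[2], tab)
  })
})
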