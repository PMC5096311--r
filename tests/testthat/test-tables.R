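test_that("information content is -ln p with p(root) = 1", {
  dag <- organelle_dag()
  # only the root annotated: its IC is 0
  root_only <- annotation_set(
    data.frame(gene = c("g1", "g2"), term = "GO:0005575"), namespace = "CC")
  ict <- build_ic_table(dag, term_counts(root_only, dag))
  expect_identical(unname(ict$ic["GO:0005575"]), 0)
  expect_identical(unname(ict$p["GO:0005575"]), 1)
  # zero-count terms are absent, and queries on them error
  expect_false("GO:0043231" %in% names(ict$ic))

  # two-term chain, one gene on each: p(child) = 1/2
  chain <- parse_obo(c("[Term]", "id: GO:0000001", "name: r",
                       "namespace: cellular_component",
                       "", "[Term]", "id: GO:0000002", "name: c",
                       "namespace: cellular_component", "is_a: GO:0000001"))
  ann <- annotation_set(data.frame(gene = c("g1", "g2"),
                                   term = c("GO:0000001", "GO:0000002")),
                        namespace = "CC")
  ict2 <- build_ic_table(chain, term_counts(ann, chain))
  expect_equal(unname(ict2$p["GO:0000002"]), 0.5)
  expect_equal(unname(ict2$ic["GO:0000002"]), log(2))

  # empty namespace is an error
  expect_error(
    build_ic_table(dag, list(closure = setNames(numeric(7), dag$terms),
                             mode = "literal")),
    "no annotations")
})

test_that("IC is monotone non-decreasing from parent to child", {
  for (seed in 1:5) {
    inst <- random_instance(seed)
    tab <- build_tables(inst$dag, inst$ann)
    e <- inst$dag$edges
    have <- e$child %in% names(tab$ic) & e$parent %in% names(tab$ic)
    expect_true(all(tab$ic[e$child[have]] >= tab$ic[e$parent[have]]))
  }
})

test_that("depth is the longest root path, found by one topological pass", {
  dag <- organelle_dag()
  dep <- build_depth_table(dag)
  expect_equal(unname(dep$depth["GO:0005575"]), 0)
  expect_equal(unname(dep$depth["GO:0005622"]), 2)
  expect_equal(unname(dep$depth["GO:0043231"]), 4)
  # dist maps: longest path from each ancestor down to the term
  expect_equal(dep$dist[["GO:0043231"]][["GO:0005575"]], 4)
  expect_equal(dep$dist[["GO:0043231"]][["GO:0043226"]], 2)
  for (seed in 6:12) {
    rdag <- random_dag(20, seed = seed)
    dep_r <- build_depth_table(rdag)
    for (t in sample(rdag$terms, 6)) {
      expect_equal(unname(dep_r$depth[t]),
                   gosimtab:::naive_depth(rdag, t))
    }
    e <- rdag$edges
    expect_true(all(dep_r$depth[e$child] >= dep_r$depth[e$parent] + 1))
  }
})

test_that("the S-value table reproduces the worked-example values exactly", {
  svt <- build_svalue_table(organelle_dag())
  s <- svt$svalues[["GO:0043231"]]
  expect_equal(s, c("GO:0005575" = 0.512, "GO:0005622" = 0.48,
                    "GO:0005623" = 0.288, "GO:0043226" = 0.64,
                    "GO:0043227" = 0.8, "GO:0043229" = 0.8,
                    "GO:0043231" = 1.0),
               tolerance = 1e-12)
  expect_equal(unname(svt$sv["GO:0043227"]), 2.44, tolerance = 1e-12)
  expect_equal(unname(svt$sv["GO:0005622"]), 2.08, tolerance = 1e-12)
})

test_that("a parentless term has S-value map {self: 1} and SV 1", {
  dag <- parse_obo(c("[Term]", "id: GO:0000001", "name: r",
                     "namespace: molecular_function"))
  svt <- build_svalue_table(dag)
  expect_identical(svt$svalues[["GO:0000001"]],
                   c("GO:0000001" = 1))
  expect_identical(unname(svt$sv["GO:0000001"]), 1)
})

test_that("S-values match memoisation-free recursive evaluation on random DAGs", {
  factors <- semantic_factors()
  for (seed in 13:20) {
    dag <- random_dag(18, seed = seed, part_of_fraction = 0.4)
    svt <- build_svalue_table(dag, factors)
    for (A in sample(dag$terms, 5)) {
      s <- svt$svalues[[A]]
      for (t in names(s)) {
        expect_equal(unname(s[t]),
                     gosimtab:::naive_svalue(dag, A, t, factors),
                     tolerance = 1e-15)
      }
      expect_true(all(s > 0 & s <= 1))
      expect_gte(unname(svt$sv[A]), 1)
    }
  }
})

test_that("S-value propagation excludes relations without a factor", {
  # child -R-> mid -is_a-> root where R carries no factor: the S-value map of
  # the child must stop at the unweighted edge
  obo <- c("[Term]", "id: GO:0000001", "name: r",
           "namespace: biological_process",
           "", "[Term]", "id: GO:0000002", "name: m",
           "namespace: biological_process", "is_a: GO:0000001",
           "", "[Term]", "id: GO:0000003", "name: c",
           "namespace: biological_process",
           "relationship: regulates GO:0000002")
  dag <- parse_obo(obo)
  # retained for plain ancestor computation ...
  expect_setequal(ancestors(dag, "GO:0000003"),
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  # ... but not for S-value propagation
  svt <- build_svalue_table(dag)
  expect_identical(names(svt$svalues[["GO:0000003"]]), "GO:0000003")
  expect_identical(unname(svt$sv["GO:0000003"]), 1)
})

test_that("gene closures are ancestor unions over direct annotations", {
  dag <- organelle_dag()
  ann <- fixture_annotations()
  gt <- build_gene_table(ann, dag)
  expect_equal(gt$gC, "GO:0005575")
  expect_equal(gt$gA, c("GO:0005575", "GO:0043226", "GO:0043227"))
  for (seed in 21:24) {
    inst <- random_instance(seed, n_terms = 20, n_genes = 10)
    gt_r <- build_gene_table(inst$ann, inst$dag)
    for (g in names(gt_r)) {
      brute <- sort(unique(unlist(lapply(inst$ann$direct[[g]], dfs_ancestors,
                                         dag = inst$dag))))
      expect_identical(gt_r[[g]], brute)
      expect_true(all(inst$ann$direct[[g]] %in% gt_r[[g]]))
      expect_true(inst$dag$roots[[1]] %in% gt_r[[g]])
    }
  }
})

test_that("save/load round trip is bit-exact and refuses mismatched factors", {
  dir <- withr::local_tempdir()
  tab <- fixture_tables()
  save_tables(tab, dir)
  back <- load_tables(dir)
  expect_identical(back$svalues, tab$svalues)
  expect_identical(back$sv, tab$sv)
  expect_identical(back$ic, tab$ic)
  expect_identical(back$p, tab$p)
  expect_identical(back$depth, tab$depth)
  expect_identical(back$dist, tab$dist)
  expect_identical(back$anc, tab$anc)
  expect_identical(back$gene_closure, tab$gene_closure)
  expect_identical(back$gene_direct, tab$gene_direct)
  expect_identical(unclass(back$factors), unclass(tab$factors))

  expect_identical(load_tables(dir, factors = semantic_factors())$namespace, "CC")
  expect_error(load_tables(dir, factors = semantic_factors(is_a = 0.7)),
               "different semantic factors")

  # truncation is detected
  sv_path <- file.path(dir, "sv.tsv")
  writeLines(readLines(sv_path)[-1], sv_path)
  expect_error(load_tables(dir), "mismatch")
})

test_that("larger random instances round-trip exactly and deterministically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  inst <- random_instance(99, n_terms = 300, n_genes = 40)
  tab <- build_tables(inst$dag, inst$ann)
  save_tables(tab, dir1)
  save_tables(tab, dir2)
  files <- list.files(dir1)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  back <- load_tables(dir1)
  expect_identical(back$svalues, tab$svalues)
  expect_identical(back$ic, tab$ic)
  expect_identical(back$dist, tab$dist)
})
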