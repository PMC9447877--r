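test_that("threshold constructor enforces its invariants", {
  th <- hit_thresholds()
  expect_equal(th$lfc_max, -1)
  expect_equal(th$fdr_max, 0.1)
  expect_equal(th$basemean_min, 100)
  expect_equal(th$min_hairpins, 2L)
  expect_equal(th$opposite_lfc_min, 1)
  expect_error(hit_thresholds(lfc_max = 0.5), "negative")
  expect_error(hit_thresholds(fdr_max = 0), "\\(0, 1\\]")
  expect_error(hit_thresholds(min_hairpins = 0), "positive integer")
})

test_that("primary calling applies the hairpin-quorum and opposite-direction rules", {
  manifest <- tiny_manifest(genes = c("HIT", "LONE", "FLIP"), hairpins_per_gene = 3L)
  res <- make_results(manifest, log2fc = 0, fdr = 0.9, baseMeanA = 500)
  set_row <- function(res, hp, lfc, fdr, bm = 500) {
    i <- res$hairpin_id == hp
    res$log2fc[i] <- lfc; res$fdr[i] <- fdr; res$baseMeanA[i] <- bm
    res
  }
  # two strong depleted hairpins -> hit
  res <- set_row(res, "HIT_sh1", -1.5, 0.01)
  res <- set_row(res, "HIT_sh2", -2.0, 0.005, 300)
  # a single passing hairpin -> too few
  res <- set_row(res, "LONE_sh1", -2.5, 0.001)
  # two passing plus a significant enrichment -> opposite-direction veto
  res <- set_row(res, "FLIP_sh1", -1.8, 0.01)
  res <- set_row(res, "FLIP_sh2", -1.6, 0.02)
  res <- set_row(res, "FLIP_sh3", 1.4, 0.02, 400)

  calls <- call_hits_primary(res, manifest, hit_thresholds(), cell_line = "CL1")
  expect_identical(hit_set(calls), "HIT")
  hit <- calls[calls$gene_symbol == "HIT", ]
  expect_identical(hit$eliminated_at, "none")
  expect_identical(hit$supporting_hairpins, "HIT_sh1;HIT_sh2")
  expect_equal(hit$n_supporting, 2L)
  expect_identical(calls$eliminated_at[calls$gene_symbol == "LONE"], "too_few_hairpins")
  expect_identical(calls$eliminated_at[calls$gene_symbol == "FLIP"], "opposite_direction")
  expect_identical(unique(calls$cell_line), "CL1")
})

test_that("boundary values are strict: thresholds themselves never pass", {
  manifest <- tiny_manifest(genes = "EDGE", hairpins_per_gene = 2L)
  res <- make_results(manifest, log2fc = -1, fdr = 0.1, baseMeanA = 100)
  calls <- call_hits_primary(res, manifest)
  expect_false(any(calls$is_hit))
  expect_identical(calls$eliminated_at, "too_few_hairpins")
})

test_that("control genes are never callable and unknown genes are rejected", {
  manifest <- validate_manifest(data.frame(
    hairpin_id = c("KIN1_sh1", "KIN1_sh2", "ESS1_sh1", "ESS1_sh2"),
    gene_symbol = c("KIN1", "KIN1", "ESS1", "ESS1"),
    gene_class = c("kinase", "kinase", "control", "control"),
    hairpin_class = c("targeting", "targeting", "essential_control", "essential_control")
  ))
  res <- make_results(manifest, log2fc = -3, fdr = 0.001, baseMeanA = 800)
  calls <- call_hits_primary(res, manifest)
  expect_identical(calls$gene_symbol, "KIN1")  # controls excluded from calling
  expect_true(calls$is_hit)

  rogue <- res
  rogue$gene_symbol[1] <- "NOT_IN_MANIFEST"
  expect_error(call_hits_primary(rogue, manifest), "absent from manifest")
})

test_that("secondary t0 filter enforces the depletion-from-reference quorum", {
  manifest <- tiny_manifest(genes = c("KEEP", "DROP"), hairpins_per_gene = 2L)
  res_tu <- make_results(manifest, log2fc = -2, fdr = 0.01, baseMeanA = 500)
  primary <- call_hits_primary(res_tu, manifest, cell_line = "CL1")
  expect_identical(hit_set(primary), c("DROP", "KEEP"))

  res_t0 <- make_results(manifest, log2fc = 0, contrast = "treated_vs_t0")
  res_t0$log2fc <- c(-0.4, -1.5, -1.5, -2.1)[match(
    c("DROP_sh1", "DROP_sh2", "KEEP_sh1", "KEEP_sh2"), res_t0$hairpin_id)]

  calls <- call_hits_secondary(primary, res_t0, hit_thresholds())
  expect_identical(hit_set(calls), "KEEP")
  expect_identical(calls$eliminated_at[calls$gene_symbol == "DROP"], "t0_filter")
  keep <- calls[calls$gene_symbol == "KEEP", ]
  expect_identical(keep$supporting_hairpins, "KEEP_sh1;KEEP_sh2")

  # with quorum "any", one passing t0 hairpin is enough
  relaxed <- call_hits_secondary(primary, res_t0, hit_thresholds(t0_quorum = "any"))
  expect_identical(hit_set(relaxed), c("DROP", "KEEP"))
  expect_identical(relaxed$supporting_hairpins[relaxed$gene_symbol == "DROP"], "DROP_sh2")

  # vacuous and error cases
  expect_identical(nrow(call_hits_secondary(primary[0, ], res_t0)), 0L)
  expect_error(call_hits_secondary(primary, res_t0[res_t0$hairpin_id != "KEEP_sh1", ]),
               "missing from treated-vs-t0.*KEEP_sh1")
})

test_that("intersection reports shared genes and an exact Venn partition", {
  gc <- function(genes, hits, cl) {
    new <- data.frame(gene_symbol = genes, cell_line = cl, is_hit = genes %in% hits,
                      n_supporting = 2L, supporting_hairpins = "", eliminated_at = "none")
    new
  }
  calls <- list(L1 = gc(LETTERS[1:4], c("A", "B"), "L1"),
                L2 = gc(LETTERS[1:4], c("A", "C"), "L2"),
                L3 = gc(LETTERS[1:4], c("A", "D"), "L3"))
  ix <- intersect_hits(calls)
  expect_identical(ix$shared_genes, "A")
  expect_equal(ix$n_shared, 1L)
  expect_equal(sum(ix$regions$n_genes), length(unique(c("A", "B", "C", "D"))))
  expect_identical(ix$regions$genes[ix$regions$region == "L1&L2&L3"], "A")

  disjoint <- intersect_hits(list(L1 = gc("A", "A", "L1"), L2 = gc("B", "B", "L2")))
  expect_identical(disjoint$shared_genes, character(0))

  same <- gc(LETTERS[1:5], LETTERS[1:5], "x")
  ident <- intersect_hits(list(L1 = same, L2 = same, L3 = same))
  expect_equal(ident$n_shared, 5L)
  expect_true(all(ident$regions$n_genes[ident$regions$region != "L1&L2&L3"] == 0L))

  expect_error(intersect_hits(list(L1 = same)), "at least 2")
})

test_that("volcano table flags strict cutoff exceedance and sorts by significance", {
  manifest <- tiny_manifest(genes = c("A", "B"), hairpins_per_gene = 1L)
  res <- make_results(manifest, log2fc = c(-1.01, -1.01), fdr = c(0.09, 0.11),
                      baseMeanA = 500)
  v <- volcano_table(res, hit_thresholds())
  expect_identical(v$beyond_cutoff, c(TRUE, FALSE))
  expect_true(all(diff(v$fdr) >= 0))
  empty <- volcano_table(res[0, ], hit_thresholds())
  expect_identical(nrow(empty), 0L)
  expect_true("beyond_cutoff" %in% names(empty))
})

test_that("the full cascade matches a literal rule-enumeration oracle", {
  set.seed(61)
  for (trial in 1:40) {
    tab <- random_gene_table(n_genes = sample(5:20, 1))
    primary <- call_hits_primary(tab$res_tu, tab$manifest, cell_line = "CL")
    calls <- call_hits_secondary(primary, tab$res_t0)
    oracle <- oracle_cascade(tab$res_tu, tab$res_t0, tab$manifest)
    expect_identical(hit_set(calls), oracle$gene_symbol[oracle$is_hit])
  }
})

test_that("hit calling is invariant to input row order", {
  set.seed(62)
  tab <- random_gene_table(n_genes = 12)
  ref <- call_hits_secondary(call_hits_primary(tab$res_tu, tab$manifest), tab$res_t0)
  perm_tu <- tab$res_tu[sample(nrow(tab$res_tu)), ]
  perm_t0 <- tab$res_t0[sample(nrow(tab$res_t0)), ]
  shuffled <- call_hits_secondary(call_hits_primary(perm_tu, tab$manifest), perm_t0)
  rownames(shuffled) <- rownames(ref) <- NULL
  expect_identical(shuffled, ref)
})

test_that("tightening any threshold never enlarges the hit set", {
  set.seed(63)
  base <- hit_thresholds()
  # hit criteria tightened with the veto held at its defaults, plus a
  # tightened veto itself; every dial must shrink (or keep) the hit set
  tighter <- list(
    hit_thresholds(fdr_max = 0.05, opposite_fdr_max = 0.1),
    hit_thresholds(lfc_max = -1.5, opposite_lfc_min = 1),
    hit_thresholds(basemean_min = 300),
    hit_thresholds(min_hairpins = 3L),
    hit_thresholds(opposite_lfc_min = 0.5),
    hit_thresholds(opposite_fdr_max = 0.3)
  )
  for (trial in 1:20) {
    tab <- random_gene_table(n_genes = 15)
    hits0 <- hit_set(call_hits_secondary(
      call_hits_primary(tab$res_tu, tab$manifest, base), tab$res_t0, base))
    for (th in tighter) {
      hits1 <- hit_set(call_hits_secondary(
        call_hits_primary(tab$res_tu, tab$manifest, th), tab$res_t0, th))
      expect_true(all(hits1 %in% hits0))
    }
    # stage ordering: secondary subset of primary subset of manifest genes
    prim <- hit_set(call_hits_primary(tab$res_tu, tab$manifest, base))
    expect_true(all(hits0 %in% prim))
    expect_true(all(prim %in% tab$manifest$gene_symbol))
  }
})
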