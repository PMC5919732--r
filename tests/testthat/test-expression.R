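test_that("FPKM flooring replaces sub-threshold values and is idempotent", {
  expect_equal(floor_fpkm(0.1), 1)
  expect_equal(floor_fpkm(0.0001), 1)
  expect_equal(floor_fpkm(0), 1)
  expect_equal(floor_fpkm(2.5), 2.5)
  x <- c(0, 0.3, 1, 7.7)
  expect_equal(floor_fpkm(floor_fpkm(x)), floor_fpkm(x))
  expect_error(floor_fpkm(-0.1), "non-negative")
})

test_that("condition means average raw replicates", {
  tbl <- tiny_expression(list(gA = c(4, 6, 10, 14), gB = c(1, 1, 2, 2)))
  m <- condition_mean(tbl, "wild-type", "untreated")
  expect_equal(unname(m["gA"]), 5)
  expect_equal(attr(m, "n_replicates"), 2L)
  expect_error(condition_mean(tbl, "wild-type", "nope"), "no samples")
  # single-replicate condition warns
  sub <- expression_table(tbl$fpkm[, -2, drop = FALSE], tbl$meta[-2, ])
  expect_warning(condition_mean(sub, "wild-type", "untreated"),
                 "single replicate")
})

test_that("log2 fold changes are floored, exact, and antisymmetric", {
  expect_equal(log2_fold_change(8, 2), 2)
  expect_equal(log2_fold_change(0.1, 0.0001), 0)  # both floored to 1
  expect_equal(log2_fold_change(5, 5), 0)
  for (pair in list(c(8, 2), c(0.2, 3), c(16, 1.5), c(1, 1))) {
    expect_equal(log2_fold_change(pair[1], pair[2]),
                 -log2_fold_change(pair[2], pair[1]))
  }
})

test_that("DE calls require both the mean-level and per-replicate cutoff", {
  tbl <- tiny_expression(list(
    gPass = c(4, 4, 16, 16),      # mean ratio 2, both replicates pass
    gRepFail = c(4, 4, 16, 1.5),  # mean 8.75 -> ratio > 1, replicate 2 fails
    gDownPass = c(16, 16, 4, 4),
    gNull = c(5, 5, 5, 5),
    gFloored = c(0.1, 0.1, 0.4, 0.4)))  # sub-floor levels never called
  de <- call_de(tbl, "wild-type", "ZnCl2-1mM")
  row <- function(g) de[de$gene_id == g, ]
  expect_equal(row("gPass")$log2_ratio, 2)
  expect_true(row("gPass")$per_replicate_pass)
  expect_equal(row("gPass")$call, "up")
  expect_gt(row("gRepFail")$log2_ratio, 1)
  expect_false(row("gRepFail")$per_replicate_pass)
  expect_equal(row("gRepFail")$call, "none")
  expect_equal(row("gDownPass")$call, "down")
  expect_equal(row("gDownPass")$log2_ratio, -2)
  expect_equal(row("gNull")$call, "none")
  expect_equal(row("gFloored")$log2_ratio, 0)
  expect_equal(row("gFloored")$call, "none")
  expect_error(call_de(tbl, "wild-type", "untreated"),
               "baseline condition equals")
})

test_that("wild-type-untreated baseline mode compares across genotypes", {
  tbl <- tiny_expression(list(gA = c(2, 2, 2, 2, 8, 8, 32, 32)),
                         genotypes = c("wild-type", "ZnT63C-KO"))
  de_same <- call_de(tbl, "ZnT63C-KO", "ZnCl2-1mM")
  de_wt <- call_de(tbl, "ZnT63C-KO", "ZnCl2-1mM",
                   baseline_genotype = "wild-type")
  expect_equal(de_same$log2_ratio, 2)   # 32 vs same-genotype untreated 8
  expect_equal(de_wt$log2_ratio, 4)     # 32 vs wild-type untreated 2
})

test_that("raising the fold-change cutoff never increases DE calls", {
  es <- simulate_expression(expression_sim_config(n_genes = 600, n_core_up = 20L,
                                                  n_core_down = 10L,
                                                  n_shared = 5L), seed = 17)
  cutoffs <- c(0.5, 1, 1.5, 2, 2.5)
  n_calls <- vapply(cutoffs, function(fc) {
    sum(call_de(es$table, "wild-type", "ZnCl2-1mM", fc_cutoff = fc)$call
        != "none")
  }, 0)
  expect_true(all(diff(n_calls) <= 0))
})

test_that("three-genotype overlap isolates the planted responsive core", {
  es <- simulate_expression(expression_sim_config(n_genes = 2000,
                                                  n_core_up = 25L,
                                                  n_core_down = 15L,
                                                  n_shared = 5L), seed = 23)
  de <- lapply(setNames(nm = es$config$genotypes), function(g)
    call_de(es$table, g, "ZnCl2-1mM"))
  core_up_truth <- with(es$truth,
                        unique(gene_id[treatment == "ZnCl2-1mM" & log2fc > 0]))
  ov <- de_overlap(de, "up")
  expect_setequal(ov$full_intersection, core_up_truth)
  # identical lists: intersection equals the list
  same <- list(a = de[[1]], b = de[[1]], c = de[[1]])
  ov2 <- de_overlap(same, "up")
  expect_setequal(ov2$full_intersection, de_genes(de[[1]], "up"))
})

test_that("cross-metal annotation separates shared from metal-specific genes", {
  es <- simulate_expression(expression_sim_config(n_genes = 2000,
                                                  n_core_up = 25L,
                                                  n_core_down = 15L,
                                                  n_shared = 5L), seed = 29)
  zn <- lapply(setNames(nm = es$config$genotypes), function(g)
    call_de(es$table, g, "ZnCl2-1mM"))
  mn <- lapply(setNames(nm = es$config$genotypes), function(g)
    call_de(es$table, g, "MnCl2-1mM"))
  ann <- cross_metal_annotation(zn, mn)
  shared_truth <- with(es$truth,
                       unique(gene_id[treatment == "MnCl2-1mM"]))
  expect_setequal(ann$gene_id[ann$annotation == "shared"], shared_truth)
  expect_false(any(shared_truth %in%
                     ann$gene_id[ann$annotation == "specific"]))
})
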