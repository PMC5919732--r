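test_that("plate normalization divides by the experimental-well average", {
  ds <- tiny_screen(signals = c(100, 200, 300, 400))
  nw <- normalize_plates(ds)
  exp_wells <- nw[nw$is_experimental, ]
  expect_equal(sort(exp_wells$norm_signal), c(0.4, 0.8, 1.2, 1.6))
  # control/edge wells pass through unnormalized and flagged
  expect_true(all(is.na(nw$norm_signal[!nw$is_experimental])))

  # constant plate -> all 1; per-plate mean is exactly 1
  nw2 <- normalize_plates(tiny_screen(signals = rep(500, 4)))
  expect_equal(nw2$norm_signal[nw2$is_experimental], rep(1, 4))
  expect_equal(mean(exp_wells$norm_signal), 1, tolerance = 1e-9)

  # scale invariance
  nw3 <- normalize_plates(tiny_screen(signals = 7.3 * c(100, 200, 300, 400)))
  expect_equal(sort(nw3$norm_signal[nw3$is_experimental]),
               c(0.4, 0.8, 1.2, 1.6), tolerance = 1e-12)

  # degenerate plate
  expect_error(normalize_plates(tiny_screen(signals = rep(0, 4))),
               "zero average")
})

test_that("per-plate normalization mean is 1 on every simulated plate", {
  sim <- simulate_screen(screen_sim_config(n_genes = 400, n_sensitizers = 5L,
                                           n_protectors = 5L), seed = 3)
  nw <- normalize_plates(sim$dataset)
  ex <- nw[nw$is_experimental, ]
  plate_means <- tapply(ex$norm_signal,
                        paste(ex$plate_id, ex$condition, ex$replicate), mean)
  expect_true(all(abs(plate_means - 1) < 1e-9))
})

test_that("replicate averaging uses available replicates only", {
  w <- do.call(rbind, lapply(1:3, function(r) {
    d <- tiny_screen(signals = c(100, 200, 300, 400) * c(0.8, 1.0, 1.2)[r],
                     replicate = r)$wells
    d
  }))
  lib <- tiny_screen()$library
  ds <- screen_dataset(w, lib)
  nw <- normalize_plates(ds)
  av <- average_replicates(nw, "control")
  # normalization removes the scale factor: each replicate contributes the
  # same normalized value, so the mean equals a single replicate
  expect_equal(av$mean_norm[av$reagent_id == "r1"], 0.4)
  expect_equal(av$n_replicates, rep(3L, 4))

  # a missing well is excluded from the mean, not imputed
  w2 <- w
  w2$raw_signal[w2$reagent_id == "r1" & w2$replicate == 3] <- NA
  nw2 <- normalize_plates(screen_dataset(w2, lib))
  av2 <- average_replicates(nw2, "control")
  expect_equal(av2$n_replicates[av2$reagent_id == "r1"], 2L)
  r1_vals <- nw2$norm_signal[nw2$reagent_id == "r1" &
                               !is.na(nw2$norm_signal)]
  expect_equal(av2$mean_norm[av2$reagent_id == "r1"], mean(r1_vals))
})

test_that("Z-scores standardize each condition to mean 0, sample sd 1", {
  mn <- data.frame(reagent_id = c("a", "b", "c"), condition = "control",
                   mean_norm = c(1, 2, 3), stringsAsFactors = FALSE)
  z <- compute_zscores(mn)
  expect_equal(z$z, c(-1, 0, 1))  # sample sd of 1,2,3 is exactly 1

  sim <- simulate_screen(screen_sim_config(n_genes = 300, n_sensitizers = 5L,
                                           n_protectors = 5L), seed = 8)
  fit <- score_screen(sim$dataset)
  for (cond in unique(fit$reagent_scores$condition)) {
    zz <- fit$reagent_scores$z[fit$reagent_scores$condition == cond]
    expect_equal(mean(zz), 0, tolerance = 1e-9)
    expect_equal(sd(zz), 1, tolerance = 1e-9)
  }
  mn$mean_norm <- rep(1, 3)
  expect_error(compute_zscores(mn), "no variance")
})

test_that("reagent hit calls use an inclusive |z| >= 1.5 boundary", {
  sc <- data.frame(reagent_id = c("a", "b", "c", "d"),
                   condition = "c", mean_norm = 1,
                   z = c(1.49, -1.5, 2.0, 1.5), stringsAsFactors = FALSE)
  out <- call_reagent_hits(sc)
  expect_equal(out$is_hit, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$direction, c("none", "down", "up", "up"))
  # cutoff is configurable
  out2 <- call_reagent_hits(sc, z_cutoff = 2)
  expect_equal(out2$is_hit, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("gene aggregation assigns tiers by design concordance", {
  lib <- data.frame(
    reagent_id = c("r1", "r2", "s1", "s2", "s3", "t1", "t2", "u1", "u2"),
    gene_id = c("gHigh", "gHigh", "gTriple", "gTriple", "gTriple",
                "gConflict", "gConflict", "gLow", "gLow"),
    gene_symbol = "x", sublibrary = "TM", stringsAsFactors = FALSE)
  sc <- data.frame(
    reagent_id = lib$reagent_id, condition = "ZnCl2", mean_norm = 1,
    z = c(-1.60, -2.02,   2.1, 1.8, 1.6,   1.9, -1.7,   2.5, 0.3),
    stringsAsFactors = FALSE)
  g <- aggregate_to_genes(call_reagent_hits(sc), lib)
  gi <- function(id, col) g[[col]][g$gene_id == id]

  # two concordant down designs: high, down, avg of all designs
  expect_equal(gi("gHigh", "tier"), "high")
  expect_equal(gi("gHigh", "direction"), "down")
  expect_equal(gi("gHigh", "avg_z"), -1.81)
  # three concordant up designs: high, up
  expect_equal(gi("gTriple", "tier"), "high")
  expect_equal(gi("gTriple", "direction"), "up")
  expect_equal(gi("gTriple", "n_hits_same_dir"), 3L)
  # hits in opposite directions cancel
  expect_equal(gi("gConflict", "tier"), "none")
  expect_equal(gi("gConflict", "direction"), "none")
  # single hitting design: low
  expect_equal(gi("gLow", "tier"), "low")
  expect_equal(gi("gLow", "avg_z"), 1.4)
  # hitting-designs-only averaging is available
  g2 <- aggregate_to_genes(call_reagent_hits(sc), lib, avg_hits_only = TRUE)
  expect_equal(g2$avg_z[g2$gene_id == "gLow"], 2.5)

  # unmapped reagent is an error
  sc$reagent_id[1] <- "zz"
  expect_error(aggregate_to_genes(call_reagent_hits(sc), lib),
               "missing from library")
})

test_that("frequent hitters are flagged strictly above the cutoff", {
  g <- data.frame(gene_id = c("a", "b", "c"), tier = "high",
                  frequent_hitter = FALSE, stringsAsFactors = FALSE)
  ft <- data.frame(gene_id = c("a", "b"), frequency = c(0.6, 0.5),
                   stringsAsFactors = FALSE)
  out <- flag_frequent_hitters(g, ft)
  expect_equal(out$frequent_hitter, c(TRUE, FALSE, FALSE))
  ft$frequency[1] <- 1.2
  expect_error(flag_frequent_hitters(g, ft), "\\[0, 1\\]")
})

test_that("replicate correlation is exact for linear and degenerate cases", {
  lib <- tiny_screen()$library
  w1 <- tiny_screen(signals = c(1, 2, 3, 4), replicate = 1L)$wells
  w2 <- tiny_screen(signals = c(2, 4, 6, 8), replicate = 2L)$wells
  w3 <- tiny_screen(signals = c(4, 3, 2, 1), replicate = 3L)$wells
  nw <- normalize_plates(screen_dataset(rbind(w1, w2, w3), lib))
  qc <- replicate_correlation(nw, use = "raw_signal")
  r12 <- qc$r[qc$replicate_1 == 1 & qc$replicate_2 == 2]
  r13 <- qc$r[qc$replicate_1 == 1 & qc$replicate_2 == 3]
  expect_equal(r12, 1)
  expect_equal(r13, -1)
  expect_true(all(qc$type == "within"))
})

test_that("condition-specific effects make within-condition correlation exceed cross", {
  sim <- simulate_screen(screen_sim_config(n_genes = 400,
                                           n_sensitizers = 5L,
                                           n_protectors = 5L), seed = 21)
  nw <- normalize_plates(sim$dataset)
  qc <- replicate_correlation(nw)
  r_within <- mean(qc$r[qc$type == "within"], na.rm = TRUE)
  r_cross <- mean(qc$r[qc$type == "cross"], na.rm = TRUE)
  expect_gt(r_within, r_cross)
})

test_that("overlap reports satisfy inclusion-exclusion and keep members", {
  lists <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
                C = c("g9"))
  ov <- cross_screen_overlap(lists)
  expect_equal(ov$pairwise$union,
               ov$pairwise$size_1 + ov$pairwise$size_2 -
                 ov$pairwise$intersection)
  expect_equal(sort(ov$pair_members[["A & B"]]), c("g2", "g3"))
  expect_equal(length(ov$full_intersection), 0L)
  expect_equal(length(ov$union), 5L)
  # disjoint lists: union is the sum of sizes
  ov2 <- cross_screen_overlap(list(X = c("a", "b"), Y = c("c")))
  expect_equal(ov2$pairwise$intersection, 0L)
  expect_equal(length(ov2$union), 3L)
})

test_that("lowering the cutoff grows the hit set; high-tier demotions only arise from direction conflicts", {
  sim <- simulate_screen(screen_sim_config(n_genes = 500, n_sensitizers = 5L,
                                           n_protectors = 5L), seed = 13)
  fit_hi <- score_screen(sim$dataset, z_cutoff = 1.5)
  fit_lo <- score_screen(sim$dataset, z_cutoff = 1.0)
  # reagent-level hit set is monotone in the cutoff
  expect_true(all(fit_hi$reagent_scores$is_hit[
    order(fit_hi$reagent_scores$reagent_id,
          fit_hi$reagent_scores$condition)] <=
      fit_lo$reagent_scores$is_hit[
        order(fit_lo$reagent_scores$reagent_id,
              fit_lo$reagent_scores$condition)]))
  key_hi <- paste(fit_hi$gene_scores$gene_id, fit_hi$gene_scores$condition)
  key_lo <- paste(fit_lo$gene_scores$gene_id, fit_lo$gene_scores$condition)
  was_high <- key_hi[fit_hi$gene_scores$tier == "high"]
  lo_tier <- fit_lo$gene_scores$tier[match(was_high, key_lo)]
  demoted <- was_high[lo_tier != "high"]
  # any demotion must be explained by a newly-hitting opposite design
  for (k in demoted) {
    row <- fit_lo$gene_scores[match(k, key_lo), ]
    sc <- fit_lo$reagent_scores
    sc <- sc[sc$condition == row$condition, ]
    lib <- sim$dataset$library
    designs <- sc[sc$reagent_id %in%
                    lib$reagent_id[lib$gene_id == row$gene_id], ]
    expect_true(all(c("up", "down") %in% designs$direction))
  }
})
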