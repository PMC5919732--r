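#' Identify edge wells of a 384-well plate
#'
#' Experimental dsRNAs are excluded from the outermost two rows and columns
#' of the assay plates to limit edge effects, so those wells never enter the
#' plate average.
#'
#' @param row character vector of plate rows (A-P).
#' @param col integer vector of plate columns (1-24).
#' @param margin number of outermost rows/columns treated as edge (default 2).
#' @return Logical vector, `TRUE` for edge wells.
#' @export
is_edge_well <- function(row, col, margin = 2L) {
  ri <- match(row, PLATE_ROWS)
  ri <= margin | ri > (length(PLATE_ROWS) - margin) |
    col <= margin | col > (max(PLATE_COLS) - margin)
}

#' Normalize well signals to the plate average
#'
#' Each physical plate (a unique `plate_id` x `condition` x `replicate`
#' combination) is normalized by dividing every experimental well's raw
#' signal by the mean raw signal of that plate's experimental wells.
#' Experimental wells are non-edge wells carrying a reagent; control and
#' edge wells pass through with `norm_signal = NA` and are flagged.
#'
#' @param dataset a `screen_dataset`.
#' @param edge_margin outermost rows/columns excluded as edge wells.
#' @return Data frame of wells with added `is_experimental` and
#'   `norm_signal` columns. The mean of `norm_signal` over the experimental
#'   wells of every plate is 1.
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 20), seed = 1)
#' nw <- normalize_plates(sim$dataset)
#' tapply(nw$norm_signal[nw$is_experimental],
#'        interaction(nw$plate_id, nw$condition, nw$replicate,
#'                    drop = TRUE)[nw$is_experimental], mean)
#' @export
normalize_plates <- function(dataset, edge_margin = 2L) {
  stopifnot(inherits(dataset, "screen_dataset"))
  wells <- dataset$wells
  wells$is_experimental <- !is.na(wells$reagent_id) &
    nzchar(wells$reagent_id) &
    !is_edge_well(wells$row, wells$col, edge_margin)
  wells$norm_signal <- NA_real_
  plate_key <- paste(wells$plate_id, wells$condition, wells$replicate,
                     sep = "\r")
  exp_idx <- which(wells$is_experimental & !is.na(wells$raw_signal))
  if (length(exp_idx) == 0L) {
    stop_format("normalize_plates: no experimental wells with signal")
  }
  plate_means <- tapply(wells$raw_signal[exp_idx], plate_key[exp_idx], mean)
  if (any(plate_means == 0)) {
    stop_format("normalize_plates: degenerate plate with zero average signal: %s",
                paste(names(plate_means)[plate_means == 0], collapse = "; "))
  }
  wells$norm_signal[exp_idx] <-
    wells$raw_signal[exp_idx] / plate_means[plate_key[exp_idx]]
  wells
}

#' Average normalized signals over replicate plates
#'
#' For one treatment condition, averages each reagent's normalized signal
#' over the replicate plates on which it was measured. Missing wells are
#' excluded, not imputed; a reagent absent (or missing) in every replicate
#' of the condition is dropped with a warning.
#'
#' @param normalized data frame from [normalize_plates()].
#' @param condition condition label to average within.
#' @return Data frame with `reagent_id`, `condition`, `mean_norm`, and
#'   `n_replicates` (replicates contributing to the mean).
#' @export
average_replicates <- function(normalized, condition) {
  sub <- normalized[normalized$condition == condition &
                      normalized$is_experimental, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop_format("average_replicates: no experimental wells for condition '%s'",
                condition)
  }
  ok <- !is.na(sub$norm_signal)
  n_all <- tapply(sub$norm_signal, sub$reagent_id, length)
  dropped <- names(n_all)[!(names(n_all) %in% unique(sub$reagent_id[ok]))]
  if (length(dropped) > 0L) {
    warning(sprintf("condition '%s': %d reagent(s) with no usable replicate dropped",
                    condition, length(dropped)), call. = FALSE)
  }
  sub <- sub[ok, , drop = FALSE]
  mean_norm <- tapply(sub$norm_signal, sub$reagent_id, mean)
  n_rep <- tapply(sub$norm_signal, sub$reagent_id, length)
  data.frame(reagent_id = names(mean_norm),
             condition = condition,
             mean_norm = as.numeric(mean_norm),
             n_replicates = as.integer(n_rep),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Standardize replicate-averaged signals to Z-scores
#'
#' Z-scores place every reagent of one condition on a common scale: the
#' reference population is all replicate-averaged normalized values of that
#' condition (pooling its plates), standardized with the sample standard
#' deviation (n-1 denominator).
#'
#' @param mean_norms data frame from [average_replicates()].
#' @return The input with a `z` column; per condition, `mean(z) = 0` and
#'   `sd(z) = 1`.
#' @export
compute_zscores <- function(mean_norms) {
  check_columns(mean_norms, c("reagent_id", "condition", "mean_norm"),
                "mean_norms")
  mean_norms$z <- NA_real_
  for (cond in unique(mean_norms$condition)) {
    idx <- mean_norms$condition == cond
    x <- mean_norms$mean_norm[idx]
    if (length(unique(x)) < 2L) {
      stop_format("compute_zscores: condition '%s' has no variance", cond)
    }
    mean_norms$z[idx] <- (x - mean(x)) / stats::sd(x)
  }
  mean_norms
}

#' Call reagent-level hits from Z-scores
#'
#' A reagent is a hit when its Z-score magnitude reaches the cutoff
#' (inclusive boundary: `|z| >= z_cutoff`); direction is `up` for positive
#' scores (increased ATP / protected) and `down` for negative scores
#' (decreased ATP / sensitized).
#'
#' @param scores data frame with a `z` column ([compute_zscores()]).
#' @param z_cutoff hit threshold on `|z|` (default 1.5).
#' @return The input with `is_hit` (logical) and `direction`
#'   (`"up"`/`"down"`/`"none"`) columns.
#' @export
call_reagent_hits <- function(scores, z_cutoff = 1.5) {
  check_columns(scores, "z", "reagent scores")
  scores$is_hit <- abs(scores$z) >= z_cutoff
  scores$direction <- ifelse(!scores$is_hit, "none",
                             ifelse(scores$z > 0, "up", "down"))
  scores
}

#' Aggregate reagent scores to gene-level confidence tiers
#'
#' Combines all dsRNA designs targeting a gene into one gene-level call per
#' condition. A gene is a high-confidence hit when at least two designs are
#' hits in the same direction and no design is a hit in the opposite
#' direction; a single hitting design (with none opposite) is a
#' low-confidence hit; designs hitting in opposite directions cancel to
#' `none`. The moderate tier is assigned only later, by enrichment-based
#' promotion ([promote_confidence()]).
#'
#' @param scores reagent scores with hit calls ([call_reagent_hits()]).
#' @param library reagent library mapping `reagent_id` to `gene_id`.
#' @param avg_hits_only if `TRUE`, `avg_z` averages only the hitting
#'   designs; the default averages all designs targeting the gene.
#' @return Gene-score data frame: `gene_id`, `gene_symbol`, `condition`,
#'   `avg_z`, `direction`, `n_designs` (designs in the library),
#'   `n_scored` (designs with a Z-score), `n_hits_same_dir`, `tier`,
#'   `frequent_hitter` (initialized `FALSE`).
#' @examples
#' lib <- data.frame(reagent_id = c("r1", "r2"), gene_id = "g1",
#'                   gene_symbol = "g1", sublibrary = "TM")
#' sc <- data.frame(reagent_id = c("r1", "r2"), condition = "ZnCl2",
#'                  mean_norm = c(0.8, 0.7), z = c(-1.60, -2.02))
#' aggregate_to_genes(call_reagent_hits(sc), lib)  # high, down, avg_z -1.81
#' @export
aggregate_to_genes <- function(scores, library, avg_hits_only = FALSE) {
  check_columns(scores, c("reagent_id", "condition", "z", "is_hit",
                          "direction"), "reagent scores")
  library <- validate_reagent_library(library)
  unknown <- setdiff(unique(scores$reagent_id), library$reagent_id)
  if (length(unknown) > 0L) {
    stop_format("aggregate_to_genes: reagent(s) missing from library: %s",
                paste(utils::head(unknown, 10L), collapse = ", "))
  }
  li <- match(scores$reagent_id, library$reagent_id)
  scores$gene_id <- library$gene_id[li]
  n_designs_lib <- table(library$gene_id)
  symbol_of <- library$gene_symbol[!duplicated(library$gene_id)]
  names(symbol_of) <- library$gene_id[!duplicated(library$gene_id)]

  out <- do.call(rbind, lapply(split(scores, scores[c("gene_id", "condition")],
                                     drop = TRUE), function(g) {
    n_up <- sum(g$direction == "up")
    n_down <- sum(g$direction == "down")
    if (n_up > 0L && n_down > 0L) {
      tier <- "none"; dir <- "none"; n_same <- 0L
    } else if (n_up + n_down >= 2L) {
      tier <- "high"; dir <- if (n_up > 0L) "up" else "down"
      n_same <- n_up + n_down
    } else if (n_up + n_down == 1L) {
      tier <- "low"; dir <- if (n_up > 0L) "up" else "down"; n_same <- 1L
    } else {
      tier <- "none"; dir <- "none"; n_same <- 0L
    }
    zz <- if (avg_hits_only && n_same > 0L) g$z[g$is_hit] else g$z
    data.frame(gene_id = g$gene_id[1],
               gene_symbol = unname(symbol_of[g$gene_id[1]]),
               condition = g$condition[1],
               avg_z = mean(zz),
               direction = dir,
               n_designs = as.integer(n_designs_lib[g$gene_id[1]]),
               n_scored = nrow(g),
               n_hits_same_dir = n_same,
               tier = tier,
               frequent_hitter = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$gene_id), , drop = FALSE]
}

#' Flag frequent hitters from reference screen frequencies
#'
#' Genes that score in a majority of unrelated public RNAi screens are
#' likely assay-generic rather than condition-specific; they are flagged
#' (not removed) when their reference hit frequency strictly exceeds the
#' cutoff. Genes absent from the frequency table count as frequency 0.
#'
#' @param gene_scores gene-score data frame ([aggregate_to_genes()]).
#' @param freq_table data frame with `gene_id` and `frequency` (fraction of
#'   reference screens in which the gene scored, in `[0, 1]`).
#' @param cutoff strict flagging threshold (default 0.5, i.e. >50%).
#' @return The gene scores with `frequent_hitter` updated.
#' @export
flag_frequent_hitters <- function(gene_scores, freq_table, cutoff = 0.5) {
  check_columns(freq_table, c("gene_id", "frequency"), "frequency table")
  if (any(freq_table$frequency < 0 | freq_table$frequency > 1, na.rm = TRUE)) {
    stop_format("frequency table: frequencies must be in [0, 1]")
  }
  freq <- freq_table$frequency[match(gene_scores$gene_id, freq_table$gene_id)]
  freq[is.na(freq)] <- 0
  gene_scores$frequent_hitter <- freq > cutoff
  gene_scores
}

#' Replicate-correlation quality control
#'
#' Pearson correlation between plate replicates, matching wells by plate
#' layout position (`plate_id`, `row`, `col`) on experimental wells.
#' Within-condition pairs (same condition, different replicate) measure
#' reproducibility; cross-condition pairs (same plate layout, different
#' conditions) measure condition specificity. Pairs sharing fewer than
#' three wells, or with zero variance in either vector, are reported as
#' `NA`.
#'
#' @param normalized data frame from [normalize_plates()].
#' @param use either `"norm_signal"` (default) or `"raw_signal"`.
#' @return Data frame with one row per plate pair: `plate_id`,
#'   `condition_1`, `replicate_1`, `condition_2`, `replicate_2`, `type`
#'   (`"within"`/`"cross"`), `n_wells`, `r`.
#' @export
replicate_correlation <- function(normalized, use = "norm_signal") {
  sub <- normalized[normalized$is_experimental &
                      !is.na(normalized[[use]]), , drop = FALSE]
  sub$inst <- paste(sub$condition, sub$replicate, sep = "\r")
  out <- list()
  for (pid in unique(sub$plate_id)) {
    p <- sub[sub$plate_id == pid, , drop = FALSE]
    insts <- unique(p$inst)
    if (length(insts) < 2L) next
    for (i in seq_len(length(insts) - 1L)) {
      for (j in seq.int(i + 1L, length(insts))) {
        a <- p[p$inst == insts[i], , drop = FALSE]
        b <- p[p$inst == insts[j], , drop = FALSE]
        key_a <- paste(a$row, a$col)
        key_b <- paste(b$row, b$col)
        shared <- intersect(key_a, key_b)
        va <- a[[use]][match(shared, key_a)]
        vb <- b[[use]][match(shared, key_b)]
        r <- if (length(shared) < 3L ||
                 stats::sd(va) == 0 || stats::sd(vb) == 0) {
          NA_real_
        } else {
          stats::cor(va, vb)
        }
        ca <- a$condition[1]; cb <- b$condition[1]
        out[[length(out) + 1L]] <- data.frame(
          plate_id = pid,
          condition_1 = ca, replicate_1 = a$replicate[1],
          condition_2 = cb, replicate_2 = b$replicate[1],
          type = if (ca == cb) "within" else "cross",
          n_wells = length(shared), r = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(plate_id = character(), condition_1 = character(),
                      replicate_1 = integer(), condition_2 = character(),
                      replicate_2 = integer(), type = character(),
                      n_wells = integer(), r = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Overlap report for labeled gene lists
#'
#' Computes all pairwise intersections, the full k-way intersection, and
#' the union of two or more deduplicated gene lists, retaining member gene
#' ids. Reported sizes satisfy inclusion-exclusion:
#' `|A u B| = |A| + |B| - |A n B|` for every pair.
#'
#' @param gene_lists named list of character vectors of gene ids.
#' @return An `overlap_report`: list with `labels`, `sizes` (per-list
#'   deduplicated sizes), `pairwise` (data frame with intersection and
#'   union sizes per pair), `pair_members` (list of intersection members),
#'   `full_intersection`, and `union`.
#' @export
cross_screen_overlap <- function(gene_lists) {
  if (is.null(names(gene_lists)) || length(gene_lists) < 2L) {
    stop_format("cross_screen_overlap: need >=2 named gene lists")
  }
  gene_lists <- lapply(gene_lists, function(g) unique(as.character(g)))
  labels <- names(gene_lists)
  pairs <- utils::combn(labels, 2L)
  pair_members <- list()
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    inter <- intersect(gene_lists[[a]], gene_lists[[b]])
    pair_members[[paste(a, b, sep = " & ")]] <<- inter
    data.frame(list_1 = a, list_2 = b,
               size_1 = length(gene_lists[[a]]),
               size_2 = length(gene_lists[[b]]),
               intersection = length(inter),
               union = length(union(gene_lists[[a]], gene_lists[[b]])),
               stringsAsFactors = FALSE)
  }))
  structure(list(labels = labels,
                 sizes = vapply(gene_lists, length, 1L),
                 pairwise = pw,
                 pair_members = pair_members,
                 full_intersection = Reduce(intersect, gene_lists),
                 union = Reduce(union, gene_lists)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report over", length(x$labels), "lists\n")
  cat("sizes:", paste(sprintf("%s=%d", x$labels, x$sizes), collapse = ", "),
      "\n")
  cat("union:", length(x$union), "genes;",
      "full intersection:", length(x$full_intersection), "genes\n")
  if (length(x$full_intersection) > 0 && length(x$full_intersection) <= 25) {
    cat("  ", paste(x$full_intersection, collapse = ", "), "\n")
  }
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Run the full screen scoring chain
#'
#' One-call wrapper over the screen statistic chain: plate-average
#' normalization, replicate averaging per condition, condition-wide
#' Z-scores, reagent hit calls at `z_cutoff`, gene-level tier aggregation,
#' optional frequent-hitter flagging, and replicate-correlation QC.
#'
#' @param dataset a `screen_dataset`.
#' @param z_cutoff reagent hit threshold on `|z|` (default 1.5).
#' @param avg_hits_only average only hitting designs in `avg_z`
#'   (default `FALSE`: all designs).
#' @param freq_table optional frequent-hitter frequency table
#'   ([flag_frequent_hitters()]).
#' @param freq_cutoff frequent-hitter cutoff (default 0.5).
#' @param edge_margin outermost rows/columns excluded as edge wells.
#' @return An object of class `screen_scores`: list with `reagent_scores`,
#'   `gene_scores`, `qc` (replicate correlations), `normalized` wells, and
#'   the parameters used.
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 50), seed = 7)
#' fit <- score_screen(sim$dataset)
#' summary(fit)
#' @export
score_screen <- function(dataset, z_cutoff = 1.5, avg_hits_only = FALSE,
                         freq_table = NULL, freq_cutoff = 0.5,
                         edge_margin = 2L) {
  nw <- normalize_plates(dataset, edge_margin = edge_margin)
  per_cond <- lapply(unique(nw$condition[nw$is_experimental]),
                     function(cond) average_replicates(nw, cond))
  scores <- compute_zscores(do.call(rbind, per_cond))
  scores <- call_reagent_hits(scores, z_cutoff = z_cutoff)
  genes <- aggregate_to_genes(scores, dataset$library,
                              avg_hits_only = avg_hits_only)
  if (!is.null(freq_table)) {
    genes <- flag_frequent_hitters(genes, freq_table, cutoff = freq_cutoff)
  }
  structure(list(reagent_scores = scores,
                 gene_scores = genes,
                 qc = replicate_correlation(nw),
                 normalized = nw,
                 z_cutoff = z_cutoff,
                 avg_hits_only = avg_hits_only),
            class = "screen_scores")
}

#' Extract a hit list from screen scores
#'
#' @param x a `screen_scores` object.
#' @param condition condition label.
#' @param tiers tiers to include (default high + moderate + low).
#' @param direction `"up"`, `"down"`, or `NULL` for both.
#' @return Character vector of gene ids.
#' @export
hit_genes <- function(x, condition, tiers = c("high", "moderate", "low"),
                      direction = NULL) {
  stopifnot(inherits(x, "screen_scores"))
  g <- x$gene_scores
  keep <- g$condition == condition & g$tier %in% tiers
  if (!is.null(direction)) keep <- keep & g$direction == direction
  unique(g$gene_id[keep])
}

#' @export
print.screen_scores <- function(x, ...) {
  cat("screen_scores (z_cutoff =", x$z_cutoff, ")\n")
  cat(nrow(x$reagent_scores), "reagent x condition scores;",
      nrow(x$gene_scores), "gene x condition scores\n")
  tab <- table(x$gene_scores$condition, x$gene_scores$tier)
  print(tab)
  invisible(x)
}

#' @export
summary.screen_scores <- function(object, ...) {
  g <- object$gene_scores
  hc <- g[g$tier == "high", , drop = FALSE]
  counts <- as.data.frame(table(condition = hc$condition,
                                direction = hc$direction))
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  qc <- object$qc
  r_within <- mean(qc$r[qc$type == "within"], na.rm = TRUE)
  r_cross <- mean(qc$r[qc$type == "cross"], na.rm = TRUE)
  out <- list(high_confidence = counts,
              n_high = nrow(hc), n_low = sum(g$tier == "low"),
              r_within = r_within, r_cross = r_cross,
              z_cutoff = object$z_cutoff)
  class(out) <- "summary.screen_scores"
  out
}

#' @export
print.summary.screen_scores <- function(x, ...) {
  cat("High-confidence hits (>=2 concordant designs), z_cutoff =",
      x$z_cutoff, "\n")
  print(x$high_confidence, row.names = FALSE)
  cat("total high:", x$n_high, " low:", x$n_low, "\n")
  cat(sprintf("replicate Pearson r: within-condition %.2f, cross-condition %.2f\n",
              x$r_within, x$r_cross))
  invisible(x)
}
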