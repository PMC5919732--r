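#' Configuration for a simulated arrayed RNAi screen
#'
#' The defaults emulate the screened library and design: ~2000 genes
#' targeted by 1-3 independent dsRNA designs each (about two on average)
#' arrayed on 384-well plates whose outermost two rows and columns carry no
#' experimental reagent, screened under a control condition (2 replicate
#' plate sets) and two metal-supplemented conditions (3 replicate sets
#' each), with multiplicative (log-normal) plate, reagent, and well noise.
#' Condition-specific sensitizer (signal down on knockdown) and protector
#' (signal up) genes are planted on two-design genes as multiplicative
#' shifts of the normalized signal.
#'
#' @param n_genes number of targeted genes (default 2000).
#' @param design_probs named probabilities of 1, 2, or 3 designs per gene.
#' @param conditions condition labels; the first is the control.
#' @param replicates named integer vector of replicate plate sets per
#'   condition.
#' @param plate_effect_sd log-scale sd of per-plate multiplicative effects.
#' @param well_noise_sd log-scale sd of per-well noise.
#' @param reagent_effect_sd log-scale sd of reagent-intrinsic effects
#'   (reproducible across replicates and conditions, e.g. generic dsRNA
#'   toxicity).
#' @param base_signal plate-average raw luminescence scale.
#' @param n_sensitizers,n_protectors planted genes per metal condition.
#' @param sensitizer_effect,protector_effect multiplicative shifts of the
#'   normalized signal for planted genes (must be positive).
#' @param planted_conditions conditions receiving planted effects
#'   (default: all but the first/control).
#' @param planted optional explicit data frame (`gene_id`, `condition`,
#'   `effect`) overriding the default planting.
#' @param edge_margin outermost rows/columns left reagent-free.
#' @return Validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 2000L,
                              design_probs = c("1" = 0.05, "2" = 0.85,
                                               "3" = 0.10),
                              conditions = c("control", "ZnCl2", "MnCl2"),
                              replicates = c(control = 2L, ZnCl2 = 3L,
                                             MnCl2 = 3L),
                              plate_effect_sd = 0.10,
                              well_noise_sd = 0.12,
                              reagent_effect_sd = 0.08,
                              base_signal = 5e4,
                              n_sensitizers = 10L,
                              n_protectors = 10L,
                              sensitizer_effect = 0.55,
                              protector_effect = 1.8,
                              planted_conditions = NULL,
                              planted = NULL,
                              edge_margin = 2L) {
  if (n_genes < 1L) stop_format("screen_sim_config: n_genes must be >= 1")
  if (abs(sum(design_probs) - 1) > 1e-8 || any(design_probs < 0)) {
    stop_format("screen_sim_config: design_probs must be a probability vector")
  }
  if (!all(names(replicates) %in% conditions) ||
      !all(conditions %in% names(replicates))) {
    stop_format("screen_sim_config: replicates must be named by condition")
  }
  if (any(c(plate_effect_sd, well_noise_sd, reagent_effect_sd) < 0)) {
    stop_format("screen_sim_config: noise sds must be non-negative")
  }
  if (sensitizer_effect <= 0 || protector_effect <= 0) {
    stop_format("screen_sim_config: planted effect sizes must be positive")
  }
  planted_conditions <- planted_conditions %||% setdiff(conditions,
                                                        conditions[1])
  structure(list(n_genes = as.integer(n_genes),
                 design_probs = design_probs,
                 conditions = conditions, replicates = replicates,
                 plate_effect_sd = plate_effect_sd,
                 well_noise_sd = well_noise_sd,
                 reagent_effect_sd = reagent_effect_sd,
                 base_signal = base_signal,
                 n_sensitizers = as.integer(n_sensitizers),
                 n_protectors = as.integer(n_protectors),
                 sensitizer_effect = sensitizer_effect,
                 protector_effect = protector_effect,
                 planted_conditions = planted_conditions,
                 planted = planted,
                 edge_margin = as.integer(edge_margin)),
            class = "screen_sim_config")
}

#' Simulate an arrayed RNAi screen with planted ground truth
#'
#' Generates raw per-well luminescence as
#' `base_signal x plate_effect x reagent_effect x condition_effect x noise`
#' on 384-well plates whose edge wells carry no reagent, together with the
#' reagent library and the planted-effect truth table. Deterministic given
#' `config` and `seed`.
#'
#' @param config a `screen_sim_config`.
#' @param seed integer random seed.
#' @return List of class `screen_sim`: `dataset` (a `screen_dataset`),
#'   `truth` (data frame `gene_id`, `condition`, `role`, `effect`), and
#'   `config`.
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 30), seed = 42)
#' sim$truth
#' @export
simulate_screen <- function(config, seed) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(as.integer(seed))
  n_designs <- sample(as.integer(names(config$design_probs)),
                      config$n_genes, replace = TRUE,
                      prob = config$design_probs)
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  lib <- data.frame(
    reagent_id = unlist(lapply(seq_len(config$n_genes), function(g) {
      sprintf("%s_d%d", gene_ids[g], seq_len(n_designs[g]))
    })),
    gene_id = rep(gene_ids, n_designs),
    gene_symbol = rep(gene_ids, n_designs),
    sublibrary = rep(sample(c("TM", "AUTGY", "MBO1", "Megadeath"),
                            config$n_genes, replace = TRUE,
                            prob = c(0.7, 0.1, 0.1, 0.1)), n_designs),
    stringsAsFactors = FALSE)
  n_reagents <- nrow(lib)

  # plate layout: reagents fill the non-edge wells plate by plate
  m <- config$edge_margin
  usable_rows <- PLATE_ROWS[(m + 1L):(16L - m)]
  usable_cols <- (m + 1L):(24L - m)
  wells_per_plate <- length(usable_rows) * length(usable_cols)
  n_plates <- ceiling(n_reagents / wells_per_plate)
  plate_ids <- sprintf("P%02d", seq_len(n_plates))
  layout_exp <- data.frame(
    plate = rep(seq_len(n_plates), each = wells_per_plate)[seq_len(n_reagents)],
    row = rep(rep(usable_rows, each = length(usable_cols)),
              n_plates)[seq_len(n_reagents)],
    col = rep(rep(usable_cols, length(usable_rows)),
              n_plates)[seq_len(n_reagents)],
    reagent_id = lib$reagent_id,
    stringsAsFactors = FALSE)
  edge_grid <- expand.grid(row = PLATE_ROWS, col = PLATE_COLS,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
  edge_grid <- edge_grid[is_edge_well(edge_grid$row, edge_grid$col, m), ]
  layout_edge <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
    data.frame(plate = p, row = edge_grid$row, col = edge_grid$col,
               reagent_id = "", stringsAsFactors = FALSE)
  }))
  layout <- rbind(layout_exp, layout_edge)

  # planted condition-specific effects on two-design genes
  truth <- config$planted
  if (is.null(truth)) {
    two_design <- gene_ids[n_designs == 2L]
    per_cond <- config$n_sensitizers + config$n_protectors
    need <- per_cond * length(config$planted_conditions)
    if (length(two_design) < need) {
      stop_format("simulate_screen: not enough two-design genes (%d) for %d planted slots",
                  length(two_design), need)
    }
    truth <- data.frame(gene_id = character(), condition = character(),
                        role = character(), effect = numeric(),
                        stringsAsFactors = FALSE)
    if (need > 0L) {
      chosen <- sample(two_design, need)
      truth <- do.call(rbind, lapply(seq_along(config$planted_conditions),
                                     function(i) {
        cond <- config$planted_conditions[i]
        off <- (i - 1L) * per_cond
        data.frame(
          gene_id = chosen[off + seq_len(per_cond)],
          condition = cond,
          role = rep(c("sensitizer", "protector"),
                     c(config$n_sensitizers, config$n_protectors)),
          effect = rep(c(config$sensitizer_effect, config$protector_effect),
                       c(config$n_sensitizers, config$n_protectors)),
          stringsAsFactors = FALSE)
      }))
    }
  }

  reagent_effect <- exp(stats::rnorm(n_reagents, 0,
                                     config$reagent_effect_sd))
  names(reagent_effect) <- lib$reagent_id
  gene_of <- lib$gene_id
  names(gene_of) <- lib$reagent_id

  all_wells <- list()
  for (cond in config$conditions) {
    effect_of <- rep(1, config$n_genes)
    names(effect_of) <- gene_ids
    tr <- truth[truth$condition == cond, , drop = FALSE]
    effect_of[tr$gene_id] <- tr$effect
    for (rep_i in seq_len(config$replicates[[cond]])) {
      plate_eff <- exp(stats::rnorm(n_plates, 0, config$plate_effect_sd))
      is_exp <- nzchar(layout$reagent_id)
      cond_eff <- rep(1, nrow(layout))
      cond_eff[is_exp] <- effect_of[gene_of[layout$reagent_id[is_exp]]]
      reag_eff <- rep(1, nrow(layout))
      reag_eff[is_exp] <- reagent_effect[layout$reagent_id[is_exp]]
      signal <- config$base_signal * plate_eff[layout$plate] * reag_eff *
        cond_eff * exp(stats::rnorm(nrow(layout), 0, config$well_noise_sd))
      all_wells[[length(all_wells) + 1L]] <- data.frame(
        plate_id = plate_ids[layout$plate],
        row = layout$row, col = layout$col,
        reagent_id = layout$reagent_id,
        raw_signal = signal,
        condition = cond, replicate = rep_i,
        stringsAsFactors = FALSE)
    }
  }
  wells <- do.call(rbind, all_wells)
  rownames(wells) <- NULL
  structure(list(dataset = screen_dataset(wells, lib,
                                          conditions = config$conditions),
                 truth = truth, config = config),
            class = "screen_sim")
}

#' Configuration for a simulated FPKM expression study
#'
#' The defaults emulate the transcriptomics design: three genotypes
#' (wild-type plus two knockout lines) x three treatments (untreated, mild
#' zinc, mild manganese supplementation) x two replicates, log-normal
#' baseline expression with a fraction of near-silent genes, log-normal
#' replicate noise, and planted multiplicative responses: a core of genes
#' responsive to the primary treatment in all genotypes (up and down), and
#' a smaller group shared between both treatments (counter-ion/generic
#' responders). Planted genes are drawn from genes with baseline FPKM >= 5
#' so that the detection floor cannot mask a planted response.
#'
#' @param n_genes number of genes (default 8000).
#' @param genotypes,treatments condition labels; the first treatment is
#'   the untreated baseline.
#' @param replicates replicates per genotype x treatment (default 2).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline FPKM
#'   parameters (natural log).
#' @param noise_sd_log2 replicate noise sd on the log2 scale.
#' @param floor_fraction fraction of genes with near-zero baseline
#'   (uniform on 0.001-0.5 FPKM).
#' @param n_core_up,n_core_down genes planted up/down in all genotypes
#'   under the primary treatment.
#' @param n_shared genes additionally planted (up) under the secondary
#'   treatment as well.
#' @param effect_log2 planted |log2| effect size (default 2, fourfold).
#' @param planted optional explicit data frame (`gene_id`, `genotype`,
#'   `treatment`, `log2fc`) overriding the default planting.
#' @return Validated list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 8000L,
                                  genotypes = c("wild-type", "IA2-KO",
                                                "ZnT63C-KO"),
                                  treatments = c("untreated", "ZnCl2-1mM",
                                                 "MnCl2-1mM"),
                                  replicates = 2L,
                                  baseline_meanlog = 1.5,
                                  baseline_sdlog = 1.5,
                                  noise_sd_log2 = 0.15,
                                  floor_fraction = 0.25,
                                  n_core_up = 60L, n_core_down = 40L,
                                  n_shared = 20L,
                                  effect_log2 = 2,
                                  planted = NULL) {
  if (noise_sd_log2 < 0) {
    stop_format("expression_sim_config: noise sd must be non-negative")
  }
  if (baseline_sdlog <= 0) {
    stop_format("expression_sim_config: baseline_sdlog must be positive")
  }
  if (floor_fraction < 0 || floor_fraction > 1) {
    stop_format("expression_sim_config: floor_fraction must be in [0, 1]")
  }
  if (!is.finite(effect_log2)) {
    stop_format("expression_sim_config: effect_log2 must be finite")
  }
  structure(list(n_genes = as.integer(n_genes), genotypes = genotypes,
                 treatments = treatments,
                 replicates = as.integer(replicates),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 noise_sd_log2 = noise_sd_log2,
                 floor_fraction = floor_fraction,
                 n_core_up = as.integer(n_core_up),
                 n_core_down = as.integer(n_core_down),
                 n_shared = as.integer(n_shared),
                 effect_log2 = effect_log2,
                 planted = planted),
            class = "expression_sim_config")
}

#' Simulate an FPKM expression table with planted responses
#'
#' FPKM values are
#' `baseline x 2^(planted log2 effect) x 2^noise`; all values are
#' non-negative by construction and the result is deterministic given
#' `config` and `seed`.
#'
#' @param config an `expression_sim_config`.
#' @param seed integer random seed.
#' @return List of class `expression_sim`: `table` (an
#'   `expression_table`), `truth` (data frame `gene_id`, `genotype`,
#'   `treatment`, `log2fc`), `baseline` (named vector), and `config`.
#' @export
simulate_expression <- function(config, seed) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(as.integer(seed))
  gene_ids <- sprintf("E%05d", seq_len(config$n_genes))
  n_floor <- round(config$floor_fraction * config$n_genes)
  baseline <- exp(stats::rnorm(config$n_genes, config$baseline_meanlog,
                               config$baseline_sdlog))
  if (n_floor > 0L) {
    low_idx <- sample(config$n_genes, n_floor)
    baseline[low_idx] <- stats::runif(n_floor, 0.001, 0.5)
  }
  names(baseline) <- gene_ids

  truth <- config$planted
  if (is.null(truth)) {
    eligible <- gene_ids[baseline >= 5]
    need <- config$n_core_up + config$n_core_down + config$n_shared
    if (length(eligible) < need) {
      stop_format("simulate_expression: only %d genes with baseline >= 5 for %d planted slots",
                  length(eligible), need)
    }
    if (need == 0L) {
      truth <- data.frame(gene_id = character(), genotype = character(),
                          treatment = character(), log2fc = numeric(),
                          stringsAsFactors = FALSE)
    } else {
    chosen <- sample(eligible, need)
    core_up <- chosen[seq_len(config$n_core_up)]
    core_down <- chosen[config$n_core_up + seq_len(config$n_core_down)]
    shared <- chosen[config$n_core_up + config$n_core_down +
                       seq_len(config$n_shared)]
    primary <- config$treatments[2]
    secondary <- if (length(config$treatments) >= 3L) config$treatments[3]
    grid <- expand.grid(gene_id = c(core_up, core_down, shared),
                        genotype = config$genotypes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$treatment <- primary
    grid$log2fc <- ifelse(grid$gene_id %in% core_down,
                          -config$effect_log2, config$effect_log2)
    truth <- grid
    if (!is.null(secondary) && config$n_shared > 0L) {
      g2 <- expand.grid(gene_id = shared, genotype = config$genotypes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      g2$treatment <- secondary
      g2$log2fc <- config$effect_log2
      truth <- rbind(truth, g2)
    }
    }
  }

  meta <- expand.grid(replicate = seq_len(config$replicates),
                      treatment = config$treatments,
                      genotype = config$genotypes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_r%d", meta$genotype, meta$treatment,
                            meta$replicate)
  meta <- meta[, c("sample_id", "genotype", "treatment", "replicate")]

  fpkm <- matrix(NA_real_, config$n_genes, nrow(meta),
                 dimnames = list(gene_ids, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    lfc <- rep(0, config$n_genes)
    tr <- truth[truth$genotype == meta$genotype[s] &
                  truth$treatment == meta$treatment[s], , drop = FALSE]
    lfc[match(tr$gene_id, gene_ids)] <- tr$log2fc
    fpkm[, s] <- baseline * 2^lfc *
      2^stats::rnorm(config$n_genes, 0, config$noise_sd_log2)
  }
  structure(list(table = expression_table(fpkm, meta), truth = truth,
                 baseline = baseline, config = config),
            class = "expression_sim")
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' Builds one set concentrated in true-effect genes (a fraction of its
#' members drawn from `true_genes`, the remainder from the universe) plus
#' random sets drawn uniformly from the universe, for exercising the
#' over-representation test against a known positive and calibrated
#' negatives.
#'
#' @param true_genes character vector of genes with planted effects.
#' @param universe character vector of all gene ids.
#' @param n_sets total number of sets (default 20; one is the planted set).
#' @param set_size members per set (must be >= 1).
#' @param planted_fraction fraction of the planted set drawn from
#'   `true_genes` (default 0.8).
#' @param seed integer random seed.
#' @return A `gene_set_collection`; the planted set is named
#'   `"planted_set"`.
#' @export
simulate_gene_sets <- function(true_genes, universe, n_sets = 20L,
                               set_size = 15L, planted_fraction = 0.8,
                               seed = 1L) {
  if (set_size < 1L) stop_format("simulate_gene_sets: set_size must be >= 1")
  if (n_sets < 1L) stop_format("simulate_gene_sets: n_sets must be >= 1")
  set.seed(as.integer(seed))
  universe <- unique(as.character(universe))
  true_genes <- intersect(unique(as.character(true_genes)), universe)
  k_true <- min(length(true_genes), round(planted_fraction * set_size))
  planted <- c(sample(true_genes, k_true),
               sample(setdiff(universe, true_genes), set_size - k_true))
  sets <- c(list(planted_set = planted),
            lapply(seq_len(n_sets - 1L), function(i) {
              sample(universe, set_size)
            }))
  names(sets)[-1] <- sprintf("random_set_%02d", seq_len(n_sets - 1L))
  gene_set_collection(sets)
}
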