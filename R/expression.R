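#' Floor FPKM values at the detection threshold
#'
#' Replaces any FPKM value below 1 (including 0) by 1 before ratio
#' computation, suppressing spurious fold changes between negligible
#' expression levels (e.g. FPKM 0.1 vs 0.0001) and removing zero
#' denominators. Idempotent.
#'
#' @param value non-negative numeric vector of FPKM values.
#' @param floor detection floor (default 1).
#' @return `pmax(value, floor)` elementwise.
#' @export
floor_fpkm <- function(value, floor = 1) {
  if (any(value < 0, na.rm = TRUE)) {
    stop_format("floor_fpkm: FPKM values must be non-negative")
  }
  pmax(value, floor)
}

#' Per-gene mean FPKM for one genotype x treatment condition
#'
#' Arithmetic mean over that condition's replicates, computed on raw
#' (unfloored) FPKM. A single-replicate condition is averaged with a
#' warning.
#'
#' @param table an `expression_table`.
#' @param genotype,treatment condition labels.
#' @return Named numeric vector of per-gene means, with a `n_replicates`
#'   attribute.
#' @export
condition_mean <- function(table, genotype, treatment) {
  stopifnot(inherits(table, "expression_table"))
  idx <- which(table$meta$genotype == genotype &
                 table$meta$treatment == treatment)
  if (length(idx) == 0L) {
    stop_format("condition_mean: no samples for genotype '%s', treatment '%s'",
                genotype, treatment)
  }
  if (length(idx) == 1L) {
    warning(sprintf("condition %s/%s has a single replicate", genotype,
                    treatment), call. = FALSE)
  }
  m <- rowMeans(table$fpkm[, idx, drop = FALSE], na.rm = TRUE)
  attr(m, "n_replicates") <- length(idx)
  m
}

#' Floored log2 fold change between two mean FPKM values
#'
#' `log2(floor_fpkm(mean_exp) / floor_fpkm(mean_base))`; flooring both
#' means removes zero denominators and zeroes out ratios between
#' sub-threshold expression levels. Swapping the arguments negates the
#' result.
#'
#' @param mean_exp,mean_base non-negative mean FPKM values (vectors
#'   recycle).
#' @param floor detection floor (default 1).
#' @return log2 ratio.
#' @examples
#' log2_fold_change(8, 2)        # 2
#' log2_fold_change(0.1, 1e-4)   # 0: both floored to 1
#' @export
log2_fold_change <- function(mean_exp, mean_base, floor = 1) {
  log2(floor_fpkm(mean_exp, floor) / floor_fpkm(mean_base, floor))
}

#' Call differentially expressed genes by the floored fold-change rule
#'
#' For one experimental genotype x treatment condition against a baseline
#' condition (by default the untreated samples of the same genotype), the
#' per-gene log2 ratio of floored replicate-mean FPKM is computed; a gene
#' is called when (a) the mean-level ratio exceeds `fc_cutoff` in
#' magnitude, and (b) every individual experimental replicate's floored
#' FPKM also exceeds the cutoff against the floored baseline mean, in the
#' same direction ("twofold change for all replicates").
#'
#' @param table an `expression_table`.
#' @param genotype,treatment experimental condition labels.
#' @param baseline_genotype baseline genotype (default: same as
#'   `genotype`; pass the wild-type label to compare against wild-type
#'   untreated).
#' @param baseline_treatment baseline treatment label (default
#'   `"untreated"`).
#' @param fc_cutoff log2 cutoff (default 1, i.e. twofold).
#' @param floor FPKM detection floor (default 1).
#' @return Data frame of class `de_result`: `gene_id`, `genotype`,
#'   `treatment`, `baseline_genotype`, `baseline_treatment`,
#'   `mean_fpkm_exp`, `mean_fpkm_base` (floored means), `log2_ratio`,
#'   `per_replicate_pass`, `call` (`"up"`/`"down"`/`"none"`).
#' @export
call_de <- function(table, genotype, treatment,
                    baseline_genotype = genotype,
                    baseline_treatment = "untreated",
                    fc_cutoff = 1, floor = 1) {
  stopifnot(inherits(table, "expression_table"))
  if (genotype == baseline_genotype && treatment == baseline_treatment) {
    stop_format("call_de: baseline condition equals the experimental condition")
  }
  mean_exp_raw <- condition_mean(table, genotype, treatment)
  mean_base_raw <- condition_mean(table, baseline_genotype, baseline_treatment)
  mean_exp <- floor_fpkm(mean_exp_raw, floor)
  mean_base <- floor_fpkm(mean_base_raw, floor)
  ratio <- log2(mean_exp / mean_base)
  dir <- ifelse(ratio > fc_cutoff, "up",
                ifelse(ratio < -fc_cutoff, "down", "none"))

  rep_idx <- which(table$meta$genotype == genotype &
                     table$meta$treatment == treatment)
  rep_vals <- floor_fpkm(table$fpkm[, rep_idx, drop = FALSE], floor)
  rep_ratio <- log2(rep_vals / mean_base)
  pass_up <- rowSums(rep_ratio > fc_cutoff, na.rm = TRUE) == length(rep_idx)
  pass_down <- rowSums(rep_ratio < -fc_cutoff, na.rm = TRUE) == length(rep_idx)
  per_rep <- (dir == "up" & pass_up) | (dir == "down" & pass_down)
  call <- ifelse(per_rep, dir, "none")

  out <- data.frame(gene_id = rownames(table$fpkm),
                    genotype = genotype, treatment = treatment,
                    baseline_genotype = baseline_genotype,
                    baseline_treatment = baseline_treatment,
                    mean_fpkm_exp = as.numeric(mean_exp),
                    mean_fpkm_base = as.numeric(mean_base),
                    log2_ratio = as.numeric(ratio),
                    per_replicate_pass = as.logical(per_rep),
                    call = call,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", class(out))
  out
}

#' Genes called in a `de_result`
#'
#' @param de a `de_result` data frame.
#' @param direction `"up"`, `"down"`, or `NULL` for both.
#' @return Character vector of gene ids.
#' @export
de_genes <- function(de, direction = NULL) {
  keep <- de$call != "none"
  if (!is.null(direction)) keep <- de$call == direction
  unique(de$gene_id[keep])
}

#' Overlap of differential-expression calls across genotypes
#'
#' Compares the genes called in a given direction across genotypes for one
#' treatment; the full (typically three-way) intersection is the
#' highest-confidence treatment-responsive core, robust to clonal effects
#' of any single knockout line.
#'
#' @param de_lists named list of `de_result` data frames (one per
#'   genotype), all from the same treatment.
#' @param direction `"up"` or `"down"`.
#' @return An `overlap_report` ([cross_screen_overlap()]); its
#'   `full_intersection` holds the core responsive genes.
#' @export
de_overlap <- function(de_lists, direction = c("up", "down")) {
  direction <- match.arg(direction)
  lists <- lapply(de_lists, de_genes, direction = direction)
  cross_screen_overlap(lists)
}

#' Annotate treatment-responsive genes as metal-specific or shared
#'
#' Each gene called in the primary-treatment results (e.g. zinc) is labeled
#' `"shared"` when some secondary-treatment list (e.g. manganese) calls it
#' in the same direction — such genes may respond to the counter-ion or be
#' general stress factors — and `"specific"` otherwise.
#'
#' @param primary named list of `de_result` data frames for the primary
#'   treatment.
#' @param secondary named list of `de_result` data frames for the
#'   secondary treatment.
#' @return Data frame: `gene_id`, `direction`, `annotation`
#'   (`"specific"`/`"shared"`).
#' @export
cross_metal_annotation <- function(primary, secondary) {
  prim <- do.call(rbind, lapply(primary, function(d) {
    d[d$call != "none", c("gene_id", "call"), drop = FALSE]
  }))
  prim <- unique(prim)
  sec <- unique(do.call(rbind, lapply(secondary, function(d) {
    d[d$call != "none", c("gene_id", "call"), drop = FALSE]
  })))
  shared <- paste(prim$gene_id, prim$call) %in% paste(sec$gene_id, sec$call)
  out <- data.frame(gene_id = prim$gene_id, direction = prim$call,
                    annotation = ifelse(shared, "shared", "specific"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$gene_id), , drop = FALSE]
}
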