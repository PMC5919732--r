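#' Expression evidence per gene
#'
#' A gene's expression evidence is the maximum replicate-mean FPKM over all
#' provided genotype x treatment conditions (a gene expressed anywhere
#' counts as expressed), or over a selected subset of conditions.
#'
#' @param expr an `expression_table`.
#' @param conditions optional data frame with `genotype` and `treatment`
#'   columns restricting which conditions are considered.
#' @return Named numeric vector of per-gene evidence values.
#' @export
expression_evidence <- function(expr, conditions = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  combos <- unique(expr$meta[, c("genotype", "treatment")])
  if (!is.null(conditions)) {
    keep <- paste(combos$genotype, combos$treatment) %in%
      paste(conditions$genotype, conditions$treatment)
    combos <- combos[keep, , drop = FALSE]
    if (nrow(combos) == 0L) {
      stop_format("expression_evidence: no matching conditions")
    }
  }
  means <- vapply(seq_len(nrow(combos)), function(i) {
    condition_mean(expr, combos$genotype[i], combos$treatment[i])
  }, numeric(nrow(expr$fpkm)))
  apply(matrix(means, nrow = nrow(expr$fpkm)), 1L, max)
}

#' Expression-evidence false-discovery assessment of screen hits
#'
#' Screen hits with no evidence of expression in the assayed cells
#' (evidence FPKM below the threshold) are probable false positives: an
#' unexpressed gene cannot produce a knockdown phenotype. Reports, per
#' confidence tier, the count and integer percentage of unexpressed hits.
#' Hits with no expression record at all are counted as unexpressed with a
#' warning.
#'
#' @param hits data frame with `gene_id` and `tier` columns (one row per
#'   gene x condition is fine; genes are deduplicated within tier).
#' @param expr an `expression_table`, or a named numeric vector of
#'   precomputed per-gene evidence values ([expression_evidence()]).
#' @param fpkm_threshold evidence threshold (default 1).
#' @param conditions optional condition restriction passed to
#'   [expression_evidence()].
#' @return List of class `expression_evidence_report`: `summary` (data
#'   frame `tier`, `n_hits`, `n_unexpressed`, `pct_unexpressed` with
#'   half-up integer rounding) and `flags` (per-gene data frame).
#' @export
expression_evidence_filter <- function(hits, expr, fpkm_threshold = 1,
                                       conditions = NULL) {
  check_columns(hits, c("gene_id", "tier"), "hit list")
  hits <- unique(hits[, c("gene_id", "tier")])
  if (nrow(hits) == 0L) stop_format("expression_evidence_filter: empty hit list")
  evidence <- if (inherits(expr, "expression_table")) {
    expression_evidence(expr, conditions)
  } else {
    expr
  }
  ev <- evidence[match(hits$gene_id, names(evidence))]
  if (anyNA(ev)) {
    warning(sprintf("%d hit gene(s) with no expression record counted as unexpressed",
                    sum(is.na(ev))), call. = FALSE)
  }
  unexpressed <- is.na(ev) | ev < fpkm_threshold
  flags <- data.frame(gene_id = hits$gene_id, tier = hits$tier,
                      evidence_fpkm = as.numeric(ev),
                      unexpressed = unexpressed,
                      stringsAsFactors = FALSE, row.names = NULL)
  tiers <- unique(hits$tier)
  summary <- do.call(rbind, lapply(tiers, function(tr) {
    f <- flags[flags$tier == tr, , drop = FALSE]
    data.frame(tier = tr, n_hits = nrow(f),
               n_unexpressed = sum(f$unexpressed),
               pct_unexpressed = as.integer(
                 round_half_up(100 * sum(f$unexpressed) / nrow(f))),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, flags = flags,
                 fpkm_threshold = fpkm_threshold),
            class = "expression_evidence_report")
}

#' @export
print.expression_evidence_report <- function(x, ...) {
  cat("expression evidence filter (FPKM <", x$fpkm_threshold,
      "= no evidence of expression)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Read a two-column ortholog map with confidence scores
#'
#' @param path tab-separated file with columns `source_gene`,
#'   `target_gene`, `score` (non-negative integer confidence).
#' @return Validated ortholog map data frame.
#' @export
read_ortholog_map <- function(path) {
  map <- read_tsv(path, "ortholog map")
  check_columns(map, c("source_gene", "target_gene", "score"), "ortholog map")
  if (any(map$score < 0, na.rm = TRUE)) {
    stop_format("ortholog map: scores must be non-negative")
  }
  map
}

#' Cross-check a control screen against an essential-gene list
#'
#' Essential genes are expected to score in the down (reduced viability)
#' direction in an untreated control screen; the concordance rate is an
#' external consistency check on the screen. The essential list may be
#' from another species, in which case an ortholog map (kept at
#' `score > score_cutoff`, the best-match filter) translates it; with no
#' map the comparison is same-species (identity).
#'
#' @param gene_scores gene-score data frame for the control condition.
#' @param essential character vector of essential gene ids (pre-filtered
#'   by the caller for reagent quality and library membership).
#' @param ortholog_map optional ortholog map data frame
#'   ([read_ortholog_map()]); `NULL` = identity.
#' @param score_cutoff strict minimum ortholog confidence (default 2,
#'   i.e. keep score > 2).
#' @return List of class `essential_crosscheck`: `detail` (per essential
#'   gene: mapped ids, whether it scored down, best tier) and `summary`
#'   (`n_essential`, `n_down`, `n_down_high`, `n_down_low`).
#' @export
essential_gene_crosscheck <- function(gene_scores, essential,
                                      ortholog_map = NULL, score_cutoff = 2) {
  check_columns(gene_scores, c("gene_id", "direction", "tier"), "gene scores")
  essential <- unique(as.character(essential))
  if (length(essential) == 0L) {
    return(structure(list(
      detail = data.frame(essential_gene = character(),
                          mapped_genes = character(),
                          scored_down = logical(), tier = character(),
                          stringsAsFactors = FALSE),
      summary = data.frame(n_essential = 0L, n_down = 0L,
                           n_down_high = 0L, n_down_low = 0L)),
      class = "essential_crosscheck"))
  }
  map_of <- function(g) {
    if (is.null(ortholog_map)) return(g)
    hit <- ortholog_map$source_gene == g & ortholog_map$score > score_cutoff
    unique(ortholog_map$target_gene[hit])
  }
  tier_rank <- c(high = 3L, moderate = 2L, low = 1L, none = 0L)
  detail <- do.call(rbind, lapply(essential, function(g) {
    mapped <- map_of(g)
    rows <- gene_scores[gene_scores$gene_id %in% mapped &
                          gene_scores$direction == "down" &
                          gene_scores$tier != "none", , drop = FALSE]
    best <- if (nrow(rows) == 0L) "none" else
      rows$tier[which.max(tier_rank[rows$tier])]
    data.frame(essential_gene = g,
               mapped_genes = paste(mapped, collapse = ";"),
               scored_down = nrow(rows) > 0L,
               tier = best, stringsAsFactors = FALSE)
  }))
  summary <- data.frame(n_essential = nrow(detail),
                        n_down = sum(detail$scored_down),
                        n_down_high = sum(detail$tier == "high"),
                        n_down_low = sum(detail$tier %in%
                                           c("low", "moderate")))
  structure(list(detail = detail, summary = summary),
            class = "essential_crosscheck")
}

#' @export
print.essential_crosscheck <- function(x, ...) {
  s <- x$summary
  cat(sprintf("essential-gene crosscheck: %d/%d scored down (%d high, %d low/moderate)\n",
              s$n_down, s$n_essential, s$n_down_high, s$n_down_low))
  invisible(x)
}
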