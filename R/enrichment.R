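#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` members of a gene set in a hit
#' list of size `n` drawn without replacement from a universe of `N` genes
#' of which `K` belong to the set: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param N universe size.
#' @param K set members in the universe.
#' @param n hit-list size.
#' @param k observed overlap.
#' @return `P(X >= k)`, a probability in `(0, 1]`.
#' @examples
#' hypergeom_upper_tail(10, 3, 4, 2)  # 70/210
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  N <- as.integer(N); K <- as.integer(K)
  n <- as.integer(n); k <- as.integer(k)
  if (any(is.na(c(N, K, n, k)))) stop_format("hypergeom_upper_tail: NA argument")
  if (K > N || n > N || k > min(K, n) || k < 0 || K < 0 || n < 0) {
    stop_format("hypergeom_upper_tail: arguments violate 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1L, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Over-representation test of a hit list against a gene-set collection
#'
#' For each gene set, counts the overlap between the hit list and the set
#' (both intersected with the universe first) and computes the upper-tail
#' hypergeometric p-value. Sets with zero overlap, or whose
#' universe-intersected size falls outside `[min_set_size, max_set_size]`,
#' are excluded. P-values are adjusted across the tested sets
#' (Benjamini-Hochberg by default; `adjust = "none"` reproduces raw-p
#' thresholding).
#'
#' @param hits character vector of hit gene ids; genes outside the universe
#'   are dropped with a warning.
#' @param universe character vector of all assayed gene ids.
#' @param sets a `gene_set_collection`.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param adjust `"BH"` (default) or `"none"`.
#' @param min_set_size,max_set_size bounds on universe-intersected set size
#'   (defaults 3 and 500).
#' @return Data frame of class `enrichment_result`, sorted by `p_value`:
#'   `set_id`, `N`, `K`, `n`, `k`, `p_value`, `p_adjusted`, `significant`,
#'   `overlap_genes` (semicolon-joined).
#' @export
enrich_collection <- function(hits, universe, sets, alpha = 0.05,
                              adjust = c("BH", "none"),
                              min_set_size = 3L, max_set_size = 500L) {
  adjust <- match.arg(adjust)
  universe <- unique(as.character(universe))
  hits <- unique(as.character(hits))
  if (length(universe) == 0L) stop_format("enrich_collection: empty universe")
  outside <- setdiff(hits, universe)
  if (length(outside) > 0L) {
    warning(sprintf("%d hit gene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    hits <- intersect(hits, universe)
  }
  if (length(hits) == 0L) stop_format("enrich_collection: empty hit list")
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(sets), function(sid) {
    members <- intersect(sets[[sid]], universe)
    K <- length(members)
    if (K < min_set_size || K > max_set_size) return(NULL)
    ov <- intersect(hits, members)
    k <- length(ov)
    if (k < 1L) return(NULL)
    data.frame(set_id = sid, N = N, K = K, n = n, k = k,
               p_value = hypergeom_upper_tail(N, K, n, k),
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    res <- data.frame(set_id = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p_value = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      overlap_genes = character(), stringsAsFactors = FALSE)
    class(res) <- c("enrichment_result", class(res))
    return(res)
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- if (adjust == "BH") {
    stats::p.adjust(res$p_value, method = "BH")
  } else {
    res$p_value
  }
  res$significant <- res$p_adjusted < alpha
  res <- res[order(res$p_value),
             c("set_id", "N", "K", "n", "k", "p_value", "p_adjusted",
               "significant", "overlap_genes")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", class(res))
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result:", nrow(x), "set(s) tested,",
      sum(x$significant), "significant\n")
  show <- utils::head(as.data.frame(x)[, c("set_id", "K", "n", "k",
                                           "p_value", "p_adjusted",
                                           "significant")], 10L)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Promote low-confidence hits supported by enrichment
#'
#' Low-confidence gene hits (single hitting design) that are members of at
#' least one significantly enriched gene set are reannotated as
#' moderate-confidence; the enrichment should be run on the full hit list
#' (high + low). High-confidence calls are never changed.
#'
#' @param gene_scores gene-score data frame ([aggregate_to_genes()]).
#' @param results an `enrichment_result`.
#' @return Gene scores with `tier` updated (`"low"` -> `"moderate"` where
#'   supported).
#' @export
promote_confidence <- function(gene_scores, results) {
  check_columns(gene_scores, c("gene_id", "tier"), "gene scores")
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0L) return(gene_scores)
  supported <- unique(unlist(strsplit(sig$overlap_genes, ";", fixed = TRUE)))
  promote <- gene_scores$tier == "low" & gene_scores$gene_id %in% supported
  gene_scores$tier[promote] <- "moderate"
  gene_scores
}
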