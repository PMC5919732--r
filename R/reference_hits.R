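#' Reference high-confidence hit lists from the metal-toxicity screens
#'
#' The gene-level high-confidence hit tables from arrayed RNAi modifier
#' screens of zinc and manganese chloride toxicity in Drosophila S2R+
#' cells, bundled as a gene-score table: 30 genes for the control
#' condition, 29 for ZnCl2 (28 up, 1 down -- the zinc-sensitizing ABCC
#' transporter rdog), and 36 for MnCl2, 86 unique genes in all. Columns
#' are `gene_id` (FlyBase id), `gene_symbol`, `human_ortholog`,
#' `condition` (`control`/`ZnCl2`/`MnCl2`), `direction`, `n_designs`
#' (dsRNA designs targeting the gene; every design scored `|z| >= 1.5` in
#' the same direction), `avg_z`, and `tier` (all `"high"`).
#'
#' @return Gene-score data frame with 95 rows.
#' @examples
#' hits <- reference_screen_hits()
#' table(hits$condition, hits$direction)
#' @export
reference_screen_hits <- function() {
  path <- system.file("extdata", "screen_high_confidence_hits.tsv",
                      package = "metalscreen", mustWork = TRUE)
  read_gene_scores(path)
}
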