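# tiny in-code fixtures shared across test files

# a one-plate, one-condition dataset: 4 experimental wells, 2 reagents
# (2 genes), plus one edge well and one empty control well
tiny_screen <- function(signals = c(100, 200, 300, 400),
                        condition = "control", replicate = 1L) {
  wells <- data.frame(
    plate_id = "P01",
    row = c("C", "C", "D", "D", "A", "H"),
    col = c(3L, 4L, 3L, 4L, 1L, 12L),
    reagent_id = c("r1", "r2", "r3", "r4", "", ""),
    raw_signal = c(signals, 999, 555),
    condition = condition,
    replicate = replicate,
    stringsAsFactors = FALSE)
  lib <- data.frame(reagent_id = c("r1", "r2", "r3", "r4"),
                    gene_id = c("g1", "g1", "g2", "g2"),
                    gene_symbol = c("geneA", "geneA", "geneB", "geneB"),
                    sublibrary = "TM", stringsAsFactors = FALSE)
  screen_dataset(wells, lib)
}

# expression table with explicit per-replicate values; `reps` is a named
# list gene -> matrix-like list of condition -> c(rep1, rep2)
tiny_expression <- function(values, genotypes = "wild-type",
                            treatments = c("untreated", "ZnCl2-1mM")) {
  meta <- expand.grid(replicate = 1:2, treatment = treatments,
                      genotype = genotypes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_r%d", meta$genotype, meta$treatment,
                            meta$replicate)
  meta <- meta[, c("sample_id", "genotype", "treatment", "replicate")]
  fpkm <- matrix(unlist(values), nrow = length(values), byrow = TRUE,
                 dimnames = list(names(values), meta$sample_id))
  expression_table(fpkm, meta)
}

# exhaustive-enumeration oracle for the hypergeometric upper tail:
# draws all size-n subsets of 1..N and counts overlap with 1..K
enumerate_upper_tail <- function(N, K, n, k) {
  if (n == 0) return(if (k == 0) 1 else 0)
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}
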