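#' Prioritize GWAS SNPs via predicted candidate genes
#'
#' Post-GWAS triage usually keeps only non-synonymous SNPs whose host genes
#' are already known disease genes, which cannot surface novel biology. This
#' step instead flags SNPs whose host genes are *predicted* candidates: a
#' SNP is `flagged_novel` when it reaches genome-wide significance
#' (`p_value < p_threshold`, strict), its host gene is not a known disease
#' gene, and the host gene sits within the top `top_n` of the genome-wide
#' ranking (known genes are counted in the rank).
#'
#' @param snps data frame from [load_snps()] (columns `snp_id`, `host_gene`,
#'   `p_value`); a SNP mapped to several genes appears once per gene. An
#'   empty table yields an empty result.
#' @param ranking ranked table from [prioritize_disease()] (or
#'   [rank_genes()]).
#' @param known a [disease_gene_set()] or character vector of known disease
#'   genes.
#' @param p_threshold significance cutoff, default `5e-8`.
#' @param top_n rank cutoff, default 500.
#' @return data frame with one row per input row: `snp_id`, `host_gene`,
#'   `p_value`, `passes_p_threshold`, `host_is_known`, `host_rank` (`NA`
#'   when the host gene is absent from the ranking or unranked),
#'   `flagged_novel`.
#' @examples
#' rk <- data.frame(rank = 1:3, gene = c("gA", "gB", "gC"),
#'                  weight = c(3, 2, 1), unranked = FALSE)
#' snps <- data.frame(snp_id = "rs1", host_gene = "gB", p_value = 1e-9)
#' prioritize_snps(snps, rk, known = "gA", top_n = 2)
#' @export
prioritize_snps <- function(snps, ranking, known, p_threshold = 5e-8,
                            top_n = 500L) {
  stopifnot(is.data.frame(snps))
  known_genes <- if (inherits(known, "disease_gene_set")) known$genes else as.character(known)
  if (nrow(snps) == 0L) {
    return(data.frame(snp_id = character(), host_gene = character(),
                      p_value = numeric(), passes_p_threshold = logical(),
                      host_is_known = logical(), host_rank = integer(),
                      flagged_novel = logical(), stringsAsFactors = FALSE))
  }
  idx <- match(snps$host_gene, ranking$gene)
  host_rank <- ranking$rank[idx]
  if ("unranked" %in% names(ranking)) {
    host_rank[!is.na(idx) & ranking$unranked[idx]] <- NA_integer_
  }
  passes <- snps$p_value < p_threshold
  host_known <- snps$host_gene %in% known_genes
  flagged <- passes & !host_known & !is.na(host_rank) & host_rank <= top_n
  data.frame(snp_id = snps$snp_id, host_gene = snps$host_gene,
             p_value = snps$p_value, passes_p_threshold = passes,
             host_is_known = host_known, host_rank = host_rank,
             flagged_novel = flagged, stringsAsFactors = FALSE)
}
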