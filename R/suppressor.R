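# Tumor-suppressor-like mutation signatures --------------------------------

#' Classify genes by a tumor-suppressor mutation signature
#'
#' Tumor suppressors are typically inactivated by truncating changes, so an
#' excess of highly deleterious events (premature nonsense mutations and
#' out-of-frame indels) over synonymous events in the same gene marks a
#' suppressor candidate. A gene qualifies when it carries at least
#' `min_deleterious` deleterious events *and* the deleterious/synonymous
#' ratio exceeds `min_ratio`. Missense and in-frame indels enter neither
#' count. With no synonymous events the ratio is `Inf`, so any gene clearing
#' the deleterious count qualifies. Events are deduplicated per
#' (sample, residue, alternate allele, class), identically to hotspot
#' counting.
#'
#' @param records protein-level mutation table (one or many genes).
#' @param min_deleterious minimum number of deleterious events (default 25).
#' @param min_ratio strict lower bound on the deleterious/synonymous ratio
#'   (default 0.7).
#' @return data.frame with one row per gene: `gene_id`, `n_deleterious`,
#'   `n_synonymous`, `ratio`, `is_suppressor_candidate`.
#' @export
suppressor_signature <- function(records, min_deleterious = 25,
                                 min_ratio = 0.7) {
  key <- paste(records$sample_id, records$gene_id, records$residue_position,
               records$alt_aa, records$consequence, sep = "\r")
  records <- records[!duplicated(key), , drop = FALSE]
  genes <- unique(records$gene_id)
  del <- records$consequence %in% c("nonsense", "frameshift_indel")
  syn <- records$consequence == "synonymous"
  n_del <- vapply(genes, function(g) sum(del & records$gene_id == g), 0L)
  n_syn <- vapply(genes, function(g) sum(syn & records$gene_id == g), 0L)
  ratio <- ifelse(n_syn > 0, n_del / n_syn, ifelse(n_del > 0, Inf, NaN))
  data.frame(gene_id = genes,
             n_deleterious = n_del, n_synonymous = n_syn, ratio = ratio,
             is_suppressor_candidate =
               n_del >= min_deleterious & !is.nan(ratio) & ratio > min_ratio,
             row.names = NULL, stringsAsFactors = FALSE)
}
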