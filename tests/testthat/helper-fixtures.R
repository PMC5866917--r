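# Shared fixture builders (all fixtures are constructed in code).

# toy gene: protein MEK encoded by ATG GAA AAA (+ stop TAA)
mek_fixture <- function(strand = "+") {
  cds <- "ATGGAAAAATAA"
  if (strand == "+") {
    genome <- c(chr1 = paste0("TT", cds, "AC"))
    iv <- data.frame(start = 3, end = 14)
  } else {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    genome <- c(chr1 = paste0("TT", rc, "AC"))
    iv <- data.frame(start = 3, end = 14)
  }
  list(genome = genome,
       tx = transcript_model("MEKG", "TX1", "chr1", strand, iv,
                             genome = genome))
}

# genomic coordinate of a CDS base for the mek fixture
mek_genomic_pos <- function(cds_base, strand) {
  if (strand == "+") 2 + cds_base else 14 - cds_base + 1
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

protein_records <- function(gene, positions, samples, alts = "K", refs = "E",
                            consequence = "missense", tumor_type = "PAN") {
  n <- max(length(positions), length(samples))
  data.frame(sample_id = rep_len(samples, n),
             tumor_type = rep_len(tumor_type, n),
             gene_id = rep_len(gene, n),
             residue_position = rep_len(positions, n),
             ref_aa = rep_len(refs, n), alt_aa = rep_len(alts, n),
             consequence = rep_len(consequence, n), stringsAsFactors = FALSE)
}

funnel_path <- function(file) {
  system.file("extdata", file, package = "mutdomino", mustWork = TRUE)
}
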