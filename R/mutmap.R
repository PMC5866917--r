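# Mapping of somatic mutation tables onto protein coordinates --------------

#' Construct a transcript model
#'
#' A transcript model ties together a gene, its coding (CDS) intervals on the
#' genome, and the encoded protein. CDS intervals are 1-based inclusive
#' genomic coordinates given in *transcription order* (ascending genomic
#' starts on the plus strand, descending on the minus strand). The CDS
#' sequence is either supplied directly, or extracted from a genome sequence
#' source; in both cases the translation (standard genetic code, trailing
#' stop trimmed) must reproduce `protein_sequence` when that is supplied.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chromosome chromosome name, matched against names of `genome`.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals data.frame with columns `start`, `end` (1-based
#'   inclusive, non-overlapping, transcription order).
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences (used to extract the CDS when `cds_sequence` is missing).
#' @param protein_sequence optional amino-acid string; validated against the
#'   translated CDS, or derived from it when missing.
#' @param cds_sequence optional CDS nucleotide string (mRNA sense strand).
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, chromosome, strand,
                             cds_intervals, genome = NULL,
                             protein_sequence = NULL, cds_sequence = NULL) {
  stopifnot(strand %in% c("+", "-"))
  cds_intervals <- as.data.frame(cds_intervals)
  stopifnot(all(c("start", "end") %in% names(cds_intervals)))
  if (any(cds_intervals$end < cds_intervals$start))
    stop("CDS interval with end < start")
  n <- nrow(cds_intervals)
  if (n > 1) {
    ord <- order(cds_intervals$start)
    s <- cds_intervals$start[ord]; e <- cds_intervals$end[ord]
    if (any(s[-1] <= e[-n])) stop("CDS intervals overlap")
    expect <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    if (!identical(ord, expect))
      stop("CDS intervals not in transcription order for strand ", strand)
  }
  lens <- cds_intervals$end - cds_intervals$start + 1L
  cds_length <- sum(lens)
  if (cds_length %% 3L != 0L)
    stop("total CDS length (", cds_length, ") not divisible by 3")

  if (is.null(cds_sequence)) {
    if (is.null(genome))
      stop("either `cds_sequence` or `genome` must be supplied")
    chrom_seq <- genome_sequence(genome, chromosome)
    chunks <- substring(chrom_seq, cds_intervals$start, cds_intervals$end)
    if (strand == "-") chunks <- reverse_complement(chunks)
    cds_sequence <- paste(chunks, collapse = "")
  }
  cds_sequence <- toupper(cds_sequence)
  if (nchar(cds_sequence) != cds_length)
    stop("CDS sequence length disagrees with CDS intervals")
  translated <- translate_cds(cds_sequence)
  if (is.null(protein_sequence)) {
    protein_sequence <- translated
  } else if (!identical(toupper(protein_sequence), translated)) {
    stop("translated CDS does not equal the supplied protein sequence for ",
         transcript_id)
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chromosome = chromosome, strand = strand,
                 cds_intervals = cds_intervals, cds_length = cds_length,
                 cds_sequence = cds_sequence,
                 protein_sequence = toupper(protein_sequence),
                 cum_len = cumsum(lens)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id, " (", x$gene_id, ") ",
      x$chromosome, x$strand, ", CDS ", x$cds_length, " nt, protein ",
      nchar(x$protein_sequence), " aa\n", sep = "")
  invisible(x)
}

genome_sequence <- function(genome, chromosome) {
  if (methods::is(genome, "DNAStringSet") || methods::is(genome, "XStringSet")) {
    if (!chromosome %in% names(genome))
      stop("chromosome ", chromosome, " not in genome")
    return(toupper(as.character(genome[[chromosome]])))
  }
  if (!chromosome %in% names(genome))
    stop("chromosome ", chromosome, " not in genome")
  toupper(as.character(genome[[chromosome]]))
}

#' Read genome or protein sequences from FASTA
#' @param path FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Select the representative transcript of a gene
#'
#' Chooses the transcript with the longest total CDS; ties are broken by the
#' lexicographically smallest transcript id.
#'
#' @param transcripts non-empty list of `transcript_model`s of one gene.
#' @return a single `transcript_model`.
#' @export
select_representative_transcript <- function(transcripts) {
  if (length(transcripts) == 0) stop("empty transcript list")
  genes <- vapply(transcripts, function(t) t$gene_id, character(1))
  if (length(unique(genes)) != 1)
    stop("transcripts belong to more than one gene")
  lens <- vapply(transcripts, function(t) t$cds_length, numeric(1))
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  best <- which(lens == max(lens))
  transcripts[[best[order(ids[best])[1]]]]
}

#' Classify the protein-level consequence of a coding change
#'
#' Single-nucleotide substitutions are classified from their reference and
#' alternate codons under the standard genetic code; insertions/deletions are
#' classified from their length alone.
#'
#' @param ref_codon,alt_codon 3-letter DNA codons (ignored for indels).
#' @param indel_length inserted/deleted length in nucleotides; when supplied
#'   the call returns `frameshift_indel` or `inframe_indel`.
#' @return one of `r paste(CONSEQUENCE_CLASSES, collapse = ", ")`.
#' @export
classify_consequence <- function(ref_codon = NULL, alt_codon = NULL,
                                 indel_length = NULL) {
  if (!is.null(indel_length)) {
    return(if (indel_length %% 3L != 0L) "frameshift_indel" else "inframe_indel")
  }
  gc <- Biostrings::GENETIC_CODE
  check <- function(codon) {
    codon <- toupper(codon)
    if (nchar(codon) != 3 ||
        !all(strsplit(codon, "")[[1]] %in% DNA_BASES))
      stop("invalid codon: ", codon)
    codon
  }
  ref_aa <- unname(gc[check(ref_codon)])
  alt_aa <- unname(gc[check(alt_codon)])
  if (ref_aa == "*") return("other")       # stop-loss and friends
  if (alt_aa == "*") return("nonsense")
  if (alt_aa == ref_aa) "synonymous" else "missense"
}

# 1-based offset of a genomic position within the CDS (NA outside the CDS)
cds_offset <- function(tx, position) {
  iv <- tx$cds_intervals
  for (i in seq_len(nrow(iv))) {
    if (position >= iv$start[i] && position <= iv$end[i]) {
      before <- if (i == 1) 0L else tx$cum_len[i - 1L]
      within <- if (tx$strand == "+") position - iv$start[i] + 1L
                else iv$end[i] - position + 1L
      return(before + within)
    }
  }
  NA_integer_
}

#' Map a genomic single-nucleotide variant onto the protein
#'
#' Locates the mutated base within the transcript's CDS, builds the reference
#' and alternate codons (reverse-complementing alleles on the minus strand),
#' and classifies the consequence. Positions outside the CDS yield a record
#' with consequence `"other"` and no residue; a mismatch between the supplied
#' reference allele and the transcript CDS is flagged (`ref_mismatch`), not
#' dropped, so QC stays auditable.
#'
#' @param mut a list or one-row data.frame with `chromosome`, `position`,
#'   `ref_base`, `alt_base` and identifier fields (`sample_id`, `tumor_type`,
#'   `gene_id`).
#' @param tx a [transcript_model()].
#' @return one-row data.frame: a protein-level mutation record.
#' @export
map_genomic_to_protein <- function(mut, tx) {
  mut <- as.list(mut)
  out <- data.frame(sample_id = mut$sample_id %||% NA_character_,
                    tumor_type = mut$tumor_type %||% NA_character_,
                    gene_id = tx$gene_id,
                    residue_position = NA_integer_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    consequence = "other",
                    chromosome = mut$chromosome, position = mut$position,
                    ref_base = toupper(mut$ref_base),
                    alt_base = toupper(mut$alt_base),
                    ref_mismatch = FALSE,
                    stringsAsFactors = FALSE)
  off <- cds_offset(tx, mut$position)
  if (is.na(off)) return(out)

  cds_ref <- if (tx$strand == "+") out$ref_base else reverse_complement(out$ref_base)
  cds_alt <- if (tx$strand == "+") out$alt_base else reverse_complement(out$alt_base)
  have <- substr(tx$cds_sequence, off, off)
  if (have != cds_ref) out$ref_mismatch <- TRUE

  res <- as.integer(ceiling(off / 3))
  codon_start <- 3L * (res - 1L) + 1L
  ref_codon <- substr(tx$cds_sequence, codon_start, codon_start + 2L)
  pos_in_codon <- off - codon_start + 1L
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- cds_alt

  gc <- Biostrings::GENETIC_CODE
  out$residue_position <- res
  out$ref_aa <- unname(gc[ref_codon])
  out$alt_aa <- unname(gc[alt_codon])
  out$consequence <- classify_consequence(ref_codon, alt_codon)
  out
}

#' Map a genomic mutation table onto protein coordinates
#'
#' Applies [map_genomic_to_protein()] to every row, picking each gene's
#' transcript model by `gene_id`. Rows for genes with no transcript model are
#' dropped and counted.
#'
#' @param mutations genomic-dialect mutation table (see
#'   [read_mutation_table()]).
#' @param transcripts a `transcript_model`, or a list of them (one per gene).
#' @return protein-level mutation table with a `"mapping_report"` attribute
#'   (`n_input`, `n_no_transcript`, `n_outside_cds`, `n_ref_mismatch`).
#' @export
map_mutations <- function(mutations, transcripts) {
  if (inherits(transcripts, "transcript_model")) transcripts <- list(transcripts)
  names(transcripts) <- vapply(transcripts, function(t) t$gene_id, character(1))
  keep <- mutations$gene_id %in% names(transcripts)
  rows <- lapply(which(keep), function(i)
    map_genomic_to_protein(mutations[i, ], transcripts[[mutations$gene_id[i]]]))
  out <- if (length(rows)) do.call(rbind, rows) else
    map_genomic_to_protein(list(chromosome = "x", position = 0L,
                                ref_base = "A", alt_base = "C"),
                           transcripts[[1]])[0, ]
  attr(out, "mapping_report") <- list(
    n_input = nrow(mutations),
    n_no_transcript = sum(!keep),
    n_outside_cds = sum(is.na(out$residue_position)),
    n_ref_mismatch = sum(out$ref_mismatch))
  out
}

#' Read a somatic mutation table
#'
#' Reads MAF-like tab-separated mutation tables in either the genomic dialect
#' (`Hugo_Symbol`/`gene`, `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`, `Tumor_Sample_Barcode`, `tumor_type`, optionally
#' `Variant_Classification`) or the protein dialect (`gene`, `position`,
#' `ref_aa`, `alt_aa`, `sample`, `tumor_type`, optionally `consequence`).
#' Rows with unparseable coordinates are dropped and counted; duplicate
#' (sample, gene, position, alt) rows are collapsed to one. The counts are
#' returned in the `"ingest_report"` attribute, so that
#' `n_input = n_records + n_dropped + n_duplicates`.
#'
#' For the protein dialect a missing `consequence` column is inferred from
#' the alleles: `alt_aa == "*"` is nonsense, `ref_aa == alt_aa` synonymous,
#' anything else missense.
#'
#' @param path TSV file.
#' @param dialect `"protein"` or `"genomic"`.
#' @return standardized mutation data.frame.
#' @export
read_mutation_table <- function(path, dialect = c("protein", "genomic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(...) {
    alts <- c(...)
    hit <- alts[alts %in% names(raw)]
    if (length(hit) == 0)
      stop("missing required column: ", alts[1], call. = FALSE)
    raw[[hit[1]]]
  }
  n_input <- nrow(raw)
  if (dialect == "genomic") {
    df <- data.frame(
      sample_id = as.character(pick("Tumor_Sample_Barcode", "sample")),
      tumor_type = as.character(pick("tumor_type", "Tumor_Type")),
      gene_id = as.character(pick("Hugo_Symbol", "gene")),
      chromosome = as.character(pick("Chromosome", "chromosome")),
      position = suppressWarnings(as.integer(pick("Start_Position", "position"))),
      ref_base = toupper(as.character(pick("Reference_Allele", "ref_base"))),
      alt_base = toupper(as.character(pick("Tumor_Seq_Allele2", "alt_base"))),
      stringsAsFactors = FALSE)
    if ("Variant_Classification" %in% names(raw))
      df$variant_classification <- as.character(raw$Variant_Classification)
    ok <- !is.na(df$position) & df$position >= 1
    key <- paste(df$sample_id, df$gene_id, df$chromosome, df$position,
                 df$alt_base, sep = "\r")
  } else {
    df <- data.frame(
      sample_id = as.character(pick("sample", "sample_id")),
      tumor_type = as.character(pick("tumor_type")),
      gene_id = as.character(pick("gene", "gene_id")),
      residue_position = suppressWarnings(as.integer(pick("position", "residue_position"))),
      ref_aa = toupper(as.character(pick("ref_aa"))),
      alt_aa = toupper(as.character(pick("alt_aa"))),
      stringsAsFactors = FALSE)
    df$consequence <- if ("consequence" %in% names(raw)) {
      as.character(raw$consequence)
    } else {
      ifelse(df$alt_aa == "*", "nonsense",
             ifelse(df$ref_aa == df$alt_aa, "synonymous", "missense"))
    }
    bad_cons <- !df$consequence %in% CONSEQUENCE_CLASSES
    if (any(bad_cons))
      stop("unknown consequence class: ",
           paste(unique(df$consequence[bad_cons]), collapse = ", "))
    ok <- !is.na(df$residue_position) & df$residue_position >= 1
    key <- paste(df$sample_id, df$gene_id, df$residue_position, df$alt_aa,
                 sep = "\r")
  }
  n_dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  dup <- duplicated(key[ok])
  n_duplicates <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "ingest_report") <- list(n_input = n_input, n_dropped = n_dropped,
                                    n_duplicates = n_duplicates,
                                    n_records = nrow(df))
  df
}

#' Read a transcript table (5-column TSV) into transcript models
#'
#' Columns: `gene`, `transcript`, `chromosome`, `strand`, `cds_intervals`
#' where the intervals are written `start-end;start-end;...` in transcription
#' order.
#'
#' @param path TSV file.
#' @param genome named character vector or `DNAStringSet` of chromosomes.
#' @return named list of `transcript_model`s (names = transcript ids).
#' @export
read_transcript_table <- function(path, genome) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "transcript", "chromosome", "strand", "cds_intervals")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing required column: ", miss[1])
  out <- lapply(seq_len(nrow(tab)), function(i) {
    parts <- strsplit(strsplit(tab$cds_intervals[i], ";", fixed = TRUE)[[1]],
                      "-", fixed = TRUE)
    iv <- data.frame(start = as.integer(vapply(parts, `[`, "", 1)),
                     end = as.integer(vapply(parts, `[`, "", 2)))
    transcript_model(tab$gene[i], tab$transcript[i], tab$chromosome[i],
                     tab$strand[i], iv, genome = genome)
  })
  names(out) <- tab$transcript
  out
}
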