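# Hotspot filtering: common variants, deleteriousness, feature annotation --

# labels accepted from PolyPhen-2-style prediction tables
PREDICTION_VOCABULARY <- c("benign", "possibly_damaging", "probably_damaging")

match_variant_key <- function(calls, variants) {
  # prefer genomic keys when both sides carry them
  v_genomic <- all(c("chromosome", "position") %in% names(variants)) ||
    all(c("chrom", "pos") %in% names(variants))
  c_genomic <- all(c("chromosome", "position") %in% names(calls))
  if (v_genomic && !c_genomic)
    stop("variants are genomic-keyed but calls carry no genomic coordinates",
         call. = FALSE)
  if (v_genomic) {
    chrom <- variants[["chromosome"]] %||% variants[["chrom"]]
    pos <- variants[["position"]] %||% variants[["pos"]]
    alt <- variants[["alt_base"]] %||% variants[["alt"]]
    list(call = paste(calls$chromosome, calls$position,
                      calls$alt_base %||% "", sep = "\r"),
         var = paste(chrom, pos, alt %||% "", sep = "\r"))
  } else {
    gene <- variants[["gene_id"]] %||% variants[["gene"]]
    res <- variants[["residue"]] %||% variants[["residue_position"]] %||%
      variants[["position"]]
    if (is.null(gene) || is.null(res))
      stop("variants carry neither genomic nor protein keys", call. = FALSE)
    # protein fallback matches (gene, residue), ignoring alleles
    list(call = paste(calls$gene_id, calls$residue, sep = "\r"),
         var = paste(gene, res, sep = "\r"))
  }
}

#' Flag hotspot calls matching common population variants
#'
#' A call is flagged `common_variant` (and excluded by [surviving_calls()])
#' when any matching variant in any source has a population frequency
#' *strictly greater* than `max_freq`; calls matching only variants at or
#' below the threshold, or matching nothing, are retained. Genomic keys are
#' preferred; with protein-keyed variant tables, matching falls back to
#' (gene, residue).
#'
#' @param calls `hotspot_calls` data.frame.
#' @param variants data.frame with a key (genomic: `chromosome`/`chrom`,
#'   `position`/`pos`, optional `alt`; or protein: `gene`, `residue`) plus
#'   `max_freq` (or `max_population_frequency`) and optional `source`.
#' @param max_freq exclusion threshold (default 0.01, i.e. 1%).
#' @return `calls` with a logical `common_variant` column added.
#' @export
filter_common_variants <- function(calls, variants, max_freq = 0.01) {
  freq <- variants[["max_freq"]] %||% variants[["max_population_frequency"]]
  if (is.null(freq)) stop("variants need a `max_freq` column")
  if (any(freq < 0 | freq > 1)) stop("variant frequencies must lie in [0, 1]")
  common <- variants[freq > max_freq, , drop = FALSE]
  if (nrow(calls) == 0) {
    calls$common_variant <- logical(0)
    return(calls)
  }
  keys <- match_variant_key(calls, common)
  calls$common_variant <- keys$call %in% keys$var
  calls
}

#' Flag hotspot calls lacking a damaging deleteriousness prediction
#'
#' A call is retained when at least one underlying change at the residue is
#' labeled damaging. Calls with predictions but no damaging label are flagged
#' `not_damaging`; calls with no prediction at all are flagged `unscored`
#' (excluded by default in [surviving_calls()]).
#'
#' @param calls `hotspot_calls` data.frame.
#' @param predictions data.frame with `gene` (or `gene_id`), `residue` (or
#'   `position`), optional `alt_aa`, and `label`.
#' @param damaging_labels labels counted as damaging.
#' @param vocabulary the full accepted label vocabulary; unknown labels are
#'   an error.
#' @return `calls` with logical `not_damaging` and `unscored` columns added.
#' @export
apply_deleteriousness_filter <- function(calls, predictions,
                                         damaging_labels =
                                           c("possibly_damaging",
                                             "probably_damaging"),
                                         vocabulary = PREDICTION_VOCABULARY) {
  lab <- predictions[["label"]]
  if (is.null(lab)) stop("predictions need a `label` column")
  unknown <- setdiff(unique(lab), vocabulary)
  if (length(unknown))
    stop("unknown prediction label(s): ", paste(unknown, collapse = ", "),
         "; accepted vocabulary: ", paste(vocabulary, collapse = ", "))
  gene <- predictions[["gene_id"]] %||% predictions[["gene"]]
  res <- predictions[["residue"]] %||% predictions[["residue_position"]] %||%
    predictions[["position"]]
  pkey <- paste(gene, res, sep = "\r")
  ckey <- paste(calls$gene_id, calls$residue, sep = "\r")
  damaging_keys <- unique(pkey[lab %in% damaging_labels])
  scored_keys <- unique(pkey)
  calls$unscored <- !ckey %in% scored_keys
  calls$not_damaging <- ckey %in% scored_keys & !ckey %in% damaging_keys
  calls
}

#' Hotspot calls surviving all applied filters
#'
#' @param calls flagged `hotspot_calls`.
#' @param include_unscored keep calls that have no deleteriousness
#'   prediction? Default `FALSE` (unscored calls are excluded).
#' @return the subset of `calls` with no exclusion flag set.
#' @export
surviving_calls <- function(calls, include_unscored = FALSE) {
  n <- nrow(calls)
  flag <- function(name) {
    if (name %in% names(calls)) calls[[name]] else rep(FALSE, n)
  }
  drop <- flag("common_variant") | flag("not_damaging")
  if (!include_unscored) drop <- drop | flag("unscored")
  calls[!drop, , drop = FALSE]
}

#' Check sequence agreement between annotation and reference proteins
#'
#' Annotations whose source protein disagrees with the sequence the mutations
#' were mapped to must not be transferred. The check passes when the global
#' identity of the two sequences is at least `min_identity` *and* the residue
#' at the hotspot position is identical in both. Equal-length sequences are
#' compared column-wise; otherwise a global alignment (BLOSUM62, gap
#' open 10 / extend 0.5) is used and identity is taken over all alignment
#' columns.
#'
#' @param annotation_seq,reference_seq amino-acid strings.
#' @param hotspot_position 1-based residue index on the reference.
#' @param min_identity identity threshold (default 0.95).
#' @return list with `pass`, `identity`, `residue_match`,
#'   `mismatch_positions` (reference coordinates) and possibly `reason`.
#' @export
check_sequence_agreement <- function(annotation_seq, reference_seq,
                                     hotspot_position, min_identity = 0.95) {
  annotation_seq <- toupper(annotation_seq)
  reference_seq <- toupper(reference_seq)
  if (!nchar(annotation_seq) || !nchar(reference_seq))
    stop("empty sequence")
  if (hotspot_position > nchar(reference_seq)) {
    return(list(pass = FALSE, identity = NA_real_, residue_match = FALSE,
                mismatch_positions = integer(0),
                reason = "hotspot position beyond reference sequence"))
  }
  if (nchar(annotation_seq) == nchar(reference_seq)) {
    a <- strsplit(annotation_seq, "")[[1]]
    r <- strsplit(reference_seq, "")[[1]]
    identity <- mean(a == r)
    mismatches <- which(a != r)
    residue_match <- a[hotspot_position] == r[hotspot_position]
  } else {
    aln <- Biostrings::pairwiseAlignment(annotation_seq, reference_seq,
                                         type = "global",
                                         substitutionMatrix = blosum62(),
                                         gapOpening = 10, gapExtension = 0.5)
    a <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
    r <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
    identity <- sum(a == r & a != "-") / length(a)
    rpos <- cumsum(r != "-")
    mismatches <- unique(rpos[a != r & r != "-"])
    col <- match(hotspot_position, rpos)
    residue_match <- !is.na(col) && a[col] == r[col] && a[col] != "-"
    if (hotspot_position > nchar(annotation_seq) && !residue_match) {
      return(list(pass = FALSE, identity = identity, residue_match = FALSE,
                  mismatch_positions = mismatches,
                  reason = "hotspot position not covered by annotation sequence"))
    }
  }
  list(pass = identity >= min_identity && residue_match,
       identity = identity, residue_match = residue_match,
       mismatch_positions = mismatches)
}

#' Overlap hotspot calls with protein feature annotations
#'
#' For every call, lists all features of the same gene whose interval
#' contains the residue, and reports the nearest-feature distance per feature
#' type (0 when the residue lies inside a feature; phosphosites a few
#' residues away from a hotspot are of interest, hence the distances).
#'
#' @param calls `hotspot_calls` data.frame.
#' @param features data.frame with `gene_id` (or `gene`), `start`, `end`
#'   (1-based inclusive), `feature_type`, optional `source` and
#'   `source_sequence`.
#' @return list with `overlaps` (long data.frame of containing features) and
#'   `nearest` (per call x feature_type minimum distance).
#' @export
overlap_features <- function(calls, features) {
  gene <- features[["gene_id"]] %||% features[["gene"]]
  if (is.null(gene)) stop("features need a gene column")
  if (any(features$start < 1) || any(features$end < features$start))
    stop("invalid feature intervals (need 1 <= start <= end)")
  features$gene_id <- gene
  overlaps <- list(); nearest <- list()
  for (i in seq_len(nrow(calls))) {
    f <- features[features$gene_id == calls$gene_id[i], , drop = FALSE]
    if (!nrow(f)) next
    r <- calls$residue[i]
    dist <- pmax(f$start - r, r - f$end, 0)
    inside <- f[dist == 0, , drop = FALSE]
    if (nrow(inside)) {
      inside$residue <- r
      overlaps[[length(overlaps) + 1]] <- inside
    }
    nd <- tapply(dist, f$feature_type, min)
    nearest[[length(nearest) + 1]] <-
      data.frame(gene_id = calls$gene_id[i], residue = r,
                 feature_type = names(nd), distance = as.integer(nd),
                 stringsAsFactors = FALSE)
  }
  empty_overlap <- features[0, , drop = FALSE]
  empty_overlap$residue <- integer(0)
  list(overlaps = if (length(overlaps)) do.call(rbind, overlaps)
                  else empty_overlap,
       nearest = if (length(nearest)) do.call(rbind, nearest)
                 else data.frame(gene_id = character(0), residue = integer(0),
                                 feature_type = character(0),
                                 distance = integer(0)))
}
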