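# Interaction interfaces: extraction, coordinate transfer, cluster test ----

#' Extract interface residues from a structure-derived residue table
#'
#' Interfaces are kept only when their complexation significance score (CSS)
#' passes the partner-class threshold (strictly greater than 0.3 for
#' protein-protein interfaces, 0.05 for ligand or nucleic-acid partners);
#' within passing interfaces, residues with buried surface area (BSA)
#' strictly greater than `bsa_min` are interface residues. Contiguous
#' residues are merged into segments.
#'
#' @param residue_table data.frame with columns `structure_id`, `chain`,
#'   `residue_index`, `residue_aa`, `ASA`, `BSA`, `interface_id`,
#'   `partner_class` (`protein`, `ligand`, `nucleic_acid`), `partner_id`,
#'   `CSS`.
#' @param css_protein_min CSS threshold for protein partners (default 0.3).
#' @param css_other_min CSS threshold for ligand/nucleic-acid partners
#'   (default 0.05).
#' @param bsa_min BSA threshold in square Angstrom (default 25).
#' @return data.frame of class `interface_segments`: one row per contiguous
#'   segment with `structure_id`, `chain`, `interface_id`, `partner_class`,
#'   `partner_id`, `css`, `start`, `end`.
#' @export
extract_interface_residues <- function(residue_table, css_protein_min = 0.3,
                                       css_other_min = 0.05, bsa_min = 25) {
  tab <- residue_table
  if (any(tab$ASA < 0) || any(tab$BSA < 0))
    stop("negative surface areas in residue table")
  css_min <- ifelse(tab$partner_class == "protein",
                    css_protein_min, css_other_min)
  tab <- tab[tab$CSS > css_min & tab$BSA > bsa_min, , drop = FALSE]
  grp <- paste(tab$structure_id, tab$chain, tab$interface_id, sep = "\r")
  pieces <- lapply(split(tab, grp), function(g) {
    idx <- sort(unique(g$residue_index))
    run <- cumsum(c(1L, diff(idx) != 1L))
    data.frame(structure_id = g$structure_id[1], chain = g$chain[1],
               interface_id = g$interface_id[1],
               partner_class = g$partner_class[1],
               partner_id = g$partner_id[1], css = g$CSS[1],
               start = as.integer(tapply(idx, run, min)),
               end = as.integer(tapply(idx, run, max)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(structure_id = character(0), chain = character(0),
               interface_id = character(0), partner_class = character(0),
               partner_id = character(0), css = numeric(0),
               start = integer(0), end = integer(0))
  rownames(out) <- NULL
  class(out) <- c("interface_segments", "data.frame")
  out
}

#' Smith-Waterman local alignment of two peptides
#'
#' Optimal local alignment under BLOSUM62 with affine gaps (open 10,
#' extend 0.5; a gap of length L costs `10 + 0.5 L`). Identity is the number
#' of identical columns divided by *all* alignment columns, gaps included.
#' When no positive-scoring alignment exists, an empty zero-score result is
#' returned.
#'
#' @param a,b amino-acid strings (20-letter alphabet).
#' @param gap_open,gap_extend gap penalties.
#' @return object of class `alignment_result`: `a_aligned`, `b_aligned`,
#'   `score`, `identity`, `length` (alignment columns), and `offsets`, a
#'   data.frame mapping aligned positions of `a` to positions of `b`
#'   (strictly increasing in both).
#' @export
local_align <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  a <- toupper(a); b <- toupper(b)
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  ok <- function(s) all(strsplit(s, "")[[1]] %in% AA20)
  if (!ok(a) || !ok(b)) stop("sequences must use the 20-letter amino-acid alphabet")
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = blosum62(),
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  sc <- Biostrings::score(aln)
  pa <- as.character(Biostrings::pattern(aln))
  pb <- as.character(Biostrings::subject(aln))
  if (sc <= 0 || !nchar(pa)) {
    return(structure(list(a_aligned = "", b_aligned = "", score = 0,
                          identity = NA_real_, length = 0L,
                          offsets = data.frame(a_pos = integer(0),
                                               b_pos = integer(0))),
                     class = "alignment_result"))
  }
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  apos <- Biostrings::start(Biostrings::pattern(aln)) - 1L + cumsum(ca != "-")
  bpos <- Biostrings::start(Biostrings::subject(aln)) - 1L + cumsum(cb != "-")
  both <- ca != "-" & cb != "-"
  structure(list(a_aligned = pa, b_aligned = pb, score = sc,
                 identity = sum(ca == cb & both) / length(ca),
                 length = length(ca),
                 offsets = data.frame(a_pos = apos[both], b_pos = bpos[both])),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> score ", x$score, ", ", x$length,
      " columns, identity ",
      if (is.na(x$identity)) "NA" else sprintf("%.1f%%", 100 * x$identity),
      "\n  ", x$a_aligned, "\n  ", x$b_aligned, "\n", sep = "")
  invisible(x)
}

#' Acceptance rule for transferring an aligned interface segment
#'
#' A segment's coordinates are transferred when the alignment identity is at
#' least `min_identity_short`, or the alignment spans more than `long_length`
#' columns and the identity is at least `min_identity_long`.
#'
#' @param identity identity over all alignment columns.
#' @param n_columns number of alignment columns.
#' @param min_identity_short,min_identity_long,long_length rule parameters
#'   (defaults 0.8, 0.6 and 10).
#' @return logical.
#' @export
interface_transfer_rule <- function(identity, n_columns,
                                    min_identity_short = 0.8,
                                    min_identity_long = 0.6,
                                    long_length = 10) {
  !is.na(identity) &
    (identity >= min_identity_short |
       (n_columns > long_length & identity >= min_identity_long))
}

# symmetric padding of [start, end] to at least min_len, clipped to [1, L];
# clipping on one side is compensated on the other when room remains
pad_segment <- function(start, end, L, min_len = 5L) {
  need <- min_len - (end - start + 1L)
  if (need > 0) {
    left <- need %/% 2L
    start <- start - left
    end <- end + (need - left)
    if (start < 1L) { end <- min(L, end + (1L - start)); start <- 1L }
    if (end > L) { start <- max(1L, start - (end - L)); end <- L }
  }
  c(start, end)
}

#' Transfer interface segments onto a target protein by local alignment
#'
#' Each structure-chain segment shorter than `min_segment` residues is first
#' padded symmetrically with flanking residues (clipped at the sequence
#' ends). The padded peptide is locally aligned to the target protein and
#' the segment is transferred if [interface_transfer_rule()] accepts the
#' alignment; transferred residue coordinates follow the alignment offset
#' map (only the original, unpadded residues are transferred).
#'
#' @param segments `interface_segments` (or data.frame with `start`, `end`).
#' @param structure_seq amino-acid sequence of the structure chain.
#' @param target_seq amino-acid sequence of the target protein.
#' @param min_segment minimum aligned segment length (default 5).
#' @return `segments` with added columns `mapped`, `identity`, `aln_length`,
#'   `target_start`, `target_end`, `n_mapped`; the full residue-level map is
#'   in the `"residue_map"` attribute (`structure_pos` -> `target_pos`).
#' @export
map_interface_to_protein <- function(segments, structure_seq, target_seq,
                                     min_segment = 5L) {
  structure_seq <- toupper(structure_seq)
  L <- nchar(structure_seq)
  if (any(segments$end > L)) stop("segment outside the structure sequence")
  segments$mapped <- FALSE
  segments$identity <- NA_real_
  segments$aln_length <- NA_integer_
  segments$target_start <- NA_integer_
  segments$target_end <- NA_integer_
  segments$n_mapped <- 0L
  maps <- list()
  for (i in seq_len(nrow(segments))) {
    se <- pad_segment(segments$start[i], segments$end[i], L, min_segment)
    peptide <- substr(structure_seq, se[1], se[2])
    aln <- tryCatch(local_align(peptide, target_seq), error = function(e) NULL)
    if (is.null(aln) || aln$length == 0) next
    segments$identity[i] <- aln$identity
    segments$aln_length[i] <- aln$length
    if (!interface_transfer_rule(aln$identity, aln$length)) next
    struct_pos <- se[1] - 1L + aln$offsets$a_pos
    inside <- struct_pos >= segments$start[i] & struct_pos <= segments$end[i]
    if (!any(inside)) next
    tpos <- aln$offsets$b_pos[inside]
    segments$mapped[i] <- TRUE
    segments$target_start[i] <- min(tpos)
    segments$target_end[i] <- max(tpos)
    segments$n_mapped[i] <- length(tpos)
    maps[[length(maps) + 1]] <-
      data.frame(segment = i, structure_pos = struct_pos[inside],
                 target_pos = tpos)
  }
  attr(segments, "residue_map") <- if (length(maps)) do.call(rbind, maps)
    else data.frame(segment = integer(0), structure_pos = integer(0),
                    target_pos = integer(0))
  segments
}

#' Test an interface region for mutation clustering
#'
#' Fits a per-residue binomial-logistic model of mutation occurrence:
#' `cbind(mutated, cohort - mutated) ~ interface + disorder`, where
#' `interface` marks interface residues and `disorder` is an optional
#' precomputed binary intrinsic-disorder track (it absorbs the higher
#' background mutation tolerance of disordered segments). The interface
#' effect is assessed with a one-sided likelihood-ratio test in the
#' enrichment direction: the two-sided LRT p is halved when the interface
#' coefficient is positive, otherwise `1 - p/2` is reported.
#'
#' @param profile a `residue_profile` of the target protein.
#' @param interface_mask logical vector (length = protein length).
#' @param disorder_mask optional logical vector; zeros when absent.
#' @param cohort_size number of patients in the cohort.
#' @return one-row data.frame: `gene_id`, `n_in`, `n_out`, `mutated_in`,
#'   `mutated_out`, `beta_interface`, `beta_disorder`, `p`, `untestable`.
#' @export
interface_cluster_test <- function(profile, interface_mask,
                                   disorder_mask = NULL, cohort_size) {
  L <- profile$length
  stopifnot(length(interface_mask) == L)
  if (is.null(disorder_mask)) disorder_mask <- rep(FALSE, L)
  stopifnot(length(disorder_mask) == L)
  k <- pmin(profile$counts, cohort_size)
  out <- data.frame(gene_id = profile$gene_id,
                    n_in = sum(interface_mask), n_out = sum(!interface_mask),
                    mutated_in = sum(k[interface_mask] > 0),
                    mutated_out = sum(k[!interface_mask] > 0),
                    beta_interface = NA_real_, beta_disorder = NA_real_,
                    p = 1, untestable = FALSE, stringsAsFactors = FALSE)
  if (sum(k) == 0 || all(interface_mask) || !any(interface_mask)) {
    out$untestable <- TRUE
    return(out)
  }
  dat <- data.frame(k = k, n = cohort_size,
                    iface = as.integer(interface_mask),
                    dis = as.integer(disorder_mask))
  use_dis <- length(unique(dat$dis)) > 1
  f_full <- if (use_dis) cbind(k, n - k) ~ iface + dis else
    cbind(k, n - k) ~ iface
  f_null <- if (use_dis) cbind(k, n - k) ~ dis else cbind(k, n - k) ~ 1
  full <- suppressWarnings(glm(f_full, family = binomial(), data = dat))
  null <- suppressWarnings(glm(f_null, family = binomial(), data = dat))
  dev <- max(0, null$deviance - full$deviance)
  p2 <- pchisq(dev, df = 1, lower.tail = FALSE)
  beta <- coef(full)[["iface"]]
  if (is.na(beta)) {
    out$untestable <- TRUE
    return(out)
  }
  out$beta_interface <- beta
  if (use_dis) out$beta_disorder <- coef(full)[["dis"]]
  p <- if (beta > 0) p2 / 2 else 1 - p2 / 2
  out$p <- min(max(p, .Machine$double.xmin), 1)
  out
}

#' Select proteins with significant interface mutation clusters
#'
#' Benjamini-Hochberg correction across proteins; proteins with adjusted
#' p below `alpha` are retained.
#'
#' @param results data.frame with one row per protein and a `p` column
#'   (e.g. stacked [interface_cluster_test()] results).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param keep_all return all rows (with `p_adjusted` and `significant`
#'   columns) instead of the significant subset?
#' @return data.frame.
#' @export
select_significant <- function(results, alpha = 0.05, keep_all = FALSE) {
  results$p_adjusted <- p.adjust(results$p, method = "BH")
  results$significant <- results$p_adjusted < alpha
  if (keep_all) results else results[results$significant, , drop = FALSE]
}
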