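# Synthetic cohorts, codon-substitution and null simulations ---------------

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Specification of one simulated gene
#'
#' @param gene_id identifier.
#' @param length protein length in residues.
#' @param background_rate expected missense events per residue per sample.
#' @param hotspots optional data.frame of planted hotspots with columns
#'   `position`, `share` (expected share of local mutations, over the
#'   clipped 300-residue window, in (0, 1]), optional `ref_aa`, `alt_aa`,
#'   and optional `n_events` (used only when the local background is zero).
#' @param nonsense_rate,frameshift_rate,synonymous_rate expected events per
#'   sample for the whole gene (positions uniform).
#' @param interface optional data.frame of intervals (`start`, `end`)
#'   marking interface residues.
#' @param interface_enrichment fold-increase of the missense rate on
#'   interface residues (default 1 = no enrichment).
#' @param common_variants optional data.frame (`position`, `frequency`,
#'   optional `ref_aa`, `alt_aa`) of population polymorphisms that
#'   contaminate the somatic calls: each sample carries the variant with the
#'   stated frequency.
#' @param bias optional named numeric vector of per-tumor-type weights for
#'   hotspot carriers (tumor-type-specific hotspot frequencies).
#' @return a `gene_spec` list.
#' @export
gene_spec <- function(gene_id, length, background_rate = 1e-4,
                      hotspots = NULL, nonsense_rate = 0,
                      frameshift_rate = 0, synonymous_rate = 0,
                      interface = NULL, interface_enrichment = 1,
                      common_variants = NULL, bias = NULL) {
  stopifnot(length >= 1, background_rate >= 0, nonsense_rate >= 0,
            frameshift_rate >= 0, synonymous_rate >= 0,
            interface_enrichment > 0)
  if (!is.null(hotspots)) {
    if (any(hotspots$share > 1))
      stop("infeasible hotspot share > 1")
    stopifnot(all(hotspots$share > 0), all(hotspots$position >= 1),
              all(hotspots$position <= length))
  }
  if (!is.null(common_variants))
    stopifnot(all(common_variants$frequency >= 0),
              all(common_variants$frequency <= 1),
              all(common_variants$position <= length))
  structure(list(gene_id = gene_id, length = as.integer(length),
                 background_rate = background_rate, hotspots = hotspots,
                 nonsense_rate = nonsense_rate,
                 frameshift_rate = frameshift_rate,
                 synonymous_rate = synonymous_rate, interface = interface,
                 interface_enrichment = interface_enrichment,
                 common_variants = common_variants, bias = bias),
            class = "gene_spec")
}

#' Specification of a synthetic cohort
#'
#' @param n_samples number of patients.
#' @param tumor_types named numeric vector of tumor-type proportions
#'   (default one pan-cancer type).
#' @param genes list of [gene_spec()]s.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples, tumor_types = c(PAN = 1), genes,
                        seed = NULL) {
  stopifnot(n_samples >= 1, all(tumor_types > 0), length(genes) >= 1)
  if (inherits(genes, "gene_spec")) genes <- list(genes)
  structure(list(n_samples = as.integer(n_samples),
                 tumor_types = tumor_types / sum(tumor_types),
                 genes = genes, seed = seed),
            class = "cohort_spec")
}

# interface residue mask of a gene spec
interface_mask_of <- function(gs) {
  mask <- rep(FALSE, gs$length)
  if (!is.null(gs$interface))
    for (i in seq_len(nrow(gs$interface)))
      mask[gs$interface$start[i]:gs$interface$end[i]] <- TRUE
  mask
}

random_missense_pair <- function(n) {
  ref <- sample(AA20, n, replace = TRUE)
  alt <- AA20[((match(ref, AA20) - 1L +
                  sample.int(19L, n, replace = TRUE)) %% 20L) + 1L]
  list(ref = ref, alt = alt)
}

#' Simulate a synthetic mutation cohort with known ground truth
#'
#' Per residue, background missense counts follow a Poisson process at the
#' gene's `background_rate` (optionally inflated on interface residues);
#' planted hotspots receive extra events drawn so that their expected share
#' of the local mutations (clipped 300-residue window) matches the spec;
#' tumor-suppressor-like genes gain nonsense/frameshift/synonymous events at
#' the stated per-sample rates; common variants contaminate each sample at
#' their population frequency. The output is a protein-dialect mutation
#' table plus truth tables for every downstream stage.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort`: `mutations` (protein-dialect
#'   data.frame), `manifest` (sample -> tumor type), `truth` (lists
#'   `hotspots` with realized planted event counts, `suppressors`,
#'   `interfaces`, `variants`), and the `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  types <- sample(names(spec$tumor_types), n, replace = TRUE,
                  prob = spec$tumor_types)
  manifest <- data.frame(sample_id = samples, tumor_type = types,
                         stringsAsFactors = FALSE)
  rows <- list()
  truth_hot <- list(); truth_var <- list(); truth_sup <- list()
  truth_ifc <- list()
  emit <- function(sample_id, gene_id, pos, ref, alt, cons) {
    data.frame(sample_id = sample_id,
               tumor_type = types[match(sample_id, samples)],
               gene_id = gene_id, residue_position = as.integer(pos),
               ref_aa = ref, alt_aa = alt, consequence = cons,
               stringsAsFactors = FALSE)
  }
  for (gs in spec$genes) {
    L <- gs$length
    w <- rep(1, L)
    mask <- interface_mask_of(gs)
    w[mask] <- gs$interface_enrichment
    n_bg_mean <- L * gs$background_rate * n
    n_bg <- rpois(1, n_bg_mean)
    if (n_bg > 0) {
      pos <- sample.int(L, n_bg, replace = TRUE, prob = w)
      aa <- random_missense_pair(n_bg)
      rows[[length(rows) + 1]] <- emit(sample(samples, n_bg, replace = TRUE),
                                       gs$gene_id, pos, aa$ref, aa$alt,
                                       "missense")
    }
    if (!is.null(gs$hotspots)) {
      for (i in seq_len(nrow(gs$hotspots))) {
        h <- gs$hotspots[i, ]
        half <- 150L
        lo <- max(1L, h$position - half); hi <- min(L, h$position + half)
        # expected background mass in the window under the position weights
        b_exp <- n_bg_mean * sum(w[lo:hi]) / sum(w)
        if (b_exp > 0 && h$share >= 1)
          stop("infeasible hotspot share ", h$share,
               " with positive local background")
        h_events <- if (b_exp > 0) rpois(1, h$share / (1 - h$share) * b_exp)
                    else as.integer(h$n_events %||% 10L)
        h_events <- min(h_events, n)
        if (h_events > 0) {
          pw <- rep(1, n)
          if (!is.null(gs$bias)) {
            pw <- gs$bias[types]
            pw[is.na(pw)] <- 0
          }
          carriers <- sample(samples, h_events, prob = pw)
          ref <- as.character(h$ref_aa %||% "E")
          alt <- as.character(h$alt_aa %||% "K")
          rows[[length(rows) + 1]] <- emit(carriers, gs$gene_id, h$position,
                                           ref, alt, "missense")
        }
        truth_hot[[length(truth_hot) + 1]] <-
          data.frame(gene_id = gs$gene_id, position = h$position,
                     share = h$share, n_planted = h_events,
                     stringsAsFactors = FALSE)
      }
    }
    class_rates <- c(nonsense = gs$nonsense_rate,
                     frameshift_indel = gs$frameshift_rate,
                     synonymous = gs$synonymous_rate)
    for (cl in names(class_rates)) {
      nev <- rpois(1, class_rates[[cl]] * n)
      if (nev == 0) next
      pos <- sample.int(L, nev, replace = TRUE)
      ref <- sample(AA20, nev, replace = TRUE)
      alt <- switch(cl, nonsense = rep("*", nev),
                    frameshift_indel = rep(NA_character_, nev),
                    synonymous = ref)
      rows[[length(rows) + 1]] <- emit(sample(samples, nev, replace = TRUE),
                                       gs$gene_id, pos, ref, alt, cl)
    }
    truth_sup[[length(truth_sup) + 1]] <-
      data.frame(gene_id = gs$gene_id,
                 expected_deleterious = (gs$nonsense_rate +
                                           gs$frameshift_rate) * n,
                 expected_synonymous = gs$synonymous_rate * n,
                 stringsAsFactors = FALSE)
    if (!is.null(gs$common_variants)) {
      for (i in seq_len(nrow(gs$common_variants))) {
        v <- gs$common_variants[i, ]
        carriers <- samples[runif(n) < v$frequency]
        ref <- as.character(v$ref_aa %||% "R")
        alt <- as.character(v$alt_aa %||% "Q")
        if (length(carriers))
          rows[[length(rows) + 1]] <- emit(carriers, gs$gene_id, v$position,
                                           ref, alt, "missense")
        truth_var[[length(truth_var) + 1]] <-
          data.frame(gene = gs$gene_id, residue = v$position,
                     ref_aa = ref, alt_aa = alt,
                     max_freq = v$frequency, source = "synthetic",
                     stringsAsFactors = FALSE)
      }
    }
    if (!is.null(gs$interface)) {
      ifc <- gs$interface
      ifc$gene_id <- gs$gene_id
      ifc$enrichment <- gs$interface_enrichment
      truth_ifc[[length(truth_ifc) + 1]] <- ifc
    }
  }
  empty <- data.frame(sample_id = character(0), tumor_type = character(0),
                      gene_id = character(0), residue_position = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      consequence = character(0), stringsAsFactors = FALSE)
  mutations <- if (length(rows)) do.call(rbind, rows) else empty
  key <- paste(mutations$sample_id, mutations$gene_id,
               mutations$residue_position, mutations$alt_aa,
               mutations$consequence, sep = "\r")
  mutations <- mutations[!duplicated(key), , drop = FALSE]
  rownames(mutations) <- NULL
  bind <- function(x, fallback) if (length(x)) do.call(rbind, x) else fallback
  structure(list(
    mutations = mutations, manifest = manifest,
    truth = list(
      hotspots = bind(truth_hot,
                      data.frame(gene_id = character(0), position = integer(0),
                                 share = numeric(0), n_planted = integer(0))),
      suppressors = bind(truth_sup, NULL),
      interfaces = bind(truth_ifc, NULL),
      variants = bind(truth_var,
                      data.frame(gene = character(0), residue = integer(0),
                                 ref_aa = character(0), alt_aa = character(0),
                                 max_freq = numeric(0), source = character(0)))),
    spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$mutations), " mutation records, ",
      x$spec$n_samples, " samples, ", length(x$spec$genes), " gene(s)\n",
      sep = "")
  invisible(x)
}

#' Simulate random single-nucleotide codon substitutions
#'
#' Each event draws an amino acid (equal weights across the 20 standard
#' amino acids), one of its codons uniformly, and one of the codon's nine
#' single-nucleotide changes uniformly (`"amino_acid_equal"`); or draws the
#' codon uniformly among the 61 sense codons (`"codon_equal"`). Outcomes are
#' tallied by (reference amino acid, outcome amino acid / stop /
#' synonymous). The exact analytic distribution, obtained by enumeration
#' over the sense codons, is returned alongside the Monte-Carlo tally.
#'
#' @param n_events number of simulated events (default 10000).
#' @param weighting `"amino_acid_equal"` or `"codon_equal"`.
#' @param seed optional RNG seed.
#' @return object of class `codon_sim` with `counts` (observed tally),
#'   `analytic` (exact probabilities), `n_events`, `weighting`. Use
#'   [substitution_frequency()] to read off a specific substitution.
#' @export
simulate_codon_substitutions <- function(n_events = 10000,
                                         weighting = c("amino_acid_equal",
                                                       "codon_equal"),
                                         seed = NULL) {
  weighting <- match.arg(weighting)
  gc <- Biostrings::GENETIC_CODE
  sense <- sense_codons()
  aa <- unname(gc[sense])
  codons_per_aa <- table(aa)
  w_codon <- if (weighting == "amino_acid_equal")
    1 / (20 * as.numeric(codons_per_aa[aa])) else rep(1 / 61, length(sense))

  # exact enumeration over (sense codon, position, alternative base)
  enum <- expand.grid(ci = seq_along(sense), pos = 1:3,
                      alt = DNA_BASES, stringsAsFactors = FALSE)
  enum$codon <- sense[enum$ci]
  enum$refbase <- substr(enum$codon, enum$pos, enum$pos)
  enum <- enum[enum$alt != enum$refbase, , drop = FALSE]
  alt_codon <- enum$codon
  substr(alt_codon, enum$pos, enum$pos) <- enum$alt
  enum$ref_aa <- aa[enum$ci]
  enum$alt_aa <- unname(gc[alt_codon])
  enum$prob <- w_codon[enum$ci] / 9
  analytic <- aggregate(prob ~ ref_aa + alt_aa, data = enum, FUN = sum)
  analytic <- analytic[order(-analytic$prob), ]
  rownames(analytic) <- NULL

  if (!is.null(seed)) set.seed(seed)
  ci <- sample.int(length(sense), n_events, replace = TRUE, prob = w_codon)
  pos <- sample.int(3L, n_events, replace = TRUE)
  codon <- sense[ci]
  refbase <- substr(codon, pos, pos)
  # pick uniformly among the three alternative bases
  shift <- sample.int(3L, n_events, replace = TRUE)
  altbase <- vapply(seq_len(n_events), function(i) {
    setdiff(DNA_BASES, refbase[i])[shift[i]]
  }, character(1))
  altc <- codon
  substr(altc, pos, pos) <- altbase
  obs <- data.frame(ref_aa = aa[ci], alt_aa = unname(gc[altc]),
                    stringsAsFactors = FALSE)
  counts <- aggregate(n ~ ref_aa + alt_aa,
                      data = transform(obs, n = 1L), FUN = sum)
  counts <- counts[order(-counts$n), ]
  rownames(counts) <- NULL
  structure(list(n_events = n_events, weighting = weighting,
                 counts = counts, analytic = analytic),
            class = "codon_sim")
}

#' Frequency of a specific substitution in a codon simulation
#'
#' @param sim a `codon_sim`.
#' @param from,to single-letter amino acids (`"*"` for stop gain).
#' @param denominator `"all"` events, or only `"changing"`
#'   (amino-acid-altering) events.
#' @param which `"observed"` Monte-Carlo frequency or exact `"analytic"`
#'   probability.
#' @return frequency as a proportion.
#' @export
substitution_frequency <- function(sim, from, to,
                                   denominator = c("all", "changing"),
                                   which = c("observed", "analytic")) {
  denominator <- match.arg(denominator)
  which <- match.arg(which)
  tab <- if (which == "observed") sim$counts else sim$analytic
  val <- function(f, t) {
    hit <- tab$ref_aa == f & tab$alt_aa == t
    if (which == "observed") sum(tab$n[hit]) else sum(tab$prob[hit])
  }
  num <- val(from, to)
  den <- if (which == "observed") sum(tab$n) else sum(tab$prob)
  if (denominator == "changing") {
    syn <- tab$ref_aa == tab$alt_aa
    den <- den - if (which == "observed") sum(tab$n[syn]) else
      sum(tab$prob[syn])
  }
  num / den
}

#' @export
print.codon_sim <- function(x, ...) {
  cat("<codon_sim> ", x$n_events, " events, ", x$weighting, " weighting\n",
      sep = "")
  ek <- substitution_frequency(x, "E", "K")
  cat(sprintf("  Glu->Lys: %.3f%% observed, %.3f%% analytic\n",
              100 * ek, 100 * substitution_frequency(x, "E", "K",
                                                     which = "analytic")))
  invisible(x)
}

#' Hotspot calls under a uniform mutation null
#'
#' Places `n_mutations` mutations uniformly at random over a protein of
#' `protein_length` residues (34,350 by default: the length of titin, the
#' most heavily mutated human gene), runs [detect_hotspots()], and repeats.
#' Under a uniform background, the detector should essentially never call a
#' hotspot on a protein this long.
#'
#' @param protein_length protein length (default 34350).
#' @param n_mutations mutations per replicate.
#' @param n_reps replicates (default 1000).
#' @param params a [hotspot_params()].
#' @param seed optional RNG seed.
#' @return integer vector: hotspot calls per replicate.
#' @export
simulate_uniform_null <- function(protein_length = 34350, n_mutations,
                                  n_reps = 1000, params = hotspot_params(),
                                  seed = NULL) {
  stopifnot(n_mutations >= 1)
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_reps), function(i) {
    counts <- tabulate(sample.int(protein_length, n_mutations,
                                  replace = TRUE), protein_length)
    nrow(detect_hotspots(residue_profile(counts), params))
  }, integer(1))
}
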