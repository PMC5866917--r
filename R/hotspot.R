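# Hotspot detection: dual-window share criterion + adjusted Poisson test ---

#' Hotspot detection parameters
#'
#' @param min_count minimum number of missense events at a residue for it to
#'   become a candidate (default 5).
#' @param windows window lengths in residues; each window is centered on the
#'   candidate and clipped to the protein (default `c(200, 300)`).
#' @param min_fraction minimum share of a window's mutations that must fall
#'   on the candidate residue, in *every* window (default 0.15).
#' @param mode `"fraction"` (share criterion) or `"overrepresentation"`
#'   (candidate count must exceed `overrep_factor` times the per-residue
#'   expectation in every window).
#' @param overrep_factor fold-overrepresentation required in
#'   `"overrepresentation"` mode (default 10).
#' @param alpha significance threshold applied to BH-adjusted p-values.
#' @return an object of class `hotspot_params`.
#' @export
hotspot_params <- function(min_count = 5L, windows = c(200L, 300L),
                           min_fraction = 0.15,
                           mode = c("fraction", "overrepresentation"),
                           overrep_factor = 10, alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(min_count >= 1, all(windows >= 1),
            min_fraction > 0, min_fraction <= 1, overrep_factor > 0,
            alpha > 0, alpha <= 1)
  structure(list(min_count = as.integer(min_count),
                 windows = as.integer(sort(windows)),
                 min_fraction = min_fraction, mode = mode,
                 overrep_factor = overrep_factor, alpha = alpha),
            class = "hotspot_params")
}

#' Per-residue mutation profile of one protein
#'
#' Counts distinct (sample, alternate amino acid) missense events per
#' residue; all consequence classes are tallied into `totals`.
#'
#' @param records mutation records of a single gene (protein-level dialect).
#' @param protein_length length of the protein in residues.
#' @param gene_id gene identifier; defaults to the records' gene.
#' @return object of class `residue_profile` with fields `gene_id`, `length`,
#'   `counts` (integer vector of length `protein_length`) and `totals`.
#' @export
build_residue_profile <- function(records, protein_length, gene_id = NULL) {
  protein_length <- as.integer(protein_length)
  if (nrow(records)) {
    g <- unique(records$gene_id)
    if (length(g) > 1) stop("records span more than one gene")
    gene_id <- gene_id %||% g
    bad <- which(records$residue_position > protein_length)
    if (length(bad))
      stop("residue position ", records$residue_position[bad[1]],
           " exceeds protein length ", protein_length, " (sample ",
           records$sample_id[bad[1]], ")")
  }
  mis <- records[records$consequence == "missense", , drop = FALSE]
  key <- paste(mis$sample_id, mis$alt_aa, mis$residue_position, sep = "\r")
  mis <- mis[!duplicated(key), , drop = FALSE]
  counts <- tabulate(mis$residue_position, nbins = protein_length)
  totals <- table(factor(records$consequence, levels = CONSEQUENCE_CLASSES))
  structure(list(gene_id = gene_id %||% NA_character_,
                 length = protein_length,
                 counts = as.integer(counts),
                 totals = setNames(as.integer(totals), CONSEQUENCE_CLASSES)),
            class = "residue_profile")
}

#' Build a residue profile directly from a count vector
#'
#' Convenience constructor used by simulations and region tests.
#'
#' @param counts integer vector of per-residue missense counts.
#' @param gene_id gene identifier.
#' @return a `residue_profile`.
#' @export
residue_profile <- function(counts, gene_id = NA_character_) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("negative counts")
  structure(list(gene_id = gene_id, length = length(counts), counts = counts,
                 totals = setNames(c(sum(counts), 0L, 0L, 0L, 0L, 0L),
                                   CONSEQUENCE_CLASSES)),
            class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  cat("<residue_profile> ", x$gene_id, ": ", x$length, " aa, ",
      sum(x$counts), " missense events at ", sum(x$counts > 0),
      " residues\n", sep = "")
  invisible(x)
}

#' Poisson tail p-value for a hotspot residue
#'
#' Under a uniform background, the expected count at one residue of a window
#' holding `n_w` mutations over `w_eff` residues is `lambda = n_w / w_eff`;
#' the hotspot p-value is the upper Poisson tail `P(X >= k)`, computed as one
#' minus the CDF at `k - 1` and clamped to (0, 1].
#'
#' @param k observed count at the candidate residue.
#' @param n_w total mutations in the (clipped) window, including the
#'   candidate's own.
#' @param w_eff clipped window length in residues.
#' @return p-value(s) in (0, 1]. Vectorized over its arguments.
#' @export
poisson_hotspot_pvalue <- function(k, n_w, w_eff) {
  stopifnot(all(k >= 0), all(w_eff >= 1))
  if (any(n_w < k)) stop("window total n_w smaller than residue count k")
  lambda <- n_w / w_eff
  p <- ppois(k - 1, lambda, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment of hotspot p-values
#'
#' @param pvals numeric vector of raw p-values in (0, 1].
#' @return BH-adjusted p-values (same length).
#' @export
adjust_pvalues <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Detect hotspot residues in one protein
#'
#' Candidate residues carry at least `min_count` missense events. For every
#' window length `W` a window `[c - W/2, c + W/2]` is centered on the
#' candidate and clipped to `[1, L]`; the candidate's share of the window's
#' mutations (its own events included in the denominator) must reach
#' `min_fraction` in *every* window (fraction mode), or its count must exceed
#' `overrep_factor` times the window's per-residue expectation
#' (overrepresentation mode). Each candidate receives a Poisson tail p-value
#' per window; `p_reported` is the maximum across windows (the most
#' conservative window governs). BH adjustment is applied at the run level by
#' [call_hotspots()], not here.
#'
#' @param profile a `residue_profile`.
#' @param params a [hotspot_params()].
#' @param keep_all keep non-passing candidates (with `passed = FALSE`)?
#' @return data.frame of class `hotspot_calls`, one row per candidate, with
#'   per-window columns `n_w<W>`, `share_w<W>`, `lambda_w<W>`, `p_w<W>`,
#'   `pass_w<W>` plus `passed`, `p_reported`, `p_adjusted`.
#' @export
detect_hotspots <- function(profile, params = hotspot_params(),
                            keep_all = FALSE) {
  stopifnot(inherits(profile, "residue_profile"))
  counts <- profile$counts
  L <- profile$length
  cand <- which(counts >= params$min_count)
  res <- data.frame(gene_id = rep(profile$gene_id, length(cand)),
                    residue = cand, k = counts[cand],
                    stringsAsFactors = FALSE)
  cs <- c(0L, cumsum(counts))
  pass_all <- rep(TRUE, length(cand))
  p_max <- rep(0, length(cand))
  for (W in params$windows) {
    h <- W %/% 2L
    lo <- pmax(1L, cand - h)
    hi <- pmin(L, cand + h)
    n_w <- cs[hi + 1L] - cs[lo]
    w_eff <- hi - lo + 1L
    k <- counts[cand]
    share <- k / n_w
    lambda <- n_w / w_eff
    p <- if (length(cand)) poisson_hotspot_pvalue(k, n_w, w_eff) else numeric(0)
    pass <- if (params$mode == "fraction") share >= params$min_fraction
            else k >= params$overrep_factor * lambda
    res[[paste0("n_w", W)]] <- n_w
    res[[paste0("share_w", W)]] <- share
    res[[paste0("lambda_w", W)]] <- lambda
    res[[paste0("p_w", W)]] <- p
    res[[paste0("pass_w", W)]] <- pass
    pass_all <- pass_all & pass
    p_max <- pmax(p_max, p)
  }
  res$passed <- pass_all
  res$p_reported <- p_max
  res$p_adjusted <- rep(NA_real_, nrow(res))
  if (!keep_all) res <- res[res$passed, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("hotspot_calls", "data.frame")
  res
}

#' Call hotspots across a cohort mutation table
#'
#' Builds a residue profile per gene, runs [detect_hotspots()], and applies
#' the Benjamini-Hochberg correction across all passing candidates of the
#' whole run (a single hotspot list, not per gene). The reference amino acid
#' of each call is the most frequent `ref_aa` among the missense records at
#' the residue.
#'
#' @param mutations protein-level mutation table.
#' @param protein_lengths named integer vector, gene id -> protein length.
#' @param params a [hotspot_params()].
#' @param keep_all keep non-passing candidates?
#' @return `hotspot_calls` data.frame across all genes.
#' @export
call_hotspots <- function(mutations, protein_lengths,
                          params = hotspot_params(), keep_all = FALSE) {
  genes <- intersect(unique(mutations$gene_id), names(protein_lengths))
  pieces <- lapply(genes, function(g) {
    rec <- mutations[mutations$gene_id == g, , drop = FALSE]
    prof <- build_residue_profile(rec, protein_lengths[[g]], gene_id = g)
    calls <- detect_hotspots(prof, params, keep_all = keep_all)
    if (nrow(calls)) {
      mis <- rec[rec$consequence == "missense", , drop = FALSE]
      calls$ref_aa <- vapply(calls$residue, function(r) {
        aa <- mis$ref_aa[mis$residue_position == r]
        if (length(aa) == 0) NA_character_
        else names(sort(table(aa), decreasing = TRUE))[1]
      }, character(1))
    } else calls$ref_aa <- character(0)
    calls
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- detect_hotspots(residue_profile(integer(0)), params)
    out$ref_aa <- character(0)
  }
  idx <- which(out$passed)
  if (length(idx)) out$p_adjusted[idx] <- adjust_pvalues(out$p_reported[idx])
  rownames(out) <- NULL
  class(out) <- c("hotspot_calls", "data.frame")
  out
}

#' @export
print.hotspot_calls <- function(x, ...) {
  n_pass <- if ("passed" %in% names(x)) sum(x$passed) else nrow(x)
  cat("<hotspot_calls> ", n_pass, " passing call(s) in ",
      length(unique(x$gene_id)), " gene(s)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
summary.hotspot_calls <- function(object, ...) {
  cat("Hotspot calls:", nrow(object), "candidates,",
      sum(object$passed), "passing\n")
  if (any(object$passed)) {
    sig <- sum(object$p_adjusted[object$passed] < 0.05, na.rm = TRUE)
    cat("  adjusted p < 0.05:", sig, "\n")
    cat("  genes:", paste(unique(object$gene_id[object$passed]),
                          collapse = ", "), "\n")
  }
  invisible(object)
}
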