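# Cohort-level analyses: tumor-type frequencies, clustering, resampling ----

strip_cohort_prefix <- function(x) sub("^[^:]+:", "", x)

#' Hotspot x tumor-type mutation frequency matrix
#'
#' For every hotspot (gene, residue) and every tumor type, the fraction of
#' that type's patients carrying a mutation at the residue. Tumor types
#' sharing a name abbreviation (an optional `COHORT:` prefix is stripped, so
#' e.g. `TCGA:BRCA` and `ICGC:BRCA` merge) are grouped; types with fewer
#' than `min_patients` patients are excluded.
#'
#' @param calls `hotspot_calls` (needs `gene_id`, `residue`).
#' @param mutations protein-level mutation table.
#' @param manifest data.frame mapping every `sample_id` to one `tumor_type`.
#' @param min_patients minimum cohort size per tumor type (default 50).
#' @return object of class `tumor_freq_matrix`: list with `matrix` (rows =
#'   `gene:residue` hotspot ids, columns = tumor types) and `n_patients`.
#' @export
build_frequency_matrix <- function(calls, mutations, manifest,
                                   min_patients = 50) {
  manifest <- manifest[!duplicated(manifest$sample_id), , drop = FALSE]
  if (anyNA(manifest$tumor_type))
    stop("manifest contains samples without a tumor type")
  missing <- setdiff(unique(mutations$sample_id), manifest$sample_id)
  if (length(missing))
    stop("sample(s) without a tumor type in the manifest: ",
         paste(head(missing, 3), collapse = ", "))
  type <- strip_cohort_prefix(manifest$tumor_type)
  n_patients <- table(type)
  keep <- names(n_patients)[n_patients >= min_patients]
  n_patients <- setNames(as.integer(n_patients[keep]), keep)
  hid <- paste0(calls$gene_id, ":", calls$residue)
  mat <- matrix(0, nrow = nrow(calls), ncol = length(keep),
                dimnames = list(hid, keep))
  stype <- setNames(type, manifest$sample_id)
  mkey <- paste0(mutations$gene_id, ":", mutations$residue_position)
  for (i in seq_len(nrow(calls))) {
    hits <- unique(mutations$sample_id[mkey == hid[i]])
    tt <- stype[hits]
    tab <- table(tt[tt %in% keep])
    mat[i, names(tab)] <- as.integer(tab) / n_patients[names(tab)]
  }
  structure(list(matrix = mat, n_patients = n_patients),
            class = "tumor_freq_matrix")
}

#' @export
print.tumor_freq_matrix <- function(x, ...) {
  cat("<tumor_freq_matrix> ", nrow(x$matrix), " hotspot(s) x ",
      ncol(x$matrix), " tumor type(s)\n", sep = "")
  invisible(x)
}

clades_of <- function(hc) {
  m <- hc$merge
  members <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    get <- function(j) if (j < 0) hc$labels[-j] else members[[j]]
    members[[i]] <- sort(c(get(m[i, 1]), get(m[i, 2])))
  }
  members
}

correlation_distance <- function(mat) {
  cc <- suppressWarnings(cor(mat))
  cc[is.na(cc)] <- 0    # constant resampled column: treat as uncorrelated
  diag(cc) <- 1
  as.dist(1 - cc)
}

#' Hierarchical clustering of tumor types with bootstrap support
#'
#' Clusters tumor-type columns by 1 - Pearson correlation with median
#' linkage, then resamples hotspot *rows* with replacement `B` times; the
#' support of each internal node is the fraction of replicate dendrograms
#' that contain the identical leaf set (the plain bootstrap probability).
#' Constant input columns have no defined correlation and are dropped with a
#' warning. Median linkage can produce height inversions; these are
#' tolerated.
#'
#' @param x `tumor_freq_matrix` or plain numeric matrix (rows = features,
#'   columns = entities to cluster; at least 2 rows and 3 columns).
#' @param linkage `hclust` agglomeration method (default `"median"`).
#' @param B bootstrap repetitions (default 10000).
#' @param seed optional RNG seed for reproducible resampling.
#' @return object of class `cluster_support`: `hclust`, `clades` (leaf-name
#'   sets per internal node), `support`, `B`.
#' @export
bootstrap_cluster <- function(x, linkage = "median", B = 10000, seed = NULL) {
  mat <- if (inherits(x, "tumor_freq_matrix")) x$matrix else as.matrix(x)
  colsd <- apply(mat, 2, sd)
  const <- !is.finite(colsd) | colsd == 0
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(mat)[const], collapse = ", "))
    mat <- mat[, !const, drop = FALSE]
  }
  if (ncol(mat) < 3 || nrow(mat) < 2)
    stop("need at least 3 columns and 2 rows to cluster")
  hc <- hclust(correlation_distance(mat), method = linkage)
  clades <- clades_of(hc)
  keys <- vapply(clades, paste, character(1), collapse = "\r")
  hits <- integer(length(keys))
  if (!is.null(seed)) set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(mat), replace = TRUE)
    hb <- hclust(correlation_distance(mat[idx, , drop = FALSE]),
                 method = linkage)
    kb <- vapply(clades_of(hb), paste, character(1), collapse = "\r")
    hits <- hits + (keys %in% kb)
  }
  structure(list(hclust = hc, clades = clades, support = hits / B, B = B),
            class = "cluster_support")
}

#' @export
print.cluster_support <- function(x, ...) {
  cat("<cluster_support> ", length(x$hclust$labels), " leaves, B = ", x$B,
      " bootstrap replicates\n", sep = "")
  for (i in seq_along(x$clades))
    cat(sprintf("  %.3f  {%s}\n", x$support[i],
                paste(x$clades[[i]], collapse = ", ")))
  invisible(x)
}

#' Export a clustering dendrogram as Newick
#'
#' @param cs `cluster_support` (or `hclust`).
#' @param path optional output file.
#' @return the Newick string, invisibly when written to a file.
#' @export
export_newick <- function(cs, path = NULL) {
  hc <- if (inherits(cs, "cluster_support")) cs$hclust else cs
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Display transform for hotspot frequency heatmaps
#'
#' Rows are kept only when the hotspot is mutated in at least
#' `display_min_fraction` of the patients of some tumor type. Fractions are
#' expressed as percentages and log2-transformed; zeros are represented as
#' the lowest value in the display (the minimum over positive entries minus
#' one log2 unit).
#'
#' @param x `tumor_freq_matrix` or numeric matrix of fractions in [0, 1].
#' @param display_min_fraction row filter threshold (default 1/3).
#' @return numeric matrix on the log2-percentage scale.
#' @export
heatmap_transform <- function(x, display_min_fraction = 1 / 3) {
  mat <- if (inherits(x, "tumor_freq_matrix")) x$matrix else as.matrix(x)
  if (any(mat < 0 | mat > 1)) stop("fractions must lie in [0, 1]")
  keep <- apply(mat, 1, max) >= display_min_fraction
  mat <- mat[keep, , drop = FALSE]
  pct <- mat * 100
  out <- pct
  pos <- pct > 0
  out[pos] <- log2(pct[pos])
  out[!pos] <- if (any(pos)) min(out[pos]) - 1 else 0
  out
}

#' Draw (and optionally save) a hotspot frequency heatmap
#'
#' @param x `tumor_freq_matrix` or matrix of fractions.
#' @param file optional PNG path.
#' @param ... passed to [heatmap_transform()].
#' @return the transformed matrix, invisibly.
#' @export
plot_frequency_heatmap <- function(x, file = NULL, ...) {
  m <- heatmap_transform(x, ...)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  axes = FALSE, main = "hotspot mutation frequency (log2 %)")
  invisible(m)
}

#' Fraction of patients carrying a mutation in a gene or hotspot set
#'
#' A patient with several mutated set members counts once. When `set` has a
#' `residue` (or `residue_position`) column, matching is per (gene, residue);
#' otherwise per gene.
#'
#' @param set data.frame of genes (`gene_id`) or hotspots (`gene_id`,
#'   `residue`).
#' @param mutations protein-level mutation table.
#' @param manifest sample manifest (`sample_id`); its distinct samples are
#'   the denominator.
#' @return fraction in [0, 1].
#' @export
patient_coverage <- function(set, mutations, manifest) {
  samples <- unique(manifest$sample_id)
  if (length(samples) == 0) stop("empty sample manifest")
  res_col <- intersect(c("residue", "residue_position"), names(set))
  if (length(res_col)) {
    skey <- paste0(set$gene_id, ":", set[[res_col[1]]])
    mkey <- paste0(mutations$gene_id, ":", mutations$residue_position)
  } else {
    skey <- set$gene_id
    mkey <- mutations$gene_id
  }
  hits <- unique(mutations$sample_id[mkey %in% skey])
  length(intersect(hits, samples)) / length(samples)
}

#' Null distribution of patient coverage for random position sets
#'
#' Draws random sets of the same size from the pool of protein positions
#' carrying at least `min_count` mutations, recomputes the patient coverage
#' of each draw, and locates the observed coverage in the resulting null via
#' a normal tail.
#'
#' @param mutations protein-level mutation table.
#' @param manifest sample manifest.
#' @param set_size positions per random set.
#' @param observed optional observed coverage to score against the null.
#' @param min_count pool admission threshold (default 5 mutations).
#' @param n_draws random sets (default 1000).
#' @param seed optional RNG seed.
#' @return object of class `coverage_null`: `null` (coverage per draw),
#'   `mean`, `sd`, `observed`, `p` (normal upper tail), `p_empirical`
#'   (`(1 + #draws >= observed) / (n_draws + 1)`).
#' @export
coverage_null <- function(mutations, manifest, set_size, observed = NULL,
                          min_count = 5, n_draws = 1000, seed = NULL) {
  ev <- mutations[!duplicated(paste(mutations$sample_id, mutations$gene_id,
                                    mutations$residue_position,
                                    mutations$alt_aa, sep = "\r")), ,
                  drop = FALSE]
  key <- paste0(ev$gene_id, ":", ev$residue_position)
  counts <- table(key)
  pool_keys <- names(counts)[counts >= min_count]
  if (length(pool_keys) <= set_size)
    stop("candidate pool (", length(pool_keys),
         ") not larger than set_size (", set_size, ")")
  pool <- do.call(rbind, strsplit(pool_keys, ":", fixed = TRUE))
  pool <- data.frame(gene_id = pool[, 1],
                     residue = as.integer(pool[, 2]),
                     stringsAsFactors = FALSE)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_draws), function(i) {
    patient_coverage(pool[sample.int(nrow(pool), set_size), , drop = FALSE],
                     mutations, manifest)
  }, numeric(1))
  m <- mean(null); s <- sd(null)
  out <- list(null = null, mean = m, sd = s, observed = observed,
              p = NA_real_, p_empirical = NA_real_, n_draws = n_draws)
  if (!is.null(observed)) {
    out$p <- if (s > 0) pnorm(observed, m, s, lower.tail = FALSE)
             else as.numeric(observed <= m)
    out$p_empirical <- (1 + sum(null >= observed)) / (n_draws + 1)
  }
  structure(out, class = "coverage_null")
}

#' @export
print.coverage_null <- function(x, ...) {
  cat(sprintf("<coverage_null> %d draws: mean %.4f, sd %.4f\n",
              x$n_draws, x$mean, x$sd))
  if (!is.null(x$observed))
    cat(sprintf("  observed %.4f, normal-tail p %.3g (empirical bound %.3g)\n",
                x$observed, x$p, x$p_empirical))
  invisible(x)
}

#' Enrichment of labeled proteins among network neighbors of a query set
#'
#' Counts labeled proteins among the first neighbors of the query proteins
#' in a physical-interaction network, and compares the count with a null
#' built by resampling interactor identities: the queries keep their network
#' positions while the identities of all other nodes are permuted over the
#' fixed (degree-preserving) topology, and the statistic is recomputed.
#' Reports a z-score and a normal upper-tail p.
#'
#' @param edges two-column data.frame of undirected edges.
#' @param query character vector of query proteins; queries absent from the
#'   network are skipped with a warning.
#' @param labels character vector of labeled proteins (e.g. known drivers).
#' @param n_resamples permutations (default 1000).
#' @param seed optional RNG seed.
#' @return list of class `enrichment_test`: `observed`, `null`, `z`, `p`.
#' @export
neighborhood_enrichment <- function(edges, query, labels, n_resamples = 1000,
                                    seed = NULL) {
  g <- igraph::simplify(igraph::graph_from_data_frame(edges[, 1:2],
                                                      directed = FALSE))
  v <- igraph::V(g)$name
  absent <- setdiff(query, v)
  if (length(absent)) {
    warning("query protein(s) absent from the network, skipped: ",
            paste(absent, collapse = ", "))
    query <- intersect(query, v)
  }
  if (length(query) == 0) stop("no query protein is present in the network")
  neighbor_names <- function(qs) {
    unique(unlist(lapply(igraph::ego(g, order = 1, nodes = qs, mindist = 1),
                         names)))
  }
  nb <- neighbor_names(query)
  observed <- sum(nb %in% labels)
  others <- setdiff(v, query)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_resamples), function(i) {
    ident <- setNames(v, v)               # queries keep their identity
    ident[others] <- sample(others)       # interactor identities resampled
    sum(unique(ident[nb]) %in% labels)
  }, numeric(1))
  m <- mean(null); s <- sd(null)
  z <- if (s > 0) (observed - m) / s else 0
  p <- if (s > 0) pnorm(observed, m, s, lower.tail = FALSE)
       else as.numeric(observed <= m)
  structure(list(observed = observed, null = null, z = z, p = p),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf("<enrichment_test> observed %d, null %.2f +/- %.2f, z %.2f, p %.3g\n",
              x$observed, mean(x$null), sd(x$null), x$z, x$p))
  invisible(x)
}

#' Compare success fractions between two sets
#'
#' Builds the 2x2 table and uses the chi-squared test with continuity
#' correction when all expected counts are at least 5, the Fisher exact test
#' otherwise (always Fisher for zero-margin tables, where p = 1). Vectorized
#' over its arguments; p-values are BH-adjusted across the batch.
#'
#' @param x_a,n_a successes and totals in set A.
#' @param x_b,n_b successes and totals in set B.
#' @return data.frame with `method`, `statistic`, `p_value`, `p_adjusted`.
#' @export
compare_set_fractions <- function(x_a, n_a, x_b, n_b) {
  stopifnot(length(x_a) == length(n_a), length(x_b) == length(n_b),
            length(x_a) == length(x_b))
  one <- function(xa, na, xb, nb) {
    stopifnot(xa >= 0, xb >= 0, xa <= na, xb <= nb)
    tab <- rbind(c(xa, na - xa), c(xb, nb - xb))
    zero_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    expected <- outer(rowSums(tab), colSums(tab)) / max(sum(tab), 1)
    if (!zero_margin && all(expected >= 5)) {
      t <- suppressWarnings(chisq.test(tab, correct = TRUE))
      data.frame(method = "chi-squared", statistic = unname(t$statistic),
                 p_value = t$p.value)
    } else {
      p <- if (zero_margin) 1 else fisher.test(tab)$p.value
      data.frame(method = "fisher", statistic = NA_real_, p_value = p)
    }
  }
  out <- do.call(rbind, Map(one, x_a, n_a, x_b, n_b))
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
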