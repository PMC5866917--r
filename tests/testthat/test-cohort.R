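toy_cohort <- function() {
  manifest <- data.frame(
    sample_id = paste0("s", 1:8),
    tumor_type = c("TCGA:BRCA", "ICGC:BRCA", "TCGA:BRCA", "ICGC:BRCA",
                   "LUAD", "LUAD", "LUAD", "KIRC"),
    stringsAsFactors = FALSE)
  mutations <- protein_records("G1", rep(10, 3), c("s1", "s2", "s5"))
  list(manifest = manifest, mutations = mutations)
}

test_that("frequency matrix merges abbreviations and applies the size filter", {
  fx <- toy_cohort()
  calls <- data.frame(gene_id = "G1", residue = 10)
  fm <- build_frequency_matrix(calls, fx$mutations, fx$manifest,
                               min_patients = 3)
  # TCGA:BRCA and ICGC:BRCA merge into one 4-patient column; KIRC (1) drops
  expect_setequal(colnames(fm$matrix), c("BRCA", "LUAD"))
  expect_equal(fm$n_patients[["BRCA"]], 4)
  expect_equal(fm$matrix["G1:10", "BRCA"], 2 / 4)
  expect_equal(fm$matrix["G1:10", "LUAD"], 1 / 3)
  # a hotspot absent from a type scores 0
  fm2 <- build_frequency_matrix(data.frame(gene_id = "G1", residue = 99),
                                fx$mutations, fx$manifest, min_patients = 3)
  expect_true(all(fm2$matrix == 0))
  # sample without a manifest entry is an error
  bad <- fx$mutations; bad$sample_id[1] <- "unknown"
  expect_error(build_frequency_matrix(calls, bad, fx$manifest), "manifest")
})

test_that("bootstrap clade support behaves at its extremes", {
  set.seed(11)
  base <- matrix(rnorm(40), nrow = 10)
  mat <- cbind(A = base[, 1], B = base[, 1],            # identical profiles
               C = base[, 2], D = base[, 3] + 5 * base[, 4])
  cs <- bootstrap_cluster(mat, B = 50, seed = 1)
  ab <- which(vapply(cs$clades, function(cl) identical(cl, c("A", "B")),
                     logical(1)))
  expect_length(ab, 1)
  expect_equal(cs$support[ab], 1)           # duplicates always merge first
  expect_true(all(cs$support >= 0 & cs$support <= 1))
  # the root clade contains every leaf in every replicate
  root <- which(lengths(cs$clades) == 4)
  expect_equal(cs$support[root], 1)
  # B = 1 gives supports in {0, 1}
  cs1 <- bootstrap_cluster(mat, B = 1, seed = 2)
  expect_true(all(cs1$support %in% c(0, 1)))
  # constant columns are dropped with a warning
  matc <- cbind(mat, E = rep(1, 10))
  expect_warning(bootstrap_cluster(matc, B = 5, seed = 3), "constant")
  expect_error(suppressWarnings(bootstrap_cluster(mat[, 1:2], B = 5)),
               "at least 3")
})

test_that("within-block clades outrank cross-block clades in noise blocks", {
  set.seed(21)
  block1 <- matrix(rnorm(60), ncol = 3) + rnorm(20) * 2  # shared row signal
  block2 <- matrix(rnorm(60), ncol = 3) + rnorm(20) * 2
  mat <- cbind(block1, block2)
  colnames(mat) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  cs <- bootstrap_cluster(mat, B = 200, seed = 4)
  within <- vapply(cs$clades, function(cl)
    length(cl) < 6 && (all(startsWith(cl, "a")) || all(startsWith(cl, "b"))),
    logical(1))
  cross <- lengths(cs$clades) < 6 & !within
  expect_gt(mean(cs$support[within]), max(0, cs$support[cross], na.rm = TRUE))
})

test_that("support is invariant to leaf relabeling", {
  set.seed(31)
  mat <- matrix(rnorm(50), nrow = 10)
  colnames(mat) <- c("V1", "V2", "V3", "V4", "V5")
  cs1 <- bootstrap_cluster(mat, B = 100, seed = 7)
  perm <- c(3, 1, 5, 2, 4)
  mat2 <- mat[, perm]
  cs2 <- bootstrap_cluster(mat2, B = 100, seed = 7)
  key <- function(cs) sort(vapply(cs$clades, paste, "", collapse = "+"))
  expect_equal(key(cs1), key(cs2))
  m1 <- setNames(cs1$support, vapply(cs1$clades, paste, "", collapse = "+"))
  m2 <- setNames(cs2$support, vapply(cs2$clades, paste, "", collapse = "+"))
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("dendrograms export as Newick", {
  set.seed(41)
  mat <- matrix(rnorm(50), nrow = 10,
                dimnames = list(NULL, paste0("T", 1:5)))
  cs <- bootstrap_cluster(mat, B = 5, seed = 1)
  nwk <- export_newick(cs)
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(vapply(paste0("T", 1:5), grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})

test_that("heatmap transform is the documented log2-percentage display", {
  m <- matrix(c(0.78, 0.01, 0, 0.5), nrow = 1)
  out <- heatmap_transform(m, display_min_fraction = 1 / 3)
  expect_equal(out[1, 1], log2(78))
  expect_equal(out[1, 2], 0)                       # log2(1) = 0
  expect_equal(out[1, 3], min(out[1, c(1, 2, 4)]) - 1)   # zero -> lowest
  # row below the display threshold is dropped
  m2 <- rbind(m, c(0.30, 0.2, 0.1, 0.05))
  expect_equal(nrow(heatmap_transform(m2)), 1)
  # monotone on positive entries
  v <- sort(runif(10, 0.34, 1))
  expect_true(all(diff(heatmap_transform(matrix(v, 1))[1, ]) > 0))
})

test_that("patient coverage counts each patient once", {
  fx <- toy_cohort()
  set <- data.frame(gene_id = "G1", residue = 10)
  expect_equal(patient_coverage(set, fx$mutations, fx$manifest), 3 / 8)
  # sample s1 with three hotspot mutations still counts once
  more <- rbind(fx$mutations,
                protein_records("G1", c(11, 12), c("s1", "s1")))
  set2 <- data.frame(gene_id = "G1", residue = 10:12)
  expect_equal(patient_coverage(set2, more, fx$manifest), 3 / 8)
  expect_equal(patient_coverage(data.frame(gene_id = "NOPE"),
                                fx$mutations, fx$manifest), 0)
  expect_error(patient_coverage(set, fx$mutations, fx$manifest[0, ]),
               "empty")
})

test_that("coverage null is reproducible and locates the observed value", {
  set.seed(3)
  n <- 60
  manifest <- data.frame(sample_id = paste0("s", 1:n), tumor_type = "PAN")
  # 30 recurrent positions, each mutated in a random subset of patients
  mutations <- do.call(rbind, lapply(1:30, function(i) {
    protein_records(paste0("G", i), 10,
                    sample(manifest$sample_id, sample(5:12, 1)))
  }))
  a <- coverage_null(mutations, manifest, set_size = 5, n_draws = 100,
                     seed = 99)
  b <- coverage_null(mutations, manifest, set_size = 5, n_draws = 100,
                     seed = 99)
  expect_identical(a$null, b$null)               # seed reproducibility
  # observed at the null mean scores p ~ 0.5
  p_mid <- coverage_null(mutations, manifest, set_size = 5, observed = a$mean,
                         n_draws = 100, seed = 99)$p
  expect_equal(p_mid, 0.5, tolerance = 1e-6)
  # observed above every draw is bounded by 1/(n_draws + 1)
  top <- coverage_null(mutations, manifest, set_size = 5, observed = 1,
                       n_draws = 100, seed = 99)
  expect_lte(top$p_empirical, 1 / 101 + 1e-12)
  expect_error(coverage_null(mutations, manifest, set_size = 500), "pool")
})

test_that("coverage of a planted hotspot set beats the resampling null", {
  # background genes carry mildly recurrent positions (below the share
  # rule) so the >= 5-mutation candidate pool is well populated
  genes <- c(list(gene_spec("HOT", 400, background_rate = 2e-4,
                            hotspots = data.frame(position = 100, share = 0.8))),
             lapply(1:16, function(i) gene_spec(
               paste0("BG", i), 400, background_rate = 8e-4,
               hotspots = data.frame(position = 200, share = 0.25))))
  sim <- simulate_cohort(cohort_spec(300, genes = genes, seed = 1234))
  obs <- patient_coverage(data.frame(gene_id = "HOT", residue = 100),
                          sim$mutations, sim$manifest)
  cn <- coverage_null(sim$mutations, sim$manifest, set_size = 1,
                      observed = obs, min_count = 5, n_draws = 200,
                      seed = 5)
  expect_lt(cn$p, 0.01)
})

test_that("neighborhood enrichment matches exact permutation enumeration", {
  edges <- data.frame(from = c("q", "q", "q", "x", "x"),
                      to   = c("a", "b", "c", "d", "e"))
  labels <- c("a", "b")
  nodes <- c("a", "b", "c", "d", "e", "x")
  ne <- neighborhood_enrichment(edges, "q", labels, n_resamples = 2000,
                                seed = 12)
  expect_equal(ne$observed, 2)
  # exact null by enumeration: the query keeps its three neighbor slots,
  # whose identities are a uniform draw without replacement from the six
  # interactor identities, 2 of which are labeled: hypergeometric with
  # N = 6, K = 2, n = 3, so mean 1 and variance 3*(1/3)*(2/3)*(3/5)
  m_exact <- 1
  v_exact <- 3 * (2 / 6) * (4 / 6) * (6 - 3) / 5
  z_exact <- (2 - m_exact) / sqrt(v_exact)
  expect_lt(abs(ne$z - z_exact), 0.25)
  expect_gt(ne$z, 0)
  # all nodes labeled: no enrichment possible
  all_lab <- neighborhood_enrichment(edges, "q", c(nodes, "q"),
                                     n_resamples = 200, seed = 1)
  expect_equal(all_lab$observed, 3)
  expect_equal(all_lab$p, 1)        # every draw matches: no enrichment
  # empty label set
  none <- neighborhood_enrichment(edges, "q", character(0),
                                  n_resamples = 200, seed = 1)
  expect_equal(none$observed, 0)
  expect_gte(none$p, 0.95)
  expect_warning(neighborhood_enrichment(edges, c("q", "ghost"), labels,
                                         n_resamples = 10, seed = 1),
                 "ghost")
})

test_that("fraction comparison picks chi-squared or Fisher appropriately", {
  # identical proportions
  same <- compare_set_fractions(50, 100, 50, 100)
  expect_gt(same$p_value, 0.9)
  expect_equal(same$method, "chi-squared")
  # strong difference agrees with the hypergeometric oracle
  diff <- compare_set_fractions(90, 100, 10, 100)
  expect_lt(diff$p_value, 1e-6)
  oracle <- fisher.test(rbind(c(90, 10), c(10, 90)))$p.value
  expect_lt(oracle, 1e-6)
  # small expected counts use Fisher
  small <- compare_set_fractions(2, 5, 0, 5)
  expect_equal(small$method, "fisher")
  # zero-margin table
  zm <- compare_set_fractions(0, 5, 0, 5)
  expect_equal(zm$p_value, 1)
  # batch of one: adjusted equals raw
  expect_equal(same$p_adjusted, same$p_value)
  batch <- compare_set_fractions(c(90, 50), c(100, 100), c(10, 50),
                                 c(100, 100))
  expect_equal(batch$p_adjusted, p.adjust(batch$p_value, "BH"))
})
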