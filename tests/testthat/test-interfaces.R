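pisa_table <- function(residues, bsa, css, partner_class = "protein",
                       interface_id = "I1") {
  data.frame(structure_id = "1ABC", chain = "A", residue_index = residues,
             residue_aa = "A", ASA = bsa + 10, BSA = bsa,
             interface_id = interface_id, partner_class = partner_class,
             partner_id = "P", CSS = css, stringsAsFactors = FALSE)
}

test_that("interface extraction applies CSS and BSA thresholds", {
  # BSA 30, protein-partner CSS 0.4: kept
  seg <- extract_interface_residues(pisa_table(5:9, 30, 0.4))
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(5, 9))
  # BSA 20 fails the strict > 25 rule; BSA exactly 25 fails too
  expect_equal(nrow(extract_interface_residues(pisa_table(5:9, 20, 0.4))), 0)
  expect_equal(nrow(extract_interface_residues(pisa_table(5:9, 25, 0.4))), 0)
  # protein-protein CSS 0.1 drops the interface; a ligand partner keeps it
  expect_equal(nrow(extract_interface_residues(pisa_table(5:9, 30, 0.1))), 0)
  expect_equal(nrow(extract_interface_residues(
    pisa_table(5:9, 30, 0.1, partner_class = "ligand"))), 1)
  # non-contiguous residues split into segments
  seg2 <- extract_interface_residues(pisa_table(c(5, 6, 9, 10), 30, 0.4))
  expect_equal(seg2$start, c(5, 9))
  expect_equal(seg2$end, c(6, 10))
  expect_error(extract_interface_residues(pisa_table(5, -1, 0.4)),
               "negative")
})

test_that("local alignment matches the brute-force Gotoh oracle", {
  a <- local_align("HEAGAWGHEE", "PAWHEAE")
  expect_equal(a$score, sw_score_oracle("HEAGAWGHEE", "PAWHEAE"))
  # identical sequences align end to end with the identity offset map
  b <- local_align("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(b$identity, 1)
  expect_equal(b$offsets$a_pos, b$offsets$b_pos)
  # no positive-scoring cell: empty zero-score alignment
  c <- local_align("WWWWW", "PPPPP")
  expect_equal(c$score, 0)
  expect_equal(c$length, 0L)
  expect_error(local_align("", "ACD"), "empty")
  expect_error(local_align("ACD", "AB1"), "alphabet")

  set.seed(55)
  for (i in 1:40) {
    x <- random_peptide(sample(8:15, 1))
    y <- random_peptide(sample(8:15, 1))
    expect_equal(local_align(x, y)$score, sw_score_oracle(x, y),
                 info = paste(x, y))
  }
})

test_that("alignment offsets are strictly increasing (injective transfer)", {
  set.seed(56)
  for (i in 1:20) {
    x <- random_peptide(12); y <- random_peptide(30)
    off <- local_align(x, y)$offsets
    if (nrow(off) > 1) {
      expect_true(all(diff(off$a_pos) > 0))
      expect_true(all(diff(off$b_pos) > 0))
    }
  }
})

test_that("transfer rule: 80% identity, or 60% beyond ten columns", {
  expect_false(interface_transfer_rule(5 / 7, 7))    # short needs >= 80%
  expect_true(interface_transfer_rule(8 / 12, 12))   # > 10 columns, >= 60%
  expect_true(interface_transfer_rule(1.0, 5))
  expect_false(interface_transfer_rule(0.79, 10))    # 10 columns is not "> 10"
  expect_true(interface_transfer_rule(0.61, 11))
})

test_that("interface segments transfer onto the target by local alignment", {
  struct <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  # exact substring: maps 1:1 at full identity
  seg <- data.frame(start = 10, end = 18)
  out <- map_interface_to_protein(seg, struct, struct)
  expect_true(out$mapped)
  expect_equal(out$identity, 1)
  expect_equal(c(out$target_start, out$target_end), c(10, 18))
  rm <- attr(out, "residue_map")
  expect_equal(rm$structure_pos, rm$target_pos)

  # a 3-residue segment is padded to five before alignment
  seg3 <- data.frame(start = 12, end = 14)
  out3 <- map_interface_to_protein(seg3, struct, struct)
  expect_true(out3$mapped)
  expect_equal(nrow(attr(out3, "residue_map")), 3)   # only original residues
  expect_gte(out3$aln_length, 5)

  # a target sharing too little sequence rejects the transfer
  out_bad <- map_interface_to_protein(seg, struct,
                                      "WWPPWWPPWWPPWWPPWWPPWWPP")
  expect_false(out_bad$mapped)
  expect_error(map_interface_to_protein(data.frame(start = 30, end = 40),
                                        struct, struct), "outside")
})

test_that("segment padding is symmetric and clipped at sequence ends", {
  struct <- "ACDEFGHIKLMNPQRSTVWY"
  # terminal 1-residue segment: padding can only extend rightward
  out <- map_interface_to_protein(data.frame(start = 1, end = 1),
                                  struct, struct)
  expect_true(out$mapped)
  expect_equal(attr(out, "residue_map")$target_pos, 1)
  out_end <- map_interface_to_protein(data.frame(start = 20, end = 20),
                                      struct, struct)
  expect_true(out_end$mapped)
})

test_that("interface cluster test finds planted enrichment, Fisher agrees", {
  L <- 200
  mask <- rep(FALSE, L); mask[91:110] <- TRUE
  counts <- integer(L)
  set.seed(42)
  counts[sample(91:110, 15, replace = TRUE)] <- 1   # all mutations inside
  res <- interface_cluster_test(residue_profile(counts, "G"), mask,
                                cohort_size = 100)
  expect_lt(res$p, 1e-3)
  expect_gt(res$beta_interface, 0)
  fish <- fisher.test(matrix(c(res$mutated_in, res$n_in - res$mutated_in,
                               res$mutated_out, res$n_out - res$mutated_out),
                             2), alternative = "greater")
  expect_lt(fish$p.value, 1e-3)   # same direction, both strongly enriched

  # zero mutations: untestable with p = 1
  none <- interface_cluster_test(residue_profile(integer(L), "G"), mask,
                                 cohort_size = 100)
  expect_true(none$untestable)
  expect_equal(none$p, 1)

  # depletion points the one-sided p the other way
  counts2 <- integer(L)
  counts2[sample(which(!mask), 30)] <- 1
  res2 <- interface_cluster_test(residue_profile(counts2, "G"), mask,
                                 cohort_size = 100)
  expect_gt(res2$p, 0.5)
})

test_that("disorder covariate absorbs disordered-region background", {
  L <- 300
  mask <- rep(FALSE, L); mask[1:30] <- TRUE
  dis <- rep(FALSE, L); dis[151:300] <- TRUE
  set.seed(43)
  counts <- integer(L)
  counts[sample(151:300, 40, replace = TRUE)] <- 1   # disorder-driven load
  with_dis <- interface_cluster_test(residue_profile(counts, "G"), mask, dis,
                                     cohort_size = 100)
  expect_false(is.na(with_dis$beta_disorder))
  expect_gt(with_dis$beta_disorder, 0)
  expect_gt(with_dis$p, 0.05)     # no interface signal
})

test_that("significant-cluster selection is BH-based", {
  res <- data.frame(gene_id = "G1", p = 0.01)
  expect_equal(nrow(select_significant(res)), 1)
  res_all <- data.frame(gene_id = paste0("G", 1:50), p = rep(1e-6, 50))
  expect_equal(nrow(select_significant(res_all)), 50)
  set.seed(9)
  res_null <- data.frame(gene_id = paste0("G", 1:100), p = runif(100))
  expect_lte(nrow(select_significant(res_null)), 2)
})
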