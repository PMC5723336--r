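fake_placement <- function(id, edge) {
  list(query_id = id,
       p = data.frame(edge_id = edge, logL = -10, lwr = 1, pendant = 0.1),
       best_edge = edge)
}

test_that("outgroup placements are discarded and clade labels attached", {
  nt <- read_newick_numbered(text = "((A:1,B:1):1,(C:1,D:1):1);")
  aln <- data.frame(id = c("A", "B", "C", "D"),
                    seq = c("MKVL", "MRVL", "MEVL", "MDVL"))
  rp <- build_refpkg("g", aln, nt, clade_map = list(X = c("A", "B")),
                     outgroup = c("C", "D"))
  idx <- clade_edges(rp)
  og_edge <- idx$edges$outgroup[1]
  stem_x <- max(idx$edges$X)   # stem edge of the clade (numbered after leaves)
  pls <- list(fake_placement("q1", idx$edges$X[1]),
              fake_placement("q2", og_edge),
              fake_placement("q3", stem_x))
  flt <- filter_outgroup_placements(pls, idx)
  expect_equal(flt$kept$query_id, c("q1", "q3"))
  expect_equal(flt$discarded$query_id, "q2")
  expect_true(all(flt$kept$clade == "X"))   # stem edge counts as the clade

  expect_error(filter_outgroup_placements(list(fake_placement("q", 99L)), idx),
               "absent")
  empty <- filter_outgroup_placements(list(), idx)
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$discarded), 0L)
})

test_that("percent of community follows the rpoB normalization equation", {
  expect_equal(percent_community(90, 1200, 90, 1200), 100)
  expect_equal(percent_community(30, 600, 90, 1200), 66.67, tolerance = 1e-4)
  expect_equal(percent_community(0, 600, 90, 1200), 0)
  expect_true(is.na(percent_community(30, 600, 0, 1200)))
  expect_error(percent_community(30, 0, 90, 1200), "length")

  # scale invariance and exact length sensitivity
  p <- percent_community(30, 600, 90, 1200)
  expect_equal(percent_community(300, 600, 900, 1200), p)
  expect_equal(percent_community(30, 1200, 90, 1200), p / 2)
})

test_that("copy-number correction divides per-clade percent", {
  expect_equal(copy_number_correct(150, 2), 75)
  expect_equal(copy_number_correct(42.5, 1), 42.5)
  expect_equal(copy_number_correct(0, 2), 0)
  expect_error(copy_number_correct(10, 0.5), ">= 1")
})

test_that("abundance tables are dense, additive, and depth-ordered", {
  nt <- read_newick_numbered(text = "((A:1,B:1):1,(C:1,D:1):1);")
  aln <- data.frame(id = c("A", "B", "C", "D"),
                    seq = c("MKVL", "MRVL", "MEVL", "MDVL"))
  rp <- build_refpkg("g", aln, nt,
                     clade_map = list(X = c("A", "B"), Y = c("C", "D")))
  idx <- clade_edges(rp)
  mk_kept <- function(n_x, n_y) {
    pls <- c(lapply(seq_len(n_x), function(i)
      fake_placement(paste0("x", i), idx$edges$X[1])),
      lapply(seq_len(n_y), function(i)
        fake_placement(paste0("y", i), idx$edges$Y[1])))
    filter_outgroup_placements(pls, idx)$kept
  }
  ab1 <- gene_abundance(mk_kept(10, 5), rp, rpob_count = 100, rpob_len = 4,
                        sample_id = "s300")
  ab2 <- gene_abundance(mk_kept(2, 0), rp, rpob_count = 80, rpob_len = 4,
                        sample_id = "s060")
  tot1 <- ab1$percent[ab1$clade == "total"]
  expect_equal(tot1, sum(ab1$percent[ab1$clade != "total"]))
  expect_equal(ab1$percent[ab1$clade == "X"],
               100 * (10 / 4) / (100 / 4))

  meta <- data.frame(sample_id = c("s300", "s060"), depth = c(300, 60),
                     fraction = "whole_water", stringsAsFactors = FALSE)
  prof <- clade_depth_profile(rbind(ab1, ab2), meta)
  # ordered by depth, shallow first
  expect_equal(unique(prof$depth), c(60, 300))
  # dense: clade Y present for s060 even though no reads placed there
  y60 <- prof[prof$sample_id == "s060" & prof$clade == "Y", ]
  expect_equal(nrow(y60), 1L)
  expect_equal(y60$placed_reads, 0L)

  dup <- rbind(ab1, ab1)
  expect_error(clade_depth_profile(dup, meta), "duplicate")
})

test_that("copy-number table is applied per clade before totals are re-summed", {
  nt <- read_newick_numbered(text = "((A:1,B:1):1,(C:1,D:1):1);")
  aln <- data.frame(id = c("A", "B", "C", "D"),
                    seq = c("MKVL", "MRVL", "MEVL", "MDVL"))
  rp <- build_refpkg("narG", aln, nt,
                     clade_map = list(SAR11 = c("A", "B"), other = c("C", "D")))
  idx <- clade_edges(rp)
  pls <- c(lapply(1:8, function(i) fake_placement(paste0("a", i),
                                                  idx$edges$SAR11[1])),
           lapply(1:2, function(i) fake_placement(paste0("b", i),
                                                  idx$edges$other[1])))
  kept <- filter_outgroup_placements(pls, idx)$kept
  ct <- data.frame(gene = "narG", clade = "SAR11", copies_per_genome = 2)
  ab <- gene_abundance(kept, rp, rpob_count = 10, rpob_len = 4, "s1",
                       copy_table = ct)
  sar <- ab[ab$clade == "SAR11", ]
  expect_equal(sar$percent_corrected, sar$percent / 2)
  oth <- ab[ab$clade == "other", ]
  expect_equal(oth$percent_corrected, oth$percent)
  tot <- ab[ab$clade == "total", ]
  expect_equal(tot$percent_corrected,
               sar$percent / 2 + oth$percent)
})

test_that("fraction enrichment is a signed, pseudo-counted log2 ratio", {
  expect_equal(fraction_enrichment(25, 5, 0.1), log2(25.1 / 5.1))
  expect_equal(round(fraction_enrichment(25, 5, 0.1), 2), 2.3)
  expect_equal(fraction_enrichment(7, 7), 0)
  expect_equal(fraction_enrichment(0, 0), 0)
  expect_gt(fraction_enrichment(10, 1), 0)
  expect_lt(fraction_enrichment(1, 10), 0)
})
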