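test_that("profile alignment registers reads onto their source columns", {
  rp <- toy_refpkg()
  refs <- refpkg_ungapped(rp)
  aa <- substr(refs$seq[1], 21, 60)
  q <- align_read_to_profile(list(read_id = "s/1", mate = "1", aa_seq = aa), rp)
  expect_equal(which(q$coverage), 21:60)
  expect_equal(q$info_cols, 40L)

  # all-X read: aligned but zero informative columns
  qx <- align_read_to_profile(list(read_id = "x/1", mate = "1",
                                   aa_seq = strrep("X", 40)), rp)
  expect_equal(qx$info_cols, 0L)

  # a deletion relative to the reference leaves exactly one gap column
  aa_del <- paste0(substr(refs$seq[1], 21, 39), substr(refs$seq[1], 41, 60))
  qd <- align_read_to_profile(list(read_id = "d/1", mate = "1",
                                   aa_seq = aa_del), rp)
  covered <- which(qd$coverage)
  expect_equal(setdiff(21:60, covered), 40)
  expect_equal(length(covered), 39L)
})

test_that("combining mates takes the union and masks disagreements", {
  rp <- toy_refpkg()
  refs <- refpkg_ungapped(rp)
  q1 <- align_read_to_profile(list(read_id = "p/1", mate = "1",
                                   aa_seq = substr(refs$seq[1], 1, 40)), rp)
  q2 <- align_read_to_profile(list(read_id = "p/2", mate = "2",
                                   aa_seq = substr(refs$seq[1], 71, 110)), rp)
  qc <- combine_pair_in_alignment(q1, q2)
  expect_equal(which(qc$coverage), c(1:40, 71:110))
  expect_equal(qc$info_cols, 80L)

  # overlapping agreement keeps residues; disagreement masks to unknown
  q3 <- align_read_to_profile(list(read_id = "p/2", mate = "2",
                                   aa_seq = substr(refs$seq[1], 21, 60)), rp)
  qa <- combine_pair_in_alignment(q1, q3)
  expect_equal(qa$residues[21:40], q1$residues[21:40])

  mut <- strsplit(substr(refs$seq[1], 21, 60), "")[[1]]
  orig <- mut[1:3]
  alt <- placeprof:::AA_ALPHABET[match(orig, placeprof:::AA_ALPHABET) %% 20 + 1]
  mut[1:3] <- alt
  q4 <- align_read_to_profile(list(read_id = "p/2", mate = "2",
                                   aa_seq = paste(mut, collapse = "")), rp)
  qm <- combine_pair_in_alignment(q1, q4)
  expect_true(all(is.na(qm$residues[21:23])))
  expect_true(all(qm$coverage[21:23]))
})

test_that("a full-length leaf query places on that leaf's pendant edge", {
  rp <- toy_refpkg()
  model <- build_model("LG", 1, 4)
  refs <- refpkg_ungapped(rp)
  td <- placeprof:::tree_data(rp$tree)
  for (leaf_i in c(1L, 4L)) {
    leaf <- refs$id[leaf_i]
    q <- align_read_to_profile(list(read_id = leaf, mate = "1",
                                    aa_seq = refs$seq[leaf_i]), rp)
    pl <- epa_place(q, rp, model)
    v <- match(leaf, rp$tree$phylo$tip.label)
    expect_equal(pl$best_edge, td$eid_of[v])
    expect_lte(pl$p$pendant[1], 1e-3)
    expect_equal(sum(pl$p$lwr), 1, tolerance = 1e-6)
    # sorted by descending LWR, pendant lengths within bounds
    expect_true(all(diff(pl$p$lwr) <= 1e-12))
    expect_true(all(pl$p$pendant >= 1e-8 & pl$p$pendant <= 2))
  }
})

test_that("placement log-likelihoods equal direct whole-tree evaluation", {
  # attach the query as a real leaf at an edge midpoint and compare the
  # per-edge EPA log-likelihood against tree_log_likelihood on that tree
  rp <- toy_refpkg(length_aa = 60)
  model <- build_model("LG", 1, 2)
  refs <- refpkg_ungapped(rp)
  aa <- substr(refs$seq[2], 1, 60)
  q <- align_read_to_profile(list(read_id = "q", mate = "1", aa_seq = aa), rp)
  pl <- epa_place(q, rp, model, min_aa = 30L)
  aln <- c(stats::setNames(rp$ref_alignment$seq, rp$ref_alignment$id),
           QUERY = paste(ifelse(is.na(q$residues), "-",
                                placeprof:::AA_ALPHABET[q$residues]),
                         collapse = ""))
  phy <- rp$tree$phylo
  td <- placeprof:::tree_data(rp$tree)
  for (row in c(1L, 3L)) {
    eid <- pl$p$edge_id[row]
    pend <- pl$p$pendant[row]
    child <- which(td$eid_of == eid)
    b <- td$len_of[child]
    phy2 <- phytools::bind.tip(phy, "QUERY", edge.length = pend,
                               where = child, position = b / 2)
    ll_direct <- tree_log_likelihood(numbered_tree(phy2), model, aln)
    expect_equal(pl$p$logL[row], ll_direct, tolerance = 1e-6)
  }
})

test_that("placement is symmetric for indistinguishable sister leaves", {
  # leaves A and B differ only at column 1; a query not covering column 1
  # cannot tell them apart, so their pendant-edge LWRs must be equal
  nwk <- "((A:0.2,B:0.2):0.1,(C:0.15,D:0.25):0.1);"
  nt <- read_newick_numbered(text = nwk)
  set.seed(55)
  base <- random_aa_string(60)
  a <- base
  b <- base; substr(b, 1, 1) <- if (substr(b, 1, 1) == "A") "R" else "A"
  cseq <- random_aa_string(60); dseq <- random_aa_string(60)
  aln <- data.frame(id = c("A", "B", "C", "D"), seq = c(a, b, cseq, dseq))
  rp <- build_refpkg("sym", aln, nt)
  model <- build_model("LG", 1, 2)
  qaa <- substr(base, 2, 60)
  q <- align_read_to_profile(list(read_id = "q", mate = "1", aa_seq = qaa), rp)
  expect_false(q$coverage[1])
  pl <- epa_place(q, rp, model, breadth = 1)  # optimize all edges
  td <- placeprof:::tree_data(nt)
  eA <- td$eid_of[match("A", nt$phylo$tip.label)]
  eB <- td$eid_of[match("B", nt$phylo$tip.label)]
  lA <- pl$p$lwr[pl$p$edge_id == eA]
  lB <- pl$p$lwr[pl$p$edge_id == eB]
  expect_equal(lA, lB, tolerance = 1e-6)
})

test_that("uninformative queries are refused with a clear error", {
  rp <- toy_refpkg()
  q <- align_read_to_profile(list(read_id = "short/1", mate = "1",
                                  aa_seq = strrep("X", 40)), rp)
  expect_error(epa_place(q, rp, build_model("LG", 1, 2)), "informative")
})

test_that("placement is deterministic", {
  rp <- toy_refpkg()
  model <- build_model("LG", 1, 4)
  refs <- refpkg_ungapped(rp)
  q <- align_read_to_profile(list(read_id = "q/1", mate = "1",
                                  aa_seq = substr(refs$seq[3], 10, 80)), rp)
  p1 <- epa_place(q, rp, model)
  p2 <- epa_place(q, rp, model)
  expect_identical(p1, p2)
})
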