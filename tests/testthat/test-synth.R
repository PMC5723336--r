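test_that("sequence evolution on a tree respects limits and determinism", {
  m <- build_model("LG", 1, 4)
  nt0 <- read_newick_numbered(text = "((A:0,B:0):0,C:0);")
  aln <- simulate_alignment_on_tree(nt0, m, 50, seed = 3)
  expect_equal(aln[["A"]], aln[["B"]])
  expect_equal(aln[["A"]], aln[["C"]])

  nt <- tiny_tree()
  a1 <- simulate_alignment_on_tree(nt, m, 40, seed = 8)
  a2 <- simulate_alignment_on_tree(nt, m, 40, seed = 8)
  expect_identical(a1, a2)
  a3 <- simulate_alignment_on_tree(nt, m, 40, seed = 9)
  expect_false(identical(a1, a3))
})

test_that("very long branches drive leaf composition to the stationary law", {
  m <- build_model("LG", 1, 1)
  nt <- read_newick_numbered(text = "(A:10000,B:10000);")
  n <- 10000
  aln <- simulate_alignment_on_tree(nt, m, n, seed = 13)
  counts <- table(factor(strsplit(aln[["A"]], "")[[1]],
                         levels = placeprof:::AA_ALPHABET))
  # each residue count within 3 sigma of the multinomial expectation
  expected <- n * m$freqs
  sds <- sqrt(n * m$freqs * (1 - m$freqs))
  expect_true(all(abs(as.numeric(counts) - expected) <= 3.5 * sds))
})

test_that("reverse translation inverts translation exactly", {
  expect_equal(substr(reverse_translate("MA", seed = 1), 1, 3), "ATG")
  set.seed(2)
  for (i in 1:5) {
    aa <- random_aa_string(30)
    dna <- reverse_translate(aa, seed = i)
    expect_equal(nchar(dna), 90L)
    expect_equal(six_frame_translate(dna)[["+1"]], aa)
  }
  expect_identical(reverse_translate("MKVLE", seed = 7),
                   reverse_translate("MKVLE", seed = 7))
  expect_error(reverse_translate("MK*V"), "stop")
})

test_that("community specifications enforce the single-copy rpoB assumption", {
  genomes <- data.frame(genome_id = c("g1", "g2"), abundance = c(0.5, 0.5))
  good <- data.frame(genome_id = c("g1", "g2"), gene = "rpoB",
                     source_leaf = "x", copies = 1L)
  expect_s3_class(community_spec(genomes, good), "community_spec")
  bad <- good; bad$copies <- 2L
  expect_error(community_spec(genomes, bad), "rpoB")
  expect_error(community_spec(genomes, good[1, ]), "rpoB")
  genomes_bad <- genomes; genomes_bad$abundance <- c(0.5, 0.6)
  expect_error(community_spec(genomes_bad, good))
})

test_that("read simulation is seeded, error-free when asked, and conserved in truth", {
  sc <- make_benchmark_scenario("basic", seed = 5, n_pairs = 60,
                                error_rate = 0)
  reads <- generate_metagenome_reads(sc$samples$s1, sc$refpkgs, sc$params)
  expect_equal(nrow(reads$r1), 60L)
  expect_equal(nrow(reads$r2), 60L)
  # truth-table conservation: every pair exactly once
  expect_equal(sort(reads$truth$read_id), sort(sub("/1$", "", reads$r1$id)))
  expect_equal(anyDuplicated(reads$truth$read_id), 0L)

  # determinism: identical seeds give identical reads
  reads2 <- generate_metagenome_reads(sc$samples$s1, sc$refpkgs, sc$params)
  expect_identical(reads$r1, reads2$r1)
  expect_identical(reads$r2, reads2$r2)

  # error-free reads are perfect substrings of their source gene DNA
  tr <- reads$truth[reads$truth$gene == "rpoB", ][1:5, ]
  for (i in seq_len(nrow(tr))) {
    r1 <- reads$r1$seq[reads$r1$id == paste0(tr$read_id[i], "/1")]
    refs <- refpkg_ungapped(sc$refpkgs$rpoB)
    aa <- refs$seq[refs$id == tr$source_leaf[i]]
    # the read translates in some frame to a substring of the source protein
    frames <- six_frame_translate(r1)
    hit <- any(vapply(frames, function(f) grepl(f, aa, fixed = TRUE), TRUE))
    expect_true(hit)
  }
})

test_that("realized read counts follow the abundance x copies x length law", {
  sc <- make_benchmark_scenario("multicopy", seed = 11, n_pairs = 4000)
  reads <- generate_metagenome_reads(sc$samples$s1, sc$refpkgs, sc$params)
  tr <- reads$truth[reads$truth$gene != "background", ]
  # expected proportions over gene instances
  spec <- sc$samples$s1
  inst <- merge(spec$gene_content, spec$genomes, by = "genome_id")
  len <- vapply(inst$gene, function(g) sc$refpkgs[[g]]$ref_length_aa * 3, 0)
  w <- inst$abundance * inst$copies * len
  p_narG <- sum(w[inst$gene == "narG"]) / sum(w)
  n <- nrow(tr)
  obs <- sum(tr$gene == "narG")
  # 99% binomial envelope
  expect_gte(obs, qbinom(0.005, n, p_narG))
  expect_lte(obs, qbinom(0.995, n, p_narG))
})

test_that("benchmark scenarios carry their documented structure", {
  expect_error(make_benchmark_scenario("nope"), "unknown scenario")
  b <- make_benchmark_scenario("basic", seed = 3, n_pairs = 10)
  expect_named(b$refpkgs, c("nirK", "rpoB"))
  expect_equal(unname(b$truth_percent["nirK"]), 20)
  carriers <- b$samples$s1$gene_content
  expect_equal(sum(carriers$gene == "nirK"), 2L)
  expect_equal(sum(carriers$gene == "rpoB"), 10L)

  mc <- make_benchmark_scenario("multicopy", seed = 3, n_pairs = 10)
  narg <- mc$samples$s1$gene_content
  expect_true(all(narg$copies[narg$gene == "narG"] == 2L))
  expect_equal(unname(mc$truth_percent["narG_uncorrected"]),
               2 * unname(mc$truth_percent["narG_corrected"]))

  og <- make_benchmark_scenario("outgroup_stress", seed = 3, n_pairs = 10)
  expect_equal(og$samples$s1$outgroup_frac, c(nirK = 0.1))

  pf <- make_benchmark_scenario("particle_vs_free", seed = 3, n_pairs = 10)
  expect_named(pf$samples, c("lt30", "gt30"))
  ab_free <- pf$samples$lt30$genomes$abundance
  ab_part <- pf$samples$gt30$genomes$abundance
  carrier_rows <- pf$samples$lt30$genomes$genome_id %in% c("g07", "g08")
  expect_equal(sum(ab_part[carrier_rows]) / sum(ab_free[carrier_rows]), 5)

  dp <- make_benchmark_scenario("depth_profile", seed = 3, n_pairs = 10)
  expect_length(dp$samples, 6L)
  expect_equal(nrow(dp$meta), 6L)
})
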