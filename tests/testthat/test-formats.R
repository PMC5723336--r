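test_that("FASTA reading normalizes whitespace, preserves order, validates ids", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "GG GT"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("a", "b"))
  expect_equal(recs$seq, c("ACGT", "GGGT"))

  writeLines(c(">a", "AC", ">a", "GG"), f)
  expect_error(read_fasta(f), "duplicate id a")

  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f)), 0L)
})

test_that("FASTA and FASTQ round-trip losslessly", {
  recs <- data.frame(id = c("r1", "r2"), seq = c("MKVLA", "GGSTE"),
                     qual = NA_character_, stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  expect_equal(read_fasta(f)[, c("id", "seq")], recs[, c("id", "seq")])

  fq <- withr::local_tempfile(fileext = ".fastq")
  reads <- data.frame(id = c("x/1", "y/1"), seq = c("ACGTACGT", "TTTTGGGG"),
                      qual = c("IIIIIIII", "IIII##II"), stringsAsFactors = FALSE)
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back, reads)
})

test_that("edge numbering is deterministic postorder with children in file order", {
  nwk <- "((A:0.1,B:0.2):0.05,C:0.3);"
  nt <- read_newick_numbered(text = nwk)
  expect_equal(sort(nt$edge_id), 0:3)
  # postorder: A, B, stem(AB), C
  leaf_edge <- function(nt, leaf) {
    v <- match(leaf, nt$phylo$tip.label)
    nt$edge_id[match(v, nt$phylo$edge[, 2])]
  }
  expect_equal(leaf_edge(nt, "A"), 0L)
  expect_equal(leaf_edge(nt, "B"), 1L)
  expect_equal(leaf_edge(nt, "C"), 3L)
  # pure function of the string
  nt2 <- read_newick_numbered(text = nwk)
  expect_identical(nt$edge_id, nt2$edge_id)
})

test_that("Newick round-trip preserves topology, lengths and edge ids", {
  nwk <- "((A:0.1,B:0.2):0.05,(C:0.3,D:0.123456789):0.07);"
  nt <- read_newick_numbered(text = nwk)
  out <- write_newick_numbered(nt)
  nt2 <- read_newick_numbered(text = out)
  expect_identical(nt$edge_id, nt2$edge_id)
  expect_equal(nt$phylo$edge.length, nt2$phylo$edge.length, tolerance = 1e-10)
  expect_true(ape::all.equal.phylo(nt$phylo, nt2$phylo))
})

test_that("Newick parsing rejects malformed input and missing lengths", {
  expect_error(read_newick_numbered(text = "((A:0.1,B:0.2);"),
               "parse error")
  expect_error(read_newick_numbered(text = "((A,B):0.05,C:0.3);"),
               "missing branch length")
  nt <- read_newick_numbered(text = "((A,B):0.05,C:0.3);", default_length = 0)
  expect_equal(sum(nt$phylo$edge.length == 0), 2L)
})

test_that("jplace output conforms to the v3 contract", {
  nt <- read_newick_numbered(text = "((A:0.1,B:0.2):0.05,C:0.3);")
  pl <- list(
    list(query_id = "q1",
         p = data.frame(edge_id = c(0L, 1L), logL = c(-10, -10.8),
                        lwr = c(0.7, 0.3), pendant = c(0.05, 0.1)),
         best_edge = 0L))
  doc <- placement_document(nt, pl)
  f <- withr::local_tempfile(fileext = ".jplace")
  write_placements(doc, f)
  obj <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(obj$version, 3L)
  expect_equal(unlist(obj$fields),
               c("edge_num", "likelihood", "like_weight_ratio", "pendant_length"))
  # every edge id annotated in the tree string
  for (e in 0:3) expect_match(obj$tree, sprintf("\\{%d\\}", e))
  # placements reference existing edges, LWRs conserved
  p <- obj$placements[[1]]$p
  expect_true(all(vapply(p, function(r) r[[1]], 0) %in% 0:3))
  expect_equal(sum(vapply(p, function(r) r[[3]], 0)), 1.0)
  # round trip through the reader
  doc2 <- read_placements(f)
  expect_equal(doc2$placements[[1]]$p$edge_id, c(0L, 1L))
  expect_equal(doc2$placements[[1]]$best_edge, 0L)

  # unknown edge id rejected; empty placements allowed
  bad <- pl
  bad[[1]]$p$edge_id <- c(0L, 99L)
  expect_error(placement_document(nt, bad), "unknown edge")
  empty_doc <- placement_document(nt, list())
  write_placements(empty_doc, f)
  obj <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_length(obj$placements, 0L)
})
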