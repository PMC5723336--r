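test_that("six-frame translation follows the codon, ambiguity and stop rules", {
  expect_equal(six_frame_translate("ATGGCC")[["+1"]], "MA")
  # reverse-complement symmetry
  expect_equal(six_frame_translate("GGCCAT")[["-1"]], "MA")
  expect_equal(six_frame_translate("ATGNNNTAA")[["+1"]], "MX*")
  expect_length(six_frame_translate("AT"), 0L)
  # trailing partial codons dropped
  fr <- six_frame_translate("ATGGCCA")
  expect_equal(fr[["+1"]], "MA")
  expect_equal(nchar(fr[["+2"]]), 2L)
})

test_that("translation/revcomp consistency across all frames", {
  set.seed(11)
  for (rep in 1:5) {
    x <- random_dna_string(50)
    a <- six_frame_translate(x)
    b <- six_frame_translate(revcomp(x))
    for (f in 1:3) {
      expect_equal(a[[paste0("-", f)]], b[[paste0("+", f)]])
      expect_equal(a[[paste0("+", f)]], b[[paste0("-", f)]])
    }
  }
})

test_that("local alignment reproduces known scores and is symmetric", {
  s62 <- scoring_scheme("BLOSUM62", 11, 1)
  r <- smith_waterman("MKV", "MKV", s62)
  expect_equal(r$score, 14)          # 5 + 5 + 4 on the BLOSUM62 diagonal
  expect_equal(r$query_interval, c(0L, 3L))

  s50 <- scoring_scheme("BLOSUM50", 0, 8)
  r2 <- smith_waterman("HEAGAWGHEE", "PAWHEAE", s50)
  expect_equal(r2$score, 28)
  expect_equal(r2$query_aln, "AWGHE")
  expect_equal(r2$ref_aln, "AW-HE")

  expect_error(smith_waterman("AAAA", "", s62), "empty")

  set.seed(4)
  for (i in 1:10) {
    a <- random_aa_string(sample(5:25, 1))
    b <- random_aa_string(sample(5:25, 1))
    expect_equal(smith_waterman(a, b, s62)$score,
                 smith_waterman(b, a, s62)$score)
  }
})

test_that("batch and interval SW kernels agree with the exhaustive DP oracle", {
  set.seed(12)
  schemes <- list(scoring_scheme("BLOSUM62", 11, 1),
                  scoring_scheme("BLOSUM50", 0, 8),
                  scoring_scheme("PAM30", 9, 1))
  for (scheme in schemes) {
    pats <- replicate(12, random_aa_string(sample(5:30, 1)))
    subs <- replicate(4, random_aa_string(sample(5:30, 1)))
    got <- sw_score_batch(pats, subs, scheme)
    for (i in seq_along(pats)) {
      for (j in seq_along(subs)) {
        expect_equal(got[i, j],
                     sw_oracle(pats[i], subs[j], scheme$matrix,
                               scheme$gap_open, scheme$gap_extend))
      }
      iv <- placeprof:::sw_intervals(pats[i], subs[1], scheme)
      expect_equal(iv$score, got[i, 1])
    }
  }
})

test_that("Karlin-Altschul e-values follow the closed form", {
  sch <- scoring_scheme(lambda = 0.267, K = 0.041, m = 100, n = 350)
  expect_equal(karlin_altschul_evalue(0, sch), 0.041 * 100 * 350)
  expect_equal(karlin_altschul_evalue(40, sch),
               0.041 * 100 * 350 * exp(-0.267 * 40), tolerance = 1e-12)
  expect_equal(round(karlin_altschul_evalue(40, sch), 3), 0.033)
  # monotone decreasing, graceful underflow
  expect_lt(karlin_altschul_evalue(50, sch), karlin_altschul_evalue(40, sch))
  expect_equal(karlin_altschul_evalue(1e6, sch), 0)
  sch2 <- scoring_scheme()
  expect_error(karlin_altschul_evalue(10, sch2), "not set")
})

test_that("pair merging respects overlap and mismatch thresholds", {
  r1 <- list(id = "p/1", seq = "AAACCCGG", qual = "IIIIIIII")
  r2 <- list(id = "p/2", seq = revcomp("CCGGTTTT"), qual = "IIIIIIII")
  m <- merge_overlapping_pair(r1, r2, min_overlap = 4, max_mismatch_frac = 0)
  expect_equal(m$seq, "AAACCCGGTTTT")
  expect_equal(m$id, "p")

  # overlap below threshold
  r2b <- list(id = "p/2", seq = revcomp("CGGTTTT"), qual = "IIIIIII")
  expect_null(merge_overlapping_pair(
    list(id = "p/1", seq = "AAACCCG", qual = "IIIIIII"), r2b,
    min_overlap = 4, max_mismatch_frac = 0))

  # too many mismatches in the overlap
  r2c <- list(id = "p/2", seq = revcomp("CCTTTTTT"), qual = "IIIIIIII")
  expect_null(merge_overlapping_pair(r1, r2c, min_overlap = 4,
                                     max_mismatch_frac = 0.25))

  # mismatch resolved by quality
  r1q <- list(id = "p/1", seq = "AAACCCGG", qual = "IIIIIII#")
  r2q <- list(id = "p/2", seq = revcomp("CCGATTTT"), qual = "IIIIIIII")
  mq <- merge_overlapping_pair(r1q, r2q, min_overlap = 4,
                               max_mismatch_frac = 0.5)
  expect_equal(substr(mq$seq, 8, 8), "A")  # r2's higher-quality base wins
})

test_that("reads recruit to their source gene and the length filter is exact", {
  rp <- toy_refpkg()
  refs <- refpkg_ungapped(rp)
  # a read copied verbatim from the middle of a reference coding sequence
  dna <- reverse_translate(substr(refs$seq[1], 11, 60), seed = 2)
  reads <- data.frame(id = "self/1", seq = dna, qual = NA, mate = "1")
  rec <- recruit_and_trim(reads, rp)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$frame, 1L)
  expect_equal(nchar(rec$aa_seq), 50L)
  expect_lt(rec$evalue, 1e-10)
  expect_equal(rec$dna_start, 0L)
  expect_equal(rec$dna_end, 150L)

  # reverse-strand recruitment
  reads_rc <- data.frame(id = "rc/1", seq = revcomp(dna), qual = NA, mate = "1")
  rec_rc <- recruit_and_trim(reads_rc, rp)
  expect_equal(nrow(rec_rc), 1L)
  expect_lt(rec_rc$frame, 0L)
  expect_equal(rec_rc$aa_seq, rec$aa_seq)

  # 33-aa boundary: a 32-aa perfect hit is dropped, 33-aa kept
  d32 <- reverse_translate(substr(refs$seq[1], 11, 42), seed = 3)
  d33 <- reverse_translate(substr(refs$seq[1], 11, 43), seed = 3)
  expect_equal(nrow(recruit_and_trim(
    data.frame(id = "a/1", seq = d32, qual = NA, mate = "1"), rp)), 0L)
  expect_equal(nrow(recruit_and_trim(
    data.frame(id = "b/1", seq = d33, qual = NA, mate = "1"), rp)), 1L)

  expect_error(recruit_and_trim(reads, list()), "empty")
})

test_that("overhang beyond the gene extent is trimmed off", {
  rp <- toy_refpkg()
  refs <- refpkg_ungapped(rp)
  core <- reverse_translate(substr(refs$seq[1], 1, 40), seed = 5)
  # prepend non-coding junk upstream of the gene start
  set.seed(8)
  read <- paste0(random_dna_string(30), core)
  rec <- recruit_and_trim(data.frame(id = "ov/1", seq = read, qual = NA,
                                     mate = "1"), rp)
  expect_equal(nrow(rec), 1L)
  # trimmed to the gene: the 30-nt overhang does not survive into aa_seq
  expect_lte(nchar(rec$aa_seq), 41L)
  expect_equal(rec$aa_seq, substr(refs$seq[1], 1, nchar(rec$aa_seq)))
})

test_that("random DNA is essentially never recruited at E < 1e-5", {
  rp <- toy_refpkg()
  set.seed(99)
  n <- 300
  reads <- data.frame(id = sprintf("rnd%03d/1", 1:n),
                      seq = replicate(n, random_dna_string(150)),
                      qual = NA, mate = "1", stringsAsFactors = FALSE)
  rec <- recruit_and_trim(reads, rp)
  expect_lte(nrow(rec), ceiling(0.01 * n))
})

test_that("recruitment is monotone in the e-value cutoff", {
  rp <- toy_refpkg()
  refs <- refpkg_ungapped(rp)
  set.seed(14)
  reads <- data.frame(
    id = sprintf("m%02d/1", 1:12),
    seq = c(vapply(1:6, function(i)
      reverse_translate(substr(refs$seq[1 + i %% 4], i * 5, i * 5 + 44),
                        seed = i), ""),
      replicate(6, random_dna_string(150))),
    qual = NA, mate = "1", stringsAsFactors = FALSE)
  strict <- recruit_and_trim(reads, rp, e_recruit = 1e-8)
  loose <- recruit_and_trim(reads, rp, e_recruit = 1e-3)
  expect_true(all(strict$read_id %in% loose$read_id))
})
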