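#' Six-frame translation
#'
#' Translates all six reading frames under the standard bacterial code.
#' Codons containing `N` translate to `X`; stop codons to `*`; trailing
#' partial codons are dropped. Frames `-1..-3` translate the reverse
#' complement.
#'
#' @param dna character scalar over `ACGTN`.
#' @return named character vector with names `+1,+2,+3,-1,-2,-3`; empty for
#'   inputs shorter than 3 nt.
#' @export
six_frame_translate <- function(dna) {
  six_frame_translate_batch(dna)[[1L]]
}

# Vectorized six-frame translation of many reads at once: one Biostrings
# translate call over all frame substrings (per-sequence calls are far too
# slow for read sets).
six_frame_translate_batch <- function(dnas) {
  dnas <- toupper(dnas)
  n <- nchar(dnas)
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(dnas)))
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  subs <- vector("list", 6L)
  for (fi in 1:6) {
    f <- c(1L, 2L, 3L, 1L, 2L, 3L)[fi]
    s <- if (fi <= 3L) dnas else rcs
    subs[[fi]] <- substr(s, f, f + 3L * ((n - f + 1L) %/% 3L) - 1L)
  }
  flat <- unlist(subs, use.names = FALSE)
  keep <- nchar(flat) >= 3L
  aa <- character(length(flat))
  if (any(keep)) {
    aa[keep] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(flat[keep]), if.fuzzy.codon = "X"))
  }
  aam <- matrix(aa, nrow = length(dnas), ncol = 6L)
  lapply(seq_along(dnas), function(i) {
    v <- stats::setNames(aam[i, ], frames)
    v[nzchar(v)]
  })
}

#' Construct a protein local-alignment scoring scheme
#'
#' Substitution matrix plus affine gap penalties and the Karlin-Altschul
#' parameters used to convert raw local-alignment scores into e-values.
#' Defaults are BLOSUM62 with gap open 11 / extend 1 and the standard gapped
#' calibration (lambda = 0.267, K = 0.041) for that scheme.
#'
#' @param matrix substitution matrix name available in Biostrings (e.g.
#'   `"BLOSUM62"`, `"BLOSUM50"`, `"PAM30"`) or a numeric matrix.
#' @param gap_open,gap_extend nonnegative gap penalties (a gap of length L
#'   costs `gap_open + L * gap_extend`).
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @param m,n search-space sizes: query length (aa) and database residues;
#'   usually filled in per search.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, m = NA, n = NA) {
  stopifnot(lambda > 0, K > 0, gap_open >= 0, gap_extend >= 0)
  sm <- if (is.matrix(matrix)) matrix else {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    get(matrix, envir = e)
  }
  structure(list(matrix = sm, matrix_name = if (is.matrix(matrix)) "custom" else matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, m = m, n = n),
            class = "scoring_scheme")
}

#' Optimal local (Smith-Waterman) protein alignment
#'
#' @param query_aa,ref_aa nonempty amino-acid strings.
#' @param scheme a [scoring_scheme()].
#' @return list with `score`, `query_interval` and `ref_interval` (0-based,
#'   half-open), and the aligned strings `query_aln`, `ref_aln`.
#' @export
smith_waterman <- function(query_aa, ref_aa, scheme = scoring_scheme()) {
  if (!nzchar(query_aa) || !nzchar(ref_aa)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_aa), Biostrings::AAString(ref_aa),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = max(sc, 0), query_interval = c(0L, 0L),
                ref_interval = c(0L, 0L), query_aln = "", ref_aln = ""))
  }
  p <- Biostrings::pattern(pa)
  s <- Biostrings::subject(pa)
  list(score = sc,
       query_interval = c(Biostrings::start(p) - 1L, Biostrings::end(p)),
       ref_interval = c(Biostrings::start(s) - 1L, Biostrings::end(s)),
       query_aln = as.character(p), ref_aln = as.character(s))
}

#' Batch Smith-Waterman scores
#'
#' Exhaustive local-alignment scores (no seeding heuristic) for every
#' pattern/subject pair under the scheme's substitution matrix and affine gap
#' penalties. Used to screen all translated frames of all reads against the
#' full reference set during recruitment.
#'
#' @param patterns,subjects character vectors of amino-acid sequences.
#' @param scheme a [scoring_scheme()].
#' @return numeric matrix `length(patterns)` x `length(subjects)`.
#' @export
sw_score_batch <- function(patterns, subjects, scheme = scoring_scheme()) {
  sw_score_batch_cpp(lapply(patterns, sw_encode, scheme = scheme),
                     lapply(subjects, sw_encode, scheme = scheme),
                     scheme$matrix, scheme$gap_open, scheme$gap_extend)
}

sw_encode <- function(s, scheme) {
  alpha <- rownames(scheme$matrix)
  v <- match(strsplit(toupper(s), "")[[1]], alpha)
  v[is.na(v)] <- match("X", alpha)
  v - 1L
}

# score + 0-based half-open query/reference intervals of one local alignment
sw_intervals <- function(query_aa, ref_aa, scheme = scoring_scheme()) {
  r <- sw_ends_cpp(sw_encode(query_aa, scheme), sw_encode(ref_aa, scheme),
                   scheme$matrix, scheme$gap_open, scheme$gap_extend)
  list(score = r$score, query_interval = c(r$q0, r$q1),
       ref_interval = c(r$r0, r$r1))
}

#' Karlin-Altschul e-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` in an `m x n` search space.
#'
#' @param score raw alignment score.
#' @param scheme a [scoring_scheme()] with `lambda`, `K`, `m`, `n` set.
#' @return e-value (underflows gracefully to 0 for very large scores).
#' @export
karlin_altschul_evalue <- function(score, scheme) {
  if (is.na(scheme$m) || is.na(scheme$n)) stop("search-space sizes m, n not set")
  scheme$K * scheme$m * scheme$n * exp(-scheme$lambda * score)
}

#' Merge an overlapping read pair
#'
#' Finds the maximal suffix(r1)/prefix(revcomp(r2)) overlap of length at
#' least `min_overlap` whose mismatch fraction is at most
#' `max_mismatch_frac`. At mismatching positions the base with the higher
#' quality wins (ties go to r1). `r2` is supplied in sequencing orientation
#' and reverse-complemented internally.
#'
#' @param r1,r2 single-row `data.frame`s (or lists) with `id`, `seq`,
#'   optional `qual`.
#' @param min_overlap minimum overlap length (default 10).
#' @param max_mismatch_frac maximum fraction of mismatches in the overlap
#'   (default 0.1).
#' @return merged record (list with `id`, `seq`, `qual`) or `NULL` if no
#'   qualifying overlap exists.
#' @export
merge_overlapping_pair <- function(r1, r2, min_overlap = 10,
                                   max_mismatch_frac = 0.1) {
  s1 <- toupper(r1$seq); s2 <- revcomp(r2$seq)
  q1 <- if (!is.null(r1$qual) && !is.na(r1$qual)) utf8ToInt(r1$qual) - 33L else
    rep(40L, nchar(s1))
  q2r <- if (!is.null(r2$qual) && !is.na(r2$qual)) rev(utf8ToInt(r2$qual) - 33L) else
    rep(40L, nchar(s2))
  n1 <- nchar(s1); n2 <- nchar(s2)
  v1 <- strsplit(s1, "")[[1]]; v2 <- strsplit(s2, "")[[1]]
  best <- NULL
  for (ov in seq(min(n1, n2), min_overlap)) {
    a <- v1[(n1 - ov + 1L):n1]; b <- v2[1:ov]
    mm <- sum(a != b)
    if (mm / ov <= max_mismatch_frac) { best <- ov; break }
  }
  if (is.null(best)) return(NULL)
  ov <- best
  i1 <- (n1 - ov + 1L):n1
  ovl_base <- ifelse(q1[i1] >= q2r[1:ov], v1[i1], v2[1:ov])
  ovl_q <- pmax(q1[i1], q2r[1:ov])
  seq <- paste0(substr(s1, 1L, n1 - ov), paste(ovl_base, collapse = ""),
                substr(s2, ov + 1L, n2))
  qual <- intToUtf8(c(q1[seq_len(n1 - ov)], ovl_q, q2r[seq(ov + 1L, length.out = n2 - ov)]) + 33L)
  list(id = sub("/[12]$", "", r1$id), seq = seq, qual = qual)
}

# dna coordinates (0-based half-open, on the original read) of an aa interval
# within a translated frame
frame_dna_span <- function(frame, read_len, aa_start0, aa_end0) {
  f <- abs(frame)
  start_in_strand <- (f - 1L) + 3L * aa_start0
  end_in_strand <- (f - 1L) + 3L * aa_end0
  if (frame > 0) c(start_in_strand, end_in_strand)
  else c(read_len - end_in_strand, read_len - start_in_strand)
}

#' Recruit reads to a gene and trim them to frame and extent
#'
#' Each read is translated in all six frames and scored against every
#' (ungapped) reference by local protein alignment. The best frame/reference
#' combination is chosen by lowest e-value (ties: highest score, then lowest
#' frame index). The read is trimmed to the locally aligned extent — which
#' removes any overhang beyond the reference gene — and internal stop codons
#' or ambiguities inside the kept segment are masked to `X`. Reads failing
#' the e-value cutoff, or shorter than `min_aa` residues after trimming, are
#' dropped. Each read yields at most one recruited record per gene.
#'
#' @param reads `data.frame` with `id`, `seq` (DNA), optional `qual`, and
#'   optionally a `mate` column (1, 2 or "merged").
#' @param refpkg target gene's `refpkg`.
#' @param scheme a [scoring_scheme()]; `m`/`n` are filled per search.
#' @param e_recruit e-value cutoff (default 1e-5).
#' @param min_aa minimum trimmed length in amino acids (default 33, i.e. the
#'   100-bp rule).
#' @return `data.frame` with columns `read_id`, `mate`, `frame`, `aa_seq`,
#'   `dna_start`, `dna_end`, `score`, `evalue`, `best_ref`.
#' @export
recruit_and_trim <- function(reads, refpkg, scheme = scoring_scheme(),
                             e_recruit = 1e-5, min_aa = 33L) {
  refs <- refpkg_ungapped(refpkg)
  if (!nrow(refs)) stop("empty reference set")
  empty <- data.frame(read_id = character(), mate = character(),
                      frame = integer(), aa_seq = character(),
                      dna_start = integer(), dna_end = integer(),
                      score = numeric(), evalue = numeric(),
                      best_ref = character(), stringsAsFactors = FALSE)
  if (!nrow(reads)) return(empty)
  db_n <- sum(nchar(refs$seq))
  # translate all frames of all reads
  frames_per_read <- six_frame_translate_batch(reads$seq)
  pat_read <- rep(seq_len(nrow(reads)), vapply(frames_per_read, length, 0L))
  pat_frame <- unlist(lapply(frames_per_read, names), use.names = FALSE)
  pat_seq <- unlist(frames_per_read, use.names = FALSE)
  if (!length(pat_seq)) return(empty)
  scores <- sw_score_batch(pat_seq, refs$seq, scheme)
  m_len <- nchar(pat_seq)
  ev <- scheme$K * m_len * db_n * exp(-scheme$lambda * scores)
  frame_num <- ifelse(substr(pat_frame, 1, 1) == "+", 1L, -1L) *
    as.integer(substr(pat_frame, 2, 2))
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rows <- which(pat_read == i)
    if (!length(rows)) next
    evi <- ev[rows, , drop = FALSE]
    sci <- scores[rows, , drop = FALSE]
    # order: lowest e-value, then highest score, then lowest frame index,
    # then first reference
    cand <- which(evi == min(evi), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      sc_c <- sci[cand]
      cand <- cand[sc_c == max(sc_c), , drop = FALSE]
      fn <- frame_num[rows[cand[, 1]]]
      fr_c <- ifelse(fn > 0, fn, 3L - fn)   # +1,+2,+3,-1,-2,-3 -> 1..6
      cand <- cand[order(fr_c, cand[, 2]), , drop = FALSE]
    }
    ri <- rows[cand[1, 1]]; rj <- cand[1, 2]
    if (ev[ri, rj] >= e_recruit) next
    sw <- sw_intervals(pat_seq[ri], refs$seq[rj], scheme)
    aa <- substr(pat_seq[ri], sw$query_interval[1] + 1L, sw$query_interval[2])
    aa_len <- nchar(aa)
    if (aa_len < min_aa) next
    aa <- gsub("[^ARNDCQEGHILKMFPSTWYV]", "X", aa)
    span <- frame_dna_span(frame_num[ri], nchar(reads$seq[i]),
                           sw$query_interval[1], sw$query_interval[2])
    mate <- if ("mate" %in% names(reads)) as.character(reads$mate[i]) else {
      m <- regmatches(reads$id[i], regexpr("/[12]$", reads$id[i]))
      if (length(m)) sub("/", "", m) else "merged"
    }
    out[[i]] <- data.frame(
      read_id = reads$id[i], mate = mate, frame = frame_num[ri],
      aa_seq = aa, dna_start = span[1], dna_end = span[2],
      score = scores[ri, rj], evalue = ev[ri, rj],
      best_ref = refs$id[rj], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) empty else res
}
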