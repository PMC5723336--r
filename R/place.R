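#' Align a recruited read to the reference alignment's columns
#'
#' Profile alignment of the trimmed amino-acid read against the reference
#' alignment: each column is scored as the frequency-weighted BLOSUM62 score
#' of the read residue against the residues observed in that column, and the
#' read is aligned global-in-read / local-in-profile with affine gaps.
#' Reference columns are never modified: read residues that cannot be
#' assigned to a column (insertions relative to the profile) are dropped.
#' All-gap reference columns are skipped free of charge.
#'
#' @param read one row of [recruit_and_trim()] output (or a list with
#'   `read_id`, `mate`, `aa_seq`).
#' @param refpkg the gene's `refpkg`.
#' @param gap_open,gap_extend affine gap penalties (defaults 11, 1).
#' @return an `aligned_query`: list with `query_id`, `mates`, `residues`
#'   (integer states per reference column, `NA` where the query has no
#'   residue), `coverage` (logical mask), `info_cols` (count of informative,
#'   i.e. non-`X`, covered columns) and `score`.
#' @export
align_read_to_profile <- function(read, refpkg, gap_open = 11, gap_extend = 1) {
  prof <- refpkg_profile(refpkg)
  aa <- toupper(read$aa_seq)
  states <- encode_aa(aa)           # NA for X
  L <- length(states)
  # column-score matrix: profile columns x read positions
  sc <- matrix(0, nrow = ncol(prof$freq), ncol = L)
  known <- !is.na(states)
  if (any(known)) {
    sc[, known] <- prof$colscore[, states[known], drop = FALSE]
  }
  sc[prof$all_gap, ] <- -1e4        # residues never placed in all-gap columns
  del_open <- rep(gap_open + gap_extend, ncol(prof$freq))
  del_ext <- rep(gap_extend, ncol(prof$freq))
  del_open[prof$all_gap] <- 0
  del_ext[prof$all_gap] <- 0
  res <- profile_align_cpp(sc, del_open, del_ext, gap_open, gap_extend)
  residues <- rep(NA_integer_, ncol(prof$freq))
  placed <- res$col > 0
  residues[res$col[placed]] <- states[placed]
  coverage <- logical(ncol(prof$freq))
  coverage[res$col[placed]] <- TRUE
  structure(list(
    query_id = sub("/[12]$", "", read$read_id),
    mates = as.character(read$mate),
    residues = residues,
    coverage = coverage,
    info_cols = sum(!is.na(residues)),
    score = res$score
  ), class = "aligned_query")
}

# Per-column residue frequencies of the reference alignment and the
# corresponding BLOSUM62 column scores; cached on the refpkg.
refpkg_profile <- function(refpkg) {
  if (!is.null(refpkg$cache$profile)) return(refpkg$cache$profile)
  rows <- lapply(refpkg$ref_alignment$seq, encode_aa)
  C <- length(rows[[1L]])
  counts <- matrix(0, 20L, C)
  for (r in rows) {
    ok <- !is.na(r)
    idx <- cbind(r[ok], which(ok))
    for (i in seq_len(nrow(idx))) {
      counts[idx[i, 1L], idx[i, 2L]] <- counts[idx[i, 1L], idx[i, 2L]] + 1
    }
  }
  tot <- colSums(counts)
  all_gap <- tot == 0
  freq <- counts
  freq[, !all_gap] <- freq[, !all_gap] / rep(tot[!all_gap], each = 20L)
  bl <- scoring_scheme("BLOSUM62")$matrix[AA_ALPHABET, AA_ALPHABET]
  colscore <- t(freq) %*% bl      # C x 20: score of residue a in column c
  prof <- list(freq = freq, colscore = colscore, all_gap = all_gap)
  refpkg$cache$profile <- prof
  prof
}

#' Combine two aligned mates into a single query
#'
#' Union of the two coverage masks; where both mates cover a column they must
#' agree, otherwise the column is masked to unknown (`NA`/`X`).
#'
#' @param q1,q2 `aligned_query` objects over the same reference columns.
#' @return combined `aligned_query`.
#' @export
combine_pair_in_alignment <- function(q1, q2) {
  if (length(q1$residues) != length(q2$residues)) {
    stop("queries are aligned to different column spaces")
  }
  res <- q1$residues
  both <- q1$coverage & q2$coverage
  only2 <- q2$coverage & !q1$coverage
  res[only2] <- q2$residues[only2]
  disagree <- both & !is.na(q1$residues) & !is.na(q2$residues) &
    q1$residues != q2$residues
  res[disagree] <- NA_integer_
  # columns covered by both where either is unknown stay unknown-covered
  unk <- both & (is.na(q1$residues) | is.na(q2$residues))
  res[unk & !disagree] <- ifelse(is.na(q1$residues[unk & !disagree]),
                                 q2$residues[unk & !disagree],
                                 q1$residues[unk & !disagree])
  structure(list(
    query_id = q1$query_id,
    mates = "1+2",
    residues = res,
    coverage = q1$coverage | q2$coverage,
    info_cols = sum(!is.na(res)),
    score = q1$score + q2$score
  ), class = "aligned_query")
}

#' Place a query on the reference tree by per-edge maximum likelihood
#'
#' Evolutionary-placement search: in phase 1 every edge is scored with the
#' query attached at the edge midpoint via a pendant branch of fixed length
#' 0.1; in phase 2 the pendant length is optimized (one-dimensional search on
#' `[1e-8, 2]`, tolerance 1e-4) for the best `max(5, ceil(breadth * E))`
#' edges. Likelihood weight ratios are computed over all evaluated edges;
#' the best edge is the argmax of the log-likelihood, ties broken by the
#' smaller edge id. Reference partial likelihoods are computed once per
#' reference package and model and reused across queries.
#'
#' @param query an `aligned_query`.
#' @param refpkg the gene's `refpkg`.
#' @param model an `aa_model`; defaults to the package's `model_spec`.
#' @param breadth fraction of edges refined in phase 2 (default 0.1).
#' @param min_aa minimum number of covered columns required (default 33).
#' @return a `placement`: list with `query_id`, `p` (data.frame `edge_id`,
#'   `logL`, `lwr`, `pendant`, sorted by descending `lwr`) and `best_edge`.
#' @export
epa_place <- function(query, refpkg, model = NULL, breadth = 0.1,
                      min_aa = 33L) {
  if (is.null(model)) model <- refpkg_model(refpkg)
  cov <- query$info_cols
  if (cov < min_aa) {
    stop("query ", query$query_id, " has only ", cov,
         " informative columns (< ", min_aa, ")")
  }
  eng <- refpkg_engine(refpkg, model)
  cols <- which(!is.na(query$residues))
  states <- query$residues[cols]
  if (!length(cols)) stop("query ", query$query_id, " has no informative columns")
  const <- sum(eng$site_logL[-cols])
  nodes <- eng$nodes_with_edge
  eids <- eng$eid_of[nodes]
  p0 <- 0.1
  logL1 <- vapply(nodes, function(v) edge_query_logL(eng, v, p0, cols, states),
                  0)
  E <- length(nodes)
  ntop <- min(E, max(5L, as.integer(ceiling(breadth * E))))
  ord <- order(-logL1, eids)
  top <- ord[seq_len(ntop)]
  logL <- logL1
  pend <- rep(p0, E)
  for (i in top) {
    v <- nodes[[i]]
    opt <- stats::optimize(function(p) edge_query_logL(eng, v, p, cols, states),
                           interval = c(1e-8, 2), maximum = TRUE, tol = 1e-4)
    if (opt$objective >= logL[[i]]) {
      logL[[i]] <- opt$objective
      pend[[i]] <- min(max(opt$maximum, 1e-8), 2)
    }
  }
  lse <- logsumexp(logL)
  lwr <- exp(logL - lse)
  df <- data.frame(edge_id = eids, logL = logL + const, lwr = lwr,
                   pendant = pend)
  df <- df[order(-df$lwr, df$edge_id), , drop = FALSE]
  rownames(df) <- NULL
  best <- df$edge_id[which(df$logL == max(df$logL))]
  structure(list(query_id = query$query_id, p = df,
                 best_edge = min(best)),
            class = "placement")
}

# Build (and cache) the model declared in the package's model_spec.
refpkg_model <- function(refpkg) {
  key <- "model"
  if (!is.null(refpkg$cache[[key]])) return(refpkg$cache[[key]])
  ms <- refpkg$model_spec
  m <- build_model(matrix = ms$matrix %||% "LG", shape = ms$shape %||% 1,
                   k = ms$k %||% 4)
  refpkg$cache[[key]] <- m
  m
}

refpkg_engine <- function(refpkg, model) {
  key <- paste0("engine_", model$name, "_", model$shape, "_", model$k)
  if (!is.null(refpkg$cache[[key]])) return(refpkg$cache[[key]])
  eng <- placement_engine(refpkg, model)
  refpkg$cache[[key]] <- eng
  eng
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recruit, align, pair and place all reads for one gene
#'
#' Convenience wrapper running the per-gene pipeline stage: recruited mates
#' are profile-aligned, mates of the same fragment are combined into one
#' query, and each query is placed on the reference tree.
#'
#' @param recruited output of [recruit_and_trim()].
#' @param refpkg the gene's `refpkg`.
#' @param model optional `aa_model` override.
#' @param breadth,min_aa passed to [epa_place()].
#' @return list of `placement` objects (queries failing the coverage
#'   threshold are skipped).
#' @export
place_recruited <- function(recruited, refpkg, model = NULL, breadth = 0.1,
                            min_aa = 33L) {
  if (!nrow(recruited)) return(list())
  aligned <- lapply(seq_len(nrow(recruited)), function(i) {
    align_read_to_profile(recruited[i, ], refpkg)
  })
  stems <- vapply(aligned, function(q) q$query_id, "")
  placements <- list()
  for (stem in unique(stems)) {
    idx <- which(stems == stem)
    q <- aligned[[idx[[1L]]]]
    if (length(idx) > 1L) {
      for (j in idx[-1L]) q <- combine_pair_in_alignment(q, aligned[[j]])
    }
    pl <- tryCatch(
      epa_place(q, refpkg, model, breadth = breadth, min_aa = min_aa),
      error = function(e) NULL)
    if (!is.null(pl)) placements[[stem]] <- pl
  }
  unname(placements)
}
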