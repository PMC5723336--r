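# Synthetic communities with known ground truth: reference packages whose
# sequences are simulated under the same substitution model the placement
# engine assumes, genomes carrying rpoB (single copy) plus configurable
# marker genes, and paired-end reads with substitution errors.

#' Simulate an aligned set of leaf sequences on a tree
#'
#' The root sequence is drawn from the model's stationary frequencies; each
#' site is assigned one discrete-gamma category, and residues evolve
#' site-independently along each branch via `P(t * r)`. With all branch
#' lengths zero every leaf equals the root; identical seeds give identical
#' output.
#'
#' @param ntree `numbered_tree` with branch lengths.
#' @param model an `aa_model`.
#' @param length_aa number of sites.
#' @param seed integer RNG seed.
#' @return named character vector of aligned (ungapped) leaf sequences.
#' @export
simulate_alignment_on_tree <- function(ntree, model, length_aa, seed) {
  set.seed(seed)
  td <- tree_data(ntree)
  cats <- sample.int(model$k, length_aa, replace = TRUE)
  states <- vector("list", td$nnode)
  states[[td$root]] <- sample.int(20L, length_aa, replace = TRUE,
                                  prob = model$freqs)
  for (nd in td$preorder) {
    if (nd == td$root) next
    par_states <- states[[td$parent[nd]]]
    child <- integer(length_aa)
    for (cat in seq_len(model$k)) {
      idx <- which(cats == cat)
      if (!length(idx)) next
      P <- substitution_probability(model, td$len_of[nd], cat)
      # sample each site's child state from its parent's row of P
      u <- stats::runif(length(idx))
      cp <- apply(P, 1L, cumsum)       # 20 x 20: cumsum within row, by column
      child[idx] <- vapply(seq_along(idx), function(i) {
        findInterval(u[i], cp[, par_states[idx[i]]]) + 1L
      }, 0L)
    }
    states[[nd]] <- child
  }
  leaves <- seq_len(td$ntip)
  stats::setNames(
    vapply(leaves, function(v) paste(AA_ALPHABET[states[[v]]], collapse = ""), ""),
    td$phy$tip.label)
}

# inverted genetic code: residue -> codons (standard code, stops excluded)
.codon_cache <- new.env(parent = emptyenv())
codon_table <- function() {
  if (is.null(.codon_cache$tab)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_cache$tab <- split(names(gc), gc)
  }
  .codon_cache$tab
}

#' Reverse-translate an amino-acid sequence
#'
#' Each residue is mapped to a codon sampled from the usage table (uniform
#' over synonymous codons by default), so that translating the result in
#' frame +1 recovers the input exactly.
#'
#' @param aa_seq amino-acid string without `*`.
#' @param codon_usage optional named list residue -> codon probability vector.
#' @param seed integer RNG seed.
#' @return DNA string of length `3 * nchar(aa_seq)`.
#' @export
reverse_translate <- function(aa_seq, codon_usage = NULL, seed = 1L) {
  set.seed(seed)
  res <- strsplit(toupper(aa_seq), "")[[1]]
  if (any(res == "*")) stop("stop codon in amino-acid input")
  tab <- codon_table()
  codons <- vapply(res, function(a) {
    cods <- tab[[a]]
    if (is.null(cods)) stop("residue with no codon: ", a)
    if (!is.null(codon_usage) && !is.null(codon_usage[[a]])) {
      sample(names(codon_usage[[a]]), 1L, prob = codon_usage[[a]])
    } else if (length(cods) == 1L) cods else sample(cods, 1L)
  }, "")
  paste(codons, collapse = "")
}

#' Describe a synthetic community
#'
#' @param genomes `data.frame` with `genome_id`, `abundance` (sums to 1).
#' @param gene_content `data.frame` with `genome_id`, `gene`, `source_leaf`,
#'   `copies` (integer >= 1). Every genome must carry `rpoB` at exactly one
#'   copy — the single-copy assumption the normalization relies on.
#' @param outgroup_frac optional named numeric: per-gene fraction of that
#'   gene's fragments re-sourced from outgroup leaves (contaminant model).
#' @return object of class `community_spec`.
#' @export
community_spec <- function(genomes, gene_content, outgroup_frac = NULL) {
  stopifnot(abs(sum(genomes$abundance) - 1) < 1e-9)
  stopifnot(all(gene_content$copies >= 1),
            all(gene_content$copies == round(gene_content$copies)))
  rp <- gene_content[gene_content$gene == "rpoB", , drop = FALSE]
  if (!setequal(rp$genome_id, genomes$genome_id) || any(rp$copies != 1L)) {
    stop("every genome must carry rpoB at exactly 1 copy")
  }
  structure(list(genomes = genomes, gene_content = gene_content,
                 outgroup_frac = outgroup_frac), class = "community_spec")
}

#' Read-simulation parameters
#'
#' @param read_length read length in bp (>= 36; default 125).
#' @param insert_mean,insert_sd fragment-length distribution (bp).
#' @param error_rate per-base substitution error rate in `[0, 0.05]`.
#' @param n_pairs total read pairs.
#' @param background_frac fraction of pairs drawn from uniform-random
#'   non-target DNA (default 0.1).
#' @param seed integer RNG seed (recorded in output).
#' @return object of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 125L, insert_mean = 220,
                            insert_sd = 30, error_rate = 0.005,
                            n_pairs = 2000L, background_frac = 0.1,
                            seed = 1L) {
  stopifnot(read_length >= 36L, error_rate >= 0, error_rate <= 0.05,
            background_frac >= 0, background_frac < 1)
  structure(list(read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, n_pairs = as.integer(n_pairs),
                 background_frac = background_frac, seed = as.integer(seed)),
            class = "read_sim_params")
}

add_substitution_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    for (i in hit) {
      v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
    }
  }
  paste(v, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Clade label of a reference leaf
#'
#' `"outgroup"` for outgroup leaves, the clade label for labeled leaves,
#' `"unassigned_ingroup"` otherwise.
#'
#' @param refpkg a `refpkg`.
#' @param leaf leaf name.
#' @return character scalar.
#' @export
leaf_clade <- function(refpkg, leaf) {
  if (leaf %in% refpkg$outgroup) return("outgroup")
  for (lbl in names(refpkg$clade_map)) {
    if (leaf %in% refpkg$clade_map[[lbl]]) return(lbl)
  }
  "unassigned_ingroup"
}

#' Simulate a paired-end metagenome from a community specification
#'
#' Gene copies are turned into DNA by reverse-translating the (ungapped)
#' reference leaf sequence of each gene instance. Fragments are drawn from
#' gene instances with probability proportional to
#' `abundance x copies x gene length (bp)`, fragment lengths from a clipped
#' normal insert-size distribution, and both ends are read with independent
#' per-base substitution errors. A configurable fraction of pairs is
#' uniform-random background DNA. The truth table records the origin of
#' every pair exactly once.
#'
#' @param spec a `community_spec`.
#' @param refpkgs named list of `refpkg`s covering every gene in the spec.
#' @param params a `read_sim_params`.
#' @return list with `r1`, `r2` (`data.frame`s `id`, `seq`, `qual`) and
#'   `truth` (`data.frame` `read_id`, `genome`, `gene`, `source_leaf`,
#'   `clade`).
#' @export
generate_metagenome_reads <- function(spec, refpkgs, params) {
  set.seed(params$seed)
  gc_tab <- spec$gene_content
  # resolve the DNA of every gene instance
  inst <- merge(gc_tab, spec$genomes, by = "genome_id")
  inst$dna <- vapply(seq_len(nrow(inst)), function(i) {
    rp <- refpkgs[[inst$gene[i]]]
    if (is.null(rp)) stop("no reference package for gene ", inst$gene[i])
    refs <- refpkg_ungapped(rp)
    j <- match(inst$source_leaf[i], refs$id)
    if (is.na(j)) stop("source leaf ", inst$source_leaf[i],
                       " absent from ", inst$gene[i], " references")
    reverse_translate(refs$seq[j], seed = params$seed + i)
  }, "")
  inst$len_bp <- nchar(inst$dna)
  w <- inst$abundance * inst$copies * inst$len_bp
  n_bg <- round(params$n_pairs * params$background_frac)
  n_target <- params$n_pairs - n_bg
  pick <- sample.int(nrow(inst), n_target, replace = TRUE, prob = w)
  # outgroup contaminants: re-source a fraction of each gene's fragments
  og_of <- rep(NA_character_, n_target)
  if (!is.null(spec$outgroup_frac)) {
    for (g in names(spec$outgroup_frac)) {
      rows <- which(inst$gene[pick] == g)
      n_og <- round(length(rows) * spec$outgroup_frac[[g]])
      if (n_og > 0) {
        sel <- rows[seq_len(n_og)]
        og_leaves <- refpkgs[[g]]$outgroup
        og_of[sel] <- og_leaves[1L + (seq_len(n_og) - 1L) %% length(og_leaves)]
      }
    }
  }
  og_dna <- new.env(parent = emptyenv())
  rl <- params$read_length
  qual <- strrep("I", rl)
  ids <- character(params$n_pairs)
  r1 <- character(params$n_pairs); r2 <- character(params$n_pairs)
  truth <- vector("list", params$n_pairs)
  for (i in seq_len(params$n_pairs)) {
    id <- sprintf("frag%06d", i)
    if (i <= n_target) {
      k <- pick[i]
      if (!is.na(og_of[i])) {
        g <- inst$gene[k]
        key <- paste0(g, "::", og_of[i])
        if (is.null(og_dna[[key]])) {
          refs <- refpkg_ungapped(refpkgs[[g]])
          j <- match(og_of[i], refs$id)
          og_dna[[key]] <- reverse_translate(refs$seq[j],
                                             seed = params$seed + 10000L + i)
        }
        dna <- og_dna[[key]]
        src <- og_of[i]; clade <- "outgroup"
      } else {
        dna <- inst$dna[k]
        src <- inst$source_leaf[k]
        clade <- leaf_clade(refpkgs[[inst$gene[k]]], src)
      }
      glen <- nchar(dna)
      flen <- round(stats::rnorm(1, params$insert_mean, params$insert_sd))
      flen <- min(max(flen, rl), glen)
      start <- sample.int(glen - flen + 1L, 1L)
      frag <- substr(dna, start, start + flen - 1L)
      truth[[i]] <- data.frame(read_id = id, genome = inst$genome_id[k],
                               gene = inst$gene[k], source_leaf = src,
                               clade = clade, stringsAsFactors = FALSE)
    } else {
      frag <- random_dna(max(rl, round(params$insert_mean)))
      truth[[i]] <- data.frame(read_id = id, genome = "background",
                               gene = "background", source_leaf = NA_character_,
                               clade = "background", stringsAsFactors = FALSE)
    }
    flen <- nchar(frag)
    ids[i] <- id
    r1[i] <- add_substitution_errors(substr(frag, 1L, min(rl, flen)),
                                     params$error_rate)
    r2[i] <- add_substitution_errors(
      revcomp(substr(frag, max(1L, flen - rl + 1L), flen)),
      params$error_rate)
  }
  list(
    r1 = data.frame(id = paste0(ids, "/1"), seq = r1,
                    qual = substr(qual, 1, nchar(r1)), stringsAsFactors = FALSE),
    r2 = data.frame(id = paste0(ids, "/2"), seq = r2,
                    qual = substr(qual, 1, nchar(r2)), stringsAsFactors = FALSE),
    truth = do.call(rbind, truth),
    seed = params$seed
  )
}
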