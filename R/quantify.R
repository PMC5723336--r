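#' Exclude outgroup placements and attach clade labels
#'
#' A placement is discarded iff its best edge falls in the outgroup edge set
#' of the reference tree. Kept placements carry the clade label of their best
#' edge (`"unassigned_ingroup"` for ingroup edges outside any labeled clade).
#' Excluding outgroup placements is what keeps closely related non-target
#' genes (e.g. nxrA reads recruited by a narG search) out of a gene's total.
#'
#' @param placements list of `placement` objects.
#' @param index a `clade_edge_index` from [clade_edges()].
#' @return list with `kept` and `discarded`, each a `data.frame` with
#'   `query_id`, `best_edge`, `clade`.
#' @export
filter_outgroup_placements <- function(placements, index) {
  if (!length(placements)) {
    empty <- data.frame(query_id = character(), best_edge = integer(),
                        clade = character(), stringsAsFactors = FALSE)
    return(list(kept = empty, discarded = empty))
  }
  best <- vapply(placements, function(p) p$best_edge, 0L)
  if (any(best + 1L > length(index$label_of)) || any(best < 0L)) {
    stop("placement references an edge absent from the clade index")
  }
  lab <- index$label_of[best + 1L]
  df <- data.frame(query_id = vapply(placements, function(p) p$query_id, ""),
                   best_edge = best, clade = lab, stringsAsFactors = FALSE)
  list(kept = df[df$clade != "outgroup", , drop = FALSE],
       discarded = df[df$clade == "outgroup", , drop = FALSE])
}

#' Percent of the prokaryotic community carrying a gene
#'
#' Length-normalized placed-read count of the gene divided by the
#' length-normalized placed-read count of the single-copy core gene rpoB:
#' `100 * (gene_count / gene_len) / (rpob_count / rpob_len)`. Because rpoB is
#' present exactly once in every bacterial and archaeal genome, the ratio
#' estimates the fraction of the community carrying the gene.
#'
#' @param gene_count placed reads for the gene (>= 0).
#' @param gene_len reference length of the gene (amino acids, > 0).
#' @param rpob_count placed rpoB reads (>= 0).
#' @param rpob_len rpoB reference length (amino acids, > 0).
#' @return percent (0 when `gene_count` is 0; `NA` when `rpob_count` is 0,
#'   the undefined marker used in batch output).
#' @export
percent_community <- function(gene_count, gene_len, rpob_count, rpob_len) {
  if (any(c(gene_len, rpob_len) <= 0)) stop("nonpositive reference length")
  stopifnot(gene_count >= 0, rpob_count >= 0)
  if (rpob_count == 0) return(NA_real_)
  100 * (gene_count / gene_len) / (rpob_count / rpob_len)
}

#' Correct a percent-community estimate for gene copy number
#'
#' Genes carried in multiple copies per genome (e.g. the two SAR11 nitrate
#' reductases) inflate the read-based estimate by the copy number; dividing
#' by copies-per-genome recovers the fraction of genomes carrying the gene.
#'
#' @param percent uncorrected percent.
#' @param copies_per_genome copies per genome (>= 1).
#' @return corrected percent.
#' @export
copy_number_correct <- function(percent, copies_per_genome) {
  if (any(copies_per_genome < 1)) stop("copies_per_genome must be >= 1")
  percent / copies_per_genome
}

#' Tabulate per-gene, per-clade abundances for a sample
#'
#' @param kept `kept` table from [filter_outgroup_placements()].
#' @param refpkg the gene's `refpkg`.
#' @param rpob_count,rpob_len placed rpoB reads and rpoB reference length for
#'   the same sample.
#' @param sample_id sample identifier.
#' @param copy_table optional `data.frame` with `gene`, `clade`,
#'   `copies_per_genome`; matching rows are applied per clade before totals
#'   are re-summed.
#' @return `data.frame` with one row per clade (all labeled clades, even at
#'   zero, plus `unassigned_ingroup`) and a `total` row; columns `sample_id`,
#'   `gene`, `clade`, `placed_reads`, `ref_length_aa`, `rpob_reads`,
#'   `rpob_length_aa`, `copies_per_genome`, `percent`, `percent_corrected`.
#' @export
gene_abundance <- function(kept, refpkg, rpob_count, rpob_len, sample_id,
                           copy_table = NULL) {
  clades <- c(names(refpkg$clade_map), "unassigned_ingroup")
  counts <- vapply(clades, function(cl) sum(kept$clade == cl), 0L)
  copies <- rep(1, length(clades))
  if (!is.null(copy_table) && nrow(copy_table)) {
    ct <- copy_table[copy_table$gene == refpkg$gene_name, , drop = FALSE]
    m <- match(clades, ct$clade)
    copies[!is.na(m)] <- ct$copies_per_genome[m[!is.na(m)]]
  }
  pct <- vapply(counts, function(ct0)
    percent_community(ct0, refpkg$ref_length_aa, rpob_count, rpob_len), 0)
  pct_corr <- copy_number_correct(pct, copies)
  df <- data.frame(
    sample_id = sample_id, gene = refpkg$gene_name, clade = clades,
    placed_reads = as.integer(counts), ref_length_aa = refpkg$ref_length_aa,
    rpob_reads = rpob_count, rpob_length_aa = rpob_len,
    copies_per_genome = copies, percent = pct,
    percent_corrected = pct_corr, stringsAsFactors = FALSE)
  total <- data.frame(
    sample_id = sample_id, gene = refpkg$gene_name, clade = "total",
    placed_reads = sum(counts), ref_length_aa = refpkg$ref_length_aa,
    rpob_reads = rpob_count, rpob_length_aa = rpob_len,
    copies_per_genome = NA_real_,
    percent = sum(pct), percent_corrected = sum(pct_corr),
    stringsAsFactors = FALSE)
  rbind(df, total)
}

#' Long-format clade-by-depth profile table
#'
#' Joins abundance rows with sample metadata and orders them by depth, the
#' layout used for phylotype depth profiles. Every (sample, clade)
#' combination is present (explicit zero rows), and per-sample totals equal
#' the sum of clade rows plus the unassigned ingroup.
#'
#' @param abundances row-bound [gene_abundance()] tables across samples.
#' @param meta `data.frame` with `sample_id`, `depth`, `fraction` (one of
#'   `whole_water`, `particle_gt30um`, `lt30um`), optionally `station`.
#' @return `data.frame` ordered by gene, depth, clade.
#' @export
clade_depth_profile <- function(abundances, meta) {
  stopifnot(all(meta$depth > 0),
            all(meta$fraction %in% c("whole_water", "particle_gt30um", "lt30um")))
  if (anyDuplicated(abundances[, c("sample_id", "gene", "clade")])) {
    stop("duplicate (sample, gene, clade) rows")
  }
  out <- merge(abundances, meta, by = "sample_id", all.x = TRUE)
  # dense output: every sample x gene x clade combination
  full <- expand.grid(sample_id = unique(meta$sample_id),
                      gene = unique(abundances$gene),
                      clade = unique(abundances$clade),
                      stringsAsFactors = FALSE)
  out <- merge(full, out, by = c("sample_id", "gene", "clade"), all.x = TRUE)
  out$placed_reads[is.na(out$placed_reads)] <- 0L
  out$percent[is.na(out$percent) & out$placed_reads == 0 &
                !is.na(out$rpob_reads)] <- 0
  miss <- is.na(out$depth)
  if (any(miss)) {
    md <- meta[match(out$sample_id[miss], meta$sample_id), ]
    out$depth[miss] <- md$depth
    out$fraction[miss] <- md$fraction
  }
  out <- out[order(out$gene, out$depth, out$sample_id, out$clade), , drop = FALSE]
  rownames(out) <- NULL
  # additivity check: total = sum of clade rows (within numerical noise)
  for (sid in unique(out$sample_id)) {
    for (g in unique(out$gene)) {
      sub <- out[out$sample_id == sid & out$gene == g, ]
      tot <- sub$percent[sub$clade == "total"]
      parts <- sum(sub$percent[sub$clade != "total"], na.rm = TRUE)
      if (length(tot) == 1L && !is.na(tot) && abs(tot - parts) > 1e-9) {
        stop("clade rows do not sum to the total for ", sid, "/", g)
      }
    }
  }
  out
}

#' Particle vs free-living enrichment (log2 ratio)
#'
#' Convenience ratio for comparing the `>30um` particle fraction with the
#' `<30um` free-living fraction at one depth. A pseudo-count keeps
#' zero-vs-zero comparisons at 0. Positive values mean particle-enriched.
#'
#' @param percent_particle,percent_freeliving percent-community values (>= 0).
#' @param pseudo pseudo-count in percent units (default 0.1).
#' @return log2 enrichment.
#' @export
fraction_enrichment <- function(percent_particle, percent_freeliving,
                                pseudo = 0.1) {
  stopifnot(pseudo > 0, all(percent_particle >= 0),
            all(percent_freeliving >= 0))
  log2((percent_particle + pseudo) / (percent_freeliving + pseudo))
}
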