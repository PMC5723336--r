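# Ground-truth benchmark drivers over the synthetic scenarios. These are the
# package's own validation experiments: each one generates a seeded synthetic
# community, runs the relevant pipeline stages, and scores the result against
# the simulator's truth table.

#' Edges adjacent to a leaf's pendant edge
#'
#' The pendant edge itself plus every edge sharing one of its endpoints —
#' the usual tolerance when scoring placement accuracy of short reads.
#'
#' @param ntree a `numbered_tree`.
#' @param leaf leaf name.
#' @return integer vector of edge ids.
#' @export
adjacent_edges <- function(ntree, leaf) {
  td <- tree_data(ntree)
  v <- match(leaf, ntree$phylo$tip.label)
  if (is.na(v)) stop("unknown leaf ", leaf)
  u <- td$parent[v]
  ids <- td$eid_of[v]
  if (u != td$root) ids <- c(ids, td$eid_of[u])
  ids <- c(ids, td$eid_of[td$kids[[u]]])
  sort(unique(ids[!is.na(ids)]))
}

#' Placement accuracy on error-free simulated reads
#'
#' Generates the `basic` scenario with zero sequencing error, recruits and
#' places each gene's reads, and scores how often a combined query with at
#' least `min_info` informative columns lands on its source leaf's pendant
#' edge or an adjacent edge.
#'
#' @param seed integer seed.
#' @param n_pairs read pairs to simulate (default 700).
#' @param min_info minimum informative columns for a query to be scored
#'   (default 60).
#' @return list with `rate`, `n_scored`, and the per-gene breakdown.
#' @export
benchmark_placement_recovery <- function(seed = 42L, n_pairs = 700L,
                                         min_info = 60L) {
  sc <- make_benchmark_scenario("basic", seed = seed, n_pairs = n_pairs,
                                error_rate = 0)
  reads <- generate_metagenome_reads(sc$samples$s1, sc$refpkgs, sc$params)
  all_reads <- rbind(cbind(reads$r1, mate = "1"), cbind(reads$r2, mate = "2"))
  all_reads$stem <- sub("/[12]$", "", all_reads$id)
  hits <- 0L; scored <- 0L
  per_gene <- list()
  for (gene in names(sc$refpkgs)) {
    rp <- sc$refpkgs[[gene]]
    tr <- reads$truth[reads$truth$gene == gene, , drop = FALSE]
    sub_reads <- all_reads[all_reads$stem %in% tr$read_id,
                           c("id", "seq", "qual", "mate")]
    if (!nrow(sub_reads)) next
    rec <- recruit_and_trim(sub_reads, rp)
    placements <- place_recruited(rec, rp, min_aa = min_info)
    g_hits <- 0L; g_scored <- 0L
    for (pl in placements) {
      src <- tr$source_leaf[match(pl$query_id, tr$read_id)]
      if (is.na(src)) next
      ok_edges <- adjacent_edges(rp$tree, src)
      g_scored <- g_scored + 1L
      if (pl$best_edge %in% ok_edges) g_hits <- g_hits + 1L
    }
    per_gene[[gene]] <- c(hits = g_hits, scored = g_scored)
    hits <- hits + g_hits; scored <- scored + g_scored
  }
  list(rate = hits / scored, n_scored = scored, per_gene = per_gene)
}

#' Outgroup filtering efficiency under contamination
#'
#' Generates the `outgroup_stress` scenario, recruits and places the focal
#' gene's reads (including the simulated outgroup contaminants), applies the
#' outgroup filter, and reports the fraction of outgroup-origin queries that
#' were discarded.
#'
#' @param seed integer seed.
#' @param n_pairs read pairs to simulate (default 2500; about 1 in 90 pairs
#'   is an outgroup contaminant of the focal gene).
#' @return list with `discard_rate`, `n_outgroup_placed`, and the ingroup
#'   placement counts before/after filtering.
#' @export
benchmark_outgroup_filter <- function(seed = 42L, n_pairs = 2500L) {
  sc <- make_benchmark_scenario("outgroup_stress", seed = seed,
                                n_pairs = n_pairs)
  reads <- generate_metagenome_reads(sc$samples$s1, sc$refpkgs, sc$params)
  rp <- sc$refpkgs$nirK
  tr <- reads$truth[reads$truth$gene == "nirK", , drop = FALSE]
  all_reads <- rbind(cbind(reads$r1, mate = "1"), cbind(reads$r2, mate = "2"))
  all_reads$stem <- sub("/[12]$", "", all_reads$id)
  sub_reads <- all_reads[all_reads$stem %in% tr$read_id,
                         c("id", "seq", "qual", "mate")]
  rec <- recruit_and_trim(sub_reads, rp)
  placements <- place_recruited(rec, rp)
  flt <- filter_outgroup_placements(placements, clade_edges(rp))
  og_ids <- tr$read_id[tr$clade == "outgroup"]
  placed_ids <- vapply(placements, function(p) p$query_id, "")
  og_placed <- intersect(placed_ids, og_ids)
  og_discarded <- intersect(flt$discarded$query_id, og_ids)
  list(discard_rate = length(og_discarded) / max(length(og_placed), 1L),
       n_outgroup_placed = length(og_placed),
       kept_ingroup = sum(!flt$kept$query_id %in% og_ids),
       kept_outgroup_leak = sum(flt$kept$query_id %in% og_ids))
}

#' End-to-end percent-community recovery for a carrier fraction
#'
#' Builds a 20-genome community in which `round(20 * f)` genomes carry nirK
#' at one copy (every genome carries rpoB once), simulates reads, runs the
#' full pipeline, and returns the estimated percent of the community
#' carrying nirK together with the realized placed-read counts. The ground
#' truth is `100 * f`.
#'
#' @param f carrier fraction (e.g. 0.05, 0.2, 0.5).
#' @param seed integer seed.
#' @param n_pairs read pairs (default 900; yields well over 500 placed rpoB
#'   pairs).
#' @param out_dir output directory (default a temporary one).
#' @return list with `percent`, `gene_placed`, `rpob_placed`, `gene_len`,
#'   `rpob_len`, `f`.
#' @export
benchmark_abundance_recovery <- function(f, seed = 42L, n_pairs = 900L,
                                         out_dir = tempfile("abrec")) {
  sc <- make_benchmark_scenario("basic", seed = seed, n_pairs = n_pairs)
  n_genomes <- 20L
  n_carriers <- round(n_genomes * f)
  stopifnot(n_carriers >= 1L)
  genomes <- data.frame(genome_id = sprintf("g%02d", seq_len(n_genomes)),
                        abundance = rep(1 / n_genomes, n_genomes),
                        stringsAsFactors = FALSE)
  rpob_leaves <- setdiff(sc$refpkgs$rpoB$tree$phylo$tip.label,
                         sc$refpkgs$rpoB$outgroup)
  ing_leaves <- unlist(sc$refpkgs$nirK$clade_map, use.names = FALSE)
  gc_tab <- rbind(
    data.frame(genome_id = genomes$genome_id, gene = "rpoB",
               source_leaf = rpob_leaves[1L + (seq_len(n_genomes) - 1L) %%
                                           length(rpob_leaves)],
               copies = 1L, stringsAsFactors = FALSE),
    data.frame(genome_id = genomes$genome_id[seq_len(n_carriers)],
               gene = "nirK",
               source_leaf = ing_leaves[1L + (seq_len(n_carriers) - 1L) %%
                                          length(ing_leaves)],
               copies = 1L, stringsAsFactors = FALSE))
  spec <- community_spec(genomes, gc_tab)
  reads <- generate_metagenome_reads(spec, sc$refpkgs, sc$params)
  cfg <- run_config(sc$refpkgs,
                    samples = list(s1 = list(r1 = reads$r1, r2 = reads$r2)),
                    meta = sc$meta, out_dir = out_dir, seed = seed)
  out <- run_pipeline(cfg)
  ab <- attr(out, "abundance")
  tot <- ab[ab$gene == "nirK" & ab$clade == "total", ]
  rpob <- ab[ab$gene == "rpoB" & ab$clade == "total", ]
  list(percent = tot$percent, gene_placed = tot$placed_reads,
       rpob_placed = rpob$placed_reads,
       gene_len = tot$ref_length_aa, rpob_len = tot$rpob_length_aa, f = f)
}

#' Copy-number correction benchmark
#'
#' Runs the `multicopy` scenario (narG at two copies per genome in half the
#' genomes) through the pipeline with a copy-number table, returning the
#' uncorrected and corrected totals; the truth is 100% uncorrected, 50%
#' corrected.
#'
#' @param seed integer seed.
#' @param n_pairs read pairs (default 1100).
#' @param out_dir output directory (default temporary).
#' @return list with `uncorrected`, `corrected`, `rpob_placed`,
#'   `gene_placed`.
#' @export
benchmark_copy_number <- function(seed = 42L, n_pairs = 1100L,
                                  out_dir = tempfile("copy")) {
  sc <- make_benchmark_scenario("multicopy", seed = seed, n_pairs = n_pairs)
  reads <- generate_metagenome_reads(sc$samples$s1, sc$refpkgs, sc$params)
  carrier_leaves <- unique(
    sc$samples$s1$gene_content$source_leaf[
      sc$samples$s1$gene_content$gene == "narG"])
  carrier_clade <- unique(vapply(carrier_leaves, function(l)
    leaf_clade(sc$refpkgs$narG, l), ""))
  ct <- data.frame(gene = "narG", clade = carrier_clade,
                   copies_per_genome = 2, stringsAsFactors = FALSE)
  cfg <- run_config(sc$refpkgs,
                    samples = list(s1 = list(r1 = reads$r1, r2 = reads$r2)),
                    meta = sc$meta, out_dir = out_dir, copy_table = ct,
                    seed = seed)
  out <- run_pipeline(cfg)
  ab <- attr(out, "abundance")
  tot <- ab[ab$gene == "narG" & ab$clade == "total", ]
  rpob <- ab[ab$gene == "rpoB" & ab$clade == "total", ]
  list(uncorrected = tot$percent, corrected = tot$percent_corrected,
       gene_placed = tot$placed_reads, rpob_placed = rpob$placed_reads)
}

#' Poisson acceptance envelope for a placed-count recovery experiment
#'
#' Given the realized number of placed rpoB reads, the expected number of
#' placed gene reads under carrier fraction `f` is
#' `f * rpob_placed * gene_len / rpob_len`; the 95% envelope on the percent
#' estimate is the Poisson 2.5/97.5% quantile interval of that count pushed
#' through the normalization equation.
#'
#' @param f true carrier fraction.
#' @param rpob_placed realized placed rpoB reads.
#' @param gene_len,rpob_len reference lengths (aa).
#' @param level envelope coverage (default 0.95).
#' @return numeric `c(lower, upper)` in percent units.
#' @export
recovery_envelope <- function(f, rpob_placed, gene_len, rpob_len,
                              level = 0.95) {
  mu <- f * rpob_placed * gene_len / rpob_len
  a <- (1 - level) / 2
  cnt <- stats::qpois(c(a, 1 - a), mu)
  100 * (cnt / gene_len) / (rpob_placed / rpob_len)
}
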