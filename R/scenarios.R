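# Seeded benchmark scenarios: synthetic reference packages and communities
# whose ground truth exercises each stage of the pipeline. Sizes default to
# a few thousand read pairs so the whole benchmark suite runs in minutes.

# random binary subtree in Newick, leaves labeled prefix1..prefixN,
# branch lengths uniform on [0.05, 0.25]
random_clade_newick <- function(labels) {
  build <- function(lab) {
    if (length(lab) == 1L) {
      return(sprintf("%s:%.4f", lab, stats::runif(1, 0.05, 0.25)))
    }
    split_at <- sample(seq_len(length(lab) - 1L), 1L)
    l <- build(lab[seq_len(split_at)])
    r <- build(lab[-seq_len(split_at)])
    sprintf("(%s,%s):%.4f", l, r, stats::runif(1, 0.05, 0.25))
  }
  build(labels)
}

#' Build a synthetic reference package
#'
#' Constructs a reference tree of `n_clades` ingroup clades (each
#' `leaves_per_clade` leaves) plus an optional monophyletic outgroup on a
#' long stem, simulates full-length amino-acid references on that tree under
#' the declared model, and bundles everything into a `refpkg`. Clade labels
#' are `cladeI`, `cladeII`, ...
#'
#' @param gene_name gene label.
#' @param n_clades number of labeled ingroup clades (default 3).
#' @param leaves_per_clade leaves per clade (default 4).
#' @param n_outgroup outgroup leaves (default 4; 0 for none).
#' @param length_aa reference length in amino acids (default 250).
#' @param model_spec substitution model settings.
#' @param seed integer RNG seed.
#' @return a `refpkg`.
#' @export
make_synthetic_refpkg <- function(gene_name, n_clades = 3L,
                                  leaves_per_clade = 4L, n_outgroup = 4L,
                                  length_aa = 250L,
                                  model_spec = list(matrix = "LG", shape = 1, k = 4),
                                  seed = 1L) {
  set.seed(seed)
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")
  clade_map <- list()
  parts <- character(0)
  for (ci in seq_len(n_clades)) {
    labels <- sprintf("%s_c%d_%02d", gene_name, ci, seq_len(leaves_per_clade))
    clade_map[[paste0("clade", roman[ci])]] <- labels
    parts <- c(parts, sprintf("(%s):%.4f", random_clade_newick(labels),
                              stats::runif(1, 0.15, 0.3)))
  }
  outgroup <- character(0)
  if (n_outgroup > 0) {
    outgroup <- sprintf("%s_og_%02d", gene_name, seq_len(n_outgroup))
    og <- if (n_outgroup == 1L) sprintf("%s:0.10", outgroup) else
      random_clade_newick(outgroup)
    parts <- c(parts, sprintf("(%s):0.6", og))
  }
  nwk <- paste0("(", paste(parts, collapse = ","), ");")
  tree <- read_newick_numbered(text = nwk)
  model <- build_model(model_spec$matrix, model_spec$shape, model_spec$k)
  aln <- simulate_alignment_on_tree(tree, model, length_aa, seed = seed + 17L)
  alignment <- data.frame(id = names(aln), seq = unname(aln),
                          stringsAsFactors = FALSE)
  build_refpkg(gene_name, alignment, tree, clade_map, outgroup, model_spec)
}

scenario_names <- c("basic", "multicopy", "outgroup_stress",
                    "particle_vs_free", "depth_profile")

#' Construct a named benchmark scenario
#'
#' Returns fully seeded fixtures: reference packages (always including
#' rpoB), one community specification per sample, read-simulation
#' parameters, and sample metadata.
#'
#' * `basic` — 10 equal-abundance genomes, nirK in 2 of 10 (truth: 20% of
#'   the community), single copy.
#' * `multicopy` — narG at 2 copies per genome in half the genomes
#'   (uncorrected truth 100%, corrected 50%).
#' * `outgroup_stress` — as basic, but 10% of nirK-targeted fragments are
#'   drawn from outgroup leaves; the truth table marks them discardable.
#' * `particle_vs_free` — two samples sharing genomes; nirK cladeII genomes
#'   are 5x more abundant in the particle sample.
#' * `depth_profile` — six depths; cladeI genomes peak shallow, cladeII
#'   genomes deep.
#'
#' @param name scenario name.
#' @param seed integer RNG seed.
#' @param n_pairs read pairs per sample (default 2000).
#' @param error_rate per-base substitution error rate (default 0.005).
#' @return list with `refpkgs`, `samples` (named list of `community_spec`),
#'   `params`, `meta` (sample metadata table) and `truth_percent` (named
#'   ground-truth percent of genomes carrying the focal gene).
#' @export
make_benchmark_scenario <- function(name, seed = 42L, n_pairs = 2000L,
                                    error_rate = 0.005) {
  if (!name %in% scenario_names) {
    stop("unknown scenario: ", name, " (choose from ",
         paste(scenario_names, collapse = ", "), ")")
  }
  rpob <- make_synthetic_refpkg("rpoB", n_clades = 3L, leaves_per_clade = 4L,
                                n_outgroup = 0L, length_aa = 400L,
                                seed = seed + 1L)
  params <- read_sim_params(n_pairs = n_pairs, error_rate = error_rate,
                            seed = seed + 5L)
  ten_genomes <- function() {
    data.frame(genome_id = sprintf("g%02d", 1:10), abundance = rep(0.1, 10),
               stringsAsFactors = FALSE)
  }
  rpob_rows <- function(genomes) {
    leaves <- setdiff(rpob$tree$phylo$tip.label, rpob$outgroup)
    data.frame(genome_id = genomes$genome_id, gene = "rpoB",
               source_leaf = leaves[1L + (seq_len(nrow(genomes)) - 1L) %%
                                      length(leaves)],
               copies = 1L, stringsAsFactors = FALSE)
  }
  if (name %in% c("basic", "outgroup_stress")) {
    gene <- make_synthetic_refpkg("nirK", seed = seed + 2L)
    genomes <- ten_genomes()
    leaves <- gene$clade_map$cladeI
    gc_tab <- rbind(
      rpob_rows(genomes),
      data.frame(genome_id = c("g01", "g02"), gene = "nirK",
                 source_leaf = leaves[1:2], copies = 1L,
                 stringsAsFactors = FALSE))
    og <- if (name == "outgroup_stress") c(nirK = 0.1) else NULL
    spec <- community_spec(genomes, gc_tab, outgroup_frac = og)
    return(list(refpkgs = list(nirK = gene, rpoB = rpob),
                samples = list(s1 = spec), params = params,
                meta = data.frame(sample_id = "s1", station = "syn",
                                  depth = 100, fraction = "whole_water",
                                  stringsAsFactors = FALSE),
                truth_percent = c(nirK = 20)))
  }
  if (name == "multicopy") {
    gene <- make_synthetic_refpkg("narG", seed = seed + 3L)
    genomes <- ten_genomes()
    carriers <- sprintf("g%02d", 1:5)
    leaves <- gene$clade_map$cladeI
    gc_tab <- rbind(
      rpob_rows(genomes),
      data.frame(genome_id = carriers, gene = "narG",
                 source_leaf = leaves[1L + (seq_along(carriers) - 1L) %%
                                        length(leaves)],
                 copies = 2L, stringsAsFactors = FALSE))
    spec <- community_spec(genomes, gc_tab)
    return(list(refpkgs = list(narG = gene, rpoB = rpob),
                samples = list(s1 = spec), params = params,
                meta = data.frame(sample_id = "s1", station = "syn",
                                  depth = 160, fraction = "whole_water",
                                  stringsAsFactors = FALSE),
                truth_percent = c(narG_uncorrected = 100, narG_corrected = 50)))
  }
  if (name == "particle_vs_free") {
    gene <- make_synthetic_refpkg("qnorB", seed = seed + 4L)
    # 8 shared genomes; genomes 7-8 carry cladeII qnorB and are 5x more
    # abundant on particles
    free_ab <- c(rep(0.92 / 6, 6), 0.04, 0.04)
    part_ab <- c(rep(0.10, 6), 0.20, 0.20)
    genomes_free <- data.frame(genome_id = sprintf("g%02d", 1:8),
                               abundance = free_ab, stringsAsFactors = FALSE)
    genomes_part <- data.frame(genome_id = sprintf("g%02d", 1:8),
                               abundance = part_ab, stringsAsFactors = FALSE)
    mk <- function(genomes) {
      leaves <- gene$clade_map$cladeII
      gc_tab <- rbind(
        rpob_rows(genomes),
        data.frame(genome_id = c("g07", "g08"), gene = "qnorB",
                   source_leaf = leaves[1:2], copies = 1L,
                   stringsAsFactors = FALSE))
      community_spec(genomes, gc_tab)
    }
    return(list(refpkgs = list(qnorB = gene, rpoB = rpob),
                samples = list(lt30 = mk(genomes_free),
                               gt30 = mk(genomes_part)),
                params = params,
                meta = data.frame(sample_id = c("lt30", "gt30"),
                                  station = "syn", depth = 120,
                                  fraction = c("lt30um", "particle_gt30um"),
                                  stringsAsFactors = FALSE),
                truth_percent = c(qnorB_free = 8, qnorB_particle = 40)))
  }
  # depth_profile
  gene <- make_synthetic_refpkg("nosZ", seed = seed + 6L)
  depths <- c(60, 80, 100, 140, 200, 300)
  shallow_peak <- c(0.30, 0.25, 0.15, 0.08, 0.04, 0.02)
  deep_peak <- c(0.02, 0.04, 0.10, 0.20, 0.28, 0.30)
  samples <- list()
  for (i in seq_along(depths)) {
    ab <- c(shallow_peak[i], deep_peak[i])
    rest <- (1 - sum(ab)) / 8
    genomes <- data.frame(genome_id = sprintf("g%02d", 1:10),
                          abundance = c(ab, rep(rest, 8)),
                          stringsAsFactors = FALSE)
    gc_tab <- rbind(
      rpob_rows(genomes),
      data.frame(genome_id = c("g01", "g02"), gene = "nosZ",
                 source_leaf = c(gene$clade_map$cladeI[1],
                                 gene$clade_map$cladeII[1]),
                 copies = 1L, stringsAsFactors = FALSE))
    samples[[sprintf("d%03d", depths[i])]] <- community_spec(genomes, gc_tab)
  }
  list(refpkgs = list(nosZ = gene, rpoB = rpob), samples = samples,
       params = params,
       meta = data.frame(sample_id = sprintf("d%03d", depths),
                         station = "syn", depth = depths,
                         fraction = "whole_water", stringsAsFactors = FALSE),
       truth_percent = NULL)
}
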