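#' De-duplicate exactly identical amino-acid sequences
#'
#' The first occurrence (in input order) of each distinct sequence is kept as
#' the representative; every input id is mapped to its representative. This
#' mirrors the de-duplication applied when reference trees are built, so that
#' reference alignments and tree leaves can be cross-matched.
#'
#' @param seqs `data.frame` with columns `id`, `seq`.
#' @return list with `unique` (subset of `seqs`) and `map` (named character
#'   vector: original id -> representative id).
#' @export
dedup_identical <- function(seqs) {
  first <- !duplicated(seqs$seq)
  rep_of <- seqs$id[first][match(seqs$seq, seqs$seq[first])]
  list(unique = seqs[first, , drop = FALSE],
       map = stats::setNames(rep_of, seqs$id))
}

#' Build a per-gene reference package
#'
#' Bundles the aligned full-length references, the numbered reference tree,
#' the clade labels and the outgroup definition, and cross-validates them:
#' tree leaves must match alignment rows (after de-duplication), clades must
#' be disjoint, monophyletic, and disjoint from the outgroup.
#'
#' `ref_length_aa` — the "gene length" used for length normalization of read
#' counts — is the median ungapped amino-acid length over ingroup reference
#' rows, which is robust to fragmentary references and alignment padding.
#'
#' @param gene_name gene label (e.g. `"nirK"`, `"rpoB"`).
#' @param alignment `data.frame` with `id`, `seq`: equal-length aligned
#'   amino-acid rows (gaps `-`).
#' @param tree a `numbered_tree` whose leaves are the alignment row ids
#'   (after de-duplication).
#' @param clade_map named list: clade label -> character vector of leaf names.
#' @param outgroup character vector of outgroup leaf names (may be empty).
#' @param model_spec list with `matrix`, `shape`, `k` (see [build_model()]).
#' @return object of class `refpkg`.
#' @export
build_refpkg <- function(gene_name, alignment, tree, clade_map = list(),
                         outgroup = character(),
                         model_spec = list(matrix = "LG", shape = 1, k = 4)) {
  stopifnot(inherits(tree, "numbered_tree"))
  widths <- unique(nchar(alignment$seq))
  if (length(widths) != 1L) stop("alignment rows differ in length")
  dd <- dedup_identical(alignment)
  alignment <- dd$unique
  leaves <- tree$phylo$tip.label
  extra_rows <- setdiff(alignment$id, leaves)
  if (length(extra_rows)) stop("unmatched reference ", extra_rows[[1L]])
  extra_leaves <- setdiff(leaves, alignment$id)
  if (length(extra_leaves)) stop("leaf without alignment row: ", extra_leaves[[1L]])
  all_clade_leaves <- unlist(clade_map, use.names = FALSE)
  if (anyDuplicated(all_clade_leaves)) stop("clades must be disjoint")
  if (length(intersect(all_clade_leaves, outgroup))) {
    stop("clades must be disjoint from the outgroup")
  }
  bad <- setdiff(c(all_clade_leaves, outgroup), leaves)
  if (length(bad)) stop("unknown leaf in clade/outgroup definition: ", bad[[1L]])
  for (lbl in names(clade_map)) {
    tips <- clade_map[[lbl]]
    if (length(tips) > 1L &&
        !ape::is.monophyletic(tree$phylo, tips)) {
      mrca <- ape::getMRCA(tree$phylo, tips)
      intruders <- setdiff(ape::extract.clade(tree$phylo, mrca)$tip.label, tips)
      stop("clade not monophyletic: ", lbl,
           " (intruding leaves: ", paste(intruders, collapse = ", "), ")")
    }
  }
  if (length(outgroup) > 1L && !ape::is.monophyletic(tree$phylo, outgroup)) {
    stop("outgroup is not monophyletic")
  }
  ingroup_rows <- alignment[!(alignment$id %in% outgroup), , drop = FALSE]
  if (nrow(ingroup_rows) < 2L) stop("need at least 2 ingroup reference rows")
  ungapped <- nchar(gsub("-", "", ingroup_rows$seq, fixed = TRUE))
  ref_length_aa <- stats::median(ungapped)
  if (ref_length_aa <= 0) stop("ingroup references are empty")
  structure(list(
    gene_name = gene_name,
    ref_alignment = alignment,
    tree = tree,
    clade_map = clade_map,
    outgroup = outgroup,
    model_spec = model_spec,
    dedup_map = dd$map,
    ref_length_aa = ref_length_aa,
    cache = new.env(parent = emptyenv())
  ), class = "refpkg")
}

#' @export
print.refpkg <- function(x, ...) {
  cat("Reference package:", x$gene_name, "\n",
      " references:", nrow(x$ref_alignment),
      " columns:", nchar(x$ref_alignment$seq[[1L]]),
      " ref_length_aa:", x$ref_length_aa, "\n",
      " clades:", paste(names(x$clade_map), collapse = ", "), "\n",
      " outgroup leaves:", length(x$outgroup), "\n")
  invisible(x)
}

# all edge ids strictly inside the subtree spanned by `tips`, plus the stem
# edge of their MRCA (a query diverging just below a clade's ancestor is
# still that lineage).
subtree_edge_ids <- function(ntree, tips) {
  phy <- ntree$phylo
  td <- tree_data(ntree)
  if (length(tips) == 1L) {
    v <- match(tips, phy$tip.label)
    return(td$eid_of[v])
  }
  mrca <- ape::getMRCA(phy, tips)
  desc <- integer(0)
  stack <- mrca
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    desc <- c(desc, nd)
    stack <- c(stack, td$kids[[nd]])
  }
  inside <- setdiff(desc, mrca)
  ids <- td$eid_of[inside]
  if (mrca != td$root) ids <- c(ids, td$eid_of[mrca])
  sort(ids)
}

#' Map every tree edge to a clade label
#'
#' For each labeled clade the index contains the edges strictly inside the
#' clade's spanned subtree plus the stem edge of its MRCA; the outgroup edge
#' set is computed the same way; every remaining edge is labeled
#' `"unassigned_ingroup"`. A placement is later attributed to the label of
#' its best edge, which is how outgroup placements are recognized and
#' excluded from gene totals.
#'
#' @param refpkg a `refpkg`.
#' @return object of class `clade_edge_index`: list with `label_of` (character
#'   vector indexed by `edge_id + 1`) and `edges` (label -> integer edge ids).
#' @export
clade_edges <- function(refpkg) {
  ntree <- refpkg$tree
  ne <- length(ntree$edge_id)
  label_of <- rep("unassigned_ingroup", ne)
  assign_ids <- function(ids, lbl) {
    taken <- label_of[ids + 1L] != "unassigned_ingroup"
    if (any(taken)) {
      stop("edge ", ids[taken][1L], " claimed by both ",
           label_of[ids + 1L][taken][1L], " and ", lbl,
           "; clades must be disjoint")
    }
    label_of[ids + 1L] <<- lbl
  }
  if (length(refpkg$outgroup)) {
    assign_ids(subtree_edge_ids(ntree, refpkg$outgroup), "outgroup")
  }
  for (lbl in names(refpkg$clade_map)) {
    assign_ids(subtree_edge_ids(ntree, refpkg$clade_map[[lbl]]), lbl)
  }
  labs <- unique(label_of)
  edges <- lapply(stats::setNames(labs, labs),
                  function(l) which(label_of == l) - 1L)
  structure(list(label_of = label_of, edges = edges), class = "clade_edge_index")
}

#' Write a reference package to a directory
#'
#' Layout: `refs.fasta` (aligned), `tree.nwk`, `clades.tsv`
#' (leaf TAB label), `outgroup.txt`, `model.yaml`.
#'
#' @param refpkg a `refpkg`.
#' @param dir output directory (created if needed).
#' @export
write_refpkg <- function(refpkg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(refpkg$ref_alignment, file.path(dir, "refs.fasta"))
  write_newick_numbered(refpkg$tree, file.path(dir, "tree.nwk"))
  cl <- data.frame(
    leaf = unlist(refpkg$clade_map, use.names = FALSE),
    label = rep(names(refpkg$clade_map),
                vapply(refpkg$clade_map, length, 0L)),
    stringsAsFactors = FALSE)
  write_tsv(cl, file.path(dir, "clades.tsv"))
  writeLines(refpkg$outgroup, file.path(dir, "outgroup.txt"))
  yaml::write_yaml(c(list(gene_name = refpkg$gene_name), refpkg$model_spec),
                   file.path(dir, "model.yaml"))
  invisible(dir)
}

#' Read a reference package from a directory written by [write_refpkg()]
#' @param dir reference package directory.
#' @return a `refpkg`.
#' @export
read_refpkg <- function(dir) {
  aln <- read_fasta(file.path(dir, "refs.fasta"))
  tree <- read_newick_numbered(file.path(dir, "tree.nwk"))
  cl <- read_tsv(file.path(dir, "clades.tsv"))
  clade_map <- if (nrow(cl)) split(cl$leaf, cl$label) else list()
  og_path <- file.path(dir, "outgroup.txt")
  outgroup <- if (file.exists(og_path)) readLines(og_path) else character()
  outgroup <- outgroup[nzchar(outgroup)]
  ms <- yaml::read_yaml(file.path(dir, "model.yaml"))
  build_refpkg(ms$gene_name, aln[, c("id", "seq")], tree, clade_map, outgroup,
               model_spec = ms[setdiff(names(ms), "gene_name")])
}

#' Ungapped reference sequences of a package
#' @param refpkg a `refpkg`.
#' @return `data.frame` with `id`, `seq` (gaps removed).
#' @export
refpkg_ungapped <- function(refpkg) {
  data.frame(id = refpkg$ref_alignment$id,
             seq = gsub("-", "", refpkg$ref_alignment$seq, fixed = TRUE),
             stringsAsFactors = FALSE)
}
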