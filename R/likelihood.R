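# Felsenstein pruning with discrete-gamma rate heterogeneity, plus the
# outside (pre-order) partial likelihoods needed for per-edge placement.
# Partial likelihoods are scaled per site, with the log of the accumulated
# scale carried separately, so no site likelihood underflows to zero.

# Traversal bookkeeping for a numbered tree.
tree_data <- function(ntree) {
  phy <- ntree$phylo
  ntip <- ape::Ntip(phy)
  nnode <- max(phy$edge)
  kids <- children_list(phy)
  parent <- integer(nnode)
  len_of <- numeric(nnode)      # branch length of edge above each node
  eid_of <- rep(NA_integer_, nnode)
  row_of <- integer(nnode)
  for (i in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[i, 2L]
    parent[ch] <- phy$edge[i, 1L]
    len_of[ch] <- phy$edge.length[i]
    eid_of[ch] <- ntree$edge_id[i]
    row_of[ch] <- i
  }
  root <- ntip + 1L
  # postorder node sequence (children before parents), children in input order
  post <- integer(0)
  stack <- root
  order_rev <- integer(0)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    order_rev <- c(order_rev, nd)
    stack <- c(stack, kids[[nd]])
  }
  post <- rev(order_rev)
  list(phy = phy, ntip = ntip, nnode = nnode, root = root, kids = kids,
       parent = parent, len_of = len_of, eid_of = eid_of, post = post,
       preorder = order_rev,
       child_of_eid = order(eid_of)[seq_len(nrow(phy$edge))])
}

# Integer-encode an aligned set of sequences: named list leaf -> states.
encode_alignment <- function(seqs) {
  lapply(seqs, encode_aa)
}

tip_partial <- function(states, nsite) {
  M <- matrix(0, 20L, nsite)
  ok <- !is.na(states)
  M[cbind(states[ok], which(ok))] <- 1
  M[, !ok] <- 1   # gaps and ambiguities are missing data
  M
}

rescale_partial <- function(M, ls) {
  sc <- colSums(M)
  sc[sc <= 0] <- 1
  list(M = M / rep(sc, each = 20L), ls = ls + log(sc))
}

# Post-order (down) partials for one rate category.
down_pass <- function(td, P_of_node, tipstates, nsite) {
  down <- vector("list", td$nnode)
  lsd <- vector("list", td$nnode)
  msg <- vector("list", td$nnode)   # P(edge) %*% down, per non-root node
  lsm <- vector("list", td$nnode)
  for (nd in td$post) {
    if (nd <= td$ntip) {
      down[[nd]] <- tip_partial(tipstates[[td$phy$tip.label[nd]]], nsite)
      lsd[[nd]] <- numeric(nsite)
    } else {
      M <- NULL; ls <- numeric(nsite)
      for (ch in td$kids[[nd]]) {
        M <- if (is.null(M)) msg[[ch]] else M * msg[[ch]]
        ls <- ls + lsm[[ch]]
      }
      r <- rescale_partial(M, ls)
      down[[nd]] <- r$M; lsd[[nd]] <- r$ls
    }
    if (nd != td$root) {
      msg[[nd]] <- P_of_node[[nd]] %*% down[[nd]]
      lsm[[nd]] <- lsd[[nd]]
    }
  }
  list(down = down, lsd = lsd, msg = msg, lsm = lsm)
}

# Pre-order (outside) partials: for the edge above node v, the conditional
# likelihood of everything outside v's subtree, evaluated at v's parent.
outside_pass <- function(td, P_of_node, dp) {
  O <- vector("list", td$nnode)
  lsO <- vector("list", td$nnode)
  nsite <- ncol(dp$down[[td$root]])
  for (nd in td$preorder) {
    if (nd <= td$ntip && nd == td$root) next
    ch <- td$kids[[nd]]
    if (!length(ch)) next
    up <- if (nd == td$root) NULL else P_of_node[[nd]] %*% O[[nd]]
    lsup <- if (nd == td$root) numeric(nsite) else lsO[[nd]]
    for (v in ch) {
      M <- up; ls <- lsup
      for (c2 in ch) {
        if (c2 == v) next
        M <- if (is.null(M)) dp$msg[[c2]] else M * dp$msg[[c2]]
        ls <- ls + dp$lsm[[c2]]
      }
      if (is.null(M)) { M <- matrix(1, 20L, nsite); ls <- numeric(nsite) }
      r <- rescale_partial(M, ls)
      O[[v]] <- r$M; lsO[[v]] <- r$ls
    }
  }
  list(O = O, lsO = lsO)
}

site_log_likelihoods <- function(td, model, tipstates, nsite) {
  k <- model$k
  pf <- model$freqs
  lcat <- matrix(NA_real_, k, nsite)
  for (cat in seq_len(k)) {
    P_of_node <- vector("list", td$nnode)
    for (nd in seq_len(td$nnode)) {
      if (nd == td$root) next
      P_of_node[[nd]] <- substitution_probability(model, td$len_of[nd], cat)
    }
    dp <- down_pass(td, P_of_node, tipstates, nsite)
    lcat[cat, ] <- log(colSums(pf * dp$down[[td$root]])) + dp$lsd[[td$root]]
  }
  m <- apply(lcat, 2, max)
  m + log(colSums(exp(lcat - rep(m, each = k)))) - log(k)
}

#' Total log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under the given amino-acid model, averaging the site
#' likelihood over the discrete-gamma rate categories. Gaps and ambiguous
#' residues are treated as missing data. The tree's root placement does not
#' affect the result (the model is reversible).
#'
#' @param tree a `numbered_tree` or a `ReferencePackage`.
#' @param model an `aa_model` from [build_model()].
#' @param alignment named character vector (or `data.frame` with `id`, `seq`)
#'   of equal-length aligned amino-acid sequences covering every leaf.
#' @return total log-likelihood (numeric scalar).
#' @export
tree_log_likelihood <- function(tree, model, alignment) {
  ntree <- if (inherits(tree, "refpkg")) tree$tree else tree
  stopifnot(inherits(ntree, "numbered_tree"))
  if (is.data.frame(alignment)) {
    alignment <- stats::setNames(alignment$seq, alignment$id)
  }
  td <- tree_data(ntree)
  leaves <- ntree$phylo$tip.label
  missing <- setdiff(leaves, names(alignment))
  if (length(missing)) stop("no sequence row for leaf ", missing[[1L]])
  widths <- unique(nchar(alignment[leaves]))
  if (length(widths) != 1L) stop("alignment rows differ in length")
  tipstates <- encode_alignment(as.list(alignment[leaves]))
  sum(site_log_likelihoods(td, model, tipstates, widths))
}

# Per-edge cached quantities for placement: for each rate category and edge
# (identified by its child node v), B = pi * (P(b/2) O_e) * (P(b/2) down_v)
# on every column, plus its log-scale. Attaching a query with pendant length
# p at the edge midpoint then costs only an elementwise product per category.
placement_engine <- function(refpkg, model) {
  ntree <- refpkg$tree
  td <- tree_data(ntree)
  aln <- stats::setNames(refpkg$ref_alignment$seq, refpkg$ref_alignment$id)
  leaves <- ntree$phylo$tip.label
  nsite <- nchar(aln[[1L]])
  tipstates <- encode_alignment(as.list(aln[leaves]))
  k <- model$k
  pf <- model$freqs
  nodes_with_edge <- which(!is.na(td$eid_of))
  B <- vector("list", k)
  lsB <- vector("list", k)
  lcat <- matrix(NA_real_, k, nsite)
  for (cat in seq_len(k)) {
    P_of_node <- vector("list", td$nnode)
    Ph <- vector("list", td$nnode)
    for (nd in nodes_with_edge) {
      P_of_node[[nd]] <- substitution_probability(model, td$len_of[nd], cat)
      Ph[[nd]] <- substitution_probability(model, td$len_of[nd] / 2, cat)
    }
    dp <- down_pass(td, P_of_node, tipstates, nsite)
    op <- outside_pass(td, P_of_node, dp)
    lcat[cat, ] <- log(colSums(pf * dp$down[[td$root]])) + dp$lsd[[td$root]]
    B[[cat]] <- vector("list", td$nnode)
    lsB[[cat]] <- vector("list", td$nnode)
    for (nd in nodes_with_edge) {
      A1 <- Ph[[nd]] %*% op$O[[nd]]
      A2 <- Ph[[nd]] %*% dp$down[[nd]]
      B[[cat]][[nd]] <- pf * A1 * A2
      lsB[[cat]][[nd]] <- op$lsO[[nd]] + dp$lsd[[nd]]
    }
  }
  m <- apply(lcat, 2, max)
  site_logL <- m + log(colSums(exp(lcat - rep(m, each = k)))) - log(k)
  list(td = td, model = model, nsite = nsite, B = B, lsB = lsB,
       nodes_with_edge = nodes_with_edge, site_logL = site_logL,
       eid_of = td$eid_of)
}

# Log-likelihood of the tree with the query attached at the midpoint of the
# edge above node v, pendant length p, restricted to the covered columns.
edge_query_logL <- function(eng, v, p, cols, states) {
  model <- eng$model
  k <- model$k
  lcat <- matrix(NA_real_, k, length(cols))
  for (cat in seq_len(k)) {
    P <- substitution_probability(model, p, cat)
    v1 <- colSums(eng$B[[cat]][[v]][, cols, drop = FALSE] *
                    P[, states, drop = FALSE])
    lcat[cat, ] <- log(v1) + eng$lsB[[cat]][[v]][cols]
  }
  m <- apply(lcat, 2, max)
  site <- m + log(colSums(exp(lcat - rep(m, each = k)))) - log(k)
  sum(site)
}
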