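#' Read a FASTA file into a sequence table
#'
#' Thin validating wrapper around [Biostrings::readBStringSet()]. Whitespace
#' inside sequence lines is removed; case and record order are preserved.
#'
#' @param path path to a FASTA file.
#' @return a `data.frame` with columns `id`, `seq`, `qual` (always `NA` for
#'   FASTA), one row per record. An empty file yields zero rows.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- gsub("[[:space:]]", "", as.character(set))
  validate_seq_records(ids, seqs)
  data.frame(id = ids, seq = unname(seqs), qual = NA_character_,
             stringsAsFactors = FALSE)
}

#' Read a FASTQ file (sequence + quality only)
#'
#' @param path path to a FASTQ file.
#' @return a `data.frame` with columns `id`, `seq`, `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  quals <- as.character(S4Vectors::mcols(set)$qualities)
  validate_seq_records(ids, seqs, quals)
  data.frame(id = ids, seq = unname(seqs), qual = unname(quals),
             stringsAsFactors = FALSE)
}

validate_seq_records <- function(ids, seqs, quals = NULL) {
  if (any(!nzchar(ids))) stop("empty sequence id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[[1L]])
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id ", ids[which(!nzchar(seqs))[1L]])
  }
  if (!is.null(quals) && any(nchar(quals) != nchar(seqs))) {
    bad <- which(nchar(quals) != nchar(seqs))[1L]
    stop("quality length mismatch for id ", ids[bad])
  }
  invisible(TRUE)
}

#' Write a sequence table to FASTA
#' @param records `data.frame` with columns `id`, `seq`.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Write a sequence table to FASTQ
#' @param records `data.frame` with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @export
write_fastq <- function(records, path) {
  qual <- records$qual
  qual[is.na(qual)] <- vapply(nchar(records$seq[is.na(qual)]),
                              function(n) strrep("I", n), "")
  lines <- as.vector(rbind(paste0("@", records$id), records$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a Newick tree and assign deterministic edge numbers
#'
#' Edges are numbered `0..E-1` in postorder, visiting children in the order
#' they appear in the Newick string: within each node, each child subtree is
#' traversed fully before its stem edge receives the next id. The numbering is
#' a pure function of the Newick string, so identical input yields identical
#' edge ids.
#'
#' @param path path to a Newick file, or use `text=`.
#' @param text optional Newick string (overrides `path`).
#' @param default_length if non-`NULL`, branch lengths missing from the input
#'   are replaced by this value; otherwise missing lengths are an error.
#' @return an object of class `numbered_tree`: a list with elements `phylo`
#'   (an [ape::read.tree()] tree) and `edge_id` (integer vector aligned with
#'   the rows of `phylo$edge`).
#' @export
read_newick_numbered <- function(path = NULL, text = NULL, default_length = NULL) {
  if (is.null(text)) {
    stopifnot(file.exists(path))
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: no tree in input")
  if (is.null(phy$edge.length)) {
    if (is.null(default_length)) stop("missing branch length(s) in Newick input")
    phy$edge.length <- rep(default_length, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length)) {
    if (is.null(default_length)) stop("missing branch length(s) in Newick input")
    phy$edge.length[is.na(phy$edge.length)] <- default_length
  }
  if (any(phy$edge.length < 0)) stop("negative branch length in Newick input")
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf name ", phy$tip.label[duplicated(phy$tip.label)][1L])
  }
  numbered_tree(phy)
}

#' Construct a `numbered_tree` from an `ape` phylo object
#'
#' @param phy an `ape::phylo` tree with branch lengths, in the node order
#'   produced by [ape::read.tree()] (cladewise, children in input order).
#' @return `numbered_tree` object.
#' @export
numbered_tree <- function(phy) {
  ne <- nrow(phy$edge)
  kids <- children_list(phy)
  root <- ape::Ntip(phy) + 1L
  # row index of each edge by child node
  row_of_child <- integer(max(phy$edge))
  row_of_child[phy$edge[, 2L]] <- seq_len(ne)
  edge_id <- integer(ne)
  ctr <- 0L
  # iterative postorder: children in stored (input) order
  stack <- list(list(node = root, i = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    ch <- kids[[top$node]]
    if (top$i <= length(ch)) {
      stack[[length(stack)]]$i <- top$i + 1L
      stack[[length(stack) + 1L]] <- list(node = ch[[top$i]], i = 1L)
    } else {
      stack[[length(stack)]] <- NULL
      if (top$node != root) {
        edge_id[row_of_child[top$node]] <- ctr
        ctr <- ctr + 1L
      }
    }
  }
  structure(list(phylo = phy, edge_id = edge_id), class = "numbered_tree")
}

children_list <- function(phy) {
  n <- max(phy$edge)
  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2L])
  }
  kids
}

#' Serialize a numbered tree to Newick
#'
#' @param ntree `numbered_tree`.
#' @param path optional output path; if `NULL` the Newick string is returned.
#' @param edge_ids if `TRUE`, append `{edge_id}` after each branch length
#'   (the jplace tree dialect).
#' @return the Newick string, invisibly when written to `path`.
#' @export
write_newick_numbered <- function(ntree, path = NULL, edge_ids = FALSE) {
  phy <- ntree$phylo
  kids <- children_list(phy)
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  ne <- nrow(phy$edge)
  row_of_child <- integer(max(phy$edge))
  row_of_child[phy$edge[, 2L]] <- seq_len(ne)
  fmt <- function(x) sprintf("%.12g", x)
  build <- function(node) {
    lab <- if (node <= ntip) phy$tip.label[node] else ""
    inner <- if (node > ntip) {
      paste0("(", paste(vapply(kids[[node]], build, ""), collapse = ","), ")")
    } else ""
    if (node == root) return(paste0(inner, lab))
    r <- row_of_child[node]
    ann <- if (edge_ids) paste0("{", ntree$edge_id[r], "}") else ""
    paste0(inner, lab, ":", fmt(phy$edge.length[r]), ann)
  }
  nwk <- paste0(build(root), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Assemble a placement document
#'
#' @param ntree `numbered_tree` the placements refer to.
#' @param placements list of placements as returned by [epa_place()].
#' @return object of class `placement_document`.
#' @export
placement_document <- function(ntree, placements) {
  valid <- ntree$edge_id
  for (pl in placements) {
    if (!all(pl$p$edge_id %in% valid)) {
      stop("placement for ", pl$query_id, " references unknown edge id")
    }
    if (abs(sum(pl$p$lwr) - 1) > 1e-6) {
      stop("likelihood weight ratios for ", pl$query_id, " do not sum to 1")
    }
  }
  structure(list(tree = ntree, placements = placements, version = 3L),
            class = "placement_document")
}

#' Write placements as jplace (version 3)
#'
#' Emits the standard jplace JSON dialect: the reference tree with `{edge_id}`
#' annotations, a `placements` array with per-query rows of
#' `[edge_num, likelihood, like_weight_ratio, pendant_length]`, the `fields`
#' manifest, and a `version` tag.
#'
#' @param doc a `placement_document`.
#' @param path output path.
#' @export
write_placements <- function(doc, path) {
  stopifnot(inherits(doc, "placement_document"))
  fields <- c("edge_num", "likelihood", "like_weight_ratio", "pendant_length")
  pl <- lapply(doc$placements, function(x) {
    p <- lapply(seq_len(nrow(x$p)), function(i) {
      list(x$p$edge_id[i], x$p$logL[i], x$p$lwr[i], x$p$pendant[i])
    })
    list(p = p, n = list(x$query_id))
  })
  obj <- list(
    version = 3L,
    tree = write_newick_numbered(doc$tree, edge_ids = TRUE),
    placements = pl,
    fields = as.list(fields),
    metadata = list(software = "placeprof")
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read a jplace file back into a placement document
#' @param path jplace path.
#' @return `placement_document`.
#' @export
read_placements <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tree_str <- obj$tree
  # strip {N} annotations, remember assignment order to cross-check numbering
  plain <- gsub("\\{[0-9]+\\}", "", tree_str)
  ntree <- read_newick_numbered(text = plain)
  placements <- lapply(obj$placements, function(x) {
    rows <- do.call(rbind, lapply(x$p, function(r) {
      data.frame(edge_id = as.integer(r[[1]]), logL = as.numeric(r[[2]]),
                 lwr = as.numeric(r[[3]]), pendant = as.numeric(r[[4]]))
    }))
    if (is.null(rows)) {
      rows <- data.frame(edge_id = integer(), logL = numeric(),
                         lwr = numeric(), pendant = numeric())
    }
    best <- if (nrow(rows)) rows$edge_id[which.max(rows$logL)] else NA_integer_
    list(query_id = x$n[[1]], p = rows, best_edge = best)
  })
  placement_document(ntree, placements)
}

#' Write a tab-delimited table deterministically
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a tab-delimited table with a header row
#' @param path input path.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}
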