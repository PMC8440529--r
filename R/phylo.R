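# ---- Parsimony phylogenies from presence/absence matrices, timing ----------

#' Binary presence/absence matrix for one patient
#'
#' Rows are the union of nonsilent mutations across regions, columns the
#' patient's regions. Mutations co-localized with an LOH segment
#' (minor_cn = 0, total_cn > 0) in any region are flagged and excluded
#' from the returned matrix (they are unreliable characters for tree
#' building); their keys are kept in the "excluded_loh" attribute.
#'
#' @param calls [mutation_calls()] for one patient (filtered + rescued).
#' @param segs optional [segments_cn()] used for the LOH exclusion.
#' @param regions optional character vector of all region ids.
#' @return logical matrix (mutations x regions) with attribute
#'   "excluded_loh"; zero rows when there are no usable mutations.
#' @export
presence_matrix <- function(calls, segs = NULL, regions = NULL) {
  calls <- mutation_calls(calls)
  calls <- calls[calls$effect == "nonsilent", , drop = FALSE]
  if (is.null(regions)) regions <- sort(unique(calls$region_id))
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  excluded <- character()
  if (!is.null(segs) && nrow(calls)) {
    segs <- as.data.frame(segs)
    loh <- segs[segs$minor_cn == 0 & segs$total_cn > 0, , drop = FALSE]
    if (nrow(loh)) {
      in_loh <- vapply(seq_len(nrow(calls)), function(i) {
        any(loh$chrom == calls$chrom[i] & loh$start <= calls$pos[i] &
              loh$end >= calls$pos[i])
      }, logical(1))
      excluded <- unique(key[in_loh])
    }
  }
  keep <- !key %in% excluded
  calls <- calls[keep, , drop = FALSE]; key <- key[keep]
  muts <- unique(key)
  if (!length(muts)) {
    warning("no usable mutations; tree will be skipped")
    m <- matrix(FALSE, 0, length(regions), dimnames = list(NULL, regions))
    attr(m, "excluded_loh") <- excluded
    return(m)
  }
  m <- matrix(FALSE, length(muts), length(regions),
              dimnames = list(muts, regions))
  m[cbind(match(key, muts), match(calls$region_id, regions))] <- TRUE
  attr(m, "excluded_loh") <- excluded
  m
}

#' Trunk/branch partition of mutations
#'
#' Trunk mutations are present in every region; all others are branch.
#'
#' @param matrix logical presence matrix from [presence_matrix()].
#' @return character vector ("trunk"/"branch") named by mutation key.
#' @export
trunk_branch_partition <- function(matrix) {
  out <- ifelse(rowSums(matrix) == ncol(matrix), "trunk", "branch")
  names(out) <- rownames(matrix)
  out
}

# enumerate multifurcating rooted trees over a leaf set; each tree is a
# nested list: list(leaf = "R1") or list(children = list(...))
enum_trees <- function(leaves) {
  if (length(leaves) == 1) return(list(list(leaf = leaves)))
  parts <- set_partitions(leaves)
  out <- list()
  for (p in parts) {
    if (length(p) < 2) next  # a root with a single child is the same tree
    blocks <- lapply(p, function(b) {
      if (length(b) == 1) list(list(leaf = b)) else enum_trees(b)
    })
    idx <- do.call(expand.grid, lapply(blocks, seq_along))
    for (r in seq_len(nrow(idx))) {
      ch <- lapply(seq_along(blocks), function(j) blocks[[j]][[idx[r, j]]])
      out[[length(out) + 1L]] <- list(children = ch)
    }
  }
  out
}

set_partitions <- function(x) {
  if (length(x) == 1) return(list(list(x)))
  rest <- set_partitions(x[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p; q[[i]] <- c(x[1], q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(x[1]), p)
  }
  out
}

canonical_newick <- function(tree, lengths = NULL) {
  render <- function(node) {
    if (!is.null(node$leaf)) return(node$leaf)
    parts <- sort(vapply(node$children, render, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  render(tree)
}

# flatten nested tree under a germline root into parent/children index form
flatten_tree <- function(tree) {
  nodes <- list()  # each: list(label, leaf)
  parent <- integer()
  add_node <- function(label, leaf, par) {
    nodes[[length(nodes) + 1L]] <<- list(label = label, leaf = leaf)
    parent[length(nodes)] <<- par
    length(nodes)
  }
  root <- add_node("germline", FALSE, 0L)
  walk <- function(node, par) {
    if (!is.null(node$leaf)) {
      add_node(node$leaf, TRUE, par)
    } else {
      id <- add_node("", FALSE, par)
      for (ch in node$children) walk(ch, id)
      id
    }
  }
  # trunk: germline -> MRCA -> subtrees
  mrca <- add_node("MRCA", FALSE, root)
  if (!is.null(tree$leaf)) {
    add_node(tree$leaf, TRUE, mrca)
  } else {
    for (ch in tree$children) walk(ch, mrca)
  }
  children <- lapply(seq_along(nodes), function(i) which(parent == i))
  list(nodes = nodes, parent = parent, children = children,
       root = root, mrca = mrca)
}

# exact unit-cost small-parsimony DP for one binary character; returns
# minimal score and a per-node state assignment (ties resolved toward
# state 1, which places gains on the trunk-most possible edge)
sankoff_binary <- function(ft, leaf_states) {
  n <- length(ft$nodes)
  cost <- matrix(0, n, 2)  # columns: state 0, state 1
  order_post <- rev(seq_len(n))  # nodes were added parent-before-child
  for (i in order_post) {
    if (ft$nodes[[i]]$leaf) {
      s <- leaf_states[[ft$nodes[[i]]$label]]
      cost[i, ] <- c(if (s == 0) 0 else Inf, if (s == 1) 0 else Inf)
    } else if (length(ft$children[[i]])) {
      for (s in 0:1) {
        tot <- 0
        for (ch in ft$children[[i]]) {
          tot <- tot + min(cost[ch, 1] + (s != 0), cost[ch, 2] + (s != 1))
        }
        cost[i, s + 1] <- tot
      }
    }
  }
  state <- integer(n)
  state[ft$root] <- 0L  # germline
  changes <- integer(0); change_child <- integer(0)
  for (i in seq_len(n)) {
    if (i == ft$root) next
    par_s <- state[ft$parent[i]]
    c0 <- cost[i, 1] + (par_s != 0)
    c1 <- cost[i, 2] + (par_s != 1)
    state[i] <- if (c1 <= c0) 1L else 0L
    if (state[i] != par_s) change_child <- c(change_child, i)
  }
  list(score = cost[ft$root, 1],  # germline root state is fixed at 0
       state = state, change_child = change_child)
}

#' Maximum-parsimony tree from a presence/absence matrix
#'
#' The tree is rooted at the all-zero germline profile, connected by a
#' trunk edge to the most recent common ancestor of the regions; the
#' topology below the MRCA is chosen by exhaustive search over all
#' multifurcating arrangements of the regions (exact for the <= 4 regions
#' typical of multi-region designs). Each mutation is assigned to edges by
#' an exact unit-cost small-parsimony pass (ties resolved toward the
#' trunk-most edge); branch lengths are the number of mutation change
#' events on each edge. Topology ties break to the lexicographically
#' smallest canonical newick.
#'
#' @param matrix logical presence matrix ([presence_matrix()]).
#' @return list of class `phylo_mr`: newick (branch lengths = mutation
#'   counts), edges (data.frame parent/child/length), edge_mutations
#'   (list of mutation keys per edge), score, topology (canonical string).
#' @export
build_tree <- function(matrix) {
  regions <- colnames(matrix)
  if (is.null(regions) || !length(regions)) stop("matrix has no regions")
  if (nrow(matrix) && any(rowSums(matrix) == 0)) {
    stop("every mutation must be present in at least one region")
  }
  cand <- if (length(regions) == 1) list(list(leaf = regions)) else
    enum_trees(regions)
  key <- vapply(cand, canonical_newick, character(1))
  cand <- cand[order(key)]
  key <- sort(key)

  best <- NULL
  for (ti in seq_along(cand)) {
    ft <- flatten_tree(cand[[ti]])
    score <- 0
    per_char <- vector("list", nrow(matrix))
    for (m in seq_len(nrow(matrix))) {
      ls <- as.list(as.integer(matrix[m, ]))
      names(ls) <- regions
      res <- sankoff_binary(ft, ls)
      score <- score + res$score
      per_char[[m]] <- res$change_child
    }
    if (is.null(best) || score < best$score) {
      best <- list(score = score, ft = ft, per_char = per_char,
                   topology = key[ti])
    }
  }
  ft <- best$ft
  n <- length(ft$nodes)
  edge_len <- integer(n)
  edge_muts <- vector("list", n)
  for (m in seq_along(best$per_char)) {
    for (ch in best$per_char[[m]]) {
      edge_len[ch] <- edge_len[ch] + 1L
      edge_muts[[ch]] <- c(edge_muts[[ch]], rownames(matrix)[m])
    }
  }
  labels <- vapply(seq_len(n), function(i) {
    if (nzchar(ft$nodes[[i]]$label)) ft$nodes[[i]]$label else sprintf("N%d", i)
  }, character(1))
  edges <- data.frame(
    parent = labels[ft$parent[-ft$root]],
    child = labels[-ft$root],
    length = edge_len[-ft$root],
    stringsAsFactors = FALSE
  )
  names(edge_muts) <- labels
  newick <- build_newick(ft, edge_len, labels)
  structure(list(newick = newick, edges = edges,
                 edge_mutations = edge_muts[-ft$root],
                 score = best$score, topology = best$topology,
                 regions = regions),
            class = "phylo_mr")
}

build_newick <- function(ft, edge_len, labels) {
  render <- function(i) {
    kids <- ft$children[[i]]
    body <- if (length(kids)) {
      paste0("(", paste(vapply(sort(kids), render, character(1)),
                        collapse = ","), ")")
    } else ""
    lab <- if (ft$nodes[[i]]$leaf || i == ft$root) labels[i] else ""
    len <- if (i == ft$root) "" else sprintf(":%d", edge_len[i])
    paste0(body, lab, len)
  }
  paste0("(", render(ft$mrca), ")germline;")
}

#' Trunk length of a parsimony tree
#' @param tree a `phylo_mr` from [build_tree()].
#' @return mutation count on the germline-MRCA edge.
#' @export
trunk_length <- function(tree) {
  tree$edges$length[tree$edges$parent == "germline"][1]
}

#' Convert a `phylo_mr` tree to an ape "phylo" object
#' @param tree a `phylo_mr`.
#' @return an [ape::read.tree()] phylo object.
#' @export
as_phylo <- function(tree) ape::read.tree(text = tree$newick)

# ---- Timing -----------------------------------------------------------------

#' Time an SNV as early or late from its mutation copy number
#'
#' Early iff mut_cn > 1 (the mutation predates a local copy gain and was
#' amplified with it); late iff mut_cn <= 1.
#'
#' @param mut_cn mutation copy number (vectorized).
#' @return character vector "early"/"late".
#' @export
time_snv <- function(mut_cn) ifelse(mut_cn > 1, "early", "late")

#' Time a CNV gain from the mutations it contains
#'
#' Requires at least 5 mutations inside the gained segment; the gain is
#' early iff their mean mutation copy number exceeds 1, late iff <= 1,
#' NA with fewer than 5 informative mutations.
#'
#' @param mut_cns mutation copy numbers of mutations inside the segment.
#' @return "early", "late" or NA.
#' @export
time_cnv_gain <- function(mut_cns) {
  if (length(mut_cns) < 5) return(NA_character_)
  if (mean(mut_cns) > 1) "early" else "late"
}

#' Time a CNV loss from clonality and WGD status
#'
#' Clonal loss coupled with whole-genome doubling is early; any loss
#' unrelated to genome doubling (subclonal, or without WGD) is late.
#'
#' @param clonality "clonal" or "subclonal".
#' @param is_wgd logical WGD status of the tumor.
#' @return "early" or "late".
#' @export
time_cnv_loss <- function(clonality, is_wgd) {
  ifelse(clonality == "clonal" & is_wgd, "early", "late")
}
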