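# Distance-based phylogeny: p-distances, Saitou-Nei neighbor-joining,
# bootstrap over an anchor-projected pseudo-alignment, 50% majority-rule
# collapse and reference-guided clade labeling. Trees are ape "phylo"
# objects; bootstrap supports live in tree$node.label (internal nodes).

#' Pairwise p-distance matrix
#'
#' `d[i,j] = 1 - identity(i,j)` from pairwise global alignment (identity
#' over mutually non-gap columns). With `model = "poisson"` the
#' Poisson-corrected distance `-log(1 - p)` is returned instead.
#'
#' @param seqs list of at least 3 [protein_sequence()] records.
#' @param model `"p"` (default) or `"poisson"`.
#' @param ... forwarded to [global_align()].
#' @return symmetric numeric matrix with sequence ids as dimnames.
#' @export
p_distance_matrix <- function(seqs, model = c("p", "poisson"), ...) {
  if (length(seqs) < 3L) stop("need at least 3 sequences")
  model <- match.arg(model)
  ids <- seq_ids(seqs)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- 1 - global_align(seqs[[i]], seqs[[j]], ...)$identity
      d[i, j] <- d[j, i] <- p
    }
  }
  if (model == "poisson") d <- -log(pmax(1 - d, 1e-10)) * (d > 0 | t(d) > 0)
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard agglomerative NJ: iteratively joins the pair minimizing the
#' Q-criterion, with branch lengths from the two-point formulas. Ties are
#' broken by the lowest (row, column) label-index pair, making the tree
#' deterministic. Negative branch lengths are clamped to zero with a
#' warning.
#'
#' @param D symmetric distance matrix with zero diagonal and labels as
#'   dimnames (at least 3).
#' @return an unrooted `phylo` tree (class from the ape package).
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (nrow(D) < 3L) stop("need at least 3 labels")
  if (any(D < 0) || any(abs(D - t(D)) > 1e-9)) {
    stop("D must be symmetric and nonnegative")
  }
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  # subtree newick fragments, one per active cluster
  frag <- labels
  d <- D
  clamped <- FALSE
  fmt <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.10g", x)
  }
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest (i,j) among minima, row-major with i < j
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    d <- d2
  }
  if (nrow(d) == 3L) {
    l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(l1), frag[2], fmt(l2),
                   frag[3], fmt(l3))
  }
  if (clamped) warning("negative NJ branch length(s) clamped to 0")
  tree <- ape::read.tree(text = nwk)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# ---- bipartitions ------------------------------------------------------

# Non-trivial bipartitions of an unrooted tree, one per internal edge.
# Returned as a named list: key -> leaf labels of the side NOT containing
# the alphabetically smallest leaf; names are the canonical keys. For trees
# read from newick, each non-root internal node corresponds to one internal
# edge. The support of that edge (if node labels are present) is attached
# as the "support" attribute (numeric vector, parallel to the list).
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  nn <- tree$Nnode
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tips_under <- vector("list", n + nn)
  # postorder via recursion-free stack
  stack <- root
  post <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    post <- c(v, post)
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  for (v in post) {
    ch <- kids[[as.character(v)]]
    tips_under[[v]] <- if (is.null(ch)) v else unlist(tips_under[ch])
  }
  anchor <- order(tree$tip.label)[1L]  # alphabetically smallest leaf index
  internal <- setdiff((n + 1L):(n + nn), root)
  parts <- list()
  supports <- numeric(0)
  node_ids <- integer(0)
  labs <- tree$tip.label
  for (v in internal) {
    side <- tips_under[[v]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (anchor %in% side) side <- setdiff(seq_len(n), side)
    key_labs <- sort(labs[side])
    key <- paste(key_labs, collapse = "\r")
    parts[[key]] <- key_labs
    sup <- NA_real_
    if (!is.null(tree$node.label)) {
      sup <- suppressWarnings(as.numeric(tree$node.label[v - n]))
    }
    supports <- c(supports, sup)
    node_ids <- c(node_ids, v)
  }
  attr(parts, "support") <- supports
  attr(parts, "node") <- node_ids
  parts
}

# ---- pseudo-alignment --------------------------------------------------

#' Anchor-projected pseudo-alignment
#'
#' Projects every sequence onto a common coordinate frame: each sequence is
#' globally aligned to its best-scoring anchor, every anchor is aligned to
#' the master anchor (the lexicographically smallest `ref_id`), and the two
#' maps are composed. Columns are master-anchor positions; unmapped columns
#' are gaps (`-`). This replaces a full progressive multiple alignment,
#' which is out of the package's scope.
#'
#' @param seqs list of [protein_sequence()] records.
#' @param refs reference annotations.
#' @param ... forwarded to the aligner.
#' @return character matrix (rows = sequences, columns = master positions).
#' @export
pseudo_alignment <- function(seqs, refs = reference_set(), ...) {
  ids <- vapply(refs, function(r) r$ref_id, character(1L))
  master <- refs[[order(ids)[1L]]]
  mlen <- length(master$seq)
  # map from master position -> position in each ref
  ref_maps <- lapply(refs, function(r) {
    if (identical(r$ref_id, master$ref_id)) return(seq_len(mlen))
    global_align(r$seq, master$seq, ...)$map
  })
  names(ref_maps) <- ids
  alns <- batch_align_to_best(seqs, refs, ...)
  mat <- matrix("-", nrow = length(seqs), ncol = mlen,
                dimnames = list(seq_ids(seqs), NULL))
  for (i in seq_along(seqs)) {
    ref <- alns[[i]]$ref
    q_of_ref <- alns[[i]]$aln$map           # ref position -> query position
    m2r <- ref_maps[[ref$ref_id]]           # master position -> ref position
    qpos <- ifelse(is.na(m2r), NA_integer_, q_of_ref[m2r])
    ok <- !is.na(qpos)
    chars <- split_residues(seqs[[i]]$residues)
    mat[i, ok] <- chars[qpos[ok]]
  }
  mat
}

# p-distance between rows of an alignment matrix (mutually non-gap columns;
# 1 when no shared columns). Vectorized via one-hot cross-products so the
# bootstrap loop stays fast.
alignment_p_dist <- function(mat) {
  n <- nrow(mat)
  letters_here <- setdiff(unique(as.vector(mat)), "-")
  nongap <- (mat != "-") * 1
  shared <- nongap %*% t(nongap)
  matches <- matrix(0, n, n)
  for (ch in letters_here) {
    x <- (mat == ch) * 1
    matches <- matches + x %*% t(x)
  }
  d <- ifelse(shared > 0, 1 - matches / pmax(shared, 1L), 1)
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the reference NJ tree from the full anchor-projected
#' pseudo-alignment, then resamples alignment columns with replacement
#' `n_reps` times, rebuilds the NJ tree for each replicate, and reports for
#' every internal edge of the reference tree the percentage of replicates
#' containing the same bipartition. Reproducible for a fixed seed.
#'
#' @param x list of at least 4 [protein_sequence()] records, or a character
#'   matrix (rows = taxa, columns = alignment columns, gaps as `-`).
#' @param refs reference annotations (used only when `x` is a sequence
#'   list).
#' @param n_reps number of bootstrap replicates (the published protocol uses
#'   1000).
#' @param seed RNG seed.
#' @param ... forwarded to [pseudo_alignment()].
#' @return the reference `phylo` tree with supports (0..100) in
#'   `node.label` (empty for the root).
#' @export
bootstrap_support <- function(x, refs = reference_set(), n_reps = 1000L,
                              seed = 1L, ...) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  mat <- if (is.matrix(x)) x else {
    if (length(x) < 4L) stop("need at least 4 sequences")
    pseudo_alignment(x, refs, ...)
  }
  if (nrow(mat) < 4L) stop("need at least 4 taxa")
  ref_tree <- neighbor_joining(alignment_p_dist(mat))
  parts0 <- tree_bipartitions(ref_tree)
  keys0 <- names(parts0)
  counts <- setNames(numeric(length(keys0)), keys0)
  ncol_m <- ncol(mat)
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol_m, ncol_m, replace = TRUE)
      tb <- suppressWarnings(neighbor_joining(alignment_p_dist(mat[, cols,
                                                                  drop = FALSE])))
      hits <- intersect(keys0, names(tree_bipartitions(tb)))
      counts[hits] <- counts[hits] + 1
    }
  })
  support <- 100 * counts / n_reps
  n <- length(ref_tree$tip.label)
  node.label <- rep("", ref_tree$Nnode)
  nodes <- attr(parts0, "node")
  node.label[nodes - n] <- sprintf("%.10g", support[keys0])
  ref_tree$node.label <- node.label
  ref_tree
}

#' Collapse poorly supported branches (majority rule)
#'
#' Contracts every internal edge whose bootstrap support is below
#' `threshold` into a polytomy; leaves (and their branch lengths) are
#' untouched. Edges without a numeric support value are kept.
#'
#' @param tree a `phylo` with supports in `node.label` (see
#'   [bootstrap_support()]).
#' @param threshold support percentage below which edges are collapsed
#'   (default 50, the published majority rule).
#' @return the collapsed `phylo` (supports of surviving edges retained).
#' @export
majority_rule_collapse <- function(tree, threshold = 50) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  root <- n + 1L
  sup <- suppressWarnings(as.numeric(tree$node.label))
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  render <- function(v) {
    es <- kids[[as.character(v)]]
    if (is.null(es)) {  # leaf
      return(tree$tip.label[v])
    }
    pieces <- character(0)
    for (e in es) {
      ch <- tree$edge[e, 2L]
      len <- if (!is.null(tree$edge.length)) tree$edge.length[e] else NA
      if (ch > n && !is.na(sup[ch - n]) && sup[ch - n] < threshold) {
        # contract: splice grandchildren in at this level (their own branch
        # lengths are kept; the collapsed edge vanishes)
        pieces <- c(pieces, splice(ch))
      } else {
        lab <- if (ch > n) tree$node.label[ch - n] %||% "" else ""
        body <- render(ch)
        pieces <- c(pieces, sprintf("%s%s%s", body,
                                    if (ch > n) lab else "",
                                    if (is.na(len)) "" else sprintf(":%.10g", len)))
      }
    }
    sprintf("(%s)", paste(pieces, collapse = ","))
  }
  splice <- function(v) {
    es <- kids[[as.character(v)]]
    pieces <- character(0)
    for (e in es) {
      ch <- tree$edge[e, 2L]
      len <- if (!is.null(tree$edge.length)) tree$edge.length[e] else NA
      if (ch > n && !is.na(sup[ch - n]) && sup[ch - n] < threshold) {
        pieces <- c(pieces, splice(ch))
      } else {
        lab <- if (ch > n) tree$node.label[ch - n] %||% "" else ""
        body <- render(ch)
        pieces <- c(pieces, sprintf("%s%s%s", body,
                                    if (ch > n) lab else "",
                                    if (is.na(len)) "" else sprintf(":%.10g", len)))
      }
    }
    pieces
  }
  nwk <- paste0(render(root), if (!is.null(tree$node.label))
    tree$node.label[1L] else "", ";")
  ape::read.tree(text = nwk)
}

#' Label query leaves by clade membership
#'
#' Each unlabeled leaf receives the subfamily of the smallest
#' well-supported clade (support at or above `support_threshold`) that
#' contains it together with at least one labeled reference leaf, provided
#' all labeled leaves in that clade agree; otherwise it is
#' `"unclassified"`.
#'
#' Clades are the descendant sets of the tree's internal nodes (the clades
#' as drawn). A leaf contained in no labeled clade at all (e.g. attached at
#' the root) is additionally tested against the complement sides of the
#' supported bipartitions, but such a side is rejected when some other
#' supported edge separates the leaf from all of the side's labeled members
#' — a leaf on its own branch outside every labeled clade therefore stays
#' unclassified; ambiguity (two equally small unanimous sides with
#' different labels) also yields unclassified.
#'
#' @param tree a `phylo` with supports in `node.label`.
#' @param labeled_refs named character vector: leaf label -> subfamily.
#' @param support_threshold minimal support for a usable clade (default 50).
#' @return named character vector over the unlabeled leaves.
#' @export
assign_clades <- function(tree, labeled_refs, support_threshold = 50) {
  stopifnot(inherits(tree, "phylo"))
  if (!length(labeled_refs) || !any(names(labeled_refs) %in% tree$tip.label)) {
    stop("no labeled reference leaves present in the tree")
  }
  parts <- tree_bipartitions(tree)
  sup <- attr(parts, "support")
  labs <- tree$tip.label
  n <- length(labs)
  root <- n + 1L
  queries <- setdiff(labs, names(labeled_refs))
  out <- setNames(rep("unclassified", length(queries)), queries)
  # rooted descendant clades, one per internal non-root node
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tips_under <- vector("list", n + tree$Nnode)
  stack <- root; post <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    post <- c(v, post)
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  for (v in post) {
    ch <- kids[[as.character(v)]]
    tips_under[[v]] <- if (is.null(ch)) v else unlist(tips_under[ch])
  }
  node_sup <- suppressWarnings(as.numeric(tree$node.label))
  clades <- list(); clade_sup <- numeric(0)
  for (v in setdiff((n + 1L):(n + tree$Nnode), root)) {
    clades[[length(clades) + 1L]] <- labs[tips_under[[v]]]
    clade_sup <- c(clade_sup, node_sup[v - n])
  }
  ref_names <- names(labeled_refs)
  unanimity <- function(side) {
    ref_in <- intersect(side, ref_names)
    if (!length(ref_in)) return(NULL)
    u <- unique(unname(labeled_refs[ref_in]))
    if (length(u) == 1L) u else NA_character_
  }
  # supported bipartitions (for the fallback separation test)
  supported_parts <- list()
  for (k in seq_along(parts)) {
    if (!is.na(sup[k]) && sup[k] >= support_threshold) {
      supported_parts[[length(supported_parts) + 1L]] <- parts[[k]]
    }
  }
  separated <- function(q, side_refs) {
    for (p in supported_parts) {
      in_p <- q %in% p
      refs_in_p <- side_refs %in% p
      if ((in_p && !any(refs_in_p)) || (!in_p && all(refs_in_p))) return(TRUE)
    }
    FALSE
  }
  for (q in queries) {
    had_labeled_clade <- FALSE
    best_size <- Inf; best_label <- NULL
    for (k in seq_along(clades)) {
      side <- clades[[k]]
      if (!q %in% side) next
      u <- unanimity(side)
      if (is.null(u)) next
      had_labeled_clade <- TRUE
      if (is.na(u) || is.na(clade_sup[k]) || clade_sup[k] < support_threshold) next
      if (length(side) < best_size) { best_size <- length(side); best_label <- u }
    }
    if (is.null(best_label) && !had_labeled_clade) {
      # fallback: complement sides, guarded against separation
      cand <- list()
      for (k in seq_along(parts)) {
        if (is.na(sup[k]) || sup[k] < support_threshold) next
        side <- setdiff(labs, parts[[k]])
        if (!q %in% side) next
        u <- unanimity(side)
        if (is.null(u) || is.na(u)) next
        side_refs <- intersect(side, ref_names)
        if (separated(q, side_refs)) next
        cand[[length(cand) + 1L]] <- list(size = length(side), label = u)
      }
      if (length(cand)) {
        sizes <- vapply(cand, `[[`, numeric(1L), "size")
        at_min <- unique(vapply(cand[sizes == min(sizes)], `[[`,
                                character(1L), "label"))
        if (length(at_min) == 1L) best_label <- at_min
      }
    }
    if (!is.null(best_label)) out[q] <- best_label
  }
  out
}
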