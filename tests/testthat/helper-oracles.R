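# Independent oracles used to derive expected values. These deliberately do
# not share code with the implementation paths they check.

# Brute-force global alignment score with affine gaps (gap of length L costs
# open + L * ext), by exhaustive enumeration of all alignments of two tiny
# strings.
oracle_align_score <- function(a, b, mat, open = 10, ext = 0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      rec(i + 1, j + 1, score + mat[a[i], b[j]], "m")
    }
    if (i <= length(a)) {  # gap in b
      pen <- ext + if (state == "gb") 0 else open
      rec(i + 1, j, score - pen, "gb")
    }
    if (j <= length(b)) {  # gap in a
      pen <- ext + if (state == "ga") 0 else open
      rec(i, j + 1, score - pen, "ga")
    }
  }
  rec(1, 1, 0, "m")
  best
}

# Fine-grid scan for the isoelectric point: independent charge equation over
# a 1e-5 pH grid (returns the grid point with smallest |charge|).
oracle_pi_grid <- function(residues, pka) {
  chars <- strsplit(residues, "")[[1]]
  ph <- seq(0, 14, by = 1e-5)
  chg <- 1 / (1 + 10^(ph - pka$nterm)) - 1 / (1 + 10^(pka$cterm - ph))
  for (a in names(pka$acidic)) {
    k <- sum(chars == a)
    if (k) chg <- chg - k / (1 + 10^(pka$acidic[[a]] - ph))
  }
  for (a in names(pka$basic)) {
    k <- sum(chars == a)
    if (k) chg <- chg + k / (1 + 10^(ph - pka$basic[[a]]))
  }
  ph[which.min(abs(chg))]
}

# Greedy dedup oracle for equal-length gap-free sequences: identity is the
# Hamming match fraction; same visit order (descending length, then id).
oracle_dedup_kept <- function(seqs, threshold) {
  ids <- vapply(seqs, function(s) s$id, character(1))
  lens <- vapply(seqs, function(s) nchar(s$residues), integer(1))
  ord <- order(-lens, ids)
  ham_id <- function(x, y) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    mean(cx == cy & cx != "X")
  }
  kept <- integer(0)
  for (k in ord) {
    dup <- any(vapply(kept, function(r) {
      ham_id(seqs[[k]]$residues, seqs[[r]]$residues) >= threshold
    }, logical(1)))
    if (!dup) kept <- c(kept, k)
  }
  sort(ids[kept])
}

# All leaf-pair path-edge indicators for an unrooted binary phylo topology.
oracle_path_matrix <- function(tree) {
  n <- length(tree$tip.label)
  m <- nrow(tree$edge)
  adj <- vector("list", n + tree$Nnode)
  for (e in seq_len(m)) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  path_edges <- function(from, to) {
    # BFS
    prev <- rep(NA_integer_, length(adj)); prev_e <- rep(NA_integer_, length(adj))
    queue <- from; seen <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == to) break
      nb <- adj[[v]]
      for (r in seq_len(NROW(nb))) {
        w <- nb[r, 1]
        if (!w %in% seen) {
          seen <- c(seen, w); prev[w] <- v; prev_e[w] <- nb[r, 2]
          queue <- c(queue, w)
        }
      }
    }
    out <- integer(0); v <- to
    while (v != from) { out <- c(out, prev_e[v]); v <- prev[v] }
    out
  }
  pairs <- utils::combn(n, 2)
  X <- matrix(0, ncol(pairs), m)
  for (p in seq_len(ncol(pairs))) {
    X[p, path_edges(pairs[1, p], pairs[2, p])] <- 1
  }
  list(pairs = pairs, X = X)
}

# Least-squares fit of a distance matrix on a fixed topology; returns the
# residual sum of squares (branch lengths unconstrained).
oracle_ls_residual <- function(topology, D) {
  pm <- oracle_path_matrix(topology)
  labs <- topology$tip.label
  y <- apply(pm$pairs, 2, function(ij) D[labs[ij[1]], labs[ij[2]]])
  fit <- lm.fit(pm$X, y)
  sum(fit$residuals^2)
}

# Best topology for a distance matrix by exhaustive enumeration of all
# unrooted binary topologies (phangorn::allTrees) under least squares.
oracle_best_topology <- function(D) {
  labs <- rownames(D)
  trees <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  rss <- vapply(trees, oracle_ls_residual, numeric(1), D = D)
  trees[[which.min(rss)]]
}
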