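# Independent reference implementations used as oracles. Deliberately naive
# (quadratic / per-base / exhaustive) and written without reference to the
# package's own code paths.

# per-base set-intersection overlap of two intervals
oracle_overlap_perbase <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(seq2(a$start, a$end - 1), seq2(b$start, b$end - 1)))
}

seq2 <- function(from, to) if (to < from) integer(0) else seq(from, to)

# quadratic all-pairs screen: for every repeat, loop over every element
oracle_screen <- function(repeats, elements, min_overlap = 30,
                          min_lod = 100) {
  keep <- logical(nrow(repeats))
  for (i in seq_len(nrow(repeats))) {
    if ("is_te" %in% names(repeats) && !repeats$is_te[i]) next
    total <- 0L
    for (j in seq_len(nrow(elements))) {
      if (elements$lod[j] <= min_lod) next
      if (elements$chrom[j] != repeats$chrom[i]) next
      ov <- min(repeats$end[i], elements$end[j]) -
        max(repeats$start[i], elements$start[j])
      if (ov > 0) total <- total + ov
    }
    keep[i] <- total > min_overlap
  }
  repeats[keep, , drop = FALSE]
}

# all-pairs screen oracle, vectorised over elements per repeat (same
# quadratic computation as oracle_screen, fast enough for many instances)
oracle_screen_allpairs <- function(repeats, elements, min_overlap = 30,
                                   min_lod = 100) {
  el <- elements[elements$lod > min_lod, , drop = FALSE]
  keep <- vapply(seq_len(nrow(repeats)), function(i) {
    same <- el$chrom == repeats$chrom[i]
    ov <- pmax(0L, pmin(repeats$end[i], el$end) -
                 pmax(repeats$start[i], el$start))
    sum(ov[same]) > min_overlap
  }, logical(1))
  if ("is_te" %in% names(repeats)) keep <- keep & repeats$is_te
  repeats[keep, , drop = FALSE]
}

# union-find over all passing pairs, pair gaps computed over the full
# quadratic pair set
oracle_chain_pairs <- function(tbl, max_gap = 600) {
  n <- nrow(tbl)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  same <- outer(tbl$chrom, tbl$chrom, "==")
  gap <- pmax(0, outer(tbl$start, tbl$start, pmax) -
                outer(tbl$end, tbl$end, pmin))
  pass <- which(same & gap < max_gap & upper.tri(same), arr.ind = TRUE)
  for (r in seq_len(nrow(pass))) {
    ri <- find(pass[r, 1]); rj <- find(pass[r, 2])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, integer(1))
}

# union-find over all interval pairs with gap < max_gap (single linkage)
oracle_chain <- function(tbl, max_gap = 600) {
  n <- nrow(tbl)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (tbl$chrom[i] != tbl$chrom[j]) next
      gap <- max(0, max(tbl$start[i], tbl$start[j]) -
                    min(tbl$end[i], tbl$end[j]))
      if (gap < max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# full three-state affine-gap local alignment DP, score only.
# gap of length L costs open + (L-1)*extend; N scores as mismatch always.
oracle_sw_score <- function(a, b, match = 2, mismatch = -3, gap_open = -5,
                            gap_extend = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1 + seq_len(n)) {
    for (j in 1 + seq_len(m)) {
      E[i, j] <- max(H[i - 1, j] + gap_open, E[i - 1, j] + gap_extend)
      F[i, j] <- max(H[i, j - 1] + gap_open, F[i, j - 1] + gap_extend)
      s <- if (av[i - 1] == "N" || bv[j - 1] == "N") {
        mismatch
      } else if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# exhaustive Dollo search: every node covering all present tips is a
# candidate gain; losses counted by brute-force subtree inspection
oracle_dollo <- function(present_tips, tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  tips_below <- function(v) {
    if (v <= n_tip) return(v)
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    unlist(lapply(kids, tips_below))
  }
  present_idx <- match(present_tips, tree$tip.label)
  best <- NULL
  for (g in seq_len(n_node)) {
    below <- tips_below(g)
    if (!all(present_idx %in% below)) next
    # count edges (u -> v) inside subtree(g) where v's subtree is all-absent
    # but u's subtree is not
    losses <- 0L
    nodes <- all_nodes_below(tree, g)
    for (v in setdiff(nodes, g)) {
      u <- tree$edge[tree$edge[, 2] == v, 1]
      v_absent <- !any(present_idx %in% tips_below(v))
      u_has <- any(present_idx %in% tips_below(u))
      if (v_absent && u_has) losses <- losses + 1L
    }
    if (is.null(best) || losses < best$losses) {
      best <- list(gain = g, losses = losses)
    }
  }
  best
}

helper_tips_below <- function(tree, v) {
  n_tip <- length(tree$tip.label)
  if (v <= n_tip) return(v)
  kids <- tree$edge[tree$edge[, 1] == v, 2]
  unlist(lapply(kids, function(k) helper_tips_below(tree, k)))
}

all_nodes_below <- function(tree, v) {
  n_tip <- length(tree$tip.label)
  if (v <= n_tip) return(v)
  kids <- tree$edge[tree$edge[, 1] == v, 2]
  c(v, unlist(lapply(kids, function(k) all_nodes_below(tree, k))))
}
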