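# Dollo gain inference on a rooted species tree.
#
# The premise: a TE insertion at an orthologous site arises once and can
# only be lost, never regained (homoplasy-free). The gain branch is then
# the stem of the most recent common ancestor of all species carrying the
# ortholog, and absences inside that clade are explained by the minimal
# number of loss events.

# integer node ids of the direct children of `node`
tree_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

# tip indices below (and including) `node`
tree_tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v <= n_tip) {
      out <- c(out, v)
    } else {
      stack <- c(stack, tree_children(tree, v))
    }
  }
  out
}

# human-readable name for a node: its label when present, the tip label for
# leaves, otherwise a name synthesised from the clade's first and last tips
node_clade_name <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  lbl <- tree$node.label
  if (!is.null(lbl)) {
    l <- lbl[node - n_tip]
    if (!is.na(l) && nzchar(l)) return(l)
  }
  tips <- tree$tip.label[tree_tips_below(tree, node)]
  paste0("mrca(", tips[1], ",", tips[length(tips)], ")")
}

#' Infer the gain branch of a TE sub-element from ortholog presence
#'
#' Places a single gain on a rooted species tree under Dollo logic: the gain
#' node is the most recent common ancestor (MRCA) of every species carrying
#' the ortholog, and `n_losses` is the minimal number of branches below that
#' node that must be cut (each deleting its whole subtree) to explain every
#' absent descendant. `n_losses` is 0 exactly when all descendants of the
#' gain node are present.
#'
#' @param presence named 0/1 (or logical) vector over species, or a one-row
#'   slice of a [read_presence_table()] tibble (the `element` column, if
#'   present, supplies the element name).
#' @param tree rooted `phylo` tree from [read_species_tree()].
#' @param element optional element name for the output.
#' @return one-row tibble: `element`, `gain_node` (integer node id in
#'   `tree`), `clade_name` (node label when available, otherwise
#'   synthesised), `n_losses`, `n_present`, and a `present_species` list
#'   column.
#' @export
infer_gain <- function(presence, tree, element = NA_character_) {
  if (is.data.frame(presence)) {
    stopifnot(nrow(presence) == 1)
    if ("element" %in% names(presence) && is.na(element)) {
      element <- presence$element[[1]]
    }
    presence <- unlist(presence[setdiff(names(presence), "element")])
  }
  present <- names(presence)[as.logical(presence)]
  if (length(present) == 0) {
    stop("element ", if (!is.na(element)) paste0("'", element, "' "),
         "absent everywhere: cannot place a gain", call. = FALSE)
  }
  missing <- setdiff(present, tree$tip.label)
  if (length(missing) > 0) {
    stop("species '", missing[1], "' not in tree", call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  tip_idx <- base::match(present, tree$tip.label)
  gain <- if (length(tip_idx) == 1) {
    tip_idx
  } else {
    ape::getMRCA(tree, tip_idx)
  }
  present_tip <- rep(FALSE, n_tip)
  present_tip[tip_idx] <- TRUE
  # minimal losses: count maximal all-absent subtrees hanging below the gain
  # node (each is removed by cutting its stem edge once)
  has_present <- function(node) {
    any(present_tip[tree_tips_below(tree, node)])
  }
  count_losses <- function(node) {
    if (node <= n_tip) return(0L)
    total <- 0L
    for (ch in tree_children(tree, node)) {
      if (has_present(ch)) {
        total <- total + count_losses(ch)
      } else {
        total <- total + 1L
      }
    }
    total
  }
  tibble(
    element = element,
    gain_node = as.integer(gain),
    clade_name = node_clade_name(tree, gain),
    n_losses = count_losses(gain),
    n_present = length(present),
    present_species = list(present)
  )
}

#' Infer gain branches for every element of a presence matrix
#'
#' @param presence tibble from [read_presence_table()].
#' @param tree rooted `phylo` tree.
#' @return tibble with one [infer_gain()] row per element.
#' @export
infer_gains <- function(presence, tree) {
  purrr::map_dfr(seq_len(nrow(presence)), function(i) {
    infer_gain(presence[i, ], tree)
  })
}

#' Relative integration order of TE sub-elements
#'
#' Orders gain assignments oldest-first by clade nesting: element `a`
#' strictly precedes `b` exactly when `a`'s gain node is a proper ancestor
#' of `b`'s. Elements whose gain nodes coincide or are incomparable (neither
#' is an ancestor of the other) share a rank — ties are reported, never
#' silently broken, because an integration-order claim rests on strict clade
#' nesting. The result is a total preorder: `rank` counts how many distinct
#' gain nodes in the input are proper ancestors of an element's own gain
#' node, so whenever `a` precedes `b`, `rank(a) < rank(b)`.
#'
#' @param assignments tibble from [infer_gains()] (needs `element`,
#'   `gain_node`, and optionally `clade_name`).
#' @param tree the rooted `phylo` tree the assignments were made on.
#' @return tibble sorted oldest-first: `element`, `gain_node`, `clade_name`,
#'   `rank` (1 = oldest; equal ranks form a tie group).
#' @export
integration_order <- function(assignments, tree) {
  n <- nrow(assignments)
  anc <- lapply(assignments$gain_node, function(v) node_ancestors(tree, v))
  nodes <- assignments$gain_node
  rank <- vapply(seq_len(n), function(i) {
    1L + length(intersect(unique(nodes), anc[[i]]))
  }, integer(1))
  out <- tibble(
    element = assignments$element,
    gain_node = nodes,
    clade_name = if ("clade_name" %in% names(assignments)) {
      assignments$clade_name
    } else {
      vapply(nodes, function(v) node_clade_name(tree, v), character(1))
    },
    rank = rank
  )
  dplyr::arrange(out, .data$rank, .data$element)
}

# node ids on the path from `node` (exclusive) up to the root (inclusive)
node_ancestors <- function(tree, node) {
  root <- length(tree$tip.label) + 1L
  out <- integer(0)
  v <- node
  while (v != root) {
    v <- tree$edge[tree$edge[, 2] == v, 1]
    out <- c(out, v)
  }
  out
}

#' Call ortholog presence from percent-identity values
#'
#' Converts per-species ortholog alignment identities into the 0/1 presence
#' calls that [infer_gain()] consumes: a species is called present when its
#' identity to the reference element reaches `threshold` percent. The 60%
#' default is this package's operating choice — there is no field-standard
#' cutoff, so it is deliberately surfaced as a prominent, tunable parameter.
#'
#' @param identities named numeric vector of percent identities in
#'   \[0, 100\] (one entry per species).
#' @param threshold presence cutoff in percent (called present when
#'   `identity >= threshold`).
#' @return named integer 0/1 vector over the same species.
#' @export
call_presence_from_identity <- function(identities, threshold = 60) {
  stopifnot(is.numeric(identities), !is.null(names(identities)))
  if (any(identities < 0 | identities > 100)) {
    stop("identities must lie in [0, 100]", call. = FALSE)
  }
  setNames(as.integer(identities >= threshold), names(identities))
}
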