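test_that("gain inference places nested clade patterns correctly", {
  tree <- small_tree()
  # present everywhere -> gain at the root, no losses
  all_on <- setNames(rep(1L, 4), tree$tip.label)
  g <- infer_gain(all_on, tree, element = "AmnSINE1")
  expect_equal(g$gain_node, ape::Ntip(tree) + 1L)
  expect_equal(g$clade_name, "Mammalia")
  expect_equal(g$n_losses, 0L)

  # placental-only pattern -> gain on the eutherian stem
  mer <- setNames(c(0L, 0L, 1L, 1L), tree$tip.label)
  g2 <- infer_gain(mer, tree, element = "MER117")
  expect_equal(g2$clade_name, "Eutheria")
  expect_equal(g2$n_losses, 0L)

  # therian pattern with a loss in one placental lineage
  x6b <- setNames(c(0L, 1L, 0L, 1L), tree$tip.label)
  g3 <- infer_gain(x6b, tree, element = "X6b_DNA")
  expect_equal(g3$clade_name, "Theria")
  expect_equal(g3$n_losses, 1L)
})

test_that("gain inference errors are informative", {
  tree <- small_tree()
  none <- setNames(rep(0L, 4), tree$tip.label)
  expect_error(infer_gain(none, tree), "absent everywhere")
  expect_error(infer_gain(c(dog = 1L), tree), "'dog' not in tree")
})

test_that("infer_gain accepts presence-table rows", {
  tree <- small_tree()
  tbl <- tibble::tibble(element = "MER117", platypus = 0L, opossum = 0L,
                        mouse = 1L, human = 1L)
  g <- infer_gain(tbl, tree)
  expect_equal(g$element, "MER117")
  expect_equal(g$clade_name, "Eutheria")
  expect_equal(sort(g$present_species[[1]]), c("human", "mouse"))
})

test_that("gain node and loss count equal the exhaustive Dollo oracle", {
  set.seed(1515)
  for (k in 1:60) {
    n <- sample(3:10, 1)
    tree <- ape::rtree(n, rooted = TRUE)
    n_present <- sample(1:n, 1)
    present <- sample(tree$tip.label, n_present)
    vec <- setNames(as.integer(tree$tip.label %in% present),
                    tree$tip.label)
    got <- infer_gain(vec, tree)
    want <- oracle_dollo(present, tree)
    expect_equal(got$gain_node, want$gain)
    expect_equal(got$n_losses, want$losses)
  }
})

test_that("losses are zero exactly when the gain clade is fully present", {
  set.seed(1616)
  for (k in 1:30) {
    tree <- ape::rtree(sample(4:9, 1), rooted = TRUE)
    present <- sample(tree$tip.label, sample(1:ape::Ntip(tree), 1))
    vec <- setNames(as.integer(tree$tip.label %in% present),
                    tree$tip.label)
    g <- infer_gain(vec, tree)
    below <- tree$tip.label[helper_tips_below(tree, g$gain_node)]
    expect_equal(g$n_losses == 0L, setequal(below, present))
    # every present species descends from the gain node
    expect_true(all(present %in% below))
  }
})

test_that("integration order recovers the nested Mammalia-Theria-Eutheria scenario", {
  tree <- small_tree()
  presence <- tibble::tibble(
    element = c("MER117", "AmnSINE1", "X6b_DNA"),
    platypus = c(0L, 1L, 0L), opossum = c(0L, 1L, 1L),
    mouse = c(1L, 1L, 1L), human = c(1L, 1L, 1L)
  )
  gains <- infer_gains(presence, tree)
  ord <- integration_order(gains, tree)
  expect_equal(ord$element, c("AmnSINE1", "X6b_DNA", "MER117"))
  expect_equal(ord$rank, 1:3)
  expect_equal(ord$clade_name, c("Mammalia", "Theria", "Eutheria"))
})

test_that("equal gain nodes form a tie group", {
  tree <- small_tree()
  presence <- tibble::tibble(
    element = c("A", "B"),
    platypus = c(0L, 0L), opossum = c(0L, 0L),
    mouse = c(1L, 1L), human = c(1L, 1L)
  )
  ord <- integration_order(infer_gains(presence, tree), tree)
  expect_equal(ord$rank, c(1L, 1L))
})

test_that("ranks agree with the pairwise ancestor relation on random assignments", {
  set.seed(1717)
  for (k in 1:25) {
    tree <- ape::rtree(sample(5:10, 1), rooted = TRUE)
    n_node <- ape::Ntip(tree) + tree$Nnode
    nodes <- sample.int(n_node, sample(2:5, 1), replace = TRUE)
    asg <- tibble::tibble(element = paste0("e", seq_along(nodes)),
                          gain_node = as.integer(nodes))
    ord <- integration_order(asg, tree)
    rank_of <- setNames(ord$rank, ord$element)
    # naive path-to-root comparison
    path <- function(v) {
      out <- v
      root <- ape::Ntip(tree) + 1L
      while (v != root) {
        v <- tree$edge[tree$edge[, 2] == v, 1]
        out <- c(out, v)
      }
      out
    }
    for (i in seq_along(nodes)) {
      for (j in seq_along(nodes)) {
        if (i == j) next
        a <- nodes[i]; b <- nodes[j]
        if (a != b && a %in% path(b)[-1]) {
          expect_lt(rank_of[[paste0("e", i)]], rank_of[[paste0("e", j)]])
        }
        if (a == b) {
          expect_equal(rank_of[[paste0("e", i)]],
                       rank_of[[paste0("e", j)]])
        }
      }
    }
  }
})

test_that("the true gain branch is recovered whenever each child clade retains a survivor", {
  set.seed(1919)
  tree <- ape::read.tree(
    text = "(platypus,((opossum,wallaby)Marsupialia,((mouse,rat)Rodentia,(human,chimp)Primates)Eutheria)Theria)Mammalia;"
  )
  clades <- c("Mammalia", "Theria", "Eutheria")
  n_checked <- 0L
  for (k in 1:1000) {
    clade <- sample(clades, 1)
    row <- simulate_presence_row(tree, clade, loss_prob = 0.1)
    node <- ape::Ntip(tree) + match(clade, tree$node.label)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    survivors <- vapply(kids, function(kid) {
      any(row[tree$tip.label[helper_tips_below(tree, kid)]] == 1)
    }, logical(1))
    if (!all(survivors)) next
    n_checked <- n_checked + 1L
    g <- infer_gain(row, tree, element = "sim")
    expect_identical(g$gain_node, node)
    expect_identical(g$clade_name, clade)
  }
  expect_gt(n_checked, 500)
})

test_that("presence calls from identity respect the threshold and are monotone", {
  ids <- c(human = 71.4, platypus = 65)
  expect_equal(call_presence_from_identity(ids, 60),
               c(human = 1L, platypus = 1L))
  expect_equal(call_presence_from_identity(c(a = 0, b = 0)),
               c(a = 0L, b = 0L))
  expect_error(call_presence_from_identity(c(a = 120)), "0, 100")

  set.seed(1818)
  for (k in 1:10) {
    ids <- setNames(runif(8, 0, 100), paste0("s", 1:8))
    prev <- rep(1L, 8)
    for (th in c(0, 25, 50, 75, 100)) {
      cur <- call_presence_from_identity(ids, th)
      expect_true(all(cur <= prev))
      prev <- cur
    }
  }
})
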