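test_that("evolve_copy honours its divergence contract", {
  set.seed(1919)
  s <- random_dna_str(300)
  # p = 0 is the identity
  expect_equal(evolve_copy(s, 0), s)
  # same seed, same draw
  expect_equal(evolve_copy(s, 0.3, seed = 5), evolve_copy(s, 0.3, seed = 5))
  # substitution-only evolution preserves length and stays on the alphabet
  e <- evolve_copy(s, 0.5)
  expect_equal(nchar(e), nchar(s))
  expect_false(grepl("[^ACGT]", e))
  # p = 1 substitutes every site to a different base
  e1 <- evolve_copy(s, 1)
  expect_true(all(strsplit(e1, "")[[1]] != strsplit(s, "")[[1]]))
})

test_that("recovered identity tracks the analytic expectation 100*(1-p)", {
  set.seed(2020)
  cons <- random_dna_str(400)
  ids <- vapply(1:40, function(i) {
    align_to_consensus(evolve_copy(cons, 0.2), cons,
                       strand_mode = "forward")$pct_identity
  }, numeric(1))
  se <- sd(ids) / sqrt(length(ids))
  expect_lt(abs(mean(ids) - 80), 3 * se + 1)
})

test_that("simulate_dataset writes parseable files that honour ground truth", {
  outdir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 3, genome_length = 200000L,
                           composite_spec = list(
                             members = c("AmnSINE1", "X6b_DNA", "MER117"),
                             n = 6L, gap_range = c(0L, 550L),
                             divergence = 0.27,
                             truncation = list(c(391L, 501L), NULL, NULL)
                           ),
                           insertion_specs = tibble::tibble(
                             name = c("AmnSINE1", "MER117"),
                             count = c(6L, 4L), divergence = 0.27,
                             conserved_prob = 0.8
                           ))
  sim <- simulate_dataset(cfg, outdir)
  reps <- read_repeatmasker_out(sim$paths$repeats)
  els <- read_conserved_bed(sim$paths$conserved)
  genome <- read_fasta(sim$paths$genome)
  consensi <- read_fasta(sim$paths$consensi)
  presence <- read_presence_table(sim$paths$presence)
  tree <- read_species_tree(sim$paths$tree)
  truth <- sim$truth$planted_repeats

  # .out coordinates exactly bracket each planted sequence: the planted
  # copy re-aligns to its own consensus slice at the planted span
  expect_equal(nrow(reps), nrow(truth))
  for (i in sample(which(truth$is_te), 5)) {
    seq <- substr(genome[[truth$chrom[i]]], truth$start[i] + 1,
                  truth$end[i])
    m <- align_to_consensus(seq, consensi[[truth$repeat_name[i]]])
    expect_gte(m$pct_identity, 55)
    # local alignment may trim a few diverged columns at either end
    expect_lte(abs(m$cons_begin - truth$cons_begin[i]), 30)
    expect_lte(abs(m$cons_end - truth$cons_end[i]), 30)
  }

  # composite gaps respect the configured range
  for (g in strsplit(sim$truth$true_composites$gaps, ",")) {
    expect_true(all(as.integer(g) >= 0 & as.integer(g) <= 550))
  }

  # presence honours Dollo: nothing outside the gain clade is present
  for (i in seq_len(nrow(presence))) {
    gain <- sim$truth$true_gains$clade[
      sim$truth$true_gains$element == presence$element[i]]
    node <- if (gain %in% tree$tip.label) {
      match(gain, tree$tip.label)
    } else {
      ape::Ntip(tree) + match(gain, tree$node.label)
    }
    clade <- tree$tip.label[helper_tips_below(tree, node)]
    called <- names(presence)[-1][presence[i, -1] == 1]
    expect_true(all(called %in% clade))
  }
})

test_that("screening the simulated files recovers the conserved planted TEs", {
  outdir <- withr::local_tempdir()
  sim <- simulate_dataset(simulation_config(seed = 9), outdir)
  reps <- read_repeatmasker_out(sim$paths$repeats)
  els <- read_conserved_bed(sim$paths$conserved)
  tc <- screen_te_cnes(reps, els)
  truth <- sim$truth$planted_repeats
  expected <- truth[truth$is_te & truth$conserved & truth$el_lod > 100 &
                      pmin(truth$end, truth$el_end) -
                        pmax(truth$start, truth$el_start) > 30, ]
  key <- function(x) sort(paste(x$chrom, x$start, x$end))
  # sensitivity 1.0 on the planted conserved set
  expect_true(all(key(expected) %in% key(tc)))
})

test_that("a zero-insertion config yields an empty .out and background-only BED", {
  outdir <- withr::local_tempdir()
  cfg <- simulation_config(
    seed = 4, genome_length = 100000L,
    insertion_specs = tibble::tibble(name = character(), count = integer(),
                                     divergence = numeric(),
                                     conserved_prob = numeric()),
    composite_spec = list(members = c("AmnSINE1", "X6b_DNA", "MER117"),
                          n = 0L, gap_range = c(0L, 550L),
                          divergence = 0.27,
                          truncation = list(c(391L, 501L), NULL, NULL)),
    n_simple_repeats = 0L
  )
  sim <- simulate_dataset(cfg, outdir)
  expect_equal(nrow(read_repeatmasker_out(sim$paths$repeats)), 0)
  els <- read_conserved_bed(sim$paths$conserved)
  expect_equal(nrow(els), 40)
})

test_that("a fixed seed reproduces byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- simulation_config(seed = 12, genome_length = 150000L,
                           composite_spec = list(
                             members = c("AmnSINE1", "X6b_DNA", "MER117"),
                             n = 5L, gap_range = c(0L, 550L),
                             divergence = 0.27,
                             truncation = list(c(391L, 501L), NULL, NULL)
                           ))
  s1 <- simulate_dataset(cfg, d1)
  s2 <- simulate_dataset(cfg, d2)
  for (nm in names(s1$paths)) {
    expect_equal(readLines(s1$paths[[nm]]), readLines(s2$paths[[nm]]),
                 info = nm)
  }
})

test_that("an overfull genome fails with actionable advice", {
  cfg <- simulation_config(seed = 1, genome_length = 20000L)
  expect_error(simulate_dataset(cfg, withr::local_tempdir()),
               "genome_length")
})
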