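test_that("overlap_length follows half-open interval arithmetic", {
  a <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
  expect_equal(overlap_length(a, tibble::tibble(chrom = "chr1",
                                                start = 150L, end = 250L)),
               50L)
  # abutting half-open intervals share nothing
  expect_equal(overlap_length(a, tibble::tibble(chrom = "chr1",
                                                start = 200L, end = 300L)),
               0L)
  # different chromosomes never overlap
  expect_equal(overlap_length(a, tibble::tibble(chrom = "chr2",
                                                start = 100L, end = 200L)),
               0L)
})

test_that("overlap_length equals the per-base oracle and is symmetric", {
  set.seed(101)
  a <- random_intervals(1000, max_pos = 2000, max_len = 150)
  b <- random_intervals(1000, max_pos = 2000, max_len = 150)
  got <- overlap_length(a, b)
  expect_equal(got, overlap_length(b, a))
  want <- vapply(seq_len(1000), function(i) {
    oracle_overlap_perbase(a[i, ], b[i, ])
  }, integer(1))
  expect_equal(got, want)
})

test_that("screen thresholds are strict, as printed (>30 bp, LOD >100)", {
  els <- make_elements("chr1", 1000L, 2000L, lod = 500L)
  # overlap exactly 30 bp -> excluded; 31 bp -> included
  r30 <- make_repeats("chr1", 970L, 1030L)
  r31 <- make_repeats("chr1", 970L, 1031L)
  expect_equal(nrow(screen_te_cnes(r30, els)), 0)
  expect_equal(nrow(screen_te_cnes(r31, els)), 1)
  expect_equal(screen_te_cnes(r31, els)$overlap_bp, 31L)
  # LOD exactly 100 -> excluded; 101 -> included
  r <- make_repeats("chr1", 1100L, 1300L)
  expect_equal(nrow(screen_te_cnes(r, make_elements("chr1", 1000L, 2000L,
                                                    lod = 100L))), 0)
  expect_equal(nrow(screen_te_cnes(r, make_elements("chr1", 1000L, 2000L,
                                                    lod = 101L))), 1)
})

test_that("overlap is summed across fragmented conserved blocks", {
  # two 20-bp overlaps: fails per-element mode, passes the summed default
  els <- make_elements("chr1", c(100L, 200L), c(120L, 220L), lod = 500L)
  r <- make_repeats("chr1", 90L, 230L)
  expect_equal(nrow(screen_te_cnes(r, els)), 1)
  expect_equal(screen_te_cnes(r, els)$overlap_bp, 40L)
  expect_equal(nrow(screen_te_cnes(r, els, per_element = TRUE)), 0)
})

test_that("non-TE repeats and empty inputs are handled", {
  els <- make_elements("chr1", 100L, 500L, lod = 500L)
  r <- make_repeats("chr1", 150L, 400L, name = "(TA)n",
                    class = "Simple_repeat", is_te = FALSE)
  expect_equal(nrow(screen_te_cnes(r, els)), 0)
  expect_equal(nrow(screen_te_cnes(make_repeats("chr1", integer(0),
                                                integer(0)), els)), 0)
  expect_equal(nrow(screen_te_cnes(make_repeats("chr1", 1L, 100L),
                                   els[0, ])), 0)
})

test_that("screen matches the quadratic all-pairs oracle on random instances", {
  set.seed(202)
  for (k in 1:25) {
    n <- sample(1:500, 1)
    m <- sample(1:200, 1)
    reps <- random_intervals(n, max_pos = 8000, max_len = 250)
    reps <- make_repeats(reps$chrom, reps$start, reps$end)
    reps$chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    els <- random_intervals(m, max_pos = 8000, max_len = 250)
    els <- make_elements(els$chrom, els$start, els$end,
                         lod = sample(50:300, m, replace = TRUE))
    got <- screen_te_cnes(reps, els)
    want <- oracle_screen(reps, els)
    key <- function(x) sort(paste(x$chrom, x$start, x$end))
    expect_equal(key(got), key(want))
  }
})

test_that("raising either threshold never adds a hit, and screening is idempotent", {
  set.seed(303)
  reps <- random_intervals(200, max_pos = 6000, max_len = 250)
  reps <- make_repeats(reps$chrom, reps$start, reps$end)
  els <- random_intervals(100, max_pos = 6000, max_len = 250)
  els <- make_elements(els$chrom, els$start, els$end,
                       lod = sample(50:300, 100, replace = TRUE))
  base <- screen_te_cnes(reps, els, min_overlap = 30, min_lod = 100)
  key <- function(x) paste(x$chrom, x$start, x$end)
  for (ov in c(40, 60)) {
    expect_true(all(key(screen_te_cnes(reps, els, min_overlap = ov)) %in%
                      key(base)))
  }
  for (lod in c(150, 250)) {
    expect_true(all(key(screen_te_cnes(reps, els, min_lod = lod)) %in%
                      key(base)))
  }
  again <- screen_te_cnes(base[, names(reps)], els)
  expect_equal(key(again), key(base))
})

test_that("merge_joins scores a fragmented insertion as one unit", {
  els <- make_elements("chr1", c(100L, 400L), c(120L, 420L), lod = 500L)
  # two fragments of one insertion, each overlapping 20 bp
  r <- make_repeats("chr1", c(90L, 390L), c(130L, 430L), join_id = c(7L, 7L))
  expect_equal(nrow(screen_te_cnes(r, els)), 0)
  merged <- screen_te_cnes(r, els, merge_joins = TRUE)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$overlap_bp, 40L)
  expect_equal(c(merged$start, merged$end), c(90L, 430L))
})

test_that("exclusion BED subtracts coding regions before overlap", {
  els <- make_elements("chr1", 1000L, 2000L, lod = 500L)
  r <- make_repeats("chr1", 950L, 1100L)  # 100 bp overlap
  exons <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1075L)
  expect_equal(nrow(screen_te_cnes(r, els)), 1)
  # only 25 bp of non-coding overlap remain -> excluded
  expect_equal(nrow(screen_te_cnes(r, els, exclude = exons)), 0)
})

test_that("filter_family uses case-sensitive exact-or-glob semantics", {
  t <- make_tecnes("chr1", c(0L, 500L, 1000L, 1500L),
                   c(100L, 600L, 1100L, 1600L),
                   name = c("AmnSINE1", "MER117", "MER130", "amnsine1"))
  expect_equal(filter_family(t, "AmnSINE1")$repeat_name, "AmnSINE1")
  expect_equal(filter_family(t, "*")$repeat_name, t$repeat_name)
  # single-char glob: MER11? matches MER117 but not MER130
  expect_equal(filter_family(t, "MER11?")$repeat_name, "MER117")
  # enumerated glob-match table over the fixture names
  pats <- c("MER*", "A*1", "?ER117", "Amn*")
  want <- list(c("MER117", "MER130"), "AmnSINE1", "MER117", "AmnSINE1")
  for (i in seq_along(pats)) {
    expect_equal(filter_family(t, pats[i])$repeat_name, want[[i]])
  }
})
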