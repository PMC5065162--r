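#' Overlap length between genomic intervals
#'
#' Number of bases shared by two 0-based half-open intervals: zero when the
#' intervals are on different chromosomes or merely abut. Vectorised
#' elementwise over the rows of `a` and `b` (recycled); symmetric in its
#' arguments.
#'
#' @param a,b data frames with columns `chrom`, `start`, `end`.
#' @return integer vector of overlap lengths in bp.
#' @export
overlap_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  ov <- pmax(0L, pmin(a$end[idx_a], b$end[idx_b]) -
                 pmax(a$start[idx_a], b$start[idx_b]))
  ov[a$chrom[idx_a] != b$chrom[idx_b]] <- 0L
  as.integer(ov)
}

#' Screen repeat annotations for TE-derived conserved non-coding elements
#'
#' The core extraction step: a TE annotation qualifies as a TE-derived CNE
#' when its total overlap with conserved elements whose LOD score exceeds
#' `min_lod` (strict) exceeds `min_overlap` bp (strict). Defaults are the
#' screen's published working point (>30 bp overlap, LOD >100). Strand is
#' ignored — conservation tracks are unstranded. Repeats tagged non-TE
#' (simple repeats, low complexity, satellites, structural RNAs) are
#' excluded.
#'
#' Overlap is summed over all qualifying conserved elements per repeat, so a
#' repeat split across two fragments of a conserved block still qualifies;
#' set `per_element = TRUE` to instead require a single element to exceed the
#' threshold (sensitivity analysis). Overlap is computed per RepeatMasker
#' fragment (row) by default; `merge_joins = TRUE` first merges fragments
#' sharing a `join_id` on the same chromosome and scores the insertion as a
#' unit.
#'
#' @param repeats tibble from [read_repeatmasker_out()].
#' @param elements tibble from [read_conserved_bed()].
#' @param min_overlap minimum total overlap in bp, strict (`> min_overlap`).
#' @param min_lod minimum conserved-element LOD, strict (`> min_lod`).
#' @param per_element require a single conserved element to exceed
#'   `min_overlap` instead of the per-repeat sum.
#' @param merge_joins merge RepeatMasker fragments sharing `join_id` before
#'   computing overlap.
#' @param exclude optional tibble of intervals (`chrom`, `start`, `end`),
#'   e.g. exons, subtracted from the conserved elements before overlap so
#'   that only non-coding conservation counts.
#' @return tibble of TE-derived CNEs sorted by `(chrom, start)`: the repeat
#'   columns plus `overlap_bp` (total qualifying overlap), `max_lod`
#'   (maximum LOD among overlapped qualifying elements), `element_ids`
#'   (comma-separated ids of those elements), and `cne_start`/`cne_end`
#'   (hull of the overlapped elements, used by
#'   `chain_proximal(distance_on = "elements")`).
#' @export
screen_te_cnes <- function(repeats, elements, min_overlap = 30L,
                           min_lod = 100L, per_element = FALSE,
                           merge_joins = FALSE, exclude = NULL) {
  stopifnot(min_overlap > 0, min_lod > 0)
  if ("is_te" %in% names(repeats)) {
    repeats <- repeats[repeats$is_te, , drop = FALSE]
  }
  elements <- elements[elements$lod > min_lod, , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude) > 0 && nrow(elements) > 0) {
    elements <- subtract_intervals(elements, exclude)
  }
  if (nrow(repeats) == 0 || nrow(elements) == 0) {
    return(empty_tecnes(repeats))
  }
  if (merge_joins) {
    repeats <- merge_join_fragments(repeats)
  }
  gr_rep <- GenomicRanges::GRanges(
    repeats$chrom, IRanges::IRanges(repeats$start + 1L, repeats$end)
  )
  gr_el <- GenomicRanges::GRanges(
    elements$chrom, IRanges::IRanges(elements$start + 1L, elements$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_rep, gr_el, ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(empty_tecnes(repeats))
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_rep)[qh], IRanges::ranges(gr_el)[sh]
  ))
  pairs <- tibble(
    rep_idx = qh, el_idx = sh, ov = as.integer(ov),
    lod = elements$lod[sh], element_id = elements$element_id[sh],
    el_start = elements$start[sh], el_end = elements$end[sh]
  )
  if (per_element) {
    pairs <- pairs[pairs$ov > min_overlap, , drop = FALSE]
  }
  if (nrow(pairs) == 0) {
    return(empty_tecnes(repeats))
  }
  agg <- pairs |>
    dplyr::group_by(.data$rep_idx) |>
    dplyr::summarise(
      overlap_bp = sum(.data$ov),
      max_lod = max(.data$lod),
      element_ids = paste(.data$element_id, collapse = ","),
      cne_start = min(.data$el_start),
      cne_end = max(.data$el_end),
      .groups = "drop"
    )
  if (!per_element) {
    agg <- agg[agg$overlap_bp > min_overlap, , drop = FALSE]
  } else {
    agg <- agg[agg$overlap_bp > 0L, , drop = FALSE]
  }
  out <- dplyr::bind_cols(repeats[agg$rep_idx, , drop = FALSE],
                          agg[, -1, drop = FALSE])
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

empty_tecnes <- function(repeats) {
  out <- repeats[integer(0), , drop = FALSE]
  out$overlap_bp <- integer()
  out$max_lod <- integer()
  out$element_ids <- character()
  out$cne_start <- integer()
  out$cne_end <- integer()
  out
}

# subtract exclusion intervals (e.g. exons) from conserved elements,
# carrying LOD/name metadata onto the surviving fragments
subtract_intervals <- function(elements, exclude) {
  gr_el <- GenomicRanges::GRanges(
    elements$chrom, IRanges::IRanges(elements$start + 1L, elements$end)
  )
  gr_ex <- GenomicRanges::reduce(GenomicRanges::GRanges(
    exclude$chrom, IRanges::IRanges(exclude$start + 1L, exclude$end)
  ))
  kept <- GenomicRanges::subtract(gr_el, gr_ex, ignore.strand = TRUE)
  n_frag <- S4Vectors::elementNROWS(kept)
  flat <- unlist(kept, use.names = FALSE)
  idx <- rep(seq_len(nrow(elements)), n_frag)
  tibble(
    chrom = elements$chrom[idx],
    start = GenomicRanges::start(flat) - 1L,
    end = GenomicRanges::end(flat),
    name = elements$name[idx],
    lod = elements$lod[idx],
    element_id = elements$element_id[idx]
  )
}

# collapse RepeatMasker fragments sharing a join_id on one chromosome into
# the insertion's hull; name/class/score taken from the top-scoring fragment
merge_join_fragments <- function(repeats) {
  repeats |>
    dplyr::group_by(.data$chrom, .data$join_id) |>
    dplyr::arrange(dplyr::desc(.data$sw_score), .by_group = TRUE) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      strand = dplyr::first(.data$strand),
      repeat_name = dplyr::first(.data$repeat_name),
      repeat_class = dplyr::first(.data$repeat_class),
      sw_score = max(.data$sw_score),
      pct_div = mean(.data$pct_div), pct_del = mean(.data$pct_del),
      pct_ins = mean(.data$pct_ins),
      cons_begin = min(.data$cons_begin), cons_end = max(.data$cons_end),
      cons_left = min(.data$cons_left),
      query_left = min(.data$query_left),
      overlapped = any(.data$overlapped), is_te = dplyr::first(.data$is_te),
      .groups = "drop"
    ) |>
    dplyr::relocate("chrom", "start", "end", "strand", "repeat_name",
                    "repeat_class")
}

#' Restrict TE-derived CNEs to a repeat family
#'
#' Case-sensitive exact-or-glob match (`*` any run, `?` one character) on
#' `repeat_name`, preserving row order. `filter_family(x, "*")` is the
#' identity.
#'
#' @param tecnes tibble from [screen_te_cnes()].
#' @param family_pattern exact subfamily name or glob pattern.
#' @return subset of `tecnes` in the original order.
#' @export
filter_family <- function(tecnes, family_pattern) {
  tecnes[glob_match(tecnes$repeat_name, family_pattern), , drop = FALSE]
}
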