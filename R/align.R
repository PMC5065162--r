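#' Align a genomic sub-element to its TE consensus
#'
#' Best local alignment (Smith-Waterman with affine gaps) of a locus
#' sequence against a TE consensus, reporting percent identity and the
#' matched 1-based inclusive span on the consensus — the computation behind
#' statements like "71.4% identical to nucleotide positions 391-501 of its
#' consensus". Local alignment is used deliberately: decayed TE relics often
#' match only an internal consensus slice.
#'
#' Percent identity is `100 * n_matches / n_columns` rounded half-up to one
#' decimal, where `n_columns` counts **all** alignment columns including gap
#' columns (gaps are non-matches). This is the conservative convention; set
#' `identity_denominator = "aligned-bases"` to divide by non-gap columns
#' instead, which approximates RepeatMasker's `100 - %div` accounting. `N`
#' never counts as a match, in either the score or the identity. A gap of
#' length L costs `gap_open + (L-1) * gap_extend`.
#'
#' With `strand_mode = "both"` the reverse complement of `locus_seq` is also
#' aligned and the higher-scoring orientation reported (forward wins ties);
#' `locus_begin`/`locus_end` always refer to the sequence as supplied. Ties
#' between equal-scoring alignments are broken deterministically towards
#' longer alignments, then smaller consensus coordinates.
#'
#' @param locus_seq genomic sequence of the sub-element (A/C/G/T/N string).
#' @param consensus_seq TE consensus sequence.
#' @param element_name optional TE subfamily label carried into the result.
#' @param match,mismatch,gap_open,gap_extend integer scoring parameters
#'   (defaults +2/-3/-5/-2).
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @param identity_denominator `"all-columns"` (default) or
#'   `"aligned-bases"`.
#' @return object of class `consensus_match`: list with `element_name`,
#'   `pct_identity`, `cons_begin`, `cons_end` (1-based inclusive consensus
#'   span), `locus_begin`, `locus_end` (1-based inclusive on `locus_seq`),
#'   `strand` (`"+"` or `"-"`), `score`, `n_columns`, `n_matches`,
#'   `n_gap_columns`. Use [tidy()] for a one-row tibble.
#' @seealso [identity_summary()]
#' @export
align_to_consensus <- function(locus_seq, consensus_seq, element_name = NA,
                               match = 2L, mismatch = -3L, gap_open = -5L,
                               gap_extend = -2L,
                               strand_mode = c("both", "forward"),
                               identity_denominator = c("all-columns",
                                                        "aligned-bases")) {
  strand_mode <- match.arg(strand_mode)
  identity_denominator <- match.arg(identity_denominator)
  check_dna(locus_seq, "locus_seq")
  check_dna(consensus_seq, "consensus_seq")
  fwd <- sw_align_cpp(locus_seq, consensus_seq, match, mismatch, gap_open,
                      gap_extend)
  strand <- "+"
  res <- fwd
  if (strand_mode == "both") {
    rc <- revcomp(locus_seq)
    rev <- sw_align_cpp(rc, consensus_seq, match, mismatch, gap_open,
                        gap_extend)
    if (rev$score > fwd$score) {
      res <- rev
      strand <- "-"
      # map span on the reverse complement back to the supplied sequence
      L <- nchar(locus_seq)
      res$a_begin <- L - rev$a_end + 1L
      res$a_end <- L - rev$a_begin + 1L
      res$a_begin <- max(res$a_begin, 1L)
    }
  }
  denom <- if (identity_denominator == "all-columns") {
    res$n_columns
  } else {
    res$n_columns - res$n_gap_columns
  }
  pct <- if (denom > 0) round_half_up(100 * res$n_matches / denom, 1) else 0
  structure(
    list(
      element_name = element_name,
      pct_identity = pct,
      cons_begin = res$b_begin, cons_end = res$b_end,
      locus_begin = res$a_begin, locus_end = res$a_end,
      strand = strand,
      score = res$score,
      n_columns = res$n_columns, n_matches = res$n_matches,
      n_gap_columns = res$n_gap_columns
    ),
    class = "consensus_match"
  )
}

#' @export
print.consensus_match <- function(x, ...) {
  cat("Consensus match",
      if (!is.na(x$element_name)) paste0(" (", x$element_name, ")"), "\n",
      sep = "")
  cat(sprintf("  %.1f%% identity over consensus positions %d-%d (strand %s, score %d)\n",
              x$pct_identity, x$cons_begin, x$cons_end, x$strand, x$score))
  cat(sprintf("  %d columns: %d matches, %d gap columns\n",
              x$n_columns, x$n_matches, x$n_gap_columns))
  invisible(x)
}

#' @describeIn align_to_consensus one-row tibble of the match fields.
#' @param x a `consensus_match` object.
#' @param ... unused.
#' @export
tidy.consensus_match <- function(x, ...) {
  tibble(
    element_name = x$element_name, pct_identity = x$pct_identity,
    cons_begin = x$cons_begin, cons_end = x$cons_end,
    locus_begin = x$locus_begin, locus_end = x$locus_end,
    strand = x$strand, score = x$score, n_columns = x$n_columns,
    n_matches = x$n_matches, n_gap_columns = x$n_gap_columns
  )
}

#' Consensus coverage of an alignment
#'
#' Distinguishes partial-consensus matches (a relic matching an internal
#' consensus slice) from effectively full-length ones: coverage is the
#' matched consensus span divided by the consensus length, and the match is
#' flagged `full_length` when coverage reaches `full_length_min`.
#'
#' @param match a `consensus_match` from [align_to_consensus()].
#' @param consensus_len length of the consensus sequence in nt.
#' @param full_length_min coverage at or above which a match counts as
#'   full-length (default 0.9).
#' @return one-row tibble: `element_name`, `consensus_coverage`,
#'   `full_length`.
#' @export
identity_summary <- function(match, consensus_len, full_length_min = 0.9) {
  stopifnot(inherits(match, "consensus_match"))
  if (consensus_len < match$cons_end) {
    stop("consensus_len (", consensus_len, ") shorter than matched span end (",
         match$cons_end, ")", call. = FALSE)
  }
  cov <- (match$cons_end - match$cons_begin + 1) / consensus_len
  tibble(
    element_name = match$element_name,
    consensus_coverage = cov,
    full_length = cov >= full_length_min
  )
}

#' Align every locus member to its consensus
#'
#' Pipeline convenience: for each TE-derived CNE in the member rows of
#' `loci`, extracts its genomic sequence and aligns it to the consensus of
#' its subfamily (matched by `repeat_name` against the names of
#' `consensus_lib`). Members without a consensus in the library are skipped.
#'
#' @param loci tibble from [chain_proximal()].
#' @param genome named character vector of chromosome sequences (from
#'   [read_fasta()]).
#' @param consensus_lib named character vector of TE consensus sequences.
#' @param ... passed to [align_to_consensus()].
#' @return tibble with one row per aligned member: `locus_id`, `chrom`,
#'   `start`, `end`, `repeat_name`, the [tidy()] consensus-match fields, and
#'   `consensus_coverage`/`full_length` from [identity_summary()].
#' @export
align_loci <- function(loci, genome, consensus_lib, ...) {
  rows <- list()
  for (li in seq_len(nrow(loci))) {
    m <- loci$members[[li]]
    for (mi in seq_len(nrow(m))) {
      nm <- m$repeat_name[mi]
      if (!nm %in% names(consensus_lib)) next
      chrom <- m$chrom[mi]
      if (!chrom %in% names(genome)) {
        stop("chromosome '", chrom, "' not in genome FASTA", call. = FALSE)
      }
      seq <- substr(genome[[chrom]], m$start[mi] + 1L, m$end[mi])
      match <- align_to_consensus(seq, consensus_lib[[nm]],
                                  element_name = nm, ...)
      row <- tidy(match)
      row$locus_id <- loci$locus_id[li]
      row$chrom <- chrom
      row$start <- m$start[mi]
      row$end <- m$end[mi]
      cov <- identity_summary(match, nchar(consensus_lib[[nm]]))
      row$consensus_coverage <- cov$consensus_coverage
      row$full_length <- cov$full_length
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      element_name = character(), pct_identity = numeric(),
      cons_begin = integer(), cons_end = integer(),
      locus_begin = integer(), locus_end = integer(), strand = character(),
      score = integer(), n_columns = integer(), n_matches = integer(),
      n_gap_columns = integer(), locus_id = integer(), chrom = character(),
      start = integer(), end = integer(), consensus_coverage = numeric(),
      full_length = logical()
    ))
  }
  dplyr::bind_rows(rows) |>
    dplyr::relocate("locus_id", "chrom", "start", "end")
}
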