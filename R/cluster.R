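#' Chain proximal TE-derived CNEs into composite candidate loci
#'
#' Partitions TE-derived CNEs into candidate loci by single-linkage chaining:
#' two records belong to one locus when the gap between their repeat
#' intervals — `max(0, next_start - prev_end)` on the same chromosome — is
#' strictly below `max_gap` bp. Overlapping repeats have gap 0. The default
#' 600 bp window is the screen's published proximity threshold (`<600 bp`,
#' strict). Because linkage is transitive, a locus may span more than
#' `max_gap` overall — the pattern of interest is an ordered run of distinct
#' TEs inside one conserved region, which a pairwise-only rule could split.
#'
#' Every input row lands in exactly one locus; singletons are retained
#' (`is_composite = FALSE`) so that companion statistics can count
#' unaccompanied focal copies.
#'
#' @param tecnes tibble from [screen_te_cnes()].
#' @param max_gap maximum inter-repeat gap in bp, strict (`gap < max_gap`).
#' @param distance_on measure gaps between the repeat intervals (default) or
#'   between the hulls of the conserved elements they overlap
#'   (`"elements"`; requires the `cne_start`/`cne_end` columns).
#' @return tibble with one row per locus: `locus_id`, `chrom`, `start`,
#'   `end` (hull of member repeats), `n_members`, `n_families` (distinct
#'   repeat names), `is_composite` (`n_members >= 2`), `member_names`
#'   (comma-separated, in genomic order), `gaps` (comma-separated
#'   consecutive inter-member gaps in bp, `n_members - 1` values), and a
#'   `members` list column holding each locus's member rows.
#' @export
chain_proximal <- function(tecnes, max_gap = 600L,
                           distance_on = c("repeats", "elements")) {
  distance_on <- match.arg(distance_on)
  stopifnot(max_gap > 0)
  if (nrow(tecnes) == 0) {
    return(tibble(
      locus_id = integer(), chrom = character(), start = integer(),
      end = integer(), n_members = integer(), n_families = integer(),
      is_composite = logical(), member_names = character(),
      gaps = character(), members = list()
    ))
  }
  x <- tecnes
  if (distance_on == "elements") {
    if (!all(c("cne_start", "cne_end") %in% names(x))) {
      stop("distance_on = \"elements\" needs cne_start/cne_end columns",
           call. = FALSE)
    }
    x$.d_start <- x$cne_start
    x$.d_end <- x$cne_end
  } else {
    x$.d_start <- x$start
    x$.d_end <- x$end
  }
  x <- dplyr::arrange(x, .data$chrom, .data$.d_start, .data$.d_end)
  # single-linkage over sorted intervals: a new locus starts when the gap to
  # the running max end reaches max_gap (strict '<' chains)
  new_chrom <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)])
  locus <- integer(nrow(x))
  cur <- 0L
  max_end <- -Inf
  for (i in seq_len(nrow(x))) {
    gap <- x$.d_start[i] - max_end
    if (new_chrom[i] || gap >= max_gap) {
      cur <- cur + 1L
      max_end <- x$.d_end[i]
    } else {
      max_end <- max(max_end, x$.d_end[i])
    }
    locus[i] <- cur
  }
  x$.locus <- locus
  x |>
    dplyr::group_by(.data$.locus) |>
    dplyr::group_map(function(g, key) {
      g <- dplyr::arrange(g, .data$start, .data$end)
      gaps <- if (nrow(g) > 1) {
        pmax(0L, g$start[-1] - g$end[-nrow(g)])
      } else {
        integer(0)
      }
      tibble(
        locus_id = key$.locus,
        chrom = g$chrom[1],
        start = min(g$start),
        end = max(g$end),
        n_members = nrow(g),
        n_families = dplyr::n_distinct(g$repeat_name),
        is_composite = nrow(g) >= 2L,
        member_names = paste(g$repeat_name, collapse = ","),
        gaps = paste(gaps, collapse = ","),
        members = list(g[, setdiff(names(g), c(".d_start", ".d_end")),
                         drop = FALSE])
      )
    }) |>
    dplyr::bind_rows()
}

#' Companion statistics for a focal TE family
#'
#' Summarises, over a set of chained loci, how often conserved copies of a
#' focal TE family are accompanied by conserved copies of *other* TE
#' families in the same locus — the headline "what fraction of focal CNEs
#' sit in a composite" number. Two fragments of the same subfamily never
#' count as companions: a companion must carry a different `repeat_name`.
#'
#' @param loci tibble from [chain_proximal()].
#' @param focal_family exact subfamily name or glob over `repeat_name`.
#' @return object of class `companion_stats`: a list with `n_focal` (focal
#'   family TE-CNEs), `n_accompanied` (those whose locus contains a member
#'   of a different family), `pct_accompanied` (percent, rounded half-up to
#'   1 decimal; `NA` when `n_focal == 0`), `focal_family`, and `companions`,
#'   a tibble counting companion subfamilies/classes across accompanied
#'   loci. Use [glance()] / [tidy()] for tabular access.
#' @export
companion_stats <- function(loci, focal_family) {
  stopifnot(nzchar(focal_family))
  n_focal <- 0L
  n_accompanied <- 0L
  companions <- list()
  for (m in loci$members) {
    focal <- glob_match(m$repeat_name, focal_family)
    if (!any(focal)) next
    n_focal <- n_focal + sum(focal)
    # companions: members whose name differs from every focal member's name
    comp <- m[!m$repeat_name %in% m$repeat_name[focal], , drop = FALSE]
    if (nrow(comp) > 0) {
      n_accompanied <- n_accompanied + sum(focal)
      companions[[length(companions) + 1L]] <-
        comp[, c("repeat_name", "repeat_class"), drop = FALSE]
    }
  }
  comp_tbl <- if (length(companions) > 0) {
    dplyr::bind_rows(companions) |>
      dplyr::count(.data$repeat_class, .data$repeat_name, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n))
  } else {
    tibble(repeat_class = character(), repeat_name = character(),
           n = integer())
  }
  structure(
    list(
      focal_family = focal_family,
      n_focal = n_focal,
      n_accompanied = n_accompanied,
      pct_accompanied = if (n_focal > 0) {
        round_half_up(100 * n_accompanied / n_focal, 1)
      } else {
        NA_real_
      },
      companions = comp_tbl
    ),
    class = "companion_stats"
  )
}

#' @export
print.companion_stats <- function(x, ...) {
  cat("Companion statistics for focal family '", x$focal_family, "'\n",
      sep = "")
  cat("  focal TE-CNEs:      ", x$n_focal, "\n", sep = "")
  cat("  accompanied:        ", x$n_accompanied,
      if (!is.na(x$pct_accompanied)) {
        paste0(" (", format(x$pct_accompanied, nsmall = 1), "%)")
      } else {
        ""
      }, "\n", sep = "")
  if (nrow(x$companions) > 0) {
    cat("  companion families: ",
        paste(head(x$companions$repeat_name, 6), collapse = ", "),
        if (nrow(x$companions) > 6) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn companion_stats one-row summary tibble (`n_focal`,
#'   `n_accompanied`, `pct_accompanied`).
#' @param x a `companion_stats` object.
#' @param ... unused.
#' @export
glance.companion_stats <- function(x, ...) {
  tibble(
    focal_family = x$focal_family,
    n_focal = x$n_focal,
    n_accompanied = x$n_accompanied,
    pct_accompanied = x$pct_accompanied
  )
}

#' @describeIn companion_stats companion subfamily breakdown as a tibble.
#' @export
tidy.companion_stats <- function(x, ...) {
  x$companions
}
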