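#' Read a RepeatMasker `.out` annotation file
#'
#' Parses the standard whitespace-delimited RepeatMasker `.out` layout (three
#' header lines, then one row per repeat fragment) into a tidy tibble of
#' repeat annotations. Query coordinates are converted from RepeatMasker's
#' 1-based inclusive convention to the package-wide 0-based half-open
#' convention, and the strand-dependent consensus column order is normalised
#' at parse time: for `C` (minus-strand) hits the file stores
#' `(left) end begin`, which is reordered so that `cons_begin <= cons_end`
#' for every row and downstream code never sees strand-dependent semantics.
#'
#' Rows whose class is not a transposable element (`Simple_repeat`,
#' `Low_complexity`, satellites, structural RNAs) are parsed but tagged
#' `is_te = FALSE`; [screen_te_cnes()] excludes them by default. Rows flagged
#' `*` (overlapped by a higher-scoring hit) are retained with
#' `overlapped = TRUE`.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return A tibble with one row per repeat fragment and columns `chrom`,
#'   `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`),
#'   `repeat_name`, `repeat_class`, `sw_score`, `pct_div`, `pct_del`,
#'   `pct_ins`, `cons_begin`, `cons_end` (1-based inclusive span on the
#'   consensus), `cons_left`, `query_left`, `join_id` (fragments of one
#'   insertion share it), `overlapped`, `is_te`.
#' @seealso [write_repeatmasker_out()]
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  is_data <- grepl("^\\s*\\d", lines)
  first <- which(is_data)[1]
  if (is.na(first)) {
    return(empty_repeats())
  }
  data_lines <- lines[seq(first, length(lines))]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  rows <- lapply(seq_along(data_lines), function(i) {
    f <- strsplit(trimws(data_lines[[i]]), "\\s+")[[1]]
    if (!(length(f) %in% c(15L, 16L))) {
      stop("line ", first + i - 1, ": expected 15 or 16 fields, found ",
           length(f), call. = FALSE)
    }
    num <- function(x, field) {
      v <- suppressWarnings(as.numeric(x))
      if (is.na(v)) {
        stop("line ", first + i - 1, ": non-numeric ", field, " '", x, "'",
             call. = FALSE)
      }
      v
    }
    unparen <- function(x) sub("^\\((.*)\\)$", "\\1", x)
    strand <- f[9]
    if (!strand %in% c("+", "C")) {
      stop("line ", first + i - 1, ": strand must be '+' or 'C', found '",
           strand, "'", call. = FALSE)
    }
    if (strand == "+") {
      cons_begin <- num(f[12], "consensus begin")
      cons_end <- num(f[13], "consensus end")
      cons_left <- num(unparen(f[14]), "consensus left")
    } else {
      # C strand stores (left) end begin; normalise so begin <= end
      cons_left <- num(unparen(f[12]), "consensus left")
      cons_end <- num(f[13], "consensus end")
      cons_begin <- num(f[14], "consensus begin")
    }
    tibble(
      chrom = f[5],
      start = as.integer(num(f[6], "query begin")) - 1L,
      end = as.integer(num(f[7], "query end")),
      strand = if (strand == "C") "-" else "+",
      repeat_name = f[10],
      repeat_class = f[11],
      sw_score = as.integer(num(f[1], "score")),
      pct_div = num(f[2], "divergence"),
      pct_del = num(f[3], "deletion"),
      pct_ins = num(f[4], "insertion"),
      cons_begin = as.integer(cons_begin),
      cons_end = as.integer(cons_end),
      cons_left = as.integer(cons_left),
      query_left = as.integer(num(unparen(f[8]), "query left")),
      join_id = as.integer(num(f[15], "join ID")),
      overlapped = length(f) == 16L && f[16] == "*"
    )
  })
  out <- dplyr::bind_rows(rows)
  bad <- out$start < 0 | out$end <= out$start
  if (any(bad)) {
    stop("line ", first + which(bad)[1] - 1,
         ": query end must exceed query begin", call. = FALSE)
  }
  out$is_te <- is_te_class(out$repeat_class)
  out
}

# class strings that are annotation noise, not transposable elements
is_te_class <- function(repeat_class) {
  non_te <- "^(Simple_repeat|Low_complexity|Satellite|rRNA|tRNA|snRNA|scRNA|srpRNA|RNA)"
  !grepl(non_te, repeat_class)
}

empty_repeats <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), repeat_name = character(),
    repeat_class = character(), sw_score = integer(), pct_div = numeric(),
    pct_del = numeric(), pct_ins = numeric(), cons_begin = integer(),
    cons_end = integer(), cons_left = integer(), query_left = integer(),
    join_id = integer(), overlapped = logical(), is_te = logical()
  )
}

#' Write repeat annotations as a RepeatMasker `.out` file
#'
#' Inverse of [read_repeatmasker_out()]: emits the standard three header
#' lines and one row per annotation, converting coordinates back to 1-based
#' inclusive and restoring the strand-dependent consensus column order
#' (`begin end (left)` on `+`, `(left) end begin` on `C`).
#'
#' @param repeats tibble as returned by [read_repeatmasker_out()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  hdr <- c(
    "   SW  perc perc perc  query     position in query     matching repeat       position in repeat",
    "score  div. del. ins.  sequence  begin  end    (left)  repeat   class/family begin  end  (left)  ID",
    ""
  )
  fmt_row <- function(r) {
    if (r$strand == "+") {
      cons <- c(r$cons_begin, r$cons_end, sprintf("(%d)", r$cons_left))
      strand <- "+"
    } else {
      cons <- c(sprintf("(%d)", r$cons_left), r$cons_end, r$cons_begin)
      strand <- "C"
    }
    paste(
      r$sw_score, sprintf("%.1f", r$pct_div), sprintf("%.1f", r$pct_del),
      sprintf("%.1f", r$pct_ins), r$chrom, r$start + 1L, r$end,
      sprintf("(%d)", r$query_left), strand, r$repeat_name, r$repeat_class,
      cons[1], cons[2], cons[3], r$join_id,
      if (isTRUE(r$overlapped)) "*" else NULL
    )
  }
  body <- vapply(seq_len(nrow(repeats)), function(i) fmt_row(repeats[i, ]),
                 character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
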