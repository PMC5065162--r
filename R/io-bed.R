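#' Read a conserved-element track (BED with LOD scores)
#'
#' Reads a phastCons-style conserved-element track: BED intervals whose name
#' field carries the log-odds conservation score as `lod=N` (the UCSC
#' dialect). When the name field lacks `lod=`, the BED score column is used
#' as a fallback; note the BED score is capped at 1000 by the UCSC dialect,
#' so `lod=` takes precedence whenever present. No LOD filtering happens
#' here — thresholds are applied by [screen_te_cnes()].
#'
#' @param path path to a BED file with at least 4 columns
#'   (`chrom start end name [score ...]`).
#' @return A tibble sorted by `(chrom, start)` with columns `chrom`, `start`,
#'   `end` (0-based half-open, as in BED), `name` (raw name field), `lod`
#'   (integer), and `element_id` (`"chrom:start-end"`, a stable identifier
#'   referenced by screen output). Records with `end <= start` are dropped
#'   with a warning.
#' @seealso [write_conserved_bed()]
#' @export
read_conserved_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), lod = integer(),
                  element_id = character()))
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 4) {
      stop("line ", i, ": BED record needs at least 4 columns", call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop("line ", i, ": non-numeric coordinate", call. = FALSE)
    }
    m <- regmatches(f[4], regexpr("lod=-?\\d+", f[4]))
    if (length(m) == 1) {
      lod <- as.integer(sub("lod=", "", m))
    } else if (length(f) >= 5) {
      lod <- suppressWarnings(as.integer(f[5]))
      if (is.na(lod)) stop("line ", i, ": non-numeric score column", call. = FALSE)
    } else {
      stop("line ", i, ": no 'lod=' in name field and no score column",
           call. = FALSE)
    }
    tibble(chrom = f[1], start = start, end = end, name = f[4], lod = lod)
  })
  out <- dplyr::bind_rows(rows)
  bad <- out$end <= out$start
  if (any(bad)) {
    warning(sum(bad), " record(s) with end <= start rejected", call. = FALSE)
    out <- out[!bad, ]
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end)
  out$element_id <- paste0(out$chrom, ":", out$start, "-", out$end)
  out
}

#' Write a conserved-element track as BED5
#'
#' Inverse of [read_conserved_bed()]: emits `chrom start end lod=N score`,
#' with the score column capped at 1000 per the UCSC BED dialect (the full
#' LOD survives in the name field).
#'
#' @param elements tibble as returned by [read_conserved_bed()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_conserved_bed <- function(elements, path) {
  lines <- sprintf("%s\t%d\t%d\tlod=%d\t%d", elements$chrom, elements$start,
                   elements$end, elements$lod, pmin(elements$lod, 1000L))
  writeLines(lines, path)
  invisible(path)
}
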