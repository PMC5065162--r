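#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that returns plain
#' uppercase character strings named by the first token of each header and
#' validates the alphabet against `{A,C,G,T,N}`.
#'
#' @param path path to an uncompressed FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  for (nm in names(seqs)) check_dna(seqs[[nm]], paste0("sequence '", nm, "'"))
  seqs
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L
  )
  invisible(path)
}

#' Read a rooted species tree from a newick file
#'
#' Wraps [ape::read.tree()] with the validity checks the phylogenetic stage
#' relies on: unique leaf labels and a rooted topology. Internal node labels
#' (clade names such as `Mammalia`, `Theria`, `Eutheria`) are preserved and
#' used to name gain branches.
#'
#' @param path path to a newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_species_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    dup <- tree$tip.label[duplicated(tree$tip.label)][1]
    stop("duplicate leaf label '", dup, "' in species tree", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    stop("species tree must be rooted", call. = FALSE)
  }
  tree
}

#' Read an ortholog presence/absence matrix
#'
#' Reads a TSV whose first column names the elements and whose remaining
#' columns (one per species) hold 0/1 ortholog presence calls.
#'
#' @param path path to the TSV file (header row of species names).
#' @return tibble with column `element` followed by one integer 0/1 column
#'   per species; every element row has at least one call.
#' @seealso [write_presence_table()], [call_presence_from_identity()]
#' @export
read_presence_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("presence table is empty: needs >=1 element row and >=1 species column",
         call. = FALSE)
  }
  names(df)[1] <- "element"
  sp <- names(df)[-1]
  if (anyDuplicated(sp)) {
    stop("duplicate species column '", sp[duplicated(sp)][1], "'", call. = FALSE)
  }
  for (s in sp) {
    v <- df[[s]]
    if (!all(v %in% c(0L, 1L))) {
      stop("presence values must be 0 or 1; column '", s, "' has '",
           v[!v %in% c(0L, 1L)][1], "'", call. = FALSE)
    }
    df[[s]] <- as.integer(v)
  }
  as_tibble(df)
}

#' Write an ortholog presence/absence matrix
#'
#' @param presence tibble as returned by [read_presence_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_presence_table <- function(presence, path) {
  utils::write.table(presence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write package result tables (TSV with a commented header)
#'
#' Result tables (`tecnes.tsv`, `loci.tsv`, `gains.tsv`, ...) are TSV files
#' whose first line is a `#`-prefixed header naming the columns, so they can
#' be fed to standard genome-arithmetic tools that skip comment lines.
#'
#' @param df data frame to write (list columns are not supported; collapse
#'   them first).
#' @param path file path.
#' @return `write_coopte_tsv()` returns `path` invisibly;
#'   `read_coopte_tsv()` returns a tibble.
#' @export
write_coopte_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_coopte_tsv
#' @export
read_coopte_tsv <- function(path) {
  lines <- readLines(path)
  cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(lines) <= 1) {
    return(as_tibble(setNames(rep(list(character()), length(cols)), cols)))
  }
  df <- utils::read.delim(path, header = FALSE, skip = 1, col.names = cols,
                          stringsAsFactors = FALSE)
  as_tibble(df)
}
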