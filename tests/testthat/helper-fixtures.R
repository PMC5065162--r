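# programmatic fixtures: tables and small files built in code at test time

make_repeats <- function(chrom, start, end, name = "AmnSINE1",
                         class = "SINE/Deu", is_te = TRUE, join_id = NULL,
                         strand = "+") {
  n <- length(start)
  tibble::tibble(
    chrom = rep_len(chrom, n), start = as.integer(start),
    end = as.integer(end), strand = rep_len(strand, n),
    repeat_name = rep_len(name, n), repeat_class = rep_len(class, n),
    sw_score = 500L, pct_div = 20, pct_del = 1, pct_ins = 1,
    cons_begin = 1L, cons_end = as.integer(end - start),
    cons_left = 0L, query_left = 0L,
    join_id = if (is.null(join_id)) seq_len(n) else as.integer(join_id),
    overlapped = FALSE, is_te = rep_len(is_te, n)
  )
}

make_elements <- function(chrom, start, end, lod = 500) {
  n <- length(start)
  out <- tibble::tibble(
    chrom = rep_len(chrom, n), start = as.integer(start),
    end = as.integer(end), name = sprintf("lod=%d", rep_len(lod, n)),
    lod = as.integer(rep_len(lod, n))
  )
  out$element_id <- paste0(out$chrom, ":", out$start, "-", out$end)
  out
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 10000L, max_len = 300L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE)
  )
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# ten-row RepeatMasker .out fixture exercising +/C strands, non-TE classes
# and the overlapped-hit flag
write_rmsk_fixture <- function(path) {
  lines <- c(
    "   SW  perc perc perc  query     position in query     matching repeat       position in repeat",
    "score  div. del. ins.  sequence  begin  end    (left)  repeat   class/family begin  end  (left)  ID",
    "",
    "  463   1.3  0.6  1.7  chr1      101    200  (99800) +  (TAACCC)n  Simple_repeat   1  100  (0)  1",
    " 2271  25.1  4.4  2.0  chr1      501    980  (99020) +  AmnSINE1   SINE/Deu      391  501  (49) 2",
    " 1243  28.2  2.1  3.3  chr1     1101   1520  (98480) C  X6b_DNA    DNA           (0)  501  391  3",
    "  950  22.0  1.0  0.5  chr1     2001   2310  (97690) +  MER117     DNA/hAT       1    310  (0)  4",
    "  120  10.5  0.0  0.0  chr1     3001   3060  (96940) +  GA-rich    Low_complexity 1    60  (0)  5",
    "  700  19.9  2.2  1.1  chr2      301    700  (99300) C  AmnSINE1   SINE/Deu      (49) 501  391  6",
    "  655  30.0  5.0  4.0  chr2     1501   1830  (98170) +  MER117     DNA/hAT       1    310  (0)  7 *",
    "  820  18.1  0.9  1.4  chr2     2501   2940  (97060) +  X6b_DNA    DNA           14   420  (0)  8",
    "  300  12.0  0.0  0.0  chr2     4001   4100  (95900) +  ALR/Alpha  Satellite     1    100  (0)  9",
    " 1500  21.7  1.8  2.5  chr2     5001   5460  (94540) C  AmnSINE1   SINE/Deu      (0)  460  1    10"
  )
  writeLines(lines, path)
  path
}

small_tree <- function() {
  ape::read.tree(text = "(platypus,(opossum,(mouse,human)Eutheria)Theria)Mammalia;")
}

# minimal tecne-like table for clustering tests
make_tecnes <- function(chrom, start, end, name = "AmnSINE1",
                        class = "SINE/Deu") {
  t <- make_repeats(chrom, start, end, name = name, class = class)
  t$overlap_bp <- as.integer(t$end - t$start)
  t$max_lod <- 500L
  t$element_ids <- paste0(t$chrom, ":", t$start, "-", t$end)
  t$cne_start <- t$start
  t$cne_end <- t$end
  t
}
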