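#' Configuration for the synthetic dataset generator
#'
#' Bundles every knob of [simulate_dataset()] with defaults that emulate the
#' composite-enhancer discovery scenario end to end: three TE consensus
#' families whose integrations are nested across Mammalia, Theria and
#' Eutheria; composite insertions of all three side-by-side with sub-600-bp
#' gaps; standalone insertions; a conservation track whose "conserved" and
#' "background" LOD distributions straddle the LOD-100 screening threshold;
#' and a presence matrix generated by a single gain on a known branch with
#' per-edge losses. The default per-site divergence of 0.27 places recovered
#' consensus identities near the low-70s-percent level typical of anciently
#' exapted TE relics.
#'
#' Planted units are separated by at least `min_spacing` bp (default
#' 1500, well above the 600 bp chaining window) so that distinct planted
#' units never chain into accidental composites and ground truth stays
#' unambiguous.
#'
#' @param seed integer RNG seed; every downstream draw derives from it.
#' @param genome_length total genome size in bp, split evenly over
#'   `n_chroms`.
#' @param n_chroms number of chromosomes.
#' @param consensus_specs tibble with columns `name`, `length` (nt),
#'   `gain_clade` (internal node label of `species_tree` where the family's
#'   orthologs arose).
#' @param insertion_specs tibble of standalone insertions: `name`, `count`,
#'   `divergence` (per-site substitution probability), `conserved_prob`
#'   (probability a copy is covered by a conserved element).
#' @param composite_spec list describing composite insertions: `members`
#'   (ordered TE names), `n` (number of composites), `gap_range`
#'   (inclusive bp range for inter-member gaps), `divergence`, `truncation`
#'   (list of `c(begin, end)` consensus slices or `NULL` for full length,
#'   one per member).
#' @param n_simple_repeats simple-repeat (non-TE) annotations planted to
#'   exercise the screen's non-TE exclusion; each gets a conserved element.
#' @param n_background_elements conserved-track records placed at random
#'   with background LOD.
#' @param lod_conserved,lod_background `c(meanlog, sdlog)` of the lognormal
#'   LOD distributions for elements covering conserved TEs vs background.
#' @param conserved_flank inclusive bp range by which a conserved element
#'   extends beyond the TE it covers.
#' @param min_spacing minimum bp between consecutive planted units.
#' @param indel_rate per-site indel probability used by [evolve_copy()].
#' @param species_tree newick string, rooted, with labelled internal nodes.
#' @param loss_prob per-edge probability that an ortholog lineage below the
#'   gain branch loses the element (subtree-wide).
#' @return a `coopte_sim_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    genome_length = 400000L,
    n_chroms = 2L,
    consensus_specs = tibble(
      name = c("AmnSINE1", "X6b_DNA", "MER117"),
      length = c(550L, 420L, 310L),
      gain_clade = c("Mammalia", "Theria", "Eutheria")
    ),
    insertion_specs = tibble(
      name = c("AmnSINE1", "X6b_DNA", "MER117"),
      count = c(20L, 8L, 8L),
      divergence = 0.27,
      conserved_prob = 0.8
    ),
    composite_spec = list(
      members = c("AmnSINE1", "X6b_DNA", "MER117"),
      n = 24L,
      gap_range = c(0L, 550L),
      divergence = 0.27,
      truncation = list(c(391L, 501L), NULL, NULL)
    ),
    n_simple_repeats = 4L,
    n_background_elements = 40L,
    lod_conserved = c(log(300), 0.3),
    lod_background = c(log(50), 0.4),
    conserved_flank = c(10L, 60L),
    min_spacing = 1500L,
    indel_rate = 0,
    species_tree = "(platypus,((opossum,wallaby)Marsupialia,((mouse,rat)Rodentia,(human,chimp)Primates)Eutheria)Theria)Mammalia;",
    loss_prob = 0.1) {
  cfg <- list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_chroms = as.integer(n_chroms), consensus_specs = consensus_specs,
    insertion_specs = insertion_specs, composite_spec = composite_spec,
    n_simple_repeats = as.integer(n_simple_repeats),
    n_background_elements = as.integer(n_background_elements),
    lod_conserved = lod_conserved, lod_background = lod_background,
    conserved_flank = as.integer(conserved_flank),
    min_spacing = as.integer(min_spacing), indel_rate = indel_rate,
    species_tree = species_tree, loss_prob = loss_prob
  )
  stopifnot(
    cfg$genome_length > 0, cfg$n_chroms > 0,
    all(cfg$insertion_specs$divergence >= 0 &
          cfg$insertion_specs$divergence <= 1),
    cfg$composite_spec$divergence >= 0, cfg$composite_spec$divergence <= 1,
    cfg$loss_prob >= 0, cfg$loss_prob <= 1,
    cfg$indel_rate >= 0, cfg$indel_rate <= 1
  )
  structure(cfg, class = "coopte_sim_config")
}

#' Evolve a TE copy away from its consensus
#'
#' Applies the generator's divergence model to a sequence: every site is
#' substituted with probability `divergence_p` to a uniformly chosen
#' different base; optionally, single-base indels occur at `indel_rate` per
#' site (deletion or random insertion, equally likely). Substitution-only
#' evolution at probability p leaves an expected `100 * (1 - p)` percent
#' identity to the original, which is the calibration the aligner is tested
#' against.
#'
#' @param consensus_seq DNA string to evolve.
#' @param divergence_p per-site substitution probability in \[0, 1\].
#' @param indel_rate per-site indel probability (default 0).
#' @param seed optional integer seed for a reproducible draw; when `NULL`
#'   the current RNG state is used.
#' @return the evolved DNA string.
#' @export
evolve_copy <- function(consensus_seq, divergence_p, indel_rate = 0,
                        seed = NULL) {
  stopifnot(divergence_p >= 0, divergence_p <= 1)
  check_dna(consensus_seq, "consensus_seq")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(consensus_seq, "", fixed = TRUE)[[1]]
  sub_mask <- runif(length(chars)) < divergence_p
  if (any(sub_mask)) {
    chars[sub_mask] <- vapply(chars[sub_mask], function(b) {
      sample(setdiff(bases, b), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  if (indel_rate > 0) {
    out <- character(0)
    for (ch in chars) {
      if (runif(1) < indel_rate) {
        if (runif(1) < 0.5) next                       # deletion
        out <- c(out, sample(bases, 1), ch)            # insertion before
      } else {
        out <- c(out, ch)
      }
    }
    chars <- out
  }
  paste(chars, collapse = "")
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Writes every input the pipeline consumes — genome FASTA, consensus-library
#' FASTA, RepeatMasker `.out`, conserved-element BED, species tree newick and
#' ortholog presence TSV — into `outdir` using the real on-disk formats, and
#' returns the ground truth needed to verify recovery. Files are
#' byte-identical across runs with the same config.
#'
#' The generative model, stage by stage: random uniform background DNA;
#' planted TE copies are consensus slices evolved by [evolve_copy()] and
#' placed without overlap and with `min_spacing` separation; composite units
#' place the configured ordered TE tuple with gaps drawn from `gap_range`;
#' the conservation track emits one element covering each conserved planted
#' TE (LOD from the "conserved" lognormal, around 300 by default) plus
#' random background elements (LOD around 50), so both screening thresholds
#' are exercised; presence rows arise from a single gain on the configured
#' clade with independent per-edge subtree losses (never outside the gain
#' clade, honouring the Dollo premise).
#'
#' @param config a [simulation_config()] object.
#' @param outdir directory for the generated files (created if needed).
#' @return invisibly, a list with `paths` (named file paths), `truth`
#'   (list of tibbles: `planted_repeats` including each copy's covering
#'   conserved element when conserved, `true_composites`, `true_gains`),
#'   and `config`.
#' @export
simulate_dataset <- function(config = simulation_config(), outdir) {
  stopifnot(inherits(config, "coopte_sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  # consensus library
  consensi <- setNames(
    vapply(config$consensus_specs$length, random_dna, character(1)),
    config$consensus_specs$name
  )
  cons_len <- setNames(config$consensus_specs$length,
                       config$consensus_specs$name)

  # --- build planted units -------------------------------------------------
  # each unit: sequence block + member table (offsets within the block)
  units <- list()
  make_member <- function(name, divergence, trunc, conserved) {
    begin <- if (is.null(trunc)) 1L else trunc[1]
    end <- if (is.null(trunc)) cons_len[[name]] else trunc[2]
    slice <- substr(consensi[[name]], begin, end)
    evolved <- evolve_copy(slice, divergence, config$indel_rate)
    strand <- sample(c("+", "-"), 1)
    planted <- if (strand == "-") revcomp(evolved) else evolved
    tibble(
      repeat_name = name, seq = planted, strand = strand,
      cons_begin = begin, cons_end = end, divergence = divergence,
      conserved = conserved
    )
  }
  cs <- config$composite_spec
  for (k in seq_len(cs$n)) {
    members <- purrr::map2_dfr(cs$members, cs$truncation, function(nm, tr) {
      make_member(nm, cs$divergence, tr, conserved = TRUE)
    })
    gaps <- sample(seq(cs$gap_range[1], cs$gap_range[2]),
                   nrow(members) - 1, replace = TRUE)
    offs <- integer(nrow(members))
    cur <- 0L
    block_parts <- character(0)
    for (i in seq_len(nrow(members))) {
      offs[i] <- cur
      block_parts <- c(block_parts, members$seq[i])
      cur <- cur + nchar(members$seq[i])
      if (i < nrow(members)) {
        if (gaps[i] > 0) block_parts <- c(block_parts, random_dna(gaps[i]))
        cur <- cur + gaps[i]
      }
    }
    members$offset <- offs
    units[[length(units) + 1L]] <- list(
      kind = "composite", composite_id = k,
      seq = paste(block_parts, collapse = ""), members = members,
      gaps = gaps
    )
  }
  for (i in seq_len(nrow(config$insertion_specs))) {
    sp <- config$insertion_specs[i, ]
    for (k in seq_len(sp$count)) {
      m <- make_member(sp$name, sp$divergence, NULL,
                       conserved = runif(1) < sp$conserved_prob)
      m$offset <- 0L
      units[[length(units) + 1L]] <- list(
        kind = "standalone", composite_id = NA_integer_,
        seq = m$seq, members = m, gaps = integer(0)
      )
    }
  }
  for (k in seq_len(config$n_simple_repeats)) {
    rep_len <- sample(60:120, 1)
    m <- tibble(
      repeat_name = "(TA)n",
      seq = substr(strrep("TA", rep_len), 1, rep_len),
      strand = "+", cons_begin = 1L, cons_end = rep_len,
      divergence = 0, conserved = TRUE, offset = 0L
    )
    units[[length(units) + 1L]] <- list(
      kind = "simple", composite_id = NA_integer_,
      seq = m$seq, members = m, gaps = integer(0)
    )
  }

  # --- place units on chromosomes -----------------------------------------
  chrom_len <- config$genome_length %/% config$n_chroms
  chroms <- paste0("chr", seq_len(config$n_chroms))
  order <- sample.int(length(units))
  chrom_of <- rep_len(seq_len(config$n_chroms), length(units))
  cursors <- setNames(rep(200L, config$n_chroms), chroms)
  for (u in order) {
    ci <- chrom_of[[u]]
    len <- nchar(units[[u]]$seq)
    start <- cursors[[ci]] +
      sample(config$min_spacing:(config$min_spacing + 1000L), 1)
    if (start + len + 200L > chrom_len) {
      # try the other chromosomes before giving up
      alt <- which(cursors + config$min_spacing + len + 1200L < chrom_len)
      if (length(alt) == 0) {
        stop("could not place all units; increase genome_length",
             call. = FALSE)
      }
      ci <- alt[[1]]
      start <- cursors[[ci]] +
        sample(config$min_spacing:(config$min_spacing + 1000L), 1)
    }
    cursors[[ci]] <- start + len
    units[[u]]$chrom <- chroms[ci]
    units[[u]]$start <- start
  }

  # --- genome sequence -----------------------------------------------------
  genome <- setNames(vapply(chroms, function(ch) random_dna(chrom_len),
                            character(1)), chroms)
  for (u in units) {
    substr(genome[[u$chrom]], u$start + 1L, u$start + nchar(u$seq)) <- u$seq
  }

  # --- ground-truth repeat table / .out rows -------------------------------
  rows <- list()
  for (u in units) {
    m <- u$members
    for (i in seq_len(nrow(m))) {
      s <- u$start + m$offset[i]
      e <- s + nchar(m$seq[i])
      name <- m$repeat_name[i]
      cls <- switch(name,
        "AmnSINE1" = "SINE/Deu",
        "X6b_DNA" = "DNA",
        "MER117" = "DNA/hAT-Charlie",
        if (u$kind == "simple") "Simple_repeat" else "Unknown"
      )
      plen <- nchar(m$seq[i])
      rows[[length(rows) + 1L]] <- tibble(
        chrom = u$chrom, start = s, end = e, strand = m$strand[i],
        repeat_name = name, repeat_class = cls,
        sw_score = as.integer(round(2 * plen * (1 - m$divergence[i]))),
        pct_div = round_half_up(100 * m$divergence[i], 1),
        pct_del = 0, pct_ins = 0,
        cons_begin = m$cons_begin[i], cons_end = m$cons_end[i],
        cons_left = if (u$kind == "simple") 0L else {
          as.integer(cons_len[[name]] - m$cons_end[i])
        },
        query_left = as.integer(chrom_len - e),
        join_id = length(rows) + 1L, overlapped = FALSE,
        is_te = u$kind != "simple",
        conserved = m$conserved[i], composite_id = u$composite_id
      )
    }
  }
  planted <- dplyr::bind_rows(rows)

  # --- conserved track -----------------------------------------------------
  fl <- config$conserved_flank
  cons_rows <- list()
  planted$el_start <- NA_integer_
  planted$el_end <- NA_integer_
  planted$el_lod <- NA_integer_
  for (i in seq_len(nrow(planted))) {
    if (!planted$conserved[i]) next
    s <- max(0L, planted$start[i] - sample(fl[1]:fl[2], 1))
    e <- min(chrom_len, planted$end[i] + sample(fl[1]:fl[2], 1))
    lod <- as.integer(round(rlnorm(1, config$lod_conserved[1],
                                   config$lod_conserved[2])))
    planted$el_start[i] <- s
    planted$el_end[i] <- e
    planted$el_lod[i] <- lod
    cons_rows[[length(cons_rows) + 1L]] <- tibble(
      chrom = planted$chrom[i], start = s, end = e,
      name = sprintf("lod=%d", lod), lod = lod
    )
  }
  for (k in seq_len(config$n_background_elements)) {
    len <- sample(80:400, 1)
    ch <- sample(chroms, 1)
    s <- sample.int(chrom_len - len - 1L, 1)
    lod <- as.integer(round(rlnorm(1, config$lod_background[1],
                                   config$lod_background[2])))
    cons_rows[[length(cons_rows) + 1L]] <- tibble(
      chrom = ch, start = s, end = s + len,
      name = sprintf("lod=%d", lod), lod = lod
    )
  }
  conserved <- dplyr::bind_rows(cons_rows) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)

  # --- presence matrix via single gain + per-edge losses -------------------
  tree <- ape::read.tree(text = config$species_tree)
  presence <- purrr::map_dfr(seq_len(nrow(config$consensus_specs)),
                             function(i) {
    spec <- config$consensus_specs[i, ]
    row <- simulate_presence_row(tree, spec$gain_clade, config$loss_prob)
    dplyr::bind_cols(tibble(element = spec$name),
                     as_tibble(as.list(row)))
  })

  # --- composites ground truth --------------------------------------------
  comp_units <- Filter(function(u) u$kind == "composite", units)
  true_composites <- if (length(comp_units) == 0) {
    tibble(composite_id = integer(), chrom = character(), start = integer(),
           end = integer(), member_names = character(), gaps = character())
  } else {
    purrr::map_dfr(comp_units, function(u) {
      tibble(
        composite_id = u$composite_id, chrom = u$chrom,
        start = u$start, end = u$start + nchar(u$seq),
        member_names = paste(u$members$repeat_name, collapse = ","),
        gaps = paste(u$gaps, collapse = ",")
      )
    }) |> dplyr::arrange(.data$composite_id)
  }

  # --- write files ---------------------------------------------------------
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    consensi = file.path(outdir, "consensi.fa"),
    repeats = file.path(outdir, "repeats.out"),
    conserved = file.path(outdir, "conserved.bed"),
    presence = file.path(outdir, "presence.tsv"),
    tree = file.path(outdir, "tree.nwk")
  )
  write_fasta(genome, paths$genome)
  write_fasta(consensi, paths$consensi)
  write_repeatmasker_out(
    planted[, setdiff(names(planted),
                      c("conserved", "composite_id", "el_start", "el_end",
                        "el_lod", "is_te"))],
    paths$repeats
  )
  write_conserved_bed(conserved, paths$conserved)
  write_presence_table(presence, paths$presence)
  writeLines(config$species_tree, paths$tree)

  invisible(list(
    paths = paths,
    truth = list(
      planted_repeats = planted,
      true_composites = true_composites,
      true_gains = tibble(
        element = config$consensus_specs$name,
        clade = config$consensus_specs$gain_clade
      )
    ),
    config = config
  ))
}

#' Simulate an ortholog presence row under the single-gain/loss model
#'
#' Draws one presence/absence pattern: the element arises once on the stem
#' of `gain_clade` (an internal node label or tip label of `tree`), and each
#' edge below the gain independently loses the element with probability
#' `loss_prob`, deleting its whole subtree. Species outside the gain clade
#' are never present, honouring the Dollo premise. If every lineage is lost
#' the draw is repeated (up to 50 times; an absent-everywhere element is
#' unobservable), falling back to full clade presence.
#'
#' @param tree rooted `phylo` tree.
#' @param gain_clade clade label naming the gain branch.
#' @param loss_prob per-edge loss probability in \[0, 1\].
#' @return named integer 0/1 vector over `tree$tip.label`.
#' @export
simulate_presence_row <- function(tree, gain_clade, loss_prob) {
  n_tip <- length(tree$tip.label)
  node <- clade_node(tree, gain_clade)
  clade_tips <- tree_tips_below(tree, node)
  for (attempt in 1:50) {
    present <- rep(FALSE, n_tip)
    survive <- function(v) {
      if (v <= n_tip) {
        present[v] <<- TRUE
        return(invisible(NULL))
      }
      for (ch in tree_children(tree, v)) {
        if (runif(1) >= loss_prob) survive(ch)
      }
    }
    survive(node)
    if (any(present)) break
  }
  if (!any(present)) present[clade_tips] <- TRUE
  setNames(as.integer(present), tree$tip.label)
}

# resolve a clade label (internal node label or tip label) to a node id
clade_node <- function(tree, label) {
  n_tip <- length(tree$tip.label)
  hit <- base::match(label, tree$tip.label)
  if (!is.na(hit)) return(hit)
  if (!is.null(tree$node.label)) {
    hit <- base::match(label, tree$node.label)
    if (!is.na(hit)) return(n_tip + hit)
  }
  stop("clade label '", label, "' not found in tree", call. = FALSE)
}
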