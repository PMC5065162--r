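#' Configuration for an end-to-end pipeline run
#'
#' Collects inputs and every threshold the screen depends on. Either supply
#' the six input paths (repeats, conserved, genome, consensus library,
#' presence, tree) or a [simulation_config()] via `sim`, in which case the
#' inputs are generated into `<outdir>/inputs` first.
#'
#' @param sim optional [simulation_config()]; when given, inputs are
#'   simulated.
#' @param repeats,conserved,genome,consensus_lib,presence,tree input file
#'   paths (ignored when `sim` is given).
#' @param min_overlap,min_lod screen thresholds, strict (defaults 30 bp,
#'   LOD 100; see [screen_te_cnes()]).
#' @param max_gap chaining window in bp, strict (default 600; see
#'   [chain_proximal()]).
#' @param focal_family focal TE subfamily for companion statistics.
#' @param identity_denominator see [align_to_consensus()].
#' @param presence_threshold percent-identity presence cutoff (only used
#'   when presence must be called from identities; see
#'   [call_presence_from_identity()]).
#' @param seed integer seed echoed into the manifest and used for
#'   simulation.
#' @return a `coopte_run_config` list.
#' @export
run_config <- function(sim = NULL, repeats = NULL, conserved = NULL,
                       genome = NULL, consensus_lib = NULL, presence = NULL,
                       tree = NULL, min_overlap = 30L, min_lod = 100L,
                       max_gap = 600L, focal_family = "AmnSINE1",
                       identity_denominator = "all-columns",
                       presence_threshold = 60, seed = 1L) {
  structure(
    list(
      sim = sim, repeats = repeats, conserved = conserved, genome = genome,
      consensus_lib = consensus_lib, presence = presence, tree = tree,
      min_overlap = as.integer(min_overlap), min_lod = as.integer(min_lod),
      max_gap = as.integer(max_gap), focal_family = focal_family,
      identity_denominator = identity_denominator,
      presence_threshold = presence_threshold, seed = as.integer(seed)
    ),
    class = "coopte_run_config"
  )
}

#' Run the full composite-enhancer discovery pipeline
#'
#' Orchestrates simulate (optional) → screen → cluster → align → phylo and
#' writes `tecnes.tsv`, `loci.tsv`, `stats.tsv`, `matches.tsv`, `gains.tsv`
#' plus a `manifest.txt` recording the package version, the seed, every
#' threshold verbatim, and the MD5 checksum of every input file. Re-running
#' with an identical config and inputs reproduces byte-identical tables
#' (the manifest differs only in its timestamp line). Stage progress is
#' logged to stderr; a failing stage aborts with the stage name and removes
#' partial outputs.
#'
#' @param config a [run_config()] object.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the result tibbles (`tecnes`, `loci`,
#'   `stats`, `matches`, `gains`, `order`), the output `paths`, and — for
#'   simulated runs — the simulation `truth`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "coopte_run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- function(name) {
    p <- file.path(outdir, name)
    written <<- c(written, p)
    p
  }

  truth <- NULL
  inputs <- stage("inputs", {
    if (!is.null(config$sim)) {
      sim <- simulate_dataset(config$sim, file.path(outdir, "inputs"))
      truth <- sim$truth
      sim$paths
    } else {
      need <- c("repeats", "conserved", "genome", "consensus_lib",
                "presence", "tree")
      miss <- need[vapply(config[need], is.null, logical(1))]
      if (length(miss) > 0) {
        stop("missing input(s): ", paste(miss, collapse = ", "))
      }
      list(genome = config$genome, consensi = config$consensus_lib,
           repeats = config$repeats, conserved = config$conserved,
           presence = config$presence, tree = config$tree)
    }
  })

  parsed <- stage("parse", {
    list(
      repeats = read_repeatmasker_out(inputs$repeats),
      conserved = read_conserved_bed(inputs$conserved),
      genome = read_fasta(inputs$genome),
      consensi = read_fasta(inputs$consensi),
      presence = read_presence_table(inputs$presence),
      tree = read_species_tree(inputs$tree)
    )
  })

  tecnes <- stage("screen", {
    x <- screen_te_cnes(parsed$repeats, parsed$conserved,
                        min_overlap = config$min_overlap,
                        min_lod = config$min_lod)
    write_coopte_tsv(
      x[, c("chrom", "start", "end", "strand", "repeat_name", "repeat_class",
            "overlap_bp", "max_lod", "element_ids")],
      out("tecnes.tsv")
    )
    x
  })

  clustered <- stage("cluster", {
    loci <- chain_proximal(tecnes, max_gap = config$max_gap)
    stats <- companion_stats(loci, config$focal_family)
    write_coopte_tsv(
      loci[, c("locus_id", "chrom", "start", "end", "n_members",
               "n_families", "is_composite", "member_names", "gaps")],
      out("loci.tsv")
    )
    write_coopte_tsv(glance(stats), out("stats.tsv"))
    list(loci = loci, stats = stats)
  })

  matches <- stage("align", {
    m <- align_loci(clustered$loci, parsed$genome, parsed$consensi,
                    identity_denominator = config$identity_denominator)
    write_coopte_tsv(m, out("matches.tsv"))
    m
  })

  phylo <- stage("phylo", {
    gains <- infer_gains(parsed$presence, parsed$tree)
    ord <- integration_order(gains, parsed$tree)
    gains_out <- dplyr::left_join(
      gains[, c("element", "clade_name", "n_losses", "n_present")],
      ord[, c("element", "rank")],
      by = "element"
    )
    write_coopte_tsv(gains_out, out("gains.tsv"))
    list(gains = gains, order = ord)
  })

  stage("manifest", {
    input_files <- unlist(inputs, use.names = TRUE)
    md5 <- tools::md5sum(input_files)
    lines <- c(
      paste0("coopte_version\t", as.character(packageVersion("coopte"))),
      paste0("seed\t", config$seed),
      paste0("min_overlap\t", config$min_overlap),
      paste0("min_lod\t", config$min_lod),
      paste0("max_gap\t", config$max_gap),
      paste0("focal_family\t", config$focal_family),
      paste0("identity_denominator\t", config$identity_denominator),
      paste0("presence_threshold\t", config$presence_threshold),
      paste0("input_md5\t", names(input_files), "\t", unname(md5)),
      paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    )
    writeLines(lines, file.path(outdir, "manifest.txt"))
  })

  invisible(list(
    tecnes = tecnes, loci = clustered$loci, stats = clustered$stats,
    matches = matches, gains = phylo$gains, order = phylo$order,
    truth = truth,
    paths = setNames(file.path(outdir, c("tecnes.tsv", "loci.tsv",
                                         "stats.tsv", "matches.tsv",
                                         "gains.tsv", "manifest.txt")),
                     c("tecnes", "loci", "stats", "matches", "gains",
                       "manifest"))
  ))
}
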