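# End-to-end pipeline: read -> (phase) -> pairwise MEDs -> NJ tree ->
# root at diploid -> ancestral reconstruction -> per-branch events ->
# WGD report -> optional bootstrap support and region scores.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

config_echo <- function(config, path) {
  flat <- lapply(config, function(v)
    if (is.null(v)) "null" else paste(format(v, trim = TRUE), collapse = ","))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(sprintf("%s\t%s", names(flat), unlist(flat)), path)
  }
  path
}

profiles_table <- function(phy) {
  tree <- phy$tree
  layout <- phy$cohort$layout
  ntip <- length(tree$tip.label)
  lab <- function(v) if (v <= ntip) tree$tip.label[v]
                     else if (v == ntip + 1L) "root"
                     else paste0("internal_", v)
  rows <- lapply(seq_along(phy$profiles), function(v) {
    p <- phy$profiles[[v]]
    data.frame(sample_id = lab(v), chrom = layout$chrom,
               start = layout$start + 1, end = layout$end,
               cn_a = p$hapA, cn_b = p$hapB, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full inference pipeline
#'
#' Reads (or accepts) a cohort, phases major/minor input, computes the
#' pairwise symmetric MED matrix, infers the NJ topology, roots it at the
#' diploid, reconstructs ancestral genomes (which sets the final branch
#' lengths), extracts per-branch events and a per-sample WGD report, and
#' optionally computes bootstrap branch support and region scores.
#' Re-running with an identical configuration reproduces identical
#' outputs.
#'
#' @param input a `cn_cohort`, or path to a TSV for [read_cohort_tsv()].
#' @param mode `phased` (allele columns are haplotypes), `major-minor`
#'   (run evolutionary phasing), or `total` (single total-copy-number
#'   column treated as one haplotype against a haploid reference).
#' @param wgd_enabled model WGD events.
#' @param bootstrap number of resampling replicates for branch support
#'   and WGD calls (0 = skip).
#' @param strategy resampling strategy for the bootstrap.
#' @param threshold WGD bootstrap calling threshold.
#' @param regions optional data.frame (or BED path) of regions of
#'   interest.
#' @param cap maximum copy number.
#' @param seed RNG seed for all stochastic steps.
#' @param workers parallel workers for the distance matrix.
#' @param outdir output directory (created); `NULL` writes nothing.
#' @param allele_columns column names for TSV input.
#' @return (invisibly) a list with `cohort`, `distances`, `tree`, `phy`,
#'   `events`, `wgd_report`, `region_scores`, `stats`, `outdir`.
#' @export
run_infer <- function(input, mode = c("phased", "major-minor", "total"),
                      wgd_enabled = TRUE, bootstrap = 0L,
                      strategy = c("chromosome_bootstrap",
                                   "segment_jackknife"),
                      threshold = 0.05, regions = NULL, cap = 8L, seed = 1L,
                      workers = 1L, outdir = NULL,
                      allele_columns = c("cn_a", "cn_b")) {
  mode <- match.arg(mode)
  strategy <- match.arg(strategy)
  t0 <- Sys.time()
  loglines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    loglines <<- c(loglines, sprintf("[%s] %s", format(Sys.time()), msg))
    message("INFO ", msg)
  }
  cohort <- if (inherits(input, "cn_cohort")) input
            else read_cohort_tsv(input, allele_columns, cap = cap)
  if (mode == "total") {
    profs <- lapply(cohort$profiles, function(p) {
      if (p$sample_id == "diploid")
        cn_profile("diploid", rep(1L, length(p$hapA)),
                   rep(0L, length(p$hapB)), cap = cohort$cap)
      else cn_profile(p$sample_id, pmin(p$hapA + p$hapB, cohort$cap),
                      rep(0L, length(p$hapB)), cap = cohort$cap)
    })
    cohort$profiles <- profs
  }
  model <- get_model(cohort$cap, wgd_enabled, cohort$cap)
  if (mode == "major-minor") {
    say("evolutionary phasing of %d samples", length(cohort$profiles) - 1L)
    cohort <- phase_cohort(cohort, model)
  }
  say("computing pairwise MEDs for %d profiles (%d workers)",
      length(cohort$profiles), workers)
  D <- pairwise_distances(cohort, model, workers = workers)
  say("neighbor joining and rooting at the diploid")
  tree <- root_at_diploid(neighbor_joining(D))
  say("ancestral reconstruction")
  phy <- reconstruct_ancestors(tree, cohort, model)
  events <- detect_tree_events(phy)
  say("detected %d events on %d branches", nrow(events),
      nrow(phy$tree$edge))
  wgd_report <- do.call(rbind, lapply(cohort$profiles, function(p) {
    if (p$sample_id == "diploid") return(NULL)
    if (bootstrap > 0) {
      r <- call_wgd_with_bootstrap(p, cohort$layout, B = bootstrap,
                                   threshold = threshold, seed = seed)
      data.frame(sample_id = r$sample_id, s = r$s, wgd_count = r$wgd_count,
                 bootstrap_fraction = r$bootstrap_fraction,
                 call = r$call, call_multi = r$call_multi,
                 stringsAsFactors = FALSE)
    } else {
      r <- wgd_evidence(p, cohort$layout)
      data.frame(sample_id = r$sample_id, s = r$s, wgd_count = r$wgd_count,
                 bootstrap_fraction = NA_real_, call = r$s >= 1,
                 call_multi = r$wgd_count >= 2, stringsAsFactors = FALSE)
    }
  }))
  rownames(wgd_report) <- NULL
  support_tree <- phy$tree
  if (bootstrap > 0) {
    say("branch support from %d %s replicates", bootstrap, strategy)
    reps <- resample_cohort(cohort, strategy, B = bootstrap, seed = seed)
    rep_trees <- lapply(reps, function(rc)
      root_at_diploid(neighbor_joining(
        pairwise_distances(rc, model, workers = workers))))
    support_tree <- branch_support(phy$tree, rep_trees)
  }
  region_scores <- NULL
  if (!is.null(regions)) {
    if (is.character(regions)) regions <- read_regions_bed(regions)
    region_scores <- score_regions(events, regions, cohort$layout)
  }
  stats <- tree_stats(phy)
  say("tree length %d, trunk %d (fraction %.2f of max root-to-leaf %d)",
      stats$tree_length, stats$trunk_length, stats$trunk_fraction,
      stats$max_root_to_leaf)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(data.frame(sample_id = rownames(D), D, check.names = FALSE),
              file.path(outdir, "pairwise_distances.tsv"))
    ape::write.tree(support_tree, file.path(outdir, "tree.new"))
    write_tsv(profiles_table(phy), file.path(outdir, "cn_profiles.tsv"))
    write_tsv(events, file.path(outdir, "branch_events.tsv"))
    write_tsv(wgd_report, file.path(outdir, "wgd_report.tsv"))
    if (!is.null(region_scores))
      write_tsv(region_scores, file.path(outdir, "region_scores.tsv"))
    config_echo(list(mode = mode, wgd_enabled = wgd_enabled,
                     bootstrap = bootstrap, strategy = strategy,
                     threshold = threshold, cap = cap, seed = seed,
                     workers = workers),
                file.path(outdir, "run_config.json"))
    writeLines(c(loglines,
                 sprintf("[%s] done in %.1f s", format(Sys.time()),
                         as.numeric(difftime(Sys.time(), t0, units = "secs")))),
               file.path(outdir, "run.log"))
  }
  invisible(list(cohort = cohort, distances = D, tree = support_tree,
                 phy = phy, events = events, wgd_report = wgd_report,
                 region_scores = region_scores, stats = stats,
                 outdir = outdir))
}

#' Simulate a cohort and write a simulation bundle
#'
#' Runs either the genome-level simulator (`kind = "genome"`) or the
#' MED-model profile simulator (`kind = "med"`) and optionally writes the
#' cohort TSV, the true tree (Newick), the per-branch event log and a
#' configuration echo.
#'
#' @param kind simulator to use.
#' @param N number of leaves (genome simulator).
#' @param n_profiles number of profiles (MED-model simulator).
#' @param config simulator configuration ([genome_sim_config()] or
#'   [med_sim_config()]).
#' @param seed RNG seed.
#' @param outdir output directory, or `NULL`.
#' @return (invisibly) the simulation results.
#' @export
run_simulate <- function(kind = c("genome", "med"), N = 10L,
                         n_profiles = 100L, config = NULL, seed = 1L,
                         outdir = NULL) {
  kind <- match.arg(kind)
  if (kind == "genome") {
    if (is.null(config)) config <- genome_sim_config()
    tree <- simulate_topology(N, seed = seed)
    sim <- evolve_genomes(tree, config, seed = seed)
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_cohort_tsv(sim$cohort, file.path(outdir, "cohort.tsv"))
      ape::write.tree(tree, file.path(outdir, "true_tree.new"))
      write_tsv(sim$event_log, file.path(outdir, "event_log.tsv"))
      config_echo(config[setdiff(names(config), "layout")],
                  file.path(outdir, "sim_config.json"))
    }
    invisible(sim)
  } else {
    if (is.null(config)) config <- med_sim_config()
    draws <- lapply(seq_len(n_profiles), function(i)
      simulate_profile_with_known_count(config, seed = seed + i - 1L))
    profs <- lapply(seq_along(draws), function(i) {
      p <- draws[[i]]$profile
      p$sample_id <- sprintf("sim_%03d", i)
      p
    })
    cohort <- cn_cohort(config$layout, profs, cap = config$cap)
    counts <- data.frame(sample_id = vapply(profs, `[[`, "", "sample_id"),
                         true_events = vapply(draws, `[[`, 0, "count"))
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_cohort_tsv(cohort, file.path(outdir, "cohort.tsv"))
      write_tsv(counts, file.path(outdir, "true_event_counts.tsv"))
      config_echo(config[setdiff(names(config), "layout")],
                  file.path(outdir, "sim_config.json"))
    }
    invisible(list(cohort = cohort, counts = counts, config = config))
  }
}
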