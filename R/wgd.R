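# WGD evidence scoring and counting, resampling-based robustness, branch
# support, per-branch event detection and region scoring.

# model cache: event machines depend only on (cap, wgd_enabled, max_wgd)
.model_cache <- new.env(parent = emptyenv())
get_model <- function(cap = 8L, wgd_enabled = TRUE, max_wgd = cap) {
  key <- paste(cap, wgd_enabled, max_wgd)
  m <- .model_cache[[key]]
  if (is.null(m)) {
    m <- build_event_model(event_config(cap = cap, wgd_enabled = wgd_enabled,
                                        max_wgd = max_wgd))
    .model_cache[[key]] <- m
  }
  m
}

# run fn() with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  fn()
}

#' WGD evidence score and WGD count for a profile
#'
#' The evidence score is `s = MED_noWGD(diploid, t) - MED_WGD(diploid, t)`
#' (always non-negative); `s >= 1` indicates that a WGD event is
#' preferred.  The WGD count is the smallest `n` such that the MED with at
#' most `n` WGDs equals the MED with unbounded WGDs.
#'
#' @param profile a `cn_profile`.
#' @param layout its `cn_layout`.
#' @return list with `sample_id`, `s`, `med_nowgd`, `med_wgd`,
#'   `wgd_count`.
#' @export
wgd_evidence <- function(profile, layout) {
  cap <- profile$cap
  dip <- diploid_profile(layout, cap)
  m0 <- get_model(cap, wgd_enabled = FALSE)
  mw <- get_model(cap, wgd_enabled = TRUE, max_wgd = cap)
  d0 <- med_asymmetric(dip, profile, m0, layout)
  dw <- med_asymmetric(dip, profile, mw, layout)
  s <- d0 - dw
  count <- 0L
  if (s > 0) {
    n <- 1L
    repeat {
      dn <- med_asymmetric(dip, profile, get_model(cap, TRUE, n), layout)
      if (dn == dw) break
      n <- n + 1L
      if (n > cap) stop("internal error: WGD count exceeded cap")
    }
    count <- n
  }
  list(sample_id = profile$sample_id, s = s, med_nowgd = d0, med_wgd = dw,
       wgd_count = count)
}

# restrict a cohort to a vector of chromosome names drawn (possibly with
# repeats) from its layout; repeats become distinct chromosomes
resample_chromosomes <- function(cohort, chroms) {
  lay <- cohort$layout
  pieces <- lapply(seq_along(chroms), function(i) {
    seg <- lay[lay$chrom == chroms[i], , drop = FALSE]
    seg$chrom <- sprintf("%s.r%d", chroms[i], i)
    seg
  })
  idx <- unlist(lapply(chroms, function(ch) which(lay$chrom == ch)))
  newlay <- do.call(rbind, pieces)
  profs <- lapply(cohort$profiles, function(p) {
    if (p$sample_id == "diploid") return(NULL)
    cn_profile(p$sample_id, p$hapA[idx], p$hapB[idx], cap = cohort$cap)
  })
  cn_cohort(cn_layout(newlay$chrom, newlay$start, newlay$end),
            profs[!vapply(profs, is.null, TRUE)], cap = cohort$cap)
}

#' Resample a cohort for robustness estimation
#'
#' Two strategies suited to copy-number profiles (ordinary site-wise
#' bootstrap is invalid because neighboring segments are dependent):
#' `chromosome_bootstrap` draws whole chromosomes with replacement
#' (gains/losses end at chromosome boundaries and WGDs are indifferent to
#' chromosome order, so no artificial events are created);
#' `segment_jackknife` draws N segments with replacement from the N
#' segments and discards duplicates, keeping the original segment order
#' (on average this discards a fraction 1/e of segments).
#'
#' @param cohort a `cn_cohort`.
#' @param strategy resampling strategy.
#' @param B number of replicates.
#' @param seed RNG seed (replicates are reproducible given the seed).
#' @return list of `B` resampled `cn_cohort`s.
#' @export
resample_cohort <- function(cohort,
                            strategy = c("chromosome_bootstrap",
                                         "segment_jackknife"),
                            B = 100L, seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(B >= 1)
  lay <- cohort$layout
  n <- layout_nseg(lay)
  if (strategy == "segment_jackknife" && n == 1)
    warning("segment jackknife on a single-segment genome is degenerate")
  chroms <- layout_chroms(lay)
  with_seed(seed, function() {
    lapply(seq_len(B), function(b) {
      if (strategy == "chromosome_bootstrap") {
        drawn <- sample(chroms, length(chroms), replace = TRUE)
        resample_chromosomes(cohort, drawn)
      } else {
        keep <- sort(unique(sample.int(n, n, replace = TRUE)))
        sub <- lay[keep, , drop = FALSE]
        profs <- lapply(cohort$profiles, function(p) {
          if (p$sample_id == "diploid") return(NULL)
          cn_profile(p$sample_id, p$hapA[keep], p$hapB[keep],
                     cap = cohort$cap)
        })
        cn_cohort(cn_layout(sub$chrom, sub$start, sub$end),
                  profs[!vapply(profs, is.null, TRUE)], cap = cohort$cap)
      }
    })
  })
}

#' Bootstrap WGD call for a single profile
#'
#' Recomputes the WGD evidence score on `B` chromosome-bootstrap
#' replicates; the sample is called WGD-positive if at least a fraction
#' `threshold` of replicates show at least one WGD (and multi-WGD
#' analogously, with at least two).
#'
#' @param profile a `cn_profile`.
#' @param layout its `cn_layout`.
#' @param B number of bootstrap replicates.
#' @param threshold calling threshold on the replicate fraction.
#' @param seed RNG seed.
#' @return list with the full-profile `s` and `wgd_count`,
#'   `bootstrap_fraction` (replicates with >= 1 WGD),
#'   `bootstrap_fraction_multi` (>= 2 WGDs), and logical `call`,
#'   `call_multi`.
#' @export
call_wgd_with_bootstrap <- function(profile, layout, B = 100L,
                                    threshold = 0.05, seed = NULL) {
  stopifnot(B >= 1, threshold > 0, threshold <= 1)
  cap <- profile$cap
  base <- wgd_evidence(profile, layout)
  coh <- cn_cohort(layout, list(profile), cap = cap)
  reps <- resample_cohort(coh, "chromosome_bootstrap", B = B, seed = seed)
  m0 <- get_model(cap, FALSE)
  mw <- get_model(cap, TRUE, cap)
  m1 <- get_model(cap, TRUE, 1L)
  hits <- vapply(reps, function(rc) {
    p <- rc$profiles[[profile$sample_id]]
    dip <- diploid_profile(rc$layout, cap)
    d0 <- med_asymmetric(dip, p, m0, rc$layout)
    dw <- med_asymmetric(dip, p, mw, rc$layout)
    if (d0 - dw < 1) return(c(0, 0))
    d1 <- med_asymmetric(dip, p, m1, rc$layout)
    c(1, as.numeric(d1 > dw))  # >= 1 WGD; >= 2 WGDs
  }, numeric(2))
  frac1 <- mean(hits[1, ]); frac2 <- mean(hits[2, ])
  list(sample_id = profile$sample_id, s = base$s,
       wgd_count = base$wgd_count, bootstrap_fraction = frac1,
       bootstrap_fraction_multi = frac2,
       call = frac1 >= threshold, call_multi = frac2 >= threshold)
}

#' Annotate branch support from replicate trees
#'
#' Each internal branch of the original tree is annotated with the
#' percentage of replicate trees containing the same bipartition of the
#' leaf set.
#'
#' @param tree a rooted or unrooted `phylo`.
#' @param replicate_trees list of `phylo` trees on the same leaf set.
#' @return `tree` with `node.label` holding integer percentages (empty
#'   for trivial splits).
#' @export
branch_support <- function(tree, replicate_trees) {
  for (rt in replicate_trees)
    if (!setequal(rt$tip.label, tree$tip.label))
      stop("replicate trees must share the leaf set of the original tree")
  rep_splits <- lapply(replicate_trees, tree_splits)
  ntip <- length(tree$tip.label)
  labs <- character(tree$Nnode)
  ref <- sort(tree$tip.label)[1]
  for (v in ntip + seq_len(tree$Nnode)) {
    tips <- ape::extract.clade(tree, v)$tip.label
    if (length(tips) <= 1 || length(tips) >= ntip - 1) { labs[v - ntip] <- ""; next }
    if (ref %in% tips) tips <- setdiff(tree$tip.label, tips)
    key <- paste(sort(tips), collapse = "|")
    pct <- round(100 * mean(vapply(rep_splits, function(s) key %in% s, TRUE)))
    labs[v - ntip] <- as.character(as.integer(pct))
  }
  tree$node.label <- labs
  tree
}

#' Per-branch event detection on a reconstructed tree
#'
#' Traverses the tree away from the diploid root and extracts the events
#' of each branch with [extract_events()]; every event is reported exactly
#' once, on the branch where the copy-number change occurs, so parallel
#' (homoplastic) events on separate branches are kept apart.
#'
#' @param phy a `cn_phylo` from [reconstruct_ancestors()].
#' @return data.frame of events with `branch` (parent label `->` child
#'   label), `child` node label, plus the [extract_events()] columns.
#' @export
detect_tree_events <- function(phy) {
  tree <- phy$tree
  layout <- phy$cohort$layout
  ntip <- length(tree$tip.label)
  lab <- function(v) if (v <= ntip) tree$tip.label[v]
                     else if (v == ntip + 1L) "root"
                     else paste0("internal_", v)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    ev <- extract_events(phy$profiles[[a]], phy$profiles[[b]], phy$model,
                         layout)
    if (nrow(ev) == 0) next
    ev$branch <- paste0(lab(a), "->", lab(b))
    ev$child <- lab(b)
    out[[length(out) + 1L]] <- ev
  }
  if (length(out) == 0)
    return(data.frame(kind = character(0), haplotype = character(0),
                      chrom = character(0), start_seg = integer(0),
                      end_seg = integer(0), start = numeric(0),
                      end = numeric(0), delta = integer(0),
                      branch = character(0), child = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score regions of interest for net gains and losses
#'
#' Counts, per region, the tree events whose genomic span covers at least
#' a fraction `min_overlap` of the region (WGD events span the whole
#' genome and therefore count as a gain for every region), summed over
#' branches; `net = gains - losses`.
#'
#' @param events event data.frame from [detect_tree_events()] (or
#'   [extract_events()]).
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name` (0-based half-open, as in BED).
#' @param layout the `cn_layout` (used to validate region chromosomes).
#' @param min_overlap required covered fraction of the region.
#' @return data.frame with `name`, `chrom`, `start`, `end`, `gains`,
#'   `losses`, `net`.
#' @export
score_regions <- function(events, regions, layout, min_overlap = 0.9) {
  if (is.null(regions$name))
    regions$name <- sprintf("%s:%d-%d", regions$chrom,
                            as.integer(regions$start),
                            as.integer(regions$end))
  known <- regions$chrom %in% layout_chroms(layout)
  if (any(!known)) {
    warning("dropping regions on unknown chromosomes: ",
            paste(unique(regions$chrom[!known]), collapse = ", "))
    regions <- regions[known, , drop = FALSE]
  }
  n_wgd <- sum(events$kind == "wgd")
  seg_ev <- events[events$kind != "wgd", , drop = FALSE]
  res <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    rlen <- r$end - r$start
    same <- seg_ev[seg_ev$chrom == r$chrom, , drop = FALSE]
    cov <- pmax(0, pmin(same$end, r$end) - pmax(same$start, r$start)) / rlen
    hit <- cov >= min_overlap
    gains <- sum(hit & same$kind == "gain") + n_wgd
    losses <- sum(hit & same$kind %in% c("loss", "loh_loss"))
    data.frame(name = r$name, chrom = r$chrom, start = r$start, end = r$end,
               gains = gains, losses = losses, net = gains - losses,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read regions of interest from a BED file
#'
#' @param path BED file path (0-based half-open).
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_regions_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
    data.frame(chrom = as.character(gr$seqnames),
               start = gr$start - 1L,  # back to BED 0-based
               end = gr$end,
               name = if (!is.null(gr$name)) gr$name else
                 sprintf("region_%d", seq_len(nrow(gr))),
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    names(df)[1:3] <- c("chrom", "start", "end")
    df$name <- if (ncol(df) >= 4) df[[4]] else
      sprintf("region_%d", seq_len(nrow(df)))
    df[, c("chrom", "start", "end", "name")]
  }
}
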