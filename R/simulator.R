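# Two validation simulators:
#  (i)  a MED-model profile simulator that applies a known number of model
#       events (gain/loss runs, WGD) to the diploid, giving profiles with
#       a known true event count;
#  (ii) a genome-level simulator that evolves an explicit segment-token
#       representation of the genome along a random tree with chromosomal
#       and focal gains/losses, insertions, BFBs, WGDs and copy-neutral
#       rearrangements (inversions, translocations), from which
#       copy-number profiles are derived by counting segment copies.
# The genome-level route deliberately does not mirror the MED model, so
# tree-reconstruction benchmarks on it are not biased toward the method.

#' Uniform genome layout
#'
#' @param n_chrom number of chromosomes.
#' @param segs_per_chrom segments per chromosome.
#' @param seg_len segment length in bp (uniform).
#' @return a `cn_layout` with chromosomes `chr1..chrN`.
#' @export
uniform_layout <- function(n_chrom = 5L, segs_per_chrom = 10L,
                           seg_len = 1e6) {
  chrom <- rep(sprintf("chr%d", seq_len(n_chrom)), each = segs_per_chrom)
  start <- rep(seg_len * (seq_len(segs_per_chrom) - 1), n_chrom)
  cn_layout(chrom, start, start + seg_len)
}

#' Configuration for the MED-model profile simulator
#'
#' Defaults follow the reconstruction-accuracy study conditions: event
#' count Poisson with rate `mu = 10`; event type 5% WGD and 47.5% gain /
#' 47.5% loss; event start uniform over positions with non-zero copy
#' number; event length geometric with success probability `p_geom =
#' 0.2`; genome of 5 chromosomes with 10 segments each.
#'
#' @param mu Poisson rate for the number of events.
#' @param p_wgd,p_gain,p_loss event-type probabilities (must sum to 1).
#' @param p_geom geometric length parameter in (0, 1].
#' @param layout genome layout.
#' @param cap maximum copy number.
#' @return list of class `cn_med_sim_config`.
#' @export
med_sim_config <- function(mu = 10, p_wgd = 0.05, p_gain = 0.475,
                           p_loss = 0.475, p_geom = 0.2,
                           layout = uniform_layout(5L, 10L), cap = 8L) {
  stopifnot(abs(p_wgd + p_gain + p_loss - 1) < 1e-9, p_geom > 0, p_geom <= 1)
  structure(list(mu = mu, p_wgd = p_wgd, p_gain = p_gain, p_loss = p_loss,
                 p_geom = p_geom, layout = layout, cap = as.integer(cap)),
            class = "cn_med_sim_config")
}

# apply one simulated segmental event in place; events obey the model's
# constraints: start on a non-zero position, terminate at the chromosome
# boundary, skip zero-copy positions, gains saturate at the cap, losses
# may reach zero (LOH)
apply_segmental <- function(hapA, hapB, layout, kind, hap, start_idx, len,
                            cap) {
  v <- if (hap == 1) hapA else hapB
  ch <- layout$chrom[start_idx]
  chrom_rows <- which(layout$chrom == ch)
  span <- start_idx:min(start_idx + len - 1L, max(chrom_rows))
  vs <- v[span]
  v[span] <- if (kind == "gain") ifelse(vs > 0, pmin(vs + 1L, cap), 0L)
             else ifelse(vs > 0, vs - 1L, 0L)
  if (hap == 1) list(hapA = v, hapB = hapB) else list(hapA = hapA, hapB = v)
}

#' Simulate a profile with a known number of model events
#'
#' Draws `k ~ Poisson(mu)` events and applies them sequentially to the
#' diploid.  The asymmetric MED from the diploid to the result is a lower
#' bound on `k` (the minimum-event criterion).
#'
#' @param config a `cn_med_sim_config`.
#' @param seed RNG seed (reproducible draws).
#' @return list with `profile` (a `cn_profile`), `count` (true number of
#'   events) and `layout`.
#' @export
simulate_profile_with_known_count <- function(config = med_sim_config(),
                                              seed = NULL) {
  layout <- config$layout
  n <- layout_nseg(layout)
  cap <- config$cap
  with_seed(seed, function() {
    hapA <- rep(1L, n); hapB <- rep(1L, n)
    k <- stats::rpois(1, config$mu)
    for (e in seq_len(k)) {
      type <- sample(c("wgd", "gain", "loss"), 1,
                     prob = c(config$p_wgd, config$p_gain, config$p_loss))
      if (type == "wgd") {
        hapA <- ifelse(hapA > 0, pmin(hapA + 1L, cap), 0L)
        hapB <- ifelse(hapB > 0, pmin(hapB + 1L, cap), 0L)
        next
      }
      avail <- rbind(cbind(1L, which(hapA != 0)), cbind(2L, which(hapB != 0)))
      if (nrow(avail) == 0) next  # fully deleted genome; event has no target
      pick <- avail[sample.int(nrow(avail), 1), ]
      len <- stats::rgeom(1, config$p_geom) + 1L
      upd <- apply_segmental(hapA, hapB, layout, type, pick[1], pick[2], len,
                             cap)
      hapA <- upd$hapA; hapB <- upd$hapB
    }
    list(profile = cn_profile("sim", as.integer(hapA), as.integer(hapB),
                              cap = cap),
         count = k, layout = layout)
  })
}

#' Random rooted tree topology by sequential joining
#'
#' Joins the `N` labeled leaves pairwise, uniformly at random, until one
#' tree remains, then attaches the diploid at the root.
#'
#' @param N number of (non-diploid) leaves.
#' @param seed RNG seed.
#' @param labels leaf labels (default `s1..sN`).
#' @return a rooted `phylo` with `N + 1` leaves (incl. `diploid`).
#' @export
simulate_topology <- function(N, seed = NULL, labels = sprintf("s%d", 1:N)) {
  stopifnot(N >= 2, length(labels) == N)
  with_seed(seed, function() {
    sub <- as.list(labels)
    while (length(sub) > 1) {
      ij <- sample.int(length(sub), 2)
      joined <- sprintf("(%s,%s)", sub[[ij[1]]], sub[[ij[2]]])
      sub[[ij[1]]] <- joined
      sub[[ij[2]]] <- NULL
    }
    ape::read.tree(text = sprintf("(%s,diploid);", sub[[1]]))
  })
}

#' Configuration for the genome-level evolution simulator
#'
#' Per branch, the number of events is Poisson with rate
#' `lambda = delta_t * S * mu` where `S` is the total number of segments
#' over both haplotypes (default 2 x 22 chromosomes x 10 segments = 440).
#' Event types are equally likely, except breakage-fusion-bridge cycles at
#' a relative weight of 0.1 and WGD at its own probability.
#'
#' @param mu per-segment per-branch event rate.
#' @param n_chrom,segs_per_chrom genome makeup (per haplotype).
#' @param delta_t branch time span.
#' @param wgd_prob probability that an event is a WGD (e.g. 0 "no WGD",
#'   0.0125 "low", 0.065 "high", 0.000125 for large trees).
#' @param bfb_relative BFB weight relative to the other event types.
#' @param p_geom geometric length parameter for focal events.
#' @param cap maximum copy number of derived profiles.
#' @return list of class `cn_genome_sim_config`.
#' @export
genome_sim_config <- function(mu = 0.025, n_chrom = 22L,
                              segs_per_chrom = 10L, delta_t = 1,
                              wgd_prob = 0.0125, bfb_relative = 0.1,
                              p_geom = 0.2, cap = 8L) {
  layout <- uniform_layout(n_chrom, segs_per_chrom)
  S <- 2L * n_chrom * segs_per_chrom
  structure(list(mu = mu, n_chrom = as.integer(n_chrom),
                 segs_per_chrom = as.integer(segs_per_chrom),
                 delta_t = delta_t, S = S, lambda = delta_t * S * mu,
                 wgd_prob = wgd_prob, bfb_relative = bfb_relative,
                 p_geom = p_geom, cap = as.integer(cap), layout = layout),
            class = "cn_genome_sim_config")
}

#' Diploid genome in the token representation
#'
#' A genome is a list of chromosome units; each unit carries its founder
#' haplotype and a token matrix with columns `hap`, `chrom`, `idx`,
#' `orient` identifying the reference segment each physical segment
#' descends from.
#'
#' @param config a `cn_genome_sim_config`.
#' @return list of units.
#' @export
new_genome <- function(config) {
  units <- list()
  for (h in 1:2)
    for (c in seq_len(config$n_chrom))
      units[[length(units) + 1L]] <- list(
        founder = h,
        tokens = cbind(hap = h, chrom = c,
                       idx = seq_len(config$segs_per_chrom), orient = 1L))
  units
}

geom_len <- function(p) stats::rgeom(1, p) + 1L

#' Apply one genomic event to a token genome
#'
#' Event mechanics: `chrom_gain`/`chrom_loss` duplicate/delete a unit;
#' `focal_loss` removes a contiguous token run; `insertion` duplicates a
#' contiguous run and inserts it at a random position of the same unit;
#' `inversion` reverses a run and flips orientations (copy-neutral);
#' `bal_transloc` swaps terminal runs of two units (copy-neutral);
#' `unbal_transloc` moves a terminal run from one unit to another;
#' `bfb` deletes a terminal run and appends an inverted duplication of the
#' new terminus; `wgd` duplicates every unit.  Deletion-type events
#' (`chrom_loss`, `focal_loss`, `bfb`) only target units founded from
#' haplotype 1, preventing homozygous deletions.  Unspecified parameters
#' are drawn randomly.
#'
#' @param genome list of units from [new_genome()].
#' @param type event type string.
#' @param config a `cn_genome_sim_config`.
#' @param unit,unit2 unit indices (optional).
#' @param start,len token run coordinates (optional).
#' @return the mutated genome (a list of units).
#' @export
apply_genome_event <- function(genome, type, config, unit = NULL,
                               unit2 = NULL, start = NULL, len = NULL) {
  nonempty <- which(vapply(genome, function(u) nrow(u$tokens) > 0, TRUE))
  deletable <- which(vapply(genome, function(u)
    u$founder == 1L && nrow(u$tokens) > 0, TRUE))
  pick_unit <- function(pool) if (length(pool) == 0) NA_integer_
    else pool[sample.int(length(pool), 1)]
  if (type == "wgd") {
    return(c(genome, genome))
  }
  if (type == "chrom_gain") {
    u <- if (is.null(unit)) pick_unit(nonempty) else unit
    if (is.na(u)) return(genome)
    return(c(genome, genome[u]))
  }
  if (type == "chrom_loss") {
    u <- if (is.null(unit)) pick_unit(deletable) else unit
    if (is.na(u)) return(genome)
    return(genome[-u])
  }
  run_in <- function(u, start, len) {
    nt <- nrow(genome[[u]]$tokens)
    s <- if (is.null(start)) sample.int(nt, 1) else start
    l <- if (is.null(len)) geom_len(config$p_geom) else len
    s:min(s + l - 1L, nt)
  }
  if (type == "focal_loss") {
    u <- if (is.null(unit)) pick_unit(deletable) else unit
    if (is.na(u)) return(genome)
    span <- run_in(u, start, len)
    genome[[u]]$tokens <- genome[[u]]$tokens[-span, , drop = FALSE]
    return(genome)
  }
  if (type == "insertion") {
    u <- if (is.null(unit)) pick_unit(nonempty) else unit
    if (is.na(u)) return(genome)
    span <- run_in(u, start, len)
    tok <- genome[[u]]$tokens
    at <- sample.int(nrow(tok) + 1L, 1) - 1L
    genome[[u]]$tokens <- rbind(tok[seq_len(at), , drop = FALSE],
                                tok[span, , drop = FALSE],
                                tok[setdiff(seq_len(nrow(tok)),
                                            seq_len(at)), , drop = FALSE])
    return(genome)
  }
  if (type == "inversion") {
    u <- if (is.null(unit)) pick_unit(nonempty) else unit
    if (is.na(u)) return(genome)
    span <- run_in(u, start, len)
    tok <- genome[[u]]$tokens
    inv <- tok[rev(span), , drop = FALSE]
    inv[, "orient"] <- -inv[, "orient"]
    tok[span, ] <- inv
    genome[[u]]$tokens <- tok
    return(genome)
  }
  if (type %in% c("bal_transloc", "unbal_transloc")) {
    if (length(nonempty) < 2) return(genome)
    u <- if (is.null(unit)) pick_unit(nonempty) else unit
    v <- if (is.null(unit2)) pick_unit(setdiff(nonempty, u)) else unit2
    if (is.na(u) || is.na(v)) return(genome)
    tu <- genome[[u]]$tokens; tv <- genome[[v]]$tokens
    bu <- sample.int(nrow(tu), 1)  # suffix from bu..end moves
    if (type == "bal_transloc") {
      bv <- sample.int(nrow(tv), 1)
      genome[[u]]$tokens <- rbind(tu[seq_len(bu - 1L), , drop = FALSE],
                                  tv[bv:nrow(tv), , drop = FALSE])
      genome[[v]]$tokens <- rbind(tv[seq_len(bv - 1L), , drop = FALSE],
                                  tu[bu:nrow(tu), , drop = FALSE])
    } else {
      genome[[u]]$tokens <- tu[seq_len(bu - 1L), , drop = FALSE]
      at <- sample.int(nrow(tv) + 1L, 1) - 1L
      genome[[v]]$tokens <- rbind(tv[seq_len(at), , drop = FALSE],
                                  tu[bu:nrow(tu), , drop = FALSE],
                                  tv[setdiff(seq_len(nrow(tv)),
                                             seq_len(at)), , drop = FALSE])
    }
    return(genome)
  }
  if (type == "bfb") {
    u <- if (is.null(unit)) pick_unit(deletable) else unit
    if (is.na(u)) return(genome)
    tok <- genome[[u]]$tokens
    if (nrow(tok) < 2) return(genome)
    b <- sample.int(nrow(tok) - 1L, 1)       # keep 1..b, lose the rest
    kept <- tok[seq_len(b), , drop = FALSE]
    m <- min(if (is.null(len)) geom_len(config$p_geom) else len, b)
    dup <- kept[b:(b - m + 1L), , drop = FALSE]  # inverted terminal run
    dup[, "orient"] <- -dup[, "orient"]
    genome[[u]]$tokens <- rbind(kept, dup)
    return(genome)
  }
  stop("unknown event type: ", type)
}

#' Derive a copy-number profile from a token genome
#'
#' The copy number of a reference segment on a haplotype is the number of
#' tokens carrying its identity, over all units, clipped at the cap.
#'
#' @param genome list of units.
#' @param config a `cn_genome_sim_config`.
#' @param sample_id profile name.
#' @return a `cn_profile` on `config$layout`.
#' @export
genome_to_profile <- function(genome, config, sample_id = "genome") {
  n <- layout_nseg(config$layout)
  counts <- matrix(0L, 2, n)
  for (u in genome) {
    tok <- u$tokens
    if (nrow(tok) == 0) next
    pos <- (tok[, "chrom"] - 1L) * config$segs_per_chrom + tok[, "idx"]
    for (r in seq_len(nrow(tok)))
      counts[tok[r, "hap"], pos[r]] <- counts[tok[r, "hap"], pos[r]] + 1L
  }
  cn_profile(sample_id, pmin(counts[1, ], config$cap),
             pmin(counts[2, ], config$cap), cap = config$cap)
}

genome_event_types <- function(config) {
  base <- c("chrom_gain", "chrom_loss", "focal_loss", "insertion",
            "inversion", "bal_transloc", "unbal_transloc")
  w <- c(rep(1, length(base)), config$bfb_relative)
  w <- w / sum(w) * (1 - config$wgd_prob)
  list(types = c(base, "bfb", "wgd"), probs = c(w, config$wgd_prob))
}

#' Evolve genomes along a tree
#'
#' Starting from the diploid genome at the root, each branch mutates the
#' genome with `Poisson(lambda)` events (`lambda = delta_t * S * mu`).
#' Each branch consumes a deterministic substream of the seed, so
#' replaying with the same seed reproduces every branch exactly.
#'
#' @param tree rooted `phylo` from [simulate_topology()] (the `diploid`
#'   leaf stays untouched).
#' @param config a `cn_genome_sim_config`.
#' @param seed RNG seed.
#' @return list with `cohort` (a `cn_cohort` of leaf profiles),
#'   `genomes` (token genomes per leaf), `event_log` (data.frame of
#'   per-branch true events) and `tree`.
#' @export
evolve_genomes <- function(tree, config = genome_sim_config(), seed = NULL) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  et <- genome_event_types(config)
  log <- list()
  genomes <- vector("list", ntip + tree$Nnode)
  genomes[[root]] <- new_genome(config)
  base_seed <- if (is.null(seed)) stats::runif(1, 0, 2^20) else seed
  visit <- function(v, g) {
    for (child in node_children(tree, v)) {
      lab <- if (child <= ntip) tree$tip.label[child]
             else paste0("internal_", child)
      if (child <= ntip && tree$tip.label[child] == "diploid") {
        genomes[[child]] <<- g
        next
      }
      g2 <- with_seed((as.integer(base_seed) + 7919L * child) %% 2147483647L,
                      function() {
        k <- stats::rpois(1, config$lambda)
        gg <- g
        for (e in seq_len(k)) {
          type <- sample(et$types, 1, prob = et$probs)
          gg <- apply_genome_event(gg, type, config)
          log[[length(log) + 1L]] <<- data.frame(branch_child = lab,
                                                 type = type,
                                                 stringsAsFactors = FALSE)
        }
        gg
      })
      genomes[[child]] <<- g2
      if (child > ntip) visit(child, g2)
    }
  }
  visit(root, genomes[[root]])
  leaf_profiles <- lapply(seq_len(ntip), function(i) {
    id <- tree$tip.label[i]
    if (id == "diploid") return(NULL)
    genome_to_profile(genomes[[i]], config, sample_id = id)
  })
  leaf_profiles <- leaf_profiles[!vapply(leaf_profiles, is.null, TRUE)]
  cohort <- cn_cohort(config$layout, leaf_profiles, cap = config$cap)
  event_log <- if (length(log)) do.call(rbind, log) else
    data.frame(branch_child = character(0), type = character(0))
  list(cohort = cohort, genomes = genomes[seq_len(ntip)],
       event_log = event_log, tree = tree)
}
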