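# Evolutionary phasing: assign major/minor copy numbers to haplotypes so
# that the summed MED of both haplotypes to the diploid reference is
# minimal.  Each haplotype is scored as a single-haplotype genome
# (chromosomes separated by "X") against an all-1s reference, using the
# same event model (including WGD) as the downstream distances.
#
# The 2^n possible assignments are encoded as an (unweighted) phasing
# transducer P with one state per segment boundary and, per segment, two
# transitions carrying major->minor and minor->major.  The optimal
# assignment is the shortest path through
#     d o T o P o T^-1 o d
# where d is the all-1s linear acceptor and T the event chain: the left
# chain accumulates MED(diploid -> hapA), P forces hapB to be the
# per-segment complement, and the inverted right chain accumulates
# MED(diploid -> hapB).  The production route solves the same shortest
# path per chromosome conditional on the two per-haplotype WGD counts
# (the factorization used throughout the distance core); the transducer
# construction above is retained as the independent oracle in the test
# suite.

# tiny penalty on minor-as-hapA transitions: among equally parsimonious
# assignments, prefer ones that put the major allele on haplotype A.
# Total penalty over a genome is << 1, so true MED optimality is never
# traded away; the integer score is recovered by rounding.
PHASE_EPS <- 1e-7

phasing_fst <- function(major_seq, minor_seq, cap) {
  # sequences are encoded single-haplotype genomes incl. X separators
  L <- length(major_seq)
  X <- x_symbol(cap)
  rows <- list(); w <- numeric(0)
  for (i in seq_len(L)) {
    if (major_seq[i] == X) {
      rows[[length(rows) + 1L]] <- c(i, X, X, i + 1L)
      w[length(w) + 1L] <- 0
    } else {
      rows[[length(rows) + 1L]] <- c(i, major_seq[i], minor_seq[i], i + 1L)
      w[length(w) + 1L] <- 0
      if (major_seq[i] != minor_seq[i]) {
        rows[[length(rows) + 1L]] <- c(i, minor_seq[i], major_seq[i], i + 1L)
        w[length(w) + 1L] <- PHASE_EPS
      }
    }
  }
  fst_new(L + 1L, do.call(rbind, rows), w, n_symbols_for_cap(cap),
          final_w = c(rep(Inf, L), 0))
}

#' Evolutionary phasing of major/minor copy numbers
#'
#' Chooses, independently at every segment, which haplotype receives the
#' major and which the minor copy number, such that
#' `med(diploid, hapA) + med(diploid, hapB)` is minimal (each haplotype
#' scored as a single-haplotype genome under `model`).  The optimum is
#' exact; among ties, assignments placing the major allele on haplotype A
#' are preferred.
#'
#' @param major,minor integer vectors per layout segment, `major >= minor
#'   >= 0`.
#' @param model a `cn_event_model`.
#' @param layout the `cn_layout`.
#' @return a list with `hapA`, `hapB` (integer vectors), and `score` (the
#'   minimal summed MED).
#' @export
evolutionary_phase <- function(major, minor, model, layout) {
  major <- as.integer(major); minor <- as.integer(minor)
  n <- layout_nseg(layout)
  stopifnot(length(major) == n, length(minor) == n)
  if (any(minor > major)) stop("minor copy number exceeds major")
  if (any(minor < 0)) stop("negative copy number")
  cap <- model$cap
  if (any(major > cap)) stop("major copy number above cap; clip first")
  # per-chromosome factorization conditional on the per-haplotype WGD
  # counts (w1 toward haplotype A, w2 toward B); segmental machines
  # reset at chromosome boundaries, so chromosomes phase independently
  # once the WGD counts are fixed
  chroms <- layout_chroms(layout)
  pieces <- lapply(chroms, function(ch) {
    idx <- which(layout$chrom == ch)
    list(idx = idx, major = major[idx], minor = minor[idx])
  })
  wmax <- model$wmax
  best <- Inf; bw <- c(0L, 0L)
  for (wsum in 0:(2 * wmax)) {
    for (w1 in max(0, wsum - wmax):min(wmax, wsum)) {
      w2 <- wsum - w1
      if (wsum >= best) break
      tot <- wsum
      for (pc in pieces) {
        tot <- tot + med_piece_trace_cpp(pc$major, pc$minor, w1, w2, cap,
                                         2L)$weight
        if (tot >= best) break
      }
      if (tot < best) { best <- tot; bw <- c(w1, w2) }
    }
    if (wsum >= best) break
  }
  if (!is.finite(best)) stop("phasing failed: no solution found")
  hapA <- integer(n); hapB <- integer(n)
  for (pc in pieces) {
    tr <- med_piece_trace_cpp(pc$major, pc$minor, bw[1], bw[2], cap,
                              2L)$trace
    flip <- tr[, "z"] == 1
    hapA[pc$idx] <- ifelse(flip, pc$minor, pc$major)
    hapB[pc$idx] <- ifelse(flip, pc$major, pc$minor)
  }
  stopifnot(all(pmax(hapA, hapB) == major), all(pmin(hapA, hapB) == minor))
  list(hapA = as.integer(hapA), hapB = as.integer(hapB),
       score = best)
}

#' Phase every sample of a major/minor cohort
#'
#' Applies [evolutionary_phase()] to each non-diploid profile of a cohort
#' whose `hapA`/`hapB` slots hold major/minor copy numbers, returning a
#' cohort of phased profiles.
#'
#' @param cohort a `cn_cohort` holding major (hapA) and minor (hapB)
#'   values.
#' @param model a `cn_event_model`.
#' @return a phased `cn_cohort`.
#' @export
phase_cohort <- function(cohort, model) {
  profs <- lapply(cohort$profiles, function(p) {
    if (p$sample_id == "diploid") return(p)
    ph <- evolutionary_phase(pmax(p$hapA, p$hapB), pmin(p$hapA, p$hapB),
                             model, cohort$layout)
    cn_profile(p$sample_id, ph$hapA, ph$hapB, cap = cohort$cap)
  })
  cn_cohort(cohort$layout, unname(profs), cap = cohort$cap)
}
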