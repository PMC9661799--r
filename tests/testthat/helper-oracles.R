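# Independent oracles used across the test suite.

# Breadth-first search over explicit phase-ordered event sequences:
# ground truth for the minimum-event distance on tiny genomes.  Events
# are applied one at a time to the copy-number state, with phases
# LOH-phase losses (1) -> WGD (2) -> segmental losses (3) -> gains (4)
# never decreasing along a history.  Returns the minimal number of
# events transforming x into y, or Inf.
bfs_med_oracle <- function(x, y, layout, cap, wgd = TRUE, max_depth = 20) {
  n <- nrow(layout)
  stopifnot(2 * n * ceiling(log2(cap + 1)) + 2 <= 30)  # packed-state budget
  base <- cap + 1L
  pows <- base^(0:(2 * n - 1))
  pack <- function(v, phase) sum(v * pows) * 4 + (phase - 1L)
  xv <- c(x$hapA, x$hapB); yv <- c(y$hapA, y$hapB)
  if (identical(xv, yv)) return(0)
  if (any(xv == 0 & yv > 0)) return(Inf)  # no regaining deleted segments
  ykey <- sum(yv * pows)
  spans <- list()
  for (ch in unique(layout$chrom)) {
    for (h in 0:1) {
      idx <- which(layout$chrom == ch) + h * n
      for (i in seq_along(idx)) for (j in i:length(idx))
        spans[[length(spans) + 1L]] <- idx[i]:idx[j]
    }
  }
  succ <- function(v, phase) {
    res <- list()
    for (sp in spans) {
      ends <- v[c(sp[1], sp[length(sp)])]
      if (phase <= 1 && all(ends >= 1)) {               # LOH-phase loss
        v2 <- v; v2[sp] <- pmax(v[sp] - 1L, 0L)
        res[[length(res) + 1L]] <- list(v2, 1L)
      }
      if (phase <= 3 && all(ends >= 2) && !any(v[sp] == 1)) {  # loss
        v2 <- v; v2[sp] <- ifelse(v[sp] >= 2, v[sp] - 1L, v[sp])
        res[[length(res) + 1L]] <- list(v2, 3L)
      }
      if (all(ends >= 1)) {                             # gain (closes phases)
        v2 <- v; v2[sp] <- ifelse(v[sp] >= 1, pmin(v[sp] + 1L, cap), 0L)
        res[[length(res) + 1L]] <- list(v2, 4L)
      }
    }
    if (wgd && phase <= 2)                              # whole-genome doubling
      res[[length(res) + 1L]] <- list(ifelse(v > 0, pmin(v + 1L, cap), 0L), 2L)
    res
  }
  seen <- logical(base^(2 * n) * 4)
  frontier <- list(list(xv, 1L))
  seen[pack(xv, 1L) + 1] <- TRUE
  depth <- 0
  while (depth < max_depth) {
    depth <- depth + 1
    nxt <- list()
    for (st in frontier) {
      for (s2 in succ(st[[1]], st[[2]])) {
        if (sum(s2[[1]] * pows) == ykey) return(depth)
        key <- pack(s2[[1]], s2[[2]]) + 1
        if (!seen[key]) {
          seen[key] <- TRUE
          nxt[[length(nxt) + 1L]] <- s2
        }
      }
    }
    if (length(nxt) == 0) return(Inf)
    frontier <- nxt
  }
  Inf
}

# exhaustive symmetric distance: minimize over every ancestor profile on
# a tiny layout (values 0..cap at every position of both haplotypes)
brute_symmetric_oracle <- function(x, y, model, layout) {
  n <- nrow(layout)
  cap <- model$cap
  grids <- rep(list(0:cap), 2 * n)
  best <- Inf
  combos <- do.call(expand.grid, grids)
  for (r in seq_len(nrow(combos))) {
    z <- cn_profile("z", as.integer(combos[r, 1:n]),
                    as.integer(combos[r, n + 1:n]), cap = cap)
    d1 <- med_asymmetric(z, x, model, layout)
    d2 <- med_asymmetric(z, y, model, layout)
    best <- min(best, d1 + d2)
  }
  best
}

# random profile on a layout, biased toward small copy numbers
random_profile <- function(layout, cap, id = "p") {
  n <- nrow(layout)
  draw <- function() sample(0:cap, n, replace = TRUE,
                            prob = c(1, 3, 2, rep(1, cap - 2)))
  cn_profile(id, draw(), draw(), cap = cap)
}

# profile derived from another by applying k random model events
evolve_profile <- function(p, layout, cap, k, wgd_prob = 0.1) {
  hA <- p$hapA; hB <- p$hapB
  for (i in seq_len(k)) {
    if (stats::runif(1) < wgd_prob) {
      hA <- ifelse(hA > 0, pmin(hA + 1L, cap), 0L)
      hB <- ifelse(hB > 0, pmin(hB + 1L, cap), 0L)
      next
    }
    hap <- sample(1:2, 1)
    v <- if (hap == 1) hA else hB
    nz <- which(v != 0)
    if (length(nz) == 0) next
    s <- nz[sample.int(length(nz), 1)]
    ch <- layout$chrom[s]
    last <- max(which(layout$chrom == ch))
    sp <- s:min(s + sample.int(3, 1) - 1L, last)
    if (stats::runif(1) < 0.5)
      v[sp] <- ifelse(v[sp] >= 1, pmin(v[sp] + 1L, cap), 0L)
    else
      v[sp] <- ifelse(v[sp] >= 1, v[sp] - 1L, 0L)
    if (hap == 1) hA <- v else hB <- v
  }
  cn_profile(p$sample_id, as.integer(hA), as.integer(hB), cap = cap)
}
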