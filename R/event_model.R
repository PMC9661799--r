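# Event transducers and the minimum-event distance (MED).
#
# Events are modelled as weighted transducers over the copy-number
# alphabet {0..cap, X} and chained in a fixed phase order:
#   LOH-phase losses -> WGDs -> segmental losses -> segmental gains.
# LOH events must precede everything (lost segments cannot be regained);
# WGDs must precede segmental losses/gains (e.g. to delete segments gained
# during the doubling).  The asymmetric MED is the tropical shortest
# distance through this chain; the symmetric distance routes through a
# common ancestor via the kernel composition of the chain with its
# inverse.
#
# The n-step machines are built in closed form as run-counting automata:
# state d = number of currently open event "layers" at this position,
# which is weight-equivalent to composing the one-step machine with itself
# n times (each layer is one pass) but has n+1 states instead of 2^n.
# Opening a layer costs 1 (one event = one contiguous run); continuing or
# closing is free.  Runs terminate at the separator "X"; copy-0 positions
# are skipped by open runs at no cost; gains saturate at the cap (the cap
# is an observation ceiling, consistent with clipping on input); losses
# cannot take a segment to 0 outside the LOH phase.

# one-step machines (2 states: idle, run); used by tests to prove the
# closed-form n-step machines below equivalent to literal self-composition
one_step_machine <- function(kind = c("loh", "loss", "gain"), cap = 8L) {
  kind <- match.arg(kind)
  X <- x_symbol(cap)
  nsym <- n_symbols_for_cap(cap)
  rows <- list(); w <- numeric(0)
  add <- function(src, a, o, dst, wt) {
    rows[[length(rows) + 1L]] <<- c(src, a, o, dst)
    w[length(w) + 1L] <<- wt
  }
  for (a in 0:cap) add(1L, a, a, 1L, 0)         # idle: copy
  add(1L, X, X, 1L, 0)
  affected <- switch(kind,
    loh  = 1:cap,                                # s -> s - 1, may reach 0
    loss = if (cap >= 2) 2:cap else integer(0),  # s -> s - 1, stays >= 1
    gain = 1:cap)                                # s -> min(s + 1, cap)
  outv <- switch(kind, loh = affected - 1L, loss = affected - 1L,
                 gain = pmin(affected + 1L, cap))
  for (i in seq_along(affected)) {
    add(1L, affected[i], outv[i], 2L, 1)         # open a run
    add(2L, affected[i], outv[i], 2L, 0)         # continue the run
  }
  add(2L, 0L, 0L, 2L, 0)                         # skip zero inside run
  for (a in 0:cap) add(2L, a, a, 1L, 0)          # close run (unaffected pos)
  add(2L, X, X, 1L, 0)                           # forced close at separator
  fst_new(2L, do.call(rbind, rows), w, nsym)
}

# closed-form n-step run-counting machine; states are d = 0..n open layers
nstep_machine <- function(kind = c("loh", "loss", "gain"), n, cap = 8L) {
  kind <- match.arg(kind)
  X <- x_symbol(cap)
  nsym <- n_symbols_for_cap(cap)
  rows <- list(); w <- numeric(0)
  add <- function(d, a, o, dp) {
    rows[[length(rows) + 1L]] <<- c(d + 1L, a, o, dp + 1L)
    w[length(w) + 1L] <<- max(0, dp - d)
  }
  for (d in 0:n) {
    for (dp in 0:n) {
      if (kind == "gain") {
        for (a in 1:cap) add(d, a, min(a + dp, cap), dp)
      } else if (kind == "loh") {
        # dp > a is allowed: once earlier layers reach 0, the remaining
        # open layers skip the position (output floors at 0)
        for (a in 1:cap) add(d, a, max(a - dp, 0L), dp)
      } else { # loss: results stay >= 1; a run cannot span a copy-1 segment
        if (cap >= 2) for (a in 2:cap) if (a - dp >= 1) add(d, a, a - dp, dp)
      }
      if (dp <= d) add(d, 0L, 0L, dp)  # zero skipped; no opens at a zero
    }
    if (kind == "loss") add(d, 1L, 1L, 0L)  # copy-1 blocks all loss runs
    add(d, X, X, 0L)                        # runs terminate at X
  }
  fst_new(n + 1L, do.call(rbind, rows), w, nsym)
}

# WGD machine allowing up to n whole-genome doublings.  One WGD is a gain
# applied to every non-zero segment of the genome: k -> min(k + 1, cap),
# both haplotypes, ignoring chromosome boundaries; 0 and X are unchanged;
# cost 1.  The number of WGDs is committed at the first symbol and spans
# the whole sequence.
wgd_machine <- function(n, cap = 8L) {
  X <- x_symbol(cap)
  nsym <- n_symbols_for_cap(cap)
  rows <- list(); w <- numeric(0)
  fk <- function(a, k) if (a == 0) 0L else min(a + k, cap)
  add <- function(src, a, o, dst, wt) {
    rows[[length(rows) + 1L]] <<- c(src, a, o, dst)
    w[length(w) + 1L] <<- wt
  }
  for (k in 0:n) {
    st <- k + 2L  # committed-k state
    for (a in 0:cap) {
      add(1L, a, fk(a, k), st, k)   # commit k doublings at first symbol
      add(st, a, fk(a, k), st, 0)
    }
    add(1L, X, X, st, k)
    add(st, X, X, st, 0)
  }
  fst_new(n + 2L, do.call(rbind, rows), w, nsym)
}

#' Configuration of the event model
#'
#' @param cap maximum copy number (alphabet is `{0..cap, X}`).
#' @param wgd_enabled allow whole-genome doubling events.
#' @param max_wgd maximum number of WGD events (n-step WGD machine);
#'   default `cap` (effectively unbounded, since doublings saturate).
#' @param loh_steps composition count for the LOH machine (default
#'   alphabet size minus 1, i.e. `cap + 1`).
#' @param seg_steps composition count for gains and losses (default
#'   alphabet size minus 2, i.e. `cap`).
#' @return a list of class `cn_event_config`.
#' @export
event_config <- function(cap = 8L, wgd_enabled = TRUE, max_wgd = cap,
                         loh_steps = cap + 1L, seg_steps = cap) {
  if (loh_steps < cap) stop("loh_steps must be >= cap")
  if (seg_steps < cap - 1L) stop("seg_steps must be >= cap - 1")
  if (max_wgd < 0) stop("max_wgd must be >= 0")
  structure(list(cap = as.integer(cap), wgd_enabled = isTRUE(wgd_enabled),
                 max_wgd = as.integer(max_wgd),
                 loh_steps = as.integer(loh_steps),
                 seg_steps = as.integer(seg_steps)),
            class = "cn_event_config")
}

# 1-state machine applying exactly k WGDs' worth of saturating gains
# (min(a + k, cap) on non-zero symbols) at weight 0; used to condition
# per-chromosome computations on a fixed WGD count
fixed_wgd_fst <- function(k, cap = 8L) {
  X <- x_symbol(cap)
  a <- 0:cap
  trans <- cbind(src = 1L, `in` = c(a, X),
                 out = c(ifelse(a == 0, 0L, pmin(a + k, cap)), X), dst = 1L)
  fst_new(1L, trans, rep(0, nrow(trans)), n_symbols_for_cap(cap))
}

#' Build the MED event model
#'
#' Constructs the n-step event machines (LOH-phase losses, WGD, segmental
#' losses, segmental gains) and their phase-ordered chains.  The
#' asymmetric chain is `T_LOH o T_WGD o T_L o T_G` (WGD omitted when
#' disabled); the symmetric kernel chain is the inverse chain followed by
#' the forward chain, so that shortest paths route through a common
#' ancestor.  Distance computations exploit the separator structure of
#' the chain (segmental machines reset at "X", only the WGD count spans
#' the genome), which factorizes the shortest distance exactly into
#' per-chromosome-per-haplotype pieces conditioned on the WGD count; the
#' monolithic chains are retained for path decoding and as test oracles.
#'
#' @param config a `cn_event_config` (default: WGD-aware model, cap 8).
#' @return an object of class `cn_event_model`.
#' @export
build_event_model <- function(config = event_config()) {
  stopifnot(inherits(config, "cn_event_config"))
  cap <- config$cap
  T_LOH <- nstep_machine("loh", config$loh_steps, cap)
  T_L <- nstep_machine("loss", config$seg_steps, cap)
  T_G <- nstep_machine("gain", config$seg_steps, cap)
  T_WGD <- if (config$wgd_enabled) wgd_machine(config$max_wgd, cap) else NULL
  fwd <- if (config$wgd_enabled) list(T_LOH, T_WGD, T_L, T_G)
         else list(T_LOH, T_L, T_G)
  bwd <- lapply(rev(fwd), fst_invert)
  structure(list(config = config, cap = cap,
                 n_symbols = n_symbols_for_cap(cap),
                 T_LOH = T_LOH, T_WGD = T_WGD, T_L = T_L, T_G = T_G,
                 chain_asym = fwd, chain_sym = c(bwd, fwd),
                 wmax = if (config$wgd_enabled)
                   min(config$max_wgd, cap - 1L) else 0L),
            class = "cn_event_model")
}

# batched piecewise MED over encoded sequences (the fast path); `pairs`
# is a 2-column index matrix into `enc`
# mode 0: vector of distances per pair; mode 1: exact conditioned grid
# (single pair); mode 2: c(distance, w1, w2) argmin (single pair)
med_batch <- function(enc, pairs, model, symmetric, mode = 0L) {
  med_batch_cpp(enc, matrix(as.integer(pairs), ncol = 2), model$cap,
                x_symbol(model$cap), model$wmax, symmetric,
                as.integer(mode))
}

#' @export
print.cn_event_model <- function(x, ...) {
  cat(sprintf("<cn_event_model: cap %d, WGD %s (max %d)>\n", x$cap,
              if (x$config$wgd_enabled) "enabled" else "disabled",
              x$config$max_wgd))
  invisible(x)
}

as_encoded <- function(p, layout) {
  if (inherits(p, "cn_profile")) encode_profile(p, layout) else as.integer(p)
}

#' Asymmetric minimum-event distance
#'
#' The minimum number of phase-ordered events (LOH-phase losses, WGDs,
#' segmental losses, segmental gains) transforming profile `x` into
#' profile `y`.  `Inf` if `y` has a positive copy number where `x` has
#' zero (lost segments cannot be regained).
#'
#' @param x,y `cn_profile`s on `layout` (or pre-encoded symbol vectors).
#' @param model a `cn_event_model`.
#' @param layout the shared `cn_layout` (not needed for pre-encoded input).
#' @return numeric distance (a non-negative integer, or `Inf`).
#' @export
med_asymmetric <- function(x, y, model, layout = NULL) {
  ex <- as_encoded(x, layout); ey <- as_encoded(y, layout)
  med_batch(list(ex, ey), cbind(1L, 2L), model, symmetric = FALSE)[1]
}

#' Symmetric minimum-event distance via a common ancestor
#'
#' `S[x, y] = min_z med(z, x) + med(z, y)` over all ancestor profiles `z`,
#' computed as the shortest distance through the kernel chain
#' `x o T^-1 o T o y`.  Optionally decodes a witnessing ancestor from the
#' intermediate symbols of one optimal path.
#'
#' @param x,y `cn_profile`s on `layout`.
#' @param model a `cn_event_model`.
#' @param layout the shared `cn_layout`.
#' @param ancestor if `TRUE`, also return a witnessing ancestor profile.
#' @return a list with `weight` and (if requested) `ancestor`.
#' @export
med_symmetric <- function(x, y, model, layout, ancestor = FALSE) {
  ex <- as_encoded(x, layout); ey <- as_encoded(y, layout)
  if (!ancestor) {
    return(list(weight =
      med_batch(list(ex, ey), cbind(1L, 2L), model, symmetric = TRUE)[1]))
  }
  am <- med_batch(list(ex, ey), cbind(1L, 2L), model, symmetric = TRUE,
                  mode = 2L)
  best <- am[1]
  out <- list(weight = best)
  if (!is.finite(best)) return(out)
  # an optimal WGD pair; deterministic for identical inputs
  w1 <- as.integer(am[2]); w2 <- as.integer(am[3])
  cap <- model$cap
  anc_sym <- integer(0)
  X <- x_symbol(cap)
  for (pc in split_pieces(ex, cap)) {
    res <- med_piece_trace_cpp(pc$symbols, ey[pc$idx], w1, w2, cap, 1L)
    anc_sym <- c(anc_sym, res$trace[, "z"], X)
  }
  anc_sym <- anc_sym[-length(anc_sym)]  # drop trailing separator
  out$ancestor <- decode_profile(anc_sym, layout, cap = cap,
                                 sample_id = "ancestor")
  out
}

# split an encoded sequence into per-chromosome-per-haplotype pieces
split_pieces <- function(enc, cap) {
  X <- x_symbol(cap)
  breaks <- which(enc == X)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks - 1L, length(enc))
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    list(idx = idx, symbols = enc[idx])
  })
}

# ---- pairwise distances with the prime-grid schedule -------------------

is_prime <- function(n) {
  if (n < 2) return(FALSE)
  if (n < 4) return(TRUE)
  if (n %% 2 == 0) return(FALSE)
  k <- 3
  while (k * k <= n) { if (n %% k == 0) return(FALSE); k <- k + 2 }
  TRUE
}

#' Prime-grid schedule for pairwise computations
#'
#' Splits `N` items into `p^2 + p` groups of size `p`, where `p` is the
#' smallest prime with `p^2 >= N`, such that every unordered pair of items
#' occurs together in exactly one group (the groups are the lines of the
#' affine plane of order `p`: `p` rows plus `p^2` modular-slope lines).
#' Group-local pairwise computation then covers each pair exactly once and
#' parallelizes over groups.
#'
#' @param N number of items.
#' @return list of integer vectors (1-based item indices).
#' @export
pair_schedule <- function(N) {
  stopifnot(N >= 2)
  p <- ceiling(sqrt(N))
  while (!is_prime(p)) p <- p + 1
  cell <- function(r, c) as.integer(r * p + c + 1L)  # 1-based id, may exceed N
  groups <- list()
  for (r in 0:(p - 1))
    groups[[length(groups) + 1L]] <- vapply(0:(p - 1), function(c) cell(r, c), 0L)
  for (s in 0:(p - 1))
    for (c0 in 0:(p - 1))
      groups[[length(groups) + 1L]] <-
        vapply(0:(p - 1), function(r) cell(r, (c0 + s * r) %% p), 0L)
  lapply(groups, function(g) g[g <= N])
}

#' Pairwise symmetric MED matrix for a cohort
#'
#' Computes the symmetric minimum-event distance between every pair of
#' profiles (diploid included).  Pairs are grouped by [pair_schedule()]
#' and groups are processed independently (optionally in parallel); the
#' result is identical for any worker count.
#'
#' @param cohort a `cn_cohort`.
#' @param model a `cn_event_model`.
#' @param workers number of parallel workers (forked; 1 = serial).
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
pairwise_distances <- function(cohort, model, workers = 1L) {
  profiles <- cohort$profiles
  N <- length(profiles)
  stopifnot(N >= 2)
  ids <- names(profiles)
  enc <- lapply(profiles, encode_profile, layout = cohort$layout)
  groups <- pair_schedule(N)
  run_group <- function(g) {
    if (length(g) < 2) return(NULL)
    prs <- t(utils::combn(sort(g), 2))
    cbind(i = prs[, 1], j = prs[, 2],
          d = med_batch(enc, prs, model, symmetric = TRUE))
  }
  res <- if (workers > 1L)
    parallel::mclapply(groups, run_group, mc.cores = workers)
  else lapply(groups, run_group)
  D <- matrix(0, N, N, dimnames = list(ids, ids))
  for (m in res) {
    if (is.null(m)) next
    D[cbind(m[, "i"], m[, "j"])] <- m[, "d"]
    D[cbind(m[, "j"], m[, "i"])] <- m[, "d"]
  }
  if (any(!is.finite(D)))
    stop("infinite symmetric distance encountered; check input profiles")
  D
}

# ---- event extraction from optimal paths -------------------------------

#' Extract the individual events of one optimal transformation
#'
#' Decodes the optimal path of the asymmetric MED from `x` to `y` into a
#' table of events: each segmental event is one contiguous run on one
#' haplotype of one chromosome; WGD events span the genome.  Replaying the
#' events in phase order on `x` yields `y` exactly, and the number of rows
#' equals `med_asymmetric(x, y)`.  The reported decomposition is the
#' engine's deterministic optimal path; other equally-parsimonious
#' decompositions may exist.
#'
#' @param x,y `cn_profile`s on `layout`.
#' @param model a `cn_event_model`.
#' @param layout the shared `cn_layout`.
#' @return data.frame with columns `kind` (`loh_loss`, `wgd`, `loss`,
#'   `gain`), `haplotype` (`A`, `B`, `both`), `chrom`, `start_seg`,
#'   `end_seg` (1-based segment indices within the chromosome's layout
#'   rows), `start`, `end` (bp), `delta`.
#' @export
extract_events <- function(x, y, model, layout) {
  ex <- as_encoded(x, layout); ey <- as_encoded(y, layout)
  am <- med_batch(list(ex, ey), cbind(1L, 2L), model, symmetric = FALSE,
                  mode = 2L)
  med <- am[1]
  if (!is.finite(med)) {
    emap <- encoding_map(layout)
    bad <- which(ex == 0 & ey > 0)
    stop("infinite MED: segments regained from copy number zero at ",
         paste(sprintf("%s:%s(hap%s)", emap$chrom[bad], emap$seg[bad],
                       emap$hap[bad]), collapse = ", "))
  }
  wstar <- as.integer(am[2])  # smallest optimal WGD count
  cap <- model$cap
  emap <- encoding_map(layout)
  events <- list()
  add_event <- function(kind, pos1, pos2) {
    ch <- emap$chrom[pos1]
    seg_rows <- which(layout$chrom == ch)
    s1 <- emap$seg[pos1] - min(seg_rows) + 1L
    s2 <- emap$seg[pos2] - min(seg_rows) + 1L
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, haplotype = emap$hap[pos1], chrom = ch,
      start_seg = s1, end_seg = s2,
      start = layout$start[seg_rows[s1]], end = layout$end[seg_rows[s2]],
      delta = if (kind == "gain") 1L else -1L,
      stringsAsFactors = FALSE)
  }
  if (wstar > 0)
    for (i in seq_len(wstar))
      events[[length(events) + 1L]] <- data.frame(
        kind = "wgd", haplotype = "both", chrom = NA_character_,
        start_seg = NA_integer_, end_seg = NA_integer_,
        start = NA_real_, end = NA_real_, delta = 1L,
        stringsAsFactors = FALSE)
  # decode each piece's optimal open-layer trajectory into runs (LIFO:
  # the most recently opened run closes first; runs still open at the
  # piece end close there)
  emit_runs <- function(kind, counts, acting, gpos) {
    open <- list()
    prev <- 0L
    for (i in seq_along(counts)) {
      cnt <- counts[i]
      n_close <- max(0L, prev - cnt)
      n_open <- max(0L, cnt - prev)
      if (n_close > 0) for (k in seq_len(n_close)) {
        run <- open[[length(open)]]
        open[[length(open)]] <- NULL
        add_event(kind, run$start, run$last)
      }
      if (n_open > 0) for (k in seq_len(n_open))
        open[[length(open) + 1L]] <- list(start = gpos[i], last = gpos[i])
      if (acting[i] && cnt > 0)
        for (k in seq_along(open)) open[[k]]$last <- gpos[i]
      prev <- cnt
    }
    while (length(open) > 0) {
      run <- open[[length(open)]]
      open[[length(open)]] <- NULL
      add_event(kind, run$start, run$last)
    }
  }
  for (pc in split_pieces(ex, cap)) {
    xp <- pc$symbols; yp <- ey[pc$idx]
    res <- med_piece_trace_cpp(xp, yp, 0L, wstar, cap, 0L)
    tr <- res$trace
    a <- tr[, "a2"]; b <- tr[, "b2"]; cc <- tr[, "c2"]
    m <- ifelse(xp >= 1, xp - a, 0L)
    s <- ifelse(m >= 1, pmin(m + wstar, cap), 0L)
    t <- ifelse(s >= 1, s - b, 0L)
    emit_runs("loh_loss", a, xp >= 1, pc$idx)
    emit_runs("loss", b, s >= 2, pc$idx)
    emit_runs("gain", cc, t >= 1, pc$idx)
  }
  if (length(events) == 0)
    return(data.frame(kind = character(0), haplotype = character(0),
                      chrom = character(0), start_seg = integer(0),
                      end_seg = integer(0), start = numeric(0),
                      end = numeric(0), delta = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, events)
  phase <- match(out$kind, c("loh_loss", "wgd", "loss", "gain"))
  out <- out[order(phase, out$chrom, out$start_seg, method = "radix"), ]
  rownames(out) <- NULL
  if (nrow(out) != med) stop("internal error: event count != MED")
  out
}

#' Replay an event table on a profile
#'
#' Applies the events of [extract_events()] in phase order (LOH-phase
#' losses, WGDs, losses, gains) and returns the resulting profile.
#'
#' @param profile starting `cn_profile`.
#' @param events event data.frame from [extract_events()].
#' @param layout the shared `cn_layout`.
#' @return the transformed `cn_profile`.
#' @export
replay_events <- function(profile, events, layout) {
  cap <- profile$cap
  hapA <- profile$hapA; hapB <- profile$hapB
  phase <- match(events$kind, c("loh_loss", "wgd", "loss", "gain"))
  events <- events[order(phase), , drop = FALSE]
  for (r in seq_len(nrow(events))) {
    kind <- events$kind[r]
    if (kind == "wgd") {
      hapA <- ifelse(hapA > 0, pmin(hapA + 1L, cap), 0L)
      hapB <- ifelse(hapB > 0, pmin(hapB + 1L, cap), 0L)
      next
    }
    rows <- which(layout$chrom == events$chrom[r])
    idx <- rows[events$start_seg[r]:events$end_seg[r]]
    v <- if (events$haplotype[r] == "A") hapA[idx] else hapB[idx]
    v2 <- switch(kind,
      loh_loss = ifelse(v > 0, v - 1L, 0L),
      loss = {
        if (any(v == 1)) stop("invalid loss run over a copy-1 segment")
        ifelse(v >= 2, v - 1L, v)
      },
      gain = ifelse(v > 0, pmin(v + 1L, cap), 0L))
    if (events$haplotype[r] == "A") hapA[idx] <- v2 else hapB[idx] <- v2
  }
  cn_profile(profile$sample_id, as.integer(hapA), as.integer(hapB), cap = cap)
}
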