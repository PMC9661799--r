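#' @useDynLib cnmed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a weighted finite-state transducer
#'
#' Machines are weighted transducers over the tropical semiring (min, +):
#' weights are summed along a path and the weight assigned to a pair of
#' strings is the minimum over all accepting paths.  All machines in this
#' package are synchronous (no epsilon transitions): every transition
#' consumes exactly one input symbol and emits exactly one output symbol.
#' Symbols are integer codes in `0:(n_symbols - 1)`; for copy-number
#' machines code `k` is copy number `k` and the highest code is the
#' chromosome separator "X".
#'
#' @param n_states number of states (states are `1:n_states`).
#' @param trans integer matrix with columns `src`, `in`, `out`, `dst`
#'   (states 1-based, symbols 0-based codes).
#' @param w numeric vector of non-negative transition weights, one per row
#'   of `trans`.
#' @param n_symbols alphabet size.
#' @param initial initial state.
#' @param lambda initial weight.
#' @param final_w numeric vector of final weights per state; `Inf` marks a
#'   non-final state.
#' @return an object of class `cn_fst`.
#' @export
fst_new <- function(n_states, trans, w, n_symbols, initial = 1L, lambda = 0,
                    final_w = rep(0, n_states)) {
  trans <- matrix(as.integer(trans), ncol = 4,
                  dimnames = list(NULL, c("src", "in", "out", "dst")))
  stopifnot(length(w) == nrow(trans), all(w >= 0), length(final_w) == n_states,
            initial >= 1, initial <= n_states)
  if (nrow(trans) > 0) {
    stopifnot(all(trans[, c(1, 4)] >= 1), all(trans[, c(1, 4)] <= n_states),
              all(trans[, c(2, 3)] >= 0), all(trans[, c(2, 3)] < n_symbols))
  }
  structure(list(n_states = as.integer(n_states), trans = trans,
                 w = as.numeric(w), n_symbols = as.integer(n_symbols),
                 initial = as.integer(initial), lambda = as.numeric(lambda),
                 final_w = as.numeric(final_w)),
            class = "cn_fst")
}

#' @export
print.cn_fst <- function(x, ...) {
  cat(sprintf("<cn_fst: %d states, %d transitions, alphabet %d>\n",
              x$n_states, nrow(x$trans), x$n_symbols))
  invisible(x)
}

#' Swap input and output labels of a transducer
#'
#' `T[x, y] == fst_invert(T)[y, x]` for all string pairs.
#'
#' @param m a `cn_fst`.
#' @return the inverted `cn_fst`.
#' @export
fst_invert <- function(m) {
  tr <- m$trans
  tr[, c("in", "out")] <- tr[, c("out", "in")]
  m$trans <- tr
  m
}

#' Project a transducer onto its output labels
#'
#' Copies the output symbol onto both labels, preserving weights; the
#' result behaves as a weighted acceptor for the set of output strings.
#'
#' @param m a `cn_fst`.
#' @return the projected `cn_fst`.
#' @export
fst_project_output <- function(m) {
  m$trans[, "in"] <- m$trans[, "out"]
  m
}

#' Linear acceptor for a fixed symbol string
#'
#' A chain machine that accepts exactly `symbols` with weight 0.
#'
#' @param symbols integer vector of 0-based symbol codes.
#' @param n_symbols alphabet size.
#' @return a `cn_fst`.
#' @export
fst_linear_acceptor <- function(symbols, n_symbols) {
  L <- length(symbols)
  stopifnot(L >= 1)
  trans <- cbind(src = seq_len(L), `in` = symbols, out = symbols,
                 dst = seq_len(L) + 1L)
  final_w <- c(rep(Inf, L), 0)
  fst_new(L + 1L, trans, w = rep(0, L), n_symbols = n_symbols,
          final_w = final_w)
}

#' Eager composition of two transducers
#'
#' Builds the reachable product machine: `(T1 o T2)[x, y]` equals
#' `min_z T1[x, z] + T2[z, y]`.  Only states reachable from the initial
#' pair are constructed; parallel transitions with identical labels and
#' endpoints are collapsed to their minimum weight.
#'
#' @param m1,m2 `cn_fst` machines over the same alphabet.
#' @return the composed `cn_fst`.
#' @export
fst_compose <- function(m1, m2) {
  stopifnot(m1$n_symbols == m2$n_symbols)
  nsym <- m1$n_symbols
  # index m1 transitions by src, m2 transitions by (src, in)
  idx1 <- split(seq_len(nrow(m1$trans)), factor(m1$trans[, "src"],
                levels = seq_len(m1$n_states)))
  key2 <- (m2$trans[, "src"] - 1L) * nsym + m2$trans[, "in"]
  idx2 <- split(seq_len(nrow(m2$trans)), factor(key2,
                levels = 0:(m2$n_states * nsym - 1L)))

  pair_id <- new.env(parent = emptyenv())
  pkey <- function(a, b) paste0(a, ",", b)
  states <- list()
  get_id <- function(a, b) {
    k <- pkey(a, b)
    id <- pair_id[[k]]
    if (is.null(id)) {
      id <- length(states) + 1L
      pair_id[[k]] <- id
      states[[id]] <<- c(a, b)
    }
    id
  }
  init <- get_id(m1$initial, m2$initial)
  queue <- c(init)
  n_enqueued <- 1L
  out <- list()
  seen_arc <- new.env(parent = emptyenv())
  head <- 1L
  while (head <= length(queue)) {
    sid <- queue[head]; head <- head + 1L
    a <- states[[sid]][1]; b <- states[[sid]][2]
    for (r1 in idx1[[a]]) {
      mid <- m1$trans[r1, "out"]
      rows2 <- idx2[[(b - 1L) * nsym + mid + 1L]]
      for (r2 in rows2) {
        d <- get_id(m1$trans[r1, "dst"], m2$trans[r2, "dst"])
        if (d > n_enqueued) { queue <- c(queue, d); n_enqueued <- d }
        ww <- m1$w[r1] + m2$w[r2]
        ak <- paste(sid, m1$trans[r1, "in"], m2$trans[r2, "out"], d)
        prev <- seen_arc[[ak]]
        if (is.null(prev) || ww < out[[prev]]$w) {
          if (is.null(prev)) {
            out[[length(out) + 1L]] <- list(src = sid,
                                            i = m1$trans[r1, "in"],
                                            o = m2$trans[r2, "out"],
                                            dst = d, w = ww)
            seen_arc[[ak]] <- length(out)
          } else {
            out[[prev]]$w <- ww
          }
        }
      }
    }
  }
  n <- length(states)
  fw <- vapply(states, function(s) m1$final_w[s[1]] + m2$final_w[s[2]],
               numeric(1))
  if (length(out) == 0) {
    trans <- matrix(integer(0), ncol = 4)
    w <- numeric(0)
  } else {
    trans <- cbind(src = vapply(out, `[[`, 0L, "src"),
                   `in` = vapply(out, function(z) as.integer(z$i), 0L),
                   out = vapply(out, function(z) as.integer(z$o), 0L),
                   dst = vapply(out, `[[`, 0L, "dst"))
    w <- vapply(out, `[[`, 0, "w")
  }
  fst_new(n, trans, w, nsym, initial = init, lambda = m1$lambda + m2$lambda,
          final_w = fw)
}

#' Compose a machine with itself n times
#'
#' `fst_self_compose(m, n)` is `m o m o ... o m` (`n` copies); the result
#' allows up to `n` one-step transductions per position.
#'
#' @param m a `cn_fst`.
#' @param n number of copies, at least 1.
#' @return the composed `cn_fst`.
#' @export
fst_self_compose <- function(m, n) {
  if (n < 1) stop("n must be >= 1")
  acc <- m
  if (n > 1) for (i in 2:n) acc <- fst_compose(acc, m)
  acc
}

# Dijkstra over an explicit machine: min over accepting paths of
# lambda + sum(w) + final weight.  Small machines only (used as the eager
# oracle for the lazy engine).
machine_shortest_distance <- function(m) {
  n <- m$n_states
  dist <- rep(Inf, n)
  dist[m$initial] <- m$lambda
  done <- rep(FALSE, n)
  adj <- split(seq_len(nrow(m$trans)), factor(m$trans[, "src"],
               levels = seq_len(n)))
  repeat {
    u <- which(!done & is.finite(dist))
    if (length(u) == 0) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    for (r in adj[[u]]) {
      v <- m$trans[r, "dst"]
      nd <- dist[u] + m$w[r]
      if (nd < dist[v]) dist[v] <- nd
    }
  }
  min(dist + m$final_w)
}

#' Shortest distance through an eagerly composed chain
#'
#' Materializes `x o chain[[1]] o ... o chain[[k]] o y` by eager
#' composition and runs a single-source shortest-distance algorithm over
#' the result.  Intended for small machines and as the independent oracle
#' for [chain_shortest_path()]; `+Inf` means no accepting path.
#'
#' @param chain list of `cn_fst` machines.
#' @param x,y integer symbol vectors (0-based codes).
#' @param n_symbols alphabet size.
#' @return numeric weight (possibly `Inf`).
#' @export
fst_shortest_distance <- function(chain, x, y, n_symbols) {
  acc <- fst_linear_acceptor(x, n_symbols)
  for (m in chain) acc <- fst_compose(acc, m)
  acc <- fst_compose(acc, fst_linear_acceptor(y, n_symbols))
  machine_shortest_distance(acc)
}

#' Lazy shortest path through a transducer chain
#'
#' Computes the tropical weight of `x o chain o y` without materializing
#' the composition: a best-first search expands the product automaton only
#' along visited paths.  Equal-cost ties are broken deterministically on
#' the packed product state, so the reported optimal path is reproducible.
#'
#' @param chain list of `cn_fst` machines (may be empty: identity).
#' @param x,y integer symbol vectors (0-based codes), equal length.
#' @param n_symbols alphabet size.
#' @param want_path if `TRUE`, also return the optimal path's transitions.
#' @return a list with `weight` (numeric, `Inf` if no accepting path) and,
#'   when `want_path`, `arcs`: an integer matrix with columns `pos`,
#'   `machine`, `in`, `out`, `src`, `dst` plus `arc_weights`.
#' @export
chain_shortest_path <- function(chain, x, y, n_symbols, want_path = FALSE) {
  machines <- lapply(chain, function(m) {
    stopifnot(inherits(m, "cn_fst"), m$n_symbols == n_symbols)
    list(n_states = m$n_states, initial = m$initial, lambda = m$lambda,
         final_w = m$final_w, trans = m$trans, w = m$w)
  })
  chain_shortest_path_cpp(as.integer(x), machines, as.integer(y),
                          as.integer(n_symbols), want_path)
}
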