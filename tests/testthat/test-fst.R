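# Generic weighted-transducer engine: eager composition, inversion,
# projection and the lazy chain shortest path.

nsym <- 4L  # small test alphabet {0, 1, 2, 3}

random_machine <- function(n_states = 3, n_trans = 8, max_w = 3) {
  trans <- cbind(src = sample(n_states, n_trans, TRUE),
                 `in` = sample(0:(nsym - 1), n_trans, TRUE),
                 out = sample(0:(nsym - 1), n_trans, TRUE),
                 dst = sample(n_states, n_trans, TRUE))
  fst_new(n_states, trans, w = sample(0:max_w, n_trans, TRUE),
          n_symbols = nsym)
}

identity_fst <- function() {
  s <- 0:(nsym - 1)
  fst_new(1L, cbind(src = 1L, `in` = s, out = s, dst = 1L),
          w = rep(0, nsym), n_symbols = nsym)
}

# weight a machine assigns to a fixed string pair
pair_weight <- function(m, x, y) fst_shortest_distance(list(m), x, y, nsym)

test_that("composition with the identity leaves weights unchanged", {
  set.seed(1)
  for (i in 1:10) {
    m <- random_machine()
    comp <- fst_compose(identity_fst(), m)
    for (j in 1:5) {
      x <- sample(0:(nsym - 1), 3, TRUE); y <- sample(0:(nsym - 1), 3, TRUE)
      expect_equal(pair_weight(comp, x, y), pair_weight(m, x, y))
    }
  }
})

test_that("composed weights equal the brute-force min over intermediates", {
  set.seed(2)
  for (i in 1:12) {
    m1 <- random_machine(2, 6); m2 <- random_machine(2, 6)
    comp <- fst_compose(m1, m2)
    for (j in 1:4) {
      L <- sample(1:3, 1)
      x <- sample(0:(nsym - 1), L, TRUE); y <- sample(0:(nsym - 1), L, TRUE)
      # enumerate every intermediate string of the same length
      mids <- as.matrix(expand.grid(rep(list(0:(nsym - 1)), L)))
      brute <- min(apply(mids, 1, function(z)
        pair_weight(m1, x, z) + pair_weight(m2, z, y)))
      expect_equal(pair_weight(comp, x, y), brute)
    }
  }
})

test_that("composition is associative on random string pairs", {
  set.seed(3)
  for (i in 1:10) {
    m1 <- random_machine(); m2 <- random_machine(); m3 <- random_machine()
    left <- fst_compose(fst_compose(m1, m2), m3)
    right <- fst_compose(m1, fst_compose(m2, m3))
    for (j in 1:5) {
      x <- sample(0:(nsym - 1), 2, TRUE); y <- sample(0:(nsym - 1), 2, TRUE)
      expect_equal(pair_weight(left, x, y), pair_weight(right, x, y))
    }
  }
})

test_that("inversion is an involution and swaps the weight relation", {
  set.seed(4)
  for (i in 1:10) {
    m <- random_machine()
    expect_identical(fst_invert(fst_invert(m)), m)
    x <- sample(0:(nsym - 1), 3, TRUE); y <- sample(0:(nsym - 1), 3, TRUE)
    expect_equal(pair_weight(m, x, y), pair_weight(fst_invert(m), y, x))
  }
})

test_that("output projection of a single-path transducer accepts its output", {
  # a linear transducer mapping 0 1 2 -> 1 2 3 with weights 1, 0, 2
  m <- fst_new(4L, cbind(src = 1:3, `in` = 0:2, out = 1:3, dst = 2:4),
               w = c(1, 0, 2), n_symbols = nsym,
               final_w = c(Inf, Inf, Inf, 0))
  p <- fst_project_output(m)
  expect_equal(pair_weight(p, c(1, 2, 3), c(1, 2, 3)), 3)
  expect_equal(pair_weight(p, c(0, 1, 2), c(0, 1, 2)), Inf)
})

test_that("shortest distance through the identity chain is 0 or Inf", {
  x <- c(1, 2, 0)
  expect_equal(fst_shortest_distance(list(identity_fst()), x, x, nsym), 0)
  expect_equal(fst_shortest_distance(list(identity_fst()), x, c(1, 2, 1),
                                     nsym), Inf)
  lz <- chain_shortest_path(list(identity_fst()), x, x, nsym,
                            want_path = TRUE)
  expect_equal(lz$weight, 0)
  expect_equal(lz$arcs[, "out"], x)
})

test_that("a hand-built machine yields the minimum over its two paths", {
  # two accepting paths for 0 0 -> 1 1: through state 2 (cost 1 + 2) or
  # state 3 (cost 2 + 0)
  m <- fst_new(4L,
               cbind(src = c(1, 1, 2, 3), `in` = c(0, 0, 0, 0),
                     out = c(1, 1, 1, 1), dst = c(2, 3, 4, 4)),
               w = c(1, 2, 2, 0), n_symbols = nsym,
               final_w = c(Inf, Inf, Inf, 0))
  expect_equal(fst_shortest_distance(list(m), c(0, 0), c(1, 1), nsym), 2)
})

test_that("lazy and eager shortest distances agree on random chains", {
  set.seed(5)
  for (i in 1:60) {
    chain <- lapply(seq_len(sample(1:2, 1)), function(k) random_machine())
    L <- sample(1:4, 1)
    x <- sample(0:(nsym - 1), L, TRUE); y <- sample(0:(nsym - 1), L, TRUE)
    eager <- fst_shortest_distance(chain, x, y, nsym)
    lazy <- chain_shortest_path(chain, x, y, nsym)
    expect_equal(lazy$weight, eager)
  }
})

test_that("the optimal lazy path replays to the output string", {
  set.seed(6)
  n_checked <- 0
  for (i in 1:30) {
    chain <- list(random_machine())
    x <- sample(0:(nsym - 1), 3, TRUE); y <- sample(0:(nsym - 1), 3, TRUE)
    res <- chain_shortest_path(chain, x, y, nsym, want_path = TRUE)
    if (is.finite(res$weight)) {
      expect_equal(res$arcs[, "in"], x)
      expect_equal(res$arcs[, "out"], y)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 0)
})

test_that("self-composition adds one-step options monotonically", {
  gain1 <- cnmed:::one_step_machine("gain", cap = 2L)
  ns <- n_symbols_for_cap(2L)
  expect_error(fst_self_compose(gain1, 0), "n must be")
  # n = 1 leaves weights unchanged
  g1 <- fst_self_compose(gain1, 1)
  expect_equal(fst_shortest_distance(list(g1), c(1, 1), c(2, 2), ns),
               fst_shortest_distance(list(gain1), c(1, 1), c(2, 2), ns))
  # a one-step +1 machine composed twice maps 1 -> 3 at weight 2
  g2 <- fst_self_compose(gain1, 2)
  expect_equal(fst_shortest_distance(list(g2), 1L, 2L, ns), 1)
  expect_equal(fst_shortest_distance(list(g2), 1L, 1L, ns), 0)
  expect_equal(fst_shortest_distance(list(gain1), 1L, 0L, ns), Inf)
  cap3 <- cnmed:::one_step_machine("gain", cap = 3L)
  expect_equal(fst_shortest_distance(list(fst_self_compose(cap3, 2)),
                                     1L, 3L, n_symbols_for_cap(3L)), 2)
  # weights never increase as n grows
  set.seed(7)
  loh1 <- cnmed:::one_step_machine("loh", cap = 3L)
  ns3 <- n_symbols_for_cap(3L)
  for (i in 1:10) {
    x <- sample(0:3, 3, TRUE); y <- sample(0:3, 3, TRUE)
    w_prev <- Inf
    for (n in 1:3) {
      w <- fst_shortest_distance(list(fst_self_compose(loh1, n)), x, y, ns3)
      expect_lte(w, w_prev)
      w_prev <- w
    }
  }
})

test_that("closed-form n-step machines match literal self-composition", {
  set.seed(8)
  cap <- 3L
  ns <- n_symbols_for_cap(cap)
  for (kind in c("loh", "loss", "gain")) {
    one <- cnmed:::one_step_machine(kind, cap)
    for (n in 2:3) {
      lit <- fst_self_compose(one, n)
      closed <- cnmed:::nstep_machine(kind, n, cap)
      for (i in 1:25) {
        L <- sample(1:4, 1)
        x <- sample(0:cap, L, TRUE); y <- sample(0:cap, L, TRUE)
        expect_equal(
          fst_shortest_distance(list(closed), x, y, ns),
          fst_shortest_distance(list(lit), x, y, ns),
          info = sprintf("%s n=%d x=%s y=%s", kind, n,
                         paste(x, collapse = ""), paste(y, collapse = "")))
      }
    }
  }
})
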