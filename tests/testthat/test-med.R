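# The minimum-event distance core: event machines, asymmetric and
# symmetric distances, pairwise matrices and event extraction.

test_that("one-step event machines implement the stated semantics", {
  m <- test_model()
  ns <- m$n_symbols
  # one contiguous +1 run costs 1
  expect_equal(fst_shortest_distance(list(m$T_G), c(1, 1, 1), c(2, 2, 2), ns),
               1)
  # an interior zero is skipped without terminating the run
  expect_equal(fst_shortest_distance(list(m$T_G), c(1, 0, 1), c(2, 0, 2), ns),
               1)
  # runs terminate at the separator: two chromosomes need two runs
  X <- x_symbol(m$cap)
  expect_equal(fst_shortest_distance(list(m$T_G), c(1, X, 1), c(2, X, 2), ns),
               2)
  # WGD lifts every non-zero symbol across separators at cost 1
  lay <- uniform_layout(2, 2)
  dip <- diploid_profile(lay)
  all2 <- cn_profile("t", rep(2L, 4), rep(2L, 4))
  expect_equal(fst_shortest_distance(list(m$T_WGD),
                                     encode_profile(dip, lay),
                                     encode_profile(all2, lay), ns), 1)
})

test_that("asymmetric MED matches hand-derived worked examples", {
  m <- test_model()
  lay <- uniform_layout(1, 3)
  dip <- diploid_profile(lay)
  expect_equal(med_asymmetric(dip, dip, m, lay), 0)
  y <- cn_profile("y", c(2, 0, 2), c(1, 1, 1))
  expect_equal(med_asymmetric(dip, y, m, lay), 2)
  lay2 <- uniform_layout(1, 2)
  x <- cn_profile("x", c(1, 0), c(1, 1))
  y2 <- cn_profile("y", c(1, 1), c(1, 1))
  expect_equal(med_asymmetric(x, y2, m, lay2), Inf)
  expect_equal(med_asymmetric(y2, x, m, lay2), 1)
})

test_that("symmetric MED routes through a witnessing ancestor", {
  m <- test_model()
  lay <- uniform_layout(1, 2)
  dip <- diploid_profile(lay)
  s0 <- med_symmetric(dip, dip, m, lay, ancestor = TRUE)
  expect_equal(s0$weight, 0)
  expect_equal(s0$ancestor$hapA, c(1L, 1L))
  x <- cn_profile("x", c(1, 0), c(1, 1))
  y <- cn_profile("y", c(1, 1), c(1, 1))
  s <- med_symmetric(x, y, m, lay, ancestor = TRUE)
  expect_equal(s$weight, 1)
  expect_equal(s$ancestor$hapA, c(1L, 1L))
  x2 <- cn_profile("x", c(2, 1), c(1, 1))
  y2 <- cn_profile("y", c(1, 2), c(1, 1))
  expect_equal(med_symmetric(x2, y2, m, lay)$weight, 2)
  # ancestor witnesses the optimum: S == med(z, x) + med(z, y)
  set.seed(20)
  cap <- 3L
  m3 <- test_model(cap = cap)
  for (i in 1:25) {
    lay3 <- uniform_layout(sample(1:2, 1), 2)
    a <- random_profile(lay3, cap, "a")
    b <- random_profile(lay3, cap, "b")
    s <- med_symmetric(a, b, m3, lay3, ancestor = TRUE)
    expect_equal(s$weight,
                 med_asymmetric(s$ancestor, a, m3, lay3) +
                   med_asymmetric(s$ancestor, b, m3, lay3))
  }
})

test_that("symmetric MED equals brute force over all ancestors", {
  set.seed(21)
  cap <- 3L
  m <- test_model(cap = cap)
  lay <- uniform_layout(1, 2)
  for (i in 1:6) {
    a <- random_profile(lay, cap, "a")
    b <- random_profile(lay, cap, "b")
    expect_equal(med_symmetric(a, b, m, lay)$weight,
                 brute_symmetric_oracle(a, b, m, lay))
  }
})

test_that("piecewise distances equal the monolithic transducer chain", {
  set.seed(22)
  cap <- 3L
  for (wgd_on in c(TRUE, FALSE)) {
    m <- test_model(cap = cap, wgd = wgd_on, max_wgd = cap)
    for (i in 1:40) {
      lay <- uniform_layout(sample(1:2, 1), sample(2:4, 1))
      x <- random_profile(lay, cap, "x")
      y <- random_profile(lay, cap, "y")
      ex <- encode_profile(x, lay); ey <- encode_profile(y, lay)
      expect_identical(med_asymmetric(x, y, m, lay),
                       chain_shortest_path(m$chain_asym, ex, ey,
                                           m$n_symbols)$weight)
      expect_identical(med_symmetric(x, y, m, lay)$weight,
                       chain_shortest_path(m$chain_sym, ex, ey,
                                           m$n_symbols)$weight)
    }
  }
})

test_that("the conditioned piece solver matches the fixed-WGD transducer chain", {
  set.seed(26)
  cap <- 3L
  m <- test_model(cap = cap)
  for (i in 1:25) {
    L <- sample(2:4, 1)
    x <- sample(0:cap, L, TRUE); y <- sample(0:cap, L, TRUE)
    for (w in 0:2) {
      chain <- list(m$T_LOH, cnmed:::fixed_wgd_fst(w, cap), m$T_L, m$T_G)
      expect_identical(
        cnmed:::med_piece_trace_cpp(x, y, 0L, w, cap, 0L)$weight,
        chain_shortest_path(chain, x, y, m$n_symbols)$weight,
        info = sprintf("w=%d x=%s y=%s", w, paste(x, collapse = ""),
                       paste(y, collapse = "")))
    }
  }
})

test_that("symmetric MED is symmetric, zero on equals, and ancestor-bounded", {
  set.seed(23)
  cap <- 3L
  m <- test_model(cap = cap)
  m0 <- test_model(cap = cap, wgd = FALSE)
  for (i in 1:25) {
    lay <- uniform_layout(sample(1:2, 1), sample(2:4, 1))
    x <- random_profile(lay, cap, "x")
    y <- random_profile(lay, cap, "y")
    sxy <- med_symmetric(x, y, m, lay)$weight
    expect_identical(sxy, med_symmetric(y, x, m, lay)$weight)
    expect_identical(med_symmetric(x, x, m, lay)$weight, 0)
    # taking z = x or z = y bounds the kernel distance
    finite_min <- suppressWarnings(min(med_asymmetric(x, y, m, lay),
                                       med_asymmetric(y, x, m, lay)))
    if (is.finite(finite_min)) expect_lte(sxy, finite_min)
    # allowing WGD can only reduce the distance
    expect_lte(sxy, med_symmetric(x, y, m0, lay)$weight)
    expect_lte(med_asymmetric(diploid_profile(lay, cap), x, m, lay),
               med_asymmetric(diploid_profile(lay, cap), x, m0, lay))
  }
})

test_that("the prime-grid schedule covers every pair exactly once", {
  for (N in 4:50) {
    groups <- pair_schedule(N)
    p <- ceiling(sqrt(N)); while (!cnmed:::is_prime(p)) p <- p + 1
    expect_length(groups, p^2 + p)
    seen <- matrix(0L, N, N)
    for (g in groups) {
      if (length(g) < 2) next
      prs <- utils::combn(g, 2)
      for (k in seq_len(ncol(prs)))
        seen[prs[1, k], prs[2, k]] <- seen[prs[1, k], prs[2, k]] + 1L
    }
    expect_true(all(seen[upper.tri(seen)] == 1L))
  }
})

test_that("pairwise distance matrices are worker-count invariant", {
  coh <- toy_cohort()
  m <- test_model()
  D1 <- pairwise_distances(coh, m, workers = 1L)
  expect_true(isSymmetric(unname(D1)))
  expect_equal(diag(D1), setNames(rep(0, 4), rownames(D1)))
  D8 <- pairwise_distances(coh, m, workers = 8L)
  expect_identical(D1, D8)
  # serial double loop gives the same matrix
  ids <- names(coh$profiles)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    expect_equal(D1[i, j],
                 med_symmetric(coh$profiles[[i]], coh$profiles[[j]], m,
                               coh$layout)$weight)
  }
  # identical profiles give a zero matrix
  lay <- coh$layout
  same <- cn_cohort(lay, list(
    cn_profile("a", rep(1L, 6), rep(1L, 6)),
    cn_profile("b", rep(1L, 6), rep(1L, 6)),
    cn_profile("c", rep(1L, 6), rep(1L, 6))))
  expect_true(all(pairwise_distances(same, m) == 0))
})

test_that("extracted events replay to the target profile", {
  m <- test_model()
  lay <- uniform_layout(1, 3)
  dip <- diploid_profile(lay)
  expect_equal(nrow(extract_events(dip, dip, m, lay)), 0)
  y <- cn_profile("y", c(2, 0, 2), c(1, 1, 1))
  ev <- extract_events(dip, y, m, lay)
  expect_equal(ev$kind, c("loh_loss", "gain"))
  expect_equal(ev$start_seg, c(2L, 1L))
  expect_equal(ev$end_seg, c(2L, 3L))
  # one WGD explains a fully doubled genome
  lay22 <- uniform_layout(22, 10)
  t2 <- cn_profile("t", rep(2L, 220), rep(2L, 220))
  ev2 <- extract_events(diploid_profile(lay22), t2, m, lay22)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$kind, "wgd")
  # infinite distance errors and names the offending segments
  lay2 <- uniform_layout(1, 2)
  expect_error(extract_events(cn_profile("x", c(1, 0), c(1, 1)),
                              cn_profile("y", c(1, 1), c(1, 1)), m, lay2),
               "copy number zero")
  # replay property and |events| == MED on random evolved pairs
  set.seed(24)
  for (i in 1:30) {
    lay <- uniform_layout(sample(1:3, 1), sample(2:6, 1))
    x <- random_profile(lay, 8L, "x")
    y <- evolve_profile(x, lay, 8L, sample(0:6, 1))
    ev <- extract_events(x, y, m, lay)
    expect_equal(nrow(ev), med_asymmetric(x, y, m, lay))
    z <- replay_events(x, ev, lay)
    expect_identical(z$hapA, y$hapA)
    expect_identical(z$hapB, y$hapB)
  }
})

test_that("search effort grows linearly in the number of segments", {
  # same three events placed at proportional positions on genomes of
  # increasing length; the DP insertion count must scale like the
  # segment count (a quadratic search would grow 64-fold here)
  m <- test_model()
  ops_for <- function(L) {
    lay <- uniform_layout(1, L)
    hA <- rep(1L, L); hB <- rep(1L, L)
    g <- function(f) round(L * f)
    hA[g(0.1):g(0.2)] <- 2L
    hB[g(0.5):g(0.6)] <- 0L
    hA[g(0.8):g(0.9)] <- 2L
    p <- cn_profile("p", hA, hB)
    cnmed:::dp_op_counter_cpp(TRUE)
    med_asymmetric(diploid_profile(lay), p, m, lay)
    cnmed:::dp_op_counter_cpp(FALSE)
  }
  o25 <- ops_for(25); o200 <- ops_for(200)
  expect_lte(o200 / o25, 16)  # 8x length: linear predicts ~8x
  expect_gte(o200 / o25, 4)
})

test_that("event extraction is deterministic across runs", {
  m <- test_model()
  lay <- uniform_layout(2, 4)
  set.seed(25)
  x <- random_profile(lay, 8L, "x")
  y <- evolve_profile(x, lay, 8L, 5)
  expect_identical(extract_events(x, y, m, lay), extract_events(x, y, m, lay))
})
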