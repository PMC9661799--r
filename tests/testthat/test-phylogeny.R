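# Neighbor joining, rooting, ancestral reconstruction and tree metrics.

test_that("NJ recovers additive matrices exactly", {
  # tree ((A:2,B:3):1,(C:4,D:5)); pairwise path lengths by hand
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  truth <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):0);")
  expect_equal(robinson_foulds(tr, truth), 0)
  expect_equal(sum(tr$edge.length), 15)
  # recovered pairwise distances equal the input (additivity)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(D), rownames(D)],
               D)
})

test_that("NJ is deterministic and validates its input", {
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
  D2 <- D; D2[1, 2] <- 5
  expect_error(neighbor_joining(D2), "symmetric")
  D3 <- D; D3[1, 2] <- D3[2, 1] <- -1
  expect_error(neighbor_joining(D3), "non-negative")
})

test_that("3-taxon NJ solves the three-point formulas", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  # branch lengths: a = (3+5-6)/2 = 1, b = (3+6-5)/2 = 2, c = (5+6-3)/2 = 4
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 2, c = 4))
})

test_that("NJ recovers random additive trees (consistency property)", {
  set.seed(41)
  for (i in 1:8) {
    n <- sample(8:16, 1)
    truth <- ape::rtree(n)
    D <- as.matrix(ape::cophenetic.phylo(truth))
    tr <- neighbor_joining(D)
    expect_equal(robinson_foulds(tr, truth), 0)
  }
})

test_that("rooting at the diploid is idempotent and length-preserving", {
  D <- matrix(c(0, 2, 4, 5,
                2, 0, 4, 5,
                4, 4, 0, 3,
                5, 5, 3, 0), 4, 4,
              dimnames = list(c("s1", "s2", "s3", "diploid"),
                              c("s1", "s2", "s3", "diploid")))
  tr <- neighbor_joining(D)
  r1 <- root_at_diploid(tr)
  expect_true(ape::is.rooted(r1))
  root_children <- r1$edge[r1$edge[, 1] == length(r1$tip.label) + 1L, 2]
  expect_true(which(r1$tip.label == "diploid") %in% root_children)
  r2 <- root_at_diploid(r1)
  expect_equal(ape::write.tree(r2), ape::write.tree(r1))
  # ingroup path lengths unchanged by rooting
  d0 <- as.matrix(ape::cophenetic.phylo(tr))
  d1 <- as.matrix(ape::cophenetic.phylo(r1))
  ids <- c("s1", "s2", "s3")
  expect_equal(d1[ids, ids], d0[ids, ids])
  expect_error(root_at_diploid(ape::rtree(4)), "no 'diploid' leaf")
})

test_that("reconstruction of two leaves plus the diploid is Steiner-optimal", {
  cap <- 3L
  m <- test_model(cap = cap)
  lay <- uniform_layout(1, 3)
  x <- cn_profile("x", c(2, 2, 1), c(1, 0, 1), cap = cap)
  y <- cn_profile("y", c(2, 1, 1), c(1, 1, 2), cap = cap)
  coh <- cn_cohort(lay, list(x, y), cap = cap)
  D <- pairwise_distances(coh, m)
  phy <- reconstruct_ancestors(root_at_diploid(neighbor_joining(D)), coh, m,
                               coordinate_refine = TRUE)
  tl <- sum(phy$tree$edge.length)
  # exhaustive Steiner point for the single internal node
  dip <- diploid_profile(lay, cap)
  grids <- do.call(expand.grid, rep(list(0:cap), 6))
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    z <- cn_profile("z", as.integer(grids[r, 1:3]), as.integer(grids[r, 4:6]),
                    cap = cap)
    tot <- med_asymmetric(dip, z, m, lay) + med_asymmetric(z, x, m, lay) +
      med_asymmetric(z, y, m, lay)
    best <- min(best, tot)
  }
  expect_equal(tl, best)
})

test_that("identical leaves reconstruct to themselves above the root", {
  m <- test_model()
  lay <- uniform_layout(1, 4)
  p <- cn_profile("s", c(2, 2, 1, 1), c(1, 1, 1, 1))
  profs <- lapply(1:3, function(i) { q <- p; q$sample_id <- paste0("s", i); q })
  coh <- cn_cohort(lay, profs)
  D <- pairwise_distances(coh, m)
  phy <- reconstruct_ancestors(root_at_diploid(neighbor_joining(D)), coh, m)
  expect_equal(sum(phy$tree$edge.length),
               med_asymmetric(diploid_profile(lay), p, m, lay))
  ntip <- length(phy$tree$tip.label)
  for (v in (ntip + 2):(ntip + phy$tree$Nnode))
    expect_identical(phy$profiles[[v]]$hapA, p$hapA)
})

test_that("reconstruction replays leaves exactly on a simulated cohort", {
  cfg <- genome_sim_config(mu = 0.02, wgd_prob = 0.0125)
  tree <- simulate_topology(6, seed = 77)
  sim <- evolve_genomes(tree, cfg, seed = 77)
  m <- test_model()
  D <- pairwise_distances(sim$cohort, m)
  phy <- reconstruct_ancestors(root_at_diploid(neighbor_joining(D)),
                               sim$cohort, m)
  tr <- phy$tree
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
    ev <- extract_events(phy$profiles[[a]], phy$profiles[[b]], m,
                         sim$cohort$layout)
    expect_equal(nrow(ev), tr$edge.length[e])
    z <- replay_events(phy$profiles[[a]], ev, sim$cohort$layout)
    expect_identical(z$hapA, phy$profiles[[b]]$hapA)
    expect_identical(z$hapB, phy$profiles[[b]]$hapB)
  }
})

test_that("tree statistics follow the path-length definitions", {
  # chain: root -> A (2) -> B (3), diploid hangs off the root
  tr <- ape::read.tree(text = "((B:3,A:0):2,diploid:0);")
  st <- tree_stats(tr)
  expect_equal(st$trunk_length, 2)
  expect_equal(st$max_root_to_leaf, 5)
  expect_equal(st$trunk_fraction, 0.4)
  expect_equal(st$tree_length, 5)
  # a star over identical samples: trunk is the full root-to-leaf path
  tr2 <- ape::read.tree(text = "((a:0,b:0,c:0):4,diploid:0);")
  st2 <- tree_stats(tr2)
  expect_equal(st2$trunk_fraction, 1)
  # tree length dominates any root-to-leaf path
  expect_gte(st$tree_length, st$max_root_to_leaf)
})

test_that("Robinson-Foulds counts bipartitions in exactly one tree", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_equal(robinson_foulds(t1, t2), 2)
  expect_error(robinson_foulds(t1, ape::read.tree(text = "((a,b),(c,e));")),
               "differing leaf sets")
  # symmetry and agreement with the independent phangorn implementation
  set.seed(43)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    r1 <- ape::rtree(n); r2 <- ape::rtree(n)
    expect_equal(robinson_foulds(r1, r2), robinson_foulds(r2, r1))
    expect_equal(robinson_foulds(r1, r2),
                 as.integer(phangorn::RF.dist(r1, r2)))
  }
})
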