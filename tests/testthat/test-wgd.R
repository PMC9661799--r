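# WGD evidence scoring and counting, resampling, branch support, tree
# events and region scores.

test_that("WGD evidence score and count behave on canonical genomes", {
  lay22 <- uniform_layout(22, 10)
  expect_equal(wgd_evidence(diploid_profile(lay22), lay22)$s, 0)
  expect_equal(wgd_evidence(diploid_profile(lay22), lay22)$wgd_count, 0)
  # a uniformly doubled genome: 44 per-chromosome-haplotype gain runs
  # without WGD versus a single WGD event
  t2 <- cn_profile("t", rep(2L, 220), rep(2L, 220))
  r <- wgd_evidence(t2, lay22)
  expect_equal(r$med_nowgd, 44)
  expect_equal(r$med_wgd, 1)
  expect_equal(r$s, 43)
  expect_equal(r$wgd_count, 1)
})

test_that("the bounded-WGD distance detects two WGDs on a ploidy-6 genome", {
  # an all-(3,3) genome over two chromosomes realizes the two-WGD
  # signature: the distance stops improving once two WGDs are allowed
  lay <- uniform_layout(2, 10)
  t3 <- cn_profile("t", rep(3L, 20), rep(3L, 20))
  dip <- diploid_profile(lay)
  meds <- vapply(1:3, function(n)
    med_asymmetric(dip, t3, test_model(max_wgd = n), lay), 0)
  expect_equal(meds, c(5, 2, 2))
  expect_equal(wgd_evidence(t3, lay)$wgd_count, 2)
  # an all-(4,4) genome needs three +1 WGD events
  t4 <- cn_profile("t", rep(4L, 20), rep(4L, 20))
  meds4 <- vapply(1:4, function(n)
    med_asymmetric(dip, t4, test_model(max_wgd = n), lay), 0)
  expect_equal(meds4, c(9, 6, 3, 3))
  expect_equal(wgd_evidence(t4, lay)$wgd_count, 3)
  # the bounded distance is non-increasing in the allowed WGD count
  expect_true(all(diff(meds4) <= 0))
})

test_that("chromosome bootstrap on one chromosome reproduces the original", {
  lay <- uniform_layout(1, 5)
  coh <- cn_cohort(lay, list(cn_profile("s", c(2, 2, 1, 1, 0),
                                        c(1, 1, 1, 1, 1))))
  reps <- resample_cohort(coh, "chromosome_bootstrap", B = 5, seed = 1)
  for (rc in reps) {
    expect_equal(rc$profiles[["s"]]$hapA, c(2L, 2L, 1L, 1L, 0L))
    expect_equal(layout_nseg(rc$layout), 5)
  }
})

test_that("the jackknife retains segments in order without duplicates", {
  lay <- uniform_layout(4, 10)
  coh <- cn_cohort(lay, list(cn_profile("s", rep(2L, 40), rep(1L, 40))))
  reps <- resample_cohort(coh, "segment_jackknife", B = 50, seed = 3)
  fr <- vapply(reps, function(rc) layout_nseg(rc$layout) / 40, 0)
  expect_true(all(fr > 0.3 & fr < 0.95))
  # identical seed reproduces identical replicates
  reps2 <- resample_cohort(coh, "segment_jackknife", B = 50, seed = 3)
  expect_identical(reps, reps2)
  # a different seed gives different replicates
  reps3 <- resample_cohort(coh, "segment_jackknife", B = 50, seed = 4)
  expect_false(identical(reps, reps3))
})

test_that("bootstrap WGD calls separate doubled from diploid genomes", {
  lay <- uniform_layout(5, 4)
  dip <- diploid_profile(lay)
  r0 <- call_wgd_with_bootstrap(dip, lay, B = 20, seed = 5)
  expect_equal(r0$bootstrap_fraction, 0)
  expect_false(r0$call)
  t2 <- cn_profile("t", rep(2L, 20), rep(2L, 20))
  r2 <- call_wgd_with_bootstrap(t2, lay, B = 20, seed = 5)
  expect_equal(r2$bootstrap_fraction, 1)
  expect_true(r2$call)
  # threshold monotonicity: a permissive threshold calls a superset
  r_strict <- call_wgd_with_bootstrap(t2, lay, B = 20, threshold = 0.5,
                                      seed = 5)
  expect_true(r2$call >= r_strict$call)
})

test_that("branch support counts replicate bipartitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  sup <- branch_support(t1, list(t1, t1, t1))
  expect_true(all(sup$node.label[sup$node.label != ""] == "100"))
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  sup2 <- branch_support(t1, list(t1, t2))
  expect_true("50" %in% sup2$node.label)
  # invariant to replicate order
  sup3 <- branch_support(t1, list(t2, t1))
  expect_equal(sup2$node.label, sup3$node.label)
  expect_error(branch_support(t1, list(ape::read.tree(text = "((a,b),(c,e));"))),
               "share the leaf set")
})

test_that("tree events place clonal changes on the trunk and homoplasy apart", {
  m <- test_model()
  lay <- uniform_layout(1, 4)
  # clonal gain: present in every leaf -> a single event at the MRCA
  gain <- c(2L, 2L, 1L, 1L)
  profs <- list(cn_profile("s1", gain, rep(1L, 4)),
                cn_profile("s2", gain, rep(1L, 4)),
                cn_profile("s3", c(2L, 2L, 2L, 1L), rep(1L, 4)))
  coh <- cn_cohort(lay, profs)
  phy <- reconstruct_ancestors(
    root_at_diploid(neighbor_joining(pairwise_distances(coh, m))), coh, m)
  ev <- detect_tree_events(phy)
  trunk_gains <- ev[ev$kind == "gain" & ev$start_seg == 1 & ev$end_seg == 2, ]
  expect_equal(nrow(trunk_gains), 1)
  expect_false(trunk_gains$child %in% c("s1", "s2", "s3"))
  # mirrored (MSAI) gains on sibling leaves stay on the terminal branches
  profs2 <- list(cn_profile("m1", c(2L, 1L, 1L, 1L), rep(1L, 4)),
                 cn_profile("m2", rep(1L, 4), c(2L, 1L, 1L, 1L)),
                 cn_profile("m3", c(1L, 1L, 1L, 2L), rep(1L, 4)))
  coh2 <- cn_cohort(lay, profs2)
  phy2 <- reconstruct_ancestors(
    root_at_diploid(neighbor_joining(pairwise_distances(coh2, m))), coh2, m)
  ev2 <- detect_tree_events(phy2)
  g1 <- ev2[ev2$kind == "gain" & ev2$start_seg == 1 & ev2$end_seg == 1, ]
  expect_equal(sort(g1$child), c("m1", "m2"))
  expect_equal(sort(g1$haplotype), c("A", "B"))
  # a leaf identical to its parent carries no events
  expect_equal(sum(ev$child == "s1") + sum(ev$child == "s2"), 0)
})

test_that("region scores honor the 90% overlap rule and count WGDs", {
  lay <- uniform_layout(1, 4)
  events <- data.frame(kind = c("gain", "loss", "wgd"),
                       haplotype = c("A", "A", "both"),
                       chrom = c("chr1", "chr1", NA),
                       start_seg = c(1L, 3L, NA), end_seg = c(2L, 3L, NA),
                       start = c(0, 2e6, NA), end = c(2e6, 3e6, NA),
                       delta = c(1L, -1L, 1L), stringsAsFactors = FALSE)
  regions <- data.frame(chrom = "chr1", start = 0, end = 2e6, name = "r1")
  sc <- score_regions(events, regions, lay)
  expect_equal(sc$gains, 2)  # the spanning gain plus the WGD
  expect_equal(sc$losses, 0)
  expect_equal(sc$net, 2)
  # a region covered only 80% by the event is not counted
  regions2 <- data.frame(chrom = "chr1", start = 0, end = 2.5e6, name = "r2")
  sc2 <- score_regions(events, regions2, lay)
  expect_equal(sc2$gains, 1)  # only the WGD
  # regions on unknown chromosomes are dropped with a warning
  expect_warning(score_regions(events,
                               data.frame(chrom = "chrX", start = 0, end = 1,
                                          name = "bad"), lay),
                 "unknown chromosomes")
})
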