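# cached event models shared across tests (machines depend only on the
# cap and WGD settings)
test_model <- function(cap = 8L, wgd = TRUE, max_wgd = cap)
  cnmed:::get_model(cap, wgd, max_wgd)

# tiny cohort with hand-built profiles on a shared layout
toy_cohort <- function() {
  lay <- uniform_layout(2, 3)
  p1 <- cn_profile("s1", c(2, 2, 2, 1, 1, 1), c(1, 1, 1, 1, 1, 1))
  p2 <- cn_profile("s2", c(2, 2, 2, 1, 1, 1), c(1, 1, 0, 1, 1, 1))
  p3 <- cn_profile("s3", c(1, 1, 1, 2, 2, 1), c(1, 1, 1, 1, 1, 1))
  cn_cohort(lay, list(p1, p2, p3))
}
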