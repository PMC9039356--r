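# Synthetic genome and walking-fixture generator.

test_that("random genomes are reproducible with controlled composition", {
  g1 <- make_genome(10000, 0.5, seed = 7)
  g2 <- make_genome(10000, 0.5, seed = 7)
  expect_identical(g1$seq, g2$seq)
  g3 <- make_genome(10000, 0.6, seed = 7)
  gc <- mean(strsplit(g3$seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.6), 0.03)
  expect_false(identical(g3$seq, g1$seq))
  expect_error(make_genome(10), class = "wwpcr_input_error")
  expect_error(make_genome(5000, 1.2), class = "wwpcr_input_error")
})

test_that("fixtures plant what they promise", {
  w <- cached_walk(7)
  fx <- w$fx
  # planted walking-primer sites all appear in the truth set at the
  # arithmetically expected tertiary size
  g3s <- fx$gsp_ref_start[3]
  m <- nchar(fx$wwps$sequence[1])
  for (i in seq_len(nrow(fx$planted_sites))) {
    j <- fx$planted_sites$three_prime_pos[i]
    expect_true(j %in% fx$truth_amplicons$three_prime_pos)
    expect_equal(fx$planted_sites$tertiary_size[i], j + m - g3s)
  }
  # decoy cassettes: requested count, recorded coordinates carry the decoy
  expect_equal(nrow(fx$decoy_sites), 2L)
  gsp1 <- fx$gsps$sequence[1]
  for (i in seq_len(nrow(fx$decoy_sites))) {
    d <- fx$decoy_sites$gsp_three_prime_pos[i]
    planted <- substr(fx$genome$seq, d + 1, d + nchar(gsp1))
    # one terminal mismatch: 24 of 25 positions match the exact complement
    diffs <- sum(strsplit(planted, "")[[1]] !=
                   strsplit(dna_revcomp(gsp1), "")[[1]])
    expect_equal(diffs, fx$decoy_sites$mismatches[i])
  }
  # the known region sits inside the genome and hosts all three GSPs
  expect_true(fx$known_region[1] >= 0 &&
                fx$known_region[2] <= nchar(fx$genome$seq))
  for (s in fx$gsps$sequence)
    expect_true(grepl(s, substr(fx$genome$seq, fx$known_region[1] + 1,
                                fx$known_region[2]), fixed = TRUE))
})

test_that("decoys yield primary-round type II products that later vanish", {
  w <- cached_walk(7)
  p1 <- w$res$rounds[[1]]
  expect_gt(sum(p1$product_class == "typeII" &
                  p1$amplification_class == "exponential"), 0)
  for (rd in 2:3) {
    p <- w$res$rounds[[rd]]
    expect_equal(sum(p$product_class == "typeII" &
                       p$amplification_class == "exponential"), 0L)
  }
})

test_that("truth enumeration is reproducible and simulator-independent", {
  w <- cached_walk(7)
  fx <- w$fx
  truth2 <- enumerate_truth_amplicons(
    fx$genome$seq, fx$gsp_ref_start, fx$gsp_len,
    setNames(fx$wwps$sequence[1:3], fx$wwps$name[1:3]),
    default_profiles(), thermo_model())
  expect_identical(fx$truth_amplicons, truth2)
  # and the simulator's bands match it exactly (both directions)
  expect_identical(sort(w$res$final_bands$size),
                   sort(as.integer(truth2$tertiary_size)))
})

test_that("different seeds give different genomes satisfying the invariants", {
  fx_a <- make_walk_fixture(seed = 101)
  fx_b <- make_walk_fixture(seed = 102)
  expect_false(identical(fx_a$genome$seq, fx_b$genome$seq))
  for (fx in list(fx_a, fx_b)) {
    expect_gt(nrow(fx$truth_amplicons), 0)
    expect_true(all(fx$truth_amplicons$tertiary_size > 0))
    expect_true(all(fx$truth_amplicons$tertiary_size <=
                      fx$extension_cap + nchar(fx$wwps$sequence[1])))
    expect_true(all(fx$truth_amplicons$three_prime_pos >= fx$junction - 200))
  }
})
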