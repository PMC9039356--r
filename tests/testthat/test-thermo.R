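# Nearest-neighbor Tm, wristwatch duplexes, site scanning, structure screens.

wwp1 <- "CGTCTCCAGTCTCCATGTGTTCGTC"
wwp2 <- "CGTCTCCAGTCTTAGGCACAGTGTC"
wwp3 <- "CGTCTCCAGTCTAGTCAGTCAGGTC"
model <- thermo_model()

test_that("perfect-duplex Tm matches independent oracles", {
  # frozen values from an external nearest-neighbor implementation
  # (unified 1998 parameters, 50 mM Na+, 200 nM primer, primer excess)
  expect_equal(tm_perfect_duplex(wwp1, model), 62.184, tolerance = 0.01)
  expect_equal(tm_perfect_duplex(wwp2, model), 61.918, tolerance = 0.01)
  expect_equal(tm_perfect_duplex(wwp3, model), 60.744, tolerance = 0.01)
  expect_equal(tm_perfect_duplex("ACGTACGTACGTACGTACGT", model),
               56.775, tolerance = 0.01)
  # hand-summed oracle agreement to 0.1 C on assorted sequences
  set.seed(5)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:30, 1), TRUE), collapse = "")
    expect_equal(tm_perfect_duplex(s, model), oracle_tm_nn(s), tolerance = 0.1)
  }
})

test_that("published walking primers melt in the 60-65 C window", {
  for (s in c(wwp1, wwp2, wwp3)) {
    tm <- tm_perfect_duplex(s, model)
    expect_gte(tm, 60); expect_lte(tm, 65)
  }
})

test_that("input validation distinguishes short and degenerate sequences", {
  expect_error(tm_perfect_duplex("ACGT", model), class = "wwpcr_short_sequence_error")
  expect_error(tm_perfect_duplex("ACGTNACGTA", model),
               class = "wwpcr_degenerate_base_error")
  expect_error(tm_perfect_duplex("acgtRacgta", model),
               class = "wwpcr_degenerate_base_error")
})

test_that("Tm is strand symmetric", {
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(8:40, 1), TRUE), collapse = "")
    expect_equal(tm_perfect_duplex(s, model),
                 tm_perfect_duplex(dna_revcomp(s), model), tolerance = 1e-6)
  }
})

test_that("wristwatch duplex Tm behaves across mask regimes", {
  arch_mask <- c(1:12, 23:25)
  ww <- tm_wristwatch_duplex(wwp2, dna_revcomp(wwp1), arch_mask, model)
  # the inter-primer annealing temperature is approximately 40 C
  expect_gte(ww, 33); expect_lte(ww, 47)
  # full mask reduces exactly to the perfect duplex
  expect_identical(tm_wristwatch_duplex(wwp1, dna_revcomp(wwp1), 1:25, model),
                   tm_perfect_duplex(wwp1, model))
  # a 3-bp 3' block alone is far less stable than the 15-bp wristwatch
  expect_lt(tm_wristwatch_duplex(wwp2, dna_revcomp(wwp1), 23:25, model), ww)
  # error paths
  expect_error(tm_wristwatch_duplex(wwp1, dna_revcomp(wwp2), 13:25, model),
               class = "wwpcr_noncomplementary_error")
  expect_error(tm_wristwatch_duplex(wwp1, dna_revcomp(wwp1), 1:12, model),
               class = "wwpcr_mask_error")  # 3' terminus unpaired
})

test_that("adding paired content never destabilizes the duplex materially", {
  # Strict monotonicity does not hold for the unified nearest-neighbor
  # parameters (an added terminal A/T pair can lower Tm slightly); the
  # working property is bounded: growth never costs more than 1 C and the
  # overall ordering (3' block < wristwatch < full duplex) is strict.
  set.seed(21)
  for (rep in 1:20) {
    p <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    site <- dna_revcomp(p)
    last <- -Inf
    for (len in 3:25) {
      cur <- tm_wristwatch_duplex(p, site, (25 - len + 1):25, model)
      expect_gte(cur, last - 1)
      last <- cur
    }
    expect_identical(last, tm_perfect_duplex(p, model))
  }
})

test_that("scan finds planted perfect sites and nothing else at high stringency", {
  set.seed(1)
  bg <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  tpl <- paste0(substr(bg, 1, 1000), dna_revcomp(wwp1), substr(bg, 1026, 2000))
  hits <- scan_annealing_sites(wwp1, tpl, 65, model)
  expect_equal(hits$three_prime_pos, 1000L)
  expect_equal(hits$terminal_match_run, 25L)
  unrelated <- paste(rep(c("A", "C"), length.out = 25), collapse = "")
  expect_equal(nrow(scan_annealing_sites(unrelated, tpl, 65, model)), 0L)
})

test_that("scan equals the exhaustive-offset oracle and nests with temperature", {
  for (seed in c(3, 17, 29)) {
    tpl <- make_scan_template(seed, wwp1)
    lo <- scan_annealing_sites(wwp1, tpl, 25, model)$three_prime_pos
    expect_identical(lo, brute_force_scan(wwp1, tpl, 25, model))
    hi <- scan_annealing_sites(wwp1, tpl, 65, model)$three_prime_pos
    expect_identical(hi, brute_force_scan(wwp1, tpl, 65, model))
    # higher stringency returns a subset of the lower-stringency sites
    expect_true(all(hi %in% lo))
  }
})

test_that("structure screens flag palindromes and forced dimers", {
  pal <- "TTTTTTGAATTCGAATTCTTTTTT"
  expect_false(structure_screens(pal, model = model)$self_dimer_pass)
  # published WWP x GSP pair is dimer-clean
  expect_true(structure_screens(wwp1, "TCCATACCCTCATCTCCATTTCCAT", model)$pass)
  # a sequence against its own reverse complement is a full-length dimer
  s <- "ACCGTTCATAGGCGAAATTGTTTGT"
  scr <- structure_screens(s, dna_revcomp(s), model)
  expect_equal(scr$cross_dimer_run, nchar(s))
  expect_false(scr$cross_dimer_pass)
})

test_that("thermo model invariants are enforced", {
  expect_error(thermo_model(monovalent_salt = 0), class = "wwpcr_input_error")
  expect_error(thermo_model(primer_conc = -1), class = "wwpcr_input_error")
  expect_error(thermo_model(min_3prime_match = 1), class = "wwpcr_input_error")
})
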