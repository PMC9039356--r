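# Staged-stringency round simulation, species classification, band prediction.

model <- thermo_model()

test_that("cycling profiles enforce the single partial-annealing cycle", {
  expect_error(cycling_profile(stage2 = c(40, 2)), class = "wwpcr_profile_error")
  expect_error(cycling_profile(stage1 = c(20, 5), stage2 = c(25, 1)),
               class = "wwpcr_profile_error")
  # hand-built profile smuggling extra stage-2 cycles is rejected at run time
  bad <- cycling_profile()
  bad$stage2[["cycles"]] <- 3
  expect_error(simulate_round(genome_pool(strrep("ACGT", 300)),
                              c(GSP = strrep("ACGT", 6)),
                              c(WWP = strrep("AC", 12)), profile = bad),
               class = "wwpcr_profile_error")
})

test_that("primary round: exponential species are bounded by GSP1 and WWP1", {
  w <- cached_walk(7)
  p1 <- w$res$rounds[[1]]
  expo <- p1[p1$amplification_class == "exponential", ]
  expect_gt(nrow(expo), 0)
  # every exponential species is primed by one of the current primers ...
  expect_true(all(expo$five_prime_primer %in% c(w$res$gsps[1], w$res$wwps[1])))
  # ... and every amplicon-bounded one runs from the GSP to the walking primer
  both <- expo[!is.na(expo$three_prime_primer), ]
  expect_gt(nrow(both), 0)
  for (i in seq_len(nrow(both))) {
    expect_setequal(c(both$five_prime_primer[i], both$three_prime_primer[i]),
                    c(w$res$gsps[1], w$res$wwps[1]))
  }
})

test_that("a genome without the anchor yields no exponential species", {
  g <- make_genome(3000, 0.5, seed = 31)
  gsp <- c(GSP1 = "TCCATACCCTCATCTCCATTTCCAT")
  wwp <- c(WWP1 = "CGTCTCCAGTCTCCATGTGTTCGTC")
  pool <- simulate_round(genome_pool(g$seq), gsp, wwp,
                         profile = cycling_profile(), model = model)
  expect_equal(sum(pool$amplification_class == "exponential"), 0L)
})

test_that("secondary-round wristwatch events equal the recount of previous-WWP termini", {
  w <- cached_walk(7)
  p2 <- w$res$rounds[[2]]
  wwp2 <- w$res$wwps[2]
  w1_seq <- w$fx$wwps$sequence[w$fx$wwps$name == w$res$wwps[1]]
  # stage-2 templates are every pool species except this round's WWP2 products
  templates <- p2[is.na(p2$five_prime_primer) | p2$five_prime_primer != wwp2, ]
  recount <- sum(endsWith(templates$seq, dna_revcomp(w1_seq)))
  expect_gt(recount, 0)
  expect_equal(w$res$stage_logs$wristwatch_events[2], recount)
})

test_that("species classification follows primer provenance", {
  primers <- c(gsp = "GSP1", wwp = "WWP1")
  mk <- function(p1, p2, start = 100L, end = 400L, strand = "-")
    list(five_prime_primer = p1, three_prime_primer = p2,
         strand = strand, start = start, end = end)
  expect_equal(classify_species(mk("WWP1", "WWP1"), 50L, primers), "typeIII")
  expect_equal(classify_species(mk("GSP1", "GSP1"), 50L, primers), "typeI")
  # GSP+WWP: on a minus-strand species the GSP complement at the 3' end puts
  # the GSP 5' base at the reference start coordinate
  expect_equal(classify_species(mk("WWP1", "GSP1", start = 100L), 100L, primers),
               "target")
  expect_equal(classify_species(mk("WWP1", "GSP1", start = 100L), 250L, primers),
               "typeII")
  expect_error(classify_species(mk(NA_character_, "GSP1"), 50L, primers),
               class = "wwpcr_provenance_error")
})

test_that("full walk recovers wristwatch-bounded target bands", {
  w <- cached_walk(7)
  fb <- w$res$final_bands
  expect_gt(nrow(fb), 0)
  w3_seq <- w$fx$wwps$sequence[w$fx$wwps$name == w$res$wwps[3]]
  gsp3_seq <- w$fx$gsps$sequence[3]
  for (i in seq_len(nrow(fb))) {
    expect_true(startsWith(fb$seq[i], w3_seq))
    expect_true(endsWith(fb$seq[i], dna_revcomp(gsp3_seq)))
    expect_equal(fb$product_class[i], "target")
  }
  cap <- w$res$extension_cap
  expect_true(all(fb$size <= cap + nchar(w3_seq)))
  # no type III species is ever exponential after the primary round
  for (rd in 2:3) {
    p <- w$res$rounds[[rd]]
    expect_equal(sum(p$product_class == "typeIII" &
                       p$amplification_class == "exponential"), 0L)
  }
})

test_that("tertiary bands nest inside secondary bands by the GSP offset", {
  w <- cached_walk(7)
  off <- w$fx$gsp_ref_start[3] - w$fx$gsp_ref_start[2]
  r2 <- w$res$rounds[[2]]
  r2b <- r2[r2$amplification_class == "exponential" &
              !is.na(r2$five_prime_primer) &
              r2$five_prime_primer == w$res$wwps[2] &
              !is.na(r2$three_prime_primer) &
              r2$three_prime_primer == w$res$gsps[2], ]
  r2_sizes <- sort(unique(nchar(r2b$seq)))
  r3_sizes <- sort(unique(w$res$final_bands$size))
  expect_true(all(r2_sizes %in% (r3_sizes + off)))
})

test_that("identical inputs give identical walk results", {
  w <- cached_walk(7)
  perm <- setNames(w$fx$wwps$sequence, w$fx$wwps$name)
  res2 <- simulate_walk(w$fx$genome, w$fx$known_region, w$fx$gsps, perm)
  expect_identical(w$res$final_bands, res2$final_bands)
  expect_identical(w$res$stage_logs, res2$stage_logs)
  for (rd in 1:3)
    expect_identical(w$res$rounds[[rd]]$id, res2$rounds[[rd]]$id)
})

test_that("band pattern is unique sizes in descending order", {
  w <- cached_walk(7)
  bands <- predict_band_pattern(w$res)
  expect_false(is.unsorted(rev(bands$size)))
  expect_equal(anyDuplicated(bands$size), 0L)
  empty <- structure(list(final_bands = w$res$final_bands[0, ]),
                     class = "walk_result")
  expect_equal(nrow(predict_band_pattern(empty)), 0L)
})

test_that("missing GSPs in the known region are rejected", {
  g <- make_genome(3000, 0.5, seed = 8)
  expect_error(
    simulate_walk(g, c(500, 1500),
                  c(GSP1 = strrep("ACGTC", 5), GSP2 = strrep("CATGA", 5),
                    GSP3 = strrep("GACTG", 5)),
                  setNames(published_primers()$sequence[1:3], c("W1", "W2", "W3"))),
    class = "wwpcr_input_error")
})
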