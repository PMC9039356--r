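# WWP set validation and generation, GSP nest design, walking permutations.

model <- thermo_model()
arch <- wwp_architecture()
t1 <- published_primers()
wwp_seqs <- setNames(t1$sequence[t1$role == "WWP"], t1$name[t1$role == "WWP"])

test_that("published WWP set passes validation with the documented layout", {
  v <- validate_wwp_set(t1, arch, model)
  expect_true(v$pass)
  meas <- setNames(v$checks$measured, v$checks$check)
  expect_equal(meas[["common_prefix"]], "12")
  expect_equal(meas[["common_suffix"]], "3")
  expect_true(all(nchar(v$spacers) == 10L))
  # spacers are mutually mismatched: pairwise Hamming identity below length
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(sum(strsplit(v$spacers[i], "")[[1]] ==
                    strsplit(v$spacers[j], "")[[1]]), 10L)
})

test_that("validator fails broken sets for the right reason", {
  twin <- c(WWPa = wwp_seqs[[1]], WWPb = wwp_seqs[[1]], WWPc = wwp_seqs[[2]])
  v <- validate_wwp_set(twin, arch, model)
  expect_false(v$pass)
  expect_false(v$checks$pass[v$checks$check == "spacer_dissimilarity"])

  broken <- wwp_seqs
  broken[[1]] <- paste0(substr(broken[[1]], 1, 22), "AAA")
  v2 <- validate_wwp_set(broken, arch, model)
  expect_false(v2$checks$pass[v2$checks$check == "common_suffix"])

  expect_error(validate_wwp_set(wwp_seqs[1], arch, model),
               class = "wwpcr_input_error")
})

test_that("validator verdict is permutation invariant", {
  v1 <- validate_wwp_set(wwp_seqs, arch, model)
  v2 <- validate_wwp_set(wwp_seqs[c(3, 1, 2)], arch, model)
  expect_identical(v1$pass, v2$pass)
  expect_identical(sort(v1$checks$pass), sort(v2$checks$pass))
})

test_that("generated sets pass their own validator and reproduce by seed", {
  p1 <- generate_wwp_set(3, arch, model, seed = 42)
  expect_true(validate_wwp_set(p1, arch, model)$pass)
  p2 <- generate_wwp_set(3, arch, model, seed = 42)
  expect_identical(p1, p2)
  p3 <- generate_wwp_set(4, arch, model, seed = 9)
  expect_equal(nrow(p3), 4L)
  expect_true(validate_wwp_set(p3, arch, model)$pass)
})

test_that("generator rejects impossible requests", {
  expect_error(generate_wwp_set(1, arch, model, seed = 1),
               class = "wwpcr_input_error")
  hot <- wwp_architecture(self_tm_window = c(90, 95), inter_tm_target = 40)
  expect_error(generate_wwp_set(3, hot, model, seed = 1, max_attempts = 5),
               class = "wwpcr_unsatisfiable_error")
})

test_that("GSP nest is ordered toward the junction with compatible Tm", {
  g <- make_genome(2000, 0.5, seed = 3)
  known <- substr(g$seq, 701, 1300)          # 600 bp known region
  nest <- design_gsp_nest(known, "right", t1, model, arch)
  d <- attr(nest, "junction_distance")
  expect_true(d[1] > d[2] && d[2] > d[3])
  for (i in 1:3) {
    expect_lte(abs(tm_perfect_duplex(nest$sequence[i], model) -
                     tm_perfect_duplex(wwp_seqs[[i]], model)), arch$gsp_tm_tol)
    expect_true(grepl(nest$sequence[i], known, fixed = TRUE))
  }
  expect_error(design_gsp_nest(substr(known, 1, 40), "right", t1, model, arch),
               class = "wwpcr_input_error")
})

test_that("left walks return minus-strand GSPs pointing at the junction", {
  g <- make_genome(2000, 0.5, seed = 13)
  known <- substr(g$seq, 701, 1300)
  nest <- design_gsp_nest(known, "left", t1, model, arch)
  # the GSPs anneal to the plus strand and extend leftward: their reverse
  # complements are substrings of the known region
  for (i in 1:3)
    expect_true(grepl(dna_revcomp(nest$sequence[i]), known, fixed = TRUE))
  off <- attr(nest, "known_offset")
  expect_true(off[1] > off[2] && off[2] > off[3])
})

test_that("published GSP sets pair with their WWPs", {
  for (target in c("gadA", "hyg")) {
    gsp <- t1[!is.na(t1$target) & t1$target == target, ]
    for (i in 1:3) {
      expect_lte(abs(tm_perfect_duplex(gsp$sequence[i], model) -
                       tm_perfect_duplex(wwp_seqs[[i]], model)),
                 arch$gsp_tm_tol)
      expect_true(structure_screens(wwp_seqs[[i]], gsp$sequence[i], model)$pass)
    }
  }
})

test_that("walk permutations are the three cyclic rotations", {
  perms <- walk_permutations(t1)
  expect_equal(perms$permutation1, c("WWP1", "WWP2", "WWP3"))
  expect_equal(perms$permutation2, c("WWP2", "WWP3", "WWP1"))
  expect_equal(perms$permutation3, c("WWP3", "WWP1", "WWP2"))
  # Latin square: each WWP once per permutation, once per tier
  mat <- do.call(rbind, perms)
  for (i in 1:3) {
    expect_equal(sort(unname(mat[i, ])), c("WWP1", "WWP2", "WWP3"))
    expect_equal(sort(unname(mat[, i])), c("WWP1", "WWP2", "WWP3"))
  }
  expect_error(walk_permutations(wwp_seqs[1:2]), class = "wwpcr_input_error")
})
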