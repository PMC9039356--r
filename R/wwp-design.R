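# Wristwatch-primer (WWP) set design and validation, nested gene-specific
# primer (GSP) selection, and the three-permutation walking scheme.

#' Wristwatch primer architecture
#'
#' The structural and thermodynamic constraints a WWP set must satisfy: all
#' primers share a 5' prefix and a 3' suffix around mutually mismatched
#' spacers, each primer's self-Tm sits in a high window, and the bipartite
#' wristwatch duplex between any two primers melts at least \code{min_tm_gap}
#' degrees below the coolest self-Tm, so that inter-primer annealing happens
#' only in the single reduced-stringency cycle.
#'
#' @param total_len Primer length, nt.
#' @param prefix_len Shared 5' part, nt.
#' @param spacer_len Mutually mismatched middle part, nt.
#' @param suffix_len Shared 3' part, nt.
#' @param self_tm_window Two-element numeric, degrees C: allowed self-Tm range.
#' @param inter_tm_target Intended wristwatch-duplex Tm, degrees C
#'   (informational; the binding constraint is \code{min_tm_gap}).
#' @param min_tm_gap Minimum of (coolest self-Tm) - (warmest pairwise
#'   wristwatch Tm), degrees C. Must be >= 20.
#' @param base_balance_tol Maximum allowed deviation of any base's count
#'   from \code{total_len / 4}.
#' @param spacer_kmer Spacers of two primers may not share any k-mer of this
#'   length.
#' @param spacer_min_hamming Minimum pairwise Hamming distance between
#'   spacers; default \code{ceiling(spacer_len / 2)}.
#' @param gsp_tm_tol Allowed absolute difference between a GSP self-Tm and
#'   its paired WWP self-Tm, degrees C.
#' @return An object of class \code{wwp_architecture}.
#' @examples
#' wwp_architecture()
#' @export
wwp_architecture <- function(total_len = 25L, prefix_len = 12L,
                             spacer_len = 10L, suffix_len = 3L,
                             self_tm_window = c(60, 65),
                             inter_tm_target = 40,
                             min_tm_gap = 20,
                             base_balance_tol = 4.5,
                             spacer_kmer = 6L,
                             spacer_min_hamming = NULL,
                             gsp_tm_tol = 5) {
  total_len <- as.integer(total_len); prefix_len <- as.integer(prefix_len)
  spacer_len <- as.integer(spacer_len); suffix_len <- as.integer(suffix_len)
  if (prefix_len + spacer_len + suffix_len != total_len)
    .wwpcr_error("wwpcr_input_error",
                 "prefix_len + spacer_len + suffix_len must equal total_len")
  if (min_tm_gap < 20)
    .wwpcr_error("wwpcr_input_error",
                 "min_tm_gap must be >= 20 C: inter-primer annealing must be confined to the reduced-stringency cycle")
  if (length(self_tm_window) != 2L || self_tm_window[1] >= self_tm_window[2])
    .wwpcr_error("wwpcr_input_error", "self_tm_window must be an increasing pair")
  if (self_tm_window[1] <= inter_tm_target)
    .wwpcr_error("wwpcr_input_error",
                 "self_tm_window lower bound must exceed inter_tm_target")
  if (is.null(spacer_min_hamming)) spacer_min_hamming <- ceiling(spacer_len / 2)
  structure(list(
    total_len = total_len, prefix_len = prefix_len, spacer_len = spacer_len,
    suffix_len = suffix_len, self_tm_window = as.numeric(self_tm_window),
    inter_tm_target = inter_tm_target, min_tm_gap = min_tm_gap,
    base_balance_tol = base_balance_tol, spacer_kmer = as.integer(spacer_kmer),
    spacer_min_hamming = as.integer(spacer_min_hamming),
    gsp_tm_tol = gsp_tm_tol), class = "wwp_architecture")
}

#' @export
print.wwp_architecture <- function(x, ...) {
  cat(sprintf("<wwp_architecture> %d nt = %d (prefix) + %d (spacer) + %d (suffix); self-Tm [%g, %g] C; Tm gap >= %g C\n",
              x$total_len, x$prefix_len, x$spacer_len, x$suffix_len,
              x$self_tm_window[1], x$self_tm_window[2], x$min_tm_gap))
  invisible(x)
}

#' Construct a primer table
#'
#' @param name Character vector of primer names (unique).
#' @param sequence DNA strings 5'->3' (A/C/G/T).
#' @param role \code{"WWP"} or \code{"GSP"}.
#' @param tier Nested use order (1 = primary/outermost, 3 = tertiary/innermost).
#' @return A data.frame with columns \code{name}, \code{sequence},
#'   \code{role}, \code{tier}.
#' @examples
#' primer_table("WWP1", "CGTCTCCAGTCTCCATGTGTTCGTC", "WWP", 1)
#' @export
primer_table <- function(name, sequence, role, tier) {
  if (anyDuplicated(name))
    .wwpcr_error("wwpcr_input_error", "duplicate primer names")
  sequence <- toupper(sequence)
  for (i in seq_along(sequence)) .dna_int(sequence[i], paste0("primer ", name[i]))
  role <- as.character(role)
  if (!all(role %in% c("WWP", "GSP")))
    .wwpcr_error("wwpcr_input_error", "role must be 'WWP' or 'GSP'")
  data.frame(name = as.character(name), sequence = sequence, role = role,
             tier = as.integer(tier), stringsAsFactors = FALSE)
}

.wwp_sequences <- function(primers) {
  if (is.data.frame(primers)) {
    w <- primers[primers$role == "WWP", , drop = FALSE]
    stats::setNames(w$sequence, w$name)
  } else if (is.character(primers)) {
    if (is.null(names(primers)))
      names(primers) <- paste0("WWP", seq_along(primers))
    toupper(primers)
  } else .wwpcr_error("wwpcr_input_error", "primers must be a primer table or character vector")
}

.lcp_len <- function(seqs) {
  n <- min(nchar(seqs))
  for (i in seq_len(n)) {
    if (length(unique(substr(seqs, i, i))) > 1L) return(i - 1L)
  }
  n
}

.lcs_len <- function(seqs) {
  rev1 <- vapply(seqs, function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = ""), "")
  .lcp_len(rev1)
}

.hamming <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])

.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# Architecture mask: prefix and suffix paired, spacer looped out.
.arch_mask <- function(arch) {
  c(seq_len(arch$prefix_len), (arch$total_len - arch$suffix_len + 1L):arch$total_len)
}

# Pairwise wristwatch Tm of primer a annealed at the locus previously
# occupied by primer b (i.e., against the complement of b's footprint).
.pairwise_wristwatch_tm <- function(a, b, arch, model) {
  tm_wristwatch_duplex(a, dna_revcomp(b), .arch_mask(arch), model)
}

#' Validate a wristwatch primer set
#'
#' Checks a candidate WWP set against a [wwp_architecture()]: lengths, the
#' shared-prefix/shared-suffix layout, spacer dissimilarity (no shared
#' k-mer, minimum Hamming distance), self-Tm window, the Tm gap between
#' self-annealing and pairwise wristwatch annealing, base-composition
#' balance, and hairpin/dimer screens.
#'
#' @param primers A primer table (rows with \code{role == "WWP"} are used)
#'   or a character vector of WWP sequences. At least 2 WWPs.
#' @param arch A [wwp_architecture()].
#' @param model A [thermo_model()].
#' @return An object of class \code{wwp_validation}: a list with a
#'   \code{checks} data.frame (check, pass, measured, detail), per-primer
#'   \code{self_tm}, the pairwise \code{wristwatch_tm} matrix, and
#'   \code{pass} (TRUE iff every check passes).
#' @examples
#' v <- validate_wwp_set(published_primers())
#' v$pass
#' @export
validate_wwp_set <- function(primers, arch = wwp_architecture(),
                             model = thermo_model()) {
  seqs <- .wwp_sequences(primers)
  if (length(seqs) < 2L)
    .wwpcr_error("wwpcr_input_error", "need at least two WWPs (a wristwatch needs a partner)")
  for (i in seq_along(seqs)) .dna_int(seqs[[i]], names(seqs)[i])
  n <- length(seqs)
  checks <- list()
  add <- function(check, pass, measured, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, measured = as.character(measured),
      detail = detail, stringsAsFactors = FALSE)
  }

  lens <- nchar(seqs)
  add("length", all(lens == arch$total_len), paste(lens, collapse = ","),
      sprintf("each primer must be %d nt", arch$total_len))

  lcp <- .lcp_len(seqs); lcs <- .lcs_len(seqs)
  add("common_prefix", lcp == arch$prefix_len, lcp,
      sprintf("longest common prefix must be exactly %d nt", arch$prefix_len))
  add("common_suffix", lcs == arch$suffix_len, lcs,
      sprintf("longest common suffix must be exactly %d nt", arch$suffix_len))

  spacer_ok <- all(lens == arch$total_len) && lcp >= arch$prefix_len &&
    lcs >= arch$suffix_len
  spacers <- substr(seqs, arch$prefix_len + 1L, arch$total_len - arch$suffix_len)
  if (spacer_ok) {
    worst_shared <- 0L; min_ham <- arch$spacer_len
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      shared <- length(intersect(.kmers(spacers[i], arch$spacer_kmer),
                                 .kmers(spacers[j], arch$spacer_kmer)))
      worst_shared <- max(worst_shared, shared)
      min_ham <- min(min_ham, .hamming(spacers[i], spacers[j]))
    }
    add("spacer_dissimilarity",
        worst_shared == 0L && min_ham >= arch$spacer_min_hamming,
        sprintf("shared %d-mers: %d; min Hamming: %d", arch$spacer_kmer,
                worst_shared, min_ham),
        sprintf("spacers must share no %d-mer and differ at >= %d positions",
                arch$spacer_kmer, arch$spacer_min_hamming))
  } else {
    add("spacer_dissimilarity", FALSE, "not evaluated",
        "architecture layout failed; spacers undefined")
  }

  self_tm <- vapply(seqs, tm_perfect_duplex, 0, model = model)
  add("self_tm_window",
      all(self_tm >= arch$self_tm_window[1] & self_tm <= arch$self_tm_window[2]),
      paste(sprintf("%.1f", self_tm), collapse = ","),
      sprintf("each self-Tm within [%g, %g] C", arch$self_tm_window[1],
              arch$self_tm_window[2]))

  ww <- matrix(NA_real_, n, n, dimnames = list(names(seqs), names(seqs)))
  if (spacer_ok) {
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
      ww[i, j] <- .pairwise_wristwatch_tm(seqs[[i]], seqs[[j]], arch, model)
    gap <- min(self_tm) - max(ww, na.rm = TRUE)
    add("tm_gap", gap >= arch$min_tm_gap, sprintf("%.1f", gap),
        sprintf("min(self Tm) - max(wristwatch Tm) must be >= %g C", arch$min_tm_gap))
  } else {
    add("tm_gap", FALSE, "not evaluated", "architecture layout failed")
  }

  target <- arch$total_len / 4
  dev <- vapply(seqs, function(s) {
    counts <- table(factor(strsplit(s, "")[[1L]], levels = c("A", "C", "G", "T")))
    max(abs(as.numeric(counts) - target))
  }, 0)
  add("base_balance", all(dev <= arch$base_balance_tol),
      paste(sprintf("%.2f", dev), collapse = ","),
      sprintf("max deviation of any base count from %g must be <= %g",
              target, arch$base_balance_tol))

  scr_ok <- TRUE; scr_detail <- character(0)
  for (i in seq_len(n)) {
    s <- structure_screens(seqs[[i]], model = model)
    if (!s$hairpin_pass || !s$self_dimer_pass) {
      scr_ok <- FALSE
      scr_detail <- c(scr_detail, sprintf("%s: hairpin %d, self-dimer %d",
                                          names(seqs)[i], s$hairpin_stem, s$self_dimer_run))
    }
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- structure_screens(seqs[[i]], seqs[[j]], model = model)
    if (!isTRUE(s$cross_dimer_pass)) {
      scr_ok <- FALSE
      scr_detail <- c(scr_detail, sprintf("%s x %s: cross-dimer %d",
                                          names(seqs)[i], names(seqs)[j], s$cross_dimer_run))
    }
  }
  add("structure_screens", scr_ok,
      if (scr_ok) "clean" else paste(scr_detail, collapse = "; "),
      "no obvious hairpin, self-dimer, or cross-dimer")

  checks <- do.call(rbind, checks)
  structure(list(checks = checks, self_tm = self_tm, wristwatch_tm = ww,
                 spacers = spacers, pass = all(checks$pass)),
            class = "wwp_validation")
}

#' @export
print.wwp_validation <- function(x, ...) {
  cat(sprintf("<wwp_validation> overall: %s\n", if (x$pass) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x$checks)))
    cat(sprintf("  %-22s %-4s  %s\n", x$checks$check[i],
                if (x$checks$pass[i]) "ok" else "FAIL", x$checks$measured[i]))
  invisible(x)
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a wristwatch primer set
#'
#' Draws a random shared prefix and suffix and mutually dissimilar random
#' spacers until the assembled set passes [validate_wwp_set()]. The search
#' redraws spacers before redrawing the shared parts, preserving the
#' shared-overlap architecture, and is reproducible for a fixed seed.
#'
#' @param n Number of WWPs (>= 2).
#' @param arch A [wwp_architecture()].
#' @param model A [thermo_model()].
#' @param seed Integer seed.
#' @param max_attempts Cap on prefix/suffix draws before giving up.
#' @return A primer table of \code{n} WWPs that passes the validator.
#' @examples
#' p <- generate_wwp_set(3, seed = 42)
#' validate_wwp_set(p)$pass
#' @export
generate_wwp_set <- function(n = 3L, arch = wwp_architecture(),
                             model = thermo_model(), seed = 1L,
                             max_attempts = 200L) {
  n <- as.integer(n)
  if (n < 2L)
    .wwpcr_error("wwpcr_input_error", "n must be >= 2 (a wristwatch needs a partner)")
  .with_seed(seed, {
    last_fail <- "no attempt"
    for (attempt in seq_len(max_attempts)) {
      prefix <- .random_dna(arch$prefix_len)
      suffix <- .random_dna(arch$suffix_len)
      for (round in 1:20) {
        seqs <- character(0)
        ok <- TRUE
        for (i in seq_len(n)) {
          placed <- FALSE
          for (try in 1:60) {
            cand <- paste0(prefix, .random_dna(arch$spacer_len), suffix)
            v <- .candidate_primer_ok(cand, seqs, arch, model)
            if (isTRUE(v)) { seqs <- c(seqs, cand); placed <- TRUE; break }
            last_fail <- v
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (!ok) next
        names(seqs) <- paste0("WWP", seq_len(n))
        val <- validate_wwp_set(seqs, arch, model)
        if (val$pass)
          return(primer_table(names(seqs), seqs, rep("WWP", n), seq_len(n)))
        last_fail <- val$checks$check[!val$checks$pass][1L]
      }
    }
    .wwpcr_error("wwpcr_unsatisfiable_error",
                 sprintf("could not generate a valid WWP set in %d attempts; last violated check: %s",
                         max_attempts, last_fail))
  })
}

# Quick per-primer feasibility used during generation; returns TRUE or the
# name of the violated check.
.candidate_primer_ok <- function(cand, accepted, arch, model) {
  tm <- tm_perfect_duplex(cand, model)
  if (tm < arch$self_tm_window[1] || tm > arch$self_tm_window[2])
    return("self_tm_window")
  target <- arch$total_len / 4
  counts <- table(factor(strsplit(cand, "")[[1L]], levels = c("A", "C", "G", "T")))
  if (max(abs(as.numeric(counts) - target)) > arch$base_balance_tol)
    return("base_balance")
  s <- structure_screens(cand, model = model)
  if (!s$hairpin_pass || !s$self_dimer_pass) return("structure_screens")
  sp <- substr(cand, arch$prefix_len + 1L, arch$total_len - arch$suffix_len)
  for (a in accepted) {
    spa <- substr(a, arch$prefix_len + 1L, arch$total_len - arch$suffix_len)
    if (length(intersect(.kmers(sp, arch$spacer_kmer),
                         .kmers(spa, arch$spacer_kmer))) > 0L)
      return("spacer_dissimilarity")
    if (.hamming(sp, spa) < arch$spacer_min_hamming)
      return("spacer_dissimilarity")
    if (!isTRUE(structure_screens(cand, a, model)$cross_dimer_pass))
      return("structure_screens")
  }
  TRUE
}

#' Design a nest of three gene-specific primers
#'
#' Selects GSP1 (outermost), GSP2, GSP3 (innermost) on the strand of
#' \code{known_seq} that points into the unknown flank. GSP1 lies farthest
#' from the known/unknown junction and GSP3 nearest, so each successive
#' round yields a slightly shorter product. Each GSP's self-Tm must lie
#' within \code{arch$gsp_tm_tol} of its paired WWP's self-Tm, and hairpin /
#' self-dimer / cross-dimer (against the paired WWP) screens must pass.
#'
#' @param known_seq The known anchor sequence, 5'->3' on the reference plus
#'   strand.
#' @param walk_direction \code{"right"} (junction at the end of
#'   \code{known_seq}) or \code{"left"} (junction at its start).
#' @param wwps A primer table or character vector of the WWPs that will be
#'   paired with GSP1..GSP3 in tier order.
#' @param model A [thermo_model()].
#' @param arch A [wwp_architecture()] (supplies \code{gsp_tm_tol}).
#' @param gsp_len GSP length, nt.
#' @param min_separation Minimum distance between the 3' ends of successive
#'   GSPs, nt; this is also the guaranteed secondary-vs-tertiary band size
#'   offset lower bound.
#' @return A primer table of three GSPs with attributes
#'   \code{junction_distance} (3' end to junction, per GSP) and
#'   \code{known_offset} (0-based start of each GSP on \code{known_seq};
#'   for left walks, offsets refer to the plus strand as given).
#' @examples
#' \donttest{
#' g <- make_genome(6000, 0.5, seed = 3)
#' known <- substr(g$seq, 2001, 3000)
#' design_gsp_nest(known, "right", published_primers())
#' }
#' @export
design_gsp_nest <- function(known_seq, walk_direction = c("right", "left"),
                            wwps, model = thermo_model(),
                            arch = wwp_architecture(), gsp_len = 25L,
                            min_separation = 40L) {
  walk_direction <- match.arg(walk_direction)
  known_seq <- toupper(known_seq)
  .dna_int(known_seq, "known_seq")
  gsp_len <- as.integer(gsp_len)
  L <- nchar(known_seq)
  if (L < 3L * gsp_len + 2L * min_separation)
    .wwpcr_error("wwpcr_input_error",
                 sprintf("known_seq too short to host a nest of three %d-nt GSPs (need >= %d nt, got %d)",
                         gsp_len, 3L * gsp_len + 2L * min_separation, L))
  wwp_seqs <- .wwp_sequences(wwps)
  if (length(wwp_seqs) < 3L)
    .wwpcr_error("wwpcr_input_error", "need three WWPs to pair with the GSP nest")
  wwp_tm <- vapply(wwp_seqs[1:3], tm_perfect_duplex, 0, model = model)

  if (walk_direction == "left") {
    res <- design_gsp_nest(dna_revcomp(known_seq), "right", wwps, model, arch,
                           gsp_len, min_separation)
    off <- attr(res, "known_offset")
    attr(res, "known_offset") <- L - off - gsp_len  # plus-strand start
    attr(res, "walk_direction") <- "left"
    return(res)
  }

  # candidate windows, scored by distance of the 3' end from the junction
  # (= end of known_seq); prefer near-junction candidates for GSP3 first.
  starts <- 0:(L - gsp_len)             # 0-based
  ok_for <- function(tier, start) {
    cand <- substr(known_seq, start + 1L, start + gsp_len)
    if (grepl("[^ACGT]", cand)) return(NULL)
    tm <- tm_perfect_duplex(cand, model)
    if (abs(tm - wwp_tm[tier]) > arch$gsp_tm_tol) return(NULL)
    s <- structure_screens(cand, wwp_seqs[[tier]], model)
    if (!s$hairpin_pass || !s$self_dimer_pass || !isTRUE(s$cross_dimer_pass))
      return(NULL)
    cand
  }
  pick <- function(tier, max_start) {
    for (start in rev(starts[starts <= max_start])) {
      cand <- ok_for(tier, start)
      if (!is.null(cand)) return(list(start = start, seq = cand))
    }
    NULL
  }
  g3 <- pick(3L, L - gsp_len)
  if (!is.null(g3)) g2 <- pick(2L, g3$start - gsp_len - min_separation) else g2 <- NULL
  if (!is.null(g2)) g1 <- pick(1L, g2$start - gsp_len - min_separation) else g1 <- NULL
  if (is.null(g3) || is.null(g2) || is.null(g1))
    .wwpcr_error("wwpcr_design_error",
                 "no Tm-compatible, screen-clean GSP nest found in known_seq")
  nest <- list(g1, g2, g3)
  tab <- primer_table(paste0("GSP", 1:3),
                      vapply(nest, `[[`, "", "seq"), rep("GSP", 3), 1:3)
  starts0 <- vapply(nest, `[[`, 0, "start")
  attr(tab, "known_offset") <- starts0
  attr(tab, "junction_distance") <- L - (starts0 + gsp_len)
  attr(tab, "walk_direction") <- "right"
  tab
}

#' The three cyclic walking permutations
#'
#' From three WWPs, builds the three cyclic rotations used to run three
#' parallel WW-PCR sets: (W1, W2, W3), (W2, W3, W1), (W3, W1, W2). Within a
#' permutation, position 1 is paired with GSP1 in the primary PCR, position
#' 2 with GSP2 in the secondary, and position 3 with GSP3 in the tertiary.
#'
#' @param wwps A primer table with exactly three WWPs, or a length-3
#'   character vector.
#' @return A list of three character vectors of WWP names (or sequences, if
#'   unnamed sequences were supplied), each of length 3; the rotation index
#'   is the list name.
#' @examples
#' walk_permutations(c(WWP1 = "a", WWP2 = "b", WWP3 = "c"))
#' @export
walk_permutations <- function(wwps) {
  if (is.data.frame(wwps)) {
    w <- wwps[wwps$role == "WWP", , drop = FALSE]
    ids <- w$name
  } else ids <- if (!is.null(names(wwps))) names(wwps) else as.character(wwps)
  if (length(ids) != 3L)
    .wwpcr_error("wwpcr_input_error",
                 sprintf("exactly 3 WWPs required (got %d)", length(ids)))
  rot <- function(k) ids[((seq_len(3L) - 1L + k) %% 3L) + 1L]
  list(permutation1 = rot(0L), permutation2 = rot(1L), permutation3 = rot(2L))
}
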