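# Seeded synthetic fixtures: random genomes with a planted known region,
# planted walking-primer annealing sites, optional decoy GSP loci, and an
# independently enumerated ground-truth amplicon set.

#' Generate a random genome sequence
#'
#' Reproducible i.i.d. nucleotide sequence with a target GC fraction.
#'
#' @param length Genome length, nt (>= 1000).
#' @param gc_fraction Expected GC content, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return A \code{dna_record}: list with \code{id} and \code{seq}.
#' @examples
#' g <- make_genome(2000, 0.5, seed = 7)
#' nchar(g$seq)
#' @export
make_genome <- function(length, gc_fraction = 0.5, seed = 1L) {
  length <- as.integer(length)
  if (is.na(length) || length < 1000L)
    .wwpcr_error("wwpcr_input_error", "genome length must be >= 1000 nt")
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1)
    .wwpcr_error("wwpcr_input_error", "gc_fraction must be strictly between 0 and 1")
  seq <- .with_seed(seed, .random_dna(length, gc_fraction))
  structure(list(id = sprintf("synthetic_genome_len%d_seed%d", length, seed),
                 seq = seq), class = "dna_record")
}

#' @export
print.dna_record <- function(x, ...) {
  cat(sprintf("<dna_record> %s (%d nt)\n", x$id, nchar(x$seq)))
  invisible(x)
}

.subseq_replace <- function(seq, start0, replacement) {
  # write `replacement` into `seq` at 0-based position start0
  paste0(substr(seq, 1L, start0),
         replacement,
         substr(seq, start0 + nchar(replacement) + 1L, nchar(seq)))
}

# Smallest 3'-terminal block length whose duplex Tm sits comfortably inside
# (lsc_gate, hsc_gate): strong enough to prime in the single low-stringency
# cycle, too weak to prime in high-stringency cycles.
.pick_site_len <- function(primer_seq, model, lsc_gate, hsc_gate) {
  m <- nchar(primer_seq)
  site <- dna_revcomp(primer_seq)
  for (len in 10:(m - 1L)) {
    mask <- (m - len + 1L):m
    tm <- tm_wristwatch_duplex(primer_seq, site, mask, model)
    if (tm >= lsc_gate + 3 && tm <= hsc_gate - 5) return(list(len = len, tm = tm))
  }
  .wwpcr_error("wwpcr_design_error",
               "no 3'-terminal block length yields a partial site between the stage gates")
}

#' Build a synthetic walking fixture
#'
#' Generates a seeded random genome, designates a known region, designs a
#' nested GSP set against it, plants partial annealing sites for the
#' primary walking primer in the unknown right flank (the loci at which the
#' walking primer will "arbitrarily" anneal in the single low-stringency
#' cycle), optionally plants decoy GSP1 loci (exact GSP1 complements with
#' one or two mismatches at the primer 5' end, each with a downstream
#' walking-primer site, so that type II background is actually produced in
#' the primary round), and enumerates the ground-truth amplicon set by
#' exhaustive offset search, independently of the simulator.
#'
#' @param genome_len Genome length, nt.
#' @param known_len Known-region length, nt (>= 200).
#' @param wwps WWP set (primer table), position/tier 1 = primary primer of
#'   the permutation that the planted sites serve. Default: the bundled
#'   published set.
#' @param arch A [wwp_architecture()].
#' @param model A [thermo_model()].
#' @param seed Integer seed.
#' @param n_sites Number of planted walking-primer sites in the unknown
#'   flank (= expected number of target bands).
#' @param n_decoys Number of planted decoy GSP1 cassettes.
#' @param decoy_mismatch Mismatches at the GSP 5' end of each decoy locus
#'   (0-2).
#' @param profiles Cycling profiles used for the truth enumeration
#'   (default [default_profiles()]).
#' @return An object of class \code{walk_fixture}: the genome, known-region
#'   coordinates and junction, the designed GSPs (with reference
#'   positions), the WWP permutation, planted site and decoy tables, and
#'   \code{truth_amplicons} (one row per reachable band: site coordinate,
#'   entry round, secondary and tertiary sizes).
#' @export
make_walk_fixture <- function(genome_len = 10000L, known_len = 1000L,
                              wwps = NULL, arch = wwp_architecture(),
                              model = thermo_model(), seed = 1L,
                              n_sites = 3L, n_decoys = 2L,
                              decoy_mismatch = 1L,
                              profiles = default_profiles()) {
  genome_len <- as.integer(genome_len); known_len <- as.integer(known_len)
  if (known_len < 200L)
    .wwpcr_error("wwpcr_input_error", "known_len must be >= 200 nt")
  if (is.null(wwps)) wwps <- published_primers()
  wwp_tab <- wwps[wwps$role == "WWP", , drop = FALSE]
  wwp_tab <- wwp_tab[order(wwp_tab$tier), , drop = FALSE]
  if (nrow(wwp_tab) < 3L)
    .wwpcr_error("wwpcr_input_error", "fixture needs three WWPs")
  decoy_mismatch <- as.integer(decoy_mismatch)
  if (decoy_mismatch < 0L || decoy_mismatch > 2L)
    .wwpcr_error("wwpcr_input_error", "decoy_mismatch must be 0, 1, or 2")

  cap <- profiles[[1L]]$extension_cap
  lsc_gate <- profiles[[1L]]$stage2[["anneal_temp"]] - model$stringency_offset
  rsc_gate <- profiles[[2L]]$stage2[["anneal_temp"]] - model$stringency_offset
  hsc_gate <- profiles[[1L]]$stage1[["anneal_temp"]] - model$stringency_offset

  genome <- make_genome(genome_len, 0.5, seed)
  kstart <- as.integer(floor((genome_len - known_len) * 0.4))
  junction <- kstart + known_len
  unknown_len <- genome_len - junction
  if (unknown_len < 600L)
    .wwpcr_error("wwpcr_input_error", "genome too short for an unknown flank")

  known_seq <- substr(genome$seq, kstart + 1L, junction)
  gsps <- design_gsp_nest(known_seq, "right", wwp_tab, model, arch)
  gsp_ref_start <- kstart + attr(gsps, "known_offset")   # 0-based, + strand
  gsp_len <- nchar(gsps$sequence[1L])

  w1 <- list(name = wwp_tab$name[1L], seq = wwp_tab$sequence[1L])
  site_pick <- .pick_site_len(w1$seq, model, lsc_gate, hsc_gate)
  site_len <- site_pick$len
  m <- nchar(w1$seq)

  # planted walking-primer sites: choose tertiary product sizes, convert to
  # the 3'-pairing coordinate j (footprint [j, j + m - 1])
  g3s <- gsp_ref_start[3L]
  max_size <- min(cap - 50L, genome_len - g3s - 100L,
                  cap + m - (g3s - gsp_ref_start[1L]) - 100L)
  min_size <- max(400L, junction - g3s + m + 150L)  # clear of the junction
  seq_state <- genome$seq
  sizes <- .with_seed(seed + 1L, {
    span <- max_size - min_size
    if (span < (n_sites - 1L) * 150L)
      .wwpcr_error("wwpcr_input_error", "unknown flank too small for the requested sites")
    sort(sample(seq(min_size, max_size, by = 1L), n_sites)) |>
      (\(x) { # enforce minimum spacing deterministically
        while (any(diff(x) < 150L)) x[which(diff(x) < 150L)[1L] + 1L] <-
            x[which(diff(x) < 150L)[1L]] + 150L
        pmin(x, max_size)
      })()
  })
  sizes <- unique(sizes)
  js <- g3s + sizes - m
  plant_pattern <- substr(dna_revcomp(w1$seq), 1L, site_len)
  for (j in js) seq_state <- .subseq_replace(seq_state, j, plant_pattern)
  planted <- data.frame(three_prime_pos = js, site_len = site_len,
                        site_tm = site_pick$tm,
                        tertiary_size = js + m - g3s, stringsAsFactors = FALSE)

  # decoy GSP1 cassettes on the minus orientation, left of the known region
  decoys <- NULL
  if (n_decoys > 0L) {
    gsp1 <- gsps$sequence[1L]
    zone_hi <- kstart - 200L
    d_positions <- .with_seed(seed + 2L, {
      lo <- 900L; hi <- zone_hi - gsp_len - 10L
      if (hi - lo < n_decoys * 1100L)
        .wwpcr_error("wwpcr_input_error", "decoy zone too small")
      sort(sample(seq(lo, hi, by = 1L), n_decoys)) |>
        (\(x) { while (any(diff(x) < 1100L)) x[which(diff(x) < 1100L)[1L] + 1L] <-
                    x[which(diff(x) < 1100L)[1L]] + 1100L; x })()
    })
    spacing <- 400L
    rows <- list()
    for (i in seq_along(d_positions)) {
      d <- d_positions[i]
      decoy_seq <- dna_revcomp(gsp1)
      if (decoy_mismatch > 0L) {
        # corrupt the template bases facing the GSP 5' end (the last planted
        # characters) so the decoy duplex carries terminal mismatches
        for (t in seq_len(decoy_mismatch)) {
          pos <- gsp_len - t + 1L
          old <- substr(decoy_seq, pos, pos)
          new <- c(A = "C", C = "A", G = "T", T = "G")[[old]]
          substr(decoy_seq, pos, pos) <- new
        }
      }
      seq_state <- .subseq_replace(seq_state, d, decoy_seq)
      # walking-primer site for the minus-sense decoy product: plant the
      # 3'-terminal site_len of the primer itself ending at reference q
      q <- d - spacing
      seq_state <- .subseq_replace(seq_state, q - site_len + 1L,
                                   substr(w1$seq, m - site_len + 1L, m))
      rows[[i]] <- data.frame(gsp_three_prime_pos = d,
                              wwp_three_prime_pos = q,
                              mismatches = decoy_mismatch,
                              stringsAsFactors = FALSE)
    }
    decoys <- do.call(rbind, rows)
  }

  genome$seq <- seq_state
  truth <- enumerate_truth_amplicons(
    genome$seq, gsp_ref_start, gsp_len,
    stats::setNames(wwp_tab$sequence[1:3], wwp_tab$name[1:3]),
    profiles, model)

  structure(list(
    genome = genome, known_region = c(kstart, junction), junction = junction,
    gsps = gsps, gsp_ref_start = gsp_ref_start, gsp_len = gsp_len,
    wwps = wwp_tab, planted_sites = planted, decoy_sites = decoys,
    truth_amplicons = truth, site_len = site_len, seed = seed,
    extension_cap = cap), class = "walk_fixture")
}

#' @export
print.walk_fixture <- function(x, ...) {
  cat(sprintf("<walk_fixture> %s | known [%d, %d), junction %d\n",
              x$genome$id, x$known_region[1], x$known_region[2], x$junction))
  cat(sprintf("  %d planted site(s), %d decoy(s), %d truth amplicon(s): %s nt\n",
              nrow(x$planted_sites),
              if (is.null(x$decoy_sites)) 0L else nrow(x$decoy_sites),
              nrow(x$truth_amplicons),
              paste(sort(x$truth_amplicons$tertiary_size), collapse = ", ")))
  invisible(x)
}

#' Enumerate ground-truth amplicons by exhaustive offset search
#'
#' Independently of the simulator, tests every offset of the reference plus
#' strand as a potential walking-primer annealing site: a site qualifies
#' when the primer's 3'-terminal bases match contiguously and the bipartite
#' duplex Tm reaches the stage-2 stringency gate of some round (primary
#' low-stringency gate for the primary walking primer; reduced-stringency
#' gate for the later primers, which can also anneal directly to carried-over
#' genome strands). A qualifying site at coordinate j yields a tertiary
#' band of \code{j + primer_len - gsp3_start} nt provided the site lies
#' beyond the GSP3 footprint and within the polymerase extension cap.
#'
#' @param genome_seq Reference plus-strand sequence.
#' @param gsp_ref_start Integer vector, 0-based starts of GSP1..GSP3 on the
#'   plus strand.
#' @param gsp_len GSP length, nt.
#' @param wwp_seqs Named character vector of the three walking primers in
#'   permutation order (position 1 = primary).
#' @param profiles The three cycling profiles.
#' @param model A [thermo_model()].
#' @return Data.frame with one row per reachable band: \code{three_prime_pos},
#'   \code{entry_round}, \code{entry_primer}, \code{duplex_tm},
#'   \code{secondary_size}, \code{tertiary_size}, \code{start}, \code{end}.
#' @export
enumerate_truth_amplicons <- function(genome_seq, gsp_ref_start, gsp_len,
                                      wwp_seqs, profiles,
                                      model = thermo_model()) {
  gseq <- toupper(genome_seq)
  L <- nchar(gseq)
  cap <- profiles[[1L]]$extension_cap
  k <- model$min_3prime_match
  gates <- vapply(profiles, function(p) p$stage2[["anneal_temp"]], 0) -
    model$stringency_offset
  g2s <- gsp_ref_start[2L]; g3s <- gsp_ref_start[3L]
  rows <- list(); nr <- 0L
  found <- integer(0)
  j_lo <- g3s + gsp_len          # footprint must clear the GSP3 footprint
  j_hi <- min(L - max(nchar(wwp_seqs)), g3s + cap)
  for (r in 1:3) {
    w <- wwp_seqs[[r]]
    m <- nchar(w)
    pat <- substr(dna_revcomp(w), 1L, k)
    idx <- j_lo:j_hi
    hits <- idx[substring(gseq, idx + 1L, idx + k) == pat]
    full_rc <- dna_revcomp(w)
    for (j in hits) {
      if (j %in% found) next
      site <- substr(gseq, j + 1L, j + m)
      site_chars <- strsplit(site, "")[[1L]]
      rc_chars <- strsplit(full_rc, "")[[1L]]
      paired <- site_chars == rc_chars          # primer i pairs site m+1-i
      mask <- rev(paired)                       # primer-indexed
      if (!mask[m]) next
      tm <- tm_wristwatch_duplex(w, site, which(mask), model)
      if (tm >= gates[r]) {
        nr <- nr + 1L
        found <- c(found, j)
        rows[[nr]] <- data.frame(
          three_prime_pos = j, entry_round = r,
          entry_primer = names(wwp_seqs)[r], duplex_tm = tm,
          secondary_size = j + m - g2s, tertiary_size = j + m - g3s,
          start = g3s, end = j + m, stringsAsFactors = FALSE)
      }
    }
  }
  if (nr == 0L)
    return(data.frame(three_prime_pos = integer(0), entry_round = integer(0),
                      entry_primer = character(0), duplex_tm = numeric(0),
                      secondary_size = integer(0), tertiary_size = integer(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$three_prime_pos), , drop = FALSE]
}
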