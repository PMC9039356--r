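# Nearest-neighbor duplex thermodynamics, bipartite ("wristwatch") duplexes,
# temperature-gated annealing-site scanning, and hairpin/dimer screens.

# Unified nearest-neighbor parameters (SantaLucia 1998), 1 M NaCl reference.
# Indexed by top-strand dinucleotide 5'->3'; dH kcal/mol, dS cal/(mol K).
.NN_DH <- c(
  AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
  CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
  GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
  TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
.NN_DS <- c(
  AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
  CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
  GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
  TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
# Duplex-terminal initiation penalties per end: A/T vs G/C closing pair.
.TERM_AT <- c(dH = 2.3, dS = 4.1)
.TERM_GC <- c(dH = 0.1, dS = -2.8)

# Internal-loop destabilization free energies at 37 C (kcal/mol), indexed by
# total number of unpaired nucleotides in the loop (both strands).  Values
# from the unified folding parameter set; sizes not tabulated are obtained by
# Jacobson-Stockmayer extrapolation from the nearest smaller tabulated size.
.LOOP_SIZES <- c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30)
.LOOP_DG37 <- c(3.2, 3.6, 4.0, 4.4, 4.6, 4.8, 4.9, 4.9, 5.2, 5.4, 5.6, 5.8,
                5.9, 6.3, 6.6)

.GAS_R <- 1.98720425864083  # cal/(mol K)
.T37 <- 310.15

.loop_dg37 <- function(n_total) {
  if (n_total <= .LOOP_SIZES[1L]) return(.LOOP_DG37[1L])
  i <- max(which(.LOOP_SIZES <= n_total))
  base <- .LOOP_DG37[i]
  if (.LOOP_SIZES[i] == n_total) return(base)
  base + 2.44 * .GAS_R * 1e-3 * .T37 * log(n_total / .LOOP_SIZES[i])
}

.wwpcr_error <- function(class, msg) {
  stop(structure(class = c(class, "wwpcr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Integer encoding A=1 C=2 G=3 T=4; complement is 5 - code.
.DNA_CODE <- local({
  v <- integer(256)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
  v[utf8ToInt("a")] <- 1L; v[utf8ToInt("c")] <- 2L
  v[utf8ToInt("g")] <- 3L; v[utf8ToInt("t")] <- 4L
  v
})
.DNA_LETTER <- c("A", "C", "G", "T")

.dna_int <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    .wwpcr_error("wwpcr_input_error", sprintf("%s must be a single string", what))
  codes <- .DNA_CODE[utf8ToInt(seq)]
  if (any(codes == 0L)) {
    bad <- unique(strsplit(seq, "")[[1L]][codes == 0L])
    .wwpcr_error("wwpcr_degenerate_base_error",
                 sprintf("%s contains non-ACGT character(s): %s (degenerate or invalid bases are rejected)",
                         what, paste(bad, collapse = ", ")))
  }
  codes
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (A/C/G/T only).
#' @return The reverse complement, uppercase.
#' @examples
#' dna_revcomp("ACGTT")
#' @export
dna_revcomp <- function(seq) {
  codes <- .dna_int(seq)
  paste(.DNA_LETTER[rev(5L - codes)], collapse = "")
}

#' Thermodynamic model for primer-template annealing
#'
#' Bundles the nearest-neighbor parameter set, solution conditions, the
#' internal-loop treatment used for bipartite ("wristwatch") duplexes, and
#' the rules that decide when an annealing event is productive.
#'
#' The melting temperature of a duplex is computed as
#' \eqn{Tm = \Delta H / (\Delta S_{salt} + R \ln C_T) - 273.15} with the
#' primer-excess two-state convention (\eqn{C_T} is the primer strand
#' concentration) and the monovalent-salt entropy correction
#' \eqn{\Delta S_{salt} = \Delta S + 0.368 (N_{bp}-1)\ln[\mathrm{Na}^+]}.
#'
#' A primer is considered to anneal productively at stage temperature
#' \eqn{T} when its duplex Tm is at least \eqn{T - } \code{stringency_offset}.
#' The offset (default 10 degrees C) absorbs the stabilization by divalent
#' cations in PCR buffer, which the monovalent-only model does not represent:
#' primers with a 50 mM-monovalent Tm of 58-63 degrees C routinely prime in
#' 65 degree annealing steps.
#'
#' @param nn_parameter_set Identifier of the nearest-neighbor table; only
#'   \code{"santalucia1998"} (the unified parameters) is available.
#' @param monovalent_salt Monovalent cation concentration, mM. Must be > 0.
#' @param primer_conc Primer strand concentration, nM. Must be > 0.
#' @param min_3prime_match Minimum number of contiguous 3'-terminal paired
#'   bases required for productive priming. Must be >= 2; the default 3
#'   equals the wristwatch-primer 3' overlap length.
#' @param stringency_offset Degrees C subtracted from a stage annealing
#'   temperature to form the effective Tm gate (see Details).
#' @param hairpin_max_stem Hairpin screens fail at stems of at least this
#'   many base pairs (minimum loop 3 nt).
#' @param dimer_max_run Dimer screens fail when the longest antiparallel
#'   complementary run reaches this many base pairs.
#' @return An object of class \code{thermo_model}.
#' @examples
#' m <- thermo_model()
#' tm_perfect_duplex("CGTCTCCAGTCTCCATGTGTTCGTC", m)
#' @export
thermo_model <- function(nn_parameter_set = "santalucia1998",
                         monovalent_salt = 50,
                         primer_conc = 200,
                         min_3prime_match = 3L,
                         stringency_offset = 10,
                         hairpin_max_stem = 5L,
                         dimer_max_run = 8L) {
  nn_parameter_set <- match.arg(nn_parameter_set)
  if (!is.numeric(monovalent_salt) || monovalent_salt <= 0)
    .wwpcr_error("wwpcr_input_error", "monovalent_salt must be > 0 (mM)")
  if (!is.numeric(primer_conc) || primer_conc <= 0)
    .wwpcr_error("wwpcr_input_error", "primer_conc must be > 0 (nM)")
  min_3prime_match <- as.integer(min_3prime_match)
  if (is.na(min_3prime_match) || min_3prime_match < 2L)
    .wwpcr_error("wwpcr_input_error",
                 "min_3prime_match must be >= 2 (priming needs a 2-nt 3' match)")
  structure(list(
    nn_parameter_set = nn_parameter_set,
    monovalent_salt = monovalent_salt,
    primer_conc = primer_conc,
    min_3prime_match = min_3prime_match,
    stringency_offset = stringency_offset,
    hairpin_max_stem = as.integer(hairpin_max_stem),
    dimer_max_run = as.integer(dimer_max_run)
  ), class = "thermo_model")
}

#' @export
print.thermo_model <- function(x, ...) {
  cat("<thermo_model> ", x$nn_parameter_set,
      sprintf(" | %g mM monovalent, %g nM primer", x$monovalent_salt, x$primer_conc),
      sprintf(" | 3' match >= %d, stringency offset %g C\n",
              x$min_3prime_match, x$stringency_offset), sep = "")
  invisible(x)
}

.as_thermo_model <- function(model) {
  if (!inherits(model, "thermo_model"))
    .wwpcr_error("wwpcr_input_error", "model must be a thermo_model object")
  model
}

# Ensemble Tm of a (possibly bipartite) duplex described by the primer-strand
# base codes and a logical paired mask of the same length (ungapped alignment;
# each unpaired primer base faces one unpaired template base, so an internal
# gap of g primer bases is a loop of 2g total nucleotides).
#
# The structure is allowed to fray: every contiguous run of paired blocks is
# evaluated as a two-state sub-duplex (stacks + terminal penalties + the
# internal-loop entropies it spans) and the maximum Tm over sub-duplexes is
# returned.  A full-length mask therefore reduces exactly to the standard
# perfect-duplex nearest-neighbor Tm.
.duplex_ensemble_tm <- function(pcodes, paired, model) {
  stopifnot(length(pcodes) == length(paired))
  r <- rle(paired)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bi <- which(r$values)
  if (length(bi) == 0L)
    .wwpcr_error("wwpcr_mask_error", "mask has zero paired positions")
  bstart <- starts[bi]; bend <- ends[bi]
  nb <- length(bi)
  # per-block stack sums
  bdH <- bdS <- numeric(nb)
  for (b in seq_len(nb)) {
    if (bend[b] > bstart[b]) {
      idx <- bstart[b]:(bend[b] - 1L)
      din <- (pcodes[idx] - 1L) * 4L + pcodes[idx + 1L]
      bdH[b] <- sum(.NN_DH[din])
      bdS[b] <- sum(.NN_DS[din])
    }
  }
  term <- function(code) if (code == 1L || code == 4L) .TERM_AT else .TERM_GC
  na_m <- model$monovalent_salt / 1000
  ct_m <- model$primer_conc * 1e-9
  lnct <- .GAS_R * log(ct_m)
  best <- -Inf
  for (i in seq_len(nb)) {
    dH <- 0; dS <- 0; np <- 0L
    for (j in i:nb) {
      dH <- dH + bdH[j]; dS <- dS + bdS[j]
      np <- np + (bend[j] - bstart[j] + 1L)
      if (j > i) {
        gap <- bstart[j] - bend[j - 1L] - 1L
        dS <- dS - .loop_dg37(2L * gap) * 1000 / .T37
      }
      t5 <- term(pcodes[bstart[i]]); t3 <- term(pcodes[bend[j]])
      dHt <- dH + t5[["dH"]] + t3[["dH"]]
      dSt <- dS + t5[["dS"]] + t3[["dS"]] + 0.368 * (np - 1L) * log(na_m)
      tm <- dHt * 1000 / (dSt + lnct) - 273.15
      if (tm > best) best <- tm
    }
  }
  best
}

#' Melting temperature of a perfect primer-template duplex
#'
#' Nearest-neighbor Tm of \code{seq} annealed to its exact complement under
#' the conditions in \code{model}.
#'
#' @param seq DNA string, length >= 8, A/C/G/T only.
#' @param model A [thermo_model()].
#' @return Tm in degrees C.
#' @examples
#' tm_perfect_duplex("CGTCTCCAGTCTCCATGTGTTCGTC", thermo_model())
#' @export
tm_perfect_duplex <- function(seq, model = thermo_model()) {
  model <- .as_thermo_model(model)
  codes <- .dna_int(seq, "seq")
  if (length(codes) < 8L)
    .wwpcr_error("wwpcr_short_sequence_error",
                 sprintf("seq must be at least 8 nt (got %d)", length(codes)))
  .duplex_ensemble_tm(codes, rep(TRUE, length(codes)), model)
}

.parse_mask <- function(mask, n) {
  if (is.character(mask) && length(mask) == 1L) {
    ch <- strsplit(mask, "")[[1L]]
    if (length(ch) != n)
      .wwpcr_error("wwpcr_mask_error", "mask string length must equal primer length")
    return(ch %in% c("|", "1", "p", "P"))
  }
  if (is.logical(mask)) {
    if (length(mask) != n)
      .wwpcr_error("wwpcr_mask_error", "logical mask length must equal primer length")
    return(mask)
  }
  if (is.numeric(mask)) {
    idx <- as.integer(mask)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > n))
      .wwpcr_error("wwpcr_mask_error", "mask indices out of range")
    out <- rep(FALSE, n); out[idx] <- TRUE
    return(out)
  }
  .wwpcr_error("wwpcr_mask_error", "mask must be a logical vector, index vector, or '|.' string")
}

#' Melting temperature of a bipartite ("wristwatch") duplex
#'
#' Tm of a primer annealed to a same-length template site where only the
#' positions marked in \code{mask} are paired.  Paired blocks contribute
#' nearest-neighbor stacks; each internal unpaired region contributes a
#' tabulated internal-loop penalty (loop size = unpaired bases on both
#' strands).  The structure may fray: the reported Tm is the maximum over
#' contiguous sub-duplexes, so a weakly paired outer block does not drag the
#' estimate below the melting point of the stable core.  With an all-paired
#' mask this equals [tm_perfect_duplex()] exactly.
#'
#' @param primer Primer sequence 5'->3'.
#' @param site Template site 5'->3' (same length as \code{primer}); the
#'   primer anneals antiparallel, so primer position i faces site position
#'   \code{n + 1 - i}.
#' @param mask Which primer positions are paired: logical vector, integer
#'   indices, or a string of \code{"|"} (paired) / \code{"."} (unpaired).
#'   Must mark at least one paired position and include the 3' terminus.
#' @param model A [thermo_model()].
#' @return Tm in degrees C.
#' @examples
#' wwp1 <- "CGTCTCCAGTCTCCATGTGTTCGTC"
#' wwp2 <- "CGTCTCCAGTCTTAGGCACAGTGTC"
#' tm_wristwatch_duplex(wwp2, dna_revcomp(wwp1), c(1:12, 23:25), thermo_model())
#' @export
tm_wristwatch_duplex <- function(primer, site, mask, model = thermo_model()) {
  model <- .as_thermo_model(model)
  p <- .dna_int(primer, "primer")
  s <- .dna_int(site, "site")
  n <- length(p)
  if (length(s) != n)
    .wwpcr_error("wwpcr_input_error", "primer and site must have equal length")
  paired <- .parse_mask(mask, n)
  if (!any(paired))
    .wwpcr_error("wwpcr_mask_error", "mask has zero paired positions")
  if (!paired[n])
    .wwpcr_error("wwpcr_mask_error", "mask must pair the primer 3' terminus")
  # antiparallel complementarity at paired positions
  facing <- rev(5L - s)              # facing[i] = base code complementary to site opposite primer i
  bad <- which(paired & (p != facing))
  if (length(bad) > 0L)
    .wwpcr_error("wwpcr_noncomplementary_error",
                 sprintf("mask pairs non-complementary bases at primer position(s) %s",
                         paste(bad, collapse = ", ")))
  .duplex_ensemble_tm(p, paired, model)
}

#' Scan a template for productive primer annealing sites
#'
#' Finds every ungapped, 3'-anchored annealing site of \code{primer} on the
#' given strand sense of \code{template}: the primer's
#' \code{min_3prime_match} terminal bases must pair contiguously (the seed),
#' and the duplex Tm of the resulting pairing arrangement must reach the
#' effective stringency gate \code{anneal_temp - stringency_offset}.
#'
#' @param primer Primer sequence 5'->3'.
#' @param template Template sequence 5'->3' (string or \code{dna_record}).
#'   The primer anneals antiparallel to this strand as written.
#' @param anneal_temp Stage annealing temperature, degrees C.
#' @param model A [thermo_model()].
#' @param template_id Optional template name carried into the result.
#' @param strand Strand label ("+" or "-") carried into the result.
#' @return A data.frame of annealing sites sorted by coordinate with columns
#'   \code{template_id}, \code{strand}, \code{three_prime_pos} (0-based
#'   template coordinate paired with the primer 3' terminus),
#'   \code{footprint_start}/\code{footprint_end} (0-based half-open),
#'   \code{duplex_tm}, \code{terminal_match_run}, \code{n_paired},
#'   \code{mask} (primer 5'->3', \code{"|"} paired / \code{"."} unpaired).
#' @examples
#' g <- paste(rep("ACGT", 30), collapse = "")
#' scan_annealing_sites("TACGTACG", g, 10, thermo_model(min_3prime_match = 3))
#' @export
scan_annealing_sites <- function(primer, template, anneal_temp,
                                 model = thermo_model(),
                                 template_id = NA_character_, strand = "+") {
  model <- .as_thermo_model(model)
  if (is.list(template) && !is.null(template$seq)) {
    if (is.na(template_id) && !is.null(template$id)) template_id <- template$id
    template <- template$seq
  }
  p <- .dna_int(primer, "primer")
  t <- .dna_int(template, "template")
  m <- length(p); L <- length(t)
  if (L < m)
    .wwpcr_error("wwpcr_input_error", "template shorter than primer")
  k <- model$min_3prime_match
  gate <- anneal_temp - model$stringency_offset
  # seed: primer positions m, m-1, ..., m-k+1 pair template j, j+1, ..., j+k-1
  nj <- L - m + 1L
  seed <- rep(TRUE, nj)
  for (tt in 0:(k - 1L)) {
    need <- 5L - p[m - tt]
    seed <- seed & (t[(1L + tt):(nj + tt)] == need)
  }
  js <- which(seed)
  if (length(js) == 0L) return(.empty_sites(template_id, strand))
  rows <- vector("list", length(js))
  nr <- 0L
  for (j in js) {
    paired <- p == rev(5L - t[j:(j + m - 1L)])
    run <- 0L
    for (i in m:1L) { if (paired[i]) run <- run + 1L else break }
    tm <- .duplex_ensemble_tm(p, paired, model)
    if (tm >= gate) {
      nr <- nr + 1L
      rows[[nr]] <- data.frame(
        template_id = template_id, strand = strand,
        three_prime_pos = j - 1L,
        footprint_start = j - 1L, footprint_end = j - 1L + m,
        duplex_tm = tm, terminal_match_run = run, n_paired = sum(paired),
        mask = paste(ifelse(paired, "|", "."), collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (nr == 0L) return(.empty_sites(template_id, strand))
  out <- do.call(rbind, rows[seq_len(nr)])
  out[order(out$three_prime_pos), , drop = FALSE]
}

.empty_sites <- function(template_id, strand) {
  data.frame(template_id = character(0), strand = character(0),
             three_prime_pos = integer(0), footprint_start = integer(0),
             footprint_end = integer(0), duplex_tm = numeric(0),
             terminal_match_run = integer(0), n_paired = integer(0),
             mask = character(0), stringsAsFactors = FALSE)
}

# Longest antiparallel complementary run between a (5'->3') and b (5'->3'),
# over all ungapped relative offsets.
.max_comp_run <- function(acodes, bcodes) {
  brc <- rev(5L - bcodes)   # now a run of equality a[i] == brc[j] is a complementary run
  na <- length(acodes); nb <- length(brc)
  best <- 0L
  for (off in (-(nb - 1L)):(na - 1L)) {
    i1 <- max(1L, 1L + off); i2 <- min(na, nb + off)
    if (i2 < i1) next
    eq <- acodes[i1:i2] == brc[(i1 - off):(i2 - off)]
    if (any(eq)) {
      r <- rle(eq)
      best <- max(best, max(r$lengths[r$values]))
    }
  }
  best
}

# Longest intramolecular stem (antiparallel self-complementary fold) with a
# minimum loop of min_loop nt.
.max_hairpin_stem <- function(codes, min_loop = 3L) {
  n <- length(codes); best <- 0L
  if (n < min_loop + 2L) return(0L)
  for (i in 1:(n - min_loop - 1L)) {
    for (j in n:(i + min_loop + 1L)) {
      run <- 0L; a <- i; b <- j
      while (a < b - min_loop && codes[a] == 5L - codes[b]) {
        run <- run + 1L; a <- a + 1L; b <- b - 1L
      }
      if (run > best) best <- run
    }
  }
  best
}

#' Hairpin and primer-dimer screens
#'
#' Exhaustive small-scale search for the worst self-complementary fold
#' (hairpin), worst self-dimer, and (when \code{seq_b} is supplied) worst
#' cross-dimer, scored as the longest antiparallel complementary run.
#'
#' @param seq_a Primer sequence.
#' @param seq_b Optional second sequence for the cross-dimer screen.
#' @param model A [thermo_model()]; supplies the failure thresholds
#'   \code{hairpin_max_stem} and \code{dimer_max_run}.
#' @return A list of class \code{structure_screens} with the three scores,
#'   per-screen pass flags, and an overall \code{pass}.
#' @examples
#' structure_screens("CGTCTCCAGTCTCCATGTGTTCGTC")
#' @export
structure_screens <- function(seq_a, seq_b = NULL, model = thermo_model()) {
  model <- .as_thermo_model(model)
  a <- .dna_int(seq_a, "seq_a")
  hairpin <- .max_hairpin_stem(a)
  self_dimer <- .max_comp_run(a, a)
  cross_dimer <- NA_integer_
  if (!is.null(seq_b)) {
    b <- .dna_int(seq_b, "seq_b")
    cross_dimer <- .max_comp_run(a, b)
  }
  res <- list(
    hairpin_stem = hairpin,
    self_dimer_run = self_dimer,
    cross_dimer_run = cross_dimer,
    hairpin_pass = hairpin < model$hairpin_max_stem,
    self_dimer_pass = self_dimer < model$dimer_max_run,
    cross_dimer_pass = if (is.na(cross_dimer)) NA else cross_dimer < model$dimer_max_run)
  res$pass <- res$hairpin_pass && res$self_dimer_pass &&
    (is.na(res$cross_dimer_pass) || res$cross_dimer_pass)
  class(res) <- "structure_screens"
  res
}

#' @export
print.structure_screens <- function(x, ...) {
  cat(sprintf("<structure_screens> hairpin stem %d (%s), self-dimer run %d (%s)",
              x$hairpin_stem, if (x$hairpin_pass) "pass" else "FAIL",
              x$self_dimer_run, if (x$self_dimer_pass) "pass" else "FAIL"))
  if (!is.na(x$cross_dimer_run))
    cat(sprintf(", cross-dimer run %d (%s)", x$cross_dimer_run,
                if (isTRUE(x$cross_dimer_pass)) "pass" else "FAIL"))
  cat("\n")
  invisible(x)
}
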