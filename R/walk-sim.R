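# Three-round staged-stringency walking-PCR simulator: species enumeration,
# target / type I-III background classification, and band-pattern prediction.

#' Thermal cycling profile for one walking-PCR round
#'
#' Three annealing stages: stage 1, a few high-stringency cycles in which
#' only the gene-specific primer primes; stage 2, exactly one low- or
#' reduced-stringency cycle in which the walking primer partially anneals;
#' stage 3, the high-stringency amplification cycles. The single stage-2
#' cycle is the method's core constraint: a primer may partially anneal to
#' the template once only, so non-target single strands made in stage 2 can
#' never acquire a second perfect primer site.
#'
#' @param stage1,stage2,stage3 Numeric pairs \code{c(anneal_temp_C, cycles)}.
#' @param denature_temp,extension_temp Degrees C (informational).
#' @param extension_time Extension step length, seconds.
#' @param elongation_rate Polymerase speed, nt/s; with the defaults the
#'   extension cap is 4 kb per cycle.
#' @return An object of class \code{cycling_profile}.
#' @examples
#' cycling_profile()                      # primary round (25 C stage 2)
#' cycling_profile(stage2 = c(40, 1))     # secondary/tertiary (40 C stage 2)
#' @export
cycling_profile <- function(stage1 = c(65, 5), stage2 = c(25, 1),
                            stage3 = c(65, 25), denature_temp = 94,
                            extension_temp = 72, extension_time = 120,
                            elongation_rate = 2000 / 60) {
  for (s in list(stage1, stage2, stage3))
    if (length(s) != 2L || any(!is.finite(s)))
      .wwpcr_error("wwpcr_input_error", "each stage must be c(anneal_temp, cycles)")
  if (stage2[2] != 1)
    .wwpcr_error("wwpcr_profile_error",
                 "stage 2 must have exactly 1 cycle: a primer may partially anneal once only")
  if (stage1[1] < stage2[1] || stage3[1] < stage2[1])
    .wwpcr_error("wwpcr_profile_error",
                 "stage 1/3 annealing temperatures must not be below the stage 2 temperature")
  structure(list(
    stage1 = c(anneal_temp = stage1[1], cycles = stage1[2]),
    stage2 = c(anneal_temp = stage2[1], cycles = stage2[2]),
    stage3 = c(anneal_temp = stage3[1], cycles = stage3[2]),
    denature_temp = denature_temp, extension_temp = extension_temp,
    extension_time = extension_time, elongation_rate = elongation_rate,
    extension_cap = as.integer(floor(elongation_rate * extension_time + 1e-9))),
    class = "cycling_profile")
}

#' @export
print.cycling_profile <- function(x, ...) {
  cat(sprintf("<cycling_profile> %g C x%d | %g C x%d | %g C x%d; cap %d nt\n",
              x$stage1[1], x$stage1[2], x$stage2[1], x$stage2[2],
              x$stage3[1], x$stage3[2], x$extension_cap))
  invisible(x)
}

#' Default cycling profiles for the three rounds
#'
#' Primary: 5 cycles at 65 C, 1 cycle at 25 C, 25 cycles at 65 C.
#' Secondary and tertiary: identical except the single middle cycle runs at
#' 40 C (the reduced-stringency, wristwatch-annealing cycle).
#'
#' @return Named list with elements \code{primary}, \code{secondary},
#'   \code{tertiary}.
#' @export
default_profiles <- function() {
  list(primary = cycling_profile(stage2 = c(25, 1)),
       secondary = cycling_profile(stage2 = c(40, 1)),
       tertiary = cycling_profile(stage2 = c(40, 1)))
}

.as_primer <- function(x, role_hint = "primer") {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L)
      .wwpcr_error("wwpcr_input_error", sprintf("%s must be a single primer record", role_hint))
    return(list(name = x$name, seq = toupper(x$sequence),
                role = if ("role" %in% names(x)) x$role else NA_character_))
  }
  if (is.list(x) && !is.null(x$seq))
    return(list(name = if (is.null(x$name)) role_hint else x$name,
                seq = toupper(x$seq), role = x$role %||% NA_character_))
  if (is.character(x) && length(x) == 1L) {
    nm <- names(x) %||% role_hint
    return(list(name = nm, seq = toupper(unname(x)), role = NA_character_))
  }
  .wwpcr_error("wwpcr_input_error", sprintf("cannot interpret %s as a primer record", role_hint))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.species_row <- function(seq, strand, start, end, five_prime_primer,
                         three_prime_primer, three_prime_origin,
                         round_created, is_amplicon = FALSE,
                         template_id = NA_character_) {
  data.frame(
    id = paste(five_prime_primer %||% "none", start, end, strand, sep = ":"),
    template_id = template_id, seq = seq, strand = strand,
    start = as.integer(start), end = as.integer(end),
    five_prime_primer = five_prime_primer,
    three_prime_primer = three_prime_primer,
    three_prime_origin = three_prime_origin,
    amplification_class = "none", product_class = "na",
    round_created = as.integer(round_created),
    is_amplicon = is_amplicon, stringsAsFactors = FALSE)
}

#' Species pool for a genome template
#'
#' Represents the denatured input genome as two primer-less single-stranded
#' species (the plus and minus strands).
#'
#' @param genome A \code{dna_record} (list with \code{id}, \code{seq}) or a
#'   DNA string.
#' @return A species-pool data.frame.
#' @export
genome_pool <- function(genome) {
  if (is.character(genome)) genome <- list(id = "genome", seq = genome)
  seq <- toupper(genome$seq)
  .dna_int(seq, "genome")
  L <- nchar(seq)
  rbind(
    .species_row(seq, "+", 0L, L, NA_character_, NA_character_,
                 "template_end", 0L, template_id = genome$id),
    .species_row(dna_revcomp(seq), "-", 0L, L, NA_character_, NA_character_,
                 "template_end", 0L, template_id = genome$id))
}

# Map a local (1-based, 5'->3') interval [lo, hi] on a species to reference
# 0-based half-open coordinates.
.local_to_ref <- function(row, lo, hi) {
  if (row$strand == "+") c(row$start + lo - 1L, row$start + hi)
  else c(row$end - hi, row$end - lo + 1L)
}

# Product of priming `primer` on template `row` at a site whose 3'-terminal
# base pairs local position j (footprint [j, j + m - 1]); extension runs
# toward the template 5' end, capped at `cap` nt.
.extension_product <- function(row, j, primer, cap, round, origin_override = NULL) {
  m <- nchar(primer$seq)
  ext_lo <- max(1L, j - cap)
  reached <- ext_lo == 1L
  ext_seq <- if (j > 1L) dna_revcomp(substr(row$seq, ext_lo, j - 1L)) else ""
  ref <- .local_to_ref(row, ext_lo, j + m - 1L)
  .species_row(
    seq = paste0(primer$seq, ext_seq),
    strand = if (row$strand == "+") "-" else "+",
    start = ref[1L], end = ref[2L],
    five_prime_primer = primer$name,
    three_prime_primer = if (reached) row$five_prime_primer else NA_character_,
    three_prime_origin = if (!is.null(origin_override)) origin_override
                         else if (reached) "template_end" else "extension_limit",
    round_created = round, is_amplicon = !is.null(origin_override),
    template_id = row$template_id)
}

.dedup_pool <- function(pool) pool[!duplicated(pool$id), , drop = FALSE]

#' Simulate one walking-PCR round
#'
#' Stage 1: the gene-specific primer extends from every high-stringency
#' annealing site on every template, creating GSP-primed single strands.
#' Stage 2 (one cycle): the walking primer anneals at the reduced stage-2
#' stringency to every single strand in the tube - in the secondary and
#' tertiary rounds this includes the wristwatch site at the previous
#' walking primer's incorporated locus - and extends, capped by the
#' polymerase extension limit. Stage 3: a species is marked
#' \code{exponential} only if its 5' terminus is one of the current primers
#' and the other (or the same) current primer has a high-stringency site on
#' it from which extension reaches its 5' end; such species define the
#' round's amplicons, which are added to the pool on both strands. All
#' other species are \code{linear} (one usable perfect site) or
#' \code{none}.
#'
#' @param templates A species pool (from [genome_pool()] or a previous
#'   round) or a \code{dna_record}/string genome.
#' @param gsp,wwp Current gene-specific and walking primer (single primer
#'   table row, \code{list(name=, seq=)}, or named string).
#' @param prev_wwp The previous round's walking primer, or \code{NULL} for
#'   the primary round (used to flag wristwatch annealing events).
#' @param profile A [cycling_profile()].
#' @param model A [thermo_model()].
#' @param round Round number stamped on new species.
#' @param gsp_ref5 Optional 0-based reference coordinate of the authentic
#'   GSP 5' terminus; enables target vs type II classification.
#' @return The deduplicated species pool after the round, with
#'   per-species \code{amplification_class} and \code{product_class} for
#'   this round; attribute \code{"stage_log"} holds per-stage event counts
#'   (including the number of wristwatch annealing events).
#' @export
simulate_round <- function(templates, gsp, wwp, prev_wwp = NULL,
                           profile = cycling_profile(), model = thermo_model(),
                           round = 1L, gsp_ref5 = NA_integer_) {
  if (!inherits(profile, "cycling_profile"))
    .wwpcr_error("wwpcr_input_error", "profile must be a cycling_profile")
  if (profile$stage2[["cycles"]] != 1)
    .wwpcr_error("wwpcr_profile_error",
                 "stage 2 must have exactly 1 cycle: a primer may partially anneal once only")
  gsp <- .as_primer(gsp, "gsp"); wwp <- .as_primer(wwp, "wwp")
  if (!is.null(prev_wwp)) prev_wwp <- .as_primer(prev_wwp, "prev_wwp")
  if (!is.data.frame(templates)) templates <- genome_pool(templates)
  cap <- profile$extension_cap

  # --- stage 1: high-stringency GSP extension
  t1 <- profile$stage1[["anneal_temp"]]
  stage1_products <- list(); n1 <- 0L
  for (r in seq_len(nrow(templates))) {
    row <- templates[r, ]
    if (nchar(row$seq) < nchar(gsp$seq)) next
    sites <- scan_annealing_sites(gsp$seq, row$seq, t1, model)
    for (s in seq_len(nrow(sites))) {
      n1 <- n1 + 1L
      stage1_products[[n1]] <-
        .extension_product(row, sites$three_prime_pos[s] + 1L, gsp, cap, round)
    }
  }
  stage1_products <- if (n1) .dedup_pool(do.call(rbind, stage1_products)) else NULL

  # --- stage 2: one low/reduced-stringency WWP annealing cycle
  t2 <- profile$stage2[["anneal_temp"]]
  stage2_templates <- rbind(templates, stage1_products)
  stage2_products <- list(); n2 <- 0L; n_wristwatch <- 0L
  for (r in seq_len(nrow(stage2_templates))) {
    row <- stage2_templates[r, ]
    if (nchar(row$seq) < nchar(wwp$seq)) next
    sites <- scan_annealing_sites(wwp$seq, row$seq, t2, model)
    for (s in seq_len(nrow(sites))) {
      n2 <- n2 + 1L
      stage2_products[[n2]] <-
        .extension_product(row, sites$three_prime_pos[s] + 1L, wwp, cap, round)
      if (!is.null(prev_wwp) &&
          identical(row$three_prime_primer, prev_wwp$name) &&
          sites$footprint_end[s] == nchar(row$seq))
        n_wristwatch <- n_wristwatch + 1L
    }
  }
  stage2_products <- if (n2) .dedup_pool(do.call(rbind, stage2_products)) else NULL

  pool <- .dedup_pool(rbind(templates, stage1_products, stage2_products))

  # --- stage 3: high-stringency conversion; exponential needs perfect sites
  # for the current primer pair on the species
  t3 <- profile$stage3[["anneal_temp"]]
  cur <- list(gsp = gsp, wwp = wwp)
  amplicons <- list(); na_ <- 0L
  pool$amplification_class <- "none"
  pool$product_class <- "na"
  for (r in seq_len(nrow(pool))) {
    row <- pool[r, ]
    five_cur <- identical(row$five_prime_primer, gsp$name) ||
      identical(row$five_prime_primer, wwp$name)
    has_site <- FALSE; expo <- FALSE
    for (p in cur) {
      if (nchar(row$seq) < nchar(p$seq)) next
      sites <- scan_annealing_sites(p$seq, row$seq, t3, model)
      if (nrow(sites) == 0L) next
      has_site <- TRUE
      if (!five_cur) next
      for (s in seq_len(nrow(sites))) {
        j <- sites$three_prime_pos[s] + 1L
        if (j - 1L <= cap) {          # return extension reaches the 5' end
          expo <- TRUE
          amp <- .extension_product(row, j, p, cap, round, origin_override = "primer_site")
          amp$amplification_class <- "exponential"
          amp$product_class <- .classify_pair(p$name, row$five_prime_primer,
                                              gsp$name, wwp$name, amp, gsp_ref5)
          partner <- amp
          partner$seq <- dna_revcomp(amp$seq)
          partner$strand <- row$strand
          partner$five_prime_primer <- row$five_prime_primer
          partner$three_prime_primer <- p$name
          partner$id <- paste(partner$five_prime_primer %||% "none",
                              partner$start, partner$end, partner$strand, sep = ":")
          partner$amplification_class <- "exponential"
          partner$product_class <- amp$product_class
          na_ <- na_ + 1L; amplicons[[na_]] <- amp
          na_ <- na_ + 1L; amplicons[[na_]] <- partner
        }
      }
    }
    pool$amplification_class[r] <-
      if (expo) "exponential" else if (has_site || five_cur) "linear" else "none"
    if (expo)
      pool$product_class[r] <- .classify_provenance(row, gsp$name, wwp$name, gsp_ref5)
  }
  if (na_) {
    amplicons <- do.call(rbind, amplicons)
    keep <- !(amplicons$id %in% pool$id)
    pool <- rbind(pool, .dedup_pool(amplicons[keep, , drop = FALSE]))
    # species already in the pool that coincide with an amplicon inherit its class
    hit <- match(pool$id, amplicons$id)
    upd <- which(!is.na(hit))
    pool$amplification_class[upd] <- "exponential"
    pool$product_class[upd] <- amplicons$product_class[hit[upd]]
  }
  attr(pool, "stage_log") <- data.frame(
    round = round,
    stage1_sites = n1, stage2_sites = n2, wristwatch_events = n_wristwatch,
    pool_size = nrow(pool),
    exponential = sum(pool$amplification_class == "exponential"),
    stringsAsFactors = FALSE)
  pool
}

# Classify by the defining primer pair of an amplicon: `p2` primes the
# returned copy, `p1` is the template species' 5' primer.
.classify_pair <- function(p2, p1, gsp_name, wwp_name, amp, gsp_ref5) {
  is_gsp <- c(identical(p2, gsp_name), identical(p1, gsp_name))
  is_wwp <- c(identical(p2, wwp_name), identical(p1, wwp_name))
  if (all(is_gsp)) return("typeI")
  if (all(is_wwp)) return("typeIII")
  if (any(is_gsp) && any(is_wwp)) {
    if (is.na(gsp_ref5)) return("target")
    # reference coordinate of the GSP 5' terminus on this amplicon
    gsp_on_p2 <- is_gsp[1L]
    ref5 <- if (gsp_on_p2) {
      if (amp$strand == "+") amp$start else amp$end - 1L
    } else {
      # the GSP sits at the amplicon 3' end; its 5' base is the last base
      if (amp$strand == "+") amp$end - 1L else amp$start
    }
    if (ref5 == gsp_ref5) "target" else "typeII"
  } else "na"
}

.classify_provenance <- function(row, gsp_name, wwp_name, gsp_ref5) {
  p1 <- row$five_prime_primer
  p2 <- row$three_prime_primer
  if (is.na(p1) || is.na(p2)) return("na")
  .classify_pair(p1, p2, gsp_name, wwp_name, row, gsp_ref5)
}

#' Classify a product species as target or type I/II/III background
#'
#' Walking PCRs produce three kinds of non-target products: type I, primed
#' by the gene-specific primer at both ends; type II, primed by the GSP at
#' an off-target locus together with the walking primer; and type III,
#' primed by the walking primer alone. A target species carries the GSP at
#' its authentic locus at one end and the walking primer at the other.
#'
#' @param species One species-pool row (or a list with
#'   \code{five_prime_primer}, \code{three_prime_primer}, \code{strand},
#'   \code{start}, \code{end}).
#' @param gsp_true_site 0-based reference coordinate of the authentic GSP
#'   5' terminus (NA disables the target/typeII distinction and any
#'   GSP+WWP product is called target).
#' @param primers Current primer pair: list or character vector with
#'   elements \code{gsp} and \code{wwp} giving the primer names.
#' @return One of \code{"target"}, \code{"typeI"}, \code{"typeII"},
#'   \code{"typeIII"}, or \code{"na"} (unknown provenance).
#' @export
classify_species <- function(species, gsp_true_site = NA_integer_, primers) {
  if (is.data.frame(species)) {
    if (nrow(species) != 1L)
      .wwpcr_error("wwpcr_input_error", "classify_species expects a single species")
    species <- as.list(species)
  }
  gsp_name <- primers[["gsp"]]; wwp_name <- primers[["wwp"]]
  p1 <- species$five_prime_primer; p2 <- species$three_prime_primer
  if (is.null(p1) || is.null(p2) || is.na(p1) || is.na(p2))
    .wwpcr_error("wwpcr_provenance_error",
                 "species has unknown primer provenance at one or both termini")
  .classify_pair(p1, p2, gsp_name, wwp_name, species, gsp_true_site)
}

#' Simulate a full three-round wristwatch walking PCR
#'
#' Chains three [simulate_round()] calls: the primary round on the genome,
#' the secondary and tertiary rounds each templated on the previous round's
#' full (deduplicated) species pool, with the walking primer of round n+1
#' annealing at the incorporated locus of round n's walking primer (the
#' wristwatch site). The final predicted bands are the tertiary round's
#' exponential amplicons.
#'
#' @param genome A \code{dna_record} or DNA string (reference plus strand).
#' @param known_region \code{c(start, end)}, 0-based half-open coordinates
#'   of the known anchor sequence on the plus strand.
#' @param gsps Primer table of GSP1..GSP3 (tier order) as designed by
#'   [design_gsp_nest()], or a length-3 character vector.
#' @param wwps The WWP permutation for this set: primer table or length-3
#'   named character vector, position 1 = primary.
#' @param profiles List of three [cycling_profile()]s (primary, secondary,
#'   tertiary); default [default_profiles()].
#' @param model A [thermo_model()].
#' @return An object of class \code{walk_result}: per-round pools and stage
#'   logs, \code{final_bands} (size-annotated tertiary exponential
#'   amplicons, walking-primer strand), and classification tallies.
#' @export
simulate_walk <- function(genome, known_region, gsps, wwps,
                          profiles = default_profiles(),
                          model = thermo_model()) {
  if (is.character(genome)) genome <- list(id = "genome", seq = toupper(genome))
  gseq <- toupper(genome$seq)
  if (length(known_region) != 2L || known_region[1] < 0 ||
      known_region[2] > nchar(gseq) || known_region[1] >= known_region[2])
    .wwpcr_error("wwpcr_input_error", "known_region must be 0-based half-open within the genome")
  gsp_list <- .primer_triple(gsps, "GSP")
  wwp_list <- .primer_triple(wwps, "WWP")
  known <- substr(gseq, known_region[1] + 1L, known_region[2])
  gsp_ref5 <- integer(3)
  for (i in 1:3) {
    hit <- regexpr(gsp_list[[i]]$seq, known, fixed = TRUE)
    if (hit == -1L) {
      hit_rc <- regexpr(dna_revcomp(gsp_list[[i]]$seq), known, fixed = TRUE)
      if (hit_rc == -1L)
        .wwpcr_error("wwpcr_input_error",
                     sprintf("GSP %s not found in the known region", gsp_list[[i]]$name))
      gsp_ref5[i] <- known_region[1] + as.integer(hit_rc) - 1L +
        nchar(gsp_list[[i]]$seq) - 1L
    } else {
      gsp_ref5[i] <- known_region[1] + as.integer(hit) - 1L
    }
  }
  if (length(profiles) != 3L)
    .wwpcr_error("wwpcr_input_error", "profiles must list three cycling profiles")

  pool <- genome_pool(genome)
  rounds <- vector("list", 3L)
  logs <- vector("list", 3L)
  for (rd in 1:3) {
    pool <- simulate_round(
      pool, gsp = gsp_list[[rd]], wwp = wwp_list[[rd]],
      prev_wwp = if (rd > 1L) wwp_list[[rd - 1L]] else NULL,
      profile = profiles[[rd]], model = model, round = rd,
      gsp_ref5 = gsp_ref5[rd])
    rounds[[rd]] <- pool
    logs[[rd]] <- attr(pool, "stage_log")
  }
  # final bands: tertiary-round exponential species bounded by the current
  # primer pair, reported on the walking-primer strand
  w3 <- wwp_list[[3L]]$name; g3 <- gsp_list[[3L]]$name
  final <- pool[pool$amplification_class == "exponential" &
                  pool$round_created == 3L &
                  !is.na(pool$five_prime_primer) &
                  pool$five_prime_primer == w3 &
                  !is.na(pool$three_prime_primer) &
                  pool$three_prime_primer == g3, , drop = FALSE]
  final$size <- nchar(final$seq)
  final <- final[order(-final$size), , drop = FALSE]
  tallies <- table(factor(pool$product_class,
                          levels = c("target", "typeI", "typeII", "typeIII", "na")),
                   factor(pool$amplification_class,
                          levels = c("exponential", "linear", "none")))
  structure(list(
    rounds = rounds, stage_logs = do.call(rbind, logs), final_bands = final,
    tallies = tallies,
    gsps = vapply(gsp_list, function(p) p$name, ""),
    wwps = vapply(wwp_list, function(p) p$name, ""),
    gsp_ref5 = gsp_ref5, genome_id = genome$id %||% "genome",
    known_region = known_region,
    extension_cap = profiles[[1L]]$extension_cap), class = "walk_result")
}

.primer_triple <- function(x, role) {
  if (is.data.frame(x)) {
    if (role %in% x$role) x <- x[x$role == role, , drop = FALSE]
    x <- x[order(x$tier), , drop = FALSE]
    if (nrow(x) != 3L)
      .wwpcr_error("wwpcr_input_error", sprintf("need exactly three %ss", role))
    return(lapply(1:3, function(i) list(name = x$name[i], seq = toupper(x$sequence[i]))))
  }
  if (is.character(x) && length(x) == 3L) {
    nms <- names(x) %||% paste0(role, 1:3)
    return(lapply(1:3, function(i) list(name = nms[i], seq = toupper(unname(x[i])))))
  }
  .wwpcr_error("wwpcr_input_error", sprintf("cannot interpret %ss", role))
}

#' @export
print.walk_result <- function(x, ...) {
  cat("<walk_result>", x$genome_id, "| GSPs:", paste(x$gsps, collapse = ","),
      "| WWPs:", paste(x$wwps, collapse = ","), "\n")
  print(x$stage_logs, row.names = FALSE)
  if (nrow(x$final_bands)) {
    cat("final bands (nt):", paste(x$final_bands$size, collapse = ", "), "\n")
  } else cat("no final bands predicted\n")
  invisible(x)
}

#' Predicted band pattern of a simulated walk
#'
#' @param result A \code{walk_result} from [simulate_walk()].
#' @return A data.frame of unique band sizes in descending order with the
#'   defining primer pair, reference coordinates, strand, and product
#'   class.
#' @export
predict_band_pattern <- function(result) {
  if (!inherits(result, "walk_result"))
    .wwpcr_error("wwpcr_input_error", "result must be a walk_result")
  fb <- result$final_bands
  if (nrow(fb) == 0L)
    return(data.frame(size = integer(0), primer_pair = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product_class = character(0),
                      stringsAsFactors = FALSE))
  fb <- fb[!duplicated(fb$size), , drop = FALSE]
  out <- data.frame(
    size = fb$size,
    primer_pair = paste(fb$five_prime_primer, fb$three_prime_primer, sep = "+"),
    start = fb$start, end = fb$end, strand = fb$strand,
    product_class = fb$product_class, stringsAsFactors = FALSE)
  out[order(-out$size), , drop = FALSE]
}
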