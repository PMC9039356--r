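# FASTA / primer-table / report readers and writers, and the run
# configuration object.

#' Read a FASTA file of DNA sequences
#'
#' Reads a (possibly multi-record, wrapped or unwrapped) FASTA file,
#' uppercasing sequences. By default records must be pure A/C/G/T, since
#' the thermodynamic model rejects degenerate bases.
#'
#' @param path FASTA file path.
#' @param require_acgt If TRUE (default), any record containing characters
#'   outside A/C/G/T raises a degenerate-base error.
#' @return A list of \code{dna_record}s (each with \code{id}, \code{seq}).
#' @export
read_fasta <- function(path, require_acgt = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L)
    .wwpcr_error("wwpcr_input_error", sprintf("no FASTA records in %s", path))
  out <- vector("list", length(set))
  ids <- sub("\\s.*$", "", names(set))
  for (i in seq_along(set)) {
    s <- toupper(as.character(set[[i]]))
    if (require_acgt && grepl("[^ACGT]", s))
      .wwpcr_error("wwpcr_degenerate_base_error",
                   sprintf("record '%s' contains non-ACGT characters; degenerate bases are not accepted as simulation input",
                           ids[i]))
    out[[i]] <- structure(list(id = ids[i], seq = s), class = "dna_record")
  }
  out
}

#' Write DNA records to a FASTA file
#'
#' @param records A \code{dna_record}, a list of them, or a named character
#'   vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "dna_record")) records <- list(records)
  if (is.character(records)) {
    nm <- names(records) %||% paste0("seq", seq_along(records))
    records <- mapply(function(id, s) list(id = id, seq = s), nm, records,
                      SIMPLIFY = FALSE)
  }
  seqs <- vapply(records, function(r) toupper(r$seq), "")
  names(seqs) <- vapply(records, function(r) r$id, "")
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a primer table (TSV)
#'
#' Expects a tab-separated file with a header containing at least the
#' columns \code{name}, \code{sequence}, \code{role}, \code{tier}.
#'
#' @param path TSV path.
#' @return A primer table data.frame (extra columns are preserved).
#' @export
read_primer_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "sequence", "role", "tier")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    .wwpcr_error("wwpcr_input_error",
                 sprintf("primer table missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  if (nrow(tab) == 0L)
    .wwpcr_error("wwpcr_input_error", "primer table has no rows")
  if (anyDuplicated(tab$name))
    .wwpcr_error("wwpcr_input_error",
                 sprintf("duplicate primer name(s): %s",
                         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", ")))
  tab$sequence <- toupper(tab$sequence)
  bad <- grepl("[^ACGT]", tab$sequence)
  if (any(bad))
    .wwpcr_error("wwpcr_degenerate_base_error",
                 sprintf("non-ACGT primer sequence at line %s (%s)",
                         paste(which(bad) + 1L, collapse = ", "),
                         paste(tab$name[bad], collapse = ", ")))
  tier <- suppressWarnings(as.integer(tab$tier))
  if (any(is.na(tier)))
    .wwpcr_error("wwpcr_input_error", "tier column must be integer")
  tab$tier <- tier
  if (!all(tab$role %in% c("WWP", "GSP")))
    .wwpcr_error("wwpcr_input_error", "role column must be 'WWP' or 'GSP'")
  tab
}

#' The published wristwatch and gene-specific primer set
#'
#' The bundled table of the three validated WWPs and the two nested GSP
#' sets (gadA of Lactobacillus brevis CD0817 and hyg of rice) shipped with
#' the package.
#'
#' @return A primer table data.frame of 9 primers.
#' @examples
#' published_primers()
#' @export
published_primers <- function() {
  read_primer_table(system.file("extdata", "published_primers.tsv",
                                package = "wwpcr", mustWork = TRUE))
}

#' Write a walk report: JSON ledger, BED6 bands, band-size TSV
#'
#' @param result A \code{walk_result}.
#' @param prefix Output path prefix; writes \code{<prefix>.json},
#'   \code{<prefix>.bed}, \code{<prefix>_bands.tsv}.
#' @return Character vector of the three paths, invisibly.
#' @export
write_walk_report <- function(result, prefix) {
  if (!inherits(result, "walk_result"))
    .wwpcr_error("wwpcr_input_error", "result must be a walk_result")
  json_path <- paste0(prefix, ".json")
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, "_bands.tsv")

  ledger <- list(
    genome_id = result$genome_id,
    known_region = result$known_region,
    gsps = result$gsps, wwps = result$wwps,
    stage_logs = result$stage_logs,
    rounds = lapply(result$rounds, function(p)
      p[, setdiff(names(p), "seq"), drop = FALSE]),
    final_bands = result$final_bands,
    tallies = as.data.frame(result$tallies, stringsAsFactors = FALSE))
  jsonlite::write_json(ledger, json_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")

  fb <- result$final_bands
  bed <- data.frame(
    chrom = rep(result$genome_id, nrow(fb)),
    start = fb$start, end = fb$end,
    name = paste(fb$five_prime_primer, fb$three_prime_primer, sep = "+"),
    score = fb$round_created, strand = fb$strand,
    stringsAsFactors = FALSE)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  bands <- predict_band_pattern(result)
  utils::write.table(bands, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json_path, bed = bed_path, bands = tsv_path))
}

#' Run configuration
#'
#' Bundles the thermodynamic model, primer architecture, and the three
#' cycling profiles; defaults equal the published protocol (stage cycles
#' 5/1/25; annealing 65/25/65 in the primary round and 65/40/65 in the
#' secondary and tertiary rounds; 25-nt primers in a 12+10+3 layout).
#' Round-trips losslessly through JSON.
#'
#' @param thermo A [thermo_model()].
#' @param architecture A [wwp_architecture()].
#' @param profiles A list of three [cycling_profile()]s.
#' @param seed Integer seed recorded for downstream runs.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(thermo = thermo_model(),
                       architecture = wwp_architecture(),
                       profiles = default_profiles(), seed = 1L) {
  structure(list(thermo = thermo, architecture = architecture,
                 profiles = profiles, seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration to JSON
#' @param config A [run_config()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config"))
    .wwpcr_error("wwpcr_input_error", "config must be a run_config")
  payload <- list(
    thermo = unclass(config$thermo),
    architecture = unclass(config$architecture),
    profiles = lapply(config$profiles, function(p) list(
      stage1 = as.numeric(p$stage1), stage2 = as.numeric(p$stage2),
      stage3 = as.numeric(p$stage3), denature_temp = p$denature_temp,
      extension_temp = p$extension_temp, extension_time = p$extension_time,
      elongation_rate = p$elongation_rate)),
    seed = config$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON path written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- do.call(thermo_model, x$thermo[c(
    "nn_parameter_set", "monovalent_salt", "primer_conc", "min_3prime_match",
    "stringency_offset", "hairpin_max_stem", "dimer_max_run")])
  ar <- do.call(wwp_architecture, x$architecture[c(
    "total_len", "prefix_len", "spacer_len", "suffix_len", "self_tm_window",
    "inter_tm_target", "min_tm_gap", "base_balance_tol", "spacer_kmer",
    "spacer_min_hamming", "gsp_tm_tol")])
  profs <- lapply(x$profiles, function(p)
    cycling_profile(stage1 = p$stage1, stage2 = p$stage2, stage3 = p$stage3,
                    denature_temp = p$denature_temp,
                    extension_temp = p$extension_temp,
                    extension_time = p$extension_time,
                    elongation_rate = p$elongation_rate))
  run_config(th, ar, profs, x$seed)
}
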