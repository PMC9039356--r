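# Independent oracles used by the tests: a hand-summed nearest-neighbor Tm
# and an exhaustive-offset annealing-site scanner. Both are deliberately
# written from the formulas, without reusing the package's scanning code.

# Naive nearest-neighbor Tm summation (unified 1998 parameters, primer-excess
# two-state, monovalent-salt entropy correction).
oracle_tm_nn <- function(seq, na_mM = 50, ct_nM = 200) {
  dH_tab <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
              CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
              GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
              TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
  dS_tab <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
              CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
              GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
              TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
  ch <- strsplit(toupper(seq), "")[[1L]]
  n <- length(ch)
  dH <- 0; dS <- 0
  for (i in seq_len(n - 1L)) {
    din <- paste0(ch[i], ch[i + 1L])
    dH <- dH + dH_tab[[din]]; dS <- dS + dS_tab[[din]]
  }
  for (b in c(ch[1L], ch[n])) {
    if (b %in% c("A", "T")) { dH <- dH + 2.3; dS <- dS + 4.1 }
    else { dH <- dH + 0.1; dS <- dS - 2.8 }
  }
  dS <- dS + 0.368 * (n - 1L) * log(na_mM / 1000)
  dH * 1000 / (dS + 1.98720425864083 * log(ct_nM * 1e-9)) - 273.15
}

# Exhaustive-offset site scanner: tests every template offset for the
# productive-priming rule (contiguous 3'-terminal match of at least
# min_3prime_match bases) and gates the bipartite duplex Tm against the
# stage temperature minus the model's stringency offset.
brute_force_scan <- function(primer, template, anneal_temp, model) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  p <- strsplit(toupper(primer), "")[[1L]]
  t <- strsplit(toupper(template), "")[[1L]]
  m <- length(p); L <- length(t)
  k <- model$min_3prime_match
  gate <- anneal_temp - model$stringency_offset
  hits <- integer(0)
  for (j in seq_len(L - m + 1L)) {
    seed_ok <- TRUE
    for (tt in 0:(k - 1L)) {
      if (comp[[p[m - tt]]] != t[j + tt]) { seed_ok <- FALSE; break }
    }
    if (!seed_ok) next
    site <- paste(t[j:(j + m - 1L)], collapse = "")
    paired <- rev(vapply(seq_len(m),
                         function(tt) comp[[p[m - tt + 1L]]] == t[j + tt - 1L],
                         TRUE))
    tm <- tm_wristwatch_duplex(paste(p, collapse = ""), site, which(paired), model)
    if (tm >= gate) hits <- c(hits, j - 1L)
  }
  sort(hits)
}

# Random template with planted full and partial walking-primer sites, for
# oracle-equivalence checks.
make_scan_template <- function(seed, primer, max_len = 5000L) {
  set.seed(seed)
  L <- sample(1500:max_len, 1L)
  bg <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  rc <- dna_revcomp(primer)
  m <- nchar(primer)
  for (plant_len in c(m, sample(10:(m - 5L), 2L, replace = TRUE))) {
    pos <- sample(seq_len(L - m - 1L), 1L)
    frag <- substr(rc, 1L, plant_len)
    bg <- paste0(substr(bg, 1L, pos), frag,
                 substr(bg, pos + plant_len + 1L, L))
  }
  bg
}
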