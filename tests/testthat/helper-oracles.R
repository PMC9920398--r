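# Independent oracles and random-sequence generators used across the suite.
# Oracles deliberately share no code with the implementation paths they
# check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# stop-free random DNA built codon-wise
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                  collapse = "")
      if (!(cd %in% stops)) break
    }
    codons[i] <- cd
  }
  paste(codons, collapse = "")
}

# translation oracle: Biostrings' own translation machinery
oracle_translate <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

# hydrophobic-moment oracle: direct complex-exponential summation
oracle_muH <- function(seq, scale_values, delta = 100) {
  ch <- strsplit(seq, "")[[1]]
  h <- scale_values[ch]
  z <- sum(h * exp(1i * (seq_along(h) - 1) * delta * pi / 180))
  Mod(z) / length(h)
}

# regex oracles for the motif scanners (lookahead finds overlapping matches)
oracle_scan_regex <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

oracle_tom20_starts <- function(seq, phi = "AILMFVWY", beta = "RKH") {
  oracle_scan_regex(seq, sprintf("(?=[%s].[%s][%s][%s])", phi, beta, phi, phi))
}

oracle_tat_starts <- function(seq, polar = "STNQYCG") {
  oracle_scan_regex(seq, sprintf("(?=[ST]RR[%s]FLK)", polar))
}

# Yen criterion recomputed per candidate level from first principles
oracle_yen <- function(pixels) {
  counts <- tabulate(as.integer(pixels) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:254) {
    lo <- p[seq_len(t + 1L)]
    hi <- p[(t + 2L):256L]
    s1 <- sum(lo^2); s2 <- sum(hi^2); P1 <- sum(lo)
    if (s1 <= 0 || s2 <= 0) next
    crit <- 2 * log(P1 * (1 - P1)) - log(s1 * s2)
    if (crit > best + 1e-12) { best <- crit; best_t <- t }
  }
  best_t
}

# random 8-bit histogram sample: mixture of two modes plus uniform spread
random_pixels <- function(n = 2000) {
  lo <- pmin(255, pmax(0, round(rnorm(n * 0.7, runif(1, 20, 80), runif(1, 3, 15)))))
  hi <- pmin(255, pmax(0, round(rnorm(n * 0.2, runif(1, 120, 230), runif(1, 5, 20)))))
  flat <- sample(0:255, n * 0.1, replace = TRUE)
  c(lo, hi, flat)
}

# tiny default field spec for fast imaging tests
tiny_field_spec <- function(...) {
  args <- list(...)
  defaults <- list(image_size = 96L, n_mitochondria = 5L, mito_radius = 3,
                   mito_radius_sd = 0.4, mito_intensity = 180,
                   er_intensity = 8, cytosol_intensity = 20, noise_sd = 2,
                   seed = 1L)
  do.call(field_spec, utils::modifyList(defaults, args))
}
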