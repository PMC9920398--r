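#' @importFrom stats rnorm rpois runif sd setNames pnorm
#' @importFrom utils write.csv head combn
NULL

AA_CANONICAL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Standard genetic code, codon -> one-letter residue ("*" = stop).
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Construct a validated coding sequence
#'
#' A coding sequence is a DNA string whose length is a positive multiple of 3
#' and that contains only the four unambiguous bases. Case is normalised to
#' upper case; ambiguity codes are rejected.
#'
#' @param bases DNA string over A, C, G, T (case-insensitive).
#' @param id Text label for the record.
#' @return An object of class `coding_sequence` (a character scalar with an
#'   `id` attribute).
#' @export
coding_sequence <- function(bases, id = "cds") {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(gsub("[[:space:]]", "", bases))
  if (nchar(bases) == 0L || nchar(bases) %% 3L != 0L) {
    stop("coding sequence length must be a positive multiple of 3, got ",
         nchar(bases))
  }
  bad <- gsub("[ACGT]", "", bases)
  if (nchar(bad) > 0L) {
    stop("coding sequence contains non-ACGT characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  structure(bases, id = id, class = "coding_sequence")
}

#' Construct a validated protein sequence
#'
#' @param residues Protein string over the 20 canonical one-letter codes.
#' @param id Text label.
#' @return An object of class `protein_sequence`. Residue positions are
#'   1-based throughout the package.
#' @export
protein_sequence <- function(residues, id = "protein") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) == 0L) stop("protein sequence must be non-empty")
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), AA_CANONICAL)
  if (length(bad) > 0L) {
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  }
  structure(residues, id = id, class = "protein_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s (%d nt)\n  %s\n",
              attr(x, "id"), nchar(x), unclass(x)))
  invisible(x)
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n  %s\n",
              attr(x, "id"), nchar(x), unclass(x)))
  invisible(x)
}

seq_chars <- function(x) strsplit(as.character(x), "")[[1]]

#' Translate a coding sequence with the standard genetic code
#'
#' One residue per codon. An internal stop codon is an error reported with
#' its codon position; a terminal stop codon is trimmed.
#'
#' @param cds A `coding_sequence` (or a string accepted by
#'   [coding_sequence()]).
#' @param id Label for the resulting protein (defaults to the CDS label).
#' @return A `protein_sequence` of length `nchar(cds) / 3` (one fewer if a
#'   terminal stop is present).
#' @examples
#' translate_dna(coding_sequence("ATGGCT"))
#' @export
translate_dna <- function(cds, id = NULL) {
  if (!inherits(cds, "coding_sequence")) cds <- coding_sequence(cds)
  n_codon <- nchar(cds) %/% 3L
  starts <- 3L * seq_len(n_codon) - 2L
  codons <- substring(as.character(cds), starts, starts + 2L)
  aa <- CODON_TABLE[codons]
  stops <- which(aa == "*")
  if (length(stops) > 0L) {
    if (any(stops < n_codon)) {
      stop("internal stop codon at codon position ", min(stops[stops < n_codon]))
    }
    aa <- aa[-n_codon]
  }
  protein_sequence(paste(aa, collapse = ""),
                   id = if (is.null(id)) attr(cds, "id") else id)
}

#' Net formal charge over a residue span
#'
#' Counts side-chain formal charges only: K and R are +1, D and E are -1,
#' histidine is neutral. When `include_n_terminus = TRUE` and the span starts
#' at residue 1, the free alpha-amino group contributes an extra +1.
#'
#' @param seq A `protein_sequence` or plain string.
#' @param span Integer vector `c(first, last)`, 1-based inclusive. Defaults
#'   to the whole sequence.
#' @param include_n_terminus Count the free N-terminal amine (+1) when the
#'   span starts at residue 1. Default `TRUE`.
#' @return Integer net charge.
#' @examples
#' net_charge("MKALERMAELATGR")  # the PmoB sp n-region: +2
#' @export
net_charge <- function(seq, span = NULL, include_n_terminus = TRUE) {
  if (!inherits(seq, "protein_sequence")) seq <- protein_sequence(seq)
  L <- nchar(seq)
  if (is.null(span)) span <- c(1L, L)
  stopifnot(length(span) == 2L)
  if (span[1] < 1L || span[2] > L || span[1] > span[2]) {
    stop("span [", span[1], ", ", span[2], "] invalid for sequence of length ", L)
  }
  ch <- seq_chars(seq)[span[1]:span[2]]
  q <- sum(ch %in% c("K", "R")) - sum(ch %in% c("D", "E"))
  if (include_n_terminus && span[1] == 1L) q <- q + 1L
  as.integer(q)
}

#' Tripartite region boundaries
#'
#' A signal peptide splits into the basic n-region (1..`n_end`), the
#' hydrophobic h-region (`n_end + 1`..`h_end`) and the polar c-region
#' (`h_end + 1`..L) that ends at the signal-peptidase site.
#'
#' @param n_end 1-based inclusive last residue of the n-region.
#' @param h_end 1-based inclusive last residue of the h-region.
#' @return An object of class `region_boundaries`.
#' @export
region_boundaries <- function(n_end, h_end) {
  n_end <- as.integer(n_end); h_end <- as.integer(h_end)
  if (is.na(n_end) || is.na(h_end) || n_end < 1L || n_end >= h_end) {
    stop("require 1 <= n_end < h_end")
  }
  structure(list(n_end = n_end, h_end = h_end), class = "region_boundaries")
}

#' Annotate a protein sequence with tripartite regions
#'
#' @param seq A `protein_sequence` or string.
#' @param boundaries A `region_boundaries` object; `h_end` must be strictly
#'   inside the sequence so the c-region is non-empty.
#' @param cleavage_after 1-based index of the last residue before
#'   signal-peptidase cleavage; for an isolated signal peptide this is the
#'   sequence length (default).
#' @return An object of class `signal_peptide` with fields `sequence`,
#'   `regions` and `cleavage_after`.
#' @export
annotate_regions <- function(seq, boundaries, cleavage_after = NULL) {
  if (!inherits(seq, "protein_sequence")) seq <- protein_sequence(seq)
  stopifnot(inherits(boundaries, "region_boundaries"))
  L <- nchar(seq)
  if (boundaries$h_end >= L) {
    stop("h_end (", boundaries$h_end, ") must be < sequence length (", L, ")")
  }
  if (is.null(cleavage_after)) cleavage_after <- L
  if (cleavage_after < 1L || cleavage_after > L) stop("cleavage_after out of range")
  structure(list(sequence = seq, regions = boundaries,
                 cleavage_after = as.integer(cleavage_after)),
            class = "signal_peptide")
}

#' Extract one tripartite region as a string
#'
#' @param sp A `signal_peptide`.
#' @param region One of `"n"`, `"h"`, `"c"`.
#' @return The exact substring of the region.
#' @export
region_sequence <- function(sp, region = c("n", "h", "c")) {
  stopifnot(inherits(sp, "signal_peptide"))
  region <- match.arg(region)
  L <- nchar(sp$sequence)
  b <- sp$regions
  idx <- switch(region,
    n = c(1L, b$n_end),
    h = c(b$n_end + 1L, b$h_end),
    c = c(b$h_end + 1L, L))
  substr(as.character(sp$sequence), idx[1], idx[2])
}

#' Residue index ranges of the three regions
#'
#' @param sp A `signal_peptide`.
#' @return Named list of integer vectors `c(first, last)` for n, h, c.
#' @export
region_spans <- function(sp) {
  stopifnot(inherits(sp, "signal_peptide"))
  b <- sp$regions
  L <- nchar(sp$sequence)
  list(n = c(1L, b$n_end), h = c(b$n_end + 1L, b$h_end), c = c(b$h_end + 1L, L))
}

#' @export
print.signal_peptide <- function(x, ...) {
  cat(sprintf("<signal_peptide> %s (%d aa), cleavage after %d\n",
              attr(x$sequence, "id"), nchar(x$sequence), x$cleavage_after))
  cat(sprintf("  n: %s\n  h: %s\n  c: %s\n",
              region_sequence(x, "n"), region_sequence(x, "h"),
              region_sequence(x, "c")))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"` or `"dna"`.
#' @return A list of `protein_sequence` or `coding_sequence` objects, named
#'   by record.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    s <- as.character(set[[i]])
    nm <- names(set)[i]
    if (type == "dna") coding_sequence(s, id = nm) else protein_sequence(s, id = nm)
  })
  names(out) <- names(set)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A single sequence object or a list of them (all
#'   `protein_sequence` or all `coding_sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!is.list(seqs)) seqs <- list(seqs)
  ids <- vapply(seqs, function(s) attr(s, "id"), character(1))
  chr <- vapply(seqs, as.character, character(1))
  if (inherits(seqs[[1]], "coding_sequence")) {
    set <- Biostrings::DNAStringSet(chr)
  } else {
    set <- Biostrings::AAStringSet(chr)
  }
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
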