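# Consensus-motif scanners: the Tom20 phi-x-beta-phi-phi hydrophobic motif
# of mitochondrial pre-sequences, the bacterial TAT twin-arginine motif, and
# the AxA signal-peptidase cleavage site. All scanners report every
# (possibly overlapping) window match in ascending start order; positions
# are 1-based.

#' Residue classes for the Tom20 motif scan
#'
#' phi is the hydrophobic class (note it includes A and Y: the canonical
#' motif instances end in alanine) and beta the basic class. The two sets
#' must be disjoint.
#'
#' @param phi Character vector of residues treated as hydrophobic.
#' @param beta Character vector of residues treated as basic.
#' @return An object of class `residue_classes`.
#' @export
residue_classes <- function(phi = c("A", "I", "L", "M", "F", "V", "W", "Y"),
                            beta = c("R", "K", "H")) {
  phi <- unique(toupper(phi)); beta <- unique(toupper(beta))
  if (length(intersect(phi, beta)) > 0L) {
    stop("phi and beta classes must be disjoint")
  }
  structure(list(phi = phi, beta = beta), class = "residue_classes")
}

match_df <- function(motif_name, starts, matched) {
  data.frame(motif_name = rep(motif_name, length(starts)),
             start = as.integer(starts), matched = matched,
             stringsAsFactors = FALSE)
}

slice_all <- function(seq, starts, width) {
  if (length(starts) == 0L) return(character(0))
  substring(as.character(seq), starts, starts + width - 1L)
}

#' Scan for the Tom20 recognition motif (phi-x-beta-phi-phi)
#'
#' Mitochondrial pre-sequences commonly carry a 5-residue hydrophobic motif
#' with consensus phi-x-beta-phi-phi (phi hydrophobic, x any residue, beta
#' basic) within a helical segment, which mediates binding to the Tom20
#' import receptor. Every matching 5-residue window is reported; overlaps
#' are not consumed.
#'
#' @param seq A `protein_sequence` or string of length >= 5.
#' @param classes A `residue_classes` object.
#' @return Data frame with columns `motif_name`, `start`, `matched`.
#' @examples
#' scan_tom20(pmob_signal_peptide()$sequence)  # LERMA at 4, VGKLL at 15
#' @export
scan_tom20 <- function(seq, classes = residue_classes()) {
  if (!inherits(seq, "protein_sequence")) seq <- protein_sequence(seq)
  stopifnot(inherits(classes, "residue_classes"))
  ch <- seq_chars(seq)
  L <- length(ch)
  if (L < 5L) stop("sequence shorter than the 5-residue motif")
  starts <- seq_len(L - 4L)
  hit <- ch[starts] %in% classes$phi &
    ch[starts + 2L] %in% classes$beta &
    ch[starts + 3L] %in% classes$phi &
    ch[starts + 4L] %in% classes$phi
  s <- starts[hit]
  match_df("tom20_phi_x_beta_phi_phi", s,
           slice_all(seq, s, 5L))
}

#' Scan for the twin-arginine (TAT) consensus motif
#'
#' The bacterial twin-arginine translocation pathway recognises the
#' consensus S/T-R-R-x-F-L-K where x is a polar residue. The polar set for
#' x defaults to the uncharged polar residues (S, T, N, Q, Y, C, G).
#'
#' @param seq A `protein_sequence` or string of length >= 7.
#' @param polar_x Residues admitted in the x slot.
#' @return Data frame with columns `motif_name`, `start`, `matched`.
#' @export
scan_tat <- function(seq, polar_x = c("S", "T", "N", "Q", "Y", "C", "G")) {
  if (!inherits(seq, "protein_sequence")) seq <- protein_sequence(seq)
  ch <- seq_chars(seq)
  L <- length(ch)
  if (L < 7L) stop("sequence shorter than the 7-residue motif")
  starts <- seq_len(L - 6L)
  hit <- ch[starts] %in% c("S", "T") &
    ch[starts + 1L] == "R" & ch[starts + 2L] == "R" &
    ch[starts + 3L] %in% toupper(polar_x) &
    ch[starts + 4L] == "F" & ch[starts + 5L] == "L" & ch[starts + 6L] == "K"
  s <- starts[hit]
  match_df("tat_twin_arginine", s, slice_all(seq, s, 7L))
}

#' Find AxA signal-peptidase cleavage motifs near the C-terminus
#'
#' Signal-peptidase cleavage follows an A-x-A triplet at the end of the
#' c-region. All A-x-A triplets whose final alanine lies within
#' `search_window` residues of the C-terminus are reported; the match ending
#' at the final residue is flagged as the canonical cleavage site.
#'
#' @param seq A `protein_sequence` or string of length >= 3.
#' @param search_window Number of C-terminal residues searched (default 6).
#' @return Data frame with columns `motif_name`, `start`, `matched`,
#'   `canonical` (logical; TRUE for the triplet ending at the last residue).
#' @export
find_cleavage_axa <- function(seq, search_window = 6L) {
  if (!inherits(seq, "protein_sequence")) seq <- protein_sequence(seq)
  ch <- seq_chars(seq)
  L <- length(ch)
  if (L < 3L) stop("sequence shorter than the 3-residue motif")
  starts <- seq_len(L - 2L)
  hit <- ch[starts] == "A" & ch[starts + 2L] == "A"
  ends <- starts + 2L
  hit <- hit & ends > L - search_window
  s <- starts[hit]
  out <- match_df("axa_cleavage", s, slice_all(seq, s, 3L))
  out$canonical <- (s + 2L) == L
  out
}
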