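# Bundled reference sequence: the PmoB signal-peptide CDS from
# Methylosinus trichosporium OB3b (GenBank U31650.2), 117 nt.

#' The PmoB signal-peptide coding sequence
#'
#' The 117-nt coding sequence of the PmoB signal peptide from
#' *Methylosinus trichosporium* OB3b (GenBank U31650.2), bundled as a FASTA
#' record under `inst/extdata/`.
#'
#' @return A `coding_sequence`.
#' @examples
#' translate_dna(pmob_cds())
#' @export
pmob_cds <- function() {
  path <- system.file("extdata", "pmob_sp_cds.fasta", package = "sptarget",
                      mustWork = TRUE)
  read_fasta(path, type = "dna")[[1]]
}

#' The annotated PmoB signal peptide
#'
#' Translates the bundled coding sequence and annotates the default
#' tripartite boundaries: n-region 1-14 (MKALERMAELATGR), h-region 15-33
#' (VGKLLGLSVAAAVAATAAS), c-region 34-39 (VAPAEA) ending at the AxA
#' signal-peptidase site. Boundaries are configurable because they are
#' inferred from sequence features (the VGKLL motif opens the h-region; the
#' AxA site closes the c-region), not measured.
#'
#' @param n_end,h_end Region boundaries (1-based inclusive last residue of
#'   the n- and h-regions).
#' @return A `signal_peptide`.
#' @examples
#' pmob_signal_peptide()
#' @export
pmob_signal_peptide <- function(n_end = 14L, h_end = 33L) {
  prot <- translate_dna(pmob_cds(), id = "PmoB_sp")
  annotate_regions(prot, region_boundaries(n_end, h_end))
}
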