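# Mutant-panel construction: edit application, panel defaults, reports.

test_that("substitutions validate against the native residue and apply in place", {
  sp <- pmob_signal_peptide()
  mut <- apply_edits(sp, mutant_spec("spS", substitutions = "M7S"))
  expect_equal(nchar(mut), 39L)
  expect_equal(substr(as.character(mut), 7, 7), "S")
  # everything else untouched
  expect_equal(substr(as.character(mut), 1, 6),
               substr(as.character(sp$sequence), 1, 6))
  expect_error(apply_edits(sp, mutant_spec("bad", substitutions = "K7S")),
               "does not match native residue")
  expect_error(apply_edits(sp, mutant_spec("bad", substitutions = "M99S")),
               "outside sequence")
})

test_that("an empty spec is the identity and deletions shorten by the span sum", {
  sp <- pmob_signal_peptide()
  same <- apply_edits(sp, mutant_spec("copy"))
  expect_equal(as.character(same), as.character(sp$sequence))
  dh <- apply_edits(sp, mutant_spec("spDH", deletions = list(c(15, 33))))
  expect_equal(nchar(dh), 20L)
  expect_equal(as.character(dh), "MKALERMAELATGRVAPAEA")
})

test_that("overlapping or malformed deletions are rejected", {
  expect_error(mutant_spec("x", deletions = list(c(5, 10), c(8, 12))),
               "overlapping")
  expect_error(mutant_spec("x", deletions = list(c(10, 5))), "invalid deletion")
  expect_error(mutant_spec("x", substitutions = "M7"), "malformed")
})

test_that("deleting then re-inserting the deleted substring restores the native", {
  sp <- pmob_signal_peptide()
  native <- as.character(sp$sequence)
  set.seed(23)
  for (i in 1:20) {
    a <- sample(1:35, 1); b <- min(39L, a + sample(0:6, 1))
    mut <- apply_edits(sp, mutant_spec("d", deletions = list(c(a, b))))
    restored <- paste0(substr(as.character(mut), 1, a - 1),
                       substr(native, a, b),
                       substr(as.character(mut), a, nchar(mut)))
    expect_equal(restored, native)
  }
})

test_that("the default panel matches its published definitions", {
  panel <- build_panel(pmob_signal_peptide())
  seqs <- lapply(panel$sequences, as.character)
  native <- as.character(panel$native$sequence)
  expect_setequal(names(seqs),
                  c("spS", "spDH", "spH", "spR", "spA", "spD1", "spD2",
                    "spD3", "spD4", "spDN", "spDN2", "spjustH"))
  # spA: both n-region glutamates to alanine
  expect_equal(substr(seqs$spA, 5, 5), "A")
  expect_equal(substr(seqs$spA, 9, 9), "A")
  # spR: glutamate at -2 (residue 38) to arginine
  expect_equal(substr(seqs$spR, 38, 38), "R")
  # spjustH is exactly the h-region
  expect_equal(seqs$spjustH, "VGKLLGLSVAAAVAATAAS")
  # spDN drops the n-region, spDN2 its first half
  expect_equal(seqs$spDN, substr(native, 15, 39))
  expect_equal(seqs$spDN2, substr(native, 8, 39))
  # the four serial deletions tile the h-region: lengths sum to 19
  del_total <- sum(39L - vapply(seqs[c("spD1", "spD2", "spD3", "spD4")],
                                nchar, 0L))
  expect_equal(del_total, 19L)
  # substitution-only mutants preserve length; all sequences re-validate
  for (nm in c("spS", "spH", "spR", "spA")) expect_equal(nchar(seqs[[nm]]), 39L)
  for (s in seqs) expect_s3_class(protein_sequence(s), "protein_sequence")
})

test_that("panel report recomputes features from each mutant sequence", {
  panel <- build_panel(pmob_signal_peptide())
  rep <- panel_report(panel)
  expect_equal(rep$name[1], "native")
  get <- function(nm, col) rep[rep$name == nm, col]
  # motif counts: M7S destroys LERMA; the h-deletion removes VGKLL
  expect_equal(get("native", "tom20_matches"), 2L)
  expect_equal(get("spS", "tom20_matches"), 1L)
  expect_equal(get("spDH", "tom20_matches"), 1L)
  # no cached native values leak: report equals independent recomputation
  for (nm in c("spS", "spDH", "spA")) {
    s <- as.character(panel$sequences[[nm]])
    expect_equal(get(nm, "net_charge"), net_charge(s))
    expect_equal(get(nm, "tom20_matches"), nrow(scan_tom20(s)))
    expect_equal(get(nm, "max_muH"),
                 max(sliding_profile(s, min(11L, nchar(s)))$muH))
  }
  # h-region mean hydrophobicity rises in spH and vanishes in spDH
  expect_true(is.na(get("spDH", "h_region_mean_H")))
  expect_gt(get("spH", "h_region_mean_H"), get("native", "h_region_mean_H"))
})

test_that("panel FASTA export round-trips all sequences", {
  panel <- build_panel(pmob_signal_peptide())
  tmp <- tempfile(fileext = ".fasta")
  write_panel_fasta(panel, tmp)
  back <- read_fasta(tmp, "protein")
  expect_equal(length(back), 13L)  # native + 12 mutants
  expect_equal(as.character(back[[1]]), as.character(panel$native$sequence))
})
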