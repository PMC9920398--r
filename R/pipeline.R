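# End-to-end orchestration: the full sequence-analysis report and the
# two-group imaging experiment, each written to an output directory with the
# resolved configuration and a log sufficient to re-run.

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Default configuration for the sequence-analysis workflow
#'
#' @param out_dir Output directory.
#' @return A named list understood by [run_sequence_analysis()]; fields
#'   mirror the tunables of the underlying modules (region boundaries,
#'   scale, window size, motif classes, panel overrides).
#' @export
sequence_config <- function(out_dir = tempfile("seq_analysis_")) {
  list(
    input_fasta = NULL,           # NULL: bundled PmoB CDS
    input_type = "dna",           # "dna" or "protein"
    n_end = 14L, h_end = 33L,
    scale = "fauchere_pliska",
    window_size = 11L,
    delta = 100,
    panel_config = NULL,          # NULL: default_panel_config()
    out_dir = out_dir
  )
}

#' Run the full sequence-analysis workflow
#'
#' Translates the input (if DNA), annotates tripartite regions, computes the
#' sliding hydrophobicity/hydrophobic-moment profile and helical-wheel
#' coordinates, runs all three motif scans, builds the mutant panel and its
#' feature report, and writes everything (CSV/JSON/FASTA plus a log and the
#' resolved config) to `config$out_dir`.
#'
#' @param config List from [sequence_config()] (fields may be overridden).
#' @return Invisibly, a list with the in-memory results: `signal_peptide`,
#'   `profile`, `wheel`, `motifs`, `panel`, `report`, `out_dir`.
#' @export
run_sequence_analysis <- function(config = sequence_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))

  if (is.null(config$input_fasta)) {
    cds <- pmob_cds()
    log_line(logf, "input: bundled PmoB signal-peptide CDS (",
             nchar(cds), " nt)")
    prot <- translate_dna(cds)
  } else if (config$input_type == "dna") {
    cds <- read_fasta(config$input_fasta, "dna")[[1]]
    log_line(logf, "input: ", config$input_fasta, " (DNA, ", nchar(cds), " nt)")
    prot <- translate_dna(cds)
  } else {
    prot <- read_fasta(config$input_fasta, "protein")[[1]]
    log_line(logf, "input: ", config$input_fasta, " (protein, skipping translation)")
  }
  log_line(logf, "protein: ", as.character(prot), " (", nchar(prot), " aa)")

  sp <- annotate_regions(prot, region_boundaries(config$n_end, config$h_end))
  write_fasta(prot, file.path(config$out_dir, "protein.fasta"))

  prof <- sliding_profile(prot, config$window_size, config$scale, config$delta)
  write_profile_csv(prof, file.path(config$out_dir, "profile.csv"))
  log_line(logf, "profile: ", nrow(prof), " windows of ", config$window_size,
           "; max muH = ", sprintf("%.3f", max(prof$muH)),
           " at window start ", prof$start[which.max(prof$muH)])

  wheel_len <- min(config$window_size, nchar(prot))
  wheel <- helical_wheel(substr(as.character(prot), 1, wheel_len), config$delta)
  jsonlite::write_json(wheel, file.path(config$out_dir, "wheel.json"),
                       dataframe = "rows", digits = NA)

  motifs <- rbind(
    scan_tom20(prot),
    scan_tat(prot),
    find_cleavage_axa(prot)[, c("motif_name", "start", "matched")])
  write.csv(motifs, file.path(config$out_dir, "motifs.csv"), row.names = FALSE)
  log_line(logf, "motifs: ", nrow(scan_tom20(prot)), " tom20, ",
           nrow(scan_tat(prot)), " tat, ",
           nrow(find_cleavage_axa(prot)), " axa")
  log_line(logf, "n-region net charge: ",
           net_charge(prot, c(1L, config$n_end)))

  panel <- build_panel(sp, config$panel_config)
  report <- panel_report(panel, config$window_size, config$scale)
  write_panel_fasta(panel, file.path(config$out_dir, "panel.fasta"))
  write.csv(report, file.path(config$out_dir, "panel_report.csv"),
            row.names = FALSE)
  log_line(logf, "panel: ", length(panel$sequences), " mutants reported")

  cfg <- config
  cfg$panel_config <- NULL   # specs are not trivially serializable
  jsonlite::write_json(cfg, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(signal_peptide = sp, profile = prof, wheel = wheel,
                 motifs = motifs, panel = panel, report = report,
                 out_dir = config$out_dir))
}

#' Default configuration for the imaging workflow
#'
#' The defaults emulate the acquisition design of the two-construct
#' comparison: 60 cells per group from 3 batches, 1024x1024 8-bit fields.
#' `spec_b` defaults to a brighter-mitochondria variant of `spec_a`.
#'
#' @param out_dir Output directory.
#' @param image_size Field edge length; smaller values give fast smoke runs.
#' @return A named list understood by [run_imaging_experiment()].
#' @export
imaging_config <- function(out_dir = tempfile("imaging_"), image_size = 1024L) {
  list(
    spec_a = field_spec(image_size = image_size),
    spec_b = field_spec(image_size = image_size, mito_intensity = 220,
                        er_intensity = 4),
    cells_per_group = 60L,
    batches = 3L,
    batch_sd = 0.08,
    seed = 1L,
    write_images = FALSE,
    out_dir = out_dir
  )
}

#' Run the two-group imaging experiment
#'
#' Simulates the two groups of synthetic fields, measures every cell
#' (Yen-threshold segmentation, intensity ratio, area fraction) and compares
#' the groups with the Mann-Whitney U test on both metrics. Writes the
#' per-cell CSV, the comparison JSON, the resolved config and a log to
#' `config$out_dir`; optionally the TIFF images themselves.
#'
#' @param config List from [imaging_config()] (fields may be overridden).
#' @return Invisibly, a list with `experiment`, `cells` (per-cell data
#'   frame), `comparison_ratio`, `comparison_area`, `out_dir`.
#' @export
run_imaging_experiment <- function(config = imaging_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))

  log_line(logf, "simulating ", config$cells_per_group, " cells/group in ",
           config$batches, " batches (seed ", config$seed, ")")
  expt <- generate_experiment(config$spec_a, config$spec_b,
                              config$cells_per_group, config$batches,
                              config$batch_sd, config$seed)
  if (isTRUE(config$write_images)) {
    write_experiment(expt, file.path(config$out_dir, "images"))
    log_line(logf, "images written to ", file.path(config$out_dir, "images"))
  }
  cells <- measure_experiment(expt)
  write.csv(cells, file.path(config$out_dir, "cells.csv"), row.names = FALSE)

  a <- cells[cells$group == "A", ]; b <- cells[cells$group == "B", ]
  cmp_ratio <- compare_groups(a, b, "intensity_ratio")
  cmp_area <- compare_groups(a, b, "mito_area_fraction")
  log_line(logf, sprintf(
    "intensity_ratio: A %.3f +/- %.3f vs B %.3f +/- %.3f, p = %.3g",
    cmp_ratio$group_a$mean, cmp_ratio$group_a$sd,
    cmp_ratio$group_b$mean, cmp_ratio$group_b$sd, cmp_ratio$p_value))
  log_line(logf, sprintf("mito_area_fraction: p = %.3g", cmp_area$p_value))

  jsonlite::write_json(
    list(intensity_ratio = unclass(cmp_ratio),
         mito_area_fraction = unclass(cmp_area)),
    file.path(config$out_dir, "comparison.json"), auto_unbox = TRUE,
    digits = NA)
  cfg <- config
  cfg$spec_a <- unclass(cfg$spec_a); cfg$spec_b <- unclass(cfg$spec_b)
  jsonlite::write_json(cfg, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(experiment = expt, cells = cells,
                 comparison_ratio = cmp_ratio, comparison_area = cmp_area,
                 out_dir = config$out_dir))
}
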