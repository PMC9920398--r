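# Programmatic construction of the signal-peptide mutant panel and
# per-mutant feature reports. Edits are expressed in the native 1-based
# coordinate frame; substitutions are validated against the native residue
# and applied before deletions.

#' Specify a mutant as a named edit list
#'
#' Substitutions use the compact `"M7S"` notation (native residue, 1-based
#' position, replacement). Deletions are `c(start, end)` spans in the native
#' coordinate frame and must not overlap.
#'
#' @param name Mutant name.
#' @param substitutions Character vector like `c("E5A", "E9A")`, or an empty
#'   vector.
#' @param deletions A list of `c(start, end)` integer spans.
#' @return An object of class `mutant_spec`.
#' @examples
#' mutant_spec("spS", substitutions = "M7S")
#' mutant_spec("spDH", deletions = list(c(15, 33)))
#' @export
mutant_spec <- function(name, substitutions = character(), deletions = list()) {
  subs <- parse_substitutions(substitutions)
  dels <- parse_deletions(deletions)
  structure(list(name = name, substitutions = subs, deletions = dels),
            class = "mutant_spec")
}

parse_substitutions <- function(x) {
  if (is.data.frame(x)) return(x)
  if (length(x) == 0L) {
    return(data.frame(position = integer(), from = character(),
                      to = character(), stringsAsFactors = FALSE))
  }
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", toupper(x)))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("malformed substitution(s): ", paste(x[bad], collapse = ", "))
  data.frame(position = as.integer(vapply(m, `[`, "", 3L)),
             from = vapply(m, `[`, "", 2L),
             to = vapply(m, `[`, "", 4L), stringsAsFactors = FALSE)
}

parse_deletions <- function(x) {
  if (length(x) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  d <- data.frame(start = vapply(x, function(s) as.integer(s[1]), 0L),
                  end = vapply(x, function(s) as.integer(s[2]), 0L))
  if (any(d$start < 1L | d$end < d$start)) stop("invalid deletion span")
  d <- d[order(d$start), , drop = FALSE]
  if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)])) {
    stop("overlapping deletions")
  }
  d
}

#' @export
print.mutant_spec <- function(x, ...) {
  subs <- if (nrow(x$substitutions)) {
    paste(sprintf("%s%d%s", x$substitutions$from, x$substitutions$position,
                  x$substitutions$to), collapse = ",")
  } else "-"
  dels <- if (nrow(x$deletions)) {
    paste(sprintf("del%d-%d", x$deletions$start, x$deletions$end), collapse = ",")
  } else "-"
  cat(sprintf("<mutant_spec> %s  subs: %s  dels: %s\n", x$name, subs, dels))
  invisible(x)
}

#' Apply a mutant specification to a native sequence
#'
#' Substitutions are applied first (each validated against the native
#' residue at its position), then deletions. The result carries an attribute
#' `native_positions` mapping each retained residue back to its native
#' 1-based coordinate.
#'
#' @param native A `signal_peptide`, `protein_sequence` or string.
#' @param spec A `mutant_spec`.
#' @return A `protein_sequence` named after the mutant.
#' @export
apply_edits <- function(native, spec) {
  if (inherits(native, "signal_peptide")) native <- native$sequence
  if (!inherits(native, "protein_sequence")) native <- protein_sequence(native)
  stopifnot(inherits(spec, "mutant_spec"))
  ch <- seq_chars(native)
  L <- length(ch)
  s <- spec$substitutions
  if (nrow(s) > 0L) {
    if (any(s$position < 1L | s$position > L)) {
      stop("substitution position outside sequence")
    }
    mismatch <- ch[s$position] != s$from
    if (any(mismatch)) {
      i <- which(mismatch)[1]
      stop("substitution ", s$from[i], s$position[i], s$to[i],
           " does not match native residue ", ch[s$position[i]],
           " at position ", s$position[i])
    }
    ch[s$position] <- s$to
  }
  keep <- rep(TRUE, L)
  d <- spec$deletions
  if (nrow(d) > 0L) {
    if (any(d$end > L)) stop("deletion span outside sequence")
    for (i in seq_len(nrow(d))) keep[d$start[i]:d$end[i]] <- FALSE
  }
  if (!any(keep)) stop("edits delete the entire sequence")
  out <- protein_sequence(paste(ch[keep], collapse = ""), id = spec$name)
  attr(out, "native_positions") <- which(keep)
  out
}

#' Default panel configuration for the PmoB signal peptide
#'
#' Edit lists for the standard mutant panel, defined against the native
#' 39-residue peptide with n-region 1-14 and h-region 15-33:
#' \describe{
#'   \item{spS}{M7S — disrupts the first Tom20 motif (LERMA).}
#'   \item{spH}{S22I + S33I — raises h-region hydrophobicity.}
#'   \item{spDH}{deletion of the h-region (15-33).}
#'   \item{spR}{E38R — arginine at position -2 of the cleavage site.}
#'   \item{spA}{E5A + E9A — removes the two n-region glutamates.}
#'   \item{spD1..spD4}{serial deletions tiling the h-region
#'     (15-19, 20-24, 25-29, 30-33).}
#'   \item{spDN}{deletion of the full n-region (1-14).}
#'   \item{spDN2}{deletion of the first half of the n-region (1-7).}
#'   \item{spjustH}{h-region only (deletes 1-14 and 34-39).}
#' }
#' The spH sites and the spD1-4/spDN2 spans are figure-inferred defaults and
#' may be overridden.
#'
#' @param boundaries `region_boundaries` used to derive region-dependent
#'   spans.
#' @param seq_length Native sequence length.
#' @return Named list of `mutant_spec` objects.
#' @export
default_panel_config <- function(boundaries = region_boundaries(14L, 33L),
                                 seq_length = 39L) {
  h0 <- boundaries$n_end + 1L; h1 <- boundaries$h_end
  tiles <- tile_spans(h0, h1, 4L)
  specs <- list(
    mutant_spec("spS", substitutions = "M7S"),
    mutant_spec("spDH", deletions = list(c(h0, h1))),
    mutant_spec("spH", substitutions = c("S22I", "S33I")),
    mutant_spec("spR", substitutions = "E38R"),
    mutant_spec("spA", substitutions = c("E5A", "E9A")),
    mutant_spec("spD1", deletions = list(tiles[[1]])),
    mutant_spec("spD2", deletions = list(tiles[[2]])),
    mutant_spec("spD3", deletions = list(tiles[[3]])),
    mutant_spec("spD4", deletions = list(tiles[[4]])),
    mutant_spec("spDN", deletions = list(c(1L, boundaries$n_end))),
    mutant_spec("spDN2", deletions = list(c(1L, boundaries$n_end %/% 2L))),
    mutant_spec("spjustH",
                deletions = list(c(1L, boundaries$n_end), c(h1 + 1L, seq_length)))
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

# Split [from, to] into k near-equal consecutive spans.
tile_spans <- function(from, to, k) {
  cuts <- round(seq(from - 1L, to, length.out = k + 1L))
  lapply(seq_len(k), function(i) c(as.integer(cuts[i] + 1L), as.integer(cuts[i + 1L])))
}

#' Build the mutant panel
#'
#' Applies every edit list in `config` to the native signal peptide.
#'
#' @param native A `signal_peptide` (the panel definitions assume the
#'   39-residue PmoB peptide unless a custom config is given).
#' @param config Named list of `mutant_spec`s; defaults to
#'   [default_panel_config()] derived from the native boundaries.
#' @return An object of class `mutant_panel`: a list with the native
#'   peptide, the specs, and the mutant sequences.
#' @examples
#' panel <- build_panel(pmob_signal_peptide())
#' names(panel$sequences)
#' @export
build_panel <- function(native, config = NULL) {
  stopifnot(inherits(native, "signal_peptide"))
  if (is.null(config)) {
    config <- default_panel_config(native$regions, nchar(native$sequence))
  }
  seqs <- lapply(config, function(sp) apply_edits(native, sp))
  names(seqs) <- names(config)
  structure(list(native = native, specs = config, sequences = seqs),
            class = "mutant_panel")
}

#' @export
print.mutant_panel <- function(x, ...) {
  cat(sprintf("<mutant_panel> native %d aa + %d mutants\n",
              nchar(x$native$sequence), length(x$sequences)))
  for (nm in names(x$sequences)) {
    cat(sprintf("  %-8s %s\n", nm, as.character(x$sequences[[nm]])))
  }
  invisible(x)
}

#' Per-mutant feature report
#'
#' Recomputes sequence features for the native peptide and every mutant:
#' length, net charge (side chains plus N-terminal amine), Tom20 motif
#' count, maximum windowed hydrophobic moment, and mean hydrophobicity of
#' the surviving h-region residues (NA when the h-region is fully deleted).
#' All values are recomputed from the mutant sequence itself.
#'
#' @param panel A `mutant_panel`.
#' @param window_size Window for the muH profile (shrunk to the sequence
#'   length for short mutants).
#' @param scale Hydrophobicity scale.
#' @return A data frame, one row per sequence (native first).
#' @export
panel_report <- function(panel, window_size = 11L, scale = "fauchere_pliska") {
  stopifnot(inherits(panel, "mutant_panel"))
  native <- panel$native
  h_span <- region_spans(native)$h
  h_idx <- h_span[1]:h_span[2]
  all_seqs <- c(list(native = native$sequence), panel$sequences)
  rows <- lapply(names(all_seqs), function(nm) {
    s <- all_seqs[[nm]]
    L <- nchar(s)
    w <- min(window_size, L)
    prof <- if (w >= 2L) sliding_profile(s, w, scale) else NULL
    np <- attr(s, "native_positions")
    if (is.null(np)) np <- seq_len(L)
    h_keep <- which(np %in% h_idx)
    h_mean <- if (length(h_keep) > 0L) {
      mean_hydrophobicity(substr(as.character(s), min(h_keep), max(h_keep)), scale)
    } else NA_real_
    data.frame(
      name = nm,
      sequence = as.character(s),
      length = L,
      net_charge = net_charge(s),
      tom20_matches = nrow(scan_tom20(s)),
      max_muH = if (is.null(prof)) NA_real_ else max(prof$muH),
      h_region_mean_H = h_mean,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a mutant panel as multi-record FASTA
#'
#' @param panel A `mutant_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "mutant_panel"))
  write_fasta(c(list(panel$native$sequence), unname(panel$sequences)), path)
}
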