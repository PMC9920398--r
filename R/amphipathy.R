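# Windowed hydrophobicity / Eisenberg hydrophobic-moment profiling and
# helical-wheel geometry.

# Fauchère & Pliska (1983) octanol/water scale as used by HeliQuest.
FAUCHERE_PLISKA <- c(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
  Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
  L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
  S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22
)

# Kyte & Doolittle (1982) hydropathy index.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Retrieve or construct a hydrophobicity scale
#'
#' Bundled scales: `"fauchere_pliska"` (the HeliQuest default, dimensionless
#' octanol/water free-energy values) and `"kyte_doolittle"`. A custom scale
#' may be supplied as a named numeric vector covering all 20 canonical
#' residues.
#'
#' @param scale Scale name, or a named numeric vector.
#' @return An object of class `hydrophobicity_scale`: a named numeric vector
#'   with a `name` attribute.
#' @export
hydrophobicity_scale <- function(scale = "fauchere_pliska") {
  if (inherits(scale, "hydrophobicity_scale")) return(scale)
  if (is.character(scale)) {
    values <- switch(match.arg(scale, c("fauchere_pliska", "kyte_doolittle")),
                     fauchere_pliska = FAUCHERE_PLISKA,
                     kyte_doolittle = KYTE_DOOLITTLE)
    nm <- scale
  } else {
    values <- scale
    nm <- "custom"
  }
  missing <- setdiff(AA_CANONICAL, names(values))
  if (length(missing) > 0L) {
    stop("scale missing residues: ", paste(missing, collapse = ", "))
  }
  structure(as.numeric(values[AA_CANONICAL]), names = AA_CANONICAL,
            name = nm, class = "hydrophobicity_scale")
}

scale_lookup <- function(chars, scale) {
  h <- unclass(scale)[chars]
  if (anyNA(h)) {
    stop("residue(s) missing from scale: ",
         paste(unique(chars[is.na(h)]), collapse = ", "))
  }
  unname(h)
}

#' Eisenberg hydrophobic moment
#'
#' The hydrophobic moment muH measures the amphipathicity of a helix: each
#' residue's hydrophobicity is placed as a vector at `delta` degrees per
#' residue around the helical axis, and muH is the magnitude of the vector
#' sum divided by the number of residues,
#' \deqn{\mu_H = \frac{1}{N}\left\|\sum_{n=0}^{N-1} H_n
#'   (\cos \delta n, \sin \delta n)\right\|.}
#' The value is invariant to a global rotation of the angular origin.
#'
#' @param seq A `protein_sequence` or string.
#' @param scale A hydrophobicity scale (see [hydrophobicity_scale()]).
#' @param delta Angular step in degrees per residue; 100 for an ideal
#'   alpha-helix (default).
#' @return Non-negative dimensionless value.
#' @examples
#' hydrophobic_moment("MKALERMAELA")  # ~0.52, a strong amphipathic helix
#' @export
hydrophobic_moment <- function(seq, scale = "fauchere_pliska", delta = 100) {
  if (!inherits(seq, "protein_sequence")) seq <- protein_sequence(seq)
  scale <- hydrophobicity_scale(scale)
  ch <- seq_chars(seq)
  h <- scale_lookup(ch, scale)
  ang <- (seq_along(h) - 1) * delta * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
}

#' Mean hydrophobicity
#'
#' Arithmetic mean of per-residue scale values over the sequence.
#'
#' @inheritParams hydrophobic_moment
#' @return Dimensionless value.
#' @export
mean_hydrophobicity <- function(seq, scale = "fauchere_pliska") {
  if (!inherits(seq, "protein_sequence")) seq <- protein_sequence(seq)
  scale <- hydrophobicity_scale(scale)
  mean(scale_lookup(seq_chars(seq), scale))
}

#' Sliding-window hydrophobicity / hydrophobic-moment profile
#'
#' Computes mean hydrophobicity and hydrophobic moment for every window of
#' `window_size` residues along the sequence (the profiling used to locate
#' amphipathic stretches: an 11-residue window matches one length of
#' alpha-helix turns typically predicted at signal-peptide N-termini).
#'
#' @inheritParams hydrophobic_moment
#' @param window_size Window length in residues (>= 2, <= sequence length).
#' @return A data frame of class `window_profile` with columns `start`,
#'   `end` (1-based inclusive), `window_sequence`, `mean_H`, `muH`; one row
#'   per window start (L - window_size + 1 rows).
#' @examples
#' sp <- pmob_signal_peptide()
#' prof <- sliding_profile(sp$sequence, window_size = 11)
#' prof[which.max(prof$muH), ]
#' @export
sliding_profile <- function(seq, window_size = 11L, scale = "fauchere_pliska",
                            delta = 100) {
  if (!inherits(seq, "protein_sequence")) seq <- protein_sequence(seq)
  window_size <- as.integer(window_size)
  L <- nchar(seq)
  if (window_size < 2L) stop("window_size must be >= 2")
  if (window_size > L) stop("window_size (", window_size,
                            ") exceeds sequence length (", L, ")")
  scale <- hydrophobicity_scale(scale)
  starts <- seq_len(L - window_size + 1L)
  wins <- substring(as.character(seq), starts, starts + window_size - 1L)
  out <- data.frame(
    start = starts,
    end = starts + window_size - 1L,
    window_sequence = wins,
    mean_H = vapply(wins, function(w) mean_hydrophobicity(w, scale), 0),
    muH = vapply(wins, function(w) hydrophobic_moment(w, scale, delta), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "window_size") <- window_size
  attr(out, "scale") <- attr(scale, "name")
  attr(out, "delta") <- delta
  class(out) <- c("window_profile", "data.frame")
  out
}

# Physicochemical class used for wheel colouring.
residue_class <- function(ch) {
  cls <- rep("apolar", length(ch))
  cls[ch %in% c("K", "R", "H")] <- "basic"
  cls[ch %in% c("D", "E")] <- "acidic"
  cls[ch %in% c("S", "T", "N", "Q", "C", "Y", "G")] <- "polar"
  cls
}

#' Helical-wheel projection coordinates
#'
#' Places residue p at angle `(p - 1) * delta` modulo 360 on the unit
#' circle, the axial projection of an ideal helix. Angles increase
#' counterclockwise with residue 1 at the top of the wheel; only the angular
#' spacing matters for amphipathicity.
#'
#' @inheritParams hydrophobic_moment
#' @return A data frame with columns `residue`, `position`, `angle`
#'   (degrees in [0, 360)), `x`, `y` (unit-circle coordinates) and `class`
#'   (basic/acidic/polar/apolar).
#' @export
helical_wheel <- function(seq, delta = 100) {
  if (!inherits(seq, "protein_sequence")) seq <- protein_sequence(seq)
  ch <- seq_chars(seq)
  ang <- ((seq_along(ch) - 1) * delta) %% 360
  rad <- ang * pi / 180
  data.frame(
    residue = ch,
    position = seq_along(ch),
    angle = ang,
    x = cos(rad),
    y = sin(rad),
    class = residue_class(ch),
    stringsAsFactors = FALSE
  )
}

#' Plot a helical wheel
#'
#' Base-graphics rendering of [helical_wheel()]: residues on the unit
#' circle coloured by physicochemical class, with the hydrophobic-moment
#' direction drawn as an arrow from the centre.
#'
#' @inheritParams hydrophobic_moment
#' @param ... Passed to [graphics::plot()].
#' @return The wheel data frame, invisibly.
#' @export
plot_helical_wheel <- function(seq, scale = "fauchere_pliska", delta = 100, ...) {
  wheel <- helical_wheel(seq, delta)
  if (!inherits(seq, "protein_sequence")) seq <- protein_sequence(seq)
  sc <- hydrophobicity_scale(scale)
  h <- scale_lookup(wheel$residue, sc)
  rad <- wheel$angle * pi / 180
  mx <- sum(h * cos(rad)); my <- sum(h * sin(rad))
  mnorm <- sqrt(mx^2 + my^2)
  cols <- c(basic = "#2166ac", acidic = "#b2182b",
            polar = "#66c2a5", apolar = "#878787")
  graphics::plot(wheel$x, wheel$y, asp = 1, xlim = c(-1.3, 1.3),
                 ylim = c(-1.3, 1.3), pch = 21, cex = 3,
                 bg = cols[wheel$class], xlab = "", ylab = "", axes = FALSE, ...)
  graphics::text(wheel$x, wheel$y, wheel$residue, cex = 0.8)
  graphics::text(wheel$x * 1.2, wheel$y * 1.2, wheel$position, cex = 0.6)
  if (mnorm > 0) {
    graphics::arrows(0, 0, 0.8 * mx / mnorm, 0.8 * my / mnorm, length = 0.1)
  }
  graphics::title(sub = sprintf("muH = %.3f", mnorm / nrow(wheel)))
  invisible(wheel)
}

#' Export a window profile as CSV
#'
#' @param profile A `window_profile` from [sliding_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "window_profile"))
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
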