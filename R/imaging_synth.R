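# Synthetic two-channel confocal-like field generator with ground truth.
#
# The reporter channel (GFP-like) contains mitochondrial puncta, an optional
# faint reticulate ER component and diffuse cytosol inside a cell region;
# the stain channel (rhodamine-like mitochondrial dye) contains the same
# puncta only. Pixels are 8-bit; a seed fully determines the output.

#' Specify a synthetic confocal field
#'
#' Intensities are on the 8-bit scale (clipped to [0, 255] after noise).
#' Mitochondria are rendered as compact puncta with a Gaussian point-spread
#' edge (a filled disc convolved with the PSF, sigma 0.5 px, matching
#' diffraction-limited confocal sampling at roughly 130 nm per pixel); the
#' ground-truth mask is the union of discs of the drawn radii. The ER is a
#' thin random-walk mesh present in the reporter channel only; the cytosol
#' is a uniform base level inside the cell.
#'
#' @param image_size Field edge length in pixels (square field; default 1024).
#' @param n_mitochondria Number of puncta.
#' @param mito_radius Mean punctum radius in pixels.
#' @param mito_radius_sd SD of the per-punctum radius.
#' @param mito_intensity Mean punctum peak intensity in the reporter channel.
#' @param mito_intensity_sd SD of per-punctum peak intensity.
#' @param er_intensity Added intensity of the ER mesh (0 disables the ER).
#' @param cytosol_intensity Uniform base intensity inside the cell.
#' @param stain_intensity Mean punctum peak intensity in the stain channel.
#' @param psf_sigma SD (px) of the Gaussian point-spread edge of each
#'   punctum; 0 renders hard-edged discs (the noiseless-construction limit).
#' @param noise_sd SD of additive Gaussian read noise.
#' @param poisson Apply Poisson shot noise before the Gaussian noise.
#' @param cell_radius_frac Mean cell radius as a fraction of the field edge.
#' @param seed Integer seed; identical seeds give bit-identical fields.
#' @return An object of class `field_spec` (a named list).
#' @export
field_spec <- function(image_size = 1024L,
                       n_mitochondria = 40L,
                       mito_radius = 4,
                       mito_radius_sd = 0.8,
                       mito_intensity = 180,
                       mito_intensity_sd = 15,
                       er_intensity = 12,
                       cytosol_intensity = 20,
                       stain_intensity = 160,
                       psf_sigma = 0.5,
                       noise_sd = 4,
                       poisson = FALSE,
                       cell_radius_frac = 0.38,
                       seed = NULL) {
  spec <- list(image_size = as.integer(image_size), bit_depth = 8L,
               n_mitochondria = as.integer(n_mitochondria),
               mito_radius = mito_radius, mito_radius_sd = mito_radius_sd,
               mito_intensity = mito_intensity,
               mito_intensity_sd = mito_intensity_sd,
               er_intensity = er_intensity,
               cytosol_intensity = cytosol_intensity,
               stain_intensity = stain_intensity,
               psf_sigma = psf_sigma,
               noise_sd = noise_sd, poisson = isTRUE(poisson),
               cell_radius_frac = cell_radius_frac, seed = seed)
  stopifnot(spec$image_size >= 32L, spec$n_mitochondria >= 0L,
            spec$mito_radius > 0, spec$noise_sd >= 0, spec$psf_sigma >= 0,
            spec$cell_radius_frac > 0, spec$cell_radius_frac < 0.5)
  for (f in c("mito_intensity", "er_intensity", "cytosol_intensity",
              "stain_intensity")) {
    if (spec[[f]] < 0 || spec[[f]] > 255) stop(f, " outside [0, 255]")
  }
  structure(spec, class = "field_spec")
}

# Smooth star-shaped cell boundary: R(theta) = r0 * (1 + sum a_k cos(k theta
# + phi_k)). Returns a logical mask; vectorized over all pixels.
make_cell_mask <- function(size, radius_frac) {
  cx <- (size + 1) / 2; cy <- (size + 1) / 2
  r0 <- radius_frac * size
  k <- 2:5
  amp <- runif(length(k), 0, 0.06)
  ph <- runif(length(k), 0, 2 * pi)
  x <- matrix(rep(seq_len(size), each = size), size) - cx
  y <- matrix(rep(seq_len(size), times = size), size) - cy
  d <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  rb <- r0 * (1 + Reduce(`+`, lapply(seq_along(k),
                                     function(i) amp[i] * cos(k[i] * th + ph[i]))))
  d <= rb
}

# Add one punctum into img (in place via return); disc of `radius` into
# mask. The radial profile is a filled disc convolved with a Gaussian PSF
# (flat plateau, Gaussian edge rolloff of `edge_sigma` px), the profile a
# small stained organelle presents in a confocal section; the plateau keeps
# the thresholded geometry fixed when only brightness changes.
render_punctum <- function(img, mask, cx, cy, radius, peak, edge_sigma = 0.5) {
  size <- nrow(img)
  ext <- ceiling(radius + 3 * edge_sigma + 1)
  xs <- max(1L, cx - ext):min(size, cx + ext)
  ys <- max(1L, cy - ext):min(size, cy + ext)
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  d <- sqrt(dx^2 + dy^2)
  prof <- if (edge_sigma > 0) peak * pnorm((radius - d) / edge_sigma)
          else peak * (d <= radius)
  img[xs, ys] <- img[xs, ys] + prof
  mask[xs, ys] <- mask[xs, ys] | (d <= radius)
  list(img = img, mask = mask)
}

# Persistent 1-px random walks seeded inside the cell; emulates a faint
# reticulate ER network.
render_er <- function(size, cell_mask, intensity, n_walks, n_steps) {
  er <- matrix(0, size, size)
  inside <- which(cell_mask)
  if (length(inside) == 0L || intensity <= 0 || n_walks == 0L) {
    return(list(img = er, mask = matrix(FALSE, size, size)))
  }
  for (w in seq_len(n_walks)) {
    p <- inside[sample.int(length(inside), 1L)]
    x <- ((p - 1L) %% size) + 1L
    y <- ((p - 1L) %/% size) + 1L
    th <- runif(1, 0, 2 * pi)
    for (s in seq_len(n_steps)) {
      th <- th + rnorm(1, 0, 0.45)
      x <- x + cos(th); y <- y + sin(th)
      xi <- round(x); yi <- round(y)
      if (xi < 1 || xi > size || yi < 1 || yi > size || !cell_mask[xi, yi]) {
        th <- th + pi  # bounce back into the cell
        x <- x + 2 * cos(th); y <- y + 2 * sin(th)
        next
      }
      er[xi, yi] <- intensity
    }
  }
  list(img = er, mask = er > 0)
}

#' Generate one synthetic two-channel field
#'
#' Renders, in order: the cell mask, mitochondrial puncta (both channels),
#' the ER mesh (reporter only), the uniform cytosol base, then optional
#' Poisson shot noise and additive Gaussian noise, and finally clips and
#' quantises to 8-bit.
#'
#' @param spec A `field_spec`.
#' @return An object of class `synthetic_field`: integer matrices
#'   `reporter` and `stain`, logical masks `cell_mask`, `mito_mask`,
#'   `er_mask`, and the generating `spec`.
#' @examples
#' f <- generate_field(field_spec(image_size = 128, n_mitochondria = 6, seed = 1))
#' mean(f$reporter[f$mito_mask]) > mean(f$reporter[f$cell_mask])
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  size <- spec$image_size
  cell <- make_cell_mask(size, spec$cell_radius_frac)
  if (sum(cell) < 16L) stop("degenerate cell region")

  reporter <- matrix(0, size, size)
  stain <- matrix(0, size, size)
  mito_mask <- matrix(FALSE, size, size)

  # place puncta inside a slightly eroded cell so discs stay inside
  inside <- which(cell)
  if (spec$n_mitochondria > 0L) {
    for (i in seq_len(spec$n_mitochondria)) {
      repeat {
        p <- inside[sample.int(length(inside), 1L)]
        cx <- ((p - 1L) %% size) + 1L
        cy <- ((p - 1L) %/% size) + 1L
        r <- max(1, rnorm(1, spec$mito_radius, spec$mito_radius_sd))
        # keep the disc inside the cell: check 4 cardinal points
        rr <- ceiling(r)
        ok <- cx - rr >= 1 && cx + rr <= size && cy - rr >= 1 && cy + rr <= size &&
          cell[cx - rr, cy] && cell[cx + rr, cy] && cell[cx, cy - rr] && cell[cx, cy + rr]
        if (ok) break
      }
      peak <- max(0, rnorm(1, spec$mito_intensity, spec$mito_intensity_sd))
      res <- render_punctum(reporter, mito_mask, cx, cy, r, peak, spec$psf_sigma)
      reporter <- res$img; mito_mask <- res$mask
      peak_s <- max(0, rnorm(1, spec$stain_intensity, spec$mito_intensity_sd))
      stain <- render_punctum(stain, mito_mask, cx, cy, r, peak_s, spec$psf_sigma)$img
    }
  }

  area <- sum(cell)
  er <- render_er(size, cell, spec$er_intensity,
                  n_walks = if (spec$er_intensity > 0) max(1L, area %/% 20000L) else 0L,
                  n_steps = 400L)
  reporter <- reporter + er$img
  reporter[cell] <- reporter[cell] + spec$cytosol_intensity

  add_noise <- function(img) {
    if (spec$poisson) img <- matrix(rpois(length(img), lambda = pmax(img, 0)),
                                    nrow(img))
    if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
    matrix(as.integer(pmin(255, pmax(0, round(img)))), nrow(img))
  }
  structure(list(reporter = add_noise(reporter), stain = add_noise(stain),
                 cell_mask = cell, mito_mask = mito_mask & cell,
                 er_mask = er$mask, spec = spec),
            class = "synthetic_field")
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf(
    "<synthetic_field> %dx%d 8-bit, %d puncta, cell area %d px (%.1f%%)\n",
    x$spec$image_size, x$spec$image_size, x$spec$n_mitochondria,
    sum(x$cell_mask), 100 * mean(x$cell_mask)))
  invisible(x)
}

#' Generate a labelled two-group imaging experiment
#'
#' Emulates the acquisition design of a two-construct comparison: `cells_per_group`
#' independent cells per group, collected in `batches` batches (e.g. plants)
#' that carry a shared multiplicative brightness offset, drawn once per
#' batch as `exp(rnorm(1, 0, batch_sd))` and applied to the mitochondrial,
#' ER and cytosol intensity means of every cell in the batch.
#'
#' Cell-to-cell variation in mitochondrial content is emulated by drawing
#' each cell's punctum count from a Poisson distribution around the spec's
#' `n_mitochondria` (floored at 1); disable with `vary_count = FALSE` for
#' geometrically identical cells.
#'
#' @param spec_a,spec_b `field_spec`s for groups A and B (their `seed` is
#'   ignored; per-cell seeds derive from `seed`).
#' @param cells_per_group Cells per group (default 60).
#' @param batches Number of batches (default 3); cells are split across
#'   batches as evenly as possible.
#' @param batch_sd SD of the log-normal batch brightness factor.
#' @param seed Master seed for the experiment.
#' @param vary_count Draw per-cell punctum counts from a Poisson
#'   distribution (default TRUE).
#' @return An object of class `synthetic_experiment`: a list with `fields`
#'   (list of `synthetic_field`s) and `manifest` (data frame with columns
#'   `cell_id`, `group`, `batch`, `seed`, `batch_factor`).
#' @export
generate_experiment <- function(spec_a, spec_b, cells_per_group = 60L,
                                batches = 3L, batch_sd = 0.08, seed = 1L,
                                vary_count = TRUE) {
  stopifnot(inherits(spec_a, "field_spec"), inherits(spec_b, "field_spec"),
            cells_per_group >= 1L, batches >= 1L)
  set.seed(seed)
  n <- 2L * cells_per_group
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n)
  batch_of <- rep(rep_len(seq_len(batches), cells_per_group), 2L)
  batch_factor <- exp(rnorm(batches, 0, batch_sd))
  group <- rep(c("A", "B"), each = cells_per_group)
  counts <- ifelse(group == "A", spec_a$n_mitochondria, spec_b$n_mitochondria)
  if (isTRUE(vary_count)) counts <- pmax(1L, rpois(n, counts))
  fields <- vector("list", n)
  for (i in seq_len(n)) {
    base <- if (group[i] == "A") spec_a else spec_b
    f <- batch_factor[batch_of[i]]
    sp <- base
    sp$n_mitochondria <- as.integer(counts[i])
    sp$mito_intensity <- min(255, base$mito_intensity * f)
    sp$stain_intensity <- min(255, base$stain_intensity * f)
    sp$er_intensity <- min(255, base$er_intensity * f)
    sp$cytosol_intensity <- min(255, base$cytosol_intensity * f)
    sp$seed <- cell_seeds[i]
    fields[[i]] <- generate_field(sp)
  }
  manifest <- data.frame(
    cell_id = sprintf("%s_%02d", group, rep(seq_len(cells_per_group), 2L)),
    group = group, batch = batch_of, seed = cell_seeds,
    batch_factor = batch_factor[batch_of], stringsAsFactors = FALSE)
  structure(list(fields = fields, manifest = manifest,
                 spec_a = spec_a, spec_b = spec_b, seed = seed),
            class = "synthetic_experiment")
}

#' Write a synthetic experiment to disk
#'
#' One 8-bit TIFF per channel per cell plus mask TIFFs, a JSON manifest with
#' the generating specs and seeds, and a CSV ground-truth table.
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame augmented with file paths, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- experiment$manifest
  paths <- lapply(seq_len(nrow(man)), function(i) {
    f <- experiment$fields[[i]]
    id <- man$cell_id[i]
    p <- list(reporter = file.path(dir, paste0(id, "_reporter.tif")),
              stain = file.path(dir, paste0(id, "_stain.tif")),
              cell_mask = file.path(dir, paste0(id, "_cellmask.tif")))
    tiff::writeTIFF(f$reporter / 255, p$reporter, bits.per.sample = 8L)
    tiff::writeTIFF(f$stain / 255, p$stain, bits.per.sample = 8L)
    tiff::writeTIFF(f$cell_mask * 1, p$cell_mask, bits.per.sample = 8L)
    p
  })
  man$reporter_path <- vapply(paths, `[[`, "", "reporter")
  man$stain_path <- vapply(paths, `[[`, "", "stain")
  man$cell_mask_path <- vapply(paths, `[[`, "", "cell_mask")
  truth <- cbind(man, data.frame(
    true_mito_area = vapply(experiment$fields, function(f) sum(f$mito_mask), 0L),
    cell_area = vapply(experiment$fields, function(f) sum(f$cell_mask), 0L)))
  write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = experiment$seed, spec_a = unclass(experiment$spec_a),
         spec_b = unclass(experiment$spec_b), cells = man),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    null = "null")
  invisible(man)
}

#' Read an 8-bit single-channel TIFF as an integer matrix
#'
#' @param path TIFF path.
#' @return Integer matrix with values in 0..255.
#' @export
read_channel_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img))
}
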