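# Targeting-efficiency quantification: Yen-threshold segmentation of bright
# mitochondrial puncta within a cell mask, per-cell intensity ratio and area
# fraction, and a two-group Mann-Whitney comparison.

#' Yen's maximum-correlation threshold on 8-bit pixel values
#'
#' Selects the level t in 0..254 maximising Yen's maximum-correlation
#' criterion on the 256-bin histogram,
#' \deqn{C(t) = 2\,\ln\!\big(P_1(t)\,(1 - P_1(t))\big) -
#'   \ln\!\big(\textstyle\sum_{i \le t} p_i^2 \cdot \sum_{i > t} p_i^2\big),}
#' where \eqn{p_i} are histogram probabilities and \eqn{P_1(t)} the
#' cumulative mass up to t. Levels with an empty class (either squared sum
#' zero) are skipped; ties break toward the lowest maximising level.
#' Foreground is defined as pixels strictly above the returned level.
#'
#' @param pixels Integer (or numeric) vector of 8-bit intensities in 0..255,
#'   e.g. the within-mask pixels of one cell.
#' @return The threshold level, an integer in 0..254.
#' @examples
#' yen_threshold(c(rep(10, 50), rep(200, 50)))
#' @export
yen_threshold <- function(pixels) {
  pixels <- as.integer(round(pixels))
  if (length(pixels) == 0L) stop("no pixels supplied")
  if (any(pixels < 0L | pixels > 255L)) stop("pixel values outside 0..255")
  if (length(unique(pixels)) < 2L) {
    stop("degenerate histogram: fewer than 2 distinct intensity values")
  }
  counts <- tabulate(pixels + 1L, nbins = 256L)
  p <- counts / sum(counts)
  P1 <- cumsum(p)
  S1 <- cumsum(p^2)             # sum of squared probs up to t
  S2 <- sum(p^2) - S1           # strictly above t
  t <- 0:254
  valid <- S1[t + 1L] > 0 & S2[t + 1L] > 0
  crit <- rep(-Inf, 255L)
  tv <- t[valid] + 1L
  crit[valid] <- 2 * log(P1[tv] * (1 - P1[tv])) - log(S1[tv] * S2[tv])
  if (!any(is.finite(crit))) stop("degenerate histogram: criterion undefined")
  as.integer(which.max(crit) - 1L)   # which.max takes the first (lowest) max
}

#' Measure one cell: total intensity, Yen segmentation, ratio, area fraction
#'
#' Reproduces the per-cell quantification used for organelle-targeting
#' efficiency: the mean reporter intensity over the whole cell mask is the
#' total fluorescence; the Yen threshold computed from the within-mask
#' pixels segments the bright mitochondrial puncta; the targeting-efficiency
#' ratio is the mean intensity of the segmented pixels divided by the total
#' mean; the area fraction is segmented pixels over cell pixels. Because the
#' threshold cuts the upper tail, the ratio is >= 1 whenever any pixel is
#' segmented. No background subtraction is performed.
#'
#' @param reporter Integer matrix (8-bit reporter channel).
#' @param cell_mask Logical matrix delimiting the cell (same dimensions).
#' @param cell_id Optional identifier copied into the result.
#' @return A one-row data frame of class `cell_measurement` with columns
#'   `cell_id`, `total_mean_intensity`, `yen_threshold`,
#'   `mito_mean_intensity`, `intensity_ratio`, `mito_area_fraction`.
#' @export
measure_cell <- function(reporter, cell_mask, cell_id = "cell") {
  stopifnot(is.matrix(reporter), is.logical(cell_mask),
            all(dim(reporter) == dim(cell_mask)))
  if (!any(cell_mask)) stop("empty cell mask")
  px <- as.numeric(reporter[cell_mask])
  total_mean <- mean(px)
  thr <- yen_threshold(px)
  fg <- px[px > thr]
  mito_mean <- if (length(fg) > 0L) mean(fg) else NA_real_
  out <- data.frame(
    cell_id = cell_id,
    total_mean_intensity = total_mean,
    yen_threshold = thr,
    mito_mean_intensity = mito_mean,
    intensity_ratio = mito_mean / total_mean,
    mito_area_fraction = length(fg) / length(px),
    stringsAsFactors = FALSE)
  class(out) <- c("cell_measurement", "data.frame")
  out
}

#' Measure every cell of a synthetic experiment
#'
#' @param experiment A `synthetic_experiment` from [generate_experiment()].
#' @return Data frame: the experiment manifest joined with one
#'   [measure_cell()] row per cell.
#' @export
measure_experiment <- function(experiment) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  rows <- lapply(seq_along(experiment$fields), function(i) {
    f <- experiment$fields[[i]]
    m <- measure_cell(f$reporter, f$cell_mask,
                      cell_id = experiment$manifest$cell_id[i])
    cbind(experiment$manifest[i, c("group", "batch")], m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed by midrank summation. When `n1 + n2 <= 12` and there are no
#' ties, the two-sided p-value is exact, by enumeration of all rank
#' assignments; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param method `"auto"` (exact when feasible, default), `"exact"`
#'   (enumeration; requires `n1 + n2 <= 12` and no ties) or `"normal"`.
#' @return A list of class `mann_whitney` with elements `U` (for the first
#'   sample), `p_value`, `n1`, `n2` and `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) > 0L, length(y) > 0L)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  all <- c(x, y)
  r <- rank(all)                       # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(all) > 0L
  use_exact <- switch(method,
    auto = N <= 12L && !has_ties,
    exact = if (N > 12L || has_ties) {
      stop("exact method requires n1 + n2 <= 12 and no ties")
    } else TRUE,
    normal = FALSE)
  if (use_exact) {
    # exact: U distribution over all choose(N, n1) assignments of ranks to x
    sets <- combn(N, n1)
    ranks <- seq_len(N)
    us <- colSums(matrix(ranks[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(all)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- abs(U - mu) - 0.5            # continuity correction
      p <- min(1, 2 * pnorm(-max(d, 0) / sqrt(sigma2)))
    }
    method <- "normal approximation (tie- and continuity-corrected)"
  }
  structure(list(U = U, p_value = p, n1 = n1, n2 = n2, method = method),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), two-sided p = %.4g\n  [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Compare a per-cell metric between two groups
#'
#' Summarises the chosen metric per group (mean, SD, n) and tests the
#' difference with the two-sided Mann-Whitney U test. Only one comparison is
#' made, so no multiplicity correction is applied.
#'
#' @param measurements_a,measurements_b Data frames of per-cell
#'   measurements (as from [measure_cell()] rows or [measure_experiment()]
#'   subsets).
#' @param metric `"intensity_ratio"` or `"mito_area_fraction"`.
#' @return A list of class `group_comparison`.
#' @export
compare_groups <- function(measurements_a, measurements_b,
                           metric = c("intensity_ratio", "mito_area_fraction")) {
  metric <- match.arg(metric)
  a <- measurements_a[[metric]]; b <- measurements_b[[metric]]
  stopifnot(!is.null(a), !is.null(b))
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  mw <- mann_whitney(a, b)
  structure(list(
    metric = metric,
    group_a = list(mean = mean(a), sd = sd(a), n = length(a)),
    group_b = list(mean = mean(b), sd = sd(b), n = length(b)),
    U = mw$U, p_value = mw$p_value, method = mw$method),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-group comparison of %s\n", x$metric))
  cat(sprintf("  group A: %.4f +/- %.4f (n = %d)\n",
              x$group_a$mean, x$group_a$sd, x$group_a$n))
  cat(sprintf("  group B: %.4f +/- %.4f (n = %d)\n",
              x$group_b$mean, x$group_b$sd, x$group_b$n))
  cat(sprintf("  Mann-Whitney U = %.1f, two-sided p = %.4g\n", x$U, x$p_value))
  invisible(x)
}
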