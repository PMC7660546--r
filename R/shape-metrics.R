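#' Segment cells from a grayscale field image
#'
#' Reproduces a standard smear-quantification chain: Gaussian blur, rolling
#' ball background subtraction (implemented as grayscale opening with a disc
#' of the given radius on the inverted image), contrast normalisation,
#' histogram thresholding by the minimum method (smooth the 256-bin histogram
#' until exactly two modes remain, cut at the valley), then morphological
#' opening, closing and hole filling. Cells are assumed darker than the
#' background. A binary input (only two distinct values) is returned
#' unchanged when `binary_passthrough` is `TRUE`.
#'
#' @param image Numeric matrix in `[0, 1]`, a single-channel image.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param rolling_radius Radius (px) of the background disc; objects larger
#'   than this are attenuated by the subtraction, as with a rolling ball.
#' @param threshold_method Only `"minimum"` is implemented.
#' @param binary_passthrough Return binary inputs untouched.
#' @return Binary integer matrix (0 background, 1 foreground).
#' @export
segment_mask <- function(image, blur_sigma = 1, rolling_radius = 7,
                         threshold_method = "minimum",
                         binary_passthrough = TRUE) {
  stopifnot(is.matrix(image), threshold_method == "minimum")
  vals <- unique(as.vector(image))
  if (binary_passthrough && length(vals) <= 2)
    return(matrix(as.integer(image == max(vals)), nrow(image)))
  img <- EBImage::gblur(image, sigma = blur_sigma)
  inv <- max(img) - img  # objects become bright
  brush <- EBImage::makeBrush(2 * rolling_radius + 1, shape = "disc")
  bg <- EBImage::opening(inv, brush)
  sub <- pmax(inv - bg, 0)
  rng <- range(sub)
  if (diff(rng) == 0)
    stop("flat image after background subtraction; no valley to threshold")
  norm <- (sub - rng[1]) / diff(rng)
  thr <- minimum_threshold(norm)
  mask <- norm > thr
  small <- EBImage::makeBrush(3, shape = "disc")
  mask <- EBImage::closing(EBImage::opening(mask, small), small)
  mask <- EBImage::fillHull(mask)
  matrix(as.integer(mask > 0), nrow(image))
}

# Minimum-method histogram threshold: iteratively smooth the 256-bin
# histogram with a length-3 mean filter until it is bimodal, return the
# (scaled) position of the minimum between the two modes.
minimum_threshold <- function(x, bins = 256, max_iter = 10000) {
  h <- tabulate(pmin(floor(as.vector(x) * bins) + 1L, bins), bins)
  h <- as.numeric(h)
  n_modes <- function(h) {
    interior <- which(diff(sign(diff(h))) < 0) + 1L
    length(interior)
  }
  it <- 0
  while (n_modes(h) > 2 && it < max_iter) {
    h <- stats::filter(h, rep(1 / 3, 3), sides = 2)
    h[is.na(h)] <- 0
    it <- it + 1
  }
  if (n_modes(h) < 2)
    stop("histogram is unimodal; the minimum method finds no valley ",
         "(consider a manual threshold)")
  peaks <- which(diff(sign(diff(h))) < 0) + 1L
  valley_range <- peaks[1]:peaks[2]
  valley <- valley_range[which.min(h[valley_range])]
  (valley - 0.5) / bins
}

#' Measure particle shapes from a binary mask
#'
#' Labels connected components (8-connectivity), drops particles touching the
#' 1-px image border, and reports for each remaining particle its area,
#' perimeter, circularity `C = 4 * pi * Area / Perimeter^2` and solidity
#' (area / convex-hull area). The perimeter uses a Crofton-style 4-direction
#' intercept estimator (`P = pi/8 * (n0 + n90 + (n45 + n135) / sqrt(2))`),
#' which is unbiased for smooth convex shapes where naive pixel-edge counting
#' is not. Area and perimeter are reported in microns via `pixel_size`.
#'
#' @param mask Binary matrix (0/1).
#' @param pixel_size Microns per pixel (> 0).
#' @return Data frame: `particle_id`, `area` (um^2), `perimeter` (um),
#'   `circularity`, `solidity`, `touches_border` is already excluded.
#' @export
measure_particles <- function(mask, pixel_size) {
  stopifnot(pixel_size > 0, all(mask %in% c(0, 1)))
  labels <- label_components8(mask)
  n <- max(labels)
  if (n == 0)
    return(data.frame(particle_id = integer(0), area = numeric(0),
                      perimeter = numeric(0), circularity = numeric(0),
                      solidity = numeric(0)))
  border_ids <- unique(c(labels[1, ], labels[nrow(labels), ],
                         labels[, 1], labels[, ncol(labels)]))
  rows <- list()
  for (id in seq_len(n)) {
    if (id %in% border_ids) next
    px <- which(labels == id, arr.ind = TRUE)
    sub <- matrix(0L, diff(range(px[, 1])) + 3, diff(range(px[, 2])) + 3)
    sub[cbind(px[, 1] - min(px[, 1]) + 2, px[, 2] - min(px[, 2]) + 2)] <- 1L
    per_px <- crofton_perimeter(sub)
    area <- nrow(px) * pixel_size^2
    per <- per_px * pixel_size
    hull <- hull_area(px) * pixel_size^2
    rows[[length(rows) + 1L]] <- data.frame(
      particle_id = id, area = area, perimeter = per,
      circularity = 4 * pi * area / per^2,
      solidity = min(area / hull, 1))
  }
  if (!length(rows))
    return(data.frame(particle_id = integer(0), area = numeric(0),
                      perimeter = numeric(0), circularity = numeric(0),
                      solidity = numeric(0)))
  do.call(rbind, rows)
}

# 8-connected labelling: EBImage::bwlabel (4-connected) then union of labels
# that touch diagonally.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (shift in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(nr - 1), if (shift[2] == 1) seq_len(nc - 1) else 2:nc]
    b <- lab[2:nr, if (shift[2] == 1) 2:nc else seq_len(nc - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    for (k in touch) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Crofton 4-direction perimeter from intercept counts on a 0-padded mask.
crofton_perimeter <- function(m) {
  n0 <- sum(abs(m[, -1] - m[, -ncol(m)])) + sum(m[, 1]) + sum(m[, ncol(m)])
  n90 <- sum(abs(m[-1, ] - m[-nrow(m), ])) + sum(m[1, ]) + sum(m[nrow(m), ])
  d1 <- sum(abs(m[-nrow(m), -ncol(m)] - m[-1, -1]))
  d2 <- sum(abs(m[-nrow(m), -1] - m[-1, -ncol(m)]))
  (pi / 8) * (n0 + n90 + (d1 + d2) / sqrt(2))
}

# Convex hull area over pixel corners (shoelace), so convex particles have
# solidity <= 1 despite discretisation.
hull_area <- function(px) {
  corners <- rbind(px + matrix(c(-0.5, -0.5), nrow(px), 2, byrow = TRUE),
                   px + matrix(c(-0.5, 0.5), nrow(px), 2, byrow = TRUE),
                   px + matrix(c(0.5, -0.5), nrow(px), 2, byrow = TRUE),
                   px + matrix(c(0.5, 0.5), nrow(px), 2, byrow = TRUE))
  h <- grDevices::chull(corners)
  pts <- corners[h, , drop = FALSE]
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Filter particles by area, circularity and solidity
#'
#' Applies the standard artifact filters for cell-shape quantification:
#' particles are retained when area lies in `area_range` (70-150 um^2 by
#' default), circularity is at least `min_circularity` (0.80) and solidity at
#' least `min_solidity` (0.93).
#'
#' @param measurements Data frame from [measure_particles()].
#' @param area_range Length-2 numeric, inclusive um^2 bounds.
#' @param min_circularity,min_solidity Inclusive lower bounds.
#' @return The measurements with a logical `retained` column and an attribute
#'   `removal_counts` (named integer vector per rule).
#' @export
filter_particles <- function(measurements, area_range = c(70, 150),
                             min_circularity = 0.80, min_solidity = 0.93) {
  stopifnot(length(area_range) == 2, area_range[1] < area_range[2],
            all(is.finite(c(area_range, min_circularity, min_solidity))))
  area_ok <- measurements$area >= area_range[1] &
    measurements$area <= area_range[2]
  circ_ok <- measurements$circularity >= min_circularity
  sol_ok <- measurements$solidity >= min_solidity
  measurements$retained <- area_ok & circ_ok & sol_ok
  attr(measurements, "removal_counts") <-
    c(area = sum(!area_ok), circularity = sum(!circ_ok),
      solidity = sum(!sol_ok))
  measurements
}

#' Compare circularity between two groups of cells
#'
#' Two-sample rank-based (Mann-Whitney/Wilcoxon rank-sum) test on the
#' circularity of retained particles from two samples.
#'
#' @param group_a,group_b Numeric vectors of circularities, or
#'   [filter_particles()] outputs (retained rows are used).
#' @return List with `statistic` (W), `p_value`, `n_a`, `n_b`,
#'   `median_a`, `median_b`.
#' @export
compare_circularity <- function(group_a, group_b) {
  get_c <- function(g) {
    if (is.data.frame(g)) {
      if ("retained" %in% names(g)) g <- g[g$retained, , drop = FALSE]
      g <- g$circularity
    }
    g
  }
  a <- get_c(group_a); b <- get_c(group_b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b),
       median_a = stats::median(a), median_b = stats::median(b))
}
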