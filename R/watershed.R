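# Coarse segmentation stage: Sobel gradient topography, automatic marker
# extraction, priority-flood watershed, mass-region selection.
# Marker label convention: 0 = unmarked, 1 = background, 2..K = foreground.

#' Sobel gradient magnitude
#'
#' Horizontal and vertical 3x3 Sobel responses combined as the Euclidean
#' magnitude, with edge-replicated borders. This is the topographic
#' surface the watershed floods: ridges of high gradient become region
#' boundaries.
#'
#' @param image numeric matrix.
#' @return numeric matrix of non-negative gradient magnitudes.
#' @export
gradient_magnitude <- function(image) {
  .validate_gray(image)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- .filter_replicate(image, kx)
  gy <- .filter_replicate(image, t(kx))
  g <- sqrt(gx^2 + gy^2)
  g[g < 0] <- 0
  g
}

.disc <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# EBImage grayscale morphology expects intensities in [0,1]; rescale
# around it (min filtering commutes with positive affine maps)
.erode_gray <- function(image, radius) {
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)
  x <- (image - lo) / (hi - lo)
  as.matrix(EBImage::erode(x, .disc(radius))) * (hi - lo) + lo
}

# opening / closing by reconstruction: flatten clutter smaller than the
# disc while restoring the exact shape of larger structures
.open_by_reconstruction <- function(image, radius) {
  er <- pmin(.erode_gray(image, radius), image)
  cpp_reconstruct_dilate(er, image)
}

.close_by_reconstruction <- function(image, radius) {
  top <- max(image)
  top - .open_by_reconstruction(top - image, radius)
}

#' Regional maxima
#'
#' Connected plateaus strictly higher than all their 8-neighbours, found
#' by h-maxima reconstruction with `h = 1` intensity level.
#'
#' @param image numeric matrix.
#' @return logical matrix marking maxima pixels.
#' @export
regional_maxima <- function(image) {
  .validate_gray(image)
  rec <- cpp_reconstruct_dilate(image - 1, image)
  (image - rec) > 1e-9
}

#' Extract watershed markers automatically
#'
#' Produces the marker map that controls watershed flooding, with no user
#' interaction. Foreground (candidate-mass) markers are the 8-connected
#' regional maxima of the image after opening-by-reconstruction then
#' closing-by-reconstruction with a disc of radius `disk_radius` (which
#' flattens texture clutter smaller than the disc), eroded by a disc of
#' radius `erosion_radius` and filtered to components of at least
#' `min_area` pixels. The background marker is every pixel darker than
#' the global Otsu threshold lying at city-block distance at least
#' `bg_distance` from all foreground components.
#'
#' Fallbacks for degenerate inputs (both emit a message): if no foreground
#' component survives, the 8-connected maxima component containing the
#' brightest pixel is used (a single pixel on a constant image); if the
#' background marker comes out empty, the one-pixel border frame (minus
#' the foreground neighbourhood) is used.
#'
#' @param image denoised numeric matrix (0-255 scale).
#' @param disk_radius structuring-element radius in px for reconstruction
#'   filtering; default 10, about a quarter of a typical mass radius.
#' @param erosion_radius marker-shrinking radius in px; default 2.
#' @param min_area minimum foreground component area in px; default 20.
#' @param bg_distance city-block clearance in px between background marker
#'   and any foreground component; default 15.
#' @return integer matrix: 0 unmarked, 1 background, 2..K foreground
#'   components.
#' @export
extract_markers <- function(image, disk_radius = 10L, erosion_radius = 2L,
                            min_area = 20L, bg_distance = 15L) {
  .validate_gray(image)
  filt <- .close_by_reconstruction(.open_by_reconstruction(image, disk_radius),
                                   disk_radius)
  rmax <- regional_maxima(filt)
  if (all(rmax)) rmax[] <- FALSE   # flat image: no informative maxima
  fg <- rmax
  if (erosion_radius >= 1L && any(fg))
    fg <- as.matrix(EBImage::erode(fg + 0, .disc(erosion_radius))) > 0.5
  lab <- cpp_label8(matrix(as.integer(fg), nrow(fg), ncol(fg)))
  if (max(lab) > 0L) {
    area <- tabulate(lab[lab > 0L])
    keep <- which(area >= min_area)
    lab[!(lab %in% keep)] <- 0L
  }
  if (max(lab) == 0L) {
    message("extract_markers: no foreground marker survived filtering; ",
            "falling back to the brightest pixel's component")
    bright <- which(filt == max(filt), arr.ind = TRUE)[1L, , drop = TRUE]
    comp <- cpp_label8(matrix(as.integer(rmax), nrow(rmax), ncol(rmax)))
    if (comp[bright[1L], bright[2L]] > 0L) {
      lab <- matrix(0L, nrow(image), ncol(image))
      lab[comp == comp[bright[1L], bright[2L]]] <- 1L
    } else {
      lab <- matrix(0L, nrow(image), ncol(image))
      lab[bright[1L], bright[2L]] <- 1L
    }
  }
  # renumber foreground components 2..K in discovery order
  ids <- sort(unique(lab[lab > 0L]))
  markers <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(ids)) markers[lab == ids[i]] <- i + 1L

  # background: below-Otsu pixels clear of every foreground component
  rng <- range(image)
  bg <- if (rng[1] < rng[2]) {
    norm <- (image - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    image < rng[1] + thr * (rng[2] - rng[1])
  } else matrix(FALSE, nrow(image), ncol(image))
  dist_fg <- .cityblock_distance(markers > 0L)
  bg <- bg & dist_fg >= bg_distance
  if (!any(bg)) {
    message("extract_markers: empty background marker; ",
            "falling back to the image border frame")
    bg <- matrix(FALSE, nrow(image), ncol(image))
    bg[c(1L, nrow(image)), ] <- TRUE
    bg[, c(1L, ncol(image))] <- TRUE
    relaxed <- bg & dist_fg >= bg_distance
    if (any(relaxed)) bg <- relaxed else bg <- bg & markers == 0L
    if (!any(bg))
      stop("cannot place a background marker disjoint from the foreground",
           call. = FALSE)
  }
  markers[bg] <- 1L
  markers
}

.cityblock_distance <- function(fg) {
  if (!any(fg)) return(matrix(Inf, nrow(fg), ncol(fg)))
  if (all(fg)) return(matrix(0, nrow(fg), ncol(fg)))
  d <- EBImage::distmap((!fg) + 0, metric = "manhattan")
  as.matrix(d)
}

#' Marker-controlled watershed by priority flooding
#'
#' Floods the gradient topography from the marker pixels: markers are
#' enqueued at their own gradient height (row-major order); pixels pop in
#' order of (height, insertion sequence) and claim their unlabelled
#' 8-neighbours, which are enqueued at the maximum of their own height and
#' the popped height. Every pixel ends up with the label of exactly one
#' marker; region boundaries are the label transitions (no one-pixel dam
#' label is produced). The FIFO tie-break makes reruns bit-identical.
#'
#' @param gradient non-negative numeric matrix (topographic surface).
#' @param markers integer matrix, 0 = unmarked, >0 = marker labels.
#' @return integer matrix of the same shape: the catchment label of every
#'   pixel.
#' @export
marker_watershed <- function(gradient, markers) {
  .validate_gray(gradient, "gradient")
  if (!is.matrix(markers) || !identical(dim(markers), dim(gradient)))
    stop("markers must be a matrix with the same shape as gradient",
         call. = FALSE)
  if (any(gradient < 0)) stop("gradient must be non-negative", call. = FALSE)
  m <- matrix(as.integer(markers), nrow(markers), ncol(markers))
  if (all(m == 0L)) stop("marker map has no nonzero marker", call. = FALSE)
  cpp_marker_watershed(gradient, m)
}

#' Count the catchment basins of the uncontrolled watershed
#'
#' The number of regions a plain (marker-free) watershed of the Sobel
#' gradient would produce: one catchment basin per 8-connected regional
#' minimum of the gradient surface. This is the over-segmentation measure
#' that noise reduction is meant to shrink and that marker control then
#' eliminates; on a noisy image it runs into the thousands.
#'
#' @param image numeric intensity matrix (typically after denoising).
#' @return integer basin count.
#' @export
watershed_region_count <- function(image) {
  g <- gradient_magnitude(image)
  mn <- regional_maxima(max(g) - g)
  max(cpp_label8(matrix(as.integer(mn), nrow(g), ncol(g))))
}

#' Select the mass region among watershed catchments
#'
#' Among regions grown from foreground markers (labels >= 2), returns the
#' one with the highest mean intensity in the original image; ties are
#' broken by larger area, then smaller label.
#'
#' @param labels integer matrix from [marker_watershed()].
#' @param markers the marker map the labels were grown from.
#' @param image the original (pre-denoising) intensity matrix.
#' @return 0/1 integer mask of the selected region.
#' @export
select_mass_region <- function(labels, markers, image) {
  .validate_gray(image)
  fg_labels <- sort(unique(markers[markers >= 2L]))
  fg_labels <- fg_labels[fg_labels %in% labels]
  if (length(fg_labels) == 0L)
    stop("no foreground-labelled region: marker extraction failed upstream",
         call. = FALSE)
  stats <- vapply(fg_labels, function(l) {
    px <- labels == l
    c(mean(image[px]), sum(px))
  }, numeric(2))
  ord <- order(-stats[1L, ], -stats[2L, ], fg_labels)
  best <- fg_labels[ord[1L]]
  matrix(as.integer(labels == best), nrow(labels), ncol(labels))
}
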