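# Synthetic mammogram-ROI phantoms with known ground truth: a bright,
# soft-edged mass over a textured noisy background, emulating ill-defined
# boundaries overlapping fibro-glandular tissue. Deterministic per seed.

#' Specify a synthetic mass phantom
#'
#' @param height,width image size in px.
#' @param center mass centre `(row, col)`; default the image centre.
#' @param radius mass radius in px.
#' @param contrast intensity lift of the mass over the background
#'   (0-255 scale).
#' @param softness boundary fall-off width in px (sigmoid scale); larger
#'   values model more ill-defined mass boundaries.
#' @param background_level base background intensity.
#' @param texture_sigma amplitude (intensity sd) of the low-frequency
#'   background texture field modelling fibro-glandular clutter.
#' @param noise_sigma per-pixel Gaussian noise sd.
#' @param seed mandatory RNG seed; identical specs give bit-identical
#'   phantoms.
#' @return list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(height = 256L, width = 256L,
                         center = c(height / 2, width / 2),
                         radius = 40, contrast = 80, softness = 6,
                         background_level = 100, texture_sigma = 10,
                         noise_sigma = 15, seed) {
  if (missing(seed) || !is.finite(seed))
    stop("seed is mandatory", call. = FALSE)
  if (height < 1L || width < 1L) stop("empty image", call. = FALSE)
  if (radius + softness >= min(height, width) / 2)
    stop("radius + softness must be < min(height, width)/2 ",
         "so the mass fits the frame", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 center = as.numeric(center), radius = radius,
                 contrast = contrast, softness = softness,
                 background_level = background_level,
                 texture_sigma = texture_sigma, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom image and its ground-truth mask
#'
#' The image is
#' `clip_[0,255](background + texture(seed) + contrast * sigmoid((radius -
#' d)/softness) + noise(seed))` where `d` is the Euclidean distance to the
#' mass centre. The texture field is seeded white noise smoothed with a
#' wide Gaussian (sd 16 px) and rescaled to amplitude `texture_sigma` —
#' a minimal model of fibro-glandular clutter, enough to provoke watershed
#' over-segmentation when the image is not denoised. The ground-truth mask
#' is the exact disc `d <= radius`, so it never depends on the noise level.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (numeric matrix, 0-255), `mask` (0/1 integer
#'   matrix) and `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 1))
#' dim(ph$image)
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("need a phantom_spec",
                                            call. = FALSE)
  h <- spec$height; w <- spec$width
  d <- sqrt(outer((seq_len(h) - spec$center[1])^2,
                  (seq_len(w) - spec$center[2])^2, `+`))
  mask <- matrix(as.integer(d <= spec$radius), h, w)

  mass <- if (spec$softness > 0)
    spec$contrast / (1 + exp(-(spec$radius - d) / spec$softness))
  else
    spec$contrast * (d <= spec$radius)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed",
                                               envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  texture <- 0
  if (spec$texture_sigma > 0) {
    white <- matrix(rnorm(h * w), h, w)
    # circular convolution keeps the field stationary to the borders;
    # kernel truncated to fit small frames
    r <- min(ceiling(4 * 16), (min(h, w) - 1L) %/% 2L)
    x <- seq(-r, r)
    k <- outer(exp(-x^2 / (2 * 16^2)), exp(-x^2 / (2 * 16^2)))
    smooth <- EBImage::filter2(white, k / sum(k), boundary = "circular")
    s <- sd(as.vector(smooth))
    if (s > 0) texture <- as.matrix(smooth) / s * spec$texture_sigma
  } else {
    rnorm(h * w)  # keep the noise draw aligned across texture settings
  }
  noise <- if (spec$noise_sigma > 0) matrix(rnorm(h * w, sd = spec$noise_sigma),
                                            h, w) else 0

  img <- spec$background_level + texture + mass + noise
  img <- pmin(pmax(img, 0), 255)
  list(image = img, mask = mask, spec = spec)
}

#' The standard phantom fixture suite
#'
#' Twenty 256 x 256 phantoms (seeds 0-19) with radius 40 px, contrast 80,
#' softness 6 px, background 100, texture amplitude 10 and noise sd 15 —
#' the package's reference test-bed standing in for a mammographic ROI
#' collection.
#'
#' @param n number of phantoms (seeds `0:(n-1)`); default 20.
#' @param noise_sigma,texture_sigma,softness overrides for noiseless or
#'   harder variants of the suite.
#' @return list of [phantom_spec()] objects.
#' @export
standard_phantom_suite <- function(n = 20L, noise_sigma = 15,
                                   texture_sigma = 10, softness = 6) {
  lapply(seq_len(n) - 1L, function(s)
    phantom_spec(height = 256L, width = 256L, radius = 40, contrast = 80,
                 softness = softness, background_level = 100,
                 texture_sigma = texture_sigma, noise_sigma = noise_sigma,
                 seed = s))
}
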