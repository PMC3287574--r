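# Noise reduction filters compared for over-segmentation control.
# All filters take and return float matrices; quantization back to 8-bit
# happens only at I/O.

#' Arithmetic mean (average) filter
#'
#' Replaces each pixel by the mean of its `size` x `size` neighbourhood,
#' with edge-replicated borders.
#'
#' @param image numeric matrix.
#' @param size odd window side length; default 5.
#' @return filtered numeric matrix, same shape.
#' @family denoising filters
#' @export
mean_filter <- function(image, size = 5L) {
  .validate_gray(image)
  size <- as.integer(size)
  if (is.na(size) || size < 1L || size %% 2L == 0L)
    stop("size must be an odd integer >= 1", call. = FALSE)
  if (size == 1L) return(image)
  k <- matrix(1 / size^2, size, size)
  .filter_replicate(image, k)
}

#' Gaussian filter
#'
#' Convolution with a normalized isotropic Gaussian kernel truncated at
#' 4 sigma, edge-replicated borders.
#'
#' @param image numeric matrix.
#' @param sigma kernel standard deviation in pixels; default 2.
#' @return filtered numeric matrix, same shape.
#' @family denoising filters
#' @export
gaussian_filter <- function(image, sigma = 2) {
  .validate_gray(image)
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  k <- gaussian_kernel(sigma)
  .filter_replicate(image, k)
}

#' @rdname gaussian_filter
#' @details `gaussian_kernel` returns the discrete kernel itself
#'   (side `2*ceiling(4*sigma) + 1`, summing to 1).
#' @export
gaussian_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# EBImage filter2 needs both image dims to exceed the kernel's; pad small
# images by replication first so borders stay edge-replicated.
.filter_replicate <- function(image, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  pr <- max(0L, kr + 1L - nr %/% 2L)
  pc <- max(0L, kc + 1L - nc %/% 2L)
  x <- image
  if (pr > 0L) x <- x[c(rep(1L, pr), seq_len(nr), rep(nr, pr)), , drop = FALSE]
  if (pc > 0L) x <- x[, c(rep(1L, pc), seq_len(nc), rep(nc, pc)), drop = FALSE]
  y <- EBImage::filter2(x, kernel, boundary = "replicate")
  y <- as.matrix(y)
  y[pr + seq_len(nr), pc + seq_len(nc), drop = FALSE]
}

#' Perona-Malik anisotropic diffusion
#'
#' Explicit 4-neighbour scheme: per step each pixel gains
#' `rate * sum_n g(d_n) * d_n` where `d_n` is the intensity difference to
#' neighbour `n` and `g` is a conduction function that shuts diffusion
#' down across strong edges. Mirrored (Neumann) boundaries make the scheme
#' conservative: the total intensity sum is preserved. Removes noise while
#' keeping mass boundaries sharp, which is why it is the pipeline default.
#'
#' @param image numeric matrix (0-255 scale assumed for `kappa`).
#' @param iterations number of diffusion steps; 0 is the identity.
#'   Default 15.
#' @param kappa edge-stopping scale in intensity units: gradients well
#'   below `kappa` diffuse freely, gradients well above are preserved.
#'   Default 30 on the 0-255 scale.
#' @param rate per-step integration constant, in `(0, 0.25]` for stability
#'   of the 4-neighbour explicit scheme. Default 0.25.
#' @param conduction `"exponential"` for `g(s) = exp(-(s/kappa)^2)`
#'   (favours high-contrast edges) or `"rational"` for
#'   `g(s) = 1 / (1 + (s/kappa)^2)` (favours wide regions).
#' @return diffused numeric matrix, same shape.
#' @family denoising filters
#' @export
#' @examples
#' img <- matrix(c(0, 100, 0), 1)
#' anisotropic_diffusion(img, iterations = 1)
anisotropic_diffusion <- function(image, iterations = 15L, kappa = 30,
                                  rate = 0.25,
                                  conduction = c("exponential", "rational")) {
  .validate_gray(image)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L)
    stop("iterations must be >= 0", call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0)
    stop("kappa must be > 0", call. = FALSE)
  if (!is.finite(rate) || rate <= 0 || rate > 0.25)
    stop("rate must lie in (0, 0.25]", call. = FALSE)
  conduction <- match.arg(conduction)
  g <- if (conduction == "exponential")
    function(s) exp(-(s / kappa)^2)
  else
    function(s) 1 / (1 + (s / kappa)^2)

  u <- image
  nr <- nrow(u); nc <- ncol(u)
  up    <- function(m) m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- function(m) m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left  <- function(m) m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- function(m) m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  for (i in seq_len(iterations)) {
    dN <- up(u) - u
    dS <- down(u) - u
    dW <- left(u) - u
    dE <- right(u) - u
    u <- u + rate * (g(abs(dN)) * dN + g(abs(dS)) * dS +
                     g(abs(dW)) * dW + g(abs(dE)) * dE)
  }
  u
}

#' Apply the configured noise-reduction method
#'
#' Dispatcher used by the pipeline: `method` selects one of the three
#' filters (or none).
#'
#' @param image numeric matrix.
#' @param method one of `"none"`, `"mean"`, `"gaussian"`, `"anisotropic"`.
#' @param size,sigma,iterations,kappa,rate,conduction forwarded to the
#'   chosen filter.
#' @return filtered numeric matrix.
#' @export
denoise <- function(image,
                    method = c("anisotropic", "none", "mean", "gaussian"),
                    size = 5L, sigma = 2, iterations = 15L, kappa = 30,
                    rate = 0.25, conduction = "exponential") {
  method <- match.arg(method)
  switch(method,
    none = image,
    mean = mean_filter(image, size),
    gaussian = gaussian_filter(image, sigma),
    anisotropic = anisotropic_diffusion(image, iterations, kappa, rate,
                                        conduction))
}
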