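# Independent brute-force reference implementations used to validate the
# package's filters, plus small fixture builders. These deliberately take
# the slow, direct route (explicit neighborhoods, dense 2-D kernels).

# whole-sample symmetric reflection, 1-based
reflect1 <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  m <- (i - 1L) %% p
  m[m < 0] <- m[m < 0] + p
  ifelse(m >= n, p - m, m) + 1L
}

# sliding-disk median, pixel by pixel
oracle_median_disk <- function(x, radius) {
  nr <- nrow(x); nc <- ncol(x)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- reflect1(i + offs$dr, nr)
    cj <- reflect1(j + offs$dc, nc)
    out[i, j] <- median(x[cbind(ri, cj)])
  }
  out
}

# dense 2-D Gaussian convolution by explicit summation (non-separable path)
oracle_gaussian <- function(x, sigma) {
  nr <- nrow(x); nc <- ncol(x)
  h <- as.integer(ceiling(3.5 * sigma))
  k1 <- exp(-((-h:h)^2) / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- reflect1(i + (-h:h), nr)
    cj <- reflect1(j + (-h:h), nc)
    out[i, j] <- sum(k2 * x[ri, cj])
  }
  out
}

# random RGB micrograph with intensities safely inside [lo, hi]
random_micrograph <- function(h = 48, w = 48, lo = 60, hi = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arr <- array(runif(h * w * 3, lo, hi), dim = c(h, w, 3),
               dimnames = list(NULL, NULL, c("red", "green", "blue")))
  micrograph(arr, pixel_size_um = 300 / 1320, subject_id = "rnd")
}

# uniform-color micrograph
flat_micrograph <- function(h, w, rgb) {
  arr <- array(rep(rgb, each = h * w), dim = c(h, w, 3),
               dimnames = list(NULL, NULL, c("red", "green", "blue")))
  micrograph(arr, pixel_size_um = 300 / 1320)
}

# shared reduced-size scene parameters used by the slower scene tests
test_scene_params <- function(...) {
  fiber_scene_params(image_size_px = c(330L, 330L), ...)
}
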