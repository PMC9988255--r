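# Seeded evaluation that leaves the caller's RNG stream untouched.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

# von Mises sampler (Best-Fisher rejection method), mean 0.
rvonmises0 <- function(n, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

disk_offsets <- function(radius) {
  g <- expand.grid(dr = -ceiling(radius):ceiling(radius),
                   dc = -ceiling(radius):ceiling(radius))
  g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
}

#' Parameters of the synthetic fiber-scene generator
#'
#' Describes a synthetic brightfield ROI: brown curvilinear fibers (1-3 px
#' wide at the study's 0.227 um/px calibration) rendered as persistent
#' random walks on a bright background, with optional large dark stain
#' blots, additive Gaussian plus shot-like impulse noise, and optional
#' defocus blur. The generator records the exact pre-noise fiber mask, so
#' every detection stage can be checked against ground truth.
#'
#' @param image_size_px integer (H, W), default `c(660, 660)`.
#' @param pixel_size_um microns per pixel, default `300/1320`.
#' @param target_density desired fiber-pixel proportion, in \[0, 0.2).
#' @param fiber_width_px integer range (min, max) of fiber widths in px.
#' @param fiber_length_px range (min, max) of fiber path lengths in steps.
#' @param tortuosity dispersion (radians) of the von Mises step-angle
#'   innovations of the random walk; larger is wigglier.
#' @param stain_count number of large dark stain blots.
#' @param stain_radius_px radius of each stain blot (px); the default 30 px
#'   gives an area of ~2800 px, above the detector's exclusion cutoff.
#' @param noise_sd SD of additive per-channel Gaussian noise (grey levels).
#' @param impulse_frac fraction of pixels hit by dark shot-like impulses.
#' @param blur_sigma_px Gaussian defocus sigma; 0 for a sharp scene.
#' @param fiber_color,stain_color,background named RGB triples (0-255).
#' @param seed integer; fixes the scene exactly.
#' @return An object of class `fiber_scene_params`.
#' @export
fiber_scene_params <- function(image_size_px = c(660L, 660L),
                               pixel_size_um = 300 / 1320,
                               target_density = 0.03,
                               fiber_width_px = c(1L, 3L),
                               fiber_length_px = c(50L, 200L),
                               tortuosity = 0.25,
                               stain_count = 1L,
                               stain_radius_px = 30,
                               noise_sd = 5,
                               impulse_frac = 5e-4,
                               blur_sigma_px = 0,
                               fiber_color = c(red = 200, green = 170, blue = 140),
                               stain_color = c(red = 70, green = 55, blue = 45),
                               background = c(red = 230, green = 225, blue = 220),
                               seed = 1L) {
  if (target_density < 0 || target_density >= 0.2)
    stop("`target_density` must lie in [0, 0.2)", call. = FALSE)
  if (any(image_size_px < 8))
    stop("`image_size_px` must be at least 8 x 8", call. = FALSE)
  if (noise_sd < 0 || blur_sigma_px < 0 || stain_count < 0 || tortuosity < 0)
    stop("noise, blur, stain and tortuosity parameters must be non-negative",
         call. = FALSE)
  structure(as.list(environment()), class = "fiber_scene_params")
}

#' Generate a synthetic micrograph with ground truth
#'
#' Renders fiber paths as persistent random walks (von Mises step angles)
#' of the configured width until the realized fiber-pixel density reaches
#' `target_density` (the last fiber is truncated at pixel granularity, so
#' the realized density matches the target to within one pixel). Stain
#' blots are stamped first and fibers drawn on top; the truth mask records
#' exactly the rendered fiber pixels, before noise and blur. Then additive
#' Gaussian noise and dark impulses are applied, optionally followed by
#' defocus blur, and the image is quantized to 8-bit levels.
#'
#' @param params a [fiber_scene_params()].
#' @param subject_id,region,hemisphere,ap_mm,group_labels metadata passed to
#'   the returned [micrograph()].
#' @param max_fibers walker budget; exceeding it raises a generation error.
#' @return A list of class `fiber_scene`: `image` (a [micrograph()]),
#'   `truth_mask` (logical matrix) and `realized_density`.
#' @export
generate_fiber_scene <- function(params = fiber_scene_params(),
                                 subject_id = "synthetic", region = "other",
                                 hemisphere = "left", ap_mm = NA_real_,
                                 group_labels = character(),
                                 max_fibers = 20000L) {
  stopifnot(inherits(params, "fiber_scene_params"))
  with_seed(params$seed, {
    H <- as.integer(params$image_size_px[1])
    W <- as.integer(params$image_size_px[2])
    npx <- H * W
    target_px <- round(params$target_density * npx)
    mask <- matrix(FALSE, H, W)
    kappa <- if (params$tortuosity > 0) 1 / params$tortuosity^2 else Inf

    # stains first; fibers are drawn on top
    stain_mask <- matrix(FALSE, H, W)
    if (params$stain_count > 0) {
      offs <- disk_offsets(params$stain_radius_px)
      for (s in seq_len(params$stain_count)) {
        cr <- sample.int(H, 1L); cc <- sample.int(W, 1L)
        rr <- cr + offs$dr; cc2 <- cc + offs$dc
        ok <- rr >= 1 & rr <= H & cc2 >= 1 & cc2 <= W
        stain_mask[cbind(rr[ok], cc2[ok])] <- TRUE
      }
    }

    n_fibers <- 0L
    while (sum(mask) < target_px) {
      n_fibers <- n_fibers + 1L
      if (n_fibers > max_fibers)
        stop(sprintf("target density %.3f unreachable within the walker budget of %d fibers",
                     params$target_density, max_fibers), call. = FALSE)
      w <- sample(params$fiber_width_px[1]:params$fiber_width_px[2], 1L)
      len <- sample(params$fiber_length_px[1]:params$fiber_length_px[2], 1L)
      dth <- if (is.finite(kappa)) rvonmises0(len, kappa) else numeric(len)
      theta <- runif(1, 0, 2 * pi) + cumsum(dth)
      pr <- round(runif(1, 1, H) + cumsum(sin(theta)))
      pc <- round(runif(1, 1, W) + cumsum(cos(theta)))
      offs <- disk_offsets(w / 2)
      rows <- rep(pr, each = nrow(offs)) + offs$dr
      cols <- rep(pc, each = nrow(offs)) + offs$dc
      ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
      idx <- (cols[ok] - 1L) * H + rows[ok]          # path order preserved
      if (!length(idx)) next                         # walker left the frame
      new <- !mask[idx] & !duplicated(idx)
      need <- target_px - sum(mask)
      cum <- cumsum(new)
      if (cum[length(cum)] >= need) idx <- idx[seq_len(which(cum >= need)[1])]
      mask[idx] <- TRUE
    }

    img <- array(0, dim = c(H, W, 3),
                 dimnames = list(NULL, NULL, c("red", "green", "blue")))
    for (ch in c("red", "green", "blue")) {
      plane <- matrix(params$background[[ch]], H, W)
      plane[stain_mask] <- params$stain_color[[ch]]
      plane[mask] <- params$fiber_color[[ch]]
      img[, , ch] <- plane
    }

    if (params$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, params$noise_sd), dim = dim(img))
    n_imp <- round(params$impulse_frac * npx)
    if (n_imp > 0) {
      hit <- sample.int(npx, n_imp)
      for (k in 1:3) { p <- img[, , k]; p[hit] <- 0; img[, , k] <- p }
    }
    if (params$blur_sigma_px > 0)
      for (k in 1:3) img[, , k] <- gaussian_smooth(img[, , k], params$blur_sigma_px)
    img <- round(pmin(pmax(img, 0), 255))

    structure(
      list(image = micrograph(img, params$pixel_size_um, subject_id = subject_id,
                              region = region, hemisphere = hemisphere,
                              ap_mm = ap_mm, group_labels = group_labels),
           truth_mask = mask,
           realized_density = sum(mask) / npx),
      class = "fiber_scene")
  })
}
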