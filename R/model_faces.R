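# 2D cartoon validation models: a fixed smiling face plus four derived
# models exercising, in order, (1) a smooth invertible deformation that
# turns the smile into a crying face, (2) random per-region gray textures
# drawn from histograms to emulate weak SNR, (3) periodic streak noise
# emulating uneven illumination stripes, (4) a triangular zero-gray tear
# emulating a torn section. Regional masks (face, eyebrows, eyes, mouth)
# travel with each model so that feature-driven registration can be tested
# without manual segmentation.

#' Default geometry and gray levels of the fixed face model
#'
#' The published experiment shows the face only as a figure; the geometry
#' here (circle radius, feature placement, gray values) is a parameterized
#' stand-in with the same qualitative layout.
#'
#' @param size image side length in pixels.
#' @return named list of geometry parameters.
#' @export
face_params <- function(size = 400L) {
  s <- size / 400
  list(size = as.integer(size), center = c(200, 200) * s,
       face_radius = 160 * s,
       eye_offset = c(60, -50) * s, eye_radius = 18 * s,
       brow_radius = c(28, 38) * s, brow_ymax = -62 * s,
       mouth_center_dy = 10 * s, mouth_radius = c(70, 88) * s,
       mouth_ymin = 45 * s,
       gray = c(face = 100, eyebrows = 160, eyes = 220, mouth = 255))
}

#' Generate the fixed (smiling) face model
#'
#' @param params geometry list from [face_params()].
#' @return Object of class `FaceModel`: `image` (size x size matrix,
#'   values 0-255), `region_masks` (named list of pairwise-disjoint logical
#'   masks `face`, `eyebrows`, `eyes`, `mouth`, all inside the face disk)
#'   and `params`.
#' @export
make_fixed_model <- function(params = face_params()) {
  n <- params$size
  g <- grid_coords(c(n, n, 1L))
  x <- g[, 1]; y <- g[, 2]
  cx <- params$center[1]; cy <- params$center[2]
  disk <- (x - cx)^2 + (y - cy)^2 <= params$face_radius^2
  eyes <- rep(FALSE, n * n)
  brows <- rep(FALSE, n * n)
  for (sgn in c(-1, 1)) {
    ex <- cx + sgn * params$eye_offset[1]
    ey <- cy + params$eye_offset[2]
    r2 <- (x - ex)^2 + (y - ey)^2
    eyes <- eyes | r2 <= params$eye_radius^2
    rb <- sqrt((x - ex)^2 + (y - ey)^2)
    brows <- brows | (rb >= params$brow_radius[1] &
                        rb <= params$brow_radius[2] &
                        y <= cy + params$brow_ymax)
  }
  mx <- cx; my <- cy + params$mouth_center_dy
  rm_ <- sqrt((x - mx)^2 + (y - my)^2)
  mouth <- rm_ >= params$mouth_radius[1] & rm_ <= params$mouth_radius[2] &
    y >= cy + params$mouth_ymin
  eyes <- eyes & disk; brows <- brows & disk & !eyes
  mouth <- mouth & disk & !eyes & !brows
  face <- disk & !eyes & !brows & !mouth
  img <- numeric(n * n)
  gray <- params$gray
  img[face] <- gray[["face"]]; img[brows] <- gray[["eyebrows"]]
  img[eyes] <- gray[["eyes"]]; img[mouth] <- gray[["mouth"]]
  structure(list(image = matrix(img, n, n),
                 region_masks = list(face = matrix(face, n, n),
                                     eyebrows = matrix(brows, n, n),
                                     eyes = matrix(eyes, n, n),
                                     mouth = matrix(mouth, n, n)),
                 params = params),
            class = "FaceModel")
}

#' Deform the fixed model into a crying face (Model 1)
#'
#' The deformation's field is a forward (push) field: a pixel at `p` moves
#' to approximately `p + t(p)`. Images and masks are resampled by
#' pull-back through the fixed-point inverse of the field; masks use
#' nearest-neighbor so they stay crisp and pairwise disjoint.
#'
#' @param fixed `FaceModel` from [make_fixed_model()].
#' @param deform a `SyntheticDeformation` (see
#'   [make_crying_deformation()], [make_synthetic_field()]).
#' @return `FaceModel` with warped image and masks; the deformation is
#'   recorded in `$deform`.
#' @export
make_model1 <- function(fixed, deform) {
  stopifnot(inherits(fixed, "FaceModel"),
            inherits(deform, "SyntheticDeformation"))
  jmin <- field_jacobian_min(deform$field)
  if (jmin <= 0)
    stop("deformation is not invertible (min Jacobian det = ",
         signif(jmin, 4), ")")
  inv <- invert_field(deform$field)
  n <- fixed$params$size
  g <- grid_coords(c(n, n, 1L))
  src <- cbind(g[, 1] + as.vector(inv$components[[1]]),
               g[, 2] + as.vector(inv$components[[2]]), 0)
  arr3 <- function(m) array(m, c(n, n, 1L))
  img <- matrix(sample_array(arr3(fixed$image), src, "linear"), n, n)
  masks <- lapply(fixed$region_masks, function(m)
    matrix(sample_array(arr3(m + 0), src, "nearest") > 0.5, n, n))
  structure(list(image = img, region_masks = masks,
                 params = fixed$params, deform = deform),
            class = "FaceModel")
}

#' Surrogate regional gray-level histograms
#'
#' Three overlapping discretized Gaussians over 0-255 standing in for
#' empirical Nissl histograms of white matter, hippocampus and cerebellum
#' textures (synthetic surrogates; no atlas download).
#'
#' @return named list of probability vectors of length 256 for regions
#'   `eyebrows`, `eyes`, `mouth`.
#' @export
surrogate_histograms <- function() {
  gauss_hist <- function(mu, sd) {
    p <- stats::dnorm(0:255, mu, sd)
    p / sum(p)
  }
  list(eyebrows = gauss_hist(90, 22), eyes = gauss_hist(140, 25),
       mouth = gauss_hist(190, 20))
}

#' Randomize region gray values from histograms (Model 2)
#'
#' Every pixel inside a listed region is drawn i.i.d. from that region's
#' discrete histogram over gray values 0-255; pixels outside the listed
#' regions (including background) are untouched.
#'
#' @param m `FaceModel`.
#' @param histograms named list (region name -> probability vector over
#'   0:255); defaults to [surrogate_histograms()].
#' @param seed RNG seed (deterministic output).
#' @return `FaceModel` with textured image.
#' @export
texture_from_histograms <- function(m, histograms = surrogate_histograms(),
                                    seed = 1L) {
  stopifnot(inherits(m, "FaceModel"))
  img <- m$image
  rs <- local_rng(seed)
  for (rg in names(histograms)) {
    h <- histograms[[rg]]
    if (length(h) != 256L || any(h < 0) || sum(h) <= 0 || anyNA(h))
      stop("histogram for ", rg, " is not normalizable over 0:255")
    mask <- m$region_masks[[rg]]
    if (is.null(mask)) stop("no region mask named ", rg)
    img[mask] <- sample(0:255, sum(mask), replace = TRUE, prob = h / sum(h))
  }
  rs()
  out <- m
  out$image <- img
  out
}

# Evaluate a function under a fixed local RNG state; returns the restorer.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

#' Add periodic streak noise (Model 3)
#'
#' Implements `y = v * (sin((pi/w) * c) + A - 1) / A` where `v` is the
#' pixel value and `c` is the 0-based pixel coordinate along `axis`, so
#' the attenuation forms spatial stripes of period `2w`. The published
#' formula writes the same symbol for the multiplier and the sin argument;
#' the spatial reading is the default here because it produces streaks,
#' and `literal = TRUE` applies the verbatim value-dependent reading
#' (`c = v`).
#'
#' @param image numeric matrix (or `FaceModel`).
#' @param w half-period in pixels (> 0); published setting 20.
#' @param A attenuation (> 1); published setting 7.
#' @param axis 1 (x) or 2 (y): streaks run perpendicular to this axis.
#' @param literal use the pixel value itself as the sin argument.
#' @return same type as `image`, values clipped to 0-255.
#' @export
add_streak_noise <- function(image, w = 20, A = 7, axis = 2L,
                             literal = FALSE) {
  if (inherits(image, "FaceModel")) {
    out <- image
    out$image <- add_streak_noise(image$image, w, A, axis, literal)
    return(out)
  }
  if (w <= 0) stop("w must be > 0")
  if (A <= 1) stop("A must be > 1 (A <= 1 can flip the sign)")
  v <- image
  c0 <- if (literal) v
  else {
    idx <- (if (axis == 1L) row(v) else col(v)) - 1
    idx
  }
  y <- v * (sin((pi / w) * c0) + A - 1) / A
  pmin(pmax(y, 0), 255)
}

#' Zero out a triangular tear area (Model 4)
#'
#' Pixels whose centers fall inside the triangle (edges included) are set
#' to gray level 0; the rasterized tear mask is recorded in `$tear`.
#'
#' @param m `FaceModel`.
#' @param triangle 3 x 2 matrix of vertex coordinates (0-based pixels);
#'   `NULL` picks a default triangle inside the mouth.
#' @return `FaceModel` with torn image and `$tear` mask.
#' @export
add_tear <- function(m, triangle = NULL) {
  stopifnot(inherits(m, "FaceModel"))
  if (is.null(triangle)) {
    p <- m$params
    cx <- p$center[1]; my <- p$center[2] + p$mouth_ymin + 15
    triangle <- rbind(c(cx - 30, my - 12), c(cx + 18, my + 14),
                      c(cx - 6, my + 30))
  }
  triangle <- as.matrix(triangle)
  if (!all(dim(triangle) == c(3L, 2L))) stop("triangle must be 3 x 2")
  a <- triangle[1, ]; b <- triangle[2, ]; c3 <- triangle[3, ]
  area2 <- (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1])
  if (abs(area2) < 1e-9) stop("degenerate triangle")
  n <- nrow(m$image)
  g <- grid_coords(c(n, ncol(m$image), 1L))
  inside <- point_in_triangle(g[, 1], g[, 2], a, b, c3)
  tear <- matrix(inside, n, ncol(m$image))
  out <- m
  out$image[tear] <- 0
  out$tear <- tear
  out
}

# Center-of-pixel inclusion, edge ties included (barycentric signs with
# tolerance).
point_in_triangle <- function(x, y, a, b, c3) {
  s <- function(p1, p2) (x - p2[1]) * (p1[2] - p2[2]) -
    (p1[1] - p2[1]) * (y - p2[2])
  d1 <- s(a, b); d2 <- s(b, c3); d3 <- s(c3, a)
  eps <- 1e-9
  neg <- d1 < -eps | d2 < -eps | d3 < -eps
  pos <- d1 > eps | d2 > eps | d3 > eps
  !(neg & pos)
}

#' Parametric "crying" deformation for Model 1
#'
#' Vertical cosine warp localized on the mouth band (flipping the smile
#' curvature) plus a random smooth residual field; a reproducible stand-in
#' for the manually designed deformation of the original experiment.
#'
#' @param params [face_params()] of the fixed model.
#' @param mouth_amp peak vertical displacement of the mouth band (pixels).
#' @param rand_amp,rand_sigma amplitude / Gaussian smoothness of the
#'   random residual field (pixels).
#' @param seed RNG seed.
#' @return `SyntheticDeformation` with a 2D (z-extent 1) forward field.
#' @export
make_crying_deformation <- function(params = face_params(), mouth_amp = 8,
                                    rand_amp = 2, rand_sigma = 30,
                                    seed = 1L) {
  n <- params$size
  shape <- c(n, n, 1L)
  g <- grid_coords(shape)
  cx <- params$center[1]
  my <- params$center[2] + params$mouth_ymin + 15
  # near-uniform over the mouth band (wide cosine plateau and y window)
  # so the mask centroid moves by about the field value at the centroid
  wm <- params$mouth_radius[2] * 4
  dy <- mouth_amp * cos(pi * (g[, 1] - cx) / (2 * wm)) *
    exp(-((g[, 2] - my)^2) / (2 * 80^2)) *
    ifelse(abs(g[, 1] - cx) < wm, 1, 0)
  dy <- array(dy, shape)
  dy <- smooth_gauss(dy, c(4, 4, 0))
  rnd <- make_synthetic_field(shape, rand_amp, rand_sigma, seed)
  fld <- displacement_field(rnd$field$components[[1]],
                            dy + rnd$field$components[[2]],
                            array(0, shape))
  jmin <- field_jacobian_min(fld)
  if (jmin <= 0) stop("crying deformation not invertible; reduce amplitudes")
  structure(list(field = fld, amplitude = max(field_norm(fld)),
                 smoothness = rand_sigma, seed = seed),
            class = "SyntheticDeformation")
}

#' Build the full model chain (Models 1-4)
#'
#' model2 = texture(model1), model3 = streak(model2),
#' model4 = tear(model3); each stage leaves the region masks of prior
#' stages unchanged.
#'
#' @param fixed `FaceModel`; default geometry if `NULL`.
#' @param seed RNG seed driving the deformation and textures.
#' @return named list `fixed`, `model1` ... `model4`.
#' @export
make_model_chain <- function(fixed = NULL, seed = 1L) {
  if (is.null(fixed)) fixed <- make_fixed_model()
  deform <- make_crying_deformation(fixed$params, seed = seed)
  m1 <- make_model1(fixed, deform)
  m2 <- texture_from_histograms(m1, seed = seed + 1L)
  m3 <- add_streak_noise(m2)
  m4 <- add_tear(m3)
  list(fixed = fixed, model1 = m1, model2 = m2, model3 = m3, model4 = m4)
}

#' Convert a face model's masks to a LabelVolume
#'
#' Labels: face = 1, eyebrows = 2, eyes = 3, mouth = 4 (z-extent 1).
#'
#' @param m `FaceModel`.
#' @param exclude optional logical mask (e.g. a tear) removed from every
#'   region.
#' @return [label_volume()].
#' @export
face_label_volume <- function(m, exclude = NULL) {
  n <- dim(m$image)
  lab <- matrix(0L, n[1], n[2])
  ids <- c(face = 1L, eyebrows = 2L, eyes = 3L, mouth = 4L)
  for (rg in names(ids)) lab[m$region_masks[[rg]]] <- ids[[rg]]
  if (!is.null(exclude)) lab[exclude] <- 0L
  label_volume(array(lab, c(n, 1L)),
               names = structure(names(ids), names = as.character(ids)))
}
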