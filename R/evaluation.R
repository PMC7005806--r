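# Multilevel quantitative evaluation: 2D Dice reports per region, STAPLE
# consensus fusion of multiple raters, human-performance (HP) vs
# registration-performance (RP) scoring, Mann-Whitney comparison and
# landmark distances.

#' Dice overlap coefficient
#'
#' `2 |I n J| / (|I| + |J|)`. Symmetric; two empty masks score 1.0 by
#' convention (identical masks should score 1), with a warning.
#'
#' @param I,J logical (or 0/1) arrays of one shape.
#' @return numeric in `[0, 1]`.
#' @export
dice <- function(I, J) {
  if (!identical(dim2(I), dim2(J)))
    stop("masks must share one shape")
  I <- as.logical(I); J <- as.logical(J)
  si <- sum(I); sj <- sum(J)
  if (si + sj == 0L) {
    warning("both masks empty; Dice defined as 1.0 by convention")
    return(1.0)
  }
  2 * sum(I & J) / (si + sj)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Per-region multi-slice 2D Dice report
#'
#' For each region, finds the slice span along `axis` where the reference
#' contains the region, picks up to `n_slices` evenly spaced slices
#' across the span (first = span start, last = span end; all slices when
#' the span is shorter than `n_slices`, with the count reported), and
#' computes the 2D Dice of the registered vs reference region masks on
#' each slice.
#'
#' @param registered,reference [label_volume()]s aligned in one space.
#' @param regions region names or ids; default: all regions of the
#'   reference.
#' @param n_slices target number of evaluated slices per region.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return `DiceReport`: data.frame with columns `region`, `label`,
#'   `slice`, `dice`; regions absent from either volume are skipped with
#'   a warning.
#' @export
region_dice_report <- function(registered, reference, regions = NULL,
                               n_slices = 50L, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  ids <- resolve_regions(reference, regions)
  out <- NULL
  for (id in ids) {
    in_ref <- reference$data == id
    in_reg <- registered$data == id
    if (!any(in_ref) || !any(in_reg)) {
      warning("region ", reference$names[[as.character(id)]],
              " absent from a volume; skipped")
      next
    }
    pres <- apply(in_ref, ax, any)
    span <- range(which(pres))
    k <- min(n_slices, span[2] - span[1] + 1L)
    slices <- unique(as.integer(round(seq(span[1], span[2],
                                          length.out = k))))
    for (sl in slices) {
      m_ref <- slice_along(in_ref, ax, sl)
      m_reg <- slice_along(in_reg, ax, sl)
      d <- if (sum(m_ref) + sum(m_reg) == 0L) 1.0
      else 2 * sum(m_ref & m_reg) / (sum(m_ref) + sum(m_reg))
      out <- rbind(out, data.frame(
        region = unname(reference$names[[as.character(id)]]),
        label = id, slice = sl - 1L, dice = d))
    }
  }
  structure(out, class = c("DiceReport", "data.frame"))
}

slice_along <- function(a, ax, i) switch(ax, a[i, , ], a[, i, ], a[, , i])

#' Median Dice per region from a report
#' @param report [region_dice_report()] output.
#' @return named numeric vector of per-region median Dice scores.
#' @export
dice_medians <- function(report) {
  vapply(split(report$dice, report$region), stats::median, 0.0)
}

#' STAPLE consensus fusion of binary segmentations
#'
#' Expectation-maximization estimate of the latent true segmentation and
#' of each rater's sensitivity `p_j` and specificity `q_j` (Warfield's
#' simultaneous truth and performance level estimation). E-step: per-pixel
#' posterior foreground probability from the current `(p_j, q_j)` and the
#' prior; M-step: re-estimate `(p_j, q_j)` from the posterior weights.
#' Initialization `p_j = q_j = 0.99`, prior = mean of the rater masks
#' (clamped away from 0/1); deterministic.
#'
#' @param masks list of >= 2 binary arrays of one shape.
#' @param tol convergence threshold on the max parameter change.
#' @param max_iter iteration cap.
#' @param prior optional per-pixel prior foreground probability (scalar
#'   or array).
#' @return `StapleResult`: `consensus_prob`, `consensus_mask`
#'   (probability >= 0.5, ties to foreground), `p` (sensitivities), `q`
#'   (specificities), `iterations`, `converged`.
#' @export
staple <- function(masks, tol = 1e-6, max_iter = 200L, prior = NULL) {
  if (length(masks) < 2L) stop("STAPLE needs >= 2 rater masks")
  shp <- dim2(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim2(m), shp), TRUE)))
    stop("all masks must share one shape")
  D <- vapply(masks, function(m) as.numeric(as.logical(m)),
              numeric(prod(shp)))
  if (sum(D) == 0) stop("all rater masks empty")
  J <- ncol(D)
  if (is.null(prior)) prior <- rowMeans(D)
  prior <- pmin(pmax(as.vector(prior), 1e-6), 1 - 1e-6)
  p <- rep(0.99, J); q <- rep(0.99, J)
  W <- prior
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step in log space
    la <- log(prior) + D %*% log(p) + (1 - D) %*% log(1 - p)
    lb <- log(1 - prior) + D %*% log(1 - q) + (1 - D) %*% log(q)
    W <- as.vector(1 / (1 + exp(lb - la)))
    sw <- sum(W); swc <- sum(1 - W)
    p_new <- as.vector(crossprod(D, W)) / sw
    q_new <- as.vector(crossprod(1 - D, 1 - W)) / swc
    p_new <- pmin(pmax(p_new, 1e-6), 1 - 1e-6)
    q_new <- pmin(pmax(q_new, 1e-6), 1 - 1e-6)
    delta <- max(abs(p_new - p), abs(q_new - q))
    p <- p_new; q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  cp <- array(W, if (length(shp) > 1) shp else c(shp, 1))
  dimnames(cp) <- NULL
  if (length(shp) == 2L) cp <- matrix(cp, shp[1], shp[2])
  structure(list(consensus_prob = cp,
                 consensus_mask = cp >= 0.5,
                 p = p, q = q, iterations = it, converged = converged),
            class = "StapleResult")
}

#' Human-performance and registration-performance scores
#'
#' `HP_j = dice(rater_j, consensus)` for every rater and
#' `RP = dice(atlas, consensus)`, where the consensus is the STAPLE
#' mask of the raters.
#'
#' @param rater_masks list of binary arrays (>= 2).
#' @param atlas_mask binary array (the registered atlas region).
#' @param staple_result optional precomputed [staple()] result.
#' @return list `HP` (numeric vector, one per rater), `RP` (scalar),
#'   `staple` (the [staple()] result used).
#' @export
hp_rp <- function(rater_masks, atlas_mask, staple_result = NULL) {
  if (is.null(staple_result)) staple_result <- staple(rater_masks)
  cons <- staple_result$consensus_mask
  HP <- vapply(rater_masks, function(m)
    dice(array(as.logical(m), dim(cons)), cons), 0.0)
  RP <- dice(array(as.logical(atlas_mask), dim(cons)), cons)
  list(HP = unname(HP), RP = RP, staple = staple_result)
}

#' Mann-Whitney U test
#'
#' Exact tie-aware enumeration of all group assignments when
#' `n_a + n_b <= 12`; otherwise the normal approximation with tie and
#' continuity corrections. The two-sided exact p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param a,b numeric score vectors (each non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `a`
#'   relative to `b`).
#' @param method `"auto"` (exact when `n_a + n_b <= 12`), `"exact"` or
#'   `"normal"`.
#' @return list `U` (statistic of group `a`), `p`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b,
                           alternative = c("two.sided", "less",
                                           "greater"),
                           method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))  # midranks under ties
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (method == "exact" || (method == "auto" && n <= 12L)) {
    sets <- utils::combn(n, na)
    Uall <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
    p_le <- mean(Uall <= U + 1e-9)
    p_ge <- mean(Uall >= U - 1e-9)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le, greater = p_ge)
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- na * nb / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig <- sqrt(na * nb / 12 * (n + 1 - tie_term))
  z <- U - mu
  cc <- sign(z) * 0.5
  z <- (z - cc) / sig
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE))
  list(U = U, p = min(1, p), method = "normal")
}

#' Euclidean distances between matched landmark pairs
#'
#' @param fixed_pts,moved_pts N x 3 matrices of matched coordinates in
#'   micrometres.
#' @return list `distances` (per pair, micrometres), `median`, `iqr`.
#' @export
landmark_distances <- function(fixed_pts, moved_pts) {
  fixed_pts <- rbind3(fixed_pts); moved_pts <- rbind3(moved_pts)
  if (nrow(fixed_pts) != nrow(moved_pts))
    stop("landmark lists must have equal length")
  d <- sqrt(rowSums((fixed_pts - moved_pts)^2))
  list(distances = d, median = stats::median(d),
       iqr = unname(stats::quantile(d, 0.75) - stats::quantile(d, 0.25)))
}
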