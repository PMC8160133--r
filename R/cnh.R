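#' Purity/ploidy search grid
#'
#' The candidate purities (malignant-cell fraction, alpha) and ploidies
#' (width-weighted mean copy number of the malignant genome, tau) over which
#' the CNH score is minimized. Defaults cover the biologically relevant
#' ranges alpha = 0.20, 0.21, ..., 1.00 and tau = 1.50, 1.55, ..., 5.00.
#' Values are generated by index (`start + k * step`) so the endpoints are
#' exact.
#'
#' @param purities ordered purity values in (0, 1].
#' @param ploidies ordered ploidy values, > 0.
#' @return an object of class `cnh_grid`.
#' @export
cnh_grid <- function(purities = 0.20 + (0:80) * 0.01,
                     ploidies = 1.50 + (0:70) * 0.05) {
  purities <- as.numeric(purities)
  ploidies <- as.numeric(ploidies)
  if (!length(purities) || !length(ploidies))
    stop_cnh("grid must contain at least one purity and one ploidy")
  if (any(purities <= 0 | purities > 1))
    stop_cnh("purities must lie in (0, 1]")
  if (any(ploidies <= 0))
    stop_cnh("ploidies must be > 0")
  structure(list(purities = sort(purities), ploidies = sort(ploidies)),
            class = "cnh_grid")
}

#' @export
print.cnh_grid <- function(x, ...) {
  cat("CNH purity/ploidy grid: ", length(x$purities), " purities in [",
      min(x$purities), ", ", max(x$purities), "] x ", length(x$ploidies),
      " ploidies in [", min(x$ploidies), ", ", max(x$ploidies), "] (",
      length(x$purities) * length(x$ploidies), " points)\n", sep = "")
  invisible(x)
}

#' Absolute copy numbers from relative values at a given purity and ploidy
#'
#' Inverts the bulk mixture model. A bulk sample with purity `alpha` mixes
#' the malignant genome (absolute copies q_i, mean ploidy tau) with diploid
#' normal cells, giving relative values
#' r_i = (alpha q_i + 2 (1 - alpha)) / (alpha tau + 2 (1 - alpha)); this
#' function returns q_i = (r_i (alpha tau + 2 (1 - alpha)) -
#' 2 (1 - alpha)) / alpha. No clipping is applied: a poor (alpha, tau)
#' candidate may produce negative q_i, which the grid minimization
#' naturally disfavours.
#'
#' @param r relative copy numbers (profile normalized to mean 1).
#' @param purity alpha in (0, 1].
#' @param ploidy tau > 0.
#' @return absolute copy numbers, same length as `r`.
#' @export
absolute_from_relative <- function(r, purity, ploidy) {
  if (purity <= 0 || purity > 1)
    stop_cnh("purity must lie in (0, 1], got ", purity)
  if (ploidy <= 0) stop_cnh("ploidy must be > 0, got ", ploidy)
  (r * (purity * ploidy + 2 * (1 - purity)) - 2 * (1 - purity)) / purity
}

#' Distance of copy numbers to the nearest integer
#'
#' d_i = |q_i - round(q_i)|, the per-segment deviation from a clonal
#' (integer) karyotype; always in [0, 0.5].
#'
#' @param q absolute copy numbers (any finite reals).
#' @return distances, same length as `q`.
#' @export
integer_distance <- function(q) {
  abs(q - round_half_away(q))
}

#' Width-weighted mean distance
#'
#' The CNH score of one (purity, ploidy) candidate:
#' sum(d_i w_i) / sum(w_i).
#'
#' @param d per-segment integer distances.
#' @param w segment widths (> 0).
#' @return the weighted mean, a scalar in `[min(d), max(d)]`.
#' @export
weighted_mean_distance <- function(d, w) {
  if (!length(d)) stop_cnh("empty distance vector")
  if (length(d) != length(w)) stop_cnh("d and w must have equal length")
  if (any(w <= 0)) stop_cnh("widths must be > 0")
  sum(d * w) / sum(w)
}

#' Fit the copy-number heterogeneity (CNH) of a bulk profile
#'
#' CNH quantifies intra-tumour heterogeneity from a single segmented bulk
#' copy-number profile. The profile is normalized to width-weighted mean 1,
#' converted to candidate absolute copy numbers at every (purity, ploidy)
#' grid point, and scored by the width-weighted mean distance of the
#' absolute values to the nearest integers. CNH is the minimum score over
#' the grid; it lies in [0, 0.5] and approximates the width-weighted
#' fraction of malignant cells deviating by one copy from the modal
#' karyotype.
#'
#' When an independent purity estimate exists, `purity` restricts the search
#' to a window of `purity_window` (relative, default 10%) around it;
#' `ploidy` fixes the ploidy to the nearest grid value. The restricted
#' minimum is never below the unconstrained one.
#'
#' @param x a [segmented_profile()] (or coercible data frame). Normalized
#'   automatically if needed.
#' @param grid a [cnh_grid()].
#' @param purity optional known purity alpha0; the search keeps grid
#'   purities with `|alpha - alpha0| <= purity_window * alpha0`.
#' @param purity_window relative half-width of the purity window
#'   (default 0.1).
#' @param ploidy optional known ploidy; fixed to the nearest grid ploidy.
#' @param keep_surface keep the full score surface (purities x ploidies
#'   matrix) in the result.
#' @return an object of class `cnh_fit` with components `cnh` (the score),
#'   `purity`, `ploidy` (the argmin, ties broken to the smallest ploidy,
#'   then smallest purity), `ties` (all grid points within 1e-12 of the
#'   minimum), `q` (absolute copies at the argmin), `d` (their integer
#'   distances), `ploidy_residual` (diagnostic: width-weighted mean of `q`
#'   minus the fitted ploidy; not enforced), `n_segments`, `profile`, and
#'   optionally `surface`.
#' @examples
#' p <- segmented_profile("chr1", c(1, 101, 201), c(100, 200, 300),
#'                        c(1, 1.5, 0.5))
#' fit <- cnh(p)
#' coef(fit)
#' @export
cnh <- function(x, grid = cnh_grid(), purity = NULL, purity_window = 0.1,
                ploidy = NULL, keep_surface = FALSE) {
  profile <- as_segmented_profile(x)
  if (!isTRUE(attr(profile, "normalized")))
    profile <- normalize_profile(profile)
  if (!inherits(grid, "cnh_grid")) stop_cnh("grid must be a cnh_grid")

  purities <- grid$purities
  ploidies <- grid$ploidies
  if (!is.null(purity)) {
    keep <- abs(purities - purity) <= purity_window * purity + 1e-12
    if (!any(keep))
      stop_cnh("no grid purities within ", purity_window * 100,
               "% of purity ", purity, " (grid spans [", min(purities),
               ", ", max(purities), "])")
    purities <- purities[keep]
  }
  if (!is.null(ploidy)) {
    ploidies <- ploidies[which.min(abs(ploidies - ploidy))]
  }

  r <- profile$value
  w <- profile$width
  if (length(unique(signif(r, 12))) < 3L)
    warning("profile has fewer than 3 distinct copy-number levels; ",
            "purity/ploidy are weakly identified and CNH should not be ",
            "interpreted for single segments", call. = FALSE)

  # paired (purity, ploidy) vectors, purity varying fastest so that the
  # first index among ties has the smallest ploidy, then smallest purity
  np <- length(purities); nt <- length(ploidies)
  a <- rep(purities, times = nt)
  tau <- rep(ploidies, each = np)
  A <- a * tau + 2 * (1 - a)      # mixture denominator alpha*tau + 2(1-a)
  B <- 2 * (1 - a)
  Q <- outer(r, A)
  Q <- sweep(Q, 2L, B, "-")
  Q <- sweep(Q, 2L, a, "/")
  D <- abs(Q - round_half_away(Q))
  scores <- as.vector(crossprod(w, D)) / sum(w)

  cnh_min <- min(scores)
  tie_idx <- which(scores <= cnh_min + 1e-12)
  best <- tie_idx[1L]
  q_best <- Q[, best]

  out <- list(
    cnh = cnh_min,
    purity = a[best],
    ploidy = tau[best],
    ties = data.frame(purity = a[tie_idx], ploidy = tau[tie_idx],
                      score = scores[tie_idx]),
    q = q_best,
    d = D[, best],
    ploidy_residual = weighted_mean2(q_best, w) - tau[best],
    n_segments = length(r),
    restricted = !is.null(purity) || !is.null(ploidy),
    profile = profile
  )
  if (keep_surface) {
    out$surface <- matrix(scores, nrow = np, ncol = nt,
                          dimnames = list(purity = format(purities),
                                          ploidy = format(ploidies)))
  }
  class(out) <- "cnh_fit"
  out
}

#' @export
print.cnh_fit <- function(x, digits = 4, ...) {
  cat("CNH fit: ", attr(x$profile, "sample_id"), "\n",
      "  CNH = ", format(x$cnh, digits = digits),
      "  (purity = ", format(x$purity, digits = digits),
      ", ploidy = ", format(x$ploidy, digits = digits), ")\n",
      "  ", x$n_segments, " segments",
      if (x$restricted) "; restricted grid" else "",
      if (nrow(x$ties) > 1L)
        paste0("; ", nrow(x$ties), " grid points tie at the minimum")
      else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.cnh_fit <- function(object, ...) {
  structure(list(
    sample_id = attr(object$profile, "sample_id"),
    cnh = object$cnh,
    purity = object$purity,
    ploidy = object$ploidy,
    n_ties = nrow(object$ties),
    n_segments = object$n_segments,
    ploidy_residual = object$ploidy_residual,
    genome_width = sum(object$profile$width),
    d_quantiles = stats::quantile(object$d, c(0, 0.25, 0.5, 0.75, 1))
  ), class = "summary.cnh_fit")
}

#' @export
print.summary.cnh_fit <- function(x, digits = 4, ...) {
  cat("CNH fit summary:", x$sample_id, "\n")
  cat("  CNH =", format(x$cnh, digits = digits),
      " purity =", format(x$purity, digits = digits),
      " ploidy =", format(x$ploidy, digits = digits), "\n")
  cat("  segments:", x$n_segments,
      " total width:", format(x$genome_width, big.mark = ","), "bp\n")
  cat("  grid ties at minimum:", x$n_ties,
      " ploidy residual:", format(x$ploidy_residual, digits = 3), "\n")
  cat("  integer distances (min/q1/median/q3/max):",
      paste(format(x$d_quantiles, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.cnh_fit <- function(object, ...) {
  c(cnh = object$cnh, purity = object$purity, ploidy = object$ploidy)
}

#' @export
fitted.cnh_fit <- function(object, ...) object$q

#' @export
residuals.cnh_fit <- function(object, ...) object$d

#' Predict absolute copy numbers from a CNH fit
#'
#' Reconstructs absolute copy numbers of the fitted profile (or of new
#' relative values) at the fitted — or any supplied — purity and ploidy.
#'
#' @param object a `cnh_fit`.
#' @param newdata optional vector of relative copy numbers; defaults to the
#'   fitted profile's values.
#' @param purity,ploidy override the fitted values.
#' @param ... ignored.
#' @return numeric vector of absolute copy numbers.
#' @export
predict.cnh_fit <- function(object, newdata = NULL, purity = NULL,
                            ploidy = NULL, ...) {
  r <- newdata %||% object$profile$value
  absolute_from_relative(r, purity %||% object$purity,
                         ploidy %||% object$ploidy)
}

#' Plot the CNH score surface
#'
#' Displays the grid of width-weighted mean integer distances as an image
#' over purity and ploidy, with the argmin marked. Several (purity, ploidy)
#' combinations typically fit almost equally well (integer translations of
#' the copy-number profile); the surface makes that degeneracy visible.
#'
#' @param x a `cnh_fit`; if it was created without `keep_surface = TRUE`
#'   the surface is recomputed.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.cnh_fit <- function(x, ...) {
  if (is.null(x$surface)) {
    refit <- cnh(x$profile, keep_surface = TRUE)
    x$surface <- refit$surface
  }
  purities <- as.numeric(rownames(x$surface))
  ploidies <- as.numeric(colnames(x$surface))
  graphics::image(purities, ploidies, x$surface,
                  xlab = "purity (alpha)", ylab = "ploidy (tau)",
                  main = sprintf("CNH surface (min = %.4g)", x$cnh), ...)
  graphics::points(x$purity, x$ploidy, pch = 4, cex = 1.5, lwd = 2)
  invisible(x)
}

#' Integer ploidy translation of a fitted solution
#'
#' Translating the absolute copy-number profile by an integer leaves CNH
#' unchanged, so a fit at (purity, ploidy) has near-equivalent companions at
#' integer ploidy shifts. Writing the reconstruction as
#' `q = r (ploidy + beta) - beta` with `beta = 2/purity - 2`, an exact
#' translation `q -> q + shift` requires `ploidy_new = ploidy + shift` and
#' `beta_new = beta - shift`, i.e. `purity_exact = 2 purity /
#' (2 - shift * purity)`. The commonly quoted adjustment
#' `purity_new = -2 / ploidy_new + purity + 2 / ploidy` is an approximation
#' to this (exact only when `purity = 2 / ploidy`); both are returned.
#'
#' The shifted pair is flagged `valid` when an equivalent solution really
#' exists inside the biologically relevant ranges: `purity_exact` in
#' [0.2, 1] and `ploidy_new` in [1.5, 5]. Re-fitting with the ploidy fixed
#' to `ploidy_new` (purity searched over the grid, see [cnh()] argument
#' `ploidy`) then reproduces CNH closely.
#'
#' @param purity,ploidy the fitted values.
#' @param shift integer ploidy shift (0 returns the pair unchanged).
#' @return a list with `ploidy_new`, `purity_new` (approximate adjustment),
#'   `purity_exact` (exact translation purity), and `valid`.
#' @export
shifted_solution <- function(purity, ploidy, shift) {
  if (shift != round(shift)) stop_cnh("shift must be an integer")
  if (shift == 0)
    return(list(ploidy_new = ploidy, purity_new = purity,
                purity_exact = purity, valid = TRUE))
  ploidy_new <- ploidy + shift
  purity_new <- -2 / ploidy_new + purity + 2 / ploidy
  purity_exact <- 2 * purity / (2 - shift * purity)
  valid <- is.finite(purity_exact) && purity_exact >= 0.2 &&
    purity_exact <= 1 && ploidy_new >= 1.5 && ploidy_new <= 5
  list(ploidy_new = ploidy_new, purity_new = purity_new,
       purity_exact = purity_exact, valid = valid)
}
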