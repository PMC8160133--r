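#' Generate a baseline integer karyotype template
#'
#' Emulates the segmented genome of an aneuploid tumour: `n_segments`
#' segments with widths drawn log-uniformly over two decades
#' (default 1e5–1e7 bp) and baseline integer copies from {1, 2, 3, 4},
#' resampled until the width fraction with copy != 2 exceeds 0.5 (a highly
#' altered genome) and, for n >= 5 segments, at least 3 distinct copy
#' levels are present (two-level profiles leave purity/ploidy
#' unidentifiable).
#'
#' @param n_segments number of segments (>= 2).
#' @param seed optional seed; the template is deterministic per seed.
#' @param width_range widths are log-uniform on this range (base pairs).
#' @param copy_prob sampling weights for copies 1..4.
#' @return a data frame (class `cnh_template`) with columns `chrom`,
#'   `start`, `end`, `width`, `copy`.
#' @export
generate_segment_template <- function(n_segments, seed = NULL,
                                      width_range = c(1e5, 1e7),
                                      copy_prob = c(0.2, 0.35, 0.3, 0.15)) {
  if (n_segments < 2L) stop_cnh("need at least 2 segments")
  if (!is.null(seed)) set.seed(seed)
  lo <- log10(width_range[1L]); hi <- log10(width_range[2L])
  for (iter in seq_len(10000L)) {
    widths <- round(10^stats::runif(n_segments, lo, hi))
    copies <- sample(1:4, n_segments, replace = TRUE, prob = copy_prob)
    altered <- sum(widths[copies != 2L]) / sum(widths)
    enough_levels <- n_segments < 5L || length(unique(copies)) >= 3L
    if (altered > 0.5 && enough_levels) break
    if (iter == 10000L)
      stop_cnh("could not draw a template meeting the altered-fraction ",
               "constraint")
  }
  end <- cumsum(widths)
  start <- end - widths + 1
  structure(data.frame(chrom = "sim1", start = start, end = end,
                       width = widths, copy = copies,
                       stringsAsFactors = FALSE),
            class = c("cnh_template", "data.frame"))
}

#' Introduce subclonal heterogeneity into a template
#'
#' Models a malignant population in which, for each segment, a fraction
#' `f` of cells carries one extra or one missing copy. Each `f_i` is drawn
#' uniformly on (0, 2h) so its expectation equals the input heterogeneity
#' `h`; the alteration direction is +/-1 with equal probability. By default
#' all altered cells of a segment share one direction
#' (`"per_segment_single_direction"`), so the bulk mean shifts by
#' `f_i * dir_i`; the alternative `"per_cell_independent"` scheme (each
#' altered cell tosses its own coin) keeps cell-level heterogeneity but
#' cancels in the bulk expectation, and is retained for sensitivity
#' analysis only.
#'
#' `h` is capped at 0.25 so that every `f_i < 0.5` and the deviation of the
#' bulk mean from the nearest integer equals `f_i` exactly.
#'
#' @param template a [generate_segment_template()] result (or any data
#'   frame with `width` and `copy`).
#' @param input_h target heterogeneity, in [0, 0.25].
#' @param seed optional seed.
#' @param direction_scheme see Details.
#' @return an object of class `simulated_tumour`: the template plus
#'   `f`, `direction`, `scheme`, `input_h`, and `truth_h` (the realized
#'   width-weighted mean of `min(f, 1 - f)`).
#' @export
introduce_heterogeneity <- function(template, input_h, seed = NULL,
                                    direction_scheme =
                                      c("per_segment_single_direction",
                                        "per_cell_independent")) {
  direction_scheme <- match.arg(direction_scheme)
  if (input_h < 0 || input_h > 0.25)
    stop_cnh("input_h must lie in [0, 0.25]: above 0.25 an altered ",
             "fraction f can exceed 0.5 and the bulk deviation from the ",
             "nearest integer no longer equals f")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(template)
  f <- if (input_h == 0) rep(0, n) else stats::runif(n, 0, 2 * input_h)
  direction <- sample(c(-1L, 1L), n, replace = TRUE)
  structure(list(template = template, f = f, direction = direction,
                 scheme = direction_scheme, input_h = input_h,
                 truth_h = weighted_mean2(pmin(f, 1 - f), template$width)),
            class = "simulated_tumour")
}

#' @export
print.simulated_tumour <- function(x, ...) {
  cat("Simulated tumour population:\n",
      "  ", nrow(x$template), " segments; input h = ", x$input_h,
      "; realized truth_h = ", format(x$truth_h, digits = 4), "\n",
      "  direction scheme: ", x$scheme, "\n", sep = "")
  invisible(x)
}

#' Emit the bulk copy-number profile of a simulated tumour
#'
#' Mixes the malignant population with diploid normal cells (fraction
#' `1 - purity`) and returns the normalized relative profile a copy-number
#' pipeline would report. In analytic mode (`n_cells = Inf`, the default)
#' the population average is taken in expectation — equivalent to the
#' ~1e9-cell populations the measure targets, without sampling noise;
#' finite `n_cells` draws each cell's alteration status (binomial counts),
#' converging to the analytic values as `O(1 / sqrt(n_cells))`. Optional
#' Gaussian measurement noise of standard deviation `bin_noise_sd` is added
#' to the relative values before normalization (values floored at 0).
#'
#' @param sim a [introduce_heterogeneity()] result.
#' @param purity malignant-cell fraction alpha in (0, 1].
#' @param bin_noise_sd standard deviation of additive Gaussian noise; 0
#'   for a noiseless profile.
#' @param n_cells `Inf` for the analytic expectation or a finite
#'   population size.
#' @param seed optional seed (used for finite-cell sampling and noise).
#' @return a normalized [segmented_profile()].
#' @export
emit_bulk <- function(sim, purity = 1, bin_noise_sd = 0, n_cells = Inf,
                      seed = NULL) {
  if (!inherits(sim, "simulated_tumour"))
    stop_cnh("sim must be a simulated_tumour")
  if (purity <= 0 || purity > 1)
    stop_cnh("purity must lie in (0, 1], got ", purity)
  if (!is.null(seed)) set.seed(seed)
  tmpl <- sim$template
  n <- nrow(tmpl)
  shift <- if (is.infinite(n_cells)) {
    if (sim$scheme == "per_segment_single_direction")
      sim$f * sim$direction
    else
      rep(0, n)  # per-cell independent +/-1 cancels in expectation
  } else {
    altered <- stats::rbinom(n, n_cells, sim$f)
    if (sim$scheme == "per_segment_single_direction") {
      sim$direction * altered / n_cells
    } else {
      up <- stats::rbinom(n, altered, 0.5)
      (2 * up - altered) / n_cells
    }
  }
  mean_malignant <- tmpl$copy + shift
  v <- purity * mean_malignant + 2 * (1 - purity)
  if (bin_noise_sd > 0)
    v <- pmax(v + stats::rnorm(n, 0, bin_noise_sd), 0)
  normalize_profile(segmented_profile(
    tmpl$chrom, tmpl$start, tmpl$end, v,
    sample_id = sprintf("sim_h%g_a%g", sim$input_h, purity)))
}

#' Simulate a tumour and its bulk profile in one call
#'
#' Convenience wrapper chaining [generate_segment_template()],
#' [introduce_heterogeneity()] and [emit_bulk()] under one seed.
#'
#' @param n_segments segments in the synthetic template (ignored when
#'   `template` is supplied).
#' @param h input heterogeneity in [0, 0.25].
#' @param purity malignant-cell fraction.
#' @param n_cells `Inf` (analytic) or a finite population size.
#' @param bin_noise_sd additive Gaussian measurement noise.
#' @param seed optional master seed for the whole construction.
#' @param direction_scheme see [introduce_heterogeneity()].
#' @param template optional pre-built template.
#' @return a `simulated_tumour` with additional components `purity` and
#'   `bulk` (the emitted [segmented_profile()]).
#' @export
simulate_tumour <- function(n_segments = 30, h = 0.1, purity = 1,
                            n_cells = Inf, bin_noise_sd = 0, seed = NULL,
                            direction_scheme =
                              c("per_segment_single_direction",
                                "per_cell_independent"),
                            template = NULL) {
  direction_scheme <- match.arg(direction_scheme)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(template)) template <- generate_segment_template(n_segments)
  sim <- introduce_heterogeneity(template, h,
                                 direction_scheme = direction_scheme)
  sim$purity <- purity
  sim$bulk <- emit_bulk(sim, purity = purity, bin_noise_sd = bin_noise_sd,
                        n_cells = n_cells)
  sim
}

#' Recovery experiment: does inferred CNH match the input heterogeneity?
#'
#' For every combination of input heterogeneity `h` and purity, simulates
#' `replicates` tumour populations, infers CNH from each bulk profile, and
#' tabulates the results. Accurate recovery means the per-condition mean of
#' inferred CNH tracks `h` irrespective of purity.
#'
#' @param h_values input heterogeneities.
#' @param purity_values purities.
#' @param replicates populations per condition (default 100).
#' @param n_segments template size per population.
#' @param seed master seed; the full table is deterministic per seed.
#' @param grid [cnh_grid()] used for inference.
#' @param n_cells,bin_noise_sd passed to [emit_bulk()].
#' @param direction_scheme passed to [introduce_heterogeneity()].
#' @return a data frame (class `cnh_recovery`) with columns `h`, `purity`,
#'   `replicate`, `truth_h`, `cnh`, `best_purity`, `best_ploidy`. Use
#'   [summary.cnh_recovery()] for per-condition means and sds.
#' @export
recovery_experiment <- function(h_values, purity_values, replicates = 100,
                                n_segments = 30, seed = NULL,
                                grid = cnh_grid(), n_cells = Inf,
                                bin_noise_sd = 0,
                                direction_scheme =
                                  c("per_segment_single_direction",
                                    "per_cell_independent")) {
  direction_scheme <- match.arg(direction_scheme)
  if (!length(h_values) || !length(purity_values))
    stop_cnh("h_values and purity_values must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(h_values) * length(purity_values) *
                   replicates)
  k <- 0L
  for (h in h_values) for (a in purity_values) for (rep_i in
                                                    seq_len(replicates)) {
    sim <- simulate_tumour(n_segments = n_segments, h = h, purity = a,
                           n_cells = n_cells, bin_noise_sd = bin_noise_sd,
                           direction_scheme = direction_scheme)
    fit <- cnh(sim$bulk, grid = grid)
    k <- k + 1L
    rows[[k]] <- data.frame(h = h, purity = a, replicate = rep_i,
                            truth_h = sim$truth_h, cnh = fit$cnh,
                            best_purity = fit$purity,
                            best_ploidy = fit$ploidy)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cnh_recovery", "data.frame")
  out
}

#' Summarize a recovery experiment per condition
#'
#' @param object a [recovery_experiment()] result.
#' @param ... ignored.
#' @return data frame with per-(h, purity) mean and sd of inferred CNH and
#'   the mean bias `mean(cnh) - h`.
#' @export
summary.cnh_recovery <- function(object, ...) {
  agg <- stats::aggregate(cnh ~ h + purity, data = object,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x)))
  out <- data.frame(h = agg$h, purity = agg$purity,
                    mean_cnh = agg$cnh[, "mean"], sd_cnh = agg$cnh[, "sd"])
  out$bias <- out$mean_cnh - out$h
  out[order(out$h, out$purity), ]
}
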