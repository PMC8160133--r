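#' Standard deviation of a segment mean
#'
#' The precision of a segment's copy-number estimate is quantified by the
#' standard deviation of the mean of its probe/bin values:
#' `sigma_mu = s / sqrt(n)`, with `s` the sample standard deviation (n - 1
#' denominator) and `n` the bin count. Computed on linear-scale values by
#' default, matching the scale CNH operates on; set `log2 = TRUE` for
#' log-ratio bins.
#'
#' @param bin_values values of the bins in one segment (>= 2).
#' @param log2 bins are log2 ratios; converted to linear before estimation.
#' @return sigma_mu, a non-negative scalar.
#' @export
segment_sigma_mu <- function(bin_values, log2 = FALSE) {
  if (length(bin_values) < 2L)
    stop_cnh("sigma_mu undefined for fewer than 2 bins")
  if (log2) bin_values <- 2^bin_values
  stats::sd(bin_values) / sqrt(length(bin_values))
}

noise_report <- function(per_segment_sigma_mu, sample_mean_sigma_mu,
                         removed_segments, removed_fraction_of_genome,
                         sample_pass) {
  structure(list(per_segment_sigma_mu = per_segment_sigma_mu,
                 sample_mean_sigma_mu = sample_mean_sigma_mu,
                 removed_segments = removed_segments,
                 removed_fraction_of_genome = removed_fraction_of_genome,
                 sample_pass = sample_pass),
            class = "cnh_noise_report")
}

#' @export
print.cnh_noise_report <- function(x, ...) {
  cat("Noise report:\n",
      "  <sigma_mu> (width-weighted): ",
      format(x$sample_mean_sigma_mu, digits = 4),
      "  sample pass: ", x$sample_pass, "\n",
      "  segments removed: ", length(x$removed_segments),
      " (", format(100 * x$removed_fraction_of_genome, digits = 3),
      "% of genome width)\n", sep = "")
  invisible(x)
}

#' Remove noisy segments from a profile
#'
#' Drops segments whose standard deviation of the mean exceeds `threshold`
#' (default 0.01, the cut used for SNP6-array cohorts, removing on average
#' a few percent of the genome) and re-normalizes the remaining profile so
#' the dropped segments no longer influence the mean used by CNH inference.
#'
#' Segments without a `sigma_mu` estimate (e.g. SEG files carrying only
#' probe counts) pass with a warning by default; `strict = TRUE` rejects
#' them instead.
#'
#' @param profile a [segmented_profile()] with a `sigma_mu` column.
#' @param threshold sigma_mu cut; segments strictly above it are removed.
#' @param strict reject segments with missing sigma_mu.
#' @return a list with `profile` (filtered, re-normalized) and `report`
#'   (a `cnh_noise_report` with the removed width fraction and the
#'   width-weighted mean sigma_mu of the input).
#' @export
filter_segments <- function(profile, threshold = 0.01, strict = FALSE) {
  profile <- as_segmented_profile(profile)
  if (!"sigma_mu" %in% names(profile))
    stop_cnh("profile carries no sigma_mu column; see segments_from_bins()")
  sig <- profile$sigma_mu
  if (anyNA(sig)) {
    if (strict)
      stop_cnh(sum(is.na(sig)), " segment(s) lack a sigma_mu estimate")
    warning(sum(is.na(sig)), " segment(s) lack a sigma_mu estimate and ",
            "pass the filter by default", call. = FALSE)
  }
  drop <- !is.na(sig) & sig > threshold
  if (all(drop))
    stop_cnh("all segments exceed the sigma_mu threshold ", threshold)
  total_w <- sum(profile$width)
  removed_fraction <- sum(profile$width[drop]) / total_w
  mean_sig <- weighted_mean2(ifelse(is.na(sig), 0, sig), profile$width)
  kept <- profile[!drop, , drop = FALSE]
  kept <- segmented_profile(kept$chrom, kept$start, kept$end, kept$value,
                            sample_id = attr(profile, "sample_id"),
                            n_bins = kept[["n_bins"]],
                            sigma_mu = kept[["sigma_mu"]])
  list(profile = normalize_profile(kept),
       report = noise_report(sig, mean_sig, which(drop), removed_fraction,
                             sample_pass = NA))
}

#' Filter noisy samples from a cohort
#'
#' Computes each sample's width-weighted mean sigma_mu,
#' `<sigma_mu> = sum(w_i sigma_mu_i) / sum(w_i)`, and excludes samples
#' above `threshold` (default 0.006, the cohort-level cut).
#'
#' @param profiles list of [segmented_profile()] objects with `sigma_mu`.
#' @param threshold `<sigma_mu>` cut; samples strictly above are excluded.
#' @return a list with `passing` (the retained profiles) and `report`
#'   (data frame: sample_id, mean_sigma_mu, n_segments, pass). An empty
#'   pass-set is allowed and reported, not an error.
#' @export
filter_samples <- function(profiles, threshold = 0.006) {
  if (is_segmented_profile(profiles)) profiles <- list(profiles)
  stats <- lapply(profiles, function(p) {
    p <- as_segmented_profile(p)
    if (!"sigma_mu" %in% names(p))
      stop_cnh("profile '", attr(p, "sample_id"),
               "' carries no sigma_mu column")
    sig <- p$sigma_mu
    if (anyNA(sig))
      warning("sample '", attr(p, "sample_id"), "': segments with missing ",
              "sigma_mu contribute 0 to <sigma_mu>", call. = FALSE)
    data.frame(sample_id = attr(p, "sample_id"),
               mean_sigma_mu = weighted_mean2(ifelse(is.na(sig), 0, sig),
                                              p$width),
               n_segments = nrow(p), stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, stats)
  report$pass <- report$mean_sigma_mu <= threshold
  list(passing = profiles[report$pass], report = report)
}
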