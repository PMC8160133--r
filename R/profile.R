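#' Construct a segmented copy-number profile
#'
#' A segmented profile is the sole input to CNH inference: an ordered set of
#' genomic segments, each with a width and a linear-scale relative copy
#' number. Coordinates follow the SEG convention (1-based, inclusive), so a
#' segment's width is `end - start + 1`.
#'
#' @param chrom chromosome labels.
#' @param start,end 1-based inclusive genomic coordinates (base pairs).
#' @param value linear-scale relative copy number per segment (finite,
#'   non-negative).
#' @param sample_id sample label.
#' @param n_bins optional probe/bin count supporting each segment.
#' @param sigma_mu optional standard deviation of the segment mean (same
#'   units as `value`); see [segment_sigma_mu()].
#' @return An object of class `segmented_profile`: a data frame with columns
#'   `chrom`, `start`, `end`, `width`, `value` (plus `n_bins`/`sigma_mu`
#'   when given) and attributes `sample_id` and `normalized`. The
#'   `normalized` flag is `TRUE` when the width-weighted mean of `value`
#'   is 1 within 1e-9.
#' @seealso [normalize_profile()], [read_segments()], [cnh()]
#' @export
segmented_profile <- function(chrom, start, end, value, sample_id = "sample",
                              n_bins = NULL, sigma_mu = NULL) {
  n <- length(value)
  if (n < 1L) stop_cnh("a segmented profile needs at least one segment")
  chrom <- as.character(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  start <- as.numeric(start)
  end <- as.numeric(end)
  value <- as.numeric(value)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop_cnh("chrom, start, end and value must have equal length")
  bad <- which(!is.finite(value) | value < 0)
  if (length(bad))
    stop_cnh("segment value must be finite and >= 0 (segment ",
             bad[1L], ": ", value[bad[1L]], ")")
  width <- end - start + 1
  bad <- which(!is.finite(width) | width <= 0)
  if (length(bad))
    stop_cnh("segment width must be positive (segment ", bad[1L],
             ": start=", start[bad[1L]], ", end=", end[bad[1L]], ")")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   width = width, value = value,
                   stringsAsFactors = FALSE)
  if (!is.null(n_bins)) df$n_bins <- as.numeric(n_bins)
  if (!is.null(sigma_mu)) {
    sigma_mu <- as.numeric(sigma_mu)
    if (any(sigma_mu < 0, na.rm = TRUE))
      stop_cnh("sigma_mu must be >= 0")
    df$sigma_mu <- sigma_mu
  }
  ord <- order(df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  # non-overlap within each chromosome
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    if (length(i) > 1L) {
      ov <- which(df$start[i][-1L] <= df$end[i][-length(i)])
      if (length(ov))
        stop_cnh("overlapping segments on ", ch, " (rows ", i[ov[1L]],
                 " and ", i[ov[1L]] + 1L, ")")
    }
  }
  attr(df, "sample_id") <- as.character(sample_id)
  attr(df, "normalized") <-
    abs(weighted_mean2(df$value, df$width) - 1) <= 1e-9
  class(df) <- c("segmented_profile", "data.frame")
  df
}

#' @export
print.segmented_profile <- function(x, ...) {
  cat("Segmented copy-number profile: ", attr(x, "sample_id"),
      "\n  ", nrow(x), " segments on ", length(unique(x$chrom)),
      " chromosome(s); total width ", format(sum(x$width), big.mark = ","),
      " bp\n  width-weighted mean value ",
      format(weighted_mean2(x$value, x$width), digits = 6),
      if (isTRUE(attr(x, "normalized"))) " (normalized)" else "",
      "\n", sep = "")
  NextMethod()
}

is_segmented_profile <- function(x) inherits(x, "segmented_profile")

#' Coerce to a segmented profile
#'
#' Accepts a `segmented_profile` (returned unchanged) or a data frame with
#' columns `chrom`, `start`, `end`, `value` (optional `n_bins`, `sigma_mu`).
#'
#' @param x object to coerce.
#' @param sample_id sample label used when `x` carries none.
#' @return a `segmented_profile`.
#' @export
as_segmented_profile <- function(x, sample_id = "sample") {
  if (is_segmented_profile(x)) return(x)
  if (!is.data.frame(x))
    stop_cnh("cannot coerce a ", class(x)[1L], " to a segmented profile")
  need <- c("chrom", "start", "end", "value")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_cnh("missing columns: ", paste(miss, collapse = ", "))
  segmented_profile(x$chrom, x$start, x$end, x$value,
                    sample_id = sample_id,
                    n_bins = x[["n_bins"]], sigma_mu = x[["sigma_mu"]])
}

#' Normalize a profile to width-weighted mean copy number 1
#'
#' Divides every segment value by the width-weighted mean value, the first
#' step of CNH inference. Normalization is idempotent and invariant to
#' rescaling of the input.
#'
#' @param profile a [segmented_profile()] (or coercible data frame).
#' @return the profile with values divided by the width-weighted mean and
#'   `normalized = TRUE`.
#' @export
normalize_profile <- function(profile) {
  profile <- as_segmented_profile(profile)
  m <- weighted_mean2(profile$value, profile$width)
  if (!is.finite(m) || m <= 0)
    stop_cnh("normalization undefined: width-weighted mean value is ", m)
  profile$value <- profile$value / m
  attr(profile, "normalized") <- TRUE
  profile
}
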