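#' A set of absolute copy-number profiles from one sample
#'
#' Holds the per-unit absolute karyotypes used by the direct heterogeneity
#' estimators: single cells (integer copies) or tumour regions
#' (bulk-derived, possibly fractional copies that are rounded before modal
#' counting). Units may have different breakpoints; they are harmonized by
#' [harmonize_breakpoints()].
#'
#' @param units named list of data frames, one per cell/region, each with
#'   columns `chrom`, `start`, `end`, `copy` (sorted, non-overlapping
#'   within a chromosome).
#' @param unit_kind `"cell"` or `"region"`.
#' @param sample_id sample label.
#' @return an object of class `karyotype_set`.
#' @export
karyotype_set <- function(units, unit_kind = c("cell", "region"),
                          sample_id = "sample") {
  unit_kind <- match.arg(unit_kind)
  if (length(units) < 2L) stop_cnh("need at least 2 units")
  if (is.null(names(units)) || anyNA(names(units)) ||
      any(names(units) == ""))
    names(units) <- sprintf("%s_%d", unit_kind, seq_along(units))
  units <- lapply(units, function(u) {
    need <- c("chrom", "start", "end", "copy")
    if (!all(need %in% names(u)))
      stop_cnh("each unit needs columns ", paste(need, collapse = ", "))
    u <- u[order(u$chrom, u$start), need, drop = FALSE]
    for (ch in unique(u$chrom)) {
      i <- which(u$chrom == ch)
      if (length(i) > 1L &&
          any(u$start[i][-1L] <= u$end[i][-length(i)]))
        stop_cnh("overlapping segments on ", ch, " in a unit")
    }
    if (any(u$end < u$start)) stop_cnh("segment with end < start in a unit")
    rownames(u) <- NULL
    u
  })
  structure(list(units = units, unit_kind = unit_kind,
                 sample_id = sample_id),
            class = "karyotype_set")
}

#' @export
print.karyotype_set <- function(x, ...) {
  cat("Karyotype set: ", x$sample_id, " (", length(x$units), " ",
      x$unit_kind, "s)\n", sep = "")
  invisible(x)
}

#' Harmonize unit breakpoints onto one minimal segment set
#'
#' Finds the minimum consecutive set of segments that jointly tiles the
#' genome territory covered by every unit: the union of all unit
#' breakpoints, restricted to the intersection of the units' coverage, with
#' adjacent pieces merged whenever no unit places a breakpoint between them
#' (minimality). Territory not covered by every unit is dropped and its
#' width reported.
#'
#' @param set a [karyotype_set()].
#' @return a list of class `harmonized_karyotypes` with `segments` (data
#'   frame `chrom`, `start`, `end`, `width`), `values` (units x segments
#'   matrix of copies), `unit_kind`, `sample_id`, `shared_width`, and
#'   `dropped_width` (width covered by at least one but not all units).
#' @export
harmonize_breakpoints <- function(set) {
  if (!inherits(set, "karyotype_set")) stop_cnh("set must be a karyotype_set")
  units <- set$units
  nu <- length(units)
  chroms <- sort(Reduce(intersect, lapply(units, function(u)
    unique(u$chrom))))
  union_width <- local({
    all_ch <- unique(unlist(lapply(units, function(u) u$chrom)))
    sum(vapply(all_ch, function(ch) {
      iv <- do.call(rbind, lapply(units, function(u)
        u[u$chrom == ch, c("start", "end")]))
      iv <- iv[order(iv$start), , drop = FALSE]
      tot <- 0; cur_s <- NA; cur_e <- -Inf
      for (i in seq_len(nrow(iv))) {
        if (is.na(cur_s) || iv$start[i] > cur_e + 1) {
          if (!is.na(cur_s)) tot <- tot + cur_e - cur_s + 1
          cur_s <- iv$start[i]; cur_e <- iv$end[i]
        } else cur_e <- max(cur_e, iv$end[i])
      }
      if (!is.na(cur_s)) tot <- tot + cur_e - cur_s + 1
      tot
    }, numeric(1L)))
  })
  seg_chrom <- character(); seg_start <- numeric(); seg_end <- numeric()
  vals <- NULL
  for (ch in chroms) {
    subs <- lapply(units, function(u) u[u$chrom == ch, , drop = FALSE])
    bounds <- sort(unique(unlist(lapply(subs, function(s)
      c(s$start, s$end + 1)))))
    if (length(bounds) < 2L) next
    a_start <- bounds[-length(bounds)]
    a_end <- bounds[-1L] - 1
    # per unit: covering source-segment index of each atom (NA = uncovered)
    src <- vapply(subs, function(s) {
      k <- findInterval(a_start, s$start)
      ok <- k >= 1L & s$end[pmax(k, 1L)] >= a_end & s$start[pmax(k, 1L)] <=
        a_start
      ifelse(ok, k, NA_integer_)
    }, integer(length(a_start)))
    src <- matrix(src, nrow = length(a_start), ncol = nu)
    covered <- rowSums(is.na(src)) == 0L
    if (!any(covered)) next
    a_start <- a_start[covered]; a_end <- a_end[covered]
    src <- src[covered, , drop = FALSE]
    # merge adjacent atoms whose source segment is identical in every unit
    # (and which are contiguous): these carry no breakpoint from any unit
    new_group <- c(TRUE, vapply(seq_len(length(a_start))[-1L], function(i) {
      a_start[i] != a_end[i - 1L] + 1 ||
        any(src[i, ] != src[i - 1L, ])
    }, logical(1L)))
    first <- which(new_group)
    last <- c(first[-1L] - 1L, length(a_end))
    g_start <- a_start[first]
    g_end <- a_end[last]
    v <- vapply(seq_len(nu), function(j)
      subs[[j]]$copy[src[first, j]], numeric(length(first)))
    v <- matrix(v, nrow = length(first), ncol = nu)
    seg_chrom <- c(seg_chrom, rep(ch, length(first)))
    seg_start <- c(seg_start, g_start)
    seg_end <- c(seg_end, unname(g_end))
    vals <- rbind(vals, v)
  }
  if (!length(seg_start))
    stop_cnh("units share no genome territory; cannot harmonize")
  segments <- data.frame(chrom = seg_chrom, start = seg_start,
                         end = seg_end, width = seg_end - seg_start + 1,
                         stringsAsFactors = FALSE)
  values <- t(vals)
  rownames(values) <- names(units)
  shared <- sum(segments$width)
  structure(list(segments = segments, values = values,
                 unit_kind = set$unit_kind, sample_id = set$sample_id,
                 shared_width = shared,
                 dropped_width = union_width - shared),
            class = "harmonized_karyotypes")
}

#' Most frequent integer copy number
#'
#' @param values per-unit copies of one harmonized segment (>= 2 values).
#' @param rounding round values (half away from zero) before counting —
#'   used for region profiles, whose bulk-derived copies are fractional.
#' @return the modal integer; ties are broken to the smaller integer.
#' @export
modal_copy <- function(values, rounding = FALSE) {
  if (length(values) < 2L) stop_cnh("need at least 2 values")
  if (rounding) values <- round_half_away(values)
  if (any(abs(values - round(values)) > 1e-9))
    stop_cnh("non-integer copy numbers; use rounding = TRUE")
  counts <- table(values)
  modes <- as.numeric(names(counts)[counts == max(counts)])
  min(modes)
}

direct_cnh_core <- function(harm, rounding) {
  v <- harm$values
  if (rounding) v <- round_half_away(v)
  het <- vapply(seq_len(ncol(v)), function(s) {
    m <- modal_copy(v[, s])
    mean(v[, s] != m)
  }, numeric(1L))
  weighted_mean2(het, harm$segments$width)
}

#' CNH measured directly from single-cell karyotypes
#'
#' The per-segment local heterogeneity is the fraction of cells whose
#' absolute copy number differs from the most frequent one; direct CNH is
#' the width-weighted mean of local heterogeneity over the harmonized
#' segments. It lies in `[0, 1 - 1/n_units]` and is zero iff all cells
#' agree everywhere.
#'
#' @param set a [karyotype_set()] (or an already harmonized set).
#' @return the direct CNH value (scalar).
#' @export
direct_cnh <- function(set) {
  harm <- if (inherits(set, "harmonized_karyotypes")) set
          else harmonize_breakpoints(set)
  direct_cnh_core(harm, rounding = FALSE)
}

#' CNH across multiple tumour regions
#'
#' Identical to [direct_cnh()] except that the bulk-derived absolute copy
#' numbers of each region are rounded (half away from zero) before the
#' modal count, since region profiles are continuous.
#'
#' @param regions a [karyotype_set()] of region profiles.
#' @return the multi-region CNH value (scalar).
#' @export
multiregion_cnh <- function(regions) {
  harm <- if (inherits(regions, "harmonized_karyotypes")) regions
          else harmonize_breakpoints(regions)
  direct_cnh_core(harm, rounding = TRUE)
}

#' Pool single cells into a quasi-bulk profile
#'
#' Averages the units' copy numbers per harmonized segment with equal
#' weight per cell (each cell contributing the same amount of signal),
#' optionally adds Gaussian measurement noise, and normalizes — producing a
#' bulk-like relative profile suitable for [cnh()].
#'
#' @param set a [karyotype_set()].
#' @param noise_sd standard deviation of additive Gaussian noise (0 = none).
#' @param seed optional seed for the noise.
#' @return a normalized [segmented_profile()].
#' @export
quasi_bulk <- function(set, noise_sd = 0, seed = NULL) {
  harm <- if (inherits(set, "harmonized_karyotypes")) set
          else harmonize_breakpoints(set)
  if (!is.null(seed)) set.seed(seed)
  v <- colMeans(harm$values)
  if (noise_sd > 0)
    v <- pmax(v + stats::rnorm(length(v), 0, noise_sd), 0)
  normalize_profile(segmented_profile(
    harm$segments$chrom, harm$segments$start, harm$segments$end, v,
    sample_id = paste0(harm$sample_id, "_quasibulk")))
}

#' Patient-level CNH as the mean over region profiles
#'
#' Each region of a multi-region experiment is itself a bulk sample, so CNH
#' can be inferred per region and averaged (unweighted) to one value per
#' patient.
#'
#' @param per_region_profiles list of relative bulk [segmented_profile()]s
#'   (one per region) or a single profile.
#' @param ... passed to [cnh()] (e.g. `grid`).
#' @return the mean CNH over regions (scalar).
#' @export
mean_region_cnh <- function(per_region_profiles, ...) {
  if (is_segmented_profile(per_region_profiles))
    per_region_profiles <- list(per_region_profiles)
  if (!length(per_region_profiles)) stop_cnh("need at least one region")
  mean(vapply(per_region_profiles,
              function(p) cnh(p, ...)$cnh, numeric(1L)))
}

#' Sample single cells from a simulated tumour population
#'
#' Draws `n_cells` malignant cells from a [introduce_heterogeneity()]
#' population: in each cell, segment i is altered with probability `f_i`
#' (by the segment's shared direction, or by an independent +/-1 under the
#' per-cell scheme). The result feeds [direct_cnh()] and [quasi_bulk()].
#'
#' @param sim a `simulated_tumour`.
#' @param n_cells number of cells to draw (>= 2).
#' @param seed optional seed.
#' @return a [karyotype_set()] of integer single-cell karyotypes.
#' @export
sample_cells <- function(sim, n_cells, seed = NULL) {
  if (!inherits(sim, "simulated_tumour"))
    stop_cnh("sim must be a simulated_tumour")
  if (n_cells < 2L) stop_cnh("need at least 2 cells")
  if (!is.null(seed)) set.seed(seed)
  tmpl <- sim$template
  n <- nrow(tmpl)
  units <- lapply(seq_len(n_cells), function(cell) {
    altered <- stats::runif(n) < sim$f
    dir <- if (sim$scheme == "per_segment_single_direction") sim$direction
           else sample(c(-1L, 1L), n, replace = TRUE)
    data.frame(chrom = tmpl$chrom, start = tmpl$start, end = tmpl$end,
               copy = tmpl$copy + ifelse(altered, dir, 0L),
               stringsAsFactors = FALSE)
  })
  karyotype_set(units, unit_kind = "cell",
                sample_id = sprintf("sim_h%g_cells", sim$input_h))
}
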