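#' Read SEG-style segmented copy-number files
#'
#' Reads a tab-separated table with a header and columns for sample,
#' chromosome, start, end, optional probe count and a segment value, the
#' dialect written by most segmentation pipelines (e.g. TCGA SNP6 SEG
#' files). Column names are matched case-insensitively against the usual
#' aliases (`Sample`/`ID`, `Chromosome`/`chrom`, `Start`/`loc.start`,
#' `End`/`loc.end`, `Num_Probes`/`num.mark`, `Segment_Mean`/`value`).
#'
#' @param path file to read.
#' @param dialect `"log2"` (values are log2 ratios; converted to linear by
#'   `2^x`) or `"linear"` (values already linear relative copy numbers).
#'   Never auto-detected; log2 is the TCGA convention and the default.
#' @param sample_column optional name of the sample-identifier column; by
#'   default the first column matching a known alias, else all rows are one
#'   sample.
#' @param drop_sex drop chrX/chrY (and X/Y, 23/24) segments; default keeps
#'   all chromosomes.
#' @return a named list of [segmented_profile()] objects, one per distinct
#'   sample identifier, in order of first appearance.
#' @export
read_segments <- function(path, dialect = c("log2", "linear"),
                          sample_column = NULL, drop_sex = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_cnh("cannot read '", path, "'")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L)
    stop_cnh("'", path, "' contains no data rows")
  pick <- function(aliases, what, required = TRUE) {
    hit <- which(tolower(names(tab)) %in% aliases)
    if (!length(hit)) {
      if (required)
        stop_cnh("'", path, "': no ", what, " column (looked for ",
                 paste(aliases, collapse = "/"), ")")
      return(NA_integer_)
    }
    hit[1L]
  }
  i_chr <- pick(c("chromosome", "chrom", "chr"), "chromosome")
  i_sta <- pick(c("start", "loc.start", "start.pos"), "start")
  i_end <- pick(c("end", "loc.end", "end.pos", "stop"), "end")
  i_val <- pick(c("segment_mean", "seg.mean", "value", "mean", "log2ratio",
                  "copy_number"), "segment value")
  i_np <- pick(c("num_probes", "num.mark", "n_probes", "probes", "n_bins"),
               "probe count", required = FALSE)
  if (!is.null(sample_column)) {
    i_smp <- which(names(tab) == sample_column)
    if (!length(i_smp))
      stop_cnh("'", path, "': no column named '", sample_column, "'")
    i_smp <- i_smp[1L]
  } else {
    i_smp <- pick(c("sample", "sample_id", "id"), "sample", required = FALSE)
  }

  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(x) & !is.na(tab[[col]]) & tab[[col]] != "NA")
    if (length(bad))
      stop_cnh("'", path, "' row ", bad[1L], ": non-numeric ", what,
               " '", tab[[col]][bad[1L]], "'")
    bad <- which(is.na(x))
    if (length(bad))
      stop_cnh("'", path, "' row ", bad[1L], ": missing ", what)
    x
  }
  start <- num(i_sta, "start")
  end <- num(i_end, "end")
  raw <- num(i_val, "segment value")
  value <- switch(dialect, log2 = 2^raw, linear = raw)
  bad <- which(value < 0)
  if (length(bad))
    stop_cnh("'", path, "' row ", bad[1L],
             ": negative linear copy number ", value[bad[1L]])
  chrom <- as.character(tab[[i_chr]])
  samples <- if (is.na(i_smp)) rep("sample", nrow(tab))
             else as.character(tab[[i_smp]])
  n_bins <- if (is.na(i_np)) NULL else num(i_np, "probe count")

  if (drop_sex) {
    sex <- grepl("^(chr)?(x|y|23|24)$", chrom, ignore.case = TRUE)
    if (all(sex)) stop_cnh("'", path, "': all segments are sex-chromosomal")
    chrom <- chrom[!sex]; start <- start[!sex]; end <- end[!sex]
    value <- value[!sex]; samples <- samples[!sex]
    if (!is.null(n_bins)) n_bins <- n_bins[!sex]
  }

  out <- lapply(unique(samples), function(s) {
    i <- which(samples == s)
    segmented_profile(chrom[i], start[i], end[i], value[i], sample_id = s,
                      n_bins = if (is.null(n_bins)) NULL else n_bins[i])
  })
  names(out) <- unique(samples)
  out
}

#' Write segmented profiles as a SEG-style file
#'
#' Writes `Sample`, `Chromosome`, `Start`, `End`, optional `Num_Probes`, and
#' `Segment_Mean` tab-separated; reading the file back with the same dialect
#' reproduces the values to 1e-12.
#'
#' @param profiles a [segmented_profile()] or a list of them.
#' @param path output file.
#' @param dialect `"log2"` (values written as `log2(x)`) or `"linear"`.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profiles, path, dialect = c("log2", "linear")) {
  dialect <- match.arg(dialect)
  if (is_segmented_profile(profiles)) profiles <- list(profiles)
  any_bins <- any(vapply(profiles, function(p) "n_bins" %in% names(p),
                         logical(1L)))
  rows <- lapply(profiles, function(p) {
    p <- as_segmented_profile(p)
    v <- switch(dialect, log2 = log2(p$value), linear = p$value)
    d <- data.frame(Sample = attr(p, "sample_id"), Chromosome = p$chrom,
                    Start = p$start, End = p$end, stringsAsFactors = FALSE)
    if (any_bins) d$Num_Probes <- if ("n_bins" %in% names(p)) p$n_bins else NA
    d$Segment_Mean <- v
    d
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(Sample = character(), Chromosome = character(),
               Start = numeric(), End = numeric(),
               Segment_Mean = numeric(), stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(format(out, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_cnh("cannot write '", path, "': ",
                            conditionMessage(ok))
  invisible(path)
}

#' Aggregate bin-level values into a segmented profile
#'
#' Given per-bin copy-number values and the segment boundaries produced by
#' an upstream segmentation, computes per-segment means together with the
#' bin count and the standard deviation of the segment mean
#' ([segment_sigma_mu()]) that the noise filters consume.
#'
#' @param bins data frame with columns `chrom`, `start`, `end`, `value`
#'   (linear scale).
#' @param breakpoints data frame with columns `chrom`, `start`, `end`
#'   defining the segments; every bin must fall entirely within one segment.
#' @param sample_id sample label for the result.
#' @return a [segmented_profile()] with `value` = mean of member-bin values,
#'   `n_bins`, and `sigma_mu` per segment.
#' @export
segments_from_bins <- function(bins, breakpoints, sample_id = "sample") {
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(bins)))
    stop_cnh("bins need columns ", paste(need, collapse = ", "))
  if (!all(c("chrom", "start", "end") %in% names(breakpoints)))
    stop_cnh("breakpoints need columns chrom, start, end")
  ns <- nrow(breakpoints)
  idx <- rep(NA_integer_, nrow(bins))
  for (k in seq_len(ns)) {
    hit <- bins$chrom == breakpoints$chrom[k] &
      bins$start >= breakpoints$start[k] & bins$end <= breakpoints$end[k]
    clash <- which(hit & !is.na(idx))
    if (length(clash))
      stop_cnh("bin ", clash[1L], " falls in more than one segment")
    idx[hit] <- k
  }
  orphan <- which(is.na(idx))
  if (length(orphan))
    stop_cnh("bin ", orphan[1L], " (", bins$chrom[orphan[1L]], ":",
             bins$start[orphan[1L]], ") is not inside any segment")
  counts <- tabulate(idx, nbins = ns)
  if (any(counts == 0L))
    stop_cnh("segment ", which(counts == 0L)[1L], " contains no bins")
  value <- vapply(seq_len(ns), function(k) mean(bins$value[idx == k]),
                  numeric(1L))
  sig <- vapply(seq_len(ns), function(k) {
    v <- bins$value[idx == k]
    if (length(v) < 2L) NA_real_ else segment_sigma_mu(v)
  }, numeric(1L))
  segmented_profile(breakpoints$chrom, breakpoints$start, breakpoints$end,
                    value, sample_id = sample_id, n_bins = counts,
                    sigma_mu = sig)
}
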