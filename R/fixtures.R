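#' Generate the synthetic test battery
#'
#' Writes a seed-deterministic set of small plain-text fixtures exercising
#' every estimator: a flat diploid profile (CNH 0), simulated tumours over a
#' small (h, purity) factorial, a bin-level table with its segmentation for
#' the noise filters, a single-cell karyotype set, and a multi-region set.
#' A `manifest.tsv` lists every file with the parameters that generated it.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @return the manifest data frame, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_cnh("cannot write to '", out_dir, "'")
  set.seed(seed)
  manifest <- list()
  note <- function(file, params)
    manifest[[length(manifest) + 1L]] <<-
      data.frame(file = file, params = params, stringsAsFactors = FALSE)

  # flat diploid genome: four segments, all relative value 1
  flat <- segmented_profile(rep("chr1", 4),
                            c(1, 1e6 + 1, 2e6 + 1, 3e6 + 1),
                            c(1e6, 2e6, 3e6, 4e6), rep(1, 4),
                            sample_id = "flat_diploid")
  write_segments(flat, file.path(out_dir, "flat_diploid.seg"),
                 dialect = "linear")
  note("flat_diploid.seg", "4 segments, value 1, linear scale")

  # simulated tumours across (h, purity)
  for (h in c(0, 0.1)) for (a in c(1, 0.6)) {
    sim <- simulate_tumour(n_segments = 30, h = h, purity = a)
    f <- sprintf("sim_h%s_a%s.seg", format(h), format(a))
    write_segments(sim$bulk, file.path(out_dir, f), dialect = "linear")
    note(f, sprintf("h=%g purity=%g segments=30 analytic truth_h=%.5f",
                    h, a, sim$truth_h))
  }

  # bin-level profile for the noise filters: 3 segments x 40 bins
  bp <- data.frame(chrom = "chr1", start = c(1, 4001, 8001),
                   end = c(4000, 8000, 12000))
  means <- c(1, 1.5, 0.5)
  sds <- c(0.02, 0.02, 0.12)  # third segment fails the 0.01 sigma_mu cut
  bins <- do.call(rbind, lapply(1:3, function(k) {
    s <- seq(bp$start[k], bp$end[k] - 99, by = 100)
    data.frame(chrom = "chr1", start = s, end = s + 99,
               value = pmax(stats::rnorm(length(s), means[k], sds[k]), 0))
  }))
  utils::write.table(bins, file.path(out_dir, "bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bp, file.path(out_dir, "breakpoints.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("bins.tsv", "3 segments x 40 bins, sd 0.02/0.02/0.12")
  note("breakpoints.tsv", "segmentation of bins.tsv")

  # single-cell karyotypes from a simulated population
  sim <- simulate_tumour(n_segments = 12, h = 0.15, purity = 1)
  cells <- sample_cells(sim, 20)
  cell_tab <- do.call(rbind, lapply(names(cells$units), function(u)
    cbind(unit_id = u, cells$units[[u]])))
  utils::write.table(cell_tab, file.path(out_dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("cells.tsv", sprintf("20 cells, 12 segments, h=0.15 truth_h=%.5f",
                            sim$truth_h))

  # multi-region set: 4 regions with fractional copies around integers
  tmpl <- generate_segment_template(10)
  regions <- lapply(1:4, function(i) {
    drift <- stats::rnorm(nrow(tmpl), 0, 0.1)
    jump <- ifelse(stats::runif(nrow(tmpl)) < 0.2,
                   sample(c(-1, 1), nrow(tmpl), replace = TRUE), 0)
    data.frame(chrom = tmpl$chrom, start = tmpl$start, end = tmpl$end,
               copy = pmax(tmpl$copy + jump + drift, 0))
  })
  region_tab <- do.call(rbind, lapply(seq_along(regions), function(i)
    cbind(unit_id = sprintf("region_%d", i), regions[[i]])))
  utils::write.table(region_tab, file.path(out_dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("regions.tsv", "4 regions, 10 segments, 20% subclonal jumps")

  manifest <- do.call(rbind, manifest)
  manifest$seed <- seed
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
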