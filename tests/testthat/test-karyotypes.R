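unit_df <- function(start, end, copy, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, copy = copy)
}

test_that("breakpoint harmonization refines to the union of breakpoints", {
  # identical breakpoints: harmonized set identical to either unit
  u <- unit_df(c(1, 101), c(100, 250), c(2, 3))
  set <- karyotype_set(list(a = u, b = u), "cell")
  h <- harmonize_breakpoints(set)
  expect_equal(h$segments$start, c(1, 101))
  expect_equal(h$segments$end, c(100, 250))
  expect_equal(h$dropped_width, 0)
  # one unit splits the other's single segment
  set2 <- karyotype_set(list(a = unit_df(1, 100, 2),
                             b = unit_df(c(1, 41), c(40, 100), c(2, 3))),
                        "cell")
  h2 <- harmonize_breakpoints(set2)
  expect_equal(h2$segments$start, c(1, 41))
  expect_equal(h2$segments$end, c(40, 100))
  expect_equal(unname(h2$values["a", ]), c(2, 2))
  expect_equal(unname(h2$values["b", ]), c(2, 3))
})

test_that("harmonization matches the sweep-line oracle on random sets", {
  set.seed(61)
  for (rep in 1:12) {
    n_units <- sample(3:5, 1)
    units <- lapply(seq_len(n_units), function(i) {
      cuts <- sort(sample(2:150, sample(2:6, 1)))
      start <- c(1, cuts)
      end <- c(cuts - 1, 200)
      # random right-trim so coverage differs between units
      if (runif(1) < 0.5) end[length(end)] <- 200 - sample(0:30, 1)
      unit_df(start, end, sample(0:5, length(start), replace = TRUE))
    })
    names(units) <- paste0("u", seq_len(n_units))
    h <- harmonize_breakpoints(karyotype_set(units, "cell"))
    o <- oracle_harmonize(units)
    expect_equal(h$segments$start, o$segments$start)
    expect_equal(h$segments$end, o$segments$end)
    expect_equal(unname(h$values), unname(t(o$values)))
    # minimality: every internal boundary is some unit's breakpoint
    internal <- h$segments$start[-1]
    unit_bp <- unlist(lapply(units, function(u) c(u$start, u$end + 1)))
    expect_true(all(internal %in% unit_bp))
  }
})

test_that("territory not covered by every unit is dropped and reported", {
  set <- karyotype_set(list(
    a = unit_df(1, 100, 2),
    b = unit_df(c(1, 151), c(120, 200), c(2, 3))), "cell")
  h <- harmonize_breakpoints(set)
  expect_equal(h$segments$end, 100)
  expect_equal(h$shared_width, 100)
  expect_equal(h$dropped_width, 200 - 30 - 100)
  # chromosomes absent from one unit are dropped entirely
  set2 <- karyotype_set(list(
    a = rbind(unit_df(1, 100, 2), unit_df(1, 50, 3, "chr2")),
    b = unit_df(1, 100, 2)), "cell")
  h2 <- harmonize_breakpoints(set2)
  expect_equal(unique(h2$segments$chrom), "chr1")
  expect_equal(h2$dropped_width, 50)
  expect_error(harmonize_breakpoints(karyotype_set(list(
    a = unit_df(1, 100, 2), b = unit_df(1, 50, 2, "chr2")), "cell")),
    "share no")
})

test_that("modal copy numbers follow the documented tie rule", {
  expect_equal(modal_copy(c(2, 2, 3)), 2)
  expect_equal(modal_copy(c(2, 2, 3, 3)), 2)   # tie to the smaller integer
  expect_equal(modal_copy(c(1.6, 2.4, 2.2), rounding = TRUE), 2)
  expect_equal(modal_copy(c(2.5, 2.5), rounding = TRUE), 3) # half away from 0
  expect_error(modal_copy(c(1.5, 2), rounding = FALSE), "non-integer")
  expect_error(modal_copy(2), "at least 2")
})

test_that("direct CNH is the width-weighted dissent fraction", {
  # all units identical: zero
  u <- unit_df(c(1, 101), c(100, 300), c(2, 4))
  expect_equal(direct_cnh(karyotype_set(list(u, u, u), "cell")), 0)
  # one dissenter of three on a single segment
  cells <- lapply(c(2, 2, 3), function(cp) unit_df(1, 100, cp))
  expect_equal(direct_cnh(karyotype_set(cells, "cell")), 1 / 3)
  # hand-weighted oracle: widths (4,3,2,1), dissent (0, 2, 5, 9) of 10
  # (maximal dissent is 9/10: the modal value is always attained by a unit)
  starts <- c(1, 5, 8, 10); ends <- c(4, 7, 9, 10)
  modal <- c(2, 2, 3, 1)
  cells <- lapply(1:10, function(i) {
    cp <- modal
    if (i <= 2) cp[2] <- 3
    if (i <= 5) cp[3] <- 4
    cp[4] <- modal[4] + i - 1  # ten distinct values; cell 1 is the mode
    unit_df(starts, ends, cp)
  })
  got <- direct_cnh(karyotype_set(cells, "cell"))
  expect_equal(got, (4 * 0 + 3 * 0.2 + 2 * 0.5 + 1 * 0.9) / 10)
  expect_equal(got, 0.25)
})

test_that("multi-region CNH rounds before modal counting", {
  regions <- lapply(c(2.1, 1.9, 3.2), function(cp) unit_df(1, 100, cp))
  expect_equal(multiregion_cnh(karyotype_set(regions, "region")), 1 / 3)
  flat <- lapply(1:3, function(i) unit_df(c(1, 51), c(50, 100), c(2, 2)))
  expect_equal(multiregion_cnh(karyotype_set(flat, "region")), 0)
  # rounded tie (2, 3): mode breaks to 2, one of two regions dissents
  pair <- lapply(c(2.4, 2.6), function(cp) unit_df(1, 100, cp))
  expect_equal(multiregion_cnh(karyotype_set(pair, "region")), 1 / 2)
})

test_that("direct CNH respects its invariants on simulated populations", {
  set.seed(71)
  sim <- simulate_tumour(10, h = 0.2, purity = 1)
  cells <- sample_cells(sim, 40)
  v <- direct_cnh(cells)
  expect_gte(v, 0)
  expect_lte(v, 1 - 1 / 40)
  # invariant under unit reordering
  shuffled <- karyotype_set(rev(cells$units), "cell")
  expect_equal(direct_cnh(shuffled), v)
  # invariant under value-preserving refinement of one unit's segmentation
  u1 <- cells$units[[1]]
  mid <- floor((u1$start[1] + u1$end[1]) / 2)
  refined <- rbind(
    unit_df(c(u1$start[1], mid + 1), c(mid, u1$end[1]),
            rep(u1$copy[1], 2), u1$chrom[1]),
    u1[-1, ])
  cells2 <- cells$units
  cells2[[1]] <- refined
  expect_equal(direct_cnh(karyotype_set(cells2, "cell")), v)
  # converges to truth_h as the population grows
  big <- sample_cells(sim, 2000)
  expect_lt(abs(direct_cnh(big) - sim$truth_h), 0.02)
})

test_that("quasi-bulk pooling averages cells with equal weight", {
  cells <- lapply(c(2, 2, 3), function(cp)
    unit_df(c(1, 101, 201), c(100, 200, 300), c(2, cp, 4)))
  qb <- quasi_bulk(karyotype_set(cells, "cell"))
  pre <- c(2, 7 / 3, 4)
  expect_equal(qb$value, pre / weighted.mean(pre, rep(100, 3)),
               tolerance = 1e-12)
  # identical integer karyotypes give an integer quasi-bulk, CNH ~ 0
  same <- lapply(1:3, function(i)
    unit_df(c(1, 101, 201), c(100, 200, 300), c(2, 3, 4)))
  fit <- cnh(quasi_bulk(karyotype_set(same, "cell")))
  expect_lt(fit$cnh, 1e-9)
})

test_that("patient-level CNH averages per-region inferences", {
  set.seed(81)
  sims <- lapply(1:5, function(i) simulate_tumour(20, h = 0.1, purity = 0.8))
  profs <- lapply(sims, `[[`, "bulk")
  expect_equal(mean_region_cnh(profs[1]), cnh(profs[[1]])$cnh)
  each <- vapply(profs, function(p) cnh(p)$cnh, numeric(1))
  expect_equal(mean_region_cnh(profs), mean(each))
  p1 <- profs[[1]]; p2 <- profs[[2]]
  expect_equal(mean_region_cnh(list(p1, p2)), (each[1] + each[2]) / 2)
})
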