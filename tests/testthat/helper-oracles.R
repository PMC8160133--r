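# independent reference implementations used to cross-check the package

# naive double-loop grid enumeration of the CNH minimum; integer distance
# via floor/ceiling, deliberately different mechanics from the main path
oracle_cnh <- function(r, w,
                       purities = 0.20 + (0:80) * 0.01,
                       ploidies = 1.50 + (0:70) * 0.05) {
  best <- Inf
  for (tau in ploidies) {
    for (a in purities) {
      q <- (r * (a * tau + 2 * (1 - a)) - 2 * (1 - a)) / a
      d <- pmin(q - floor(q), ceiling(q) - q)
      s <- sum(d * w) / sum(w)
      if (s < best) best <- s
    }
  }
  best
}

# integer profile whose width-weighted mean copy number is exactly 2
# (integer arithmetic, so exact in floating point): q from {2, 3, 4} with a
# final copy-1 segment balancing sum(w * (q - 2)) to zero
make_integer_profile <- function(n_segments) {
  stopifnot(n_segments >= 2)
  q <- sample(2:4, n_segments - 1L, replace = TRUE)
  if (all(q == 2L)) q[1L] <- 3L
  w <- sample(50:500, n_segments - 1L, replace = TRUE)
  excess <- sum(w * (q - 2L))
  q <- c(q, 1L)
  w <- c(w, excess)
  end <- cumsum(w)
  start <- end - w + 1
  segmented_profile("chr1", start, end, q / 2, sample_id = "integer_profile")
}

# sweep-line harmonization oracle: point-containment lookups over sorted
# boundaries, merging runs with identical source-segment tuples
oracle_harmonize <- function(units) {
  chroms <- sort(Reduce(intersect, lapply(units, function(u)
    unique(u$chrom))))
  rows <- list()
  vals <- list()
  for (ch in chroms) {
    subs <- lapply(units, function(u) u[u$chrom == ch, , drop = FALSE])
    bounds <- sort(unique(unlist(lapply(subs, function(s)
      c(s$start, s$end + 1)))))
    prev <- NULL
    flush <- function(p) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = ch, start = p$start, end = p$end,
        width = p$end - p$start + 1)
      vals[[length(vals) + 1L]] <<- p$vals
    }
    for (k in seq_len(length(bounds) - 1L)) {
      a <- bounds[k]; b <- bounds[k + 1L] - 1
      ids <- vapply(subs, function(s) {
        i <- which(s$start <= a & s$end >= b)
        if (length(i) == 1L) i else NA_integer_
      }, integer(1L))
      if (anyNA(ids)) {
        if (!is.null(prev)) flush(prev)
        prev <- NULL
        next
      }
      if (!is.null(prev) && prev$end + 1 == a &&
          identical(prev$ids, ids)) {
        prev$end <- b
      } else {
        if (!is.null(prev)) flush(prev)
        prev <- list(start = a, end = b, ids = ids,
                     vals = mapply(function(s, i) s$copy[i], subs, ids))
      }
    }
    if (!is.null(prev)) flush(prev)
  }
  list(segments = do.call(rbind, rows),
       values = do.call(rbind, lapply(vals, identity)))
}

# uniform random relative profile, normalized, for oracle-equivalence tests
random_profile <- function(n_segments) {
  w <- sample(10:1000, n_segments, replace = TRUE)
  end <- cumsum(w)
  normalize_profile(segmented_profile(
    "chr1", end - w + 1, end, stats::runif(n_segments, 0.3, 2.5)))
}
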