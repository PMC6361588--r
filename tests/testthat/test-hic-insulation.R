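# toy two-block matrix: within-block contacts c, cross-block c/10
two_block_matrix <- function(n = 24, cut = 12, c_within = 100) {
  m <- matrix(c_within / 10, n, n)
  m[1:cut, 1:cut] <- c_within
  m[(cut + 1):n, (cut + 1):n] <- c_within
  contact_matrix(m, resolution_bp = 25000L)
}

test_that("pair binning matches a naive oracle and applies the capture filter", {
  none <- tibble::tibble(chrom1 = "chr2", pos1 = 5L,
                         chrom2 = "chr2", pos2 = 10L)
  cm0 <- build_contact_matrix(none, "chrX", 0L, 100000L, 25000L)
  expect_true(all(cm0$matrix == 0))
  expect_equal(cm0$total_reads, 0L)

  one <- tibble::tibble(chrom1 = "chrX", pos1 = 10L, chrom2 = "chrX",
                        pos2 = 20L)
  cm1 <- build_contact_matrix(one, "chrX", 0L, 100000L, 25000L)
  expect_equal(cm1$matrix[1, 1], 1)
  expect_equal(sum(cm1$matrix), 1)

  withr::with_seed(61, {
    pairs <- tibble::tibble(
      chrom1 = sample(c("chrX", "chr1"), 10000, TRUE, prob = c(0.9, 0.1)),
      pos1 = sample.int(1.2e6, 10000),
      chrom2 = sample(c("chrX", "chr1"), 10000, TRUE, prob = c(0.9, 0.1)),
      pos2 = sample.int(1.2e6, 10000)
    )
  })
  cm <- build_contact_matrix(pairs, "chrX", 0L, 1e6, 25000L)
  # naive oracle
  n_bins <- 40L
  oracle <- matrix(0, n_bins, n_bins)
  kept <- 0L
  for (k in seq_len(nrow(pairs))) {
    if (pairs$chrom1[k] != "chrX" || pairs$chrom2[k] != "chrX") next
    p1 <- pairs$pos1[k] - 1L; p2 <- pairs$pos2[k] - 1L
    if (p1 >= 1e6 || p2 >= 1e6) next
    kept <- kept + 1L
    i <- p1 %/% 25000L + 1L; j <- p2 %/% 25000L + 1L
    oracle[i, j] <- oracle[i, j] + 1
    if (i != j) oracle[j, i] <- oracle[j, i] + 1
  }
  expect_equal(cm$matrix, oracle)
  expect_equal(cm$total_reads, kept)
  expect_identical(cm$matrix, t(cm$matrix))

  expect_error(build_contact_matrix(one, "chrX", 0L, 50000L, 25000L),
               class = "phospeaks_arg_error")
})

test_that("sqrt-coverage normalization matches hand arithmetic and preserves the mean", {
  uni <- contact_matrix(matrix(7, 10, 10), resolution_bp = 25000L)
  nu <- sqrt_coverage_normalize(uni)
  expect_true(all(abs(nu$matrix - nu$matrix[1, 1]) < 1e-12))
  expect_equal(mean(nu$matrix), 7)

  m <- contact_matrix(matrix(c(4, 2, 2, 1), 2), "r", 0L, 50000L, 25000L)
  nm <- sqrt_coverage_normalize(m)$matrix
  ref <- matrix(c(4, 2, 2, 1), 2) / sqrt(outer(c(6, 3), c(6, 3)))
  ref <- ref * mean(matrix(c(4, 2, 2, 1), 2)) / mean(ref)
  expect_equal(nm, ref, tolerance = 1e-12)

  # scale invariance up to the preserved mean
  tb <- two_block_matrix()
  a <- sqrt_coverage_normalize(tb)$matrix
  tb9 <- tb; tb9$matrix <- tb$matrix * 9
  b <- sqrt_coverage_normalize(tb9)$matrix
  expect_equal(b / a, matrix(9, 24, 24), tolerance = 1e-12)

  zero <- contact_matrix(matrix(0, 5, 5), resolution_bp = 25000L)
  expect_error(sqrt_coverage_normalize(zero),
               class = "phospeaks_input_error")
})

test_that("insulation is zero on uniform matrices and scale-invariant", {
  uni <- contact_matrix(matrix(3, 20, 20), resolution_bp = 25000L)
  tr <- insulation_score(uni)
  expect_lt(max(abs(tr$score[tr$valid])), 1e-12)

  tb <- two_block_matrix()
  t1 <- insulation_score(tb)
  tb7 <- tb; tb7$matrix <- tb$matrix * 7
  t7 <- insulation_score(tb7)
  expect_equal(t1$score[t1$valid], t7$score[t7$valid], tolerance = 1e-12)

  # default parameters give 5x5 squares at 25 kb resolution
  expect_equal(attr(t1, "is_bp") %/% attr(t1, "resolution_bp"), 5L)

  # mask is exactly the edge rule (no empty squares here)
  w <- 5L
  expect_equal(which(!t1$valid), c(1:w, (24 - w + 1):24))
  expect_false(any(is.na(t1$score[t1$valid])))

  small <- contact_matrix(matrix(1, 8, 8), resolution_bp = 25000L)
  expect_error(insulation_score(small), class = "phospeaks_arg_error")
})

test_that("the two-block matrix puts the insulation minimum at the cut", {
  tb <- two_block_matrix(n = 24, cut = 12)
  tr <- insulation_score(tb)
  # brute-force square sums
  w <- 5L
  raw <- rep(NA_real_, 24)
  for (i in (w + 1):(24 - w)) {
    s <- 0
    for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w)) {
      s <- s + tb$matrix[a, b]
    }
    raw[i] <- s
  }
  expect_equal(tr$raw[tr$valid], raw[!is.na(raw)])
  # the cut lies between 0-based bins 11 and 12; their insulation
  # squares are identical, so either bin is the constructed boundary
  min_bin <- tr$bin[tr$valid][which.min(tr$score[tr$valid])]
  expect_true(min_bin %in% c(11L, 12L))

  bounds <- delta_and_boundaries(tr)
  expect_equal(nrow(bounds), 1L)
  expect_true(bounds$bin %in% c(11L, 12L))
})

test_that("region-read normalization scales raw sums and not the log track", {
  tb <- two_block_matrix()
  tr <- insulation_score(tb)
  n1 <- region_read_normalize(tr, total_reads = 1e6)
  expect_equal(n1$raw_per_million, n1$raw)

  n2 <- region_read_normalize(tr, total_reads = 2e6)
  expect_equal(n2$raw_per_million, n2$raw / 2)
  expect_equal(n2$score, tr$score)   # log track unchanged

  # doubling matrix and total leaves the scaled track unchanged
  tb2 <- tb; tb2$matrix <- tb$matrix * 2
  tr2 <- insulation_score(tb2)
  expect_equal(region_read_normalize(tr2, 2e6)$raw_per_million,
               region_read_normalize(tr, 1e6)$raw_per_million)

  expect_error(region_read_normalize(tr, 0), class = "phospeaks_arg_error")
})

test_that("boundary detection handles flat and V-shaped tracks", {
  flat <- contact_matrix(matrix(2, 30, 30), resolution_bp = 25000L)
  tr <- insulation_score(flat)
  expect_equal(nrow(delta_and_boundaries(tr)), 0L)
  expect_equal(tad_score(tr, 10L, 20L)$tad_score, 0)

  # V-shaped synthetic track: forge scores directly
  v <- tr
  idx <- which(v$valid)
  vals <- abs(v$bin[idx] - 14) * 0.3 - 1
  v$score[idx] <- vals
  bounds <- delta_and_boundaries(v)
  expect_equal(bounds$bin, 14L)
  # strength: mean of flank maxima minus the minimum
  d <- 3L
  i <- which(v$bin == 14L)
  left_max <- max(v$score[(i - d):(i - 1)])
  right_max <- max(v$score[(i + 1):(i + d)])
  expect_equal(bounds$strength, (left_max + right_max) / 2 - v$score[i])
  ts <- tad_score(v, 10L, 14L)
  expect_equal(ts$right_strength, bounds$strength)
  expect_gte(ts$left_strength, 0)
  expect_equal(ts$tad_score, mean(c(ts$left_strength, ts$right_strength)))

  expect_error(tad_score(v, 14L, 14L), class = "phospeaks_arg_error")
  expect_error(tad_score(v, 1L, 14L), class = "phospeaks_input_error")
})

test_that("stronger simulated boundaries score higher TADs", {
  depletions <- c(0.1, 0.3, 0.5, 0.7, 1.0)
  scores <- vapply(depletions, function(dep) {
    cm <- simulate_contact_matrix(40, 25000, tad_boundaries = c(12L, 28L),
                                  boundary_depletion = dep,
                                  decay_exponent = 1, depth = 2e6,
                                  seed = 71)
    tr <- insulation_score(sqrt_coverage_normalize(cm))
    tad_score(tr, 12L, 28L)$tad_score
  }, 0)
  expect_true(all(diff(scores) < 0))
})

test_that("end-to-end simulated boundary is detected within one bin", {
  hits <- 0L
  for (s in 1:10) {
    cm <- simulate_contact_matrix(30, 25000, tad_boundaries = 15L,
                                  boundary_depletion = 0.25,
                                  decay_exponent = 1, depth = 1e6,
                                  seed = 100 + s)
    tr <- insulation_score(sqrt_coverage_normalize(cm))
    b <- delta_and_boundaries(tr)
    if (nrow(b) && any(abs(b$bin - 15L) <= 1L)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("contact matrices and insulation tracks round-trip through plots", {
  cm <- simulate_contact_matrix(20, 25000, tad_boundaries = 10L,
                                boundary_depletion = 0.3, depth = 2e5,
                                seed = 5)
  expect_s3_class(autoplot(cm), "ggplot")
  expect_s3_class(autoplot(insulation_score(cm)), "ggplot")
})
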