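test_that("window tiling matches the documented layout", {
  tt <- tag_track(list(chr1 = rep(0L, 10000)))
  w <- window_counts(tt)
  expect_equal(nrow(w), 46L)
  expect_equal(w$start, seq(0L, 9000L, by = 200L))
  expect_true(all(w$k == 0))

  # terminal truncated window only when full windows stop short
  tt2 <- tag_track(list(chr1 = rep(0L, 10100)))
  w2 <- window_counts(tt2)
  expect_equal(utils::tail(w2$end, 1), 10100L)
  expect_equal(utils::tail(w2$start, 1), 9200L)

  # chromosome shorter than one window
  tt3 <- tag_track(list(chr1 = rep(1L, 600)))
  w3 <- window_counts(tt3)
  expect_equal(nrow(w3), 1L)
  expect_equal(w3$end, 600L)
  expect_equal(w3$k, 600)
})

test_that("tags land in exactly the windows that cover them", {
  v <- rep(0L, 10000); v[1501] <- 5L   # 0-based position 1500
  w <- window_counts(tag_track(list(chr1 = v)))
  hit <- w$start[w$k == 5]
  expect_equal(hit, seq(600L, 1400L, by = 200L))
  expect_true(all(w$k[!w$start %in% hit] == 0))
})

test_that("window counts equal naive per-window summation on random tracks", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      tt <- random_track(list(chr1 = 4100L, chr2 = 2050L), lambda = 0.5)
      w <- window_counts(tt)
      naive <- bf_interval_sums(tt$counts, w)
      expect_equal(w$k, naive)
    }
  })
})

test_that("NB enrichment p-values match brute-force pmf summation", {
  withr::with_seed(7, {
    cases <- expand.grid(k = c(0, 1, 3, 10, 40, 120),
                         mu = c(0.5, 2, 10, 35),
                         r = c(1, 5, 10, 50))
    for (i in seq_len(nrow(cases))) {
      k <- cases$k[i]; mu <- cases$mu[i]; r <- cases$r[i]
      got <- nb_enrichment_z(k, mu / 1 - 0.5, 1, 1, r = r,
                             pseudocount = 0.5)   # mu = k_input + 0.5
      expect_lt(abs(got$p_upper - bf_nb_upper(k, mu, r)), 1e-10)
      if (got$p_upper > 1e-300 && got$p_upper < 1) {
        expect_equal(got$z, qnorm(got$p_upper, lower.tail = FALSE),
                     tolerance = 1e-6)
      }
    }
  })
})

test_that("z-score edge cases follow the documented conventions", {
  # k = 0: whole mass in the tail, z at the negative clamp
  at_zero <- nb_enrichment_z(0, 10, 1e6, 1e6, r = 10)
  expect_equal(at_zero$p_upper, 1)
  expect_equal(at_zero$z, -38)

  # deep tail: finite z from the moment fallback, clamped at +38
  deep <- nb_enrichment_z(1e5, 2, 1e6, 1e6, r = 50)
  expect_true(is.finite(deep$z))
  expect_lte(deep$z, 38)

  # monotone in k for fixed mu, r
  zz <- nb_enrichment_z(0:300, 20, 1e6, 1e6, r = 10)$z
  expect_true(all(diff(zz) >= 0))

  expect_error(nb_enrichment_z(1, 1, 0, 1, r = 10),
               class = "phospeaks_arg_error")
  expect_error(nb_enrichment_z(1, 1, 1, 1, r = 0),
               class = "phospeaks_arg_error")
})

test_that("call_windows respects thresholds and validates inputs", {
  g <- generate_genome(1, 50000, 0.5, seed = 1, with_sequence = FALSE)
  cfg <- sim_config(seed = 2, n_sites = 0)
  tr <- simulate_tags(g, NULL, cfg)
  inf_cfg <- caller_config(z_threshold = Inf)
  expect_equal(nrow(call_windows(tr$chip, tr$input, inf_cfg)), 0L)

  other <- tag_track(list(chrX = rep(1L, 5000)))
  expect_error(call_windows(tr$chip, other),
               class = "phospeaks_input_error")
})

test_that("merging windows matches the pairwise-merge oracle and is idempotent", {
  # the documented boundary: gap of exactly 1 kb still merges
  w <- tibble::tibble(chrom = "chr1", start = c(0L, 2000L),
                      end = c(1000L, 3000L), z = c(7, 8))
  m <- merge_windows(w, 1000L)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 3000L))
  expect_equal(m$z_max, 8)

  single <- merge_windows(w[1, ], 1000L)
  expect_equal(nrow(single), 1L)
  expect_equal(single$z_max, 7)

  withr::with_seed(11, {
    for (rep in 1:4) {
      rw <- random_intervals(250, len = 20000L, max_w = 800L)
      rw$z <- runif(250, 6, 20)
      got <- merge_windows(rw, 300L)
      oracle <- bf_merge(rw, 300L)
      expect_equal(got$start, oracle$start)
      expect_equal(got$end, oracle$end)
      expect_equal(got$z_max, oracle$z_max)
      expect_identical(merge_windows(got, 300L)[, 1:4],
                       got[, 1:4])   # idempotent
    }
  })
})

test_that("the caller recovers planted sites and stays quiet elsewhere", {
  g <- generate_genome(1, 3e5, 0.45, seed = 1, with_sequence = FALSE)
  cfg <- sim_config(seed = 8, n_sites = 10, site_min_gap_bp = 10000)
  # truth needs no sequence: place sites directly
  ps <- plant_sites(generate_genome(1, 3e5, 0.45, seed = 1), ctcf_like_pwm(),
                    cfg)
  tr <- simulate_tags(g, ps$sites, cfg)
  calls <- call_peaks(tr$chip, tr$input)
  peaks <- tidy(calls)
  covered <- bf_overlap_counts(ps$sites, peaks) > 0
  expect_gte(mean(covered), 0.9)
  false_peaks <- sum(bf_overlap_counts(peaks, ps$sites) == 0)
  expect_lte(false_peaks, 1L)
  expect_true(all(peaks$z_max >= calls$config$z_threshold))
  # peak boundaries lie on the window lattice
  expect_true(all(peaks$start %% calls$config$step_bp == 0))
})

test_that("an empty ChIP library yields an empty peak set", {
  chip <- tag_track(list(chr1 = rep(0L, 20000)))
  input <- tag_track(list(chr1 = rep(1L, 20000)))
  calls <- call_peaks(chip, input)
  expect_equal(nrow(tidy(calls)), 0L)
})

test_that("normalized coverage is zero under identical or proportional tracks", {
  withr::with_seed(3, {
    v <- rpois(5000, 2)
    a <- tag_track(list(chr1 = v))
    expect_true(all(abs(normalized_coverage(a, a)$score) < 1e-12))

    b <- tag_track(list(chr1 = 2L * v))
    expect_true(all(abs(normalized_coverage(b, a)$score) < 1e-9))
  })

  # hand-computed 3-bin example at bin_bp = 2
  chip <- tag_track(list(chr1 = c(4L, 0L, 1L, 1L, 0L, 0L)))
  input <- tag_track(list(chr1 = c(1L, 1L, 1L, 1L, 1L, 1L)))
  got <- normalized_coverage(chip, input, bin_bp = 2L, pseudocount = 0.01)
  expected <- log2((c(4, 2, 0) / 6 + 0.01) / (c(2, 2, 2) / 6 + 0.01))
  expect_equal(got$score, expected)
})

test_that("peak_calls tidiers and plots expose the fitted results", {
  g <- generate_genome(1, 50000, 0.5, seed = 1, with_sequence = FALSE)
  cfg <- sim_config(seed = 13, n_sites = 2, site_min_gap_bp = 10000)
  ps <- plant_sites(generate_genome(1, 50000, 0.5, seed = 1),
                    ctcf_like_pwm(), cfg)
  tr <- simulate_tags(g, ps$sites, cfg)
  calls <- call_peaks(tr$chip, tr$input)
  expect_s3_class(tidy(calls), "tbl_df")
  gl <- glance(calls)
  expect_equal(gl$n_peaks, nrow(tidy(calls)))
  expect_s3_class(autoplot(calls), "ggplot")
})
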