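#' Window caller configuration
#'
#' Parameters of the sliding-window negative-binomial enrichment caller:
#' tag counts are summed in `window_bp` windows advanced by `step_bp`,
#' tested for enrichment over the input-derived expectation with an
#' NB(mean, size) upper tail, thresholded at `z_threshold`, and adjacent
#' significant windows separated by at most `merge_gap_bp` are merged into
#' peaks. The defaults — 1 kb windows, 200 bp step, merge across gaps of
#' up to 1 kb, z >= 6 — are the standard configuration of this caller.
#' The NB size is a data-analyst choice (here default 10); the pseudocount
#' guards windows with zero input tags.
#'
#' @param window_bp window width in bp (default 1000).
#' @param step_bp step between window starts (default 200); must divide
#'   into `window_bp` sensibly (`window_bp >= step_bp > 0`).
#' @param merge_gap_bp maximal gap between significant windows that still
#'   merges them (default 1000).
#' @param z_threshold significance threshold on the enrichment z
#'   (default 6).
#' @param nb_size NB dispersion size r of the window-count null;
#'   variance = mu + mu^2/r (default 10).
#' @param pseudocount added to the input window count before scaling
#'   (default 0.5).
#' @return A validated list of class `caller_config`.
#' @export
caller_config <- function(window_bp = 1000L, step_bp = 200L,
                          merge_gap_bp = 1000L, z_threshold = 6,
                          nb_size = 10, pseudocount = 0.5) {
  if (!is_count(step_bp) || !is_count(window_bp) || window_bp < step_bp) {
    stop_arg("need window_bp >= step_bp > 0")
  }
  if (!is_count(merge_gap_bp, positive = FALSE)) {
    stop_arg("`merge_gap_bp` must be >= 0")
  }
  if (nb_size <= 0) stop_arg("`nb_size` must be > 0")
  if (pseudocount < 0) stop_arg("`pseudocount` must be >= 0")
  structure(
    list(window_bp = as.integer(window_bp), step_bp = as.integer(step_bp),
         merge_gap_bp = as.integer(merge_gap_bp),
         z_threshold = z_threshold, nb_size = nb_size,
         pseudocount = pseudocount),
    class = "caller_config"
  )
}

# internal: window starts/ends tiling one chromosome. Full windows begin
# at 0, step, 2*step, ... while start + window <= len; when the last full
# window stops short of the chromosome end, one additional terminal
# window (truncated at the end) is appended so every base is covered.
window_tiling <- function(len, window_bp, step_bp) {
  if (len <= 0) return(list(start = integer(0), end = integer(0)))
  if (len <= window_bp) {
    return(list(start = 0L, end = as.integer(len)))
  }
  last_full <- ((len - window_bp) %/% step_bp) * step_bp
  starts <- seq.int(0L, last_full, by = step_bp)
  ends <- starts + window_bp
  if (ends[length(ends)] < len) {
    starts <- c(starts, last_full + step_bp)
    ends <- c(ends, len)
  }
  list(start = as.integer(starts), end = as.integer(ends))
}

#' Sliding-window tag counts
#'
#' Sums tag counts in sliding windows over every chromosome of a track.
#' Windows start at 0, `step_bp`, 2*`step_bp`, ...; the terminal window is
#' truncated at the chromosome end (see [caller_config()]).
#'
#' @param track a [tag_track].
#' @param config a [caller_config()]. The track resolution must divide
#'   `step_bp`.
#' @return tibble with columns `chrom`, `start`, `end`, `k` (window tag
#'   count), sorted by (chrom, start).
#' @export
window_counts <- function(track, config = caller_config()) {
  stopifnot(is_tag_track(track), inherits(config, "caller_config"))
  if (config$step_bp %% track$resolution != 0) {
    stop_arg("track resolution must divide step_bp")
  }
  out <- purrr::imap(track$counts, function(v, nm) {
    len <- length(v) * track$resolution
    tl <- window_tiling(len, config$window_bp, config$step_bp)
    if (length(tl$start) == 0L) return(NULL)
    tibble(chrom = nm, start = tl$start, end = tl$end,
           k = track_interval_sums(track, nm, tl$start, tl$end))
  })
  dplyr::bind_rows(out)
}

#' Negative-binomial enrichment z-score
#'
#' The window enrichment test: the expected ChIP count under the null is
#' the (pseudocounted) input window count scaled by the library-size
#' ratio, `mu = (k_input + pseudocount) * total_chip / total_input`; the
#' upper-tail p-value is `P(X >= k_chip)` for `X ~ NB(mean = mu, size =
#' r)`; and the z-score is the standard-normal complementary quantile of
#' that p-value, computed in log space so extreme tails keep precision.
#' When the tail underflows even in log space the moment approximation
#' `(k - mu)/sqrt(mu + mu^2/r)` is used instead. z is clamped to
#' `[-38, 38]`.
#'
#' All arguments are vectorized.
#'
#' @param k_chip,k_input window tag counts in ChIP and input.
#' @param total_chip,total_input library totals (> 0).
#' @param r NB size (dispersion) parameter (> 0).
#' @param pseudocount added to `k_input` (default 0.5).
#' @return tibble with columns `mu`, `p_upper`, `z`.
#' @examples
#' nb_enrichment_z(10, 2, 1e6, 1e6, r = 5)
#' @export
nb_enrichment_z <- function(k_chip, k_input, total_chip, total_input,
                            r, pseudocount = 0.5) {
  if (any(total_chip <= 0) || any(total_input <= 0)) {
    stop_arg("library totals must be > 0")
  }
  if (any(r <= 0)) stop_arg("`r` must be > 0")
  mu <- (k_input + pseudocount) * total_chip / total_input
  # P(X >= k) = P(X > k - 1); log-space upper tail
  logp <- pnbinom(k_chip - 1, size = r, mu = mu,
                  lower.tail = FALSE, log.p = TRUE)
  z <- qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  underflow <- logp == -Inf   # tail lost even in log space
  if (any(underflow)) {
    mz <- (k_chip - mu) / sqrt(mu + mu^2 / r)
    z[underflow] <- mz[underflow]
  }
  z <- pmin(pmax(z, -38), 38)
  tibble(mu = mu, p_upper = exp(logp), z = z)
}

#' Significant enrichment windows
#'
#' Runs [window_counts()] on ChIP and input over the same tiling, applies
#' [nb_enrichment_z()] per window, and keeps windows with
#' `z >= z_threshold`.
#'
#' @param chip,input [tag_track]s over identical chromosomes.
#' @param config a [caller_config()].
#' @param keep_all also return non-significant windows (default FALSE);
#'   with `keep_all = TRUE` the result carries all windows and a logical
#'   `significant` column.
#' @return tibble of windows: `chrom`, `start`, `end`, `k_chip`,
#'   `k_input`, `mu`, `z` (and `significant` when `keep_all`).
#' @export
call_windows <- function(chip, input, config = caller_config(),
                         keep_all = FALSE) {
  stopifnot(is_tag_track(chip), is_tag_track(input))
  if (!setequal(track_chroms(chip), track_chroms(input))) {
    stop_input("chip and input tracks cover different chromosomes")
  }
  wc <- window_counts(chip, config)
  wi <- window_counts(input, config)
  if (nrow(wc) != nrow(wi) || !all(wc$start == wi$start & wc$chrom == wi$chrom)) {
    stop_input("chip and input window tilings disagree; ",
               "chromosome lengths must match")
  }
  if (chip$total_tags == 0) {
    # an empty ChIP library is enriched nowhere
    stats <- tibble(mu = rep(0, nrow(wc)), z = rep(-38, nrow(wc)))
  } else {
    stats <- nb_enrichment_z(wc$k, wi$k, chip$total_tags, input$total_tags,
                             r = config$nb_size,
                             pseudocount = config$pseudocount)
  }
  out <- tibble(chrom = wc$chrom, start = wc$start, end = wc$end,
                k_chip = wc$k, k_input = wi$k,
                mu = stats$mu, z = stats$z)
  if (keep_all) {
    out$significant <- out$z >= config$z_threshold
    out
  } else {
    dplyr::filter(out, .data$z >= config$z_threshold)
  }
}

#' Merge significant windows into peaks
#'
#' Unions overlapping windows and windows whose gap (next start minus
#' previous end) is at most `merge_gap_bp`, per chromosome. Idempotent:
#' merging a merged set changes nothing.
#'
#' @param windows tibble with `chrom`, `start`, `end` and optionally `z`;
#'   sorted internally if needed.
#' @param merge_gap_bp maximal gap that still merges (default 1000).
#' @return tibble of peaks: `chrom`, `start`, `end`, `z_max` (max member
#'   z, `NA` if no z column), `width`; sorted, non-overlapping.
#' @export
merge_windows <- function(windows, merge_gap_bp = 1000L) {
  stopifnot(is.data.frame(windows))
  if (nrow(windows) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  z_max = numeric(), width = integer()))
  }
  windows <- as_tibble(windows)
  # re-merging a merged set (z_max column) stays idempotent
  windows$z <- windows[["z"]] %||% windows[["z_max"]] %||% NA_real_
  windows <- dplyr::arrange(windows, .data$chrom, .data$start, .data$end)
  windows |>
    group_by(.data$chrom) |>
    mutate(
      prev_max_end = dplyr::lag(cummax(as.numeric(.data$end)),
                                default = -Inf),
      new_peak = .data$start > .data$prev_max_end + merge_gap_bp,
      peak_id = cumsum(.data$new_peak)
    ) |>
    group_by(.data$chrom, .data$peak_id) |>
    summarise(start = min(.data$start), end = max(.data$end),
              z_max = if (all(is.na(.data$z))) NA_real_ else
                max(.data$z, na.rm = TRUE),
              .groups = "drop") |>
    mutate(width = .data$end - .data$start) |>
    select(!"peak_id") |>
    arrange(.data$chrom, .data$start)
}

#' Call peaks from ChIP and input tag tracks
#'
#' The full caller: window counts, NB enrichment test, z-thresholding,
#' and merging of adjacent significant windows. Returns a `peak_calls`
#' object holding the peak set, the complete per-window statistics log,
#' and the configuration; `tidy()` extracts the peaks, `glance()` a
#' one-row summary, and `autoplot()` shows z along the genome.
#'
#' @inheritParams call_windows
#' @return An object of class `peak_calls` with elements `peaks` (tibble:
#'   `chrom`, `start`, `end`, `z_max`, `width`), `windows` (all windows
#'   with statistics), and `config`.
#' @examples
#' g <- generate_genome(1, 50000, seed = 1, with_sequence = FALSE)
#' cfg <- sim_config(n_sites = 2, site_min_gap_bp = 10000)
#' ps <- plant_sites(generate_genome(1, 50000, seed = 1), ctcf_like_pwm(),
#'                   cfg)
#' tr <- simulate_tags(g, ps$sites, cfg)
#' calls <- call_peaks(tr$chip, tr$input)
#' tidy(calls)
#' @export
call_peaks <- function(chip, input, config = caller_config()) {
  windows <- call_windows(chip, input, config, keep_all = TRUE)
  sig <- dplyr::filter(windows, .data$significant)
  peaks <- merge_windows(sig, config$merge_gap_bp)
  structure(
    list(peaks = peaks, windows = windows, config = config,
         total_chip = chip$total_tags, total_input = input$total_tags),
    class = "peak_calls"
  )
}

#' @export
print.peak_calls <- function(x, ...) {
  cat("<peak_calls> ", nrow(x$peaks), " peak(s) from ",
      nrow(x$windows), " windows (z >= ", x$config$z_threshold, ")\n",
      sep = "")
  print(x$peaks, n = 5)
  invisible(x)
}

#' @rdname call_peaks
#' @param x a `peak_calls` object.
#' @param ... unused.
#' @method tidy peak_calls
#' @export
tidy.peak_calls <- function(x, ...) x$peaks

#' @rdname call_peaks
#' @method glance peak_calls
#' @export
glance.peak_calls <- function(x, ...) {
  tibble(
    n_peaks = nrow(x$peaks),
    n_windows = nrow(x$windows),
    n_significant = sum(x$windows$significant),
    mean_width = if (nrow(x$peaks)) mean(x$peaks$width) else NA_real_,
    max_z = if (nrow(x$peaks)) max(x$peaks$z_max) else NA_real_,
    z_threshold = x$config$z_threshold,
    nb_size = x$config$nb_size
  )
}

#' Input-normalized log2 coverage track
#'
#' Bins both libraries at `bin_bp`, converts to library-relative
#' densities, and reports `log2((chip_density + pseudocount) /
#' (input_density + pseudocount))` per bin. This is the simple
#' visualization/metagene track of the pipeline (a deliberately plain
#' normalization; no fragment-model smoothing).
#'
#' @param chip,input [tag_track]s over identical chromosomes.
#' @param bin_bp bin width in bp (default 200).
#' @param pseudocount added to both densities (default 1e-7, roughly one
#'   tag in a 10 M-tag library).
#' @return tibble: `chrom`, `start`, `end`, `score`.
#' @export
normalized_coverage <- function(chip, input, bin_bp = 200L,
                                pseudocount = 1e-7) {
  stopifnot(is_tag_track(chip), is_tag_track(input))
  if (!is_count(bin_bp)) stop_arg("`bin_bp` must be a positive integer")
  if (chip$total_tags <= 0 || input$total_tags <= 0) {
    stop_input("both libraries must contain tags")
  }
  if (!setequal(track_chroms(chip), track_chroms(input))) {
    stop_input("chip and input tracks cover different chromosomes")
  }
  out <- purrr::map(track_chroms(chip), function(nm) {
    len <- track_chrom_length(chip, nm)
    starts <- seq.int(0L, len - 1L, by = bin_bp)
    ends <- pmin(starts + bin_bp, len)
    c_dens <- track_interval_sums(chip, nm, starts, ends) / chip$total_tags
    i_dens <- track_interval_sums(input, nm, starts, ends) / input$total_tags
    tibble(chrom = nm, start = starts, end = ends,
           score = log2((c_dens + pseudocount) / (i_dens + pseudocount)))
  })
  dplyr::bind_rows(out)
}
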