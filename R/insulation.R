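#' Insulation score along a contact matrix
#'
#' For each bin i, sums contacts in the `w x w` square upstream-by-
#' downstream of the bin (rows `i-w ... i-1`, columns `i+1 ... i+w`,
#' excluding bin i itself) where `w = is_bp / resolution`, then reports
#' the log2 ratio of each bin's square sum to the mean square sum over
#' valid bins. Bins within `w` of either region edge, and bins whose
#' square sums to zero (or touches masked entries), are masked. At 25 kb
#' resolution the default insulation span of 125 kb gives 5 x 5 squares.
#'
#' The log2-ratio track is invariant to any global scaling of the matrix,
#' so it can be computed from raw or coverage-normalized matrices alike.
#'
#' @param x a [contact_matrix] (raw or from
#'   [sqrt_coverage_normalize()]).
#' @param is_bp insulation span in bp (default 125000); must be a
#'   multiple of the matrix resolution. The matrix must have at least
#'   `2 * (is_bp/resolution) + 1` bins.
#' @param ids_bp insulation delta span in bp (default 75000), carried on
#'   the result for boundary detection.
#' @return An object of class `insulation_track`: tibble with `bin`
#'   (0-based), `start`, `end`, `raw` (square sum), `score` (log2 ratio;
#'   `NA` when masked), `valid`; attributes `is_bp`, `ids_bp`,
#'   `resolution_bp`, `total_reads`.
#' @export
insulation_score <- function(x, is_bp = 125000L, ids_bp = 75000L) {
  stopifnot(inherits(x, "contact_matrix"))
  res <- x$resolution_bp
  if (is_bp %% res != 0L || ids_bp %% res != 0L) {
    stop_arg("`is_bp` and `ids_bp` must be multiples of the resolution")
  }
  w <- is_bp %/% res
  n <- ncol(x$matrix)
  if (n < 2L * w + 1L) {
    stop_arg("matrix too small: need at least ", 2L * w + 1L, " bins")
  }
  m <- x$matrix
  raw <- rep(NA_real_, n)
  for (i in (w + 1L):(n - w)) {
    sq <- m[(i - w):(i - 1L), (i + 1L):(i + w), drop = FALSE]
    raw[i] <- sum(sq)   # NA if any masked entry
  }
  valid <- !is.na(raw) & raw > 0
  score <- rep(NA_real_, n)
  if (any(valid)) {
    score[valid] <- log2(raw[valid] / mean(raw[valid]))
  }
  out <- tibble(
    bin = seq_len(n) - 1L,
    start = x$start + (seq_len(n) - 1L) * res,
    end = pmin(x$start + seq_len(n) * res, x$end),
    raw = raw, score = score, valid = valid
  )
  structure(out, class = c("insulation_track", class(out)),
            is_bp = as.integer(is_bp), ids_bp = as.integer(ids_bp),
            resolution_bp = res, chrom = x$chrom,
            total_reads = x$total_reads)
}

#' Depth-normalize raw insulation square sums
#'
#' Scales the raw square sums of an insulation track by the total read
#' count *in the capture region* per million — the scaling needed before
#' comparing raw insulation between libraries of different depth. The
#' log2-ratio `score` column is unchanged: it is already scale-free.
#'
#' @param track an `insulation_track` (see [insulation_score()]).
#' @param total_reads region read count; defaults to the count recorded
#'   on the track.
#' @return the track with a `raw_per_million` column appended.
#' @export
region_read_normalize <- function(track, total_reads = NULL) {
  stopifnot(inherits(track, "insulation_track"))
  total_reads <- total_reads %||% attr(track, "total_reads")
  if (is.null(total_reads) || total_reads <= 0) {
    stop_arg("`total_reads` must be > 0")
  }
  dplyr::mutate(track, raw_per_million = .data$raw / (total_reads / 1e6))
}

# internal: boundary strength at bin i of insulation values `v`:
# mean of the maxima over the d-span flanks minus the value at i,
# floored at zero. Flank spans are truncated at the valid range (masked
# bins dropped); NA when a flank has no valid bin at all.
boundary_strength_at <- function(v, i, d) {
  n <- length(v)
  if (is.na(v[i])) return(NA_real_)
  left <- v[seq(max(1L, i - d), i - 1L)]
  right <- v[seq(i + 1L, min(n, i + d))]
  left <- left[!is.na(left)]
  right <- right[!is.na(right)]
  if (i == 1L || i == n || !length(left) || !length(right)) {
    return(NA_real_)
  }
  max(0, (max(left) + max(right)) / 2 - v[i])
}

#' Detect insulation boundaries
#'
#' Computes the delta vector `delta(i) = mean(score[i+1 ... i+d]) -
#' mean(score[i-d ... i-1])` with `d = ids_bp / resolution`, and calls a
#' boundary at each local minimum of the insulation score where delta
#' changes sign from negative to positive. Boundary strength is the mean
#' of the flanking score maxima (over the d-span on each side) minus the
#' score at the minimum; boundaries weaker than `min_strength` are
#' discarded. Near the masked region edges both the delta and strength
#' spans truncate to the available valid bins (at least one per side is
#' required), so boundaries close to an edge remain scoreable.
#'
#' @param track an `insulation_track`.
#' @param ids_bp delta span in bp; defaults to the span recorded on the
#'   track.
#' @param min_strength minimum boundary strength in log2 units
#'   (default 0.1).
#' @return tibble of boundaries: `bin` (0-based), `start`, `end`,
#'   `score`, `strength`; empty when the track has too few valid bins.
#' @export
delta_and_boundaries <- function(track, ids_bp = NULL,
                                 min_strength = 0.1) {
  stopifnot(inherits(track, "insulation_track"))
  res <- attr(track, "resolution_bp")
  ids_bp <- ids_bp %||% attr(track, "ids_bp")
  if (ids_bp %% res != 0L) {
    stop_arg("`ids_bp` must be a multiple of the resolution")
  }
  d <- ids_bp %/% res
  v <- ifelse(track$valid, track$score, NA_real_)
  n <- length(v)
  empty <- tibble(bin = integer(), start = integer(), end = integer(),
                  score = numeric(), strength = numeric())
  if (sum(track$valid) < 2L * d + 1L) return(empty)
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    left <- v[seq(max(1L, i - d), i - 1L)]
    right <- v[seq(i + 1L, min(n, i + d))]
    left <- left[!is.na(left)]
    right <- right[!is.na(right)]
    if (!length(left) || !length(right)) next
    delta[i] <- mean(right) - mean(left)
  }
  hits <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (is.na(delta[i]) || is.na(delta[i + 1L])) next
    if (delta[i] <= 0 && delta[i + 1L] > 0) {
      # sign change: boundary at whichever of the two bins is lower
      cand <- c(i, i + 1L)
      cand <- cand[!is.na(v[cand])]
      if (length(cand)) hits <- c(hits, cand[which.min(v[cand])])
    }
  }
  hits <- unique(hits)
  if (length(hits) == 0L) return(empty)
  strength <- vapply(hits, function(i) boundary_strength_at(v, i, d), 0)
  keep <- !is.na(strength) & strength >= min_strength
  tibble(
    bin = track$bin[hits[keep]],
    start = track$start[hits[keep]],
    end = track$end[hits[keep]],
    score = v[hits[keep]],
    strength = strength[keep]
  ) |> dplyr::arrange(.data$bin)
}

#' TAD strength from two boundary bins
#'
#' Scores a TAD defined by its two boundary bins as the mean of the
#' insulation boundary strengths evaluated at those bins (whether or not
#' they were auto-detected); a higher score means a stronger, more
#' insulated domain. The strength formula is that of
#' [delta_and_boundaries()].
#'
#' @param track an `insulation_track`.
#' @param left_bin,right_bin 0-based bin indices, `left_bin <
#'   right_bin`, both valid (unmasked, with full d-spans).
#' @param ids_bp delta span in bp; defaults to the span on the track.
#' @return one-row tibble of class `tad_interval`: `left_bin`,
#'   `right_bin`, `left_strength`, `right_strength`, `tad_score`.
#' @export
tad_score <- function(track, left_bin, right_bin, ids_bp = NULL) {
  stopifnot(inherits(track, "insulation_track"))
  if (left_bin >= right_bin) stop_arg("need left_bin < right_bin")
  res <- attr(track, "resolution_bp")
  d <- (ids_bp %||% attr(track, "ids_bp")) %/% res
  v <- ifelse(track$valid, track$score, NA_real_)
  idx <- match(c(left_bin, right_bin), track$bin)
  if (anyNA(idx) || anyNA(v[idx])) {
    stop_input("boundary bins must be valid (unmasked) track bins")
  }
  s <- vapply(idx, function(i) boundary_strength_at(v, i, d), 0)
  if (anyNA(s)) {
    stop_input("boundary bins need a full delta span of valid bins")
  }
  structure(
    tibble(left_bin = left_bin, right_bin = right_bin,
           left_strength = s[1L], right_strength = s[2L],
           tad_score = mean(s)),
    class = c("tad_interval", "tbl_df", "tbl", "data.frame")
  )
}
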