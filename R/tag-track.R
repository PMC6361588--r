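#' Tag track: per-base (or per-bin) sequencing tag counts
#'
#' A `tag_track` holds, for each chromosome, a vector of non-negative
#' integer tag counts at a fixed resolution (default 1 bp), together with
#' the library total. It is the in-memory form of a ChIP or input sample
#' after alignment and tag counting, and the unit the window caller
#' consumes.
#'
#' @param counts named list of non-negative integer vectors, one per
#'   chromosome. Names must be unique.
#' @param resolution bp per vector element (default 1).
#' @return An object of class `tag_track` with fields `counts`,
#'   `resolution` and `total_tags`.
#' @examples
#' tt <- tag_track(list(chr1 = c(0L, 2L, 1L, 0L)))
#' tt$total_tags
#' @export
tag_track <- function(counts, resolution = 1L) {
  if (!is.list(counts) || is.null(names(counts)) ||
      anyDuplicated(names(counts)) || any(names(counts) == "")) {
    stop_arg("`counts` must be a named list with unique chromosome names")
  }
  counts <- lapply(counts, function(x) {
    if (anyNA(x) || any(x < 0)) stop_arg("tag counts must be non-negative")
    as.integer(round(x))
  })
  if (!is_count(resolution)) stop_arg("`resolution` must be a positive integer")
  structure(
    list(
      counts = counts,
      resolution = as.integer(resolution),
      total_tags = sum(vapply(counts, function(x) sum(as.double(x)), 0))
    ),
    class = "tag_track"
  )
}

#' @export
print.tag_track <- function(x, ...) {
  lens <- vapply(x$counts, length, 0L)
  cat("<tag_track> ", length(lens), " chromosome(s), resolution ",
      x$resolution, " bp, ", format(x$total_tags, big.mark = ","),
      " tags\n", sep = "")
  for (nm in names(lens)) {
    cat("  ", nm, ": ", format(lens[[nm]] * x$resolution, big.mark = ","),
        " bp\n", sep = "")
  }
  invisible(x)
}

is_tag_track <- function(x) inherits(x, "tag_track")

track_chroms <- function(x) names(x$counts)

track_chrom_length <- function(x, chrom) {
  length(x$counts[[chrom]]) * x$resolution
}

#' Convert a tag track to a long tibble
#'
#' One row per non-zero run is not attempted; this is a plain per-bin
#' expansion, mainly useful for plotting and for writing bedGraph.
#'
#' @param x a `tag_track`.
#' @param drop_zero drop zero-count bins (default TRUE).
#' @return tibble with columns `chrom`, `start`, `end`, `count`
#'   (0-based half-open).
#' @export
track_tibble <- function(x, drop_zero = TRUE) {
  stopifnot(is_tag_track(x))
  res <- x$resolution
  out <- purrr::imap(x$counts, function(v, nm) {
    idx <- if (drop_zero) which(v != 0L) else seq_along(v)
    tibble(
      chrom = nm,
      start = (idx - 1L) * res,
      end = idx * res,
      count = v[idx]
    )
  })
  dplyr::bind_rows(out)
}

# internal: sum track counts over a set of 0-based half-open intervals
# on one chromosome, via a cumulative sum. Intervals may exceed the
# chromosome end; they are truncated.
track_interval_sums <- function(track, chrom, starts, ends) {
  v <- track$counts[[chrom]]
  if (is.null(v)) stop_input("unknown chromosome: ", chrom)
  res <- track$resolution
  if (any(starts %% res != 0)) {
    stop_arg("interval starts must align to the track resolution")
  }
  cs <- c(0, cumsum(as.double(v)))
  i0 <- pmin(starts %/% res, length(v)) + 1L
  i1 <- pmin(ceiling(ends / res), length(v)) + 1L
  cs[i1] - cs[i0]
}

#' Build a tag track from a bedGraph tibble
#'
#' Expands interval records (e.g. from [read_bedgraph()]) into per-bp
#' integer counts. Scores must be non-negative integers; uncovered
#' positions are zero.
#'
#' @param bg tibble with `chrom`, `start`, `end`, `score` (or `count`).
#' @param chrom_lengths named lengths; default: the max `end` seen per
#'   chromosome.
#' @return A [tag_track] at 1 bp resolution.
#' @export
bedgraph_to_track <- function(bg, chrom_lengths = NULL) {
  stopifnot(is.data.frame(bg))
  score <- bg[["score"]] %||% bg[["count"]]
  if (any(score < 0) || any(score != round(score))) {
    stop_arg("tag-track scores must be non-negative integers")
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(bg$end, bg$chrom, max)
  }
  counts <- lapply(seq_along(chrom_lengths), function(i) {
    nm <- names(chrom_lengths)[i]
    v <- integer(chrom_lengths[[i]])
    rows <- which(bg$chrom == nm)
    for (r in rows) {
      v[(bg$start[r] + 1L):bg$end[r]] <- as.integer(score[r])
    }
    v
  })
  names(counts) <- names(chrom_lengths)
  tag_track(counts)
}
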