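#' Contact matrix for one capture region
#'
#' A symmetric matrix of contact counts over fixed-resolution bins of a
#' single genomic region, with the total number of read pairs retained
#' inside the region.
#'
#' @param m square symmetric non-negative numeric matrix.
#' @param chrom,start,end region coordinates (0-based half-open);
#'   `ncol(m)` must equal `ceiling((end - start)/resolution_bp)`.
#' @param resolution_bp bin size in bp (default 25000).
#' @param total_reads pairs inside the region (default `sum` of the upper
#'   triangle including the diagonal).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(m, chrom = "region", start = 0L,
                           end = start + ncol(m) * resolution_bp,
                           resolution_bp = 25000L, total_reads = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_arg("matrix must be square")
  if (max(abs(m - t(m))) > 1e-9) stop_arg("matrix must be symmetric")
  if (any(m < 0)) stop_arg("contact counts must be non-negative")
  n_expected <- ceiling((end - start) / resolution_bp)
  if (ncol(m) != n_expected) {
    stop_arg("matrix dimension ", ncol(m), " does not match region (",
             n_expected, " bins)")
  }
  if (is.null(total_reads)) {
    total_reads <- sum(m[upper.tri(m, diag = TRUE)])
  }
  structure(
    list(matrix = m, chrom = chrom, start = as.integer(start),
         end = as.integer(end), resolution_bp = as.integer(resolution_bp),
         total_reads = total_reads),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", x$chrom, ":", x$start, "-", x$end, " @ ",
      x$resolution_bp, " bp (", ncol(x$matrix), " bins, ",
      format(x$total_reads, big.mark = ","), " reads)\n", sep = "")
  invisible(x)
}

#' Bin tag pairs into a capture-region contact matrix
#'
#' Keeps only pairs with *both* ends inside the region (the capture
#' filter), bins ends at `resolution_bp`, and accumulates a symmetric
#' matrix: every pair adds one count to `[i,j]` and `[j,i]`; same-bin
#' pairs add once to the diagonal.
#'
#' @param pairs tibble with columns `chrom1`, `pos1`, `chrom2`, `pos2`
#'   (1-based positions, as in pair files; see [read_pairs()]).
#' @param chrom,start,end the capture region (0-based half-open).
#' @param resolution_bp bin size (default 25000). The region must span at
#'   least 3 bins.
#' @return A [contact_matrix]; `total_reads` is the number of retained
#'   pairs.
#' @export
build_contact_matrix <- function(pairs, chrom, start, end,
                                 resolution_bp = 25000L) {
  stopifnot(is.data.frame(pairs))
  n_bins <- ceiling((end - start) / resolution_bp)
  if (n_bins < 3L) stop_arg("region spans fewer than 3 bins")
  p1 <- pairs$pos1 - 1L   # to 0-based
  p2 <- pairs$pos2 - 1L
  keep <- pairs$chrom1 == chrom & pairs$chrom2 == chrom &
    p1 >= start & p1 < end & p2 >= start & p2 < end
  i <- (p1[keep] - start) %/% resolution_bp + 1L
  j <- (p2[keep] - start) %/% resolution_bp + 1L
  m <- matrix(0, n_bins, n_bins)
  for (k in seq_along(i)) {
    m[i[k], j[k]] <- m[i[k], j[k]] + 1
    if (i[k] != j[k]) m[j[k], i[k]] <- m[j[k], i[k]] + 1
  }
  contact_matrix(m, chrom = chrom, start = start, end = end,
                 resolution_bp = resolution_bp, total_reads = sum(keep))
}

#' Square-root coverage normalization
#'
#' Divides each entry by the square root of its row and column sums
#' (`M'[i,j] = M[i,j] / sqrt(r_i * r_j)`), then rescales so the mean of
#' the unmasked entries equals the mean of the corresponding input
#' entries. Bins with zero coverage are masked (`NA` row/column). This is
#' the "coverage (sqrt)" balancing used for capture-region matrices; the
#' downstream insulation score is invariant to the preserved-mean
#' constant.
#'
#' @param x a [contact_matrix].
#' @return A [contact_matrix] with the normalized (real-valued) matrix;
#'   masked bins are `NA`.
#' @export
sqrt_coverage_normalize <- function(x) {
  stopifnot(inherits(x, "contact_matrix"))
  m <- x$matrix
  rs <- rowSums(m)
  if (all(rs == 0)) stop_input("all-zero contact matrix")
  v <- sqrt(rs)
  ok <- v > 0
  norm <- m / outer(v, v)
  norm[!ok, ] <- NA_real_
  norm[, !ok] <- NA_real_
  mask <- outer(ok, ok, "&")
  norm[mask] <- norm[mask] * mean(m[mask]) / mean(norm[mask])
  out <- x
  out$matrix <- norm
  out
}

#' Simulate a capture-region contact matrix
#'
#' Expected contacts decay with bin distance as
#' `(|i - j| + 1)^(-decay_exponent)` and are multiplied by
#' `boundary_depletion` once for every TAD boundary lying strictly
#' between the two bins, giving the familiar block structure along the
#' diagonal. Expectations are scaled to `depth` total pairs and counts
#' are Poisson-sampled (upper triangle drawn, then mirrored).
#'
#' @param n_bins number of bins (>= 12).
#' @param resolution_bp bin size (default 25000).
#' @param tad_boundaries integer cut positions in `[1, n_bins - 1]`: a
#'   boundary `b` separates bins `b-1` and `b` (0-based bins).
#' @param boundary_depletion factor in (0, 1] applied per crossed
#'   boundary.
#' @param decay_exponent power-law distance-decay slope.
#' @param depth expected total pair count.
#' @param seed RNG seed.
#' @return A [contact_matrix].
#' @export
simulate_contact_matrix <- function(n_bins = 59L, resolution_bp = 25000L,
                                    tad_boundaries = c(34L, 52L),
                                    boundary_depletion = 0.25,
                                    decay_exponent = 1, depth = 5e5,
                                    seed = 1L) {
  if (n_bins < 12L) stop_arg("`n_bins` must be >= 12")
  if (length(tad_boundaries) &&
      (any(tad_boundaries < 1L) || any(tad_boundaries > n_bins - 1L))) {
    stop_arg("boundaries must lie strictly inside [1, n_bins - 1]")
  }
  if (boundary_depletion <= 0 || boundary_depletion > 1) {
    stop_arg("`boundary_depletion` must be in (0, 1]")
  }
  idx <- seq_len(n_bins) - 1L
  d <- abs(outer(idx, idx, "-"))
  e <- (d + 1)^(-decay_exponent)
  for (b in tad_boundaries) {
    # boundary b is crossed when min(i,j) < b <= max(i,j)
    crossed <- outer(idx, idx, function(i, j) pmin(i, j) < b & pmax(i, j) >= b)
    e[crossed] <- e[crossed] * boundary_depletion
  }
  ut <- upper.tri(e, diag = TRUE)
  e <- e * depth / sum(e[ut])
  m <- matrix(0, n_bins, n_bins)
  with_seed(as.integer(seed) + 4L, {
    m[ut] <- rpois(sum(ut), e[ut])
  })
  m <- m + t(m) - diag(diag(m))
  contact_matrix(m, chrom = "capture", start = 0L,
                 resolution_bp = resolution_bp)
}
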