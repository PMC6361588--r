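# Independent brute-force oracles. These deliberately use the simplest
# possible algorithm (per-base loops, all-pairs scans, full enumeration)
# and never call the package functions they check.

# upper tail P(X >= k) for NB(mean mu, size r) by direct pmf summation
bf_nb_upper <- function(k, mu, r, tol = 1e-18) {
  if (k <= 0) return(1)
  p <- 0
  x <- k
  repeat {
    term <- dnbinom(x, size = r, mu = mu)
    p <- p + term
    x <- x + 1
    if (term < tol && x > mu + 10 * sqrt(mu + mu^2 / r) + 10) break
  }
  p
}

# O(n^2) union of intervals with a merge gap, one chromosome at a time
bf_merge <- function(windows, gap) {
  out <- list()
  for (nm in unique(windows$chrom)) {
    w <- windows[windows$chrom == nm, ]
    groups <- seq_len(nrow(w))
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(w))) {
        for (j in seq_len(nrow(w))) {
          if (groups[i] != groups[j] &&
              w$start[i] <= w$end[j] + gap && w$start[j] <= w$end[i] + gap) {
            groups[groups == groups[j]] <- groups[i]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    for (g in unique(groups)) {
      m <- w[groups == g, ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = nm, start = min(m$start), end = max(m$end),
        z_max = if (is.null(m$z)) NA_real_ else max(m$z)
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

# all-pairs overlap counting (>= 1 bp, half-open intervals)
bf_overlap_counts <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sum(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  }, 0L)
}

# per-base interval sums over a per-bp counts list
bf_interval_sums <- function(counts, peaks) {
  vapply(seq_len(nrow(peaks)), function(i) {
    v <- counts[[peaks$chrom[i]]]
    s <- max(0L, peaks$start[i]) + 1L
    e <- min(length(v), peaks$end[i])
    if (e < s) 0 else sum(v[s:e])
  }, 0)
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(m+n, m) assignments of ranks to sample a
bf_wilcoxon_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * n / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# naive per-position PWM scan on one sequence, integer grid scores
bf_scan_scores <- function(seq_chars, smat, grid) {
  w <- ncol(smat)
  L <- length(seq_chars)
  idx <- match(seq_chars, c("A", "C", "G", "T"))
  vapply(seq_len(L - w + 1L), function(i) {
    s <- 0
    for (j in seq_len(w)) {
      ij <- idx[i + j - 1L]
      if (is.na(ij)) return(-Inf)
      s <- s + smat[ij, j]
    }
    s * grid
  }, 0)
}

# random interval set on a small genome
random_intervals <- function(n, chroms = c("chr1", "chr2"), len = 10000L,
                            max_w = 500L) {
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = sample.int(len - max_w, n, replace = TRUE) - 1L
  ) |>
    dplyr::mutate(end = start + sample.int(max_w, n, replace = TRUE)) |>
    dplyr::arrange(chrom, start)
}

# small deterministic per-bp track
random_track <- function(chrom_lens, lambda = 0.2) {
  counts <- lapply(chrom_lens, function(L) rpois(L, lambda))
  tag_track(counts)
}
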