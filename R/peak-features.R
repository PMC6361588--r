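# internal: IRanges from a 0-based half-open interval tibble (one chrom)
iranges_0h <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# internal: per-row count of >=1 bp overlaps of `a` rows with `b` rows,
# chromosome-aware.
overlap_counts <- function(a, b) {
  n <- integer(nrow(a))
  for (nm in unique(a$chrom)) {
    ai <- which(a$chrom == nm)
    bi <- which(b$chrom == nm)
    if (length(bi) == 0L) next
    n[ai] <- IRanges::countOverlaps(
      iranges_0h(a$start[ai], a$end[ai]),
      iranges_0h(b$start[bi], b$end[bi])
    )
  }
  n
}

#' Intersect two peak sets
#'
#' Reports the peaks of `a` that overlap at least one peak of `b` by at
#' least 1 bp (single-overlap semantics: each peak of `a` is reported
#' once however many peaks of `b` it touches — the `-u` convention of
#' interval tools), together with the overlapped fraction of `a`.
#'
#' @param a,b peak tibbles with columns `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from `tidy(call_peaks(...))`.
#' @return list with `shared` (the overlapping subset of `a`, original
#'   order and columns), `fraction` (shared/|a|; `NA` with a warning when
#'   `a` is empty), `n_a`, `n_shared`.
#' @export
intersect_peaks <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  if (nrow(a) == 0L) {
    warn("empty peak set `a`: overlap fraction undefined")
    return(list(shared = a, fraction = NA_real_, n_a = 0L, n_shared = 0L))
  }
  hit <- overlap_counts(a, b) > 0L
  list(shared = a[hit, , drop = FALSE],
       fraction = mean(hit),
       n_a = nrow(a), n_shared = sum(hit))
}

#' Tag coverage over peaks
#'
#' Sums track tag counts over each peak interval (any-overlap semantics
#' at the track's resolution; at 1 bp resolution this is the per-base
#' sum over `[start, end)`). Row order matches the input peaks.
#'
#' @param track a [tag_track].
#' @param peaks tibble with `chrom`, `start`, `end`.
#' @return the `peaks` tibble with a `coverage` column appended.
#' @export
peak_coverage <- function(track, peaks) {
  stopifnot(is_tag_track(track), is.data.frame(peaks))
  cov <- numeric(nrow(peaks))
  for (nm in unique(peaks$chrom)) {
    if (!nm %in% track_chroms(track)) {
      stop_input("track does not cover chromosome: ", nm)
    }
    i <- which(peaks$chrom == nm)
    cov[i] <- track_interval_sums(track, nm, peaks$start[i], peaks$end[i])
  }
  dplyr::mutate(as_tibble(peaks), coverage = cov)
}

#' Coefficient of determination of a simple linear fit
#'
#' Ordinary least squares of `y` on `x` with intercept, via `lm()`;
#' returns R-squared = 1 - SSres/SStot. Used to ask how much variation in
#' one ChIP signal is explained by another across peaks.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return one-row tibble: `r_squared`, `slope`, `intercept`, `n`,
#'   `defined`. A constant `y` (SStot = 0) leaves R-squared undefined
#'   (`NA`, `defined = FALSE`) rather than erroring.
#' @export
linear_r2 <- function(x, y) {
  if (length(x) != length(y)) stop_arg("`x` and `y` lengths differ")
  if (length(x) < 3L) stop_arg("need at least 3 points")
  if (var(y) == 0) {
    warn("`y` is constant: R-squared undefined")
    return(tibble(r_squared = NA_real_, slope = NA_real_,
                  intercept = NA_real_, n = length(x), defined = FALSE))
  }
  fit <- lm(y ~ x)
  # exact fits trigger an informational warning from summary.lm
  tibble(r_squared = suppressWarnings(summary(fit)$r.squared),
         slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]),
         n = length(x), defined = TRUE)
}

#' Count motif hits per peak
#'
#' A motif counts toward a peak iff it overlaps it by at least 1 bp; a
#' motif overlapping two peaks counts for both (the `-counts` convention
#' of interval coverage tools).
#'
#' @param motifs tibble of motif hits (`chrom`, `start`, `end`), e.g.
#'   from [scan_motifs()].
#' @param peaks tibble with `chrom`, `start`, `end`.
#' @return the `peaks` tibble with an `n_motifs` column appended.
#' @export
count_motifs_in_peaks <- function(motifs, peaks) {
  stopifnot(is.data.frame(motifs), is.data.frame(peaks))
  dplyr::mutate(as_tibble(peaks),
                n_motifs = overlap_counts(peaks, motifs))
}

#' Average a per-base score track over intervals
#'
#' Means a (possibly gapped) real-valued track — conservation scores,
#' say — over each interval, counting covered bases only. Intervals with
#' no covered base are flagged missing rather than zero.
#'
#' @param score_track tibble with `chrom`, `start`, `end`, `score`
#'   (0-based half-open, non-overlapping runs), e.g. from
#'   [read_bedgraph()].
#' @param intervals tibble with `chrom`, `start`, `end`.
#' @return the `intervals` tibble with `mean_score` (NA when uncovered)
#'   and `covered_bp` columns appended.
#' @export
average_conservation <- function(score_track, intervals) {
  stopifnot(is.data.frame(score_track), is.data.frame(intervals))
  ms <- rep(NA_real_, nrow(intervals))
  cb <- integer(nrow(intervals))
  for (nm in unique(intervals$chrom)) {
    ii <- which(intervals$chrom == nm)
    ti <- which(score_track$chrom == nm)
    if (length(ti) == 0L) next
    ir_i <- iranges_0h(intervals$start[ii], intervals$end[ii])
    ir_t <- iranges_0h(score_track$start[ti], score_track$end[ti])
    ov <- IRanges::findOverlaps(ir_i, ir_t)
    if (length(ov) == 0L) next
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(ir_i[qi], ir_t[si]))
    v <- score_track$score[ti][si]
    sums <- tapply(w * v, qi, sum)
    bps <- tapply(w, qi, sum)
    idx <- ii[as.integer(names(sums))]
    ms[idx] <- as.numeric(sums) / as.numeric(bps)
    cb[idx] <- as.integer(bps)
  }
  dplyr::mutate(as_tibble(intervals), mean_score = ms, covered_bp = cb)
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum comparison as used throughout the peak-feature
#' analyses. The exact null distribution is used when the combined sample
#' size is at most 20 and there are no ties; otherwise the normal
#' approximation with tie and continuity correction. The chosen path is
#' reported.
#'
#' @param a,b numeric samples (each non-empty).
#' @param alternative "two.sided" (default), "greater" or "less"
#'   (`a` relative to `b`).
#' @return one-row tibble: `statistic` (the Mann-Whitney U of `a`),
#'   `p_value`, `method` ("exact" or "normal_approx"), `n_a`, `n_b`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = c("two.sided",
                                                    "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) < 1L || length(b) < 1L) {
    stop_arg("both samples must be non-empty")
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 20L) && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = exact,
                correct = TRUE)
  )
  tibble(statistic = unname(ht$statistic),
         p_value = ht$p.value,
         method = if (exact) "exact" else "normal_approx",
         n_a = length(a), n_b = length(b))
}

#' Classify a pileup of codon reads
#'
#' Tallies base calls at the three codon positions and reports the
#' fraction of reads spelling a glutamate codon (GAA or GAG by the
#' standard code) among reads with no N — the readout used to quantify
#' expression of a phosphomimetic (Ser->Glu) transgene from RNA-seq reads
#' over the mutated codon.
#'
#' @param read_bases tibble with columns `base1`, `base2`, `base3`
#'   (one row per read), e.g. from [simulate_codon_reads()]. Any call
#'   outside A/C/G/T is counted as N.
#' @param target_codons codons counted as "mutant" (default `c("GAA",
#'   "GAG")`).
#' @return An object of class `codon_tally`: list with `counts` (5 x 3
#'   matrix, rows A/C/G/T/N, columns pos1..pos3), `n_reads`,
#'   `mutant_fraction` (reads spelling a target codon / reads with no N).
#' @export
classify_codon_reads <- function(read_bases,
                                 target_codons = c("GAA", "GAG")) {
  stopifnot(is.data.frame(read_bases),
            all(c("base1", "base2", "base3") %in% names(read_bases)))
  m <- cbind(toupper(read_bases$base1), toupper(read_bases$base2),
             toupper(read_bases$base3))
  m[!m %in% BASES] <- "N"
  lv <- c(BASES, "N")
  counts <- vapply(1:3, function(j) {
    table(factor(m[, j], levels = lv))
  }, integer(5L))
  dimnames(counts) <- list(lv, paste0("pos", 1:3))
  clean <- rowSums(m == "N") == 0L
  codon <- paste0(m[, 1L], m[, 2L], m[, 3L])
  frac <- if (any(clean)) mean(codon[clean] %in% target_codons) else NA_real_
  structure(
    list(counts = counts, n_reads = nrow(m), mutant_fraction = frac,
         target_codons = target_codons),
    class = "codon_tally"
  )
}

#' @export
print.codon_tally <- function(x, ...) {
  cat("<codon_tally> ", x$n_reads, " reads; ",
      paste(x$target_codons, collapse = "/"), " fraction = ",
      signif(x$mutant_fraction, 4), "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @rdname classify_codon_reads
#' @param x a `codon_tally`.
#' @param ... unused.
#' @method tidy codon_tally
#' @export
tidy.codon_tally <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE)) |>
    setNames(c("base", "position", "count"))
}

#' @rdname classify_codon_reads
#' @method glance codon_tally
#' @export
glance.codon_tally <- function(x, ...) {
  tibble(n_reads = x$n_reads, mutant_fraction = x$mutant_fraction)
}
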