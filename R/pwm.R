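BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' Constructs a PWM from a 4 x w matrix of per-position base probabilities
#' (rows A, C, G, T). Motif occurrences are scored as log2 odds against the
#' background; to keep the exact tail-probability machinery and the scanner
#' consistent, scores are discretized on a fixed grid (default 1e-3 log2
#' units, see [pwm_threshold()]).
#'
#' @param prob 4 x w numeric matrix of probabilities, rows named A,C,G,T
#'   (or in that order). Each column must sum to 1 (tolerance 1e-9);
#'   w >= 4.
#' @param background background base frequencies (A,C,G,T), default uniform.
#' @param name optional motif name.
#' @return An object of class `pwm`.
#' @seealso [pwm_from_consensus()], [read_pwm()], [scan_motifs()]
#' @export
pwm <- function(prob, background = rep(0.25, 4), name = NULL) {
  prob <- as.matrix(prob)
  if (nrow(prob) != 4L) stop_arg("`prob` must have 4 rows (A, C, G, T)")
  if (is.null(rownames(prob))) rownames(prob) <- BASES
  prob <- prob[BASES, , drop = FALSE]
  if (ncol(prob) < 4L) stop_arg("PWM width must be >= 4")
  if (any(abs(colSums(prob) - 1) > 1e-9)) {
    stop_arg("each PWM column must sum to 1 (tolerance 1e-9)")
  }
  if (any(prob < 0)) stop_arg("PWM probabilities must be non-negative")
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6 ||
      any(background <= 0)) {
    stop_arg("`background` must be 4 positive frequencies summing to 1")
  }
  structure(
    list(prob = prob, background = setNames(background, BASES),
         width = ncol(prob), name = name),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name %||% "(unnamed)", ", width ", x$width, ", consensus ",
      pwm_consensus(x), "\n", sep = "")
  print(round(x$prob, 3))
  invisible(x)
}

#' Build a PWM from a consensus word
#'
#' Each position gives probability `dominant` to the consensus base and
#' splits the remainder evenly over the other three. A convenient way to
#' define sharply informative synthetic motifs.
#'
#' @param consensus string over A/C/G/T, length >= 4.
#' @param dominant probability of the consensus base per position
#'   (default 0.85).
#' @inheritParams pwm
#' @return A `pwm`.
#' @export
pwm_from_consensus <- function(consensus, dominant = 0.85,
                               background = rep(0.25, 4), name = NULL) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% BASES)) stop_arg("`consensus` must be over A/C/G/T")
  if (dominant <= 0.25 || dominant >= 1) {
    stop_arg("`dominant` must be in (0.25, 1)")
  }
  m <- matrix((1 - dominant) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(BASES, NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- dominant
  pwm(m, background = background, name = name)
}

#' Synthetic CTCF-like motif
#'
#' A sharply informative 16-position PWM whose consensus resembles the
#' GC-rich core of the CTCF zinc-finger binding motif. This is a synthetic
#' stand-in constructed in code (no database matrix is shipped); use
#' [read_pwm()] to score with a real downloaded matrix.
#'
#' @inheritParams pwm_from_consensus
#' @return A `pwm` named "CTCF-like (synthetic)".
#' @export
ctcf_like_pwm <- function(dominant = 0.85) {
  pwm_from_consensus("CCACCAGGGGGCGCTA", dominant = dominant,
                     name = "CTCF-like (synthetic)")
}

#' @rdname pwm
#' @param x a `pwm`.
#' @return `pwm_consensus()`: the consensus word (ties broken A<C<G<T).
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(BASES[apply(x$prob, 2, which.max)], collapse = "")
}

# internal: integer score matrix on the discretization grid.
# Probabilities are floored at `prob_floor` so log-odds stay finite;
# this floor is part of the documented scoring convention.
pwm_int_scores <- function(x, grid = 1e-3, prob_floor = 1e-4) {
  p <- pmax(x$prob, prob_floor)
  s <- log2(p / x$background)
  matrix(as.integer(round(s / grid)), nrow = 4,
         dimnames = dimnames(x$prob))
}

# internal: reverse complement of a pwm (complement rows, reverse columns)
pwm_revcomp <- function(x) {
  m <- x$prob[c("T", "G", "C", "A"), rev(seq_len(x$width)), drop = FALSE]
  rownames(m) <- BASES
  pwm(m, background = x$background[c("T", "G", "C", "A")],
      name = x$name)
}

#' Exact null distribution of PWM scores under the background
#'
#' Computes, by dynamic programming over the per-position discretized
#' score distributions, the exact probability mass function of the
#' log2-odds score of a random w-mer drawn from the background. All
#' probability mass is accounted for, so tail probabilities from this
#' distribution agree with exhaustive enumeration of all 4^w words (up to
#' floating-point summation order).
#'
#' @inheritParams pwm_consensus
#' @param grid score discretization in log2-odds units (default 1e-3).
#' @param prob_floor lower floor applied to matrix probabilities before
#'   taking log-odds (default 1e-4), so that zero entries score finitely.
#' @return tibble with columns `score` (log2-odds, on the grid) and `prob`,
#'   ascending in score; probs sum to 1.
#' @export
pwm_score_distribution <- function(x, grid = 1e-3, prob_floor = 1e-4) {
  stopifnot(inherits(x, "pwm"))
  smat <- pwm_int_scores(x, grid = grid, prob_floor = prob_floor)
  bg <- x$background
  lo <- sum(apply(smat, 2, min))
  hi <- sum(apply(smat, 2, max))
  # dp[k] = P(partial score == lo_partial + k - 1)
  dp <- 1
  dp_lo <- 0L
  for (j in seq_len(ncol(smat))) {
    s <- smat[, j]
    new_lo <- dp_lo + min(s)
    new_hi <- dp_lo + length(dp) - 1L + max(s)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- dp_lo + s[b] - new_lo
      idx <- seq_along(dp) + off
      new[idx] <- new[idx] + dp * bg[b]
    }
    dp <- new
    dp_lo <- new_lo
  }
  keep <- dp > 0
  tibble(
    score = (dp_lo + which(keep) - 1L) * grid,
    prob = dp[keep]
  )
}

#' Score threshold for a target motif p-value
#'
#' Finds the minimal log2-odds score t such that the probability that a
#' random background w-mer scores >= t is at most `p_cutoff`, using the
#' exact discretized null distribution of [pwm_score_distribution()].
#' Matches the convention of genome-wide motif scans thresholded at a
#' per-position p-value (e.g. the 3e-5 cutoff used for CTCF motif tracks).
#'
#' @inheritParams pwm_score_distribution
#' @param p_cutoff target upper-tail probability, in (0,1); default 3e-5.
#' @return the threshold score (numeric scalar, on the grid) with
#'   attributes `tail_prob` (attained tail probability) and `attainable`.
#'   When even the maximal score has null probability above `p_cutoff`,
#'   no threshold below the maximum exists: returns `Inf` with
#'   `attainable = FALSE` and a warning.
#' @export
pwm_threshold <- function(x, p_cutoff = 3e-5, grid = 1e-3,
                          prob_floor = 1e-4) {
  if (!is.numeric(p_cutoff) || length(p_cutoff) != 1L ||
      p_cutoff <= 0 || p_cutoff >= 1) {
    stop_arg("`p_cutoff` must be in (0, 1)")
  }
  dist <- pwm_score_distribution(x, grid = grid, prob_floor = prob_floor)
  tail <- rev(cumsum(rev(dist$prob)))
  ok <- which(tail <= p_cutoff)
  if (length(ok) == 0L) {
    warn(paste0("no score threshold attains p <= ", p_cutoff,
                " for this PWM; returning Inf"))
    return(structure(Inf, tail_prob = tail[length(tail)],
                     attainable = FALSE))
  }
  i <- ok[1L]
  structure(dist$score[i], tail_prob = tail[i], attainable = TRUE)
}

# internal: score every offset of one sequence (character string) with an
# integer score matrix; N (or any non-ACGT) contributes -Inf.
scan_one_strand <- function(codes, smat, w) {
  L <- length(codes)
  if (L < w) return(numeric(0))
  n <- L - w + 1L
  s <- numeric(n)
  bad <- logical(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    nj <- is.na(cj)
    bad <- bad | nj
    cj[nj] <- 1L
    s <- s + smat[cbind(cj, j)]
  }
  s[bad] <- -Inf
  s
}

#' Scan sequences for motif occurrences
#'
#' Slides the PWM along every position of the given sequence(s) (and, by
#' default, their reverse complements) and reports all offsets whose
#' discretized log2-odds score meets the threshold. Overlapping hits are
#' retained. Positions containing N never match.
#'
#' @param sequences a named character vector of A/C/G/T/N sequences, a
#'   single string, or a [genome_model] carrying sequence.
#' @param pwm a [pwm].
#' @param threshold minimal log2-odds score, typically from
#'   [pwm_threshold()].
#' @param both_strands also scan the reverse strand (default TRUE).
#' @inheritParams pwm_score_distribution
#' @return tibble of motif hits: `chrom`, `start`, `end` (0-based
#'   half-open, width = PWM width), `strand` ("+"/"-"), `score`; sorted by
#'   (chrom, start, strand).
#' @export
scan_motifs <- function(sequences, pwm, threshold, both_strands = TRUE,
                        grid = 1e-3, prob_floor = 1e-4) {
  if (inherits(sequences, "genome_model")) {
    sequences <- genome_sequences(sequences)
  }
  if (is.null(names(sequences))) {
    if (length(sequences) != 1L) {
      stop_arg("multiple sequences must be named")
    }
    names(sequences) <- "seq"
  }
  stopifnot(inherits(pwm, "pwm"), is.numeric(threshold))
  if (!is.finite(threshold)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric()))
  }
  w <- pwm$width
  smat_f <- pwm_int_scores(pwm, grid = grid, prob_floor = prob_floor)
  smat_r <- pwm_int_scores(pwm_revcomp(pwm), grid = grid,
                           prob_floor = prob_floor)
  hits <- purrr::imap(sequences, function(s, nm) {
    codes <- match(strsplit(toupper(s), "")[[1]], BASES)
    res <- list()
    sc <- scan_one_strand(codes, smat_f, w) * grid
    i <- which(sc >= threshold)
    if (length(i)) {
      res$f <- tibble(chrom = nm, start = i - 1L, end = i - 1L + w,
                      strand = "+", score = sc[i])
    }
    if (both_strands) {
      sc <- scan_one_strand(codes, smat_r, w) * grid
      i <- which(sc >= threshold)
      if (length(i)) {
        res$r <- tibble(chrom = nm, start = i - 1L, end = i - 1L + w,
                        strand = "-", score = sc[i])
      }
    }
    dplyr::bind_rows(res)
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric()))
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
}

# internal: reverse complement of plain character sequences
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
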