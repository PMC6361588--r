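#' Synthetic genome model
#'
#' A minimal genome container: chromosome names and lengths, optional
#' A/C/G/T sequence per chromosome, and the bp-per-position resolution of
#' any derived tracks (default 1).
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param sequence optional named character vector of sequences; when
#'   present, each must match its chromosome length.
#' @param resolution bp per track position, default 1.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chrom_lengths, sequence = NULL, resolution = 1L) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths))) {
    stop_arg("`chrom_lengths` must be named, names unique")
  }
  if (any(chrom_lengths <= 0)) stop_arg("chromosome lengths must be positive")
  if (!is.null(sequence)) {
    if (!setequal(names(sequence), names(chrom_lengths))) {
      stop_arg("`sequence` names must match `chrom_lengths` names")
    }
    sequence <- sequence[names(chrom_lengths)]
    if (any(nchar(sequence) != chrom_lengths)) {
      stop_arg("sequence lengths must equal chromosome lengths")
    }
  }
  structure(
    list(
      chroms = tibble(chrom = names(chrom_lengths),
                      length = as.integer(chrom_lengths)),
      sequence = sequence,
      resolution = as.integer(resolution)
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$chroms), " chromosome(s), ",
      format(sum(as.double(x$chroms$length)), big.mark = ","), " bp",
      if (is.null(x$sequence)) " (no sequence)" else " (with sequence)",
      "\n", sep = "")
  invisible(x)
}

genome_sequences <- function(genome) {
  if (is.null(genome$sequence)) {
    stop_input("this genome_model carries no sequence")
  }
  genome$sequence
}

#' Generate a random genome
#'
#' Draws i.i.d. bases with the requested GC content. Deterministic for a
#' fixed seed.
#'
#' @param n_chroms number of chromosomes (named chr1, chr2, ...).
#' @param length_bp length of each chromosome in bp (scalar, recycled);
#'   must be >= 10000 — tracks and windowed statistics degenerate below
#'   that scale.
#' @param gc_fraction target G+C fraction, in (0,1).
#' @param seed RNG seed.
#' @param with_sequence generate the actual base string (default TRUE).
#'   Large null-simulation genomes that only feed the tag simulator can
#'   skip it.
#' @return A [genome_model].
#' @examples
#' g <- generate_genome(1, 10000, 0.5, seed = 1)
#' @export
generate_genome <- function(n_chroms, length_bp, gc_fraction = 0.42,
                            seed = 1L, with_sequence = TRUE) {
  if (!is_count(n_chroms)) stop_arg("`n_chroms` must be a positive integer")
  length_bp <- rep_len(as.integer(length_bp), n_chroms)
  if (any(length_bp <= 0)) stop_arg("`length_bp` must be positive")
  if (any(length_bp < 10000L)) stop_arg("`length_bp` must be >= 10000")
  if (gc_fraction <= 0 || gc_fraction > 1) {
    stop_arg("`gc_fraction` must be in (0, 1]")
  }
  lens <- setNames(length_bp, paste0("chr", seq_len(n_chroms)))
  seqs <- NULL
  if (with_sequence) {
    probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
               gc_fraction / 2, (1 - gc_fraction) / 2)
    seqs <- with_seed(seed, vapply(lens, function(L) {
      paste(BASES[sample.int(4L, L, replace = TRUE, prob = probs)],
            collapse = "")
    }, ""))
  }
  genome_model(lens, sequence = seqs)
}

#' Plant motif-bearing binding sites in a genome
#'
#' Places `n_sites` non-overlapping sites, assigns each a binding affinity
#' (expected ChIP enrichment multiplier) drawn uniformly from
#' `affinity_range`, and overwrites the genomic sequence inside each site
#' with `n_motifs` copies of the PWM consensus. A `phospho_fraction` of
#' the sites — those at the top of the affinity distribution — are flagged
#' as the phospho-bound subset and receive at least the median motif count
#' of the remaining sites, reproducing the empirical structure in which
#' the modified factor concentrates at higher-affinity, multi-motif sites.
#'
#' Sites keep a configurable minimum separation so that a window caller at
#' kilobase scale resolves them as distinct peaks.
#'
#' @param genome a [genome_model]; if it carries sequence, motifs are
#'   written into it (a copy is returned).
#' @param pwm the motif to plant ([pwm]).
#' @param config a [sim_config()].
#' @return list with elements `genome` (possibly rewritten) and `sites`, a
#'   tibble sorted by coordinate with columns `chrom`, `start`, `end`,
#'   `affinity`, `n_motifs`, `phospho`.
#' @export
plant_sites <- function(genome, pwm, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(pwm, "pwm"))
  config <- validate_sim_config(config)
  w <- pwm$width
  if (w > min(genome$chroms$length)) {
    stop_arg("motif longer than the shortest chromosome")
  }
  n <- config$n_sites
  with_seed(config$seed + 1L, {
    n_phospho <- round(config$phospho_fraction * n)
    affinity <- runif(n, config$affinity_range[1], config$affinity_range[2])
    phospho <- rank(-affinity, ties.method = "first") <= n_phospho
    n_motifs <- integer(n)
    n_motifs[!phospho] <- sample(1:3, sum(!phospho), replace = TRUE)
    med <- if (any(!phospho)) max(1, median(n_motifs[!phospho])) else 1
    hi <- max(4, med)
    n_motifs[phospho] <- sample(seq(med, hi), sum(phospho), replace = TRUE)
    widths <- pmax(config$site_width_bp, n_motifs * (w + 4L))
    placed <- place_intervals(genome$chroms, widths,
                              min_gap = config$site_min_gap_bp)
    sites <- tibble(
      chrom = placed$chrom, start = placed$start,
      end = placed$start + widths,
      affinity = affinity, n_motifs = n_motifs, phospho = phospho
    )
  })
  sites <- dplyr::arrange(sites, .data$chrom, .data$start)
  if (!is.null(genome$sequence)) {
    cons <- pwm_consensus(pwm)
    seqs <- genome$sequence
    for (i in seq_len(nrow(sites))) {
      s <- sites$start[i]; e <- sites$end[i]; k <- sites$n_motifs[i]
      # spread k consensus copies evenly across the site
      offs <- s + floor((e - s - w) * (seq_len(k) - 1) / max(1, k - 1) *
                          (if (k > 1) 1 else 0))
      if (k == 1) offs <- s + (e - s - w) %/% 2L
      for (o in offs) {
        substr(seqs[[sites$chrom[i]]], o + 1L, o + w) <- cons
      }
    }
    genome$sequence <- seqs
  }
  list(genome = genome, sites = sites)
}

# internal: place non-overlapping intervals of the given widths uniformly
# across chromosomes, enforcing a minimum gap; rejection sampling.
place_intervals <- function(chroms, widths, min_gap, max_tries = 200L) {
  n <- length(widths)
  probs <- chroms$length / sum(chroms$length)
  chrom_i <- sample.int(nrow(chroms), n, replace = TRUE, prob = probs)
  starts <- integer(n)
  for (i in seq_len(n)) {
    L <- chroms$length[chrom_i[i]]
    if (L < widths[i]) stop_arg("site wider than its chromosome")
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(L - widths[i] + 1L, 1L) - 1L
      prev <- which(chrom_i[seq_len(i - 1L)] == chrom_i[i])
      clash <- any(s < starts[prev] + widths[prev] + min_gap &
                     starts[prev] < s + widths[i] + min_gap)
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) {
      stop_arg("could not place ", n, " non-overlapping sites; ",
               "reduce n_sites or site_min_gap_bp, or enlarge the genome")
    }
    starts[i] <- s
  }
  list(chrom = chroms$chrom[chrom_i], start = starts)
}
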