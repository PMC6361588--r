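#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults are
#' the package's desk-scale study conditions: background ChIP depth 0.02
#' tags/bp with a five-fold deeper input (so a 1 kb window holds ~20
#' background ChIP tags, the regime where a kilobase window caller is
#' typically run), per-bp negative-binomial dispersion size 10 (the
#' dispersion of real ChIP libraries is not published for this design;
#' size 10 is a conventional moderately overdispersed choice), 50
#' window-scale (1 kb) planted sites of which 10% form the
#' phospho-bound subset, affinities 8-16x background, and a capture-region
#' contact model with two TAD boundaries (bins 34 and 52 of a 59-bin,
#' 25 kb-resolution region — the bin geometry of a ~1.46 Mb capture
#' design) depleted to 0.25 with distance-decay exponent 1.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @param depth_chip,depth_input expected background tags per bp; both > 0.
#' @param nb_size negative-binomial size (dispersion) of per-bp ChIP
#'   counts; variance is mu + mu^2/size.
#' @param nb_size_input size for the input library (defaults to
#'   `nb_size`); ChIP and input libraries need not share a dispersion.
#' @param n_sites number of planted binding sites.
#' @param phospho_fraction fraction of sites in the phospho-bound subset,
#'   in `[0,1]`.
#' @param affinity_range range (min, max) of the uniform affinity draw;
#'   min >= 1.
#' @param site_width_bp nominal planted-site width (bp).
#' @param site_min_gap_bp minimum separation between planted sites (bp);
#'   default 5000 keeps sites resolvable by a 1 kb window caller that
#'   merges across <= 1 kb gaps.
#' @param tad_boundaries bin indices of simulated TAD boundaries (cuts
#'   between bin b-1 and b, 0-based bins), strictly inside the region.
#' @param boundary_depletion multiplicative depletion of cross-boundary
#'   contacts, in (0, 1].
#' @param decay_exponent power-law slope of contact distance decay.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       depth_chip = 0.02,
                       depth_input = 0.1,
                       nb_size = 10,
                       nb_size_input = nb_size,
                       n_sites = 50L,
                       phospho_fraction = 0.1,
                       affinity_range = c(8, 16),
                       site_width_bp = 1000L,
                       site_min_gap_bp = 5000L,
                       tad_boundaries = c(34L, 52L),
                       boundary_depletion = 0.25,
                       decay_exponent = 1) {
  cfg <- structure(
    list(seed = as.integer(seed), depth_chip = depth_chip,
         depth_input = depth_input, nb_size = nb_size,
         nb_size_input = nb_size_input, n_sites = as.integer(n_sites),
         phospho_fraction = phospho_fraction,
         affinity_range = affinity_range,
         site_width_bp = as.integer(site_width_bp),
         site_min_gap_bp = as.integer(site_min_gap_bp),
         tad_boundaries = as.integer(tad_boundaries),
         boundary_depletion = boundary_depletion,
         decay_exponent = decay_exponent),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop_arg("expected a `sim_config`")
  if (cfg$depth_chip <= 0 || cfg$depth_input <= 0) {
    stop_arg("depths must be > 0")
  }
  if (cfg$nb_size <= 0 || cfg$nb_size_input <= 0) {
    stop_arg("nb_size must be > 0")
  }
  if (cfg$phospho_fraction < 0 || cfg$phospho_fraction > 1) {
    stop_arg("`phospho_fraction` must be in [0, 1]")
  }
  if (length(cfg$affinity_range) != 2L || cfg$affinity_range[1] < 1 ||
      diff(cfg$affinity_range) < 0) {
    stop_arg("`affinity_range` must be (min, max) with min >= 1")
  }
  if (cfg$boundary_depletion <= 0 || cfg$boundary_depletion > 1) {
    stop_arg("`boundary_depletion` must be in (0, 1]")
  }
  if (cfg$n_sites < 0) stop_arg("`n_sites` must be >= 0")
  cfg
}

#' Simulate ChIP and input tag tracks
#'
#' Draws per-bp tag counts from a negative binomial. The input mean is
#' `depth_input` everywhere; the ChIP mean is `depth_chip` multiplied by
#' each site's affinity inside planted sites and `depth_chip` elsewhere.
#' Deterministic for a fixed config seed.
#'
#' @param genome a [genome_model] (sequence not required).
#' @param sites tibble of planted sites as returned by [plant_sites()];
#'   may be empty (`NULL`) for a null simulation.
#' @param config a [sim_config()].
#' @return list with `chip` and `input`, both [tag_track]s at 1 bp
#'   resolution.
#' @export
simulate_tags <- function(genome, sites, config) {
  stopifnot(inherits(genome, "genome_model"))
  config <- validate_sim_config(config)
  if (is.null(sites)) {
    sites <- tibble(chrom = character(), start = integer(),
                    end = integer(), affinity = numeric())
  }
  lens <- setNames(genome$chroms$length, genome$chroms$chrom)
  with_seed(config$seed + 2L, {
    chip <- lapply(names(lens), function(nm) {
      L <- lens[[nm]]
      mu <- rep(config$depth_chip, L)
      ss <- sites[sites$chrom == nm, , drop = FALSE]
      if (nrow(ss)) {
        for (i in seq_len(nrow(ss))) {
          idx <- (ss$start[i] + 1L):ss$end[i]
          mu[idx] <- config$depth_chip * ss$affinity[i]
        }
      }
      rnbinom(L, size = config$nb_size, mu = mu)
    })
    names(chip) <- names(lens)
    input <- lapply(lens, function(L) {
      rnbinom(L, size = config$nb_size_input, mu = config$depth_input)
    })
  })
  list(chip = tag_track(chip), input = tag_track(input))
}

#' Simulate reads over a single codon
#'
#' Emulates an RNA-seq read pileup over one codon of a transgene carrying
#' a phosphomimetic substitution: a deterministic `round(mutant_fraction
#' * n_reads)` of the reads carry the mutant (glutamate) codon, the rest
#' the reference (serine) codon, and every base is then independently
#' miscalled with probability `error_rate` (uniformly to one of the other
#' three bases).
#'
#' @param n_reads number of reads.
#' @param mutant_fraction fraction carrying the mutant codon, in `[0,1]`.
#' @param error_rate per-base miscall probability, in `[0,1)`.
#' @param seed RNG seed.
#' @param mutant_codon,ref_codon codon spellings; defaults GAG (Glu) and
#'   TCC (Ser).
#' @return tibble with columns `read_id`, `base1`, `base2`, `base3`.
#' @export
simulate_codon_reads <- function(n_reads, mutant_fraction, error_rate = 0,
                                 seed = 1L, mutant_codon = "GAG",
                                 ref_codon = "TCC") {
  if (mutant_fraction < 0 || mutant_fraction > 1) {
    stop_arg("`mutant_fraction` must be in [0, 1]")
  }
  if (error_rate < 0 || error_rate >= 1) {
    stop_arg("`error_rate` must be in [0, 1)")
  }
  stopifnot(nchar(mutant_codon) == 3L, nchar(ref_codon) == 3L)
  n_mut <- round(mutant_fraction * n_reads)
  codons <- c(rep(mutant_codon, n_mut), rep(ref_codon, n_reads - n_mut))
  m <- matrix(unlist(strsplit(codons, "")), ncol = 3L, byrow = TRUE)
  with_seed(as.integer(seed) + 3L, {
    ord <- sample.int(n_reads)
    m <- m[ord, , drop = FALSE]
    if (error_rate > 0) {
      flip <- matrix(runif(3L * n_reads) < error_rate, ncol = 3L)
      if (any(flip)) {
        idx <- which(flip)
        cur <- m[idx]
        m[idx] <- vapply(cur, function(b) {
          sample(setdiff(BASES, b), 1L)
        }, "")
      }
    }
  })
  tibble(read_id = sprintf("read_%06d", seq_len(n_reads)),
         base1 = m[, 1L], base2 = m[, 2L], base3 = m[, 3L])
}
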