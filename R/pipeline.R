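#' Run the full synthetic-to-report demo pipeline
#'
#' Executes every stage of the package on synthetic data and writes all
#' declared outputs plus a run manifest under `out_dir`:
#'
#' 1. **simulate** — genome with planted motif sites ([plant_sites()]);
#'    a "total" ChIP/input tag pair driven by all sites and a "phospho"
#'    pair driven by the phospho-flagged subset ([simulate_tags()]).
#' 2. **callpeaks** — [call_peaks()] on both pairs.
#' 3. **compare** — shared-peak fraction ([intersect_peaks()]), per-peak
#'    coverage and R-squared ([peak_coverage()], [linear_r2()]), motif
#'    counts at the exact-tail score threshold ([pwm_threshold()],
#'    [scan_motifs()]), and a Wilcoxon shared-vs-all coverage test.
#' 4. **insulation** — simulated capture contact matrix,
#'    sqrt-coverage normalization, insulation track, boundaries and TAD
#'    score.
#' 5. **report** — codon-read classification and the DE up/down tally.
#'
#' Deterministic: the same `seed` reproduces every output byte for byte.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param genome_length chromosome length of the demo genome (bp).
#' @param sim a [sim_config()]; default
#'   `sim_config(seed = seed, n_sites = 60, phospho_fraction = 0.25)`.
#' @param caller a [caller_config()].
#' @param hic_depth expected pair count of the simulated contact matrix.
#' @param n_codon_reads,codon_mutant_fraction codon-read simulation; the
#'   default mutant fraction 0.14 sits mid-range of a modestly expressed
#'   phosphomimetic transgene.
#' @param de_counts named vector `c(up=, down=, null=)` for the synthetic
#'   DE table.
#' @param write_tracks also write the (large) per-200bp normalized
#'   coverage bedGraphs (default TRUE).
#' @return invisibly, the run manifest (class `run_manifest`): config
#'   echo, seeds, output paths, md5 checksums, and the stage summary
#'   tibbles under `$summary`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, genome_length = 2e6,
                         sim = NULL, caller = caller_config(),
                         hic_depth = 5e5, n_codon_reads = 5000L,
                         codon_mutant_fraction = 0.14,
                         de_counts = c(up = 118L, down = 257L,
                                       null = 11625L),
                         write_tracks = TRUE) {
  seed <- as.integer(seed)
  sim <- sim %||% sim_config(seed = seed, n_sites = 60L,
                             phospho_fraction = 0.25)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  out <- function(name, file) {
    paths[[name]] <<- file.path(out_dir, file)
    paths[[name]]
  }
  stage <- "simulate"
  res <- tryCatch({
    motif <- ctcf_like_pwm()
    genome <- generate_genome(1L, genome_length, gc_fraction = 0.42,
                              seed = seed)
    planted <- plant_sites(genome, motif, sim)
    genome <- planted$genome
    sites <- planted$sites
    tags_total <- simulate_tags(genome, sites, sim)
    sim_ph <- sim
    sim_ph$seed <- sim$seed + 101L
    tags_ph <- simulate_tags(genome, sites[sites$phospho, ], sim_ph)
    write_fasta(genome, out("genome_fasta", "genome.fa"))
    truth <- dplyr::mutate(sites,
                           name = sprintf("site_%03d", dplyr::row_number()),
                           score = round(100 * .data$affinity),
                           strand = ".")
    write_bed(truth, out("truth_sites_bed", "truth_sites.bed"))

    stage <- "callpeaks"
    calls_total <- call_peaks(tags_total$chip, tags_total$input, caller)
    calls_ph <- call_peaks(tags_ph$chip, tags_ph$input, caller)
    for (lbl in c("total", "phospho")) {
      cc <- if (lbl == "total") calls_total else calls_ph
      pk <- dplyr::mutate(tidy(cc),
                          name = sprintf("%s_peak_%04d", lbl,
                                         dplyr::row_number()),
                          score = pmin(1000, round(100 * .data$z_max)),
                          strand = ".")
      write_bed(pk, out(paste0("peaks_", lbl, "_bed"),
                        paste0("peaks_", lbl, ".bed")))
      readr::write_tsv(cc$windows,
                       out(paste0("windows_", lbl, "_tsv"),
                           paste0("windows_", lbl, ".tsv")))
      if (write_tracks) {
        cov <- normalized_coverage(
          (if (lbl == "total") tags_total else tags_ph)$chip,
          (if (lbl == "total") tags_total else tags_ph)$input
        )
        write_bedgraph(cov, out(paste0("coverage_", lbl, "_bedgraph"),
                                paste0("coverage_", lbl, ".bedGraph")))
      }
    }

    stage <- "compare"
    peaks_total <- tidy(calls_total)
    peaks_ph <- tidy(calls_ph)
    shared <- intersect_peaks(peaks_ph, peaks_total)
    shared_total <- intersect_peaks(peaks_total, peaks_ph)$shared
    cov_t <- peak_coverage(tags_total$chip, peaks_total)$coverage
    cov_p <- peak_coverage(tags_ph$chip, peaks_total)$coverage
    r2_all <- linear_r2(cov_t, cov_p)
    idx_shared <- overlap_counts(peaks_total, peaks_ph) > 0L
    r2_shared <- if (sum(idx_shared) >= 3L) {
      linear_r2(cov_t[idx_shared], cov_p[idx_shared])
    } else tibble(r_squared = NA_real_)
    wil <- if (nrow(shared_total) >= 1L) {
      wilcoxon_rank_sum(
        peak_coverage(tags_total$chip, shared_total)$coverage, cov_t
      )
    } else tibble(p_value = NA_real_)
    thr <- pwm_threshold(motif)
    motifs <- scan_motifs(genome, motif, thr)
    write_bed(dplyr::mutate(motifs, name = "motif", score = .data$score),
              out("motifs_bed", "motifs.bed"))
    n_mot_total <- count_motifs_in_peaks(motifs, peaks_total)$n_motifs
    n_mot_shared <- n_mot_total[idx_shared]

    stage <- "insulation"
    cm <- simulate_contact_matrix(
      n_bins = 59L, resolution_bp = 25000L,
      tad_boundaries = sim$tad_boundaries,
      boundary_depletion = sim$boundary_depletion,
      decay_exponent = sim$decay_exponent,
      depth = hic_depth, seed = seed
    )
    write_matrix(cm, out("matrix_tsv", "contact_matrix.tsv"))
    ins <- insulation_score(sqrt_coverage_normalize(cm))
    ins_bg <- dplyr::filter(
      dplyr::mutate(ins, chrom = attr(ins, "chrom")), .data$valid
    )[, c("chrom", "start", "end", "score")]
    write_bedgraph(ins_bg, out("insulation_bedgraph",
                               "insulation.bedGraph"))
    bounds <- delta_and_boundaries(ins)
    write_bed(dplyr::mutate(bounds, chrom = attr(ins, "chrom"),
                            name = "boundary",
                            score = round(100 * .data$strength)),
              out("boundaries_bed", "boundaries.bed"))
    tad <- tad_score(ins, sim$tad_boundaries[1], sim$tad_boundaries[2])
    jsonlite::write_json(as.list(tad), out("tad_json", "tad_score.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "report"
    reads <- simulate_codon_reads(n_codon_reads, codon_mutant_fraction,
                                  error_rate = 0.005, seed = seed)
    readr::write_tsv(reads, out("codon_reads_tsv", "codon_reads.tsv"))
    tally <- classify_codon_reads(reads)
    de_tab <- synthetic_de_table(de_counts[["up"]], de_counts[["down"]],
                                 de_counts[["null"]], seed = seed)
    readr::write_tsv(de_tab, out("de_table_tsv", "de_table.tsv"))
    de <- report_de_fractions(de_tab)

    summary <- list(
      peaks = tibble(
        n_total_peaks = nrow(peaks_total),
        n_phospho_peaks = nrow(peaks_ph),
        n_sites = nrow(sites),
        n_phospho_sites = sum(sites$phospho),
        shared_fraction = shared$fraction
      ),
      r2 = tibble(r2_all = r2_all$r_squared,
                  r2_shared = r2_shared$r_squared),
      coverage_wilcoxon_p = wil$p_value,
      motif_counts = tibble(
        mean_motifs_total = mean(n_mot_total),
        mean_motifs_shared = if (length(n_mot_shared)) mean(n_mot_shared)
                             else NA_real_
      ),
      tad = tad,
      codon = glance(tally),
      de = de
    )
    jsonlite::write_json(
      summary, out("summary_json", "summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null"
    )
    summary
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)),
          class = "phospeaks_stage_error", parent = e)
  })

  manifest <- list(
    tool = "phospeaks",
    version = as.character(utils::packageVersion("phospeaks")),
    seed = seed,
    params = list(
      genome_length = genome_length,
      sim = unclass(sim),
      caller = unclass(caller),
      hic_depth = hic_depth,
      n_codon_reads = n_codon_reads,
      codon_mutant_fraction = codon_mutant_fraction,
      de_counts = as.list(de_counts),
      write_tracks = write_tracks
    ),
    outputs = lapply(paths, normalizePath),
    checksums = as.list(tools::md5sum(unlist(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$summary <- res
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' Re-run a pipeline from its manifest
#'
#' Reads a `manifest.json` written by [run_pipeline()] and re-executes
#' the pipeline with the recorded parameters; with an unchanged package
#' version the outputs are byte-identical.
#'
#' @param manifest_path path to a manifest.json.
#' @param out_dir where to write the re-run (default: alongside the
#'   manifest).
#' @return the new run manifest, invisibly.
#' @export
rerun_pipeline <- function(manifest_path, out_dir = dirname(manifest_path)) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  p <- man$params
  sim <- do.call(sim_config, p$sim[setdiff(names(p$sim), character(0))])
  caller <- do.call(caller_config, p$caller)
  run_pipeline(out_dir, seed = man$seed, genome_length = p$genome_length,
               sim = sim, caller = caller, hic_depth = p$hic_depth,
               n_codon_reads = p$n_codon_reads,
               codon_mutant_fraction = p$codon_mutant_fraction,
               de_counts = unlist(p$de_counts),
               write_tracks = isTRUE(p$write_tracks))
}
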