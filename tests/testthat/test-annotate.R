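make_gene <- function(gene_id, chrom, strand, tx_start, tx_end,
                      cds_start, cds_end, exon_starts, exon_ends) {
  tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 tx_start = tx_start, tx_end = tx_end,
                 cds_start = cds_start, cds_end = cds_end,
                 exon_starts = list(exon_starts),
                 exon_ends = list(exon_ends))
}

two_genes <- function() {
  dplyr::bind_rows(
    # plus-strand gene: 5'UTR 1000-1200, CDS 1200-2600 over 2 exons,
    # 3'UTR 2600-3000
    make_gene("gA", "chr1", "+", 1000L, 3000L, 1200L, 2600L,
              c(1000L, 2000L), c(1500L, 3000L)),
    # minus-strand single-exon gene
    make_gene("gB", "chr1", "-", 6000L, 8000L, 6300L, 7600L,
              6000L, 8000L)
  )
}

test_that("gene tables validate exon structure and parse refFlat strings", {
  g <- two_genes()
  expect_s3_class(genes_tibble(g), "tbl_df")
  flat <- dplyr::mutate(g, exon_starts = "1000,2000",
                        exon_ends = "1500,3000")
  parsed <- genes_tibble(flat[1, ])
  expect_equal(parsed$exon_starts[[1]], c(1000L, 2000L))
  bad <- dplyr::mutate(g, exon_ends = list(c(900L, 3000L), 8000L))
  expect_error(genes_tibble(bad), class = "phospeaks_arg_error")
})

test_that("peaks are assigned by midpoint with the documented priority", {
  genes <- two_genes()
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(940L,    # mid 965: promoter of gA ([900, 1100))
              1290L,   # mid 1315: CDS exon
              1690L,   # mid 1715: intron
              1080L,   # mid 1105: 5'UTR (just outside the promoter)
              2680L,   # mid 2705: 3'UTR
              3010L,   # mid 3035: downstream of gA (+)
              4600L,   # mid 4625: intergenic
              7900L),  # mid 7925: promoter of gB (TSS at tx_end, minus)
    end = start + 50L
  )
  fd <- annotate_peaks(peaks, genes, promoter_bp = 100L,
                       chrom_lengths = c(chr1 = 10000L))
  got <- tibble::as_tibble(fd)
  expect_equal(sum(got$fraction), 1)
  expect_equal(sum(got$background_fraction), 1)
  frac <- function(cat) got$fraction[got$category == cat]
  expect_equal(frac("promoter"), 2 / 8)
  expect_equal(frac("utr5"), 1 / 8)
  expect_equal(frac("utr3"), 1 / 8)
  expect_equal(frac("exon"), 1 / 8)
  expect_equal(frac("intron"), 1 / 8)
  expect_equal(frac("downstream"), 1 / 8)
  expect_equal(frac("intergenic"), 1 / 8)

  # promoter wins over exonic UTR when both apply (mid 7950 is inside
  # gB's 5'UTR exon and its promoter window)
  overlap_peak <- tibble::tibble(chrom = "chr1", start = 7925L, end = 7975L)
  fd2 <- annotate_peaks(overlap_peak, genes, promoter_bp = 100L,
                        chrom_lengths = c(chr1 = 10000L))
  expect_equal(tibble::as_tibble(fd2)$fraction[1], 1)   # promoter row

  # permutation invariance
  perm <- peaks[sample.int(nrow(peaks)), ]
  fd3 <- annotate_peaks(perm, genes, promoter_bp = 100L,
                        chrom_lengths = c(chr1 = 10000L))
  expect_equal(tibble::as_tibble(fd3)$fraction, got$fraction)

  expect_error(annotate_peaks(peaks[0, ], genes),
               class = "phospeaks_input_error")
})

test_that("without genes everything is intergenic", {
  peaks <- tibble::tibble(chrom = "chr1", start = c(10L, 500L),
                          end = c(60L, 900L))
  fd <- annotate_peaks(peaks, two_genes()[0, ],
                       chrom_lengths = c(chr1 = 5000L))
  got <- tibble::as_tibble(fd)
  expect_equal(got$fraction[got$category == "intergenic"], 1)
})

test_that("metagene profiles rescale bodies and orient minus-strand genes", {
  genes <- two_genes()
  # constant coverage: flat profile
  const <- tag_track(list(chr1 = rep(3L, 10000)))
  prof <- metagene_profile(const, genes, n_body_bins = 10L,
                           flank_bp = 500L, flank_bins = 5L)
  expect_true(all(abs(prof$mean_value - 3) < 1e-12))
  expect_equal(nrow(prof), 20L)

  # signal only upstream of the plus-strand TSS stays in the left flank
  v <- rep(0L, 10000); v[601:1000] <- 10L   # bp 600-1000, upstream of gA
  up <- tag_track(list(chr1 = v))
  prof2 <- metagene_profile(up, genes[1, ], n_body_bins = 10L,
                            flank_bp = 500L, flank_bins = 5L)
  expect_true(any(prof2$mean_value[prof2$region == "upstream"] > 0))
  expect_true(all(prof2$mean_value[prof2$region != "upstream"] == 0))

  # minus-strand orientation: signal upstream of gB's TSS (right of
  # tx_end) appears in the left (5') flank after reversal
  v2 <- rep(0L, 10000); v2[8001:8400] <- 4L
  prof3 <- metagene_profile(tag_track(list(chr1 = v2)), genes[2, ],
                            n_body_bins = 10L, flank_bp = 500L,
                            flank_bins = 5L)
  expect_true(any(prof3$mean_value[prof3$region == "upstream"] > 0))
  expect_true(all(prof3$mean_value[prof3$region == "downstream"] == 0))

  # hand-binned two-gene oracle
  withr::with_seed(53, {
    vv <- rpois(10000, 1)
  })
  tr <- tag_track(list(chr1 = vv))
  prof4 <- metagene_profile(tr, genes, n_body_bins = 4L,
                            flank_bp = 400L, flank_bins = 2L)
  hand_gene <- function(tx_start, tx_end, minus) {
    body_cuts <- tx_start + floor((tx_end - tx_start) * (0:4) / 4)
    bins <- c(
      mean(vv[(tx_start - 400 + 1):(tx_start - 200)]),
      mean(vv[(tx_start - 200 + 1):tx_start]),
      vapply(1:4, function(j) {
        mean(vv[(body_cuts[j] + 1):body_cuts[j + 1]])
      }, 0),
      mean(vv[(tx_end + 1):(tx_end + 200)]),
      mean(vv[(tx_end + 200 + 1):(tx_end + 400)])
    )
    if (minus) rev(bins) else bins
  }
  oracle <- colMeans(rbind(hand_gene(1000, 3000, FALSE),
                           hand_gene(6000, 8000, TRUE)))
  expect_equal(prof4$mean_value, oracle)

  # genes shorter than the bin count are skipped and counted
  short <- make_gene("gS", "chr1", "+", 100L, 105L, 100L, 105L, 100L, 105L)
  prof5 <- metagene_profile(tr, dplyr::bind_rows(genes, short),
                            n_body_bins = 10L, flank_bp = 500L,
                            flank_bins = 5L)
  expect_equal(attr(prof5, "n_skipped"), 1L)
  expect_equal(attr(prof5, "n_genes"), 2L)

  expect_s3_class(autoplot(prof4), "ggplot")
})
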