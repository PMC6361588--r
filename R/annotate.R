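FEATURE_LEVELS <- c("promoter", "utr5", "utr3", "exon", "intron",
                    "downstream", "intergenic")

#' Gene model table
#'
#' Validates a tibble of gene models: columns `gene_id`, `chrom`,
#' `strand` ("+"/"-"), `tx_start`, `tx_end`, `cds_start`, `cds_end`
#' (0-based half-open) and list-columns `exon_starts`, `exon_ends`
#' (sorted, non-overlapping, within the transcript).
#'
#' @param genes a data frame as above; `exon_starts`/`exon_ends` may also
#'   be comma-separated strings (refFlat style), which are parsed.
#' @return the validated tibble.
#' @export
genes_tibble <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exon_starts", "exon_ends")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop_arg("missing gene columns: ",
                             paste(miss, collapse = ", "))
  genes <- as_tibble(genes)
  parse_pos <- function(x) {
    if (is.list(x)) lapply(x, as.integer)
    else lapply(strsplit(as.character(x), ","), as.integer)
  }
  genes$exon_starts <- parse_pos(genes$exon_starts)
  genes$exon_ends <- parse_pos(genes$exon_ends)
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) != length(ee) || any(ee <= es) ||
        is.unsorted(es, strictly = TRUE) ||
        any(es < genes$tx_start[i]) || any(ee > genes$tx_end[i]) ||
        any(utils::head(ee, -1) > utils::tail(es, -1))) {
      stop_arg("invalid exon structure for gene ", genes$gene_id[i])
    }
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop_arg("strand must be '+' or '-'")
  }
  genes
}

# internal: per-category interval tibbles derived from gene models
feature_intervals <- function(genes, promoter_bp) {
  rows <- purrr::pmap(genes, function(gene_id, chrom, strand, tx_start,
                                      tx_end, cds_start, cds_end,
                                      exon_starts, exon_ends, ...) {
    tss <- if (strand == "+") tx_start else tx_end
    promoter <- c(tss - promoter_bp, tss + promoter_bp)
    down <- if (strand == "+") c(tx_end, tx_end + promoter_bp)
            else c(tx_start - promoter_bp, tx_start)
    ex <- tibble(start = exon_starts, end = exon_ends)
    clip <- function(df, lo, hi) {
      df <- dplyr::mutate(df, start = pmax(.data$start, lo),
                          end = pmin(.data$end, hi))
      dplyr::filter(df, .data$end > .data$start)
    }
    utr_left <- clip(ex, tx_start, cds_start)   # exonic, left of CDS
    utr_right <- clip(ex, cds_end, tx_end)      # exonic, right of CDS
    cds_ex <- clip(ex, cds_start, cds_end)
    list(
      chrom = chrom,
      promoter = tibble(start = promoter[1], end = promoter[2]),
      utr5 = if (strand == "+") utr_left else utr_right,
      utr3 = if (strand == "+") utr_right else utr_left,
      exon = cds_ex,
      tx = tibble(start = tx_start, end = tx_end),
      downstream = tibble(start = down[1], end = down[2])
    )
  })
  cats <- c("promoter", "utr5", "utr3", "exon", "tx", "downstream")
  out <- lapply(cats, function(cat) {
    dplyr::bind_rows(lapply(rows, function(r) {
      dplyr::mutate(r[[cat]], chrom = r$chrom)
    }))
  })
  names(out) <- cats
  out
}

# internal: classify 0-based points by the fixed priority
classify_points <- function(chrom, pos, feats) {
  pts <- tibble(chrom = chrom, start = pos, end = pos + 1L)
  inside <- function(set) {
    if (nrow(set) == 0L) return(logical(length(pos)))
    overlap_counts(pts, set) > 0L
  }
  in_tx <- inside(feats$tx)
  in_exonic <- inside(feats$exon) | inside(feats$utr5) | inside(feats$utr3)
  cat <- rep("intergenic", length(pos))
  cat[inside(feats$downstream)] <- "downstream"
  cat[in_tx & !in_exonic] <- "intron"
  cat[inside(feats$exon)] <- "exon"
  cat[inside(feats$utr3)] <- "utr3"
  cat[inside(feats$utr5)] <- "utr5"
  cat[inside(feats$promoter)] <- "promoter"
  factor(cat, levels = FEATURE_LEVELS)
}

#' Genomic feature distribution of a peak set
#'
#' Assigns each peak — by its midpoint — to exactly one genomic feature
#' category with the fixed priority promoter > 5'UTR > 3'UTR > exon >
#' intron > downstream > intergenic, and reports the fraction of peaks
#' per category. A genome background is computed by classifying uniformly
#' spaced probe points with the same rule, so the two columns are
#' directly comparable.
#'
#' @param peaks tibble with `chrom`, `start`, `end`; must be non-empty.
#' @param genes gene models (see [genes_tibble()]).
#' @param promoter_bp promoter half-width around the TSS, also used for
#'   the downstream window (default 1000).
#' @param chrom_lengths named vector of chromosome lengths for the
#'   background probes, or a [genome_model]; when NULL, inferred as the
#'   max coordinate seen per chromosome.
#' @param probe_step spacing of background probe points (default 1000).
#' @return An object of class `feature_distribution`: tibble with
#'   `category`, `n`, `fraction`, `background_fraction`; both fraction
#'   columns sum to 1.
#' @export
annotate_peaks <- function(peaks, genes, promoter_bp = 1000L,
                           chrom_lengths = NULL, probe_step = 1000L) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0L) stop_input("empty peak set")
  genes <- genes_tibble(genes)
  feats <- feature_intervals(genes, promoter_bp)
  mid <- (peaks$start + peaks$end) %/% 2L
  cat <- classify_points(peaks$chrom, mid, feats)

  if (inherits(chrom_lengths, "genome_model")) {
    chrom_lengths <- setNames(chrom_lengths$chroms$length,
                              chrom_lengths$chroms$chrom)
  }
  if (is.null(chrom_lengths)) {
    all_pos <- dplyr::bind_rows(
      dplyr::select(peaks, "chrom", "end"),
      tibble(chrom = genes$chrom, end = genes$tx_end + promoter_bp)
    )
    chrom_lengths <- tapply(all_pos$end, all_pos$chrom, max)
  }
  probes <- purrr::imap(as.list(chrom_lengths), function(L, nm) {
    tibble(chrom = nm, pos = seq.int(0L, L - 1L, by = probe_step))
  }) |> dplyr::bind_rows()
  bg <- classify_points(probes$chrom, probes$pos, feats)

  tab <- table(cat)
  bgt <- table(bg)
  out <- tibble(
    category = FEATURE_LEVELS,
    n = as.integer(tab[FEATURE_LEVELS]),
    fraction = as.numeric(tab[FEATURE_LEVELS] / sum(tab)),
    background_fraction = as.numeric(bgt[FEATURE_LEVELS] / sum(bgt))
  )
  structure(out, class = c("feature_distribution", class(out)),
            n_peaks = nrow(peaks), promoter_bp = promoter_bp)
}

#' Metagene coverage profile
#'
#' Averages a per-base coverage track over a set of genes after rescaling
#' every gene body to `n_body_bins` bins and attaching fixed-width
#' flanking bins on both sides. Minus-strand genes are reversed so the
#' profile always reads 5' to 3' left to right. Genes whose body is
#' shorter than `n_body_bins` bases are skipped (their count is
#' reported); flank positions beyond a chromosome end are ignored in the
#' means.
#'
#' @param track a [tag_track] holding per-base coverage.
#' @param genes gene models (see [genes_tibble()]).
#' @param n_body_bins number of gene-body bins (default 60).
#' @param flank_bp flank width in bp on each side (default 2000).
#' @param flank_bins number of bins per flank (default 20); must divide
#'   `flank_bp`.
#' @return An object of class `metagene_profile`: tibble with `bin`
#'   (1-based across upstream, body, downstream), `region`,
#'   `mean_value`; attributes `n_genes`, `n_skipped`.
#' @export
metagene_profile <- function(track, genes, n_body_bins = 60L,
                             flank_bp = 2000L, flank_bins = 20L) {
  stopifnot(is_tag_track(track))
  genes <- genes_tibble(genes)
  if (flank_bp %% flank_bins != 0L) {
    stop_arg("`flank_bins` must divide `flank_bp`")
  }
  fw <- flank_bp %/% flank_bins
  total_bins <- flank_bins + n_body_bins + flank_bins
  acc <- matrix(0, nrow = 0, ncol = total_bins)
  n_skipped <- 0L
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    v <- track$counts[[g$chrom]]
    if (is.null(v)) stop_input("track does not cover chromosome: ", g$chrom)
    Lb <- g$tx_end - g$tx_start
    if (Lb < n_body_bins) { n_skipped <- n_skipped + 1L; next }
    # flank bins (genomic orientation), NA outside the chromosome
    bin_mean <- function(s, e) {   # 0-based half-open bp
      s <- max(s, 0L); e <- min(e, length(v))
      if (e <= s) return(NA_real_)
      mean(v[(s + 1L):e])
    }
    left <- vapply(seq_len(flank_bins), function(j) {
      bin_mean(g$tx_start - flank_bp + (j - 1L) * fw,
               g$tx_start - flank_bp + j * fw)
    }, 0)
    right <- vapply(seq_len(flank_bins), function(j) {
      bin_mean(g$tx_end + (j - 1L) * fw, g$tx_end + j * fw)
    }, 0)
    cuts <- g$tx_start + floor(Lb * (0:n_body_bins) / n_body_bins)
    body <- vapply(seq_len(n_body_bins), function(j) {
      bin_mean(cuts[j], cuts[j + 1L])
    }, 0)
    prof <- c(left, body, right)
    if (g$strand == "-") prof <- rev(prof)
    rows[[i]] <- prof
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) stop_input("no gene long enough to profile")
  m <- do.call(rbind, rows)
  out <- tibble(
    bin = seq_len(total_bins),
    region = rep(c("upstream", "body", "downstream"),
                 c(flank_bins, n_body_bins, flank_bins)),
    mean_value = colMeans(m, na.rm = TRUE)
  )
  structure(out, class = c("metagene_profile", class(out)),
            n_genes = length(rows), n_skipped = n_skipped,
            n_body_bins = n_body_bins, flank_bins = flank_bins,
            flank_bp = flank_bp)
}
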