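# Readers and writers for the plain-text formats the pipeline exchanges.
# All interval records are 0-based half-open in memory and on disk (BED
# convention); pair files carry 1-based positions. Malformed lines are
# rejected with their line number.

read_lines_table <- function(path, n_min_cols, what) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(NULL)
  parts <- strsplit(lines, "\t| +")
  ncols <- lengths(parts)
  bad <- which(ncols < n_min_cols)
  if (length(bad)) {
    stop_input(what, ": line ", bad[1L], " has ", ncols[bad[1L]],
               " field(s), need >= ", n_min_cols)
  }
  parts
}

num_field <- function(parts, i, what, integer = TRUE) {
  v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", i)))
  bad <- which(is.na(v))
  if (length(bad)) {
    stop_input(what, ": line ", bad[1L], " has a non-numeric field ", i)
  }
  if (integer) as.integer(v) else v
}

#' Read and write BED intervals
#'
#' BED3-BED6; coordinates stay 0-based half-open. `write_bed()` fills
#' `name`/`score`/`strand` with defaults when absent and writes BED6.
#'
#' @param path file path.
#' @return `read_bed()`: tibble with `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  parts <- read_lines_table(path, 3L, "BED")
  if (is.null(parts)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  out <- tibble(
    chrom = vapply(parts, `[[`, "", 1L),
    start = num_field(parts, 2L, "BED"),
    end = num_field(parts, 3L, "BED")
  )
  bad <- which(out$end <= out$start)
  if (length(bad)) {
    stop_input("BED: line ", bad[1L], " has end <= start")
  }
  nc <- min(lengths(parts))
  if (nc >= 4L) out$name <- vapply(parts, `[[`, "", 4L)
  if (nc >= 5L) out$score <- num_field(parts, 5L, "BED", integer = FALSE)
  if (nc >= 6L) out$strand <- vapply(parts, `[[`, "", 6L)
  out
}

#' @rdname read_bed
#' @param x interval tibble (`chrom`, `start`, `end`, optionally `name`,
#'   `score`, `strand`).
#' @export
write_bed <- function(x, path) {
  stopifnot(is.data.frame(x))
  df <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    name = x[["name"]] %||% sprintf("region_%d", seq_len(nrow(x))),
    score = x[["score"]] %||% 0,
    strand = x[["strand"]] %||% "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write bedGraph tracks
#'
#' Four columns (`chrom`, `start`, `end`, `score`), 0-based half-open.
#' Overlapping intervals on a chromosome are rejected with the offending
#' line number: a bedGraph is a function of position, not a feature list.
#'
#' @param path file path.
#' @return `read_bedgraph()`: tibble `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  parts <- read_lines_table(path, 4L, "bedGraph")
  if (is.null(parts)) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), score = numeric()))
  }
  out <- tibble(
    chrom = vapply(parts, `[[`, "", 1L),
    start = num_field(parts, 2L, "bedGraph"),
    end = num_field(parts, 3L, "bedGraph"),
    score = num_field(parts, 4L, "bedGraph", integer = FALSE),
    .line = seq_along(parts)
  )
  bad <- which(out$end <= out$start)
  if (length(bad)) stop_input("bedGraph: line ", bad[1L], " has end <= start")
  for (nm in unique(out$chrom)) {
    sub <- out[out$chrom == nm, ]
    o <- order(sub$start)
    ov <- which(utils::head(sub$end[o], -1) > utils::tail(sub$start[o], -1))
    if (length(ov)) {
      ln <- max(sub$.line[o][ov[1L]], sub$.line[o][ov[1L] + 1L])
      stop_input("bedGraph: line ", ln,
                 " overlaps a previous interval on ", nm)
    }
  }
  dplyr::select(out, !".line")
}

#' @rdname read_bedgraph
#' @param x tibble with `chrom`, `start`, `end`, `score` (a `count`
#'   column is accepted as the score).
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(is.data.frame(x))
  score <- x[["score"]] %||% x[["count"]]
  if (is.null(score)) stop_arg("need a `score` (or `count`) column")
  utils::write.table(
    data.frame(x$chrom, x$start, x$end, score),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read and write JASPAR-style PWM text
#'
#' The four-row count/frequency format: an optional `>name` header, then
#' rows `A [ 1 2 3 ]` (brackets optional). Counts are normalized
#' column-wise to probabilities.
#'
#' @param path file path.
#' @return `read_pwm()`: a [pwm].
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- NULL
  if (grepl("^>", lines[1L])) {
    name <- trimws(sub("^>", "", lines[1L]))
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stop_input("PWM: need 4 base rows")
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("\\[|\\]", " ", l)
    toks <- strsplit(trimws(l), "[ \t]+")[[1]]
    base <- toupper(toks[1L])
    vals <- suppressWarnings(as.numeric(toks[-1L]))
    if (!base %in% BASES || anyNA(vals)) {
      stop_input("PWM: malformed base row: ", l)
    }
    setNames(list(vals), base)
  })
  counts <- do.call(rbind, unlist(rows, recursive = FALSE))
  counts <- counts[BASES, , drop = FALSE]
  cs <- colSums(counts)
  if (any(cs <= 0)) stop_input("PWM: a column sums to zero")
  pwm(sweep(counts, 2, cs, "/"), name = name)
}

#' @rdname read_pwm
#' @param x a [pwm].
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", x$name %||% "motif"), con)
  for (b in BASES) {
    writeLines(paste0(b, "  [ ", paste(format(x$prob[b, ], digits = 6),
                                       collapse = " "), " ]"), con)
  }
  invisible(path)
}

#' Read and write dense contact-matrix TSV
#'
#' Tab-delimited square matrix with a header row and column of bin start
#' coordinates; the top-left cell carries the region as
#' `chrom:start-end`. Round-trips a [contact_matrix].
#'
#' @param path file path.
#' @return `read_matrix()`: a [contact_matrix].
#' @export
read_matrix <- function(path) {
  region <- strsplit(readLines(path, n = 1L), "\t")[[1]][1L]
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(tab)
  rg <- regmatches(region, regexec("^(.+):(\\d+)-(\\d+)$",
                                   as.character(region)))[[1]]
  if (length(rg) != 4L) {
    stop_input("matrix: top-left cell must be chrom:start-end, got '",
               region, "'")
  }
  starts <- as.integer(colnames(m))
  res <- if (length(starts) > 1L) diff(starts)[1L] else
    as.integer(rg[4L]) - as.integer(rg[3L])
  dimnames(m) <- NULL
  contact_matrix(m, chrom = rg[2L], start = as.integer(rg[3L]),
                 end = as.integer(rg[4L]), resolution_bp = res)
}

#' @rdname read_matrix
#' @param x a [contact_matrix].
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "contact_matrix"))
  starts <- x$start + (seq_len(ncol(x$matrix)) - 1L) * x$resolution_bp
  df <- as.data.frame(x$matrix)
  colnames(df) <- starts
  df <- cbind(setNames(data.frame(starts), paste0(x$chrom, ":", x$start,
                                                  "-", x$end)), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write Hi-C tag-pair files
#'
#' Tab-delimited `chrom1 pos1 strand1 chrom2 pos2 strand2` (strands are
#' read but ignored downstream); positions are 1-based. A 4-column
#' variant without strands is accepted.
#'
#' @param path file path.
#' @return `read_pairs()`: tibble `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @export
read_pairs <- function(path) {
  parts <- read_lines_table(path, 4L, "pairs")
  if (is.null(parts)) {
    return(tibble(chrom1 = character(), pos1 = integer(),
                  chrom2 = character(), pos2 = integer()))
  }
  nc <- min(lengths(parts))
  six <- nc >= 6L
  tibble(
    chrom1 = vapply(parts, `[[`, "", 1L),
    pos1 = num_field(parts, 2L, "pairs"),
    chrom2 = vapply(parts, `[[`, "", if (six) 4L else 3L),
    pos2 = num_field(parts, if (six) 5L else 4L, "pairs")
  )
}

#' @rdname read_pairs
#' @param x tibble with `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @export
write_pairs <- function(x, path) {
  utils::write.table(
    data.frame(x$chrom1, x$pos1, "+", x$chrom2, x$pos2, "+"),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings. `read_fasta()` returns a named
#' character vector; `genome_from_fasta()` additionally wraps it in a
#' [genome_model].
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub(" .*$", "", names(out))
  out
}

#' @rdname read_fasta
#' @param x named character vector (or a [genome_model] with sequence).
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "genome_model")) x <- genome_sequences(x)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path,
                              width = 70L)
  invisible(path)
}

#' @rdname read_fasta
#' @export
genome_from_fasta <- function(path) {
  seqs <- read_fasta(path)
  genome_model(setNames(nchar(seqs), names(seqs)), sequence = seqs)
}

#' Read a differential-expression table
#'
#' Tab-delimited with a header; needs a gene identifier, a log2 fold
#' change and an adjusted p-value. Common column spellings
#' (`log2FoldChange`, `padj`, `adj.P.Val`, ...) are recognized.
#'
#' @param path file path.
#' @return tibble `gene_id`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path) {
  tab <- as_tibble(utils::read.delim(path, check.names = FALSE))
  pick <- function(cands, what) {
    hit <- intersect(cands, names(tab))
    if (length(hit) == 0L) {
      stop_input("DE table: no ", what, " column (looked for ",
                 paste(cands, collapse = ", "), ")")
    }
    tab[[hit[1L]]]
  }
  out <- tibble(
    gene_id = as.character(pick(c("gene_id", "gene", "id", "symbol"),
                                "gene id")),
    log2fc = as.numeric(pick(c("log2fc", "log2FoldChange", "logFC", "lfc"),
                             "log2 fold change")),
    padj = as.numeric(pick(c("padj", "adj_p", "adj.P.Val", "qvalue",
                             "fdr", "FDR"), "adjusted p-value"))
  )
  if (anyDuplicated(out$gene_id)) stop_input("DE table: duplicate gene ids")
  if (any(out$padj < 0 | out$padj > 1, na.rm = TRUE)) {
    stop_input("DE table: adjusted p-values outside [0, 1]")
  }
  out
}
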