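# Readers and writers for the BED-family plain-text formats the pipeline
# consumes. Everything is converted into (and back out of) the package's
# 0-based half-open coordinate convention, which is already BED's.

#' Read a chromosome sizes file
#'
#' Two-column TSV of chromosome name and length in bp.
#'
#' @param path Path to a chrom.sizes file.
#' @return A genome tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  g <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  if (any(duplicated(g$chrom))) abort("duplicated chromosome names")
  if (any(g$length <= 0)) abort("chromosome lengths must be > 0")
  g
}

#' Write a chromosome sizes file
#' @param genome Genome tibble (`chrom`, `length`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  readr::write_tsv(genome[c("chrom", "length")], path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path Path to a BED file (3 to 6 columns).
#' @return Interval tibble with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing columns filled with defaults).
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       progress = FALSE)
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character()))
  }
  cn <- c("chrom", "start", "end", "name", "score", "strand")
  names(x)[seq_len(min(ncol(x), 6))] <- cn[seq_len(min(ncol(x), 6))]
  x <- as_tibble(x)
  if (!"name" %in% names(x)) x$name <- sprintf("interval_%d", seq_len(nrow(x)))
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "."
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  as_intervals(x[cn])
}

#' Write intervals as BED6
#' @param x Interval tibble; `name`, `score`, `strand` are optional.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_intervals(x)
  if (!"name" %in% names(x)) x$name <- sprintf("interval_%d", seq_len(nrow(x)))
  if (!"score" %in% names(x)) x$score <- 0
  out <- x[c("chrom", "start", "end", "name", "score", "strand")]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a narrowPeak file
#'
#' ENCODE narrowPeak: BED6 plus signalValue, pValue, qValue and `peak`, the
#' summit offset from `start` (-1 when absent). The returned tibble carries
#' an absolute `summit` column (`start + peak`); when the offset is -1 the
#' interval midpoint is used.
#'
#' @param path Path to a narrowPeak file.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`,
#'   `signal_value`, `p_value`, `q_value`, `summit`.
#' @export
read_narrowpeak <- function(path) {
  cn <- c("chrom", "start", "end", "name", "score", "strand",
          "signal_value", "p_value", "q_value", "peak")
  x <- readr::read_tsv(path, col_names = cn, col_types = "ciicdcdddi",
                       progress = FALSE)
  if (nrow(x) == 0) {
    x$summit <- integer()
    return(as_tibble(x[setdiff(names(x), "peak")]))
  }
  x$summit <- ifelse(x$peak < 0,
                     as.integer(floor((x$start + x$end) / 2)),
                     x$start + x$peak)
  bad <- x$summit < x$start | x$summit >= x$end
  if (any(bad)) abort("narrowPeak summit outside its interval")
  as_intervals(x[c("chrom", "start", "end", "name", "score", "strand",
                   "signal_value", "p_value", "q_value", "summit")])
}

#' Write peaks as narrowPeak
#' @param x Peak tibble with at least `chrom`, `start`, `end`, `summit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(x, path) {
  x <- as_intervals(x, "peaks")
  if (!"summit" %in% names(x)) abort("peaks need a `summit` column")
  if (!"name" %in% names(x)) x$name <- sprintf("peak_%d", seq_len(nrow(x)))
  if (!"score" %in% names(x)) x$score <- 0
  if (!"signal_value" %in% names(x)) x$signal_value <- 0
  if (!"p_value" %in% names(x)) x$p_value <- -1
  if (!"q_value" %in% names(x)) x$q_value <- -1
  out <- tibble(chrom = x$chrom, start = x$start, end = x$end,
                name = x$name, score = x$score, strand = x$strand,
                signal_value = x$signal_value, p_value = x$p_value,
                q_value = x$q_value, peak = as.integer(x$summit - x$start))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @param library_size Total mapped reads backing the track (> 0).
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, library_size) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       col_types = "ciid", progress = FALSE)
  signal_track(x, library_size)
}

#' Write a signal track as bedGraph
#' @param track A [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  readr::write_tsv(track$cov, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene annotation TSV
#'
#' Columns `gene_id`, `chrom`, `strand`, `tss`, `start`, `end` (bp,
#' 0-based; `tss` is the position of the transcription start base, which
#' must lie inside `[start, end]`).
#'
#' @param path Path to the annotation TSV (with header).
#' @return Annotation tibble.
#' @export
read_gene_annotation <- function(path) {
  a <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "start", "end")
  if (!all(need %in% names(a))) {
    abort(sprintf("annotation must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  if (any(duplicated(a$gene_id))) abort("gene ids must be unique")
  if (any(a$tss < a$start | a$tss > a$end)) {
    abort("TSS must lie within the gene span")
  }
  as_tibble(a[need])
}

#' Read an expression matrix TSV
#'
#' Genes in rows (first column `gene_id`), samples in columns, values
#' normalized log-intensities.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with gene ids as rownames, sample ids as colnames.
#' @export
read_expression_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (names(x)[1] != "gene_id") abort("first column must be `gene_id`")
  if (any(duplicated(x$gene_id))) abort("gene ids must be unique")
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix TSV
#' @param m Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  out <- dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a sample metadata TSV
#'
#' Expects at least `sample_id`; typical columns are `group`, `time`,
#' `event`, `age`, `psa`, `gleason`, `margin`.
#'
#' @param path Path to the TSV.
#' @return Metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"sample_id" %in% names(x)) abort("metadata must have `sample_id`")
  as_tibble(x)
}

#' Read a samples manifest TSV
#'
#' One row per ChIP-seq replicate: `background` (EV/HES6), `treatment`
#' (vehicle/bicalutamide), `replicate`, `peaks` (narrowPeak path), `track`
#' (bedGraph path, optional), `library_size`.
#'
#' @param path Path to the manifest TSV.
#' @param base_dir Directory against which relative paths are resolved;
#'   defaults to the manifest's directory.
#' @return Manifest tibble with resolved paths.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("background", "treatment", "replicate", "peaks", "library_size")
  if (!all(need %in% names(x))) {
    abort(sprintf("manifest must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base_dir, p))
  x$peaks <- resolve(x$peaks)
  if ("track" %in% names(x)) x$track <- resolve(x$track)
  as_tibble(x)
}
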