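#' @keywords internal
"_PACKAGE"

#' @importFrom dplyr %>% arrange bind_rows distinct filter group_by left_join
#'   mutate n n_distinct pull rename select summarise ungroup across all_of
#'   if_else slice row_number first everything
#' @importFrom rlang .data abort warn .env
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats sd cor pt qnorm rnorm rpois runif rexp rbinom setNames
#'   p.adjust phyper hclust cutree dist pchisq quantile complete.cases median
#' @importFrom utils head tail
NULL

# Intervals are tibbles with columns chrom, start, end (0-based half-open,
# BED convention) and optionally strand in {"+", "-", "."}. Readers convert
# into this convention; writers convert out of it.

as_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals", what))
  }
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
  x <- as_tibble(x)
  if (!"strand" %in% names(x)) x$strand <- "."
  if (nrow(x) > 0 && any(x$start < 0 | x$end <= x$start)) {
    abort(sprintf("`%s` must satisfy 0 <= start < end", what))
  }
  x
}

check_on_genome <- function(x, genome, what = "intervals") {
  if (is.null(genome)) return(invisible(x))
  bad <- setdiff(unique(x$chrom), genome$chrom)
  if (length(bad) > 0) {
    abort(sprintf("`%s` uses chromosome(s) not in the genome: %s", what,
                  paste(bad, collapse = ", ")))
  }
  len <- setNames(genome$length, genome$chrom)
  if (nrow(x) > 0 && any(x$end > len[x$chrom])) {
    abort(sprintf("`%s` extends past chromosome ends", what))
  }
  invisible(x)
}

# IRanges uses 1-based closed coordinates; BED is 0-based half-open.
to_iranges <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

from_iranges <- function(ir, chrom) {
  tibble(chrom = chrom,
         start = as.integer(IRanges::start(ir)) - 1L,
         end = as.integer(IRanges::end(ir)),
         strand = ".")
}

#' Merge intervals into a disjoint sorted set
#'
#' Computes the union of a set of genomic intervals: overlapping and abutting
#' intervals (e.g. `[0,10)` and `[10,20)`) are coalesced, and the result is
#' sorted by chromosome and start. Strand is ignored (and dropped to `"."`):
#' base-pair occupancy statistics downstream are strandless.
#'
#' @param x A data frame of intervals with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genome Optional genome tibble (`chrom`, `length`); when supplied,
#'   intervals on unknown chromosomes or past chromosome ends are an error.
#' @return A tibble of pairwise-disjoint sorted intervals covering exactly
#'   the same bases as the input.
#' @examples
#' merge_intervals(tibble::tibble(chrom = "chr1", start = c(0, 50), end = c(100, 150)))
#' @export
merge_intervals <- function(x, genome = NULL) {
  x <- as_intervals(x)
  check_on_genome(x, genome)
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  x %>%
    dplyr::group_split(.data$chrom) %>%
    purrr::map(function(d) {
      from_iranges(IRanges::reduce(to_iranges(d)), d$chrom[1])
    }) %>%
    bind_rows() %>%
    arrange(.data$chrom, .data$start)
}

#' Total base-pair occupancy of an interval set
#'
#' Number of distinct genomic bases covered by the set (the set is merged
#' implicitly, so overlapping input intervals are not double-counted). This
#' is the denominator of the co-occurrence score.
#'
#' @inheritParams merge_intervals
#' @return A single non-negative number of base pairs.
#' @export
bp_occupancy <- function(x) {
  m <- merge_intervals(x)
  sum(as.numeric(m$end - m$start))
}

#' Base-pair overlap between two interval sets
#'
#' Number of bases in the intersection of the merged unions of the two sets;
#' symmetric in its arguments and strandless.
#'
#' @param a,b Data frames of intervals (`chrom`, `start`, `end`).
#' @return A single non-negative number of base pairs.
#' @export
bp_overlap <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  shared <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(shared) == 0) return(0)
  total <- 0
  for (ch in shared) {
    ia <- to_iranges(a[a$chrom == ch, ])
    ib <- to_iranges(b[b$chrom == ch, ])
    total <- total + sum(as.numeric(IRanges::width(
      IRanges::intersect(ia, ib))))
  }
  total
}

#' Reads-per-million normalization
#'
#' Scales a read count by library size: `count * 1e6 / library_size`.
#' Linear in `count`.
#'
#' @param count Read count(s), non-negative.
#' @param library_size Total mapped reads in the library; must be positive.
#' @return Numeric vector of RPM values.
#' @export
rpm <- function(count, library_size) {
  if (any(library_size <= 0)) abort("`library_size` must be > 0")
  count * 1e6 / library_size
}

#' A coverage signal track
#'
#' Bundles a per-chromosome step function of read counts per base pair
#' (a bedGraph-style tibble `chrom`, `start`, `end`, `value`) with the
#' library size used as the RPM denominator. Bases not covered by a row
#' carry zero signal.
#'
#' @param cov Data frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open; `value` = reads per bp over the run, >= 0).
#' @param library_size Total mapped reads (> 0). The track may cover only a
#'   subset of the genome, so the track total need not equal `library_size`.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(cov, library_size) {
  cov <- as_tibble(cov)
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(cov))) {
    abort("coverage must have columns chrom, start, end, value")
  }
  if (nrow(cov) > 0 && any(cov$value < 0)) abort("coverage values must be >= 0")
  if (length(library_size) != 1 || library_size <= 0) {
    abort("`library_size` must be a single positive number")
  }
  structure(list(cov = cov[need], library_size = as.numeric(library_size)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %d runs on %d chromosome(s), library size %g\n",
              nrow(x$cov), dplyr::n_distinct(x$cov$chrom), x$library_size))
  invisible(x)
}

# Sum of track counts over [from, to) on one chromosome (read counts, not RPM).
track_window_sum <- function(track, chrom, from, to) {
  d <- track$cov[track$cov$chrom == chrom, ]
  if (nrow(d) == 0 || to <= from) return(0)
  ov_start <- pmax(d$start, from)
  ov_end <- pmin(d$end, to)
  w <- pmax(ov_end - ov_start, 0)
  sum(d$value * w)
}

#' Binned read counts in a window around a position
#'
#' Sums track counts in `n_bins` equal half-open sub-windows of
#' `[center - half_width, center + half_width)`. Windows running past
#' chromosome ends are clipped: bins falling outside report the signal
#' actually present (zero beyond the end). The bin sums add up to the total
#' count in the clipped window.
#'
#' @param track A [signal_track()].
#' @param chrom Chromosome of the window center.
#' @param center Center position (bp, 0-based).
#' @param half_width Half window width in bp; `2 * half_width` must be a
#'   multiple of `n_bins`.
#' @param n_bins Number of bins (>= 1).
#' @param genome Optional genome tibble used to validate `center` and clip.
#' @return Numeric vector of length `n_bins` of read counts (not RPM).
#' @export
window_counts <- function(track, chrom, center, half_width, n_bins = 1,
                          genome = NULL) {
  stopifnot(inherits(track, "signal_track"), n_bins >= 1, half_width > 0)
  if ((2 * half_width) %% n_bins != 0) {
    abort("window width 2*half_width must be a multiple of n_bins")
  }
  if (!is.null(genome)) {
    if (!chrom %in% genome$chrom) abort(sprintf("unknown chromosome `%s`", chrom))
    clen <- genome$length[genome$chrom == chrom][1]
    if (center < 0 || center >= clen) {
      abort("window center is off the chromosome")
    }
  }
  bw <- (2 * half_width) / n_bins
  lo <- center - half_width + bw * (seq_len(n_bins) - 1)
  hi <- lo + bw
  lo <- pmax(lo, 0)
  if (!is.null(genome)) hi <- pmin(hi, clen)
  vapply(seq_len(n_bins),
         function(i) track_window_sum(track, chrom, lo[i], hi[i]),
         numeric(1))
}
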