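# Signal profiles around consensus summits, the base-pair co-occurrence
# Z-score statistic between interval sets, and TSS-relative genomic
# distribution of sites against a whole-genome background.

#' Signal profile matrix around site summits
#'
#' One row per site: mean over a condition's replicate tracks of
#' RPM-normalized binned counts in `summit +/- half_width`. Rows are
#' ordered by the sort signal (descending), by default the sites' mean
#' signal in the baseline EV + vehicle condition when available, else the
#' profile's own row means.
#'
#' @param sites Consensus-site tibble with `site_id`, `chrom`, `summit`.
#' @param tracks Named list (by condition id) of lists of [signal_track()].
#' @param condition Condition id to profile.
#' @param half_width Window half-width in bp (default 1000, i.e. +/- 1 kb).
#' @param bin_width Bin width in bp (default 10).
#' @param sort_by Optional numeric vector (one per site) used to order rows
#'   descending; default column `signal_EV_vehicle` of `sites` if present.
#' @return An object of class `profile_matrix`: list with `values` (sites x
#'   bins RPM matrix), `positions` (bin centers relative to summit),
#'   `site_id`, `condition`.
#' @export
profile_matrix <- function(sites, tracks, condition, half_width = 1000,
                           bin_width = 10, sort_by = NULL) {
  if (!condition %in% names(tracks)) {
    abort(sprintf("no tracks for condition `%s`", condition))
  }
  if ((2 * half_width) %% bin_width != 0) {
    abort("2*half_width must be a multiple of bin_width")
  }
  n_bins <- as.integer(2 * half_width / bin_width)
  reps <- tracks[[condition]]
  n <- nrow(sites)
  # expand sites x bins into windows, evaluate per replicate, average
  bin_lo <- rep(sites$summit, each = n_bins) - half_width +
    bin_width * (rep(seq_len(n_bins), times = n) - 1)
  bin_hi <- bin_lo + bin_width
  chrom <- rep(sites$chrom, each = n_bins)
  acc <- 0
  for (tr in reps) {
    counts <- windowed_track_sums(tr, chrom, bin_lo, bin_hi)
    acc <- acc + rpm(counts, tr$library_size)
  }
  vals <- matrix(acc / max(length(reps), 1), nrow = n, ncol = n_bins,
                 byrow = TRUE)
  rownames(vals) <- sites$site_id
  if (is.null(sort_by)) {
    sort_by <- if ("signal_EV_vehicle" %in% names(sites)) {
      sites$signal_EV_vehicle
    } else {
      rowMeans(vals)
    }
  }
  ord <- order(sort_by, decreasing = TRUE)
  vals <- vals[ord, , drop = FALSE]
  structure(list(values = vals,
                 positions = seq(-half_width + bin_width / 2,
                                 half_width - bin_width / 2, by = bin_width),
                 site_id = sites$site_id[ord],
                 condition = condition),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d sites x %d bins, condition %s\n",
              nrow(x$values), ncol(x$values), x$condition))
  invisible(x)
}

#' Mean signal profile across sites
#'
#' Column means of a profile matrix: the average-signal curve across
#' binding sites, typically drawn per site class and condition.
#'
#' @param m A [profile_matrix()].
#' @return Tibble with `position` (bp relative to summit), `signal`
#'   (mean RPM) and `condition`.
#' @export
mean_profile <- function(m) {
  stopifnot(inherits(m, "profile_matrix"))
  if (nrow(m$values) == 0) abort("profile matrix has no rows")
  tibble(position = m$positions, signal = colMeans(m$values),
         condition = m$condition)
}

#' @rdname plot_regrescue
#' @export
autoplot.profile_matrix <- function(object, ...) {
  mp <- mean_profile(object)
  ggplot2::ggplot(mp, ggplot2::aes(x = .data$position, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to summit (bp)",
                  y = "mean signal (RPM)", title = object$condition)
}

#' Co-occurrence score of a test set against a query set
#'
#' Total base-pair overlap between the merged test and query sets, divided
#' by the query set's total base-pair occupancy; lies in `[0, 1]` and is 1
#' when the query is contained in the test set.
#'
#' @param test,query Interval tibbles (`chrom`, `start`, `end`).
#' @return A single score in `[0, 1]`.
#' @export
cooccurrence_score <- function(test, query) {
  occ <- bp_occupancy(query)
  if (occ == 0) abort("query set has zero occupancy; score undefined")
  bp_overlap(test, query) / occ
}

#' Co-occurrence Z-score matrix between named interval sets
#'
#' Fills a test x query matrix of raw co-occurrence scores, then, to make
#' test sets of different extents comparable, normalizes each test row to
#' Z-scores: `(raw - row mean) / row sample sd` (denominator n - 1). A row
#' whose raw scores are all equal has undefined spread; its Z-scores are
#' set to zero with a warning.
#'
#' @param tests Named list of interval tibbles (rows of the result).
#' @param queries Named list of interval tibbles (columns); at least two.
#' @return An object of class `cooccurrence_result`: list with `raw` and
#'   `z` matrices and the normalization choice in `meta`.
#' @export
cooccurrence_zscores <- function(tests, queries) {
  if (length(queries) < 2) abort("need at least two query sets")
  if (is.null(names(tests)) || is.null(names(queries))) {
    abort("`tests` and `queries` must be named lists")
  }
  raw <- matrix(NA_real_, length(tests), length(queries),
                dimnames = list(names(tests), names(queries)))
  for (i in seq_along(tests)) {
    for (j in seq_along(queries)) {
      raw[i, j] <- cooccurrence_score(tests[[i]], queries[[j]])
    }
  }
  z <- raw
  for (i in seq_len(nrow(raw))) {
    s <- sd(raw[i, ])
    if (!is.finite(s) || s == 0) {
      warn(sprintf("test set `%s` has constant co-occurrence scores; Z set to 0",
                   rownames(raw)[i]))
      z[i, ] <- 0
    } else {
      z[i, ] <- (raw[i, ] - mean(raw[i, ])) / s
    }
  }
  structure(list(raw = raw, z = z,
                 meta = list(normalization = "per-test-row Z, sample sd (n-1)")),
            class = "cooccurrence_result")
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  cat("<cooccurrence_result> Z-scores (per test row):\n")
  print(round(x$z, 3))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.cooccurrence_result <- function(x, ...) {
  as_tibble(as.data.frame.table(x$raw, responseName = "raw",
                                stringsAsFactors = FALSE)) %>%
    rename(test = "Var1", query = "Var2") %>%
    mutate(z = as.vector(x$z))
}

#' @rdname plot_regrescue
#' @export
autoplot.cooccurrence_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$query, y = .data$test,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z")
}

#' TSS-relative bin scheme
#'
#' Ordered, strand-aware bins relative to the nearest transcription start
#' site. Defaults follow the distal/proximal promoter split used for
#' AR-binding-site distribution: upstream 500-2,000 bp, upstream 0-500 bp,
#' downstream 0-500 bp, then gene body, then intergenic. Offsets are
#' measured from the TSS against gene orientation (upstream positive).
#'
#' @param upstream_far,upstream_near,downstream Extents (bp) of the three
#'   promoter-region bins.
#' @return A `tss_bin_scheme` object; bin labels in precedence order.
#' @export
tss_bin_scheme <- function(upstream_far = 2000, upstream_near = 500,
                           downstream = 500) {
  stopifnot(upstream_far > upstream_near, upstream_near > 0, downstream > 0)
  structure(list(upstream_far = upstream_far,
                 upstream_near = upstream_near,
                 downstream = downstream,
                 labels = c(sprintf("upstream_%d_%d", upstream_near, upstream_far),
                            sprintf("upstream_0_%d", upstream_near),
                            sprintf("downstream_0_%d", downstream),
                            "gene_body", "intergenic")),
            class = "tss_bin_scheme")
}

#' Assign genomic positions to TSS-relative bins
#'
#' Each position (typically a peak summit) is labelled by its strand-aware
#' offset from the *nearest* TSS: upstream bins, proximal promoter and
#' immediate downstream take precedence, then gene body (position inside
#' any gene span), then intergenic.
#'
#' @param chrom,position Vectors of chromosome and 0-based position.
#' @param annotation Gene annotation tibble (see [read_gene_annotation()]).
#' @param scheme A [tss_bin_scheme()].
#' @return Factor of bin labels (levels in scheme order).
#' @export
assign_bin <- function(chrom, position, annotation,
                       scheme = tss_bin_scheme()) {
  stopifnot(inherits(scheme, "tss_bin_scheme"))
  if (length(chrom) != length(position)) {
    abort("`chrom` and `position` must have equal length")
  }
  bad <- setdiff(unique(chrom), unique(annotation$chrom))
  if (length(bad) > 0) {
    abort(sprintf("position(s) on chromosome(s) absent from annotation: %s",
                  paste(bad, collapse = ", ")))
  }
  out <- rep("intergenic", length(chrom))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    ann <- annotation[annotation$chrom == ch, ]
    if (nrow(ann) == 0) next
    pos <- position[sel]
    # nearest TSS
    ord <- order(ann$tss)
    tss <- ann$tss[ord]
    str <- ann$strand[ord]
    idx <- findInterval(pos, tss)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, length(tss))
    d_left <- abs(pos - tss[left])
    d_right <- abs(pos - tss[right])
    nearest <- ifelse(d_right < d_left, right, left)
    # signed offset: positive = upstream of the gene
    off <- ifelse(str[nearest] == "+", tss[nearest] - pos, pos - tss[nearest])
    lab <- rep(NA_character_, length(pos))
    lab[off > scheme$upstream_near & off <= scheme$upstream_far] <-
      scheme$labels[1]
    lab[off > 0 & off <= scheme$upstream_near] <- scheme$labels[2]
    lab[off <= 0 & -off < scheme$downstream] <- scheme$labels[3]
    # gene body: inside any gene span, and not already in a promoter bin
    body <- rep(FALSE, length(pos))
    ir_pos <- IRanges::IRanges(start = pos + 1L, width = 1L)
    ir_gene <- IRanges::IRanges(start = ann$start + 1L, end = ann$end)
    body[!is.na(IRanges::findOverlaps(ir_pos, ir_gene, select = "first"))] <- TRUE
    lab[is.na(lab) & body] <- "gene_body"
    lab[is.na(lab)] <- "intergenic"
    out[sel] <- lab
  }
  factor(out, levels = scheme$labels)
}

#' Genome-wide base fractions per TSS-relative bin
#'
#' Evaluates [assign_bin()] over every base of the genome (in chunks) to
#' obtain the background fraction of genomic bases falling in each bin —
#' the "compared to whole genome" reference of the distribution analysis.
#'
#' @param genome Genome tibble (`chrom`, `length`).
#' @param annotation Gene annotation tibble.
#' @param scheme A [tss_bin_scheme()].
#' @param chunk Bases evaluated per chunk.
#' @return Tibble with `bin` and `background` fractions summing to 1.
#' @export
genome_bin_fractions <- function(genome, annotation,
                                 scheme = tss_bin_scheme(),
                                 chunk = 1e6) {
  counts <- setNames(numeric(length(scheme$labels)), scheme$labels)
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]
    len <- genome$length[i]
    starts <- seq(0, len - 1, by = chunk)
    for (s in starts) {
      pos <- s:min(s + chunk - 1, len - 1)
      lab <- assign_bin(rep(ch, length(pos)), pos, annotation, scheme)
      tb <- table(lab)
      counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
    }
  }
  tibble(bin = factor(scheme$labels, levels = scheme$labels),
         background = as.numeric(counts) / sum(counts))
}

#' TSS-relative genomic distribution of site sets
#'
#' Locates each site by its summit, tabulates the fraction of sites per
#' TSS-relative bin for every named set, and compares with the
#' whole-genome background: `fold = fraction / background`.
#'
#' @param site_sets Named list of tibbles with `chrom` and `summit`
#'   columns (e.g. the output of [class_sets()]); all non-empty.
#' @param genome Genome tibble.
#' @param annotation Gene annotation tibble.
#' @param scheme A [tss_bin_scheme()].
#' @param background Optional precomputed [genome_bin_fractions()] result
#'   (recomputed when NULL).
#' @return An object of class `distribution_result`: tibble with `bin`,
#'   `set`, `n`, `fraction`, `background`, `fold`.
#' @export
genomic_distribution <- function(site_sets, genome, annotation,
                                 scheme = tss_bin_scheme(),
                                 background = NULL) {
  if (is.null(names(site_sets))) abort("`site_sets` must be a named list")
  if (any(purrr::map_int(site_sets, nrow) == 0)) {
    abort("site sets must be non-empty")
  }
  if (is.null(background)) {
    background <- genome_bin_fractions(genome, annotation, scheme)
  }
  res <- purrr::imap(site_sets, function(d, nm) {
    lab <- assign_bin(d$chrom, d$summit, annotation, scheme)
    tb <- table(lab)
    tibble(bin = factor(names(tb), levels = scheme$labels),
           set = nm, n = as.numeric(tb),
           fraction = as.numeric(tb) / sum(tb))
  }) %>%
    bind_rows() %>%
    left_join(background, by = "bin") %>%
    mutate(fold = .data$fraction / .data$background)
  structure(res, class = c("distribution_result", class(res)))
}

#' Fold enrichment of one set over another per bin
#'
#' Pairwise comparison (e.g. rescued versus lost) of per-bin site
#' fractions.
#'
#' @param dist A [genomic_distribution()] result.
#' @param set_a,set_b Set names; the fold reported is `a / b`.
#' @return Tibble with `bin`, `fraction_a`, `fraction_b`, `fold`.
#' @export
pairwise_fold <- function(dist, set_a, set_b) {
  stopifnot(inherits(dist, "distribution_result"))
  a <- dist[dist$set == set_a, c("bin", "fraction")]
  b <- dist[dist$set == set_b, c("bin", "fraction")]
  if (nrow(a) == 0 || nrow(b) == 0) abort("unknown set name")
  out <- left_join(rename(a, fraction_a = "fraction"),
                   rename(b, fraction_b = "fraction"), by = "bin")
  out$fold <- out$fraction_a / out$fraction_b
  out
}

#' @rdname plot_regrescue
#' @export
autoplot.distribution_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bin, y = .data$fold,
                               fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "fold over genome background") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
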