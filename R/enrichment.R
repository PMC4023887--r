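# Nearest-gene target assignment around binding-site summits and
# hypergeometric overlap enrichment between target genes and a
# differential-expression list.

#' Genes near binding sites
#'
#' Returns all genes whose TSS lies within `max_dist` bp of a site summit
#' (`|TSS - summit| <= max_dist`); with `closest_only = TRUE`, only the
#' single nearest TSS per site (still subject to `max_dist`).
#'
#' @param sites Tibble with `chrom` and `summit` columns.
#' @param annotation Gene annotation tibble.
#' @param max_dist Maximum summit-to-TSS distance in bp (default 25,000).
#' @param closest_only Keep only the nearest gene per site.
#' @return For [target_geneset()], a deduplicated character vector of gene
#'   ids; [genes_near_site()] returns a list of per-site gene-id vectors.
#' @export
genes_near_site <- function(sites, annotation, max_dist = 25000,
                            closest_only = FALSE) {
  purrr::map(seq_len(nrow(sites)), function(i) {
    ann <- annotation[annotation$chrom == sites$chrom[i], ]
    if (nrow(ann) == 0) return(character())
    d <- abs(ann$tss - sites$summit[i])
    hit <- d <= max_dist
    if (!any(hit)) return(character())
    if (closest_only) {
      ann$gene_id[which.min(d)]
    } else {
      ann$gene_id[hit]
    }
  })
}

#' @rdname genes_near_site
#' @export
target_geneset <- function(sites, annotation, max_dist = 25000,
                           closest_only = FALSE) {
  out <- unique(unlist(genes_near_site(sites, annotation, max_dist,
                                       closest_only)))
  if (is.null(out)) character() else out
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` containing `K` marked genes. Computed in log space via
#' [stats::phyper()] so extreme tails stay accurate.
#'
#' @param N Universe size.
#' @param K Marked genes in the universe.
#' @param n Draw size.
#' @param k Observed overlap; must satisfy `k <= min(K, n)` and
#'   `N >= K + n - k`.
#' @return The tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N) {
    abort("need 0 <= K, n <= N and k >= 0")
  }
  if (k > min(K, n)) abort("k cannot exceed min(K, n)")
  if (k < max(0, K + n - N)) abort("k below the hypergeometric support")
  if (k == 0) return(1)
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Overlap enrichment between a target gene set and a DEG list
#'
#' Tests whether the overlap `k = |targets ∩ degs|` is larger than
#' expected when drawing `|degs|` genes at random from the universe. The
#' overlap percentage is reported relative to the DEG list, and the
#' p-value is the hypergeometric upper tail (which is symmetric in the two
#' sets; the implementation asserts this numerically).
#'
#' @param targets Character vector of target gene ids (e.g. nearest genes
#'   of a site class).
#' @param degs Character vector of differentially expressed gene ids.
#' @param universe Character vector of all testable gene ids; both sets
#'   must be contained in it (supplied explicitly to avoid silent universe
#'   inflation).
#' @return An object of class `overlap_test` with fields `N`, `K`, `n`,
#'   `k`, `overlap_pct`, `p_value`.
#' @export
overlap_enrichment <- function(targets, degs, universe) {
  targets <- unique(targets)
  degs <- unique(degs)
  universe <- unique(universe)
  if (length(setdiff(targets, universe)) > 0 ||
      length(setdiff(degs, universe)) > 0) {
    abort("`targets` and `degs` must be subsets of `universe`")
  }
  N <- length(universe)
  K <- length(targets)
  n <- length(degs)
  k <- length(intersect(targets, degs))
  p <- hypergeom_tail(N, K, n, k)
  p_swapped <- hypergeom_tail(N, n, K, k)
  stopifnot(isTRUE(all.equal(p, p_swapped, tolerance = 1e-9)))
  structure(list(N = N, K = K, n = n, k = k,
                 overlap_pct = if (n > 0) 100 * k / n else NA_real_,
                 p_value = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test> %d of %d DEGs are targets (%.1f%%), universe %d, K %d, P = %.3g\n",
    x$k, x$n, x$overlap_pct, x$N, x$K, x$p_value))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.overlap_test <- function(x, ...) {
  tibble(N = x$N, K = x$K, n = x$n, k = x$k,
         overlap_pct = x$overlap_pct, p_value = x$p_value)
}

#' @rdname tidiers
#' @export
glance.overlap_test <- function(x, ...) tidy(x)
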