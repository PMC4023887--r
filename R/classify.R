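# Consolidation of replicate peak calls into consensus sites and their
# classification as lost / rescued / enhanced across the 2x2 design
# (background EV/HES6 x treatment vehicle/bicalutamide). The baseline is
# EV + vehicle; classes describe what happens to a baseline site under
# androgen-receptor inhibition with and without the co-factor.

#' The four conditions of the 2x2 design
#' @return Character vector of canonical condition ids.
#' @export
design_conditions <- function() {
  c("EV_vehicle", "EV_bicalutamide", "HES6_vehicle", "HES6_bicalutamide")
}

#' Build canonical condition ids
#' @param background `"EV"` or `"HES6"`.
#' @param treatment `"vehicle"` or `"bicalutamide"`.
#' @return Character vector like `"EV_vehicle"`.
#' @export
condition_id <- function(background, treatment) {
  if (!all(background %in% c("EV", "HES6"))) {
    abort('`background` must be "EV" or "HES6"')
  }
  if (!all(treatment %in% c("vehicle", "bicalutamide"))) {
    abort('`treatment` must be "vehicle" or "bicalutamide"')
  }
  paste(background, treatment, sep = "_")
}

#' Classification configuration
#'
#' Thresholds behind "highly reproducible" presence and "clearly enhanced"
#' signal, neither of which is pinned down by convention; both are exposed.
#'
#' @param reproducibility_min_fraction A site counts as present in a
#'   condition when at least this fraction of the condition's replicates
#'   called a peak there. Default 0.5: majority support (2 of 4, 2 of 3),
#'   which stays robust to single-replicate drop-out; see the methods
#'   vignette for the calibration argument.
#' @param merge_max_gap Maximum gap (bp) between replicate peaks grouped
#'   into one consensus site; default 0, i.e. overlap (or abutment) required.
#' @param summit_window_half_width Half-width (bp) of the summit-centered
#'   window used for mean-RPM signal; default 250.
#' @param enhancement_fold_min Minimum HES6-bicalutamide / EV-bicalutamide
#'   mean-RPM fold for an "enhanced" call; default 1.5.
#' @return A `classification_config` list.
#' @export
classification_config <- function(reproducibility_min_fraction = 0.5,
                                  merge_max_gap = 0,
                                  summit_window_half_width = 250,
                                  enhancement_fold_min = 1.5) {
  if (reproducibility_min_fraction <= 0 || reproducibility_min_fraction > 1) {
    abort("`reproducibility_min_fraction` must be in (0, 1]")
  }
  if (enhancement_fold_min <= 1) abort("`enhancement_fold_min` must be > 1")
  if (merge_max_gap < 0) abort("`merge_max_gap` must be >= 0")
  if (summit_window_half_width <= 0) {
    abort("`summit_window_half_width` must be > 0")
  }
  structure(list(reproducibility_min_fraction = reproducibility_min_fraction,
                 merge_max_gap = merge_max_gap,
                 summit_window_half_width = summit_window_half_width,
                 enhancement_fold_min = enhancement_fold_min),
            class = "classification_config")
}

#' Consolidate replicate peak calls into consensus sites
#'
#' Replicate peaks from all samples are grouped by single-linkage overlap
#' (peaks closer than `merge_max_gap` join the same site). Each consensus
#' site spans the union of its contributing peaks, its summit is the
#' rounded arithmetic mean of contributing peak summits, and per condition
#' it records `support_*` (fraction of that condition's replicates
#' contributing at least one peak) and `present_*` (support at or above
#' `reproducibility_min_fraction`).
#'
#' @param peaks Long tibble of peaks from every replicate, with columns
#'   `chrom`, `start`, `end`, `summit`, `background`, `treatment`,
#'   `replicate` (e.g. stacked [read_narrowpeak()] outputs annotated from a
#'   manifest).
#' @param config A [classification_config()].
#' @return Tibble of consensus sites: `site_id`, `chrom`, `start`, `end`,
#'   `summit`, then `support_<condition>` and `present_<condition>` for the
#'   four design conditions, sorted by position. The replicate design is
#'   attached as attribute `"replicates"`.
#' @export
consolidate_replicates <- function(peaks, config = classification_config()) {
  peaks <- as_intervals(peaks, "peaks")
  need <- c("summit", "background", "treatment", "replicate")
  if (!all(need %in% names(peaks))) {
    abort("peaks need columns summit, background, treatment, replicate")
  }
  peaks$condition <- condition_id(peaks$background, peaks$treatment)
  reps <- peaks %>%
    distinct(.data$condition, .data$replicate) %>%
    dplyr::count(.data$condition, name = "n_replicates")
  missing <- setdiff(design_conditions(), reps$condition)
  if (length(missing) > 0) {
    abort(sprintf("no replicates for condition(s): %s",
                  paste(missing, collapse = ", ")))
  }
  n_reps <- setNames(reps$n_replicates, reps$condition)

  # single-linkage grouping: reduce with the allowed gap, then assign every
  # peak to the reduced range it falls in
  peaks <- arrange(peaks, .data$chrom, .data$start)
  grouped <- peaks %>%
    dplyr::group_split(.data$chrom) %>%
    purrr::map(function(d) {
      ir <- to_iranges(d)
      red <- IRanges::reduce(ir, min.gapwidth = config$merge_max_gap + 1L)
      hit <- IRanges::findOverlaps(ir, red, select = "first")
      d$cluster <- paste(d$chrom[1], hit, sep = ":")
      d
    }) %>%
    bind_rows()

  sites <- grouped %>%
    group_by(.data$cluster) %>%
    summarise(chrom = first(.data$chrom),
              start = min(.data$start),
              end = max(.data$end),
              summit = as.integer(round(mean(.data$summit))),
              .groups = "drop")

  support <- grouped %>%
    distinct(.data$cluster, .data$condition, .data$replicate) %>%
    dplyr::count(.data$cluster, .data$condition, name = "n_rep_with_peak") %>%
    mutate(support = .data$n_rep_with_peak / unname(n_reps[.data$condition])) %>%
    select("cluster", "condition", "support") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "support",
                       names_prefix = "support_")

  out <- left_join(sites, support, by = "cluster")
  for (cond in design_conditions()) {
    sc <- paste0("support_", cond)
    if (!sc %in% names(out)) out[[sc]] <- 0
    out[[sc]][is.na(out[[sc]])] <- 0
    out[[paste0("present_", cond)]] <-
      out[[sc]] >= config$reproducibility_min_fraction
  }
  out <- out %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(site_id = sprintf("site_%05d", row_number())) %>%
    select("site_id", "chrom", "start", "end", "summit",
           dplyr::starts_with("support_"), dplyr::starts_with("present_"))
  attr(out, "replicates") <- n_reps
  out
}

#' Mean RPM signal per condition in summit windows
#'
#' For each consensus site and condition, counts reads in the window
#' `summit +/- summit_window_half_width` in every replicate track, converts
#' to RPM with that replicate's library size, and averages over replicates.
#'
#' @param sites Consensus-site tibble from [consolidate_replicates()].
#' @param tracks Named list (by condition id) of lists of [signal_track()]
#'   objects, one per replicate.
#' @param config A [classification_config()].
#' @return `sites` with one `signal_<condition>` column per supplied
#'   condition.
#' @export
site_signal <- function(sites, tracks, config = classification_config()) {
  if (is.null(names(tracks)) ||
      !all(names(tracks) %in% design_conditions())) {
    abort("`tracks` must be a list named by condition id")
  }
  missing <- setdiff(design_conditions(), names(tracks))
  if (length(missing) > 0) {
    abort(sprintf("no tracks for condition(s): %s",
                  paste(missing, collapse = ", ")))
  }
  hw <- config$summit_window_half_width
  for (cond in names(tracks)) {
    reps <- tracks[[cond]]
    per_rep <- purrr::map(reps, function(tr) {
      counts <- windowed_track_sums(tr, sites$chrom, sites$summit - hw,
                                    sites$summit + hw)
      rpm(counts, tr$library_size)
    })
    sites[[paste0("signal_", cond)]] <-
      Reduce(`+`, per_rep) / length(per_rep)
  }
  sites
}

# Vectorized window sums over one track for many windows.
windowed_track_sums <- function(track, chrom, from, to) {
  out <- numeric(length(chrom))
  from <- pmax(from, 0)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    d <- track$cov[track$cov$chrom == ch, ]
    if (nrow(d) == 0) next
    win <- IRanges::IRanges(start = from[sel] + 1L, end = pmax(to[sel], from[sel] + 1L))
    run <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    hits <- IRanges::findOverlaps(win, run)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    w <- pmin(IRanges::end(win)[qi], IRanges::end(run)[si]) -
      pmax(IRanges::start(win)[qi], IRanges::start(run)[si]) + 1
    sums <- tapply(d$value[si] * w, qi, sum)
    idx <- which(sel)[as.integer(names(sums))]
    out[idx] <- as.numeric(sums)
  }
  out
}

#' Classify consensus sites as lost, rescued, enhanced or other
#'
#' Baseline sites are those present in EV + vehicle; all others are
#' `other`. A baseline site is `lost` when absent in both bicalutamide
#' conditions, `rescued` when absent in EV + bicalutamide but present in
#' HES6 + bicalutamide, `enhanced` when still present in EV + bicalutamide
#' with HES6-bicalutamide mean RPM at least `enhancement_fold_min` times
#' the EV-bicalutamide signal, and `other` otherwise. HES6 + vehicle
#' presence is recorded but plays no part in the rules.
#'
#' @param sites Consensus sites with `present_*` columns and, for the
#'   enhanced rule, `signal_EV_bicalutamide` / `signal_HES6_bicalutamide`
#'   (see [site_signal()]).
#' @param config A [classification_config()].
#' @return `sites` with a `class` factor column
#'   (`lost`/`rescued`/`enhanced`/`other`).
#' @export
classify_sites <- function(sites, config = classification_config()) {
  need <- paste0("present_", design_conditions())
  if (!all(need %in% names(sites))) {
    abort("sites lack present_* columns; run consolidate_replicates() first")
  }
  base <- sites$present_EV_vehicle
  ev_bic <- sites$present_EV_bicalutamide
  h6_bic <- sites$present_HES6_bicalutamide
  enhanced_ok <- rep(FALSE, nrow(sites))
  needs_signal <- base & ev_bic
  if (any(needs_signal)) {
    sig_cols <- c("signal_EV_bicalutamide", "signal_HES6_bicalutamide")
    if (!all(sig_cols %in% names(sites))) {
      abort("enhanced calls need signal_* columns; run site_signal() first")
    }
    enhanced_ok <- sites$signal_HES6_bicalutamide >=
      config$enhancement_fold_min * sites$signal_EV_bicalutamide
  }
  cls <- dplyr::case_when(
    !base ~ "other",
    !ev_bic & !h6_bic ~ "lost",
    !ev_bic & h6_bic ~ "rescued",
    ev_bic & enhanced_ok ~ "enhanced",
    TRUE ~ "other")
  sites$class <- factor(cls, levels = site_classes())
  sites
}

#' Site class labels
#' @return Character vector `c("lost", "rescued", "enhanced", "other")`.
#' @export
site_classes <- function() c("lost", "rescued", "enhanced", "other")

#' Split classified sites into per-class interval sets
#'
#' @param sites Classified consensus sites (see [classify_sites()]).
#' @return Named list with one tibble per class (possibly empty), a
#'   partition of the input.
#' @export
class_sets <- function(sites) {
  if (!"class" %in% names(sites)) abort("sites are not classified")
  purrr::map(setNames(site_classes(), site_classes()),
             function(cl) sites[sites$class == cl, , drop = FALSE])
}

#' Write one BED file per site class
#'
#' Every class gets a file, empty classes included.
#'
#' @param sites Classified consensus sites.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_class_beds <- function(sites, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- class_sets(sites)
  paths <- purrr::imap_chr(sets, function(d, cl) {
    p <- file.path(dir, paste0(cl, ".bed"))
    d$name <- d$site_id
    d$score <- 0
    d$strand <- "."
    write_bed(d[c("chrom", "start", "end", "name", "score", "strand")], p)
    p
  })
  invisible(paths)
}

#' Compare recovered classes with planted truth
#'
#' Matches each true site to the consensus site whose interval contains its
#' summit and tabulates agreement of the class labels. True sites with no
#' matching consensus site count as errors.
#'
#' @param sites Classified consensus sites.
#' @param truth Tibble of true sites with `chrom`, `summit`, `class`.
#' @return List with `accuracy` (fraction of true sites recovered with the
#'   planted label) and `table` (per-site match tibble).
#' @export
evaluate_classification <- function(sites, truth) {
  if (!"class" %in% names(sites)) abort("sites are not classified")
  matched <- rep(NA_character_, nrow(truth))
  for (ch in unique(truth$chrom)) {
    ti <- which(truth$chrom == ch)
    si <- which(sites$chrom == ch)
    if (length(si) == 0) next
    pts <- IRanges::IRanges(start = truth$summit[ti] + 1L, width = 1L)
    ivs <- IRanges::IRanges(start = sites$start[si] + 1L, end = sites$end[si])
    hit <- IRanges::findOverlaps(pts, ivs, select = "first")
    ok <- !is.na(hit)
    matched[ti[ok]] <- as.character(sites$class[si[hit[ok]]])
  }
  tab <- tibble(true_class = as.character(truth$class),
                recovered_class = matched)
  list(accuracy = mean(!is.na(matched) & matched == tab$true_class),
       table = tab)
}
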