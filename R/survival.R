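# Patient stratification by signature expression and the survival arm:
# Kaplan-Meier product-limit curves, Mantel-Haenszel logrank tests, a
# maximally selected single-gene cut-point, two-cluster partitioning of
# signature expression, and Cox proportional-hazards models with clinical
# covariates. Model fitting is delegated to the survival package; this
# layer owns the record validation, the cut-point scan, the clustering
# convention and the tidy result surfaces.

check_records <- function(records) {
  need <- c("time", "event")
  if (!all(need %in% names(records))) {
    abort("records need `time` and `event` columns")
  }
  if (nrow(records) == 0) abort("no survival records")
  if (any(records$time <= 0)) abort("survival times must be > 0")
  if (!all(records$event %in% c(0, 1, FALSE, TRUE))) {
    abort("`event` must be 0/1 (1 = relapse, 0 = censored)")
  }
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records Tibble with `time` (months, > 0) and `event`
#'   (1 = relapse, 0 = censored), optionally `sample_id`.
#' @param group Optional vector (length `nrow(records)`) of group labels
#'   for stratified curves.
#' @return An object of class `km_curve`: tibble with `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (non-increasing from 1 within
#'   each group), carrying the underlying `survfit` as attribute `fit`.
#' @export
km_estimate <- function(records, group = NULL) {
  records <- check_records(records)
  if (is.null(group)) group <- rep("all", nrow(records))
  if (length(group) != nrow(records)) {
    abort("`group` must have one entry per record")
  }
  d <- data.frame(time = records$time, event = as.integer(records$event),
                  group = as.character(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(d$group)[1], length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  out <- tibble(group = grp, time = sm$time, n_risk = sm$n.risk,
                n_event = sm$n.event, n_censor = sm$n.censor,
                surv = sm$surv)
  structure(out, class = c("km_curve", class(out)), fit = fit)
}

#' @rdname plot_regrescue
#' @export
autoplot.km_curve <- function(object, ...) {
  d <- as_tibble(object) %>%
    group_by(.data$group) %>%
    dplyr::group_modify(function(g, key) {
      bind_rows(tibble(time = 0, n_risk = max(g$n_risk), n_event = 0,
                       n_censor = 0, surv = 1), g)
    }) %>%
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "relapse-free survival")
}

#' Mantel-Haenszel logrank test
#'
#' Compares survival distributions across two or more groups over pooled
#' event times; the statistic is chi-squared with `groups - 1` degrees of
#' freedom.
#'
#' @inheritParams km_estimate
#' @param group Vector of group labels (at least two groups, at least one
#'   event overall).
#' @return List with `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(records, group) {
  records <- check_records(records)
  if (length(unique(group)) < 2) abort("need at least two groups")
  if (sum(records$event) < 1) abort("need at least one event")
  d <- data.frame(time = records$time, event = as.integer(records$event),
                  group = as.character(group))
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(fit$n) - 1
  list(chisq = unname(fit$chisq), df = df,
       p_value = pchisq(fit$chisq, df = df, lower.tail = FALSE))
}

#' Maximally selected expression cut-point
#'
#' Implements "recursive partitioning to high and low expression" as a
#' single maximally selected logrank split: every midpoint between
#' consecutive distinct expression values inside the 10th-90th percentile
#' range is scored by the two-group logrank chi-square, and the threshold
#' with the largest statistic wins (ties: smallest threshold). Because the
#' cut is selected post hoc the unadjusted p-value is optimistic; an
#' optional permutation adjustment re-runs the scan on permuted expression
#' values.
#'
#' @param expression Numeric vector, one value per record (not constant).
#' @param records Survival records (at least 10).
#' @param n_permutations Number of permutations for the adjusted p-value
#'   (0 = skip).
#' @return List with `threshold`, `chisq`, `p_value` (unadjusted),
#'   `p_permutation` (NA when skipped), `group` (factor `low`/`high` per
#'   record at the selected threshold).
#' @export
single_gene_cutpoint <- function(expression, records, n_permutations = 0) {
  records <- check_records(records)
  if (length(expression) != nrow(records)) {
    abort("`expression` must have one value per record")
  }
  if (nrow(records) < 10) abort("need at least 10 samples")
  if (sd(expression) == 0) abort("expression is constant; no cut-point")
  scan_best <- function(values) {
    qs <- quantile(values, c(0.1, 0.9), names = FALSE, type = 7)
    v <- sort(unique(values))
    mids <- (v[-1] + v[-length(v)]) / 2
    mids <- mids[mids >= qs[1] & mids <= qs[2]]
    if (length(mids) == 0) abort("no candidate cut-points in the 10th-90th percentile range")
    best <- list(chisq = -Inf, threshold = NA_real_)
    for (m in mids) {
      grp <- ifelse(values > m, "high", "low")
      lr <- tryCatch(logrank_test(records, grp), error = function(e) NULL)
      if (is.null(lr)) next
      if (lr$chisq > best$chisq + 1e-12) {
        best <- list(chisq = lr$chisq, threshold = m, p = lr$p_value)
      }
    }
    best
  }
  best <- scan_best(expression)
  p_perm <- NA_real_
  if (n_permutations > 0) {
    exceed <- 0
    for (b in seq_len(n_permutations)) {
      perm <- sample(expression)
      pb <- tryCatch(scan_best(perm), error = function(e) list(chisq = -Inf))
      if (pb$chisq >= best$chisq) exceed <- exceed + 1
    }
    p_perm <- (1 + exceed) / (1 + n_permutations)
  }
  list(threshold = best$threshold, chisq = best$chisq,
       p_value = best$p, p_permutation = p_perm,
       group = factor(ifelse(expression > best$threshold, "high", "low"),
                      levels = c("low", "high")))
}

#' Two-cluster partition of signature expression
#'
#' Splits samples into two clusters by hierarchical agglomerative
#' clustering (Ward linkage on Euclidean distances) of per-gene
#' standardized signature expression, cutting the tree at k = 2. Labels
#' are deterministic given the matrix and independent of sample order:
#' the cluster with the higher mean standardized signature expression is
#' `"high"`.
#'
#' @param m Numeric matrix restricted to signature genes (genes x
#'   samples); at least 2 genes and 2 samples.
#' @return Named factor (`low`/`high`) of cluster labels per sample.
#' @export
two_cluster_partition <- function(m) {
  if (nrow(m) < 2) abort("need at least 2 signature genes in the matrix")
  if (ncol(m) < 2) abort("need at least 2 samples")
  keep <- apply(m, 1, sd) > 0
  if (sum(keep) < 2) abort("fewer than 2 signature genes vary across samples")
  z <- t(scale(t(m[keep, , drop = FALSE])))
  hc <- hclust(dist(t(z)), method = "ward.D2")
  cl <- cutree(hc, k = 2)
  means <- tapply(colMeans(z), cl, mean)
  high <- as.integer(names(means)[which.max(means)])
  out <- factor(ifelse(cl == high, "high", "low"), levels = c("low", "high"))
  names(out) <- colnames(m)
  out
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Efron tie handling) of relapse against the
#' supplied covariates; records with missing covariates are dropped
#' listwise and the dropped count is reported. Gleason score is treated as
#' numeric by default (one hazard ratio); pass it as a factor for a
#' categorical fit.
#'
#' @param records Survival records (`time`, `event`).
#' @param covariates Data frame of covariates aligned with `records`
#'   (e.g. cluster label, age, PSA, Gleason, margin status). Constant
#'   covariates are an error.
#' @param conf_level Confidence level for hazard-ratio intervals.
#' @return An object of class `cox_fit`: tibble with one row per model
#'   term (`term`, `estimate` = log hazard ratio, `hr`, `conf_low`,
#'   `conf_high`, `p_value`), with the `coxph` fit and the listwise
#'   deletion count as attributes.
#' @export
cox_fit <- function(records, covariates, conf_level = 0.95) {
  records <- check_records(records)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(records)) {
    abort("`covariates` must align with `records`")
  }
  if (sum(records$event) < 2) abort("need at least 2 events")
  d <- cbind(data.frame(.time = records$time,
                        .event = as.integer(records$event)),
             covariates)
  cc <- complete.cases(d)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message(sprintf("cox_fit: dropped %d record(s) with missing covariates",
                    n_dropped))
  }
  d <- d[cc, , drop = FALSE]
  for (v in names(covariates)) {
    vals <- d[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2) {
      abort(sprintf("covariate `%s` is constant across the fitted records", v))
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = "efron")
  if (any(!is.finite(stats::coef(fit))) ||
      any(sqrt(diag(fit$var)) > 100)) {
    abort("Cox fit did not converge (possible separation); inspect covariates")
  }
  s <- summary(fit, conf.int = conf_level)
  res <- tibble(term = rownames(s$coefficients),
                estimate = s$coefficients[, "coef"],
                hr = s$coefficients[, "exp(coef)"],
                conf_low = s$conf.int[, 3],
                conf_high = s$conf.int[, 4],
                p_value = s$coefficients[, "Pr(>|z|)"])
  structure(res, class = c("cox_fit", class(res)), fit = fit,
            n = s$n, n_events = sum(d$.event), n_dropped = n_dropped)
}

#' @rdname tidiers
#' @export
tidy.cox_fit <- function(x, ...) as_tibble(unclass(x))

#' @rdname tidiers
#' @export
glance.cox_fit <- function(x, ...) {
  fit <- attr(x, "fit")
  s <- summary(fit)
  tibble(n = attr(x, "n"), n_events = attr(x, "n_events"),
         n_dropped = attr(x, "n_dropped"),
         concordance = unname(s$concordance[1]),
         logrank_p = unname(s$sctest["pvalue"]))
}

#' @rdname plot_regrescue
#' @export
autoplot.cox_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (log scale)", y = NULL)
}

#' Generic plotting and tidying methods
#'
#' `autoplot()` methods draw each result type with ggplot2 (`profile_matrix`
#' mean curves, `cooccurrence_result` Z heatmaps, `distribution_result`
#' fold bars, `km_curve` step curves, `cox_fit` forest plots);
#' `tidy()`/`glance()` return tibbles in broom style.
#'
#' @param object,x A result object from this package.
#' @param ... Unused.
#' @name plot_regrescue
NULL

#' @rdname tidiers
#' @name tidiers
#' @param x A result object.
#' @param ... Unused.
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
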