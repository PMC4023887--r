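# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and IRanges): interval statistics are computed
# on explicit per-base membership sets, the hypergeometric tail by direct
# summation over binomial coefficients, and survival estimators by hand
# application of their defining formulas.

# --- per-base membership oracle for interval algebra -------------------------

oracle_bases <- function(x) {
  if (nrow(x) == 0) return(character())
  unlist(lapply(seq_len(nrow(x)), function(i) {
    paste(x$chrom[i], seq(x$start[i], x$end[i] - 1), sep = ":")
  }))
}

oracle_occupancy <- function(x) length(unique(oracle_bases(x)))

oracle_overlap <- function(a, b) {
  length(intersect(unique(oracle_bases(a)), unique(oracle_bases(b))))
}

oracle_merge_bases <- function(x) sort(unique(oracle_bases(x)))

random_intervals <- function(n, chroms = c("chrA", "chrB"), max_len = 10000) {
  start <- sample.int(max_len - 1, n, replace = TRUE) - 1L
  width <- sample.int(200, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = pmin(start + width, max_len))
}

# --- hypergeometric tail by direct summation ---------------------------------

oracle_hyper_tail <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# --- Kaplan-Meier product-limit by hand --------------------------------------

oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# --- two-group Mantel-Haenszel logrank by hand -------------------------------

oracle_logrank_chisq <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- unique(group)[1]
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# small helper: survival records tibble
records_of <- function(time, event, ...) {
  tibble::tibble(time = time, event = event, ...)
}
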