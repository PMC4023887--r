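test_that("Kaplan-Meier estimates equal the hand product-limit", {
  # two events
  km <- km_estimate(records_of(c(1, 2), c(1, 1)))
  expect_equal(km$surv[km$time == 1], 0.5)
  expect_equal(km$surv[km$time == 2], 0)
  # second observation censored: curve stays at 0.5
  km2 <- km_estimate(records_of(c(1, 2), c(1, 0)))
  expect_equal(km2$surv[km2$time == 1], 0.5)
  expect_equal(min(km2$surv), 0.5)
  # all censored: survival identically 1
  km3 <- km_estimate(records_of(c(3, 5, 7), c(0, 0, 0)))
  expect_true(all(km3$surv == 1))
  # random instance against the oracle
  set.seed(111)
  time <- round(rexp(40, 0.1), 2) + 0.01
  event <- rbinom(40, 1, 0.7)
  km4 <- km_estimate(records_of(time, event))
  want <- oracle_km(time, event)
  got <- km4[km4$n_event > 0, ]
  expect_equal(got$surv, want$surv, tolerance = 1e-12)
  expect_true(all(diff(km4$surv) <= 1e-12))
  expect_error(km_estimate(records_of(c(0, 1), c(1, 1))), "> 0")
})

test_that("logrank matches the worked example and the hand formula", {
  rec <- records_of(c(1, 2, 3, 4), c(1, 1, 1, 1))
  grp <- c("A", "A", "B", "B")
  lr <- logrank_test(rec, grp)
  expect_equal(lr$chisq, 2.8824, tolerance = 1e-4)
  expect_equal(lr$chisq, oracle_logrank_chisq(rec$time, rec$event, grp),
               tolerance = 1e-9)
  # label swap invariance
  lr2 <- logrank_test(rec, c("B", "B", "A", "A"))
  expect_equal(lr2$chisq, lr$chisq)
  # identical groups: statistic 0, p 1
  rec2 <- records_of(rep(c(1, 2, 3), 2), rep(1, 6))
  lr0 <- logrank_test(rec2, rep(c("A", "B"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-9)
  expect_equal(lr0$p_value, 1, tolerance = 1e-9)
  # random instances agree with the hand formula
  set.seed(121)
  for (rep in 1:10) {
    time <- round(rexp(30, 0.1), 1) + 0.1
    event <- rbinom(30, 1, 0.8)
    grp <- sample(c("A", "B"), 30, replace = TRUE)
    if (length(unique(grp)) < 2 || sum(event) == 0) next
    expect_equal(logrank_test(records_of(time, event), grp)$chisq,
                 oracle_logrank_chisq(time, event, grp), tolerance = 1e-8)
  }
  expect_error(logrank_test(records_of(c(1, 2), c(0, 0)), c("A", "B")),
               "at least one event")
})

test_that("the maximally selected cut-point finds a planted separation", {
  # low expression -> late events, high expression -> early events
  expr <- c(rep(1, 10), rep(5, 10))
  rec <- records_of(c(seq(20, 29), seq(1, 10)), rep(1, 20))
  cut <- single_gene_cutpoint(expr, rec)
  expect_gt(cut$threshold, 1)
  expect_lt(cut$threshold, 5)
  expect_equal(as.character(cut$group), rep(c("low", "high"), each = 10))
  # the scan optimum dominates any fixed threshold
  for (thr in c(1.5, 2.5, 4)) {
    fixed <- logrank_test(rec, ifelse(expr > thr, "high", "low"))
    expect_gte(cut$chisq, fixed$chisq - 1e-9)
  }
  # invariant to monotone transformation of expression
  cut2 <- single_gene_cutpoint(exp(expr), rec)
  expect_equal(cut2$chisq, cut$chisq)
  expect_equal(as.character(cut2$group), as.character(cut$group))
  expect_error(single_gene_cutpoint(rep(1, 20), rec), "constant")
  # permutation-adjusted p is conservative for a planted signal
  set.seed(131)
  cut3 <- single_gene_cutpoint(expr, rec, n_permutations = 19)
  expect_lte(cut3$p_permutation, 0.1)
})

test_that("two-cluster partitioning recovers planted sample blocks", {
  set.seed(141)
  n_genes <- 30
  m <- cbind(matrix(rnorm(n_genes * 12, mean = 0), n_genes, 12),
             matrix(rnorm(n_genes * 12, mean = 3), n_genes, 12))
  colnames(m) <- sprintf("s%02d", 1:24)
  rownames(m) <- sprintf("g%02d", 1:n_genes)
  cl <- two_cluster_partition(m)
  expect_equal(as.character(cl), rep(c("low", "high"), each = 12))
  # invariant to sample order (up to the relabelling convention)
  perm <- sample(24)
  cl2 <- two_cluster_partition(m[, perm])
  expect_equal(as.character(cl2), as.character(cl)[perm])
  # duplicated samples co-cluster
  dup <- cbind(m, m[, 1:2])
  cl3 <- two_cluster_partition(dup)
  expect_equal(as.character(cl3)[25:26], as.character(cl3)[1:2])
  expect_error(two_cluster_partition(m[1, , drop = FALSE]), "at least 2")
})

test_that("Cox fits recover a planted log hazard ratio", {
  set.seed(151)
  n <- 500
  cluster <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = 0.02 * exp(0.7 * cluster))
  censored <- runif(n) < 0.3
  rec <- records_of(ifelse(censored, runif(n) * t_event, t_event) + 1e-6,
                    as.integer(!censored))
  fit <- cox_fit(rec, data.frame(cluster = cluster))
  expect_equal(fit$estimate[1], 0.7, tolerance = 0.15)
  expect_equal(fit$hr[1], exp(fit$estimate[1]))
  expect_true(fit$conf_low[1] < fit$hr[1], fit$hr[1] < fit$conf_high[1])
  # a pure-noise covariate stays near zero
  noise <- rnorm(n)
  fit2 <- cox_fit(rec, data.frame(cluster = cluster, noise = noise))
  expect_lt(abs(fit2$estimate[fit2$term == "noise"]), 0.15)
  # constant covariate is an explicit failure
  expect_error(cox_fit(rec, data.frame(flat = rep(1, n))), "constant")
  # listwise deletion is reported
  cl_na <- cluster
  cl_na[1:5] <- NA
  expect_message(fit3 <- cox_fit(rec, data.frame(cluster = cl_na)),
                 "dropped 5")
  expect_equal(attr(fit3, "n_dropped"), 5)
  expect_equal(glance(fit)$n, n)
})
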