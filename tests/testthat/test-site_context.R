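iv <- function(chrom, start, end) tibble::tibble(chrom = chrom, start = start, end = end)

test_that("profile rows are RPM-binned signal around summits", {
  sites <- tibble::tibble(site_id = "s1", chrom = "chr1", start = 4000L,
                          end = 6000L, summit = 5000L)
  uniform <- signal_track(iv("chr1", 0L, 20000L) %>% dplyr::mutate(value = 1),
                          1e6)
  tracks <- list(EV_vehicle = list(uniform))
  pm <- profile_matrix(sites, tracks, "EV_vehicle", half_width = 1000,
                       bin_width = 10)
  # 1 read/bp, 10 bp bins, library 1e6 -> 10 RPM units per bin
  expect_equal(dim(pm$values), c(1, 200))
  expect_true(all(pm$values == 10))
  # mean over two identical replicates equals the single-replicate row
  pm2 <- profile_matrix(sites, list(EV_vehicle = list(uniform, uniform)),
                        "EV_vehicle", half_width = 1000, bin_width = 10)
  expect_equal(pm2$values, pm$values)
  # zero track -> zero matrix
  zero <- signal_track(iv("chr1", 0L, 20000L) %>% dplyr::mutate(value = 0), 1e6)
  pm0 <- profile_matrix(sites, list(EV_vehicle = list(zero)), "EV_vehicle")
  expect_true(all(pm0$values == 0))
})

test_that("mean_profile is the column mean and rejects empty matrices", {
  set.seed(9)
  m <- matrix(rexp(35), 5, 7)
  pm <- structure(list(values = m, positions = seq_len(7), site_id = 1:5,
                       condition = "EV_vehicle"), class = "profile_matrix")
  expect_equal(mean_profile(pm)$signal, colMeans(m))
  pm$values <- m[0, , drop = FALSE]
  expect_error(mean_profile(pm), "no rows")
  # symmetric rows average to a constant
  r <- rexp(7)
  pm$values <- rbind(r, -r + 2 * 3)
  expect_equal(mean_profile(pm)$signal, rep(3, 7))
})

test_that("co-occurrence score is overlap over query occupancy", {
  expect_equal(cooccurrence_score(iv("chr1", 0, 100), iv("chr1", 50, 150)), 0.5)
  q <- iv("chr1", 20, 80)
  expect_equal(cooccurrence_score(iv("chr1", 0, 100), q), 1)
  expect_equal(cooccurrence_score(iv("chr2", 0, 100), q), 0)
  expect_error(cooccurrence_score(iv("chr1", 0, 100), q[0, ]), "zero occupancy")
  # monotone non-decreasing as the test set grows
  set.seed(15)
  test_small <- random_intervals(10)
  extra <- random_intervals(10)
  query <- random_intervals(10)
  expect_gte(cooccurrence_score(dplyr::bind_rows(test_small, extra), query),
             cooccurrence_score(test_small, query))
})

test_that("Z-normalization is per test row with sample sd", {
  # construct three queries giving raw scores 0.2 / 0.5 / 0.8 for one test
  test <- iv("chr1", 0, 100)
  queries <- list(q1 = iv("chr1", c(80, 200), c(100, 280)),   # 20/100
                  q2 = iv("chr1", c(50, 300), c(100, 350)),   # 50/100
                  q3 = iv("chr1", c(20, 400), c(100, 420)))   # 80/100
  res <- cooccurrence_zscores(list(t = test), queries)
  expect_equal(unname(res$raw[1, ]), c(0.2, 0.5, 0.8))
  expect_equal(unname(res$z[1, ]), c(-1, 0, 1))
  # every non-degenerate row has mean 0 and sample sd 1
  set.seed(21)
  tests <- list(a = random_intervals(20), b = random_intervals(20))
  qs <- list(x = random_intervals(12), y = random_intervals(12),
             z = random_intervals(12), w = random_intervals(12))
  res2 <- cooccurrence_zscores(tests, qs)
  for (i in 1:2) {
    expect_lt(abs(mean(res2$z[i, ])), 1e-12)
    expect_lt(abs(sd(res2$z[i, ]) - 1), 1e-12)
  }
  # degenerate row: all-zero Z with a warning
  far <- iv("chr9", 0, 50)
  expect_warning(res3 <- cooccurrence_zscores(list(t = far), queries),
                 "constant")
  expect_equal(unname(res3$z[1, ]), c(0, 0, 0))
  expect_error(cooccurrence_zscores(list(t = test), queries[1]),
               "at least two")
})

ann1 <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                       tss = 5000L, start = 5000L, end = 7000L)

test_that("TSS bin assignment is strand-aware with stated precedence", {
  # + strand: summit 1,000 bp upstream of the TSS
  expect_equal(as.character(assign_bin("chr1", 4000L, ann1)),
               "upstream_500_2000")
  # - strand mirror
  ann_m <- ann1 %>% dplyr::mutate(strand = "-", tss = 5000L,
                                  start = 3000L, end = 5001L)
  expect_equal(as.character(assign_bin("chr1", 6000L, ann_m)),
               "upstream_500_2000")
  # inside the gene, beyond the promoter bins -> gene body
  expect_equal(as.character(assign_bin("chr1", 6000L, ann1)), "gene_body")
  # far away -> intergenic
  expect_equal(as.character(assign_bin("chr1", 9000L, ann1)), "intergenic")
  # proximal promoter and immediate downstream
  expect_equal(as.character(assign_bin("chr1", 4800L, ann1)), "upstream_0_500")
  expect_equal(as.character(assign_bin("chr1", 5100L, ann1)), "downstream_0_500")
  expect_error(assign_bin("chrX", 100L, ann1), "absent from annotation")
  # a site between two genes goes to the nearest TSS only
  ann2 <- dplyr::bind_rows(
    ann1,
    tibble::tibble(gene_id = "g2", chrom = "chr1", strand = "+",
                   tss = 11000L, start = 11000L, end = 12000L))
  expect_equal(as.character(assign_bin("chr1", 9800L, ann2)),
               "upstream_500_2000")
})

test_that("one-gene genome background matches arithmetic", {
  genome <- tibble::tibble(chrom = "chr1", length = 10000)
  bg <- genome_bin_fractions(genome, ann1, chunk = 2500)
  expect_equal(bg$background[bg$bin == "upstream_500_2000"], 1500 / 10000)
  expect_equal(bg$background[bg$bin == "upstream_0_500"], 500 / 10000)
  expect_equal(bg$background[bg$bin == "downstream_0_500"], 500 / 10000)
  expect_equal(sum(bg$background), 1)
})

test_that("genomic distribution reports per-set fractions and folds", {
  genome <- tibble::tibble(chrom = "chr1", length = 10000)
  sets <- list(promoterish = tibble::tibble(chrom = "chr1",
                                            summit = c(4000L, 3600L, 9000L,
                                                       6500L, 4100L, 3900L)),
               bodyish = tibble::tibble(chrom = "chr1",
                                        summit = c(6000L, 6500L)))
  d <- genomic_distribution(sets, genome, ann1)
  dd <- tibble::as_tibble(d)
  frs <- tapply(dd$fraction, dd$set, sum)
  expect_equal(as.vector(frs), c(1, 1))
  row <- dd[dd$set == "promoterish" & dd$bin == "upstream_500_2000", ]
  expect_equal(row$fraction, 4 / 6)
  expect_equal(row$fold, (4 / 6) / 0.15)
  pf <- pairwise_fold(d, "promoterish", "bodyish")
  expect_equal(pf$fold[pf$bin == "gene_body"], (1 / 6) / 1)
  expect_error(genomic_distribution(list(e = sets$promoterish[0, ]),
                                    genome, ann1), "non-empty")
})
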