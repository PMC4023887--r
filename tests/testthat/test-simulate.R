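small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed,
             n_chrom = 2, chrom_length = 1e6, n_genes = 200,
             sites_per_class = c(lost = 30, rescued = 30,
                                 enhanced = 30, other = 30),
             n_samples = 20, n_expr_genes = 300, block_size = 10,
             n_block_deg = 8, n_extra_deg = 30, ...)
}

test_that("generation is a pure function of the configuration", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(small_cfg(seed = 9), d1)
  simulate_study(small_cfg(seed = 9), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 20)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_study(small_cfg(seed = 10), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "expression.tsv"))),
    unname(tools::md5sum(file.path(d3, "expression.tsv")))))
})

test_that("generated files round-trip through the package readers", {
  d <- withr::local_tempdir()
  paths <- simulate_study(small_cfg(seed = 2), d)
  genome <- read_chrom_sizes(paths$chrom_sizes)
  expect_equal(nrow(genome), 2)
  ann <- read_gene_annotation(paths$annotation)
  expect_equal(nrow(ann), 200)
  expect_true(all(ann$tss >= 0 & ann$tss < 1e6))
  expect_setequal(unique(ann$strand), c("+", "-"))
  man <- read_manifest(paths$manifest)
  expect_equal(nrow(man), 4 + 3 + 4 + 4)
  pk <- read_narrowpeak(man$peaks[1])
  expect_gt(nrow(pk), 0)
  expect_true(all(pk$summit >= pk$start & pk$summit < pk$end))
  tr <- read_bedgraph(man$track[1], man$library_size[1])
  expect_gt(nrow(tr$cov), 0)
  m <- read_expression_matrix(paths$expression)
  expect_equal(dim(m), c(300, 20))
  md <- read_sample_metadata(paths$metadata)
  expect_equal(md$sample_id, colnames(m))
})

test_that("planted presence patterns follow the class definitions", {
  cfg <- small_cfg(seed = 3)
  ga <- sim_genome_annotation(cfg)
  truth <- sim_peak_truth(cfg, ga$genome, ga$annotation)
  expect_equal(as.vector(table(truth$class)), rep(30, 4))
  r <- truth[truth$class == "rescued", ]
  expect_true(all(r$EV_vehicle & !r$EV_bicalutamide & r$HES6_bicalutamide))
  l <- truth[truth$class == "lost", ]
  expect_true(all(l$EV_vehicle & !l$EV_bicalutamide & !l$HES6_bicalutamide))
  e <- truth[truth$class == "enhanced", ]
  expect_true(all(e$EV_vehicle & e$EV_bicalutamide & e$HES6_bicalutamide))
  # summits stay apart so consolidation cannot merge distinct sites
  by_chr <- split(truth$summit, truth$chrom)
  expect_true(all(unlist(lapply(by_chr, function(s) diff(sort(s)) >= 300))))
})

test_that("replicate drop-out thins peak calls at the configured rate", {
  cfg <- sim_config(seed = 4, n_chrom = 2, chrom_length = 2e6, n_genes = 100,
                    sites_per_class = c(lost = 500, rescued = 0,
                                        enhanced = 0, other = 0),
                    dropout = 0.2, spurious_rate = 0)
  ga <- sim_genome_annotation(cfg)
  truth <- sim_peak_truth(cfg, ga$genome, ga$annotation)
  peaks <- sim_replicate_peaks(truth, cfg, ga$genome)
  ev <- peaks[peaks$background == "EV" & peaks$treatment == "vehicle", ]
  frac <- nrow(ev) / (500 * 4)
  expect_equal(frac, 0.8, tolerance = 0.05)
  # drop-out 1 with no spurious peaks -> empty replicates
  cfg1 <- sim_config(seed = 4, sites_per_class = c(lost = 50, rescued = 0,
                                                   enhanced = 0, other = 0),
                     dropout = 1, spurious_rate = 0)
  ga1 <- sim_genome_annotation(cfg1)
  t1 <- sim_peak_truth(cfg1, ga1$genome, ga1$annotation)
  expect_equal(nrow(sim_replicate_peaks(t1, cfg1, ga1$genome)), 0)
})

test_that("signal tracks carry the planted class-condition amplitudes", {
  cfg <- small_cfg(seed = 5)
  ga <- sim_genome_annotation(cfg)
  truth <- sim_peak_truth(cfg, ga$genome, ga$annotation)
  tracks <- sim_signal_tracks(truth, cfg)
  sites <- truth %>% dplyr::rename(site_id = "true_id") %>%
    dplyr::mutate(start = .data$summit - 200L, end = .data$summit + 200L)
  sig <- site_signal(sites, tracks, classification_config())
  enh <- sig$class == "enhanced"
  oth <- sig$class == "other"
  fold_enh <- mean(sig$signal_HES6_bicalutamide[enh]) /
    mean(sig$signal_EV_bicalutamide[enh])
  fold_oth <- mean(sig$signal_HES6_bicalutamide[oth]) /
    mean(sig$signal_EV_bicalutamide[oth])
  expect_equal(fold_enh, 3, tolerance = 0.15)
  expect_equal(fold_oth, 1, tolerance = 0.1)
  # lost sites carry only background under bicalutamide
  lost <- sig$class == "lost"
  expect_lt(mean(sig$signal_HES6_bicalutamide[lost]),
            0.2 * mean(sig$signal_HES6_bicalutamide[enh]))
})

test_that("the expression block is tightly correlated with the anchor", {
  cfg <- sim_config(seed = 6)
  es <- sim_expression_survival(cfg)
  expect_equal(dim(es$expression), c(2000, 30))
  block <- es$truth$gene_id[es$truth$block]
  expect_length(block, 40)
  r <- vapply(block, function(g) {
    cor(es$expression[g, ], es$expression["HES6", ])
  }, numeric(1))
  expect_gte(mean(abs(r)), 0.9)
  # censoring close to its configured fraction (binomial noise at n = 30)
  expect_lt(abs(mean(es$metadata$event == 0) - 0.3), 0.2)
  # true clusters follow the group labels
  st <- attr(es$truth, "sample_truth")
  expect_equal(st$cluster == "high", es$metadata$group == "aggressive")
})
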