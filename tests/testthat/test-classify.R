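# Small hand-built replicate designs for consolidation and classification.

peak_row <- function(chrom, start, end, summit, background, treatment, rep) {
  tibble::tibble(chrom = chrom, start = start, end = end, summit = summit,
                 background = background, treatment = treatment,
                 replicate = rep)
}

# a design with one replicate per condition carrying no peaks near the locus
# under test is not allowed, so give every condition a far-away anchor peak
anchor_peaks <- function() {
  dplyr::bind_rows(
    peak_row("chr9", 1000L, 1300L, 1150L, "EV", "vehicle", 1L),
    peak_row("chr9", 1000L, 1300L, 1150L, "EV", "bicalutamide", 1L),
    peak_row("chr9", 1000L, 1300L, 1150L, "HES6", "vehicle", 1L),
    peak_row("chr9", 1000L, 1300L, 1150L, "HES6", "bicalutamide", 1L))
}

test_that("consensus summit is the rounded mean of replicate summits", {
  pk <- dplyr::bind_rows(
    peak_row("chr1", 50L, 200L, 100L, "EV", "vehicle", 1L),
    peak_row("chr1", 60L, 210L, 110L, "EV", "vehicle", 2L),
    peak_row("chr1", 70L, 220L, 120L, "EV", "vehicle", 3L),
    anchor_peaks())
  sites <- consolidate_replicates(pk, classification_config())
  s <- sites[sites$chrom == "chr1", ]
  expect_equal(nrow(s), 1)
  expect_equal(s$summit, 110L)
  expect_equal(s$start, 50L)
  expect_equal(s$end, 220L)
})

test_that("presence follows the reproducibility threshold", {
  four_reps <- function(reps_with_peak) {
    dplyr::bind_rows(
      purrr::map(reps_with_peak, function(r) {
        peak_row("chr1", 100L, 300L, 200L, "EV", "vehicle", as.integer(r))
      }),
      purrr::map(1:4, function(r) {
        peak_row("chr2", 5000L, 5200L, 5100L, "EV", "vehicle", as.integer(r))
      }),
      anchor_peaks())
  }
  strict <- classification_config(reproducibility_min_fraction = 0.75)
  # 3 of 4 replicates passes at 0.75
  s <- consolidate_replicates(four_reps(1:3), strict)
  expect_true(s$present_EV_vehicle[s$chrom == "chr1"])
  expect_equal(s$support_EV_vehicle[s$chrom == "chr1"], 0.75)
  # 1 of 4 does not
  s <- consolidate_replicates(four_reps(1), strict)
  expect_false(s$present_EV_vehicle[s$chrom == "chr1"])
  # at the default majority threshold, 2 of 4 passes
  s <- consolidate_replicates(four_reps(1:2), classification_config())
  expect_true(s$present_EV_vehicle[s$chrom == "chr1"])
})

test_that("consolidation errors when a condition has no replicates", {
  pk <- peak_row("chr1", 0L, 100L, 50L, "EV", "vehicle", 1L)
  expect_error(consolidate_replicates(pk), "no replicates")
})

test_that("classification implements the lost/rescued/enhanced rules", {
  base <- tibble::tibble(
    site_id = sprintf("s%d", 1:5), chrom = "chr1",
    start = seq(0L, 4000L, 1000L), end = seq(400L, 4400L, 1000L),
    summit = seq(200L, 4200L, 1000L),
    present_EV_vehicle = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    present_EV_bicalutamide = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    present_HES6_vehicle = TRUE,
    present_HES6_bicalutamide = c(TRUE, FALSE, TRUE, TRUE, FALSE),
    signal_EV_bicalutamide = c(1, 1, 2, 2, 1),
    signal_HES6_bicalutamide = c(3, 0, 4, 2.5, 1))
  cls <- classify_sites(base, classification_config())
  expect_equal(as.character(cls$class),
               c("rescued",   # present base, absent EV-bic, present HES6-bic
                 "lost",      # absent in both bicalutamide conditions
                 "enhanced",  # fold 2 >= 1.5
                 "other",     # fold 1.25 < 1.5
                 "other"))    # not a baseline site
  # every baseline site gets exactly one label; the split is a partition
  sets <- class_sets(cls)
  expect_equal(sum(purrr::map_int(sets, nrow)), nrow(cls))
  expect_equal(sort(unlist(purrr::map(sets, "site_id"), use.names = FALSE)),
               sort(cls$site_id))
})

test_that("per-class BED output emits a file for every class, empty included", {
  tmp <- withr::local_tempdir()
  sites <- tibble::tibble(
    site_id = "s1", chrom = "chr1", start = 0L, end = 100L, summit = 50L,
    present_EV_vehicle = TRUE, present_EV_bicalutamide = FALSE,
    present_HES6_vehicle = TRUE, present_HES6_bicalutamide = TRUE,
    signal_EV_bicalutamide = 0, signal_HES6_bicalutamide = 0)
  sites <- classify_sites(sites)
  paths <- write_class_beds(sites, tmp)
  expect_true(all(file.exists(paths)))
  expect_equal(nrow(read_bed(paths[["rescued"]])), 1)
  expect_equal(nrow(read_bed(paths[["lost"]])), 0)
})

test_that("site_signal averages replicate RPM in the summit window", {
  sites <- tibble::tibble(site_id = "s1", chrom = "chr1", start = 4000L,
                          end = 6000L, summit = 5000L)
  flat <- function(value, lib) {
    signal_track(tibble::tibble(chrom = "chr1", start = 0L, end = 10000L,
                                value = value), lib)
  }
  cfg <- classification_config(summit_window_half_width = 250)
  # 5 reads in the window at library 2M -> 2.5 RPM
  tracks <- list(EV_vehicle = list(flat(5 / 500, 2e6)),
                 EV_bicalutamide = list(flat(0, 1e6)),
                 HES6_vehicle = list(flat(0, 1e6)),
                 HES6_bicalutamide = list(flat(2 / 500, 1e6), flat(4 / 500, 1e6)))
  out <- site_signal(sites, tracks, cfg)
  expect_equal(out$signal_EV_vehicle, 2.5)
  expect_equal(out$signal_EV_bicalutamide, 0)
  expect_equal(out$signal_HES6_bicalutamide, 3)  # mean of 2 and 4 RPM
  expect_error(site_signal(sites, tracks[1:3], cfg), "no tracks")
})

test_that("classification is invariant to replicate and row order", {
  cfg <- sim_config(seed = 5, sites_per_class = c(lost = 25, rescued = 25,
                                                  enhanced = 0, other = 25),
                    spurious_rate = 0)
  ga <- sim_genome_annotation(cfg)
  truth <- sim_peak_truth(cfg, ga$genome, ga$annotation)
  peaks <- sim_replicate_peaks(truth, cfg, ga$genome)
  a <- consolidate_replicates(peaks)
  set.seed(1)
  b <- consolidate_replicates(peaks[sample(nrow(peaks)), ])
  expect_identical(a, b)
})

test_that("noiseless replicates recover every planted class exactly", {
  cfg <- sim_config(seed = 2,
                    sites_per_class = c(lost = 40, rescued = 40,
                                        enhanced = 40, other = 40),
                    dropout = 0, summit_jitter_sd = 0, spurious_rate = 0,
                    background_rate = 0)
  ga <- sim_genome_annotation(cfg)
  truth <- sim_peak_truth(cfg, ga$genome, ga$annotation)
  peaks <- sim_replicate_peaks(truth, cfg, ga$genome)
  tracks <- sim_signal_tracks(truth, cfg)
  sites <- consolidate_replicates(peaks)
  sites <- site_signal(sites, tracks)
  sites <- classify_sites(sites)
  ev <- evaluate_classification(sites, truth)
  expect_equal(ev$accuracy, 1)
})
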