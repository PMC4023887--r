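# Seeded generators for every input the pipeline consumes, emulating the
# statistical structure of the study design: a 2x2 replicated ChIP-seq
# peak design with class-dependent presence patterns and drop-out,
# coverage tracks with class-dependent amplitude, an expression matrix
# with a planted anchor-correlated block and planted differential
# expression, and survival times whose hazard depends on true cluster
# membership. Planted truth is always serialized alongside the data.

#' Simulation configuration
#'
#' Defaults define the reference synthetic study: a compact, gene-dense
#' two-chromosome genome (so promoter bins carry substantial genomic
#' mass), the 4/3/4/4 replicate design (every condition in biological
#' quadruplicate except EV + bicalutamide in triplicate), 300 sites per
#' class with 10% per-replicate peak drop-out, a 3-fold signal gain at
#' enhanced sites, a 2-fold promoter-bin enrichment planted in the rescued
#' class, and an expression cohort of 30 samples with a 40-gene block
#' correlated at rho = 0.95 to the anchor gene, 30 of which are planted
#' DEGs. Survival uses an exponential baseline with log hazard ratio 0.7
#' for the signature-high cluster and ~30% censoring.
#'
#' @param seed Integer seed; all generators are pure functions of the
#'   configuration.
#' @param n_chrom,chrom_length Genome shape.
#' @param n_genes Genes placed on a regular grid (strand alternating).
#' @param gene_length,gene_spacing Gene span and slot size in bp.
#' @param sites_per_class Named counts for lost/rescued/enhanced/other.
#' @param replicates Named replicate counts per condition.
#' @param dropout Probability a truly present peak is missed in one
#'   replicate's peak calls.
#' @param summit_jitter_sd Gaussian sd (bp) of replicate summit jitter.
#' @param spurious_rate Expected spurious peaks per replicate, as a
#'   fraction of the number of true sites.
#' @param peak_half_width Half-width (bp) of called peak intervals.
#' @param promoter_enrichment Named per-class fold by which summits are
#'   enriched in the upstream 500-2,000 bp bin relative to its genomic
#'   background fraction.
#' @param reads_per_peak Expected reads under one present peak's bump.
#' @param enhanced_fold Signal fold for enhanced sites in
#'   HES6 + bicalutamide.
#' @param bump_sd Gaussian bump sd in bp.
#' @param background_rate Background coverage (reads per bp).
#' @param library_size Mapped reads per replicate track.
#' @param n_samples,n_expr_genes Expression cohort shape.
#' @param anchor Anchor gene id.
#' @param block_size Genes in the planted anchor-correlated block.
#' @param rho Planted correlation of block genes with the anchor.
#' @param n_block_deg Block genes also planted in the DEG list.
#' @param n_extra_deg Non-block planted DEGs.
#' @param deg_effect Between-group shift (log units) for planted DEGs.
#' @param anchor_shift Between-group shift of the anchor itself.
#' @param baseline_hazard Exponential baseline hazard (per month).
#' @param log_hr Planted log hazard ratio for the signature-high cluster.
#' @param censoring Target censoring fraction.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 2, chrom_length = 5e6,
                       n_genes = 2000, gene_length = 2000,
                       gene_spacing = 5000,
                       sites_per_class = c(lost = 300, rescued = 300,
                                           enhanced = 300, other = 300),
                       replicates = c(EV_vehicle = 4, EV_bicalutamide = 3,
                                      HES6_vehicle = 4, HES6_bicalutamide = 4),
                       dropout = 0.1,
                       summit_jitter_sd = 10,
                       spurious_rate = 0.05,
                       peak_half_width = 150,
                       promoter_enrichment = c(lost = 1, rescued = 2,
                                               enhanced = 1, other = 1),
                       reads_per_peak = 300,
                       enhanced_fold = 3,
                       bump_sd = 100,
                       background_rate = 0.02,
                       library_size = 2e7,
                       n_samples = 30, n_expr_genes = 2000,
                       anchor = "HES6",
                       block_size = 40, rho = 0.95,
                       n_block_deg = 30, n_extra_deg = 170,
                       deg_effect = 2, anchor_shift = 2.5,
                       baseline_hazard = 0.02, log_hr = 0.7,
                       censoring = 0.3) {
  stopifnot(dropout >= 0, dropout <= 1, rho > -1, rho < 1,
            censoring >= 0, censoring < 1,
            all(sites_per_class >= 0), all(replicates >= 1),
            n_block_deg <= block_size, seed == floor(seed))
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# Deterministic per-stage seeds derived from the master seed (kept < 2^31).
stage_seed <- function(config, stage) {
  offsets <- c(genome = 11L, peaks = 23L, replicates = 37L, tracks = 53L,
               expression = 71L)
  (as.integer(config$seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Simulated genome and gene annotation
#'
#' Genes are laid on a regular grid of `gene_spacing`-bp slots (alternating
#' strand, small seeded jitter within the slot) so genes never overlap and
#' every promoter bin fits inside its slot.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (tibble `chrom`, `length`) and `annotation`
#'   (gene annotation tibble).
#' @export
sim_genome_annotation <- function(config) {
  genome <- tibble(chrom = sprintf("chr%d", seq_len(config$n_chrom)),
                   length = rep(config$chrom_length, config$n_chrom))
  if (config$n_genes == 0) {
    return(list(genome = genome,
                annotation = tibble(gene_id = character(), chrom = character(),
                                    strand = character(), tss = integer(),
                                    start = integer(), end = integer())))
  }
  slots_per_chrom <- floor(config$chrom_length / config$gene_spacing)
  if (config$n_genes > slots_per_chrom * config$n_chrom) {
    abort("genes cannot fit without overlap; enlarge the genome")
  }
  set.seed(stage_seed(config, "genome"))
  per_chrom <- ceiling(config$n_genes / config$n_chrom)
  ann <- purrr::map(seq_len(config$n_chrom), function(i) {
    n_here <- min(per_chrom, config$n_genes - (i - 1) * per_chrom)
    if (n_here <= 0) return(NULL)
    slot0 <- (seq_len(n_here) - 1) * config$gene_spacing
    # leave room for the upstream promoter bin inside the slot
    margin <- config$gene_spacing - config$gene_length - 2100
    offset <- 2050 + floor(runif(n_here, 0, max(margin, 1)))
    start <- as.integer(slot0 + offset)
    end <- as.integer(start + config$gene_length)
    # one strand per chromosome: TSS counts stay strand-balanced across the
    # genome while promoter bins of neighbouring genes never overlap
    strand <- rep(if (i %% 2 == 1) "+" else "-", n_here)
    tibble(gene_id = sprintf("gene_%s_%04d", genome$chrom[i], seq_len(n_here)),
           chrom = genome$chrom[i], strand = strand,
           tss = as.integer(ifelse(strand == "+", start, end - 1L)),
           start = start, end = end)
  }) %>% bind_rows()
  list(genome = genome, annotation = ann)
}

class_presence <- function() {
  tibble(class = site_classes(),
         EV_vehicle = c(TRUE, TRUE, TRUE, TRUE),
         EV_bicalutamide = c(FALSE, FALSE, TRUE, TRUE),
         HES6_vehicle = c(TRUE, TRUE, TRUE, TRUE),
         HES6_bicalutamide = c(FALSE, TRUE, TRUE, TRUE))
}

#' Simulated true binding sites with planted classes
#'
#' Summits are placed with a minimum separation so distinct sites never
#' merge during consolidation. Per class, summits land in the upstream
#' 500-2,000 bp promoter bin with probability `promoter_enrichment x`
#' (genomic background fraction of that bin), otherwise uniformly outside
#' it. Presence patterns per condition follow the class definitions
#' exactly (lost: baseline only; rescued: absent in EV + bicalutamide,
#' present in HES6 + bicalutamide; enhanced and other: present
#' everywhere, differing only in signal fold).
#'
#' @param config A [sim_config()].
#' @param genome,annotation From [sim_genome_annotation()].
#' @return Tibble of true sites: `true_id`, `chrom`, `summit`, `class`,
#'   and one logical presence column per condition.
#' @export
sim_peak_truth <- function(config, genome, annotation) {
  scheme <- tss_bin_scheme()
  set.seed(stage_seed(config, "peaks"))
  # promoter-bin intervals (upstream 500-2000), per gene, strand-aware
  promo <- annotation %>%
    mutate(start_bin = if_else(.data$strand == "+",
                               .data$tss - scheme$upstream_far,
                               .data$tss + scheme$upstream_near + 1L),
           end_bin = if_else(.data$strand == "+",
                             .data$tss - scheme$upstream_near,
                             .data$tss + scheme$upstream_far + 1L)) %>%
    select(chrom = "chrom", start = "start_bin", end = "end_bin") %>%
    mutate(start = pmax(.data$start, 0L))
  promo <- merge_intervals(promo)
  promo_bp <- bp_occupancy(promo)
  genome_bp <- sum(genome$length)
  f_bg <- promo_bp / genome_bp

  # separation keeps peaks (half-width + jitter) of distinct sites disjoint
  min_sep <- 2 * config$peak_half_width + 5 * config$summit_jitter_sd
  occupied <- list()
  draw_in_set <- function(ivs) {
    # uniform base within an interval set
    w <- ivs$end - ivs$start
    i <- sample.int(nrow(ivs), 1, prob = w)
    ivs$start[i] + sample.int(w[i], 1) - 1L
  }
  draw_uniform <- function() {
    ci <- sample.int(nrow(genome), 1, prob = genome$length)
    list(chrom = genome$chrom[ci],
         pos = sample.int(genome$length[ci] - 2000L, 1) + 1000L)
  }
  sites <- list()
  taken <- lapply(setNames(genome$chrom, genome$chrom), function(x) integer())
  place <- function(class, enrich) {
    p_in <- min(1, enrich * f_bg)
    # the bin-membership coin is flipped exactly once per site; every
    # rejection (outside-branch draws falling into the promoter set, or
    # violations of the minimum separation) resamples within the chosen
    # branch only, so P(in bin) is enrich * f_bg regardless of crowding
    inside <- runif(1) < p_in && nrow(promo) > 0
    for (iter in seq_len(100000L)) {
      if (inside) {
        w <- promo$end - promo$start
        i <- sample.int(nrow(promo), 1, prob = w)
        ch <- promo$chrom[i]
        pos <- promo$start[i] + sample.int(w[i], 1) - 1L
      } else {
        u <- draw_uniform()
        ch <- u$chrom
        pos <- u$pos
        if (f_bg > 0 &&
            any(promo$chrom == ch & promo$start <= pos & pos < promo$end)) {
          next
        }
      }
      if (length(taken[[ch]]) == 0 || all(abs(taken[[ch]] - pos) >= min_sep)) {
        taken[[ch]] <<- c(taken[[ch]], pos)
        return(list(chrom = ch, summit = pos))
      }
    }
    abort("could not place sites at the configured density; enlarge the genome")
  }
  classes <- rep(names(config$sites_per_class), config$sites_per_class)
  placed <- purrr::map(classes, function(cl) {
    place(cl, config$promoter_enrichment[[cl]])
  })
  truth <- tibble(true_id = sprintf("true_%05d", seq_along(classes)),
                  chrom = purrr::map_chr(placed, "chrom"),
                  summit = purrr::map_int(placed, ~ as.integer(.x$summit)),
                  class = factor(classes, levels = site_classes())) %>%
    arrange(.data$chrom, .data$summit) %>%
    mutate(true_id = sprintf("true_%05d", row_number()))
  left_join(truth,
            class_presence() %>% mutate(class = factor(.data$class, site_classes())),
            by = "class")
}

#' Simulated replicate peak calls
#'
#' For every condition in which a true site is present, each replicate
#' calls the peak with probability `1 - dropout`, with Gaussian summit
#' jitter; spurious peaks are added uniformly at the configured rate.
#'
#' @param truth From [sim_peak_truth()].
#' @param config A [sim_config()].
#' @param genome Genome tibble.
#' @return Long peak tibble (one row per called peak) with `chrom`,
#'   `start`, `end`, `summit`, `score`, `background`, `treatment`,
#'   `replicate` — the input shape of [consolidate_replicates()].
#' @export
sim_replicate_peaks <- function(truth, config, genome) {
  set.seed(stage_seed(config, "replicates"))
  hw <- config$peak_half_width
  clen <- setNames(genome$length, genome$chrom)
  out <- list()
  for (cond in design_conditions()) {
    n_rep <- config$replicates[[cond]]
    bg <- sub("_.*", "", cond)
    tx <- sub(".*_", "", cond)
    present <- truth[truth[[cond]], ]
    for (r in seq_len(n_rep)) {
      called <- present[runif(nrow(present)) >= config$dropout, ]
      n_spur <- rpois(1, config$spurious_rate * nrow(truth))
      if (n_spur > 0) {
        ci <- sample.int(nrow(genome), n_spur, replace = TRUE,
                         prob = genome$length)
        spur <- tibble(chrom = genome$chrom[ci],
                       summit = purrr::map_int(ci, function(i) {
                         as.integer(sample.int(genome$length[i] - 2L * hw, 1) + hw)
                       }))
      } else {
        spur <- tibble(chrom = character(), summit = integer())
      }
      summit <- c(as.integer(round(called$summit +
                                     rnorm(nrow(called), 0,
                                           config$summit_jitter_sd))),
                  spur$summit)
      chrom <- c(called$chrom, spur$chrom)
      summit <- pmin(pmax(summit, hw), as.integer(clen[chrom]) - hw - 1L)
      out[[length(out) + 1]] <- tibble(
        chrom = chrom,
        start = as.integer(summit - hw),
        end = as.integer(summit + hw),
        summit = as.integer(summit),
        score = 100,
        background = bg, treatment = tx, replicate = r)
    }
  }
  bind_rows(out) %>% arrange(.data$chrom, .data$start)
}

#' Simulated coverage tracks
#'
#' One [signal_track()] per condition and replicate: each present site
#' contributes a discretized Gaussian bump (sd `bump_sd`, expected
#' `reads_per_peak` reads; `enhanced_fold` times more at enhanced sites in
#' HES6 + bicalutamide), with Poisson noise per 10-bp tile on top of a
#' Poisson background, tiled over `summit +/- flank` around every site so
#' profile windows are covered.
#'
#' @param truth From [sim_peak_truth()].
#' @param config A [sim_config()].
#' @param flank Half-extent (bp) of the tiled region around each summit.
#' @return Named list (condition id) of lists of [signal_track()].
#' @export
sim_signal_tracks <- function(truth, config, flank = 1100) {
  set.seed(stage_seed(config, "tracks"))
  tile <- 10L
  n_tiles <- as.integer(2 * flank / tile)
  rel <- (seq_len(n_tiles) - 1) * tile - flank   # tile starts, summit-relative
  centers <- rel + tile / 2
  w <- exp(-centers^2 / (2 * config$bump_sd^2))
  w <- w / sum(w)                                 # bump weight per tile
  tracks <- list()
  for (cond in design_conditions()) {
    reps <- list()
    amp <- ifelse(!truth[[cond]], 0, config$reads_per_peak)
    if (cond == "HES6_bicalutamide") {
      amp[truth$class == "enhanced" & truth[[cond]]] <-
        config$reads_per_peak * config$enhanced_fold
    }
    for (r in seq_len(config$replicates[[cond]])) {
      lam <- as.vector(outer(w, amp)) +              # tiles x sites, col-major
        config$background_rate * tile
      counts <- rpois(length(lam), lam)
      cov <- tibble(
        chrom = rep(truth$chrom, each = n_tiles),
        start = as.integer(rep(truth$summit, each = n_tiles) + rel),
        end = as.integer(rep(truth$summit, each = n_tiles) + rel + tile),
        value = counts / tile) %>%
        filter(.data$start >= 0)
      reps[[r]] <- signal_track(cov, config$library_size)
    }
    tracks[[cond]] <- reps
  }
  tracks
}

#' Simulated expression cohort with survival
#'
#' The anchor gene is shifted between the two sample groups
#' (`anchor_shift`); block genes are built as
#' `rho * anchor_z + sqrt(1 - rho^2) * noise` so they are both highly
#' correlated with the anchor and differential. The planted DEG list —
#' standing in for an independently derived differential-expression list —
#' contains `n_block_deg` of the block genes plus `n_extra_deg` non-block
#' genes given their own group shift; when a `deg_pool` is supplied (e.g.
#' genes near rescued binding sites), half of the extra DEGs are drawn
#' from it so binding-site targets genuinely overlap the DEG list.
#' Survival times are exponential with hazard multiplied by `exp(log_hr)`
#' in the signature-high group; censoring is uniform over `(0, t)` for a
#' configured fraction of samples.
#'
#' @param config A [sim_config()].
#' @param n_samples Optional override of the cohort size.
#' @param gene_ids Optional gene ids to use for the non-anchor rows
#'   (e.g. annotation gene ids, so ChIP-seq targets and expression share a
#'   namespace); synthetic ids are generated when `NULL`.
#' @param deg_pool Optional gene ids preferred when drawing the extra
#'   (non-block) planted DEGs.
#' @return List with `expression` (matrix genes x samples), `metadata`
#'   (tibble `sample_id`, `group`, `time`, `event`, `age`, `psa`,
#'   `gleason`, `margin`), and `truth` (tibble `gene_id`, `block`, `deg`;
#'   plus attribute `"sample_truth"` with the true cluster per sample).
#' @export
sim_expression_survival <- function(config, n_samples = NULL,
                                    gene_ids = NULL, deg_pool = NULL) {
  set.seed(stage_seed(config, "expression"))
  n <- if (is.null(n_samples)) config$n_samples else n_samples
  g <- config$n_expr_genes
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("expr_gene_%04d", seq_len(g - 1))
  } else {
    gene_ids <- setdiff(gene_ids, config$anchor)
    if (length(gene_ids) < g - 1) {
      gene_ids <- c(gene_ids,
                    sprintf("expr_gene_%04d", seq_len(g - 1 - length(gene_ids))))
    }
    gene_ids <- gene_ids[seq_len(g - 1)]
  }
  genes <- c(config$anchor, gene_ids)
  block <- sample(gene_ids, config$block_size)
  deg_block <- block[seq_len(config$n_block_deg)]
  nonblock <- setdiff(gene_ids, block)
  pool <- intersect(setdiff(deg_pool, block), nonblock)
  n_pooled <- min(length(pool), floor(config$n_extra_deg / 2))
  deg_extra <- c(if (n_pooled > 0) sample(pool, n_pooled),
                 sample(setdiff(nonblock, pool),
                        config$n_extra_deg - n_pooled))
  degs <- c(deg_block, deg_extra)

  group <- factor(rep(c("primary", "aggressive"), length.out = n),
                  levels = c("primary", "aggressive"))
  anchor_raw <- rnorm(n) + config$anchor_shift * (group == "aggressive")
  anchor_z <- as.vector(scale(anchor_raw))
  m <- matrix(rnorm(g * n), nrow = g, dimnames = list(genes, NULL))
  m[config$anchor, ] <- anchor_raw
  for (b in block) {
    m[b, ] <- config$rho * anchor_z +
      sqrt(1 - config$rho^2) * rnorm(n)
  }
  m[deg_extra, ] <- m[deg_extra, , drop = FALSE] +
    config$deg_effect * rep(group == "aggressive", each = length(deg_extra))
  colnames(m) <- sprintf("sample_%03d", seq_len(n))

  cluster <- factor(ifelse(group == "aggressive", "high", "low"),
                    levels = c("low", "high"))
  hazard <- config$baseline_hazard * exp(config$log_hr * (cluster == "high"))
  t_event <- rexp(n, rate = hazard)
  censored <- runif(n) < config$censoring
  time <- ifelse(censored, runif(n) * t_event, t_event)
  metadata <- tibble(
    sample_id = colnames(m),
    group = as.character(group),
    time = pmax(time, 0.01),
    event = as.integer(!censored),
    age = round(rnorm(n, 62, 7), 1),
    psa = round(exp(rnorm(n, 2, 0.6)), 1),
    gleason = sample(6:9, n, replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1)),
    margin = sample(c("negative", "positive"), n, replace = TRUE))
  truth <- tibble(gene_id = genes,
                  block = genes %in% block,
                  deg = genes %in% degs)
  attr(truth, "sample_truth") <- tibble(sample_id = colnames(m),
                                        cluster = as.character(cluster))
  list(expression = m, metadata = metadata, truth = truth)
}

#' Generate and serialize a complete synthetic study
#'
#' Writes every pipeline input under `dir`: chrom.sizes, gene annotation,
#' one narrowPeak and one bedGraph per replicate with a samples manifest,
#' the expression matrix and sample metadata, and the planted truth
#' tables (site classes, gene block/DEG membership, sample clusters).
#' Regeneration from the same configuration is byte-identical.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  ga <- sim_genome_annotation(config)
  truth <- sim_peak_truth(config, ga$genome, ga$annotation)
  peaks <- sim_replicate_peaks(truth, config, ga$genome)
  tracks <- sim_signal_tracks(truth, config)
  rescued <- truth[truth$class == "rescued", ]
  deg_pool <- if (nrow(rescued) > 0) {
    target_geneset(rescued, ga$annotation, closest_only = TRUE)
  } else {
    NULL
  }
  es <- sim_expression_survival(config, gene_ids = ga$annotation$gene_id,
                                deg_pool = deg_pool)

  paths <- list(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    annotation = file.path(dir, "annotation.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"),
    config = file.path(dir, "sim_config.yaml"))

  write_chrom_sizes(ga$genome, paths$chrom_sizes)
  readr::write_tsv(ga$annotation, paths$annotation)
  man <- list()
  for (cond in design_conditions()) {
    for (r in seq_len(config$replicates[[cond]])) {
      pk <- peaks[peaks$background == sub("_.*", "", cond) &
                    peaks$treatment == sub(".*_", "", cond) &
                    peaks$replicate == r, ]
      ppath <- file.path("peaks", sprintf("%s_rep%d.narrowPeak", cond, r))
      tpath <- file.path("tracks", sprintf("%s_rep%d.bedGraph", cond, r))
      write_narrowpeak(pk, file.path(dir, ppath))
      write_bedgraph(tracks[[cond]][[r]], file.path(dir, tpath))
      man[[length(man) + 1]] <- tibble(
        background = sub("_.*", "", cond), treatment = sub(".*_", "", cond),
        replicate = r, peaks = ppath, track = tpath,
        library_size = config$library_size)
    }
  }
  readr::write_tsv(bind_rows(man), paths$manifest)
  write_expression_matrix(es$expression, paths$expression)
  readr::write_tsv(es$metadata, paths$metadata)
  readr::write_tsv(truth, paths$truth_sites)
  readr::write_tsv(es$truth, paths$truth_genes)
  readr::write_tsv(attr(es$truth, "sample_truth"), paths$truth_samples)
  cfg <- unclass(config)
  cfg <- purrr::map(cfg, function(v) if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}
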