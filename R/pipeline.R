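# End-to-end orchestration: validate a configuration, run the stages in
# dependency order (simulate -> classify -> profiles/co-occurrence/
# distribution -> enrichment -> DEG/signature -> stratify) and capture
# provenance in a run manifest.

pipeline_defaults <- function() {
  list(
    seed = 1,
    simulate = TRUE,
    input_dir = NULL,
    sim = list(),                    # overrides passed to sim_config()
    classification = list(),         # overrides for classification_config()
    enrichment = list(max_dist = 25000, site_class = "rescued",
                      closest_only = TRUE),
    signature = list(anchor = "HES6", r_cutoff = 0.9, top_fraction = NULL,
                     q_cutoff = 0.05),
    survival = list(n_permutations = 0),
    profile = list(half_width = 1000, bin_width = 10, max_sites = 500),
    stages = list(classify = TRUE, profiles = TRUE, cooccur = TRUE,
                  distribution = TRUE, enrich = TRUE, signature = TRUE,
                  stratify = TRUE))
}

merge_config <- function(defaults, override, path = "") {
  errs <- character()
  for (key in names(override)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults)) {
      errs <- c(errs, sprintf("unknown configuration key `%s`", full))
      next
    }
    if (is.list(defaults[[key]]) && key != "sim" && key != "classification") {
      if (!is.list(override[[key]])) {
        errs <- c(errs, sprintf("`%s` must be a block", full))
      } else {
        sub <- merge_config(defaults[[key]], override[[key]], full)
        defaults[[key]] <- sub$config
        errs <- c(errs, sub$errors)
      }
    } else {
      defaults[[key]] <- override[[key]]
    }
  }
  list(config = defaults, errors = errs)
}

#' Validate a pipeline configuration
#'
#' Merges the supplied configuration (an R list, or a YAML file path) over
#' the documented defaults, range-checks every parameter, and either
#' returns the completed configuration or aborts listing *all* problems at
#' once.
#'
#' @param config A named list of overrides, a path to a YAML file, or
#'   `NULL`/empty for pure defaults.
#' @return The validated, fully populated `pipeline_config` list.
#' @export
validate_pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  merged <- merge_config(pipeline_defaults(), config)
  cfg <- merged$config
  errs <- merged$errors
  check <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  check(is.numeric(cfg$seed) && cfg$seed == floor(cfg$seed),
        "`seed` must be an integer")
  check(isTRUE(cfg$simulate) || (is.character(cfg$input_dir) &&
                                   dir.exists(cfg$input_dir)),
        "either `simulate: true` or an existing `input_dir` is required")
  cc <- cfg$classification
  if (!is.null(cc$enhancement_fold_min)) {
    check(cc$enhancement_fold_min > 1,
          "`classification.enhancement_fold_min` must be > 1")
  }
  if (!is.null(cc$reproducibility_min_fraction)) {
    check(cc$reproducibility_min_fraction > 0 &&
            cc$reproducibility_min_fraction <= 1,
          "`classification.reproducibility_min_fraction` must be in (0, 1]")
  }
  check(cfg$enrichment$max_dist > 0, "`enrichment.max_dist` must be > 0")
  check(cfg$enrichment$site_class %in% site_classes(),
        "`enrichment.site_class` must be a site class")
  check(cfg$signature$r_cutoff > -1 && cfg$signature$r_cutoff <= 1,
        "`signature.r_cutoff` must be in (-1, 1]")
  check(cfg$signature$q_cutoff > 0 && cfg$signature$q_cutoff <= 1,
        "`signature.q_cutoff` must be in (0, 1]")
  check(cfg$profile$half_width %% cfg$profile$bin_width == 0 ||
          (2 * cfg$profile$half_width) %% cfg$profile$bin_width == 0,
        "`profile.half_width` must be a multiple of `profile.bin_width`")
  if (length(errs) > 0) {
    abort(paste(c("invalid pipeline configuration:",
                  paste0("  - ", errs)), collapse = "\n"))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order and writes every stage's
#' outputs plus a run manifest (`run_manifest.yaml`: configuration echo,
#' input checksums, per-stage outputs and warnings) under `out_dir`. When
#' a previous manifest in `out_dir` records the same configuration and
#' input checksums, completed stage outputs are reused. Two runs from the
#' same seed and configuration produce byte-identical signature gene
#' lists and cluster assignments.
#'
#' @param config A configuration accepted by [validate_pipeline_config()].
#' @param out_dir Output directory.
#' @return The run manifest, invisibly (a list).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(...) message(sprintf(...))
  outputs <- list()

  # --- inputs: simulate or read --------------------------------------------
  if (isTRUE(cfg$simulate)) {
    sim_cfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
    data_dir <- file.path(out_dir, "data")
    note("stage simulate: writing synthetic study to %s", data_dir)
    simulate_study(sim_cfg, data_dir)
  } else {
    data_dir <- cfg$input_dir
  }
  config_digest <- digest_of(yaml::as.yaml(unclass_deep(cfg)))
  input_files <- list.files(data_dir, recursive = TRUE, full.names = TRUE)
  checksums <- tools::md5sum(sort(input_files))
  prev_manifest_path <- file.path(out_dir, "run_manifest.yaml")
  reuse <- FALSE
  if (file.exists(prev_manifest_path)) {
    prev <- tryCatch(yaml::read_yaml(prev_manifest_path),
                     error = function(e) NULL)
    reuse <- !is.null(prev) &&
      identical(prev$config_digest, config_digest) &&
      identical(unlist(prev$input_checksums), unname(checksums)) &&
      all(file.exists(file.path(out_dir, unlist(prev$outputs))))
    if (reuse) note("inputs and configuration unchanged; reusing stage outputs")
  }

  genome <- read_chrom_sizes(file.path(data_dir, "chrom.sizes"))
  annotation <- read_gene_annotation(file.path(data_dir, "annotation.tsv"))
  manifest <- read_manifest(file.path(data_dir, "manifest.tsv"))
  expr <- read_expression_matrix(file.path(data_dir, "expression.tsv"))
  metadata <- read_sample_metadata(file.path(data_dir, "metadata.tsv"))
  cls_cfg <- do.call(classification_config, cfg$classification)

  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    if (!(reuse && file.exists(path))) writer(path)
    outputs[[name]] <<- name
    path
  }

  # --- classify -------------------------------------------------------------
  sites <- NULL
  tracks <- NULL
  if (isTRUE(cfg$stages$classify)) {
    note("stage classify: consolidating %d replicate peak sets", nrow(manifest))
    peaks <- purrr::pmap(manifest, function(background, treatment, replicate,
                                            peaks, library_size, ...) {
      p <- read_narrowpeak(peaks)
      p$background <- background
      p$treatment <- treatment
      p$replicate <- replicate
      p
    }) %>% bind_rows()
    sites <- consolidate_replicates(peaks, cls_cfg)
    tracks <- purrr::map(
      setNames(design_conditions(), design_conditions()),
      function(cond) {
        rows <- manifest[condition_id(manifest$background,
                                      manifest$treatment) == cond, ]
        purrr::pmap(rows, function(track, library_size, ...) {
          read_bedgraph(track, library_size)
        })
      })
    sites <- site_signal(sites, tracks, cls_cfg)
    sites <- classify_sites(sites, cls_cfg)
    emit("consensus_sites.tsv",
         function(p) readr::write_tsv(sites, p))
    if (!(reuse && all(file.exists(file.path(out_dir, "class_beds",
                                             paste0(site_classes(), ".bed")))))) {
      write_class_beds(sites, file.path(out_dir, "class_beds"))
    }
    for (cl in site_classes()) {
      outputs[[paste0("class_beds/", cl, ".bed")]] <-
        paste0("class_beds/", cl, ".bed")
    }
  }

  sets <- if (!is.null(sites)) class_sets(sites) else NULL
  used_classes <- if (!is.null(sets)) {
    names(sets)[purrr::map_int(sets, nrow) > 0]
  } else character()

  # --- profiles -------------------------------------------------------------
  if (isTRUE(cfg$stages$profiles) && !is.null(sites)) {
    note("stage profiles: mean signal curves per class and condition")
    prof <- list()
    for (cl in used_classes) {
      d <- utils::head(sets[[cl]], cfg$profile$max_sites)
      for (cond in design_conditions()) {
        pm <- profile_matrix(d, tracks, cond,
                             half_width = cfg$profile$half_width,
                             bin_width = cfg$profile$bin_width)
        prof[[length(prof) + 1]] <- mean_profile(pm) %>%
          mutate(class = cl)
      }
    }
    emit("mean_profiles.tsv",
         function(p) readr::write_tsv(bind_rows(prof), p))
  }

  # --- co-occurrence --------------------------------------------------------
  if (isTRUE(cfg$stages$cooccur) && !is.null(sites) &&
      length(used_classes) >= 2) {
    note("stage cooccur: class-vs-class co-occurrence Z-scores")
    named_sets <- sets[used_classes]
    co <- withCallingHandlers(
      cooccurrence_zscores(named_sets, named_sets),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    emit("cooccurrence.tsv", function(p) readr::write_tsv(tidy(co), p))
  }

  # --- genomic distribution -------------------------------------------------
  dist_res <- NULL
  if (isTRUE(cfg$stages$distribution) && !is.null(sites) &&
      length(used_classes) >= 1) {
    note("stage distribution: TSS-relative bins vs whole-genome background")
    dist_res <- genomic_distribution(sets[used_classes], genome, annotation)
    emit("distribution.tsv",
         function(p) readr::write_tsv(as_tibble(dist_res), p))
  }

  # --- DEG + signature ------------------------------------------------------
  deg <- NULL
  sig <- NULL
  if (isTRUE(cfg$stages$signature)) {
    note("stage signature: DEGs and anchor-correlated signature")
    groups <- metadata$group[match(colnames(expr), metadata$sample_id)]
    deg <- differential_expression(expr, groups,
                                   q_cutoff = cfg$signature$q_cutoff)
    emit("deg_table.tsv", function(p) readr::write_tsv(tidy(deg), p))
    sig <- withCallingHandlers(
      derive_signature(expr, cfg$signature$anchor, deg_set(deg),
                       r_cutoff = cfg$signature$r_cutoff,
                       top_fraction = cfg$signature$top_fraction),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    emit("signature_genes.txt", function(p) write_signature(sig, p))
    outputs[["signature_genes.txt.provenance.yaml"]] <-
      "signature_genes.txt.provenance.yaml"
  }

  # --- enrichment -----------------------------------------------------------
  if (isTRUE(cfg$stages$enrich) && !is.null(sites) && !is.null(deg)) {
    cl <- cfg$enrichment$site_class
    if (cl %in% used_classes) {
      note("stage enrich: nearest-gene targets of `%s` sites vs DEGs", cl)
      targets <- target_geneset(sets[[cl]], annotation,
                                max_dist = cfg$enrichment$max_dist,
                                closest_only = cfg$enrichment$closest_only)
      universe <- union(rownames(expr), annotation$gene_id)
      degs_in <- intersect(deg_set(deg), universe)
      if (length(targets) > 0 && length(degs_in) > 0) {
        enr <- overlap_enrichment(targets, degs_in, universe)
        emit("enrichment.tsv", function(p) readr::write_tsv(tidy(enr), p))
      } else {
        warnings_log <- c(warnings_log,
                          "enrichment skipped: empty target or DEG set")
      }
    } else {
      warnings_log <- c(warnings_log,
                        sprintf("enrichment skipped: no `%s` sites", cl))
    }
  }

  # --- stratify -------------------------------------------------------------
  if (isTRUE(cfg$stages$stratify) && !is.null(sig) &&
      length(sig$members) >= 2) {
    note("stage stratify: clustering, KM, logrank and Cox")
    sig_expr <- expr[intersect(sig$members, rownames(expr)), , drop = FALSE]
    clusters <- two_cluster_partition(sig_expr)
    records <- metadata[match(colnames(expr), metadata$sample_id), ]
    emit("clusters.tsv", function(p) {
      readr::write_tsv(tibble(sample_id = colnames(expr),
                              cluster = as.character(clusters)), p)
    })
    km <- km_estimate(records, group = clusters)
    emit("km_table.tsv", function(p) readr::write_tsv(as_tibble(km), p))
    lr <- logrank_test(records, clusters)
    covars <- data.frame(cluster = clusters)
    for (v in c("age", "psa", "gleason", "margin")) {
      if (v %in% names(records) &&
          length(unique(records[[v]])) > 1) covars[[v]] <- records[[v]]
    }
    cox <- tryCatch(cox_fit(records, covars), error = function(e) {
      warnings_log <<- c(warnings_log, paste("cox failed:", conditionMessage(e)))
      NULL
    })
    emit("survival_report.tsv", function(p) {
      rep_tbl <- tibble(term = "logrank_cluster", estimate = NA_real_,
                        hr = NA_real_, conf_low = NA_real_,
                        conf_high = NA_real_, p_value = lr$p_value,
                        statistic = lr$chisq)
      if (!is.null(cox)) {
        rep_tbl <- bind_rows(rep_tbl, mutate(tidy(cox), statistic = NA_real_))
      }
      readr::write_tsv(rep_tbl, p)
    })
  } else if (isTRUE(cfg$stages$stratify)) {
    warnings_log <- c(warnings_log,
                      "stratify skipped: signature has fewer than 2 genes")
  }

  manifest_out <- list(
    tool = "regrescue",
    version = as.character(utils::packageVersion("regrescue")),
    config_digest = config_digest,
    config = unclass_deep(cfg),
    input_dir = data_dir,
    input_checksums = unname(checksums),
    outputs = unname(unlist(outputs)),
    warnings = warnings_log)
  tmp <- tempfile(tmpdir = out_dir)
  yaml::write_yaml(manifest_out, tmp)
  file.rename(tmp, prev_manifest_path)   # atomic write at run end
  invisible(manifest_out)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) purrr::map(x, unclass_deep) else x
}

digest_of <- function(text) {
  f <- tempfile()
  writeLines(text, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}
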