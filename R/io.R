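#' Write a cohort to delimited text files
#'
#' Writes the regional density samples as one long-format table
#' (`subject_id, group, arm, timepoint, region, value`) and the clinical
#' covariates as a CSV, the interchange format of the pipeline.
#'
#' @param cohort A `morph_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`samples`, `clinical`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl <- cohort$clinical
  keys <- names(cohort$samples)
  long <- do.call(rbind, lapply(keys, function(k) {
    x <- cohort$samples[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    rowi <- which(cl$subject_id == parts[1] & cl$timepoint == parts[2])[1]
    data.frame(subject_id = parts[1], group = cl$group[rowi],
               arm = cl$arm[rowi], timepoint = parts[2],
               region = rep(seq_len(nrow(x)), ncol(x)),
               value = as.vector(x), stringsAsFactors = FALSE)
  }))
  samples_path <- file.path(dir, "samples.csv")
  clinical_path <- file.path(dir, "clinical.csv")
  utils::write.csv(long, samples_path, row.names = FALSE)
  utils::write.csv(cl, clinical_path, row.names = FALSE)
  invisible(list(samples = samples_path, clinical = clinical_path))
}

#' Read a cohort from delimited text files
#'
#' Parses and validates the long-format sample table and clinical table
#' written by [write_cohort()] (or produced externally in the same layout).
#' Every subject-timepoint must carry a complete set of region indices
#' `1..n_regions` with equal sample counts per region.
#'
#' @param samples_path Long-format sample table
#'   (`subject_id, group, arm, timepoint, region, value`).
#' @param clinical_path Clinical covariate CSV.
#' @param n_regions Expected region count (default: maximum region index
#'   found).
#' @return A list of class `morph_cohort` with `samples`, `clinical`; the
#'   generator-only fields (`params`, `layout`) are absent, and `config`
#'   carries only what is recoverable from the files.
#' @export
read_cohort <- function(samples_path, clinical_path, n_regions = NULL) {
  long <- utils::read.csv(samples_path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "arm", "timepoint", "region", "value")
  miss <- setdiff(need, names(long))
  if (length(miss) > 0L) {
    stop(sprintf("read_cohort(): sample table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  clinical <- utils::read.csv(clinical_path, comment.char = "#",
                              stringsAsFactors = FALSE)
  cl_need <- c("subject_id", "group", "arm", "timepoint", "age", "sex",
               "ymrs", "cdrs")
  cl_miss <- setdiff(cl_need, names(clinical))
  if (length(cl_miss) > 0L) {
    stop(sprintf("read_cohort(): clinical table is missing column(s): %s",
                 paste(cl_miss, collapse = ", ")), call. = FALSE)
  }
  dup <- duplicated(clinical[, c("subject_id", "timepoint")])
  if (any(dup)) {
    stop(sprintf("read_cohort(): duplicate subject-timepoint clinical rows: %s",
                 paste(unique(clinical$subject_id[dup]), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(n_regions)) n_regions <- max(long$region)
  if (any(long$region < 1L | long$region > n_regions)) {
    bad <- unique(long$region[long$region < 1L | long$region > n_regions])
    stop(sprintf("read_cohort(): unknown region indices: %s",
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  }
  key <- paste0(long$subject_id, ".", long$timepoint)
  samples <- lapply(split(seq_len(nrow(long)), key), function(rows) {
    reg <- long$region[rows]
    present <- sort(unique(reg))
    missing_reg <- setdiff(seq_len(n_regions), present)
    if (length(missing_reg) > 0L) {
      stop(sprintf("read_cohort(): scan '%s' is missing region(s): %s",
                   key[rows[1]], paste(missing_reg, collapse = ", ")),
           call. = FALSE)
    }
    counts <- tabulate(reg, nbins = n_regions)
    if (length(unique(counts)) != 1L) {
      stop(sprintf("read_cohort(): scan '%s' has unequal sample counts per region",
                   key[rows[1]]), call. = FALSE)
    }
    v <- long$value[rows][order(reg)]
    matrix(v, nrow = n_regions, byrow = TRUE)
  })
  tps <- unique(clinical$timepoint)
  structure(list(clinical = clinical, samples = samples,
                 params = NULL, layout = NULL,
                 config = list(n_regions = n_regions, timepoints = tps)),
            class = "morph_cohort")
}

#' Write similarity matrices as long-format delimited text
#'
#' One row per unordered region pair per scan:
#' `key, region_i, region_j, value`.
#'
#' @param networks Named list of `similarity_matrix` objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_networks <- function(networks, path) {
  long <- do.call(rbind, lapply(names(networks), function(k) {
    fv <- vectorize_connectome(networks[[k]])
    data.frame(key = k, region_i = fv$index_map[, 1],
               region_j = fv$index_map[, 2], value = fv$values,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read similarity matrices written by [write_networks()]
#'
#' @param path CSV path.
#' @param region_labels Optional node labels (default [aal90_labels()]).
#' @return Named list of `similarity_matrix` objects.
#' @export
read_networks <- function(path, region_labels = NULL) {
  long <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("key", "region_i", "region_j", "value")
  miss <- setdiff(need, names(long))
  if (length(miss) > 0L) {
    stop(sprintf("read_networks(): missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  n <- max(long$region_i, long$region_j)
  if (is.null(region_labels)) region_labels <- aal90_labels(n)
  out <- lapply(split(long, long$key), function(d) {
    m <- matrix(0, n, n)
    m[cbind(d$region_i, d$region_j)] <- d$value
    m <- m + t(m)
    diag(m) <- 1
    dimnames(m) <- list(region_labels, region_labels)
    structure(list(values = m, region_labels = region_labels,
                   subject_id = d$key[1]), class = "similarity_matrix")
  })
  out[unique(long$key)]
}

# Write a data.frame as CSV with a provenance header comment.
write_table_stamped <- function(df, path, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# morphconn config_hash=%s", config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Assemble a full pipeline run configuration
#'
#' Collects the stage parameters of an end-to-end run. Every stochastic stage
#' receives a seed derived deterministically from `seed`, and the config
#' round-trips through YAML unchanged.
#'
#' @param cohort List of overrides passed to [cohort_config()].
#' @param s_min,s_max,s_step Sparsity threshold scheme.
#' @param n_nulls Rewired nulls per threshold for the small-world summary
#'   (0 skips gamma/lambda/sigma in the metric stage).
#' @param n_perm Permutations for the group AUC tests.
#' @param n_perm_svm Label permutations for prediction significance
#'   (0 skips the permutation p).
#' @param n_folds Cross-validation folds.
#' @param seed Global integer seed.
#' @param out_dir Output directory.
#' @param write_samples Whether the simulate stage also writes the (large)
#'   long-format sample table.
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = list(), s_min = 0.10, s_max = 0.34,
                       s_step = 0.01, n_nulls = 0L, n_perm = 10000L,
                       n_perm_svm = 0L, n_folds = 10L, seed = 1L,
                       out_dir = "morphconn_run", write_samples = FALSE) {
  structure(list(cohort = cohort, s_min = s_min, s_max = s_max,
                 s_step = s_step, n_nulls = as.integer(n_nulls),
                 n_perm = as.integer(n_perm),
                 n_perm_svm = as.integer(n_perm_svm),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 out_dir = out_dir, write_samples = isTRUE(write_samples)),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the study's analysis order end to end: simulate -> build KLS
#' networks -> threshold and summarize metrics (AUC) -> case-control and
#' longitudinal statistics -> treatment-response prediction. All outputs are
#' CSV/JSON files under `config$out_dir`, each stamped with the config hash;
#' a `manifest.json` lists them. The run is fully reproducible from the
#' config: the same config and seed give byte-identical numeric outputs. A
#' stage failure aborts with the stage name; outputs of completed stages are
#' kept.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  files <- c(config = cfg_path)
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message("[morphconn] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("run_pipeline(): stage '%s' failed: %s",
                   name, conditionMessage(e)), call. = FALSE)
    })
  }

  ## simulate ---------------------------------------------------------------
  cohort <- stage("simulate", {
    c_args <- config$cohort
    c_args$seed <- config$seed
    cohort <- generate_cohort(do.call(cohort_config, c_args))
    say("simulate: %d subjects x %d scans, seed %d",
        cohort$config$n_patients + cohort$config$n_controls,
        length(cohort$config$timepoints), config$seed)
    write_table_stamped(cohort$clinical, file.path(out_dir, "clinical.csv"),
                        config_hash)
    files <- c(files, clinical = file.path(out_dir, "clinical.csv"))
    if (config$write_samples) {
      paths <- write_cohort(cohort, out_dir)
      files <- c(files, samples = paths$samples)
    }
    cohort
  })
  tps <- cohort$config$timepoints
  baseline <- tps[1]
  endpoint <- tps[length(tps)]

  ## build-networks ---------------------------------------------------------
  networks <- stage("build-networks", {
    nets <- build_cohort_networks(cohort)
    say("build-networks: %d KLS matrices (%d regions)", length(nets),
        cohort$config$n_regions)
    p <- file.path(out_dir, "networks.csv")
    write_networks(nets, p)
    files <- c(files, networks = p)
    nets
  })
  net_tp <- sub("^[^.]+\\.", "", names(networks))
  net_id <- sub("\\.[^.]+$", "", names(networks))

  ## metrics ----------------------------------------------------------------
  scheme <- threshold_scheme(config$s_min, config$s_max, config$s_step)
  metrics <- stage("metrics", {
    aucs <- cohort_global_aucs(networks, scheme, n_nulls = config$n_nulls,
                               seed = config$seed + 1L)
    aucs$subject_id <- net_id
    aucs$timepoint <- net_tp
    base_keys <- names(networks)[net_tp == baseline]
    nodal <- lapply(base_keys, function(k) nodal_metric_curves(networks[[k]], scheme)$auc)
    names(nodal) <- base_keys
    say("metrics: global AUCs for %d scans, nodal AUCs for %d baseline scans over %d thresholds",
        nrow(aucs), length(nodal), length(scheme$s_values))
    p <- file.path(out_dir, "global_auc.csv")
    write_table_stamped(aucs, p, config_hash)
    files <- c(files, global_auc = p)
    list(global = aucs, nodal = nodal)
  })

  ## compare ----------------------------------------------------------------
  stats_out <- stage("compare", {
    cl <- cohort$clinical
    sub_group <- cl$group[match(net_id, cl$subject_id)]
    g <- metrics$global
    met_names <- setdiff(names(g), c("key", "subject_id", "timepoint"))
    base_rows <- g$timepoint == baseline
    perm_rows <- do.call(rbind, lapply(met_names, function(m) {
      pr <- permutation_test(g[[m]][base_rows & sub_group == "patient"],
                             g[[m]][base_rows & sub_group == "control"],
                             n_perm = config$n_perm, seed = config$seed + 2L)
      data.frame(metric = m, observed = pr$observed, p = pr$p_two_tailed,
                 n_perm = pr$n_perm, stringsAsFactors = FALSE)
    }))
    perm_rows$q <- fdr_adjust(perm_rows$p)
    write_table_stamped(perm_rows, file.path(out_dir, "group_auc_tests.csv"),
                        config_hash)

    # per-region 2-of-3 nodal screening at baseline
    nodal <- metrics$nodal
    nodal_group <- cl$group[match(sub("\\.[^.]+$", "", names(nodal)),
                                  cl$subject_id)]
    p_tab <- t(vapply(seq_len(cohort$config$n_regions), function(r) {
      vapply(c("degree", "efficiency", "betweenness"), function(m) {
        vals <- vapply(nodal, function(a) a[r, m], numeric(1))
        permutation_test(vals[nodal_group == "patient"],
                         vals[nodal_group == "control"],
                         n_perm = max(1000L, config$n_perm %/% 10L),
                         seed = config$seed + 3L + r)$p_two_tailed
      }, numeric(1))
    }, numeric(3)))
    p_df <- as.data.frame(p_tab)
    p_df$region <- aal90_labels(cohort$config$n_regions)
    flags <- abnormal_regions(p_df)
    write_table_stamped(flags, file.path(out_dir, "nodal_flags.csv"),
                        config_hash)

    # group-by-time mixed models on Cp and Lp AUC
    demo <- cl[!duplicated(cl$subject_id),
               c("subject_id", "group", "age", "sex")]
    inter_rows <- NULL
    if (length(tps) >= 2L) {
      inter_rows <- do.call(rbind, lapply(c("Cp", "Lp"), function(m) {
        lt <- data.frame(value = g[[m]], subject_id = net_id,
                         timepoint = net_tp, stringsAsFactors = FALSE)
        lt <- merge(lt, demo, by = "subject_id")
        res <- interaction_model(lt)
        data.frame(metric = m, effect = res$effect, F = res$F, p = res$p,
                   stringsAsFactors = FALSE)
      }))
      inter_rows$q <- fdr_adjust(inter_rows$p)
      write_table_stamped(inter_rows,
                          file.path(out_dir, "interaction_tests.csv"),
                          config_hash)
    }

    # change correlations (baseline -> endpoint) in patients
    corr_rows <- NULL
    if (length(tps) >= 2L) {
      pat_ids <- unique(cl$subject_id[cl$group == "patient"])
      d_ymrs <- vapply(pat_ids, function(id) {
        cl$ymrs[cl$subject_id == id & cl$timepoint == baseline] -
          cl$ymrs[cl$subject_id == id & cl$timepoint == endpoint]
      }, numeric(1))
      corr_rows <- do.call(rbind, lapply(c("Cp", "Lp"), function(m) {
        d_met <- vapply(pat_ids, function(id) {
          g[[m]][net_id == id & net_tp == baseline] -
            g[[m]][net_id == id & net_tp == endpoint]
        }, numeric(1))
        cc <- change_correlation(d_met, d_ymrs)
        data.frame(metric = m, r = cc$r, p = cc$p, n = cc$n,
                   stringsAsFactors = FALSE)
      }))
      corr_rows$q <- fdr_adjust(corr_rows$p)
      write_table_stamped(corr_rows,
                          file.path(out_dir, "change_correlations.csv"),
                          config_hash)
    }
    say("compare: %d global AUC tests, %d regions screened%s", nrow(perm_rows),
        nrow(flags),
        if (is.null(inter_rows)) "" else
          sprintf(", %d interaction models", nrow(inter_rows)))
    files <- c(files,
                group_auc_tests = file.path(out_dir, "group_auc_tests.csv"),
                nodal_flags = file.path(out_dir, "nodal_flags.csv"))
    if (!is.null(inter_rows)) {
      files <- c(files, interaction_tests = file.path(out_dir, "interaction_tests.csv"))
    }
    if (!is.null(corr_rows)) {
      files <- c(files, change_correlations = file.path(out_dir, "change_correlations.csv"))
    }
    list(perm = perm_rows, flags = flags, interactions = inter_rows,
         correlations = corr_rows)
  })

  ## predict ----------------------------------------------------------------
  prediction <- stage("predict", {
    cl <- cohort$clinical
    pat_base <- networks[net_tp == baseline &
                           net_id %in% cl$subject_id[cl$group == "patient"]]
    ids <- sub("\\.[^.]+$", "", names(pat_base))
    labels <- classify_responder(
      cl$ymrs[match(paste0(ids, ".", baseline),
                    paste0(cl$subject_id, ".", cl$timepoint))],
      cl$ymrs[match(paste0(ids, ".", endpoint),
                    paste0(cl$subject_id, ".", cl$timepoint))])
    x <- connectome_feature_matrix(pat_base)
    report <- cross_validated_classification(x, labels,
                                             n_folds = config$n_folds,
                                             seed = config$seed + 5L)
    if (config$n_perm_svm > 0L) {
      report$permutation_p <- permutation_significance(
        x, labels, n_perm = config$n_perm_svm, n_folds = config$n_folds,
        seed = config$seed + 6L)$p
    }
    ranking <- nodal_weight_ranking(report)
    say("predict: mean balanced accuracy %.3f over %d folds%s",
        report$mean_balanced_accuracy, config$n_folds,
        if (is.na(report$permutation_p)) "" else
          sprintf(", permutation p = %.4g", report$permutation_p))
    p_json <- file.path(out_dir, "prediction.json")
    jsonlite::write_json(list(
      mean_balanced_accuracy = report$mean_balanced_accuracy,
      fold_balanced_accuracies = report$fold_balanced_accuracies,
      permutation_p = report$permutation_p,
      top_regions = ranking$region), p_json, auto_unbox = TRUE, digits = NA)
    write_table_stamped(ranking, file.path(out_dir, "nodal_weights.csv"),
                        config_hash)
    files <- c(files, prediction = p_json,
                nodal_weights = file.path(out_dir, "nodal_weights.csv"))
    report
  })

  manifest <- list(config_hash = config_hash, seed = config$seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   files = as.list(files), log = log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, cohort = cohort, networks = networks,
                 metrics = metrics, stats = stats_out,
                 prediction = prediction))
}
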