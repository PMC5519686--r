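#' Pipeline run configuration
#'
#' Collects the paths and per-stage parameters of a full analysis run.
#' When `phenotype_csv` is `NULL` a synthetic cohort is generated from
#' `cohort` instead.
#'
#' @param output_dir writable output directory.
#' @param phenotype_csv optional phenotype CSV path.
#' @param volume_dir optional directory of NIfTI volumes.
#' @param cohort a [cohort_config()] used when generating synthetic data.
#' @param regions effect regions for synthetic volumes.
#' @param rules a [rule_set()].
#' @param tfce a [tfce_params()].
#' @param n_perm permutations for the voxelwise tests.
#' @param n_boot bootstrap replicates.
#' @param ntree,mtry ensemble settings.
#' @param alpha familywise level.
#' @param t_star bootstrap mean-map threshold.
#' @param seed master seed; stage seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir = tempfile("morphpair_run_"),
                       phenotype_csv = NULL, volume_dir = NULL,
                       cohort = cohort_config(),
                       regions = default_effect_regions(),
                       rules = rule_set(), tfce = tfce_params(),
                       n_perm = 1000, n_boot = 100, ntree = 500, mtry = 2,
                       alpha = 0.05, t_star = 2.87, seed = 1L) {
  structure(list(output_dir = output_dir, phenotype_csv = phenotype_csv,
                 volume_dir = volume_dir, cohort = cohort, regions = regions,
                 rules = rules, tfce = tfce, n_perm = n_perm,
                 n_boot = n_boot, ntree = ntree, mtry = mtry, alpha = alpha,
                 t_star = t_star, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from JSON
#'
#' Scalar fields override [run_config()] defaults; nested blocks
#' (`cohort`, `rules`, `tfce`) override the corresponding constructor
#' arguments.
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- do.call(cohort_config, as.list(js$cohort %||% list()))
  rules <- do.call(rule_set, as.list(js$rules %||% list()))
  tf <- do.call(tfce_params, as.list(js$tfce %||% list()))
  args <- js[setdiff(names(js), c("cohort", "rules", "tfce"))]
  do.call(run_config, c(args, list(cohort = cohort, rules = rules, tfce = tf)))
}

stage_seed <- function(config, k) (config$seed * 1000L + k) %% .Machine$integer.max

#' Run the full matched-pair morphometry analysis
#'
#' Stages, mirroring the analysis order: profile classification ->
#' matching -> residualization and paired/unpaired voxelwise inference ->
#' bootstrap -> covariate control on the embedding dimensions. Writes
#' cluster tables, balance and reliability reports, and a manifest with
#' seeds and parameter hashes. A stage failure aborts with a stage-tagged
#' error; completed outputs are retained on disk.
#'
#' @param config a [run_config()].
#' @return The report bundle (named list of stage results), invisibly
#'   written under `config$output_dir`.
#' @export
run_all <- function(config = run_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = config, stages = character(0))
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  # data
  bundle$subjects <- wrap("data", {
    if (!is.null(config$phenotype_csv)) read_phenotypes(config$phenotype_csv)
    else generate_cohort(config$cohort)
  })
  bundle$volumes <- wrap("data", {
    if (!is.null(config$volume_dir)) read_volume_set(config$volume_dir)
    else generate_volumes(bundle$subjects, config$regions, config$cohort)
  })
  write_phenotypes(bundle$subjects, file.path(config$output_dir, "phenotypes.csv"))
  bundle$stages <- c(bundle$stages, "data")

  # profiles
  bundle$profiles <- wrap("profiles", {
    labels <- classify_expert_rules(bundle$subjects, config$rules)
    loocv <- classify_ensemble_loocv(bundle$subjects, labels,
                                     ntree = config$ntree, mtry = config$mtry,
                                     seed = stage_seed(config, 1))
    mds <- classical_mds(loocv$probabilities, k = 2)
    case_lab <- labels[labels != "Control" & labels != "Unclassifiable"]
    anova_tab <- if (length(unique(case_lab)) >= 2)
      dimension_anova(mds$points[labels %in% unique(case_lab), , drop = FALSE],
                      labels[labels %in% unique(case_lab)]) else NULL
    list(labels = labels, loocv = loocv, mds = mds, anova = anova_tab)
  })
  utils::write.csv(data.frame(subject_id = bundle$subjects$subject_id,
                              label = bundle$profiles$labels),
                   file.path(config$output_dir, "labels.csv"), row.names = FALSE)
  bundle$stages <- c(bundle$stages, "profiles")

  # matching
  bundle$matching <- wrap("matching", {
    strata <- stratify(bundle$subjects)
    model <- fit_propensity(bundle$subjects)
    pairs <- pair_nearest(strata, model, bundle$subjects)
    balance <- balance_diagnostics(pairs, bundle$subjects, model,
                                   profiles = setNames(bundle$profiles$labels,
                                                       bundle$subjects$subject_id))
    list(strata = strata, model = model, pairs = pairs, balance = balance)
  })
  utils::write.csv(bundle$matching$pairs$pairs,
                   file.path(config$output_dir, "pairs.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$matching$balance,
                       file.path(config$output_dir, "balance.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  bundle$stages <- c(bundle$stages, "matching")

  # vbm
  bundle$vbm <- wrap("vbm", {
    adj <- residualize(bundle$volumes, bundle$matching$model$scores)
    diffs <- pair_differences(adj, bundle$matching$pairs)
    paired <- permutation_fwe(diffs, "sign_flip", params = config$tfce,
                              P = config$n_perm, seed = stage_seed(config, 2))
    flags <- setNames(bundle$subjects$is_case, bundle$subjects$subject_id)
    used <- c(bundle$matching$pairs$pairs$case_id,
              bundle$matching$pairs$pairs$control_id)
    sub_vs <- adj
    sub_vs$data <- adj$data[, used, drop = FALSE]
    unpaired <- permutation_fwe(sub_vs, "label_perm", params = config$tfce,
                                P = config$n_perm,
                                seed = stage_seed(config, 3),
                                case_flags = flags[used])
    clusters <- extract_clusters(paired, alpha = config$alpha,
                                 affine = bundle$volumes$affine)
    dmaps <- cohens_d_maps(adj, bundle$matching$pairs, case_flags = flags)
    list(adjusted = adj, differences = diffs, paired = paired,
         unpaired = unpaired, clusters = clusters, d = dmaps)
  })
  utils::write.csv(bundle$vbm$clusters,
                   file.path(config$output_dir, "clusters.csv"), row.names = FALSE)
  bundle$stages <- c(bundle$stages, "vbm")

  # bootstrap
  bundle$bootstrap <- wrap("bootstrap", {
    rois <- if (nrow(bundle$vbm$clusters)) {
      labs <- array(label_components_cpp(
        as.logical(!is.na(bundle$vbm$paired$p) &
                     bundle$vbm$paired$p < config$alpha & bundle$volumes$mask),
        bundle$volumes$dim, config$tfce$connectivity), bundle$volumes$dim)
      lapply(seq_len(max(labs)), function(l) which(labs == l))
    } else lapply(config$regions, function(r)
      which(region_mask(r, bundle$volumes$dim, bundle$volumes$voxel_size,
                        bundle$volumes$affine) & bundle$volumes$mask))
    names(rois) <- paste0("roi", seq_along(rois))
    run_bootstrap(bundle$subjects, bundle$volumes, B = config$n_boot,
                  seed = stage_seed(config, 4), rois = rois,
                  t_star = config$t_star)
  })
  bundle$stages <- c(bundle$stages, "bootstrap")

  # covariate control on the two embedding dimensions
  bundle$covariate <- wrap("covariate", {
    pts <- bundle$profiles$mds$points
    pt <- bundle$matching$pairs$pairs
    out <- list()
    for (j in 1:2) {
      cov_j <- pts[pt$case_id, j] - pts[pt$control_id, j]
      out[[paste0("dim", j)]] <- covariate_control(
        bundle$vbm$differences, cov_j, mode = "intercept",
        params = config$tfce, P = min(config$n_perm, 500),
        seed = stage_seed(config, 4L + j))
    }
    out
  })
  bundle$stages <- c(bundle$stages, "covariate")

  # manifest
  bundle$manifest <- wrap("manifest", {
    # hash the scientific parameters only, not filesystem paths
    par_fields <- setdiff(names(config),
                          c("output_dir", "phenotype_csv", "volume_dir"))
    cfg_json <- jsonlite::toJSON(config[par_fields], auto_unbox = TRUE,
                                 force = TRUE, digits = NA)
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    manifest <- list(package_version = as.character(utils::packageVersion("morphpair")),
                     seed = config$seed,
                     stages = bundle$stages,
                     n_subjects = nrow(bundle$subjects),
                     n_pairs = nrow(bundle$matching$pairs$pairs),
                     config_md5 = unname(tools::md5sum(tmp)))
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest
  })
  bundle$stages <- c(bundle$stages, "manifest")
  invisible(bundle)
}

#' Human-readable summary of a report bundle
#'
#' Cluster table plus per-profile subgroup ROI t-tests: the clusters found
#' on the full sample are reused and the one-sample t of the mean
#' adjusted-Jacobian difference inside each cluster is recomputed within
#' the pairs of each case profile.
#'
#' @param bundle result of [run_all()].
#' @return Character vector of report lines (also printed), invisibly;
#'   attribute `subgroup` holds the per-profile ROI t table.
#' @export
make_report <- function(bundle) {
  lines <- c("Matched-pair morphometry report",
             sprintf("subjects: %d  pairs: %d  unmatched: %d",
                     nrow(bundle$subjects),
                     nrow(bundle$matching$pairs$pairs),
                     length(bundle$matching$pairs$unmatched)))
  cl <- bundle$vbm$clusters
  if (is.null(cl) || !nrow(cl)) {
    lines <- c(lines, "clusters: none significant")
    sub_tab <- NULL
  } else {
    lines <- c(lines, sprintf(
      "cluster %d: %d voxels, peak (%.0f, %.0f, %.0f) mm, peak t=%.2f, min p=%.4f",
      cl$label, cl$n_voxels, cl$peak_x, cl$peak_y, cl$peak_z, cl$peak_stat,
      cl$min_p))
    # per-profile subgroup t on cluster ROI means
    labels <- setNames(bundle$profiles$labels, bundle$subjects$subject_id)
    pt <- bundle$matching$pairs$pairs
    p_map <- bundle$vbm$paired$p
    labs <- array(label_components_cpp(
      as.logical(!is.na(p_map) & p_map < bundle$config$alpha &
                   bundle$volumes$mask),
      bundle$volumes$dim, bundle$config$tfce$connectivity),
      bundle$volumes$dim)
    sub_tab <- NULL
    for (l in cl$label) {
      idx <- which(labs == l)
      d_roi <- colMeans(bundle$vbm$differences$data[idx, , drop = FALSE])
      for (pr in unique(labels[pt$case_id])) {
        sel <- labels[pt$case_id] == pr
        if (sum(sel) < 2) next
        tt <- t.test(d_roi[sel])
        sub_tab <- rbind(sub_tab, data.frame(
          cluster = l, profile = pr, n_pairs = sum(sel),
          t = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value))
      }
    }
    if (!is.null(sub_tab))
      lines <- c(lines, sprintf(
        "  cluster %d / %s (n=%d pairs): t(%d)=%.2f, p=%.4f",
        sub_tab$cluster, sub_tab$profile, sub_tab$n_pairs, sub_tab$df,
        sub_tab$t, sub_tab$p))
  }
  if (!is.null(bundle$bootstrap$pooled_t)) {
    pm <- apply(bundle$bootstrap$pooled_t, 3, mean, na.rm = TRUE)
    lines <- c(lines, sprintf("bootstrap mean pooled t: well=%.2f random=%.2f",
                              pm["well"], pm["random"]))
  }
  cat(lines, sep = "\n")
  attr(lines, "subgroup") <- sub_tab
  invisible(lines)
}

#' Command-line entry point
#'
#' `morphpair run-all --config config.json --out dir --seed N` and
#' `morphpair bias-sim --out report.json` are supported; see
#' `inst/cli/morphpair`.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status, invisibly.
#' @export
morphpair_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: morphpair <run-all|bias-sim> [--config f] [--out dir] [--seed N]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list(config = NULL, out = NULL, seed = 1L)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (cmd == "run-all") {
    cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else run_config()
    if (!is.null(opt$out)) cfg$output_dir <- opt$out
    cfg$seed <- as.integer(opt$seed)
    bundle <- run_all(cfg)
    make_report(bundle)
  } else if (cmd == "bias-sim") {
    sc <- bias_scenario(seed = as.integer(opt$seed))
    res <- simulate_bias(sc)
    out <- opt$out %||% "bias_report.json"
    jsonlite::write_json(res, out, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    cat(sprintf("wrote %s\n", out))
  } else {
    cat(sprintf("unknown command '%s'\n", cmd))
    return(invisible(1L))
  }
  invisible(0L)
}
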