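#' Bootstrap comparison of well-matched and randomly matched designs
#'
#' The baseline matched cohort (the members of the optimally matched
#' pairs, within which every stratum holds equally many cases and
#' controls) is re-paired twice per replicate: (a) well-matched, by
#' shuffling the case-control assignment within each site x brain-size
#' stratum (without replacement), and (b) randomly, by a uniform
#' cross-site bijection of the same cases to the same controls. Both
#' conditions therefore use the identical subjects and pair count, so
#' differences in the voxel-level t maps reflect matching quality alone.
#' ROI-pooled mean t values are recorded per replicate and the
#' per-condition mean t maps are thresholded at `t_star`.
#'
#' @param subjects cohort data frame.
#' @param vs a [volume_set()] of the subjects' volumes (raw; they are
#'   residualized internally on the propensity score).
#' @param B replicates (>= 2).
#' @param seed RNG seed.
#' @param rois named list of regions ([effect_region()] / logical array /
#'   voxel indices) to pool t over; may be empty.
#' @param t_star threshold applied to the mean t maps.
#' @param keep_pairings retain per-replicate pairings (needed by
#'   [balance_check_bootstrap()]).
#' @return An object of class `bootstrap_summary`: mean t maps and
#'   thresholded maps per condition, `pooled_t` (B x ROI x condition),
#'   `B`, `t_star`, and optionally the pairings.
#' @export
run_bootstrap <- function(subjects, vs, B = 1000, seed = 1L,
                          rois = list(), t_star = 2.87,
                          keep_pairings = TRUE) {
  if (B < 2) stopf("B must be >= 2")
  if (!length(rois)) warnf("no ROI supplied; pooled t distributions skipped")
  strata <- stratify(subjects)
  model <- fit_propensity(subjects)
  adj <- residualize(vs, model$scores)
  assignment <- attr(strata, "assignment")
  # restrict to the matched cohort: within it each stratum is balanced
  base <- pair_nearest(strata, model, subjects)
  matched_ids <- c(base$pairs$case_id, base$pairs$control_id)
  msub <- subjects[subjects$subject_id %in% matched_ids, , drop = FALSE]
  massign <- assignment[subjects$subject_id %in% matched_ids]
  roi_idx <- lapply(rois, function(r) {
    if (inherits(r, "effect_region"))
      which(region_mask(r, vs$dim, vs$voxel_size, vs$affine) & vs$mask)
    else if (is.logical(r) || is.array(r)) which(as.logical(r))
    else as.integer(r)
  })
  msum <- list(well = 0, random = 0)
  pooled <- array(NA_real_, c(B, max(1, length(rois)), 2),
                  dimnames = list(NULL, names(rois) %||% "roi1",
                                  c("well", "random")))
  pairings <- if (keep_pairings) list(well = vector("list", B),
                                      random = vector("list", B)) else NULL
  with_seed(seed, {
    for (b in seq_len(B)) {
      # (a) well-matched: shuffle the assignment within each stratum
      pw <- NULL
      for (r in seq_len(nrow(strata))) {
        st <- strata$stratum[r]
        idx <- which(!is.na(massign) & massign == st)
        cases <- msub$subject_id[idx][msub$is_case[idx]]
        controls <- msub$subject_id[idx][!msub$is_case[idx]]
        k <- min(length(cases), length(controls))
        if (k == 0) next
        cs <- if (length(cases) > 1) sample(cases) else cases
        ks <- if (length(controls) > 1) sample(controls) else controls
        pw <- rbind(pw, data.frame(case_id = cs[seq_len(k)],
                                   control_id = ks[seq_len(k)],
                                   stratum = st, distance = NA_real_,
                                   stringsAsFactors = FALSE))
      }
      well <- structure(list(pairs = pw, unmatched = character(0)),
                        class = "matched_pair_set")
      # (b) random cross-site pairing of the same subjects; derived seed
      # keeps both conditions inside this replicate's stream
      rnd <- random_pairing(msub,
                            seed = sample.int(.Machine$integer.max, 1))
      for (cond in c("well", "random")) {
        prs <- if (cond == "well") well else rnd
        tmap <- one_sample_t(pair_differences(adj, prs))
        msum[[cond]] <- msum[[cond]] + tmap$data
        for (j in seq_along(roi_idx))
          pooled[b, j, cond] <- mean(tmap$data[roi_idx[[j]]])
        if (keep_pairings) pairings[[cond]][[b]] <- prs
      }
    }
  })
  mean_well <- msum$well / B
  mean_random <- msum$random / B
  structure(list(
    mean_t = list(well = new_stat_map(mean_well, vs$mask, "mean_t"),
                  random = new_stat_map(mean_random, vs$mask, "mean_t")),
    thresholded = list(well = mean_well >= t_star & vs$mask,
                       random = mean_random >= t_star & vs$mask),
    pooled_t = if (length(rois)) pooled else NULL,
    B = B, t_star = t_star, seed = seed,
    pairings = pairings),
    class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> B=%d, t*=%.2f; suprathreshold voxels well=%d random=%d\n",
              x$B, x$t_star, sum(x$thresholded$well), sum(x$thresholded$random)))
  invisible(x)
}

#' Covariate balance across bootstrap replicates
#'
#' Paired t-test p-values for gray matter, white matter and age per
#' replicate and condition; reports the per-variable minimum p and the
#' fraction of replicates above `threshold`.
#'
#' @param summary a [run_bootstrap()] result with pairings retained.
#' @param subjects cohort data frame.
#' @param threshold reference p-value (balance is "retained" above it).
#' @return List with `p_values` (B x variable x condition array),
#'   `minima` and `fraction_above`.
#' @export
balance_check_bootstrap <- function(summary, subjects, threshold = 0.26) {
  if (is.null(summary$pairings)) stopf("bootstrap was run without keep_pairings")
  vars <- c("gm_volume", "wm_volume", "age")
  B <- summary$B
  rownames(subjects) <- subjects$subject_id
  p <- array(NA_real_, c(B, length(vars), 2),
             dimnames = list(NULL, vars, c("well", "random")))
  for (cond in c("well", "random")) {
    for (b in seq_len(B)) {
      pt <- summary$pairings[[cond]][[b]]$pairs
      for (v in vars) {
        d <- subjects[pt$case_id, v] - subjects[pt$control_id, v]
        p[b, v, cond] <- if (all(abs(d) < 1e-12)) 1 else t.test(d)$p.value
      }
    }
  }
  list(p_values = p,
       minima = apply(p, c(2, 3), min),
       fraction_above = apply(p > threshold, c(2, 3), mean),
       threshold = threshold)
}
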