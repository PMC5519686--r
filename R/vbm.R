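#' TFCE parameters
#'
#' Canonical defaults: height exponent `H = 2`, extent exponent
#' `E = 0.5`, 26-voxel connectivity, and `dh = 0` meaning one hundredth of
#' the map maximum per integration step.
#'
#' @param H height exponent (> 0).
#' @param E extent exponent (> 0).
#' @param dh integration step; `0` selects `max(stat)/100` per map.
#' @param connectivity 6, 18 or 26.
#' @return An object of class `tfce_params`.
#' @export
tfce_params <- function(H = 2, E = 0.5, dh = 0, connectivity = 26) {
  if (H <= 0 || E <= 0) stopf("H and E must be positive")
  if (dh < 0) stopf("dh must be >= 0")
  if (!connectivity %in% c(6, 18, 26)) stopf("connectivity must be 6, 18 or 26")
  structure(list(H = H, E = E, dh = dh, connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

new_stat_map <- function(data, mask, statistic, df = NA_real_) {
  structure(list(data = data, mask = mask, statistic = statistic, df = df),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$data[x$mask]
  cat(sprintf("<stat_map> %s (df=%s): range [%.3g, %.3g] over %d voxels\n",
              x$statistic, format(x$df), min(v), max(v), sum(x$mask)))
  invisible(x)
}

mask_matrix <- function(vs) vs$data  # voxels x subjects, full grid

#' Residualize volumes for nuisance effects
#'
#' Per voxel, ordinary least squares of intensity on an intercept and the
#' propensity score; the output is the residual plus the voxel's grand
#' mean (the "adjusted" Jacobian determinant). With a constant propensity
#' the adjustment reduces to mean-centering plus the grand mean (a
#' no-op) and a warning is raised.
#'
#' @param vs a [volume_set()].
#' @param scores propensity score per subject (named or in column order).
#' @return A [volume_set()] of adjusted volumes.
#' @export
residualize <- function(vs, scores) {
  ids <- subject_ids(vs)
  if (!is.null(names(scores))) scores <- scores[ids]
  if (length(scores) != length(ids)) stopf("one score per volume required")
  if (length(ids) < 3) stopf("need at least 3 subjects")
  Y <- t(vs$data)                      # subjects x voxels
  if (sd(scores) < 1e-12) {
    warnf("constant propensity; adjustment is mean-centering only")
    adj <- Y  # residual + grand mean == original
  } else {
    X <- cbind(1, as.numeric(scores))
    fit <- lm.fit(X, Y)
    gm <- colMeans(Y)
    adj <- fit$residuals + matrix(gm, nrow(Y), ncol(Y), byrow = TRUE)
  }
  out <- vs
  out$data <- t(adj)
  colnames(out$data) <- ids
  out
}

#' Case-minus-control difference volumes
#'
#' @param vs a [volume_set()] of (adjusted) volumes.
#' @param pairs a `matched_pair_set`.
#' @return A [volume_set()] with one column per pair, named by case id.
#' @export
pair_differences <- function(vs, pairs) {
  pt <- pairs$pairs
  ids <- subject_ids(vs)
  miss <- setdiff(c(pt$case_id, pt$control_id), ids)
  if (length(miss)) stopf("volumes missing for: %s", paste(miss, collapse = ", "))
  D <- vs$data[, pt$case_id, drop = FALSE] -
    vs$data[, pt$control_id, drop = FALSE]
  colnames(D) <- pt$case_id
  out <- vs
  out$data <- D
  out
}

#' Voxelwise one-sample t map
#'
#' `t = mean / (sd / sqrt(n))` with `df = n - 1`. Zero-variance voxels get
#' t = 0 when the mean is 0 and are otherwise flagged with a large finite
#' value.
#'
#' @param vs a [volume_set()] of difference volumes.
#' @return A `stat_map`.
#' @export
one_sample_t <- function(vs) {
  n <- ncol(vs$data)
  if (n < 2) stopf("need at least 2 volumes")
  m <- rowMeans(vs$data)
  sdv <- sqrt(rowSums((vs$data - m)^2) / (n - 1))
  t <- ifelse(sdv > 0, m / (sdv / sqrt(n)),
              ifelse(m == 0, 0, sign(m) * 1e6))
  new_stat_map(array(t, vs$dim), vs$mask, "one_sample_t", df = n - 1)
}

#' Voxelwise pooled-variance two-sample t map
#'
#' @param vs a [volume_set()] of (adjusted) volumes.
#' @param case_flags logical per subject (named or in column order).
#' @return A `stat_map` (case minus control), `df = n - 2`.
#' @export
two_sample_t <- function(vs, case_flags) {
  ids <- subject_ids(vs)
  if (!is.null(names(case_flags))) case_flags <- case_flags[ids]
  g1 <- which(case_flags)
  g0 <- which(!case_flags)
  if (length(g1) < 2 || length(g0) < 2) stopf("need >= 2 subjects per group")
  n1 <- length(g1); n0 <- length(g0)
  m1 <- rowMeans(vs$data[, g1, drop = FALSE])
  m0 <- rowMeans(vs$data[, g0, drop = FALSE])
  ss <- rowSums((vs$data[, g1, drop = FALSE] - m1)^2) +
    rowSums((vs$data[, g0, drop = FALSE] - m0)^2)
  sp <- sqrt(ss / (n1 + n0 - 2))
  se <- sp * sqrt(1 / n1 + 1 / n0)
  t <- ifelse(se > 0, (m1 - m0) / se,
              ifelse(m1 == m0, 0, sign(m1 - m0) * 1e6))
  new_stat_map(array(t, vs$dim), vs$mask, "two_sample_t", df = n1 + n0 - 2)
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(p) = sum_h e_h(p)^E * h^H * dh` over thresholds `h = dh, 2dh,
#' ...` up to the map maximum, where `e_h(p)` is the size of the connected
#' component containing `p` at threshold `h`. Non-positive voxels map to
#' zero (positive-tail analysis; negate the input for the other tail).
#'
#' @param map a `stat_map` (or 3-D array with a `mask` argument).
#' @param params a [tfce_params()].
#' @param mask logical array when `map` is a bare array.
#' @return A `stat_map` of TFCE scores.
#' @export
tfce <- function(map, params = tfce_params(), mask = NULL) {
  if (inherits(map, "stat_map")) {
    data <- map$data
    mask <- map$mask
  } else {
    data <- map
    if (is.null(mask)) mask <- array(TRUE, dim(data))
  }
  vals <- tfce_cpp(as.numeric(data), dim(data), as.logical(mask),
                   params$H, params$E, params$dh, params$connectivity)
  new_stat_map(array(vals, dim(data)), mask, "tfce")
}

new_permutation_result <- function(raw, vs, params, P, seed, df,
                                   design) {
  structure(list(
    t = new_stat_map(array(raw$t, vs$dim), vs$mask, "t", df = df),
    tfce = new_stat_map(array(raw$tfce, vs$dim), vs$mask, "tfce"),
    p = array(raw$p, vs$dim),
    max_null = raw$max_null,
    P = raw$n_perm, exhaustive = raw$exhaustive,
    seed = seed, params = params, design = design),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s, %s permutations%s; min corrected p = %.4g\n",
              x$design, format(x$P),
              if (x$exhaustive) " (exhaustive)" else "",
              min(x$p[x$t$mask])))
  invisible(x)
}

#' Permutation test with TFCE and familywise error correction
#'
#' One-sample designs flip the signs of difference volumes; two-sample
#' designs permute group labels. Each permutation recomputes the t map,
#' its TFCE enhancement, and the maximum TFCE over the mask; the
#' FWE-corrected p-value of a voxel is the fraction of permutation maxima
#' at or above its observed TFCE score, with the identity permutation
#' included so `p >= 1/(P+1)`. With 12 or fewer pairs (or whenever `P`
#' covers all distinct sign patterns) the one-sample null is enumerated
#' exhaustively and `p = count / 2^n`.
#'
#' @param vs a [volume_set()] of difference volumes (`sign_flip`) or
#'   subject volumes (`label_perm`).
#' @param design `"sign_flip"` or `"label_perm"`.
#' @param params a [tfce_params()].
#' @param P number of permutations (>= 100).
#' @param seed RNG seed.
#' @param case_flags group labels, required for `label_perm`.
#' @param max_exhaustive sign-flip designs with `n <= max_exhaustive`
#'   pairs are enumerated exactly.
#' @return An object of class `permutation_result` with elements `t`,
#'   `tfce`, `p` (corrected p array), `max_null`, `P`, `exhaustive`.
#' @export
permutation_fwe <- function(vs, design = c("sign_flip", "label_perm"),
                            params = tfce_params(), P = 10000, seed = 1L,
                            case_flags = NULL, max_exhaustive = 12L) {
  design <- match.arg(design)
  if (P < 100) stopf("P must be at least 100")
  if (design == "sign_flip") {
    raw <- perm_signflip_cpp(vs$data, vs$dim, as.logical(vs$mask),
                             params$H, params$E, params$dh,
                             params$connectivity, as.integer(P),
                             as.integer(seed), as.integer(max_exhaustive))
    df <- ncol(vs$data) - 1
  } else {
    if (is.null(case_flags)) stopf("case_flags required for label_perm")
    ids <- subject_ids(vs)
    if (!is.null(names(case_flags))) case_flags <- case_flags[ids]
    raw <- perm_labelperm_cpp(vs$data, as.integer(case_flags), vs$dim,
                              as.logical(vs$mask), params$H, params$E,
                              params$dh, params$connectivity, as.integer(P),
                              as.integer(seed))
    df <- ncol(vs$data) - 2
  }
  new_permutation_result(raw, vs, params, P, seed, df, design)
}

#' Paired and unpaired Cohen's d maps
#'
#' Paired `d = mean(diff) / sd(diff)`; unpaired `d = (mean_case -
#' mean_control) / pooled sd`. The histogram summary bins masked-voxel d
#' values for both designs on a common grid.
#'
#' @param vs a [volume_set()] of (adjusted) subject volumes.
#' @param pairs a `matched_pair_set`.
#' @param case_flags logical per subject; defaults to membership in the
#'   pair table's case column.
#' @param breaks histogram bin count.
#' @return List with `paired` and `unpaired` `stat_map`s and `histogram`
#'   (data frame of bin mids and counts for each design).
#' @export
cohens_d_maps <- function(vs, pairs, case_flags = NULL, breaks = 60) {
  pt <- pairs$pairs
  ids <- subject_ids(vs)
  if (is.null(case_flags))
    case_flags <- setNames(ids %in% pt$case_id, ids)
  D <- vs$data[, pt$case_id, drop = FALSE] - vs$data[, pt$control_id, drop = FALSE]
  m <- rowMeans(D)
  sdv <- sqrt(rowSums((D - m)^2) / (ncol(D) - 1))
  paired <- ifelse(sdv > 0, m / sdv, 0)
  g1 <- which(case_flags[ids]); g0 <- which(!case_flags[ids])
  n1 <- length(g1); n0 <- length(g0)
  m1 <- rowMeans(vs$data[, g1, drop = FALSE])
  m0 <- rowMeans(vs$data[, g0, drop = FALSE])
  sp <- sqrt((rowSums((vs$data[, g1, drop = FALSE] - m1)^2) +
                rowSums((vs$data[, g0, drop = FALSE] - m0)^2)) / (n1 + n0 - 2))
  unpaired <- ifelse(sp > 0, (m1 - m0) / sp, 0)
  msk <- as.logical(vs$mask)
  rng <- range(c(paired[msk], unpaired[msk]))
  brk <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = breaks + 1)
  hp <- hist(paired[msk], breaks = brk, plot = FALSE)
  hu <- hist(unpaired[msk], breaks = brk, plot = FALSE)
  list(paired = new_stat_map(array(paired, vs$dim), vs$mask, "cohens_d_paired",
                             df = ncol(D) - 1),
       unpaired = new_stat_map(array(unpaired, vs$dim), vs$mask,
                               "cohens_d_unpaired", df = n1 + n0 - 2),
       histogram = data.frame(mid = hp$mids, paired = hp$counts,
                              unpaired = hu$counts))
}

#' Extract suprathreshold clusters
#'
#' Connected components (same connectivity as the TFCE step) of voxels
#' with corrected p below `alpha`, with per-cluster size, peak statistic,
#' world-mm peak coordinate, cluster-mean statistic and minimum corrected
#' p.
#'
#' @param result a `permutation_result` (or a corrected p array).
#' @param stat optional `stat_map` supplying the peak statistic (defaults
#'   to the result's t map).
#' @param alpha significance threshold.
#' @param affine voxel-to-world affine when `result` is a bare array.
#' @param connectivity component connectivity.
#' @return Data frame (possibly empty) with one row per cluster.
#' @export
extract_clusters <- function(result, stat = NULL, alpha = 0.05,
                             affine = NULL, connectivity = 26) {
  if (inherits(result, "permutation_result")) {
    p <- result$p
    if (is.null(stat)) stat <- result$t
    connectivity <- result$params$connectivity
  } else p <- result
  if (is.null(stat)) stopf("a stat_map is required")
  if (is.null(affine)) affine <- attr(stat, "affine")
  mask <- stat$mask
  sig <- !is.na(p) & p < alpha & mask
  empty <- data.frame(label = integer(0), n_voxels = integer(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0), peak_stat = numeric(0),
                      mean_stat = numeric(0), min_p = numeric(0))
  if (!any(sig)) return(empty)
  labs <- array(label_components_cpp(as.logical(sig), dim(p),
                                     as.integer(connectivity)), dim(p))
  out <- NULL
  for (l in seq_len(max(labs))) {
    vox <- which(labs == l)
    s <- stat$data[vox]
    peak <- vox[which.max(s)]
    ijk <- arrayInd(peak, dim(p))
    xyz <- if (is.null(affine)) c(ijk) else voxel_to_world(ijk, affine)
    out <- rbind(out, data.frame(label = l, n_voxels = length(vox),
                                 peak_x = xyz[1], peak_y = xyz[2],
                                 peak_z = xyz[3], peak_stat = max(s),
                                 mean_stat = mean(s), min_p = min(p[vox])))
  }
  out
}

#' Mean statistic or intensity over a region
#'
#' @param vs a [volume_set()] (per-subject means) or a `stat_map`.
#' @param region an [effect_region()], a logical array, or a vector of
#'   voxel indices.
#' @return Named per-subject scalars (volume set) or a single scalar
#'   (stat map).
#' @export
roi_mean <- function(vs, region) {
  dims <- if (inherits(vs, "volume_set")) vs$dim else dim(vs$data)
  if (inherits(region, "effect_region")) {
    affine <- if (inherits(vs, "volume_set")) vs$affine else default_affine(dims, c(1, 1, 1))
    voxsz <- if (inherits(vs, "volume_set")) vs$voxel_size else c(1, 1, 1)
    region <- region_mask(region, dims, voxsz, affine)
  }
  idx <- if (is.logical(region) || is.array(region)) which(as.logical(region)) else as.integer(region)
  if (!length(idx)) stopf("empty region")
  if (inherits(vs, "volume_set")) {
    colMeans(vs$data[idx, , drop = FALSE])
  } else {
    mean(vs$data[idx])
  }
}

#' Permutation inference controlling for a pairwise covariate
#'
#' Per voxel the difference volumes are modeled as `diff ~ b0 + b1 *
#' covariate`. Mode `"slope"` tests `b1` with Freedman-Lane permutation
#' (residuals of the intercept-only reduced model are permuted); mode
#' `"intercept"` tests `b0` by sign-flipping the residuals of the
#' covariate-only reduced model. TFCE and max-statistic correction follow
#' [permutation_fwe()].
#'
#' @param vs a [volume_set()] of pair difference volumes.
#' @param covariate one value per pair (e.g. the case-control difference
#'   on an embedding dimension).
#' @param mode `"intercept"` or `"slope"`.
#' @param params a [tfce_params()].
#' @param P permutations.
#' @param seed RNG seed.
#' @param center center the covariate first? The default (`FALSE`) makes
#'   the intercept the case-control effect at zero covariate difference,
#'   i.e. the effect remaining when case and control do not differ on the
#'   covariate; with centering the intercept is instead the adjusted mean
#'   effect at the average covariate difference.
#' @return A `permutation_result` for the tested coefficient.
#' @export
covariate_control <- function(vs, covariate, mode = c("intercept", "slope"),
                              params = tfce_params(), P = 1000, seed = 1L,
                              center = FALSE) {
  mode <- match.arg(mode)
  n <- ncol(vs$data)
  if (length(covariate) != n) stopf("one covariate value per pair required")
  if (mode == "slope" && sd(covariate) < 1e-12)
    stopf("constant covariate cannot be tested in slope mode")
  msk <- as.logical(vs$mask)
  Y <- t(vs$data)                       # pairs x voxels
  X <- cbind(1, if (center) covariate - mean(covariate) else covariate)
  coef_t <- function(Yp, col) {
    fit <- lm.fit(X, Yp)
    cf <- fit$coefficients
    sigma2 <- colSums(fit$residuals^2) / (n - 2)
    xtxinv <- solve(crossprod(X))
    se <- sqrt(sigma2 * xtxinv[col, col])
    # exact fits leave numerical dust in both numerator and denominator
    ifelse(se > 1e-10 * sqrt(colMeans(Yp^2) + 1e-300), cf[col, ] / se, 0)
  }
  col <- if (mode == "intercept") 1L else 2L
  # reduced model excludes the tested term
  Xr <- if (mode == "intercept") X[, 2, drop = FALSE] else X[, 1, drop = FALSE]
  fit_r <- lm.fit(Xr, Y)
  R <- fit_r$residuals
  Fhat <- Y - R
  tfce_of <- function(tv) {
    full <- numeric(length(msk))
    full[msk] <- tv[msk]
    tfce_cpp(full, vs$dim, msk, params$H, params$E, params$dh,
             params$connectivity)
  }
  obs_t <- coef_t(Y, col)
  obs_tf <- tfce_of(obs_t)
  max_null <- numeric(P)
  with_seed(seed, {
    for (p in seq_len(P)) {
      Rp <- if (mode == "intercept") R * sample(c(-1, 1), n, replace = TRUE)
            else R[sample.int(n), , drop = FALSE]
      tv <- coef_t(Fhat + Rp, col)
      max_null[p] <- max(tfce_of(tv)[msk], 0)
    }
  })
  pmap <- array(NA_real_, vs$dim)
  cnt <- vapply(obs_tf[msk], function(o) sum(max_null >= o), 0)
  pmap[msk] <- pmin(1, (1 + cnt) / (P + 1))
  structure(list(
    t = new_stat_map(array(obs_t, vs$dim), vs$mask, paste0("t_", mode),
                     df = n - 2),
    tfce = new_stat_map(array(obs_tf, vs$dim), vs$mask, "tfce"),
    p = pmap, max_null = max_null, P = P, exhaustive = FALSE,
    seed = seed, params = params, design = paste0("covariate_", mode)),
    class = "permutation_result")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (n >= 3).
#' @return List with `r`, `df = n - 2`, and two-sided `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stopf("need n >= 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance input")
  r <- cor(x, y)
  df <- length(x) - 2
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * pt(-abs(t), df))
}
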