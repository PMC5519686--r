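#' Convert a percentile to a standard score
#'
#' Standard scores are scaled to a population mean of 100 and sd of 15, so
#' the conversion is the inverse normal CDF: `100 + 15 * qnorm(p/100)`.
#'
#' @param p percentile(s) in (0, 100), exclusive.
#' @return Standard score(s).
#' @export
percentile_to_standard <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 100))
    stopf("percentile must lie strictly between 0 and 100")
  100 + 15 * qnorm(p / 100)
}

#' @rdname percentile_to_standard
#' @param s standard score(s).
#' @export
standard_to_percentile <- function(s) 100 * pnorm((s - 100) / 15)

#' Configuration of a synthetic multi-site cohort
#'
#' The defaults state the world the generator emulates: 8 research sites
#' totalling 134 children, a case share of one half split across the three
#' reading-disability profiles in the observed 33/22/12 proportions, cases
#' on average `brain_size_case_shift` cm^3 smaller than controls, case
#' prevalence varying across sites, additive per-site Jacobian offsets,
#' a global Jacobian component proportional to standardized brain size,
#' and spatially smoothed Gaussian noise.
#'
#' @param n_per_site integer vector of subjects per site.
#' @param profile_mix named proportions over
#'   Control/PoorDecoder/PoorComprehender/GenerallyPoorReader; must sum to 1.
#' @param site_case_spread multiplicative spread of the case share across
#'   sites (prevalence_s = case share * spread_s, clamped to (0.05, 0.95));
#'   `rep(1, S)` removes the site-status confound.
#' @param site_offsets additive per-site Jacobian shifts.
#' @param site_brain_shift additive per-site brain-size shifts, cm^3.
#' @param brain_size_case_shift mean case brain-size deficit, cm^3.
#' @param brain_size_coef Jacobian change per SD of brain size. Negative:
#'   smaller brains require expansion to fit a template. The default -0.07
#'   is the volume-ratio scale: the Jacobian tracks template/subject
#'   volume, so one SD of brain size (~82 cm^3 of ~1200 cm^3) moves it by
#'   about 0.07, making between-subject variance dominate focal
#'   case-control effects as it does in real multi-site Jacobian data.
#' @param noise_sd voxel noise sd after smoothing.
#' @param smoothing_fwhm_mm noise smoothing kernel FWHM, mm.
#' @param dim,voxel_size grid geometry (mm).
#' @param age_mean,age_sd,female_frac demographic model.
#' @param gm_mean,gm_sd,wm_mean,wm_sd tissue-volume model, cm^3.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_site = c(24, 22, 20, 18, 16, 14, 12, 8),
                          profile_mix = c(Control = 67, PoorDecoder = 33,
                                          PoorComprehender = 22,
                                          GenerallyPoorReader = 12) / 134,
                          site_case_spread = NULL,
                          site_offsets = NULL,
                          site_brain_shift = NULL,
                          brain_size_case_shift = 40,
                          brain_size_coef = -0.07,
                          noise_sd = 0.04,
                          smoothing_fwhm_mm = 8,
                          dim = c(24, 24, 24),
                          voxel_size = c(4, 4, 4),
                          age_mean = 9.61, age_sd = 1.57,
                          female_frac = 0.43,
                          gm_mean = 740, gm_sd = 60,
                          wm_mean = 460, wm_sd = 50,
                          seed = 1L) {
  S <- length(n_per_site)
  if (S < 1 || any(n_per_site < 1)) stopf("need at least one subject per site")
  if (abs(sum(profile_mix) - 1) > 1e-8) stopf("profile_mix must sum to 1")
  if (any(profile_mix < 0)) stopf("profile_mix must be non-negative")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  need <- c("Control", "PoorDecoder", "PoorComprehender", "GenerallyPoorReader")
  if (!all(need %in% names(profile_mix))) stopf("profile_mix must name all four classes")
  if (is.null(site_case_spread))
    site_case_spread <- seq(0.7, 1.3, length.out = S)
  if (is.null(site_offsets))
    site_offsets <- seq(-0.06, 0.06, length.out = S)
  # alternating sign keeps the site brain-size shifts roughly orthogonal
  # to the monotone prevalence spread
  if (is.null(site_brain_shift))
    site_brain_shift <- rep_len(c(-25, 25), S) * rep(seq(1, 0.4, length.out = ceiling(S / 2)), each = 2)[seq_len(S)]
  stopifnot(length(site_case_spread) == S, length(site_offsets) == S,
            length(site_brain_shift) == S)
  structure(list(n_per_site = as.integer(n_per_site), profile_mix = profile_mix,
                 site_case_spread = site_case_spread,
                 site_offsets = site_offsets,
                 site_brain_shift = site_brain_shift,
                 brain_size_case_shift = brain_size_case_shift,
                 brain_size_coef = brain_size_coef,
                 noise_sd = noise_sd, smoothing_fwhm_mm = smoothing_fwhm_mm,
                 dim = as.integer(dim), voxel_size = voxel_size,
                 age_mean = age_mean, age_sd = age_sd,
                 female_frac = female_frac,
                 gm_mean = gm_mean, gm_sd = gm_sd,
                 wm_mean = wm_mean, wm_sd = wm_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# truncated standard-score sampler: uniform on the percentile interval
# (p_lo, p_hi) pushed through the inverse normal CDF, i.e. a truncated
# normal on the score scale
rtrunc_std <- function(n, p_lo, p_hi) {
  100 + 15 * qnorm(runif(n, p_lo / 100, p_hi / 100))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

# rule-consistent score windows, in percentiles; margins keep generated
# subjects away from the decision boundaries so the expert rules recover
# every true profile
profile_score_windows <- list(
  Control = list(verbal_comp = c(10, 97), word_attack = c(30, 97),
                 word_id = c(30, 97), passage_comp = c(30, 97),
                 ran = c(5, 97)),
  PoorDecoder = list(verbal_comp = c(30, 95), word_attack = c(2, 22),
                     word_id = c(2, 22), passage_comp = c(2, 22),
                     ran = c(2, 22)),
  PoorComprehender = list(verbal_comp = c(30, 95), word_attack = c(30, 95),
                          word_id = c(2, 22), passage_comp = c(2, 22),
                          ran = c(20, 95)),
  GenerallyPoorReader = list(verbal_comp = c(2, 22), word_attack = c(2, 22),
                             word_id = c(2, 22), passage_comp = c(2, 22),
                             ran = c(2, 95))
)

#' Generate a synthetic multi-site cohort
#'
#' Draws one phenotype row per subject: site, sex, age, the six standard
#' scores, gray/white matter volumes, case status, and the simulation's
#' ground-truth profile. Scores are truncated normals inside the percentile
#' windows implied by each profile's classification rules, so
#' [classify_expert_rules()] recovers every generated label. Case status is
#' confounded with brain size (cases smaller by `brain_size_case_shift` on
#' average) and with site (prevalence varies by `site_case_spread`).
#'
#' @param config a [cohort_config()].
#' @return A data frame with one row per subject.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  mix <- config$profile_mix
  case_share <- sum(mix[names(mix) != "Control"])
  if (case_share > 0) {
    case_profiles <- mix[names(mix) != "Control"] / case_share
  } else {
    case_profiles <- NULL
  }
  with_seed(config$seed, {
    rows <- list()
    sid <- 0L
    for (s in seq_along(config$n_per_site)) {
      n <- config$n_per_site[s]
      prev <- min(0.95, max(0.05, case_share * config$site_case_spread[s]))
      if (case_share == 0) prev <- 0
      for (i in seq_len(n)) {
        sid <- sid + 1L
        is_case <- runif(1) < prev
        profile <- if (!is_case || is.null(case_profiles)) "Control" else
          sample(names(case_profiles), 1, prob = case_profiles)
        w <- profile_score_windows[[profile]]
        age_lo <- if (profile == "PoorComprehender") 8.3 else 6
        age <- rtrunc_norm(1, config$age_mean, config$age_sd, age_lo, 14)
        gm <- rnorm(1, config$gm_mean, config$gm_sd)
        wm <- rnorm(1, config$wm_mean, config$wm_sd)
        site_shift <- config$site_brain_shift[s]
        gm <- gm + site_shift * config$gm_mean / (config$gm_mean + config$wm_mean)
        wm <- wm + site_shift * config$wm_mean / (config$gm_mean + config$wm_mean)
        if (is_case) {
          shift <- config$brain_size_case_shift
          gm <- gm - shift * config$gm_mean / (config$gm_mean + config$wm_mean)
          wm <- wm - shift * config$wm_mean / (config$gm_mean + config$wm_mean)
        }
        rows[[sid]] <- data.frame(
          subject_id = sprintf("sub%03d", sid),
          site = s,
          sex = if (runif(1) < config$female_frac) "F" else "M",
          age = age,
          word_attack = rtrunc_std(1, w$word_attack[1], w$word_attack[2]),
          word_id = rtrunc_std(1, w$word_id[1], w$word_id[2]),
          passage_comp = rtrunc_std(1, w$passage_comp[1], w$passage_comp[2]),
          verbal_comp = rtrunc_std(1, w$verbal_comp[1], w$verbal_comp[2]),
          perceptual_reasoning = rtrunc_std(1, 5, 97),
          ran = rtrunc_std(1, w$ran[1], w$ran[2]),
          gm_volume = gm, wm_volume = wm,
          is_case = is_case,
          true_profile = profile,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out$brain_size <- out$gm_volume + out$wm_volume
    # word id / passage comp must stay consistent with word attack for
    # Poor Decoders; windows already force <= 25th pct, which suffices
    rownames(out) <- NULL
    out
  })
}

#' Define an ellipsoidal effect region
#'
#' @param center world-mm center.
#' @param radii ellipsoid semi-axes, mm (all positive).
#' @param amplitude additive Jacobian offset applied to cases inside the
#'   region.
#' @param name region label.
#' @return An object of class `effect_region`.
#' @export
effect_region <- function(center, radii, amplitude, name = "region") {
  if (any(radii <= 0)) stopf("radii must be positive")
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 amplitude = amplitude, name = name),
            class = "effect_region")
}

#' Default case-effect regions
#'
#' Two ellipsoids standing in for the kind of focal loci reported in
#' matched-pair morphometry studies: a left parietal surface region and a
#' deeper right-hemisphere white-matter region. Synthetic placeholders,
#' not anatomical claims.
#'
#' @param amplitude additive Jacobian offset in cases.
#' @return List of [effect_region()]s.
#' @export
default_effect_regions <- function(amplitude = 0.05) {
  list(effect_region(c(-22, -18, 16), c(12, 12, 12), amplitude, "L_parietal"),
       effect_region(c(18, 8, 4), c(12, 12, 12), amplitude, "R_deep_wm"))
}

# ellipsoidal analysis mask covering most of the grid
make_brain_mask <- function(dim, voxel_size, affine, frac = 0.85) {
  idx <- as.matrix(expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                               k = seq_len(dim[3])))
  xyz <- voxel_to_world(idx, affine)
  half <- (dim - 1) / 2 * voxel_size * frac
  inside <- rowSums(sweep(xyz, 2, half, "/")^2) <= 1
  array(inside, dim)
}

region_mask <- function(region, dim, voxel_size, affine) {
  idx <- as.matrix(expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                               k = seq_len(dim[3])))
  xyz <- voxel_to_world(idx, affine)
  inside <- rowSums(sweep(sweep(xyz, 2, region$center, "-"), 2,
                          region$radii, "/")^2) <= 1
  array(inside, dim)
}

#' Generate Jacobian-determinant volumes for a cohort
#'
#' Each subject's volume is `1 + site offset + brain-size component +
#' smoothed noise (+ case amplitude inside the effect regions)`. The
#' brain-size component is `brain_size_coef` times the cohort-standardized
#' brain size, applied globally. Raw determinants must stay positive.
#'
#' @param subjects cohort data frame from [generate_cohort()].
#' @param regions list of [effect_region()]s (may be empty).
#' @param config the [cohort_config()] used to generate `subjects`.
#' @return A [volume_set()] with subject-id columns and an ellipsoidal
#'   analysis mask.
#' @export
generate_volumes <- function(subjects, regions = default_effect_regions(),
                             config = cohort_config()) {
  d <- config$dim
  vx <- config$voxel_size
  affine <- default_affine(d, vx)
  mask <- make_brain_mask(d, vx, affine)
  for (r in regions) {
    if (!any(region_mask(r, d, vx, affine) & mask))
      stopf("effect region '%s' does not intersect the mask", r$name)
  }
  reg_masks <- lapply(regions, function(r) as.numeric(region_mask(r, d, vx, affine)))
  zbs <- as.numeric(scale(subjects$brain_size))
  if (any(!is.finite(zbs))) zbs <- rep(0, nrow(subjects))
  n <- nrow(subjects)
  mat <- matrix(NA_real_, prod(d), n,
                dimnames = list(NULL, subjects$subject_id))
  with_seed(config$seed + 1L, {
    for (i in seq_len(n)) {
      vol <- 1 + config$site_offsets[subjects$site[i]] +
        config$brain_size_coef * zbs[i]
      vol <- rep(vol, prod(d))
      if (config$noise_sd > 0) {
        eps <- array(rnorm(prod(d)), d)
        eps <- gaussian_smooth3d(eps, config$smoothing_fwhm_mm, vx)
        eps <- eps / sd(eps) * config$noise_sd
        vol <- vol + as.numeric(eps)
      }
      if (isTRUE(subjects$is_case[i])) {
        for (k in seq_along(regions))
          vol <- vol + regions[[k]]$amplitude * reg_masks[[k]]
      }
      mat[, i] <- vol
    }
  })
  if (any(mat[rep(as.logical(mask), n)] <= 0))
    stopf("generated Jacobian determinants <= 0; reduce offsets/amplitude")
  volume_set(mat, d, voxel_size = vx, affine = affine, mask = mask)
}

#' Write / read a phenotype table
#'
#' One row per subject with the documented header (subject_id, site, sex,
#' age, the six standard scores, tissue volumes, brain_size, is_case and,
#' for synthetic data, true_profile).
#'
#' @param subjects cohort data frame.
#' @param path CSV path.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_phenotypes <- function(subjects, path) {
  write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "site", "sex", "age", "word_attack", "word_id",
           "passage_comp", "verbal_comp", "perceptual_reasoning", "ran",
           "gm_volume", "wm_volume", "is_case")
  miss <- setdiff(req, names(out))
  if (length(miss)) stopf("phenotype file lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (is.null(out$brain_size)) out$brain_size <- out$gm_volume + out$wm_volume
  out$is_case <- as.logical(out$is_case)
  out
}
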