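# Independent oracles and shared fixtures. The oracles deliberately use
# naive per-threshold / enumeration computations so they stay independent
# of the fast paths they check.

# Brute-force TFCE: recompute connected components at every threshold.
brute_tfce <- function(stat, mask = NULL, H = 2, E = 0.5, dh = 0, conn = 26) {
  d <- dim(stat)
  if (is.null(mask)) mask <- array(TRUE, d)
  vals <- ifelse(as.logical(mask) & stat > 0, stat, 0)
  out <- numeric(prod(d))
  hmax <- max(vals)
  if (hmax <= 0) return(array(out, d))
  step <- if (dh > 0) dh else hmax / 100
  nst <- floor(hmax / step + 1e-9)
  for (k in seq_len(nst)) {
    h <- k * step
    supra <- array(vals >= h - 1e-9 * step, d)
    if (!any(supra)) next
    labs <- brute_components(supra, conn)
    sizes <- tabulate(labs)
    pos <- labs > 0
    out[pos] <- out[pos] + sizes[labs[pos]]^E * h^H * step
  }
  array(out, d)
}

# Flood-fill connected components (pure R).
brute_components <- function(binary, conn = 26) {
  d <- dim(binary)
  offs <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1))
  l1 <- rowSums(abs(offs))
  offs <- offs[l1 > 0 & l1 <= switch(as.character(conn), "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  labs <- array(0L, d)
  cur <- 0L
  idx_all <- which(binary)
  for (start in idx_all) {
    if (labs[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labs[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (m in seq_len(nrow(offs))) {
        n_ijk <- ijk + offs[m, ]
        if (any(n_ijk < 1) || any(n_ijk > d)) next
        u <- n_ijk[1] + d[1] * (n_ijk[2] - 1 + d[2] * (n_ijk[3] - 1))
        if (binary[u] && labs[u] == 0L) {
          labs[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  labs
}

# Exhaustive sign-flip FWE oracle for tiny n: all 2^n sign patterns,
# per-pattern t map, brute TFCE, max over mask; p = count / 2^n.
brute_signflip_fwe <- function(D, dims, mask, H = 2, E = 0.5, dh = 0,
                               conn = 26) {
  n <- ncol(D)
  patterns <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  maxes <- numeric(nrow(patterns))
  tfces <- vector("list", nrow(patterns))
  for (p in seq_len(nrow(patterns))) {
    Ds <- sweep(D, 2, patterns[p, ], "*")
    m <- rowMeans(Ds)
    sdv <- apply(Ds, 1, sd)
    tv <- ifelse(sdv > 0, m / (sdv / sqrt(n)), 0)
    tf <- brute_tfce(array(tv * as.logical(mask), dims), array(mask, dims),
                     H, E, dh, conn)
    tfces[[p]] <- tf
    maxes[p] <- max(tf[as.logical(mask)])
  }
  obs <- tfces[[1]]  # pattern 1 = all +1 (identity)
  pmap <- array(NA_real_, dims)
  msk <- as.logical(mask)
  pmap[msk] <- vapply(which(msk), function(v) mean(maxes >= obs[v]), 0)
  list(p = pmap, max_null = maxes, tfce = obs)
}

# small deterministic cohort builder with explicit case/control layout:
# `pairs_per_site` cases and controls per site, fixed assignment
balanced_cohort <- function(pairs_per_site = 3, n_sites = 8, seed = 1,
                            brain_size_case_shift = 0, noise_sd = 0.04,
                            site_offsets = NULL, brain_size_coef = -0.03,
                            dim = c(16, 16, 16), amplitude = 0,
                            smoothing_fwhm_mm = 8) {
  cfg <- cohort_config(
    n_per_site = rep(2 * pairs_per_site, n_sites),
    site_case_spread = rep(1, n_sites),
    site_offsets = site_offsets %||% seq(-0.06, 0.06, length.out = n_sites),
    brain_size_case_shift = brain_size_case_shift,
    brain_size_coef = brain_size_coef,
    noise_sd = noise_sd, smoothing_fwhm_mm = smoothing_fwhm_mm,
    dim = dim, voxel_size = c(4, 4, 4), seed = seed)
  coh <- generate_cohort(cfg)
  # force an exact balanced case/control layout per site, keeping the
  # case brain-size deficit aligned with the forced flags
  orig_case <- coh$is_case
  coh$is_case <- unlist(lapply(seq_len(n_sites), function(s)
    rep(c(TRUE, FALSE), each = pairs_per_site)))
  shift <- cfg$brain_size_case_shift
  if (shift != 0) {
    delta <- (as.numeric(orig_case) - as.numeric(coh$is_case)) * shift
    gm_share <- cfg$gm_mean / (cfg$gm_mean + cfg$wm_mean)
    coh$gm_volume <- coh$gm_volume + delta * gm_share
    coh$wm_volume <- coh$wm_volume + delta * (1 - gm_share)
    coh$brain_size <- coh$gm_volume + coh$wm_volume
  }
  list(config = cfg, cohort = coh)
}

# fixed within-site pairing for a balanced_cohort
fixed_pairs <- function(coh) {
  pt <- NULL
  for (s in unique(coh$site)) {
    cases <- coh$subject_id[coh$site == s & coh$is_case]
    controls <- coh$subject_id[coh$site == s & !coh$is_case]
    k <- min(length(cases), length(controls))
    pt <- rbind(pt, data.frame(case_id = cases[seq_len(k)],
                               control_id = controls[seq_len(k)],
                               stratum = paste0("site", s),
                               distance = NA_real_))
  }
  structure(list(pairs = pt, unmatched = character(0)),
            class = "matched_pair_set")
}

# effect regions that fit inside a 16^3 x 4mm grid's ellipsoidal mask
small_regions <- function(amplitude) {
  list(effect_region(c(-12, -8, 8), c(10, 10, 10), amplitude, "regA"),
       effect_region(c(10, 8, -6), c(10, 10, 10), amplitude, "regB"))
}
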