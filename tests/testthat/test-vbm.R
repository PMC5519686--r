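rand_vs <- function(V = c(8, 8, 8), n = 10, sd = 1, seed = 1, mask = NULL) {
  set.seed(seed)
  D <- matrix(rnorm(prod(V) * n, 0, sd), prod(V), n)
  colnames(D) <- sprintf("s%03d", seq_len(n))
  volume_set(D, V, mask = mask)
}

test_that("residualization obeys OLS identities", {
  vs <- rand_vs(n = 12, seed = 2)
  ps <- runif(12, 0.2, 0.8)
  names(ps) <- colnames(vs$data)
  adj <- residualize(vs, ps)
  # adjusted intensities are orthogonal to the propensity at every voxel
  cors <- apply(adj$data, 1, function(y) cor(y, ps))
  expect_lt(max(abs(cors)), 1e-8)
  # grand means are preserved
  expect_equal(rowMeans(adj$data), rowMeans(vs$data), tolerance = 1e-10)

  # propensity orthogonal to intensities: output equals input
  vs2 <- rand_vs(n = 8, seed = 3)
  y <- vs2$data[1, ]
  ps2 <- y - mean(y)
  vs2$data <- matrix(rep(seq_len(8), each = nrow(vs2$data)), nrow(vs2$data), 8)
  vs2$data <- vs2$data - tcrossprod(rep(1, nrow(vs2$data)), ps2) * 0
  # build intensities constant per subject but orthogonal to ps2
  ortho <- residuals(lm(rnorm(8) ~ ps2))
  vs2$data <- tcrossprod(rep(1, nrow(vs2$data)), ortho + 5)
  colnames(vs2$data) <- sprintf("s%03d", 1:8)
  adj2 <- residualize(vs2, setNames(ps2, colnames(vs2$data)))
  expect_equal(adj2$data, vs2$data, tolerance = 1e-10)

  # intensities exactly linear in propensity collapse to the grand mean
  vs3 <- rand_vs(n = 8, seed = 4)
  ps3 <- runif(8)
  vs3$data <- outer(rnorm(nrow(vs3$data)), ps3) + 2
  colnames(vs3$data) <- sprintf("s%03d", 1:8)
  adj3 <- residualize(vs3, setNames(ps3, colnames(vs3$data)))
  expect_equal(adj3$data, matrix(rowMeans(vs3$data), nrow(vs3$data), 8),
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_warning(residualize(vs, setNames(rep(0.5, 12), colnames(vs$data))),
                 "constant propensity")
})

test_that("pair differences are exact subtractions", {
  vs <- rand_vs(n = 6, seed = 5)
  prs <- structure(list(pairs = data.frame(
    case_id = c("s001", "s003", "s005"),
    control_id = c("s002", "s004", "s006"),
    stratum = "x", distance = 0), unmatched = character(0)),
    class = "matched_pair_set")
  d <- pair_differences(vs, prs)
  expect_equal(d$data[, "s001"], vs$data[, "s001"] - vs$data[, "s002"])
  # swapping roles negates the volume
  prs_sw <- prs
  prs_sw$pairs[c("case_id", "control_id")] <- prs$pairs[c("control_id", "case_id")]
  expect_equal(pair_differences(vs, prs_sw)$data, -d$data, ignore_attr = TRUE)
  # algebraic identity: sum of differences = sum(cases) - sum(controls)
  expect_equal(rowSums(d$data),
               rowSums(vs$data[, prs$pairs$case_id]) -
                 rowSums(vs$data[, prs$pairs$control_id]))
  bad <- prs
  bad$pairs$case_id[1] <- "nope"
  expect_error(pair_differences(vs, bad), "missing")
})

test_that("t statistics match hand formulas", {
  # n=4 values {1,2,3,4}: t = 2.5 / (1.29099/2) = 3.873
  vs <- rand_vs(V = c(2, 2, 2), n = 4, seed = 6)
  vs$data[1, ] <- c(1, 2, 3, 4)
  tm <- one_sample_t(vs)
  expect_equal(tm$data[1, 1, 1], 3.872983, tolerance = 1e-6)
  expect_equal(tm$df, 3)
  # antisymmetric pairs give t = 0 everywhere
  vs2 <- rand_vs(V = c(4, 4, 4), n = 6, seed = 7)
  vs2$data <- cbind(vs2$data[, 1:3], -vs2$data[, 1:3])
  colnames(vs2$data) <- sprintf("s%03d", 1:6)
  expect_true(all(abs(one_sample_t(vs2)$data) < 1e-10))

  # two-sample: closed form with two points per group
  vs3 <- rand_vs(V = c(2, 2, 2), n = 4, seed = 8)
  vs3$data[1, ] <- c(1, 3, 6, 10)
  fl <- setNames(c(TRUE, TRUE, FALSE, FALSE), colnames(vs3$data))
  t2 <- two_sample_t(vs3, fl)
  m1 <- 2; m0 <- 8; sp <- sqrt((2 + 8) / 2)
  expect_equal(t2$data[1, 1, 1], (m1 - m0) / (sp * sqrt(1)), tolerance = 1e-10)
  expect_equal(t2$df, 2)
  # identical groups: zero map
  vs4 <- vs3
  vs4$data <- cbind(vs3$data[, 1:2], vs3$data[, 1:2])
  colnames(vs4$data) <- colnames(vs3$data)
  expect_true(all(abs(two_sample_t(vs4, fl)$data) < 1e-10))
  # equals one-way ANOVA F = t^2
  y <- vs3$data[2, ]
  f <- anova(aov(y ~ factor(fl)))$`F value`[1]
  expect_equal(t2$data[2, 1, 1]^2, f, tolerance = 1e-10)
})

test_that("TFCE matches direct summation and brute force", {
  # all-zero map
  z <- array(0, c(6, 6, 6))
  expect_true(all(tfce(z, tfce_params())$data == 0))
  # single voxel of height 1: sum of h^2 * 0.1 over h in 0.1..1.0
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 1
  got <- tfce(a, tfce_params(H = 2, E = 0.5, dh = 0.1))$data[3, 3, 3]
  expect_equal(got, sum((seq(0.1, 1, 0.1))^2 * 0.1), tolerance = 1e-10)
  # negative voxels contribute nothing and score zero
  b <- array(rnorm(6^3), c(6, 6, 6))
  tf <- tfce(b, tfce_params())$data
  expect_true(all(tf[b <= 0] == 0))
  expect_true(all(tf[b > 0] >= 0))
  # brute-force equivalence on random maps with masks
  set.seed(33)
  for (i in 1:6) {
    a <- array(rnorm(8^3), c(8, 8, 8))
    m <- array(runif(8^3) > 0.15, c(8, 8, 8))
    conn <- c(6, 18, 26)[1 + i %% 3]
    f <- tfce(a, tfce_params(connectivity = conn), mask = m)$data
    o <- brute_tfce(a, m, conn = conn)
    expect_lt(max(abs(f - o)) / max(o), 1e-6)
  }
  expect_error(tfce(array(NaN, c(2, 2, 2))), "non-finite")
})

test_that("TFCE height scaling follows c^(H+1) for a single voxel", {
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 1
  base <- tfce(a, tfce_params())$data[3, 3, 3]
  for (cc in c(0.5, 2, 3)) {
    scaled <- tfce(a * cc, tfce_params())$data[3, 3, 3]
    # dh = hmax/100 rescales with the map, so the relation is exact
    expect_equal(scaled, cc^3 * base, tolerance = 1e-8)
  }
})

test_that("exhaustive sign-flip inference equals enumeration", {
  set.seed(14)
  dims <- c(5, 5, 5)
  D <- matrix(rnorm(prod(dims) * 4), prod(dims), 4)
  D[1:20, ] <- D[1:20, ] + 1.5
  colnames(D) <- sprintf("p%d", 1:4)
  mask <- array(TRUE, dims)
  vs <- volume_set(D, dims, mask = mask)
  res <- permutation_fwe(vs, "sign_flip", P = 100, seed = 3)
  expect_true(res$exhaustive)
  expect_equal(res$P, 16)
  oracle <- brute_signflip_fwe(D, dims, mask)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(sort(res$max_null), sort(oracle$max_null), tolerance = 1e-9)
  # seed-invariance of the exhaustive result
  res2 <- permutation_fwe(vs, "sign_flip", P = 100, seed = 99)
  expect_identical(res$p, res2$p)
})

test_that("a strong focal effect saturates at the minimum p", {
  set.seed(15)
  dims <- c(8, 8, 8)
  n <- 20
  D <- matrix(rnorm(prod(dims) * n, 0, 0.1), prod(dims), n)
  region <- 100:140
  D[region, ] <- D[region, ] + 3
  colnames(D) <- sprintf("p%02d", 1:n)
  vs <- volume_set(D, dims)
  res <- permutation_fwe(vs, "sign_flip", P = 400, seed = 8)
  expect_false(res$exhaustive)
  expect_equal(min(res$p[region]), 1 / 401)
  # p is monotone non-increasing in the observed TFCE score
  ord <- order(res$tfce$data)
  expect_true(all(diff(res$p[ord]) <= 1e-12))
})

test_that("Cohen's d maps separate paired and unpaired designs", {
  vs <- rand_vs(n = 12, seed = 16)
  prs <- structure(list(pairs = data.frame(
    case_id = sprintf("s%03d", 1:6), control_id = sprintf("s%03d", 7:12),
    stratum = "x", distance = 0), unmatched = character(0)),
    class = "matched_pair_set")
  # identical groups: both d maps are zero
  vs$data[, 7:12] <- vs$data[, 1:6]
  d0 <- cohens_d_maps(vs, prs)
  expect_true(all(d0$paired$data == 0) && all(d0$unpaired$data == 0))

  # shared within-pair variance boosts paired d in effect voxels
  set.seed(17)
  site <- rnorm(6, 0, 2)
  noise_c <- matrix(rnorm(512 * 6, 0, 0.5), 512, 6)
  noise_k <- matrix(rnorm(512 * 6, 0, 0.5), 512, 6)
  eff <- numeric(512); eff[1:60] <- 1
  case <- sweep(noise_c, 2, site, "+") + eff
  ctrl <- sweep(noise_k, 2, site, "+")
  dat2 <- cbind(case, ctrl)
  colnames(dat2) <- sprintf("s%03d", 1:12)
  vs2 <- volume_set(dat2, c(8, 8, 8))
  d1 <- cohens_d_maps(vs2, prs)
  expect_gt(median(abs(d1$paired$data[1:60])),
            median(abs(d1$unpaired$data[1:60])))
  expect_equal(sum(d1$histogram$paired), sum(vs2$mask))
})

test_that("cluster extraction reports sizes, peaks and world coordinates", {
  dims <- c(10, 10, 10)
  p <- array(1, dims)
  stat <- array(0, dims)
  # one 3x3x3 block and one isolated voxel, clearly separated
  blk <- as.matrix(expand.grid(2:4, 2:4, 2:4))
  idx <- blk[, 1] + 10 * (blk[, 2] - 1 + 10 * (blk[, 3] - 1))
  p[idx] <- 0.01
  stat[idx] <- 3
  stat[5 + 10 * (4 + 10 * 3)] <- 0  # inside block coords for peak below
  p[9, 9, 9] <- 0.01; stat[9, 9, 9] <- 5
  sm <- morphpair:::new_stat_map(stat, array(TRUE, dims), "t", df = 10)
  af <- default_affine(dims, c(2, 2, 2))
  cl <- extract_clusters(p, stat = sm, alpha = 0.05, affine = af)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$n_voxels, c(27, 1))
  one <- cl[cl$n_voxels == 1, ]
  expect_equal(unlist(one[c("peak_x", "peak_y", "peak_z")]),
               as.numeric(voxel_to_world(c(9, 9, 9), af)), ignore_attr = TRUE)
  expect_equal(one$peak_stat, 5)
  # no suprathreshold voxels: empty table
  expect_equal(nrow(extract_clusters(array(1, dims), stat = sm)), 0)
  # two diagonal-touching blocks merge under 26- but not 6-connectivity
  p2 <- array(1, c(6, 6, 6))
  p2[1:2, 1:2, 1:2] <- 0.01
  p2[3, 3, 3] <- 0.01
  sm2 <- morphpair:::new_stat_map(array(1, c(6, 6, 6)), array(TRUE, c(6, 6, 6)), "t")
  expect_equal(nrow(extract_clusters(p2, stat = sm2, connectivity = 26)), 1)
  expect_equal(nrow(extract_clusters(p2, stat = sm2, connectivity = 6)), 2)
})

test_that("ROI means reduce to the masked average", {
  vs <- rand_vs(n = 4, seed = 18)
  reg <- array(FALSE, c(8, 8, 8)); reg[2:3, 2:3, 2:3] <- TRUE
  got <- roi_mean(vs, reg)
  expect_equal(got, colMeans(vs$data[which(reg), ]))
  # constant volume returns the constant; single voxel returns itself
  vs$data[] <- 7
  expect_true(all(roi_mean(vs, reg) == 7))
  one <- array(FALSE, c(8, 8, 8)); one[5, 5, 5] <- TRUE
  vs2 <- rand_vs(n = 3, seed = 19)
  expect_equal(roi_mean(vs2, one), vs2$data[which(one), ])
  expect_error(roi_mean(vs2, array(FALSE, c(8, 8, 8))), "empty")
})

test_that("covariate control behaves across modes", {
  set.seed(20)
  dims <- c(6, 6, 6); V <- prod(dims); n <- 16
  D <- matrix(rnorm(V * n), V, n)
  colnames(D) <- sprintf("p%02d", 1:n)
  vs <- volume_set(D, dims)
  covar <- rnorm(n)
  # diffs exactly proportional to the covariate: intercept test is null
  vs_prop <- vs
  vs_prop$data <- outer(rnorm(V), covar)
  colnames(vs_prop$data) <- colnames(D)
  r0 <- covariate_control(vs_prop, covar, "intercept", P = 150, seed = 2)
  expect_true(all(r0$p[vs$mask] > 0.5))
  # orthogonal covariate: intercept-mode p ranks like the plain sign-flip test
  r1 <- covariate_control(vs, covar, "intercept", P = 300, seed = 3)
  r2 <- permutation_fwe(vs, "sign_flip", P = 300, seed = 4)
  expect_gt(cor(rank(r1$tfce$data[vs$mask]), rank(r2$tfce$data[vs$mask])), 0.95)
  # slope mode detects a covariate-linked effect
  vs_eff <- vs
  vs_eff$data[1:30, ] <- vs_eff$data[1:30, ] +
    2 * matrix(covar, 30, n, byrow = TRUE)
  colnames(vs_eff$data) <- colnames(D)
  r3 <- covariate_control(vs_eff, covar, "slope", P = 300, seed = 5)
  expect_lt(min(r3$p[1:30]), 0.05)
  expect_error(covariate_control(vs, rep(1, n), "slope"), "constant covariate")
})

test_that("pearson_r reproduces printed r-to-p pairings", {
  x <- 1:10
  expect_equal(pearson_r(x, x * 2)$r, 1)
  set.seed(21)
  y <- residuals(lm(rnorm(10) ~ x))
  expect_lt(abs(pearson_r(x, y)$r), 1e-8)
  # r = -0.32 with df = 65 corresponds to p ~= 0.008
  set.seed(22)
  r_target <- -0.32
  # construct a vector pair with exactly this correlation
  a <- rnorm(67); b <- rnorm(67)
  b <- residuals(lm(b ~ a)); b <- b / sd(b)
  a <- (a - mean(a)) / sd(a)
  y2 <- r_target * a + sqrt(1 - r_target^2) * b
  got <- pearson_r(a, y2)
  expect_equal(got$r, r_target, tolerance = 1e-10)
  expect_equal(got$df, 65)
  expect_equal(got$p, 0.008295, tolerance = 2e-3)
  expect_error(pearson_r(x, rep(1, 10)), "zero variance")
})
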