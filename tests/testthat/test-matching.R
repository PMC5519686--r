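mini_subjects <- function(brain = c(900, 1000, 1100, 1200),
                          case = c(TRUE, FALSE, TRUE, FALSE),
                          site = rep(1, 4)) {
  n <- length(brain)
  data.frame(subject_id = sprintf("s%02d", seq_len(n)), site = site,
             sex = rep(c("F", "M"), length.out = n), age = 10,
             word_attack = 100, word_id = 100, passage_comp = 100,
             verbal_comp = 100, perceptual_reasoning = 100, ran = 100,
             gm_volume = brain * 0.6, wm_volume = brain * 0.4,
             brain_size = brain, is_case = case,
             stringsAsFactors = FALSE)
}

test_that("stratification splits at the site median and drops one-sided strata", {
  s <- mini_subjects()
  st <- stratify(s)
  expect_equal(sort(st$stratum), c("site1_larger", "site1_smaller"))
  asg <- attr(st, "assignment")
  expect_equal(asg, c("site1_smaller", "site1_smaller",
                      "site1_larger", "site1_larger"))
  # a site with only controls contributes no strata
  s2 <- mini_subjects(brain = c(900, 1000, 1100, 1200, 800, 850),
                      case = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
                      site = c(1, 1, 1, 1, 2, 2))
  st2 <- stratify(s2)
  expect_true(all(grepl("^site1", st2$stratum)))
  expect_true(all(is.na(attr(st2, "assignment")[5:6])))
  expect_error(stratify(mini_subjects(brain = 1000, case = TRUE)[1, ]),
               "2 subjects")
})

test_that("every retained stratum holds a case and a control on synthetic cohorts", {
  for (seed in 1:5) {
    coh <- generate_cohort(cohort_config(seed = seed))
    st <- stratify(coh)
    expect_true(all(st$n_cases >= 1 & st$n_controls >= 1))
    # weights follow the coarsened-matching convention
    tc <- sum(coh$is_case[!is.na(attr(st, "assignment"))])
    tk <- sum(!coh$is_case[!is.na(attr(st, "assignment"))])
    expect_equal(st$cem_weight, (st$n_controls / st$n_cases) * (tc / tk))
  }
})

test_that("propensity model recovers the data-generating structure", {
  # null model: score equals prevalence everywhere
  s <- mini_subjects(brain = rep(1000, 8),
                     case = rep(c(TRUE, FALSE), 4))
  m <- fit_propensity(s)
  expect_true(all(abs(m$scores - 0.5) < 1e-6))
  expect_false(m$separation)

  # deterministic separation is flagged
  s2 <- mini_subjects(brain = c(900, 905, 1100, 1105, 910, 1110),
                      case = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                      site = rep(1, 6))
  expect_warning(m2 <- fit_propensity(s2), "separation")
  expect_true(m2$separation)
  expect_true(all(m2$scores > 0 & m2$scores < 1))

  # coefficient recovery: logit(p) = b0 - 0.01 * brain_size
  set.seed(77)
  bs <- rnorm(2000, 1200, 80)
  eta <- 12 - 0.01 * bs
  case <- runif(2000) < plogis(eta)
  s3 <- mini_subjects(brain = bs, case = case, site = rep(1, 2000))
  m3 <- fit_propensity(s3)
  fit <- glm(case ~ bs, family = binomial())
  se <- summary(fit)$coefficients["bs", "Std. Error"]
  expect_lt(abs(m3$coefficients[["brain_size"]] - (-0.01)), 2 * se)
})

test_that("greedy pairing is unique, deterministic, and near the optimum", {
  s <- mini_subjects()
  st <- stratify(s)
  m <- fit_propensity(s)
  prs <- pair_nearest(st, m, s)
  expect_equal(nrow(prs$pairs), 2)
  expect_equal(anyDuplicated(c(prs$pairs$case_id, prs$pairs$control_id)), 0L)
  expect_true(all(prs$pairs$case_id %in% c("s01", "s03")))

  # 2 cases, 1 control: one pair, one unmatched case
  s2 <- mini_subjects(brain = c(990, 1000, 1010), case = c(TRUE, FALSE, TRUE),
                      site = rep(1, 3))
  st2 <- stratify(s2)
  prs2 <- pair_nearest(st2, fit_propensity(s2), s2)
  expect_equal(nrow(prs2$pairs), 1)
  expect_equal(length(prs2$unmatched), 1)

  # greedy total distance is bounded below by the optimal assignment
  for (seed in 1:10) {
    set.seed(seed)
    n <- 6
    s3 <- mini_subjects(brain = rnorm(2 * n, 1100, 90),
                        case = rep(c(TRUE, FALSE), n),
                        site = rep(1, 2 * n))
    s3$brain_size <- s3$gm_volume + s3$wm_volume
    st3 <- stratify(s3)
    m3 <- fit_propensity(s3)
    g <- pair_nearest(st3, m3, s3, method = "greedy")
    o <- pair_nearest(st3, m3, s3, method = "optimal")
    expect_equal(nrow(g$pairs), nrow(o$pairs))
    expect_gte(sum(g$pairs$distance) + 1e-12, sum(o$pairs$distance))
    # pairs never straddle strata
    asg <- setNames(attr(st3, "assignment"), s3$subject_id)
    expect_equal(asg[g$pairs$case_id], asg[g$pairs$control_id],
                 ignore_attr = TRUE)
  }
})

test_that("optimal assignment matches exhaustive enumeration", {
  set.seed(9)
  for (rep in 1:5) {
    D <- matrix(runif(25), 5, 5)
    sol <- morphpair:::optimal_assignment(D)
    got <- sum(D[cbind(sol$rows, sol$cols)])
    best <- Inf
    idx <- seq_len(5)
    rec <- function(left, cols, cost) {
      if (!length(left)) { best <<- min(best, cost); return() }
      for (j in cols) rec(left[-1], setdiff(cols, j), cost + D[left[1], j])
    }
    rec(idx, idx, 0)
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("random pairing is seeded, exhaustive-by-id, and roughly uniform", {
  s <- mini_subjects(brain = rnorm(12, 1100, 50),
                     case = rep(c(TRUE, FALSE), 6), site = rep(1:2, each = 6))
  a <- random_pairing(s, seed = 4)
  b <- random_pairing(s, seed = 4)
  expect_identical(a, b)
  expect_equal(nrow(a$pairs), 6)
  expect_equal(anyDuplicated(c(a$pairs$case_id, a$pairs$control_id)), 0L)

  # frequency of a fixed (case, control) match across seeds is ~ 1/n
  hits <- 0
  for (seed in 1:400) {
    p <- random_pairing(s, seed = seed)$pairs
    hits <- hits + (p$control_id[p$case_id == "s01"] == "s02")
  }
  expect_lt(abs(hits / 400 - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / 400))
})

test_that("balance diagnostics reproduce closed forms", {
  coh <- generate_cohort(cohort_config(seed = 13))
  st <- stratify(coh)
  m <- fit_propensity(coh)
  prs <- pair_nearest(st, m, coh)
  bal <- balance_diagnostics(prs, coh, m)
  expect_true(all(c("age", "gm_volume", "wm_volume", "brain_size", "sex",
                    "propensity") %in% bal$variable))

  # identical case/control covariates: all paired tests collapse to p = 1
  s <- mini_subjects(brain = rep(c(1000, 1000, 1100, 1100), 2),
                     case = rep(c(TRUE, FALSE), 4), site = rep(1, 8))
  s$age <- rep(10, 8)
  prs2 <- structure(list(pairs = data.frame(
    case_id = c("s01", "s03"), control_id = c("s02", "s04"),
    stratum = "site1_smaller", distance = 0), unmatched = character(0)),
    class = "matched_pair_set")
  bal2 <- balance_diagnostics(prs2, s)
  expect_true(all(bal2$p[bal2$test == "paired_t"] == 1))

  # Yates chi-square equals the textbook formula on random 2x2 tables
  set.seed(21)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    got <- suppressWarnings(chisq.test(tab, correct = TRUE)$statistic)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    oracle <- sum((pmax(abs(tab - E) - 0.5, 0))^2 / E)
    expect_equal(unname(got), oracle, tolerance = 1e-12)
  }
})
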