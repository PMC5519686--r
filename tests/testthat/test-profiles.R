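subject_row <- function(wa = 100, wid = 100, pc = 100, vc = 100, ran = 100,
                        age = 10, pr = 100) {
  data.frame(word_attack = wa, word_id = wid, passage_comp = pc,
             verbal_comp = vc, perceptual_reasoning = pr, ran = ran,
             age = age)
}

test_that("expert rules label the canonical score patterns", {
  # classic decoding deficit: all reading scores depressed, verbal spared
  expect_equal(classify_expert_rules(
    subject_row(wa = 82, wid = 84, pc = 85, vc = 102, ran = 84)),
    "PoorDecoder")
  # intact scores across the board
  expect_equal(classify_expert_rules(
    subject_row(wa = 100, wid = 100, pc = 100, vc = 100)), "Control")
  # comprehension-specific deficit with intact decoding and naming speed
  expect_equal(classify_expert_rules(
    subject_row(wa = 98, wid = 84, pc = 83, vc = 105, ran = 95, age = 10)),
    "PoorComprehender")
  # broad depression including verbal comprehension
  expect_equal(classify_expert_rules(
    subject_row(wa = 82, wid = 84, pc = 85, vc = 84, ran = 84)),
    "GenerallyPoorReader")
  # comprehension pattern but too young for the profile
  expect_equal(classify_expert_rules(
    subject_row(wa = 98, wid = 84, pc = 83, vc = 105, ran = 95, age = 7)),
    "Unclassifiable")
  # decoding deficit with fast naming: matches no profile
  expect_equal(classify_expert_rules(
    subject_row(wa = 82, wid = 84, pc = 85, vc = 102, ran = 110, age = 7)),
    "Unclassifiable")
  expect_error(classify_expert_rules(subject_row(wa = NA)), "missing")
})

test_that("rule classifier is total and deterministic on random inputs", {
  set.seed(42)
  subj <- data.frame(word_attack = rnorm(300, 95, 15),
                     word_id = rnorm(300, 95, 15),
                     passage_comp = rnorm(300, 95, 15),
                     verbal_comp = rnorm(300, 95, 15),
                     perceptual_reasoning = rnorm(300, 100, 15),
                     ran = rnorm(300, 95, 15),
                     age = runif(300, 6, 14))
  lab <- classify_expert_rules(subj)
  expect_true(all(lab %in% c("Control", "PoorDecoder", "PoorComprehender",
                             "GenerallyPoorReader", "Unclassifiable")))
  expect_identical(lab, classify_expert_rules(subj))
})

test_that("ensemble LOOCV separates rule-consistent profiles and is honest on noise", {
  cfg <- cohort_config(n_per_site = rep(15, 8), seed = 11)
  coh <- generate_cohort(cfg)
  lab <- coh$true_profile
  res <- classify_ensemble_loocv(coh, lab, ntree = 150, seed = 4)
  expect_gte(res$accuracy, 0.9)
  expect_true(all(abs(rowSums(res$probabilities) - 1) < 1e-9))
  expect_identical(dim(res$probabilities),
                   c(nrow(coh), length(unique(lab))))

  # identical features, two balanced classes: accuracy near chance and
  # vote fractions near one half
  n <- 12
  flat <- data.frame(subject_id = sprintf("s%02d", 1:n),
                     word_attack = 90, word_id = 90, passage_comp = 90,
                     verbal_comp = 90, perceptual_reasoning = 90, ran = 90,
                     age = 10)
  lab2 <- rep(c("A", "B"), n / 2)
  res2 <- classify_ensemble_loocv(flat, lab2, ntree = 200, seed = 8)
  expect_lt(abs(mean(res2$probabilities[, "A"]) - 0.5), 0.15)
  expect_lt(res2$accuracy, 0.8)
})

test_that("permutation importance tracks the informative features", {
  set.seed(31)
  n <- 120
  # only word_attack separates the two classes
  lab <- rep(c("lo", "hi"), each = n / 2)
  subj <- data.frame(word_attack = ifelse(lab == "lo", rnorm(n, 80, 4),
                                          rnorm(n, 110, 4)),
                     word_id = rnorm(n, 95, 10), passage_comp = rnorm(n, 95, 10),
                     verbal_comp = rnorm(n, 95, 10),
                     perceptual_reasoning = rnorm(n, 100, 10),
                     ran = rnorm(n, 95, 10), age = runif(n, 6, 14))
  imp <- variable_importance(subj, lab, ntree = 200, seed = 6)
  expect_equal(names(which.max(imp)), "word_attack")
  # the uninformative features sit near zero (within 2 percentage points)
  expect_true(all(abs(imp[setdiff(names(imp), "word_attack")]) < 2))
})

test_that("Cronbach's alpha matches its closed form", {
  expect_equal(cronbach_alpha(cbind(c(1, 2, 3), c(1, 2, 3)))$alpha, 1)
  # shifted columns are still perfectly consistent
  expect_equal(cronbach_alpha(cbind(c(1, 2, 3), c(3, 4, 5)))$alpha, 1)
  # hand-computed: k=2, item vars 1 and 7/3, var of row sums 19/3
  expect_equal(cronbach_alpha(cbind(c(1, 2, 3), c(1, 2, 4)))$alpha, 18 / 19)
  set.seed(12)
  a <- cronbach_alpha(cbind(rnorm(1000), rnorm(1000)))$alpha
  expect_lt(abs(a), 0.1)
  expect_lte(cronbach_alpha(matrix(rnorm(40), 10, 4))$alpha, 1)
  expect_error(cronbach_alpha(cbind(rep(1, 5), rep(2, 5))), "variance")
  expect_error(cronbach_alpha(matrix(1:5, 5, 1)), "2 columns")
})

test_that("classical MDS embeds exactly and fixes signs", {
  # three collinear points at mutual distances 1, 1, 2
  prob <- matrix(c(0, 1, 2), ncol = 1)
  mds <- classical_mds(prob, k = 2)
  expect_equal(sort(mds$points[, 1]), c(-1, 0, 1), tolerance = 1e-8)
  expect_equal(unname(mds$points[, 2]), rep(0, 3), tolerance = 1e-6)
  # sign convention: correlation with the input column is positive
  expect_gt(cor(prob[, 1], mds$points[, 1]), 0)

  # points already in 2-D are recovered up to rotation: distances match
  set.seed(5)
  xy <- matrix(rnorm(20), 10, 2)
  mds2 <- classical_mds(xy, k = 2)
  expect_equal(as.numeric(dist(mds2$points)), as.numeric(dist(xy)),
               tolerance = 1e-8)
  expect_gt(mds2$goodness_of_fit, 0.999)
  expect_true(all(diff(mds2$eigenvalues) <= 1e-8))
  # genuinely non-Euclidean request fails
  expect_error(classical_mds(matrix(c(0, 1), 2, 1), k = 3), "subjects")
})

test_that("dimension ANOVA matches the two-group t identity and detects separation", {
  set.seed(6)
  pts <- matrix(c(rnorm(20, 0), rnorm(20, 0.7)), ncol = 1)
  lab <- rep(c("a", "b"), each = 20)
  an <- dimension_anova(pts, lab)
  tt <- t.test(pts[lab == "a"], pts[lab == "b"], var.equal = TRUE)
  expect_equal(an$F[1], unname(tt$statistic)^2, tolerance = 1e-10)

  pts3 <- cbind(c(rnorm(20, -1, 0.1), rnorm(20, 0, 0.1), rnorm(20, 1, 0.1)))
  lab3 <- rep(c("a", "b", "c"), each = 20)
  an3 <- dimension_anova(pts3, lab3)
  expect_lt(an3$p[1], 1e-3)
  expect_equal(an3$df1[1], 2)
  expect_error(dimension_anova(pts3, rep(c("a", "b", "c"),
                                         times = c(59, 1, 0))), "at least 2")
})
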