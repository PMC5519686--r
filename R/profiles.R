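#' Reading-disability classification rule set
#'
#' Percentile thresholds of the expert rules. "Typically" clauses are
#' implemented strictly for determinism; the consistency of Word
#' Identification / Passage Comprehension with Word Attack is read as
#' "within `consistency_pts` standard-score points of Word Attack, or at
#' or below the 25th percentile".
#'
#' @param verbal_min Verbal Comprehension percentile floor for decoders and
#'   comprehenders.
#' @param word_attack_max Word Attack percentile ceiling for Poor Decoders.
#' @param above_wa Word Attack percentile floor for Poor Comprehenders.
#' @param pc_wid_max Word Id / Passage Comprehension ceiling ("at or
#'   below") for Poor Comprehenders.
#' @param ran_pd_max RAN percentile ceiling for Poor Decoders.
#' @param ran_pc_min RAN percentile floor for Poor Comprehenders.
#' @param poorreader_max percentile ceiling ("at or below") for Generally
#'   Poor Readers.
#' @param pc_min_age minimum age (years) for the Poor Comprehender profile.
#' @param consistency_pts standard-score tolerance for the consistency
#'   clause.
#' @return An object of class `rule_set`.
#' @export
rule_set <- function(verbal_min = 25, word_attack_max = 25, above_wa = 25,
                     pc_wid_max = 25, ran_pd_max = 25, ran_pc_min = 16,
                     poorreader_max = 25, pc_min_age = 8,
                     consistency_pts = 10) {
  th <- c(verbal_min, word_attack_max, above_wa, pc_wid_max, ran_pd_max,
          ran_pc_min, poorreader_max)
  if (any(th <= 0 | th >= 100)) stopf("thresholds must lie in (0, 100)")
  structure(list(verbal_min = verbal_min, word_attack_max = word_attack_max,
                 above_wa = above_wa, pc_wid_max = pc_wid_max,
                 ran_pd_max = ran_pd_max, ran_pc_min = ran_pc_min,
                 poorreader_max = poorreader_max, pc_min_age = pc_min_age,
                 consistency_pts = consistency_pts),
            class = "rule_set")
}

profile_levels <- c("Control", "PoorDecoder", "PoorComprehender",
                    "GenerallyPoorReader", "Unclassifiable")

#' Classify subjects with the expert rule set
#'
#' Deterministic application of the profile rules on the percentile scale
#' (scores are converted from the standard-score scale first):
#' Control if Word Attack, Word Identification and Passage Comprehension
#' are all above the 25th percentile; Generally Poor Reader if Verbal
#' Comprehension and all three reading scores are at or below the 25th;
#' Poor Decoder if Verbal Comprehension is above the 25th, Word Attack
#' below the 25th with consistent Word Id / Passage Comprehension, and RAN
#' below the 25th; Poor Comprehender if Verbal Comprehension and Word
#' Attack are above the 25th, Word Id or Passage Comprehension at or below
#' the 25th, RAN above the 16th, and age above `pc_min_age`; otherwise
#' Unclassifiable.
#'
#' @param subjects data frame with the six score columns and age (a single
#'   row is fine).
#' @param rules a [rule_set()].
#' @return Character vector of profile labels.
#' @export
classify_expert_rules <- function(subjects, rules = rule_set()) {
  need <- c("word_attack", "word_id", "passage_comp", "verbal_comp", "ran",
            "age")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (any(!complete.cases(subjects[need]))) stopf("missing score or age values")
  pct <- function(x) standard_to_percentile(x)
  wa <- pct(subjects$word_attack)
  wid <- pct(subjects$word_id)
  pc <- pct(subjects$passage_comp)
  vc <- pct(subjects$verbal_comp)
  ran <- pct(subjects$ran)
  age <- subjects$age

  control <- wa > 25 & wid > 25 & pc > 25
  gpr <- vc <= rules$poorreader_max & wa <= rules$poorreader_max &
    wid <= rules$poorreader_max & pc <= rules$poorreader_max
  consistent <- function(score_std, wa_std) {
    abs(score_std - wa_std) <= rules$consistency_pts |
      standard_to_percentile(score_std) <= rules$word_attack_max
  }
  pd <- vc > rules$verbal_min & wa < rules$word_attack_max &
    consistent(subjects$word_id, subjects$word_attack) &
    consistent(subjects$passage_comp, subjects$word_attack) &
    ran < rules$ran_pd_max
  pcomp <- vc > rules$verbal_min & wa > rules$above_wa &
    (wid <= rules$pc_wid_max | pc <= rules$pc_wid_max) &
    ran > rules$ran_pc_min & age > rules$pc_min_age

  out <- rep("Unclassifiable", nrow(subjects))
  out[pcomp] <- "PoorComprehender"
  out[pd] <- "PoorDecoder"
  out[gpr] <- "GenerallyPoorReader"
  out[control] <- "Control"
  out
}

ensemble_features <- c("word_attack", "word_id", "passage_comp",
                       "verbal_comp", "ran", "age")

#' Ensemble classification with leave-one-out cross-validation
#'
#' For each subject, a bagged ensemble of `ntree` decision trees with
#' `mtry` candidate features per split is trained on all other subjects
#' and predicts the held-out subject's class; accuracy is the fraction of
#' predictions matching the expert labels, and the probability matrix
#' holds the out-of-fold vote fractions (rows sum to 1).
#'
#' @param subjects cohort data frame; the features are the five behavioral
#'   scores plus age.
#' @param labels character vector of expert labels.
#' @param ntree number of trees.
#' @param mtry candidate features per split.
#' @param seed RNG seed for the ensemble.
#' @return List with `predicted`, `accuracy`, `probabilities` (subjects x
#'   classes) and `classes`.
#' @export
classify_ensemble_loocv <- function(subjects, labels, ntree = 500, mtry = 2,
                                    seed = 1L) {
  cls <- sort(unique(labels))
  if (length(cls) < 2) stopf("need at least 2 classes")
  if (any(table(labels) < 2))
    warnf("a class has a single member; its LOOCV fold lacks that class")
  X <- as.matrix(subjects[, ensemble_features])
  y <- match(labels, cls) - 1L
  res <- rf_loocv_cpp(X, y, length(cls), as.integer(ntree), as.integer(mtry),
                      1L, as.integer(seed))
  votes <- res$votes
  colnames(votes) <- cls
  rownames(votes) <- subjects$subject_id
  predicted <- cls[res$pred + 1L]
  list(predicted = predicted,
       accuracy = mean(predicted == labels),
       probabilities = votes,
       classes = cls)
}

#' Permutation variable importance
#'
#' Trains one ensemble on the full data and reports, per feature, the mean
#' decrease in out-of-bag accuracy when that feature's values are shuffled
#' (averaged over trees and `nrep` shuffles), in percentage points.
#'
#' @inheritParams classify_ensemble_loocv
#' @param nrep shuffles per tree and feature.
#' @return Named numeric vector of accuracy decreases (percentage points),
#'   with the ensemble's OOB accuracy as attribute `oob_accuracy`.
#' @export
variable_importance <- function(subjects, labels, ntree = 500, mtry = 2,
                                seed = 1L, nrep = 3) {
  cls <- sort(unique(labels))
  X <- as.matrix(subjects[, ensemble_features])
  y <- match(labels, cls) - 1L
  res <- rf_importance_cpp(X, y, length(cls), as.integer(ntree),
                           as.integer(mtry), 1L, as.integer(seed),
                           as.integer(nrep))
  imp <- setNames(as.numeric(res$importance), ensemble_features)
  attr(imp, "oob_accuracy") <- res$oob_accuracy
  imp
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(var(columns)) / var(row sums))` for a
#' subjects x raters (or occasions) matrix of numeric codes.
#'
#' @param ratings numeric matrix, one column per rater/occasion.
#' @return List with `alpha`, `n_items` (subjects) and `n_raters`.
#' @export
cronbach_alpha <- function(ratings) {
  ratings <- as.matrix(ratings)
  k <- ncol(ratings)
  if (k < 2) stopf("need at least 2 columns")
  total_var <- var(rowSums(ratings))
  if (total_var <= 0) stopf("zero total variance; alpha undefined")
  alpha <- k / (k - 1) * (1 - sum(apply(ratings, 2, var)) / total_var)
  list(alpha = alpha, n_items = nrow(ratings), n_raters = k)
}

#' Classical multidimensional scaling of class probabilities
#'
#' Pairwise Euclidean distances between probability rows are double
#' centered (-D^2/2) and eigendecomposed; the top-`k` eigenvectors scaled
#' by the square root of their eigenvalues give the coordinates. The
#' goodness of fit is the retained share `(lambda_1 + ... + lambda_k) /
#' sum(|lambda_i|)`. Axis signs are fixed by making each dimension's
#' correlation with its highest-loading input column positive.
#'
#' @param prob probability matrix (subjects x classes) or any numeric
#'   matrix of row features.
#' @param k number of dimensions.
#' @return List with `points` (n x k), `eigenvalues`, `goodness_of_fit`.
#' @export
classical_mds <- function(prob, k = 2) {
  prob <- as.matrix(prob)
  n <- nrow(prob)
  if (n < k + 1) stopf("need at least k + 1 subjects")
  d2 <- as.matrix(dist(prob))^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  # near-zero eigenvalues are acceptable (they contribute zero
  # coordinates); genuinely negative ones inside the first k are not
  tol <- 1e-8 * max(abs(eg$values), 1e-300)
  if (eg$values[k] < -tol) stopf("fewer than k positive eigenvalues")
  pts <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  for (j in seq_len(k)) {
    cors <- suppressWarnings(cor(prob, pts[, j]))
    cors[!is.finite(cors)] <- 0
    lead <- which.max(abs(cors))
    if (cors[lead] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(prob)
  colnames(pts) <- paste0("Dim", seq_len(k))
  gof <- sum(eg$values[seq_len(k)]) / sum(abs(eg$values))
  list(points = pts, eigenvalues = eg$values, goodness_of_fit = gof)
}

#' Per-dimension ANOVA over profile groups
#'
#' One-way ANOVA of each embedding dimension over the group labels, with
#' Tukey HSD post-hoc pairwise comparisons.
#'
#' @param dims result of [classical_mds()] or an n x k coordinate matrix.
#' @param labels group labels (e.g., the three reading-disability
#'   profiles).
#' @return Data frame with one row per dimension (`F`, `df1`, `df2`, `p`)
#'   and attribute `posthoc`, a list of Tukey HSD tables.
#' @export
dimension_anova <- function(dims, labels) {
  pts <- if (is.list(dims) && !is.null(dims$points)) dims$points else as.matrix(dims)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stopf("need at least 2 groups")
  if (any(table(labels) < 2)) stopf("each group needs at least 2 members")
  out <- NULL
  posthoc <- list()
  for (j in seq_len(ncol(pts))) {
    fit <- aov(pts[, j] ~ labels)
    a <- anova(fit)
    out <- rbind(out, data.frame(dimension = colnames(pts)[j] %||% j,
                                 F = a$`F value`[1], df1 = a$Df[1],
                                 df2 = a$Df[2], p = a$`Pr(>F)`[1]))
    posthoc[[j]] <- TukeyHSD(fit)$labels
  }
  attr(out, "posthoc") <- posthoc
  out
}
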