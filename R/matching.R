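#' Coarsened stratification by site and brain size
#'
#' Within each research site, subjects are split at the site-wise
#' brain-size quantile (default the median) into smaller/larger bins;
#' site x bin cells are the strata. Strata lacking either a case or a
#' control are dropped. Control match-quality weights follow the coarsened
#' exact matching convention
#' `(stratum controls / stratum cases) * (total cases / total controls)`
#' over the retained strata; cases have weight 1.
#'
#' @param subjects cohort data frame with `site`, `brain_size`, `is_case`.
#' @param split_q quantile for the size split.
#' @return Data frame of strata (`stratum`, `site`, `bin`, `cem_weight`,
#'   counts) with attribute `assignment`: per-subject stratum labels (NA
#'   for subjects in dropped strata).
#' @export
stratify <- function(subjects, split_q = 0.5) {
  if (nrow(subjects) < 2) stopf("no valid strata from fewer than 2 subjects")
  bin <- rep(NA_character_, nrow(subjects))
  for (s in unique(subjects$site)) {
    i <- subjects$site == s
    med <- quantile(subjects$brain_size[i], split_q, names = FALSE)
    bin[i] <- ifelse(subjects$brain_size[i] <= med, "smaller", "larger")
  }
  stratum <- paste0("site", subjects$site, "_", bin)
  tab <- data.frame(stratum = stratum, is_case = subjects$is_case)
  agg <- do.call(rbind, lapply(split(tab, tab$stratum), function(d) {
    data.frame(stratum = d$stratum[1], n_cases = sum(d$is_case),
               n_controls = sum(!d$is_case))
  }))
  keep <- agg$n_cases > 0 & agg$n_controls > 0
  if (!any(keep)) stopf("no stratum contains both a case and a control")
  agg <- agg[keep, , drop = FALSE]
  assignment <- ifelse(stratum %in% agg$stratum, stratum, NA_character_)
  total_cases <- sum(subjects$is_case[!is.na(assignment)])
  total_controls <- sum(!subjects$is_case[!is.na(assignment)])
  agg$cem_weight <- (agg$n_controls / agg$n_cases) *
    (total_cases / total_controls)
  agg$site <- as.integer(sub("^site(\\d+)_.*$", "\\1", agg$stratum))
  agg$bin <- sub("^site\\d+_", "", agg$stratum)
  rownames(agg) <- NULL
  attr(agg, "assignment") <- assignment
  agg
}

#' Propensity model for case status
#'
#' Maximum-likelihood logistic regression of case status on research site
#' (factor) and total brain size. If the fit separates perfectly the model
#' is re-estimated with a small ridge penalty and flagged.
#'
#' @param subjects cohort data frame.
#' @return List with `coefficients`, per-subject `scores` (clamped to the
#'   open unit interval), and `separation` flag.
#' @export
fit_propensity <- function(subjects) {
  if (length(unique(subjects$is_case)) < 2) stopf("both classes required")
  df <- data.frame(y = as.numeric(subjects$is_case),
                   site = factor(subjects$site),
                   brain_size = subjects$brain_size)
  form <- if (nlevels(df$site) > 1) y ~ site + brain_size else y ~ brain_size
  fit <- suppressWarnings(glm(form, family = binomial(), data = df))
  p <- fitted(fit)
  sep <- !fit$converged || any(p < 1e-8 | p > 1 - 1e-8)
  coefs <- coef(fit)
  if (sep) {
    ridge <- ridge_logistic(stats::model.matrix(form, df), df$y, lambda = 1e-2)
    p <- ridge$p
    coefs <- ridge$beta
    warnf("perfect separation in propensity model; using ridge-penalized fit")
  }
  eps <- 1e-6
  scores <- pmin(1 - eps, pmax(eps, p))
  list(coefficients = coefs, scores = setNames(scores, subjects$subject_id),
       separation = sep)
}

# IRLS ridge-penalized logistic regression (intercept unpenalized)
ridge_logistic <- function(X, y, lambda = 1e-2, iter = 50) {
  beta <- rep(0, ncol(X))
  pen <- diag(rep(lambda, ncol(X)))
  pen[1, 1] <- 0
  for (it in seq_len(iter)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    H <- crossprod(X, X * W) + pen
    g <- crossprod(X, y - p) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- as.numeric(X %*% beta)
  list(beta = setNames(as.numeric(beta), colnames(X)),
       p = 1 / (1 + exp(-eta)))
}

#' Greedy nearest-neighbor pairing within strata
#'
#' Within each retained stratum, cases are processed in deterministic
#' order (descending distance of their propensity score from the stratum
#' mean, ties broken by id) and each takes the unused control minimizing
#' `w_ps * |dPS| / sd(PS) + w_bs * |dBS| / sd(BS)`, scaled by the
#' stratum's match-quality weight (constant within a stratum, so pairing
#' is unaffected; it is recorded in the reported distance). Every subject
#' appears in at most one pair; leftover subjects are reported unmatched.
#'
#' @param strata result of [stratify()].
#' @param model result of [fit_propensity()].
#' @param subjects cohort data frame.
#' @param w_ps,w_bs distance weights for the standardized propensity and
#'   brain-size gaps.
#' @param method `"greedy"` (deterministic, as described) or `"optimal"`
#'   (minimum total distance per stratum, for comparison).
#' @return An object of class `matched_pair_set`: list with `pairs` (data
#'   frame `case_id`, `control_id`, `stratum`, `distance`) and `unmatched`.
#' @export
pair_nearest <- function(strata, model, subjects, w_ps = 1, w_bs = 1,
                         method = c("greedy", "optimal")) {
  method <- match.arg(method)
  assignment <- attr(strata, "assignment")
  ps <- model$scores[subjects$subject_id]
  sd_ps <- sd(ps[!is.na(assignment)])
  sd_bs <- sd(subjects$brain_size[!is.na(assignment)])
  if (!is.finite(sd_ps) || sd_ps == 0) sd_ps <- 1
  if (!is.finite(sd_bs) || sd_bs == 0) sd_bs <- 1
  pairs <- NULL
  matched <- character(0)
  for (r in seq_len(nrow(strata))) {
    st <- strata$stratum[r]
    idx <- which(!is.na(assignment) & assignment == st)
    cases <- idx[subjects$is_case[idx]]
    controls <- idx[!subjects$is_case[idx]]
    dist_fun <- function(ci, ki) {
      (w_ps * abs(ps[ci] - ps[ki]) / sd_ps +
         w_bs * abs(subjects$brain_size[ci] - subjects$brain_size[ki]) / sd_bs) *
        strata$cem_weight[r]
    }
    if (method == "greedy") {
      mu <- mean(ps[idx])
      ord <- cases[order(-abs(ps[cases] - mu), subjects$subject_id[cases])]
      used <- logical(length(controls))
      for (ci in ord) {
        avail <- which(!used)
        if (!length(avail)) break
        d <- vapply(controls[avail], function(ki) dist_fun(ci, ki), 0)
        pick <- avail[order(d, subjects$subject_id[controls[avail]])[1]]
        used[pick] <- TRUE
        pairs <- rbind(pairs, data.frame(
          case_id = subjects$subject_id[ci],
          control_id = subjects$subject_id[controls[pick]],
          stratum = st, distance = min(d), stringsAsFactors = FALSE))
      }
    } else {
      D <- outer(cases, controls, Vectorize(dist_fun))
      sol <- optimal_assignment(D)
      for (k in seq_along(sol$rows)) {
        ci <- cases[sol$rows[k]]
        ki <- controls[sol$cols[k]]
        pairs <- rbind(pairs, data.frame(
          case_id = subjects$subject_id[ci],
          control_id = subjects$subject_id[ki],
          stratum = st, distance = D[sol$rows[k], sol$cols[k]],
          stringsAsFactors = FALSE))
      }
    }
  }
  matched <- c(pairs$case_id, pairs$control_id)
  unmatched <- setdiff(subjects$subject_id, matched)
  structure(list(pairs = pairs, unmatched = unmatched),
            class = "matched_pair_set")
}

# branch-and-bound minimum-cost assignment over min(nr, nc) pairs
optimal_assignment <- function(D) {
  nr <- nrow(D); nc <- ncol(D)
  transposed <- FALSE
  if (nr > nc) { D <- t(D); tmp <- nr; nr <- nc; nc <- tmp; transposed <- TRUE }
  best <- list(cost = Inf, cols = integer(0))
  lb_row <- vapply(seq_len(nr), function(i) min(D[i, ]), 0)
  rec <- function(i, used, cost, cols) {
    if (cost + sum(lb_row[seq_len(nr) >= i]) >= best$cost) return()
    if (i > nr) { best <<- list(cost = cost, cols = cols); return() }
    ord <- order(D[i, ])
    for (j in ord) {
      if (used[j]) next
      used[j] <- TRUE
      rec(i + 1, used, cost + D[i, j], c(cols, j))
      used[j] <- FALSE
    }
  }
  rec(1, logical(nc), 0, integer(0))
  rows <- seq_len(nr)
  if (transposed) list(rows = best$cols, cols = rows) else
    list(rows = rows, cols = best$cols)
}

#' Uniform random case-control pairing
#'
#' Pairs cases with controls uniformly at random, ignoring site and brain
#' size; the larger group is truncated at random to equalize counts.
#'
#' @param subjects cohort data frame.
#' @param seed RNG seed.
#' @return A `matched_pair_set`.
#' @export
random_pairing <- function(subjects, seed = 1L) {
  cases <- subjects$subject_id[subjects$is_case]
  controls <- subjects$subject_id[!subjects$is_case]
  if (!length(cases) || !length(controls)) stopf("need both cases and controls")
  with_seed(seed, {
    n <- min(length(cases), length(controls))
    cs <- if (length(cases) > n) sample(cases, n) else cases
    ks <- if (length(controls) > n) sample(controls, n) else controls
    ks <- sample(ks, n)
    pairs <- data.frame(case_id = cs, control_id = ks, stratum = NA_character_,
                        distance = NA_real_, stringsAsFactors = FALSE)
    structure(list(pairs = pairs,
                   unmatched = setdiff(subjects$subject_id,
                                       c(cs, ks))),
              class = "matched_pair_set")
  })
}

#' Balance diagnostics for a matched pair set
#'
#' Paired t-tests on age and tissue volumes, a Yates-corrected 2x2
#' chi-square for sex by group, a pooled-variance unpaired t on the
#' propensity score, and a one-way ANOVA of case-control propensity
#' differences across the case profiles.
#'
#' @param pairs a `matched_pair_set`.
#' @param subjects cohort data frame.
#' @param model optional [fit_propensity()] result; refit when omitted.
#' @param profiles optional per-subject profile labels (defaults to
#'   `true_profile` when present).
#' @return Data frame with one row per test (`variable`, `test`,
#'   `statistic`, `df`, `p`).
#' @export
balance_diagnostics <- function(pairs, subjects, model = NULL,
                                profiles = NULL) {
  pt <- pairs$pairs
  if (nrow(pt) < 2) stopf("need at least 2 pairs")
  rownames(subjects) <- subjects$subject_id
  ci <- subjects[pt$case_id, ]
  ki <- subjects[pt$control_id, ]
  out <- NULL
  for (v in c("age", "gm_volume", "wm_volume", "brain_size")) {
    d <- ci[[v]] - ki[[v]]
    if (all(abs(d) < 1e-12)) {
      out <- rbind(out, data.frame(variable = v, test = "paired_t",
                                   statistic = 0, df = length(d) - 1, p = 1))
    } else {
      tt <- t.test(d)
      out <- rbind(out, data.frame(variable = v, test = "paired_t",
                                   statistic = unname(tt$statistic),
                                   df = unname(tt$parameter),
                                   p = tt$p.value))
    }
  }
  sex_tab <- rbind(case = table(factor(ci$sex, c("F", "M"))),
                   control = table(factor(ki$sex, c("F", "M"))))
  cs <- suppressWarnings(chisq.test(sex_tab, correct = TRUE))
  out <- rbind(out, data.frame(variable = "sex", test = "chisq_yates",
                               statistic = unname(cs$statistic),
                               df = unname(cs$parameter), p = cs$p.value))
  if (is.null(model)) model <- fit_propensity(subjects)
  ps <- model$scores
  if (sd(c(ps[pt$case_id], ps[pt$control_id])) < 1e-12) {
    out <- rbind(out, data.frame(variable = "propensity", test = "unpaired_t",
                                 statistic = 0, df = 2 * nrow(pt) - 2, p = 1))
  } else {
    tt <- t.test(ps[pt$case_id], ps[pt$control_id], var.equal = TRUE)
    out <- rbind(out, data.frame(variable = "propensity", test = "unpaired_t",
                                 statistic = unname(tt$statistic),
                                 df = unname(tt$parameter), p = tt$p.value))
  }
  if (is.null(profiles) && !is.null(subjects$true_profile))
    profiles <- setNames(subjects$true_profile, subjects$subject_id)
  if (!is.null(profiles)) {
    pd <- ps[pt$case_id] - ps[pt$control_id]
    grp <- factor(profiles[pt$case_id])
    if (nlevels(droplevels(grp)) >= 2) {
      a <- anova(aov(pd ~ droplevels(grp)))
      out <- rbind(out, data.frame(variable = "propensity_diff_by_profile",
                                   test = "anova_F",
                                   statistic = a$`F value`[1],
                                   df = a$Df[1], p = a$`Pr(>F)`[1]))
    }
  }
  rownames(out) <- NULL
  out
}
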