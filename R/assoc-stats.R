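# Statistical layer: exact Mann-Whitney tail probabilities, 2x2 tests,
# Spearman correlation, Kaplan-Meier / log-rank / Cox survival analysis,
# shadow-feature (Boruta-style) importance, and ROC discrimination.

#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Counts, for each u in 0..n1*n2, the number of labelings of n1+n2
#' distinct values with U = u. Computed by the Gaussian-binomial
#' polynomial recurrence (multiply by 1-q^(n2+k), divide by 1-q^k for
#' k = 1..n1), algebraically identical to the counting recurrence
#' N(u; n1, n2) = N(u; n1-1, n2) + N(u-n2; n1, n2-1). All counts are
#' bounded by choose(n1+n2, n1) and stay exact in double precision for
#' cohort-scale group sizes.
#'
#' @param n1,n2 Group sizes.
#' @return Numeric vector of counts, index u+1 holding N(u).
#' @export
mann_whitney_counts <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  U <- n1 * n2
  cf <- numeric(U + 1)
  cf[1] <- 1
  for (k in seq_len(n1)) {
    d <- n2 + k
    if (d <= U) {
      cf[(d + 1):(U + 1)] <- cf[(d + 1):(U + 1)] - cf[1:(U + 1 - d)]
    }
    if (k <= U) {
      for (u in k:U) cf[u + 1] <- cf[u + 1] + cf[u + 1 - k]
    }
  }
  cf
}

#' Exact two-sided Mann-Whitney tail probability
#'
#' For an observed integer U with no ties: lower tail = P(U' <= u), upper
#' tail = P(U' >= u) under the exact null distribution; two-sided p is
#' 2 * min(lower, upper), capped at 1.
#'
#' @param n1,n2 Group sizes.
#' @param u Observed U statistic, integer in `[0, n1*n2]`.
#' @return list classed `rank_sum_result` with `u_statistic`,
#'   `p_two_sided`, `p_lower`, `p_upper`, `method = "exact"`.
#' @export
mann_whitney_exact <- function(n1, n2, u) {
  if (u < 0 || u > n1 * n2) {
    stop("u must lie in [0, n1*n2]", call. = FALSE)
  }
  if (u != round(u)) {
    stop("exact mode requires an integer U (no ties)", call. = FALSE)
  }
  counts <- mann_whitney_counts(n1, n2)
  total <- choose(n1 + n2, n1)
  lower <- sum(counts[seq_len(u + 1)]) / total
  upper <- sum(counts[(u + 1):length(counts)]) / total
  structure(list(u_statistic = u,
                 p_two_sided = min(1, 2 * min(lower, upper)),
                 p_lower = lower, p_upper = upper,
                 n1 = n1, n2 = n2, method = "exact"),
            class = "rank_sum_result")
}

#' Mann-Whitney test from two samples
#'
#' Mid-rank U statistic oriented to the smaller group (first group on a
#' size tie). Exact p when the data carry no ties and `n1*n2` is at most
#' `exact_cap`; otherwise the normal approximation with tie-corrected
#' variance and a 0.5 continuity correction.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_cap Largest `n1*n2` for which the exact distribution is
#'   enumerated.
#' @return `rank_sum_result` list; `method` records which path was used.
#' @export
mann_whitney_from_samples <- function(x, y, exact_cap = 10000) {
  if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_y <- n1 * n2 - u_x
  # orient U to the smaller group (x on ties)
  if (n1 <= n2) { u <- u_x; m1 <- n1; m2 <- n2 }
  else { u <- u_y; m1 <- n2; m2 <- n1 }
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && n1 * n2 <= exact_cap) {
    res <- mann_whitney_exact(m1, m2, u)
    res$u_statistic <- u
    return(res)
  }
  N <- n1 + n2
  mu <- m1 * m2 / 2
  tie_tab <- table(c(x, y))
  sigma2 <- m1 * m2 / 12 *
    ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  structure(list(u_statistic = u,
                 p_two_sided = min(1, 2 * stats::pnorm(-abs(z))),
                 p_lower = stats::pnorm(z), p_upper = stats::pnorm(-z),
                 n1 = m1, n2 = m2, method = "normal-approximation"),
            class = "rank_sum_result")
}

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != floor(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  tab
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson statistic (no Yates continuity correction) at
#' 1 degree of freedom -- the plain likelihood-theory statistic,
#' equal to `N*(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with `statistic`, `p_value`, `df = 1`, `expected`.
#' @export
pearson_chi2_2x2 <- function(tab) {
  tab <- check_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square requires positive margins", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = 1L, expected = ct$expected)
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p by hypergeometric summation over tables as or more
#' extreme; defined even with a zero margin.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- check_2x2(tab)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

# all permutations of 1..n (n small), one per row
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[i, ], n, after = pos - 1)
      row <- row + 1L
    }
  }
  out
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of mid-ranks. Two-sided p by exhaustive
#' permutation enumeration for n at most 9; t-approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return list with `rho`, `p_value`, `method`; `NA` sentinels when
#'   either input is constant.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_,
                method = "undefined-constant-input"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    return(list(rho = rho, p_value = p, method = "exact-permutation"))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), df = n - 2),
       method = "t-approximation")
}

matching_bins <- function() c("0", "1-2", "3-6", ">6")

#' Stratum label for a tissue-matching plasma variant count
#'
#' 0 -> "0"; 1-2 -> "1-2"; 3-6 -> "3-6" (6 inclusive); 7+ -> ">6".
#'
#' @param k Non-negative integer count(s).
#' @return Factor over the ordered levels `0, 1-2, 3-6, >6`.
#' @export
bin_matching_count <- function(k) {
  if (any(is.na(k)) || any(k < 0) || any(k != floor(k))) {
    stop("matching counts must be non-negative integers", call. = FALSE)
  }
  lab <- ifelse(k == 0, "0",
         ifelse(k <= 2, "1-2",
         ifelse(k <= 6, "3-6", ">6")))
  factor(lab, levels = matching_bins())
}

#' Kaplan-Meier estimator with the explicit median rule
#'
#' Product-limit estimate of the survival curve; the reported median is
#' the smallest observed time at which the estimate drops to 0.5 or
#' below (an `NA` sentinel when the curve never reaches 0.5).
#'
#' @param times Non-negative follow-up times.
#' @param events Logical event indicators (TRUE = death observed).
#' @return list with `curve` (time, n_risk, n_event, surv), `median`, and
#'   the underlying `survfit` object.
#' @export
km_estimator <- function(times, events) {
  stopifnot(all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  at_or_below <- curve$time[curve$surv <= 0.5]
  med <- if (length(at_or_below)) min(at_or_below) else NA_real_
  list(curve = curve, median = med, fit = fit)
}

#' k-sample log-rank test
#'
#' @param times,events As in [km_estimator()].
#' @param group Stratum labels (factor or character).
#' @return list with `statistic` (chi-square), `df = k-1`, `p_value`, and
#'   per-stratum medians by the [km_estimator()] rule.
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  k <- length(sd$n)
  medians <- vapply(levels(group), function(g) {
    km_estimator(times[group == g], events[group == g])$median
  }, numeric(1))
  list(statistic = sd$chisq, df = k - 1L,
       p_value = stats::pchisq(sd$chisq, df = k - 1, lower.tail = FALSE),
       medians = medians)
}

#' Cox proportional hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; Wald p-values per
#' coefficient, with Holm-adjusted values reported alongside.
#'
#' @param times,events As in [km_estimator()].
#' @param covariates data.frame of covariates (no constant column).
#' @return data.frame with `term`, `coef`, `se`, `z`, `p_wald`, `p_holm`.
#' @export
cox_ph <- function(times, events, covariates) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(times))
  num <- covariates[vapply(covariates, is.numeric, logical(1))]
  if (length(num) && any(vapply(num, function(x) stats::sd(x) == 0,
                                logical(1)))) {
    stop("constant covariate column", call. = FALSE)
  }
  if (length(unique(times[as.logical(events)])) < 2) {
    stop("need at least 2 distinct event times", call. = FALSE)
  }
  dat <- cbind(data.frame(.time = times, .event = as.logical(events)),
               covariates)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                         ties = "efron")
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design (collinear covariates): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  s <- summary(fit)$coefficients
  out <- data.frame(term = rownames(s), coef = s[, "coef"],
                    se = s[, "se(coef)"], z = s[, "z"],
                    p_wald = s[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  out$p_holm <- stats::p.adjust(out$p_wald, method = "holm")
  rownames(out) <- NULL
  out
}

#' Shadow-feature importance (Boruta algorithm)
#'
#' Each iteration appends a permuted "shadow" copy of every feature, fits
#' a random forest with permutation importance, and scores a hit for a
#' feature whose importance exceeds the maximum shadow importance.
#' Final decisions come from two-sided binomial tests on the hit counts
#' with Holm step-down correction: confirmed / rejected / tentative.
#'
#' @param features data.frame of numeric predictors.
#' @param labels Two-class outcome (factor or coercible).
#' @param n_iterations Number of forest iterations (>= 20).
#' @param alpha Decision level after correction.
#' @param ntree Trees per forest.
#' @return data.frame with `feature`, `hits`, `n_iterations`, `decision`.
#' @export
shadow_importance <- function(features, labels, n_iterations = 100,
                              alpha = 0.05, ntree = 100) {
  if (n_iterations < 20) {
    stop("n_iterations must be at least 20", call. = FALSE)
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes", call. = FALSE)
  stopifnot(is.data.frame(features), nrow(features) == length(labels))
  constant <- vapply(features, function(x) stats::sd(as.numeric(x)) == 0,
                     logical(1))
  active <- features[!constant]
  hits <- stats::setNames(integer(ncol(active)), names(active))
  if (ncol(active)) {
    for (it in seq_len(n_iterations)) {
      shadows <- as.data.frame(lapply(active, sample))
      names(shadows) <- paste0("shadow_", names(active))
      rf <- randomForest::randomForest(
        x = cbind(active, shadows), y = labels,
        ntree = ntree, importance = TRUE)
      imp <- randomForest::importance(rf, type = 1)[, 1]
      max_shadow <- max(imp[paste0("shadow_", names(active))])
      winners <- imp[names(active)] > max_shadow
      hits[winners] <- hits[winners] + 1L
    }
  }
  p_conf <- stats::p.adjust(
    stats::pbinom(hits - 1, n_iterations, 0.5, lower.tail = FALSE),
    method = "holm")
  p_rej <- stats::p.adjust(
    stats::pbinom(hits, n_iterations, 0.5), method = "holm")
  decision <- ifelse(p_conf < alpha, "confirmed",
              ifelse(p_rej < alpha, "rejected", "tentative"))
  out <- data.frame(feature = names(features),
                    hits = NA_integer_,
                    n_iterations = n_iterations,
                    decision = "rejected",
                    stringsAsFactors = FALSE)
  out$hits[match(names(hits), out$feature)] <- hits
  out$decision[match(names(hits), out$feature)] <- decision
  out
}

#' Area under the ROC curve by the rank statistic
#'
#' AUC = U / (n1 * n0) via mid-ranks (the Mann-Whitney identity); tied
#' scores receive 0.5 credit.
#'
#' @param scores Numeric scores, larger = more positive-like.
#' @param labels Two-class labels; the second factor level (or TRUE / the
#'   larger value) is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as.logical(if (is.factor(labels)) labels == levels(labels)[2]
                    else if (is.logical(labels)) labels
                    else labels == max(labels))
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("need both classes present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated discrimination of a two-class outcome
#'
#' Fits the configured classifier (random forest by default, logistic
#' regression as the alternative) under leave-one-out cross-validation --
#' appropriate at cohort size -- and reports the AUC of the out-of-fold
#' class probabilities.
#'
#' @param features data.frame of numeric predictors.
#' @param labels Two-class outcome (e.g. M0/M1).
#' @param method `"rf"` or `"logistic"`.
#' @param ntree Trees per forest (rf only).
#' @param importance Optional [shadow_importance()] result to attach.
#' @return list classed `discrimination_result` with `auc`, `scheme`,
#'   `method`, `features`, `oof_probs`, `importance`.
#' @export
discriminate <- function(features, labels, method = c("rf", "logistic"),
                         ntree = 500, importance = NULL) {
  method <- match.arg(method)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need a two-class outcome", call. = FALSE)
  stopifnot(is.data.frame(features), nrow(features) == length(labels))
  n <- length(labels)
  probs <- numeric(n)
  pos_level <- levels(labels)[2]
  for (i in seq_len(n)) {
    tr_x <- features[-i, , drop = FALSE]; tr_y <- labels[-i]
    te_x <- features[i, , drop = FALSE]
    if (method == "rf") {
      fit <- randomForest::randomForest(x = tr_x, y = tr_y, ntree = ntree)
      probs[i] <- stats::predict(fit, te_x, type = "prob")[, pos_level]
    } else {
      dat <- cbind(data.frame(.y = as.integer(tr_y == pos_level)), tr_x)
      fit <- suppressWarnings(
        stats::glm(.y ~ ., family = stats::binomial(), data = dat))
      probs[i] <- stats::predict(fit, te_x, type = "response")
    }
  }
  structure(list(auc = roc_auc(probs, labels),
                 scheme = "leave-one-out", method = method,
                 features = names(features), oof_probs = probs,
                 importance = importance),
            class = "discrimination_result")
}
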