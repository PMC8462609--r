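# The statistical layer: exact rank-sum distribution, 2x2 tests,
# Spearman correlation, survival estimation, Cox regression, shadow
# importance, and ROC identities.

test_that("exact U-distribution equals exhaustive enumeration (small n)", {
  for (sz in list(c(2, 3), c(3, 3), c(4, 4), c(5, 5), c(4, 6))) {
    expect_equal(mann_whitney_counts(sz[1], sz[2]),
                 enumerate_u_counts(sz[1], sz[2]),
                 info = paste(sz, collapse = "x"))
  }
})

test_that("exact two-sided tail probabilities match hand calculations", {
  # both orderings equally extreme at n1 = n2 = 1
  expect_equal(mann_whitney_exact(1, 1, 0)$p_two_sided, 1.0)
  # (3,3,u=2): 4 of the 20 labelings have U <= 2 -> p = 2*4/20
  expect_equal(mann_whitney_exact(3, 3, 2)$p_two_sided, 0.4)
  # U out of range rejected
  expect_error(mann_whitney_exact(3, 3, 10), "n1\\*n2")
  expect_error(mann_whitney_exact(3, 3, 1.5), "integer")
})

test_that("sample-based rank test agrees with the exact path and wilcox", {
  # complete separation at 20 vs 29 gives U = 0 and the exact tail
  x <- seq(0.1, 2, length.out = 20)
  y <- seq(10, 30, length.out = 29)
  r <- mann_whitney_from_samples(x, y)
  expect_equal(r$u_statistic, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p_two_sided, 2 / choose(49, 20), tolerance = 1e-12)
  # identical multisets: U = n1*n2/2, p near 1 (ties -> normal approx)
  z <- c(1, 2, 3, 4, 5)
  r2 <- mann_whitney_from_samples(z, z)
  expect_equal(r2$u_statistic, length(z)^2 / 2)
  expect_gt(r2$p_two_sided, 0.9)
  # agreement with wilcox.test exact p on random tie-free samples
  set.seed(14)
  for (i in 1:20) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    ours <- mann_whitney_from_samples(a, b)$p_two_sided
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  expect_error(mann_whitney_from_samples(numeric(0), 1:3), "empty")
})

test_that("exact p matches brute-force permutation enumeration", {
  set.seed(3)
  for (i in 1:5) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    r <- mann_whitney_from_samples(x, y)
    # enumerate all labelings of the pooled sample
    pool <- c(x, y)
    combos <- utils::combn(n1 + n2, n1)
    u_all <- apply(combos, 2, function(idx) {
      rk <- rank(pool)
      sum(rk[idx]) - n1 * (n1 + 1) / 2
    })
    # two-sided p is orientation-symmetric, so enumerate in group-1 terms
    u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
    lower <- mean(u_all <= u_obs); upper <- mean(u_all >= u_obs)
    p_oracle <- min(1, 2 * min(lower, upper))
    expect_equal(r$p_two_sided, p_oracle, tolerance = 1e-12)
  }
})

test_that("2x2 chi-square equals the closed form on arbitrary tables", {
  set.seed(6)
  for (i in 1:25) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
    res <- pearson_chi2_2x2(tab)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    closed <- sum(tab) * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(res$statistic, closed, tolerance = 1e-12)
  }
  expect_equal(pearson_chi2_2x2(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  expect_equal(pearson_chi2_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_error(pearson_chi2_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
  expect_error(pearson_chi2_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("Fisher exact p equals direct hypergeometric summation", {
  tab <- matrix(c(1, 9, 11, 3), 2)
  # sum P(table) over tables with probability <= observed
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  probs <- dhyper(0:min(m, k), m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  p_oracle <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  expect_equal(fisher_exact_2x2(tab), p_oracle, tolerance = 1e-9)
  # still defined with a zero margin
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), 1)
})

test_that("Spearman correlation: monotone limits and permutation oracle", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  # n = 5 fixture against the 120-permutation enumeration
  set.seed(10)
  y <- rnorm(5)
  r <- spearman_cor(x, y)
  perms <- grid_permutations(5)
  rx <- rank(x); ry <- rank(y)
  rho_all <- apply(perms, 1, function(p) cor(rx, ry[p]))
  p_oracle <- mean(abs(rho_all) >= abs(r$rho) - 1e-12)
  expect_equal(r$p_value, p_oracle, tolerance = 1e-12)
  # constant input -> NA sentinel
  expect_true(is.na(spearman_cor(rep(1, 5), y)$rho))
  # large-n t-approximation agrees with cor.test
  set.seed(11)
  a <- rnorm(40); b <- a + rnorm(40)
  expect_equal(spearman_cor(a, b)$rho,
               unname(cor.test(a, b, method = "spearman")$estimate))
})

test_that("matching-count bins follow the stated edges", {
  expect_equal(as.character(bin_matching_count(c(0, 1, 2, 3, 6, 7, 12))),
               c("0", "1-2", "1-2", "3-6", "3-6", ">6", ">6"))
  expect_error(bin_matching_count(-1), "non-negative")
})

test_that("KM estimator reproduces the hand product-limit computation", {
  km <- km_estimator(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km$curve$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)  # smallest t with S(t) <= 0.5
  # with no censoring the curve is 1 - ECDF
  set.seed(20)
  t <- rexp(60)
  km2 <- km_estimator(t, rep(TRUE, 60))
  ecdf_surv <- 1 - ecdf(t)(km2$curve$time)
  expect_equal(km2$curve$surv, ecdf_surv, tolerance = 1e-12)
  # all-censored stratum: NA median sentinel
  km3 <- km_estimator(c(5, 6), c(FALSE, FALSE))
  expect_true(is.na(km3$median))
})

test_that("log-rank test is null on identical strata", {
  t <- c(1, 2, 3, 4, 5, 6)
  e <- rep(TRUE, 6)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("A", "B"), each = 6))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-9)
  expect_equal(lr$df, 1L)
})

test_that("Cox regression recovers a programmed hazard ratio", {
  set.seed(30)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = 0.001 * exp(log(2) * x))
  cens <- runif(n, 0, 3000)
  fit <- cox_ph(pmin(t_event, cens), t_event <= cens,
                data.frame(x = x))
  expect_lt(abs(fit$coef - log(2)), 3 * fit$se)
})

test_that("Cox null covariates stay within +/-3 z in almost all seeds", {
  n_seeds <- 200
  extreme <- 0
  set.seed(31)
  for (s in seq_len(n_seeds)) {
    n <- 120
    x <- rnorm(n)
    t_event <- rexp(n, 0.01)
    cens <- runif(n, 0, 200)
    fit <- cox_ph(pmin(t_event, cens), t_event <= cens,
                  data.frame(x = x))
    if (abs(fit$z) >= 3) extreme <- extreme + 1
  }
  expect_lte(extreme, 0.01 * n_seeds + 2)
})

test_that("Cox fit rejects degenerate designs", {
  t <- c(2, 3, 5, 7, 11, 13)
  e <- rep(TRUE, 6)
  x <- c(0, 1, 0, 1, 1, 0)
  expect_error(cox_ph(t, e, data.frame(a = x, b = x)), "rank-deficient")
  expect_error(cox_ph(t, e, data.frame(a = rep(1, 6))), "constant")
})

test_that("shadow importance recovers a planted signal", {
  n_confirmed <- 0; noise_rejected <- 0; noise_total <- 0
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 120
    labels <- factor(rep(c("M0", "M1"), each = n / 2))
    signal <- as.integer(labels == "M1") + rnorm(n, 0, 0.3)
    noise <- as.data.frame(matrix(rnorm(n * 9), n))
    names(noise) <- paste0("noise", 1:9)
    feats <- cbind(data.frame(signal = signal), noise)
    res <- shadow_importance(feats, labels, n_iterations = 30,
                             ntree = 60)
    if (res$decision[res$feature == "signal"] == "confirmed") {
      n_confirmed <- n_confirmed + 1
    }
    noise_rejected <- noise_rejected +
      sum(res$decision[res$feature != "signal"] == "rejected")
    noise_total <- noise_total + 9
  }
  expect_equal(n_confirmed, 5)
  expect_gte(noise_rejected / noise_total, 8 / 9)
})

test_that("shadow importance makes no confirmations on pure noise", {
  confirmed <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    n <- 80
    labels <- factor(rep(c("A", "B"), each = n / 2))
    feats <- as.data.frame(matrix(rnorm(n * 6), n))
    res <- shadow_importance(feats, labels, n_iterations = 25,
                             ntree = 60)
    confirmed <- confirmed + sum(res$decision == "confirmed")
  }
  expect_lte(confirmed, 1)
})

test_that("shadow importance guards its inputs", {
  labels <- factor(rep(c("A", "B"), 10))
  feats <- data.frame(x = rnorm(20), const = rep(1, 20))
  expect_error(shadow_importance(feats, labels, n_iterations = 5),
               "at least 20")
  res <- shadow_importance(feats, labels, n_iterations = 20, ntree = 40)
  expect_equal(res$decision[res$feature == "const"], "rejected")
})

test_that("ROC AUC is the rank statistic and matches U/(n1*n2)", {
  labels <- c(rep(FALSE, 10), rep(TRUE, 10))
  scores <- c(rnorm(10, 0), rnorm(10, 5))
  set.seed(60)
  # cross-module identity on arbitrary data
  for (i in 1:10) {
    sc <- rnorm(20)
    la <- sample(labels)
    auc <- roc_auc(sc, la)
    u <- mann_whitney_from_samples(sc[la], sc[!la])$u_statistic
    n1 <- sum(la); n0 <- sum(!la)
    u_pos <- sum(rank(sc)[la]) - n1 * (n1 + 1) / 2
    expect_equal(auc, u_pos / (n1 * n0), tolerance = 1e-12)
  }
  # perfect separation and monotone invariance
  perfect <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  expect_equal(roc_auc(perfect, labels), 1)
  expect_equal(roc_auc(exp(perfect / 3), labels),
               roc_auc(perfect, labels))
  # null behavior at larger n
  set.seed(61)
  expect_lt(abs(roc_auc(rnorm(2000), rep(c(TRUE, FALSE), 1000)) - 0.5),
            0.05)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("leave-one-out discrimination separates a separable cohort", {
  set.seed(70)
  n <- 30
  labels <- factor(rep(c("M0", "M1"), each = n / 2))
  feats <- data.frame(a = as.integer(labels == "M1") * 2 + rnorm(n, 0, 0.4),
                      b = rnorm(n))
  d <- discriminate(feats, labels, ntree = 100)
  expect_gt(d$auc, 0.9)
  expect_equal(d$scheme, "leave-one-out")
  d2 <- discriminate(feats, labels, method = "logistic")
  expect_gt(d2$auc, 0.9)
  expect_error(discriminate(feats, factor(rep("M0", n))), "two-class")
})
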