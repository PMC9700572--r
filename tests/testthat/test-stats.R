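test_that("Mann-Whitney exact p comes from complete enumeration", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)        # 2 of the C(6,3)=20 rank splits
  expect_equal(mw$method, "exact")
  mw2 <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_gt(mw2$p_value, 0.3)
  expect_error(mann_whitney_u(5, numeric(0)),
               class = "annulusFD_invalid_parameter")
})

test_that("exact and approximate Mann-Whitney agree within 0.02 at n=10+10", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      a <- rnorm(10)
      b <- rnorm(10, 0.6)
      p_exact <- mann_whitney_u(a, b)$p_value
      p_approx <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
      expect_lt(abs(p_exact - p_approx), 0.02)
    }
  })
})

test_that("tied samples fall back to the corrected normal approximation", {
  a <- c(1, 2, 2, 3)
  b <- c(2, 3, 3, 4)
  mw <- mann_whitney_u(a, b)
  expect_equal(mw$method, "normal_approximation")
  expect_equal(mw$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Pearson correlation matches closed forms", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  res <- pearson_correlation(c(1, 2, 3), c(1, 3, 2))
  expect_equal(res$r, 0.5, tolerance = 1e-12)
  ref <- cor.test(c(1, 2, 3), c(1, 3, 2))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "annulusFD_degenerate_input")
  expect_error(pearson_correlation(1:2, 1:2),
               class = "annulusFD_invalid_parameter")
})

test_that("ROC analysis reproduces the worked 4-point example", {
  r <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)            # 3 of 4 concordant pairs
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  # separable case
  sep <- roc_analysis(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1)
  expect_equal(sep$cutoff, 11)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  # all-tied scores
  tied <- roc_analysis(rep(2.2, 8), c(0, 1, 0, 1, 0, 1, 0, 1))
  expect_equal(tied$auc, 0.5)
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)),
               class = "annulusFD_invalid_parameter")
})

test_that("AUC equals the brute-force concordant-pair fraction", {
  withr::with_seed(77, {
    for (rep in 1:15) {
      n <- sample(6:30, 1)
      scores <- round(rnorm(n), 1)      # ties likely
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      pos <- scores[labels]
      neg <- scores[!labels]
      pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
      expect_equal(roc_analysis(scores, labels)$auc, mean(pairs),
                   tolerance = 1e-12)
    }
  })
})

test_that("Youden ties break toward the smallest cutoff", {
  # cutoffs 2 and 4 both give J = 0.5; the smaller must win
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r$cutoff, 2)
})

test_that("agreement identities hold to numerical precision", {
  x <- c(10.2, 11.5, 9.8, 12.1, 10.9, 11.7, 9.5, 10.0)
  same <- agreement(x, x)
  expect_equal(same$cronbach_alpha, 1, tolerance = 1e-12)
  expect_equal(same$icc, 1, tolerance = 1e-12)
  off <- agreement(x, x + 1.5)
  expect_equal(off$cronbach_alpha, 1, tolerance = 1e-12)
  expect_lt(off$icc, 1)                # absolute agreement sees the offset
  # frozen reference values (two-way random, absolute agreement, single
  # measures) computed with an independent implementation
  expect_equal(off$icc, 0.4570368, tolerance = 1e-6)
  expect_equal(off$icc_ci_low, 0.0, tolerance = 0.01)
  expect_equal(off$icc_ci_high, 0.87, tolerance = 0.01)
  noisy <- c(9.9594205724, 11.1026923013, 9.7254915134, 12.2261335714,
             11.2408139597, 11.7329119198, 9.3342058038, 9.7645658934)
  expect_equal(agreement(x, noisy)$icc, 0.973927, tolerance = 1e-5)
  expect_error(agreement(x, x[-1]), class = "annulusFD_invalid_parameter")
})

test_that("independent raters give near-zero ICC over replicates", {
  withr::with_seed(55, {
    iccs <- replicate(200, agreement(rnorm(12), rnorm(12))$icc)
  })
  expect_lt(abs(mean(iccs)), 0.1)
})

test_that("compare_cohort finds only the planted cell significant", {
  # diastolic annulus FD differs between groups; all other cells are null
  withr::with_seed(62, {
    n <- 30
    records <- lapply(seq_len(2 * n), function(i) {
      pos <- i > n
      fd <- list(
        "annulus.diastole" = rnorm(1, if (pos) 1.09 else 1.03, 0.008),
        "annulus.systole" = rnorm(1, 1.04, 0.008),
        "lvot.diastole" = rnorm(1, 1.04, 0.008),
        "lvot.systole" = rnorm(1, 1.04, 0.008))
      subject_record(sprintf("S%03d", i), fd = fd,
                     pvr_grade = if (pos) "mild" else "none")
    })
  })
  rep <- compare_cohort(records)
  tab <- rep$table
  expect_lt(tab$p_value[tab$cell == "annulus.diastole"], 0.001)
  expect_true(all(tab$p_value[tab$cell != "annulus.diastole"] > 0.05))
  expect_gt(rep$roc$auc, 0.9)
  expect_gt(tab$median_pos[tab$cell == "annulus.diastole"],
            tab$median_neg[tab$cell == "annulus.diastole"])
})

test_that("missing cells are excluded listwise and tiny groups error", {
  recs <- list(
    subject_record("a", fd = list("annulus.diastole" = 1.01), pvr_grade = "none"),
    subject_record("b", fd = list("annulus.diastole" = 1.02), pvr_grade = "none"),
    subject_record("c", fd = list("annulus.diastole" = 1.05), pvr_grade = "mild"),
    subject_record("d", fd = list("annulus.diastole" = 1.06), pvr_grade = "mild"),
    subject_record("e", fd = list("annulus.systole" = 1.04), pvr_grade = "mild"))
  rep <- compare_cohort(recs)
  row <- rep$table[rep$table$cell == "annulus.diastole", ]
  expect_equal(row$n_neg + row$n_pos, 4)   # subject e drops out of the cell
  expect_error(compare_cohort(recs[c(1, 3)]),
               class = "annulusFD_insufficient_data")
})

test_that("pvr dichotomy follows the none/trace vs mild+ rule", {
  grades <- c("none", "trace", "mild", "moderate", "severe")
  got <- vapply(grades, function(g) {
    annulusFD:::record_group(subject_record("x", pvr_grade = g), "pvr")
  }, logical(1))
  expect_identical(unname(got), c(FALSE, FALSE, TRUE, TRUE, TRUE))
})
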