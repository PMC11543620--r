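test_that("ROC AUC: perfect, inverted, and pair-counting oracle agreement", {
  perfect <- labeled_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(roc_auc(perfect)$auc, 1)
  inverted <- labeled_scores(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1))
  expect_equal(roc_auc(inverted)$auc, 0)
  expect_error(roc_auc(labeled_scores(1:4, rep(1, 4))), "both classes")
  set.seed(61)
  for (i in 1:200) {
    m <- sample(4:12, 1)
    sc <- sample(seq_len(100), m)  # distinct scores
    lb <- sample(c(0, 1), m, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(labeled_scores(sc, lb))$auc, oracle_auc_pairs(sc, lb),
                 tolerance = 1e-12)
  }
})

test_that("average precision reproduces the step-sum definition", {
  # 4-point worked example, thresholds at each distinct score descending:
  # t=0.9: R=0,   P=0;   t=0.8: R=1/2, P=1/2
  # t=0.7: R=1/2, P=1/3; t=0.6: R=1,   P=1/2
  # AP = (1/2-0)*1/2 + 0 + (1-1/2)*1/2 = 0.5
  d <- labeled_scores(c(0.9, 0.8, 0.7, 0.6), c(0, 1, 0, 1))
  expect_equal(average_precision(d)$ap, 0.5)
  expect_equal(average_precision(d)$ap, oracle_ap_walk(d$scores, d$labels))
  perfect <- labeled_scores(c(5, 4, 3, 2, 1), c(1, 1, 1, 0, 0))
  expect_equal(average_precision(perfect)$ap, 1)
  allpos <- labeled_scores(c(3, 1, 2), c(1, 1, 1))
  expect_equal(average_precision(allpos)$ap, 1)
  expect_error(average_precision(labeled_scores(1:3, c(0, 0, 0))), "no positive")
  set.seed(62)
  for (i in 1:50) {
    m <- sample(5:15, 1)
    sc <- round(runif(m), 2)  # ties allowed
    lb <- sample(c(0, 1), m, replace = TRUE)
    if (sum(lb) == 0) next
    expect_equal(average_precision(labeled_scores(sc, lb))$ap,
                 oracle_ap_walk(sc, lb), tolerance = 1e-12)
  }
})

test_that("AP and AUC are invariant under strictly monotone score transforms", {
  set.seed(63)
  sc <- rnorm(20); lb <- rep(c(0, 1), 10)
  for (f in list(function(x) 3 * x + 2, function(x) exp(x), function(x) atan(x))) {
    expect_equal(roc_auc(labeled_scores(f(sc), lb))$auc,
                 roc_auc(labeled_scores(sc, lb))$auc)
    expect_equal(average_precision(labeled_scores(f(sc), lb))$ap,
                 average_precision(labeled_scores(sc, lb))$ap)
  }
  # tie-free complement identity
  expect_equal(roc_auc(labeled_scores(sc, lb))$auc +
                 roc_auc(labeled_scores(-sc, lb))$auc, 1)
})

test_that("max MCC/F1 sweep matches brute force; degenerate cases follow conventions", {
  perfect <- labeled_scores(c(4, 3, 2, 1), c(1, 1, 0, 0))
  mf <- max_mcc_f1(perfect)
  expect_equal(mf$max_mcc, 1)
  expect_equal(mf$max_f1, 1)
  const <- labeled_scores(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(max_mcc_f1(const)$max_mcc, 0)
  set.seed(64)
  for (i in 1:50) {
    sc <- round(runif(10), 1)
    lb <- sample(c(0, 1), 10, replace = TRUE)
    if (length(unique(lb)) < 2) next
    mf <- max_mcc_f1(labeled_scores(sc, lb))
    o <- oracle_mcc_f1_sweep(sc, lb)
    expect_equal(mf$max_mcc, unname(o["mcc"]), tolerance = 1e-12)
    expect_equal(mf$max_f1, unname(o["f1"]), tolerance = 1e-12)
  }
})

test_that("top-N hit curves match sort-and-count and respect stable ties", {
  d <- labeled_scores(c(5, 4, 3, 2), c(1, 1, 0, 0))
  h <- topn_hits(d)$aggregate
  expect_equal(h$hits, c(1, 2, 2, 2))         # min(N, H) with H = 2
  z <- topn_hits(labeled_scores(c(5, 4, 3), c(0, 0, 0)))$aggregate
  expect_equal(z$hits, c(0, 0, 0))
  # stable tie-break: equal scores keep input order
  tie <- labeled_scores(c(1, 1, 1), c(0, 1, 0))
  expect_equal(topn_hits(tie)$aggregate$hits, c(0, 1, 1))
  set.seed(65)
  for (i in 1:100) {
    m <- 12
    sc <- round(runif(m), 1)
    lb <- sample(c(0, 1), m, replace = TRUE)
    grp <- sample(c("t1", "t2", "t3"), m, replace = TRUE)
    d <- labeled_scores(sc, lb)
    res <- topn_hits(d, stats::setNames(grp, d$ids))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      ord <- idx[order(-sc[idx])]
      expect_equal(res$per_target[[g]]$hits, cumsum(lb[ord]))
    }
    expect_true(all(diff(res$aggregate$hits) >= 0))
  }
})

test_that("ensemble averaging normalizes then averages; anti-correlated pairs tie", {
  expect_equal(ensemble_scores(list(c(3, 1, 2), c(3, 1, 2))), c(1, 0, 0.5))
  expect_equal(ensemble_scores(list(c(1, 2), c(2, 1))), c(0.5, 0.5))
  a <- c(0.1, 0.4, 0.3); b <- c(10, 20, 60); c3 <- c(5, 5, 5)
  manual <- ((a - 0.1) / 0.3 + (b - 10) / 50 + 0.5) / 3
  expect_equal(ensemble_scores(list(a, b, c3)), manual)
  expect_error(ensemble_scores(list(1:3, 1:4)), "misaligned")
  expect_error(ensemble_scores(list(stats::setNames(1:2, c("x", "y")),
                                    stats::setNames(1:2, c("y", "x")))), "misaligned")
})

test_that("DeLong test: identical inputs give z=0/p=1; Bonferroni multiplies", {
  set.seed(66)
  lb <- rep(c(0, 1), 10)
  sc <- rnorm(20)
  a <- labeled_scores(sc, lb)
  res <- delong_test(a, a)
  expect_equal(res$z, 0)
  expect_equal(res$p_raw, 1)
  res2 <- delong_test(a, labeled_scores(sc + rnorm(20, sd = 0.5), lb),
                      n_comparisons = 3)
  expect_equal(res2$p_bonferroni, min(1, res2$p_raw * 3))
  b <- labeled_scores(sc, rev(lb))
  expect_error(delong_test(a, b), "unpaired")
})

test_that("DeLong variance is close to a paired-bootstrap estimate", {
  set.seed(67)
  m <- 40
  lb <- rep(c(0, 1), each = m / 2)
  latent <- rnorm(m) + lb
  a <- labeled_scores(latent + rnorm(m, sd = 0.7), lb)
  b <- labeled_scores(latent + rnorm(m, sd = 0.7), lb)
  res <- delong_test(a, b)
  boots <- replicate(2000, {
    idx <- sample(m, replace = TRUE)
    while (length(unique(lb[idx])) < 2) idx <- sample(m, replace = TRUE)
    d1 <- labeled_scores(a$scores[idx], lb[idx])
    d2 <- labeled_scores(b$scores[idx], lb[idx])
    roc_auc(d1)$auc - roc_auc(d2)$auc
  })
  expect_lt(abs(stats::var(boots) - res$var_diff) / res$var_diff, 0.25)
})

test_that("DeLong AUCs and p-value agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(68)
  lb <- rep(c(0, 1), each = 15)
  a <- labeled_scores(rnorm(30) + lb, lb)
  b <- labeled_scores(rnorm(30) + 0.5 * lb, lb)
  res <- delong_test(a, b)
  ra <- pROC::roc(lb, a$scores, quiet = TRUE, direction = "<")
  rb <- pROC::roc(lb, b$scores, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(res$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  expect_equal(res$auc_b, as.numeric(pROC::auc(rb)), tolerance = 1e-12)
  expect_equal(res$p_raw, as.numeric(ref$p.value), tolerance = 1e-9)
})

test_that("AP equals the step-interpolated area of the module's own PR curve", {
  set.seed(69)
  for (i in 1:20) {
    sc <- runif(15); lb <- sample(c(0, 1), 15, replace = TRUE)
    if (sum(lb) == 0 || sum(lb) == 15) next
    pr <- average_precision(labeled_scores(sc, lb))
    steps <- diff(c(0, pr$pr_points$recall))
    expect_equal(pr$ap, sum(steps * pr$pr_points$precision), tolerance = 1e-12)
  }
})
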