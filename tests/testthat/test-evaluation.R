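test_that("classify splits counts by label and threshold side", {
  d <- rbind(make_scored(rep("HLA-A*01:01", 100), el_rank = rep(1, 100),
                         role = "ligand"),
             make_scored(rep("HLA-A*01:01", 100), el_rank = rep(99, 100),
                         role = "background"))
  cc <- classify(d, "el_rank", 50)
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               c(tp = 100L, fp = 0L, tn = 100L, fn = 0L))
  low <- classify(d, "el_rank", 0.5)               # below every score
  expect_equal(low[["tp"]], 0L)
  expect_equal(low[["fp"]], 0L)
  expect_error(classify(d[0, ], "el_rank", 1), "no peptides")
})

test_that("classify equals a per-peptide brute-force oracle and conserves totals", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 400
    d <- make_scored(rep("HLA-A*01:01", n),
                     el_rank = round(runif(n, 0, 10), 1),  # forces ties
                     role = sample(c("ligand", "epitope", "background"), n,
                                   replace = TRUE))
    t <- runif(1, 0, 10)
    cc <- classify(d, "el_rank", t)
    tp <- fp <- tn <- fn <- 0L
    for (i in seq_len(n)) {
      pos <- d$role[i] != "background"
      below <- d$el_rank[i] <= t
      if (pos && below) tp <- tp + 1L else if (!pos && below) fp <- fp + 1L
      else if (!pos && !below) tn <- tn + 1L else fn <- fn + 1L
    }
    expect_equal(unclass(cc), c(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_equal(sum(cc), n)
  }
})

test_that("compute_metrics evaluates the five ratios with NA for 0/0", {
  m <- compute_metrics(c(tp = 80, fn = 20, tn = 9900, fp = 100))
  expect_equal(unclass(m),
               c(sensitivity = 0.8, specificity = 9900 / 10000,
                 ppv = 80 / 180, npv = 9900 / 9920,
                 accuracy = 9980 / 10100))
  expect_true(is.na(compute_metrics(c(tp = 0, fp = 0, tn = 5, fn = 5))[["ppv"]]))
  allcorrect <- compute_metrics(c(tp = 10, fp = 0, tn = 10, fn = 0))
  expect_equal(allcorrect[["accuracy"]], 1.0)
  expect_error(compute_metrics(c(tp = 0, fp = 0, tn = 0, fn = 0)), "zero")
})

test_that("summarize_across_alleles gives unweighted mean/SD and counts NAs", {
  m1 <- compute_metrics(c(tp = 6, fn = 4, tn = 90, fp = 10))
  m2 <- compute_metrics(c(tp = 10, fn = 0, tn = 80, fp = 20))
  s <- summarize_across_alleles(list("HLA-A*01:01" = m1, "HLA-B*07:02" = m2))
  expect_equal(s$mean[["sensitivity"]], 0.8)     # (0.6 + 1.0) / 2
  expect_equal(s$sd[["sensitivity"]], sd(c(0.6, 1.0)))
  same <- summarize_across_alleles(list(a = m1, b = m1, c = m1))
  expect_true(all(same$sd == 0))
  # spreadsheet-style recomputation on a 5-allele fixture
  set.seed(83)
  counts <- lapply(1:5, function(i)
    c(tp = sample(50:99, 1), fn = sample(1:50, 1),
      tn = sample(900:999, 1), fp = sample(1:100, 1)))
  names(counts) <- sprintf("HLA-A*%02d:01", 1:5)
  s5 <- summarize_across_alleles(lapply(counts, compute_metrics))
  sens <- vapply(counts, function(k) k[["tp"]] / (k[["tp"]] + k[["fn"]]),
                 numeric(1))
  expect_equal(s5$mean[["sensitivity"]], sum(sens) / 5)
  expect_equal(s5$sd[["sensitivity"]],
               sqrt(sum((sens - mean(sens))^2) / 4))
  # undefined values excluded and counted
  mna <- compute_metrics(c(tp = 0, fp = 0, tn = 10, fn = 5))
  sna <- summarize_across_alleles(list(a = m1, b = mna))
  expect_equal(sna$n_undefined[["ppv"]], 1L)
  expect_equal(sna$mean[["ppv"]], m1[["ppv"]])
})

test_that("roc_auc hits the separated and exchangeable limits", {
  expect_equal(roc_auc(c(1, 2, 3), c(10, 11, 12))$auc, 1.0)
  set.seed(97)
  r <- roc_auc(runif(4000), runif(4000))
  expect_lt(abs(r$auc - 0.5), 0.04)
})

test_that("roc_auc equals all-pairs counting with half credit for ties", {
  set.seed(101)
  for (rep in 1:10) {
    pos <- sample(1:8, 6, replace = TRUE) + sample(c(0, 0.5), 6, TRUE)
    neg <- sample(1:8, 6, replace = TRUE) + sample(c(0, 0.5), 6, TRUE)
    pairs <- outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q))
    expect_equal(roc_auc(pos, neg)$auc, mean(pairs))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(103)
  pos <- rexp(50); neg <- runif(50, 0, 5)
  a0 <- roc_auc(pos, neg)$auc
  expect_equal(roc_auc(log(pos + 1), log(neg + 1))$auc, a0)
  expect_equal(roc_auc(pos^3, neg^3)$auc, a0)
})

test_that("roc_auc agrees with an independent ROC implementation", {
  set.seed(107)
  pos <- rexp(80, 2); neg <- runif(80, 0, 20)
  ours <- roc_auc(pos, neg)$auc
  ref <- pROC::auc(response = rep(c(1, 0), each = 80),
                   predictor = c(pos, neg), direction = ">",
                   levels = c(0, 1), quiet = TRUE)
  expect_equal(ours, as.numeric(ref))
})

test_that("ROC points agree with classify at each threshold", {
  set.seed(109)
  d <- rbind(make_scored(rep("HLA-A*01:01", 50), rexp(50, 2), "ligand"),
             make_scored(rep("HLA-A*01:01", 50), runif(50, 0, 20),
                         "background"))
  r <- roc_auc(d$el_rank[d$role == "ligand"],
               d$el_rank[d$role == "background"])
  for (i in sample(nrow(r$points), 10)) {
    t <- r$points$threshold[i]
    cc <- classify(d, "el_rank", t)
    m <- compute_metrics(cc)
    sens <- if (is.na(m[["sensitivity"]])) 0 else m[["sensitivity"]]
    expect_equal(r$points$sensitivity[i], sens)
    expect_equal(r$points$fpr[i], 1 - m[["specificity"]])
  }
})

test_that("evaluate_thresholds reproduces per-allele sensitivity at target", {
  set.seed(113)
  alleles <- sprintf("HLA-B*%02d:01", 1:4)
  lig <- make_scored(rep(alleles, each = 50), el_rank = rexp(200, 2))
  bg <- make_scored(rep(alleles, each = 200), el_rank = runif(800, 0, 100),
                    role = "background")
  fit <- calibrate_thresholds(lig, "el_rank", 0.8)
  s <- evaluate_thresholds(fit, rbind(lig, bg), "allele")
  expect_equal(s$per_allele$sensitivity, rep(0.8, 4))
  s_common <- evaluate_thresholds(fit, rbind(lig, bg), "common")
  expect_gte(s_common$mean[["sensitivity"]], 0.6)
  expect_true(all(s_common$per_allele$specificity <= 1))
})

test_that("two_allele_demo compares pooled allele-specific vs common calls", {
  set.seed(127)
  a <- "HLA-A*02:01"; b <- "HLA-A*11:01"
  d <- rbind(make_scored(rep(a, 50), rexp(50, 0.4), "epitope"),
             make_scored(rep(b, 50), rexp(50, 4), "epitope"),
             make_scored(rep(a, 500), runif(500, 0, 100), "background"),
             make_scored(rep(b, 500), runif(500, 0, 100), "background"))
  thr <- setNames(c(allele_threshold(d$el_rank[d$allele == a &
                                                 d$role == "epitope"], 0.8),
                    allele_threshold(d$el_rank[d$allele == b &
                                                 d$role == "epitope"], 0.8)),
                  c(a, b))
  common <- common_threshold(d$el_rank[d$role == "epitope"], 0.8)
  tab <- two_allele_demo(d, "el_rank", thr, common)
  # allele-specific thresholds recover pooled sensitivity the common cutoff loses
  expect_gte(tab["allele_specific", "sensitivity"],
             tab["common", "sensitivity"])
  # degenerate case: identical threshold values give identical rows
  same <- two_allele_demo(d, "el_rank", setNames(c(2, 2), c(a, b)), 2)
  expect_equal(same["allele_specific", ], same["common", ],
               ignore_attr = TRUE)
  expect_error(two_allele_demo(d[d$allele == a, ], "el_rank", thr, common),
               "exactly two")
  nopos <- d[!(d$allele == b & d$role == "epitope"), ]
  expect_error(two_allele_demo(nopos, "el_rank", thr, common),
               "zero positives")
})
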