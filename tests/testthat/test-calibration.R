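test_that("allele_threshold is the ceiling(s*n)-th order statistic", {
  expect_equal(allele_threshold(sample(1:100), 0.8), 80)
  expect_equal(allele_threshold(c(5, 5, 5), 0.3), 5)
  expect_equal(allele_threshold(c(5, 5, 5), 1), 5)
  # brute-force sort oracle on continuous draws
  set.seed(31)
  x <- rexp(100)
  expect_equal(allele_threshold(x, 0.8), sort(x)[80])
  expect_equal(allele_threshold(x, 0.801), sort(x)[81])  # ceiling, not round
  expect_error(allele_threshold(numeric(0)), "nonempty")
  expect_error(allele_threshold(1:10, 0), "\\(0, 1\\]")
})

test_that("common_threshold pools alleles and sits between per-allele extremes", {
  expect_equal(common_threshold(c(sample(1:100), sample(101:200)), 0.8), 160)
  expect_equal(common_threshold(rep(7, 10)), 7)
  # degenerate pooling: one allele
  set.seed(5)
  x <- runif(50)
  expect_equal(common_threshold(x, 0.8), allele_threshold(x, 0.8))
  # pooling bound property over random multi-allele cases
  set.seed(17)
  for (i in 1:10) {
    scores <- lapply(1:4, function(j) rlnorm(30, meanlog = rnorm(1)))
    per <- vapply(scores, allele_threshold, numeric(1), 0.8)
    pooled <- common_threshold(unlist(scores), 0.8)
    expect_gte(pooled, min(per))
    expect_lte(pooled, max(per))
  }
})

test_that("calibrate_thresholds fits per-allele and common families", {
  set.seed(23)
  d <- make_scored(rep(c("HLA-A*01:01", "HLA-B*07:02"), each = 100),
                   el_rank = c(rexp(100, 5), rexp(100, 0.5)))
  fit <- calibrate_thresholds(d, "el_rank", 0.8)
  expect_s3_class(fit, "threshold_fit")
  expect_named(fit$per_allele, c("HLA-A*01:01", "HLA-B*07:02"))
  expect_equal(unname(fit$per_allele[1]),
               sort(d$el_rank[d$allele == "HLA-A*01:01"])[80])
  expect_equal(fit$common, sort(d$el_rank)[160])
  expect_equal(fit$scale_applied, c(common = 1, per_allele = 1))
  # background rows are ignored as positives
  withbg <- rbind(d, make_scored(rep("HLA-A*01:01", 50), runif(50, 50, 100),
                                 role = "background"))
  expect_equal(coef(calibrate_thresholds(withbg)), coef(fit))
  # coef / summary / print accessors
  expect_equal(coef(fit, "common"), c(ALL = fit$common))
  expect_length(coef(fit, "all"), 3L)
  s <- summary(fit)
  expect_equal(s$n_alleles, 2L)
  expect_output(print(fit), "common threshold")
})

test_that("binder_fraction_thresholds converts binder fractions to rank cutoffs", {
  bg <- make_scored(rep("HLA-A*01:01", 10000), el_rank = runif(10000),
                    role = "background")
  bg$ic50_nm <- c(rep(100, 200), rep(10000, 9800))   # 200/10000 below 500 nM
  ts <- binder_fraction_thresholds(bg, ic50_cutoff = 500)
  expect_equal(unname(ts$per_allele), 2.0)
  expect_equal(ts$common, 2.0)
  expect_equal(ts$provenance, "binder_derived")
  expect_equal(ts$metric, "el_rank")
  bg$ic50_nm <- 10000
  expect_warning(z <- binder_fraction_thresholds(bg), "degenerate")
  expect_equal(unname(z$per_allele), 0)
})

test_that("scale_to_target stops at the first compliant multiplicative step", {
  fit <- structure(list(metric = "el_rank", target_sensitivity = 0.8,
                        common = 7.3,
                        per_allele = c("HLA-A*01:01" = 7.3),
                        provenance = "el_derived",
                        scale_applied = c(common = 1, per_allele = 1),
                        n_positives = c("HLA-A*01:01" = 10L)),
                   class = "threshold_fit")
  ep <- make_scored(rep("HLA-A*01:01", 10), el_rank = 1:10, role = "epitope")
  sc <- scale_to_target(fit, ep, scaling_config(step = 0.05))
  # needs exactly two 5% steps: 7.3 -> 7.665 (sens 0.7) -> 8.0475 (sens 0.8)
  expect_equal(sc$scale_applied[["per_allele"]], 1.05^2)
  expect_equal(sc$scale_applied[["common"]], 1.05^2)
  expect_equal(unname(sc$per_allele), 7.3 * 1.1025)
  expect_equal(sc$provenance, "scaled")
  # already-compliant thresholds are returned unchanged
  fit2 <- fit; fit2$common <- 8; fit2$per_allele[] <- 8
  sc2 <- scale_to_target(fit2, ep)
  expect_equal(sc2$scale_applied, c(common = 1, per_allele = 1))
  expect_equal(unname(sc2$per_allele), 8)
  expect_error(scale_to_target(fit, ep, scaling_config(max_iterations = 1L)),
               "did not reach")
})

test_that("scale_to_target matches a brute-force iteration oracle", {
  set.seed(41)
  alleles <- sprintf("HLA-A*%02d:01", 1:5)
  lig <- make_scored(rep(alleles, each = 100), el_rank = rexp(500, 3))
  ep <- make_scored(rep(alleles, each = 40),
                    el_rank = 3 * rexp(200, 3), role = "epitope")
  fit <- calibrate_thresholds(lig, "el_rank", 0.8)
  cfg <- scaling_config(step = 0.05, target_mean_sensitivity = 0.8)
  sc <- scale_to_target(fit, ep, cfg)
  oracle_iter <- function(thr_of_allele) {
    i <- 0
    repeat {
      sens <- vapply(alleles, function(a)
        mean(ep$el_rank[ep$allele == a] <=
               thr_of_allele(a) * 1.05^i), numeric(1))
      if (mean(sens) >= 0.8) return(i)
      i <- i + 1
    }
  }
  i_allele <- oracle_iter(function(a) fit$per_allele[[a]])
  i_common <- oracle_iter(function(a) fit$common)
  expect_equal(sc$scale_applied[["per_allele"]], 1.05^i_allele)
  expect_equal(sc$scale_applied[["common"]], 1.05^i_common)
  expect_equal(unname(sc$scaling$iterations),
               c(i_common, i_allele))
  expect_gte(sc$scaling$mean_sensitivity[["per_allele"]], 0.8)
  expect_gte(sc$scaling$mean_sensitivity[["common"]], 0.8)
})

test_that("repertoire_size counts the bound fraction and is monotone", {
  bg <- make_scored(rep("HLA-A*01:01", 10), el_rank = c(10, 3, 8, 1, 7, 5,
                                                        9, 2, 6, 4),
                    role = "background")
  r <- repertoire_size(bg, "el_rank", threshold = 4)  # 4th smallest value
  expect_equal(r$fraction_bound, 0.4)
  expect_equal(repertoire_size(bg, "el_rank", 100)$fraction_bound, 1.0)
  expect_equal(repertoire_size(bg, "el_rank", 0.5)$fraction_bound, 0.0)
  fr <- vapply(seq(0, 12, by = 0.5), function(t)
    repertoire_size(bg, "el_rank", t)$fraction_bound, numeric(1))
  expect_true(all(diff(fr) >= 0))
  # named per-allele thresholds
  bg2 <- rbind(bg, make_scored(rep("HLA-B*07:02", 10), el_rank = 1:10,
                               role = "background"))
  r2 <- repertoire_size(bg2, "el_rank",
                        c("HLA-A*01:01" = 4, "HLA-B*07:02" = 8))
  expect_equal(r2$fraction_bound, c(0.4, 0.8))
})

test_that("capture fraction returns at least the target, exactly when tie-free", {
  set.seed(59)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    s <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    x <- runif(n)                        # continuous: ties impossible
    t <- allele_threshold(x, s)
    expect_gte(mean(x <= t), s)
    if ((s * n) %% 1 == 0) expect_equal(mean(x <= t), s)
  }
  # ties at the cutoff overshoot and are reported, never truncated
  expect_equal(mean(c(1, 2, 2, 2, 5) <=
                      allele_threshold(c(1, 2, 2, 2, 5), 0.5)), 0.8)
})

test_that("write_thresholds emits the allele/metric/provenance table", {
  d <- make_scored(rep(c("HLA-A*01:01", "HLA-B*07:02"), each = 10),
                   el_rank = runif(20))
  fit <- calibrate_thresholds(d)
  path <- tempfile(fileext = ".tsv")
  write_thresholds(fit, path)
  tab <- read.delim(path)
  expect_equal(tab$allele, c("ALL", "HLA-A*01:01", "HLA-B*07:02"))
  expect_equal(tab$threshold, unname(coef(fit, "all")))
  expect_true(all(tab$scale_applied == 1))
})
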