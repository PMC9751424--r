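test_that("normality check accepts normal samples and rejects skewed ones", {
  set.seed(401)
  hits_norm <- hits_exp <- 0L
  for (i in 1:100) {
    if (normality_check(rnorm(200))$is_normal) hits_norm <- hits_norm + 1L
    if (!normality_check(rexp(200))$is_normal) hits_exp <- hits_exp + 1L
  }
  expect_gte(hits_norm, 90)
  expect_gte(hits_exp, 90)

  # constant and tiny samples are non-testable, routed to the rank test
  nc <- normality_check(rep(3, 10))
  expect_false(nc$testable)
  expect_false(nc$is_normal)
  expect_false(normality_check(c(1, 2, 3))$testable)

  # the naive KS variant is available by flag
  set.seed(5)
  x <- rnorm(50)
  expect_true(is.finite(normality_check(x, method = "ks")$p_value))
})

test_that("paired comparison handles degenerate and forced cases", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  cmp <- compare_paired(x, x)
  expect_true(cmp$degenerate)
  expect_equal(cmp$p_value, 1)
  expect_identical(cmp$test_used, "degenerate")

  expect_error(compare_paired(c(1, 2), c(3, 4)), "fewer than 3")

  # uniformly positive differences at n = 5: exact two-sided p = 2/32
  cmp2 <- compare_paired(c(11, 12, 13, 14, 15), c(10, 10, 10, 10, 10),
                         test = "wilcoxon")
  expect_identical(cmp2$test_used, "wilcoxon_signed_rank")
  expect_equal(cmp2$p_value, 0.0625)
})

test_that("paired comparison is symmetric under group swap", {
  set.seed(42)
  for (i in 1:5) {
    r <- rnorm(15, 10, 2); cl <- rnorm(15, 11, 2)
    a <- compare_paired(r, cl)
    b <- compare_paired(cl, r)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$research$mean - a$control$mean,
                 -(b$research$mean - b$control$mean))
    expect_identical(a$test_used, b$test_used)
  }
})

test_that("exact Wilcoxon route matches full sign-assignment enumeration", {
  set.seed(77)
  for (n in 3:10) {
    for (rep in 1:3) {
      d <- round(runif(n, 0.5, 20), 3) * sample(c(-1, 1), n, replace = TRUE)
      while (anyDuplicated(abs(d))) d <- d + runif(n, 0, 1e-3)
      cmp <- compare_paired(d, rep(0, n), test = "wilcoxon")
      expect_equal(cmp$p_value, enum_signrank_p(d), tolerance = 1e-12,
                   label = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("interval stratification uses right-closed month bins that partition", {
  mk_metrics <- function(intervals) {
    n <- length(intervals)
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(subject_id = sprintf("S%03d", i),
                 eye_role = rep(c("research", "control"), each = 2),
                 eyelid = rep(c("upper", "lower"), 2), gland_id = "AGGREGATE",
                 height_px = rnorm(4, 100, 5), width_px = rnorm(4, 20, 2),
                 tortuosity = rnorm(4, 0.5, 0.05), density = runif(4, 0.1, 0.3),
                 vagueness = rnorm(4, 27, 3), interval_months = intervals[i],
                 tbut_s = 6, tmh_mm = 0.2, stringsAsFactors = FALSE)
    }))
  }
  set.seed(8)
  m <- mk_metrics(c(3.0, 12.01, runif(38, 0.01, 24)))
  tab <- stratify_by_interval(m, "height")
  expect_identical(tab$interval_bin, c("0-3", "3-6", "6-12", ">12"))
  expect_equal(sum(tab$n_pairs), 40)

  # boundary conventions: 3.0 -> (0,3]; 12.01 -> (12, Inf)
  one <- stratify_by_interval(mk_metrics(rep(3.0, 4)), "height")
  expect_equal(one$n_pairs[one$interval_bin == "0-3"], 4)
  two <- stratify_by_interval(mk_metrics(rep(12.01, 4)), "height")
  expect_equal(two$n_pairs[two$interval_bin == ">12"], 4)

  # small bins are descriptive, without a p-value
  three <- stratify_by_interval(mk_metrics(c(1, 1, 8, 8, 8)), "height")
  expect_true(is.na(three$p_value[three$interval_bin == "0-3"]))
  expect_identical(three$test_used[three$interval_bin == "0-3"], "none")
  expect_false(is.na(three$research_mean[three$interval_bin == "0-3"]))

  bad <- mk_metrics(c(-1, 2, 3))
  expect_error(stratify_by_interval(bad, "height"), "negative")
})

test_that("clinical correlations use Spearman ranks with pairwise deletion", {
  n <- 12
  base <- data.frame(subject_id = sprintf("S%03d", 1:n), eye_role = "research",
                     eyelid = "upper", gland_id = "AGGREGATE",
                     height_px = seq(80, 135, length.out = n), width_px = 20,
                     tortuosity = 0.5, density = 0.2, vagueness = 25,
                     interval_months = 6,
                     tbut_s = NA_real_, tmh_mm = 0.2, stringsAsFactors = FALSE)
  ctrl <- base; ctrl$eye_role <- "control"
  lower <- rbind(transform(base, eyelid = "lower"),
                 transform(ctrl, eyelid = "lower"))
  # covariate = exact monotone transform of the metric -> coefficient 1
  base$tbut_s <- log(base$height_px)
  ctrl$tbut_s <- 6
  m <- rbind(base, ctrl, lower)
  m$tbut_s[m$eyelid == "lower"] <- m$tbut_s[m$eyelid == "upper"]
  ct <- correlate_with_clinical(m, "height", "tbut_s", "research", level = "upper")
  expect_equal(ct$coefficient, 1)

  # too few observations and constant covariates are flagged
  m2 <- m[m$subject_id %in% c("S001", "S002"), ]
  expect_error(correlate_with_clinical(m2, "height", "tbut_s", "research",
                                       level = "upper"), "fewer than 3")
  expect_error(correlate_with_clinical(m, "height", "tbut_s", "control",
                                       level = "upper"), "constant")
})

test_that("independent covariates show null-calibrated correlations", {
  set.seed(55)
  n <- 26
  rej <- 0L; coefs <- numeric(200)
  for (i in 1:200) {
    x <- rnorm(n); y <- rnorm(n)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
    coefs[i] <- ct$estimate
    if (ct$p.value < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(mean(coefs)), 0.05)
  expect_gte(rej / 200, 0.01)
  expect_lte(rej / 200, 0.12)
})

test_that("report tables are complete and byte-stable", {
  cfg <- cohort_config(n_subjects = 8, scale = 1 / 3, seed = 19)
  sim <- simulate_study(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  rep1 <- build_report(sim$metrics, d1, seed = 19, config = cfg)
  build_report(sim$metrics, d2, seed = 19, config = cfg)
  for (f in c("table_vagueness.csv", "table_parameters.csv",
              "table_by_interval.csv", "manifest.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  expect_identical(nrow(rep1$vagueness), 3L)          # upper/lower/both
  expect_identical(nrow(rep1$parameters), 12L)        # 3 levels x 4 parameters
  expect_identical(nrow(rep1$by_interval), 16L)       # 4 bins x 4 parameters
  man <- jsonlite::fromJSON(file.path(d1, "manifest.json"))
  expect_equal(man$n_subjects, 8)
  expect_false(is.na(man$config_md5))

  expect_error(build_report(sim$metrics[0, ], withr::local_tempdir()), "empty cohort")
})
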