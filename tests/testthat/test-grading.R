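test_that("Fisher score reproduces the worked examples", {
  # identical class distributions: class means equal the grand mean
  expect_equal(fisherScore(c(1, 2, 1, 2), c("A", "A", "B", "B")), 0)
  # population variances: num = 2*1 + 2*1, den = 2*0.25 + 2*0.25
  expect_equal(fisherScore(c(0, 1, 2, 3), c("A", "A", "B", "B")), 4.0)
  expect_error(fisherScore(c(1, 2, 3), c("A", "A", "A")), "2 classes")
  expect_error(fisherScore(c(1, 2, 3), c("A", "A", "B")), "at least 2")
  expect_warning(
    inf <- fisherScore(c(1, 1, 2, 2), c("A", "A", "B", "B")), "infinite")
  expect_identical(inf, Inf)
})

test_that("Fisher score is affine invariant and matches the loop oracle", {
  set.seed(41)
  for (k in 1:100) {
    ncl <- sample(2:5, 1)
    classes <- rep(seq_len(ncl), times = sample(2:8, ncl, replace = TRUE))
    values <- rnorm(length(classes), mean = classes, sd = 0.7)
    fs <- fisherScore(values, classes)
    expect_equal(fs, naiveFisher(values, classes), tolerance = 1e-12)
    a <- runif(1, 0.1, 9); b <- runif(1, -5, 5)
    expect_equal(fisherScore(a * values + b, classes), fs,
                 tolerance = 1e-9)
  }
  # sample-variance convention differs but stays proportional per class size
  expect_equal(fisherScore(c(0, 1, 2, 3), c(1, 1, 2, 2),
                           variance = "sample"), 2.0)
})

test_that("Spearman correlation handles monotone, reversed and tied input", {
  expect_equal(spearmanVsHb(c(1, 2, 3, 4, 5), 0:4)$rho, 1)
  expect_equal(spearmanVsHb(c(5, 4, 3, 2, 1), 0:4)$rho, -1)
  expect_equal(spearmanVsHb(c(1, 1, 2, 2), c(0, 0, 1, 1))$rho, 1)
  expect_error(spearmanVsHb(c(1, 2, 3), c(0, 1, 2)), "at least 4")
  expect_error(spearmanVsHb(1:4, rep(1, 4)), "distinct")
  expect_warning(res <- spearmanVsHb(rep(2, 5), 0:4), "constant")
  expect_true(is.na(res$rho))
})

test_that("Spearman rho matches the exhaustive rank oracle with ties", {
  set.seed(51)
  for (k in 1:60) {
    n <- sample(4:8, 1)
    ai <- sample(1:4, n, replace = TRUE) + runif(n, 0, 0.01)
    grp <- sample(0:2, n, replace = TRUE)
    if (length(unique(grp)) < 2 || sd(ai) == 0) next
    got <- spearmanVsHb(ai, grp)
    expect_equal(got$rho, naiveSpearman(ai, grp), tolerance = 1e-12)
  }
  # t-approximation p agrees with cor.test's asymptotic value
  set.seed(52)
  ai <- rnorm(12); grp <- rep(0:3, each = 3)
  got <- spearmanVsHb(ai, grp)
  ref <- suppressWarnings(cor.test(ai, grp, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  # exact permutation p for tiny n is a valid p-value and symmetric
  ex <- spearmanVsHb(c(1, 3, 2, 5), c(0, 1, 1, 2), exact = TRUE)
  expect_true(ex$p_value > 0 && ex$p_value <= 1)
  expect_error(spearmanVsHb(rnorm(9), rep(0:2, 3), exact = TRUE), "n <= 8")
})

test_that("motion contrast computes paired t and partial eta squared", {
  mv <- c(5, 6, 7, 8); rs <- c(1, 1.5, 2, 2.2)
  ct <- motionContrast(mv, rs)
  ref <- t.test(mv, rs, paired = TRUE)
  expect_equal(ct$t_stat, unname(ref$statistic))
  expect_equal(ct$p_value, ref$p.value)
  expect_equal(ct$df, 3)
  expect_equal(ct$partial_eta_sq, ct$t_stat^2 / (ct$t_stat^2 + 3))
  # move == rest: zero effect, flagged degenerate
  eq <- motionContrast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t_stat, 0)
  expect_equal(eq$partial_eta_sq, 0)
  expect_true(eq$degenerate)
  # constant non-zero shift: degenerate flag with NA statistics
  expect_warning(sh <- motionContrast(c(2, 3, 4), c(1, 2, 3)),
                 "zero-variance")
  expect_true(sh$degenerate && is.na(sh$t_stat))
  expect_error(motionContrast(c(1, 2), c(1, 2)), "at least 3")
  expect_error(motionContrast(1:4, 1:3), "paired")
})

test_that("feature ranking orders by Fisher score with documented ties", {
  rk <- data.frame(movement = "smile", intensity = "strong",
                   feature = c("mav", "zc", "rms"),
                   fisher_score = c(0.5, 0.01, 0.5),
                   spearman_rho = c(0.9, 0.1, 0.9),
                   spearman_p = c(0.001, 0.8, 0.001), n = 10)
  out <- rankFeatures(rk)
  expect_equal(out$feature, c("mav", "rms", "zc"))  # tie broken by name
  expect_equal(out$flagged, c(TRUE, TRUE, FALSE))
  expect_error(rankFeatures(rk, movement = "eyes"), "empty")
})

test_that("ranking and contrast tables assemble from an asymmetry table", {
  set.seed(61)
  n <- 12
  md <- data.frame(subject_id = sprintf("S%02d", 1:n),
                   hb_grade = rep(c(1, 3, 6), each = 4),
                   is_control = rep(c(TRUE, FALSE, FALSE), each = 4),
                   lesioned_side = rep(c("none", "left", "right"), each = 4))
  grp <- hbGroupCode(md$hb_grade, md$is_control)
  rows <- list()
  for (i in 1:n) for (feat in c("mav", "zc")) {
    trend <- if (feat == "mav") grp[i] * 20 else 0
    rows[[paste(i, feat)]] <- data.frame(
      subject_id = md$subject_id[i], movement = "smile",
      intensity = "strong", condition = c("MOVE", "REST"), feature = feat,
      healthy = 1, lesioned = 1,
      ai_percent = trend + rnorm(2, 0, 2),
      hb_grade = md$hb_grade[i], hb_group = grp[i])
  }
  ai <- do.call(rbind, rows)
  rk <- featureRankingTable(ai)
  expect_equal(nrow(rk), 2)
  expect_gt(rk$fisher_score[rk$feature == "mav"],
            rk$fisher_score[rk$feature == "zc"])
  expect_gt(rk$spearman_rho[rk$feature == "mav"], 0.8)
  rk_adj <- featureRankingTable(ai, adjust_p = TRUE)
  expect_true("p_adj" %in% names(rk_adj))
  expect_true(all(rk_adj$p_adj >= rk_adj$spearman_p - 1e-12))
})
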