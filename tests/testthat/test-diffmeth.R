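test_that("two-group OLS effect equals the difference of group means", {
  sheet <- two_group_sheet(4L)
  y <- random_beta_matrix(30L, 8L)
  colnames(y) <- sheet$sample_id
  des <- build_design(sheet, paired = FALSE, batch = FALSE)
  fit <- fit_probe_models(y, des)
  ba <- sheet$sample_id[sheet$limb == "BaCl2"]
  pbs <- sheet$sample_id[sheet$limb == "PBS"]
  expect_equal(unname(fit$effect),
               unname(rowMeans(y[, ba]) - rowMeans(y[, pbs])),
               tolerance = 1e-12)
})

test_that("per-probe fits match a direct normal-equations solve", {
  set.seed(21)
  sheet <- two_group_sheet(6L)
  sheet$batch <- rep(c("chipA", "chipB"), each = 6)  # 3 animals per chip
  y <- random_beta_matrix(50L, 12L, seed = 22)
  colnames(y) <- sheet$sample_id
  y[1, 3] <- NA  # exercise the missing-value path
  des <- build_design(sheet, paired = FALSE, batch = TRUE)
  fit <- fit_probe_models(y, des)
  for (i in c(1L, 10L, 50L)) {
    ok <- !is.na(y[i, ])
    X <- des$X[ok, , drop = FALSE]
    b <- solve(t(X) %*% X, t(X) %*% y[i, ok])
    expect_equal(unname(fit$effect[i]), sum(des$contrast * b),
                 tolerance = 1e-10)
    r <- y[i, ok] - drop(X %*% b)
    expect_equal(fit$sigma2[i], sum(r^2) / (sum(ok) - ncol(X)),
                 tolerance = 1e-10)
    expect_equal(fit$df[i], sum(ok) - ncol(X))
  }
  expect_error(
    fit_probe_models(y, list(X = cbind(des$X, des$X[, 2]),
                             contrast = c(des$contrast, 0),
                             sample_ids = des$sample_ids)),
    "rank-deficient")
})

test_that("probe with zero residual variance is flagged as s2 = 0", {
  sheet <- two_group_sheet(3L)
  y <- random_beta_matrix(35L, 6L)
  colnames(y) <- sheet$sample_id
  y[1, ] <- ifelse(sheet$limb == "BaCl2", 0.8, 0.2)  # perfect fit
  des <- build_design(sheet, paired = FALSE, batch = FALSE)
  fit <- fit_probe_models(y, des)
  expect_equal(fit$sigma2[[1]], 0, tolerance = 1e-28)
})

test_that("moderation limits behave as the theory dictates", {
  # identical variances: no excess dispersion, d0 -> Inf, posterior = s0^2
  s2 <- rep(0.04, 100)
  m <- moderate_variances(s2, rep(10, 100))
  expect_identical(m$d0, Inf)
  expect_equal(m$s0_sq, 0.04, tolerance = 1e-6)
  expect_equal(m$post_var, rep(0.04, 100), tolerance = 1e-6)

  # d0 = Inf posterior makes the moderated t use s0 for every probe
  fit <- list(effect = c(a = 0.2, b = -0.1), u = c(0.5, 0.5),
              df = c(10, 10))
  tt <- moderated_t(fit, list(d0 = Inf, s0_sq = 0.04,
                              post_var = c(0.04, 0.04)))
  expect_equal(unname(tt$t), c(0.2, -0.1) / (0.5 * 0.2), tolerance = 1e-12)
})

test_that("moderated t interpolates ordinary and pooled t at d0 extremes", {
  set.seed(33)
  s2 <- 0.02 * rchisq(200, 8) / 8
  d <- rep(8, 200)
  eff <- rnorm(200, 0, 0.05)
  u <- rep(0.4, 200)
  fit <- list(effect = eff, u = u, df = d)
  t_ord <- eff / (u * sqrt(s2))
  tt0 <- moderated_t(fit, list(d0 = 0, s0_sq = 1, post_var = s2))
  expect_equal(unname(tt0$t), unname(t_ord), tolerance = 1e-12)
  s0 <- mean(s2)
  ttI <- moderated_t(fit, list(d0 = Inf, s0_sq = s0,
                               post_var = rep(s0, 200)))
  expect_equal(unname(ttI$t), unname(eff / (u * sqrt(s0))),
               tolerance = 1e-12)
})

test_that("moderated statistics agree with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(44)
  sheet <- two_group_sheet(5L)
  y <- matrix(rnorm(300 * 10, 0.5, 0.1), 300, 10,
              dimnames = list(sprintf("p%03d", 1:300), sheet$sample_id))
  des <- build_design(sheet, paired = FALSE, batch = FALSE)
  fit <- fit_probe_models(y, des)
  mod <- moderate_variances(fit$sigma2, fit$df)
  tt <- moderated_t(fit, mod)

  lf <- limma::lmFit(y, des$X)
  lf <- limma::eBayes(limma::contrasts.fit(lf, des$contrast))
  expect_equal(mod$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_sq, lf$s2.prior, tolerance = 1e-6)
  expect_equal(unname(tt$t), unname(lf$t[, 1]), tolerance = 1e-8)
  expect_equal(unname(tt$p), unname(lf$p.value[, 1]), tolerance = 1e-8)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0,1\\]")
  # q >= p and monotone in p-order, on random draws
  set.seed(5)
  p <- runif(50)
  q <- benjamini_hochberg(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("direction classification follows sign and threshold", {
  rec <- data.frame(effect = c(-0.1, -0.4, 0.2, 0),
                    q = c(0.04, 0.06, 0.01, 0.02))
  out <- suppressMessages(classify_dm(rec, 0.05))
  expect_equal(out$direction, c("hypo", "ns", "hyper", "ns"))
})

test_that("feature tallies count and conserve", {
  rec <- data.frame(
    probe_id = sprintf("p%d", 1:6),
    gene_id = c("g1", "g1", "g2", NA, NA, "g3"),
    feature_class = c("promoter", "promoter", "promoter", "exon",
                      "intergenic", "intron"),
    direction = c("hypo", "hypo", "hypo", "hyper", "ns", "ns"),
    stringsAsFactors = FALSE)
  tal <- tally_by_feature(rec)
  expect_equal(tal$tally$hypo[tal$tally$feature_class == "promoter"], 3L)
  expect_equal(tal$tally$hyper[tal$tally$feature_class == "exon"], 1L)
  expect_equal(sum(tal$tally$hypo + tal$tally$hyper),
               sum(rec$direction != "ns"))
  expect_equal(tal$promoter_by_gene$n_hypo,
               c(2L, 1L))  # g1, g2
})

test_that("paired fold changes are per-animal ratios with geometric mean", {
  sheet <- two_group_sheet(2L)
  beta <- matrix(0.5, 2, 4, dimnames = list(c("cgX", "cgY"),
                                            sheet$sample_id))
  pfc <- paired_fold_change(beta, sheet, "cgX")
  expect_equal(unname(pfc$ratios), c(1, 1))
  expect_equal(pfc$geometric_mean, 1)

  beta["cgY", sheet$limb == "PBS"] <- 0.4
  beta["cgY", sheet$limb == "BaCl2"] <- c(0.2, 0.8)  # ratios 0.5, 2
  pfc2 <- paired_fold_change(beta, sheet, "cgY")
  expect_equal(sort(unname(pfc2$ratios)), c(0.5, 2))
  expect_equal(pfc2$geometric_mean, 1)
})

test_that("planted rank-1 factor is recovered exactly on a clean matrix", {
  set.seed(55)
  sheet <- two_group_sheet(6L)
  n <- nrow(sheet)
  f <- rnorm(n)
  lam <- rnorm(40, 0, 0.5)
  grp <- as.integer(sheet$limb == "BaCl2")
  Y <- outer(lam, f) + outer(rep(0.5, 40), 1 + 0.3 * grp)
  dimnames(Y) <- list(sprintf("ctl%02d", 1:40), sheet$sample_id)
  des <- build_design(sheet, paired = FALSE, batch = FALSE)
  est <- estimate_ruv_factor(Y, des, rownames(Y))
  fr <- f - drop(des$X %*% solve(crossprod(des$X), crossprod(des$X, f)))
  expect_gt(abs(cor(est, fr)), 1 - 1e-8)

  Yc <- matrix(0.5, 40, n, dimnames = dimnames(Y))
  expect_error(estimate_ruv_factor(Yc, des, rownames(Yc)), "rank 0")
})

test_that("simulated latent factor is recovered from control probes", {
  cors <- vapply(1:10, function(s) {
    st <- simulate_study(tiny_config(
      seed = s, n_genes = 200L, n_animals = c(YV = 6L, OV = 11L, OS = 9L),
      batch_sd = 0, ruv_sd = 0.3, noise_sd = 0.05, animal_sd = 0,
      n_control_probes = 200L))
    des <- build_design(st$sheet, paired = FALSE, batch = FALSE)
    f <- estimate_ruv_factor(st$beta, des, st$truth$control_probes)
    abs(cor(f, st$truth$ruv_factor[names(f)]))
  }, 0)
  expect_gte(mean(cors), 0.95)
})

test_that("modelling the true factor reduces residual variance", {
  st <- simulate_study(tiny_config(
    seed = 77, n_genes = 150L, n_animals = c(YV = 0L, OV = 10L, OS = 0L),
    ruv_sd = 0.5, batch_sd = 0, noise_sd = 0.1))
  des0 <- build_design(st$sheet, paired = FALSE, batch = FALSE)
  des1 <- build_design(st$sheet, paired = FALSE, batch = FALSE,
                       ruv = st$truth$ruv_factor)
  f0 <- fit_probe_models(st$beta, des0)
  f1 <- fit_probe_models(st$beta, des1)
  expect_lt(median(f1$sigma2), median(f0$sigma2))
})

test_that("full diffmeth chain annotates, orders q consistently, recovers", {
  st <- simulate_study(tiny_config(
    seed = 8, n_genes = 150L, n_animals = c(YV = 0L, OV = 10L, OS = 0L),
    effect_fraction = 0.3))
  dm <- suppressMessages(
    diff_methylation(st$beta, st$sheet, st$manifest, arm = "OV"))
  expect_true(all(dm$q >= dm$p - 1e-15))
  expect_setequal(dm$probe_id, st$manifest$probe_id)
  resp <- st$truth$responsive$probe_id
  expect_gt(mean(dm$direction[dm$probe_id %in% resp] == "hypo"), 0.8)
  expect_lte(sum(dm$direction != "ns" & !dm$probe_id %in% resp), 5)
})
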