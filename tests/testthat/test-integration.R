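toy_gene <- function(tss = 1e6, strand = "+", chrom = "chr1") {
  data.frame(gene_id = "g1", symbol = "G1", chrom = chrom, strand = strand,
             start = if (strand == "+") tss else tss - 5e4,
             end = if (strand == "+") tss + 5e4 else tss,
             tss = tss, stringsAsFactors = FALSE)
}

toy_peaks <- function(pos, chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             probe_id = sprintf("cg%03d", seq_along(pos)),
             direction = "hypo", stringsAsFactors = FALSE)
}

test_that("peak conversion filters by significance and direction", {
  man <- data.frame(probe_id = c("a", "b", "c", "d"), chrom = "chr1",
                    pos = c(10L, 30L, 20L, 40L), gene_id = NA,
                    feature_class = "intergenic", tss_distance = NA,
                    stringsAsFactors = FALSE)
  dm <- data.frame(probe_id = c("a", "b", "c", "d"),
                   q = c(0.01, 0.04, 0.03, 0.5),
                   direction = c("hypo", "hyper", "hypo", "ns"),
                   stringsAsFactors = FALSE)
  expect_equal(nrow(peaks_from_dm(dm[dm$q > 0.9, ], man)), 0L)
  both <- peaks_from_dm(dm, man)
  expect_equal(nrow(both), 3L)
  expect_equal(both$pos, sort(both$pos))  # sorted output
  expect_equal(nrow(peaks_from_dm(dm, man, direction_filter = "hypo_only")),
               2L)
  expect_error(peaks_from_dm(dm, man[-1, ]), "absent from manifest: a")
})

test_that("regulatory potential matches its closed form", {
  g <- toy_gene()
  expect_equal(regulatory_potential(g, toy_peaks(1e6))$rp, exp(-0.5),
               tolerance = 1e-12)
  expect_equal(regulatory_potential(g, toy_peaks(1e6 + 2e5))$rp, 0)
  two <- regulatory_potential(g, toy_peaks(c(1e6, 1e6 + 1e5)))
  expect_equal(two$rp, exp(-0.5) + exp(-4.5), tolerance = 1e-12)
  expect_equal(two$n_peaks, 2L)
})

test_that("regulatory potential is additive, monotone and strand-symmetric", {
  set.seed(99)
  for (rep in 1:200) {
    tss <- sample.int(5e6, 1) + 2e5
    d <- sample.int(99999, 4)
    gp <- toy_gene(tss, "+")
    gm <- toy_gene(tss, "-")
    pk <- toy_peaks(tss + c(-d[1], d[2], -d[3], d[4]))
    rp <- regulatory_potential(gp, pk)$rp
    # additivity over single peaks, order-invariance
    singles <- vapply(seq_len(4), function(i)
      regulatory_potential(gp, pk[i, ])$rp, 0)
    expect_equal(rp, sum(singles), tolerance = 1e-12)
    expect_equal(regulatory_potential(gp, pk[sample(4), ])$rp, rp,
                 tolerance = 1e-12)
    # strand mirror: same absolute distances on a minus-strand gene
    expect_equal(regulatory_potential(gm, pk)$rp, rp, tolerance = 1e-12)
    # monotone decreasing in distance
    d2 <- sort(d[1:2])
    rp_near <- regulatory_potential(gp, toy_peaks(tss + d2[1]))$rp
    rp_far <- regulatory_potential(gp, toy_peaks(tss + d2[2]))$rp
    if (d2[1] < d2[2]) expect_gt(rp_near, rp_far)
  }
})

test_that("rank products follow the hand-computed competition ranking", {
  de <- data.frame(gene_id = c("gA", "gB", "gC"),
                   log2_fold_change = c(2, 1, 3),
                   p = c(0.002, 0.001, 0.003),
                   adj_p = c(0.01, 0.01, 0.01), stringsAsFactors = FALSE)
  rp <- data.frame(gene_id = c("gA", "gB", "gC"), rp = c(3, 2, 1),
                   n_peaks = c(2L, 1L, 1L), stringsAsFactors = FALSE)
  sc <- rank_product_integration(rp, de)
  # rp ranks: gA 1, gB 2, gC 3; DE p ranks: gB 1, gA 2, gC 3
  expect_equal(sc$rank_product[match(c("gA", "gB", "gC"), sc$gene_id)],
               c(2, 2, 9) / 9)
})

test_that("single-gene set and no-peak genes behave at the boundaries", {
  de <- data.frame(gene_id = c("up1", "bgA", "bgB"),
                   log2_fold_change = c(1.5, 0, 0),
                   p = c(0.001, 0.9, 0.8), adj_p = c(0.01, 0.95, 0.9),
                   stringsAsFactors = FALSE)
  rp <- data.frame(gene_id = c("up1", "bgA", "bgB"), rp = c(0.4, 0, 0),
                   n_peaks = c(1L, 0L, 0L), stringsAsFactors = FALSE)
  sc <- suppressMessages(rank_product_integration(rp, de))
  up <- sc[sc$gene_id == "up1", ]
  expect_equal(up$rank_product, 1)   # 1*1/1^2
  expect_false(up$predicted)         # cutoff 0.25 < 1
  sc2 <- suppressMessages(
    rank_product_integration(rp, de, rp_cutoff = 1.01))
  expect_true(sc2$predicted[sc2$gene_id == "up1"])

  # a no-peak gene ranks last for rp and is never predicted
  de$adj_p <- c(0.01, 0.01, 0.01)
  de$log2_fold_change <- c(1, 1, 1)
  sc3 <- suppressMessages(rank_product_integration(rp, de, rp_cutoff = 1.01))
  expect_equal(sc3$rank_rp[sc3$gene_id == "up1"], 1)
  expect_true(all(sc3$rank_rp[sc3$gene_id != "up1"] >= 2))
  expect_false(any(sc3$predicted[sc3$n_peaks == 0]))
})

test_that("gene input order does not affect the scores", {
  set.seed(13)
  n <- 40
  de <- data.frame(gene_id = sprintf("g%02d", 1:n),
                   log2_fold_change = rnorm(n), p = runif(n),
                   adj_p = runif(n), stringsAsFactors = FALSE)
  rp <- data.frame(gene_id = de$gene_id, rp = rexp(n),
                   n_peaks = rpois(n, 1), stringsAsFactors = FALSE)
  a <- suppressMessages(rank_product_integration(rp, de))
  shuf <- sample(n)
  b <- suppressMessages(rank_product_integration(rp[shuf, ], de[rev(shuf), ]))
  expect_equal(a, b)
  ok <- !is.na(a$rank_product)
  expect_true(all(a$rank_product[ok] > 0 & a$rank_product[ok] <= 1))
})

test_that("extreme separation gives the permutation minimum p", {
  sc <- data.frame(rp = c(rexp(20) + 10, rexp(20)),
                   de_class = rep(c("up", "static"), each = 20),
                   stringsAsFactors = FALSE)
  dt <- direction_test(sc, "up", method = "permutation", B = 999L, seed = 3)
  expect_equal(dt$d_plus, 1)
  expect_equal(dt$p, 1 / 1000)
})

test_that("permutation p matches exhaustive enumeration on a 6-vs-6 toy", {
  set.seed(17)
  vals <- round(rexp(12), 3)
  sc <- data.frame(rp = vals, de_class = rep(c("up", "static"), each = 6),
                   stringsAsFactors = FALSE)
  d_obs <- direction_test(sc, "up", method = "permutation", B = 99L,
                          seed = 1)$d_plus
  # exhaustive oracle over all 924 label assignments
  combos <- utils::combn(12, 6)
  dp <- apply(combos, 2L, function(idx)
    methregen:::dplus_stat(vals[idx], vals[-idx]))
  p_exact <- mean(dp >= d_obs - 1e-12)
  B <- 4999L
  dt <- direction_test(sc, "up", method = "permutation", B = B, seed = 2)
  se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(dt$p - p_exact), 4 * se + 2 / B)
})

test_that("asymptotic and permutation p agree for large balanced groups", {
  set.seed(29)
  sc <- data.frame(rp = rexp(400),
                   de_class = rep(c("up", "static"), each = 200),
                   stringsAsFactors = FALSE)
  pa <- direction_test(sc, "up", method = "asymptotic")$p
  pp <- direction_test(sc, "up", method = "permutation", B = 1999L,
                       seed = 5)$p
  expect_lt(abs(pa - pp), 0.02 + 0.05)  # asymptotic error + MC error
})

test_that("direction test statistic matches the one-sided KS oracle", {
  set.seed(31)
  x <- rnorm(80, 1); y <- rnorm(120)
  sc <- data.frame(rp = c(x, y),
                   de_class = rep(c("up", "static"), c(80, 120)))
  dt <- direction_test(sc, "up", method = "asymptotic")
  ks <- suppressWarnings(stats::ks.test(x, y, alternative = "less"))
  # "less" tests whether x's CDF lies below y's, i.e. x stochastically larger
  expect_equal(dt$d_plus, unname(ks$statistic), tolerance = 1e-12)
})

test_that("set overlaps partition correctly", {
  expect_equal(overlap_sets("a", "b")$n_shared, 0L)
  ident <- overlap_sets(c("x", "y"), c("y", "x"))
  expect_equal(ident$n_shared, 2L)
  expect_equal(ident$n_a_only + ident$n_b_only, 0L)
  set.seed(7)
  a <- sample(letters, 12); b <- sample(letters, 15)
  ov <- overlap_sets(a, b)
  expect_equal(ov$n_a_only + ov$n_b_only + ov$n_shared,
               length(union(a, b)))
  expect_equal(ov$n_a_only + ov$n_shared, length(unique(a)))
})
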