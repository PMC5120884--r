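test_that("size factors are 1 for identical samples and follow scaling law", {
  m <- matrix(rpois(500, 50), ncol = 5,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:5)))
  m_id <- matrix(rep(m[, 1], 5), ncol = 5,
                 dimnames = dimnames(m))
  expect_equal(unname(size_factors(m_id)), rep(1, 5), tolerance = 1e-12)

  # two samples, B = 2A: median-of-ratios gives (1/sqrt(2), sqrt(2))
  a <- rpois(200, 100) + 1L
  two <- cbind(A = a, B = 2L * a)
  expect_equal(unname(size_factors(two)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # scaling one sample by c multiplies its factor by c (relative to others)
  set.seed(8)
  base <- matrix(rpois(600, 80) + 1L, ncol = 6)
  colnames(base) <- paste0("s", 1:6)
  sf0 <- size_factors(base)
  scaled <- base; scaled[, 3] <- scaled[, 3] * 3L
  sf1 <- size_factors(scaled)
  expect_equal(sf1[3] / sf1[1], 3 * sf0[3] / sf0[1], tolerance = 1e-9)
})

test_that("size factors agree with the established median-of-ratios reference", {
  set.seed(12)
  m <- matrix(rnbinom(3000, mu = 60, size = 5) + 1L, ncol = 6,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:6)))
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("all-zero samples are rejected by name", {
  m <- matrix(1L, 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[, 2] <- 0L
  expect_error(size_factors(m), "b")
})

test_that("nb test is calibrated under the null and symmetric in labels", {
  set.seed(71)
  g <- 800
  mu <- rgamma(g, 0.5, 0.005)
  counts <- sapply(1:7, function(j) rnbinom(g, mu = mu, size = 10))
  rownames(counts) <- paste0("g", 1:g)
  grp <- c(rep("A", 4), rep("B", 3))
  res <- nb_test(counts, grp, sf = rep(1, 7))
  keep <- !res$all_zero
  rej <- mean(res$p[keep] < 0.05)
  expect_gt(rej, 0.02); expect_lt(rej, 0.08)
  expect_true(all(res$p > 0 & res$p <= 1))

  relabeled <- nb_test(counts, ifelse(grp == "A", "B", "A"), sf = rep(1, 7))
  expect_equal(res$p, relabeled$p, tolerance = 1e-12)
  expect_equal(res$stat, -relabeled$stat, tolerance = 1e-12)
})

test_that("all-zero genes get p = 1 and groups with one sample are rejected", {
  counts <- rbind(g1 = c(5L, 7L, 6L, 4L, 8L),
                  g2 = c(0L, 0L, 0L, 0L, 0L))
  res <- nb_test(counts, c("A", "A", "A", "B", "B"), sf = rep(1, 5))
  expect_equal(res$p[2], 1)
  expect_true(res$all_zero[2])
  expect_error(nb_test(counts, c("A", "A", "A", "A", "B")), ">= 2")
})

test_that("nb test p values track a permutation oracle", {
  set.seed(83)
  g <- 300
  mu <- rgamma(g, 1, 0.01) + 5
  fc <- c(rep(3, 50), rep(1, g - 50))
  counts <- sapply(1:7, function(j) {
    f <- if (j <= 4) fc else 1
    rnbinom(g, mu = mu * f, size = 10)
  })
  rownames(counts) <- paste0("g", 1:g)
  grp <- c(rep("A", 4), rep("B", 3))
  res <- nb_test(counts, grp, sf = rep(1, 7))

  # oracle: exact permutation distribution of the Wald statistic over all
  # 35 group relabelings
  combs <- combn(7, 4)
  perm_stats <- sapply(seq_len(ncol(combs)), function(k) {
    lab <- rep("B", 7); lab[combs[, k]] <- "A"
    nb_test(counts, lab, sf = rep(1, 7))$stat
  })
  obs <- abs(res$stat)
  perm_p <- rowMeans(abs(perm_stats) >= obs - 1e-12)
  dev <- abs(res$p - perm_p)
  # the permutation law over 4+3 samples has granularity 1/35, so exact
  # per-gene agreement is impossible; require close median agreement,
  # strong rank agreement, and permutation-extreme calls for strong genes
  expect_lt(median(dev), 0.05)
  expect_gt(cor(res$p, perm_p, method = "spearman"), 0.9)
  strong <- res$p < 0.001
  expect_gt(sum(strong), 20)
  expect_true(all(perm_p[strong] <= 5 / 35))
})

test_that("BH adjustment equals its brute-force definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("enrichment calls follow the q-and-ratio filter with strict bounds", {
  # worked example rows: highly enriched in wild type, not in the mutant
  expect_true(call_enrichment(q = 2.37e-06, mean_gfp = 265.6,
                              mean_all = 34.4))
  expect_false(call_enrichment(q = 0.72, mean_gfp = 101.7, mean_all = 56.0))
  # boundary: q exactly at the threshold is not enriched
  expect_false(call_enrichment(q = 0.05, mean_gfp = 100, mean_all = 10))
  # ratio exactly 1 is not enriched
  expect_false(call_enrichment(q = 0.01, mean_gfp = 10, mean_all = 10))
  # zero reference with signal: infinite ratio, q decides
  expect_true(call_enrichment(q = 0.01, mean_gfp = 50, mean_all = 0))
  expect_false(call_enrichment(q = 0.2, mean_gfp = 50, mean_all = 0))
})

test_that("fold changes reproduce worked-example values at one decimal", {
  expect_equal(round(fold_change(265.6, 34.4), 1), 7.7)
  expect_equal(round(fold_change(19547.2, 2917.5), 1), 6.7)
  expect_equal(round(fold_change(67.0, 9.8), 1), 6.8)
  expect_equal(fold_change(10, 10), 1.0)
  expect_true(is.infinite(fold_change(5, 0)))
  expect_true(is.na(fold_change(0, 0)))
  # reciprocal identity
  expect_equal(fold_change(7, 3) * fold_change(3, 7), 1, tolerance = 1e-12)
})

test_that("subtractive set arithmetic reproduces known counts and identities", {
  set.seed(15)
  universe <- paste0("g", 1:2000)
  wt <- sample(universe, 574)
  mut <- c(sample(wt, 421), sample(setdiff(universe, wt), 446))
  s <- subtract_sets(wt, mut, universe)
  expect_equal(unname(s$counts["shared"]), 421)
  expect_equal(unname(s$counts["wt_only"]), 153)
  expect_equal(unname(s$counts["mut_only"]), 446)
  expect_equal(unname(s$counts["preferential"]), 599)
  # identities hold for arbitrary random sets
  for (i in 1:10) {
    a <- sample(universe, sample(50:500, 1))
    b <- sample(universe, sample(50:500, 1))
    cs <- subtract_sets(a, b, universe)$counts
    expect_equal(unname(cs["shared"] + cs["wt_only"]), length(a))
    expect_equal(unname(cs["shared"] + cs["mut_only"]), length(b))
    expect_equal(unname(cs["wt_only"] + cs["mut_only"]),
                 unname(cs["preferential"]))
  }
  # identical sets: empty symmetric difference
  expect_equal(unname(subtract_sets(wt, wt)$counts["preferential"]), 0)
})

test_that("planted transcripts are recovered and land in the wt-only set", {
  sim <- simulate_counts(count_sim_spec(), seed = 7)
  r <- run_enrichment(sim$wt, sim$mut)
  planted <- sim$truth$planted_genes
  called <- r$wt$gene[r$wt$enriched]
  sens <- mean(planted %in% called)
  fdr <- if (length(called)) mean(!(called %in% planted)) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
  expect_gte(mean(r$category[planted] == "wt_only"), 0.9)
})

test_that("marker validation reports planted positives and null negatives", {
  sim <- simulate_counts(count_sim_spec(n_planted = 20), seed = 9)
  res <- enrich_genotype(sim$wt$counts, sim$wt$meta)
  positives <- sim$truth$planted_genes
  # abundant genes shared across all types act as negative markers
  shared <- setdiff(res$gene[res$mean_all > 100], positives)
  negatives <- head(shared, 10)
  v <- validate_markers(res, positive = positives, negative = negatives)
  expect_gte(v$n_pos_pass / length(positives), 0.9)
  expect_equal(v$n_neg_pass, length(negatives))
  vu <- validate_markers(res, positive = c("nonexistent-1"))
  expect_equal(vu$unresolved, "nonexistent-1")
  v0 <- validate_markers(res)
  expect_true(v0$pass)
})

test_that("count matrices round-trip through TSV and seeds reproduce them", {
  sim <- simulate_counts(count_sim_spec(n_genes = 120, n_planted = 5),
                         seed = 33)
  sim2 <- simulate_counts(count_sim_spec(n_genes = 120, n_planted = 5),
                          seed = 33)
  expect_identical(sim$wt$counts, sim2$wt$counts)
  expect_identical(sim$mut$counts, sim2$mut$counts)

  tmp_c <- tempfile(fileext = ".tsv"); tmp_m <- tempfile(fileext = ".tsv")
  write_counts_tsv(sim$wt, tmp_c, tmp_m)
  back <- read_counts_tsv(tmp_c, tmp_m)
  expect_equal(unname(back$counts), unname(sim$wt$counts))
  expect_equal(back$meta$fraction, sim$wt$meta$fraction)
})
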