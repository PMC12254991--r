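test_that("window construction follows half-open 1-Mb interval arithmetic", {
  map <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                    pos_bp = c(1e5, 5e5, 15e5))
  wm <- build_windows(map)
  expect_equal(wm$members, list(c(1L, 2L), 2L, 3L))
  expect_true(is.logical(wm$windows$duplicate))

  # SNP exactly 1 Mb after the anchor is excluded
  map2 <- data.frame(snp_id = c("a", "b"), chrom = "1",
                     pos_bp = c(1e6, 2e6))
  expect_equal(build_windows(map2)$members, list(1L, 2L))

  # single-SNP genome
  map3 <- data.frame(snp_id = "only", chrom = "7", pos_bp = 123L)
  expect_equal(build_windows(map3)$members, list(1L))

  # unsorted input is a data error
  expect_error(build_windows(data.frame(snp_id = c("a", "b"), chrom = "1",
                                        pos_bp = c(200L, 100L))), "sorted")
  # duplicate member sets (co-located anchors) are kept but flagged
  map4 <- data.frame(snp_id = c("a", "b"), chrom = "1",
                     pos_bp = c(100L, 100L))
  expect_equal(build_windows(map4)$windows$duplicate, c(FALSE, TRUE))
})

test_that("a single active SNP gives its windows all the genetic variance", {
  set.seed(41)
  g <- toy_genotypes(matrix(rbinom(200, 2, 0.4), 20, 10),
                     pos = (1:10) * 2e6) # disjoint single-SNP windows
  al <- array(0, c(5, 10, 2))
  al[, 4, 1] <- 0.7; al[, 4, 2] <- -0.3
  fit <- fake_fit(al, g)
  wm <- build_windows(g$map)
  wr <- window_variance(fit, wm, g)
  expect_equal(wr$pct_var_trait1[4], 100)
  expect_equal(wr$pct_var_trait2[4], 100)
  expect_equal(wr$pct_var_trait1[-4], rep(0, 9))
  expect_equal(wr$ppa_trait1, c(rep(0, 3), 1, rep(0, 6)))
})

test_that("orthogonal equal-variance SNPs split the share 50/50 and sum to 100", {
  # hand-built orthogonal dosage columns: balanced 0/2 patterns
  geno <- cbind(rep(c(0, 2), each = 10),
                rep(rep(c(0, 2), each = 5), 2))
  expect_equal(sum((geno[, 1] - mean(geno[, 1])) *
                     (geno[, 2] - mean(geno[, 2]))), 0)
  g <- toy_genotypes(geno, chrom = c("1", "2"), pos = c(100L, 100L))
  al <- array(0, c(3, 2, 2))
  al[, 1, 1] <- 0.5; al[, 2, 1] <- 0.5 # equal Var(z alpha)
  al[, 1, 2] <- 1.0; al[, 2, 2] <- -1.0
  fit <- fake_fit(al, g)
  wm <- build_windows(g$map)
  wr <- window_variance(fit, wm, g)
  expect_equal(wr$pct_var_trait1, c(50, 50), tolerance = 1e-10)
  expect_equal(sum(wr$pct_var_trait1), 100, tolerance = 1e-6)
  expect_equal(sum(wr$pct_var_trait2), 100, tolerance = 1e-6)
})

test_that("disjoint-window shares on orthogonalized columns sum to 100", {
  set.seed(43)
  n <- 40; k <- 12
  raw <- matrix(rnorm(n * k), n, k)
  # columns exactly orthogonal to each other AND to the constant (zero mean)
  ortho <- qr.Q(qr(cbind(1, raw)))[, -1]
  g <- toy_genotypes(matrix(rbinom(n * k, 2, 0.5), n, k),
                     pos = (1:k) * 2e6)
  wm <- build_windows(g$map)
  al <- array(0, c(4, k, 2))
  for (s in 1:4) al[s, sample(k, 6), ] <- rnorm(12)
  fit <- fake_fit(al, g)
  # swap in the orthogonal covariates through the genotype container
  g$geno <- ortho * 2
  rownames(g$geno) <- fit$animal_ids
  colnames(g$geno) <- fit$snp_ids
  wr <- suppressWarnings(window_variance(fit, wm, g))
  expect_equal(sum(wr$pct_var_trait1), 100, tolerance = 1e-6)
  expect_equal(sum(wr$pct_var_trait2), 100, tolerance = 1e-6)
})

test_that("all-null draws are flagged as having no genetic variance", {
  g <- toy_genotypes(matrix(rbinom(40, 2, 0.4), 10, 4))
  fit <- fake_fit(array(0, c(5, 4, 2)), g)
  wm <- build_windows(g$map)
  wr <- window_variance(fit, wm, g)
  expect_true(attr(wr, "no_genetic_variance"))
  expect_true(all(is.na(wr$pct_var_trait1)))
})

test_that("window genetic correlations behave on constructed draws", {
  set.seed(44)
  g <- toy_genotypes(matrix(rbinom(120, 2, 0.4), 30, 4), pos = (1:4) * 2e6)
  al <- array(0, c(6, 4, 2))
  al[, 1, 1] <- rnorm(6, 1, .2); al[, 1, 2] <- 2 * al[, 1, 1] # proportional
  al[, 2, 1] <- 1; al[, 2, 2] <- -1                            # sign-flipped
  al[, 3, 1] <- 0.5                                            # trait 1 only
  fit <- fake_fit(al, g)
  r1 <- window_genetic_correlation(fit, 1L, g)
  expect_equal(r1$mean, 1); expect_equal(r1$sd, 0)
  r2 <- window_genetic_correlation(fit, 2L, g)
  expect_equal(r2$mean, -1)
  r3 <- window_genetic_correlation(fit, 3L, g)
  expect_true(r3$undefined)
  expect_equal(r3$n_draws, 0L)
  # window_variance carries the same statistics
  wm <- build_windows(g$map)
  wr <- window_variance(fit, wm, g)
  expect_equal(wr$gencor_mean[1], 1)
  expect_equal(wr$gencor_mean[2], -1)
  expect_true(is.na(wr$gencor_mean[3]) || wr$gencor_ndraws[3] == 0)
})

test_that("region calling honours the threshold direction and merges overlap", {
  base <- data.frame(
    window_id = 1:3, chrom = "1", anchor = c("a", "b", "c"),
    start_bp = c(1e6, 2e6, 3e6), end_bp = c(1.9e6, 3.1e6, 3.9e6),
    n_snps = 1L, duplicate = FALSE,
    pct_var_trait1 = c(0.74, 0.75, 0.76),
    ppa_trait1 = 0.5
  )
  class(base) <- c("window_result", "data.frame")
  reg <- call_regions(base, 0.75)
  expect_equal(nrow(reg), 1) # windows 2 and 3 flagged ("at least") and merged
  expect_equal(reg$start_bp, 2e6)
  expect_equal(reg$end_bp, 3.9e6)
  expect_equal(reg$n_windows, 2)
  expect_equal(reg$max_pct_var, 0.76)

  # non-overlapping flagged windows stay separate regions
  base$end_bp <- c(1.1e6, 2.1e6, 3.1e6)
  expect_equal(nrow(call_regions(base, 0.75)), 2)

  # different chromosomes never merge
  base$chrom <- c("1", "2", "2")
  base$pct_var_trait1 <- c(0.8, 0.8, 0.8)
  base$start_bp <- c(1e6, 1e6, 1.05e6)
  base$end_bp <- c(2e6, 2e6, 2.05e6)
  reg <- call_regions(base, 0.75)
  expect_equal(nrow(reg), 2)
  expect_setequal(reg$chrom, c("1", "2"))
})

test_that("region PPA counts draws with any included member SNP", {
  g <- toy_genotypes(matrix(rbinom(100, 2, 0.4), 10, 10),
                     pos = c((1:5) * 1e5, (1:5) * 1e5 + 5e6))
  al <- array(0, c(10, 10, 2))
  al[1:4, 2, 1] <- 1  # member of the first cluster, trait 1
  al[3:8, 4, 1] <- -1 # another member; union covers draws 1:8
  fit <- fake_fit(al, g)
  wm <- build_windows(g$map)
  wr <- window_variance(fit, wm, g)
  reg <- call_regions(wr, threshold_pct = 0.5, wmap = wm, fit = fit)
  r1 <- reg[reg$trait == 1 & reg$start_bp < 5e6, ]
  expect_equal(r1$region_ppa[1], 0.8)
})
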