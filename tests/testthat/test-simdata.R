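test_that("founder simulation respects the frequency band and determinism", {
  cfg <- sim_config(n_snps = 400, n_chromosomes = 2,
                    founder_maf_low = 0.5, founder_maf_high = 0.5,
                    n_sires_per_line = 30, n_dams_per_line = 120, seed = 4)
  g <- simulate_founders(cfg)
  n <- nrow(g$geno)
  # p = 0.5 means mean dosage 1.0 within 3 binomial SE per SNP
  se <- sqrt(2 * 0.5 * 0.5 / n)
  expect_true(all(abs(colMeans(g$geno) - 1) <= 3 * se + 1e-12))
  # positions strictly ordered within chromosome, dosages in range
  expect_true(all(g$geno %in% 0:2))
  for (ch in unique(g$map$chrom)) {
    expect_false(is.unsorted(g$map$pos_bp[g$map$chrom == ch]))
  }
  g2 <- simulate_founders(cfg)
  expect_identical(g$geno, g2$geno)
  expect_identical(g$map, g2$map)

  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(founder_maf_low = 0.6), "band")
  expect_error(sim_config(h2 = c(0.6, 0.6), c2 = c(0.4, 0.4)), "residual")
})

test_that("gene dropping is Mendelian-consistent and respects linkage", {
  cfg <- sim_config(n_snps = 10, n_chromosomes = 1, seed = 5)
  founders <- simulate_founders(cfg)
  # force informative parent states at the first two SNPs
  f <- founders
  s <- rownames(f$geno)[1]; d <- rownames(f$geno)[2]
  f$haplo[[1]][s, ] <- 0L; f$haplo[[2]][s, ] <- 0L   # sire homozygous 0
  f$haplo[[1]][d, ] <- 1L; f$haplo[[2]][d, ] <- 1L   # dam homozygous 2
  f$geno <- f$haplo[[1]] + f$haplo[[2]]
  kids <- sprintf("k%02d", 1:50)
  ped <- rbind(
    data.frame(animal = c(s, d), sire = NA, dam = NA),
    data.frame(animal = kids, sire = s, dam = d)
  )
  dropped <- gene_drop(ped, f, seed = 6)
  expect_true(all(dropped$geno[kids, ] == 1)) # 0 x 2 cross -> all het

  # zero bp distance -> no recombination across 1,000 meioses
  map0 <- data.frame(snp_id = c("m1", "m2"), chrom = "1",
                     pos_bp = c(5000L, 5000L))
  h1 <- matrix(1L, 2, 2, dimnames = list(c("p", "q"), map0$snp_id))
  h2 <- matrix(0L, 2, 2, dimnames = list(c("p", "q"), map0$snp_id))
  f0 <- genotype_data(h1 + h2, map0, haplo = list(h1, h2))
  kids <- sprintf("c%04d", 1:1000)
  ped0 <- rbind(data.frame(animal = c("p", "q"), sire = NA, dam = NA),
                data.frame(animal = kids, sire = "p", dam = "q"))
  d0 <- gene_drop(ped0, f0, seed = 8)
  # each transmitted gamete must be (1,1) or (0,0): zero recombinants
  gam <- rbind(d0$haplo[[1]][kids, ], d0$haplo[[2]][kids, ])
  expect_identical(sum(gam[, 1] != gam[, 2]), 0L)

  # missing founder genotypes and half-known parents are errors
  expect_error(gene_drop(rbind(ped0, data.frame(animal = "x", sire = "p",
                                                dam = NA)), f0),
               "both parents")
})

test_that("degenerate phenotype model reproduces the residual covariance", {
  # no QTL, h2 = c2 = 0 up to a tiny epsilon: phenotypic covariance ~ R
  eps <- 1e-6
  cfg <- sim_config(n_snps = 50, h2 = c(eps, eps), c2 = c(eps, eps),
                    r_e = 0.3, seed = 10)
  n <- 2000
  ped <- data.frame(animal = sprintf("i%04d", 1:n), sire = NA, dam = NA)
  g <- toy_genotypes(matrix(rbinom(n * 50, 2, 0.3), n, 50,
                            dimnames = list(ped$animal, NULL)))
  sim <- simulate_phenotypes(g, ped, cfg, seed = 11)
  y <- cbind(sim$phenotypes$y1, sim$phenotypes$y2)
  # remove the generated fixed effects before comparing covariances
  y[, 1] <- resid(lm(y[, 1] ~ factor(sim$phenotypes$month) +
                       sim$phenotypes$sex + factor(sim$phenotypes$parity)))
  y[, 2] <- resid(lm(y[, 2] ~ factor(sim$phenotypes$month) +
                       sim$phenotypes$sex + factor(sim$phenotypes$parity)))
  expect_equal(unname(cov(y)), sim$varcomp$R, tolerance = 0.08)
})

test_that("a shared QTL with unit effect correlation gives proportional genetic values", {
  qtl <- data.frame(chrom = "1", pos_bp = 5e6, share1 = 0.2, share2 = 0.2,
                    cor = 1)
  cfg <- sim_config(n_snps = 100, n_chromosomes = 1, qtl_spec = qtl,
                    seed = 12)
  sim <- simulate_divergent_lines(cfg)
  qv <- sim$genotypes$geno[, rowSums(abs(sim$true_effects)) > 0, drop = FALSE]
  gvals <- qv %*% sim$true_effects[rowSums(abs(sim$true_effects)) > 0, ,
                                   drop = FALSE]
  expect_equal(cor(gvals[, 1], gvals[, 2]), 1, tolerance = 1e-12)
})

test_that("midparent-offspring regression recovers the simulated heritability", {
  # random-mating two-generation design as an independent quantitative-genetic
  # oracle: the slope of offspring litter means on midparent estimates h2
  cfg <- sim_config(n_snps = 200, h2 = c(0.3, 0.49), c2 = c(0.1, 0.1),
                    n_sires_per_line = 25, n_dams_per_line = 125, seed = 13)
  set.seed(14)
  n_s <- 50; n_d <- 250; per <- 8
  sires <- sprintf("S%03d", 1:n_s); dams <- sprintf("D%03d", 1:n_d)
  kid_dam <- rep(dams, each = per)
  kid_sire <- rep(rep(sires, length.out = n_d), each = per)
  kids <- sprintf("K%04d", seq_along(kid_dam))
  ped <- rbind(data.frame(animal = c(sires, dams), sire = NA, dam = NA),
               data.frame(animal = kids, sire = kid_sire, dam = kid_dam))
  founders <- simulate_founders(cfg)
  rownames(founders$geno) <- rownames(founders$haplo[[1]]) <-
    rownames(founders$haplo[[2]]) <- c(sires, dams,
                                       sprintf("unused%02d",
                                               seq_len(nrow(founders$geno) -
                                                         n_s - n_d)))
  dropped <- gene_drop(ped, founders, seed = 15)
  sim <- simulate_phenotypes(dropped, ped, cfg, seed = 16)
  ph <- sim$phenotypes
  mid <- (ph$y2[match(kid_sire, ph$animal_id)] +
            ph$y2[match(kid_dam, ph$animal_id)]) / 2
  kid_y <- ph$y2[match(kids, ph$animal_id)]
  lit <- tapply(kid_y, kid_dam, mean)
  midl <- tapply(mid, kid_dam, mean)
  fit <- lm(lit ~ midl[names(lit)])
  ci <- confint(fit)[2, ]
  expect_gt(0.49, ci[1])
  expect_lt(0.49, ci[2])
})

test_that("founder count guards selection and ranking is reproducible", {
  cfg <- sim_config(n_sires_per_line = 8, n_dams_per_line = 15,
                    progeny_per_dam = 4, n_snps = 60, seed = 20)
  cand <- data.frame(
    animal_id = sprintf("x%02d", 1:40),
    line = rep(c("H", "L"), each = 20),
    sex = rep(c("M", "F"), 20),
    sire = NA_character_, dam = NA_character_,
    y1 = rnorm(40), y2 = rnorm(40), stringsAsFactors = FALSE
  )
  expect_error(apply_divergent_selection(cand, cfg), "too few")

  cfg2 <- sim_config(n_sires_per_line = 4, n_dams_per_line = 6,
                     n_snps = 60, seed = 20)
  m1 <- apply_divergent_selection(cand, cfg2)
  m2 <- apply_divergent_selection(cand, cfg2)
  expect_identical(m1, m2)
  # H takes the top trait-2 males, L the bottom
  top_H_males <- cand[cand$line == "H" & cand$sex == "M", ]
  top_H_males <- top_H_males[order(-top_H_males$y2, top_H_males$animal_id), ]
  expect_setequal(unique(m1$sire[m1$line == "H"]),
                  top_H_males$animal_id[1:4])
})

test_that("divergent selection separates the line means on the selected trait", {
  ok <- 0
  for (seed in 1:5) {
    qtl <- data.frame(chrom = "1", pos_bp = 2e7, share1 = 0, share2 = 0.15,
                      cor = 1)
    cfg <- sim_config(n_generations = 3, n_snps = 300, n_chromosomes = 2,
                      qtl_spec = qtl, seed = seed)
    sim <- simulate_divergent_lines(cfg)
    last <- sim$phenotypes[sim$phenotypes$generation == 3, ]
    dH <- mean(last$y2[last$line == "H"])
    dL <- mean(last$y2[last$line == "L"])
    ok <- ok + (dH > dL)
  }
  expect_gte(ok, 4)
})

test_that("selection drives allele-frequency divergence at QTL above neutral drift", {
  qtl_div <- c(); neut_div <- c()
  for (seed in 1:5) {
    qtl <- data.frame(chrom = "1", pos_bp = 1.5e7, share1 = 0,
                      share2 = 0.25, cor = 1)
    cfg <- sim_config(n_generations = 3, n_snps = 200, n_chromosomes = 4,
                      qtl_spec = qtl, seed = 40 + seed)
    sim <- simulate_divergent_lines(cfg)
    last <- sim$phenotypes$animal_id[sim$phenotypes$generation == 3]
    ln <- sim$line_assignment[last]
    G <- sim$genotypes$geno[last, ]
    dp <- abs(colMeans(G[ln == "H", ]) - colMeans(G[ln == "L", ])) / 2
    qi <- which(rowSums(abs(sim$true_effects)) > 0)
    qtl_div <- c(qtl_div, dp[qi])
    # unlinked neutral SNPs: other chromosomes only
    neut <- which(sim$genotypes$map$chrom != "1")
    neut_div <- c(neut_div, dp[sample(neut, 40)])
  }
  p <- wilcox.test(qtl_div, neut_div, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("full-sib intraclass correlation matches c2 + h2/2 without QTL", {
  cfg <- sim_config(n_generations = 1, n_snps = 60, h2 = c(0.4, 0.4),
                    c2 = c(0.15, 0.15), n_dams_per_line = 60,
                    progeny_per_dam = 6, seed = 50)
  sim <- simulate_divergent_lines(cfg)
  ph <- sim$phenotypes[sim$phenotypes$generation == 1, ]
  y <- resid(lm(y1 ~ factor(month) + sex + factor(parity), data = ph))
  a <- anova(lm(y ~ factor(ph$litter_id)))
  ms_b <- a$`Mean Sq`[1]; ms_w <- a$`Mean Sq`[2]
  icc <- (ms_b - ms_w) / (ms_b + (cfg$progeny_per_dam - 1) * ms_w)
  expect_lt(abs(icc - (0.15 + 0.4 / 2)), 0.09)
})

test_that("everything is a pure function of config and seed", {
  cfg <- sim_config(n_generations = 1, n_snps = 80, seed = 33)
  s1 <- simulate_divergent_lines(cfg)
  s2 <- simulate_divergent_lines(cfg)
  expect_identical(s1$genotypes$geno, s2$genotypes$geno)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$true_effects, s2$true_effects)
})
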