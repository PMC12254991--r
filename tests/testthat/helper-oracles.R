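# Independent oracles and small fixture builders used across tests.

# Monte-Carlo additive-relationship estimate by gene dropping: founders get
# unique allele labels, alleles are transmitted at random, and a(i,j) is
# twice the probability that randomly drawn alleles from i and j are IBD.
# Independent of the tabular recursion it is used to check.
genedrop_relationship <- function(ped, reps = 20000, seed = 1) {
  ped <- as_pedigree(ped)
  set.seed(seed)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$animal
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  pat <- mat <- matrix(0L, reps, n)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      pat[, i] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(reps) < 0.5
      pat[, i] <- ifelse(pick, pat[, si[i]], mat[, si[i]])
    }
    if (is.na(di[i])) {
      mat[, i] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(reps) < 0.5
      mat[, i] <- ifelse(pick, pat[, di[i]], mat[, di[i]])
    }
  }
  A_hat <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  A_se <- A_hat
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        score <- (pat[, i] == mat[, i]) * 1
        A_hat[i, i] <- 1 + mean(score)
        A_se[i, i] <- stats::sd(score) / sqrt(reps)
      } else {
        score <- ((pat[, i] == pat[, j]) + (pat[, i] == mat[, j]) +
                    (mat[, i] == pat[, j]) + (mat[, i] == mat[, j])) / 4
        A_hat[i, j] <- A_hat[j, i] <- 2 * mean(score)
        A_se[i, j] <- A_se[j, i] <- 2 * stats::sd(score) / sqrt(reps)
      }
    }
  }
  list(A = A_hat, se = A_se)
}

# three-generation pedigree with a full-sib mating and a cousin mating,
# exercising inbreeding paths of the tabular method
inbred_test_pedigree <- function() {
  data.frame(
    animal = c("f1", "f2", "f3", "f4",
               "a", "b", "c", "d",
               "e", "g", "h", "i", "j"),
    sire = c(NA, NA, NA, NA,
             "f1", "f1", "f3", "f3",
             "a", "a", "c", "e", "e"),
    dam = c(NA, NA, NA, NA,
            "f2", "f2", "f4", "f4",
            "b", "d", "d", "g", "h"),
    stringsAsFactors = FALSE
  )
}

# minimal genotype_data from a dosage matrix on one chromosome
toy_genotypes <- function(geno, chrom = "1",
                          pos = seq_len(ncol(geno)) * 1000L) {
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("s%03d", seq_len(ncol(geno)))
  }
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("a%03d", seq_len(nrow(geno)))
  }
  genotype_data(geno, data.frame(snp_id = colnames(geno),
                                 chrom = rep(chrom, length.out = ncol(geno)),
                                 pos_bp = pos, stringsAsFactors = FALSE))
}

# hand-built posterior container for window algebra tests: alpha_draws is an
# n_save x k x t array; delta mirrors the nonzero pattern
fake_fit <- function(alpha_draws, genotypes, t = dim(alpha_draws)[3]) {
  nS <- dim(alpha_draws)[1]; k <- dim(alpha_draws)[2]
  delta <- (alpha_draws != 0) * 1L
  code <- matrix(0L, nS, k)
  if (t == 1) {
    code[] <- delta[, , 1]
  } else {
    code[] <- delta[, , 1] + 2L * delta[, , 2]
  }
  structure(list(
    samples = list(alpha = alpha_draws, delta = delta, delta_cfg = code),
    n_saved = nS, n = nrow(genotypes$geno), k = k, t = t,
    snp_ids = colnames(genotypes$geno),
    animal_ids = rownames(genotypes$geno),
    ped_id = NULL
  ), class = "bayesb_fit")
}

# standard bivariate prior set used by sampler tests
test_priors <- function(t = 2) {
  if (t == 2) {
    bayesb_priors(R0 = matrix(c(0.5, 0.05, 0.05, 0.5), 2),
                  G0 = diag(0.002, 2),
                  C0 = diag(0.15, 2),
                  U0 = matrix(c(0.43, 0.13, 0.13, 0.49), 2))
  } else {
    bayesb_priors(R0 = matrix(0.5), G0 = matrix(0.002),
                  C0 = matrix(0.15), U0 = matrix(0.45))
  }
}
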