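#' Genotype container
#'
#' Dosage matrix (animals x SNPs, 0/1/2 with NA for missing) plus a SNP map.
#' Phased haplotypes, when available (simulated data), travel along as the
#' `haplo` element: a list of two 0/1 matrices of the same shape.
#'
#' @param geno numeric/integer matrix, animals in rows (rownames = animal IDs),
#'   SNPs in columns (colnames = SNP IDs).
#' @param map data frame with columns `snp_id`, `chrom`, `pos_bp` (1-based),
#'   one row per genotype column, positions non-decreasing within chromosome.
#' @param haplo optional list of two 0/1 matrices (paternal, maternal gamete).
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(geno, map, haplo = NULL) {
  stopifnot(is.matrix(geno), is.data.frame(map))
  need <- c("snp_id", "chrom", "pos_bp")
  if (!all(need %in% names(map))) {
    stop("map needs columns snp_id, chrom, pos_bp", call. = FALSE)
  }
  if (nrow(map) != ncol(geno)) {
    stop("map rows must equal genotype columns", call. = FALSE)
  }
  bad <- !(geno %in% c(0, 1, 2)) & !is.na(geno)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (is.unsorted(p)) {
      stop("map positions must be non-decreasing within chromosome ", ch,
           call. = FALSE)
    }
  }
  if (is.null(colnames(geno))) colnames(geno) <- map$snp_id
  if (is.null(rownames(geno))) rownames(geno) <- seq_len(nrow(geno))
  map$chrom <- as.character(map$chrom)
  structure(list(geno = geno, map = map, haplo = haplo),
            class = "genotype_data")
}

#' @exportS3Method base::print
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", nrow(x$geno), "animals x", ncol(x$geno), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s);",
      sum(is.na(x$geno)), "missing calls\n")
  invisible(x)
}

#' Simulation configuration for a two-line divergent selection experiment
#'
#' Defaults emulate a compact divergent-selection design: two lines bred from a
#' common base population, 8 sires and 40 dams per line and generation, six
#' progeny per litter (so ~240 phenotyped progeny per line and generation,
#' matching the scale of a rabbit selection experiment), selection on trait 2
#' upward in line H and downward in line L. Trait 2 plays the role of the
#' selection criterion (an intramuscular-fat-like trait, heritability 0.49,
#' common-litter fraction 0.17); trait 1 is a correlated carcass-type trait.
#'
#' @param n_generations number of selected generations after the founders.
#' @param n_sires_per_line,n_dams_per_line parents per line per generation.
#' @param progeny_per_dam litter size (full sibs sharing one litter draw).
#' @param n_snps,n_chromosomes,chrom_length_bp marker panel geometry.
#' @param founder_maf_low,founder_maf_high base-population allele-frequency
#'   band in (0, 0.5].
#' @param qtl_spec data frame with columns `chrom`, `pos_bp`, `share1`,
#'   `share2`, `cor`: per-QTL fractions of phenotypic variance per trait and
#'   the sign of the trait-2 effect relative to trait 1 (see
#'   [qtl_window_pair()] for intermediate effect correlations).
#' @param h2 length-2 polygenic heritabilities (excluding QTL shares).
#' @param c2 length-2 common-litter variance fractions.
#' @param r_g_polygenic,r_c,r_e polygenic, litter and residual correlations.
#' @param selection_trait trait index (1 or 2) used as selection criterion.
#' @param selection_direction named vector `c(H = 1, L = -1)`.
#' @param hidden_qtl if TRUE the causal columns are removed from the output
#'   genotypes (LD-only detection regime).
#' @param seed integer RNG seed; all outputs are a pure function of
#'   (config, seed).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_generations = 3,
                       n_sires_per_line = 8,
                       n_dams_per_line = 40,
                       progeny_per_dam = 6,
                       n_snps = 2000,
                       n_chromosomes = 5,
                       chrom_length_bp = 4e7,
                       founder_maf_low = 0.1,
                       founder_maf_high = 0.5,
                       qtl_spec = NULL,
                       h2 = c(0.43, 0.49),
                       c2 = c(0.14, 0.17),
                       r_g_polygenic = 0.28,
                       r_c = 0,
                       r_e = 0.1,
                       selection_trait = 2,
                       selection_direction = c(H = 1, L = -1),
                       hidden_qtl = FALSE,
                       seed = 1) {
  cfg <- list(n_generations = n_generations,
              n_sires_per_line = n_sires_per_line,
              n_dams_per_line = n_dams_per_line,
              progeny_per_dam = progeny_per_dam,
              n_snps = n_snps, n_chromosomes = n_chromosomes,
              chrom_length_bp = chrom_length_bp,
              founder_maf_low = founder_maf_low,
              founder_maf_high = founder_maf_high,
              qtl_spec = qtl_spec, h2 = h2, c2 = c2,
              r_g_polygenic = r_g_polygenic, r_c = r_c, r_e = r_e,
              selection_trait = selection_trait,
              selection_direction = selection_direction,
              hidden_qtl = hidden_qtl, seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_snps < 1) stop("n_snps must be >= 1", call. = FALSE)
  if (cfg$founder_maf_low <= 0 || cfg$founder_maf_high > 0.5 ||
      cfg$founder_maf_low > cfg$founder_maf_high) {
    stop("founder allele-frequency band must satisfy 0 < low <= high <= 0.5",
         call. = FALSE)
  }
  if (length(cfg$h2) != 2 || length(cfg$c2) != 2) {
    stop("h2 and c2 must have length 2", call. = FALSE)
  }
  qshare <- c(0, 0)
  if (!is.null(cfg$qtl_spec)) {
    qs <- cfg$qtl_spec
    need <- c("chrom", "pos_bp", "share1", "share2", "cor")
    if (!all(need %in% names(qs))) {
      stop("qtl_spec needs columns chrom, pos_bp, share1, share2, cor",
           call. = FALSE)
    }
    if (any(qs$pos_bp < 1 | qs$pos_bp > cfg$chrom_length_bp)) {
      stop("QTL positions fall outside chromosome bounds", call. = FALSE)
    }
    qshare <- c(sum(qs$share1), sum(qs$share2))
  }
  tot <- cfg$h2 + cfg$c2 + qshare
  if (any(tot >= 1)) {
    stop("h2 + c2 + QTL variance fractions must sum to < 1 per trait ",
         "(residual fraction must be positive)", call. = FALSE)
  }
  if (!cfg$selection_trait %in% c(1, 2)) {
    stop("selection_trait must be 1 or 2", call. = FALSE)
  }
  for (r in c(cfg$r_g_polygenic, cfg$r_c, cfg$r_e)) {
    if (abs(r) > 1) stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Two-locus QTL block with an intermediate effect correlation
#'
#' A single biallelic locus can only give a within-window genetic correlation
#' of -1, 0 or +1. To plant a window whose two-trait breeding values correlate
#' at an intermediate rho, this helper returns two `qtl_spec` rows: locus A
#' loads on both traits (trait-2 loading rho), locus B loads on trait 2 only
#' (loading sqrt(1 - rho^2)). For linkage-equilibrium loci the window
#' correlation is rho and each trait's total share is as requested.
#'
#' @param chrom chromosome label.
#' @param pos_bp length-2 positions of the two loci (same window).
#' @param share1,share2 total phenotypic-variance fractions per trait.
#' @param rho target within-window genetic correlation in [-1, 1].
#' @return A two-row `qtl_spec` data frame.
#' @export
qtl_window_pair <- function(chrom, pos_bp, share1, share2, rho) {
  stopifnot(length(pos_bp) == 2, abs(rho) <= 1)
  data.frame(
    chrom = as.character(chrom), pos_bp = pos_bp,
    share1 = c(share1, 0),
    share2 = c(rho^2 * share2, (1 - rho^2) * share2),
    cor = c(sign(rho + (rho == 0)), 1)
  )
}

.chol2 <- function(v, r) {
  # 2x2 covariance from variances v and correlation r
  S <- diag(sqrt(v), 2) %*% matrix(c(1, r, r, 1), 2) %*% diag(sqrt(v), 2)
  (S + t(S)) / 2
}

.rmvnorm2 <- function(n, Sigma) {
  L <- t(chol(Sigma + diag(1e-12, nrow(Sigma))))
  t(L %*% matrix(stats::rnorm(n * nrow(Sigma)), nrow(Sigma), n))
}

.build_map <- function(cfg) {
  k <- cfg$n_snps
  per <- rep(k %/% cfg$n_chromosomes, cfg$n_chromosomes)
  per[seq_len(k %% cfg$n_chromosomes)] <- per[seq_len(k %% cfg$n_chromosomes)] + 1L
  chrom <- rep(as.character(seq_len(cfg$n_chromosomes)), per)
  pos <- unlist(lapply(per, function(m) {
    sort(sample.int(cfg$chrom_length_bp, m))
  }))
  map <- data.frame(snp_id = sprintf("snp_%05d", seq_len(k)),
                    chrom = chrom, pos_bp = pos,
                    stringsAsFactors = FALSE)
  # anchor each QTL exactly on a marker (observed-QTL regime)
  if (!is.null(cfg$qtl_spec)) {
    for (q in seq_len(nrow(cfg$qtl_spec))) {
      ch <- as.character(cfg$qtl_spec$chrom[q])
      bp <- cfg$qtl_spec$pos_bp[q]
      on_ch <- which(map$chrom == ch)
      if (!length(on_ch)) stop("QTL on a chromosome with no SNPs", call. = FALSE)
      j <- on_ch[which.min(abs(map$pos_bp[on_ch] - bp))]
      map$pos_bp[j] <- bp
    }
    map <- map[order(match(map$chrom, unique(map$chrom)), map$pos_bp), ]
    map$snp_id <- sprintf("snp_%05d", seq_len(k))
    rownames(map) <- NULL
  }
  map
}

#' Simulate base-population founder genotypes
#'
#' Per-SNP allele frequencies are drawn uniformly on the configured band;
#' founder haplotypes are independent Bernoulli draws (linkage equilibrium in
#' the base population). Returns phased genotypes for the combined founder set
#' of both lines (sires + dams per line).
#'
#' @param config a [sim_config()].
#' @return A [genotype_data()] with haplotypes; attribute `base_freq` carries
#'   the generating allele frequencies.
#' @export
simulate_founders <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  map <- .build_map(cfg)
  k <- cfg$n_snps
  n <- 2 * (cfg$n_sires_per_line + cfg$n_dams_per_line)
  freq <- .base_frequencies(cfg, map)
  h1 <- matrix(stats::rbinom(n * k, 1, rep(freq, each = n)), n, k)
  h2 <- matrix(stats::rbinom(n * k, 1, rep(freq, each = n)), n, k)
  ids <- sprintf("F%04d", seq_len(n))
  g <- h1 + h2
  dimnames(g) <- dimnames(h1) <- dimnames(h2) <- list(ids, map$snp_id)
  out <- genotype_data(g, map, haplo = list(h1, h2))
  attr(out, "base_freq") <- freq
  out
}

# Base-population allele frequencies: uniform on the configured band, except
# that QTL loci are pinned at 0.4 so the configured variance shares are
# attainable and survive selection-driven frequency change (a low-frequency
# causal allele driven toward loss would carry a fraction of its nominal
# variance, silently breaking the scenario the QTL specification states).
.base_frequencies <- function(cfg, map) {
  freq <- stats::runif(nrow(map), cfg$founder_maf_low, cfg$founder_maf_high)
  if (!is.null(cfg$qtl_spec)) {
    freq[.qtl_indices(cfg$qtl_spec, map)] <- 0.4
  }
  freq
}

# Per-gamete recombination switch probabilities: Haldane map at 1 cM/Mb;
# independent segregation (r = 0.5) at chromosome starts.
.recomb_fractions <- function(map) {
  k <- nrow(map)
  r <- rep(0.5, k)
  if (k > 1) {
    same <- map$chrom[-1] == map$chrom[-k]
    d_m <- (map$pos_bp[-1] - map$pos_bp[-k]) * 1e-8 # Morgans at 1 cM/Mb
    r[-1] <- ifelse(same, 0.5 * (1 - exp(-2 * d_m)), 0.5)
  }
  r
}

# One gamete from a parent's two haplotype rows (0/1 vectors).
.meiosis <- function(h1, h2, rfrac) {
  k <- length(h1)
  switches <- stats::runif(k) < rfrac # element 1 picks the starting strand
  strand <- cumsum(switches) %% 2L
  ifelse(strand == 0L, h1, h2)
}

#' Drop founder genotypes through a pedigree
#'
#' Simulates meiosis with recombination (Haldane map function at 1 cM/Mb from
#' bp distances) for every non-founder, in pedigree order. Founders must have
#' phased genotypes; every non-founder must have both parents in the pedigree.
#'
#' @param pedigree pedigree table; founders are rows with unknown parents.
#' @param founder_genotypes [genotype_data()] with haplotypes for all founders.
#' @param map SNP map (defaults to the founder map).
#' @param seed integer seed.
#' @return [genotype_data()] with haplotypes for all pedigree animals.
#' @export
gene_drop <- function(pedigree, founder_genotypes, map = founder_genotypes$map,
                      seed = 1) {
  ped <- as_pedigree(pedigree)
  fg <- founder_genotypes
  if (is.null(fg$haplo)) stop("founder genotypes must be phased", call. = FALSE)
  set.seed(seed)
  rfrac <- .recomb_fractions(map)
  n <- nrow(ped)
  k <- nrow(map)
  H1 <- matrix(0L, n, k, dimnames = list(ped$animal, map$snp_id))
  H2 <- H1
  founders <- is.na(ped$sire) & is.na(ped$dam)
  for (i in which(founders)) {
    id <- ped$animal[i]
    if (!id %in% rownames(fg$haplo[[1]])) {
      stop("missing founder genotype for animal ", id, call. = FALSE)
    }
    H1[i, ] <- fg$haplo[[1]][id, ]
    H2[i, ] <- fg$haplo[[2]][id, ]
  }
  partial <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(partial)) {
    stop("non-founders must have both parents known: ",
         paste(ped$animal[partial][seq_len(min(3, sum(partial)))],
               collapse = ", "), call. = FALSE)
  }
  idx <- seq_len(n); names(idx) <- ped$animal
  for (i in which(!founders)) {
    s <- idx[[ped$sire[i]]]
    d <- idx[[ped$dam[i]]]
    H1[i, ] <- .meiosis(H1[s, ], H2[s, ], rfrac)
    H2[i, ] <- .meiosis(H1[d, ], H2[d, ], rfrac)
  }
  genotype_data(H1 + H2, map, haplo = list(H1, H2))
}

# Resolve qtl_spec rows to SNP column indices; error when absent from the map.
.qtl_indices <- function(qtl_spec, map) {
  vapply(seq_len(nrow(qtl_spec)), function(q) {
    j <- which(map$chrom == as.character(qtl_spec$chrom[q]) &
                 map$pos_bp == qtl_spec$pos_bp[q])
    if (!length(j)) {
      stop("QTL at ", qtl_spec$chrom[q], ":", qtl_spec$pos_bp[q],
           " has no matching SNP in the map", call. = FALSE)
    }
    j[1]
  }, integer(1))
}

# True substitution-effect matrix (k x 2) on the unit-phenotypic-variance
# scale; per-locus dosage variance taken as 2p(1-p) of the base frequencies.
.true_effects <- function(cfg, map, base_freq) {
  k <- nrow(map)
  alpha <- matrix(0, k, 2, dimnames = list(map$snp_id, c("trait1", "trait2")))
  if (is.null(cfg$qtl_spec)) return(alpha)
  qs <- cfg$qtl_spec
  jj <- .qtl_indices(qs, map)
  v <- 2 * base_freq[jj] * (1 - base_freq[jj])
  for (q in seq_along(jj)) {
    a1 <- sqrt(qs$share1[q] / v[q])
    a2 <- sqrt(qs$share2[q] / v[q])
    s2 <- if (qs$share1[q] > 0 && qs$share2[q] > 0) sign(qs$cor[q]) else 1
    if (s2 == 0) s2 <- 1
    alpha[jj[q], ] <- c(a1, s2 * a2)
  }
  alpha
}

# Fixed-effect values used by the generator (phenotypic-SD units, same for
# both traits): month (5 levels, cycling over generations), sex, parity.
.fixed_effect_values <- function() {
  list(month = c(-0.2, -0.1, 0, 0.1, 0.2),
       sex = c(-0.15, 0.15),
       parity = c(-0.1, 0.1))
}

#' Simulate phenotypes for a pedigree of genotyped animals
#'
#' Generates two traits with unit phenotypic variance each under the additive
#' model the association analysis assumes: fixed effects (month by generation
#' cohort, sex, parity), a common-litter effect shared by full sibs, a
#' pedigree polygenic effect (recursive Mendelian-sampling construction), QTL
#' contributions `dosage x true effect`, and a correlated bivariate residual.
#'
#' @param genotypes [genotype_data()] covering every pedigree animal.
#' @param pedigree pedigree table.
#' @param config [sim_config()].
#' @param seed integer seed.
#' @param meta optional data frame (animal_id, generation, sex, litter_id,
#'   month, parity) from the driver; missing columns are generated.
#' @return List with `phenotypes` (data frame), `true_effects` (k x 2),
#'   `components` (per-animal u, c, e draws) and `varcomp` (generating C, U, R
#'   and QTL shares).
#' @export
simulate_phenotypes <- function(genotypes, pedigree, config, seed = 1,
                                meta = NULL) {
  cfg <- validate_sim_config(config)
  ped <- as_pedigree(pedigree)
  g <- genotypes
  set.seed(seed)
  n <- nrow(ped)
  ids <- ped$animal
  if (!all(ids %in% rownames(g$geno))) {
    stop("every pedigree animal needs a genotype row", call. = FALSE)
  }
  base_freq <- attr(g, "base_freq")
  if (is.null(base_freq)) {
    p <- colMeans(g$geno, na.rm = TRUE) / 2
    base_freq <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  }
  alpha <- .true_effects(cfg, g$map, base_freq)
  qshare <- if (is.null(cfg$qtl_spec)) c(0, 0) else
    c(sum(cfg$qtl_spec$share1), sum(cfg$qtl_spec$share2))
  U <- .chol2(cfg$h2, cfg$r_g_polygenic)
  C <- .chol2(cfg$c2, cfg$r_c)
  R <- .chol2(1 - cfg$h2 - cfg$c2 - qshare, cfg$r_e)

  idx <- seq_len(n); names(idx) <- ids
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  # generation = pedigree depth
  gen <- integer(n)
  for (i in seq_len(n)) {
    gp <- c(if (!is.na(si[i])) gen[si[i]], if (!is.na(di[i])) gen[di[i]])
    gen[i] <- if (length(gp)) max(gp) + 1L else 0L
  }
  if (is.null(meta)) {
    meta <- data.frame(animal_id = ids, generation = gen,
                       sex = sample(c("M", "F"), n, replace = TRUE),
                       parity = sample(1:2, n, replace = TRUE),
                       stringsAsFactors = FALSE)
    meta$litter_id <- ifelse(is.na(ped$dam), paste0("lit_base_", ids),
                             paste0("lit_", ped$dam, "_g", gen))
    # slaughter-batch month: litters cycle over 5 levels
    meta$month <- ((as.integer(factor(meta$litter_id)) - 1L) %% 5L) + 1L
  } else {
    meta <- meta[match(ids, meta$animal_id), , drop = FALSE]
  }
  fe <- .fixed_effect_values()
  # polygenic recursion: founders ~ N(0, U); offspring = midparent + N(0, U/2)
  u <- matrix(0, n, 2)
  founders <- is.na(si) & is.na(di)
  u[founders, ] <- .rmvnorm2(sum(founders), U)
  ms <- .rmvnorm2(n, 0.5 * U)
  for (i in which(!founders)) {
    u[i, ] <- 0.5 * (u[si[i], ] + u[di[i], ]) + ms[i, ]
  }
  lit <- factor(meta$litter_id)
  cl <- .rmvnorm2(nlevels(lit), C)
  cmat <- cl[as.integer(lit), , drop = FALSE]
  e <- .rmvnorm2(n, R)
  qcols <- which(rowSums(abs(alpha)) > 0)
  qv <- if (length(qcols)) {
    g$geno[ids, qcols, drop = FALSE] %*% alpha[qcols, , drop = FALSE]
  } else matrix(0, n, 2)
  fx <- fe$month[meta$month] + fe$sex[as.integer(factor(meta$sex, c("M", "F")))] +
    fe$parity[meta$parity]
  y <- cbind(fx, fx) + cmat + u + qv + e
  phen <- data.frame(animal_id = ids, generation = meta$generation,
                     sex = meta$sex, month = meta$month, parity = meta$parity,
                     litter_id = meta$litter_id,
                     y1 = y[, 1], y2 = y[, 2], stringsAsFactors = FALSE)
  list(phenotypes = phen, true_effects = alpha,
       components = list(u = u, c = cmat, e = e, qtl = qv),
       varcomp = list(C = C, U = U, R = R, qtl_shares = qshare))
}

#' Select parents for the next generation of a divergent selection scheme
#'
#' Ranks candidates within line on the selection trait's phenotype (direction
#' +1 selects the highest, -1 the lowest; ties broken by animal ID), takes the
#' required number of sires (males) and dams (females), and mates them
#' round-robin while avoiding full-sib pairs when possible.
#'
#' @param candidates phenotype data frame with columns `animal_id`, `line`,
#'   `sex`, `sire`, `dam`, and the trait columns `y1`, `y2`.
#' @param config [sim_config()].
#' @return Data frame of matings (`line`, `sire`, `dam`).
#' @export
apply_divergent_selection <- function(candidates, config) {
  cfg <- validate_sim_config(config)
  ycol <- paste0("y", cfg$selection_trait)
  out <- list()
  for (ln in names(cfg$selection_direction)) {
    dirn <- cfg$selection_direction[[ln]]
    cc <- candidates[candidates$line == ln, , drop = FALSE]
    males <- cc[cc$sex == "M", , drop = FALSE]
    females <- cc[cc$sex == "F", , drop = FALSE]
    if (nrow(males) < cfg$n_sires_per_line ||
        nrow(females) < cfg$n_dams_per_line) {
      stop("too few candidates in line ", ln, " (need ",
           cfg$n_sires_per_line, " males and ", cfg$n_dams_per_line,
           " females)", call. = FALSE)
    }
    pick <- function(df, m) {
      o <- order(-dirn * df[[ycol]], df$animal_id)
      df[o[seq_len(m)], , drop = FALSE]
    }
    sires <- pick(males, cfg$n_sires_per_line)
    dams <- pick(females, cfg$n_dams_per_line)
    sire_of <- rep(seq_len(nrow(sires)), length.out = nrow(dams))
    # avoid full-sib matings by rotating the assigned sire where possible
    for (i in seq_len(nrow(dams))) {
      tries <- 0
      while (tries < nrow(sires) &&
             identical(sires$sire[sire_of[i]], dams$sire[i]) &&
             identical(sires$dam[sire_of[i]], dams$dam[i]) &&
             !is.na(dams$sire[i])) {
        sire_of[i] <- sire_of[i] %% nrow(sires) + 1L
        tries <- tries + 1
      }
    }
    out[[ln]] <- data.frame(line = ln, sire = sires$animal_id[sire_of],
                            dam = dams$animal_id, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate a full two-line divergent selection experiment
#'
#' Drives the generator end to end: a common base population founds two lines;
#' each generation, parents are selected on trait 2's phenotype (upward in H,
#' downward in L by default), mated, and litters of full sibs are produced by
#' gene dropping with recombination. All animals are genotyped and phenotyped.
#'
#' @param config [sim_config()].
#' @return List of class `sim_output`: `genotypes`, `phenotypes` (with `line`,
#'   `sire`, `dam` columns), `pedigree`, `true_effects`,
#'   `true_variance_components`, `line_assignment`, and `final_generation`
#'   (animal IDs of the last, GWAS-ready cohort).
#' @export
simulate_divergent_lines <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  map <- .build_map(cfg)
  k <- cfg$n_snps
  freq <- .base_frequencies(cfg, map)
  alpha <- .true_effects(cfg, map, freq)
  qshare <- if (is.null(cfg$qtl_spec)) c(0, 0) else
    c(sum(cfg$qtl_spec$share1), sum(cfg$qtl_spec$share2))
  U <- .chol2(cfg$h2, cfg$r_g_polygenic)
  C <- .chol2(cfg$c2, cfg$r_c)
  R <- .chol2(1 - cfg$h2 - cfg$c2 - qshare, cfg$r_e)
  fe <- .fixed_effect_values()
  rfrac <- .recomb_fractions(map)
  qcols <- which(rowSums(abs(alpha)) > 0)

  n_par <- cfg$n_sires_per_line + cfg$n_dams_per_line
  lines <- names(cfg$selection_direction)
  # founder cohort (generation 0), split evenly between lines
  n0 <- 2 * n_par
  ids0 <- sprintf("G0_%04d", seq_len(n0))
  H1 <- matrix(stats::rbinom(n0 * k, 1, rep(freq, each = n0)), n0, k)
  H2 <- matrix(stats::rbinom(n0 * k, 1, rep(freq, each = n0)), n0, k)
  rownames(H1) <- rownames(H2) <- ids0
  colnames(H1) <- colnames(H2) <- map$snp_id
  line0 <- rep(lines, each = n_par)
  sex0 <- rep(c(rep("M", cfg$n_sires_per_line), rep("F", cfg$n_dams_per_line)),
              2)
  anim <- data.frame(animal_id = ids0, sire = NA_character_,
                     dam = NA_character_, line = line0, generation = 0L,
                     sex = sex0,
                     month = ((seq_len(n0) - 1L) %% 5L) + 1L,
                     parity = sample(1:2, n0, replace = TRUE),
                     litter_id = paste0("lit_base_", ids0),
                     stringsAsFactors = FALSE)
  u <- .rmvnorm2(n0, U)
  rownames(u) <- ids0
  draw_pheno <- function(block, ublock, H1b, H2b) {
    nb <- nrow(block)
    lit <- factor(block$litter_id)
    cl <- .rmvnorm2(nlevels(lit), C)
    cb <- cl[as.integer(lit), , drop = FALSE]
    eb <- .rmvnorm2(nb, R)
    gq <- (H1b + H2b)[, qcols, drop = FALSE]
    qv <- if (length(qcols)) gq %*% alpha[qcols, , drop = FALSE]
          else matrix(0, nb, 2)
    fx <- fe$month[block$month] +
      fe$sex[as.integer(factor(block$sex, c("M", "F")))] +
      fe$parity[block$parity]
    cbind(fx, fx) + cb + ublock + qv + eb
  }
  y <- draw_pheno(anim, u, H1, H2)
  anim$y1 <- y[, 1]; anim$y2 <- y[, 2]

  all_anim <- anim
  all_H1 <- H1; all_H2 <- H2; all_u <- u
  current <- anim

  for (g in seq_len(cfg$n_generations)) {
    matings <- apply_divergent_selection(current, cfg)
    nd <- nrow(matings)
    npr <- nd * cfg$progeny_per_dam
    ids <- sprintf("G%d_%04d", g, seq_len(npr))
    sire <- rep(matings$sire, each = cfg$progeny_per_dam)
    dam <- rep(matings$dam, each = cfg$progeny_per_dam)
    line <- rep(matings$line, each = cfg$progeny_per_dam)
    block <- data.frame(animal_id = ids, sire = sire, dam = dam, line = line,
                        generation = g,
                        sex = sample(c("M", "F"), npr, replace = TRUE),
                        # slaughter-batch month: litters cycle over 5 levels
                        month = rep(((seq_len(nd) - 1L) %% 5L) + 1L,
                                    each = cfg$progeny_per_dam),
                        parity = rep(sample(1:2, nd, replace = TRUE),
                                     each = cfg$progeny_per_dam),
                        litter_id = paste0("lit_", dam, "_g", g),
                        stringsAsFactors = FALSE)
    H1b <- matrix(0L, npr, k, dimnames = list(ids, map$snp_id))
    H2b <- H1b
    for (i in seq_len(npr)) {
      H1b[i, ] <- .meiosis(all_H1[sire[i], ], all_H2[sire[i], ], rfrac)
      H2b[i, ] <- .meiosis(all_H1[dam[i], ], all_H2[dam[i], ], rfrac)
    }
    ub <- 0.5 * (all_u[sire, , drop = FALSE] + all_u[dam, , drop = FALSE]) +
      .rmvnorm2(npr, 0.5 * U)
    rownames(ub) <- ids
    y <- draw_pheno(block, ub, H1b, H2b)
    block$y1 <- y[, 1]; block$y2 <- y[, 2]
    all_anim <- rbind(all_anim, block)
    all_H1 <- rbind(all_H1, H1b); all_H2 <- rbind(all_H2, H2b)
    all_u <- rbind(all_u, ub)
    current <- block
  }

  keep <- seq_len(k)
  if (cfg$hidden_qtl && length(qcols)) keep <- setdiff(keep, qcols)
  geno <- genotype_data((all_H1 + all_H2)[, keep, drop = FALSE],
                        map[keep, , drop = FALSE],
                        haplo = list(all_H1[, keep, drop = FALSE],
                                     all_H2[, keep, drop = FALSE]))
  attr(geno, "base_freq") <- freq[keep]
  ped <- data.frame(animal = all_anim$animal_id, sire = all_anim$sire,
                    dam = all_anim$dam, stringsAsFactors = FALSE)
  line_assignment <- stats::setNames(all_anim$line, all_anim$animal_id)
  structure(list(
    genotypes = geno,
    phenotypes = all_anim,
    pedigree = as_pedigree(ped),
    true_effects = alpha,
    true_variance_components = list(C = C, U = U, R = R,
                                    qtl_shares = qshare,
                                    qtl_spec = cfg$qtl_spec),
    true_polygenic = all_u,
    line_assignment = line_assignment,
    final_generation = all_anim$animal_id[all_anim$generation ==
                                            cfg$n_generations],
    config = cfg
  ), class = "sim_output")
}

#' @exportS3Method base::print
print.sim_output <- function(x, ...) {
  cat("sim_output:", nrow(x$phenotypes), "animals over",
      max(x$phenotypes$generation), "selected generation(s);",
      ncol(x$genotypes$geno), "SNPs;",
      sum(rowSums(abs(x$true_effects)) > 0), "QTL\n")
  invisible(x)
}
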