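#' SNP quality-control filter
#'
#' Retains SNPs with call rate >= `min_call_rate`, minor allele frequency
#' >= `min_maf` (computed on non-missing calls, after the call-rate check) and
#' a position on a known autosome. Threshold directions follow the usual
#' convention: `>=` keeps at the boundary.
#'
#' @param g [genotype_data()].
#' @param min_call_rate minimum fraction of non-missing calls per SNP.
#' @param min_maf minimum minor allele frequency.
#' @param autosomes character vector of chromosome labels counted as
#'   autosomal; defaults to every numeric label present.
#' @return List with `genotypes` (filtered) and `report` (a `qc_report` data
#'   frame of per-step removal counts).
#' @export
filter_snps <- function(g, min_call_rate = 0.95, min_maf = 0.05,
                        autosomes = NULL) {
  stopifnot(inherits(g, "genotype_data"))
  if (min_call_rate < 0 || min_call_rate > 1 || min_maf < 0 || min_maf > 1) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(autosomes)) {
    autosomes <- unique(g$map$chrom[grepl("^[0-9]+$", g$map$chrom)])
  }
  k0 <- ncol(g$geno)
  call_rate <- colMeans(!is.na(g$geno))
  keep1 <- call_rate >= min_call_rate
  p <- colMeans(g$geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep2 <- keep1 & maf >= min_maf
  keep3 <- keep2 & g$map$chrom %in% autosomes
  report <- data.frame(
    step = c("snp_call_rate", "snp_maf", "snp_autosome"),
    unit = "snp",
    removed = c(sum(!keep1), sum(keep1) - sum(keep2), sum(keep2) - sum(keep3)),
    retained = c(sum(keep1), sum(keep2), sum(keep3)),
    threshold = c(min_call_rate, min_maf, NA),
    stringsAsFactors = FALSE
  )
  class(report) <- c("qc_report", "data.frame")
  if (!any(keep3)) {
    err <- simpleError("no SNPs retained after QC")
    err$report <- report
    stop(err)
  }
  out <- genotype_data(g$geno[, keep3, drop = FALSE],
                       g$map[keep3, , drop = FALSE],
                       haplo = if (!is.null(g$haplo)) {
                         lapply(g$haplo, function(h) h[, keep3, drop = FALSE])
                       })
  stopifnot(report$removed + report$retained ==
              c(k0, report$retained[1], report$retained[2]))
  list(genotypes = out, report = report)
}

# Per-animal rate of opposing-homozygote conflicts against each genotyped
# parent (offspring 0 vs parent 2 or vice versa), over SNPs called in both.
.mendel_conflict_rate <- function(g, ped) {
  ids <- rownames(g$geno)
  rate <- stats::setNames(rep(0, length(ids)), ids)
  ped <- as_pedigree(ped)
  for (i in seq_along(ids)) {
    row <- ped[ped$animal == ids[i], ]
    if (!nrow(row)) next
    worst <- 0
    for (par in c(row$sire, row$dam)) {
      if (is.na(par) || !(par %in% ids)) next
      go <- g$geno[ids[i], ]
      gp <- g$geno[par, ]
      both <- !is.na(go) & !is.na(gp)
      if (!any(both)) next
      conflict <- (go == 0 & gp == 2) | (go == 2 & gp == 0)
      worst <- max(worst, sum(conflict[both]) / sum(both))
    }
    rate[i] <- worst
  }
  rate
}

#' Animal quality-control filter
#'
#' Removes animals with strictly more than `max_missing` missing genotypes
#' ("more than" removes above the boundary) or failing the Mendelian
#' inheritance test against a genotyped parent. The Mendelian statistic is the
#' per-animal rate of opposing-homozygote conflicts with each genotyped
#' parent; an offspring exceeding `mendel_threshold` is removed while the
#' parent is retained.
#'
#' @param g [genotype_data()].
#' @param ped pedigree used to locate genotyped parents.
#' @param max_missing maximum tolerated missing fraction per animal.
#' @param mendel_threshold maximum tolerated conflict rate.
#' @return List with `genotypes` and `report` (a `qc_report`).
#' @export
filter_animals <- function(g, ped, max_missing = 0.03,
                           mendel_threshold = 0.01) {
  stopifnot(inherits(g, "genotype_data"))
  n0 <- nrow(g$geno)
  miss <- rowMeans(is.na(g$geno))
  keep1 <- miss <= max_missing
  mrate <- .mendel_conflict_rate(g, ped)
  keep2 <- keep1 & mrate <= mendel_threshold
  report <- data.frame(
    step = c("animal_missingness", "animal_mendel"),
    unit = "animal",
    removed = c(sum(!keep1), sum(keep1) - sum(keep2)),
    retained = c(sum(keep1), sum(keep2)),
    threshold = c(max_missing, mendel_threshold),
    stringsAsFactors = FALSE
  )
  class(report) <- c("qc_report", "data.frame")
  if (!any(keep2)) {
    err <- simpleError("no animals retained after QC")
    err$report <- report
    stop(err)
  }
  out <- genotype_data(g$geno[keep2, , drop = FALSE], g$map,
                       haplo = if (!is.null(g$haplo)) {
                         lapply(g$haplo, function(h) h[keep2, , drop = FALSE])
                       })
  stopifnot(report$removed + report$retained == c(n0, report$retained[1]))
  list(genotypes = out, report = report)
}

#' Single-marker mean/HWE imputation of residual missing genotypes
#'
#' Fills each remaining missing dosage either with the per-SNP expected dosage
#' rounded to 0/1/2 (`mode = "expected"`) or with a draw from the
#' Hardy-Weinberg genotype distribution at the observed allele frequency
#' (`mode = "stochastic"`). This is a deliberately simple single-marker fill,
#' not haplotype-based imputation; a warning says so whenever anything is
#' filled.
#'
#' @param g [genotype_data()] after QC.
#' @param seed seed for stochastic mode.
#' @param mode `"expected"` or `"stochastic"`.
#' @return [genotype_data()] with no missing dosages.
#' @export
naive_impute <- function(g, seed = 1, mode = c("expected", "stochastic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "genotype_data"))
  geno <- g$geno
  nmiss <- colSums(is.na(geno))
  if (any(nmiss == nrow(geno))) {
    stop("SNP(s) with all calls missing cannot be imputed: ",
         paste(colnames(geno)[nmiss == nrow(geno)][1:3], collapse = ", "),
         call. = FALSE)
  }
  if (!any(nmiss > 0)) return(g)
  set.seed(seed)
  p <- colMeans(geno, na.rm = TRUE) / 2
  for (j in which(nmiss > 0)) {
    mi <- which(is.na(geno[, j]))
    geno[mi, j] <- if (mode == "expected") {
      round(2 * p[j])
    } else {
      stats::rbinom(length(mi), 2, p[j])
    }
  }
  warning("missing genotypes filled by single-marker ", mode,
          "-dosage imputation (not haplotype-based)", call. = FALSE)
  genotype_data(geno, g$map, haplo = g$haplo)
}

#' Full genotype QC cascade
#'
#' SNP filters (call rate, MAF, autosome), then animal filters (missingness,
#' Mendelian test), then imputation of the remainder. The cascade is
#' idempotent: its output passes unchanged through a second run.
#'
#' @inheritParams filter_snps
#' @inheritParams filter_animals
#' @param impute_mode passed to [naive_impute()]; `"none"` skips imputation.
#' @param recheck_maf re-apply the SNP filters after animal removal, since
#'   dropping animals can push a marginal SNP below the MAF or call-rate
#'   bound; required for idempotence.
#' @param seed imputation seed.
#' @return List with `genotypes` and the concatenated `report`.
#' @export
qc_pipeline <- function(g, ped, min_call_rate = 0.95, min_maf = 0.05,
                        autosomes = NULL, max_missing = 0.03,
                        mendel_threshold = 0.01,
                        impute_mode = c("expected", "stochastic", "none"),
                        recheck_maf = TRUE, seed = 1) {
  impute_mode <- match.arg(impute_mode)
  s1 <- filter_snps(g, min_call_rate, min_maf, autosomes)
  s2 <- filter_animals(s1$genotypes, ped, max_missing, mendel_threshold)
  if (recheck_maf) {
    s3 <- filter_snps(s2$genotypes, min_call_rate, min_maf, autosomes)
    s3$report$step <- paste0(s3$report$step, "_recheck")
    s2$genotypes <- s3$genotypes
    s2$report <- rbind(s2$report, s3$report)
  }
  out <- s2$genotypes
  if (impute_mode != "none") {
    out <- withCallingHandlers(
      naive_impute(out, seed = seed, mode = impute_mode),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }
  report <- rbind(s1$report, s2$report)
  class(report) <- c("qc_report", "data.frame")
  list(genotypes = out, report = report)
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  print.data.frame(x)
  invisible(x)
}
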