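#' Write genotypes as TSV (animal rows, SNP columns) plus a SNP map TSV
#'
#' @param g [genotype_data()].
#' @param geno_path,map_path output paths.
#' @export
write_genotypes_tsv <- function(g, geno_path, map_path) {
  stopifnot(inherits(g, "genotype_data"))
  d <- data.frame(animal_id = rownames(g$geno), g$geno, check.names = FALSE,
                  stringsAsFactors = FALSE)
  data.table::fwrite(d, geno_path, sep = "\t", na = "NA")
  data.table::fwrite(g$map, map_path, sep = "\t")
  invisible(c(geno_path, map_path))
}

#' Read genotypes from TSV (animal rows, SNP columns) plus a SNP map TSV
#'
#' @param geno_path,map_path input paths.
#' @return [genotype_data()].
#' @export
read_genotypes_tsv <- function(geno_path, map_path) {
  d <- data.table::fread(geno_path, sep = "\t", data.table = FALSE)
  map <- data.table::fread(map_path, sep = "\t", data.table = FALSE)
  geno <- as.matrix(d[, -1, drop = FALSE])
  rownames(geno) <- as.character(d[[1]])
  genotype_data(geno, map)
}

#' Write PLINK-style text .ped/.map files
#'
#' Dosages are expanded to allele pairs with alleles A (reference) and B;
#' missing dosage becomes `0 0`. The .map holds chromosome, SNP id, 0 cM, bp.
#'
#' @param g [genotype_data()].
#' @param prefix output prefix (writes `prefix.ped` and `prefix.map`).
#' @param phenotypes optional phenotype table supplying sex and family
#'   (line) columns.
#' @export
write_plink <- function(g, prefix, phenotypes = NULL) {
  stopifnot(inherits(g, "genotype_data"))
  n <- nrow(g$geno)
  ids <- rownames(g$geno)
  sex <- rep(0L, n); fam <- rep("FAM", n)
  if (!is.null(phenotypes)) {
    m <- match(ids, phenotypes$animal_id)
    if ("sex" %in% names(phenotypes)) {
      sex <- ifelse(phenotypes$sex[m] == "M", 1L, 2L)
    }
    if ("line" %in% names(phenotypes)) fam <- phenotypes$line[m]
  }
  a1 <- matrix("0", n, ncol(g$geno))
  a2 <- a1
  gg <- g$geno
  a1[!is.na(gg) & gg >= 1] <- "B"; a1[!is.na(gg) & gg == 0] <- "A"
  a2[!is.na(gg) & gg == 2] <- "B"; a2[!is.na(gg) & gg <= 1] <- "A"
  inter <- matrix("", n, 2 * ncol(gg))
  inter[, seq(1, 2 * ncol(gg), 2)] <- a1
  inter[, seq(2, 2 * ncol(gg), 2)] <- a2
  ped <- cbind(fam, ids, "0", "0", sex, "-9", inter)
  data.table::fwrite(data.table::as.data.table(ped), paste0(prefix, ".ped"),
                     sep = " ", col.names = FALSE)
  mp <- data.frame(chrom = g$map$chrom, snp = g$map$snp_id, cm = 0,
                   bp = g$map$pos_bp)
  data.table::fwrite(mp, paste0(prefix, ".map"), sep = "\t",
                     col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK-style text .ped/.map files into a genotype set
#'
#' Allele B is counted as the reference dosage allele; `0` marks missing.
#'
#' @param prefix path prefix (reads `prefix.ped` and `prefix.map`).
#' @return [genotype_data()].
#' @export
read_plink <- function(prefix) {
  mp <- data.table::fread(paste0(prefix, ".map"), header = FALSE,
                          data.table = FALSE)
  map <- data.frame(snp_id = as.character(mp[[2]]),
                    chrom = as.character(mp[[1]]), pos_bp = mp[[4]],
                    stringsAsFactors = FALSE)
  pd <- data.table::fread(paste0(prefix, ".ped"), header = FALSE,
                          data.table = FALSE, colClasses = "character")
  ids <- pd[[2]]
  al <- as.matrix(pd[, -(1:6), drop = FALSE])
  k <- nrow(map)
  a1 <- al[, seq(1, 2 * k, 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * k, 2), drop = FALSE]
  geno <- (a1 == "B") + (a2 == "B")
  geno[a1 == "0" | a2 == "0"] <- NA
  rownames(geno) <- ids
  colnames(geno) <- map$snp_id
  genotype_data(geno, map)
}

#' Write region calls as a BED-like TSV
#'
#' Columns: chrom, start, end (1-based inclusive bp), trait, max window
#' variance percentage, region PPA and (bivariate) the highest member-window
#' genetic correlation with its SD.
#'
#' @param regions a `region_table` from [call_regions()].
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  data.table::fwrite(as.data.frame(regions), path, sep = "\t", na = "NA")
  invisible(path)
}

#' Write a complete simulated dataset to a directory
#'
#' Emits genotype + map TSV, PLINK text export, phenotype and pedigree CSV,
#' and truth tables (true effects, generating variance components, line
#' assignment), plus a manifest of file checksums.
#'
#' @param sim a `sim_output` from [simulate_divergent_lines()].
#' @param dir output directory (created if needed).
#' @param force overwrite an existing non-empty directory.
#' @return Invisibly, the manifest data frame.
#' @export
write_sim_output <- function(sim, dir, force = FALSE) {
  stopifnot(inherits(sim, "sim_output"))
  if (dir.exists(dir) && length(dir(dir)) && !force) {
    stop("output directory exists and is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_genotypes_tsv(sim$genotypes, fp("genotypes.tsv"), fp("snp_map.tsv"))
  write_plink(sim$genotypes, fp("plink"), sim$phenotypes)
  data.table::fwrite(sim$phenotypes, fp("phenotypes.csv"))
  write_pedigree(sim$pedigree, fp("pedigree.csv"))
  te <- data.frame(snp_id = rownames(sim$true_effects), sim$true_effects)
  data.table::fwrite(te[rowSums(abs(sim$true_effects)) > 0, ],
                     fp("true_effects.csv"))
  vc <- sim$true_variance_components
  data.table::fwrite(data.frame(component = c("C", "U", "R"),
                                v1 = c(vc$C[1, 1], vc$U[1, 1], vc$R[1, 1]),
                                cov = c(vc$C[1, 2], vc$U[1, 2], vc$R[1, 2]),
                                v2 = c(vc$C[2, 2], vc$U[2, 2], vc$R[2, 2])),
                     fp("true_varcomp.csv"))
  data.table::fwrite(data.frame(animal_id = names(sim$line_assignment),
                                line = unname(sim$line_assignment)),
                     fp("line_assignment.csv"))
  files <- setdiff(dir(dir, full.names = TRUE),
                   file.path(dir, "MANIFEST.csv"))
  manifest <- data.frame(
    file = basename(files),
    md5 = vapply(files, function(f) unname(tools::md5sum(f)), character(1)),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(manifest, fp("MANIFEST.csv"))
  invisible(manifest)
}
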