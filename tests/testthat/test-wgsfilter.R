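toy_variants <- function() {
  variants <- data.frame(
    chrom = c("1", "1", "1", "2", "2", "2"),
    pos = c(100L, 500L, 900L, 150L, 300L, 800L),
    ref = "A", alt = "T",
    consequence = c("missense_variant", "synonymous_variant",
                    "frameshift_variant", "intergenic_region",
                    "stop_gained", "missense_variant&splice_region_variant"),
    impact = c("MODERATE", "LOW", "HIGH", "MODIFIER", "HIGH", "MODERATE"),
    gene = sprintf("g%d", 1:6),
    stringsAsFactors = FALSE
  )
  # 4 H + 4 L samples; columns are variants
  gt <- rbind(
    H1 = c(2, 2, 2, 2, 2, 1), H2 = c(2, 2, 2, 2, 2, 1),
    H3 = c(2, 2, 2, 2, 1, 2), H4 = c(2, 2, 2, 2, 2, 2),
    L1 = c(0, 0, 1, 0, 0, 1), L2 = c(0, 0, 1, 0, 0, 0),
    L3 = c(1, 0, 0, 0, 0, 1), L4 = c(1, 0, 1, 0, 1, 0)
  )
  variant_set(variants, gt)
}

test_that("impact filter keeps only listed moderate/high coding consequences", {
  vs <- toy_variants()
  out <- impact_filter(vs)
  expect_equal(out$variants$gene, c("g1", "g3", "g5", "g6"))
  expect_equal(attr(out, "n_removed"), 2)
  # unknown impact tokens are data errors that name the offenders
  bad <- vs$variants; bad$impact[2] <- "SEVERE"
  expect_error(variant_set(bad), "SEVERE")
})

test_that("line frequencies count alt alleles over called samples", {
  vs <- toy_variants()
  la <- setNames(rep(c("H", "L"), each = 4), rownames(vs$gt))
  fr <- line_frequencies(vs, la)
  expect_equal(fr$freq_H[1], 1.0)           # all H homozygous alt
  expect_equal(fr$freq_L[1], 2 / 8)         # 2 het among 4 L samples
  # 4 het + 6 hom-ref of 10 samples -> 0.2
  gt1 <- matrix(c(rep(1, 4), rep(0, 6), rep(0, 10)), 10, 2)
  rownames(gt1) <- sprintf("s%02d", 1:10)
  v1 <- variant_set(data.frame(chrom = "1", pos = c(1L, 2L), ref = "A",
                               alt = "T", consequence = "missense_variant",
                               impact = "MODERATE", gene = "g"), gt1)
  la1 <- setNames(rep(c("H", "L"), each = 5), rownames(gt1))
  fr1 <- line_frequencies(v1, la1)
  expect_equal(fr1$freq_H[1], 4 / 10)
  # all genotypes missing in one line -> flagged and skipped
  gt1[6:10, 2] <- NA
  v2 <- variant_set(v1$variants, gt1)
  expect_message(fr2 <- line_frequencies(v2, la1), "skipped")
  expect_false(fr2$defined[2])
})

test_that("divergence criteria follow the fixed and opposite-frequency rules", {
  mk <- function(pH, pL) {
    d <- data.frame(chrom = "1", pos = seq_along(pH), ref = "A", alt = "T",
                    freq_H = pH, n_called_H = 10L,
                    freq_L = pL, n_called_L = 10L, defined = TRUE)
    attr(d, "lines") <- c("H", "L")
    class(d) <- c("line_frequencies", "data.frame")
    d
  }
  # reference allele fixed in L, alt at 0.4 in H (so ref 0.6 in H): the
  # fixed allele segregates at 0.6 >= 0.5 in the other line -> excluded
  fr <- mk(pH = c(0.4, 0.70, 0.60, 1.0, 0.0),
           pL = c(0.0, 0.30, 0.40, 0.45, 0.55))
  out <- divergence_filter(fr)
  # pos 5: ref fixed in H (alt 0) while ref is at 0.45 < 0.5 in L -> kept
  expect_equal(out$pos, c(2, 4, 5))
  expect_equal(out$criterion, c("opposite_frequencies",
                                "fixed_vs_segregating",
                                "fixed_vs_segregating"))
  # boundary: exactly 0.65 both ways is NOT retained (strict >)
  expect_equal(nrow(divergence_filter(mk(0.65, 0.35))), 0)
  expect_error(divergence_filter(fr, opposite_min = 0.4), "opposite_min")
})

test_that("divergence outcomes are symmetric in line labels and allele coding", {
  set.seed(21)
  pH <- round(runif(200), 2); pL <- round(runif(200), 2)
  pH[1:20] <- 1; pL[21:40] <- 0 # plant exact fixations
  mk <- function(p1, p2, lines = c("H", "L")) {
    d <- data.frame(chrom = "1", pos = seq_along(p1), ref = "A", alt = "T")
    d[[paste0("freq_", lines[1])]] <- p1
    d[[paste0("n_called_", lines[1])]] <- 10L
    d[[paste0("freq_", lines[2])]] <- p2
    d[[paste0("n_called_", lines[2])]] <- 10L
    d$defined <- TRUE
    attr(d, "lines") <- sort(lines)
    class(d) <- c("line_frequencies", "data.frame")
    d
  }
  base <- divergence_filter(mk(pH, pL))$pos
  swapped_lines <- divergence_filter(mk(pL, pH))$pos
  swapped_alleles <- divergence_filter(mk(1 - pH, 1 - pL))$pos
  expect_identical(base, swapped_lines)
  expect_identical(base, swapped_alleles)
})

test_that("region intersection uses 1-based inclusive bounds", {
  regions <- data.frame(chrom = "1", start_bp = 100, end_bp = 500)
  v <- data.frame(chrom = c("1", "1", "1", "3"),
                  pos = c(100, 501, 500, 200))
  out <- intersect_regions(v, regions)
  expect_equal(out$in_region, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$region[1], "1:100-500")
})

test_that("the full screen reproduces a hand-tallied toy count", {
  vs <- toy_variants()
  la <- setNames(rep(c("H", "L"), each = 4), rownames(vs$gt))
  regions <- data.frame(chrom = c("1", "2"), start_bp = c(1, 1),
                        end_bp = c(1e6, 1e6))
  out <- screen_variants(vs, la, regions)
  # by hand: impact keeps g1,g3,g5,g6; divergence keeps g1 (1.0 vs 0.25)
  # and g5 (0.875 vs 0.125); g3 (1.0 vs 0.375 BUT alt fixed in H with
  # alt 0.375 < 0.5 in L -> kept too); g6 (0.75 vs 0.25 not > 0.65 barely:
  # 0.75 > 0.65 and 1-0.25 = 0.75 > 0.65 -> kept)
  expect_setequal(out$gene, c("g1", "g3", "g5", "g6"))
  counts <- attr(out, "stage_counts")
  expect_equal(unname(counts["input"]), 6)
  expect_equal(unname(counts["impact"]), 4)
  # empty regions give an empty result without error
  out0 <- screen_variants(vs, la, regions[0, ])
  expect_equal(nrow(out0), 0)
})

test_that("flat TSV and annotated VCF inputs parse to the same screen", {
  td <- withr::local_tempdir()
  tsv <- file.path(td, "variants.tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tconsequence\timpact\tgene\tH1\tH2\tL1\tL2",
    "1\t100\tA\tT\tmissense_variant\tMODERATE\tgA\t1/1\t1/1\t0/0\t0/0",
    "1\t200\tG\tC\tsynonymous_variant\tLOW\tgB\t0/1\t0/0\t0/1\t0/0",
    "2\t300\tT\tG\tstop_gained\tHIGH\tgC\t1/1\t0/1\t0/0\t./."
  ), tsv)
  vs <- read_variant_table(tsv)
  expect_equal(nrow(vs$variants), 3)
  expect_equal(unname(vs$gt["H1", ]), c(2, 1, 2))
  expect_true(is.na(vs$gt["L2", 3]))

  vcf <- file.path(td, "variants.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Annotation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "H1\tH2\tL1\tL2"),
    paste0("1\t100\t.\tA\tT\t50\tPASS\t",
           "ANN=T|missense_variant|MODERATE|gA|g1|x\tGT\t1/1\t1/1\t0/0\t0/0"),
    paste0("1\t200\t.\tG\tC\t50\tPASS\t",
           "ANN=C|synonymous_variant|LOW|gB|g2|x\tGT\t0/1\t0/0\t0/1\t0/0"),
    paste0("2\t300\t.\tT\tG\t50\tPASS\t",
           "ANN=G|stop_gained|HIGH|gC|g3|x\tGT\t1/1\t0/1\t0/0\t./.")
  ), vcf)
  vsv <- read_annotated_vcf(vcf)
  expect_equal(vsv$variants$consequence, vs$variants$consequence)
  expect_equal(vsv$variants$impact, vs$variants$impact)
  expect_equal(unname(vsv$gt[rownames(vs$gt), ]), unname(vs$gt))
})
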