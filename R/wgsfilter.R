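#' Consequence terms accepted by the impact filter
#'
#' Sequence-ontology terms for moderate-to-high-impact coding changes:
#' missense, frameshift, start lost, stop gained, and conservative in-frame
#' insertions/deletions.
#' @export
IMPACTFUL_CONSEQUENCES <- c(
  "missense_variant", "frameshift_variant", "start_lost", "stop_gained",
  "conservative_inframe_deletion", "conservative_inframe_insertion"
)

.IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Variant table container
#'
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`, `impact`, `gene` (impact from
#'   HIGH/MODERATE/LOW/MODIFIER).
#' @param gt numeric matrix of alt-allele dosages (samples x variants,
#'   0/1/2/NA), one column per variant row.
#' @return List of class `variant_set`.
#' @export
variant_set <- function(variants, gt = NULL) {
  stopifnot(is.data.frame(variants))
  need <- c("chrom", "pos", "ref", "alt", "consequence", "impact")
  if (!all(need %in% names(variants))) {
    stop("variant table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(variants$pos < 1)) stop("positions must be >= 1", call. = FALSE)
  bad <- !(variants$impact %in% .IMPACT_LEVELS)
  if (any(bad)) {
    stop("unknown impact token(s): ",
         paste(unique(variants$impact[bad]), collapse = ", "),
         " at rows ", paste(utils::head(which(bad), 5), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(gt)) {
    gt <- as.matrix(gt)
    if (ncol(gt) != nrow(variants)) {
      stop("gt must have one column per variant", call. = FALSE)
    }
  }
  variants$chrom <- as.character(variants$chrom)
  structure(list(variants = variants, gt = gt), class = "variant_set")
}

#' @exportS3Method base::print
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "variants",
      if (!is.null(x$gt)) paste0("x ", nrow(x$gt), " samples"), "\n")
  invisible(x)
}

#' Keep moderate/high-impact variants of the listed coding consequences
#'
#' A variant is retained iff its impact class is MODERATE or HIGH and at least
#' one of its (possibly `&`- or `,`-separated) consequence terms is in the
#' accepted set.
#'
#' @param vs [variant_set()].
#' @param consequences accepted consequence terms.
#' @return Filtered [variant_set()], with attribute `n_removed`.
#' @export
impact_filter <- function(vs, consequences = IMPACTFUL_CONSEQUENCES) {
  stopifnot(inherits(vs, "variant_set"))
  v <- vs$variants
  terms <- strsplit(v$consequence, "[&,;]")
  hit <- vapply(terms, function(x) any(trimws(x) %in% consequences),
                logical(1))
  keep <- v$impact %in% c("MODERATE", "HIGH") & hit
  out <- variant_set(v[keep, , drop = FALSE],
                     if (!is.null(vs$gt)) vs$gt[, keep, drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-line alternative-allele frequencies
#'
#' Alt frequency per line = alt allele count / (2 x called diploid samples),
#' over non-missing genotype calls only. Variants with zero called samples in
#' either line are flagged (`defined = FALSE`) and reported via a message.
#'
#' @param vs [variant_set()] with genotypes.
#' @param line_assignment named vector (sample -> line label, two lines).
#' @return Data frame `line_frequencies`: `freq_H`, `freq_L` (columns named
#'   after the actual line labels), call counts, and `defined`.
#' @export
line_frequencies <- function(vs, line_assignment) {
  stopifnot(inherits(vs, "variant_set"))
  if (is.null(vs$gt)) stop("variant set has no genotypes", call. = FALSE)
  samples <- rownames(vs$gt)
  if (is.null(samples)) stop("gt needs sample rownames", call. = FALSE)
  missing_assign <- setdiff(samples, names(line_assignment))
  if (length(missing_assign)) {
    stop("samples without a line assignment: ",
         paste(utils::head(missing_assign, 3), collapse = ", "),
         call. = FALSE)
  }
  lines <- sort(unique(unname(line_assignment[samples])))
  if (length(lines) != 2) stop("exactly two lines required", call. = FALSE)
  out <- vs$variants[, c("chrom", "pos", "ref", "alt")]
  for (ln in lines) {
    g <- vs$gt[line_assignment[samples] == ln, , drop = FALSE]
    called <- colSums(!is.na(g))
    out[[paste0("freq_", ln)]] <- colSums(g, na.rm = TRUE) / (2 * called)
    out[[paste0("n_called_", ln)]] <- called
  }
  out$defined <- out[[paste0("n_called_", lines[1])]] > 0 &
    out[[paste0("n_called_", lines[2])]] > 0
  if (any(!out$defined)) {
    message(sum(!out$defined),
            " variant(s) skipped: no called samples in one line")
  }
  attr(out, "lines") <- lines
  class(out) <- c("line_frequencies", "data.frame")
  out
}

#' Allele-frequency divergence filter between selection lines
#'
#' A variant is retained when either criterion holds for its alt-allele
#' frequencies `p1`, `p2` in the two lines (both criteria are symmetric in
#' line label and in ref/alt coding):
#' * criterion 1 ("fixed/segregating"): some allele is fixed (frequency
#'   exactly 1) in one line while that same allele's frequency is below
#'   `fixed_other_max` in the other line;
#' * criterion 2 ("opposite frequencies"): one allele exceeds `opposite_min`
#'   in one line while the alternative allele exceeds `opposite_min` in the
#'   other (strict `>`).
#'
#' @param freqs [line_frequencies()] output.
#' @param fixed_other_max frequency bound for the non-fixed line (default
#'   0.5, strict `<`).
#' @param opposite_min opposite-frequency bound (default 0.65, strict `>`).
#' @return `freqs` rows retained, with a `criterion` label column.
#' @export
divergence_filter <- function(freqs, fixed_other_max = 0.5,
                              opposite_min = 0.65) {
  stopifnot(inherits(freqs, "line_frequencies"))
  if (fixed_other_max <= 0 || fixed_other_max > 1 ||
      opposite_min <= 0.5 || opposite_min > 1) {
    stop("fixed_other_max must be in (0, 1], opposite_min in (0.5, 1]",
         call. = FALSE)
  }
  lines <- attr(freqs, "lines")
  p1 <- freqs[[paste0("freq_", lines[1])]]
  p2 <- freqs[[paste0("freq_", lines[2])]]
  ok <- freqs$defined
  # criterion 1 over both alleles and both line directions
  c1 <- (p1 == 1 & p2 < fixed_other_max) |
        (p2 == 1 & p1 < fixed_other_max) |
        ((1 - p1) == 1 & (1 - p2) < fixed_other_max) |
        ((1 - p2) == 1 & (1 - p1) < fixed_other_max)
  # criterion 2: alt high in one line while ref high in the other
  c2 <- (p1 > opposite_min & (1 - p2) > opposite_min) |
        (p2 > opposite_min & (1 - p1) > opposite_min)
  keep <- ok & (c1 | c2)
  out <- freqs[keep, , drop = FALSE]
  out$criterion <- ifelse(c1[keep], "fixed_vs_segregating",
                          "opposite_frequencies")
  attr(out, "lines") <- lines
  class(out) <- class(freqs)
  out
}

#' Label variants with the associated regions containing them
#'
#' Region intervals are 1-based inclusive on `[start_bp, end_bp]`.
#'
#' @param variants data frame with `chrom` and `pos` columns.
#' @param regions a `region_table` from [call_regions()] (or any data frame
#'   with `chrom`, `start_bp`, `end_bp`).
#' @return `variants` with added columns `in_region` (logical) and `region`
#'   (comma-separated `chrom:start-end` labels, "" when outside).
#' @export
intersect_regions <- function(variants, regions) {
  lab <- character(nrow(variants))
  hit <- logical(nrow(variants))
  if (nrow(regions)) {
    for (i in seq_len(nrow(variants))) {
      m <- which(regions$chrom == variants$chrom[i] &
                   regions$start_bp <= variants$pos[i] &
                   regions$end_bp >= variants$pos[i])
      if (length(m)) {
        hit[i] <- TRUE
        lab[i] <- paste(unique(sprintf("%s:%d-%d", regions$chrom[m],
                                       regions$start_bp[m],
                                       regions$end_bp[m])),
                        collapse = ",")
      }
    }
  }
  variants$in_region <- hit
  variants$region <- lab
  variants
}

#' Full variant screen: impact, line divergence, region intersection
#'
#' @param vs [variant_set()] with genotypes.
#' @param line_assignment named sample -> line vector.
#' @param regions `region_table` (may be empty).
#' @param fixed_other_max,opposite_min see [divergence_filter()].
#' @param consequences see [impact_filter()].
#' @param within_regions if TRUE (default) only variants inside a region are
#'   returned.
#' @return Data frame of retained variants with line frequencies, criterion
#'   label and containing region; attribute `stage_counts` logs per-stage
#'   variant counts.
#' @export
screen_variants <- function(vs, line_assignment, regions,
                            fixed_other_max = 0.5, opposite_min = 0.65,
                            consequences = IMPACTFUL_CONSEQUENCES,
                            within_regions = TRUE) {
  n0 <- nrow(vs$variants)
  vs1 <- impact_filter(vs, consequences)
  fr <- line_frequencies(vs1, line_assignment)
  dv <- divergence_filter(fr, fixed_other_max, opposite_min)
  keep_idx <- match(interaction(dv$chrom, dv$pos, dv$ref, dv$alt),
                    interaction(vs1$variants$chrom, vs1$variants$pos,
                                vs1$variants$ref, vs1$variants$alt))
  extra <- intersect(c("consequence", "impact", "gene"),
                     names(vs1$variants))
  out <- cbind(dv, vs1$variants[keep_idx, extra, drop = FALSE])
  out <- intersect_regions(out, regions)
  n_div <- nrow(out)
  if (within_regions) out <- out[out$in_region, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage_counts") <- c(input = n0, impact = nrow(vs1$variants),
                                 divergence = n_div, in_region = nrow(out))
  out
}

#' Read an annotated VCF into a variant set
#'
#' Parses a snpEff-style `ANN` INFO field (first annotation per variant:
#' consequence in subfield 2, impact in subfield 3, gene in subfield 4) and
#' the per-sample GT field into alt-allele dosages. Multi-allelic records are
#' not supported; split them upstream.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return [variant_set()] with genotypes.
#' @export
read_annotated_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ann <- vcfR::extract.info(v, "ANN")
  parse1 <- function(a) {
    if (is.na(a)) return(c(NA, NA, NA))
    first <- strsplit(a, ",", fixed = TRUE)[[1]][1]
    f <- strsplit(first, "|", fixed = TRUE)[[1]]
    c(f[2], f[3], f[4])
  }
  pieces <- t(vapply(ann, parse1, character(3)))
  variants <- data.frame(
    chrom = fx$CHROM, pos = as.integer(fx$POS), ref = fx$REF, alt = fx$ALT,
    consequence = pieces[, 1], impact = pieces[, 2], gene = pieces[, 3],
    stringsAsFactors = FALSE
  )
  gtc <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gtc, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  })
  variant_set(variants, gt = t(dos))
}

#' Read a flat annotated-variant TSV
#'
#' Columns `chrom`, `pos`, `ref`, `alt`, `consequence`, `impact`, `gene`,
#' then one column per sample holding GT strings (`0/0`, `0/1`, `1/1`,
#' `./.`).
#'
#' @param path TSV path.
#' @return [variant_set()] with genotypes.
#' @export
read_variant_table <- function(path) {
  d <- data.table::fread(path, data.table = FALSE, colClasses = list(
    character = c("chrom", "ref", "alt", "consequence", "impact", "gene")))
  meta <- c("chrom", "pos", "ref", "alt", "consequence", "impact", "gene")
  samples <- setdiff(names(d), meta)
  gt <- t(vapply(samples, function(s) {
    vapply(d[[s]], function(g) {
      if (is.na(g) || grepl("\\.", g)) return(NA_real_)
      sum(strsplit(g, "[/|]")[[1]] == "1")
    }, numeric(1), USE.NAMES = FALSE)
  }, numeric(nrow(d))))
  if (nrow(d) == 1) gt <- matrix(gt, ncol = 1, dimnames = list(samples, NULL))
  variant_set(d[, intersect(meta, names(d))], gt = gt)
}
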