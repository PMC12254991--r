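#' Build 1-Mb SNP-anchored sliding windows
#'
#' One window is anchored at every SNP and contains all SNPs of the same
#' chromosome with positions in the half-open interval
#' `[anchor_pos, anchor_pos + window_bp)`. Windows whose member set duplicates
#' the previous anchor's are kept but flagged.
#'
#' @param map SNP map data frame (`snp_id`, `chrom`, `pos_bp`), sorted by
#'   position within chromosome.
#' @param window_bp window span in bp (default 1 Mb).
#' @return Object of class `window_map`: `windows` (data frame with
#'   `window_id`, `chrom`, `anchor`, `start_bp`, `end_bp`, `n_snps`,
#'   `duplicate`) and `members` (list of SNP row indices per window).
#' @export
build_windows <- function(map, window_bp = 1e6) {
  stopifnot(all(c("snp_id", "chrom", "pos_bp") %in% names(map)))
  for (ch in unique(map$chrom)) {
    if (is.unsorted(map$pos_bp[map$chrom == ch])) {
      stop("map must be sorted by position within chromosome ", ch,
           call. = FALSE)
    }
  }
  k <- nrow(map)
  members <- vector("list", k)
  dup <- logical(k)
  for (j in seq_len(k)) {
    same <- map$chrom == map$chrom[j]
    inw <- same & map$pos_bp >= map$pos_bp[j] &
      map$pos_bp < map$pos_bp[j] + window_bp
    members[[j]] <- which(inw)
    dup[j] <- j > 1 && map$chrom[j] == map$chrom[j - 1] &&
      identical(members[[j]], members[[j - 1]])
  }
  windows <- data.frame(
    window_id = seq_len(k),
    chrom = map$chrom,
    anchor = map$snp_id,
    start_bp = map$pos_bp,
    end_bp = vapply(members, function(m) max(map$pos_bp[m]), numeric(1)),
    n_snps = lengths(members),
    duplicate = dup,
    stringsAsFactors = FALSE
  )
  structure(list(windows = windows, members = members, window_bp = window_bp),
            class = "window_map")
}

#' @exportS3Method base::print
print.window_map <- function(x, ...) {
  cat("window_map:", nrow(x$windows), "windows of", x$window_bp, "bp (",
      sum(x$windows$duplicate), "duplicate member sets)\n")
  invisible(x)
}

# genotype covariates aligned with a fit (centered; centering does not affect
# variances/correlations across individuals)
.fit_markers <- function(fit, genotypes) {
  ids <- fit$animal_ids
  M <- genotypes$geno[ids, , drop = FALSE]
  if (!identical(colnames(M), fit$snp_ids)) {
    stop("genotype columns do not match the sampled effects", call. = FALSE)
  }
  M
}

#' Sliding-window genetic-variance percentages from posterior draws
#'
#' For each saved draw s and trait t, the window's breeding values are
#' `g_w = sum_{j in w} z_j alpha_j(s)` across individuals, and the window's
#' share is `Var_i(g_w) / Var_i(g_total) * 100`, where `g_total` sums over all
#' SNPs (`denominator = "markers"`) or over all SNPs plus the polygenic draw
#' (`"markers_plus_polygenic"`). Draws with zero total genetic variance are
#' skipped. Bivariate fits additionally get the posterior mean and SD of the
#' window genetic correlation (Pearson correlation across individuals of the
#' two traits' window breeding values, over draws where both variances are
#' positive).
#'
#' @param fit `bayesb_fit` from [bayesb_gwas()].
#' @param wmap [build_windows()] result.
#' @param genotypes [genotype_data()] matching the fit.
#' @param denominator denominator mode for the share.
#' @return A `window_result` data frame (one row per window) with per-trait
#'   `pct_var_*` posterior means, per-trait window PPAs, and (bivariate)
#'   `gencor_mean`, `gencor_sd`, `gencor_ndraws`. Attribute
#'   `no_genetic_variance` flags a fit whose draws never contained a nonzero
#'   effect.
#' @export
window_variance <- function(fit, wmap, genotypes,
                            denominator = c("markers",
                                            "markers_plus_polygenic")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(fit, "bayesb_fit"), inherits(wmap, "window_map"))
  if (fit$n_saved < 1) stop("no saved draws", call. = FALSE)
  M <- .fit_markers(fit, genotypes)
  n <- nrow(M); k <- ncol(M); t <- fit$t
  nS <- fit$n_saved
  W <- nrow(wmap$windows)
  # window lists per SNP
  win_of <- vector("list", k)
  for (w in seq_len(W)) {
    for (j in wmap$members[[w]]) win_of[[j]] <- c(win_of[[j]], w)
  }
  use_u <- denominator == "markers_plus_polygenic"
  if (use_u && (length(fit$samples$u) == 0 || is.null(fit$ped_id))) {
    stop("polygenic draws not available for this denominator mode",
         call. = FALSE)
  }
  sums <- matrix(0, W, t)      # accumulated shares over contributing draws
  ppa_hit <- matrix(0, W, t)   # draws with >= 1 included member SNP
  gc_sum <- gc_sumsq <- numeric(W)
  gc_n <- integer(W)
  contrib <- rep(0L, t)
  for (s in seq_len(nS)) {
    A <- matrix(fit$samples$alpha[s, , ], nrow = k, ncol = t)
    act <- which(rowSums(A != 0) > 0)
    dlt <- matrix(fit$samples$delta[s, , ], nrow = k, ncol = t)
    if (length(act)) {
      wact <- sort(unique(unlist(win_of[act])))
      for (tt in seq_len(t)) ppa_hit[wact, tt] <-
          ppa_hit[wact, tt] + vapply(wact, function(w) {
            any(dlt[wmap$members[[w]], tt] != 0)
          }, logical(1))
    } else wact <- integer(0)
    Gtot <- if (length(act)) {
      M[, act, drop = FALSE] %*% A[act, , drop = FALSE]
    } else matrix(0, n, t)
    if (use_u) {
      for (tt in seq_len(t)) {
        Gtot[, tt] <- Gtot[, tt] + fit$samples$u[s, fit$ped_id, tt]
      }
    }
    vtot <- apply(Gtot, 2, stats::var)
    gw_cache <- list()
    for (tt in seq_len(t)) {
      if (vtot[tt] <= 0) next
      contrib[tt] <- contrib[tt] + 1L
      for (w in wact) {
        mm <- intersect(wmap$members[[w]], act)
        if (!length(mm)) next
        key <- as.character(w)
        if (is.null(gw_cache[[key]])) {
          gw_cache[[key]] <- M[, mm, drop = FALSE] %*% A[mm, , drop = FALSE]
        }
        sums[w, tt] <- sums[w, tt] +
          stats::var(gw_cache[[key]][, tt]) / vtot[tt] * 100
      }
    }
    if (t == 2) {
      for (w in wact) {
        key <- as.character(w)
        gw <- gw_cache[[key]]
        if (is.null(gw)) next
        v1 <- stats::var(gw[, 1]); v2 <- stats::var(gw[, 2])
        if (v1 > 0 && v2 > 0) {
          r <- stats::cor(gw[, 1], gw[, 2])
          gc_sum[w] <- gc_sum[w] + r
          gc_sumsq[w] <- gc_sumsq[w] + r^2
          gc_n[w] <- gc_n[w] + 1L
        }
      }
    }
  }
  out <- wmap$windows
  for (tt in seq_len(t)) {
    out[[paste0("pct_var_trait", tt)]] <-
      if (contrib[tt] > 0) sums[, tt] / contrib[tt] else NA_real_
    out[[paste0("ppa_trait", tt)]] <- ppa_hit[, tt] / nS
  }
  if (t == 2) {
    out$gencor_mean <- ifelse(gc_n > 0, gc_sum / gc_n, NA_real_)
    gvar <- ifelse(gc_n > 1,
                   pmax(0, (gc_sumsq - gc_sum^2 / gc_n) / (gc_n - 1)), NA)
    out$gencor_sd <- sqrt(gvar)
    out$gencor_ndraws <- gc_n
  }
  attr(out, "denominator") <- denominator
  attr(out, "n_draws") <- nS
  attr(out, "contributing_draws") <- contrib
  attr(out, "no_genetic_variance") <- all(contrib == 0)
  class(out) <- c("window_result", "data.frame")
  out
}

#' Call associated genomic regions from window results
#'
#' Windows whose posterior-mean genetic-variance share meets the threshold
#' (`>=`, so 0.75 itself is associated) are flagged per trait; overlapping
#' flagged windows on the same chromosome are merged into one region. Region
#' coordinates span from the first member SNP of the first window to the last
#' member SNP of the last window. The region's variance is the maximum over
#' its member windows; its PPA is the fraction of saved draws in which at
#' least one member SNP carried a nonzero effect on the trait (computed when
#' `fit` is supplied).
#'
#' @param result a `window_result` from [window_variance()].
#' @param threshold_pct association threshold on the percentage scale
#'   (default 0.75, i.e. 0.75% of the genetic variance).
#' @param wmap the [build_windows()] map used for `result`.
#' @param fit optional `bayesb_fit` for region PPAs.
#' @return Data frame of regions: `trait`, `chrom`, `start_bp`, `end_bp`,
#'   `n_windows`, `max_pct_var`, `region_ppa`, and for bivariate results
#'   `highest_gencor` / `highest_gencor_sd` (taken over member windows).
#' @export
call_regions <- function(result, threshold_pct = 0.75, wmap = NULL,
                         fit = NULL) {
  stopifnot(inherits(result, "window_result"))
  traits <- grep("^pct_var_trait", names(result), value = TRUE)
  regions <- list()
  for (tc in traits) {
    tt <- as.integer(sub("pct_var_trait", "", tc))
    flagged <- which(!is.na(result[[tc]]) & result[[tc]] >= threshold_pct)
    if (!length(flagged)) next
    for (ch in unique(result$chrom[flagged])) {
      fch <- flagged[result$chrom[flagged] == ch]
      fch <- fch[order(result$start_bp[fch])]
      grp <- integer(length(fch)); g <- 1L; grp[1] <- 1L
      if (length(fch) > 1) {
        for (i in 2:length(fch)) {
          prev <- fch[seq_len(i - 1)][grp[seq_len(i - 1)] == g]
          if (result$start_bp[fch[i]] <= max(result$end_bp[prev])) {
            grp[i] <- g
          } else {
            g <- g + 1L; grp[i] <- g
          }
        }
      }
      for (gg in unique(grp)) {
        wset <- fch[grp == gg]
        ppa <- NA_real_
        if (!is.null(fit) && !is.null(wmap)) {
          mem <- sort(unique(unlist(wmap$members[wset])))
          dlt <- fit$samples$delta[, mem, tt, drop = FALSE]
          ppa <- mean(apply(dlt, 1, function(x) any(x != 0)))
        }
        row <- data.frame(
          trait = tt, chrom = ch,
          start_bp = min(result$start_bp[wset]),
          end_bp = max(result$end_bp[wset]),
          n_windows = length(wset),
          max_pct_var = max(result[[tc]][wset]),
          region_ppa = ppa,
          stringsAsFactors = FALSE
        )
        if ("gencor_mean" %in% names(result)) {
          gc <- result$gencor_mean[wset]
          if (any(!is.na(gc))) {
            best <- wset[which.max(abs(gc))]
            row$highest_gencor <- result$gencor_mean[best]
            row$highest_gencor_sd <- result$gencor_sd[best]
          } else {
            row$highest_gencor <- NA_real_
            row$highest_gencor_sd <- NA_real_
          }
        }
        regions[[length(regions) + 1L]] <- row
      }
    }
  }
  if (!length(regions)) {
    out <- data.frame(trait = integer(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_windows = integer(0), max_pct_var = numeric(0),
                      region_ppa = numeric(0))
  } else {
    out <- do.call(rbind, regions)
  }
  attr(out, "threshold_pct") <- threshold_pct
  class(out) <- c("region_table", "data.frame")
  out
}

#' Posterior window genetic correlation for an arbitrary SNP set
#'
#' @param fit bivariate `bayesb_fit`.
#' @param members integer SNP column indices defining the window or region.
#' @param genotypes [genotype_data()] matching the fit.
#' @return List with `mean`, `sd`, `n_draws` (contributing draws with positive
#'   variance for both traits); `mean` is NA when no draw contributes.
#' @export
window_genetic_correlation <- function(fit, members, genotypes) {
  stopifnot(inherits(fit, "bayesb_fit"))
  if (fit$t != 2) stop("window genetic correlation needs a bivariate fit",
                       call. = FALSE)
  M <- .fit_markers(fit, genotypes)
  rs <- numeric(0)
  for (s in seq_len(fit$n_saved)) {
    A <- matrix(fit$samples$alpha[s, members, ], nrow = length(members))
    if (all(A == 0)) next
    gw <- M[, members, drop = FALSE] %*% A
    v1 <- stats::var(gw[, 1]); v2 <- stats::var(gw[, 2])
    if (v1 > 0 && v2 > 0) rs <- c(rs, stats::cor(gw[, 1], gw[, 2]))
  }
  if (!length(rs)) {
    return(list(mean = NA_real_, sd = NA_real_, n_draws = 0L,
                undefined = TRUE))
  }
  list(mean = mean(rs), sd = stats::sd(rs), n_draws = length(rs),
       undefined = FALSE)
}

#' Manhattan-style plot of window variance shares
#'
#' @param result a `window_result`.
#' @param trait trait index to plot.
#' @param thresholds tier thresholds (percent); windows above each tier are
#'   highlighted.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(result, trait = 1, thresholds = c(0.75, 1.5)) {
  stopifnot(inherits(result, "window_result"))
  pc <- paste0("pct_var_trait", trait)
  df <- data.frame(chrom = result$chrom, pos = result$start_bp / 1e6,
                   pct = result[[pc]])
  df$tier <- cut(df$pct, c(-Inf, sort(thresholds), Inf),
                 labels = c("below", paste0(">=", sort(thresholds))))
  ggplot2::ggplot(df, ggplot2::aes(x = pos, y = pct, colour = tier)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "position (Mb)", y = "% genetic variance (window)",
                  colour = "tier") +
    ggplot2::theme_minimal()
}
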