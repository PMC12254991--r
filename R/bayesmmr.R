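#' Per-configuration inclusion prior from the joint-null mass
#'
#' In the bivariate model a SNP's indicator pair has four configurations:
#' null/null, trait-1 only, trait-2 only, both. Given the joint-null
#' probability `pi00`, the remaining mass is split equally over the three
#' non-null configurations.
#'
#' @param pi00 prior probability that a SNP affects neither trait.
#' @return Named numeric vector `c(pi00, pi10, pi01, pi11)` summing to 1.
#' @examples
#' pi_config(0.9982) # each non-null configuration gets 0.0006
#' @export
pi_config <- function(pi00 = 0.9982) {
  stopifnot(pi00 >= 0, pi00 <= 1)
  rest <- (1 - pi00) / 3
  c(pi00 = pi00, pi10 = rest, pi01 = rest, pi11 = rest)
}

.as_covmat <- function(x, t, name) {
  if (is.null(x)) return(NULL)
  if (length(x) == 1 && !is.matrix(x)) x <- diag(as.numeric(x), t)
  x <- as.matrix(x)
  if (!all(dim(x) == c(t, t))) {
    stop(name, " must be a ", t, "x", t, " matrix", call. = FALSE)
  }
  if (max(abs(x - t(x))) > 1e-10 * max(1, max(abs(x))) ||
      any(eigen(x, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop(name, " must be symmetric positive definite", call. = FALSE)
  }
  x
}

#' Prior specification for the BayesB sampler
#'
#' All (co)variance matrices carry inverse-Wishart priors. Degrees of freedom
#' default to `t + 2` (traits + 2) so the prior mean equals the supplied
#' matrix, the natural way to centre the prior on externally estimated
#' variance components.
#'
#' @param R0 residual (co)variance prior matrix (t x t, or scalar).
#' @param G0 marker substitution-effect (co)variance prior matrix.
#' @param C0 common-litter (co)variance prior matrix (NULL = no litter term).
#' @param U0 polygenic (co)variance prior matrix (NULL = no polygenic term).
#' @param pi00 bivariate joint-null inclusion probability (default 0.9982,
#'   giving 0.0006 per non-null configuration).
#' @param pi_uni univariate exclusion probability (default 0.9988).
#' @param nu inverse-Wishart degrees of freedom (single value used for all
#'   components; default `t + 2`).
#' @param pi optional explicit configuration-probability vector overriding
#'   `pi00`/`pi_uni` (length 4 bivariate, 2 univariate; must sum to 1).
#' @return List of class `bayesb_priors`.
#' @export
bayesb_priors <- function(R0, G0, C0 = NULL, U0 = NULL,
                          pi00 = 0.9982, pi_uni = 0.9988,
                          nu = NULL, pi = NULL) {
  structure(list(R0 = R0, G0 = G0, C0 = C0, U0 = U0, pi00 = pi00,
                 pi_uni = pi_uni, nu = nu, pi = pi),
            class = "bayesb_priors")
}

.resolve_priors <- function(prior, t) {
  R0 <- .as_covmat(prior$R0, t, "R0")
  G0 <- .as_covmat(prior$G0, t, "G0")
  C0 <- .as_covmat(prior$C0, t, "C0")
  U0 <- .as_covmat(prior$U0, t, "U0")
  nu <- if (is.null(prior$nu)) t + 2 else prior$nu
  if (nu <= t + 1) stop("nu must exceed t + 1 for a finite prior mean",
                        call. = FALSE)
  pi <- prior$pi
  if (is.null(pi)) {
    pi <- if (t == 2) pi_config(prior$pi00)
          else c(prior$pi_uni, 1 - prior$pi_uni)
  }
  if (length(pi) != (if (t == 2) 4 else 2) || any(pi < 0) ||
      abs(sum(pi) - 1) > 1e-8) {
    stop("inclusion prior must be a probability vector over the ",
         if (t == 2) 4 else 2, " indicator configurations", call. = FALSE)
  }
  list(R0 = R0, G0 = G0, C0 = C0, U0 = U0, nu = nu, pi = pi)
}

#' MCMC schedule
#'
#' Defaults follow a long production schedule (470,000 iterations, 70,000
#' burn-in, thinning 40, i.e. 10,000 saved draws); scale down for desk-size
#' analyses.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in discarded leading iterations (must be < `n_iter`).
#' @param thin save one draw every `thin` iterations.
#' @param seed integer RNG seed.
#' @param locus_variance_mode `"per_locus"` (each SNP its own effect
#'   (co)variance, classic BayesB) or `"shared"` (one matrix for all SNPs).
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 470000, burn_in = 70000, thin = 40,
                        seed = 1,
                        locus_variance_mode = c("per_locus", "shared")) {
  locus_variance_mode <- match.arg(locus_variance_mode)
  stopifnot(burn_in >= 0, burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 locus_variance_mode = locus_variance_mode),
            class = "mcmc_config")
}

#' Low-level BayesB Gibbs sampler
#'
#' Direct matrix interface used by [bayesb_gwas()] and by degenerate-case
#' analyses (prior-only runs, marker-free fits). Most users should call
#' [bayesb_gwas()].
#'
#' @param Y numeric matrix n x t (t = 1 or 2) of phenotypes; NA = missing
#'   record for that trait. n = 0 gives a prior-only run.
#' @param X fixed-effect design matrix (flat prior). NULL = none.
#' @param litter factor/integer of litter codes per row, or NULL.
#' @param ped list with elements `id` (integer, phenotype row to pedigree
#'   position) and `ainv` (sparse A-inverse from [sparse_ainverse()]), or NULL.
#' @param M marker covariate matrix n x k (0/1/2 dosages; columns are centered
#'   internally unless `center = FALSE`). NULL = no markers.
#' @param priors a [bayesb_priors()].
#' @param mcmc an [mcmc_config()].
#' @param center center marker columns before sampling.
#' @param store_u,store_resid store polygenic draws / residual draws.
#' @return Object of class `bayesb_fit`; see [bayesb_gwas()].
#' @export
bayesb_sampler <- function(Y, X = NULL, litter = NULL, ped = NULL, M = NULL,
                           priors, mcmc = mcmc_config(), center = TRUE,
                           store_u = TRUE, store_resid = FALSE) {
  Y <- as.matrix(Y)
  t <- ncol(Y)
  if (!t %in% 1:2) stop("Y must have 1 or 2 columns", call. = FALSE)
  n <- nrow(Y)
  for (s in seq_len(t)) {
    ys <- Y[, s][!is.na(Y[, s])]
    if (length(ys) > 1 && stats::var(ys) == 0) {
      stop("phenotype for trait ", s, " has zero variance", call. = FALSE)
    }
  }
  pr <- .resolve_priors(priors, t)
  if (is.null(X)) X <- matrix(0, n, 0)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  if (is.null(M)) M <- matrix(0, n, 0)
  M <- as.matrix(M)
  stopifnot(nrow(M) == n)
  Mc <- M
  if (center && ncol(M) > 0 && n > 0) {
    Mc <- sweep(M, 2, colMeans(M, na.rm = TRUE))
  }
  if (anyNA(Mc)) stop("marker matrix must be fully imputed before sampling",
                      call. = FALSE)
  if (is.null(litter)) {
    lit <- integer(n); q <- 0L
  } else {
    f <- factor(litter)
    lit <- as.integer(f); q <- nlevels(f)
  }
  if (is.null(ped)) {
    ped_id <- integer(n); m <- 0L
    ai <- aj <- integer(0); ax <- numeric(0)
  } else {
    ped_id <- as.integer(ped$id)
    A <- methods::as(methods::as(ped$ainv, "generalMatrix"), "TsparseMatrix")
    ai <- A@i + 1L; aj <- A@j + 1L; ax <- A@x
    m <- nrow(A)
    if (is.null(pr$U0)) stop("polygenic term requires U0", call. = FALSE)
  }
  if (q > 0 && is.null(pr$C0)) stop("litter term requires C0", call. = FALSE)
  Ct <- if (is.null(pr$C0)) diag(t) else pr$C0
  Ut <- if (is.null(pr$U0)) diag(t) else pr$U0
  set.seed(mcmc$seed)
  res <- .bayesb_mcmc_cpp(Y, X, lit, q, ped_id, m, ai, aj, ax, Mc,
                          pr$R0, pr$nu, Ct, pr$nu, Ut, pr$nu,
                          pr$G0, pr$nu, pr$pi,
                          mcmc$locus_variance_mode == "shared",
                          mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                          store_u, store_resid)
  k <- ncol(M)
  code <- res$delta_cfg
  delta <- array(0L, c(nrow(code), k, t))
  if (k > 0) {
    if (t == 1) {
      delta[, , 1] <- (code == 1L) * 1L
    } else {
      delta[, , 1] <- (code %in% c(1L, 3L)) * 1L
      delta[, , 2] <- (code %in% c(2L, 3L)) * 1L
    }
  }
  structure(list(
    samples = list(alpha = res$alpha, delta = delta, delta_cfg = code,
                   beta = res$beta, R = res$R, C = res$C, U = res$U,
                   G_mean = res$G_mean, u = res$u, litter = res$litter,
                   resid = res$resid),
    n_saved = res$n_saved, n = n, k = k, t = t,
    ped_id = if (!is.null(ped)) ped_id else NULL,
    X_names = colnames(X), snp_ids = colnames(M),
    marker_center = if (center && ncol(M) > 0 && n > 0)
      colMeans(M) else rep(0, ncol(M)),
    prior = pr, mcmc = mcmc
  ), class = "bayesb_fit")
}

#' Bivariate (or univariate) BayesB genome-wide association
#'
#' Fits the Bayesian multiple-marker regression: fixed effects (month, sex,
#' parity by default), a common-litter random effect, a pedigree polygenic
#' random effect, and per-SNP substitution effects under a spike-and-slab
#' inclusion indicator with 4 (bivariate) or 2 (univariate) configurations.
#' Covariance matrices are updated from inverse-Wishart full conditionals;
#' trait records missing for one trait are handled by residual augmentation.
#'
#' @param genotypes [genotype_data()], fully imputed (no missing dosages).
#' @param phenotypes data frame with `animal_id`, the trait columns and the
#'   fixed-effect/litter columns.
#' @param traits character vector of 1 or 2 phenotype column names (in the
#'   bivariate case the second trait is conventionally the selection
#'   criterion).
#' @param pedigree pedigree table for the polygenic term; NULL drops it.
#' @param fixed one-sided formula for fixed effects, evaluated in
#'   `phenotypes`.
#' @param litter name of the litter column, or NULL to drop the litter term.
#' @param priors a [bayesb_priors()].
#' @param mcmc an [mcmc_config()].
#' @param ... passed to [bayesb_sampler()].
#' @return A `bayesb_fit`: thinned posterior draws of marker effects and
#'   indicators, fixed/litter/polygenic effects, and the C, U, R, G matrices.
#' @export
bayesb_gwas <- function(genotypes, phenotypes, traits, pedigree = NULL,
                        fixed = ~ factor(month) + factor(sex) + factor(parity),
                        litter = "litter_id",
                        priors, mcmc = mcmc_config(), ...) {
  stopifnot(inherits(genotypes, "genotype_data"))
  if (!all(traits %in% names(phenotypes))) {
    stop("trait column(s) not found in phenotype table: ",
         paste(setdiff(traits, names(phenotypes)), collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(phenotypes$animal_id)
  gmiss <- setdiff(ids, rownames(genotypes$geno))
  if (length(gmiss)) {
    stop("phenotyped animals without genotypes: ",
         paste(utils::head(gmiss, 3), collapse = ", "), call. = FALSE)
  }
  Y <- as.matrix(phenotypes[, traits, drop = FALSE])
  storage.mode(Y) <- "double"
  X <- .fixed_design(fixed, phenotypes)
  lit <- if (!is.null(litter)) phenotypes[[litter]] else NULL
  ped <- NULL
  if (!is.null(pedigree)) {
    pp <- as_pedigree(pedigree)
    pmiss <- setdiff(ids, pp$animal)
    if (length(pmiss)) {
      stop("phenotyped animals missing from pedigree: ",
           paste(utils::head(pmiss, 3), collapse = ", "), call. = FALSE)
    }
    ped <- list(id = match(ids, pp$animal), ainv = sparse_ainverse(pp))
  }
  M <- genotypes$geno[ids, , drop = FALSE]
  fit <- bayesb_sampler(Y, X = X, litter = lit, ped = ped, M = M,
                        priors = priors, mcmc = mcmc, ...)
  fit$traits <- traits
  fit$map <- genotypes$map
  fit$animal_ids <- ids
  fit
}

# model.matrix with single-level factor terms dropped (a cohort slaughtered
# in one month, say, contributes no month contrast)
.fixed_design <- function(fixed, data) {
  vars <- all.vars(fixed)
  keep <- vapply(vars, function(v) {
    length(unique(data[[v]][!is.na(data[[v]])])) > 1
  }, logical(1))
  if (!all(keep)) {
    dropped <- vars[!keep]
    message("dropping constant fixed-effect term(s): ",
            paste(dropped, collapse = ", "))
    vars <- vars[keep]
    fixed <- if (length(vars)) {
      stats::reformulate(paste0("factor(", vars, ")"))
    } else ~ 1
  }
  stats::model.matrix(fixed, data = data)
}

#' Per-SNP posterior probability of association
#'
#' Fraction of saved draws in which each SNP's effect on each trait is
#' nonzero.
#'
#' @param fit a `bayesb_fit`.
#' @return k x t matrix of PPA values in `[0, 1]`.
#' @export
ppa_per_snp <- function(fit) {
  stopifnot(inherits(fit, "bayesb_fit"))
  if (fit$n_saved < 1) stop("no saved draws", call. = FALSE)
  out <- apply(fit$samples$delta, c(2, 3), mean)
  rownames(out) <- fit$snp_ids
  colnames(out) <- paste0("trait", seq_len(fit$t))
  out
}

#' @exportS3Method base::print
print.bayesb_fit <- function(x, ...) {
  cat("bayesb_fit:", x$t, "trait(s),", x$n, "records,", x$k, "SNPs,",
      x$n_saved, "saved draws\n")
  if (x$n_saved > 0) {
    Rm <- matrix(colMeans(x$samples$R), x$t, x$t)
    cat("posterior mean residual (co)variance:\n")
    print(round(Rm, 4))
    if (x$k > 0) {
      cat("mean per-draw included SNPs:",
          round(mean(apply(x$samples$delta_cfg != 0, 1, sum)), 2), "of",
          x$k, "\n")
    }
  }
  invisible(x)
}
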