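#' Validate and topologically order a pedigree
#'
#' A pedigree is a data frame with columns `animal`, `sire`, `dam`. Unknown
#' parents are coded as `NA`, `0` or `""`. Records are reordered so that
#' parents always precede their offspring; a cycle (an animal that is its own
#' ancestor) is an error.
#'
#' @param ped data frame with columns `animal`, `sire`, `dam` (character or
#'   integer IDs).
#' @return A data frame of class `pedigree` with character ID columns, unknown
#'   parents as `NA`, ordered parents-before-offspring.
#' @export
as_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped))) {
    stop("pedigree must have columns animal, sire, dam", call. = FALSE)
  }
  ped <- data.frame(
    animal = as.character(ped$animal),
    sire   = .clean_parent(ped$sire),
    dam    = .clean_parent(ped$dam),
    stringsAsFactors = FALSE
  )
  if (anyNA(ped$animal) || any(ped$animal == "")) {
    stop("animal IDs must be non-missing", call. = FALSE)
  }
  if (anyDuplicated(ped$animal)) {
    stop("duplicated animal IDs in pedigree", call. = FALSE)
  }
  for (p in c("sire", "dam")) {
    unknown <- !is.na(ped[[p]]) & !(ped[[p]] %in% ped$animal)
    if (any(unknown)) {
      # parents without their own record become founders appended up front
      extra <- unique(ped[[p]][unknown])
      ped <- rbind(
        data.frame(animal = extra, sire = NA_character_, dam = NA_character_,
                   stringsAsFactors = FALSE),
        ped
      )
    }
  }
  ord <- .ped_toposort(ped)
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

.clean_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "0" | x == ""] <- NA_character_
  x
}

# Kahn's algorithm; stops on cycles.
.ped_toposort <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire]) # NA where unknown
  di <- unname(idx[ped$dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) {
    stop("pedigree contains a cycle (an animal is its own ancestor)",
         call. = FALSE)
  }
  out
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the pedigree-expected additive relationship matrix A using the
#' tabular recurrences a(i,j) = (a(j, sire_i) + a(j, dam_i)) / 2 and
#' a(i,i) = 1 + a(sire_i, dam_i) / 2, with unknown parents contributing zero.
#' The diagonal equals 1 plus the inbreeding coefficient.
#'
#' @param ped a pedigree (coerced with [as_pedigree()]).
#' @return A symmetric numeric matrix with animal IDs as dimnames.
#' @examples
#' ped <- data.frame(animal = c("s", "d", "o"),
#'                   sire = c(NA, NA, "s"), dam = c(NA, NA, "d"))
#' A <- build_numerator_relationship(ped)
#' A["s", "o"] # 0.5
#' @export
build_numerator_relationship <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' @param ped a pedigree.
#' @return Named numeric vector of inbreeding coefficients F (diagonal of A
#'   minus one).
#' @export
inbreeding <- function(ped) {
  A <- build_numerator_relationship(ped)
  diag(A) - 1
}

#' Matrix square root of a relationship matrix
#'
#' Cholesky factor L with L %*% t(L) = A. Falls back to a symmetric eigen
#' factor when A is only positive semi-definite (e.g. clones or duplicated
#' founder rows), zeroing eigenvalues below tolerance.
#'
#' @param A symmetric positive semi-definite matrix.
#' @param tol reconstruction/symmetry tolerance.
#' @return Lower-triangular (or dense, in the PSD fallback) matrix L.
#' @export
factor_relationship <- function(A, tol = 1e-8) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("A must be a square matrix", call. = FALSE)
  }
  if (max(abs(A - t(A))) > tol * max(1, max(abs(A)))) {
    stop("A is not symmetric within tolerance", call. = FALSE)
  }
  L <- tryCatch(t(chol(A)), error = function(e) NULL)
  if (is.null(L)) {
    ee <- eigen(A, symmetric = TRUE)
    vals <- pmax(ee$values, 0)
    L <- ee$vectors %*% diag(sqrt(vals), nrow = length(vals))
    dimnames(L) <- dimnames(A)
  }
  if (max(abs(L %*% t(L) - A)) > max(tol, 1e-8) * max(1, max(abs(A)))) {
    stop("factorization failed to reconstruct A within tolerance",
         call. = FALSE)
  }
  L
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes its Mendelian
#' sampling precision d_i to the (animal, parent) block pattern, where
#' d_i = 1 / (1 - 0.25 (1 + F_s) - 0.25 (1 + F_d)) for two known parents
#' (terms dropped for unknown parents). Used by the Gibbs sampler for
#' single-site polygenic updates.
#'
#' @param ped a pedigree.
#' @return A sparse symmetric `Matrix::dsCMatrix` with animal IDs as dimnames.
#' @export
sparse_ainverse <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  Fcoef <- inbreeding(ped)
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    vs <- if (is.na(s)) 0 else 0.25 * (1 + Fcoef[s])
    vd <- if (is.na(d)) 0 else 0.25 * (1 + Fcoef[d])
    dinv <- 1 / (1 - vs - vd)
    add(i, i, dinv)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        add(i, p, -0.5 * dinv)
        add(p, i, -0.5 * dinv)
      }
    }
    if (!is.na(s)) add(s, s, 0.25 * dinv)
    if (!is.na(d)) add(d, d, 0.25 * dinv)
    if (!is.na(s) && !is.na(d)) {
      add(s, d, 0.25 * dinv)
      add(d, s, 0.25 * dinv)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' Read a pedigree CSV
#'
#' Expects columns animal, sire, dam; 0 or empty marks an unknown parent.
#'
#' @param path file path.
#' @return A [as_pedigree()]-validated pedigree.
#' @export
read_pedigree <- function(path) {
  as_pedigree(data.table::fread(path, colClasses = "character",
                                data.table = FALSE))
}

#' Write a pedigree CSV
#' @param ped pedigree data frame.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  ped <- as_pedigree(ped)
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  data.table::fwrite(out, path)
  invisible(path)
}
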