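# Small-scale pedigree machinery: numerator relationship matrix by the
# tabular method and a dense direct solve of Henderson's mixed model
# equations. Intended for phenotype correction, simulation and as the
# generalized-least-squares oracle, not national-scale evaluation.

# topological order: parents before offspring; error on cycles
pedigree_order <- function(ped) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  ids <- as.character(ped$animal)
  if (anyDuplicated(ids))
    stop("duplicated animals in pedigree: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sire <- as.character(ped$sire); dam <- as.character(ped$dam)
  unknown <- function(p) is.na(p) | p == "0" | p == ""
  placed <- logical(length(ids)); ord <- integer(0)
  repeat {
    ready <- !placed &
      (unknown(sire) | sire %in% ids[placed] | !(sire %in% ids)) &
      (unknown(dam) | dam %in% ids[placed] | !(dam %in% ids))
    if (!any(ready)) break
    ord <- c(ord, which(ready)); placed[ready] <- TRUE
  }
  if (!all(placed))
    stop("pedigree contains a cycle involving: ",
         paste(ids[!placed], collapse = ", "))
  ord
}

#' Additive (numerator) relationship matrix from a pedigree
#'
#' Tabular-method recursion: founders have diagonal 1 and are mutually
#' unrelated; for a non-founder the relationship with any older animal is
#' the average of that animal's relationships with the two parents, and the
#' diagonal is `1 + 0.5 * A[sire, dam]` (inbreeding of descendants is
#' accumulated, founders are assumed non-inbred). Parents absent from the
#' pedigree are treated as unknown.
#'
#' @param ped data frame with columns `animal`, `sire`, `dam`; `"0"`, `""`
#'   or `NA` denote an unknown parent.
#' @return Symmetric matrix with dimnames in the input animal order.
#' @export
build_A <- function(ped) {
  ord <- pedigree_order(ped)
  ids <- as.character(ped$animal)[ord]
  sire <- as.character(ped$sire)[ord]
  dam <- as.character(ped$dam)[ord]
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  si <- match(sire, ids); di <- match(dam, ids)   # NA for unknown/absent
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    prior <- seq_len(j - 1L)
    if (length(prior)) {
      rel <- numeric(j - 1L)
      if (!is.na(s)) rel <- rel + 0.5 * A[prior, s]
      if (!is.na(d)) rel <- rel + 0.5 * A[prior, d]
      A[prior, j] <- rel
      A[j, prior] <- rel
    }
    A[j, j] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  back <- match(as.character(ped$animal), ids)
  A[back, back, drop = FALSE]
}

# solve that falls back to the Moore-Penrose inverse on singular systems
solve_g <- function(M, rhs) {
  out <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(out)) {
    out <- MASS::ginv(M) %*% rhs
    attr(out, "singular") <- TRUE
  }
  out
}

#' Solve Henderson's mixed model equations
#'
#' Direct dense solve of the MME for the model `y = X b + Z a + e` with
#' `var(a) = sigma2_a A`, `var(e) = sigma2_e I` and
#' `lambda = sigma2_e / sigma2_a`:
#' the joint system `[X'X, X'Z; Z'X, Z'Z + lambda A^-1] (b, a) = (X'y, Z'y)`.
#' The fixed-effect solution equals the generalized least squares estimate
#' computed with an explicit `V` inverse (see [gls_blue()]), which is the
#' exactness this package's approximate-GLS correction relies on.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix.
#' @param Z random-effect incidence matrix (columns = pedigree animals).
#' @param A additive relationship matrix from [build_A()].
#' @param lambda variance ratio `sigma2_e / sigma2_a` (> 0).
#' @return List with `b_hat` (fixed effects), `a_hat` (predicted breeding
#'   values, named by the columns of `Z`/rows of `A`) and `singular` flag.
#' @export
solve_mme <- function(y, X, Z, A, lambda) {
  stopifnot(lambda > 0, nrow(X) == length(y), nrow(Z) == length(y),
            ncol(Z) == nrow(A))
  X <- as.matrix(X); Z <- as.matrix(Z)
  Ainv <- solve(A)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Ainv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve_g(C, rhs)
  p <- ncol(X)
  list(b_hat = drop(sol)[seq_len(p)],
       a_hat = stats::setNames(drop(sol)[-seq_len(p)],
                               colnames(Z) %||% rownames(A)),
       singular = isTRUE(attr(sol, "singular")))
}

#' Generalized least squares fixed effects with an explicit V inverse
#'
#' `b_hat = (X' V^-1 X)^- X' V^-1 y` with
#' `V = sigma2_a Z A Z' + sigma2_e I`. Dense; used as the exact oracle the
#' mixed-model-equations route must match.
#'
#' @inheritParams solve_mme
#' @param sigma2_a,sigma2_e additive and residual variance components.
#' @return Numeric vector of fixed-effect estimates.
#' @export
gls_blue <- function(y, X, Z, A, sigma2_a, sigma2_e) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  V <- sigma2_a * Z %*% A %*% t(Z) + sigma2_e * diag(length(y))
  W <- solve(V)
  drop(solve_g(t(X) %*% W %*% X, t(X) %*% W %*% y))
}
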