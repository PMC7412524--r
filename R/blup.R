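#' Solve the maternal/direct mixed-model equations
#'
#' Fits the colony performance model
#' `y = year-by-apiary fixed effect + maternal(queen entity)
#'  + direct(worker-group entity) + e`
#' with random effects distributed as `N(0, Sigma_A (x) A)` over the
#' entity pedigree and i.i.d. residuals `N(0, sigma_e2)`.  Henderson's
#' equations are assembled sparsely (the relationship inverse comes from
#' [entity_a_inverse()]) and solved by a direct sparse Cholesky
#' factorization.
#'
#' @param y numeric vector of performance records.
#' @param level factor/integer fixed-effect level per record (one level
#'   per year-by-apiary combination).
#' @param queen_entity,wg_entity entity ids receiving each record's
#'   maternal and direct effect.
#' @param ep an [entity_pedigree()] (or a precomputed sparse relationship
#'   inverse via `a_inverse`).
#' @param sigma_a current 2 x 2 additive covariance (or `c(vm, vd, cov)`).
#' @param sigma_e2 residual variance.
#' @param a_inverse optional precomputed `entity_a_inverse(ep)`.
#' @return list with `fixed` (named estimates per level), `ebv_m` and
#'   `ebv_d` (per-entity solutions), and `ebv_ic = ebv_m + ebv_d`
#'   (the inheritance-criterion index used for selection).
#' @export
solve_mme <- function(y, level, queen_entity, wg_entity, ep, sigma_a,
                      sigma_e2, a_inverse = NULL) {
  if (length(y) < 1L) stop("at least one record is required")
  sigma_a <- as_sigma_a(sigma_a)
  lev <- as.factor(level)
  nf <- nlevels(lev)
  ne <- if (is.null(a_inverse)) nrow(ep) else nrow(a_inverse)
  nr <- length(y)
  if (is.null(a_inverse)) a_inverse <- entity_a_inverse(ep)
  W <- Matrix::sparseMatrix(
    i = rep.int(seq_len(nr), 3L),
    j = c(as.integer(lev), nf + queen_entity, nf + ne + wg_entity),
    x = rep.int(1, 3L * nr),
    dims = c(nr, nf + 2L * ne))
  C <- Matrix::crossprod(W)
  Ginv <- solve(sigma_a) * sigma_e2
  P <- Matrix::bdiag(Matrix::sparseMatrix(i = integer(), j = integer(),
                                          dims = c(nf, nf)),
                     Matrix::kronecker(Ginv, a_inverse))
  M <- Matrix::forceSymmetric(C + P)
  rhs <- Matrix::crossprod(W, y)
  # supernodal Cholesky handles the fill-in of deep multi-generation
  # pedigrees far better than the simplicial default
  sol <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(M, LDL = FALSE, super = TRUE),
                             rhs, system = "A")),
    error = function(e) as.numeric(Matrix::solve(M, rhs)))
  fixed <- sol[seq_len(nf)]
  names(fixed) <- levels(lev)
  ebv_m <- sol[nf + seq_len(ne)]
  ebv_d <- sol[nf + ne + seq_len(ne)]
  list(fixed = fixed, ebv_m = ebv_m, ebv_d = ebv_d,
       ebv_ic = ebv_m + ebv_d)
}

#' Re-estimate the additive genetic covariance from simulated drones
#'
#' Within-family estimator of the current additive covariance, immune to
#' the Bulmer effect: each of the `N` supplied queens produces
#' `n_drones` drones (meiotic gametes on the doubled homozygous scale);
#' the Mendelian-sampling deviations
#' `delta = TBV(queen) - TBV(drone)` satisfy
#' `var(delta) = (1 - F_Q) Sigma_A`, so
#' `Sigma_hat = (1/(N n_drones - 1)) sum_i (1 - F_i)^-1 sum_j
#'  delta_ij delta_ij'`.
#' Queens with pedigree inbreeding within 1e-6 of 1 are excluded with a
#' warning.  A non-positive-semidefinite raw estimate is projected to
#' the nearest PSD matrix by clipping eigenvalues at 1e-8.
#'
#' Uses the current R random number stream.
#'
#' @param haplotypes list of `n_loci` x 2 genotype matrices, one per
#'   queen.
#' @param f_queen pedigree inbreeding coefficients of the queens.
#' @param arch a [trait_architecture()].
#' @param n_drones drones sampled per queen (default 100).
#' @return list with `sigma_hat` (2 x 2), `n_queens`, `n_drones`.
#' @export
reestimate_variance <- function(haplotypes, f_queen, arch, n_drones = 100L) {
  keep <- which(f_queen < 1 - 1e-6)
  if (length(keep) < length(f_queen))
    warning("excluding ", length(f_queen) - length(keep),
            " queen(s) with inbreeding within 1e-6 of 1")
  if (!length(keep)) stop("no queens left for variance re-estimation")
  S <- matrix(0, 2L, 2L)
  p2 <- 2 * arch$allele_freq
  for (i in keep) {
    h <- haplotypes[[i]]
    g <- make_gamete(h, n_drones)
    dv <- arch$effects %*% (2 * g - p2)           # 2 x n_drones
    qv <- drop(arch$effects %*% (h[, 1L] + h[, 2L] - p2))
    delta <- qv - dv
    S <- S + tcrossprod(delta) / (1 - f_queen[i])
  }
  sigma_hat <- S / (length(keep) * n_drones - 1)
  sigma_hat <- (sigma_hat + t(sigma_hat)) / 2
  ev <- eigen(sigma_hat, symmetric = TRUE)
  if (any(ev$values < 1e-8)) {
    ev$values <- pmax(ev$values, 1e-8)
    sigma_hat <- ev$vectors %*% (ev$values * t(ev$vectors))
  }
  list(sigma_hat = sigma_hat, n_queens = length(keep), n_drones = n_drones)
}
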