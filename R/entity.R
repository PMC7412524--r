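#' Evaluation-entity pedigree for honeybee BLUP
#'
#' The genetic evaluation works on three kinds of entities: breeding
#' *queens*, their colonies' *worker groups*, and mating-station
#' *pseudo-sires* (the pooled drones of a station's eight
#' drone-producing queens, the honeybee analogue of a sire).  Every
#' non-base entity has exactly two parent entities with weight 1/2 each:
#'
#' * queen: (dam queen, dam's mating pseudo-sire);
#' * worker group: (own queen, own mating pseudo-sire);
#' * pseudo-sire: (station founder queen, founder's mating pseudo-sire).
#'
#' Each entity carries a Mendelian-sampling variance coefficient `d`
#' such that the generalized decomposition `A = T D T'` reproduces the
#' pool-averaged relationship matrix exactly (see
#' [entity_relationship_exact()] for the reference recursion).  The
#' closed forms, with `a_xx` the parental diagonal elements of `A`:
#'
#' * queen: `d = 1 - (a_dd + a_ss)/4`;
#' * pseudo-sire: `d = (1 - (a_dd + a_ss)/4) / n_dpq`, the founder-
#'   daughter coefficient diluted over the `n_dpq` drone-producing
#'   queens whose (infinitely many) drones make up the pool;
#' * worker group: `d = (2 - a_ss)/(4 n_mates)`: the mean of `n_mates`
#'   independent pool drones (a doubled gamete has relationship
#'   diagonal 2) deviates from the pool mean with variance
#'   `(2 - a_ss)/n_mates`, and enters the worker-group value with
#'   weight 1/2;
#' * base queen: `d = 1`; base pseudo-sire: `d = 2/n_base_drones`
#'   (a pool of unrelated doubled gametes).
#'
#' @param id integer entity ids 1..n, parents preceding offspring.
#' @param kind character: `"queen"`, `"worker_group"` or `"pseudo_sire"`.
#' @param dam,sire parent entity ids (0 = base entity; either both 0 or
#'   both positive).
#' @param d Mendelian-sampling variance coefficients (>= 0).
#' @param n_dpq drone-producing queens per mating station.
#' @param n_mates drones mated per queen.
#' @param n_base_drones drones (from distinct unrelated queens) forming
#'   a base pseudo-sire pool.
#' @return An object of class `entity_pedigree` (a data frame with
#'   attributes `n_dpq`, `n_mates`, `n_base_drones`).
#' @export
entity_pedigree <- function(id, kind, dam, sire, d,
                            n_dpq = 8L, n_mates = 12L, n_base_drones = 12L) {
  n <- length(id)
  kind <- match.arg(kind, c("queen", "worker_group", "pseudo_sire"),
                    several.ok = TRUE)
  kind <- rep_len(kind, n)
  if (!identical(as.integer(id), seq_len(n)))
    stop("entity ids must be 1..n in order")
  if (any((dam == 0L) != (sire == 0L)))
    stop("entities have either two parent entities or none")
  if (any(dam >= id & dam > 0L) || any(sire >= id & sire > 0L))
    stop("dangling or unordered parent reference")
  if (any(d < 0)) stop("Mendelian-sampling coefficients must be non-negative")
  structure(data.frame(id = as.integer(id), kind = kind,
                       dam = as.integer(dam), sire = as.integer(sire),
                       d = as.numeric(d)),
            n_dpq = as.integer(n_dpq), n_mates = as.integer(n_mates),
            n_base_drones = as.integer(n_base_drones),
            class = c("entity_pedigree", "data.frame"))
}

#' Sparse inverse of the entity relationship matrix
#'
#' Generalized Henderson rules: entity `i` with parents `p1, p2` and
#' Mendelian-sampling coefficient `d_i` contributes
#' `(1/d_i) k k'` with `k = e_i - e_p1/2 - e_p2/2` (base entities:
#' `1/d_i` on the diagonal).
#'
#' @param ep an [entity_pedigree()].
#' @return a sparse symmetric `dsCMatrix`.
#' @export
entity_a_inverse <- function(ep) {
  n <- nrow(ep)
  has <- ep$dam > 0L
  w <- 1 / ep$d
  i0 <- ep$id[!has]
  ii <- ep$id[has]; dd <- ep$dam[has]; ss <- ep$sire[has]; wh <- w[has]
  trip_i <- c(i0, ii, dd, ss, ii, ii, dd, dd, ss, ss)
  trip_j <- c(i0, ii, dd, ss, dd, ss, ii, ss, ii, dd)
  trip_x <- c(w[!has], wh, wh / 4, wh / 4, -wh / 2, -wh / 2,
              -wh / 2, wh / 4, -wh / 2, wh / 4)
  M <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n, n))
  Matrix::forceSymmetric(M)
}

#' Entity relationship matrix via the generalized decomposition
#'
#' Dense `A = T D T'` with `T = (I - P)^-1` where `P` holds the parent
#' weights 1/2.  Intended for small pedigrees (tests, diagnostics).
#'
#' @inheritParams entity_a_inverse
#' @export
entity_relationship_tdt <- function(ep) {
  n <- nrow(ep)
  P <- matrix(0, n, n)
  has <- which(ep$dam > 0L)
  P[cbind(has, ep$dam[has])] <- P[cbind(has, ep$dam[has])] + 0.5
  P[cbind(has, ep$sire[has])] <- P[cbind(has, ep$sire[has])] + 0.5
  Tm <- solve(diag(n) - P)
  Tm %*% (ep$d * t(Tm))
}

#' Exact pool-averaged entity relationship matrix (reference recursion)
#'
#' Reference implementation of the relationship matrix among evaluation
#' entities, derived from first principles of the pool-averaging model
#' and *independent of the stored Mendelian-sampling coefficients*:
#' a queen's father is a random drone from her dam's mating pool, a
#' worker group averages `n_mates` independent pool drones, and a
#' pseudo-sire is the average of the (infinitely many) drones of its
#' `n_dpq` drone-producing queens, which share the founder as dam.
#' Off-diagonals follow `a_ij = (a_i,dam(j) + a_i,sire(j))/2`;
#' diagonals follow the pool-composition identities:
#'
#' * queen: `1 + a_{dam,sire}/2`;
#' * pseudo-sire: `a_vv/n_dpq + (1 - 1/n_dpq) a_vv'` with the virtual
#'   DPQ diagonal `a_vv = 1 + a_{F,S_F}/2` and the between-DPQ
#'   relationship `a_vv' = a_FF/4 + a_SFSF/4 + a_{F,S_F}/2`;
#' * worker group: `a_QQ/4 + (2/n_mates + (1 - 1/n_mates) a_SS)/4
#'   + a_QS/2`;
#' * base queen: 1; base pseudo-sire: `2/n_base_drones`.
#'
#' Quadratic in the number of entities; use for small pedigrees only.
#'
#' @inheritParams entity_a_inverse
#' @export
entity_relationship_exact <- function(ep) {
  n <- nrow(ep)
  ndpq <- attr(ep, "n_dpq"); nmat <- attr(ep, "n_mates")
  nbd <- attr(ep, "n_base_drones")
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dj <- ep$dam[j]; sj <- ep$sire[j]
    if (dj > 0L)
      for (i in seq_len(j - 1L)) A[i, j] <- A[j, i] <- (A[i, dj] + A[i, sj]) / 2
    A[j, j] <- switch(ep$kind[j],
      queen = if (dj == 0L) 1 else 1 + A[dj, sj] / 2,
      pseudo_sire = if (dj == 0L) 2 / nbd else {
        avv <- 1 + A[dj, sj] / 2
        avw <- A[dj, dj] / 4 + A[sj, sj] / 4 + A[dj, sj] / 2
        avv / ndpq + (1 - 1 / ndpq) * avw
      },
      worker_group = {
        if (dj == 0L) stop("a worker group always has a queen and a sire")
        A[dj, dj] / 4 + (2 / nmat + (1 - 1 / nmat) * A[sj, sj]) / 4 +
          A[dj, sj] / 2
      })
  }
  A
}
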