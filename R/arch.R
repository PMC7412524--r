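#' Construct a trait architecture from explicit components
#'
#' A trait architecture holds the finite-locus genetic model of a single
#' selection trait with a maternal (queen) and a direct (worker-group)
#' effect: biallelic loci, base-population allele frequencies, and a
#' 2 x `n_loci` matrix of per-allele-copy substitution effects (row 1
#' maternal, row 2 direct).  The implied base-population additive
#' covariance is `sum_l 2 p_l (1 - p_l) e_l e_l'`.
#'
#' @param allele_freq numeric vector of base allele frequencies, all
#'   strictly inside (0, 1).
#' @param effects 2 x `length(allele_freq)` numeric matrix of allele
#'   substitution effects; row 1 maternal, row 2 direct.
#' @param sigma_a target 2 x 2 additive covariance matrix (or length-3
#'   vector `c(var_maternal, var_direct, cov)`).
#' @param sigma_e2 residual variance of the performance record.
#' @return An object of class `trait_architecture`: a list with elements
#'   `n_loci`, `allele_freq`, `effects`, `sigma_a`, `sigma_e2` and
#'   `sigma_ic` (the base genetic standard deviation of the inheritance
#'   criterion, `sqrt(var_m + var_d + 2 cov)`).
#' @seealso [sample_architecture()] to draw an architecture matching a
#'   target covariance exactly.
#' @export
trait_architecture <- function(allele_freq, effects, sigma_a, sigma_e2) {
  sigma_a <- as_sigma_a(sigma_a)
  if (any(allele_freq <= 0) || any(allele_freq >= 1))
    stop("allele frequencies must lie strictly inside (0, 1)")
  effects <- as.matrix(effects)
  if (nrow(effects) != 2L || ncol(effects) != length(allele_freq))
    stop("'effects' must be a 2 x n_loci matrix matching 'allele_freq'")
  sic2 <- sum(sigma_a)
  if (sic2 < 0) stop("implied inheritance-criterion variance is negative")
  structure(list(
    n_loci      = length(allele_freq),
    allele_freq = as.numeric(allele_freq),
    effects     = effects,
    sigma_a     = sigma_a,
    sigma_e2    = as.numeric(sigma_e2),
    sigma_ic    = sqrt(sic2)
  ), class = "trait_architecture")
}

# Normalise sigma_a input and insist on symmetric positive definiteness.
as_sigma_a <- function(sigma_a) {
  if (length(sigma_a) == 3L)
    sigma_a <- matrix(c(sigma_a[1], sigma_a[3], sigma_a[3], sigma_a[2]), 2L)
  sigma_a <- as.matrix(sigma_a)
  if (!isTRUE(all.equal(sigma_a, t(sigma_a))))
    stop("sigma_a must be symmetric")
  ev <- eigen(sigma_a, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("sigma_a must be positive definite")
  sigma_a
}

#' Sample a finite-locus trait architecture
#'
#' Draws base allele frequencies from a U-shaped Beta(0.5, 0.5)
#' distribution (redrawn when within 1e-6 of 0 or 1) and per-locus
#' maternal/direct effect pairs from an equal-weight mixture of a
#' bivariate Laplace and a bivariate Normal distribution.  The raw
#' effects are then post-corrected by a single 2 x 2 whitening/recoloring
#' transform so that the implied base-population additive covariance
#' equals `sigma_a` *exactly* (to numerical precision), for any seed.
#'
#' Uses the current R random number stream; call `set.seed()` first for
#' reproducibility.
#'
#' @param n_loci number of unlinked biallelic loci (>= 2).
#' @inheritParams trait_architecture
#' @return A [trait_architecture()] object.
#' @examples
#' set.seed(1)
#' arch <- sample_architecture(200, c(1, 2, -0.75), 1)
#' round(arch$sigma_ic, 2)  # 1.22
#' @export
sample_architecture <- function(n_loci, sigma_a, sigma_e2) {
  sigma_a <- as_sigma_a(sigma_a)
  if (n_loci < 2L) stop("n_loci must be at least 2")
  p <- stats::rbeta(n_loci, 0.5, 0.5)
  bad <- which(p < 1e-6 | p > 1 - 1e-6)
  while (length(bad)) {
    p[bad] <- stats::rbeta(length(bad), 0.5, 0.5)
    bad <- bad[p[bad] < 1e-6 | p[bad] > 1 - 1e-6]
  }
  L <- t(chol(sigma_a))
  z <- matrix(stats::rnorm(2L * n_loci), 2L)
  lap <- stats::runif(n_loci) < 0.5
  # elliptical bivariate Laplace: sqrt(Exp(1)) * L z has covariance L L'
  scale <- rep(1, n_loci)
  scale[lap] <- sqrt(stats::rexp(sum(lap)))
  # raw per-locus pairs are i.i.d. with covariance sigma_a / n_loci,
  # independent of allele frequency
  eff <- L %*% z * rep(scale / sqrt(n_loci), each = 2L)
  # exact post-correction: recolor achieved covariance onto the target
  w <- 2 * p * (1 - p)
  achieved <- tcrossprod(eff * rep(sqrt(w), each = 2L))
  Tm <- L %*% solve(t(chol(achieved)))
  eff <- Tm %*% eff
  trait_architecture(p, eff, sigma_a, sigma_e2)
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("Trait architecture:", x$n_loci, "unlinked biallelic loci\n")
  cat(sprintf("  sigma_a: var_m = %.4g, var_d = %.4g, cov_md = %.4g (r_md = %.2f)\n",
              x$sigma_a[1, 1], x$sigma_a[2, 2], x$sigma_a[1, 2],
              x$sigma_a[1, 2] / sqrt(x$sigma_a[1, 1] * x$sigma_a[2, 2])))
  cat(sprintf("  sigma_e2 = %.4g, sigma_ic = %.4g\n", x$sigma_e2, x$sigma_ic))
  invisible(x)
}

#' Mendelian gamete of a queen
#'
#' Per locus, one of the two maternal alleles is transmitted
#' independently with probability 1/2; loci are unlinked and there is no
#' mutation.
#'
#' @param haplotypes `n_loci` x 2 matrix of 0/1 allele counts (one column
#'   per haplotype).
#' @param n number of independent gametes to draw.
#' @return `n_loci` x `n` integer matrix of gametes (one column each).
#' @export
make_gamete <- function(haplotypes, n = 1L) {
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) != 2L) stop("a queen genotype has exactly two haplotypes")
  nl <- nrow(haplotypes)
  pick <- matrix(stats::runif(nl * n) < 0.5, nl, n)
  g <- haplotypes[, 1L] * pick + haplotypes[, 2L] * (1 - pick)
  storage.mode(g) <- "integer"
  g
}

#' True breeding values of queens, drones, and worker groups
#'
#' Breeding values are linear in allele counts centered at the base
#' allele frequencies, so the base-population expectation is zero and
#' cohort means read directly as gain over the base population.  Drones
#' are haploid but interpreted as diploid and homozygous at all loci, so
#' a drone's allele counts are twice its haplotype.
#'
#' @param haplotypes queen: `n_loci` x 2 matrix; drone: `n_loci` x `n`
#'   matrix of 0/1 haplotypes (one drone per column).
#' @param arch a [trait_architecture()].
#' @return `queen_tbv`: named numeric `c(maternal, direct)`.
#'   `drone_tbv`: 2 x `n` matrix of breeding values on the doubled
#'   homozygous scale.
#' @export
queen_tbv <- function(haplotypes, arch) {
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) != arch$n_loci)
    stop("genotype does not conform to the architecture (locus count)")
  v <- drop(arch$effects %*% (haplotypes[, 1L] + haplotypes[, 2L] - 2 * arch$allele_freq))
  c(maternal = v[1L], direct = v[2L])
}

#' @rdname queen_tbv
#' @export
drone_tbv <- function(haplotypes, arch) {
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) != arch$n_loci)
    stop("haplotype does not conform to the architecture (locus count)")
  v <- arch$effects %*% (2 * haplotypes - 2 * arch$allele_freq)
  rownames(v) <- c("maternal", "direct")
  v
}

#' Direct breeding value of a worker group
#'
#' The worker group is modeled as the expectation over an infinite group
#' of workers, each carrying one maternal gamete of the queen and the
#' haplotype of one of her mates: the direct-effect row applied to
#' `0.5 * (queen counts - 2p) + mean_j (mate haplotype_j - p)`.
#' Deterministic given the queen and her stored mates; invariant to mate
#' order.
#'
#' @param queen_haplotypes `n_loci` x 2 matrix.
#' @param mate_haplotypes `n_loci` x `n_mates` matrix of drone
#'   haplotypes (the queen's stored mates, usually 12).
#' @inheritParams queen_tbv
#' @return scalar direct breeding value of the worker group.
#' @export
worker_group_tbv <- function(queen_haplotypes, mate_haplotypes, arch) {
  mate_haplotypes <- as.matrix(mate_haplotypes)
  if (ncol(mate_haplotypes) < 1L) stop("a mated queen has at least one mate")
  if (nrow(mate_haplotypes) != arch$n_loci)
    stop("mate haplotypes do not conform to the architecture (locus count)")
  qh <- as.matrix(queen_haplotypes)
  cw <- 0.5 * (qh[, 1L] + qh[, 2L] - 2 * arch$allele_freq) +
    rowMeans(mate_haplotypes) - arch$allele_freq
  sum(arch$effects[2L, ] * cw)
}

#' Serialize a trait architecture to a delimited text file
#'
#' Writes a small commented header (target covariance, residual
#' variance, optional seed) followed by a tab-separated table with
#' columns `locus`, `frequency`, `maternal_effect`, `direct_effect`.
#'
#' @param arch a [trait_architecture()].
#' @param path file path.
#' @param seed optional integer recorded in the header for provenance.
#' @export
write_architecture <- function(arch, path, seed = NA) {
  hdr <- c(
    sprintf("# sigma_a %.17g %.17g %.17g", arch$sigma_a[1, 1],
            arch$sigma_a[2, 2], arch$sigma_a[1, 2]),
    sprintf("# sigma_e2 %.17g", arch$sigma_e2),
    sprintf("# seed %s", as.character(seed))
  )
  writeLines(hdr, path)
  tab <- data.frame(locus = seq_len(arch$n_loci),
                    frequency = arch$allele_freq,
                    maternal_effect = arch$effects[1L, ],
                    direct_effect = arch$effects[2L, ])
  suppressWarnings(utils::write.table(
    format(tab, digits = 17), path, append = TRUE, sep = "\t",
    quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  hdr <- readLines(path, n = 3L)
  sa <- as.numeric(strsplit(hdr[1L], " ")[[1L]][3:5])
  se <- as.numeric(strsplit(hdr[2L], " ")[[1L]][3L])
  tab <- utils::read.table(path, header = TRUE, skip = 3L, sep = "\t")
  trait_architecture(tab$frequency,
                     rbind(tab$maternal_effect, tab$direct_effect),
                     c(sa[1L], sa[2L], sa[3L]), se)
}

# Implied base-population additive covariance of an effect matrix.
implied_base_covariance <- function(allele_freq, effects) {
  w <- 2 * allele_freq * (1 - allele_freq)
  tcrossprod(effects * rep(sqrt(w), each = 2L))
}
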