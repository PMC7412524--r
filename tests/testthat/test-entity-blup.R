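# Entity pedigree, sparse relationship inverse, mixed-model equations,
# and the drone-based covariance re-estimator.

test_that("generalized decomposition matches the exact pool-average
           relationships on simulated pedigrees", {
  # <= 60 entities with full depth; then a deeper/wider case
  for (spec in list(c(n = 5, years = 1, seed = 1),
                    c(n = 14, years = 3, seed = 2),
                    c(n = 14, years = 5, seed = 3))) {
    sim <- sim_entity_pedigree(n_queens = spec[["n"]], years = spec[["years"]],
                               seed = spec[["seed"]])
    ep <- sim$ep
    A_exact <- entity_relationship_exact(ep)
    A_tdt <- entity_relationship_tdt(ep)
    expect_lt(max(abs(A_exact - A_tdt)), 1e-8)
    Ainv <- entity_a_inverse(ep)
    expect_lt(max(abs(as.matrix(Ainv %*% A_exact) - diag(nrow(ep)))), 1e-6)
    # the driver's incremental window agrees with the oracle
    st <- sim$st
    expect_lt(max(abs(st$ke[seq_len(st$ke_n), seq_len(st$ke_n)] -
                        A_exact[st$ke_e, st$ke_e])), 1e-10)
  }
})

test_that("base entities and pseudo-sire diagonals behave as derived", {
  sim <- sim_entity_pedigree(n_queens = 8, years = 2, seed = 4)
  ep <- sim$ep
  base_q <- ep$kind == "queen" & ep$dam == 0
  expect_true(all(ep$d[base_q] == 1))
  A <- entity_relationship_exact(ep)
  sires <- which(ep$kind == "pseudo_sire")
  expect_true(all(diag(A)[sires] < 2))
  # a base pool of 12 unrelated doubled gametes has variance 2/12
  base_s <- which(ep$kind == "pseudo_sire" & ep$dam == 0)
  expect_equal(unname(diag(A)[base_s]), rep(2 / 12, length(base_s)))
  # growing the pool shrinks the diagonal toward the between-DPQ average
  one_station <- function(ndpq) {
    epo <- entity_pedigree(1:3, c("queen", "pseudo_sire", "pseudo_sire"),
                           c(0, 0, 1), c(0, 0, 2),
                           d = c(1, 2 / 12, (1 - 0.25 * (1 + 2 / 12)) / ndpq),
                           n_dpq = ndpq)
    entity_relationship_exact(epo)[3, 3]
  }
  diags <- vapply(c(2, 8, 64, 1024), one_station, 0)
  expect_true(all(diff(diags) < 0))
  a_between <- 0.25 * 1 + 0.25 * (2 / 12)   # unrelated founder and base sire
  expect_lt(abs(diags[4] - a_between), 1e-3)
})

test_that("mixed-model solutions equal the dense GLS oracle", {
  sim <- sim_entity_pedigree(n_queens = 14, years = 2, seed = 5)
  ep <- sim$ep; st <- sim$st
  A <- entity_relationship_exact(ep)
  G <- matrix(c(1, -0.75, -0.75, 2), 2)
  se2 <- 1.3
  y <- st$r_y; lev <- factor(st$r_lev); qe <- st$r_qe; we <- st$r_we
  fit <- solve_mme(y, lev, qe, we, ep, G, se2)
  n <- nrow(ep); nr <- length(y)
  X <- stats::model.matrix(~ lev - 1)
  Zm <- matrix(0, nr, n); Zm[cbind(seq_len(nr), qe)] <- 1
  Zd <- matrix(0, nr, n); Zd[cbind(seq_len(nr), we)] <- 1
  Z <- cbind(Zm, Zd)
  GA <- kronecker(G, A)
  V <- Z %*% GA %*% t(Z) + diag(nr) * se2
  beta <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% y)
  u <- GA %*% t(Z) %*% solve(V, y - X %*% beta)
  expect_lt(max(abs(fit$fixed - beta)), 1e-6)
  expect_lt(max(abs(c(fit$ebv_m, fit$ebv_d) - u)), 1e-6)
})

test_that("a single confounded record yields zero EBVs and doubling the
           residual variance shrinks all EBVs", {
  ep <- entity_pedigree(1:3, c("queen", "pseudo_sire", "worker_group"),
                        c(0, 0, 1), c(0, 0, 2), d = c(1, 1 / 6, 11 / 288))
  G <- matrix(c(1, -0.75, -0.75, 2), 2)
  fit1 <- solve_mme(3.7, factor("a"), 1L, 3L, ep, G, 1)
  expect_lt(max(abs(c(fit1$ebv_m, fit1$ebv_d))), 1e-10)
  expect_equal(unname(fit1$fixed), 3.7)
  # two levels, informative data
  sim <- sim_entity_pedigree(n_queens = 14, years = 2, seed = 6)
  st <- sim$st
  f1 <- solve_mme(st$r_y, st$r_lev, st$r_qe, st$r_we, sim$ep,
                  st$sigma_hat, 1)
  f2 <- solve_mme(st$r_y, st$r_lev, st$r_qe, st$r_we, sim$ep,
                  st$sigma_hat, 2)
  # with correlated maternal/direct effects individual solutions can
  # move either way, but the solution vector as a whole shrinks to 0
  expect_lt(stats::sd(f2$ebv_ic), stats::sd(f1$ebv_ic))
  expect_lt(sum(f2$ebv_m^2 + f2$ebv_d^2), sum(f1$ebv_m^2 + f1$ebv_d^2))
})

test_that("the drone-based covariance estimator is unbiased on a known
           architecture", {
  set.seed(7)
  arch <- sample_architecture(200, c(1, 2, -0.75), 1)
  reps <- 24
  est <- array(0, c(2, 2, reps))
  for (r in seq_len(reps)) {
    haps <- lapply(seq_len(50), function(i)
      matrix(rbinom(400, 1, arch$allele_freq), 200, 2))
    est[, , r] <- reestimate_variance(haps, rep(0, 50), arch, 100)$sigma_hat
  }
  m <- apply(est, c(1, 2), mean)
  se <- apply(est, c(1, 2), stats::sd) / sqrt(reps)
  expect_true(all(abs(m - arch$sigma_a) < 3 * se))
  # negative covariance architecture yields a negative off-diagonal
  expect_lt(m[1, 2], 0)
})

test_that("estimator reduces to the plain scatter for non-inbred queens
           and excludes fully inbred queens", {
  arch <- test_arch(50)
  set.seed(8)
  haps <- lapply(1:10, function(i)
    matrix(rbinom(100, 1, arch$allele_freq), 50, 2))
  set.seed(9)
  a <- reestimate_variance(haps, rep(0, 10), arch, 20)$sigma_hat
  # weights 1/(1-F) with F = 0 are all 1: the estimator must equal the
  # plain sample scatter of the deviations, computed independently
  set.seed(9)
  S <- matrix(0, 2, 2)
  for (h in haps) {
    g <- make_gamete(h, 20)
    delta <- drop(arch$effects %*% (h[, 1] + h[, 2] - 2 * arch$allele_freq)) -
      arch$effects %*% (2 * g - 2 * arch$allele_freq)
    S <- S + tcrossprod(delta)
  }
  expect_equal(a, S / (10 * 20 - 1), tolerance = 1e-12)
  expect_warning(
    reestimate_variance(haps, c(1 - 1e-9, rep(0, 9)), arch, 5),
    "excluding")
  expect_error(
    suppressWarnings(reestimate_variance(haps[1], 1 - 1e-9, arch, 5)),
    "no queens")
})
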