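# Yearly simulation driver for one breeding scheme.
#
# Internal state lives in an environment with columnar queen/entity/
# record storage (batch-appended once per cohort).  Two dense "active"
# matrices are maintained in preallocated buffers over a sliding window
# of the last few birth cohorts:
#   st$kx -- exact drone-level kinship (f-scale) among active queens
#            (breeding queens and drone-producing queens), including
#            shared-father-drone terms among sisters;
#   st$ke -- pool-averaged entity relationships (a-scale) among active
#            queen entities and pseudo-sire entities, the source of the
#            Mendelian-sampling coefficients d_i for the sparse
#            relationship inverse.
# Both are trimmed to birth years >= t - 2 at the end of year t;
# everything needed later (F, d_i, relationship-inverse links, breeding
# values, records) is extracted at creation time.

new_sim_state <- function(config, arch) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$arch <- arch
  st$sigma_hat <- as_sigma_a(config$sigma_a)
  N <- config$n_queens
  nst <- max(1L, as.integer(round(N * config$ks / 100)))
  st$n_st <- nst
  # queens (breeding queens and DPQs)
  st$q_birth <- integer(); st$q_breed <- logical()
  st$q_dam <- integer(); st$q_fm <- integer(); st$q_fdrone <- integer()
  st$q_ent <- integer(); st$q_went <- integer()
  st$q_sireent <- integer(); st$q_station <- integer()
  st$q_F <- numeric(); st$q_tbvm <- numeric(); st$q_tbvd <- numeric()
  st$q_wgd <- numeric(); st$q_apiary <- integer()
  st$geno <- list()
  # entities
  st$e_kind <- integer(); st$e_dam <- integer(); st$e_sire <- integer()
  st$e_d <- numeric(); st$e_birth <- integer()
  # records
  st$r_year <- integer(); st$r_lev <- integer()
  st$r_qe <- integer(); st$r_we <- integer(); st$r_y <- numeric()
  # active kinship buffers
  per_year_q <- N + config$n_dpq * nst
  capx <- 3L * N + 4L * per_year_q + 16L
  st$kx <- matrix(0, capx, capx); st$kx_n <- 0L; st$kx_q <- integer()
  cape <- max(6L * N + N + nst, 4L * (N + nst)) + 16L
  st$ke <- matrix(0, cape, cape); st$ke_n <- 0L; st$ke_e <- integer()
  st$drone_counter <- 0L
  st$station_counter <- 0L
  st$summary <- list()
  st
}

add_entities <- function(st, kind, dam, sire, d, birth) {
  n <- length(d)
  ids <- length(st$e_kind) + seq_len(n)
  st$e_kind <- c(st$e_kind, rep_len(as.integer(kind), n))
  st$e_dam <- c(st$e_dam, as.integer(rep_len(dam, n)))
  st$e_sire <- c(st$e_sire, as.integer(rep_len(sire, n)))
  st$e_d <- c(st$e_d, d)
  st$e_birth <- c(st$e_birth, rep_len(as.integer(birth), n))
  ids
}

# Sparse relationship inverse over all entities created so far.
state_a_inverse <- function(st) {
  n <- length(st$e_d)
  has <- st$e_dam > 0L
  w <- 1 / st$e_d
  ii <- which(has); dd <- st$e_dam[has]; ss <- st$e_sire[has]; wh <- w[has]
  i0 <- which(!has)
  M <- Matrix::sparseMatrix(
    i = c(i0, ii, dd, ss, ii, ii, dd, dd, ss, ss),
    j = c(i0, ii, dd, ss, dd, ss, ii, ss, ii, dd),
    x = c(w[!has], wh, wh / 4, wh / 4, -wh / 2, -wh / 2,
          -wh / 2, wh / 4, -wh / 2, wh / 4),
    dims = c(n, n))
  Matrix::forceSymmetric(M)
}

# Append a batch of queens to the exact kinship buffer.  dam_q/fm_q are
# queen indices (fm_q = 0 when the father drone came from a base
# drone-source queen); drone_id identifies the father drone so that
# sisters sharing a father get the extra identical-by-descent term,
# both within the batch and against active older sisters (a dam reused
# as station founder keeps her stored mates).  Returns pedigree F.
kx_append <- function(st, dam_q, fm_q, drone_id, new_q) {
  m <- length(dam_q)
  n <- st$kx_n
  K <- st$kx
  dr <- match(dam_q, st$kx_q)
  has <- fm_q > 0L
  fr <- match(fm_q, st$kx_q)
  if (anyNA(dr) || anyNA(fr[has]))
    stop("internal: parent queen missing from the active kinship window")
  Rnew <- 0.5 * K[dr, seq_len(n), drop = FALSE]
  if (any(has))
    Rnew[has, ] <- Rnew[has, , drop = FALSE] +
      0.5 * K[fr[has], seq_len(n), drop = FALSE]
  Fnew <- numeric(m)
  Fnew[has] <- K[cbind(dr[has], fr[has])]
  fmm0 <- numeric(m)
  fmm0[has] <- K[cbind(fr[has], fr[has])]
  if (n > 0L) {
    act_dr <- st$q_fdrone[st$kx_q]
    hit <- which(outer(drone_id, act_dr, "==") &
                   matrix(drone_id > 0L, m, n), arr.ind = TRUE)
    if (nrow(hit))
      Rnew[hit] <- Rnew[hit] + 0.25 * (1 - fmm0[hit[, 1L]])
  }
  Cnn <- 0.5 * t(Rnew[, dr, drop = FALSE])
  if (any(has))
    Cnn[has, ] <- Cnn[has, , drop = FALSE] +
      0.5 * t(Rnew[, fr[has], drop = FALSE])
  for (g in split(seq_len(m)[drone_id > 0L], drone_id[drone_id > 0L])) {
    if (length(g) < 2L) next
    for (a in seq_len(length(g) - 1L)) for (b in (a + 1L):length(g)) {
      i <- g[a]; j <- g[b]
      Cnn[i, j] <- Cnn[i, j] + 0.25 * (1 - fmm0[i])
      Cnn[j, i] <- Cnn[i, j]
    }
  }
  diag(Cnn) <- 0.5 * (1 + Fnew)
  idx <- n + seq_len(m)
  K[idx, seq_len(n)] <- Rnew
  K[seq_len(n), idx] <- t(Rnew)
  K[idx, idx] <- Cnn
  st$kx <- K
  st$kx_n <- n + m
  st$kx_q <- c(st$kx_q, new_q)
  Fnew
}

# Append entities (queens or pseudo-sires) with parents dam_e/sire_e
# and given relationship diagonals to the active entity buffer.
ke_append <- function(st, dam_e, sire_e, diag_vals, ids) {
  n <- st$ke_n
  K <- st$ke
  m <- length(ids)
  dr <- match(dam_e, st$ke_e)
  sr <- match(sire_e, st$ke_e)
  if (anyNA(dr) || anyNA(sr))
    stop("internal: parent entity missing from the active relationship window")
  R <- 0.5 * K[dr, seq_len(n), drop = FALSE] +
       0.5 * K[sr, seq_len(n), drop = FALSE]
  C <- 0.5 * t(R[, dr, drop = FALSE]) + 0.5 * t(R[, sr, drop = FALSE])
  diag(C) <- diag_vals
  idx <- n + seq_len(m)
  K[idx, seq_len(n)] <- R
  K[seq_len(n), idx] <- t(R)
  K[idx, idx] <- C
  st$ke <- K
  st$ke_n <- n + m
  st$ke_e <- c(st$ke_e, ids)
  invisible(NULL)
}

ke_val <- function(st, e1, e2) st$ke[cbind(match(e1, st$ke_e), match(e2, st$ke_e))]
ke_diag <- function(st, e) { i <- match(e, st$ke_e); st$ke[cbind(i, i)] }

level_id <- function(year, apiary) (year + 10L) * 10000L + apiary

#' @keywords internal
initialize_base <- function(st) {
  cf <- st$config; arch <- st$arch
  N <- cf$n_queens; nl <- arch$n_loci; p <- arch$allele_freq
  n_base <- 3L * N
  nm <- cf$n_mates
  base_ass <- 2 / nm   # pool of n_mates unrelated doubled gametes
  geno <- vector("list", n_base)
  haps <- lapply(seq_len(n_base), function(b)
    matrix(as.integer(stats::runif(2L * nl) < p), nl, 2L))
  tbvm <- tbvd <- wgd <- numeric(n_base)
  for (b in seq_len(n_base)) {
    h <- haps[[b]]
    # drones from n_mates distinct other queens of the closed base
    mm <- sample(seq_len(n_base)[-b], nm)
    mh <- matrix(0L, nl, nm)
    for (j in seq_len(nm)) mh[, j] <- make_gamete(haps[[mm[j]]])
    md <- st$drone_counter + seq_len(nm)
    st$drone_counter <- st$drone_counter + nm
    geno[[b]] <- list(h = h, mh = mh, mm = as.integer(mm), md = md)
    cc <- h[, 1L] + h[, 2L] - 2 * p
    tv <- drop(arch$effects %*% cc)
    tbvm[b] <- tv[1L]; tbvd[b] <- tv[2L]
    wgd[b] <- sum(arch$effects[2L, ] * (0.5 * cc + rowMeans(mh) - p))
  }
  birth <- rep(-2:0, each = N)
  qe <- 3L * (seq_len(n_base) - 1L) + 1L
  se <- qe + 1L
  we <- qe + 2L
  for (b in seq_len(n_base)) {
    add_entities(st, 1L, 0L, 0L, 1, birth[b])
    add_entities(st, 3L, 0L, 0L, base_ass, birth[b])
    add_entities(st, 2L, qe[b], se[b], (2 - base_ass) / (4 * nm), birth[b])
  }
  apiary <- sample.int(cf$n_apiaries, n_base, replace = TRUE)
  st$q_birth <- birth; st$q_breed <- rep(TRUE, n_base)
  st$q_dam <- st$q_fm <- st$q_fdrone <- st$q_station <- rep(0L, n_base)
  st$q_ent <- qe; st$q_went <- we; st$q_sireent <- se
  st$q_F <- rep(0, n_base)
  st$q_tbvm <- tbvm; st$q_tbvd <- tbvd; st$q_wgd <- wgd
  st$q_apiary <- apiary
  st$geno <- geno
  st$r_year <- birth
  st$r_lev <- level_id(birth, apiary)
  st$r_qe <- qe; st$r_we <- we
  st$r_y <- tbvm + wgd + stats::rnorm(n_base, 0, sqrt(arch$sigma_e2))
  # base queens are mutually unrelated and non-inbred
  st$kx[seq_len(n_base), seq_len(n_base)] <- diag(0.5, n_base)
  st$kx_n <- n_base; st$kx_q <- seq_len(n_base)
  ne <- 2L * n_base
  st$ke[seq_len(ne), seq_len(ne)] <-
    diag(rep(c(1, base_ass), n_base))
  st$ke_n <- ne
  st$ke_e <- as.integer(rbind(qe, se))
  invisible(st)
}

select_truncation <- function(cand, ebv, n_sel, what) {
  if (length(cand) < n_sel)
    stop("fewer ", what, " candidates (", length(cand),
         ") than required selections (", n_sel, ")")
  if (is.null(ebv)) return(cand[sample.int(length(cand), n_sel)])
  cand[order(-ebv, cand)][seq_len(n_sel)]
}

run_year <- function(st, t) {
  cf <- st$config; arch <- st$arch
  N <- cf$n_queens; nl <- arch$n_loci; p <- arch$allele_freq; p2 <- 2 * p
  blup <- cf$selection == "blup"

  # (1) five-yearly covariance re-estimation from the latest cohort
  if (blup && cf$reestimate_every > 0L && t %% cf$reestimate_every == 0L &&
      t >= cf$reestimate_every) {
    coh <- which(st$q_birth == t - 1L & st$q_breed)
    est <- reestimate_variance(lapply(st$geno[coh], `[[`, "h"),
                               st$q_F[coh], arch, cf$n_drones_reest)
    st$sigma_hat <- est$sigma_hat
  }

  # (2) BLUP on the full pedigree and all historical records
  sel_index <- NULL
  if (blup) {
    fit <- solve_mme(st$r_y, st$r_lev, st$r_qe, st$r_we, ep = NULL,
                     sigma_a = st$sigma_hat, sigma_e2 = arch$sigma_e2,
                     a_inverse = state_a_inverse(st))
    sel_index <- function(q) {
      if (identical(cf$selection_index, "colony"))
        fit$ebv_m[st$q_ent[q]] + fit$ebv_d[st$q_went[q]]
      else fit$ebv_ic[st$q_ent[q]]
    }
  }

  # (3) truncation selection: dams among 2-year-olds, station founders
  #     among 3-year-olds, on the estimated selection index
  cand2 <- which(st$q_birth == t - 2L & st$q_breed)
  cand3 <- which(st$q_birth == t - 3L & st$q_breed)
  n_dams <- floor(N / cf$kd)
  dams <- select_truncation(cand2, if (blup) sel_index(cand2), n_dams, "dam")
  n_st <- st$n_st
  founders <- select_truncation(cand3, if (blup) sel_index(cand3), n_st,
                                "station-founder")

  # (4) mating stations: pseudo-sire entities + n_dpq DPQ daughters each
  fq_e <- st$q_ent[founders]; sf_e <- st$q_sireent[founders]
  d_s <- (1 - 0.25 * (ke_diag(st, fq_e) + ke_diag(st, sf_e))) / cf$n_dpq
  ass <- 0.25 * ke_diag(st, fq_e) + 0.25 * ke_diag(st, sf_e) +
         0.5 * ke_val(st, fq_e, sf_e) + d_s
  sent <- add_entities(st, 3L, fq_e, sf_e, d_s, t)
  ke_append(st, fq_e, sf_e, ass, sent)
  st_ids <- st$station_counter + seq_len(n_st)
  st$station_counter <- st$station_counter + n_st
  ndpq <- cf$n_dpq
  nq0 <- length(st$q_birth)
  dpq_mat <- matrix(nq0 + seq_len(ndpq * n_st), ndpq, n_st)
  dpq_dam <- rep(founders, each = ndpq)
  dpq_fm <- dpq_dr <- integer(ndpq * n_st)
  dpq_h <- vector("list", ndpq * n_st)
  k <- 0L
  for (s in seq_len(n_st)) {
    f <- founders[s]; gf <- st$geno[[f]]
    if (is.null(gf)) stop("internal: founder genotype already dropped")
    ji <- sample.int(cf$n_mates, ndpq, replace = TRUE)
    gam <- make_gamete(gf$h, ndpq)
    for (d in seq_len(ndpq)) {
      k <- k + 1L
      dpq_fm[k] <- gf$mm[ji[d]]
      dpq_dr[k] <- gf$md[ji[d]]
      dpq_h[[k]] <- cbind(gam[, d], gf$mh[, ji[d], drop = TRUE])
    }
  }
  ndp <- ndpq * n_st
  Fdpq <- kx_append(st, dpq_dam, dpq_fm, dpq_dr, nq0 + seq_len(ndp))
  st$q_birth <- c(st$q_birth, rep.int(t, ndp))
  st$q_breed <- c(st$q_breed, rep.int(FALSE, ndp))
  st$q_dam <- c(st$q_dam, dpq_dam)
  st$q_fm <- c(st$q_fm, dpq_fm)
  st$q_fdrone <- c(st$q_fdrone, dpq_dr)
  st$q_ent <- c(st$q_ent, rep.int(0L, ndp))
  st$q_went <- c(st$q_went, rep.int(0L, ndp))
  st$q_sireent <- c(st$q_sireent, rep.int(0L, ndp))
  st$q_station <- c(st$q_station, rep(st_ids, each = ndpq))
  st$q_F <- c(st$q_F, Fdpq)
  st$q_tbvm <- c(st$q_tbvm, rep.int(NA_real_, ndp))
  st$q_tbvd <- c(st$q_tbvd, rep.int(NA_real_, ndp))
  st$q_wgd <- c(st$q_wgd, rep.int(NA_real_, ndp))
  st$q_apiary <- c(st$q_apiary, rep.int(0L, ndp))
  st$geno <- c(st$geno, lapply(dpq_h, function(h) list(h = h)))

  # (5) produce the year-t cohort: quotas kd per dam, remainder dams
  #     drawn with replacement among the selected
  rem <- N - cf$kd * n_dams
  extra <- if (rem > 0L) dams[sample.int(n_dams, rem, replace = TRUE)] else integer()
  dam_assign <- c(rep(dams, each = cf$kd), extra)
  jsel <- sample.int(cf$n_mates, N, replace = TRUE)
  stat <- sample.int(n_st, N, replace = TRUE)
  # maternal gametes batched per dam
  mat_gam <- matrix(0L, nl, N)
  for (dq in unique(dam_assign)) {
    gd <- st$geno[[dq]]
    if (is.null(gd)) stop("internal: dam genotype already dropped")
    cols <- which(dam_assign == dq)
    mat_gam[, cols] <- make_gamete(gd$h, length(cols))
  }
  new_h <- vector("list", N)
  new_fm <- new_dr <- integer(N)
  for (i in seq_len(N)) {
    gd <- st$geno[[dam_assign[i]]]
    new_h[[i]] <- cbind(mat_gam[, i], gd$mh[, jsel[i], drop = TRUE])
    new_fm[i] <- gd$mm[jsel[i]]
    new_dr[i] <- gd$md[jsel[i]]
  }
  nq1 <- length(st$q_birth)
  Fq <- kx_append(st, dam_assign, new_fm, new_dr, nq1 + seq_len(N))

  # entities: queen parents = (dam entity, dam's mating pseudo-sire)
  de <- st$q_ent[dam_assign]; se <- st$q_sireent[dam_assign]
  d_q <- 1 - 0.25 * (ke_diag(st, de) + ke_diag(st, se))
  qent <- add_entities(st, 1L, de, se, d_q, t)
  ke_append(st, de, se, 1 + 0.5 * ke_val(st, de, se), qent)
  went <- add_entities(st, 2L, qent, sent[stat],
                       (2 - ass[stat]) / (4 * cf$n_mates), t)

  # (6) mate each virgin at her uniformly assigned station;
  # (7) apiaries: dam's with probability 0.7, else uniform
  apiary <- st$q_apiary[dam_assign]
  reassign <- stats::runif(N) >= cf$apiary_inherit_prob
  apiary[reassign] <- sample.int(cf$n_apiaries, sum(reassign), replace = TRUE)
  nm <- cf$n_mates
  # mate drones batched per drone-producing queen
  dpi <- matrix(sample.int(ndpq, N * nm, replace = TRUE), nm, N)
  dpq_flat <- dpq_mat[cbind(as.vector(dpi), rep(stat, each = nm))]
  mh_all <- matrix(0L, nl, N * nm)
  for (dq in unique(dpq_flat)) {
    cols <- which(dpq_flat == dq)
    mh_all[, cols] <- make_gamete(st$geno[[dq]]$h, length(cols))
  }
  md_all <- st$drone_counter + seq_len(N * nm)
  st$drone_counter <- st$drone_counter + N * nm
  # cohort allele counts and breeding values in one pass
  cnt <- vapply(new_h, function(h) h[, 1L] + h[, 2L], numeric(nl))
  tv <- arch$effects %*% (cnt - p2)
  tbvm <- tv[1L, ]; tbvd <- tv[2L, ]
  pat_mean <- vapply(seq_len(N), function(i)
    rowMeans(mh_all[, (i - 1L) * nm + seq_len(nm), drop = FALSE]), numeric(nl))
  wgd <- drop(arch$effects[2L, ] %*% (0.5 * (cnt - p2) + pat_mean - p))
  new_geno <- vector("list", N)
  for (i in seq_len(N)) {
    sl <- (i - 1L) * nm + seq_len(nm)
    new_geno[[i]] <- list(h = new_h[[i]], mh = mh_all[, sl, drop = FALSE],
                          mm = dpq_flat[sl], md = md_all[sl])
  }
  st$q_birth <- c(st$q_birth, rep.int(t, N))
  st$q_breed <- c(st$q_breed, rep.int(TRUE, N))
  st$q_dam <- c(st$q_dam, dam_assign)
  st$q_fm <- c(st$q_fm, new_fm)
  st$q_fdrone <- c(st$q_fdrone, new_dr)
  st$q_ent <- c(st$q_ent, qent)
  st$q_went <- c(st$q_went, went)
  st$q_sireent <- c(st$q_sireent, sent[stat])
  st$q_station <- c(st$q_station, st_ids[stat])
  st$q_F <- c(st$q_F, Fq)
  st$q_tbvm <- c(st$q_tbvm, tbvm)
  st$q_tbvd <- c(st$q_tbvd, tbvd)
  st$q_wgd <- c(st$q_wgd, wgd)
  st$q_apiary <- c(st$q_apiary, apiary)
  st$geno <- c(st$geno, new_geno)

  # (8) performance records of the new cohort
  st$r_year <- c(st$r_year, rep.int(t, N))
  st$r_lev <- c(st$r_lev, level_id(t, apiary))
  st$r_qe <- c(st$r_qe, qent)
  st$r_we <- c(st$r_we, went)
  st$r_y <- c(st$r_y, tbvm + wgd + stats::rnorm(N, 0, sqrt(arch$sigma_e2)))

  # (9) year summary
  st$summary[[length(st$summary) + 1L]] <- data.frame(
    year = t,
    mean_F = mean(Fq),
    delta_f = delta_f(mean(Fq), elapsed_years = max(t - 1L, 1L)),
    performance = mean(tbvm + wgd),
    var_ic = stats::var(tbvm + tbvd),
    var_ic_rel = stats::var(tbvm + tbvd) / arch$sigma_ic^2,
    sigma_hat_m = st$sigma_hat[1L, 1L],
    sigma_hat_d = st$sigma_hat[2L, 2L],
    sigma_hat_md = st$sigma_hat[1L, 2L],
    n_dams = n_dams, n_stations = n_st)

  # trim active windows and drop genotypes no longer needed; base queens
  # stay until year 3 (their drones father DPQs while base-born founders
  # are in use)
  keep <- which(st$q_birth[st$kx_q] >= t - 2L |
                  (st$q_birth[st$kx_q] <= 0L & t < 4L))
  st$kx[seq_along(keep), seq_along(keep)] <-
    st$kx[keep, keep, drop = FALSE]
  st$kx_n <- length(keep)
  st$kx_q <- st$kx_q[keep]
  keepe <- which(st$e_birth[st$ke_e] >= t - 2L)
  st$ke[seq_along(keepe), seq_along(keepe)] <-
    st$ke[keepe, keepe, drop = FALSE]
  st$ke_n <- length(keepe)
  st$ke_e <- st$ke_e[keepe]
  old <- if (t < 4L) integer() else which(st$q_birth <= t - 4L)
  for (qi in old) if (!is.null(st$geno[[qi]])) st$geno[qi] <- list(NULL)
  invisible(st)
}

#' Simulate one breeding scheme over the full horizon
#'
#' Runs the yearly cycle for `config$years` years: BLUP evaluation of
#' all historical records, truncation selection of two-year-old dams
#' (`floor(N/kd)`, quota `kd` daughters each) and three-year-old
#' mating-station founders (`round(N ks/100)`), station construction
#' with eight drone-producing sister queens, matings with twelve
#' drones, apiary assignment (70% dam inheritance), phenotype
#' generation, and exact drone-level pedigree inbreeding.  Three base
#' cohorts (birth years -2, -1, 0) provide 1-, 2- and 3-year-old
#' candidates from year 1 on.
#'
#' @param config a [scheme_config()].
#' @param seed integer seed for the replicate (all randomness).
#' @param arch optional [trait_architecture()]; by default one is drawn
#'   from the config's trait parameters under the same seed.
#' @return An object of class `apisel_sim`: list with `summary` (one
#'   row per year: `mean_F`, `delta_f` to date, `performance` criterion,
#'   inheritance-criterion variance `var_ic` and its ratio to the exact
#'   base variance `var_ic_rel`, current covariance estimate, selection
#'   counts), `pedigree` (exportable queen pedigree), `config`, `arch`,
#'   `seed`.
#' @export
simulate_scheme <- function(config, seed, arch = NULL) {
  stopifnot(inherits(config, "scheme_config"))
  set.seed(as.integer(seed))
  if (is.null(arch))
    arch <- sample_architecture(config$n_loci, config$sigma_a, config$sigma_e2)
  if (arch$n_loci != config$n_loci)
    stop("architecture and config disagree on the locus count")
  st <- new_sim_state(config, arch)
  initialize_base(st)
  for (t in seq_len(config$years)) run_year(st, t)
  res <- list(summary = do.call(rbind, st$summary),
              pedigree = state_pedigree(st),
              config = config, arch = arch, seed = as.integer(seed))
  class(res) <- "apisel_sim"
  res
}

state_pedigree <- function(st) {
  data.frame(queen_id = seq_along(st$q_birth),
             birth_year = st$q_birth,
             kind = ifelse(st$q_breed, "breeding", "dpq"),
             dam_id = st$q_dam,
             father_dpq_id = st$q_fm,
             father_drone_id = st$q_fdrone,
             station_id = st$q_station,
             apiary_id = st$q_apiary,
             F = st$q_F)
}

#' @export
print.apisel_sim <- function(x, ...) {
  cf <- x$config
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("Breeding-scheme simulation S^%s_%s, N = %d, %d years (seed %d)\n",
              format(cf$ks), cf$kd, cf$n_queens, cf$years, x$seed))
  cat(sprintf("  final cohort: mean F = %.4f, dF = %.3f%%, gain = %.2f, retained variance = %.1f%%\n",
              last$mean_F, 100 * last$delta_f, last$performance,
              100 * last$var_ic_rel))
  invisible(x)
}

#' Export the realized queen pedigree as a delimited table
#'
#' Columns: `queen_id`, `birth_year`, `kind`, `dam_id`,
#' `father_dpq_id`, `father_drone_id`, `station_id`, `apiary_id`, `F`;
#' missing parents are coded 0 (base queens, and father drones supplied
#' by base drone-source queens).
#'
#' @param sim an `apisel_sim` result.
#' @param path output file (tab-separated).
#' @export
write_pedigree <- function(sim, path) {
  utils::write.table(sim$pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
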