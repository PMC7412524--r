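# Shared oracles and fixture builders.  Everything is generated in code.

# Monte-Carlo gene-dropping IBD oracle over a bee_pedigree: founders get
# uniquely labelled alleles at one locus, transmissions are resampled
# `n_drop` times, and the kinship of (x, y) is estimated as the
# probability that a random allele of x is identical by descent to a
# random allele of y.  Vectorized over replicates.
gene_drop_kinship <- function(ped, x, y, n_drop = 1e5) {
  n <- length(ped$id)
  a1 <- matrix(0L, n_drop, n)  # allele labels, slot 1
  a2 <- matrix(0L, n_drop, n)  # slot 2 (drones: copy of slot 1)
  lab <- 0L
  for (i in seq_len(n)) {
    if (ped$type[i] == "drone") {
      m <- ped$parent1[i]
      if (m == 0L) {
        lab <- lab + 1L
        a1[, i] <- lab
      } else {
        pick <- stats::runif(n_drop) < 0.5
        a1[, i] <- ifelse(pick, a1[, m], a2[, m])
      }
      a2[, i] <- a1[, i]
    } else {
      d <- ped$parent1[i]; s <- ped$parent2[i]
      if (d == 0L) {
        a1[, i] <- lab + 1L; a2[, i] <- lab + 2L; lab <- lab + 2L
      } else {
        pick <- stats::runif(n_drop) < 0.5
        a1[, i] <- ifelse(pick, a1[, d], a2[, d])
        a2[, i] <- a1[, s]  # father drone passes his single allele
      }
    }
  }
  (rowMeans(cbind(a1[, x] == a1[, y], a1[, x] == a2[, y],
                  a2[, x] == a1[, y], a2[, x] == a2[, y])) |> mean())
}

# Rebuild a drone-level bee_pedigree from a simulation's pedigree table
# (father drones become explicit haploid individuals).
sim_to_bee_pedigree <- function(ped) {
  nq <- nrow(ped)
  id <- integer(); type <- character(); p1 <- integer(); p2 <- integer()
  qmap <- integer(nq); dmap <- new.env(parent = emptyenv()); nid <- 0L
  for (i in seq_len(nq)) {
    dr <- ped$father_drone_id[i]
    if (ped$dam_id[i] > 0) {
      key <- as.character(dr)
      if (is.null(dmap[[key]])) {
        nid <- nid + 1L
        id[nid] <- nid; type[nid] <- "drone"
        p1[nid] <- if (ped$father_dpq_id[i] > 0) qmap[ped$father_dpq_id[i]] else 0L
        p2[nid] <- 0L
        dmap[[key]] <- nid
      }
    }
    nid <- nid + 1L
    id[nid] <- nid; type[nid] <- "queen"
    p1[nid] <- if (ped$dam_id[i] > 0) qmap[ped$dam_id[i]] else 0L
    p2[nid] <- if (ped$dam_id[i] > 0) dmap[[as.character(dr)]] else 0L
    qmap[i] <- nid
  }
  list(ped = bee_pedigree(id, type, p1, p2), qmap = qmap)
}

# Entity pedigree of a (small) simulation, rebuilt from the driver's
# internal state, for the relationship-decomposition oracle tests.
sim_entity_pedigree <- function(n_queens = 14, kd = 2, ks = 10, years = 3,
                                n_loci = 30, seed = 1) {
  cfg <- scheme_config(n_queens = n_queens, kd = kd, ks = ks,
                       years = years, n_loci = n_loci)
  set.seed(seed)
  arch <- sample_architecture(cfg$n_loci, cfg$sigma_a, cfg$sigma_e2)
  st <- apisel:::new_sim_state(cfg, arch)
  apisel:::initialize_base(st)
  for (t in seq_len(years)) apisel:::run_year(st, t)
  kinds <- c("queen", "worker_group", "pseudo_sire")[st$e_kind]
  list(ep = entity_pedigree(seq_along(st$e_d), kinds, st$e_dam, st$e_sire,
                            st$e_d, n_dpq = cfg$n_dpq, n_mates = cfg$n_mates,
                            n_base_drones = cfg$n_mates),
       st = st)
}

# A small random architecture for unit tests.
test_arch <- function(n_loci = 60, sigma_a = c(1, 2, -0.75), sigma_e2 = 1,
                      seed = 42) {
  set.seed(seed)
  sample_architecture(n_loci, sigma_a, sigma_e2)
}
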