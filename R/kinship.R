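#' Build a haplodiploid pedigree for kinship computations
#'
#' A pedigree over queens (diploid) and drones (haploid, interpreted as
#' diploid homozygous).  A queen's parents are her dam (a queen) and her
#' father drone; a drone's single parent is his mother queen.  Founders
#' (missing parents, coded 0) are assumed unrelated and non-inbred.
#' Records must be ordered so parents precede offspring.
#'
#' @param id integer identifiers (1-based, unique).
#' @param type character, `"queen"` or `"drone"`.
#' @param parent1 for queens, the dam id; for drones, the mother id
#'   (0 = founder).
#' @param parent2 for queens, the father drone id (0 = founder);
#'   ignored for drones.
#' @return An object of class `bee_pedigree`.
#' @export
bee_pedigree <- function(id, type, parent1, parent2 = 0L) {
  n <- length(id)
  type <- match.arg(type, c("queen", "drone"), several.ok = TRUE)
  type <- rep_len(type, n)
  parent2 <- rep_len(parent2, n)
  if (anyDuplicated(id)) stop("pedigree ids must be unique")
  pos <- match(seq_along(id), id)  # require ids 1..n in order
  if (any(is.na(pos))) stop("ids must be 1..n with parents preceding offspring")
  for (i in seq_len(n)) {
    ps <- c(parent1[i], if (type[i] == "queen") parent2[i])
    if (any(ps >= id[i]))
      stop("cycle or unordered pedigree: parent id not smaller than own id")
    if (any(ps > 0 & !(ps %in% id))) stop("unknown parent identifier")
  }
  if (any(type == "drone" & parent2 != 0L))
    stop("drones have a single parent (their mother queen)")
  structure(list(id = as.integer(id), type = type,
                 parent1 = as.integer(parent1),
                 parent2 = as.integer(parent2),
                 cache = new.env(parent = emptyenv())),
            class = "bee_pedigree")
}

#' Coancestry (kinship) of two pedigree members
#'
#' Exact recursive coancestry over the realized queen-drone pedigree:
#' the probability that a random allele from `x` and a random allele
#' from `y` are identical by descent.  A drone carries a single meiotic
#' gamete of his mother, so his kinship with himself is 1 and his
#' kinship with any non-descendant equals his mother's.  For queens,
#' `f(Q, Q) = (1 + F_Q)/2` with `F_Q = f(dam, father drone)`.
#' Memoized; recursion proceeds on the younger member of each pair, so
#' only ancestors of the query pair are visited.
#'
#' @param ped a [bee_pedigree()].
#' @param x,y member ids.
#' @return kinship probability in `[0, 1]`.
#' @export
coancestry <- function(ped, x, y) {
  if (!all(c(x, y) %in% ped$id)) stop("unknown identifier in kinship query")
  kin_rec(ped, as.integer(x), as.integer(y))
}

kin_rec <- function(ped, x, y) {
  if (x > y) { tmp <- x; x <- y; y <- tmp }
  key <- paste0(x, ":", y)
  hit <- ped$cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (x == y) {
    if (ped$type[x] == "drone") 1 else {
      d <- ped$parent1[x]; s <- ped$parent2[x]
      Fx <- if (d == 0L || s == 0L) 0 else kin_rec(ped, d, s)
      (1 + Fx) / 2
    }
  } else {
    # recurse on the younger member y (never an ancestor of x)
    if (ped$type[y] == "drone") {
      m <- ped$parent1[y]
      if (m == 0L) 0 else kin_rec(ped, x, m)
    } else {
      d <- ped$parent1[y]; s <- ped$parent2[y]
      0.5 * ((if (d == 0L) 0 else kin_rec(ped, x, d)) +
             (if (s == 0L) 0 else kin_rec(ped, x, s)))
    }
  }
  assign(key, val, envir = ped$cache)
  val
}

#' Pedigree inbreeding coefficient of a queen
#'
#' `F = f(dam, father drone)`; base queens (missing a parent) have
#' `F = 0`.
#'
#' @inheritParams coancestry
#' @param q queen id.
#' @param base_zero if `TRUE` (default) queens with a missing parent are
#'   treated as base animals with `F = 0`; if `FALSE` this is an error.
#' @export
queen_inbreeding <- function(ped, q, base_zero = TRUE) {
  q <- as.integer(q)
  if (!(q %in% ped$id) || ped$type[q] != "queen") stop("unknown queen id")
  d <- ped$parent1[q]; s <- ped$parent2[q]
  if (d == 0L || s == 0L) {
    if (!base_zero && (d != 0L || s != 0L))
      stop("non-base queen with a missing parent")
    return(0)
  }
  kin_rec(ped, d, s)
}

#' Additive relationship between two pedigree members
#'
#' `a(x, y) = 2 f(x, y)`; the diagonal is `1 + F` for queens and 2 for
#' drones.
#'
#' @inheritParams coancestry
#' @export
additive_relationship <- function(ped, x, y) 2 * coancestry(ped, x, y)

#' Generational inbreeding rate from terminal-cohort inbreeding
#'
#' Inverts the constant-rate recursion `F_{t+1} = F_t + dF (1 - F_t)`
#' over `elapsed_years / generation_interval` generations:
#' `dF = 1 - (1 - F)^(generation_interval / elapsed_years)`.  The
#' default generation interval of 2.5 years averages the two-year
#' maternal and three-year paternal paths; the default 99 elapsed years
#' spans year 1 to year 100.
#'
#' @param f_terminal mean inbreeding coefficient of the terminal cohort,
#'   in `[0, 1)`.
#' @param elapsed_years years elapsed since the first cohort.
#' @param generation_interval average generation interval in years.
#' @return per-generation inbreeding rate (proportion, not percent).
#' @examples
#' delta_f(0.5)          # ~0.01735
#' effective_size(0.01)  # 50
#' @export
delta_f <- function(f_terminal, elapsed_years = 99, generation_interval = 2.5) {
  if (any(f_terminal >= 1) || any(f_terminal < 0))
    stop("terminal inbreeding must lie in [0, 1)")
  1 - (1 - f_terminal)^(generation_interval / elapsed_years)
}

#' Effective population size from a generational inbreeding rate
#'
#' `N_e = 1 / (2 dF)`.
#'
#' @param dfg per-generation inbreeding rate (proportion), > 0.
#' @export
effective_size <- function(dfg) {
  if (any(dfg <= 0)) stop("effective size requires dF > 0")
  1 / (2 * dfg)
}

#' Wright's heuristic inbreeding rate
#'
#' For a population with `n_sires` reproducing males and `n_dams`
#' reproducing females, `dF ~ (F + M) / (8 M F)`.  Reported as a
#' comparator only; it does not account for haplodiploidy or
#' mating-station structure.
#'
#' @param n_sires,n_dams counts of reproducing males and females (>= 1).
#' @return per-generation inbreeding rate (proportion).
#' @export
wright_delta_f <- function(n_sires, n_dams) {
  if (any(n_sires < 1) || any(n_dams < 1)) stop("counts must be at least 1")
  (n_sires + n_dams) / (8 * n_sires * n_dams)
}

#' Summarize inbreeding over the years of a simulation
#'
#' @param f_by_year named numeric vector of mean cohort inbreeding per
#'   year (names = years).
#' @param generation_interval average generation interval in years.
#' @return list with `f_by_year`, `f_terminal`, `delta_f` and `n_e`
#'   (`NA` when `delta_f` is 0).
#' @export
inbreeding_summary <- function(f_by_year, generation_interval = 2.5) {
  yrs <- as.numeric(names(f_by_year))
  if (!length(yrs) || anyNA(yrs)) yrs <- seq_along(f_by_year)
  ft <- f_by_year[[length(f_by_year)]]
  el <- max(yrs) - min(yrs[yrs >= 1], 1)
  df <- delta_f(ft, elapsed_years = max(el, 1), generation_interval)
  list(f_by_year = f_by_year, f_terminal = ft, delta_f = df,
       n_e = if (df > 0) effective_size(df) else NA_real_)
}
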