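#' Breeding-scheme configuration
#'
#' Assembles and validates the parameters of one selection scheme
#' `S^ks_kd` on a closed population of `n_queens` breeding queens per
#' year.  Defaults follow the standard study design: eight
#' drone-producing queens per mating station, twelve mates per queen,
#' `round(7 N / 100)` apiaries with 70% dam-apiary inheritance, and
#' five-yearly re-estimation of the genetic covariance from 100
#' simulated drones per queen.
#'
#' @param n_queens `N`, breeding queens (selection candidates) per year.
#' @param kd sister-group size: number of daughter queens per selected
#'   dam; the dam selection rate is `1/kd`.
#' @param ks percentage of three-year-old queens selected to found one
#'   mating station each; the number of stations (sires) is
#'   `max(1, round(N ks / 100))`.
#' @param years simulation horizon.
#' @param n_loci,sigma_a,sigma_e2 trait-architecture parameters passed
#'   to [sample_architecture()] unless an architecture is supplied to
#'   [simulate_scheme()] directly.
#' @param n_dpq drone-producing queens per station.
#' @param n_mates drones each queen mates with.
#' @param n_apiaries number of apiaries (default `round(7 N/100)`,
#'   minimum 1).
#' @param apiary_inherit_prob probability a daughter keeps her dam's
#'   apiary.
#' @param reestimate_every re-estimate the additive covariance every
#'   this many years (first in year `reestimate_every`); earlier years
#'   use the exact base parameters.
#' @param n_drones_reest drones per queen for the re-estimation.
#' @param selection `"blup"` (truncation on the estimated selection
#'   index) or `"random"` (selection replaced by random choice; no
#'   evaluation is run -- the drift/null model).
#' @param selection_index `"queen"` ranks candidates by their own
#'   estimated maternal + direct EBV (the inheritance criterion);
#'   `"colony"` ranks by the colony's estimated genetic level (queen
#'   maternal EBV + her worker group's direct EBV).
#' @return a validated list of class `scheme_config`.
#' @export
scheme_config <- function(n_queens = 200L, kd = 3L, ks = 10L, years = 100L,
                          n_loci = 200L, sigma_a = c(1, 2, -0.75),
                          sigma_e2 = 1, n_dpq = 8L, n_mates = 12L,
                          n_apiaries = NULL, apiary_inherit_prob = 0.7,
                          reestimate_every = 5L, n_drones_reest = 100L,
                          selection = c("blup", "random"),
                          selection_index = c("queen", "colony")) {
  selection <- match.arg(selection)
  selection_index <- match.arg(selection_index)
  n_queens <- as.integer(n_queens)
  if (is.na(n_queens) || n_queens < 2L) stop("n_queens must be at least 2")
  if (kd < 1) stop("kd must be at least 1 (Table 1 range is 1..10)")
  if (ks < 1 || ks > 100) stop("ks must lie in [1, 100] (Table 1 range is 1..10)")
  if (years < 1) stop("years must be at least 1")
  if (3L * n_queens - 1L < n_mates)
    stop("the base population (3 cohorts of n_queens) cannot supply n_mates drone mothers per queen")
  if (floor(n_queens / kd) < 1) stop("kd leaves no selected dam")
  if (is.null(n_apiaries)) n_apiaries <- max(1L, round(7 * n_queens / 100))
  structure(list(
    n_queens = n_queens, kd = as.integer(kd), ks = as.numeric(ks),
    years = as.integer(years), n_loci = as.integer(n_loci),
    sigma_a = sigma_a, sigma_e2 = sigma_e2,
    n_dpq = as.integer(n_dpq), n_mates = as.integer(n_mates),
    n_apiaries = as.integer(n_apiaries),
    apiary_inherit_prob = apiary_inherit_prob,
    reestimate_every = as.integer(reestimate_every),
    n_drones_reest = as.integer(n_drones_reest),
    selection = selection, selection_index = selection_index),
    class = "scheme_config")
}

#' @export
print.scheme_config <- function(x, ...) {
  cat(sprintf("Scheme S^%s_%s: N = %d queens/year, %d years, %s selection\n",
              format(x$ks), x$kd, x$n_queens, x$years, x$selection))
  cat(sprintf("  dams: floor(N/kd) = %d at rate %.0f%%; stations: %d\n",
              floor(x$n_queens / x$kd), 100 / x$kd,
              max(1L, round(x$n_queens * x$ks / 100))))
  cat(sprintf("  trait: %d loci, sigma_a = (%s), sigma_e2 = %g\n",
              x$n_loci, paste(x$sigma_a, collapse = ", "), x$sigma_e2))
  invisible(x)
}

config_keys <- function() names(formals(scheme_config))

#' Parse a scheme configuration from a YAML file and/or overrides
#'
#' All keys are optional and default to the values of
#' [scheme_config()]; unknown keys are rejected.  `sigma_a` may be given
#' as a length-3 `c(var_m, var_d, cov)` vector.
#'
#' @param file optional path to a YAML file.
#' @param ... named overrides applied after the file.
#' @return a `scheme_config`.
#' @export
parse_config <- function(file = NULL, ...) {
  vals <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    vals <- yaml::read_yaml(file)
    if (is.null(vals)) vals <- list()
  }
  dots <- list(...)
  vals[names(dots)] <- dots
  unknown <- setdiff(names(vals), config_keys())
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(scheme_config, vals)
}

#' Derive independent replicate seeds from a master seed
#'
#' Deterministic function of `(master_seed, replicate index)`: the
#' master seed initialises the stream from which one sub-seed per
#' replicate is drawn without replacement from `1..(2^31 - 2)`.
#'
#' @param master_seed integer master seed.
#' @param n_reps number of replicates (>= 1).
#' @return integer vector of `n_reps` seeds.
#' @export
seed_replicates <- function(master_seed, n_reps) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n_reps)
}

#' Run manifest for exact reproduction
#'
#' Records the fully resolved configuration, package version, master
#' seed, derived replicate seeds, the implied maternal-direct genetic
#' correlation `r_md`, and a timestamp.  The manifest alone suffices to
#' reproduce a run bit-exactly.
#'
#' @param config a [scheme_config()].
#' @param master_seed integer master seed.
#' @param n_reps replicate count.
#' @return a list; write it with [write_manifest()].
#' @export
run_manifest <- function(config, master_seed, n_reps = 1L) {
  sa <- as_sigma_a(config$sigma_a)
  list(package = "apisel",
       version = as.character(utils::packageVersion("apisel")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       master_seed = as.integer(master_seed),
       replicate_seeds = seed_replicates(master_seed, n_reps),
       r_md = sa[1, 2] / sqrt(sa[1, 1] * sa[2, 2]),
       config = unclass(config))
}

#' @rdname run_manifest
#' @param manifest a manifest list.
#' @param path output file.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) yaml::read_yaml(path)
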