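#' Cohort-level selection metrics
#'
#' The *performance criterion* of a cohort is the mean over colonies of
#' (queen maternal TBV + worker-group direct TBV): the average genetic
#' superiority of colony performance over the base population.  The
#' *inheritance criterion* of a queen is the sum of her own maternal
#' and direct TBVs; its cohort variance measures the genetic variance
#' still available to selection, since only queens reproduce.
#'
#' @param tbv_maternal,tbv_direct per-queen true breeding values.
#' @param wg_direct per-colony worker-group direct TBVs.
#' @return scalar criterion value.
#' @export
performance_criterion <- function(tbv_maternal, wg_direct) {
  if (!length(tbv_maternal)) stop("empty cohort")
  mean(tbv_maternal + wg_direct)
}

#' @rdname performance_criterion
#' @export
inheritance_variance <- function(tbv_maternal, tbv_direct) {
  if (!length(tbv_maternal)) stop("empty cohort")
  stats::var(tbv_maternal + tbv_direct)
}

#' FAO sustainability classification of an inbreeding rate
#'
#' Breeding schemes should not raise inbreeding by more than 0.5% to 1%
#' per generation (equivalently, keep the effective population size
#' above 100 to 50).  Boundaries are inclusive.
#'
#' @param dfg per-generation inbreeding rate(s), as a proportion
#'   (0.01 = 1%).
#' @return factor with levels `strict` (<= 0.5%), `sustainable`
#'   (<= 1%), `unsustainable`.
#' @examples
#' classify_sustainability(c(0.0064, 0.005, 0.0201))
#' @export
classify_sustainability <- function(dfg) {
  if (any(dfg < 0)) stop("inbreeding rates must be non-negative")
  cut(dfg, breaks = c(-Inf, 0.005, 0.01, Inf),
      labels = c("strict", "sustainable", "unsustainable"))
}

#' Competitive breeding schemes
#'
#' A scheme is competitive when its 100-year genetic gain is not more
#' than `tolerance` (default 5%) below the best scheme of its
#' population-size/trait cell; the band roughly matches one replicate
#' standard deviation of the gain.
#'
#' @param gain named numeric vector of terminal gains, one per scheme
#'   (all from one population-size/trait cell).
#' @param tolerance relative shortfall allowed (0.05 = 5%).
#' @return logical vector: is each scheme competitive?
#' @examples
#' competitive_schemes(c(a = 10, b = 9.6, c = 9.4))  # a, b
#' @export
competitive_schemes <- function(gain, tolerance = 0.05) {
  if (!length(gain)) stop("at least one scheme is required")
  gain >= (1 - tolerance) * max(gain)
}

#' Run a grid of breeding schemes with replicates
#'
#' Simulates every `(kd, ks)` combination for `reps` independent
#' replicates (seeds derived from `master_seed` via
#' [seed_replicates()]), collecting per-replicate terminal metrics and
#' the 15-year gain.
#'
#' @param base_config a [scheme_config()]; its `kd`/`ks` are replaced
#'   by the grid values.
#' @param kd_values,ks_values grid axes.
#' @param reps replicates per cell.
#' @param master_seed master seed.
#' @return data frame of class `apisel_grid`, one row per scheme x
#'   replicate: `kd`, `ks`, `rep`, `seed`, `gain_15` (performance
#'   criterion in year `min(15, years)`), `gain_end`, `var_end_rel`,
#'   `delta_f` (proportion), `mean_f_end`.
#' @export
run_grid <- function(base_config, kd_values, ks_values, reps = 3L,
                     master_seed = 1L) {
  seeds <- seed_replicates(master_seed, reps * length(kd_values) *
                             length(ks_values))
  out <- list(); si <- 0L
  for (kd in kd_values) for (ks in ks_values) {
    cfg <- base_config
    cfg$kd <- as.integer(kd); cfg$ks <- as.numeric(ks)
    for (r in seq_len(reps)) {
      si <- si + 1L
      row <- tryCatch({
        sim <- simulate_scheme(cfg, seeds[si])
        s <- sim$summary
        y15 <- min(15L, cfg$years)
        data.frame(kd = kd, ks = ks, rep = r, seed = seeds[si],
                   gain_15 = s$performance[y15],
                   gain_end = s$performance[cfg$years],
                   var_end_rel = s$var_ic_rel[cfg$years],
                   delta_f = s$delta_f[cfg$years],
                   mean_f_end = s$mean_F[cfg$years],
                   error = NA_character_)
      }, error = function(e)
        data.frame(kd = kd, ks = ks, rep = r, seed = seeds[si],
                   gain_15 = NA_real_, gain_end = NA_real_,
                   var_end_rel = NA_real_, delta_f = NA_real_,
                   mean_f_end = NA_real_, error = conditionMessage(e)))
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("apisel_grid", "data.frame")
  res
}

#' Aggregate a scheme grid and identify competitive schemes
#'
#' Averages replicates per scheme, flags competitive breeding schemes
#' (within `tolerance` of the best mean terminal gain), classifies
#' their inbreeding rates against the FAO thresholds, and reports the
#' competitive schemes with the lowest and highest inbreeding rate --
#' the layout of a scheme-comparison summary table.
#'
#' @param grid result of [run_grid()].
#' @param tolerance competitive-scheme tolerance.
#' @return list with `schemes` (per-scheme means and SDs over
#'   replicates, competitiveness flag, sustainability class), `n_cbs`,
#'   `n_cbs_1pct`, `n_cbs_05pct`, `lowest_df_cbs`, `highest_df_cbs`.
#' @export
grid_summary <- function(grid, tolerance = 0.05) {
  ok <- grid[is.na(grid$error), , drop = FALSE]
  if (!nrow(ok)) stop("no successful replicates in the grid")
  key <- interaction(ok$kd, ok$ks, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ok, key), function(d) data.frame(
    kd = d$kd[1L], ks = d$ks[1L], reps = nrow(d),
    gain_15 = mean(d$gain_15), gain_end = mean(d$gain_end),
    gain_end_sd = stats::sd(d$gain_end),
    var_end_rel = mean(d$var_end_rel),
    delta_f = mean(d$delta_f), delta_f_sd = stats::sd(d$delta_f))))
  agg <- agg[order(agg$kd, agg$ks), , drop = FALSE]
  rownames(agg) <- NULL
  agg$competitive <- competitive_schemes(agg$gain_end, tolerance)
  agg$sustainability <- classify_sustainability(agg$delta_f)
  cbs <- agg[agg$competitive, , drop = FALSE]
  list(schemes = agg,
       n_cbs = nrow(cbs),
       n_cbs_1pct = sum(cbs$delta_f <= 0.01),
       n_cbs_05pct = sum(cbs$delta_f <= 0.005),
       lowest_df_cbs = cbs[which.min(cbs$delta_f), , drop = FALSE],
       highest_df_cbs = cbs[which.max(cbs$delta_f), , drop = FALSE])
}

#' @export
print.apisel_grid <- function(x, ...) {
  cat("Breeding-scheme grid:", length(unique(x$kd)), "kd x",
      length(unique(x$ks)), "ks values,", max(x$rep), "replicate(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}
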