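#' Run the full synthetic experiment end to end
#'
#' simulate -> deflection chain -> force decomposition -> treatment
#' statistics. All randomness flows from `config$seed`; a different seed
#' changes only the stochastic outputs.
#'
#' @param config A [generator_config()].
#' @return An object of class `circumpen_report`: list with
#'   `deflection` (per-treatment cone deflection, amplitude, relative force
#'   error), `summary` (treatment means of mechanical resistance),
#'   `reductions` (percent reduction vs the stationary treatment per
#'   material), `forces` (full cavity-expansion decomposition per
#'   treatment), `ancova`, `lsd`, `ff_ci_regression` (friction force vs
#'   circumnutation intensity), `rescale` (friction-coefficient rescaling
#'   of the f = 10 treatments), and `config`.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("config must be a generator_config")
  probes <- config_probes(config)
  fric <- friction_params(mu = config$mu)

  # deflection chain per treatment x replicate
  dt <- config$deflection_table
  defl <- list()
  for (r in seq_len(nrow(dt))) {
    for (rep_i in seq_len(config$n_replicates)) {
      ser <- gen_deflection_series(
        config, dt$material[r], dt$f[r],
        seed = config$seed + 1000L + 101L * r + rep_i)
      seg <- segment_oscillations(ser, dt$f[r],
                                  speed = config$speed_cm_h)
      s <- deflection_summary(seg, probes[[dt$material[r]]])
      defl[[length(defl) + 1]] <- cbind(
        data.frame(material = dt$material[r], f = dt$f[r],
                   replicate = rep_i), s)
    }
  }
  defl <- do.call(rbind, defl)
  defl_mean <- stats::aggregate(
    cbind(delta_c_mm, erel_pct) ~ material + f, data = defl, FUN = mean)
  amp <- stats::aggregate(amplitude_mm ~ material + f,
                          data = defl[defl$f > 0, ], FUN = mean)
  defl_mean <- merge(defl_mean, amp, all.x = TRUE)

  # force traces and treatment summary
  sim <- gen_force_traces(config, seed = config$seed)
  summ <- treatment_summary(sim$traces, probes, depth_mm = config$depth_mm)

  # percent reductions vs stationary, per material
  reductions <- do.call(rbind, lapply(split(summ, summ$material),
                                      function(s) {
    ref <- s$Q_mean_MPa[s$f == 0]
    data.frame(material = s$material, f = s$f,
               reduction_pct = percent_reduction(ref, s$Q_mean_MPa))
  }))
  rownames(reductions) <- NULL

  # decomposition from treatment means
  tr <- merge(summ, defl_mean[c("material", "f", "delta_c_mm")],
              by = c("material", "f"))
  tr$Fz_N <- mapply(function(Q, m) force_from_resistance(Q, probes[[m]]),
                    tr$Q_mean_MPa, tr$material)
  forces <- decompose_forces(tr, probes, fric, fmax = config$fmax)

  # statistics: ANCOVA + LSD on per-replicate means, Ff ~ CI regression
  reps <- attr(summ, "replicates")
  anc <- ancova_resistance(reps)
  lsd <- lsd_letters(reps$Q, interaction(reps$material, reps$f, sep = ":"))
  moving <- forces[forces$f > 0, ]
  reg <- ols_regression(moving$CI, moving$Ff_N)

  # friction rescaling of the fastest treatments
  fr <- friction_params(mu = config$mu, mu_prime = seq(0.1, 0.5, by = 0.1))
  resc <- do.call(rbind, lapply(which(forces$f == config$fmax), function(i)
    cbind(material = forces$material[i],
          friction_rescale(forces$Fz_N[i], fr, probes[[forces$material[i]]],
                           forces$Fc_s_N[i]))))

  structure(
    list(deflection = defl_mean, deflection_replicates = defl,
         summary = summ, reductions = reductions, forces = forces,
         ancova = anc, lsd = lsd, ff_ci_regression = reg, rescale = resc,
         config = config),
    class = "circumpen_report")
}

#' @export
print.circumpen_report <- function(x, ...) {
  cat("Circumnutation penetrometer experiment (synthetic)\n\n")
  cat("Treatment means (MPa):\n")
  print(x$summary, row.names = FALSE)
  cat("\nPercent reduction vs stationary:\n")
  print(x$reductions[x$reductions$f > 0, ], row.names = FALSE)
  cat(sprintf("\nFf ~ CI: slope %.2f N per unit CI, R^2 = %.2f, p = %.3g\n",
              x$ff_ci_regression$slope, x$ff_ci_regression$r_squared,
              x$ff_ci_regression$p_value))
  invisible(x)
}

#' Write a report to CSV/JSON files
#'
#' Writes `summary.csv` (treatment means and reductions), `forces.csv`
#' (force decomposition) and `stats.json` (ANCOVA, LSD letters,
#' regression) into a directory.
#'
#' @param report A `circumpen_report` from [run_experiment()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "circumpen_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summ <- merge(report$summary, report$reductions, by = c("material", "f"))
  utils::write.csv(summ, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(report$forces, file.path(dir, "forces.csv"),
                   row.names = FALSE)
  stats_out <- list(
    ancova = report$ancova$table,
    lsd = report$lsd,
    ff_ci_regression = report$ff_ci_regression[
      c("slope", "intercept", "r_squared", "p_value", "n")],
    seed = report$config$seed)
  jsonlite::write_json(stats_out, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
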