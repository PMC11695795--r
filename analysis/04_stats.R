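#!/usr/bin/env Rscript
# Step 4 -- treatment statistics.
#
# ANCOVA (circumnutation frequency continuous x shaft material
# categorical), LSD letter display over the eight treatment cells,
# percent reductions against the stationary treatment, the friction-force
# vs circumnutation-intensity regression, and the rescaling of the total
# axial force to root-like friction coefficients.

suppressPackageStartupMessages(library(circumpen))

out <- "results"
if (!file.exists(file.path(out, "forces.csv")))
  stop("run analysis/02_decompose.R first")

cfg <- generator_config(seed = 42L)
probes <- config_probes(cfg)
traces <- read.csv("results/raw/traces.csv")
summ <- treatment_summary(traces, probes, depth_mm = cfg$depth_mm)
forces <- read.csv(file.path(out, "forces.csv"))
reps <- attr(summ, "replicates")

## percent reduction vs stationary, per material
reductions <- do.call(rbind, lapply(split(summ, summ$material), function(s)
  data.frame(material = s$material, f = s$f,
             reduction_pct = percent_reduction(s$Q_mean_MPa[s$f == 0],
                                               s$Q_mean_MPa))))
print(reductions[reductions$f > 0, ], row.names = FALSE)

## ANCOVA and LSD letters on per-replicate means
anc <- ancova_resistance(reps)
cat("\nANCOVA (type II):\n")
print(anc$table, row.names = FALSE)
lsd <- lsd_letters(reps$Q, interaction(reps$material, reps$f, sep = ":"))
cat("\nLSD letters (alpha = 0.05):\n")
print(lsd, row.names = FALSE)

## friction force vs circumnutation intensity
moving <- forces[forces$f > 0, ]
reg <- ols_regression(moving$CI, moving$Ff_N)
cat(sprintf("\nFf ~ CI: slope %.1f N, R^2 = %.2f, p = %.3g\n",
            reg$slope, reg$r_squared, reg$p_value))

## rescaling to root-like friction coefficients
fr <- friction_params(mu = cfg$mu, mu_prime = seq(0.1, 0.5, by = 0.1))
resc <- do.call(rbind, lapply(which(forces$f == cfg$fmax), function(i)
  cbind(material = forces$material[i],
        f = forces$f[i],
        friction_rescale(forces$Fz_N[i], fr,
                         probes[[forces$material[i]]],
                         forces$Fc_s_N[i]))))
write.csv(resc, file.path(out, "friction_rescale.csv"), row.names = FALSE)

jsonlite::write_json(
  list(reductions = reductions, ancova = anc$table, lsd = lsd,
       ff_ci_regression = reg[c("slope", "intercept", "r_squared",
                                "p_value", "n")],
       seed = cfg$seed),
  file.path(out, "stats.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
cat("done: stats.json, friction_rescale.csv under", out, "\n")
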