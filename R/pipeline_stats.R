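#' Treatment-level summary of mechanical resistance
#'
#' Converts each replicate's force trace to mechanical resistance, averages
#' it over the full penetration depth, and summarises per treatment
#' (mean, standard error, n).
#'
#' @param traces Data frame `material, f, replicate, depth_mm, Fz_N` (from
#'   [gen_force_traces()] or measured data).
#' @param probes Named list of [probe_spec()] per material.
#' @param depth_mm Required depth coverage (default 10 mm); traces that do
#'   not span it raise an error.
#' @return Data frame with one row per (material, f): `Q_mean_MPa`,
#'   `Q_se_MPa` (NA for a single replicate), `n`; plus the per-replicate
#'   means as attribute `replicates`.
#' @export
treatment_summary <- function(traces, probes, depth_mm = 10) {
  need <- c("material", "f", "replicate", "depth_mm", "Fz_N")
  stopifnot(is.data.frame(traces), all(need %in% names(traces)))
  cover <- stats::aggregate(depth_mm ~ material + f + replicate,
                            data = traces, FUN = max)
  low <- stats::aggregate(depth_mm ~ material + f + replicate,
                          data = traces, FUN = min)
  if (any(cover$depth_mm < 0.95 * depth_mm) || any(low$depth_mm > 1))
    stop("traces do not cover the 0-", depth_mm, " mm depth range")
  areas <- vapply(probes, cone_base_area, numeric(1))
  traces$Q <- traces$Fz_N / areas[traces$material]
  reps <- stats::aggregate(Q ~ material + f + replicate, data = traces,
                           FUN = mean)
  agg <- stats::aggregate(Q ~ material + f, data = reps, FUN = function(x)
    c(mean = mean(x), se = if (length(x) > 1)
      stats::sd(x) / sqrt(length(x)) else NA_real_, n = length(x)))
  out <- data.frame(material = agg$material, f = agg$f,
                    Q_mean_MPa = agg$Q[, "mean"],
                    Q_se_MPa = agg$Q[, "se"],
                    n = as.integer(agg$Q[, "n"]))
  out <- out[order(out$material, out$f), ]
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  out
}

#' Percent reduction of a treatment mean against a reference
#'
#' @param Q_ref Reference (e.g. stationary) mean resistance (> 0).
#' @param Q_treat Treatment mean resistance.
#' @return 100 (Q_ref - Q_treat) / Q_ref, in percent.
#' @export
percent_reduction <- function(Q_ref, Q_treat) {
  stopifnot(is.numeric(Q_ref), is.numeric(Q_treat))
  if (any(Q_ref <= 0)) stop("reference must be positive")
  100 * (Q_ref - Q_treat) / Q_ref
}

#' Least-squares linear regression
#'
#' Ordinary least squares of y on x with the coefficient of determination
#' and the two-sided t-test p-value of the slope.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n` and
#'   the underlying `lm` fit.
#' @export
ols_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("regression needs at least 3 points")
  if (stats::var(y) == 0) {
    fit <- stats::lm(y ~ x)
    return(list(slope = 0, intercept = y[1], r_squared = 0, p_value = 1,
                n = length(x), fit = fit))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  p <- if (nrow(co) < 2 || is.na(co[2, 4])) 1 else co[2, 4]
  slope <- if (nrow(co) < 2) 0 else unname(co[2, 1])
  list(slope = slope, intercept = unname(co[1, 1]),
       r_squared = sm$r.squared, p_value = p, n = length(x), fit = fit)
}

#' Analysis of covariance on treatment resistance
#'
#' Fits `Q ~ f + material + f:material` with the circumnutation frequency
#' as a continuous covariate and the shaft material as a categorical
#' factor, and reports type-II F-tests per term (the design is balanced,
#' so type choice is immaterial there).
#'
#' @param data Data frame with columns `Q`, `f` (numeric) and `material`.
#' @return List with `table` (term, F, p), and the `lm` fit.
#' @export
ancova_resistance <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("Q", "f", "material") %in% names(data)))
  counts <- table(data$material)
  if (any(counts < 2)) stop("each material needs at least 2 replicates")
  data$material <- factor(data$material)
  fit <- stats::lm(Q ~ f * material, data = data)
  an <- car::Anova(fit, type = 2)
  terms <- c("f", "material", "f:material")
  tab <- data.frame(term = c("CF", "M", "CF:M"),
                    F = an[terms, "F value"],
                    p = an[terms, "Pr(>F)"])
  list(table = tab, fit = fit)
}

#' LSD multiple comparisons with a letter display
#'
#' Pairwise t-tests between group means using the pooled residual variance
#' of the one-way layout (Fisher's least significant difference). Groups
#' that do not differ significantly share a letter; letters are assigned in
#' descending order of the group means, starting at "a". The letter display
#' is built from the maximal cliques of the non-significance graph, so it
#' is invariant to the input order of groups.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (coerced to character).
#' @param alpha Significance level (default 0.05).
#' @return Data frame `group, mean, n, letters`, ordered by descending
#'   mean.
#' @export
lsd_letters <- function(values, groups, alpha = 0.05) {
  stopifnot(is.numeric(values), length(values) == length(groups))
  groups <- as.character(groups)
  g <- sort(unique(groups))
  k <- length(g)
  if (k < 2) stop("need at least 2 groups")
  means <- vapply(g, function(x) mean(values[groups == x]), numeric(1))
  ns <- vapply(g, function(x) sum(groups == x), numeric(1))
  df_res <- length(values) - k
  if (df_res < 1) stop("no residual degrees of freedom")
  s2 <- sum(vapply(g, function(x) {
    v <- values[groups == x]
    sum((v - mean(v))^2)
  }, numeric(1))) / df_res
  tcrit <- stats::qt(1 - alpha / 2, df_res)
  # non-significance adjacency (TRUE also on the diagonal)
  nonsig <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
    if (i == j) return(TRUE)
    lsd <- tcrit * sqrt(s2 * (1 / ns[i] + 1 / ns[j]))
    abs(means[i] - means[j]) <= lsd
  }))
  # maximal cliques by subset enumeration (k is small: treatment cells)
  if (k > 16) stop("letter display supports up to 16 groups")
  subsets <- lapply(seq_len(2^k - 1), function(b) which(bitwAnd(
    b, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) all(nonsig[s, s]), logical(1))
  cl <- subsets[is_clique]
  maximal <- cl[vapply(seq_along(cl), function(i) !any(vapply(
    seq_along(cl), function(j) i != j && all(cl[[i]] %in% cl[[j]]),
    logical(1))), logical(1))]
  ord <- order(-means, g)  # descending mean, ties by name
  rank_of <- integer(k); rank_of[ord] <- seq_len(k)
  best_rank <- vapply(maximal, function(s) min(rank_of[s]), numeric(1))
  maximal <- maximal[order(best_rank)]
  lett <- rep("", k)
  for (i in seq_along(maximal))
    lett[maximal[[i]]] <- paste0(lett[maximal[[i]]], letters[i])
  data.frame(group = g[ord], mean = means[ord], n = as.integer(ns[ord]),
             letters = lett[ord], row.names = NULL)
}

#' Shapiro-Wilk residual check (convenience diagnostic, not a gate)
#' @param fit An `lm` fit.
#' @return The `htest` result of [stats::shapiro.test()] on the residuals.
#' @export
residual_normality <- function(fit) {
  stats::shapiro.test(stats::residuals(fit))
}
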