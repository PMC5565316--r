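## Paired patient/control cohort statistics: Shapiro-Wilk gated paired
## tests (Wilcoxon signed-rank with exact small-sample p-values), 2x2
## chi-squared, Spearman correlations with clinical covariates, Bonferroni
## correction, and the orchestration that applies them per imaging metric.

#' Paired Wilcoxon signed-rank test
#'
#' Tests within-pair differences `x - y`. Zero differences are dropped
#' (Wilcoxon's convention); `n` reports the pairs remaining. For n <= 15
#' the two-sided p-value is exact, computed from the full distribution of
#' the positive-rank sum over all 2^n sign assignments (handled with
#' average ranks, so ties are respected); for larger n a normal
#' approximation with the usual tie correction is used. The exact
#' two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y paired numeric vectors of equal length >= 5.
#' @param exact_n_max largest n for the exact branch (default 15).
#' @return a `stat_result` list: `test`, `statistic` (W, the positive-rank
#'   sum), `p_value`, `n`, `method` ("exact" or "normal").
#' @examples
#' paired_wilcoxon(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1))$p_value  # 0.03125
#' @export
paired_wilcoxon <- function(x, y, exact_n_max = 15L) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) stop("all differences zero")
  n <- length(d)
  r <- rank(abs(d))                    # average ranks under ties
  w <- sum(r[d > 0])
  if (n <= exact_n_max) {
    ## distribution of W by generating-function convolution over 2*ranks
    ## (doubling makes average ranks integral)
    s <- as.integer(round(2 * r))
    tot <- sum(s)
    dist <- c(1, numeric(tot))         # dist[k + 1] = P(2W = k) * 2^n
    for (si in s) {
      shifted <- c(numeric(si), dist[seq_len(tot + 1 - si)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(test = "paired_wilcoxon", statistic = w, p_value = p,
                 n = n, method = method), class = "stat_result")
}

#' Pearson chi-squared test on a 2x2 table (no continuity correction)
#'
#' @param table 2x2 matrix of non-negative counts with all margins > 0.
#' @return a `stat_result`: `test`, `statistic`, `p_value`, `df`, `n`.
#' @examples
#' chi2_2x2(matrix(c(4, 11, 11, 4), 2, byrow = TRUE))  # p ~ 0.0106
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0), sum(table) >= 1)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in 2x2 table")
  ct <- stats::chisq.test(table, correct = FALSE)
  structure(list(test = "chi2_2x2", statistic = unname(ct$statistic),
                 p_value = ct$p.value, df = 1L, n = sum(table)),
            class = "stat_result")
}

#' Spearman rank correlation with two-sided t approximation
#'
#' rho is the Pearson correlation of average ranks; the p-value uses the
#' t distribution with n - 2 degrees of freedom (rho = +/-1 gives p = 0).
#'
#' @param x,y numeric vectors, pairwise complete, length >= 5.
#' @return a `stat_result`: `test`, `statistic` (rho), `p_value`, `n`.
#' @export
spearman_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a variable")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(test = "spearman", statistic = rho, p_value = p, n = n),
            class = "stat_result")
}

#' Shapiro-Wilk normality gate
#'
#' Runs `shapiro.test` and recommends the nonparametric test family when
#' p < alpha. Degenerate (all-identical) samples cannot be tested and are
#' routed to the nonparametric family.
#'
#' @param values numeric vector, 3 <= n <= 50.
#' @param alpha rejection level (default 0.05).
#' @return list: `normality_p` (NA when degenerate), `family`
#'   ("parametric" or "nonparametric").
#' @export
shapiro_gate <- function(values, alpha = 0.05) {
  n <- sum(is.finite(values))
  if (n < 3 || n > 50) stop("Shapiro-Wilk gate requires 3 <= n <= 50")
  values <- values[is.finite(values)]
  if (stats::sd(values) == 0)
    return(list(normality_p = NA_real_, family = "nonparametric"))
  p <- stats::shapiro.test(values)$p.value
  list(normality_p = p,
       family = if (p < alpha) "nonparametric" else "parametric")
}

#' Bonferroni correction
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param m family size, at least `length(p_values)` (defaults to it).
#' @return corrected p-values `min(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  if (m < length(p_values)) stop("family size m must be >= number of p-values")
  pmin(1, m * p_values)
}

#' Simulate a paired patient/control cohort of subject summaries
#'
#' Generates subject-level imaging summaries for `n_pairs` patient/control
#' couples. Each metric is a pair (couple) random effect plus a subject
#' residual, reflecting the paired recruitment design in which couples
#' share diet and lifestyle: for the responder percentage the defaults are
#' a control mean of 57.3%, pair-effect SD 22 and residual SD 15 (total
#' between-subject SD ~ 27, intraclass correlation ~ 0.68), clamped to
#' \[0, 100\]. `effects` shifts the PD group mean of any metric (e.g.
#' `c(hk_pct_responders = -20)`); the default is a null cohort.
#'
#' @param n_pairs number of patient/control pairs.
#' @param effects named numeric vector of additive PD-group shifts.
#' @param seed integer seed.
#' @return data.frame with one row per subject: `subject_id`, `pair_id`,
#'   `group` ("PD"/"control"), imaging metrics, and clinical covariates
#'   (`age`, `scopa_total`, `scopa_gi`, `updrs3_off`,
#'   `disease_duration_years` — the last two PD-only).
#' @export
simulate_cohort <- function(n_pairs = 15, effects = numeric(0), seed = 1L) {
  stopifnot(n_pairs >= 2)
  metrics <- list(
    ## name = c(control mean, pair SD, residual SD, lo, hi)
    hk_pct_responders = c(57.3, 22, 15, 0, 100),
    hk_mean_amplitude_pct = c(3.6, 1.4, 1.2, 0, Inf),
    mito_volume_ratio = c(0.08, 0.025, 0.02, 0, 1),
    mito_density_per_1000um3 = c(12, 3.5, 3, 0, Inf),
    mito_mean_single_volume_um3 = c(2.0, 0.5, 0.45, 0, Inf),
    mito_fluctuation_score_pct = c(10, 2.5, 2, 0, Inf))
  with_seed(seed, {
    out <- data.frame(
      subject_id = sprintf("S%02d_%s", rep(seq_len(n_pairs), each = 2),
                           rep(c("PD", "C"), n_pairs)),
      pair_id = rep(seq_len(n_pairs), each = 2),
      group = rep(c("PD", "control"), n_pairs),
      stringsAsFactors = FALSE)
    for (m in names(metrics)) {
      par <- metrics[[m]]
      pair_eff <- rnorm(n_pairs, 0, par[2])
      vals <- par[1] + pair_eff[out$pair_id] + rnorm(nrow(out), 0, par[3])
      shift <- if (m %in% names(effects)) effects[[m]] else 0
      vals[out$group == "PD"] <- vals[out$group == "PD"] + shift
      out[[m]] <- pmin(pmax(vals, par[4]), par[5])
    }
    out$age <- round(rnorm(nrow(out), 58, 8))
    out$scopa_total <- pmax(round(rnorm(nrow(out), 6, 3) +
                                    4 * (out$group == "PD")), 0)
    out$scopa_gi <- pmax(round(rnorm(nrow(out), 1, 1) +
                                 2 * (out$group == "PD")), 0)
    out$updrs3_off <- ifelse(out$group == "PD",
                             pmax(round(rnorm(nrow(out), 23, 10)), 5), NA)
    out$disease_duration_years <- ifelse(out$group == "PD",
                                         pmax(round(rnorm(nrow(out), 8, 4)), 1), NA)
    out
  })
}

#' Paired cohort comparison with normality gating and Bonferroni correction
#'
#' For each metric, both groups' values pass a Shapiro-Wilk gate; when
#' either group departs from normality (or is degenerate) the paired
#' Wilcoxon signed-rank test is used, otherwise a paired t-test. P-values
#' are Bonferroni-corrected within the metric family (m = number of
#' metrics). When `covariates` are given, each metric is additionally
#' Spearman-correlated with each covariate over PD subjects, corrected
#' within each metric's covariate family.
#'
#' @param cohort data.frame with `pair_id`, `group` ("PD"/"control") and
#'   the metric columns; exactly one PD and one control per pair.
#' @param metrics character vector of metric column names.
#' @param covariates character vector of clinical covariate columns
#'   (PD-side values used), or `NULL`.
#' @param alpha significance level applied to corrected p-values.
#' @return list: `comparisons` data.frame (metric, test, statistic, n,
#'   normality_p_pd, normality_p_control, p_value, corrected_p,
#'   significant, family_size), `correlations` data.frame or NULL.
#' @export
run_cohort_comparison <- function(cohort, metrics,
                                  covariates = NULL, alpha = 0.05) {
  stopifnot(all(c("pair_id", "group") %in% names(cohort)),
            all(metrics %in% names(cohort)))
  tab <- table(cohort$pair_id, cohort$group)
  if (!all(tab == 1) || ncol(tab) != 2)
    stop("cohort must contain exactly one PD and one control per pair_id")
  pd <- cohort[cohort$group == "PD", ]
  co <- cohort[cohort$group == "control", ]
  co <- co[match(pd$pair_id, co$pair_id), ]
  m_fam <- length(metrics)
  rows <- vector("list", m_fam)
  for (k in seq_along(metrics)) {
    met <- metrics[k]
    xs <- pd[[met]]; ys <- co[[met]]
    g1 <- shapiro_gate(xs); g2 <- shapiro_gate(ys)
    nonpar <- g1$family == "nonparametric" || g2$family == "nonparametric"
    res <- tryCatch({
      if (nonpar) paired_wilcoxon(xs, ys)
      else {
        tt <- stats::t.test(xs, ys, paired = TRUE)
        list(test = "paired_t", statistic = unname(tt$statistic),
             p_value = tt$p.value, n = length(xs))
      }
    }, error = function(e) list(test = if (nonpar) "paired_wilcoxon" else "paired_t",
                                statistic = NA_real_, p_value = NA_real_,
                                n = length(xs)))
    rows[[k]] <- data.frame(metric = met, test = res$test,
                            statistic = res$statistic, n = res$n,
                            normality_p_pd = g1$normality_p,
                            normality_p_control = g2$normality_p,
                            p_value = res$p_value, stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, rows)
  comparisons$corrected_p <- bonferroni_na(comparisons$p_value, m_fam)
  comparisons$significant <- !is.na(comparisons$corrected_p) &
    comparisons$corrected_p < alpha
  comparisons$family_size <- m_fam
  correlations <- NULL
  if (!is.null(covariates) && length(covariates) > 0) {
    crows <- list()
    for (met in metrics) for (cv in covariates) {
      res <- tryCatch(spearman_corr(pd[[met]], pd[[cv]]),
                      error = function(e) list(statistic = NA_real_,
                                               p_value = NA_real_, n = NA_integer_))
      crows[[length(crows) + 1]] <- data.frame(
        metric = met, covariate = cv, rho = res$statistic, n = res$n,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
    correlations <- do.call(rbind, crows)
    correlations$corrected_p <- NA_real_
    for (met in metrics) {
      i <- correlations$metric == met
      correlations$corrected_p[i] <- bonferroni_na(correlations$p_value[i],
                                                   length(covariates))
    }
    correlations$significant <- !is.na(correlations$corrected_p) &
      correlations$corrected_p < alpha
  }
  list(comparisons = comparisons, correlations = correlations)
}

#' Bonferroni that passes NAs through
#' @noRd
bonferroni_na <- function(p, m) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- bonferroni(p[ok], max(m, sum(ok)))
  out
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g (n = %d%s)\n",
              x$test, x$statistic, x$p_value, x$n,
              if (!is.null(x$method)) paste0(", ", x$method) else ""))
  invisible(x)
}
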