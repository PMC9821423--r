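# Overall-survival analysis: Kaplan-Meier curves, log-rank tests,
# maximally-selected optimal cutpoints with a permutation p-value, and Cox
# proportional-hazards fits (Breslow ties) with covariate adjustment.

.check_survival <- function(time, event) {
  if (anyNA(time) || any(time <= 0)) stop("survival times must be positive")
  if (anyNA(event)) stop("event indicator must not contain NA")
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator per group; censored times do not drop the curve.
#'
#' @param time Positive survival times (months).
#' @param event Logical/0-1 event indicator (TRUE = death).
#' @param group Optional group labels (single group when NULL).
#' @return data.frame `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  .check_survival(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ grp,
                           data = data.frame(time = time, event = event,
                                             grp = as.factor(group)))
  smry <- summary(fit, censored = TRUE)
  grp_col <- if (is.null(smry$strata)) rep(levels(as.factor(group))[1L],
                                           length(smry$time))
             else sub("^grp=", "", as.character(smry$strata))
  data.frame(group = grp_col, time = smry$time, n_risk = smry$n.risk,
             n_event = smry$n.event, surv = smry$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected statistic over event times, chi-square
#' with (#groups - 1) degrees of freedom. Empty groups are excluded.
#'
#' @inheritParams km_estimate
#' @param group Group labels (>= 2 non-empty groups with events overall).
#' @return List with `statistic`, `dof`, `p`.
#' @export
log_rank_test <- function(time, event, group) {
  .check_survival(time, event)
  group <- as.factor(as.character(group))  # drops empty levels
  if (nlevels(group) < 2L) stop("need at least two non-empty groups")
  if (sum(event) == 0L) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ grp,
                           data = data.frame(time = time, event = event,
                                             grp = group))
  dof <- nlevels(group) - 1L
  list(statistic = sd$chisq, dof = dof,
       p = stats::pchisq(sd$chisq, dof, lower.tail = FALSE))
}

# standardized two-group log-rank statistic (group1 = TRUE side):
# Z = sum(d1 - E1) / sqrt(sum V); vectorized over event times
.lr_stat2 <- function(time, event, in_high) {
  # within tied times events sort first, so the at-risk count at the first
  # event of a tie block includes the tied censored observations
  ord <- order(time, -as.integer(event))
  t_s <- time[ord]; e_s <- as.integer(event[ord]); g_s <- as.integer(in_high[ord])
  n <- length(t_s)
  # at-risk counts just before each position
  n_tot <- n - seq_len(n) + 1L
  n_high <- rev(cumsum(rev(g_s)))
  ev <- which(e_s == 1L)
  if (!length(ev)) return(0)
  dt <- t_s[ev]
  # aggregate by distinct event time, preserving the ascending time order
  first <- !duplicated(dt)
  idx <- ev[first]
  f <- factor(dt, levels = unique(dt))
  d <- as.numeric(tapply(rep(1L, length(ev)), f, sum))
  d1 <- as.numeric(tapply(g_s[ev], f, sum))
  N <- n_tot[idx]
  N1 <- n_high[idx]
  E <- d * N1 / N
  V <- ifelse(N > 1, d * (N1 / N) * (1 - N1 / N) * (N - d) / (N - 1), 0)
  sv <- sum(V)
  if (sv <= 0) return(0)
  sum(d1 - E) / sqrt(sv)
}

#' Optimal cutpoint by maximally selected log-rank statistic
#'
#' Scans candidate cutpoints of a continuous biomarker between the
#' `minprop` and `1 - minprop` quantiles (dichotomizing as
#' high = value > cutpoint) and picks the cutpoint maximizing the absolute
#' standardized two-group log-rank statistic. The selection-corrected
#' p-value is obtained by permuting the biomarker values and re-maximizing.
#'
#' @param values Per-patient biomarker (non-constant, length >= 10).
#' @param time,event Survival outcome.
#' @param minprop Minimum group proportion, default 0.1.
#' @param n_permutations Default 1000.
#' @param seed Integer seed for the permutations.
#' @return List with `cutpoint`, `statistic` (max |Z|), `p`, `candidates`.
#' @export
optimal_cutpoint <- function(values, time, event, minprop = 0.1,
                             n_permutations = 1000L, seed = 1L) {
  .check_survival(time, event)
  if (length(values) < 10L) stop("need at least 10 patients")
  if (length(unique(values)) < 2L) stop("biomarker is constant")
  lo <- stats::quantile(values, minprop, type = 1)
  hi <- stats::quantile(values, 1 - minprop, type = 1)
  cand <- sort(unique(values[values >= lo & values < hi]))
  if (!length(cand)) stop("no candidate cutpoints within the minprop bounds")
  max_abs_z <- function(v) {
    max(vapply(cand, function(cp) abs(.lr_stat2(time, event, v > cp)), numeric(1)))
  }
  zs <- vapply(cand, function(cp) abs(.lr_stat2(time, event, values > cp)), numeric(1))
  best <- which.max(zs)
  obs <- zs[best]
  set.seed(seed)
  perm_max <- vapply(seq_len(n_permutations), function(i)
    max_abs_z(sample(values)), numeric(1))
  p <- (1 + sum(perm_max >= obs)) / (n_permutations + 1)
  list(cutpoint = cand[best], statistic = obs, p = p,
       candidates = data.frame(cutpoint = cand, abs_z = zs))
}

#' Dichotomize a biomarker at a cutpoint
#' @param values Numeric biomarker.
#' @param cutpoint From [optimal_cutpoint()].
#' @return Factor with levels `low`, `high` (high = value strictly above).
#' @export
surv_categorize_at <- function(values, cutpoint) {
  factor(ifelse(values > cutpoint, "high", "low"), levels = c("low", "high"))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling. Reports per-covariate
#' coefficients, hazard ratios, Wald p-values and 95% confidence intervals,
#' plus the model likelihood-ratio statistic. Non-convergence or monotone
#' likelihood (infinite coefficients) is flagged rather than silently
#' returned.
#'
#' @param data data.frame containing `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names.
#' @return List with `converged`, `flag`, `coefficients` (data.frame:
#'   `term`, `coef`, `hr`, `se`, `wald_p`, `hr_lo`, `hr_hi`), `lr_statistic`,
#'   `lr_dof`, `lr_p`, `fit`.
#' @export
cox_ph_fit <- function(data, covariates) {
  .check_survival(data$time, data$event)
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) stop("covariate not found: ", cv)
    if (length(unique(v)) < 2L) stop("covariate is constant: ", cv)
  }
  if (sum(data$event) < length(covariates) + 1L) {
    stop("too few events for the number of covariates")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, as.integer(event)) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = data, ties = "breslow",
                    control = survival::coxph.control(iter.max = 100,
                                                      eps = 1e-9)),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(fml, data = data, ties = "breslow",
                        control = survival::coxph.control(iter.max = 100,
                                                          eps = 1e-9)))
      attr(f, "flag") <- conditionMessage(w)
      f
    })
  flag <- attr(fit, "flag")
  smry <- summary(fit)
  coefs <- data.frame(term = rownames(smry$coefficients),
                      coef = smry$coefficients[, "coef"],
                      hr = smry$coefficients[, "exp(coef)"],
                      se = smry$coefficients[, "se(coef)"],
                      wald_p = smry$coefficients[, "Pr(>|z|)"],
                      hr_lo = smry$conf.int[, "lower .95"],
                      hr_hi = smry$conf.int[, "upper .95"],
                      row.names = NULL, stringsAsFactors = FALSE)
  diverged <- any(!is.finite(coefs$coef)) || any(abs(coefs$coef) > 15)
  list(converged = fit$iter < 100 && !diverged,
       flag = if (diverged) paste(c("possible monotone likelihood", flag),
                                  collapse = "; ")
              else if (!is.null(flag)) flag else "ok",
       coefficients = coefs,
       lr_statistic = unname(smry$logtest["test"]),
       lr_dof = unname(smry$logtest["df"]),
       lr_p = unname(smry$logtest["pvalue"]),
       fit = fit)
}

#' Screen biomarkers for survival association via optimal cutpoints
#'
#' For each biomarker column: find the optimal cutpoint, dichotomize and
#' run a two-group log-rank test; p-values across markers are adjusted by
#' Benjamini-Hochberg (configurable).
#'
#' @param markers data.frame of per-patient biomarkers (rows aligned with
#'   `time`/`event`).
#' @param time,event Survival outcome.
#' @param minprop,n_permutations,seed Passed to [optimal_cutpoint()].
#' @param adjust [stats::p.adjust()] method, default `"BH"`.
#' @return data.frame `marker`, `cutpoint`, `statistic`, `log_rank_p`,
#'   `adjusted_p`.
#' @export
survival_screen <- function(markers, time, event, minprop = 0.1,
                            n_permutations = 200L, seed = 1L, adjust = "BH") {
  rows <- lapply(names(markers), function(m) {
    v <- markers[[m]]
    ok <- is.finite(v)
    res <- tryCatch(
      optimal_cutpoint(v[ok], time[ok], event[ok], minprop = minprop,
                       n_permutations = n_permutations, seed = seed),
      error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(marker = m, cutpoint = NA_real_, statistic = NA_real_,
                        log_rank_p = NA_real_, stringsAsFactors = FALSE))
    }
    grp <- surv_categorize_at(v[ok], res$cutpoint)
    lr <- log_rank_test(time[ok], event[ok], grp)
    data.frame(marker = m, cutpoint = res$cutpoint, statistic = res$statistic,
               log_rank_p = lr$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$adjusted_p <- stats::p.adjust(out$log_rank_p, method = adjust)
  out[order(out$adjusted_p, out$marker), , drop = FALSE]
}
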