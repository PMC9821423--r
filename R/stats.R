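# Rank tests, exact tests, correlation, per-peptide prognosis association
# and flow-marker clustering. The elementary tests are implemented from
# their defining formulas so that downstream code and the simulation layer
# share a single seedable, dependency-free statistical core.

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with the chi-square approximation on
#' `length(groups) - 1` degrees of freedom. Average ranks are used for ties.
#' When every value is identical the convention H = 0, p = 1 is returned.
#'
#' @param groups List of >= 2 numeric vectors (empty groups are dropped).
#' @return List with `statistic`, `dof`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least two non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(x)
  if (N < 3L) stop("need total n >= 3")
  r <- rank(x)
  g <- rep(seq_along(groups), n)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / n) - 3 * (N + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (correction > 0) H / correction else 0
  H <- max(H, 0)
  dof <- length(groups) - 1L
  list(statistic = H, dof = dof,
       p = if (H == 0) 1 else stats::pchisq(H, dof, lower.tail = FALSE))
}

#' Dunn post-hoc test
#'
#' Pairwise z statistics from the pooled tie-corrected rank variance,
#' following a Kruskal-Wallis test. Two-sided unadjusted p-values by default;
#' any [stats::p.adjust()] method can be requested.
#'
#' @param groups Named list of numeric vectors (empty groups excluded with a
#'   message).
#' @param adjust p-value adjustment method, default `"none"`.
#' @return data.frame with `group_a`, `group_b`, `z`, `p`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjust = "none") {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    message("dunn_posthoc: excluding empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  if (length(groups) < 2L) stop("need at least two non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(x)
  r <- rank(x)
  g <- rep(seq_along(groups), n)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2L)
  z <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    if (se == 0) 0 else (rbar[i] - rbar[j]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group_a = names(groups)[pairs[1L, ]],
             group_b = names(groups)[pairs[2L, ]],
             z = z, p = p, p_adjusted = stats::p.adjust(p, method = adjust),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher exact test for a 2x2 table (two-sided)
#'
#' Computed by direct hypergeometric enumeration over all tables with the
#' observed margins; the two-sided p sums the probabilities of tables whose
#' point probability does not exceed that of the observed table (with the
#' customary relative tolerance guarding floating-point comparisons).
#' A zero margin gives p = 1.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (anyNA(table) || any(table < 0) || any(table != round(table))) {
    stop("table must contain non-negative integers")
  }
  m <- sum(table[1L, ])          # first row margin
  n <- sum(table[2L, ])
  k <- sum(table[, 1L])          # first column margin
  if (m == 0 || n == 0 || k == 0 || sum(table[, 2L]) == 0) return(1)
  support <- max(0L, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(table[1L, 1L], m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Chi-square goodness-of-fit test
#'
#' `sum((O - E)^2 / E)` over categories with positive expected proportion;
#' degrees of freedom = (number of such categories) - 1.
#'
#' @param observed Non-negative counts.
#' @param expected_props Proportions summing to 1 (within 1e-6).
#' @return List with `statistic`, `dof`, `p`.
#' @export
chi_square_gof <- function(observed, expected_props) {
  stopifnot(length(observed) == length(expected_props))
  if (abs(sum(expected_props) - 1) > 1e-6) stop("expected proportions must sum to 1")
  if (sum(observed) <= 0) stop("no observations")
  keep <- expected_props > 0
  if (!any(keep)) stop("all expected proportions are zero")
  O <- observed[keep]
  E <- sum(observed) * expected_props[keep] / sum(expected_props[keep])
  dof <- sum(keep) - 1L
  if (dof < 1L) stop("chi-square goodness-of-fit needs at least two categories with positive expectation")
  stat <- sum((O - E)^2 / E)
  list(statistic = stat, dof = dof,
       p = stats::pchisq(stat, dof, lower.tail = FALSE))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values.
#' @return List with `r`, `p`, and `flag` (`"ok"` or `"zero-variance"`,
#'   in which case `r` and `p` are NA).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, flag = "zero-variance"))
  }
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(r = r, p = 0, flag = "ok"))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2), flag = "ok")
}

#' Prognosis labels from recurrence-free survival
#'
#' Four-level label: `worst` (RFS < 6 months, no response to first-line
#' therapy), `poor` (RFS < 6 months with response), `good` (6 <= RFS <= 12)
#' and `excellent` (RFS > 12). RFS exactly 6 months is assigned to `good`;
#' the boundary is configurable via `six_to`.
#'
#' @param clinical data.frame with `patient_id`, `rfs_months`, `responded`.
#' @param six_to Label for RFS == 6 exactly, default `"good"`.
#' @return data.frame `patient_id`, `label` (factor worst/poor/good/excellent).
#' @export
prognosis_labels <- function(clinical, six_to = c("good", "poor", "worst")) {
  six_to <- match.arg(six_to)
  rfs <- clinical$rfs_months
  resp <- clinical$responded
  lab <- ifelse(rfs < 6, ifelse(resp, "poor", "worst"),
                ifelse(rfs <= 12, "good", "excellent"))
  lab[rfs == 6] <- six_to
  data.frame(patient_id = clinical$patient_id,
             label = factor(lab, levels = c("worst", "poor", "good", "excellent")),
             stringsAsFactors = FALSE)
}

#' Per-peptide prognosis association
#'
#' For every productive CDR3beta peptide present in at least `min_patients`
#' patients: a Kruskal-Wallis test of the per-patient productive frequency of
#' the peptide across the four prognosis groups (absent = frequency 0), and a
#' Fisher exact test of presence/absence against favorable (good + excellent)
#' versus unfavorable (poor + worst) prognosis. A peptide is flagged
#' associated when the smaller of the two unadjusted p-values is below
#' `alpha`.
#'
#' @param reps List of [repertoire] objects.
#' @param labels Output of [prognosis_labels()] covering all patients.
#' @param alpha Significance threshold, default 0.05.
#' @param min_patients Minimum carriers for a peptide to be tested, default 2.
#' @return data.frame sorted by `min_p` with columns `cdr3_aa`, `n_patients`,
#'   `kw_p`, `fisher_p`, `min_p`, `associated`.
#' @export
peptide_prognosis_association <- function(reps, labels, alpha = 0.05,
                                          min_patients = 2L) {
  pep_freq <- data.table::rbindlist(lapply(reps, function(r) {
    ct <- r$clonotypes[productive(r) & r$clonotypes$templates > 0]
    tot <- sum(ct$templates)
    ct[, list(freq = sum(templates) / tot, patient_id = r$patient_id), by = "cdr3_aa"]
  }))
  lab <- stats::setNames(as.character(labels$label), labels$patient_id)
  ids <- vapply(reps, function(r) r$patient_id, character(1))
  if (anyNA(lab[ids])) stop("missing prognosis label for some patients")
  patient_group <- lab[ids]
  favorable <- patient_group %in% c("good", "excellent")
  counts <- pep_freq[, list(n_patients = data.table::uniqueN(patient_id)),
                     by = "cdr3_aa"]
  tested <- counts$cdr3_aa[counts$n_patients >= min_patients]
  if (!length(tested)) {
    return(data.frame(cdr3_aa = character(), n_patients = integer(),
                      kw_p = numeric(), fisher_p = numeric(),
                      min_p = numeric(), associated = logical()))
  }
  # dense patient x peptide frequency matrix (absent = 0)
  freq_t <- pep_freq[pep_freq$cdr3_aa %in% tested]
  mat <- matrix(0, nrow = length(ids), ncol = length(tested),
                dimnames = list(ids, tested))
  mat[cbind(match(freq_t$patient_id, ids), match(freq_t$cdr3_aa, tested))] <- freq_t$freq
  res <- lapply(tested, function(pep) {
    v <- mat[, pep]
    kw <- kruskal_wallis(split(v, patient_group))
    present <- v > 0
    tab <- matrix(c(sum(present & favorable), sum(present & !favorable),
                    sum(!present & favorable), sum(!present & !favorable)),
                  nrow = 2L, byrow = TRUE)
    fp <- fisher_exact_2x2(tab)
    data.frame(cdr3_aa = pep, n_patients = sum(present),
               kw_p = kw$p, fisher_p = fp,
               min_p = min(kw$p, fp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$associated <- out$min_p < alpha
  out[order(out$min_p, out$cdr3_aa), , drop = FALSE]
}

# within-cluster dispersion W_k (Tibshirani) from a distance matrix
.gap_Wk <- function(d, cl) {
  dm <- as.matrix(d)
  sum(vapply(split(seq_along(cl), cl), function(idx) {
    if (length(idx) < 2L) return(0)
    # full submatrix counts each unordered pair twice, i.e. equals D_r
    sum(dm[idx, idx]^2) / (2 * length(idx))
  }, numeric(1)))
}

.flow_cluster_once <- function(mat, k) {
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  hc <- stats::hclust(d, method = "average")
  list(cl = stats::cutree(hc, k = k), d = d, hc = hc)
}

#' Hierarchically cluster flow-marker profiles with gap-statistic selection
#'
#' Marker percentages are log2-transformed (zeros offset by half the
#' smallest positive value per marker), z-score normalized per marker, and
#' patients are clustered by average-linkage agglomeration on the
#' 1 - Pearson correlation distance. The number of clusters is selected by
#' the gap statistic over `k_range` against `B_refs` uniform reference
#' draws, using the standard 1-SE rule.
#'
#' @param flow Numeric matrix or data.frame, patients x markers (percent of
#'   CD3+ live lymphocytes); rownames are patient ids.
#' @param k_range Candidate cluster counts, default `1:6`.
#' @param B_refs Number of uniform reference datasets, default 50.
#' @param seed Integer seed for the reference draws.
#' @return List with `labels` (named cluster assignment), `k`, `gap`
#'   (per-k gap values and standard errors), and `hclust`.
#' @export
cluster_flow_profiles <- function(flow, k_range = 1:6, B_refs = 50L, seed = 1L) {
  mat <- as.matrix(flow)
  if (nrow(mat) < 4L || ncol(mat) < 2L) stop("need >= 4 patients and >= 2 markers")
  if (anyNA(mat)) {
    keep <- stats::complete.cases(mat)
    message("cluster_flow_profiles: dropping ", sum(!keep), " patient(s) with missing values")
    mat <- mat[keep, , drop = FALSE]
  }
  # log2 with per-marker half-minimum offset for zeros
  for (j in seq_len(ncol(mat))) {
    pos <- mat[, j][mat[, j] > 0]
    eps <- if (length(pos)) min(pos) / 2 else 1
    mat[, j] <- log2(mat[, j] + eps)
  }
  const <- apply(mat, 2L, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant marker column(s): ",
            paste(colnames(mat)[const], collapse = ", "))
    mat <- mat[, !const, drop = FALSE]
  }
  mat <- scale(mat)
  k_range <- k_range[k_range <= nrow(mat) - 1L & k_range >= 1L]
  set.seed(seed)
  rng <- apply(mat, 2L, range)
  logW <- gap <- se <- numeric(length(k_range))
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  hc <- stats::hclust(d, method = "average")
  ref_logW <- matrix(NA_real_, B_refs, length(k_range))
  for (b in seq_len(B_refs)) {
    ref <- apply(rng, 2L, function(r) stats::runif(nrow(mat), r[1L], r[2L]))
    rd <- stats::as.dist(1 - stats::cor(t(ref)))
    rhc <- stats::hclust(rd, method = "average")
    for (i in seq_along(k_range)) {
      ref_logW[b, i] <- log(max(.gap_Wk(rd, stats::cutree(rhc, k = k_range[i])), 1e-12))
    }
  }
  for (i in seq_along(k_range)) {
    logW[i] <- log(max(.gap_Wk(d, stats::cutree(hc, k = k_range[i])), 1e-12))
    gap[i] <- mean(ref_logW[, i]) - logW[i]
    se[i] <- stats::sd(ref_logW[, i]) * sqrt(1 + 1 / B_refs)
  }
  # 1-SE rule: smallest k with gap(k) >= gap(k+1) - se(k+1)
  k_idx <- length(k_range)
  for (i in seq_len(length(k_range) - 1L)) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) { k_idx <- i; break }
  }
  k <- k_range[k_idx]
  list(labels = stats::cutree(hc, k = k), k = k,
       gap = data.frame(k = k_range, gap = gap, se = se, logW = logW),
       hclust = hc)
}

#' CD8-to-Treg ratio column
#'
#' Ratio of the percentage of live CD8+ lymphocytes to the percentage of
#' live CD4+FoxP3+ lymphocytes; undefined (NA) when the denominator is 0.
#'
#' @param flow data.frame/matrix with columns `cd8` and `cd4_foxp3`.
#' @return Numeric vector of ratios.
#' @export
cd8_treg_ratio <- function(flow) {
  num <- flow[, "cd8"]
  den <- flow[, "cd4_foxp3"]
  ifelse(den == 0, NA_real_, num / den)
}
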