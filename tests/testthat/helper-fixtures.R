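# Shared fixtures and independent oracles. Oracles deliberately use a
# different computational route than the implementation they check.

# build a repertoire from template counts (productive unless stated)
make_rep <- function(id, counts, cdr3 = NULL, frame = NULL, v = NULL, j = NULL) {
  n <- length(counts)
  if (is.null(cdr3)) {
    cdr3 <- vapply(seq_len(n), function(i)
      paste0("CASS", paste(rep(LETTERS[(i %% 20) + 1], 4), collapse = ""),
             sprintf("%02d", i), "EQFF"), character(1))
  }
  repertoire(id, data.frame(
    cdr3_aa = cdr3,
    v_gene = if (is.null(v)) "TCRBV01-01*01" else v,
    d_gene = "unresolved",
    j_gene = if (is.null(j)) "TCRBJ01-01*01" else j,
    templates = counts,
    frame = if (is.null(frame)) "in-frame" else frame,
    stringsAsFactors = FALSE))
}

write_immunoseq_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# exhaustive edit-script oracle: plain memoized recursion over the
# insert/delete/substitute alternatives (independent of the row-rolling DP)
lev_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  memo <- new.env()
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- min(rec(i - 1, j) + 1,
             rec(i, j - 1) + 1,
             rec(i - 1, j - 1) + (x[i] != y[j]))
    memo[[key]] <- v
    v
  }
  rec(length(x), length(y))
}

# two-sided Fisher p via explicit choose() ratios (implementation uses dhyper)
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, k - n):min(m, k)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, tab[1, 1]) * choose(n, k - tab[1, 1]) / choose(m + n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# labelled prognosis table for a toy cohort
make_labels <- function(ids, labels) {
  data.frame(patient_id = ids,
             label = factor(labels, levels = c("worst", "poor", "good", "excellent")),
             stringsAsFactors = FALSE)
}

# small reference database for annotation tests
make_ref_db <- function() {
  reference_db(data.frame(
    cdr3_aa = c("CASSLVNTEAFF", "CASSLVNTEAFF", "CASQDRGGYEQYF",
                "CAWSVSDLAKNIQYF", "CASSPGQGAYEQYF"),
    category = c("cancer", "pathogens", "cancer", "autoimmune", "allergy"),
    pathology = c("Epithelial ovarian cancer", "Influenza", "Melanoma",
                  "Celiac disease", "Birch allergy"),
    epitope_peptide = c("RCSDSDGLAPPQNLIRVEGNLRVEY", "", "KTWGQYWQV", "", ""),
    epitope_gene = c("TP53", "", "PMEL", "", ""),
    stringsAsFactors = FALSE))
}

# deterministic scaled-down cohort for module tests (fewer clones than the
# default stated world, same structure)
small_cohort <- function(seed = 1) {
  generate_cohort(cohort_config(seed = seed, clones_per_patient = 60L,
                                templates_per_patient = 250L))
}
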