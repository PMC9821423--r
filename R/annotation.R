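# Antigen-database annotation of cohort CDR3beta peptides: edit-distance
# matching, functional-category enrichment, per-condition prognosis tests,
# group-level cancer-match frequencies, epitope-gene matrices, V/J usage.

.ANNOTATION_CATEGORIES <- c("pathogens", "cancer", "autoimmune", "allergy", "other")

# database category background used for goodness-of-fit comparisons
.DEFAULT_CATEGORY_PROPS <- c(pathogens = 0.68, cancer = 0.16, autoimmune = 0.13,
                             allergy = 0.027, other = 0.003)

#' Levenshtein edit distance
#'
#' Standard unit-cost insertion/deletion/substitution distance between two
#' strings, computed by dynamic programming (row-rolling Wagner-Fischer).
#'
#' @param a,b Character scalars.
#' @return Non-negative integer distance; 0 iff the strings are equal.
#' @export
levenshtein_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L,
                         cur[j] + 1L,
                         prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Construct a reference annotation table
#'
#' Schema-compatible with curated TCR-antigen catalogs: one record per
#' (CDR3beta, condition) association.
#'
#' @param df data.frame with columns `cdr3_aa`, `category` (one of
#'   pathogens/cancer/autoimmune/allergy/other), `pathology`,
#'   `epitope_peptide`, `epitope_gene` (last two may be empty strings).
#' @return Validated data.frame of class `reference_db`.
#' @export
reference_db <- function(df) {
  req <- c("cdr3_aa", "category", "pathology", "epitope_peptide", "epitope_gene")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) stop("reference table lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(df$category), .ANNOTATION_CATEGORIES)
  if (length(bad)) stop("unknown category value(s): ", paste(bad, collapse = ", "))
  if (any(!nzchar(df$cdr3_aa))) stop("reference cdr3_aa must be non-empty")
  out <- as.data.frame(df)[, req]
  class(out) <- c("reference_db", class(out))
  out
}

#' Read a reference annotation TSV
#' @param path TSV file with the [reference_db()] columns.
#' @return A `reference_db` data.frame.
#' @export
read_reference_db <- function(path) {
  reference_db(data.table::fread(path, sep = "\t", header = TRUE,
                                 data.table = FALSE, na.strings = NULL))
}

#' Annotate cohort peptides against a reference database
#'
#' Matches every distinct productive cohort peptide against every reference
#' record. In `"fuzzy"` mode (curated-catalog style) a hit is any pair
#' within Levenshtein distance `max_dist` (default 1); in `"exact"` mode
#' (database style requiring a complete CDR3beta match) only identical
#' peptides hit. A (patient, peptide, record) triple is counted once even
#' when several clonotypes share the CDR3beta.
#'
#' @param reps List of [repertoire] objects.
#' @param db A [reference_db()] table.
#' @param mode `"fuzzy"` or `"exact"`.
#' @param max_dist Maximum edit distance; defaults to 1 for fuzzy, 0 for
#'   exact (exact mode enforces 0).
#' @param peptides Optional character vector restricting the query set (e.g.
#'   prognosis-associated peptides only).
#' @return data.frame of hits: `patient_id`, `cdr3_aa`, `record_index`,
#'   `ref_cdr3`, `category`, `pathology`, `epitope_peptide`, `epitope_gene`,
#'   `edit_distance`, `mode`.
#' @export
annotate_cohort <- function(reps, db, mode = c("fuzzy", "exact"),
                            max_dist = NULL, peptides = NULL) {
  mode <- match.arg(mode)
  if (is.null(max_dist)) max_dist <- if (mode == "fuzzy") 1L else 0L
  if (mode == "exact" && max_dist != 0L) stop("exact mode requires max_dist = 0")
  empty <- data.frame(patient_id = character(), cdr3_aa = character(),
                      record_index = integer(), ref_cdr3 = character(),
                      category = character(), pathology = character(),
                      epitope_peptide = character(), epitope_gene = character(),
                      edit_distance = integer(), mode = character(),
                      stringsAsFactors = FALSE)
  if (nrow(db) == 0L) {
    warning("empty reference database: no annotations")
    return(empty)
  }
  occ <- data.table::rbindlist(lapply(reps, function(r) {
    ct <- r$clonotypes[productive(r)]
    data.table::data.table(patient_id = r$patient_id, cdr3_aa = unique(ct$cdr3_aa))
  }))
  if (!is.null(peptides)) occ <- occ[occ$cdr3_aa %in% peptides]
  if (nrow(occ) == 0L) return(empty)
  queries <- unique(occ$cdr3_aa)
  if (max_dist == 0L) {
    pair <- data.table::data.table(cdr3_aa = db$cdr3_aa,
                                   record_index = seq_len(nrow(db)))
    pair <- pair[pair$cdr3_aa %in% queries]
    pair$edit_distance <- 0L
  } else {
    # all-pairs generalized edit distance; restrict to length-compatible pairs
    qlen <- nchar(queries); rlen <- nchar(db$cdr3_aa)
    pair_list <- list()
    for (L in sort(unique(qlen))) {
      qi <- which(qlen == L)
      ri <- which(abs(rlen - L) <= max_dist)
      if (!length(ri)) next
      dmat <- utils::adist(queries[qi], db$cdr3_aa[ri])
      hit <- which(dmat <= max_dist, arr.ind = TRUE)
      if (nrow(hit)) {
        pair_list[[length(pair_list) + 1L]] <- data.table::data.table(
          cdr3_aa = queries[qi][hit[, 1L]],
          record_index = ri[hit[, 2L]],
          edit_distance = as.integer(dmat[hit]))
      }
    }
    if (!length(pair_list)) return(empty)
    pair <- data.table::rbindlist(pair_list)
  }
  if (nrow(pair) == 0L) return(empty)
  hits <- merge(occ, pair, by = "cdr3_aa", allow.cartesian = TRUE)
  hits$ref_cdr3 <- db$cdr3_aa[hits$record_index]
  hits$category <- db$category[hits$record_index]
  hits$pathology <- db$pathology[hits$record_index]
  hits$epitope_peptide <- db$epitope_peptide[hits$record_index]
  hits$epitope_gene <- db$epitope_gene[hits$record_index]
  hits$mode <- mode
  hits <- unique(hits, by = c("patient_id", "cdr3_aa", "record_index"))
  data.table::setorderv(hits, c("patient_id", "cdr3_aa", "record_index"))
  data.table::setcolorder(hits, c("patient_id", "cdr3_aa", "record_index",
                                  "ref_cdr3", "category", "pathology",
                                  "epitope_peptide", "epitope_gene",
                                  "edit_distance", "mode"))
  as.data.frame(hits)
}

#' Functional-category enrichment of annotations
#'
#' Compares the observed distribution of annotation records over the five
#' functional categories with the database background using the chi-square
#' goodness-of-fit test. The default background (pathogens 68%, cancer 16%,
#' autoimmune 13%, allergy 2.7%, other 0.3%) reflects the composition of
#' the curated catalog.
#'
#' @param hits Annotation table from [annotate_cohort()].
#' @param background_props Named per-category proportions summing to 1.
#' @return List with `observed` counts, `proportions`, `statistic`, `dof`, `p`.
#' @export
category_enrichment <- function(hits, background_props = .DEFAULT_CATEGORY_PROPS) {
  if (abs(sum(background_props) - 1) > 1e-6) stop("background proportions must sum to 1")
  cats <- names(background_props)
  obs <- table(factor(hits$category, levels = cats))
  if (sum(obs) == 0L) stop("zero annotations: enrichment undefined")
  gof <- chi_square_gof(as.numeric(obs), as.numeric(background_props))
  list(observed = stats::setNames(as.integer(obs), cats),
       proportions = stats::setNames(as.numeric(obs) / sum(obs), cats),
       background = background_props,
       statistic = gof$statistic, dof = gof$dof, p = gof$p)
}

#' Per-condition prognosis association of annotation counts
#'
#' For each pathologic condition, the per-patient number of annotation
#' records is normalized (by default to the patient's number of unique
#' productive rearrangements) and compared across the four prognosis groups
#' with the Kruskal-Wallis test; conditions significant at `alpha` get a
#' Dunn post-hoc. Conditions annotated in fewer than two patients are
#' skipped.
#'
#' @param hits Annotation table from [annotate_cohort()].
#' @param reps List of [repertoire] objects (normalization denominators).
#' @param labels [prognosis_labels()] table.
#' @param normalize `"rearrangements"` (per-patient unique productive
#'   rearrangements, default) or `"annotations"` (patient's total annotation
#'   records).
#' @param alpha Post-hoc trigger threshold, default 0.05.
#' @return List with `table` (per-condition KW results, skipped conditions
#'   flagged) and `dunn` (named list of post-hoc tables for significant
#'   conditions).
#' @export
condition_prognosis_test <- function(hits, reps, labels,
                                     normalize = c("rearrangements", "annotations"),
                                     alpha = 0.05) {
  normalize <- match.arg(normalize)
  ids <- vapply(reps, function(r) r$patient_id, character(1))
  lab <- stats::setNames(as.character(labels$label), labels$patient_id)[ids]
  if (anyNA(lab)) stop("missing prognosis label for some patients")
  denom <- if (normalize == "rearrangements") {
    vapply(reps, function(r) sum(productive(r) & r$clonotypes$templates > 0), numeric(1))
  } else {
    cnt <- table(factor(hits$patient_id, levels = ids))
    pmax(as.numeric(cnt), 1)
  }
  names(denom) <- ids
  h <- data.table::as.data.table(hits)
  conditions <- sort(unique(h$pathology))
  rows <- list(); dunn <- list()
  for (cond in conditions) {
    sub <- h[h$pathology == cond]
    n_pat <- data.table::uniqueN(sub$patient_id)
    if (n_pat < 2L) {
      rows[[cond]] <- data.frame(pathology = cond, n_patients = n_pat,
                                 kw_statistic = NA_real_, kw_p = NA_real_,
                                 note = "skipped: <2 annotated patients")
      next
    }
    cnt <- table(factor(sub$patient_id, levels = ids))
    norm <- as.numeric(cnt) / denom
    kw <- kruskal_wallis(split(norm, lab))
    note <- ""
    if (kw$p < alpha) {
      dunn[[cond]] <- dunn_posthoc(split(norm, lab))
      note <- "significant"
    }
    rows[[cond]] <- data.frame(pathology = cond, n_patients = n_pat,
                               kw_statistic = kw$statistic, kw_p = kw$p, note = note)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(table = tab, dunn = dunn)
}

#' Per-group frequency of cancer-matched peptides
#'
#' For each prognosis group, the number of distinct (patient, peptide)
#' occurrences matching a cancer-associated database record exactly, divided
#' by the number of patients in the group.
#'
#' @param hits Exact-mode annotation table (rows with `category == "cancer"`
#'   are used; others are ignored).
#' @param labels [prognosis_labels()] table for the whole cohort.
#' @return data.frame `label`, `n_patients`, `n_matches`, `frequency`.
#' @export
cancer_match_group_frequency <- function(hits, labels) {
  if (nrow(hits) && any(hits$mode != "exact")) {
    stop("cancer_match_group_frequency expects exact-mode hits")
  }
  cancer <- hits[hits$category == "cancer", , drop = FALSE]
  occ <- unique(cancer[, c("patient_id", "cdr3_aa")])
  lab <- stats::setNames(as.character(labels$label), labels$patient_id)
  sizes <- table(factor(as.character(labels$label),
                        levels = c("worst", "poor", "good", "excellent")))
  empty <- sizes == 0
  if (any(empty)) warning("excluding empty prognosis group(s): ",
                          paste(names(sizes)[empty], collapse = ", "))
  grp <- factor(lab[occ$patient_id], levels = names(sizes)[!empty])
  matches <- table(grp)
  data.frame(label = names(sizes)[!empty],
             n_patients = as.integer(sizes[!empty]),
             n_matches = as.integer(matches),
             frequency = as.numeric(matches) / as.integer(sizes[!empty]),
             stringsAsFactors = FALSE)
}

#' Patient x epitope-gene presence matrix
#'
#' Binary presence of exact-match annotations per epitope gene; genes found
#' in strictly more than `prevalence_cutoff` of patients are excluded as
#' uninformative. Columns are ordered by decreasing patient count; rows are
#' grouped by prognosis and, within a group, ordered by decreasing number of
#' genes carried.
#'
#' @param hits Exact-mode annotation table.
#' @param labels [prognosis_labels()] table (defines the full patient set).
#' @param prevalence_cutoff Fraction of patients above which a gene is
#'   dropped (strict inequality), default 0.75.
#' @return Binary matrix (possibly 0 columns) with patients as rows.
#' @export
epitope_gene_matrix <- function(hits, labels, prevalence_cutoff = 0.75) {
  patients <- labels$patient_id
  h <- hits[nzchar(hits$epitope_gene), , drop = FALSE]
  occ <- unique(h[, c("patient_id", "epitope_gene")])
  genes <- sort(unique(occ$epitope_gene))
  mat <- matrix(0L, nrow = length(patients), ncol = length(genes),
                dimnames = list(patients, genes))
  if (nrow(occ)) mat[cbind(match(occ$patient_id, patients),
                           match(occ$epitope_gene, genes))] <- 1L
  keep <- colSums(mat) <= prevalence_cutoff * length(patients)
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat)) mat <- mat[, order(-colSums(mat), colnames(mat)), drop = FALSE]
  ord <- order(as.integer(labels$label), -rowSums(mat), labels$patient_id)
  mat[ord, , drop = FALSE]
}

#' Per-patient V- and J-segment usage
#'
#' Frequencies of gene-segment calls over productive clonotypes (unresolved
#' calls pooled into `"unresolved"`); optionally restricted to clonotypes
#' carrying a given CDR3beta peptide, as used when asking which V segments
#' originate a known peptide.
#'
#' @param reps List of [repertoire] objects.
#' @param cdr3 Optional CDR3beta peptide restricting the clonotype set.
#' @param weight `"clonotypes"` (default) or `"templates"`.
#' @return List with `v` and `j`: data.frames `patient_id`, `gene`, `freq`
#'   (per-patient frequencies sum to 1; patients with no qualifying
#'   clonotypes are omitted).
#' @export
vj_usage <- function(reps, cdr3 = NULL, weight = c("clonotypes", "templates")) {
  weight <- match.arg(weight)
  one_side <- function(col) {
    data.table::rbindlist(lapply(reps, function(r) {
      ct <- r$clonotypes[productive(r)]
      if (!is.null(cdr3)) ct <- ct[ct$cdr3_aa == cdr3]
      if (nrow(ct) == 0L) return(NULL)
      w <- if (weight == "templates") ct$templates else rep(1, nrow(ct))
      agg <- tapply(w, ct[[col]], sum)
      data.table::data.table(patient_id = r$patient_id, gene = names(agg),
                             freq = as.numeric(agg) / sum(w))
    }))
  }
  list(v = as.data.frame(one_side("v_gene")), j = as.data.frame(one_side("j_gene")))
}
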