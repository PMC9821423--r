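# Synthetic-cohort generation with planted ground truth. The generator
# emulates the four pipeline inputs (clonotype tables, antigen reference
# database, clinical table, flow-marker table) under a fully seeded model:
# per-group power-law clone frequencies (steeper in unfavorable groups,
# hence lower entropy and higher top-k dominance), motif-sharing clones
# planted into chosen prognosis groups, database-matching clones planted
# denser in the excellent group, group-shifted flow markers and per-group
# exponential survival.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.random_cdr3 <- function(n, min_len = 10L, max_len = 18L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(L) {
    paste0("C", paste(sample(.AA20, L - 2L, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

.random_cdr3_avoiding <- function(n, motifs, min_len = 10L, max_len = 18L) {
  out <- character(0)
  while (length(out) < n) {
    cand <- .random_cdr3(n - length(out), min_len, max_len)
    if (length(motifs)) {
      bad <- Reduce(`|`, lapply(motifs, function(m) grepl(m, cand, fixed = TRUE)))
      cand <- cand[!bad]
    }
    out <- c(out, cand)
  }
  out
}

.V_GENES <- sprintf("TCRBV%02d-01*01", 1:30)
.J_GENES <- sprintf("TCRBJ%02d-0%d*01", rep(1:2, each = 7), rep(1:7, 2))

# fixed sentinel record used by end-to-end tests: a known ovarian-cancer
# CDR3beta and its TP53 neoantigen epitope
.SENTINEL_RECORD <- data.frame(
  cdr3_aa = "CASSLVNTEAFF", category = "cancer",
  pathology = "Epithelial ovarian cancer",
  epitope_peptide = "RCSDSDGLAPPQNLIRVEGNLRVEY", epitope_gene = "TP53",
  stringsAsFactors = FALSE)

.CANCER_PATHOLOGIES <- c("Epithelial ovarian cancer", "Melanoma",
                         "Breast cancer", "Colorectal cancer")
.CANCER_GENES <- c("TP53", "AKAP13", "SMARCD3", "TKT", "KRAS", "NRAS", "TEAD1")
.OTHER_PATHOLOGIES <- list(
  pathogens = c("Influenza", "Cytomegalovirus (CMV)", "Epstein Barr virus (EBV)",
                "M. tuberculosis", "HIV"),
  autoimmune = c("Celiac disease", "Multiple sclerosis", "Diabetes Type 1"),
  allergy = c("Birch allergy", "Peanut allergy"),
  other = c("Unknown"))

#' Generate a synthetic antigen reference database
#'
#' Random CDR3-like sequences (length 10-18, C...F convention) with
#' multinomial category assignment matching the curated-catalog background
#' (pathogens 68%, cancer 16%, autoimmune 13%, allergy 2.7%, other 0.3%),
#' plus a fixed sentinel ovarian-cancer/TP53 record for end-to-end tests.
#'
#' @param n_records Number of random records, default 400.
#' @param category_props Named proportions over the five categories.
#' @param seed Integer seed.
#' @param eoc_fraction Fraction of cancer records annotated as epithelial
#'   ovarian cancer, default 0.3.
#' @return A [reference_db()] table (`n_records + 1` rows).
#' @export
generate_reference_db <- function(n_records = 400L,
                                  category_props = c(pathogens = 0.68,
                                                     cancer = 0.16,
                                                     autoimmune = 0.13,
                                                     allergy = 0.027,
                                                     other = 0.003),
                                  seed = 1L, eoc_fraction = 0.3) {
  if (abs(sum(category_props) - 1) > 1e-6) stop("category proportions must sum to 1")
  if (n_records < length(category_props)) stop("n_records below the number of categories")
  set.seed(seed)
  cats <- sample(names(category_props), n_records, replace = TRUE,
                 prob = category_props)
  cdr3 <- .random_cdr3(n_records)
  pathology <- character(n_records)
  gene <- character(n_records)
  peptide <- character(n_records)
  for (i in seq_len(n_records)) {
    if (cats[i] == "cancer") {
      pathology[i] <- if (stats::runif(1) < eoc_fraction) "Epithelial ovarian cancer"
                      else sample(.CANCER_PATHOLOGIES[-1L], 1L)
      gene[i] <- sample(.CANCER_GENES, 1L)
      peptide[i] <- paste(sample(.AA20, 9L, replace = TRUE), collapse = "")
    } else {
      pathology[i] <- sample(.OTHER_PATHOLOGIES[[cats[i]]], 1L)
      gene[i] <- ""
      peptide[i] <- ""
    }
  }
  reference_db(rbind(.SENTINEL_RECORD,
                     data.frame(cdr3_aa = cdr3, category = cats,
                                pathology = pathology, epitope_peptide = peptide,
                                epitope_gene = gene, stringsAsFactors = FALSE)))
}

#' Generate a reference CDR3 repertoire for motif enrichment
#'
#' Random background peptides guaranteed not to contain any of the supplied
#' motifs, emulating an unselected T-cell reference set (e.g. sorted CD4 or
#' CD8 repertoires).
#'
#' @param n Number of sequences, default 2000.
#' @param seed Integer seed.
#' @param exclude_motifs Character vector of k-mers the reference must avoid.
#' @return Character vector of CDR3 peptides.
#' @export
generate_reference_repertoire <- function(n = 2000L, seed = 1L,
                                          exclude_motifs = character()) {
  set.seed(seed)
  .random_cdr3_avoiding(n, exclude_motifs)
}

#' Default synthetic-cohort configuration
#'
#' The stated world of the generator: a 47-patient cohort in four prognosis
#' groups (worst 4, poor 16, good 13, excellent 14); per-group power-law
#' clone-frequency exponents making unfavorable repertoires more oligoclonal
#' (lower entropy, higher top-k frequency); six planted 4-mer motifs, three
#' carried only by excellent-group patients and three only by poor/worst
#' patients at 80% carriage, inserted as interior k-mers of >1-read clones;
#' exact database-matching clones planted twice as densely in excellent
#' patients as elsewhere, with epithelial-ovarian-cancer records drawn only
#' for excellent patients; per-group exponential survival hazards and a
#' 72-month administrative censoring horizon (roughly 30% censoring);
#' log-normal flow markers with CD8 up and Treg down in unfavorable groups
#' (higher CD8/Treg ratio).
#'
#' @param seed Integer seed.
#' @param ... Overrides for any listed component.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L, ...) {
  cfg <- list(
    group_sizes = c(worst = 4L, poor = 16L, good = 13L, excellent = 14L),
    clones_per_patient = 130L,
    templates_per_patient = 600L,
    powerlaw_alpha = c(worst = 1.30, poor = 1.15, good = 0.90, excellent = 0.75),
    # pairwise-disjoint 2-mer composition keeps the planted specificity
    # groups structurally separated (no submotif can bridge two clusters)
    planted_motifs = data.frame(
      motif = c("QWDH", "KYRT", "WNQV", "HDYK", "RMGY", "VKHW"),
      carrier_groups = c("excellent", "excellent", "excellent",
                         "poor+worst", "poor+worst", "poor+worst"),
      carrier_fraction = 0.8,
      stringsAsFactors = FALSE),
    planted_matches = c(excellent = 6L, other = 3L),
    motif_templates = 4L,
    match_templates = 3L,
    hazards = c(worst = 1 / 12, poor = 1 / 24, good = 1 / 60, excellent = 1 / 120),
    censor_horizon = 72,
    flow_means_log2 = c(cd4 = 5, cd8 = 4.5, cd4_foxp3 = 2,
                        cd8_ctla4 = 1, cd4_icos = 1, cd8_ki67 = 1),
    flow_sd_log2 = 0.5,
    flow_shift_log2 = c(cd8 = 0.8, cd4_foxp3 = -0.8),  # applied to worst/poor
    reference_db_records = 400L,
    seed = as.integer(seed)
  )
  # 4-mer motifs: strip the XX placeholders used to keep widths aligned
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  for (g in unique(unlist(strsplit(cfg$planted_motifs$carrier_groups, "+", fixed = TRUE)))) {
    if (!g %in% names(cfg$group_sizes)) stop("carrier group not in group_sizes: ", g)
  }
  if (any(cfg$group_sizes <= 0)) stop("group sizes must be positive")
  if (any(cfg$planted_motifs$carrier_fraction < 0 |
          cfg$planted_motifs$carrier_fraction > 1)) {
    stop("carrier fractions must lie in [0, 1]")
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' @param config A [cohort_config()].
#' @return List with `repertoires` (list of [repertoire]), `clinical`
#'   (data.frame `patient_id`, `rfs_months`, `responded`, `os_months`,
#'   `os_event`, `debulking`), `flow` (data.frame, patients x markers),
#'   `labels` ([prognosis_labels()] table), `reference_db`, and `truth`
#'   (list: `labels`, `motif_clusters`, `planted_matches`, `hazards`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  gs <- config$group_sizes
  n <- sum(gs)
  patient_id <- sprintf("P%02d", seq_len(n))
  group <- rep(names(gs), gs)

  db <- generate_reference_db(config$reference_db_records,
                              seed = config$seed + 1000L)
  cancer_db <- db[db$category == "cancer", , drop = FALSE]
  cancer_non_eoc <- cancer_db[cancer_db$pathology != "Epithelial ovarian cancer", ,
                              drop = FALSE]

  motifs <- config$planted_motifs
  # planted motif-sharing clones: one clone per carrier patient per motif
  motif_clusters <- vector("list", nrow(motifs))
  planted <- vector("list", n)
  for (mi in seq_len(nrow(motifs))) {
    carriers_pool <- which(group %in%
                             strsplit(motifs$carrier_groups[mi], "+", fixed = TRUE)[[1L]])
    n_carry <- max(2L, round(motifs$carrier_fraction[mi] * length(carriers_pool)))
    carriers <- sort(sample(carriers_pool, n_carry))
    members <- data.frame(patient_id = patient_id[carriers],
                          cdr3_aa = vapply(carriers, function(i) {
                            paste0("CAS",
                                   paste(sample(.AA20, 2L, replace = TRUE), collapse = ""),
                                   motifs$motif[mi],
                                   paste(sample(.AA20, 3L, replace = TRUE), collapse = ""),
                                   "EQFF")
                          }, character(1)),
                          stringsAsFactors = FALSE)
    motif_clusters[[mi]] <- list(motif = motifs$motif[mi],
                                 carrier_groups = motifs$carrier_groups[mi],
                                 members = members)
    for (r in seq_len(nrow(members))) {
      i <- carriers[r]
      planted[[i]] <- rbind(planted[[i]],
                            data.frame(cdr3_aa = members$cdr3_aa[r],
                                       templates = config$motif_templates,
                                       kind = "motif", stringsAsFactors = FALSE))
    }
  }

  # planted database-matching clones, denser in the excellent group;
  # epithelial-ovarian-cancer records are drawn only for excellent patients
  planted_matches <- vector("list", n)
  for (i in seq_len(n)) {
    if (group[i] == "excellent") {
      k <- config$planted_matches[["excellent"]]
      pool <- cancer_db
    } else {
      k <- config$planted_matches[["other"]]
      pool <- cancer_non_eoc
    }
    k <- min(k, nrow(pool))
    rows <- sample(nrow(pool), k)
    planted_matches[[i]] <- data.frame(patient_id = patient_id[i],
                                       cdr3_aa = pool$cdr3_aa[rows],
                                       stringsAsFactors = FALSE)
    planted[[i]] <- rbind(planted[[i]],
                          data.frame(cdr3_aa = pool$cdr3_aa[rows],
                                     templates = config$match_templates,
                                     kind = "match", stringsAsFactors = FALSE))
  }

  # background clones under the per-group power law
  reps <- vector("list", n)
  for (i in seq_len(n)) {
    nc <- config$clones_per_patient
    alpha <- config$powerlaw_alpha[[group[i]]]
    w <- (seq_len(nc))^(-alpha)
    counts <- as.integer(stats::rmultinom(1L, config$templates_per_patient, w / sum(w)))
    keep <- counts > 0
    bg <- data.frame(cdr3_aa = .random_cdr3_avoiding(sum(keep), motifs$motif),
                     templates = counts[keep], stringsAsFactors = FALSE)
    extra <- planted[[i]]
    clones <- if (is.null(extra)) bg else rbind(bg, extra[, c("cdr3_aa", "templates")])
    nt <- nrow(clones)
    tab <- data.frame(
      cdr3_aa = clones$cdr3_aa,
      v_gene = sample(.V_GENES, nt, replace = TRUE),
      d_gene = "unresolved",
      j_gene = sample(.J_GENES, nt, replace = TRUE),
      templates = clones$templates,
      frame = "in-frame", stringsAsFactors = FALSE)
    # a realistic nonproductive tail
    n_np <- max(3L, round(0.1 * nt))
    np <- data.frame(cdr3_aa = .random_cdr3_avoiding(n_np, motifs$motif),
                     v_gene = sample(.V_GENES, n_np, replace = TRUE),
                     d_gene = "unresolved",
                     j_gene = sample(.J_GENES, n_np, replace = TRUE),
                     templates = sample(1:3, n_np, replace = TRUE),
                     frame = sample(c("out-of-frame", "stop"), n_np, replace = TRUE),
                     stringsAsFactors = FALSE)
    reps[[i]] <- repertoire(patient_id[i], rbind(tab, np))
  }

  # clinical: RFS consistent with the group definition, OS exponential
  rfs <- numeric(n); responded <- logical(n)
  for (i in seq_len(n)) {
    switch(group[i],
           worst = { rfs[i] <- stats::runif(1, 1, 5.5); responded[i] <- FALSE },
           poor = { rfs[i] <- stats::runif(1, 1, 5.5); responded[i] <- TRUE },
           good = { rfs[i] <- stats::runif(1, 6.5, 12); responded[i] <- TRUE },
           excellent = { rfs[i] <- stats::runif(1, 13, 60); responded[i] <- TRUE })
  }
  os_true <- stats::rexp(n, rate = config$hazards[group])
  os_event <- os_true <= config$censor_horizon
  os_months <- pmin(os_true, config$censor_horizon)
  # survival must not undercut the observed recurrence-free interval
  os_months <- pmax(os_months, rfs + 0.5)
  clinical <- data.frame(patient_id = patient_id, rfs_months = round(rfs, 2),
                         responded = responded,
                         os_months = round(os_months, 2), os_event = os_event,
                         debulking = sample(c("optimal", "suboptimal"), n,
                                            replace = TRUE, prob = c(0.6, 0.4)),
                         stringsAsFactors = FALSE)
  labels <- prognosis_labels(clinical)

  # flow markers: log-normal percentages with unfavorable-group shifts
  unfavorable <- group %in% c("worst", "poor")
  flow <- sapply(names(config$flow_means_log2), function(mk) {
    shift <- if (mk %in% names(config$flow_shift_log2))
      config$flow_shift_log2[[mk]] else 0
    mu <- config$flow_means_log2[[mk]] + ifelse(unfavorable, shift, 0)
    2^stats::rnorm(n, mu, config$flow_sd_log2)
  })
  rownames(flow) <- patient_id
  flow <- as.data.frame(flow)
  flow$cd8_treg <- cd8_treg_ratio(flow)

  list(repertoires = reps, clinical = clinical, flow = flow, labels = labels,
       reference_db = db,
       truth = list(labels = labels, motif_clusters = motif_clusters,
                    planted_matches = do.call(rbind, planted_matches),
                    hazards = config$hazards, config = config))
}

#' Write a generated cohort to disk in the consumed input formats
#'
#' One immunoSEQ-style TSV per patient under `dir/repertoires/`, the
#' reference database TSV, the clinical and flow CSVs, and the planted
#' truth as JSON.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  rep_dir <- file.path(dir, "repertoires")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  for (r in cohort$repertoires) {
    ct <- r$clonotypes
    out <- data.frame(amino_acid = ct$cdr3_aa, v_gene = ct$v_gene,
                      d_gene = ct$d_gene, j_gene = ct$j_gene,
                      templates = ct$templates, frame_type = ct$frame,
                      stringsAsFactors = FALSE)
    utils::write.table(out, file.path(rep_dir, paste0(r$patient_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cohort$reference_db, file.path(dir, "reference_db.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  flow <- cbind(patient_id = rownames(cohort$flow), cohort$flow)
  utils::write.csv(flow, file.path(dir, "flow.csv"), row.names = FALSE,
                   quote = FALSE)
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#' @param dir Directory produced by [write_cohort()].
#' @return List with `repertoires`, `clinical`, `flow`, `labels`,
#'   `reference_db`.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(file.path(dir, "repertoires"), full.names = TRUE,
                           pattern = "\\.tsv$"))
  reps <- lapply(files, function(f)
    parse_immunoseq_table(f, tools::file_path_sans_ext(basename(f))))
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  flow <- utils::read.csv(file.path(dir, "flow.csv"), stringsAsFactors = FALSE)
  rownames(flow) <- flow$patient_id
  flow$patient_id <- NULL
  list(repertoires = reps, clinical = clinical, flow = flow,
       labels = prognosis_labels(clinical),
       reference_db = read_reference_db(file.path(dir, "reference_db.tsv")))
}

#' Compare pipeline outputs against the planted truth
#'
#' Matches planted motif clusters to recovered specificity clusters by the
#' Jaccard index of their (patient, peptide) member sets (threshold 0.5) and
#' checks the recovered prognosis direction; reports cluster-recovery
#' sensitivity and false-discovery rate, plus survival hazard-ratio recovery
#' (Cox fit of unfavorable vs favorable prognosis against the planted
#' hazards).
#'
#' @param truth `truth` component of [generate_cohort()].
#' @param cluster_table Output of [associate_clusters()].
#' @param clusters The clusters the table was computed from.
#' @param clinical Clinical table of the same cohort.
#' @param jaccard_min Member-overlap threshold, default 0.5.
#' @return List with `cluster_sensitivity`, `cluster_fdr`, `matches`
#'   (per planted cluster), `hr_estimated`, `hr_true`.
#' @export
truth_report <- function(truth, cluster_table, clusters, clinical,
                         jaccard_min = 0.5) {
  if (!all(unique(truth$labels$patient_id) %in% clinical$patient_id)) {
    stop("cohort ids in truth and clinical do not match")
  }
  planted <- truth$motif_clusters
  rec_sets <- lapply(clusters, function(cl)
    paste(cl$members$patient_id, cl$members$cdr3_aa))
  names(rec_sets) <- vapply(clusters, `[[`, character(1), "cluster_id")
  assoc <- cluster_table$associated_with
  names(assoc) <- cluster_table$cluster_id
  match_rows <- lapply(planted, function(pl) {
    pset <- paste(pl$members$patient_id, pl$members$cdr3_aa)
    jac <- vapply(rec_sets, function(rs)
      length(intersect(pset, rs)) / length(union(pset, rs)), numeric(1))
    best <- if (length(jac)) which.max(jac) else integer(0)
    expected_dir <- if (pl$carrier_groups == "excellent") "excellent" else "poor/worst"
    hit <- length(best) > 0 && jac[best] >= jaccard_min
    data.frame(motif = pl$motif, expected = expected_dir,
               jaccard = if (hit) jac[best] else max(jac, 0),
               matched_cluster = if (hit) names(rec_sets)[best] else NA_character_,
               recovered = hit,
               direction_ok = hit && identical(unname(assoc[names(rec_sets)[best]]),
                                               expected_dir),
               stringsAsFactors = FALSE)
  })
  matches <- do.call(rbind, c(match_rows, list(make.row.names = FALSE)))
  sens <- if (nrow(matches)) mean(matches$direction_ok) else 0
  called <- cluster_table$cluster_id[cluster_table$associated_with != "none"]
  true_pos <- stats::na.omit(matches$matched_cluster[matches$direction_ok])
  fdr <- if (length(called)) mean(!called %in% true_pos) else 0
  lab <- truth$labels$label[match(clinical$patient_id, truth$labels$patient_id)]
  unfav <- as.integer(lab %in% c("worst", "poor"))
  hr_est <- tryCatch({
    fit <- cox_ph_fit(data.frame(time = clinical$os_months,
                                 event = clinical$os_event, unfav = unfav),
                      "unfav")
    fit$coefficients$hr[1L]
  }, error = function(e) NA_real_)
  hz <- truth$hazards
  hr_true <- mean(hz[c("worst", "poor")]) / mean(hz[c("good", "excellent")])
  list(cluster_sensitivity = sens, cluster_fdr = fdr, matches = matches,
       hr_estimated = hr_est, hr_true = unname(hr_true))
}
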