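test_that("levenshtein_distance matches the recursive edit-script oracle", {
  expect_equal(levenshtein_distance("CASSLVNTEAFF", "CASSLVNTEAFF"), 0L)
  expect_equal(levenshtein_distance("CASSLVNTEAFF", "CASSLANTEAFF"), 1L)
  expect_equal(levenshtein_distance("CASS", "CAT"), 2L)
  expect_equal(levenshtein_distance("", "ABC"), 3L)
  set.seed(3)
  alphabet <- c("A", "C", "G", "T")
  for (i in 1:200) {
    a <- paste(sample(alphabet, sample(0:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(0:6, 1), replace = TRUE), collapse = "")
    expect_equal(levenshtein_distance(a, b), lev_oracle(a, b))
    expect_equal(levenshtein_distance(a, b), levenshtein_distance(b, a))
  }
})

test_that("annotate_cohort honours mode and distance threshold", {
  rep <- make_rep("P01", c(5, 3), cdr3 = c("CASSLINTEAFF", "CAWSVSDLAKNIQYF"))
  db <- make_ref_db()
  fuzzy <- annotate_cohort(list(rep), db, mode = "fuzzy")
  # CASSLINTEAFF is distance 1 from CASSLVNTEAFF (two records)
  expect_equal(sum(fuzzy$cdr3_aa == "CASSLINTEAFF"), 2L)
  expect_true(all(fuzzy$edit_distance[fuzzy$cdr3_aa == "CASSLINTEAFF"] == 1L))
  exact <- annotate_cohort(list(rep), db, mode = "exact")
  expect_false("CASSLINTEAFF" %in% exact$cdr3_aa)
  expect_true("CAWSVSDLAKNIQYF" %in% exact$cdr3_aa)
  expect_true(all(exact$edit_distance == 0L))
  # identical query hits in both modes at distance 0
  rep2 <- make_rep("P02", 4, cdr3 = "CASSLVNTEAFF")
  for (mode in c("fuzzy", "exact")) {
    hits <- annotate_cohort(list(rep2), db, mode = mode)
    expect_equal(sort(unique(hits$edit_distance)), 0L)
    expect_equal(nrow(hits), 2L)
  }
  expect_warning(out <- annotate_cohort(list(rep), db[0, ], mode = "exact"), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("fuzzy annotation at max_dist 0 equals exact annotation", {
  co <- small_cohort(2)
  f0 <- annotate_cohort(co$repertoires, co$reference_db, mode = "fuzzy", max_dist = 0L)
  ex <- annotate_cohort(co$repertoires, co$reference_db, mode = "exact")
  expect_equal(f0[, c("patient_id", "cdr3_aa", "record_index", "edit_distance")],
               ex[, c("patient_id", "cdr3_aa", "record_index", "edit_distance")])
})

test_that("reported fuzzy distances equal levenshtein_distance recomputed", {
  co <- small_cohort(3)
  hits <- annotate_cohort(co$repertoires, co$reference_db, mode = "fuzzy")
  pick <- hits[sample.int(nrow(hits), min(50, nrow(hits))), ]
  recomputed <- mapply(levenshtein_distance, pick$cdr3_aa, pick$ref_cdr3)
  expect_equal(unname(recomputed), pick$edit_distance)
})

test_that("category_enrichment matches an independent summation oracle", {
  bg <- c(pathogens = 0.68, cancer = 0.16, autoimmune = 0.13,
          allergy = 0.027, other = 0.003)
  mk_hits <- function(counts) {
    data.frame(category = rep(names(bg), counts))
  }
  # observed exactly proportional to background
  prop <- mk_hits(c(680, 160, 130, 27, 3))
  res0 <- category_enrichment(prop, bg)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # observed (68,16,13,3,0) at n = 100: independent term-by-term sum
  res <- category_enrichment(mk_hits(c(68, 16, 13, 3, 0)), bg)
  E <- 100 * bg
  oracle <- sum((c(68, 16, 13, 3, 0) - E)^2 / E)
  expect_equal(res$statistic, oracle, tolerance = 1e-12)
  expect_equal(res$dof, 4L)
  expect_error(category_enrichment(mk_hits(rep(0, 5)), bg), "zero annotations")
})

test_that("condition-level prognosis test flags the planted condition only", {
  ids <- sprintf("P%02d", 1:12)
  labels <- make_labels(ids, rep(c("worst", "poor", "good", "excellent"), each = 3))
  reps <- lapply(ids, function(id) make_rep(id, rep(2, 20)))
  eoc <- data.frame(patient_id = rep(ids[10:12], each = 5),
                    pathology = "Epithelial ovarian cancer")
  flu <- data.frame(patient_id = rep(ids, 2), pathology = "Influenza")
  one <- data.frame(patient_id = ids[1], pathology = "Rare condition")
  hits <- rbind(eoc, flu, one)
  res <- condition_prognosis_test(hits, reps, labels)
  tab <- res$table
  expect_lt(tab$kw_p[tab$pathology == "Epithelial ovarian cancer"], 0.05)
  expect_gt(tab$kw_p[tab$pathology == "Influenza"], 0.05)
  expect_match(tab$note[tab$pathology == "Rare condition"], "skipped")
  expect_true("Epithelial ovarian cancer" %in% names(res$dunn))
})

test_that("cancer match frequency implements the per-group formula", {
  ids <- sprintf("P%02d", 1:20)
  labels <- make_labels(ids, rep(c("worst", "poor", "good", "excellent"), each = 5))
  # 10 distinct matched occurrences in excellent (2.0 per patient), none in worst
  hits <- data.frame(patient_id = rep(ids[16:20], each = 2),
                     cdr3_aa = paste0("CASS", LETTERS[1:10], "F"),
                     category = "cancer", mode = "exact",
                     stringsAsFactors = FALSE)
  res <- cancer_match_group_frequency(hits, labels)
  expect_equal(res$frequency[res$label == "excellent"], 2)
  expect_equal(res$frequency[res$label == "worst"], 0)
  expect_error(cancer_match_group_frequency(transform(hits, mode = "fuzzy"), labels),
               "exact")
})

test_that("epitope gene matrix applies the strict prevalence cutoff", {
  ids <- sprintf("P%02d", 1:8)
  labels <- make_labels(ids, rep(c("poor", "excellent"), each = 4))
  hits <- rbind(
    data.frame(patient_id = ids[1:7], epitope_gene = "TP53"),   # 7/8 = 87.5%
    data.frame(patient_id = ids[1:6], epitope_gene = "KRAS"),   # 6/8 = 75% exactly
    data.frame(patient_id = ids[1:2], epitope_gene = "TKT"))
  hits$cdr3_aa <- paste0("CASS", seq_len(nrow(hits)), "F")
  mat <- epitope_gene_matrix(hits, labels, prevalence_cutoff = 0.75)
  expect_false("TP53" %in% colnames(mat))     # strictly above 75%: excluded
  expect_true("KRAS" %in% colnames(mat))      # exactly 75%: retained
  expect_equal(colnames(mat), c("KRAS", "TKT"))  # ordered by patient count
  empty <- epitope_gene_matrix(hits[0, ], labels)
  expect_equal(ncol(empty), 0L)
  expect_equal(nrow(empty), 8L)
})

test_that("V/J usage frequencies are normalized per patient", {
  rep <- make_rep("P01", c(4, 6), v = c("TCRBV11-02*02", "TCRBV07-08*01"))
  usage <- vj_usage(list(rep))
  v <- usage$v
  expect_equal(sum(v$freq[v$patient_id == "P01"]), 1)
  single <- vj_usage(list(make_rep("P02", 5, v = "TCRBV11-02*02")))
  expect_equal(single$v$freq, 1)
  expect_equal(single$v$gene, "TCRBV11-02*02")
  # restriction to one peptide
  rep3 <- make_rep("P03", c(2, 2), cdr3 = c("CASSLVNTEAFF", "CASSOTHERF"),
                   v = c("TCRBV11-02*02", "TCRBV05-01*01"))
  restricted <- vj_usage(list(rep3), cdr3 = "CASSLVNTEAFF")
  expect_equal(restricted$v$gene, "TCRBV11-02*02")
  expect_equal(restricted$v$freq, 1)
})
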