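test_that("Kruskal-Wallis matches the hand-evaluated rank formula", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$dof, 2L)
  # all values identical
  flat <- kruskal_wallis(list(rep(5, 3), rep(5, 3), rep(5, 3)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  # agreement with stats::kruskal.test on tied data
  set.seed(21)
  for (i in 1:10) {
    g <- list(sample(1:5, 8, TRUE), sample(1:5, 6, TRUE), sample(1:5, 7, TRUE))
    ours <- kruskal_wallis(g)
    ref <- stats::kruskal.test(g)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("KW is invariant under strictly monotone transforms", {
  set.seed(31)
  g <- list(rnorm(8), rnorm(6, 1), rnorm(7, 2))
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, function(x) exp(3 * x)))$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("Dunn post-hoc behaves on forced orderings and adjustments", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- dunn_posthoc(g)
  extreme <- res[res$group_a == "a" & res$group_b == "c", ]
  expect_equal(max(abs(res$z)), abs(extreme$z))
  bh <- dunn_posthoc(g, adjust = "BH")
  expect_true(all(bh$p_adjusted >= bh$p - 1e-15))
  expect_message(dunn_posthoc(list(a = 1:3, b = numeric(), c = 4:6)), "empty")
})

test_that("Fisher exact p matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 3, 0, 4), 2)), 1)
  set.seed(41)
  for (i in 1:50) {
    tab <- matrix(sample(0:10, 4, TRUE), 2)
    if (sum(tab) == 0) next
    ours <- fisher_exact_2x2(tab)
    expect_equal(ours, fisher_oracle(tab), tolerance = 1e-12)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(ours, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  }
  expect_error(fisher_exact_2x2(matrix(c(1.5, 0, 0, 2), 2)), "integer")
})

test_that("chi-square GOF follows the defining sum", {
  prop <- chi_square_gof(c(50, 50), c(0.5, 0.5))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)
  res <- chi_square_gof(c(10, 0), c(0.5, 0.5))
  expect_equal(res$statistic, 10)
  expect_error(chi_square_gof(5, 1), "two categories")
  # zero-expectation categories are dropped from the dof
  res2 <- chi_square_gof(c(8, 2, 0), c(0.8, 0.2, 0))
  expect_equal(res2$dof, 1L)
  expect_equal(res2$statistic, 0)
})

test_that("Pearson correlation matches hand computation and cor.test", {
  expect_equal(pearson_r(1:4, 2 * (1:4) + 1)$r, 1)
  expect_equal(pearson_r(1:4, -(1:4))$r, -1)
  res <- pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  ct <- stats::cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  flagged <- pearson_r(rep(1, 5), 1:5)
  expect_equal(flagged$flag, "zero-variance")
  expect_true(is.na(flagged$r))
})

test_that("prognosis labels implement the RFS rules with the 6-month convention", {
  clin <- data.frame(patient_id = c("a", "b", "c", "d", "e"),
                     rfs_months = c(3, 3, 6, 9, 13),
                     responded = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  lab <- prognosis_labels(clin)
  expect_equal(as.character(lab$label), c("worst", "poor", "good", "good", "excellent"))
  lab2 <- prognosis_labels(clin, six_to = "poor")
  expect_equal(as.character(lab2$label[3]), "poor")
})

test_that("peptide-prognosis association flags planted peptides only", {
  ids <- sprintf("P%02d", 1:16)
  labels <- make_labels(ids, rep(c("worst", "poor", "good", "excellent"), each = 4))
  reps <- lapply(seq_along(ids), function(i) {
    cdr3 <- c(paste0("CASSBG", sprintf("%02d", i), "AEQFF"), "CASSSHAREDEQFF")
    counts <- c(10, 5)
    if (i >= 13) { # all excellent patients carry the planted peptide
      cdr3 <- c(cdr3, "CASSPLANTEQFF")
      counts <- c(counts, 8)
    } else {
      # balance total templates so the shared peptide has equal frequency
      cdr3 <- c(cdr3, paste0("CASSFILL", sprintf("%02d", i), "EQFF"))
      counts <- c(counts, 8)
    }
    make_rep(ids[i], counts, cdr3 = cdr3)
  })
  res <- peptide_prognosis_association(reps, labels)
  planted <- res[res$cdr3_aa == "CASSPLANTEQFF", ]
  expect_true(planted$associated)
  shared <- res[res$cdr3_aa == "CASSSHAREDEQFF", ]
  expect_false(shared$associated)
})

test_that("label shuffling keeps the peptide association type-I rate near alpha", {
  co <- small_cohort(6)
  set.seed(61)
  rates <- vapply(1:8, function(i) {
    shuf <- co$labels
    shuf$label <- sample(shuf$label)
    res <- peptide_prognosis_association(co$repertoires, shuf)
    mean(res$associated)
  }, numeric(1))
  expect_lt(mean(rates), 0.12)
})

test_that("flow clustering separates duplicated profiles and selects k", {
  base <- matrix(c(10, 1, 5, 2, 8, 1,
                   1, 12, 2, 9, 1, 7), nrow = 2, byrow = TRUE)
  mat <- base[rep(1:2, each = 4), ] + matrix(runif(48, 0, 1e-3), 8)
  rownames(mat) <- paste0("P", 1:8)
  colnames(mat) <- paste0("m", 1:6)
  res <- cluster_flow_profiles(mat, k_range = 1:4, B_refs = 20, seed = 2)
  expect_equal(res$k, 2L)
  expect_equal(length(unique(res$labels[1:4])), 1L)
  expect_equal(length(unique(res$labels[5:8])), 1L)
  expect_true(res$labels[1] != res$labels[5])
})

test_that("gap statistic prefers k = 2 for two pattern-separated blobs", {
  # correlation distance sees marker *patterns*, so the blobs must differ in
  # shape (high-low vs low-high), not in overall level
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    up <- c(4, 4, 4, 0, 0, 0)
    blob <- rbind(matrix(rnorm(60, rep(up, each = 10), 0.3), 10),
                  matrix(rnorm(60, rep(rev(up), each = 10), 0.3), 10))
    blob <- 2^blob
    rownames(blob) <- paste0("P", 1:20)
    colnames(blob) <- paste0("m", 1:6)
    cluster_flow_profiles(blob, k_range = 1:5, B_refs = 25, seed = s)$k
  }, numeric(1))
  expect_gte(mean(hits == 2), 0.9)
})

test_that("cd8_treg ratio handles zero denominators", {
  flow <- data.frame(cd8 = c(10, 5), cd4_foxp3 = c(2, 0))
  r <- cd8_treg_ratio(as.matrix(flow))
  expect_equal(r[1], 5)
  expect_true(is.na(r[2]))
})
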