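test_that("clustering_input applies the >1-read rule and deduplicates", {
  r1 <- make_rep("P01", c(1, 2, 5), cdr3 = c("CASSAAAAAEQFF", "CASSBBBBBEQFF",
                                             "CASSCCCCCEQFF"))
  out <- clustering_input(list(r1))
  expect_setequal(out$cdr3_aa, c("CASSBBBBBEQFF", "CASSCCCCCEQFF"))
  expect_error(clustering_input(list(make_rep("P02", 1))), "threshold")
})

test_that("enriched_motifs finds a planted motif and controls the null", {
  set.seed(5)
  ref <- generate_reference_repertoire(4000, seed = 5, exclude_motifs = "WQKY")
  # plant WQKY into 30% of a 200-sequence sample
  samp <- generate_reference_repertoire(200, seed = 6, exclude_motifs = "WQKY")
  carry <- 1:60
  samp[carry] <- paste0(substr(samp[carry], 1, 4), "WQKY",
                        substr(samp[carry], 9, nchar(samp[carry])))
  res <- enriched_motifs(samp, ref, seed = 11)
  expect_true("WQKY" %in% res$motif)
  expect_lte(res$p[res$motif == "WQKY"], 1 / 1001)
  # sample drawn from the reference itself: nothing should pass fold >= 10.
  # At cohort-scale sample sizes the resampled p-value is binding; tiny
  # samples (~200) can let rare k-mer coincidences through, which is why
  # clustering inputs are pooled across the whole cohort.
  ref10k <- generate_reference_repertoire(10000, seed = 50)
  null_hits <- vapply(1:10, function(s) {
    set.seed(s)
    nullsamp <- sample(ref10k, 1000)
    nrow(enriched_motifs(nullsamp, ref10k, seed = s))
  }, numeric(1))
  expect_lte(mean(null_hits > 0), 0.05)
  # an unattainable p_max is flagged
  expect_warning(enriched_motifs(samp[1:5], ref, n_resamples = 500),
                 "attainable")
})

test_that("short sequences yield no motifs when the fallback is disabled", {
  expect_warning(res <- enriched_motifs(c("CASSF", "CASTF"),
                                        c("CAAAF", "CTTTF"),
                                        whole_string_fallback = FALSE),
                 "no k-mers")
  expect_equal(nrow(res), 0L)
})

test_that("global similarity pairs require equal length and Hamming <= 1", {
  pairs <- global_similarity_pairs(c("CASSLVNTEAFF", "CASSLANTEAFF"))
  expect_equal(nrow(pairs), 1L)
  expect_equal(nrow(global_similarity_pairs(c("CASSLVNTEAFF", "CASSLVNTEAF"))), 0L)
  expect_equal(nrow(global_similarity_pairs(c("CASSLVNTEAFF", "CASSAANTEAFF"))), 0L)
})

test_that("clusters are connected components over motif and similarity edges", {
  members <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4", "P5"),
    cdr3_aa = c("CASXXMOTAYYEQFF", "CASZZMOTAWWEQFF", "CASQQMOTARREQFF",
                "CASGGHIJKLMEQFF", "CASGGHIJKLREQFF"),
    stringsAsFactors = FALSE)
  motifs <- data.frame(motif = "MOTA", k = 4L, sample_count = 3L,
                       sample_freq = 0.6, ref_mean_freq = 0, fold = Inf,
                       p = 0.001)
  cl <- build_specificity_clusters(members, motifs)
  expect_equal(length(cl), 2L)
  sizes <- sort(vapply(cl, function(x) length(x$peptides), integer(1)))
  expect_equal(sizes, c(2L, 3L))
  motif_cl <- cl[[which(vapply(cl, function(x) "MOTA" %in% x$seed_motifs, logical(1)))]]
  expect_equal(motif_cl$subjects, 3L)
})

test_that("clustering is invariant to member input order", {
  co <- small_cohort(4)
  mem <- clustering_input(co$repertoires)
  ref <- generate_reference_repertoire(3000, seed = 8,
                                       exclude_motifs = co$truth$config$planted_motifs$motif)
  mo <- enriched_motifs(mem$cdr3_aa, ref, seed = 8)
  cl1 <- build_specificity_clusters(mem, mo)
  perm <- mem[sample(nrow(mem)), ]
  cl2 <- build_specificity_clusters(perm, mo)
  expect_equal(vapply(cl1, `[[`, character(1), "cluster_id"),
               vapply(cl2, `[[`, character(1), "cluster_id"))
  expect_equal(lapply(cl1, `[[`, "peptides"), lapply(cl2, `[[`, "peptides"))
})

test_that("cluster_pattern produces the wildcard consensus", {
  pat <- cluster_pattern(c("CASSLVNTEAFF", "CASSLANTEAFF", "CAISLTNTEAFF"))
  expect_equal(pat$pattern, "CA%SL%NTEAFF")
  expect_equal(cluster_pattern("CASSLVNTEAFF")$pattern, "CASSLVNTEAFF")
  expect_equal(cluster_pattern(rep("CASSLVNTEAFF", 3))$pattern, "CASSLVNTEAFF")
  # every member matches its own cluster pattern at non-wildcard positions
  seqs <- c("CASSLVNTEAFF", "CASSLANTEAFF", "CASSLVNTGAFF")
  p <- cluster_pattern(seqs)
  rx <- paste0("^", gsub("%", ".", p$pattern), "$")
  expect_true(all(grepl(rx, seqs)))
  # position-frequency matrix columns sum to the member count
  expect_true(all(colSums(p$pfm) == length(seqs)))
})

test_that("cluster association follows the contingency contract", {
  ids <- sprintf("P%02d", 1:16)
  labels <- make_labels(ids, rep(c("worst", "poor", "good", "excellent"), each = 4))
  dataset <- data.frame(patient_id = rep(ids, each = 4),
                        cdr3_aa = paste0("CASS", seq_len(64), "EQFF"),
                        stringsAsFactors = FALSE)
  # a cluster of 5 member occurrences spread over the 4 excellent patients
  exc_rows <- dataset[dataset$patient_id %in% ids[13:16], ][c(1, 5, 9, 13, 14), ]
  clus <- structure(list(cluster_id = "c1", members = exc_rows,
                         peptides = exc_rows$cdr3_aa,
                         subjects = length(unique(exc_rows$patient_id)),
                         seed_motifs = character(), pattern = "", pfm = NULL),
                    class = "specificity_cluster")
  res <- cluster_prognosis_association(clus, labels, dataset, count_unit = "occurrences")
  # oracle: direct chi-square on the implied 2x2 without correction
  tab <- res$table
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_lt(res$p, 0.05)
  expect_true(res$associated)
  # three subjects: not evaluated
  small <- clus
  small$members <- exc_rows[1:3, ]
  small$subjects <- 3L
  res3 <- cluster_prognosis_association(small, labels, dataset)
  expect_false(res3$evaluated)
  # proportions equal to the dataset: no association
  bal_rows <- dataset[c(1, 17, 33, 49), ]
  bal <- structure(list(cluster_id = "c2", members = bal_rows,
                        peptides = bal_rows$cdr3_aa, subjects = 4L,
                        seed_motifs = character(), pattern = "", pfm = NULL),
                   class = "specificity_cluster")
  resb <- cluster_prognosis_association(bal, labels, dataset)
  expect_gt(resb$p, 0.5)
  expect_false(resb$associated)
})

test_that("degenerate contingency tables return p = 1 with a flag", {
  ids <- c("P1", "P2", "P3", "P4")
  labels <- make_labels(ids, rep("excellent", 4))
  dataset <- data.frame(patient_id = rep(ids, each = 2),
                        cdr3_aa = paste0("C", 1:8, "F"))
  clus <- structure(list(cluster_id = "c", members = dataset[1:4, ],
                         peptides = dataset$cdr3_aa[1:4], subjects = 4L,
                         seed_motifs = character(), pattern = "", pfm = NULL),
                    class = "specificity_cluster")
  res <- cluster_prognosis_association(clus, labels, dataset,
                                       group1 = c("worst", "poor"))
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
})

test_that("neighbor joining recovers known geometry", {
  # two identical sequences: single zero-length branch
  two <- neighbor_joining_tree(c(a = "CASSF", b = "CASSF"))
  expect_match(two$newick, "a:0")
  expect_null(two$tree)
  # three taxa: branch lengths from the three-point formulas
  seqs <- c(s1 = "AAAA", s2 = "AAAB", s3 = "ABBB")
  d12 <- 1 / 4; d13 <- 3 / 4; d23 <- 2 / 4
  res3 <- neighbor_joining_tree(seqs)
  tr <- res3$tree
  lens <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens["s1"]), (d12 + d13 - d23) / 2, tolerance = 1e-12)
  expect_equal(unname(lens["s2"]), (d12 + d23 - d13) / 2, tolerance = 1e-12)
  expect_equal(unname(lens["s3"]), (d13 + d23 - d12) / 2, tolerance = 1e-12)
  expect_error(neighbor_joining_tree(c(x = "AA", x = "AB")), "duplicate")
})

test_that("NJ on an additive four-taxon matrix reproduces the tree exactly", {
  # tree: (A:1, B:2)--5--(C:3, D:4)
  dm <- matrix(c(0, 3, 9, 10,
                 3, 0, 10, 11,
                 9, 10, 0, 7,
                 10, 11, 7, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  res <- nj_from_distances(dm)
  expect_equal(res$n_clamped, 0L)
  # pairwise path lengths on the recovered tree equal the input distances
  coph <- ape::cophenetic.phylo(res$tree)
  expect_equal(coph[rownames(dm), colnames(dm)], dm, tolerance = 1e-10)
  # topology: A,B adjacent through one internal node
  expect_true(ape::is.monophyletic(ape::unroot(res$tree), c("A", "B")))
})
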