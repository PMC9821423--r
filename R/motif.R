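# Specificity-group discovery on CDR3beta peptides: local motif enrichment
# against a reference repertoire, global single-mismatch similarity, graph
# clustering, wildcard consensus patterns, cluster-prognosis contingency
# statistics and neighbor-joining trees of clustered peptides.

#' Peptides eligible for specificity clustering
#'
#' Productive clonotypes covered by more than one read (templates > 1),
#' deduplicated per patient.
#'
#' @param reps List of [repertoire] objects.
#' @param min_templates Exclusive lower bound on templates, default 1
#'   (i.e. keep clones with more than 1 read).
#' @return data.frame `patient_id`, `cdr3_aa`.
#' @export
clustering_input <- function(reps, min_templates = 1L) {
  out <- data.table::rbindlist(lapply(reps, function(r) {
    ct <- r$clonotypes[productive(r) & r$clonotypes$templates > min_templates]
    if (nrow(ct) == 0L) return(NULL)
    data.table::data.table(patient_id = r$patient_id, cdr3_aa = unique(ct$cdr3_aa))
  }))
  if (nrow(out) == 0L) {
    stop("no clonotypes exceed the read threshold (templates > ", min_templates,
         "); consider lowering it")
  }
  data.table::setorderv(out, c("patient_id", "cdr3_aa"))
  as.data.frame(out)
}

# unique interior k-mers per sequence: the first and last `trim` residues are
# excluded; sequences shorter than k + 2*trim fall back to the whole string
# (when allowed)
.interior_kmers <- function(seqs, k, trim = 3L, whole_string_fallback = TRUE) {
  n <- nchar(seqs)
  interior <- ifelse(n >= k + 2L * trim, substr(seqs, trim + 1L, n - trim),
                     ifelse(whole_string_fallback, seqs, ""))
  len <- nchar(interior)
  idx <- which(len >= k)
  if (!length(idx)) {
    return(data.table::data.table(seq_index = integer(), kmer = character()))
  }
  reps_n <- len[idx] - k + 1L
  seq_index <- rep(idx, reps_n)
  start <- unlist(lapply(reps_n, seq_len), use.names = FALSE)
  dt <- data.table::data.table(seq_index = seq_index,
                               kmer = substr(rep(interior[idx], reps_n),
                                             start, start + k - 1L))
  unique(dt)
}

.kmer_table <- function(seqs, k_set, trim, whole_string_fallback) {
  data.table::rbindlist(lapply(k_set, .interior_kmers, seqs = seqs, trim = trim,
                               whole_string_fallback = whole_string_fallback))
}

#' Motifs enriched in a sample relative to a reference repertoire
#'
#' Contiguous interior k-mers (first and last `trim` residues of each CDR3
#' excluded) are counted as present/absent per sequence. For each candidate
#' motif seen in the sample, `n_resamples` size-matched draws from the
#' reference yield a null frequency distribution; the fold change is the
#' sample frequency over the mean resampled reference frequency and the
#' empirical p-value is `(1 + #resamples with frequency >= sample) /
#' (n_resamples + 1)`. Motifs with fold >= `fold_min` and p <= `p_max` are
#' reported.
#'
#' @param sample_cdr3s Character vector of sample peptides (one entry per
#'   clonotype occurrence to weight by carriage; duplicates allowed).
#' @param reference_cdr3s Character vector of reference peptides.
#' @param k_set k-mer lengths, default `c(3, 4)`.
#' @param fold_min Minimum fold enrichment, default 10.
#' @param p_max Maximum empirical p, default 0.001.
#' @param n_resamples Reference resamples, default 1000.
#' @param seed Integer seed for the resampling.
#' @param min_depth Minimum number of sample sequences carrying a motif for
#'   it to be considered (the clustering tool's documented
#'   `kmer_mindepth` default of 3); guards against spurious singleton motifs
#'   that are trivially absent from a finite reference.
#' @param trim Residues excluded from each end, default 3.
#' @param whole_string_fallback Use the whole sequence when shorter than
#'   `k + 2 * trim`; default TRUE.
#' @return data.frame `motif`, `k`, `sample_count`, `sample_freq`,
#'   `ref_mean_freq`, `fold`, `p`, sorted by p then fold.
#' @export
enriched_motifs <- function(sample_cdr3s, reference_cdr3s, k_set = c(3L, 4L),
                            fold_min = 10, p_max = 0.001, n_resamples = 1000L,
                            seed = 1L, min_depth = 3L, trim = 3L,
                            whole_string_fallback = TRUE) {
  if (!length(reference_cdr3s)) stop("reference repertoire must be non-empty")
  if (p_max < 1 / (n_resamples + 1)) {
    warning(sprintf(paste("the smallest attainable empirical p is 1/(n_resamples",
                          "+ 1) = %.2g > p_max = %.2g; no motif can pass"),
                    1 / (n_resamples + 1), p_max))
  }
  ns <- length(sample_cdr3s)
  samp_km <- .kmer_table(sample_cdr3s, k_set, trim, whole_string_fallback)
  if (nrow(samp_km) == 0L) {
    warning("no k-mers could be extracted from the sample")
    return(data.frame(motif = character(), k = integer(), sample_count = integer(),
                      sample_freq = numeric(), ref_mean_freq = numeric(),
                      fold = numeric(), p = numeric()))
  }
  cand <- samp_km[, list(sample_count = .N), by = "kmer"]
  cand <- cand[cand$sample_count >= min_depth]
  if (nrow(cand) == 0L) {
    return(data.frame(motif = character(), k = integer(), sample_count = integer(),
                      sample_freq = numeric(), ref_mean_freq = numeric(),
                      fold = numeric(), p = numeric()))
  }
  ref_km <- .kmer_table(reference_cdr3s, k_set, trim, whole_string_fallback)
  ref_km <- ref_km[ref_km$kmer %in% cand$kmer]
  nref <- length(reference_cdr3s)
  K <- nrow(cand)
  ref_count <- table(factor(ref_km$kmer, levels = cand$kmer))
  m <- as.numeric(ref_count)   # reference sequences carrying each motif
  set.seed(seed)
  # a size-matched resample draws ns reference sequences uniformly with
  # replacement, so a motif carried by m of nref reference sequences is seen
  # Binomial(ns, m/nref) times; sampling that count directly is
  # distributionally identical to materializing the resample
  counts <- matrix(stats::rbinom(K * n_resamples, ns, rep(m / nref, n_resamples)),
                   nrow = K)
  ref_freq <- counts / ns
  sample_freq <- cand$sample_count / ns
  ref_mean <- rowMeans(ref_freq)
  fold <- ifelse(ref_mean == 0, Inf, sample_freq / ref_mean)
  p <- (1 + rowSums(ref_freq >= matrix(sample_freq, K, n_resamples))) /
    (n_resamples + 1)
  out <- data.frame(motif = cand$kmer, k = nchar(cand$kmer),
                    sample_count = cand$sample_count, sample_freq = sample_freq,
                    ref_mean_freq = ref_mean, fold = fold, p = p,
                    stringsAsFactors = FALSE)
  out <- out[out$fold >= fold_min & out$p <= p_max, , drop = FALSE]
  out[order(out$p, -out$fold, out$motif), , drop = FALSE]
}

#' Global similarity pairs (equal length, Hamming distance <= 1)
#'
#' @param cdr3s Character vector; duplicates collapse to one node.
#' @return data.frame `a`, `b` of unordered distinct peptide pairs.
#' @export
global_similarity_pairs <- function(cdr3s) {
  seqs <- sort(unique(cdr3s))
  if (length(seqs) < 2L) return(data.frame(a = character(), b = character()))
  pieces <- list()
  for (L in unique(nchar(seqs))) {
    grp <- seqs[nchar(seqs) == L]
    if (length(grp) < 2L) next
    # sequences sharing a one-position-masked key are at Hamming distance <= 1
    for (pos in seq_len(L)) {
      key <- paste0(substr(grp, 1L, pos - 1L), ".", substr(grp, pos + 1L, L))
      dup <- split(grp, key)
      dup <- dup[lengths(dup) > 1L]
      for (members in dup) {
        cmb <- utils::combn(members, 2L)
        pieces[[length(pieces) + 1L]] <- data.table::data.table(a = cmb[1L, ],
                                                                b = cmb[2L, ])
      }
    }
  }
  if (!length(pieces)) return(data.frame(a = character(), b = character()))
  out <- unique(data.table::rbindlist(pieces))
  data.table::setorderv(out, c("a", "b"))
  as.data.frame(out)
}

#' Build specificity clusters
#'
#' Connects distinct member peptides that share an enriched motif (as an
#' interior k-mer) or form a global-similarity pair; clusters are the
#' connected components with at least two distinct peptides. Cluster ids are
#' deterministic (lexicographically smallest member peptide).
#'
#' @param members data.frame from [clustering_input()].
#' @param motifs data.frame from [enriched_motifs()] (may have zero rows).
#' @param pairs data.frame from [global_similarity_pairs()] (may be NULL to
#'   compute from `members`).
#' @param trim,whole_string_fallback Passed to the k-mer extraction so that
#'   motif membership matches the enrichment definition.
#' @return List of `specificity_cluster` objects: `cluster_id`, `members`
#'   (patient_id, cdr3_aa), `peptides`, `subjects`, `seed_motifs`, `pattern`,
#'   `pfm`.
#' @export
build_specificity_clusters <- function(members, motifs, pairs = NULL,
                                       trim = 3L, whole_string_fallback = TRUE) {
  peps <- sort(unique(members$cdr3_aa))
  if (is.null(pairs)) pairs <- global_similarity_pairs(peps)
  edges <- data.table::data.table(a = pairs$a, b = pairs$b)
  motif_of <- list()
  if (nrow(motifs)) {
    k_set <- sort(unique(nchar(motifs$motif)))
    km <- .kmer_table(peps, k_set, trim, whole_string_fallback)
    km <- km[km$kmer %in% motifs$motif]
    if (nrow(km)) {
      km$pep <- peps[km$seq_index]
      motif_of <- split(km$pep, km$kmer)
      motif_edges <- data.table::rbindlist(lapply(motif_of, function(m) {
        m <- sort(unique(m))
        if (length(m) < 2L) return(NULL)
        # star around the first member is enough for connectivity
        data.table::data.table(a = m[1L], b = m[-1L])
      }))
      if (!is.null(motif_edges) && nrow(motif_edges)) {
        edges <- rbind(edges, motif_edges)
      }
    }
  }
  if (nrow(edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(unique(edges), directed = FALSE,
                                     vertices = peps)
  comp <- igraph::components(g)
  clusters <- list()
  for (ci in seq_len(comp$no)) {
    cpeps <- sort(names(comp$membership)[comp$membership == ci])
    if (length(cpeps) < 2L) next
    mem <- members[members$cdr3_aa %in% cpeps, c("patient_id", "cdr3_aa"), drop = FALSE]
    mem <- mem[order(mem$patient_id, mem$cdr3_aa), , drop = FALSE]
    rownames(mem) <- NULL
    seed_motifs <- names(motif_of)[vapply(motif_of, function(m)
      sum(unique(m) %in% cpeps) >= 2L, logical(1))]
    pat <- cluster_pattern(cpeps)
    clusters[[length(clusters) + 1L]] <- structure(list(
      cluster_id = cpeps[1L],
      members = mem,
      peptides = cpeps,
      subjects = length(unique(mem$patient_id)),
      seed_motifs = sort(seed_motifs),
      pattern = pat$pattern,
      pfm = pat$pfm
    ), class = "specificity_cluster")
  }
  clusters[order(vapply(clusters, `[[`, character(1), "cluster_id"))]
}

#' @export
print.specificity_cluster <- function(x, ...) {
  cat(sprintf("<specificity_cluster> %s: %d peptides, %d subjects, pattern %s\n",
              x$cluster_id, length(x$peptides), x$subjects, x$pattern))
  invisible(x)
}

#' Wildcard consensus pattern of a peptide set
#'
#' Computed over the members of the modal length (ties broken toward the
#' shorter length): per position, the residue when unanimous, otherwise the
#' `%` wildcard. Also returns the position-frequency matrix (residue counts
#' per position) over the same members.
#'
#' @param sequences Character vector of peptides (non-empty).
#' @return List with `pattern` (string), `length`, `pfm` (matrix residues x
#'   positions), `n_used` (members of the modal length).
#' @export
cluster_pattern <- function(sequences) {
  if (!length(sequences)) stop("empty cluster")
  lens <- nchar(sequences)
  tab <- table(lens)
  modal <- as.integer(names(tab)[which.max(tab)])  # which.max takes first = shortest on ties
  used <- sequences[lens == modal]
  chars <- do.call(rbind, strsplit(used, "", fixed = TRUE))
  pattern <- vapply(seq_len(modal), function(j) {
    u <- unique(chars[, j])
    if (length(u) == 1L) u else "%"
  }, character(1))
  residues <- sort(unique(as.vector(chars)))
  pfm <- vapply(seq_len(modal), function(j)
    table(factor(chars[, j], levels = residues)), integer(length(residues)))
  dimnames(pfm) <- list(residues, seq_len(modal))
  list(pattern = paste(pattern, collapse = ""), length = modal,
       pfm = pfm, n_used = length(used))
}

# 2x2 chi-square without continuity correction
.chisq_2x2 <- function(tab) {
  rm <- rowSums(tab); cm <- colSums(tab); N <- sum(tab)
  if (any(rm == 0) || any(cm == 0)) {
    return(list(statistic = 0, p = 1, degenerate = TRUE, min_expected = 0))
  }
  E <- outer(rm, cm) / N
  stat <- sum((tab - E)^2 / E)
  list(statistic = stat, p = stats::pchisq(stat, 1L, lower.tail = FALSE),
       degenerate = FALSE, min_expected = min(E))
}

#' Cluster-prognosis contingency association
#'
#' For a cluster with at least `min_subjects` distinct patients, a 2x2
#' chi-square contingency test (no continuity correction), with the two
#' screens used throughout: group 1 = excellent vs the rest, and group 1 =
#' worst + poor vs excellent + good. With `count_unit = "carriers"` (the
#' default) the in-cluster row counts each carrier patient once (labels are
#' assigned per patient, so repeated member peptides from one patient are
#' not independent observations) while the comparison row holds the
#' remaining (patient, peptide) occurrences of the dataset; with
#' `"occurrences"` both rows count raw member occurrences, which inflates
#' the test when one patient contributes several member peptides. Direction
#' is the enriched
#' side; `strict = TRUE` additionally requires the cluster to contain no
#' members from the opposing extreme groups.
#'
#' @param cluster A `specificity_cluster`.
#' @param labels [prognosis_labels()] table.
#' @param dataset_members Full clustering input (denominator of the table).
#' @param group1 Character vector of prognosis labels forming group 1,
#'   default `"excellent"`.
#' @param min_subjects Minimum distinct patients, default 4.
#' @param strict Exclusivity requirement, default FALSE.
#' @param alpha Significance threshold for the associated flag, default 0.05.
#' @param count_unit `"carriers"` (one count per carrier patient in the
#'   cluster row, default) or `"occurrences"` (raw (patient, peptide)
#'   member occurrences).
#' @return List with `evaluated`, `statistic`, `p`, `direction`
#'   (`"group1"`/`"group2"`/`"none"`), `associated`, `table`, `degenerate`,
#'   `min_expected`, `group1`.
#' @export
cluster_prognosis_association <- function(cluster, labels, dataset_members,
                                          group1 = "excellent",
                                          min_subjects = 4L, strict = FALSE,
                                          alpha = 0.05,
                                          count_unit = c("carriers", "occurrences")) {
  count_unit <- match.arg(count_unit)
  lab <- stats::setNames(as.character(labels$label), labels$patient_id)
  if (cluster$subjects < min_subjects) {
    return(list(evaluated = FALSE, statistic = NA_real_, p = NA_real_,
                direction = "not evaluated", associated = FALSE,
                table = NULL, degenerate = NA, min_expected = NA_real_,
                group1 = group1))
  }
  in_cluster <- paste(dataset_members$patient_id, dataset_members$cdr3_aa) %in%
    paste(cluster$members$patient_id, cluster$members$cdr3_aa)
  g1_occ <- lab[dataset_members$patient_id] %in% group1
  if (count_unit == "carriers") {
    carriers <- unique(cluster$members$patient_id)
    a <- sum(lab[carriers] %in% group1)
    b <- length(carriers) - a
  } else {
    a <- sum(in_cluster & g1_occ)
    b <- sum(in_cluster & !g1_occ)
  }
  tab <- matrix(c(a, b,
                  sum(!in_cluster & g1_occ), sum(!in_cluster & !g1_occ)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("cluster", "rest"), c("group1", "group2")))
  cs <- .chisq_2x2(tab)
  prop_in <- if (sum(tab[1L, ]) > 0) tab[1L, 1L] / sum(tab[1L, ]) else 0
  prop_out <- if (sum(tab[2L, ]) > 0) tab[2L, 1L] / sum(tab[2L, ]) else 0
  direction <- if (cs$degenerate || prop_in == prop_out) "none"
               else if (prop_in > prop_out) "group1" else "group2"
  associated <- !cs$degenerate && cs$p < alpha && direction == "group1"
  if (strict && associated) {
    opposing <- if (setequal(group1, "excellent")) c("worst", "poor") else "excellent"
    member_labs <- lab[cluster$members$patient_id]
    if (any(member_labs %in% opposing)) associated <- FALSE
  }
  list(evaluated = TRUE, statistic = cs$statistic, p = cs$p,
       direction = direction, associated = associated, table = tab,
       degenerate = cs$degenerate, min_expected = cs$min_expected,
       group1 = group1)
}

#' Screen all clusters against both prognosis contrasts
#'
#' Runs [cluster_prognosis_association()] with group 1 = excellent and
#' group 1 = worst + poor for every cluster.
#'
#' @inheritParams cluster_prognosis_association
#' @param clusters List of `specificity_cluster` objects.
#' @param count_unit Contingency counting unit, see
#'   [cluster_prognosis_association()].
#' @return data.frame: `cluster_id`, `pattern`, `subjects`, `n_peptides`,
#'   `excellent_p`, `poorworst_p`, `associated_with`
#'   (`"excellent"`, `"poor/worst"` or `"none"`), `evaluated`.
#' @export
associate_clusters <- function(clusters, labels, dataset_members,
                               min_subjects = 4L, strict = FALSE, alpha = 0.05,
                               count_unit = c("carriers", "occurrences")) {
  count_unit <- match.arg(count_unit)
  rows <- lapply(clusters, function(cl) {
    exc <- cluster_prognosis_association(cl, labels, dataset_members,
                                         group1 = "excellent",
                                         min_subjects = min_subjects,
                                         strict = strict, alpha = alpha,
                                         count_unit = count_unit)
    pw <- cluster_prognosis_association(cl, labels, dataset_members,
                                        group1 = c("worst", "poor"),
                                        min_subjects = min_subjects,
                                        strict = strict, alpha = alpha,
                                        count_unit = count_unit)
    assoc <- if (exc$associated && (!pw$associated || exc$p <= pw$p)) "excellent"
             else if (pw$associated) "poor/worst" else "none"
    data.frame(cluster_id = cl$cluster_id, pattern = cl$pattern,
               subjects = cl$subjects, n_peptides = length(cl$peptides),
               excellent_p = exc$p, poorworst_p = pw$p,
               associated_with = assoc, evaluated = exc$evaluated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Neighbor-joining tree of peptide sequences
#'
#' Pairwise distance = Levenshtein distance divided by the longer sequence
#' length (an uncorrected normalized edit distance); canonical
#' neighbor-joining agglomeration; negative branch lengths are clamped to
#' zero with a note.
#'
#' @param sequences Named character vector (>= 2, unique names; unnamed
#'   input is labelled by the sequences themselves, which must then be
#'   unique).
#' @return List with `tree` (ape phylo, NULL for n = 2), `newick` (string),
#'   `n_clamped`.
#' @export
neighbor_joining_tree <- function(sequences) {
  if (length(sequences) < 2L) stop("need at least two sequences")
  if (is.null(names(sequences))) names(sequences) <- sequences
  if (anyDuplicated(names(sequences))) stop("duplicate sequence labels")
  labs <- names(sequences)
  d <- utils::adist(sequences, sequences)
  norm <- outer(nchar(sequences), nchar(sequences), pmax)
  dm <- d / norm
  dimnames(dm) <- list(labs, labs)
  if (length(sequences) == 2L) {
    half <- dm[1L, 2L] / 2
    nwk <- sprintf("(%s:%s,%s:%s);", labs[1L], format(half), labs[2L], format(half))
    return(list(tree = NULL, newick = nwk, n_clamped = 0L))
  }
  nj_from_distances(dm)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ agglomeration on an arbitrary symmetric distance matrix
#' (>= 3 taxa); negative branch lengths are clamped to zero. On an additive
#' (tree-metric) matrix NJ recovers the generating topology and branch
#' lengths exactly.
#'
#' @param dm Symmetric numeric matrix with dimnames, or a [stats::dist].
#' @return List with `tree` (ape phylo), `newick`, `n_clamped`.
#' @export
nj_from_distances <- function(dm) {
  tree <- ape::nj(stats::as.dist(dm))
  n_clamped <- sum(tree$edge.length < 0)
  if (n_clamped) tree$edge.length[tree$edge.length < 0] <- 0
  list(tree = tree, newick = ape::write.tree(tree), n_clamped = n_clamped)
}
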