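# End-to-end orchestration: repertoire statistics, flow clustering, survival
# screening, peptide association, database annotation and enrichment,
# specificity-group clustering against two reference repertoires, cluster
# association, sample networks, and (for synthetic cohorts) a planted-truth
# report. Every stage logs its parameters; a single JSON report aggregates
# the headline results.

#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `input_dir` (a directory in [write_cohort()] layout) or
#' `synthetic` (a [cohort_config()]) must be supplied.
#'
#' @param input_dir Directory with real inputs (repertoires/, clinical.csv,
#'   flow.csv, reference_db.tsv), or NULL.
#' @param synthetic A [cohort_config()], or NULL.
#' @param outdir Output directory.
#' @param seed Integer seed for all stochastic stages.
#' @param max_edit_distance Fuzzy annotation threshold, default 1.
#' @param read_cutoff Clustering read threshold (templates must exceed it),
#'   default 1.
#' @param min_cluster_subjects Contingency-evaluation threshold, default 4.
#' @param alpha Significance level, default 0.05.
#' @param network_r Network correlation threshold, default 0.60.
#' @param minprop Cutpoint scan bound, default 0.1.
#' @param n_resamples Motif-enrichment resamples, default 1000.
#' @param n_permutations Cutpoint permutations, default 200.
#' @param reference_size Size of each synthetic clustering reference
#'   repertoire, default 10000 (an empirical-resampling reference must be
#'   large enough that ordinary k-mers are represented).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, synthetic = NULL,
                            outdir = tempfile("tcrcohort_run_"), seed = 1L,
                            max_edit_distance = 1L, read_cutoff = 1L,
                            min_cluster_subjects = 4L, alpha = 0.05,
                            network_r = 0.60, minprop = 0.1,
                            n_resamples = 1000L, n_permutations = 200L,
                            reference_size = 10000L) {
  if (is.null(input_dir) == is.null(synthetic)) {
    stop("validation error: supply exactly one of input_dir or synthetic")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "cohort_config")) {
    stop("synthetic must be a cohort_config")
  }
  stopifnot(max_edit_distance >= 0, read_cutoff >= 0,
            min_cluster_subjects >= 1, alpha > 0, alpha < 1,
            network_r >= -1, network_r <= 1, minprop > 0, minprop < 0.5)
  structure(list(input_dir = input_dir, synthetic = synthetic, outdir = outdir,
                 seed = as.integer(seed), max_edit_distance = max_edit_distance,
                 read_cutoff = read_cutoff,
                 min_cluster_subjects = min_cluster_subjects, alpha = alpha,
                 network_r = network_r, minprop = minprop,
                 n_resamples = n_resamples, n_permutations = n_permutations,
                 reference_size = reference_size),
            class = "pipeline_config")
}

.write_tsv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(v, digits = 10, format = "g"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages run in a fixed order; a stage failure halts the pipeline with the
#' stage name while earlier outputs are preserved in `config$outdir`.
#'
#' @param config A [pipeline_config()].
#' @return The report list (also written as `report.json`), invisibly
#'   containing per-stage headline results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                               "\n", file = log_path, append = TRUE)
  # run-local paths stay out of the report so identical configurations
  # produce byte-identical reports wherever they are written
  report <- list(seed = config$seed,
                 parameters = unclass(config)[!(names(unclass(config)) %in%
                                                  c("synthetic", "outdir",
                                                    "input_dir"))])
  stage <- function(name, expr) {
    logline("stage:", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline halted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("load", {
    if (!is.null(config$synthetic)) {
      co <- generate_cohort(config$synthetic)
      write_cohort(co, file.path(outdir, "cohort"))
      co
    } else read_cohort(config$input_dir)
  })
  labels <- cohort$labels
  reps <- cohort$repertoires

  stats_tab <- stage("repertoire_stats", {
    tab <- cohort_stats_table(reps)
    write_cohort_stats(tab, file.path(outdir, "repertoire_stats.tsv"))
    tab
  })
  report$n_patients <- nrow(stats_tab)
  report$mean_productive_entropy_bits <- mean(stats_tab$productive_entropy_bits)

  flow_cl <- stage("flow_clustering", {
    flow <- cohort$flow
    flow <- flow[, colSums(!is.na(flow)) > 0, drop = FALSE]
    cl <- cluster_flow_profiles(as.matrix(flow), seed = config$seed)
    .write_tsv(data.frame(patient_id = names(cl$labels), cluster = cl$labels),
               file.path(outdir, "flow_clusters.tsv"))
    cl
  })
  report$flow_k <- flow_cl$k

  surv_screen <- stage("survival_screen", {
    clin <- cohort$clinical
    markers <- cbind(cohort$flow,
                     stats_tab[match(clin$patient_id, stats_tab$patient_id),
                               c("productive_entropy_bits", "productive_clonality",
                                 "max_pf", "top10_pf", "top100_pf")])
    scr <- survival_screen(markers, clin$os_months, clin$os_event,
                           minprop = config$minprop,
                           n_permutations = config$n_permutations,
                           seed = config$seed)
    .write_tsv(scr, file.path(outdir, "survival_screen.tsv"))
    scr
  })
  report$survival_screen_top <- surv_screen$marker[1L]

  pep_assoc <- stage("peptide_association", {
    pa <- peptide_prognosis_association(reps, labels, alpha = config$alpha)
    .write_tsv(pa, file.path(outdir, "peptide_association.tsv"))
    pa
  })
  report$n_associated_peptides <- sum(pep_assoc$associated)

  annot <- stage("annotation", {
    fuzzy <- annotate_cohort(reps, cohort$reference_db, mode = "fuzzy",
                             max_dist = config$max_edit_distance)
    exact <- annotate_cohort(reps, cohort$reference_db, mode = "exact")
    .write_tsv(fuzzy, file.path(outdir, "annotation_fuzzy.tsv"))
    .write_tsv(exact, file.path(outdir, "annotation_exact.tsv"))
    enr <- category_enrichment(fuzzy)
    jsonlite::write_json(enr[c("observed", "proportions", "statistic", "dof", "p")],
                         file.path(outdir, "category_enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    cond <- condition_prognosis_test(fuzzy, reps, labels, alpha = config$alpha)
    .write_tsv(cond$table, file.path(outdir, "condition_association.tsv"))
    grp_freq <- cancer_match_group_frequency(exact, labels)
    .write_tsv(grp_freq, file.path(outdir, "cancer_match_frequency.tsv"))
    gene_mat <- epitope_gene_matrix(exact, labels)
    .write_tsv(cbind(patient_id = rownames(gene_mat), as.data.frame(gene_mat)),
               file.path(outdir, "epitope_gene_matrix.tsv"))
    list(fuzzy = fuzzy, exact = exact, enrichment = enr,
         condition = cond, group_freq = grp_freq)
  })
  report$enrichment_p <- annot$enrichment$p
  report$cancer_match_frequency <- stats::setNames(
    annot$group_freq$frequency, annot$group_freq$label)

  motif_run <- stage("motif_clustering", {
    members <- clustering_input(reps, min_templates = config$read_cutoff)
    planted <- if (!is.null(config$synthetic))
      config$synthetic$planted_motifs$motif else character()
    out <- list()
    for (ref_name in c("cd4", "cd8")) {
      ref_seed <- config$seed + match(ref_name, c("cd4", "cd8"))
      reference <- generate_reference_repertoire(config$reference_size,
                                                 seed = ref_seed,
                                                 exclude_motifs = planted)
      motifs <- enriched_motifs(members$cdr3_aa, reference,
                                n_resamples = config$n_resamples,
                                seed = ref_seed)
      clusters <- build_specificity_clusters(members, motifs)
      assoc <- associate_clusters(clusters, labels, members,
                                  min_subjects = config$min_cluster_subjects,
                                  alpha = config$alpha)
      if (!is.null(assoc)) {
        .write_tsv(assoc, file.path(outdir, paste0("clusters_", ref_name, ".tsv")))
      }
      out[[ref_name]] <- list(reference = ref_name, motifs = motifs,
                              clusters = clusters, association = assoc,
                              members = members)
    }
    out
  })
  report$n_clusters <- vapply(motif_run, function(m) length(m$clusters), integer(1))
  report$n_associated_clusters <- vapply(motif_run, function(m) {
    if (is.null(m$association) || !nrow(m$association)) return(0L)
    sum(m$association$associated_with != "none")
  }, integer(1))

  networks <- stage("association_network", {
    out <- list()
    for (ref_name in names(motif_run)) {
      mr <- motif_run[[ref_name]]
      if (is.null(mr$association)) next
      assoc_ids <- mr$association$cluster_id[mr$association$associated_with != "none"]
      assoc_clusters <- mr$clusters[vapply(mr$clusters, `[[`, character(1),
                                           "cluster_id") %in% assoc_ids]
      if (!length(assoc_clusters)) next
      mm <- membership_matrix(assoc_clusters, labels$patient_id)
      net <- build_network(mm, labels, r_threshold = config$network_r)
      write_network(net, file.path(outdir, paste0("network_", ref_name, ".tsv")),
                    file.path(outdir, paste0("network_", ref_name, ".graphml")))
      out[[ref_name]] <- net
    }
    out
  })
  report$network_assortativity <- vapply(networks, function(net)
    suppressWarnings(prognosis_assortativity(net)), numeric(1))
  side_map <- c(worst = "unfavorable", poor = "unfavorable",
                good = "favorable", excellent = "favorable")
  report$network_assortativity_side <- vapply(networks, function(net)
    suppressWarnings(prognosis_assortativity(net, collapse = side_map)),
    numeric(1))

  if (!is.null(config$synthetic)) {
    truth_res <- stage("truth_report", {
      mr <- motif_run$cd4
      truth_report(cohort$truth, mr$association, mr$clusters, cohort$clinical)
    })
    report$cluster_sensitivity <- truth_res$cluster_sensitivity
    report$cluster_fdr <- truth_res$cluster_fdr
    report$hr_estimated <- truth_res$hr_estimated
    report$hr_true <- truth_res$hr_true
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  logline("done")
  invisible(report)
}
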