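# Clonotype tables and sample-level repertoire characteristics.

#' Construct a repertoire object
#'
#' A repertoire holds one patient's CDR3beta clonotypes: the amino-acid
#' sequence, V/D/J gene-segment calls, the template (read) count and the
#' frame type. Clonotypes are unique by (cdr3_aa, v_gene, j_gene); duplicate
#' rows are merged by summing their template counts.
#'
#' @param patient_id Sample identifier (scalar character).
#' @param clonotypes A data.frame with columns `cdr3_aa`, `templates`,
#'   `frame` and optionally `v_gene`, `d_gene`, `j_gene`. `frame` must be one
#'   of `"in-frame"`, `"out-of-frame"`, `"stop"`.
#' @return An object of class `repertoire`.
#' @export
repertoire <- function(patient_id, clonotypes) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L, nzchar(patient_id))
  ct <- data.table::as.data.table(clonotypes)
  for (g in c("v_gene", "d_gene", "j_gene")) {
    if (!g %in% names(ct)) ct[[g]] <- "unresolved"
    ct[[g]][is.na(ct[[g]]) | !nzchar(ct[[g]])] <- "unresolved"
  }
  required <- c("cdr3_aa", "templates", "frame")
  missing_cols <- setdiff(required, names(ct))
  if (length(missing_cols)) {
    stop("clonotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ct$cdr3_aa[is.na(ct$cdr3_aa)] <- ""
  bad_frame <- setdiff(unique(ct$frame), c("in-frame", "out-of-frame", "stop"))
  if (length(bad_frame)) stop("unknown frame value(s): ", paste(bad_frame, collapse = ", "))
  if (anyNA(ct$templates) || any(ct$templates < 0)) {
    stop("templates must be non-negative")
  }
  ct <- ct[, list(templates = sum(templates)),
           by = c("cdr3_aa", "v_gene", "d_gene", "j_gene", "frame")]
  data.table::setcolorder(ct, c("cdr3_aa", "v_gene", "d_gene", "j_gene", "templates", "frame"))
  data.table::setorderv(ct, c("cdr3_aa", "v_gene", "j_gene"))
  structure(list(patient_id = patient_id, clonotypes = ct[]), class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  pr <- sum(productive(x))
  cat(sprintf("<repertoire> patient %s: %d clonotypes (%d productive), %d templates\n",
              x$patient_id, nrow(x$clonotypes), pr, sum(x$clonotypes$templates)))
  invisible(x)
}

#' Productive-clonotype indicator
#'
#' A rearrangement is productive when it is in frame, its CDR3 amino-acid
#' sequence is non-empty and it carries no stop symbol (`*`).
#'
#' @param rep A `repertoire`.
#' @return Logical vector along the clonotype rows.
#' @export
productive <- function(rep) {
  ct <- rep$clonotypes
  ct$frame == "in-frame" & nzchar(ct$cdr3_aa) & !grepl("*", ct$cdr3_aa, fixed = TRUE)
}

# header synonym groups for immunoSEQ-style exports
.col_synonyms <- list(
  cdr3_aa   = c("cdr3_aa", "amino_acid", "aminoAcid", "cdr3_amino_acid"),
  templates = c("templates", "count (templates/reads)", "seq_reads", "count"),
  frame     = c("frame", "frame_type", "sequenceStatus"),
  v_gene    = c("v_gene", "vGeneName", "v_resolved"),
  d_gene    = c("d_gene", "dGeneName", "d_resolved"),
  j_gene    = c("j_gene", "jGeneName", "j_resolved")
)

.normalize_frame <- function(x) {
  key <- tolower(trimws(x))
  out <- rep(NA_character_, length(key))
  out[key %in% c("in", "in-frame", "inframe")] <- "in-frame"
  out[key %in% c("out", "out-of-frame", "outofframe")] <- "out-of-frame"
  out[key %in% c("stop", "has stop", "stop codon")] <- "stop"
  if (anyNA(out)) stop("unrecognized frame values: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Read an immunoSEQ-style clonotype table
#'
#' Parses a tab-separated clonotype export (one sample per file) into a
#' [repertoire]. Standard column-name synonyms are accepted
#' (`amino_acid`/`aminoAcid`/`cdr3_amino_acid`; `templates`/
#' `count (templates/reads)`/`seq_reads`; `frame_type`/`sequenceStatus`).
#' Rows with an empty CDR3 amino-acid sequence are retained but can never be
#' productive; duplicate (cdr3_aa, V, J) rows are merged by summing templates.
#'
#' @param path Path to the TSV file.
#' @param patient_id Sample identifier to attach.
#' @return A [repertoire].
#' @export
parse_immunoseq_table <- function(path, patient_id) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = 1), data.table = TRUE)
  out <- data.table::data.table(row = seq_len(nrow(raw)))
  for (canon in names(.col_synonyms)) {
    hit <- intersect(.col_synonyms[[canon]], names(raw))
    mandatory <- canon %in% c("cdr3_aa", "templates", "frame")
    if (!length(hit)) {
      if (mandatory) {
        stop(sprintf("format error: mandatory column '%s' missing (accepted names: %s)",
                     canon, paste(.col_synonyms[[canon]], collapse = ", ")))
      }
      next
    }
    out[[canon]] <- raw[[hit[1L]]]
  }
  out$row <- NULL
  out$cdr3_aa <- toupper(trimws(as.character(out$cdr3_aa)))
  out$templates <- as.numeric(out$templates)
  if (anyNA(out$templates) || any(out$templates < 0)) {
    stop("validation error: templates must be non-negative numbers")
  }
  out$frame <- .normalize_frame(out$frame)
  # an empty CDR3 cannot be called productive whatever the reported frame
  out$frame[!nzchar(out$cdr3_aa) & out$frame == "in-frame"] <- "out-of-frame"
  repertoire(patient_id, out)
}

#' Sample-level repertoire characteristics
#'
#' Computes the six characteristics used throughout cohort analyses, all over
#' productive rearrangements only: the number of unique productive
#' rearrangements R, total productive templates, Shannon entropy of the
#' productive frequencies in bits, clonality `1 - H / log2(R)`, and the
#' maximum / top-10 / top-100 summed productive frequencies. For a
#' single-clone repertoire clonality is defined as 1 (maximally clonal).
#'
#' @param rep A [repertoire] with at least one productive clonotype.
#' @return A one-row data.frame of class `repertoire_stats`.
#' @export
compute_repertoire_stats <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  ct <- rep$clonotypes[productive(rep) & rep$clonotypes$templates > 0]
  if (nrow(ct) == 0L) stop("empty productive repertoire for patient ", rep$patient_id)
  f <- ct$templates / sum(ct$templates)
  R <- length(f)
  H <- -sum(f * log2(f))
  clonality <- if (R > 1L) 1 - H / log2(R) else 1
  fs <- sort(f, decreasing = TRUE)
  out <- data.frame(
    patient_id = rep$patient_id,
    productive_rearrangements = R,
    total_productive_templates = sum(ct$templates),
    productive_entropy_bits = H,
    productive_clonality = clonality,
    max_pf = fs[1L],
    top10_pf = sum(fs[seq_len(min(10L, R))]),
    top100_pf = sum(fs[seq_len(min(100L, R))]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("repertoire_stats", class(out))
  out
}

#' Cohort table of repertoire characteristics
#'
#' @param reps List of [repertoire] objects with distinct patient ids.
#' @return data.frame, one row per patient, ordered by `patient_id`.
#' @export
cohort_stats_table <- function(reps) {
  if (!length(reps)) stop("empty repertoire list")
  ids <- vapply(reps, function(r) r$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tab <- do.call(rbind, lapply(reps, compute_repertoire_stats))
  tab <- tab[order(tab$patient_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write the cohort statistics table as TSV
#'
#' Fixed column order matching the documented external interface.
#' @param tab Output of [cohort_stats_table()].
#' @param path Destination file.
#' @export
write_cohort_stats <- function(tab, path) {
  cols <- c("patient_id", "productive_rearrangements", "total_productive_templates",
            "productive_entropy_bits", "productive_clonality",
            "max_pf", "top10_pf", "top100_pf")
  utils::write.table(format(tab[, cols], digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
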