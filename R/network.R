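# Sample-sample association networks from shared prognosis-associated
# specificity clusters.

#' Patient x cluster membership matrix
#'
#' @param clusters List of `specificity_cluster` objects (typically the
#'   prognosis-associated subset).
#' @param patients Character vector of all patient ids (rows; patients in no
#'   cluster keep an all-zero row).
#' @return Binary matrix, rows = patients, columns = cluster ids.
#' @export
membership_matrix <- function(clusters, patients) {
  if (!length(clusters)) stop("need at least one cluster")
  ids <- vapply(clusters, `[[`, character(1), "cluster_id")
  mat <- matrix(0L, nrow = length(patients), ncol = length(clusters),
                dimnames = list(patients, ids))
  for (j in seq_along(clusters)) {
    mat[unique(clusters[[j]]$members$patient_id), j] <- 1L
  }
  mat
}

#' Build a sample association network
#'
#' Pairwise Pearson correlation between patient membership profiles; an
#' undirected edge is drawn where r >= `r_threshold`. Patients with a
#' constant profile (all zeros or all ones) have undefined correlation and
#' are excluded with a note.
#'
#' @param matrix Binary membership matrix from [membership_matrix()].
#' @param labels Optional [prognosis_labels()] table attached as node
#'   attributes.
#' @param r_threshold Edge threshold, default 0.60.
#' @return Object of class `sample_network`: list with `nodes` (data.frame
#'   `patient_id`, `label`), `edges` (data.frame `a`, `b`, `r`), `excluded`.
#' @export
build_network <- function(matrix, labels = NULL, r_threshold = 0.60) {
  if (nrow(matrix) < 2L) stop("need at least two patients")
  const <- apply(matrix, 1L, function(r) stats::sd(r) == 0)
  if (all(const)) {
    warning("all membership profiles are constant: empty network")
  } else if (any(const)) {
    message("build_network: excluding ", sum(const),
            " patient(s) with constant membership profiles")
  }
  keep <- rownames(matrix)[!const]
  edges <- data.frame(a = character(), b = character(), r = numeric(),
                      stringsAsFactors = FALSE)
  if (length(keep) >= 2L) {
    cm <- stats::cor(t(matrix[keep, , drop = FALSE]))
    idx <- which(upper.tri(cm) & cm >= r_threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(a = keep[idx[, 1L]], b = keep[idx[, 2L]],
                          r = cm[idx], stringsAsFactors = FALSE)
      edges <- edges[order(edges$a, edges$b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  nodes <- data.frame(patient_id = rownames(matrix), stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    nodes$label <- as.character(labels$label)[match(nodes$patient_id,
                                                    labels$patient_id)]
  }
  structure(list(nodes = nodes, edges = edges,
                 excluded = rownames(matrix)[const],
                 r_threshold = r_threshold),
            class = "sample_network")
}

#' @export
print.sample_network <- function(x, ...) {
  cat(sprintf("<sample_network> %d nodes, %d edges (r >= %.2f), %d excluded\n",
              nrow(x$nodes), nrow(x$edges), x$r_threshold, length(x$excluded)))
  invisible(x)
}

.as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges[, c("a", "b", "r")],
                                directed = FALSE,
                                vertices = network$nodes)
}

#' Prognosis assortativity of a sample network
#'
#' Nominal (categorical) assortativity coefficient of the prognosis labels
#' over the network edges: 1 when every edge joins same-label patients,
#' negative for predominantly cross-label edges, approximately 0 for random
#' mixing.
#'
#' @param network A `sample_network` with node labels and >= 1 edge.
#' @param collapse Optional named character vector mapping prognosis labels
#'   onto coarser classes before computing the coefficient, e.g.
#'   `c(worst = "unfavorable", poor = "unfavorable", good = "favorable",
#'   excellent = "favorable")` to measure the separation of the two
#'   prognosis sides (specificity groups are screened against
#'   excellent-vs-rest and worst+poor-vs-rest contrasts, so poor and worst
#'   patients legitimately share clusters).
#' @return Scalar in [-1, 1]; NA with a warning when the network has no
#'   edges or a single label.
#' @export
prognosis_assortativity <- function(network, collapse = NULL) {
  if (nrow(network$edges) == 0L) {
    warning("network has no edges: assortativity undefined")
    return(NA_real_)
  }
  if (is.null(network$nodes$label)) stop("network nodes carry no prognosis labels")
  g <- .as_igraph(network)
  raw <- igraph::V(g)$label
  if (!is.null(collapse)) raw <- unname(collapse[raw])
  labs <- factor(raw)
  if (nlevels(droplevels(labs[igraph::degree(g) > 0])) < 2L) {
    # perfectly assortative by definition when one label spans all edges
    return(1)
  }
  igraph::assortativity_nominal(g, types = as.integer(labs), directed = FALSE)
}

#' Write a network as an edge-list TSV and GraphML
#'
#' @param network A `sample_network`.
#' @param edge_path TSV destination for the `a`, `b`, `r` edge list.
#' @param graphml_path Optional GraphML destination (for network viewers).
#' @export
write_network <- function(network, edge_path, graphml_path = NULL) {
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(.as_igraph(network), graphml_path, format = "graphml")
  }
  invisible(edge_path)
}
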