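#' Hierarchical clustering of association matrices and network export
#'
#' Percentage (fraction) matrices are clustered with the Manhattan
#' distance; RR/OR matrices are log2-transformed and clustered with the
#' Euclidean distance; both use average linkage. For ratio matrices,
#' non-positive or undefined cells are masked pairwise: each pairwise
#' distance is computed over the mutually defined coordinates and rescaled
#' by coverage (the behavior of \code{stats::dist} with \code{NA}s).
#' @name netviz
NULL

# canonical leaf order: at every merge, the subtree containing the
# lexicographically smallest leaf comes first — makes the order invariant
# to input row permutation (resolving the mirror-image ambiguity)
canonical_order <- function(merge, labels) {
  leaves_of <- function(node) {
    if (node < 0L) return(labels[-node])
    kids <- merge[node, ]
    a <- leaves_of(kids[1]); b <- leaves_of(kids[2])
    if (min(a) <= min(b)) c(a, b) else c(b, a)
  }
  leaves_of(nrow(merge))
}

#' Cluster the rows and columns of an association matrix
#'
#' @param matrix a \code{met_assoc} or plain numeric matrix.
#' @param kind \code{"percent"} (Manhattan distance on raw fractions) or
#'   \code{"ratio"} (Euclidean distance on log2 values; non-positive cells
#'   masked).
#' @return list with elements \code{rows} and \code{cols}, each a
#'   \code{met_cluster} holding the canonical leaf order, the merge tree
#'   with heights, and the distance/linkage names.
#' @examples
#' m <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("a", "b", "c"), "x"))
#' cluster_matrix(m, kind = "percent")$rows$order
#' @export
cluster_matrix <- function(matrix, kind = c("percent", "ratio")) {
  kind <- match.arg(kind)
  m <- if (inherits(matrix, "met_assoc")) matrix$statistic else matrix
  cluster_one <- function(m) {
    if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))
    if (nrow(m) < 2L) {
      message("fewer than 2 items on one margin; skipping that clustering")
      return(NULL)
    }
    if (kind == "ratio") {
      m[!is.na(m) & m <= 0] <- NA  # log2 undefined; masked pairwise
      m <- log2(m)
      method <- "euclidean"
    } else {
      method <- "manhattan"
    }
    all_na <- rowSums(!is.na(m)) == 0L
    if (any(all_na)) {
      warning("excluding all-undefined row(s): ",
              paste(rownames(m)[all_na], collapse = ", "))
      m <- m[!all_na, , drop = FALSE]
    }
    if (nrow(m) < 2L) stop("need at least 2 rows/columns to cluster")
    d <- stats::dist(m, method = method)
    hc <- stats::hclust(d, method = "average")
    out <- list(order = canonical_order(hc$merge, hc$labels),
                merge = hc$merge, height = hc$height,
                labels = hc$labels, dist_method = method,
                linkage = "average")
    class(out) <- "met_cluster"
    out
  }
  list(rows = cluster_one(m), cols = cluster_one(t(m)))
}

#' @export
print.met_cluster <- function(x, ...) {
  cat("Hierarchical clustering (", x$dist_method, " distance, ",
      x$linkage, " linkage) of ", length(x$labels), " items\n", sep = "")
  cat("  leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' Build the metastatic-progression graph
#'
#' One node per primary site (size = number of patients with that primary)
#' and per secondary site (size = number of metastatic hits); one directed
#' edge per defined progression cell with positive weight. Edge weight is
#' the fraction of tumors progressing along the route; edge color encodes
#' the RR screen: \code{enriched} / \code{depleted} where the
#' FDR-adjusted q < 0.05, otherwise \code{neutral}.
#'
#' @param cohort the \code{met_cohort} both matrices were computed from.
#' @param progression a 16 x 20 \code{met_assoc} from
#'   [progression_matrix()].
#' @param rr a 16 x 20 \code{met_assoc} from
#'   \code{rr_screen(cohort, "primary_to_secondary")}.
#' @return a \code{met_graph}: data frames \code{nodes} (label, role,
#'   size_count) and \code{edges} (from, to, weight, rr, q, color).
#' @export
build_graph <- function(cohort, progression, rr) {
  if (!identical(progression$row_labels, rr$row_labels) ||
      !identical(progression$col_labels, rr$col_labels)) {
    stop("progression and RR matrices have mismatched labels")
  }
  inc <- cohort$included
  prim_counts <- table(factor(inc$primary_site, levels = primary_sites()))
  site_counts <- colSums(met_matrix(cohort))
  nodes <- data.frame(
    label = c(primary_sites(), secondary_sites()),
    role = c(rep("primary", 16L), rep("secondary", 20L)),
    size_count = c(as.integer(prim_counts), as.integer(site_counts)),
    stringsAsFactors = FALSE
  )
  w <- progression$statistic
  cells <- which(!is.na(w) & w > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = progression$row_labels[cells[, 1]],
    to = progression$col_labels[cells[, 2]],
    weight = w[cells],
    rr = rr$statistic[cells],
    q = rr$q[cells],
    color = ifelse(rr$flag[cells] == "null", "neutral", rr$flag[cells]),
    stringsAsFactors = FALSE
  )
  out <- list(nodes = nodes, edges = edges)
  class(out) <- "met_graph"
  out
}

#' @export
print.met_graph <- function(x, ...) {
  cat("Progression graph:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  cat("  enriched routes:", sum(x$edges$color == "enriched"),
      "| depleted:", sum(x$edges$color == "depleted"), "\n")
  invisible(x)
}

#' Export / import a progression graph as GraphML
#'
#' GraphML keeps node and edge attributes typed, so a round trip through
#' [read_progression_graph()] restores them exactly. An optional JSON
#' sidecar duplicates the node/edge tables for plotting tools.
#'
#' @param graph a \code{met_graph}.
#' @param path output \code{.graphml} file.
#' @param json_path optional path for a JSON sidecar.
#' @return \code{path}, invisibly.
#' @export
write_progression_graph <- function(graph, path, json_path = NULL) {
  g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                     vertices = graph$nodes)
  igraph::write_graph(g, path, format = "graphml")
  if (!is.null(json_path)) {
    jsonlite::write_json(list(nodes = graph$nodes, edges = graph$edges),
                         json_path, digits = NA)
  }
  invisible(path)
}

#' @rdname write_progression_graph
#' @export
read_progression_graph <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  out <- list(
    nodes = data.frame(label = nodes$name, role = nodes$role,
                       size_count = as.integer(nodes$size_count),
                       stringsAsFactors = FALSE),
    edges = data.frame(from = edges$from, to = edges$to,
                       weight = edges$weight, rr = edges$rr, q = edges$q,
                       color = edges$color, stringsAsFactors = FALSE)
  )
  class(out) <- "met_graph"
  out
}
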