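#' Stratified comparison of metastatic patterns
#'
#' Compares per-secondary-site metastasis frequencies between two patient
#' strata: adenocarcinoma vs squamous histology, smoking- vs
#' non-smoking-related primaries, node-positive vs node-negative disease,
#' or male vs female. For each of the 20 secondary sites a two-sided
#' Fisher exact test is run on the 2 x 2 (group x site-hit) table and the
#' Benjamini-Hochberg correction is applied across the 20 sites as one
#' family. Records with an unknown stratum value (e.g. unknown histology)
#' are dropped for that comparison only and counted.
#'
#' @param cohort a \code{met_cohort}.
#' @param stratifier one of \code{"histology"}, \code{"smoking"},
#'   \code{"nodal"}, \code{"sex"}.
#' @param scope optional primary-site label restricting the comparison to
#'   that primary (e.g. \code{scope = "lung"} for the lung-only
#'   histology contrast).
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return a \code{met_group_comparison}: per-site fractions for the two
#'   groups, the 2 x 2 counts, p, BH-adjusted q and a significance flag,
#'   plus group sizes and the number of dropped records.
#' @examples
#' \donttest{
#' coh <- apply_inclusion_filters(make_paper_fixture())
#' compare_groups(coh, "smoking")
#' }
#' @export
compare_groups <- function(cohort,
                           stratifier = c("histology", "smoking", "nodal",
                                          "sex"),
                           scope = NULL, alpha = 0.05) {
  stratifier <- match.arg(stratifier)
  inc <- cohort$included
  if (!is.null(scope)) {
    if (!scope %in% primary_sites()) stop("unknown scope primary: ", scope)
    inc <- inc[inc$primary_site == scope, , drop = FALSE]
  }
  assign_group <- switch(
    stratifier,
    histology = function(df) {
      g <- rep(NA_character_, nrow(df))
      g[df$histology == "adenocarcinoma"] <- "adenocarcinoma"
      g[df$histology == "squamous"] <- "squamous"
      list(g = g, labels = c("adenocarcinoma", "squamous"))
    },
    smoking = function(df) {
      list(g = classify_smoking(df$primary_site),
           labels = c("smoking_related", "non_smoking_related"))
    },
    nodal = function(df) {
      g <- rep(NA_character_, nrow(df))
      g[df$nodal_status == "N+"] <- "N+"
      g[df$nodal_status == "N-"] <- "N-"
      list(g = g, labels = c("N+", "N-"))
    },
    sex = function(df) list(g = df$sex, labels = c("male", "female"))
  )
  gr <- assign_group(inc)
  keep <- !is.na(gr$g)
  n_dropped <- sum(!keep)
  inc <- inc[keep, , drop = FALSE]
  g <- gr$g[keep]
  n1 <- sum(g == gr$labels[1])
  n2 <- sum(g == gr$labels[2])
  if (n1 == 0L) stop("empty stratum: ", gr$labels[1])
  if (n2 == 0L) stop("empty stratum: ", gr$labels[2])
  m <- as.matrix(inc[, met_cols(), drop = FALSE])
  hits1 <- colSums(m[g == gr$labels[1], , drop = FALSE])
  hits2 <- colSums(m[g == gr$labels[2], , drop = FALSE])
  p <- vapply(seq_len(20L), function(j) {
    stats::fisher.test(matrix(c(hits1[j], n1 - hits1[j],
                                hits2[j], n2 - hits2[j]),
                              nrow = 2L, byrow = TRUE))$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  out <- list(
    stratifier = stratifier,
    scope = scope,
    groups = gr$labels,
    n = stats::setNames(c(n1, n2), gr$labels),
    n_dropped = n_dropped,
    table = data.frame(
      site = secondary_sites(),
      fraction_g1 = unname(hits1 / n1),
      fraction_g2 = unname(hits2 / n2),
      hits_g1 = unname(hits1),
      hits_g2 = unname(hits2),
      p = p,
      q = q,
      significant = q < alpha,
      stringsAsFactors = FALSE
    )
  )
  class(out) <- "met_group_comparison"
  out
}

#' @export
print.met_group_comparison <- function(x, ...) {
  cat("Subgroup comparison by ", x$stratifier,
      if (!is.null(x$scope)) paste0(" (scope: ", x$scope, ")"), "\n",
      sep = "")
  cat("  ", x$groups[1], " n=", x$n[1], " vs ", x$groups[2], " n=", x$n[2],
      if (x$n_dropped > 0) paste0("  (", x$n_dropped, " dropped: unknown ",
                                  x$stratifier, ")"),
      "\n", sep = "")
  df <- x$table
  df$fraction_g1 <- round(df$fraction_g1, 3)
  df$fraction_g2 <- round(df$fraction_g2, 3)
  df$p <- signif(df$p, 3); df$q <- signif(df$q, 3)
  print(df[order(df$p), c("site", "fraction_g1", "fraction_g2", "p", "q",
                          "significant")],
        row.names = FALSE)
  invisible(x)
}
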