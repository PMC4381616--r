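#' Association matrices and relative-risk screening
#'
#' The two analysis methods for primary/secondary-site association are the
#' *fractional method* — the plain conditional fraction of tumors
#' progressing from a primary to a secondary site — and the *relative risk
#' (RR) method*, which quantifies enrichment or depletion of an association
#' against the whole cohort:
#' \deqn{RR(a,b) = f(a \wedge b) / (f(a) f(b))}
#' with \eqn{f} the relative frequency over all included patients. RR
#' significance is assessed by the two-sided Fisher exact test and the
#' resulting p-values are corrected with the Benjamini-Hochberg step-up
#' (FDR control at 5%), one family per matrix.
#' @name pattern_stats
NULL

new_assoc <- function(statistic, p = NULL, q = NULL, flag = NULL,
                      counts = NULL, kind = "fraction") {
  empty <- function(fill) {
    matrix(fill, nrow(statistic), ncol(statistic),
           dimnames = dimnames(statistic))
  }
  out <- list(statistic = statistic,
              p = if (is.null(p)) empty(NA_real_) else p,
              q = if (is.null(q)) empty(NA_real_) else q,
              flag = if (is.null(flag)) empty("null") else flag,
              counts = counts,
              row_labels = rownames(statistic),
              col_labels = colnames(statistic),
              kind = kind)
  class(out) <- "met_assoc"
  out
}

#' @export
print.met_assoc <- function(x, ...) {
  cat("Association matrix (", x$kind, "): ",
      length(x$row_labels), " x ", length(x$col_labels), "\n", sep = "")
  n_sig <- sum(x$flag != "null", na.rm = TRUE)
  if (n_sig > 0L) {
    cat("  significant cells (q < 0.05):", n_sig,
        "(", sum(x$flag == "enriched", na.rm = TRUE), "enriched /",
        sum(x$flag == "depleted", na.rm = TRUE), "depleted )\n")
  }
  print(round(x$statistic, 3))
  invisible(x)
}

#' Metastasis-burden summary by primary site
#'
#' Counts the number of involved secondary sites per patient, summarizes
#' mean and standard deviation per primary, and tests for differences
#' across primaries with the Kruskal-Wallis rank test (tie-corrected).
#'
#' @param cohort a \code{met_cohort}.
#' @return a \code{met_burden}: data frame \code{per_primary} with
#'   \code{n, mean, sd} per primary plus the Kruskal-Wallis statistic and
#'   p-value.
#' @export
burden_summary <- function(cohort) {
  inc <- cohort$included
  if (nrow(inc) == 0L) stop("empty cohort")
  counts <- rowSums(met_matrix(cohort))
  grp <- factor(inc$primary_site, levels = primary_sites())
  absent <- levels(grp)[tabulate(grp, nbins = 16L) == 0L]
  if (length(absent) > 0L) {
    warning("primary site(s) with no patients dropped from the test: ",
            paste(absent, collapse = ", "))
  }
  grp <- droplevels(grp)
  per <- data.frame(
    primary = levels(grp),
    n = as.integer(table(grp)),
    mean = as.numeric(tapply(counts, grp, mean)),
    sd = as.numeric(tapply(counts, grp, stats::sd)),
    stringsAsFactors = FALSE
  )
  if (nlevels(grp) < 2L || length(unique(counts)) == 1L) {
    kw_stat <- 0; kw_p <- 1
  } else {
    kw <- stats::kruskal.test(counts, grp)
    kw_stat <- unname(kw$statistic); kw_p <- kw$p.value
  }
  out <- list(per_primary = per, kruskal_wallis_stat = kw_stat,
              kruskal_wallis_p = kw_p)
  class(out) <- "met_burden"
  out
}

#' @export
print.met_burden <- function(x, ...) {
  cat("Metastasis burden by primary site (number of involved sites)\n")
  df <- x$per_primary
  df$mean <- round(df$mean, 2); df$sd <- round(df$sd, 2)
  print(df, row.names = FALSE)
  cat("Kruskal-Wallis p =", format(x$kruskal_wallis_p, digits = 3), "\n")
  invisible(x)
}

#' Per-secondary-site hit frequency
#'
#' Fraction of included patients with a metastasis at each of the 20
#' secondary sites, plus a chi-square goodness-of-fit heterogeneity test of
#' the 20 hit counts against equal proportions.
#'
#' @param cohort a \code{met_cohort}.
#' @return list with \code{fraction} (named 20-vector), \code{hits} (named
#'   counts) and \code{p_heterogeneity}.
#' @export
site_frequency <- function(cohort) {
  if (cohort_size(cohort) == 0L) stop("empty cohort")
  m <- met_matrix(cohort)
  hits <- colSums(m)
  p_het <- if (sum(hits) > 0L) {
    stats::chisq.test(hits)$p.value
  } else NA_real_
  list(fraction = hits / nrow(m), hits = hits, p_heterogeneity = p_het)
}

#' Fractional association matrices
#'
#' \code{progression_matrix()}: 16 x 20 matrix whose cell (p, s) is the
#' fraction of patients with primary p that metastasized to secondary site
#' s. \code{origin_matrix()}: the reverse 20 x 16 view — the fraction of
#' metastases at site s that originate from primary p (rows sum to 1
#' whenever the site is hit). \code{cooccurrence_matrix()}: 20 x 20 Jaccard
#' matrix — for each pair of secondary sites, the fraction of patients with
#' metastases at both sites among patients with a metastasis at least at
#' one of the two.
#'
#' Primaries with no patients (or sites never hit) yield rows of \code{NA}.
#'
#' @param cohort a \code{met_cohort}.
#' @return a \code{met_assoc} with the \code{statistic} matrix filled
#'   (p/q/flag are not applicable to plain fractions and stay \code{NA}).
#' @export
progression_matrix <- function(cohort) {
  if (cohort_size(cohort) == 0L) stop("empty cohort")
  m <- met_matrix(cohort)
  grp <- factor(cohort$included$primary_site, levels = primary_sites())
  hits <- matrix(0, 16L, 20L, dimnames = list(primary_sites(),
                                              secondary_sites()))
  present <- rowsum(m, grp)                # rows = primaries present
  hits[rownames(present), ] <- present
  n_p <- tabulate(grp, nbins = 16L)
  stat <- hits / n_p
  stat[n_p == 0L, ] <- NA_real_
  dimnames(stat) <- list(primary_sites(), secondary_sites())
  a <- new_assoc(stat, kind = "progression fraction")
  a$n_primary <- stats::setNames(n_p, primary_sites())
  a
}

#' @rdname progression_matrix
#' @export
origin_matrix <- function(cohort) {
  if (cohort_size(cohort) == 0L) stop("empty cohort")
  m <- met_matrix(cohort)
  grp <- factor(cohort$included$primary_site, levels = primary_sites())
  joint <- matrix(0, 16L, 20L, dimnames = list(primary_sites(),
                                               secondary_sites()))
  present <- rowsum(m, grp)
  joint[rownames(present), ] <- present
  hits <- t(joint)                            # 20 x 16 counts
  n_s <- colSums(m)
  stat <- hits / n_s
  stat[n_s == 0L, ] <- NA_real_
  dimnames(stat) <- list(secondary_sites(), primary_sites())
  a <- new_assoc(stat, kind = "origin fraction")
  a$n_site <- n_s
  a
}

#' @rdname progression_matrix
#' @export
cooccurrence_matrix <- function(cohort) {
  if (cohort_size(cohort) == 0L) stop("empty cohort")
  m <- met_matrix(cohort)
  both <- crossprod(m)                       # |A intersect B|
  n_a <- diag(both)
  union <- outer(n_a, n_a, `+`) - both       # |A union B|
  stat <- both / union
  stat[union == 0] <- NA_real_
  dimnames(stat) <- list(secondary_sites(), secondary_sites())
  new_assoc(stat, kind = "co-occurrence (Jaccard)")
}

site_indicator <- function(cohort, label) {
  inc <- cohort$included
  if (label %in% secondary_sites()) {
    as.logical(inc[[paste0("met_", label)]])
  } else if (label %in% primary_sites()) {
    !is.na(inc$primary_site) & inc$primary_site == label
  } else {
    stop("unknown site label: ", label)
  }
}

#' Relative risk of association between two sites
#'
#' Computes \eqn{RR(a,b) = f(a \wedge b)/(f(a) f(b))} where the relative
#' frequencies \eqn{f} are taken over the full included cohort, together
#' with the two-sided Fisher exact p-value of the underlying 2 x 2 patient
#' table. \code{a} may be a primary-site label or a secondary-site code;
#' \code{b} is a secondary-site code.
#'
#' @param cohort a \code{met_cohort}.
#' @param a,b site labels.
#' @return list with \code{rr} (NA when \eqn{f(a)} or \eqn{f(b)} is zero),
#'   \code{p} and the 2 x 2 \code{counts} table.
#' @examples
#' \donttest{
#' coh <- apply_inclusion_filters(make_paper_fixture())
#' relative_risk(coh, "melanoma", "SPL")
#' }
#' @export
relative_risk <- function(cohort, a, b) {
  n <- cohort_size(cohort)
  if (n == 0L) stop("empty cohort")
  ia <- site_indicator(cohort, a)
  ib <- site_indicator(cohort, b)
  tab <- matrix(c(sum(ia & ib), sum(ia & !ib),
                  sum(!ia & ib), sum(!ia & !ib)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("a", "not_a"), c("b", "not_b")))
  fa <- sum(ia) / n; fb <- sum(ib) / n
  if (fa == 0 || fb == 0) {
    return(list(rr = NA_real_, p = 1, counts = tab))
  }
  rr <- (tab[1, 1] / n) / (fa * fb)
  p <- min(stats::fisher.test(tab)$p.value, 1)  # guard FP overshoot above 1
  list(rr = rr, p = p, counts = tab)
}

#' Relative-risk screen with FDR control
#'
#' Computes the full relative-risk matrix — either primary sites against
#' secondary sites (16 x 20) or all pairs of secondary sites (20 x 20,
#' symmetric, diagonal undefined) — with per-cell Fisher exact p-values,
#' then applies the Benjamini-Hochberg correction across all defined cells
#' of the matrix as a single family. Cells are flagged \code{enriched} when
#' q < 0.05 and RR > 1, \code{depleted} when q < 0.05 and RR < 1.
#' Undefined cells (zero-frequency margins) are excluded from the family.
#'
#' @param cohort a \code{met_cohort}.
#' @param mode \code{"primary_to_secondary"} or \code{"secondary_pairs"}.
#' @param alpha FDR level for flagging (default 0.05).
#' @return a \code{met_assoc} with \code{statistic} (RR), \code{p},
#'   \code{q} and \code{flag} matrices.
#' @export
rr_screen <- function(cohort, mode = c("primary_to_secondary",
                                       "secondary_pairs"),
                      alpha = 0.05) {
  mode <- match.arg(mode)
  if (cohort_size(cohort) == 0L) stop("empty cohort")
  rows <- if (mode == "primary_to_secondary") primary_sites() else {
    secondary_sites()
  }
  cols <- secondary_sites()
  rr <- p <- matrix(NA_real_, length(rows), length(cols),
                    dimnames = list(rows, cols))
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      if (mode == "secondary_pairs" && i == j) next    # diagonal undefined
      if (mode == "secondary_pairs" && i > j) next     # fill by symmetry
      res <- relative_risk(cohort, rows[i], cols[j])
      rr[i, j] <- res$rr
      p[i, j] <- if (is.na(res$rr)) NA_real_ else res$p
    }
  }
  if (mode == "secondary_pairs") {
    rr[lower.tri(rr)] <- t(rr)[lower.tri(rr)]
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  # BH family = defined, non-redundant cells of this matrix
  fam <- which(!is.na(p) & (mode != "secondary_pairs" |
                              row(p) < col(p)))
  q <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  q[fam] <- stats::p.adjust(p[fam], method = "BH")
  if (mode == "secondary_pairs") {
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
  }
  flag <- matrix("null", nrow(p), ncol(p), dimnames = dimnames(p))
  flag[!is.na(q) & q < alpha & !is.na(rr) & rr > 1] <- "enriched"
  flag[!is.na(q) & q < alpha & !is.na(rr) & rr < 1] <- "depleted"
  out <- new_assoc(rr, p = p, q = q, flag = flag,
                   kind = paste0("relative risk (", gsub("_", " ", mode), ")"))
  out$alpha <- alpha
  out$family_size <- length(fam)
  out
}

#' Write the matrices of an association object as TSV files
#'
#' Writes \code{statistic.tsv}, \code{p.tsv}, \code{q.tsv} and
#' \code{flags.tsv} (row/column headers from the vocabularies) plus a
#' \code{summary.json} into \code{dir}.
#'
#' @param assoc a \code{met_assoc}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_assoc <- function(assoc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) {
    utils::write.table(cbind(site = rownames(m), as.data.frame(m)),
                       file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(assoc$statistic, "statistic.tsv")
  wr(assoc$p, "p.tsv")
  wr(assoc$q, "q.tsv")
  wr(assoc$flag, "flags.tsv")
  jsonlite::write_json(
    list(kind = assoc$kind,
         n_cells = length(assoc$statistic),
         n_defined = sum(!is.na(assoc$statistic)),
         n_enriched = sum(assoc$flag == "enriched", na.rm = TRUE),
         n_depleted = sum(assoc$flag == "depleted", na.rm = TRUE),
         bh_family = "all defined cells of this matrix"),
    file.path(dir, "summary.json"), auto_unbox = TRUE)
  invisible(dir)
}
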