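#' Total-lifetime hazard analysis
#'
#' Cox proportional-hazards modelling of *total lifetime* — the time axis
#' is age at death, not post-diagnosis survival — describing the population
#' burden of tumors and metastases at given sites rather than individual
#' prognosis. Only cancer-related deaths count as events; deaths from
#' other causes are kept in the risk sets as censored observations.
#' Covariates are sex, the primary site (one-hot, lung as the reference,
#' it being the most common primary) and the 20 secondary-site indicators.
#' Ties are handled with the Breslow approximation by default (Efron by
#' flag); significance is per-covariate Wald. Left truncation is not
#' modelled.
#'
#' @param cohort a \code{met_cohort}; every record needs
#'   \code{age_at_death}.
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @return a \code{met_lifetime}: data frame \code{table} with
#'   \code{covariate, block, hr, ci_low, ci_high, wald_p}, the event and
#'   censoring counts, and the underlying \code{survival::coxph} fit.
#' @examples
#' \donttest{
#' coh <- apply_inclusion_filters(make_paper_fixture())
#' fit_lifetime(coh)
#' }
#' @export
fit_lifetime <- function(cohort, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  inc <- cohort$included
  if (nrow(inc) == 0L) stop("empty cohort")
  if (anyNA(inc$age_at_death)) {
    stop("age_at_death missing for ", sum(is.na(inc$age_at_death)),
         " record(s)")
  }
  event <- as.integer(inc$cancer_related_death)
  if (sum(event) < 2L) stop("fewer than 2 cancer-related deaths; cannot fit")

  prim <- factor(inc$primary_site,
                 levels = c("lung", setdiff(primary_sites(), "lung")))
  X_prim <- stats::model.matrix(~prim)[, -1L, drop = FALSE]
  colnames(X_prim) <- sub("^prim", "primary: ", colnames(X_prim))
  X_sex <- cbind("sex: male" = as.numeric(inc$sex == "male"))
  X_met <- met_matrix(cohort)
  colnames(X_met) <- paste0("met: ", colnames(X_met))
  X <- cbind(X_sex, X_prim, X_met)
  block <- c("sex", rep("primary", ncol(X_prim)), rep("secondary", 20L))

  const <- apply(X, 2L, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    message("dropping constant covariate(s): ",
            paste(colnames(X)[const], collapse = ", "))
    block <- block[!const]
    X <- X[, !const, drop = FALSE]
  }

  fit <- survival::coxph(survival::Surv(inc$age_at_death, event) ~ X,
                         ties = ties)
  if (any(is.na(stats::coef(fit)))) {
    bad <- colnames(X)[is.na(stats::coef(fit))]
    stop("Cox fit did not identify coefficient(s) for: ",
         paste(bad, collapse = ", "))
  }
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(
    covariate = colnames(X),
    block = block,
    hr = exp(b),
    ci_low = exp(b - 1.96 * se),
    ci_high = exp(b + 1.96 * se),
    wald_p = 2 * stats::pnorm(-abs(b / se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- list(table = tab, n_events = sum(event),
              n_censored = sum(1L - event), ties = ties, fit = fit)
  class(out) <- "met_lifetime"
  out
}

#' @export
print.met_lifetime <- function(x, ...) {
  cat("Total-lifetime Cox model (", x$ties, " ties): ", x$n_events,
      " events, ", x$n_censored, " censored\n", sep = "")
  df <- x$table
  df$hr <- round(df$hr, 2)
  df$ci <- sprintf("[%.2f, %.2f]", df$ci_low, df$ci_high)
  df$wald_p <- signif(df$wald_p, 2)
  print(df[, c("covariate", "block", "hr", "ci", "wald_p")],
        row.names = FALSE)
  invisible(x)
}

#' Write the lifetime table as TSV
#' @param result a \code{met_lifetime}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_lifetime <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
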