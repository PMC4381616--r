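#' Primary-site prediction from metastasis profiles
#'
#' Two complementary views of the cancer-of-unknown-primary question:
#' per-primary logistic regressions giving the odds ratio of each secondary
#' site for a given primary, and a multinomial classifier over all 16
#' primaries validated by repeated random train/test splitting with top-k
#' accuracy reporting.
#' @name prediction
NULL

# Ridge-penalized logistic regression by Newton/IRLS.
# Penalty 0.5 * lambda * sum(beta_j^2) over the non-intercept coefficients;
# a fixed weak lambda keeps rare-site covariates finite under perfect
# separation while leaving large-sample estimates essentially unbiased.
# Wald covariance from the penalized information matrix.
ridge_logistic <- function(X, y, lambda = 1, max_iter = 100L, tol = 1e-9) {
  X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  V <- solve(crossprod(X * w, X) + pen)
  list(coef = stats::setNames(drop(beta), colnames(X)),
       se = stats::setNames(sqrt(diag(V)), colnames(X)),
       converged = it < max_iter, iter = it)
}

#' Per-primary logistic odds-ratio profiles
#'
#' For each primary site, fits a multivariate logistic regression of the
#' indicator (primary = target) on the 20 secondary-site indicators and
#' reports the coefficient exponentials as odds ratios with 95% Wald
#' intervals. A fixed weak ridge penalty (default \code{lambda = 1} on the
#' non-intercept coefficients) keeps estimates finite when a rare site
#' perfectly separates a small stratum; covariates whose marginal 2 x 2
#' table against the outcome has an empty cell are flagged as
#' separation-prone. Benjamini-Hochberg correction is applied across the
#' 20 covariates within each profile.
#'
#' @param cohort a \code{met_cohort}.
#' @param primaries primaries to profile (default: all present in the
#'   cohort). Requesting a primary absent from the cohort is an error.
#' @param lambda ridge penalty strength.
#' @param alpha FDR level for the higher/lower flags.
#' @return a \code{met_or_profiles}: named list of per-primary data frames
#'   with \code{site, or, ci_low, ci_high, p, q, flag, separation}.
#' @export
fit_or_profiles <- function(cohort, primaries = NULL, lambda = 1,
                            alpha = 0.05) {
  inc <- cohort$included
  if (nrow(inc) == 0L) stop("empty cohort")
  present <- unique(inc$primary_site)
  if (is.null(primaries)) {
    primaries <- intersect(primary_sites(), present)
  }
  missing <- setdiff(primaries, present)
  if (length(missing) > 0L) {
    stop("primary site(s) absent from cohort: ",
         paste(missing, collapse = ", "))
  }
  X <- met_matrix(cohort)
  profiles <- lapply(primaries, function(target) {
    y <- as.numeric(inc$primary_site == target)
    fit <- ridge_logistic(X, y, lambda = lambda)
    b <- fit$coef[-1L]
    se <- fit$se[-1L]
    z <- b / se
    p <- 2 * stats::pnorm(-abs(z))
    q <- stats::p.adjust(p, method = "BH")
    sep <- vapply(seq_len(ncol(X)), function(j) {
      tab <- table(factor(X[, j], levels = 0:1), factor(y, levels = 0:1))
      any(tab == 0L)
    }, logical(1))
    flag <- rep("null", length(b))
    flag[q < alpha & b > 0] <- "higher"
    flag[q < alpha & b < 0] <- "lower"
    data.frame(site = secondary_sites(),
               or = exp(b),
               ci_low = exp(b - 1.96 * se),
               ci_high = exp(b + 1.96 * se),
               p = p, q = q, flag = flag, separation = sep,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(profiles) <- primaries
  structure(list(profiles = profiles, lambda = lambda,
                 n = nrow(inc)), class = "met_or_profiles")
}

#' @export
print.met_or_profiles <- function(x, ...) {
  cat("Per-primary logistic OR profiles (", length(x$profiles),
      " primaries, ridge lambda = ", x$lambda, ")\n", sep = "")
  for (nm in names(x$profiles)) {
    df <- x$profiles[[nm]]
    sig <- df[df$flag != "null", ]
    cat("  ", nm, ": ", nrow(sig), " significant site(s)",
        if (nrow(sig) > 0) paste0(" [",
          paste0(sig$site, " OR=", signif(sig$or, 3), collapse = ", "), "]"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Fit a multinomial primary-site classifier
#'
#' Multinomial logistic regression of the primary site on the 20
#' secondary-site indicators (via \code{nnet::multinom}). A training set
#' with a single primary class yields a degenerate classifier that always
#' returns that class with probability 1 (with a message).
#'
#' @param train a \code{met_cohort} or registry data frame of training
#'   patients.
#' @return a \code{met_classifier} with a \code{predict} method returning
#'   a probability matrix (rows = patients, columns = the classes present
#'   in training, vocabulary order; rows sum to 1).
#' @export
fit_multinomial <- function(train) {
  inc <- if (inherits(train, "met_cohort")) train$included else train
  if (nrow(inc) == 0L) stop("empty training set")
  classes <- intersect(primary_sites(), unique(inc$primary_site))
  if (length(classes) < 2L) {
    message("single-class training set; returning degenerate classifier")
    out <- list(classes = classes, fit = NULL, degenerate = TRUE)
    class(out) <- "met_classifier"
    return(out)
  }
  dat <- as.data.frame(inc[, met_cols(), drop = FALSE])
  dat$.primary <- factor(inc$primary_site, levels = classes)
  fit <- nnet::multinom(.primary ~ ., data = dat, trace = FALSE,
                        maxit = 500L, MaxNWts = 5000L)
  out <- list(classes = classes, fit = fit, degenerate = FALSE)
  class(out) <- "met_classifier"
  out
}

#' @export
predict.met_classifier <- function(object, newdata, ...) {
  inc <- if (inherits(newdata, "met_cohort")) newdata$included else newdata
  n <- nrow(inc)
  if (object$degenerate) {
    pr <- matrix(1, n, 1L, dimnames = list(NULL, object$classes))
    return(pr)
  }
  dat <- as.data.frame(inc[, met_cols(), drop = FALSE])
  pr <- stats::predict(object$fit, newdata = dat, type = "probs")
  if (is.null(dim(pr))) {
    # two-class fits return P(second class); single rows return one vector
    if (length(object$classes) == 2L) {
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- object$classes
    } else {
      pr <- matrix(pr, nrow = 1L, dimnames = list(NULL, names(pr)))
    }
  }
  pr[, object$classes, drop = FALSE]
}

#' Top-k prediction accuracy
#'
#' Fraction of test patients whose true primary is among the k classes
#' with the highest predicted probability. Probability ties are broken by
#' the fixed vocabulary order (determinism over optimism); a true class
#' the classifier was never trained on scores as a miss.
#'
#' @param classifier a \code{met_classifier}.
#' @param test a \code{met_cohort} or registry data frame.
#' @param k number of top predictions considered (1 to number of classes).
#' @return accuracy in [0, 1].
#' @export
topk_hits <- function(classifier, test, k = 1L) {
  inc <- if (inherits(test, "met_cohort")) test$included else test
  if (nrow(inc) == 0L) stop("empty test set")
  pr <- predict(classifier, inc)
  truth <- inc$primary_site
  vocab_rank <- match(colnames(pr), primary_sites())
  hits <- vapply(seq_len(nrow(pr)), function(i) {
    ord <- order(-pr[i, ], vocab_rank)
    truth[i] %in% colnames(pr)[ord[seq_len(min(k, ncol(pr)))]]
  }, logical(1))
  mean(hits)
}

#' Repeated random subsampling cross-validation of primary-site prediction
#'
#' Draws \code{n_splits} independent train/test partitions (training size
#' \code{floor(train_fraction * n)}, sampled without replacement, not
#' stratified), fits the multinomial classifier on each training set and
#' scores top-1/2/3 accuracy on the held-out third. Summaries are the mean
#' and the 2.5th/97.5th percentiles across splits; per-primary top-3
#' recall is computed by pooling test-set outcomes over all splits.
#'
#' @param cohort a \code{met_cohort}.
#' @param n_splits number of random splits (the full protocol uses 1000).
#' @param train_fraction fraction of patients in each training set.
#' @param seed integer seed; the whole report is reproducible from it.
#' @return a \code{met_cv}: per-split accuracies, summary with percentile
#'   confidence intervals, pooled per-primary top-3 recall.
#' @export
cross_validate <- function(cohort, n_splits = 1000L, train_fraction = 2 / 3,
                           seed = 1L) {
  inc <- cohort$included
  n <- nrow(inc)
  if (n < 30L) stop("cohort too small for cross-validation (n < 30)")
  n_train <- floor(train_fraction * n)
  with_seed(seed, {
    acc <- matrix(NA_real_, n_splits, 3L,
                  dimnames = list(NULL, c("top1", "top2", "top3")))
    pool_hit <- pool_n <- stats::setNames(numeric(16L), primary_sites())
    n_incomplete <- 0L
    for (s in seq_len(n_splits)) {
      idx <- sample.int(n, n_train)
      train <- inc[idx, , drop = FALSE]
      test <- inc[-idx, , drop = FALSE]
      if (length(unique(train$primary_site)) <
          length(unique(inc$primary_site))) {
        n_incomplete <- n_incomplete + 1L
      }
      clf <- fit_multinomial(train)
      pr <- predict(clf, test)
      vocab_rank <- match(colnames(pr), primary_sites())
      truth <- test$primary_site
      rank_of_truth <- vapply(seq_len(nrow(pr)), function(i) {
        ord <- order(-pr[i, ], vocab_rank)
        pos <- match(truth[i], colnames(pr)[ord])
        if (is.na(pos)) Inf else pos
      }, numeric(1))
      acc[s, ] <- c(mean(rank_of_truth <= 1), mean(rank_of_truth <= 2),
                    mean(rank_of_truth <= 3))
      t3 <- tapply(rank_of_truth <= 3, factor(truth, primary_sites()), sum)
      tn <- table(factor(truth, primary_sites()))
      pool_hit <- pool_hit + ifelse(is.na(t3), 0, t3)
      pool_n <- pool_n + as.numeric(tn)
    }
    summ <- apply(acc, 2L, function(v) {
      c(mean = mean(v), ci_low = unname(stats::quantile(v, 0.025)),
        ci_high = unname(stats::quantile(v, 0.975)))
    })
    if (n_incomplete > 0L) {
      message(n_incomplete, " split(s) had training sets missing a class; ",
              "their test rows were scored against the fitted classes")
    }
    out <- list(n_splits = n_splits, train_fraction = train_fraction,
                n_train = n_train, n = n, seed = seed,
                per_split = as.data.frame(acc),
                summary = t(summ),
                per_primary_top3 = ifelse(pool_n > 0, pool_hit / pool_n,
                                          NA_real_),
                n_incomplete_train = n_incomplete)
    class(out) <- "met_cv"
    out
  })
}

#' @export
print.met_cv <- function(x, ...) {
  cat("Repeated random subsampling CV: ", x$n_splits, " splits, train ",
      x$n_train, "/", x$n, " patients\n", sep = "")
  s <- x$summary
  for (k in rownames(s)) {
    cat(sprintf("  %s accuracy: %.1f%% (%.1f%% - %.1f%%)\n", k,
                100 * s[k, "mean"], 100 * s[k, "ci_low"],
                100 * s[k, "ci_high"]))
  }
  top <- sort(x$per_primary_top3, decreasing = TRUE)
  top <- top[!is.na(top)]
  cat("  best-recovered primaries (pooled top-3 recall):",
      paste0(names(top)[seq_len(min(3, length(top)))], " ",
             round(100 * top[seq_len(min(3, length(top)))]), "%",
             collapse = ", "), "\n")
  invisible(x)
}
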