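# Fixture builders and independent oracles used across the suite.

# Build a registry data frame row-by-row. `mets` is a list of character
# vectors of secondary-site codes (one element per patient).
make_registry_df <- function(primary, mets,
                             has_cancer = !is.na(primary),
                             n_primaries = as.integer(has_cancer),
                             age = rep(70, length(primary)),
                             sex = rep("male", length(primary)),
                             histology = rep("unknown", length(primary)),
                             nodal = rep("unknown", length(primary)),
                             death = has_cancer) {
  n <- length(primary)
  m <- matrix(0L, n, 20L, dimnames = list(NULL,
                                          paste0("met_", secondary_sites())))
  for (i in seq_len(n)) {
    if (length(mets[[i]]) > 0L) m[i, paste0("met_", mets[[i]])] <- 1L
  }
  df <- data.frame(
    id = sprintf("T%04d", seq_len(n)),
    age_at_death = age,
    sex = sex,
    autopsy_year = rep(2005L, n),
    has_cancer = has_cancer,
    n_primaries = n_primaries,
    primary_site = primary,
    histology = histology,
    nodal_status = nodal,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(m))
  df$cancer_related_death <- death
  df
}

make_cohort <- function(...) apply_inclusion_filters(make_registry_df(...))

# Random small eligible cohort for property tests (every patient has >= 1
# metastasis bit so the inclusion filter keeps everyone).
random_cohort <- function(n, n_primaries_used = 4, seed) {
  set.seed(seed)
  prim <- sample(primary_sites()[seq_len(n_primaries_used)], n,
                 replace = TRUE)
  mets <- lapply(seq_len(n), function(i) {
    k <- sample(1:5, 1)
    sample(secondary_sites(), k)
  })
  make_cohort(prim, mets, sex = sample(c("male", "female"), n, TRUE))
}

# --- two-sided Fisher exact p by full hypergeometric enumeration ---------
# table = matrix(c(x11, x12, x21, x22), 2, byrow = TRUE); two-sided p is
# the sum of probabilities of all tables (fixed margins) no more likely
# than the observed one.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k) {
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[ks == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- relative risk by direct patient enumeration -------------------------
rr_oracle <- function(cohort, a, b) {
  inc <- cohort$included
  in_a <- if (a %in% secondary_sites()) {
    inc[[paste0("met_", a)]] == 1L
  } else inc$primary_site == a
  in_b <- inc[[paste0("met_", b)]] == 1L
  n <- nrow(inc)
  fa <- mean(in_a); fb <- mean(in_b)
  if (fa == 0 || fb == 0) return(NA_real_)
  mean(in_a & in_b) / (fa * fb)
}

# --- Benjamini-Hochberg step-up by hand ----------------------------------
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# --- brute-force Breslow partial-likelihood maximizer --------------------
# one covariate vector x, all-events, arbitrary times (ties allowed).
cox_oracle_loglik <- function(beta, time, x) {
  ll <- 0
  for (tt in unique(time[order(time)])) {
    dead <- which(time == tt)
    risk <- which(time >= tt)
    ll <- ll + beta * sum(x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}
cox_oracle <- function(time, x) {
  stats::optimize(function(b) -cox_oracle_loglik(b, time, x),
                  c(-15, 15))$minimum
}
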