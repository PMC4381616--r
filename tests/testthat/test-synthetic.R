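test_that("identical config and seed give byte-identical registries", {
  cfg <- synthetic_config(n_total = 800, seed = 42)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  f1 <- tempfile(); f2 <- tempfile()
  write_registry(r1, f1); write_registry(r2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  r3 <- generate_registry(synthetic_config(n_total = 800, seed = 43))
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("degenerate marginals give exactly the forced site", {
  mp <- matrix(0, 16, 20, dimnames = list(primary_sites(),
                                          secondary_sites()))
  mp[, "HEP"] <- 1
  cfg <- synthetic_config(
    n_total = 200,
    stratum_fractions = c(no_cancer = 0, cancer_no_mets = 0,
                          rare_or_multiple = 0),
    marginal_probs = mp, seed = 5)
  reg <- generate_registry(cfg)
  m <- met_matrix(reg)
  expect_true(all(m[, "HEP"] == 1L))
  expect_true(all(m[, setdiff(secondary_sites(), "HEP")] == 0L))
})

test_that("marginals are recovered under independence and RRs sit near 1", {
  q <- 0.3
  mp <- matrix(q, 16, 20, dimnames = list(primary_sites(),
                                          secondary_sites()))
  cp <- diag(20); dimnames(cp) <- list(secondary_sites(), secondary_sites())
  cfg <- synthetic_config(
    n_total = 20000,
    stratum_fractions = c(no_cancer = 0, cancer_no_mets = 0,
                          rare_or_multiple = 0),
    marginal_probs = mp, coupling = cp, seed = 11)
  coh <- apply_inclusion_filters(generate_registry(cfg))
  n <- nrow(coh$included)
  freq <- colMeans(met_matrix(coh))
  # the all-zero redraw inflates marginals slightly; with q = 0.3 the
  # all-zero probability is (1-q)^20 ~ 8e-4, far below a binomial SE
  se <- sqrt(q * (1 - q) / n)
  expect_true(all(abs(freq - q) < 3 * se + q * (1 - q)^20))
  rrs <- rr_screen(coh, "secondary_pairs")
  off <- rrs$statistic[upper.tri(rrs$statistic)]
  expect_lt(abs(mean(off) - 1), 0.02)
})

test_that("distinct per-primary marginals are recovered at n = 20000", {
  set.seed(77)
  mp <- matrix(runif(16 * 20, 0.2, 0.8), 16, 20,
               dimnames = list(primary_sites(), secondary_sites()))
  cp <- diag(20); dimnames(cp) <- list(secondary_sites(), secondary_sites())
  cfg <- synthetic_config(
    n_total = 20000,
    stratum_fractions = c(no_cancer = 0, cancer_no_mets = 0,
                          rare_or_multiple = 0),
    primary_mixture = rep(1 / 16, 16),
    marginal_probs = mp, coupling = cp, seed = 19)
  coh <- apply_inclusion_filters(generate_registry(cfg))
  inc <- coh$included
  m <- met_matrix(coh)
  for (p in primary_sites()) {
    rows <- inc$primary_site == p
    n_p <- sum(rows)
    emp <- colMeans(m[rows, , drop = FALSE])
    tgt <- mp[p, ]
    se <- sqrt(tgt * (1 - tgt) / n_p)
    # eligibility conditioning inflates marginals by at most P(all zero),
    # bounded here by 0.8^20 < 0.012
    expect_true(all(abs(emp - tgt) < 3 * se + 0.012), info = p)
  }
})

test_that("raising a coupling entry raises the co-occurrence RR", {
  mp <- matrix(0.25, 16, 20, dimnames = list(primary_sites(),
                                             secondary_sites()))
  base_cp <- diag(20)
  dimnames(base_cp) <- list(secondary_sites(), secondary_sites())
  high_cp <- base_cp
  high_cp["HEP", "PUL"] <- high_cp["PUL", "HEP"] <- 0.6
  rr_at <- function(cp) {
    cfg <- synthetic_config(
      n_total = 8000,
      stratum_fractions = c(no_cancer = 0, cancer_no_mets = 0,
                            rare_or_multiple = 0),
      marginal_probs = mp, coupling = cp, seed = 303)
    coh <- apply_inclusion_filters(generate_registry(cfg))
    relative_risk(coh, "HEP", "PUL")$rr
  }
  expect_gt(rr_at(high_cp), rr_at(base_cp) + 0.3)
})

test_that("indefinite couplings are repaired by clipping or rejected", {
  cp <- diag(20); dimnames(cp) <- list(secondary_sites(), secondary_sites())
  cp["HEP", "PUL"] <- cp["PUL", "HEP"] <- 0.7
  cp["HEP", "OSS"] <- cp["OSS", "HEP"] <- 0.7
  cp["PUL", "OSS"] <- cp["OSS", "PUL"] <- -0.2   # mildly indefinite
  expect_message(cfg <- synthetic_config(coupling = cp, n_total = 10),
                 "clipping")
  ev <- eigen(cfg$coupling, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(unname(diag(cfg$coupling)), rep(1, 20), tolerance = 1e-8)
  bad <- matrix(-0.8, 20, 20); diag(bad) <- 1
  dimnames(bad) <- list(secondary_sites(), secondary_sites())
  expect_error(synthetic_config(coupling = bad, n_total = 10),
               "positive semi-definite")
})

test_that("the bundled worked-example fixture reproduces the stratum counts", {
  reg <- make_paper_fixture()
  expect_equal(nrow(reg), 6597L)
  coh <- apply_inclusion_filters(reg)
  expect_equal(nrow(coh$included), 1008L)
  expect_equal(unname(coh$exclusions), c(4497L, 1016L, 76L))
  expect_setequal(unique(coh$included$primary_site), primary_sites())
  expect_true(all(rowSums(met_matrix(coh)) >= 1L))
})

test_that("YAML configs mirror the constructor arguments", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_total: 123",
    "seed: 9",
    "cancer_death_prob: 0.5",
    "stratum_fractions:",
    "  no_cancer: 0.2",
    "  cancer_no_mets: 0.1",
    "  rare_or_multiple: 0.0"
  ), f)
  cfg <- read_synthetic_config(f)
  expect_equal(cfg$n_total, 123L)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$cancer_death_prob, 0.5)
  expect_equal(unname(cfg$stratum_fractions["no_cancer"]), 0.2)
  reg <- generate_registry(cfg)
  expect_equal(nrow(reg), 123L)
})
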