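test_that("burden summary: degenerate and hand-computed rank tests", {
  # identical counts everywhere -> H = 0, p = 1
  coh <- suppressWarnings(make_cohort(
    rep(c("lung", "breast"), each = 3),
    replicate(6, c("HEP", "PUL"), simplify = FALSE)))
  b <- suppressWarnings(burden_summary(coh))
  expect_equal(b$kruskal_wallis_p, 1)
  expect_true(all(b$per_primary$mean == 2))

  # groups {1,1,1} vs {5,5,5}: tie-corrected H computed by hand from ranks
  mets <- c(replicate(3, "HEP", simplify = FALSE),
            replicate(3, c("HEP", "PUL", "OSS", "BRA", "LYM"),
                      simplify = FALSE))
  coh2 <- make_cohort(rep(c("liver", "melanoma"), each = 3), mets)
  b2 <- suppressWarnings(burden_summary(coh2))
  expect_equal(b2$per_primary$mean[b2$per_primary$primary == "liver"], 1)
  expect_equal(b2$per_primary$mean[b2$per_primary$primary == "melanoma"], 5)
  # ranks: {2,2,2} and {5,5,5}; H_unadj = 12/(6*7)*(6^2/3 + 15^2/3) - 3*7
  h_unadj <- 12 / 42 * (36 / 3 + 225 / 3) - 21
  h <- h_unadj / (1 - (24 + 24) / (216 - 6))
  expect_equal(b2$kruskal_wallis_stat, h, tolerance = 1e-12)
  expect_equal(b2$kruskal_wallis_p, pchisq(h, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_warning(burden_summary(coh2), "no patients")
})

test_that("site frequencies are direct counts", {
  mets <- c(replicate(6, "HEP", simplify = FALSE),
            replicate(4, "PUL", simplify = FALSE))
  coh <- make_cohort(rep("lung", 10), mets)
  sf <- suppressWarnings(site_frequency(coh))  # tiny counts: chisq warning
  expect_equal(unname(sf$fraction["HEP"]), 0.6)
  expect_equal(unname(sf$fraction["PUL"]), 0.4)
  all_sites <- make_cohort(rep("lung", 3),
                           replicate(3, secondary_sites(),
                                     simplify = FALSE))
  expect_true(all(suppressWarnings(site_frequency(all_sites))$fraction == 1))
})

test_that("fractional matrices match direct counts", {
  coh <- make_cohort(
    c(rep("breast", 4), "lung"),
    list("HEP", "HEP", c("HEP", "BRA"), "OSS", c("BRA", "PUL")))
  prog <- progression_matrix(coh)
  expect_equal(unname(prog$statistic["breast", "HEP"]), 0.75)
  expect_equal(unname(prog$statistic["lung", "PUL"]), 1)
  expect_true(all(is.na(prog$statistic["ovary", ])))  # no patients
  org <- origin_matrix(coh)
  expect_equal(unname(org$statistic["BRA", "lung"]), 0.5)
  expect_equal(unname(org$statistic["BRA", "breast"]), 0.5)
  # rows of the origin matrix sum to 1 over primaries whenever hit
  hit <- rowSums(org$statistic, na.rm = TRUE)[colSums(met_matrix(coh)) > 0]
  expect_true(all(abs(hit - 1) < 1e-12))
  single <- make_cohort(rep("prostate", 3),
                        replicate(3, "OSS", simplify = FALSE))
  sp <- progression_matrix(single)$statistic["prostate", ]
  expect_equal(unname(sp["OSS"]), 1)
  expect_equal(sum(sp), 1)
})

test_that("co-occurrence matrix is the Jaccard index of patient sets", {
  # A = {1,2,3} (HEP), B = {3,4} (PUL): |A&B|/|A|B| = 1/4
  coh <- make_cohort(rep("lung", 5),
                     list("HEP", "HEP", c("HEP", "PUL"), "PUL", "OSS"))
  cc <- cooccurrence_matrix(coh)$statistic
  expect_equal(unname(cc["HEP", "PUL"]), 0.25)
  expect_equal(unname(cc["HEP", "OSS"]), 0)       # disjoint
  expect_equal(unname(cc["HEP", "HEP"]), 1)       # A = B nonempty
  expect_true(is.na(cc["MEN", "THY"]))            # empty union
  expect_identical(cc, t(cc))
})

test_that("progression/origin counts are mutually consistent", {
  for (seed in 1:4) {
    coh <- random_cohort(n = 40, n_primaries_used = 5, seed = seed)
    prog <- progression_matrix(coh)
    org <- origin_matrix(coh)
    m <- met_matrix(coh)
    grp <- coh$included$primary_site
    n_p <- table(factor(grp, primary_sites()))
    n_s <- colSums(m)
    for (p in primary_sites()[1:5]) {
      for (s in secondary_sites()) {
        joint <- sum(m[grp == p, s])
        if (n_p[[p]] > 0) {
          expect_equal(prog$statistic[p, s] * n_p[[p]], joint,
                       tolerance = 1e-9)
        }
        if (n_s[[s]] > 0) {
          expect_equal(org$statistic[s, p] * n_s[[s]], joint,
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("relative risk follows the frequency-ratio definition", {
  # n = 10, |a| = 4, |b| = 5, |a&b| = 3 -> RR = 0.3/(0.4*0.5) = 1.5
  prim <- c(rep("breast", 4), rep("lung", 6))
  mets <- list(c("HEP"), c("HEP"), c("HEP"), c("OSS"),
               c("HEP", "PUL"), c("HEP", "PUL"), "PUL", "PUL", "PUL", "PUL")
  coh <- make_cohort(prim, mets)
  r <- relative_risk(coh, "breast", "HEP")
  expect_equal(r$rr, 1.5)
  expect_equal(as.vector(r$counts), c(3, 2, 1, 4))
  # b present in every patient -> RR = 1
  all_b <- make_cohort(rep(c("lung", "breast"), 3),
                       replicate(6, c("HEP"), simplify = FALSE))
  expect_equal(relative_risk(all_b, "lung", "HEP")$rr, 1)
  # never co-occurring -> RR = 0
  disj <- make_cohort(rep("lung", 4),
                      list("HEP", "HEP", "PUL", "PUL"))
  expect_equal(relative_risk(disj, "HEP", "PUL")$rr, 0)
  # zero-frequency margin -> undefined with p = 1
  expect_true(is.na(relative_risk(disj, "OSS", "HEP")$rr))
  expect_equal(relative_risk(disj, "OSS", "HEP")$p, 1)
})

test_that("relative risk equals the brute-force oracle on small cohorts", {
  for (seed in 1:6) {
    coh <- random_cohort(n = sample(8:30, 1), n_primaries_used = 3,
                         seed = 100 + seed)
    labels <- c(primary_sites()[1:3], secondary_sites())
    for (a in labels) {
      for (b in secondary_sites()) {
        got <- relative_risk(coh, a, b)
        expect_equal(got$rr, rr_oracle(coh, a, b), tolerance = 1e-12,
                     info = paste(seed, a, b))
        if (!is.na(got$rr)) {
          expect_equal(got$p, fisher_oracle(got$counts), tolerance = 1e-9,
                       info = paste(seed, a, b))
        }
      }
    }
  }
})

test_that("rr_screen applies BH per matrix and flags consistently", {
  coh <- random_cohort(n = 60, n_primaries_used = 6, seed = 9)
  scr <- rr_screen(coh, "primary_to_secondary")
  defined <- !is.na(scr$p)
  expect_true(all(scr$q[defined] >= scr$p[defined]))
  expect_equal(scr$q[defined], bh_oracle(scr$p[defined]), tolerance = 1e-12)
  sig <- scr$flag != "null"
  expect_true(all(scr$q[sig] < 0.05))
  expect_true(all(is.na(scr$q[!defined])))
  pairs <- rr_screen(coh, "secondary_pairs")
  expect_identical(pairs$statistic, t(pairs$statistic))
  expect_identical(pairs$q, t(pairs$q))
  expect_true(all(is.na(diag(pairs$statistic))))
})

test_that("BH step-up matches the hand calculation", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("write_assoc emits the four matrices plus a summary", {
  coh <- random_cohort(n = 30, n_primaries_used = 4, seed = 2)
  scr <- rr_screen(coh)
  d <- tempfile()
  write_assoc(scr, d)
  expect_setequal(list.files(d), c("statistic.tsv", "p.tsv", "q.tsv",
                                   "flags.tsv", "summary.json"))
  back <- utils::read.delim(file.path(d, "statistic.tsv"), row.names = 1)
  expect_equal(as.matrix(back), scr$statistic, tolerance = 1e-9,
               ignore_attr = TRUE)
})
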