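test_that("vectorised rank-sum p-values agree with wilcox.test", {
  set.seed(6)
  x <- matrix(round(rexp(80 * 6), 1), 80, 6) # ties present
  x[, 3] <- 0                                # constant feature
  labels <- rep(c(1, 2), c(25, 55))
  tb <- test_cluster_features(x, labels, 1, method = "ranksum")
  for (v in c(1, 2, 4, 5, 6)) {
    ref <- suppressWarnings(
      stats::wilcox.test(x[labels == 1, v], x[labels == 2, v],
                         alternative = "greater", exact = FALSE,
                         correct = TRUE))
    got <- tb$p[tb$concept_id == paste0("f", v)]
    expect_equal(got, ref$p.value, tolerance = 1e-10)
  }
  expect_equal(tb$p[tb$concept_id == "f3"], 1) # constant: recorded, no error
})

test_that("a feature expressed only inside the cluster is significant", {
  set.seed(7)
  x <- matrix(0, 60, 5)
  x[, 1:4] <- runif(60 * 4)
  labels <- rep(c(1, 2), each = 30)
  x[labels == 1, 5] <- runif(30, 0.5, 1)
  for (m in c("ranksum", "ttest")) {
    tb <- test_cluster_features(x, labels, 1, alpha = 0.05, method = m)
    expect_true(tb$significant[tb$concept_id == "f5"])
  }
  expect_error(test_cluster_features(x, c(1, rep(2, 59)), 1), "fewer than 2")
})

test_that("bonferroni significant sets are monotone in alpha", {
  set.seed(8)
  x <- matrix(rnorm(100 * 20), 100, 20)
  labels <- sample(1:2, 100, replace = TRUE)
  x[labels == 1, 1:6] <- x[labels == 1, 1:6] + seq(0.1, 1.1, length.out = 6)
  tb <- test_cluster_features(x, labels, 1)
  strict <- tb$concept_id[tb$p_adj < 0.01]
  loose <- tb$concept_id[tb$p_adj < 0.1]
  expect_true(all(strict %in% loose))
  # sorted by raw p, adjusted = min(1, p * V)
  expect_false(is.unsorted(tb$p))
  expect_equal(tb$p_adj, pmin(1, tb$p * 20))
})

test_that("the rank-sum path is invariant to monotone feature transforms", {
  set.seed(9)
  x <- matrix(rexp(50 * 4), 50, 4)
  labels <- sample(1:2, 50, replace = TRUE)
  a <- test_cluster_features(x, labels, 1, method = "ranksum")
  b <- test_cluster_features(exp(x), labels, 1, method = "ranksum")
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("significant_vocabularies matches per-cluster test calls", {
  co <- small_cohort()
  b <- build_snapshot_matrix(co$mentions)
  tl <- truth_labels(co, b$matrix)
  vs <- significant_vocabularies(b$matrix, tl, alpha = 0.05)
  for (cl in c(1, 3)) {
    tb <- test_cluster_features(b$matrix, tl, cl, alpha = 0.05)
    expect_setequal(vs[[cl]], tb$concept_id[tb$significant])
  }
})

test_that("planted signatures are recovered and competitors excluded", {
  co <- small_cohort() # signature_lift = 20
  b <- build_snapshot_matrix(co$mentions)
  tl <- truth_labels(co, b$matrix)
  vs <- significant_vocabularies(b$matrix, tl, alpha = 0.05)
  for (g in 1:4) {
    sig <- intersect(co$truth$state_signatures[[g]], b$matrix$vocabulary)
    expect_true(all(sig %in% vs[[g]]))
    others <- setdiff(unlist(co$truth$state_signatures[-g]),
                      co$truth$state_signatures[[g]])
    expect_length(intersect(vs[[g]], others), 0)
  }
})

test_that("keyword grouping is case-insensitive, first-declared wins", {
  map <- data.frame(phenotype = c("anemia", "kidney disease", "anemia"),
                    keyword = c("anemia", "kidney", "iron"),
                    stringsAsFactors = FALSE)
  gm <- group_complaints(c("Iron-deficiency anemia", "Chronic Kidney Disease",
                           "Dyspnea"), map)
  expect_equal(gm$phenotype, c("anemia", "kidney disease", NA))
  # overlap: "anemia of kidney disease" matches both; first declared wins
  gm2 <- group_complaints("Anemia of kidney disease", map)
  expect_equal(gm2$phenotype, "anemia")
  expect_error(group_complaints("x", map[0, ]), "empty")
})

test_that("phenotype presence and enrichment follow the 2x2 arithmetic", {
  # toy: 40 in-cluster (30 with phenotype), 60 outside (10 with phenotype)
  presence <- matrix(c(rep(TRUE, 30), rep(FALSE, 10),
                       rep(TRUE, 10), rep(FALSE, 50)), ncol = 1,
                     dimnames = list(NULL, "ph"))
  labels <- rep(c(1, 2), c(40, 60))
  en <- phenotype_enrichment(presence, labels)
  r1 <- en[en$cluster == 1, ]
  expect_equal(r1$prevalence, 75)
  expect_equal(r1$odds_ratio, (30 * 50) / (10 * 10)) # = 15
  expect_false(r1$corrected)

  # balanced: equal prevalence inside and out -> OR exactly 1
  presence2 <- matrix(rep(c(TRUE, FALSE), 40), ncol = 1,
                      dimnames = list(NULL, "ph"))
  en2 <- phenotype_enrichment(presence2, rep(c(1, 2), each = 40))
  expect_equal(en2$odds_ratio, c(1, 1))

  # phenotype everywhere in cluster, nowhere outside: corrected, finite, huge
  presence3 <- matrix(rep(c(TRUE, FALSE), each = 20), ncol = 1,
                      dimnames = list(NULL, "ph"))
  en3 <- phenotype_enrichment(presence3, rep(c(1, 2), each = 20))
  expect_true(en3$corrected[1])
  expect_true(is.finite(en3$odds_ratio[1]))
  expect_gt(en3$odds_ratio[1], 100)
  expect_equal(en3$prevalence[1], 100)
})

test_that("clinical summaries cap age at 90 and window BMI correctly", {
  rows <- data.frame(patient_id = c("P1", "P1", "P2"),
                     bin_index = c(0L, 2L, 0L),
                     anchor_day = c(0, 0, 0))
  demo <- data.frame(patient_id = c("P1", "P2"),
                     birth_day = c(-round(95 * 365.25), -round(40 * 365.25)),
                     sex = c("F", "M"), stringsAsFactors = FALSE)
  bmi <- data.frame(patient_id = c("P1", "P1", "P2"),
                    timestamp = c(5, 10, 70), # P2's falls outside bin 0
                    bmi = c(30, 32, 25))
  cs <- clinical_summary(c(1, 1, 2), rows, demo, bmi = bmi)
  expect_equal(cs$median_age[cs$cluster == 1], 32872 / 365.25) # capped at 32,872 days
  expect_equal(cs$median_bmi[cs$cluster == 1], 31) # mean of in-window 30, 32
  expect_equal(cs$bmi_fraction[cs$cluster == 2], 0) # no in-window measurement
  expect_true(is.na(cs$median_bmi[cs$cluster == 2]))
  expect_equal(cs$pct_female[cs$cluster == 1], 100)
  expect_equal(cs$n_patients, c(1, 1))
})

test_that("synthetic per-state demographics are recovered", {
  dm <- data.frame(state = 1:2, age_mean = c(45, 75), age_sd = 5,
                   p_female = c(0.3, 0.7), bmi_mean = c(24, 31), bmi_sd = 2)
  co <- generate_cohort(cohort_spec(
    n_patients = 600, n_states = 2, hierarchy = c(1, 2),
    transition_matrix = diag(2), # absorbing: patients stay in initial state
    demographics_model = dm, seed = 77))
  b <- build_snapshot_matrix(co$mentions)
  tl <- truth_labels(co, b$matrix)
  cs <- clinical_summary(tl, b$matrix$rows, co$demographics, bmi = co$bmi)
  for (g in 1:2) {
    r <- cs[cs$cluster == g, ]
    expect_lt(abs(r$median_age - dm$age_mean[g]), 2)
    expect_lt(abs(r$median_bmi - dm$bmi_mean[g]), 1)
    n_pat <- r$n_patients
    se <- sqrt(dm$p_female[g] * (1 - dm$p_female[g]) / n_pat)
    expect_lt(abs(r$pct_female / 100 - dm$p_female[g]), 3 * se + 0.02)
  }
})

test_that("the bundled example map loads with the documented shape", {
  map <- example_phenotype_map()
  expect_named(map, c("phenotype", "keyword"))
  expect_equal(length(unique(map$phenotype)), 50)
})
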