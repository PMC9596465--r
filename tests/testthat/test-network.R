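# build a labelled cohort from per-patient state sequences
seq_cohort <- function(seqs) {
  pid <- rep(names(seqs), lengths(seqs))
  data.frame(patient_id = pid,
             bin_index = unlist(lapply(seqs, seq_along)) - 1L,
             state = unlist(seqs), stringsAsFactors = FALSE)
}

test_that("co-occurrence odds ratio follows the 2x2 formula", {
  # 30 patients with both states, 10 with i only, 10 with j only, 50 neither
  seqs <- c(lapply(1:30, function(i) c(1, 2)),
            lapply(1:10, function(i) 1),
            lapply(1:10, function(i) 2),
            lapply(1:50, function(i) 3))
  names(seqs) <- sprintf("P%03d", seq_along(seqs))
  d <- seq_cohort(seqs)
  co <- cooccurrence_odds(d$state, d$patient_id, K = 3)
  r <- co[co$state_i == 1 & co$state_j == 2, ]
  expect_equal(r$or, (30 * 50) / (10 * 10)) # = 15
  expect_equal(c(r$n11, r$n10, r$n01, r$n00), c(30, 10, 10, 50))
  expect_true(r$significant)
  expect_error(cooccurrence_odds(rep(1, 5), letters[1:5], K = 1), "at least 2")
})

test_that("co-occurrence counts equal a patient-set-intersection oracle", {
  set.seed(15)
  for (rep in 1:5) {
    n_pat <- sample(30:100, 1)
    seqs <- lapply(seq_len(n_pat), function(i)
      sample(1:4, sample(1:6, 1), replace = TRUE))
    names(seqs) <- sprintf("P%03d", seq_len(n_pat))
    d <- seq_cohort(seqs)
    co <- cooccurrence_odds(d$state, d$patient_id, K = 4)
    for (r in seq_len(nrow(co))) {
      cells <- cooccurrence_bruteforce(d$state, d$patient_id,
                                       co$state_i[r], co$state_j[r])
      expect_equal(unname(c(co$n11[r], co$n10[r], co$n01[r], co$n00[r])),
                   unname(cells))
    }
  }
})

test_that("OR is symmetric under state relabelling; ordering is antisymmetric", {
  set.seed(16)
  seqs <- lapply(1:80, function(i) sample(1:3, sample(1:5, 1), replace = TRUE))
  names(seqs) <- sprintf("P%03d", 1:80)
  d <- seq_cohort(seqs)
  co <- cooccurrence_odds(d$state, d$patient_id, K = 3)
  # swap state ids 1 <-> 2: the {1,2} pair's OR must be unchanged
  swapped <- c(2, 1, 3)[d$state]
  co2 <- cooccurrence_odds(swapped, d$patient_id, K = 3)
  expect_equal(co2$or[co2$state_i == 1 & co2$state_j == 2],
               co$or[co$state_i == 1 & co$state_j == 2])

  ord <- ordering_probabilities(d$state, d$patient_id, d$bin_index, K = 3)
  cooc <- ord[!is.na(ord$p_ij), ]
  expect_equal(cooc$p_ij + cooc$p_ji, rep(1, nrow(cooc)))
})

test_that("ordering probabilities and medians match hand-built timelines", {
  seqs <- list(P1 = c(1, 1, 2), P2 = c(1, 2), P3 = c(1, 3, 2), P4 = c(2, 3))
  d <- seq_cohort(seqs)
  ord <- ordering_probabilities(d$state, d$patient_id, d$bin_index, K = 3)
  r12 <- ord[ord$state_i == 1 & ord$state_j == 2, ]
  expect_equal(r12$n_both, 3)
  expect_equal(r12$p_ij, 1) # state 1 always first
  expect_equal(r12$p_ji, 0)
  expect_equal(r12$median_bins_ij, 2) # transitions after 2, 1, 2 bins
  r13 <- ord[ord$state_i == 1 & ord$state_j == 3, ]
  expect_equal(r13$n_both, 1)
})

test_that("median transition time tracks the planted geometric dwell", {
  co <- generate_cohort(cohort_spec(
    n_patients = 600, n_states = 2, hierarchy = c(1, 2),
    transition_matrix = matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE),
    initial_distribution = c(1, 0),
    timeline_sampler = function(n) rep(12L, n), seed = 19))
  truth <- co$truth$snapshot_states
  ord <- ordering_probabilities(truth$state, truth$patient_id,
                                truth$bin_index, K = 2)
  r <- ord[ord$state_i == 1 & ord$state_j == 2, ]
  expect_gt(r$n_both, 450)
  expect_equal(r$p_ij, 1)
  expect_lt(abs(r$median_bins_ij - 2), 1 + 1e-9) # geometric dwell mean 2 bins
})

test_that("network edges respect the OR threshold and direction bands", {
  co <- data.frame(state_i = c(1, 1, 2), state_j = c(2, 3, 3),
                   n11 = 50, n10 = 20, n01 = 20, n00 = 200,
                   or = c(1.2, 2.5, 2.5),
                   ci_lo = c(1.05, 1.5, 1.5), ci_hi = c(1.4, 4, 4),
                   significant = TRUE, corrected = FALSE)
  class(co) <- c("cooccurrence_stats", "data.frame")
  ord <- data.frame(state_i = c(1, 1, 2), state_j = c(2, 3, 3),
                    n_both = 50, p_ij = c(0.9, 0.5, 0.2),
                    p_ji = c(0.1, 0.5, 0.8),
                    median_bins_ij = c(2, 3, 5), median_bins_ji = c(1, 1, 2))
  class(ord) <- c("ordering_stats", "data.frame")
  net <- build_network(co, ord)
  # OR = 1.2 significant but below 1.33: masked
  expect_equal(nrow(net$edges), 2)
  e13 <- net$edges[net$edges$or == 2.5 & net$edges$direction == "bidirectional", ]
  expect_equal(e13$median_bins, 2) # mean of 3 and 1
  e32 <- net$edges[net$edges$direction == "j->i", ]
  expect_equal(c(e32$from, e32$to), c(3, 2))
  # start/end classification: a bidirectional arrow is also incoming, so the
  # only "only outgoing" candidate (state 3) is disqualified by its
  # bidirectional tie; state 2 has only incoming arrows
  expect_equal(net$nodes$is_start, c(FALSE, FALSE, FALSE))
  expect_equal(net$nodes$is_end, c(FALSE, TRUE, FALSE))
})

test_that("insignificant or absent pairs produce isolated nodes", {
  co <- data.frame(state_i = 1, state_j = 2, n11 = 5, n10 = 5, n01 = 5,
                   n00 = 5, or = 1, ci_lo = 0.5, ci_hi = 2,
                   significant = FALSE, corrected = FALSE)
  class(co) <- c("cooccurrence_stats", "data.frame")
  ord <- data.frame(state_i = 1, state_j = 2, n_both = 5, p_ij = 0.6,
                    p_ji = 0.4, median_bins_ij = 1, median_bins_ji = 1)
  class(ord) <- c("ordering_stats", "data.frame")
  expect_warning(net <- build_network(co, ord), "isolated")
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$nodes), 2)
})

test_that("independent states show OR near 1; co-planted states are enriched", {
  set.seed(18)
  # independent: each of 2 states present independently per patient; the
  # pair should be flagged significant only at the nominal ~5% rate
  n_sig <- 0L
  for (rep in 1:20) {
    n <- 400
    has1 <- runif(n) < 0.4; has2 <- runif(n) < 0.4
    seqs <- lapply(seq_len(n), function(i) c(if (has1[i]) 1, if (has2[i]) 2, 3))
    names(seqs) <- sprintf("P%04d", seq_len(n))
    d <- seq_cohort(seqs)
    co12 <- cooccurrence_odds(d$state, d$patient_id, K = 3)
    n_sig <- n_sig + co12$significant[co12$state_i == 1 & co12$state_j == 2]
  }
  expect_lte(n_sig, 4) # Binom(20, 0.05) exceeds 4 with prob < 0.003

  # co-planted: states 1 and 2 always together in half the patients
  seqs2 <- c(lapply(1:300, function(i) c(1, 2)),
             lapply(1:300, function(i) 3))
  names(seqs2) <- sprintf("P%04d", 1:600)
  d2 <- seq_cohort(seqs2)
  co2 <- cooccurrence_odds(d2$state, d2$patient_id, K = 3)
  r2 <- co2[co2$state_i == 1 & co2$state_j == 2, ]
  expect_true(r2$significant && r2$or > 1)
})

test_that("annotations join by state and round-trip source values", {
  seqs <- c(lapply(1:40, function(i) c(1, 2)), lapply(1:40, function(i) c(2, 1)),
            lapply(1:20, function(i) 3))
  names(seqs) <- sprintf("P%03d", 1:100)
  d <- seq_cohort(seqs)
  co <- cooccurrence_odds(d$state, d$patient_id, K = 3)
  ord <- ordering_probabilities(d$state, d$patient_id, d$bin_index, K = 3)
  net <- suppressWarnings(build_network(co, ord))
  summaries <- data.frame(cluster = 1:3, n_snapshots = c(80, 80, 20),
                          median_age = c(60, 65, 70))
  ann <- annotate_network(net, summaries)
  expect_equal(ann$nodes$median_age, c(60, 65, 70))
  expect_error(annotate_network(net, summaries[1:2, ]), "state")
})

test_that("networks export as GraphML and TSV", {
  seqs <- c(lapply(1:50, function(i) c(1, 2)), lapply(1:30, function(i) 3))
  names(seqs) <- sprintf("P%03d", 1:80)
  d <- seq_cohort(seqs)
  net <- suppressWarnings(build_network(
    cooccurrence_odds(d$state, d$patient_id, K = 3),
    ordering_probabilities(d$state, d$patient_id, d$bin_index, K = 3)))
  g <- withr::local_tempfile(fileext = ".graphml")
  e <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, graphml = g, edges_tsv = e)
  expect_gt(file.size(g), 0)
  back <- utils::read.delim(e)
  expect_equal(nrow(back), nrow(net$edges))
  if (nrow(back) > 0) expect_equal(back$or, net$edges$or)
})
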