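mk_mentions <- function(pid, day, concept = "cA", pol = "pos") {
  data.frame(patient_id = pid, timestamp = day, concept_id = concept,
             polarity = pol, stringsAsFactors = FALSE)
}

test_that("polarity filtering keeps exactly the positive rows in order", {
  m <- mk_mentions(rep("P1", 10), 0:9,
                   pol = c("pos", "neg", "pos", "pos", "neg", "pos",
                           "pos", "neg", "pos", "pos"))
  out <- filter_polarity(m)
  expect_equal(nrow(out), 7)
  expect_equal(out$timestamp, c(0, 2, 3, 5, 6, 8, 9))
  expect_error(filter_polarity(m[, -4]), "polarity")
  all_neg <- mk_mentions("P1", 0:2, pol = "neg")
  expect_error(bin_snapshots(filter_polarity(all_neg)), "empty cohort")
})

test_that("retained fraction matches the configured negative-polarity rate", {
  co <- generate_cohort(cohort_spec(n_patients = 150, neg_polarity_rate = 0.2,
                                    seed = 31))
  n <- nrow(co$mentions)
  frac <- nrow(filter_polarity(co$mentions)) / n
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(frac - 0.8), 3 * se)
})

test_that("binning uses half-open 30-day windows anchored at the first mention", {
  s <- bin_snapshots(mk_mentions("P1", c(0, 29)))
  expect_equal(s$info$bin_index, 0L)
  expect_equal(s$info$mention_total, 2L)

  s <- bin_snapshots(mk_mentions("P1", c(0, 30)))
  expect_equal(s$info$bin_index, c(0L, 1L))

  s <- bin_snapshots(mk_mentions("P1", c(0, 65)))
  expect_equal(s$info$bin_index, c(0L, 2L)) # bin 1 absent

  expect_error(bin_snapshots(mk_mentions("P1", "not-a-date")), "unparseable")
})

test_that("binning is invariant to shifting a patient's timeline", {
  m <- mk_mentions(rep("P1", 6), c(0, 3, 40, 41, 100, 129),
                   concept = c("cA", "cB", "cA", "cA", "cC", "cA"))
  a <- bin_snapshots(m)
  m$timestamp <- m$timestamp + 1000
  b <- bin_snapshots(m)
  expect_equal(a$counts, b$counts)
  expect_equal(a$info, b$info)
})

test_that("duplicate concept mentions aggregate into counts", {
  m <- mk_mentions(rep("P1", 5), c(0, 1, 2, 3, 35),
                   concept = c("cA", "cA", "cB", "cA", "cA"))
  s <- bin_snapshots(m)
  expect_equal(s$counts$n[s$counts$bin_index == 0 & s$counts$concept_id == "cA"], 3L)
  expect_equal(s$info$mention_total, c(4L, 1L))
})

test_that("patient-level exclusion removes whole patients on a strict < threshold", {
  m <- rbind(mk_mentions(rep("P1", 12), rep(0, 12)),
             mk_mentions(rep("P1", 9), rep(40, 9)),   # 9-mention snapshot
             mk_mentions(rep("P2", 10), rep(0, 10)),  # exactly 10: kept
             mk_mentions(rep("P3", 25), rep(0, 25)))
  s <- bin_snapshots(m)
  ex <- apply_cohort_exclusion(s, min_mentions = 10)
  expect_equal(ex$report$patient_id, "P1")
  expect_false("P1" %in% ex$snapshots$info$patient_id) # both snapshots gone
  expect_setequal(unique(ex$snapshots$info$patient_id), c("P2", "P3"))
  # snapshot-level mode drops only the offending snapshot
  ex2 <- apply_cohort_exclusion(s, min_mentions = 10, mode = "snapshot")
  expect_true("P1" %in% ex2$snapshots$info$patient_id)
  expect_equal(sum(ex2$snapshots$info$patient_id == "P1"), 1)
})

test_that("vocabulary truncation takes the smallest high-frequency prefix", {
  m <- rbind(mk_mentions(rep("P1", 98), rep(0, 98), concept = "cA"),
             mk_mentions("P1", 0, concept = "cB"),
             mk_mentions("P1", 0, concept = "cC"))
  s <- bin_snapshots(m)
  expect_equal(truncate_vocabulary(s, 0.99), c("cA", "cB"))

  u <- counts_to_mentions(matrix(1, 1, 100))
  expect_length(truncate_vocabulary(bin_snapshots(u), 0.99), 99)
})

test_that("truncation agrees with a brute-force cumulative sum on Zipf data", {
  co <- small_cohort()
  s <- bin_snapshots(filter_polarity(co$mentions))
  vocab <- truncate_vocabulary(s, 0.99)
  # oracle: sort totals desc (tie: lexicographic), walk the cumulative sum
  tot <- tapply(s$counts$n, s$counts$concept_id, sum)
  df <- data.frame(id = names(tot), n = as.integer(tot))
  df <- df[order(-df$n, df$id), ]
  k <- 0; acc <- 0; target <- 0.99 * sum(df$n)
  while (acc < target) { k <- k + 1; acc <- acc + df$n[k] }
  expect_equal(vocab, df$id[seq_len(k)])
  expect_lt(length(vocab), nrow(df)) # a tail was actually removed
})

test_that("tfidf formulas match an independent reimplementation", {
  set.seed(5)
  counts <- matrix(rpois(20 * 15, 1.2), 20, 15)
  counts[rowSums(counts) == 0, 1] <- 1
  m <- counts_to_mentions(counts)
  s <- bin_snapshots(m)
  vocab <- sprintf("c%03d", 1:15)
  x <- vectorize(s, vocab)
  expect_equal(unname(as.matrix(x$tfidf)), tfidf_bruteforce(counts),
               tolerance = 1e-12)
  expect_true(all(abs(sqrt(Matrix::rowSums(x$tfidf^2)) - 1) < 1e-12))
})

test_that("single-concept rows normalize to one; idf cancels on identical support", {
  s <- bin_snapshots(mk_mentions(rep("P1", 5), rep(0, 5), concept = "cA"))
  x <- vectorize(s, "cA")
  expect_equal(as.numeric(x$tfidf), 1)

  m <- rbind(mk_mentions(rep("P1", 3), rep(0, 3), concept = "cA"),
             mk_mentions(rep("P2", 7), rep(0, 7), concept = "cA"))
  x2 <- vectorize(bin_snapshots(m), "cA")
  expect_equal(as.numeric(x2$tfidf), c(1, 1))
})

test_that("vectorize is permutation-equivariant in rows and columns", {
  set.seed(9)
  counts <- matrix(rpois(12 * 8, 2), 12, 8)
  counts[rowSums(counts) == 0, 1] <- 1
  s <- bin_snapshots(counts_to_mentions(counts))
  vocab <- sprintf("c%03d", 1:8)
  x <- as.matrix(vectorize(s, vocab)$tfidf)
  perm <- sample(8)
  xp <- as.matrix(vectorize(s, vocab[perm])$tfidf)
  expect_equal(unname(xp), unname(x[, perm]), tolerance = 1e-12)
})

test_that("snapshots outside the vocabulary are dropped with a warning", {
  m <- rbind(mk_mentions(rep("P1", 5), rep(0, 5), concept = "cA"),
             mk_mentions(rep("P2", 4), rep(0, 4), concept = "cB"))
  s <- bin_snapshots(m)
  expect_warning(x <- vectorize(s, "cA"), "dropped")
  expect_equal(nrow(x$tfidf), 1)
  expect_equal(x$dropped$patient_id, "P2")
})

test_that("mentions are conserved across the funnel", {
  co <- small_cohort()
  built <- build_snapshot_matrix(co$mentions)
  pos <- filter_polarity(co$mentions)
  snaps <- bin_snapshots(pos)
  excluded_pat <- built$exclusion$patient_id
  excluded_mentions <- sum(snaps$info$mention_total[
    snaps$info$patient_id %in% excluded_pat])
  kept_in_vocab <- sum(built$matrix$counts)
  kept_oov <- sum(built$matrix$rows$mention_total) - kept_in_vocab
  dropped_mentions <- sum(built$matrix$dropped$mention_total)
  expect_gte(kept_oov, 0)
  expect_equal(kept_in_vocab + kept_oov + dropped_mentions + excluded_mentions,
               nrow(pos))
})
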