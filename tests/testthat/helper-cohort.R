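# Shared fixtures, generated once per test session.

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_spec(n_patients = 200, seed = 42))
    cache
  }
})

# truth state per row of a snapshot matrix (NA for snapshots whose patient
# was excluded upstream never happens: truth covers all patient-bins)
truth_labels <- function(cohort, mat) {
  truth <- cohort$truth$snapshot_states
  truth$state[match(paste(mat$rows$patient_id, mat$rows$bin_index),
                    paste(truth$patient_id, truth$bin_index))]
}

# map recovered cluster ids onto planted state ids by majority vote
map_clusters_to_truth <- function(labels, truth) {
  tab <- table(labels, truth)
  as.integer(colnames(tab))[apply(tab, 1, which.max)]
}

# long count data into a mentions table (one patient per row index, bin 0)
counts_to_mentions <- function(counts) {
  # counts: matrix snapshots x concepts
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      if (counts[i, j] > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("S%03d", i),
          timestamp = rep(0L, counts[i, j]),
          concept_id = sprintf("c%03d", j),
          polarity = "pos", stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# independent brute-force oracle for the data-point-weighted Jaccard J
jaccard_bruteforce <- function(ref, boot) {
  N <- length(ref)
  total <- 0
  for (i in unique(ref)) {
    ci <- which(ref == i)
    for (j in unique(boot)) {
      cj <- which(boot == j)
      nij <- length(intersect(ci, cj))
      if (nij == 0) next
      total <- total + nij * nij / length(union(ci, cj))
    }
  }
  total / N
}

# independent brute-force oracle for semantic stability S
semantic_bruteforce <- function(ref, boot, ref_vocab, boot_vocab) {
  N <- length(ref)
  total <- 0
  for (i in unique(ref)) {
    for (j in unique(boot)) {
      nij <- sum(ref == i & boot == j)
      if (nij == 0) next
      vb <- boot_vocab[[j]]
      sij <- if (length(vb) == 0) 0 else length(intersect(ref_vocab[[i]], vb)) / length(vb)
      total <- total + nij * sij
    }
  }
  total / N
}

# independent TF-IDF oracle: plain loops over the written-out formulas
tfidf_bruteforce <- function(counts) {
  N <- nrow(counts)
  df <- colSums(counts > 0)
  idf <- log((1 + N) / (1 + df)) + 1
  out <- matrix(0, N, ncol(counts))
  for (i in seq_len(N)) {
    for (j in seq_len(ncol(counts))) {
      if (counts[i, j] > 0) out[i, j] <- (1 + log(counts[i, j])) * idf[j]
    }
    nrm <- sqrt(sum(out[i, ]^2))
    if (nrm > 0) out[i, ] <- out[i, ] / nrm
  }
  out
}

# patient-set-intersection oracle for the co-occurrence 2x2 odds ratio
cooccurrence_bruteforce <- function(labels, patient_ids, i, j) {
  pats <- unique(patient_ids)
  with_i <- unique(patient_ids[labels == i])
  with_j <- unique(patient_ids[labels == j])
  n11 <- length(intersect(with_i, with_j))
  n10 <- length(setdiff(with_i, with_j))
  n01 <- length(setdiff(with_j, with_i))
  n00 <- length(pats) - n11 - n10 - n01
  c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
}
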