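#' Keep only positive-polarity mentions
#'
#' Negated concept mentions (e.g. "no evidence of heart failure") carry no
#' information about a patient's current problems and are removed before
#' binning. Row order is preserved.
#'
#' @param mentions data frame with columns `patient_id`, `timestamp`,
#'   `concept_id`, `polarity` (`"pos"`/`"neg"`).
#' @return the positive-polarity rows of `mentions`.
#' @export
filter_polarity <- function(mentions) {
  stop_if_missing_cols(mentions, c("polarity"), "mention table")
  out <- mentions[mentions$polarity == "pos", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate mentions into 30-day snapshots
#'
#' Bins are anchored at each patient's first mention: bin index
#' `floor((timestamp - first timestamp) / bin_width)` with half-open
#' `[start, start + bin_width)` day windows and 0-based indices. Bins in
#' which a patient has no mentions are simply absent. Duplicate mentions of
#' the same concept within a bin are aggregated into counts.
#'
#' @param mentions positively-polarised mention table.
#' @param bin_width window width in days (30 by default).
#' @return an object of class `snapshots`: a list with `counts` (long data
#'   frame `patient_id`, `bin_index`, `concept_id`, `n`), `info` (one row per
#'   snapshot with `mention_total`), `anchors` (per-patient first-mention
#'   day), and `bin_width`.
#' @export
bin_snapshots <- function(mentions, bin_width = 30) {
  stop_if_missing_cols(mentions, c("patient_id", "timestamp", "concept_id"),
                       "mention table")
  if (nrow(mentions) == 0) stop("empty cohort: no mentions to bin", call. = FALSE)
  if (any(!nzchar(as.character(mentions$concept_id))))
    stop("concept_id must be non-empty", call. = FALSE)
  day <- as_day_offset(mentions$timestamp, mentions$patient_id)
  pid <- as.character(mentions$patient_id)
  anchor <- tapply(day, pid, min)
  bin <- as.integer(floor((day - anchor[pid]) / bin_width))

  key <- paste(pid, bin, as.character(mentions$concept_id), sep = "\r")
  agg <- rowsum(rep(1L, length(key)), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  counts <- data.frame(
    patient_id = vapply(parts, `[`, "", 1L),
    bin_index = as.integer(vapply(parts, `[`, "", 2L)),
    concept_id = vapply(parts, `[`, "", 3L),
    n = as.integer(agg[, 1]),
    stringsAsFactors = FALSE)
  counts <- counts[order(counts$patient_id, counts$bin_index, counts$concept_id), ]
  rownames(counts) <- NULL

  skey <- paste(counts$patient_id, counts$bin_index, sep = "\r")
  tot <- rowsum(counts$n, skey)
  sparts <- strsplit(rownames(tot), "\r", fixed = TRUE)
  info <- data.frame(
    patient_id = vapply(sparts, `[`, "", 1L),
    bin_index = as.integer(vapply(sparts, `[`, "", 2L)),
    mention_total = as.integer(tot[, 1]),
    stringsAsFactors = FALSE)
  info <- info[order(info$patient_id, info$bin_index), ]
  rownames(info) <- NULL

  structure(list(counts = counts, info = info,
                 anchors = data.frame(patient_id = names(anchor),
                                      anchor_day = as.numeric(anchor),
                                      stringsAsFactors = FALSE),
                 bin_width = bin_width),
            class = "snapshots")
}

#' @exportS3Method base::print
print.snapshots <- function(x, ...) {
  cat("Snapshots:", nrow(x$info), "snapshots,",
      length(unique(x$info$patient_id)), "patients,",
      x$bin_width, "day bins\n")
  invisible(x)
}

#' Exclude patients with sparse snapshots
#'
#' A patient having at least one snapshot with fewer than `min_mentions`
#' complaint mentions is removed entirely (all of their snapshots), the
#' cohort-level reading of the exclusion rule. `mode = "snapshot"` instead
#' drops only the offending snapshots.
#'
#' @param snapshots a [bin_snapshots()] result.
#' @param min_mentions exclusion threshold; snapshots with
#'   `mention_total < min_mentions` trigger it (strict `<`).
#' @param mode `"patient"` (default) or `"snapshot"`.
#' @return list with `snapshots` (the kept `snapshots` object) and `report`
#'   (data frame of excluded `patient_id`s with reason and their minimum
#'   snapshot total).
#' @export
apply_cohort_exclusion <- function(snapshots, min_mentions = 10,
                                   mode = c("patient", "snapshot")) {
  stopifnot(inherits(snapshots, "snapshots"))
  mode <- match.arg(mode)
  if (nrow(snapshots$info) == 0) stop("empty cohort", call. = FALSE)
  info <- snapshots$info
  if (mode == "patient") {
    min_by_pat <- tapply(info$mention_total, info$patient_id, min)
    bad <- names(min_by_pat)[min_by_pat < min_mentions]
    report <- data.frame(
      patient_id = bad,
      reason = sprintf("snapshot with < %d mentions", min_mentions),
      min_snapshot_total = as.integer(min_by_pat[bad]),
      stringsAsFactors = FALSE)
    keep_info <- !(info$patient_id %in% bad)
    keep_counts <- !(snapshots$counts$patient_id %in% bad)
  } else {
    drop_key <- paste(info$patient_id, info$bin_index)[info$mention_total < min_mentions]
    keep_info <- !(paste(info$patient_id, info$bin_index) %in% drop_key)
    keep_counts <- !(paste(snapshots$counts$patient_id,
                           snapshots$counts$bin_index) %in% drop_key)
    report <- data.frame(patient_id = unique(info$patient_id[!keep_info]),
                         reason = sprintf("snapshot(s) with < %d mentions dropped",
                                          min_mentions),
                         min_snapshot_total = NA_integer_,
                         stringsAsFactors = FALSE)
  }
  kept <- snapshots
  kept$info <- info[keep_info, , drop = FALSE]
  kept$counts <- snapshots$counts[keep_counts, , drop = FALSE]
  kept$anchors <- snapshots$anchors[snapshots$anchors$patient_id %in%
                                      kept$info$patient_id, , drop = FALSE]
  rownames(kept$info) <- rownames(kept$counts) <- rownames(kept$anchors) <- NULL
  list(snapshots = kept, report = report)
}

#' Truncate the complaint vocabulary to its most frequent mass
#'
#' Returns the smallest prefix of complaints, sorted by descending total
#' mention count (ties broken lexicographically by concept id), whose
#' cumulative mention count reaches at least `coverage` of all mentions.
#' Under the power-law complaint frequencies typical of clinical text this
#' removes a long tail of rare concepts. `method = "rank"` instead keeps the
#' top `ceiling(coverage * n_concepts)` concepts by frequency.
#'
#' @param snapshots a [bin_snapshots()] (possibly exclusion-filtered) result.
#' @param coverage cumulative mention-mass target in (0, 1]; default 0.99.
#' @param method `"mass"` (default, cumulative-mass reading) or `"rank"`.
#' @return ordered character vector of retained concept ids.
#' @export
truncate_vocabulary <- function(snapshots, coverage = 0.99,
                                method = c("mass", "rank")) {
  stopifnot(inherits(snapshots, "snapshots"))
  method <- match.arg(method)
  if (nrow(snapshots$counts) == 0) stop("empty cohort", call. = FALSE)
  tot <- rowsum(snapshots$counts$n, snapshots$counts$concept_id)
  df <- data.frame(concept_id = rownames(tot), n = tot[, 1],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n, df$concept_id), ]
  if (method == "rank") return(df$concept_id[seq_len(ceiling(coverage * nrow(df)))])
  cum <- cumsum(df$n)
  k <- which(cum >= coverage * sum(df$n))[1]
  df$concept_id[seq_len(k)]
}

#' Vectorize snapshots as a log-TF-IDF matrix
#'
#' Builds the N x V snapshot-by-complaint matrix: raw counts alongside a
#' sublinear term-frequency / smoothed inverse-document-frequency weighting
#' with row-wise L2 normalization,
#' \deqn{tf(c) = 1 + \ln(count), \quad
#'       idf(c) = \ln\frac{1 + N}{1 + df(c)} + 1,}
#' entries `tf * idf`, each row scaled to unit Euclidean norm. Snapshots
#' whose every complaint falls outside the vocabulary would be all-zero rows
#' and are dropped with a warning.
#'
#' @param snapshots a [bin_snapshots()] result (after cohort exclusion).
#' @param vocabulary ordered concept ids defining the columns (see
#'   [truncate_vocabulary()]).
#' @param tf `"log"` (default) or `"linear"` term frequency.
#' @param idf_smooth use the smoothed IDF above (default) or
#'   `ln(N / df) + 1`.
#' @return object of class `snapshot_matrix`: sparse `counts` and `tfidf`
#'   matrices (rows = snapshots, columns = vocabulary), `rows` metadata
#'   (`patient_id`, `bin_index`, `mention_total`, `in_vocab_total`,
#'   `anchor_day`), `vocabulary`, `idf` (the column weights, reusable for new
#'   data), and `dropped` (metadata of all-zero rows removed).
#' @export
vectorize <- function(snapshots, vocabulary, tf = c("log", "linear"),
                      idf_smooth = TRUE) {
  stopifnot(inherits(snapshots, "snapshots"))
  tf <- match.arg(tf)
  if (length(vocabulary) == 0) stop("vocabulary must be non-empty", call. = FALSE)
  cc <- snapshots$counts
  info <- snapshots$info
  skey <- paste(info$patient_id, info$bin_index, sep = "\r")
  row_of <- stats::setNames(seq_len(nrow(info)), skey)
  col_of <- stats::setNames(seq_along(vocabulary), vocabulary)
  in_vocab <- cc$concept_id %in% vocabulary
  ccv <- cc[in_vocab, , drop = FALSE]
  i <- row_of[paste(ccv$patient_id, ccv$bin_index, sep = "\r")]
  j <- col_of[ccv$concept_id]
  counts <- Matrix::sparseMatrix(i = i, j = j, x = ccv$n,
                                 dims = c(nrow(info), length(vocabulary)),
                                 dimnames = list(skey, vocabulary))
  in_vocab_total <- Matrix::rowSums(counts)
  zero <- in_vocab_total == 0
  dropped <- info[zero, , drop = FALSE]
  if (any(zero)) {
    warning(sum(zero), " snapshot(s) had no in-vocabulary complaints and were dropped")
    counts <- counts[!zero, , drop = FALSE]
    info <- info[!zero, , drop = FALSE]
    in_vocab_total <- in_vocab_total[!zero]
  }
  N <- nrow(counts)
  df_count <- Matrix::colSums(counts > 0)
  idf <- if (idf_smooth) log((1 + N) / (1 + df_count)) + 1 else {
    ifelse(df_count > 0, log(N / pmax(df_count, 1)) + 1, 0)
  }
  tfm <- counts
  if (tf == "log") tfm@x <- 1 + log(tfm@x)
  tfidf <- tfm %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(tfidf^2))
  tfidf <- Matrix::Diagonal(x = 1 / norms) %*% tfidf
  tfidf <- methods::as(tfidf, "CsparseMatrix")
  dimnames(tfidf) <- dimnames(counts)

  rows <- info
  rows$in_vocab_total <- as.integer(in_vocab_total)
  anchors <- stats::setNames(snapshots$anchors$anchor_day,
                             snapshots$anchors$patient_id)
  rows$anchor_day <- as.numeric(anchors[rows$patient_id])
  rownames(rows) <- NULL

  structure(list(counts = counts, tfidf = tfidf, rows = rows,
                 vocabulary = vocabulary, idf = idf,
                 bin_width = snapshots$bin_width, dropped = dropped,
                 tf = tf, idf_smooth = idf_smooth),
            class = "snapshot_matrix")
}

#' @exportS3Method base::print
print.snapshot_matrix <- function(x, ...) {
  cat("Snapshot matrix:", nrow(x$tfidf), "snapshots x",
      ncol(x$tfidf), "complaints (",
      length(unique(x$rows$patient_id)), "patients )\n")
  invisible(x)
}

#' @export
dim.snapshot_matrix <- function(x) dim(x$tfidf)

#' Run the full snapshot pipeline
#'
#' Convenience wrapper: polarity filter, 30-day binning, patient-level
#' exclusion, vocabulary truncation, and TF-IDF vectorization, returning the
#' matrix together with the exclusion report and a record-count funnel
#' (mention/patient/snapshot/vocabulary counts at every stage).
#'
#' @param mentions raw mention table.
#' @param min_mentions snapshot mention-count exclusion threshold.
#' @param coverage vocabulary cumulative-mass target.
#' @param bin_width bin width in days.
#' @param ... passed to [vectorize()].
#' @return list with `matrix` (a `snapshot_matrix`), `exclusion` (report) and
#'   `funnel` (named counts).
#' @export
build_snapshot_matrix <- function(mentions, min_mentions = 10, coverage = 0.99,
                                  bin_width = 30, ...) {
  pos <- filter_polarity(mentions)
  if (nrow(pos) == 0) stop("empty cohort: no positive-polarity mentions", call. = FALSE)
  snaps <- bin_snapshots(pos, bin_width = bin_width)
  excl <- apply_cohort_exclusion(snaps, min_mentions = min_mentions)
  if (nrow(excl$snapshots$info) == 0)
    stop("empty cohort: all patients excluded", call. = FALSE)
  vocab <- truncate_vocabulary(excl$snapshots, coverage = coverage)
  mat <- vectorize(excl$snapshots, vocab, ...)
  funnel <- c(
    mentions_total = nrow(mentions),
    mentions_positive = nrow(pos),
    patients_binned = length(unique(snaps$info$patient_id)),
    snapshots_binned = nrow(snaps$info),
    patients_excluded = nrow(excl$report),
    patients_kept = length(unique(excl$snapshots$info$patient_id)),
    snapshots_kept = nrow(excl$snapshots$info),
    vocabulary_full = length(unique(excl$snapshots$counts$concept_id)),
    vocabulary_kept = length(vocab),
    snapshots_vectorized = nrow(mat$tfidf))
  list(matrix = mat, exclusion = excl$report, funnel = funnel)
}
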