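#' Significantly over-represented complaints of one cluster
#'
#' For every complaint feature, a one-sided (greater) comparison of TF-IDF
#' values in cluster `i` against all other snapshots identifies complaints
#' over-represented in the cluster. The default test is the Mann-Whitney
#' rank-sum (sparse TF-IDF features are far from normal); a one-sided Welch
#' t-test is available via `method = "ttest"`. P-values are Bonferroni
#' corrected over the feature family, by default the `|V|` tests within this
#' cluster's battery (`family = "global"` corrects over `|V| * K` instead,
#' with `n_clusters` supplying K).
#'
#' @param x a `snapshot_matrix` or numeric matrix (rows = snapshots,
#'   columns = complaint features).
#' @param labels cluster label per snapshot.
#' @param cluster the cluster id to characterise.
#' @param alpha significance threshold on the adjusted p-value.
#' @param method `"ranksum"` (default) or `"ttest"`.
#' @param family Bonferroni family: `"cluster"` (default) or `"global"`.
#' @param n_clusters number of clusters, required for `family = "global"`.
#' @return data frame (`concept_id`, `statistic`, `p`, `p_adj`,
#'   `significant`), sorted by raw p ascending, with `alpha`, `method` and
#'   `cluster` attached as attributes. Constant features get `p = 1`.
#' @export
test_cluster_features <- function(x, labels, cluster, alpha = 0.05,
                                  method = c("ranksum", "ttest"),
                                  family = c("cluster", "global"),
                                  n_clusters = NULL) {
  method <- match.arg(method)
  family <- match.arg(family)
  xm <- as_dense(x)
  in_group <- labels == cluster
  if (sum(in_group) < 2)
    stop("cluster ", cluster, " has fewer than 2 snapshots", call. = FALSE)
  if (sum(!in_group) < 1)
    stop("cluster ", cluster, " has an empty complement", call. = FALSE)
  res <- if (method == "ranksum") ranksum_battery(xm, in_group)
         else welch_battery(xm, in_group)
  n_tests <- ncol(xm) * if (family == "global") {
    if (is.null(n_clusters)) stop("family = 'global' needs n_clusters", call. = FALSE)
    n_clusters
  } else 1L
  concept <- colnames(xm) %||% paste0("f", seq_len(ncol(xm)))
  out <- data.frame(concept_id = concept,
                    statistic = res$statistic,
                    p = res$p,
                    p_adj = pmin(1, res$p * n_tests),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$concept_id), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  attr(out, "cluster") <- cluster
  out
}

#' Significant complaint vocabularies for every cluster
#'
#' Runs [test_cluster_features()] for each cluster (sharing the rank
#' computation across clusters for the rank-sum path) and returns the
#' significant concept sets, the `V_s` vocabularies used both for cluster
#' interpretation and for the semantic stability statistic.
#'
#' @inheritParams test_cluster_features
#' @return list of character vectors, indexed by cluster id.
#' @export
significant_vocabularies <- function(x, labels, alpha = 0.05,
                                     method = c("ranksum", "ttest"),
                                     family = c("cluster", "global")) {
  method <- match.arg(method)
  family <- match.arg(family)
  xm <- as_dense(x)
  clusters <- sort(unique(labels))
  concept <- colnames(xm) %||% paste0("f", seq_len(ncol(xm)))
  K <- length(clusters)
  n_tests <- ncol(xm) * if (family == "global") K else 1L
  n <- nrow(xm)

  if (method == "ranksum") {
    ## ranks and tie variances are label-independent: compute once
    R <- matrix(0, n, ncol(xm))
    tie_term <- numeric(ncol(xm))
    for (v in seq_len(ncol(xm))) {
      col <- xm[, v]
      R[, v] <- rank(col)
      tl <- rle(sort(col))$lengths
      tie_term[v] <- sum(as.numeric(tl)^3 - tl)
    }
    out <- lapply(clusters, function(cl) {
      ing <- labels == cl
      n1 <- sum(ing); n2 <- n - n1
      if (n1 < 2 || n2 < 1) return(character(0))
      u <- colSums(R[ing, , drop = FALSE]) - n1 * (n1 + 1) / 2
      sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
      p <- ifelse(sigma2 > 0,
                  stats::pnorm((u - n1 * n2 / 2 - 0.5) / sqrt(pmax(sigma2, 0)),
                               lower.tail = FALSE),
                  1)
      concept[pmin(1, p * n_tests) < alpha]
    })
  } else {
    out <- lapply(clusters, function(cl) {
      tb <- test_cluster_features(xm, labels, cl, alpha = alpha,
                                  method = method, family = family,
                                  n_clusters = K)
      tb$concept_id[tb$significant]
    })
  }
  names(out) <- as.character(clusters)
  ## return a plain positional list when clusters are 1..K
  if (identical(clusters, seq_len(K))) names(out) <- NULL
  out
}

#' Map complaint concepts to grouped clinical phenotypes
#'
#' Keyword-based grouping of specific complaints into high-level clinical
#' phenotypes (e.g. every anemia variant into "anemia"): a concept belongs to
#' a phenotype when any of the phenotype's keywords is a case-insensitive
#' substring of the concept's display string. A concept maps to at most one
#' phenotype; when keywords overlap, the first-declared phenotype in the map
#' wins, so resolution is deterministic given map order.
#'
#' @param concepts character vector of concept display strings.
#' @param map data frame with columns `phenotype` and `keyword` (one row per
#'   keyword; a phenotype may have several). See [example_phenotype_map()].
#' @return data frame (`concept_id`, `phenotype`); `phenotype` is `NA` for
#'   unmatched concepts.
#' @export
group_complaints <- function(concepts, map) {
  stop_if_missing_cols(map, c("phenotype", "keyword"), "phenotype map")
  if (nrow(map) == 0) stop("phenotype map is empty", call. = FALSE)
  lc <- tolower(concepts)
  assigned <- rep(NA_character_, length(concepts))
  phenos <- unique(map$phenotype) # declaration order
  for (ph in phenos) {
    kws <- tolower(map$keyword[map$phenotype == ph])
    hit <- rep(FALSE, length(concepts))
    for (kw in kws) hit <- hit | grepl(kw, lc, fixed = TRUE)
    assigned[is.na(assigned) & hit] <- ph
  }
  data.frame(concept_id = concepts, phenotype = assigned,
             stringsAsFactors = FALSE)
}

#' Per-snapshot phenotype presence
#'
#' A snapshot exhibits a phenotype when it mentions any concept mapped to it.
#'
#' @param x a `snapshot_matrix`.
#' @param map phenotype keyword map (see [group_complaints()]).
#' @return logical matrix, snapshots x phenotypes.
#' @export
phenotype_presence <- function(x, map) {
  stopifnot(inherits(x, "snapshot_matrix"))
  gm <- group_complaints(x$vocabulary, map)
  phenos <- unique(map$phenotype)
  out <- matrix(FALSE, nrow(x$counts), length(phenos),
                dimnames = list(rownames(x$counts), phenos))
  for (ph in phenos) {
    cols <- which(gm$phenotype == ph & !is.na(gm$phenotype))
    if (length(cols) > 0)
      out[, ph] <- Matrix::rowSums(x$counts[, cols, drop = FALSE]) > 0
  }
  out
}

#' Phenotype prevalence and enrichment per cluster
#'
#' For each (cluster, phenotype): prevalence (% of the cluster's snapshots
#' exhibiting the phenotype), the cohort-wide prevalence for comparison, and
#' the odds ratio of the 2x2 in-cluster x phenotype-present table, with a
#' Haldane-Anscombe 0.5 correction applied to all cells whenever any cell is
#' zero.
#'
#' @param presence logical snapshot x phenotype matrix
#'   ([phenotype_presence()]).
#' @param labels cluster label per snapshot.
#' @return tidy data frame (`cluster`, `phenotype`, `prevalence`,
#'   `cohort_prevalence`, `odds_ratio`, `corrected`).
#' @export
phenotype_enrichment <- function(presence, labels) {
  stopifnot(nrow(presence) == length(labels))
  clusters <- sort(unique(labels))
  rows <- list()
  for (cl in clusters) {
    ing <- labels == cl
    for (ph in colnames(presence)) {
      a <- sum(presence[ing, ph]);  b <- sum(ing) - a
      c_ <- sum(presence[!ing, ph]); d <- sum(!ing) - c_
      corrected <- any(c(a, b, c_, d) == 0)
      if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, phenotype = ph,
        prevalence = 100 * sum(presence[ing, ph]) / sum(ing),
        cohort_prevalence = 100 * mean(presence[, ph]),
        odds_ratio = (a * d) / (b * c_),
        corrected = corrected,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clinical characteristics of each disease state
#'
#' Summarises the clusters in terms of snapshot/patient counts, % female,
#' median age, median windowed BMI, and in-hospital mortality prevalence.
#' Age per snapshot is the patient's age on first entering the snapshot (the
#' bin's start day minus birth day), capped at 32,872 days (90 years) and
#' converted to years. BMI per snapshot is the mean of all measurements
#' falling inside the 30-day window; the fraction of snapshots contributing
#' a BMI is reported alongside the median. Snapshots with a missing birth
#' date are omitted from the age median.
#'
#' @param labels cluster label per snapshot.
#' @param rows snapshot metadata (`patient_id`, `bin_index`, `anchor_day`),
#'   e.g. the `rows` of a `snapshot_matrix`.
#' @param demographics data frame `patient_id`, `birth_day` (day offset on
#'   the mention clock), `sex` (`"F"`/`"M"`).
#' @param bmi optional data frame `patient_id`, `timestamp`, `bmi`.
#' @param events optional event table; rows whose `event_type` equals
#'   `mortality_event` define in-hospital mortality.
#' @param mortality_event event type treated as in-hospital mortality.
#' @param bin_width bin width in days.
#' @return data frame, one row per cluster.
#' @export
clinical_summary <- function(labels, rows, demographics, bmi = NULL,
                             events = NULL,
                             mortality_event = "in_hospital_mortality",
                             bin_width = 30) {
  stop_if_missing_cols(demographics, c("patient_id", "birth_day", "sex"),
                       "demographics table")
  stopifnot(length(labels) == nrow(rows))
  birth <- stats::setNames(demographics$birth_day, demographics$patient_id)
  sex <- stats::setNames(demographics$sex, demographics$patient_id)
  bin_start <- rows$anchor_day + bin_width * rows$bin_index
  age_days <- bin_start - birth[rows$patient_id]
  missing_birth <- is.na(age_days)
  if (any(missing_birth))
    message(sum(missing_birth), " snapshot(s) lack a birth date; omitted from age medians")
  age_years <- pmin(age_days, 32872) / 365.25

  snap_bmi <- rep(NA_real_, nrow(rows))
  if (!is.null(bmi) && nrow(bmi) > 0) {
    stop_if_missing_cols(bmi, c("patient_id", "timestamp", "bmi"), "BMI table")
    bday <- as_day_offset(bmi$timestamp, bmi$patient_id)
    skey <- paste(rows$patient_id, rows$bin_index, sep = "\r")
    anchors <- stats::setNames(rows$anchor_day, rows$patient_id)
    bbin <- floor((bday - anchors[as.character(bmi$patient_id)]) / bin_width)
    bkey <- paste(bmi$patient_id, bbin, sep = "\r")
    means <- tapply(bmi$bmi, bkey, mean)
    snap_bmi <- as.numeric(means[skey])
  }

  mort <- rep(FALSE, nrow(rows))
  if (!is.null(events) && nrow(events) > 0) {
    ev <- events[events$event_type == mortality_event, , drop = FALSE]
    if (nrow(ev) > 0) {
      el <- label_events(rows, ev, bin_width = bin_width)
      mort <- as.logical(el$present[, mortality_event])
    }
  }

  clusters <- sort(unique(labels))
  out <- lapply(clusters, function(cl) {
    ing <- labels == cl
    data.frame(
      cluster = cl,
      n_snapshots = sum(ing),
      n_patients = length(unique(rows$patient_id[ing])),
      pct_female = 100 * mean(sex[rows$patient_id[ing]] == "F", na.rm = TRUE),
      median_age = stats::median(age_years[ing & !missing_birth]),
      median_bmi = stats::median(snap_bmi[ing], na.rm = TRUE),
      bmi_fraction = mean(!is.na(snap_bmi[ing])),
      mortality_prevalence = 100 * mean(mort[ing]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Example phenotype keyword map
#'
#' Loads the package's bundled example map of 50 high-level cardiology-
#' flavoured phenotypes with search keywords. The map illustrates the
#' format (`phenotype`, `keyword`; several rows per phenotype allowed) and is
#' meant to be replaced by a clinician-curated map for real analyses.
#'
#' @return data frame with columns `phenotype` and `keyword`.
#' @export
example_phenotype_map <- function() {
  path <- system.file("extdata", "phenotype_map_example.csv",
                      package = "snapstate")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
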