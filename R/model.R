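#' Control parameters for a disease-state analysis
#'
#' Collects every tunable of the pipeline with defaults matching the
#' reference analysis: 30-day bins, patient exclusion below 10 mentions per
#' snapshot, 99% vocabulary coverage, K swept over 2..30, the geometric
#' subsampling schedule 0.5, 0.25, ..., 0.0078125 with 1000 bootstrap
#' replicates, alpha = 0.05 with Bonferroni correction, rank-sum feature
#' tests, an odds-ratio edge threshold of 1.33 and a [0.45, 0.55]
#' bidirectional ordering band. `n_reps` and `k_range` are the knobs to
#' shrink for desk-scale runs.
#'
#' @param bin_width snapshot window in days.
#' @param min_mentions per-snapshot mention threshold for patient exclusion.
#' @param coverage vocabulary cumulative-mass target.
#' @param k_range cluster counts to sweep.
#' @param f_d subsampling fractions for the stability bootstrap.
#' @param n_reps bootstrap replicates per (K, f_d) cell.
#' @param alpha significance level for feature testing.
#' @param test_method `"ranksum"` or `"ttest"`.
#' @param or_threshold network edge odds-ratio threshold.
#' @param bidir_band bidirectional ordering-probability band.
#' @param nstart,nstart_boot k-means++ restarts (reference / bootstrap).
#' @param compute_semantic also compute the semantic stability statistic S.
#' @param select_fd fraction at which stable K local maxima are assessed.
#' @param stat replicate summary for maxima detection (`"mean"`/`"median"`).
#' @param seed master seed for clustering and bootstrapping.
#' @return a list of class `ds_control`.
#' @export
ds_control <- function(bin_width = 30, min_mentions = 10, coverage = 0.99,
                       k_range = 2:30, f_d = 0.5 * 2^-(0:6), n_reps = 1000,
                       alpha = 0.05, test_method = c("ranksum", "ttest"),
                       or_threshold = 1.33, bidir_band = c(0.45, 0.55),
                       nstart = 10, nstart_boot = 2,
                       compute_semantic = FALSE, select_fd = 0.5,
                       stat = c("mean", "median"), seed = 1L) {
  structure(list(bin_width = bin_width, min_mentions = min_mentions,
                 coverage = coverage, k_range = as.integer(k_range),
                 f_d = f_d, n_reps = n_reps, alpha = alpha,
                 test_method = match.arg(test_method),
                 or_threshold = or_threshold, bidir_band = bidir_band,
                 nstart = nstart, nstart_boot = nstart_boot,
                 compute_semantic = compute_semantic, select_fd = select_fd,
                 stat = match.arg(stat), seed = as.integer(seed)),
            class = "ds_control")
}

#' Fit a disease-state model to longitudinal complaint mentions
#'
#' The end-to-end analysis: polarity filtering, 30-day binning, cohort
#' exclusion, vocabulary truncation and log-TF-IDF vectorization; a K-means
#' sweep with bootstrapped Jaccard cluster stability and local-maximum
#' selection of stable K; the cross-K state hierarchy; per-state significant
#' complaint vocabularies (and phenotype enrichment / clinical summaries /
#' event risk when the corresponding tables are supplied); and the temporal
#' progression network from patient-level co-occurrence odds ratios and
#' first-occurrence ordering.
#'
#' The snapshot — all of a patient's positive complaint mentions inside one
#' 30-day window — is the clustering unit, and every snapshot receives one
#' hard disease-state assignment at the chosen K (the finest stable K unless
#' `K` is given).
#'
#' @param mentions data frame `patient_id`, `timestamp` (date or integer day
#'   offset), `concept_id`, `polarity` (`"pos"`/`"neg"`).
#' @param events optional data frame `patient_id`, `timestamp`, `event_type`.
#' @param demographics optional data frame `patient_id`, `birth_day`, `sex`.
#' @param bmi optional data frame `patient_id`, `timestamp`, `bmi`.
#' @param phenotype_map optional keyword map (`phenotype`, `keyword`);
#'   defaults to the bundled [example_phenotype_map()].
#' @param K fix the number of states instead of using the finest stable K.
#' @param control a [ds_control()].
#' @return an object of class `snapstate` with components `matrix`
#'   (snapshot_matrix), `runs`, `profile` (stability), `stable_k`, `K`,
#'   `labels`, `hierarchy`, `vocabularies`, `feature_tests`, `enrichment`,
#'   `clinical`, `event_labels`, `risk`, `cooccurrence`, `ordering`,
#'   `network`, `funnel`, `exclusion`, and `control`.
#' @seealso [predict.snapstate()], [plot.snapstate()], [render_reports()]
#' @export
snapstate <- function(mentions, events = NULL, demographics = NULL,
                      bmi = NULL, phenotype_map = NULL, K = NULL,
                      control = ds_control()) {
  stopifnot(inherits(control, "ds_control"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  built <- stage("snapshot_pipeline",
                 build_snapshot_matrix(mentions,
                                       min_mentions = control$min_mentions,
                                       coverage = control$coverage,
                                       bin_width = control$bin_width))
  x <- built$matrix
  n <- nrow(x$tfidf)
  k_range <- control$k_range[control$k_range < n]
  if (length(k_range) == 0) stop("no feasible K below the snapshot count", call. = FALSE)

  runs <- stage("state_discovery",
                run_kmeans_sweep(x, k_range, nstart = control$nstart,
                                 seed = control$seed))
  profile <- NULL
  if (length(k_range) > 1 && is.null(K)) {
    profile <- stage("state_discovery",
                     bootstrap_stability(x, runs = runs, f_d = control$f_d,
                                         n_reps = control$n_reps,
                                         seed = control$seed,
                                         nstart_boot = control$nstart_boot,
                                         compute_semantic = control$compute_semantic,
                                         alpha = control$alpha,
                                         test_method = control$test_method))
    stable_k <- select_stable_k(profile, f_d = control$select_fd,
                                stat = control$stat)
    K_use <- max(stable_k)
  } else {
    stable_k <- integer(0)
    K_use <- K %||% k_range[1]
    if (length(k_range) == 1)
      message("single K requested; stability selection and hierarchy skipped")
  }
  if (!is.null(K)) K_use <- K
  if (!K_use %in% k_range)
    runs[[as.character(K_use)]] <- run_kmeans_sweep(x, K_use,
                                                    nstart = control$nstart,
                                                    seed = control$seed)[[1]]
  labels <- runs[[as.character(K_use)]]$labels

  hierarchy <- NULL
  if (length(stable_k) >= 2)
    hierarchy <- stage("state_discovery", build_hierarchy(runs, stable_k))

  vocabularies <- stage("state_characterization",
                        significant_vocabularies(x, labels,
                                                 alpha = control$alpha,
                                                 method = control$test_method))
  map <- phenotype_map %||% tryCatch(example_phenotype_map(),
                                     error = function(e) NULL)
  enrichment <- NULL
  if (!is.null(map)) {
    presence <- stage("state_characterization", phenotype_presence(x, map))
    enrichment <- stage("state_characterization",
                        phenotype_enrichment(presence, labels))
  }
  clinical <- NULL
  if (!is.null(demographics))
    clinical <- stage("state_characterization",
                      clinical_summary(labels, x$rows, demographics, bmi = bmi,
                                       events = events,
                                       bin_width = control$bin_width))
  event_labels <- risk <- NULL
  if (!is.null(events) && nrow(events) > 0) {
    event_labels <- stage("event_risk",
                          label_events(x$rows, events,
                                       bin_width = control$bin_width))
    risk <- stage("event_risk", state_risk_table(labels, event_labels))
  }

  co <- stage("progression_network",
              cooccurrence_odds(labels, x$rows$patient_id, K = K_use))
  ord <- stage("progression_network",
               ordering_probabilities(labels, x$rows$patient_id,
                                      x$rows$bin_index, K = K_use))
  network <- stage("progression_network",
                   suppressWarnings(
                     build_network(co, ord, or_threshold = control$or_threshold,
                                   bidir_band = control$bidir_band,
                                   snapshot_counts = table(labels))))
  funnel <- c(built$funnel, chosen_K = K_use)

  structure(list(matrix = x, runs = runs, profile = profile,
                 stable_k = stable_k, K = K_use, labels = labels,
                 hierarchy = hierarchy, vocabularies = vocabularies,
                 enrichment = enrichment, clinical = clinical,
                 event_labels = event_labels, risk = risk,
                 cooccurrence = co, ordering = ord, network = network,
                 funnel = funnel, exclusion = built$exclusion,
                 control = control),
            class = "snapstate")
}

#' @exportS3Method base::print
print.snapstate <- function(x, ...) {
  cat("Disease-state model\n")
  cat("  snapshots:", nrow(x$matrix$tfidf), " patients:",
      length(unique(x$matrix$rows$patient_id)),
      " vocabulary:", length(x$matrix$vocabulary), "\n")
  if (length(x$stable_k) > 0)
    cat("  stable K:", paste(x$stable_k, collapse = ", "), "\n")
  cat("  states (K):", x$K, " edges:", nrow(x$network$edges), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.snapstate <- function(object, ...) {
  sizes <- tabulate(object$labels, object$K)
  voc <- vapply(object$vocabularies, length, 0L)
  out <- list(funnel = object$funnel,
              stable_k = object$stable_k,
              K = object$K,
              state_sizes = sizes,
              n_significant_complaints = voc,
              n_edges = nrow(object$network$edges),
              start_states = object$network$nodes$state[object$network$nodes$is_start],
              end_states = object$network$nodes$state[object$network$nodes$is_end])
  class(out) <- "summary.snapstate"
  out
}

#' @exportS3Method base::print
print.summary.snapstate <- function(x, ...) {
  cat("Disease-state model summary\n\nRecord funnel:\n")
  print(x$funnel)
  cat("\nStable K:", if (length(x$stable_k)) paste(x$stable_k, collapse = ", ")
      else "(not assessed)", "\n")
  cat("States at K =", x$K, "- snapshot counts:\n")
  print(stats::setNames(x$state_sizes, paste0("state_", seq_along(x$state_sizes))))
  cat("\nSignificant complaints per state:\n")
  print(x$n_significant_complaints)
  cat("\nNetwork:", x$n_edges, "edges; start states:",
      paste(x$start_states, collapse = ", "), "; end states:",
      paste(x$end_states, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.snapstate <- function(object, ...) object$runs[[as.character(object$K)]]$centroids

#' Assign new snapshots to fitted disease states
#'
#' New mention data are binned, vectorized with the training vocabulary and
#' the training IDF weights, L2-normalised, and assigned to the nearest
#' fitted centroid (Euclidean, equivalent to cosine on unit vectors).
#'
#' @param object a fitted [snapstate()] model.
#' @param newdata a mention table, or a `snapshots` object, or a numeric
#'   matrix with columns matching the training vocabulary.
#' @param ... unused.
#' @return data frame (`patient_id`, `bin_index`, `state`) for table input,
#'   or an integer label vector for matrix input.
#' @export
predict.snapstate <- function(object, newdata, ...) {
  cent <- coef(object)
  if (is.matrix(newdata)) {
    return(nearest_centroid(newdata, cent))
  }
  snaps <- if (inherits(newdata, "snapshots")) newdata else
    bin_snapshots(filter_polarity(newdata), bin_width = object$control$bin_width)
  vocab <- object$matrix$vocabulary
  cc <- snaps$counts[snaps$counts$concept_id %in% vocab, , drop = FALSE]
  info <- snaps$info
  skey <- paste(info$patient_id, info$bin_index, sep = "\r")
  i <- match(paste(cc$patient_id, cc$bin_index, sep = "\r"), skey)
  j <- match(cc$concept_id, vocab)
  counts <- Matrix::sparseMatrix(i = i, j = j, x = cc$n,
                                 dims = c(nrow(info), length(vocab)))
  tfm <- counts
  if (object$matrix$tf == "log") tfm@x <- 1 + log(tfm@x)
  tfidf <- as.matrix(tfm %*% Matrix::Diagonal(x = object$matrix$idf))
  norms <- sqrt(rowSums(tfidf^2))
  ok <- norms > 0
  tfidf[ok, ] <- tfidf[ok, , drop = FALSE] / norms[ok]
  state <- rep(NA_integer_, nrow(info))
  state[ok] <- nearest_centroid(tfidf[ok, , drop = FALSE], cent)
  data.frame(patient_id = info$patient_id, bin_index = info$bin_index,
             state = state, stringsAsFactors = FALSE)
}

nearest_centroid <- function(x, centroids) {
  d <- outer(rowSums(x^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(x)), rowSums(centroids^2)) -
    2 * x %*% t(centroids)
  as.integer(apply(d, 1, which.min))
}

#' Two-dimensional embedding of snapshots
#'
#' Projects the TF-IDF rows onto their first two principal components for
#' map-style figures and density overlays. Deterministic given the input
#' (component signs are fixed by convention); `seed` is accepted for
#' interface stability with stochastic embeddings.
#'
#' @param x a `snapshot_matrix` or numeric matrix.
#' @param seed unused by the PCA embedding; kept for interface stability.
#' @return N x 2 coordinate matrix.
#' @export
embed_2d <- function(x, seed = 1L) {
  xm <- as_dense(x)
  if (nrow(xm) < 3) stop("need at least 3 snapshots to embed", call. = FALSE)
  pc <- stats::prcomp(xm, center = TRUE, scale. = FALSE, rank. = 2)
  coords <- pc$x[, 1:2, drop = FALSE]
  ## sign convention: largest-magnitude loading positive
  for (k in 1:2) {
    v <- pc$rotation[, k]
    if (v[which.max(abs(v))] < 0) coords[, k] <- -coords[, k]
  }
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Plot method for disease-state models
#'
#' `type = "stability"` draws the mean J per K with inter-quartile corridors
#' for each subsampling fraction (stable K marked); `"hierarchy"` the state
#' dendrogram annotated with split K; `"network"` the progression network;
#' `"embedding"` the 2D snapshot map coloured by state.
#'
#' @param x a fitted [snapstate()] model.
#' @param type which panel to draw.
#' @param ... passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.snapstate <- function(x, type = c("stability", "hierarchy", "network",
                                       "embedding"), ...) {
  type <- match.arg(type)
  if (type == "stability") {
    if (is.null(x$profile)) stop("model was fitted without a stability profile")
    plot_stability(x$profile, stable_k = x$stable_k, ...)
  } else if (type == "hierarchy") {
    if (is.null(x$hierarchy)) stop("model has no hierarchy (needs >= 2 stable K)")
    hc <- x$hierarchy$hclust
    graphics::plot(hc, main = "Disease-state hierarchy",
                   xlab = "", sub = "", ...)
  } else if (type == "network") {
    plot_network(x$network, ...)
  } else {
    coords <- embed_2d(x$matrix)
    graphics::plot(coords, col = x$labels, pch = 16, cex = 0.5,
                   main = paste0("Snapshot map (K = ", x$K, ")"), ...)
  }
  invisible(x)
}

#' Stability corridor plot
#'
#' @param profile a [bootstrap_stability()] result.
#' @param stable_k K values to mark.
#' @param ... passed to [graphics::plot()].
#' @return the summary table, invisibly.
#' @export
plot_stability <- function(profile, stable_k = integer(0), ...) {
  sm <- summary(profile)
  fds <- sort(unique(sm$f_d), decreasing = TRUE)
  cols <- grDevices::hcl.colors(length(fds), "viridis")
  graphics::plot(range(sm$K), c(0, 1), type = "n", xlab = "K",
                 ylab = "Jaccard stability J", ...)
  for (i in seq_along(fds)) {
    d <- sm[sm$f_d == fds[i], ]
    graphics::polygon(c(d$K, rev(d$K)), c(d$J_lo, rev(d$J_hi)),
                      col = grDevices::adjustcolor(cols[i], 0.15), border = NA)
    graphics::lines(d$K, d$J_mean, col = cols[i], lwd = 2)
  }
  if (length(stable_k) > 0)
    graphics::abline(v = stable_k, lty = 3, col = "darkgreen")
  graphics::legend("bottomleft", legend = paste0("f_d=", signif(fds, 3)),
                   col = cols, lwd = 2, cex = 0.7, bty = "n")
  invisible(sm)
}

#' Draw a progression network
#'
#' @param network a [build_network()] result.
#' @param ... passed to [igraph::plot.igraph()].
#' @return the network, invisibly.
#' @export
plot_network <- function(network, ...) {
  g <- network$graph
  sizes <- network$nodes$n_snapshots
  vsize <- if (all(is.na(sizes))) 15 else
    10 + 20 * sizes / max(sizes, na.rm = TRUE)
  cols <- ifelse(network$nodes$is_start, "palegreen",
                 ifelse(network$nodes$is_end, "lightcoral", "lightblue"))
  igraph::plot.igraph(g, vertex.size = vsize, vertex.color = cols,
                      edge.arrow.size = 0.5,
                      edge.label = signif(network$edges$or, 3), ...)
  invisible(network)
}
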