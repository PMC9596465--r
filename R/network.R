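#' Patient-level disease-state co-occurrence odds ratios
#'
#' For every unordered state pair \{i, j\}, patients are cross-classified by
#' whether state i and state j each appear anywhere in their timeline, and
#' the odds ratio
#' \deqn{OR_{ij} = \frac{n_{ij} \, n_{\neg i, \neg j}}{n_{i,\neg j} \, n_{\neg i, j}}}
#' is computed from the resulting 2x2 table, with a Haldane-Anscombe 0.5
#' correction applied to all four cells whenever any cell is zero. The 95%
#' confidence interval is Wald on the log odds ratio,
#' `exp(ln OR +/- 1.96 sqrt(sum of reciprocal cells))`; a pair is flagged
#' significant when the interval excludes 1 (pairs whose interval covers 1
#' are masked downstream).
#'
#' @param labels cluster label per snapshot.
#' @param patient_ids patient id per snapshot (same length as `labels`).
#' @param K number of states (default: max label observed).
#' @return data frame of class `cooccurrence_stats`, one row per unordered
#'   pair: counts `n11`, `n10`, `n01`, `n00`, `or`, `ci_lo`, `ci_hi`,
#'   `significant`, `corrected`.
#' @export
cooccurrence_odds <- function(labels, patient_ids, K = NULL) {
  stopifnot(length(labels) == length(patient_ids))
  K <- K %||% max(labels)
  if (K < 2) stop("co-occurrence needs at least 2 states", call. = FALSE)
  has <- table(patient_ids, factor(labels, levels = 1:K)) > 0 # patients x states
  n_pat <- nrow(has)
  pairs <- utils::combn(K, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    n11 <- sum(has[, i] & has[, j])
    n10 <- sum(has[, i] & !has[, j])
    n01 <- sum(!has[, i] & has[, j])
    n00 <- n_pat - n11 - n10 - n01
    cells <- c(n11, n10, n01, n00)
    corrected <- any(cells == 0)
    if (corrected) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    se <- sqrt(sum(1 / cells))
    ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
    data.frame(state_i = i, state_j = j,
               n11 = n11, n10 = n10, n01 = n01, n00 = n00,
               or = or, ci_lo = ci[1], ci_hi = ci[2],
               significant = ci[1] > 1 | ci[2] < 1,
               corrected = corrected)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cooccurrence_stats", "data.frame")
  out
}

#' First-occurrence ordering between disease states
#'
#' Among patients in whose timeline both states of a pair appear, counts
#' which state's first occurrence comes first. Under one state per snapshot
#' first-occurrence bins cannot tie, so `p_ij + p_ji = 1` for every
#' co-occurring pair. The median transition time for direction i -> j is the
#' median, over patients where i comes first, of
#' `firstBin(j) - firstBin(i)` in 30-day bins of calendar time (gaps
#' included). Pairs never co-occurring are reported with missing
#' probabilities.
#'
#' @param labels cluster label per snapshot.
#' @param patient_ids patient id per snapshot.
#' @param bins bin index per snapshot.
#' @param K number of states (default: max label observed).
#' @return data frame of class `ordering_stats`, one row per unordered pair:
#'   `n_both`, `p_ij` (probability i's first occurrence precedes j's),
#'   `p_ji`, `median_bins_ij`, `median_bins_ji`.
#' @export
ordering_probabilities <- function(labels, patient_ids, bins, K = NULL) {
  stopifnot(length(labels) == length(patient_ids),
            length(labels) == length(bins))
  K <- K %||% max(labels)
  ## first-occurrence bin of each state per patient
  key <- paste(patient_ids, labels, sep = "\r")
  fb <- tapply(bins, key, min)
  parts <- strsplit(names(fb), "\r", fixed = TRUE)
  fdf <- data.frame(patient_id = vapply(parts, `[`, "", 1L),
                    state = as.integer(vapply(parts, `[`, "", 2L)),
                    first_bin = as.numeric(fb), stringsAsFactors = FALSE)
  pats <- unique(fdf$patient_id)
  fmat <- matrix(NA_real_, length(pats), K, dimnames = list(pats, NULL))
  fmat[cbind(match(fdf$patient_id, pats), fdf$state)] <- fdf$first_bin

  pairs <- utils::combn(K, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    both <- !is.na(fmat[, i]) & !is.na(fmat[, j])
    nb <- sum(both)
    if (nb == 0) {
      return(data.frame(state_i = i, state_j = j, n_both = 0L,
                        p_ij = NA_real_, p_ji = NA_real_,
                        median_bins_ij = NA_real_, median_bins_ji = NA_real_))
    }
    di <- fmat[both, i]; dj <- fmat[both, j]
    i_first <- di < dj
    data.frame(state_i = i, state_j = j, n_both = nb,
               p_ij = mean(i_first), p_ji = mean(!i_first),
               median_bins_ij = if (any(i_first))
                 stats::median(dj[i_first] - di[i_first]) else NA_real_,
               median_bins_ji = if (any(!i_first))
                 stats::median(di[!i_first] - dj[!i_first]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ordering_stats", "data.frame")
  out
}

#' Build the temporal disease-state progression network
#'
#' Edges connect state pairs whose co-occurrence odds ratio is statistically
#' significant (95% CI excluding 1) and exceeds `or_threshold` (1.33 by
#' default). Edge direction follows the first-occurrence ordering
#' probability: i -> j when `p_ij` is above the bidirectional band, j -> i
#' when below, and bidirectional inside `[0.45, 0.55]`. Each edge carries the
#' median transition time in 30-day bins (for bidirectional edges, the mean
#' of the two directional medians). States with only outgoing directed
#' arrows are start states; states with only incoming arrows are end states
#' (bidirectional arrows count in both directions).
#'
#' @param co a [cooccurrence_odds()] result.
#' @param ord an [ordering_probabilities()] result over the same states.
#' @param or_threshold minimum odds ratio for an edge.
#' @param bidir_band ordering-probability band rendered bidirectional.
#' @param snapshot_counts optional named per-state snapshot counts (node
#'   sizes).
#' @param p_adjust multiplicity correction across the K(K-1)/2 pair tests
#'   applied to the significance mask: `"none"` (default) or `"bonferroni"`
#'   (re-derives the mask from Wald CIs at level `0.05 / n_pairs`).
#' @return object of class `progression_network`: `edges` (data frame
#'   `from`, `to`, `or`, `ci_lo`, `ci_hi`, `direction`, `p_order`,
#'   `median_bins`), `nodes` (data frame `state`, `n_snapshots`, `is_start`,
#'   `is_end`), and `graph` (an igraph object). An empty edge set yields a
#'   valid network of isolated nodes with a warning.
#' @export
build_network <- function(co, ord, or_threshold = 1.33,
                          bidir_band = c(0.45, 0.55),
                          snapshot_counts = NULL,
                          p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(co, "cooccurrence_stats"), inherits(ord, "ordering_stats"))
  K <- max(co$state_i, co$state_j)
  sig <- co$significant
  if (p_adjust == "bonferroni") {
    z <- stats::qnorm(1 - 0.05 / (2 * nrow(co)))
    cells <- cbind(co$n11, co$n10, co$n01, co$n00)
    cells[rowSums(cells == 0) > 0, ] <- cells[rowSums(cells == 0) > 0, ] + 0.5
    se <- sqrt(rowSums(1 / cells))
    lo <- exp(log(co$or) - z * se); hi <- exp(log(co$or) + z * se)
    sig <- lo > 1 | hi < 1
  }
  okey <- paste(ord$state_i, ord$state_j)
  edges <- list()
  for (r in which(sig & co$or > or_threshold)) {
    i <- co$state_i[r]; j <- co$state_j[r]
    o <- ord[okey == paste(i, j), ]
    if (nrow(o) == 0 || is.na(o$p_ij)) next
    if (o$p_ij > bidir_band[2]) {
      dir <- "i->j"; from <- i; to <- j; med <- o$median_bins_ij; p <- o$p_ij
    } else if (o$p_ij < bidir_band[1]) {
      dir <- "j->i"; from <- j; to <- i; med <- o$median_bins_ji; p <- o$p_ji
    } else {
      dir <- "bidirectional"; from <- i; to <- j
      med <- mean(c(o$median_bins_ij, o$median_bins_ji), na.rm = TRUE)
      p <- o$p_ij
    }
    edges[[length(edges) + 1L]] <- data.frame(
      from = from, to = to, or = co$or[r], ci_lo = co$ci_lo[r],
      ci_hi = co$ci_hi[r], direction = dir, p_order = p,
      median_bins = med, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = integer(), to = integer(), or = numeric(),
               ci_lo = numeric(), ci_hi = numeric(), direction = character(),
               p_order = numeric(), median_bins = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(edges) == 0) warning("no edges pass the threshold; network has isolated nodes")

  out_deg <- in_deg <- rep(0L, K)
  for (r in seq_len(nrow(edges))) {
    if (edges$direction[r] == "bidirectional") {
      out_deg[edges$from[r]] <- out_deg[edges$from[r]] + 1L
      out_deg[edges$to[r]] <- out_deg[edges$to[r]] + 1L
      in_deg[edges$from[r]] <- in_deg[edges$from[r]] + 1L
      in_deg[edges$to[r]] <- in_deg[edges$to[r]] + 1L
    } else {
      out_deg[edges$from[r]] <- out_deg[edges$from[r]] + 1L
      in_deg[edges$to[r]] <- in_deg[edges$to[r]] + 1L
    }
  }
  counts <- rep(NA_integer_, K)
  if (!is.null(snapshot_counts))
    counts[as.integer(names(snapshot_counts))] <- as.integer(snapshot_counts)
  nodes <- data.frame(state = 1:K, n_snapshots = counts,
                      is_start = out_deg > 0 & in_deg == 0,
                      is_end = in_deg > 0 & out_deg == 0)

  g <- igraph::graph_from_data_frame(
    transform(edges, from = as.character(from), to = as.character(to)),
    directed = TRUE,
    vertices = data.frame(name = as.character(1:K), nodes[-1]))
  structure(list(edges = edges, nodes = nodes, graph = g,
                 or_threshold = or_threshold, bidir_band = bidir_band),
            class = "progression_network")
}

#' @exportS3Method base::print
print.progression_network <- function(x, ...) {
  cat("Progression network:", nrow(x$nodes), "states,", nrow(x$edges),
      "edges (OR >", x$or_threshold, ", significant);",
      sum(x$nodes$is_start), "start,", sum(x$nodes$is_end), "end state(s)\n")
  invisible(x)
}

#' Attach clinical annotations to network nodes
#'
#' Joins per-state clinical summaries (and optionally the event-risk table)
#' onto the network's node table. Pure joins, no computation; errors when a
#' network state is missing from the summaries.
#'
#' @param network a [build_network()] result.
#' @param summaries per-cluster [clinical_summary()] data frame.
#' @param risk optional [state_risk_table()] data frame (spread to one
#'   column pair per event type).
#' @return the network with an augmented `nodes` table.
#' @export
annotate_network <- function(network, summaries, risk = NULL) {
  stopifnot(inherits(network, "progression_network"))
  miss <- setdiff(network$nodes$state, summaries$cluster)
  if (length(miss) > 0)
    stop("no clinical summary for state(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  nodes <- merge(network$nodes, summaries, by.x = "state", by.y = "cluster",
                 all.x = TRUE, sort = TRUE)
  if (!is.null(risk) && nrow(risk) > 0) {
    for (ty in unique(risk$event_type)) {
      sub <- risk[risk$event_type == ty, c("cluster", "present_pct", "future_pct")]
      names(sub) <- c("state", paste0(ty, "_present_pct"), paste0(ty, "_future_pct"))
      nodes <- merge(nodes, sub, by = "state", all.x = TRUE, sort = TRUE)
    }
  }
  network$nodes <- nodes[order(nodes$state), ]
  rownames(network$nodes) <- NULL
  network
}

#' Write a progression network to disk
#'
#' @param network a [build_network()] result.
#' @param graphml optional GraphML path.
#' @param edges_tsv optional edge-list TSV path.
#' @param nodes_tsv optional node-table TSV path.
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, graphml = NULL, edges_tsv = NULL,
                          nodes_tsv = NULL) {
  stopifnot(inherits(network, "progression_network"))
  if (!is.null(graphml)) igraph::write_graph(network$graph, graphml,
                                             format = "graphml")
  if (!is.null(edges_tsv))
    utils::write.table(network$edges, edges_tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(nodes_tsv))
    utils::write.table(network$nodes, nodes_tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(c(graphml = graphml, edges = edges_tsv, nodes = nodes_tsv))
}
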