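#' K-means reference partitions across a range of K
#'
#' Runs K-means (Lloyd iterations, k-means++ seeding, `nstart` restarts, best
#' within-cluster sum of squares kept) on the L2-normalised TF-IDF rows for
#' every K in `k_range`. On unit-norm vectors squared Euclidean distance is a
#' monotone transform of cosine distance, so plain K-means groups snapshots
#' by complaint-profile similarity. Deterministic given `seed`.
#'
#' @param x a `snapshot_matrix` or numeric matrix (rows = snapshots).
#' @param k_range integer vector of cluster counts, each in `[2, N)`.
#' @param nstart k-means++ restarts per K.
#' @param iter_max Lloyd iteration cap.
#' @param seed integer seed; each K uses an independent derived stream.
#' @return list of `clustering_run` objects (fields `K`, `labels` in `1..K`,
#'   `centroids`, `inertia`, `seed`), named by K.
#' @export
run_kmeans_sweep <- function(x, k_range = 2:30, nstart = 10, iter_max = 50,
                             seed = 1L) {
  xm <- as_dense(x)
  n <- nrow(xm)
  k_range <- as.integer(k_range)
  if (any(k_range < 2)) stop("K must be at least 2", call. = FALSE)
  if (any(k_range >= n)) stop("K must be smaller than the number of snapshots",
                              call. = FALSE)
  runs <- lapply(k_range, function(k) {
    withr::with_seed(seed + k, {
      fit <- kmeans_pp(xm, k, nstart = nstart, iter_max = iter_max)
      structure(list(K = k, labels = as.integer(fit$cluster),
                     centroids = fit$centers, inertia = fit$tot.withinss,
                     seed = seed + k),
                class = "clustering_run")
    })
  })
  names(runs) <- as.character(k_range)
  runs
}

#' @exportS3Method base::print
print.clustering_run <- function(x, ...) {
  cat("K-means run: K =", x$K, "on", length(x$labels), "snapshots; sizes:",
      paste(tabulate(x$labels, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' Data-point-weighted Jaccard stability between two partitions
#'
#' For a reference partition and a partition of a (sub)sample labelled on the
#' same points,
#' \deqn{J = \frac{1}{N} \sum_i \sum_j n_{ij} J_{ij}, \qquad
#'       J_{ij} = \frac{|c_i^{ref} \cap c_j^{boot}|}{|c_i^{ref} \cup c_j^{boot}|},}
#' where \eqn{n_{ij}} counts points in reference cluster i and bootstrap
#' cluster j, all restricted to the common point set. `J = 1` iff the two
#' partitions are identical up to cluster relabelling; `J` is invariant to
#' label permutations in either argument.
#'
#' @param ref,boot label vectors over the same points (equal length).
#' @return a value in `[0, 1]`.
#' @export
jaccard_stability <- function(ref, boot) {
  if (length(ref) != length(boot) || length(ref) == 0)
    stop("ref and boot must label the same non-empty point set", call. = FALSE)
  tab <- table(ref, boot)
  ni <- rowSums(tab)
  nj <- colSums(tab)
  uni <- outer(ni, nj, "+") - tab
  sum(tab * (tab / uni)) / length(ref)
}

#' Data-point-weighted semantic stability between two partitions
#'
#' Complements [jaccard_stability()] on the vocabulary side:
#' \deqn{S = \frac{1}{N} \sum_i \sum_j n_{ij} S_{ij}, \qquad
#'       S_{ij} = \frac{|v_i^{ref} \cap v_j^{boot}|}{|v_j^{boot}|},}
#' where \eqn{v} are the significantly enriched complaint vocabularies of
#' each cluster (see [significant_vocabularies()]). A bootstrap cluster with
#' an empty significant vocabulary contributes \eqn{S_{ij} = 0} (no evidence
#' of semantic agreement).
#'
#' @param ref,boot label vectors over the same points.
#' @param ref_vocab,boot_vocab lists of character vectors of significant
#'   concepts, indexed by cluster id of the respective partition.
#' @return a value in `[0, 1]`.
#' @export
semantic_stability <- function(ref, boot, ref_vocab, boot_vocab) {
  if (length(ref) != length(boot) || length(ref) == 0)
    stop("ref and boot must label the same non-empty point set", call. = FALSE)
  if (is.null(ref_vocab) || is.null(boot_vocab))
    stop("significant vocabularies are required for both partitions", call. = FALSE)
  tab <- table(ref, boot)
  ri <- as.integer(rownames(tab))
  bj <- as.integer(colnames(tab))
  S <- 0
  for (a in seq_along(ri)) {
    for (b in seq_along(bj)) {
      if (tab[a, b] == 0) next
      vb <- boot_vocab[[bj[b]]]
      sij <- if (length(vb) == 0) 0 else
        length(intersect(ref_vocab[[ri[a]]], vb)) / length(vb)
      S <- S + tab[a, b] * sij
    }
  }
  S / length(ref)
}

#' Bootstrapped cluster-stability profile
#'
#' For each K and each subsampling fraction `f_d`, repeatedly draws
#' `floor(f_d * N)` snapshots without replacement, re-runs K-means on the
#' subsample, and scores the result against the reference partition
#' restricted to the sampled rows with [jaccard_stability()] (and, when
#' `compute_semantic = TRUE`, [semantic_stability()] using per-replicate
#' significant vocabularies on the subsample against the reference's
#' full-data vocabularies). Cells whose subsample is smaller than K are
#' skipped with a warning.
#'
#' @param x a `snapshot_matrix` or numeric matrix.
#' @param k_range cluster counts to profile.
#' @param f_d subsampling fractions; the default geometric schedule
#'   `0.5, 0.25, ..., 0.0078125` probes how clustering degrades as data
#'   shrinks.
#' @param n_reps bootstrap replicates per (K, f_d) cell (1000 to match the
#'   reference analysis; reducible for desk-scale runs).
#' @param seed master seed; every replicate gets an independent derived seed.
#' @param runs optional precomputed [run_kmeans_sweep()] result.
#' @param nstart,nstart_boot k-means++ restarts for reference/bootstrap runs.
#' @param compute_semantic also compute S (needs a full significance battery
#'   per replicate; markedly slower).
#' @param alpha significance level for the S vocabularies.
#' @param test_method feature test for the S vocabularies.
#' @return a `stability_profile`: data frame (`K`, `f_d`, `rep`, `J`, `S`)
#'   with the reference runs attached as an attribute.
#' @export
bootstrap_stability <- function(x, k_range = 2:30,
                                f_d = 0.5 * 2^-(0:6), n_reps = 1000,
                                seed = 1L, runs = NULL,
                                nstart = 10, nstart_boot = 2,
                                compute_semantic = FALSE, alpha = 0.05,
                                test_method = c("ranksum", "ttest")) {
  test_method <- match.arg(test_method)
  xm <- as_dense(x)
  n <- nrow(xm)
  if (is.null(runs)) runs <- run_kmeans_sweep(x, k_range, nstart = nstart, seed = seed)
  k_range <- as.integer(names(runs))
  ref_vocabs <- NULL
  if (compute_semantic) {
    ref_vocabs <- lapply(runs, function(r)
      significant_vocabularies(xm, r$labels, alpha = alpha, method = test_method))
  }
  seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L,
                      length(k_range) * length(f_d) * n_reps, replace = TRUE),
           nrow = n_reps))
  out <- vector("list", length(k_range) * length(f_d))
  cell <- 0L
  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    ref <- runs[[as.character(K)]]
    for (fi in seq_along(f_d)) {
      cell <- cell + 1L
      m <- floor(f_d[fi] * n)
      if (m < K) {
        warning("skipping K=", K, ", f_d=", f_d[fi],
                ": subsample smaller than K")
        next
      }
      J <- S <- rep(NA_real_, n_reps)
      for (r in seq_len(n_reps)) {
        withr::with_seed(seeds[r, (ki - 1L) * length(f_d) + fi], {
          idx <- sample.int(n, m)
          boot <- kmeans_pp(xm[idx, , drop = FALSE], K,
                            nstart = nstart_boot, iter_max = 50)
          J[r] <- jaccard_stability(ref$labels[idx], boot$cluster)
          if (compute_semantic) {
            bv <- significant_vocabularies(xm[idx, , drop = FALSE], boot$cluster,
                                           alpha = alpha, method = test_method)
            S[r] <- semantic_stability(ref$labels[idx], boot$cluster,
                                       ref_vocabs[[as.character(K)]], bv)
          }
        })
      }
      out[[cell]] <- data.frame(K = K, f_d = f_d[fi], rep = seq_len(n_reps),
                                J = J, S = S)
    }
  }
  prof <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(prof) <- NULL
  structure(prof, class = c("stability_profile", "data.frame"),
            runs = runs, n_reps = n_reps, seed = seed)
}

#' @exportS3Method base::summary
summary.stability_profile <- function(object, probs = c(0.25, 0.75), ...) {
  split_by <- interaction(object$K, object$f_d, drop = TRUE)
  rows <- lapply(split(object, split_by), function(d) {
    data.frame(K = d$K[1], f_d = d$f_d[1], n = nrow(d),
               J_mean = mean(d$J, na.rm = TRUE),
               J_median = stats::median(d$J, na.rm = TRUE),
               J_lo = stats::quantile(d$J, probs[1], na.rm = TRUE, names = FALSE),
               J_hi = stats::quantile(d$J, probs[2], na.rm = TRUE, names = FALSE),
               S_mean = mean(d$S, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$f_d, out$K), ]
  rownames(out) <- NULL
  out
}

#' Select stable cluster counts
#'
#' A value of K is stable when the summary (mean by default) of the Jaccard
#' stability J at `f_d = 0.5` is a strict local maximum over the examined K
#' grid; grid endpoints use a one-sided comparison. In `strict` mode K must
#' additionally be a local maximum of the semantic statistic S and remain a
#' local maximum of J at every smaller `f_d` present in the profile.
#'
#' @param profile a [bootstrap_stability()] result.
#' @param f_d fraction at which maxima are assessed (0.5 by default).
#' @param stat summary over replicates: `"mean"` (default) or `"median"`.
#' @param strict require the S maximum and cross-`f_d` persistence.
#' @return increasing integer vector of stable K values.
#' @export
select_stable_k <- function(profile, f_d = 0.5, stat = c("mean", "median"),
                            strict = FALSE) {
  stat <- match.arg(stat)
  fun <- if (stat == "mean") mean else stats::median
  fds <- sort(unique(profile$f_d), decreasing = TRUE)
  if (!any(abs(fds - f_d) < 1e-12))
    stop("profile does not cover f_d = ", f_d, call. = FALSE)
  local_maxima <- function(vals, ks) {
    ord <- order(ks)
    ks <- ks[ord]; vals <- vals[ord]
    n <- length(vals)
    ok <- vapply(seq_len(n), function(i) {
      left <- i == 1 || vals[i] > vals[i - 1]
      right <- i == n || vals[i] > vals[i + 1]
      left && right
    }, TRUE)
    ks[ok]
  }
  stat_at <- function(col, fd) {
    d <- profile[abs(profile$f_d - fd) < 1e-12, ]
    vapply(split(d[[col]], d$K), fun, 0, na.rm = TRUE)
  }
  j_half <- stat_at("J", f_d)
  ks <- as.integer(names(j_half))
  stable <- local_maxima(j_half, ks)
  if (strict) {
    s_half <- stat_at("S", f_d)
    if (all(is.na(s_half)))
      stop("strict mode requires S values in the profile", call. = FALSE)
    stable <- intersect(stable, local_maxima(s_half, as.integer(names(s_half))))
    for (fd in fds[fds < f_d]) {
      jv <- stat_at("J", fd)
      stable <- intersect(stable, local_maxima(jv, as.integer(names(jv))))
    }
  }
  sort(stable)
}

#' Cross-K disease-state hierarchy
#'
#' Builds the dendrogram over the clusters of the finest stable K
#' (`m* = max(stable K)`). For every coarser stable K the `m* x m` matrix of
#' cluster-pair Jaccard indices is computed; the rows of that matrix are
#' per-fine-cluster similarity profiles, and the Euclidean distances between
#' profiles give an `m* x m*` distance matrix. Distance matrices are averaged
#' over all coarser stable K and agglomerated with complete linkage. Each
#' merge is annotated with the smallest stable K whose partition separates
#' the two branches.
#'
#' @param runs list of `clustering_run`s (or plain label vectors) keyed by K,
#'   e.g. the reference runs attached to a stability profile.
#' @param stable_k the stable K values to use (default: all keys of `runs`).
#' @return object of class `state_hierarchy`: `hclust` tree over the m*
#'   clusters, the averaged distance matrix, `split_k` (per internal merge),
#'   `stable_k`, `m_star`.
#' @export
build_hierarchy <- function(runs, stable_k = NULL) {
  labels_of <- function(r) if (inherits(r, "clustering_run")) r$labels else r
  ks <- as.integer(names(runs))
  if (is.null(stable_k)) stable_k <- ks
  stable_k <- sort(as.integer(intersect(stable_k, ks)))
  if (length(stable_k) < 2)
    stop("hierarchy undefined: need at least 2 stable K values", call. = FALSE)
  m_star <- max(stable_k)
  fine <- labels_of(runs[[as.character(m_star)]])
  coarser <- setdiff(stable_k, m_star)
  dists <- lapply(coarser, function(m) {
    coarse <- labels_of(runs[[as.character(m)]])
    tab <- table(factor(fine, levels = 1:m_star), coarse) # m* x m counts
    ni <- rowSums(tab); nj <- colSums(tab)
    Jmat <- tab / (outer(ni, nj, "+") - tab)
    as.matrix(stats::dist(Jmat))
  })
  avg <- Reduce(`+`, dists) / length(dists)
  hc <- stats::hclust(stats::as.dist(avg), method = "complete")
  hc$labels <- paste0("state_", 1:m_star)

  ## smallest stable K at which the two branches of each merge separate
  coarse_assign <- lapply(coarser, function(m) {
    coarse <- labels_of(runs[[as.character(m)]])
    tab <- table(factor(fine, levels = 1:m_star), coarse)
    apply(tab, 1, which.max) # modal coarse cluster of each fine cluster
  })
  names(coarse_assign) <- as.character(coarser)
  leaves_under <- function(node) {
    if (node < 0) return(-node)
    c(leaves_under(hc$merge[node, 1]), leaves_under(hc$merge[node, 2]))
  }
  split_k <- vapply(seq_len(nrow(hc$merge)), function(i) {
    l1 <- leaves_under(hc$merge[i, 1])
    l2 <- leaves_under(hc$merge[i, 2])
    for (m in coarser) {
      a <- coarse_assign[[as.character(m)]]
      mode1 <- as.integer(names(which.max(table(a[l1]))))
      mode2 <- as.integer(names(which.max(table(a[l2]))))
      if (mode1 != mode2) return(m)
    }
    m_star
  }, 0L)

  structure(list(hclust = hc, dist = avg, split_k = split_k,
                 stable_k = stable_k, m_star = m_star),
            class = "state_hierarchy")
}

#' @exportS3Method base::print
print.state_hierarchy <- function(x, ...) {
  cat("Disease-state hierarchy over", x$m_star, "states (stable K:",
      paste(x$stable_k, collapse = ", "), ")\n")
  invisible(x)
}

#' Export a state hierarchy as Newick
#'
#' Branch lengths come from the complete-linkage merge heights; node labels
#' carry the K value at which each split first appears.
#'
#' @param hierarchy a [build_hierarchy()] result.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_hierarchy <- function(hierarchy, file) {
  stopifnot(inherits(hierarchy, "state_hierarchy"))
  phy <- ape::as.phylo(hierarchy$hclust)
  ## map hclust merges to phylo internal nodes by their descendant leaf sets
  hc <- hierarchy$hclust
  leaves_under <- function(node) {
    if (node < 0) return(-node)
    c(leaves_under(hc$merge[node, 1]), leaves_under(hc$merge[node, 2]))
  }
  merge_sets <- lapply(seq_len(nrow(hc$merge)),
                       function(i) sort(leaves_under(i)))
  ntip <- length(phy$tip.label)
  tip_idx <- match(phy$tip.label, hc$labels)
  node_lab <- character(phy$Nnode)
  for (nd in seq_len(phy$Nnode) + ntip) {
    tips <- descendant_tips(phy, nd, ntip)
    set <- sort(tip_idx[tips])
    hit <- which(vapply(merge_sets, identical, TRUE, y = set))
    node_lab[nd - ntip] <- if (length(hit) == 1)
      paste0("K", hierarchy$split_k[hit]) else ""
  }
  phy$node.label <- node_lab
  ape::write.tree(phy, file = file)
  invisible(file)
}

## tips descending from an internal node of a phylo tree (simple recursion,
## avoids pulling in extra tree utilities for one traversal)
descendant_tips <- function(phy, node, ntip) {
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  out <- integer(0)
  for (k in kids) {
    out <- c(out, if (k <= ntip) k else descendant_tips(phy, k, ntip))
  }
  out
}
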