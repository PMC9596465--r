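#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans pnorm pt qnorm rpois rgeom rbinom rnorm runif
#'   median quantile sd var hclust as.dist dist prcomp setNames p.adjust
#' @importFrom utils head read.csv write.csv write.table read.table combn
#' @importFrom methods as
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Timestamps are handled internally as integer day offsets. ISO-8601 dates
## are converted relative to the epoch; integer/numeric columns pass through.
as_day_offset <- function(x, patient_id = NULL) {
  if (inherits(x, "Date")) return(as.numeric(x))
  if (is.numeric(x)) return(as.numeric(x))
  d <- tryCatch(suppressWarnings(as.Date(as.character(x))),
                error = function(e)
                  as.Date(as.character(x), format = "%Y-%m-%d"))
  bad <- is.na(d) & !is.na(x)
  if (any(bad)) {
    who <- if (!is.null(patient_id)) {
      paste0(" (patient_id: ", paste(unique(patient_id[bad])[1:min(5, sum(bad))],
                                     collapse = ", "), ")")
    } else ""
    stop("unparseable timestamp(s) in rows ",
         paste(head(which(bad), 5), collapse = ", "), who, call. = FALSE)
  }
  as.numeric(d)
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

## Adjusted Rand index between two hard partitions (permutation-model
## expectation correction). Cross-checked against mclust in the test suite.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_i * sum_j / choose(n, 2)
  max_ij <- (sum_i + sum_j) / 2
  if (max_ij == exp_ij) return(1)
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}

## k-means++ seeding (squared-Euclidean D^2 weighting).
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  rs <- rowSums(x^2)
  d2 <- rs + sum(x[idx[1], ]^2) - 2 * drop(x %*% x[idx[1], ])
  d2 <- pmax(d2, 0)
  if (k > 1) {
    for (i in 2:k) {
      prob <- if (sum(d2) > 0) d2 else rep(1, n)
      idx[i] <- sample.int(n, 1L, prob = prob)
      d2i <- rs + sum(x[idx[i], ]^2) - 2 * drop(x %*% x[idx[i], ])
      d2 <- pmin(d2, pmax(d2i, 0))
    }
  }
  x[idx, , drop = FALSE]
}

## Lloyd k-means with k-means++ restarts; retries on degenerate (empty
## cluster) solutions, keeps the lowest within-cluster sum of squares.
kmeans_pp <- function(x, k, nstart = 10, iter_max = 50) {
  best <- NULL
  tries <- 0L
  while (tries < nstart + 5L && (is.null(best) || tries < nstart)) {
    tries <- tries + 1L
    centers <- kmeanspp_centers(x, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit) || length(unique(fit$cluster)) < k) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed to find a partition with ", k,
                          " non-empty clusters", call. = FALSE)
  best
}

## Column-wise one-sided (greater) Mann-Whitney rank-sum statistics for a
## group-vs-rest comparison, normal approximation with tie correction and
## continuity correction. This is the same large-sample path that
## stats::wilcox.test takes in the presence of ties; it is vectorised over
## features so that a full test battery is a single pass.
ranksum_battery <- function(x, in_group) {
  n <- nrow(x)
  n1 <- sum(in_group)
  n2 <- n - n1
  if (n1 < 2 || n2 < 1) stop("group must have >= 2 members and a non-empty complement")
  stat <- p <- numeric(ncol(x))
  for (v in seq_len(ncol(x))) {
    col <- x[, v]
    r <- rank(col)
    u <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- rle(sort(col))$lengths
    tie_term <- sum(as.numeric(ties)^3 - ties)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) { # constant feature: no evidence either way
      stat[v] <- 0
      p[v] <- 1
      next
    }
    z <- (u - n1 * n2 / 2 - 0.5) / sqrt(sigma2)
    stat[v] <- z
    p[v] <- stats::pnorm(z, lower.tail = FALSE)
  }
  list(statistic = stat, p = p)
}

## Column-wise one-sided Welch t statistics, group vs rest.
welch_battery <- function(x, in_group) {
  n1 <- sum(in_group)
  n2 <- nrow(x) - n1
  if (n1 < 2 || n2 < 2) stop("both arms need >= 2 snapshots for the t-test")
  x1 <- x[in_group, , drop = FALSE]
  x2 <- x[!in_group, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2, stats::var); v2 <- apply(x2, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- ifelse(se2 > 0, stats::pt(stat, df, lower.tail = FALSE), 1)
  list(statistic = stat, p = p)
}

as_dense <- function(x) {
  if (inherits(x, "snapshot_matrix")) x <- x$tfidf
  as.matrix(x)
}
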