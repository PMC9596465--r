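#' Read a mention table from CSV/TSV
#'
#' Required columns: `patient_id`, `timestamp` (ISO-8601 date or integer day
#' offset), `concept_id`, `polarity` in `{pos, neg}`.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @return data frame.
#' @export
read_mentions <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("patient_id", "timestamp", "concept_id", "polarity"),
                       path)
  bad <- setdiff(unique(df$polarity), c("pos", "neg"))
  if (length(bad) > 0)
    stop(path, ": polarity must be 'pos' or 'neg' (found: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  df
}

#' Write a snapshot matrix as MatrixMarket plus metadata
#'
#' Writes `counts.mtx` and `tfidf.mtx` (MatrixMarket sparse format) with
#' `rows.tsv` (snapshot metadata) and `columns.tsv` (vocabulary) beside them.
#'
#' @param x a `snapshot_matrix`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_snapshot_matrix <- function(x, dir) {
  stopifnot(inherits(x, "snapshot_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.mtx", "tfidf.mtx", "rows.tsv", "columns.tsv"))
  Matrix::writeMM(methods::as(x$counts, "CsparseMatrix"), paths[1])
  Matrix::writeMM(x$tfidf, paths[2])
  utils::write.table(x$rows, paths[3], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(concept_id = x$vocabulary, idf = x$idf),
                     paths[4], sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Render the output bundle of a fitted disease-state model
#'
#' Writes all analysis artifacts to a run directory: the run manifest
#' (record-count funnel, seeds, chosen K) and config echo as JSON; snapshot
#' labels, the tidy stability profile, per-state significant complaints,
#' phenotype enrichment, clinical summaries, event-risk and network tables as
#' TSV; the hierarchy as Newick; the network as GraphML; and figures
#' (stability corridors, dendrogram, network, embedding map) as PNG.
#'
#' @param fit a fitted [snapstate()] model.
#' @param dir output directory (created if absent).
#' @param figures render PNG figures (set `FALSE` on headless boxes without
#'   a PNG device).
#' @return invisibly, a named vector of written paths.
#' @export
render_reports <- function(fit, dir, figures = TRUE) {
  stopifnot(inherits(fit, "snapstate"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths[[name]] <<- p
  }

  manifest <- list(funnel = as.list(fit$funnel),
                   stable_k = fit$stable_k, K = fit$K,
                   seed = fit$control$seed,
                   n_excluded_patients = nrow(fit$exclusion))
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  paths[["manifest.json"]] <- p
  p <- file.path(dir, "config_echo.json")
  jsonlite::write_json(unclass(fit$control), p, auto_unbox = TRUE, digits = NA)
  paths[["config_echo.json"]] <- p

  tsv(data.frame(fit$matrix$rows[c("patient_id", "bin_index")],
                 state = fit$labels), "labels.tsv")
  if (!is.null(fit$profile)) tsv(as.data.frame(fit$profile), "stability.tsv")
  vs <- do.call(rbind, lapply(seq_along(fit$vocabularies), function(cl)
    if (length(fit$vocabularies[[cl]]) > 0)
      data.frame(cluster = cl, concept_id = fit$vocabularies[[cl]]) else NULL))
  if (!is.null(vs)) tsv(vs, "significant_complaints.tsv")
  if (!is.null(fit$enrichment)) tsv(fit$enrichment, "phenotype_enrichment.tsv")
  if (!is.null(fit$clinical)) tsv(fit$clinical, "clinical_summary.tsv")
  if (!is.null(fit$risk)) tsv(fit$risk, "event_risk.tsv")
  tsv(fit$cooccurrence, "cooccurrence.tsv")
  tsv(fit$ordering, "ordering.tsv")
  write_network(fit$network,
                graphml = file.path(dir, "network.graphml"),
                edges_tsv = file.path(dir, "network_edges.tsv"),
                nodes_tsv = file.path(dir, "network_nodes.tsv"))
  paths[["network.graphml"]] <- file.path(dir, "network.graphml")
  if (!is.null(fit$hierarchy)) {
    write_hierarchy(fit$hierarchy, file.path(dir, "hierarchy.nwk"))
    paths[["hierarchy.nwk"]] <- file.path(dir, "hierarchy.nwk")
  }

  if (figures && capabilities("png")) {
    fig <- function(name, expr) {
      p <- file.path(dir, name)
      grDevices::png(p, width = 900, height = 700)
      on.exit(grDevices::dev.off(), add = TRUE)
      tryCatch(expr, error = function(e) NULL)
      paths[[name]] <<- p
    }
    if (!is.null(fit$profile))
      fig("stability.png", plot(fit, type = "stability"))
    if (!is.null(fit$hierarchy))
      fig("hierarchy.png", plot(fit, type = "hierarchy"))
    fig("network.png", plot(fit, type = "network"))
    fig("embedding.png", plot(fit, type = "embedding"))
  }
  invisible(unlist(paths))
}

#' Run the full pipeline from a configuration
#'
#' Config-driven driver over [snapstate()] and [render_reports()]. The config
#' is a list (or path to a YAML file) with input table paths (`mentions`,
#' optional `events`, `demographics`, `bmi`, `phenotype_map`), an
#' `output_dir`, and any [ds_control()] overrides under `control`.
#'
#' @param config list or YAML path.
#' @return the fitted model, invisibly; artifacts land in `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$mentions)) stop("config must name a mentions table", call. = FALSE)
  mentions <- if (is.character(config$mentions)) read_mentions(config$mentions)
              else config$mentions
  load_tab <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  }
  ctrl <- do.call(ds_control, config$control %||% list())
  fit <- snapstate(mentions,
                   events = load_tab(config$events),
                   demographics = load_tab(config$demographics),
                   bmi = load_tab(config$bmi),
                   phenotype_map = load_tab(config$phenotype_map),
                   K = config$K,
                   control = ctrl)
  if (!is.null(config$output_dir)) render_reports(fit, config$output_dir)
  invisible(fit)
}
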