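#' Specify a synthetic longitudinal cohort
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' generator emulates the statistical structure the snapshot-clustering
#' analysis assumes: per-patient timelines of complaint mentions whose
#' marginal frequencies follow a Zipf law, latent disease states with
#' distinctive complaint signatures arranged in a known two-level hierarchy,
#' Markov state dynamics over a planted transition matrix, state-dependent
#' clinical-event emission, state-linked demographics, and a configurable
#' fraction of negative-polarity mentions.
#'
#' Each state enriches `signature_size` dedicated complaints by the
#' multiplicative factor `signature_lift` over the Zipf background; sibling
#' states under the same `hierarchy` group additionally share a parent-level
#' signature block (lifted by `parent_lift`), which is what the downstream
#' dendrogram stage recovers. Dwell times are geometric via self-transition
#' probabilities. Timestamps are day offsets from a per-patient index date so
#' 30-day binning is exact; a small fraction of bins (`empty_bin_rate`) carry
#' zero mentions to exercise downstream bin dropping.
#'
#' @param n_patients number of patients.
#' @param vocab_size number of distinct complaint concepts.
#' @param zipf_exponent exponent of the background rank-frequency law;
#'   background concept `r` has weight `r^-zipf_exponent`.
#' @param n_states number of latent disease states `G`.
#' @param hierarchy integer vector of length `G` assigning each state to a
#'   parent group (default: balanced split into two groups).
#' @param signature_size complaints in each state (and parent) signature.
#' @param signature_lift multiplicative enrichment of a state's signature
#'   complaints over background.
#' @param parent_lift enrichment of the shared parent-group signature block.
#' @param transition_matrix `G x G` row-stochastic matrix (default: a chain
#'   with self-transition 0.5 and an absorbing final state).
#' @param initial_distribution initial-state probabilities (default uniform).
#' @param mean_mentions_per_bin Poisson rate of mentions per 30-day bin.
#' @param empty_bin_rate probability that a bin carries zero mentions.
#' @param neg_polarity_rate fraction of mentions flagged negative polarity.
#' @param event_rates `G x E` matrix of per-bin Bernoulli event emission
#'   probabilities, with event types as column names (default: a
#'   "hospitalization" event at a uniform low rate plus a "decompensation"
#'   event enriched in the final state).
#' @param demographics_model data frame with one row per state and columns
#'   `age_mean`, `age_sd`, `p_female`, `bmi_mean`, `bmi_sd`; a patient's
#'   demographics are drawn from their initial state's row.
#' @param bmi_measure_rate probability that a bin carries a BMI measurement.
#' @param timeline_sampler function of `n` returning per-patient timeline
#'   lengths in 30-day bins. The default gives a median near 4 bins with a
#'   long right tail, echoing routinely collected EHR timelines.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_patients = 2000,
                        vocab_size = 500,
                        zipf_exponent = 1.5,
                        n_states = 4,
                        hierarchy = NULL,
                        signature_size = 8,
                        signature_lift = 20,
                        parent_lift = signature_lift,
                        transition_matrix = NULL,
                        initial_distribution = NULL,
                        mean_mentions_per_bin = 25,
                        empty_bin_rate = 0.05,
                        neg_polarity_rate = 0.1,
                        event_rates = NULL,
                        demographics_model = NULL,
                        bmi_measure_rate = 0.5,
                        timeline_sampler = function(n) pmin(1L + stats::rgeom(n, 1 / 5), 30L),
                        seed = 1L) {
  G <- as.integer(n_states)
  if (G < 1) stop("n_states must be a positive count", call. = FALSE)
  if (n_patients < 1) stop("n_patients must be a positive count", call. = FALSE)
  if (vocab_size < 1) stop("vocab_size must be a positive count", call. = FALSE)
  if (zipf_exponent <= 0) stop("zipf_exponent must be positive", call. = FALSE)
  if (is.null(hierarchy)) hierarchy <- ((seq_len(G) - 1L) %/% max(1L, ceiling(G / 2))) + 1L
  if (length(hierarchy) != G) stop("hierarchy must assign each of the ", G,
                                   " states to a group", call. = FALSE)
  if (is.null(transition_matrix)) transition_matrix <- chain_transitions(G)
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(G, G)))
    stop("transition_matrix must be ", G, " x ", G, call. = FALSE)
  if (any(transition_matrix < 0 | transition_matrix > 1))
    stop("transition_matrix entries must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-12))
    stop("transition_matrix rows must sum to 1 (tolerance 1e-12)", call. = FALSE)
  if (is.null(initial_distribution)) initial_distribution <- rep(1 / G, G)
  if (length(initial_distribution) != G || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-12)
    stop("initial_distribution must be a length-", G,
         " probability vector summing to 1", call. = FALSE)
  for (nm in c("empty_bin_rate", "neg_polarity_rate", "bmi_measure_rate")) {
    val <- get(nm)
    if (!is.numeric(val) || val < 0 || val > 1)
      stop(nm, " must lie in [0, 1]", call. = FALSE)
  }
  if (mean_mentions_per_bin <= 0)
    stop("mean_mentions_per_bin must be positive", call. = FALSE)
  if (is.null(event_rates)) {
    event_rates <- cbind(hospitalization = rep(0.05, G),
                         decompensation = c(rep(0.02, G - 1), 0.3)[seq_len(G)])
  }
  event_rates <- as.matrix(event_rates)
  if (nrow(event_rates) != G)
    stop("event_rates must have one row per state", call. = FALSE)
  if (any(event_rates < 0 | event_rates > 1))
    stop("event_rates must lie in [0, 1]", call. = FALSE)
  if (is.null(colnames(event_rates)))
    colnames(event_rates) <- paste0("event_", seq_len(ncol(event_rates)))
  if (is.null(demographics_model)) {
    demographics_model <- data.frame(
      state = seq_len(G),
      age_mean = seq(55, 75, length.out = G),
      age_sd = 8,
      p_female = 0.45,
      bmi_mean = 27,
      bmi_sd = 4)
  }
  if (nrow(demographics_model) != G)
    stop("demographics_model must have one row per state", call. = FALSE)
  if (any(demographics_model$p_female < 0 | demographics_model$p_female > 1))
    stop("demographics_model$p_female must lie in [0, 1]", call. = FALSE)
  n_sig <- (length(unique(hierarchy)) + G) * signature_size
  if (signature_size > 0 && n_sig + 10 > vocab_size)
    stop("vocab_size too small for ", n_sig, " signature concepts", call. = FALSE)

  structure(list(
    n_patients = as.integer(n_patients), vocab_size = as.integer(vocab_size),
    zipf_exponent = zipf_exponent, n_states = G, hierarchy = as.integer(hierarchy),
    signature_size = as.integer(signature_size), signature_lift = signature_lift,
    parent_lift = parent_lift, transition_matrix = transition_matrix,
    initial_distribution = initial_distribution,
    mean_mentions_per_bin = mean_mentions_per_bin, empty_bin_rate = empty_bin_rate,
    neg_polarity_rate = neg_polarity_rate, event_rates = event_rates,
    demographics_model = demographics_model, bmi_measure_rate = bmi_measure_rate,
    timeline_sampler = timeline_sampler, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Chain transition matrix with geometric dwell
#'
#' Convenience constructor: state `g` stays with probability `p_stay` and
#' advances to `g + 1` otherwise; the final state is absorbing. Useful for
#' planting simple progressions.
#'
#' @param G number of states.
#' @param p_stay self-transition probability (geometric dwell, mean
#'   `1 / (1 - p_stay)` bins).
#' @return a `G x G` row-stochastic matrix.
#' @export
chain_transitions <- function(G, p_stay = 0.5) {
  P <- diag(p_stay, G)
  if (G > 1) for (g in seq_len(G - 1)) P[g, g + 1] <- 1 - p_stay
  P[G, G] <- 1
  P
}

#' Branching transition matrix over two disjoint chains
#'
#' Plants a 5-state structure made of two independent progression chains
#' (1 -> 2 -> 3 and 4 -> 5) with geometric dwell. States on different chains
#' never co-occur within a patient, giving the co-occurrence analysis a
#' negative-association contrast, while within-chain ancestor/descendant
#' pairs are positively associated and temporally ordered.
#'
#' @param p_stay self-transition probability.
#' @return a list with elements `transition_matrix` (5 x 5),
#'   `initial_distribution`, and `n_states`.
#' @export
two_chain_transitions <- function(p_stay = 0.5) {
  P <- diag(p_stay, 5)
  P[1, 2] <- 1 - p_stay
  P[2, 3] <- 1 - p_stay
  P[3, 3] <- 1
  P[4, 5] <- 1 - p_stay
  P[5, 5] <- 1
  list(transition_matrix = P,
       initial_distribution = c(0.3, 0.1, 0.1, 0.3, 0.2),
       n_states = 5L)
}

## Per-state complaint mixtures: Zipf background with lifted signature blocks.
## Signatures occupy contiguous concept ranks starting after the top 10 so
## that lifted concepts are distinctive but not vanishingly rare.
state_mixtures <- function(spec) {
  G <- spec$n_states
  w0 <- (seq_len(spec$vocab_size))^(-spec$zipf_exponent)
  groups <- sort(unique(spec$hierarchy))
  ss <- spec$signature_size
  ## state-specific signatures take the better ranks so that each state's own
  ## signal outweighs the shared parent block it sits on
  offset <- 10L
  state_idx <- lapply(seq_len(G), function(g)
    offset + (g - 1L) * ss + seq_len(ss))
  offset2 <- offset + G * ss
  parent_idx <- lapply(seq_along(groups), function(i)
    offset2 + (i - 1L) * ss + seq_len(ss))
  mix <- matrix(0, nrow = G, ncol = spec$vocab_size)
  for (g in seq_len(G)) {
    w <- w0
    if (ss > 0) {
      w[parent_idx[[match(spec$hierarchy[g], groups)]]] <-
        w[parent_idx[[match(spec$hierarchy[g], groups)]]] * spec$parent_lift
      w[state_idx[[g]]] <- w[state_idx[[g]]] * spec$signature_lift
    }
    mix[g, ] <- w / sum(w)
  }
  list(mixtures = mix,
       state_signatures = state_idx,
       parent_signatures = parent_idx)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates mention, event, demographics, and BMI tables from a
#' [cohort_spec()], together with the latent truth every downstream stage can
#' be scored against. Generation is deterministic given the spec (including
#' its seed): two calls return identical tables.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `synthetic_cohort`:
#' \describe{
#'   \item{mentions}{data frame `patient_id`, `timestamp` (integer day
#'     offset), `concept_id`, `polarity` (`"pos"`/`"neg"`).}
#'   \item{events}{data frame `patient_id`, `timestamp`, `event_type`.}
#'   \item{demographics}{data frame `patient_id`, `birth_day` (day offset,
#'     negative), `sex` (`"F"`/`"M"`).}
#'   \item{bmi}{data frame `patient_id`, `timestamp`, `bmi`.}
#'   \item{truth}{ground truth: `snapshot_states` (patient, bin, state),
#'     `hierarchy`, `transition_edges` (direct planted edges),
#'     `progression_pairs` (ordered reachability closure of the planted
#'     edges — the estimand of the pairwise co-occurrence network),
#'     `state_signatures`, `parent_signatures`, `mixtures`, `event_rates`.}
#'   \item{spec}{the spec echo.}
#' }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  G <- spec$n_states
  n <- spec$n_patients
  pid <- sprintf("P%05d", seq_len(n))

  L <- spec$timeline_sampler(n)
  if (any(L < 1)) stop("timeline_sampler returned non-positive lengths", call. = FALSE)
  maxL <- max(L)

  ## Markov state sequences, vectorised across patients one step at a time
  states <- matrix(NA_integer_, nrow = n, ncol = maxL)
  states[, 1] <- sample.int(G, n, replace = TRUE, prob = spec$initial_distribution)
  if (maxL > 1) {
    for (t in 2:maxL) {
      prev <- states[, t - 1]
      nxt <- integer(n)
      for (g in seq_len(G)) {
        rows <- which(prev == g)
        if (length(rows) > 0)
          nxt[rows] <- sample.int(G, length(rows), replace = TRUE,
                                  prob = spec$transition_matrix[g, ])
      }
      states[, t] <- nxt
    }
  }

  ## snapshot-level frame (one row per patient-bin)
  keep <- sequence(L)
  snap <- data.frame(
    patient_id = rep(pid, L),
    bin_index = keep - 1L,
    state = states[cbind(rep(seq_len(n), L), keep)],
    stringsAsFactors = FALSE)

  ## mention counts per bin: Poisson thinned by forced-empty bins
  m <- stats::rpois(nrow(snap), spec$mean_mentions_per_bin)
  m[stats::runif(nrow(snap)) < spec$empty_bin_rate] <- 0L

  mx <- state_mixtures(spec)
  ## draw concepts grouped by state (order within a snapshot is irrelevant)
  concept_of <- integer(sum(m))
  snap_of <- rep.int(seq_len(nrow(snap)), m)
  for (g in seq_len(G)) {
    sel <- which(snap$state[snap_of] == g)
    if (length(sel) > 0)
      concept_of[sel] <- sample.int(spec$vocab_size, length(sel), replace = TRUE,
                                    prob = mx$mixtures[g, ])
  }
  day <- 30L * snap$bin_index[snap_of] + sample.int(30L, length(snap_of), replace = TRUE) - 1L
  mentions <- data.frame(
    patient_id = snap$patient_id[snap_of],
    timestamp = day,
    concept_id = sprintf("c%04d", concept_of),
    polarity = ifelse(stats::runif(length(snap_of)) < spec$neg_polarity_rate,
                      "neg", "pos"),
    stringsAsFactors = FALSE)

  ## events: per bin, per type, Bernoulli with the true state's rate
  ev_list <- list()
  for (e in seq_len(ncol(spec$event_rates))) {
    pr <- spec$event_rates[snap$state, e]
    hit <- which(stats::runif(nrow(snap)) < pr)
    if (length(hit) > 0) {
      ev_list[[colnames(spec$event_rates)[e]]] <- data.frame(
        patient_id = snap$patient_id[hit],
        timestamp = 30L * snap$bin_index[hit] +
          sample.int(30L, length(hit), replace = TRUE) - 1L,
        event_type = colnames(spec$event_rates)[e],
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev_list) > 0) do.call(rbind, ev_list) else
    data.frame(patient_id = character(), timestamp = integer(),
               event_type = character(), stringsAsFactors = FALSE)
  rownames(events) <- NULL
  events <- events[order(events$patient_id, events$timestamp, events$event_type), ,
                   drop = FALSE]
  rownames(events) <- NULL

  ## demographics from the patient's initial state
  s0 <- states[, 1]
  dm <- spec$demographics_model
  age <- pmax(stats::rnorm(n, dm$age_mean[s0], dm$age_sd[s0]), 1)
  demographics <- data.frame(
    patient_id = pid,
    birth_day = -round(age * 365.25),
    sex = ifelse(stats::runif(n) < dm$p_female[s0], "F", "M"),
    stringsAsFactors = FALSE)

  ## BMI measurements within bins, mean tied to the current state
  has_bmi <- which(stats::runif(nrow(snap)) < spec$bmi_measure_rate)
  bmi <- data.frame(
    patient_id = snap$patient_id[has_bmi],
    timestamp = 30L * snap$bin_index[has_bmi] +
      sample.int(30L, length(has_bmi), replace = TRUE) - 1L,
    bmi = stats::rnorm(length(has_bmi), dm$bmi_mean[snap$state[has_bmi]],
                       dm$bmi_sd[snap$state[has_bmi]]),
    stringsAsFactors = FALSE)

  ## planted directed edges and their ordered reachability closure
  A <- spec$transition_matrix > 0
  diag(A) <- FALSE
  edges <- which(A, arr.ind = TRUE)
  transition_edges <- data.frame(from = edges[, 1], to = edges[, 2])
  R <- A
  for (i in seq_len(G)) R <- R | (R %*% A > 0) # transitive closure
  reach <- which(R & !diag(TRUE, G), arr.ind = TRUE)
  progression_pairs <- data.frame(from = reach[, 1], to = reach[, 2])

  truth <- list(
    snapshot_states = snap,
    hierarchy = spec$hierarchy,
    transition_edges = transition_edges,
    progression_pairs = progression_pairs,
    state_signatures = lapply(mx$state_signatures, function(i) sprintf("c%04d", i)),
    parent_signatures = lapply(mx$parent_signatures, function(i) sprintf("c%04d", i)),
    mixtures = mx$mixtures,
    event_rates = spec$event_rates)

  structure(list(mentions = mentions, events = events,
                 demographics = demographics, bmi = bmi,
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$spec$n_patients, "patients,",
      nrow(x$truth$snapshot_states), "snapshots,",
      nrow(x$mentions), "mentions,", x$spec$n_states, "latent states\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the mention/event/demographics/BMI tables as CSV, the ground truth
#' as JSON, and a config echo (spec parameters and seed) as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mentions = file.path(dir, "mentions.csv"),
    events = file.path(dir, "events.csv"),
    demographics = file.path(dir, "demographics.csv"),
    bmi = file.path(dir, "bmi.csv"),
    truth = file.path(dir, "ground_truth.json"),
    config = file.path(dir, "config_echo.json"))
  utils::write.csv(cohort$mentions, paths[["mentions"]], row.names = FALSE)
  utils::write.csv(cohort$events, paths[["events"]], row.names = FALSE)
  utils::write.csv(cohort$demographics, paths[["demographics"]], row.names = FALSE)
  utils::write.csv(cohort$bmi, paths[["bmi"]], row.names = FALSE)
  tr <- cohort$truth
  tr$mixtures <- NULL # large; reconstructible from the spec
  jsonlite::write_json(tr, paths[["truth"]], dataframe = "columns", digits = NA)
  sp <- cohort$spec
  sp$timeline_sampler <- deparse(sp$timeline_sampler)
  jsonlite::write_json(sp, paths[["config"]], auto_unbox = TRUE,
                       dataframe = "columns", digits = NA, force = TRUE)
  invisible(paths)
}
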