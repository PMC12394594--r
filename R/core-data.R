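#' emotrans: emotion transition prediction analyses with internal meta-analysis
#'
#' Analyses of emotion-transition likelihood ratings (the "emotion transition
#' task": participants rate, on a 0--100% scale, how likely a target -- the
#' self or another person -- is to move from one emotion state to another)
#' and their association with trait loneliness, pooled across studies with a
#' random-effects meta-analysis.  A synthetic multi-study generator makes
#' every stage verifiable by parameter recovery.
#'
#' @keywords internal
#' @importFrom stats cor sd rnorm plogis pnorm optim qnorm model.matrix var
#' @importFrom stats complete.cases aggregate setNames
#' @importFrom utils read.csv write.csv
"_PACKAGE"

VALENCE_LEVELS <- c("positive", "negative", "neutral")
CATEGORY_LEVELS <- c("PP", "PN", "NP", "NN", "NEUTRAL_INVOLVED")
TARGET_LEVELS <- c("self", "other")

#' Default valence map for the in-task emotion states
#'
#' Maps every emotion label used by the seven-state and six-state task
#' variants to a valence.  Study-specific maps (e.g. a fifteen-state set)
#' must be supplied by the user or a synthetic study config.
#'
#' @return Named character vector: label -> one of
#'   `"positive"`, `"negative"`, `"neutral"`.
#' @export
default_valence_map <- function() {
  c(
    happy = "positive", calm = "positive", amused = "positive",
    satisfied = "positive", hopeful = "positive", content = "positive",
    anxious = "negative", sad = "negative", irritable = "negative",
    sluggish = "negative",
    "full of thought" = "neutral", alert = "neutral"
  )
}

#' Standard reverse-keyed items of the 20-item loneliness scale
#' @return Integer vector of 1-based item indices.
#' @export
ucla_reverse_keys <- function() c(1L, 5L, 6L, 9L, 10L, 15L, 16L, 19L, 20L)

#' Score the 20-item UCLA Loneliness scale
#'
#' Responses are coded 0 = Never ... 3 = Often; reverse-keyed items are
#' scored `3 - x`.  The total ranges over \[0, 60\].
#'
#' @param responses Integer vector of exactly 20 responses in `{0,1,2,3}`.
#' @param reverse_keys Item indices (1-based) that are reverse-worded.
#' @return Integer sum score in \[0, 60\].
#' @examples
#' score_ucla(rep(0L, 20))  # 27: nine reversed items contribute 3 each
#' @export
score_ucla <- function(responses, reverse_keys = ucla_reverse_keys()) {
  if (length(responses) != 20L) {
    stop("`responses` must contain exactly 20 items, got ", length(responses))
  }
  if (anyNA(responses)) {
    stop("missing loneliness item response; incomplete scales are dropped, not prorated")
  }
  if (!all(responses %in% 0:3)) {
    stop("loneliness responses must be integers in {0,1,2,3}")
  }
  if (length(reverse_keys) && !all(reverse_keys %in% 1:20)) {
    stop("`reverse_keys` must be a subset of 1..20")
  }
  x <- as.integer(responses)
  x[reverse_keys] <- 3L - x[reverse_keys]
  sum(x)
}

#' Enumerate directed emotion transitions
#'
#' Ordered pairs of states, from-state major / to-state minor in the input
#' order; `n^2` pairs with same-state transitions, `n(n-1)` without.
#'
#' @param states Character vector of unique emotion labels.
#' @param include_same_state Include A->A transitions?
#' @return data.frame with columns `from`, `to`, `same_state`.
#' @export
enumerate_transitions <- function(states, include_same_state = FALSE) {
  states <- as.character(states)
  if (length(states) < 1L) stop("need at least one emotion state")
  if (anyDuplicated(states)) {
    stop("duplicate emotion labels: ",
         paste(unique(states[duplicated(states)]), collapse = ", "))
  }
  if (any(!nzchar(states))) stop("emotion labels must be non-empty")
  grid <- expand.grid(to = states, from = states,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(from = grid$from, to = grid$to,
                    stringsAsFactors = FALSE)
  out$same_state <- out$from == out$to
  if (!include_same_state) out <- out[!out$same_state, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify transitions into valence categories
#'
#' Endpoint valences define the category: PP, PN, NP, NN, or
#' `NEUTRAL_INVOLVED` when either endpoint is neutral.  Neutral-involving
#' transitions are excluded from valence analyses downstream; same-state
#' pairs classify by their (identical) endpoint valences.
#'
#' @param from,to Character vectors of emotion labels (recycled together).
#' @param valence_map Named character vector label -> valence.
#' @return Character vector of categories.
#' @examples
#' classify_transition("calm", "happy")      # "PP"
#' classify_transition("calm", "irritable")  # "PN"
#' @export
classify_transition <- function(from, to, valence_map = default_valence_map()) {
  labs <- unique(c(from, to))
  missing <- setdiff(labs, names(valence_map))
  if (length(missing)) {
    stop("emotion labels missing from valence map: ",
         paste(missing, collapse = ", "))
  }
  if (!all(valence_map %in% VALENCE_LEVELS)) {
    stop("valence map values must be one of: ",
         paste(VALENCE_LEVELS, collapse = ", "))
  }
  vf <- unname(valence_map[from])
  vt <- unname(valence_map[to])
  out <- ifelse(
    vf == "neutral" | vt == "neutral", "NEUTRAL_INVOLVED",
    paste0(ifelse(vf == "positive", "P", "N"),
           ifelse(vt == "positive", "P", "N"))
  )
  out
}

#' Z-score a numeric vector (sample SD, denominator n - 1)
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return Vector with mean 0 and sample SD 1.
#' @export
standardize_z <- function(x) {
  if (length(x) < 2L) stop("standardization needs at least 2 values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zero variance: skip standardization for constant input")
  }
  (x - mean(x)) / s
}

#' Construct a study dataset
#'
#' Bundles one study's emotion set, long-format ratings and participant
#' profiles, validating the structural invariants shared by all analyses.
#'
#' @param study_id Study identifier.
#' @param emotion_set data.frame with columns `label`, `valence`.
#' @param ratings data.frame with columns `participant_id`, `target`
#'   (`"self"`/`"other"`), `from_state`, `to_state`, `rating` (0--100).
#' @param participants data.frame with columns `participant_id`,
#'   `loneliness_raw` (0--60), `completion_fraction`; `loneliness_z` is
#'   (re)computed within study.
#' @param include_same_state Whether the design includes same-state
#'   transitions.
#' @param completion_threshold Participants below this completion fraction
#'   are dropped (with their ratings) before z-scoring loneliness.
#' @return Object of class `study_dataset`.
#' @export
study_dataset <- function(study_id, emotion_set, ratings, participants,
                          include_same_state = TRUE,
                          completion_threshold = 0.5) {
  stopifnot(is.data.frame(emotion_set),
            all(c("label", "valence") %in% names(emotion_set)))
  emotion_set$label <- as.character(emotion_set$label)
  emotion_set$valence <- as.character(emotion_set$valence)
  if (anyDuplicated(emotion_set$label)) stop("duplicate labels in emotion set")
  if (!all(emotion_set$valence %in% VALENCE_LEVELS)) {
    stop("emotion set valences must be in {",
         paste(VALENCE_LEVELS, collapse = ", "), "}")
  }
  req <- c("participant_id", "target", "from_state", "to_state", "rating")
  miss <- setdiff(req, names(ratings))
  if (length(miss)) stop("ratings table missing column(s): ",
                         paste(miss, collapse = ", "))
  preq <- c("participant_id", "loneliness_raw", "completion_fraction")
  pmiss <- setdiff(preq, names(participants))
  if (length(pmiss)) stop("participants table missing column(s): ",
                          paste(pmiss, collapse = ", "))

  ratings$participant_id <- as.character(ratings$participant_id)
  participants$participant_id <- as.character(participants$participant_id)
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicate participant ids in participants table")
  }

  bad <- which(!is.finite(ratings$rating) |
                 ratings$rating < 0 | ratings$rating > 100)
  if (length(bad)) {
    stop("rating outside [0, 100] at ratings row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!all(ratings$target %in% TARGET_LEVELS)) {
    stop("ratings target must be 'self' or 'other'")
  }
  unknown <- setdiff(unique(c(ratings$from_state, ratings$to_state)),
                     emotion_set$label)
  if (length(unknown)) {
    stop("unknown emotion label(s) in ratings: ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(ratings[c("participant_id", "target",
                              "from_state", "to_state")])) {
    stop("duplicate (participant, target, transition) rating")
  }
  same <- ratings$from_state == ratings$to_state
  if (!include_same_state && any(same)) {
    stop("same-state ratings present but include_same_state = FALSE")
  }
  if (any(!is.finite(participants$loneliness_raw)) ||
      any(participants$loneliness_raw < 0 | participants$loneliness_raw > 60)) {
    stop("loneliness_raw must lie in [0, 60]")
  }

  dropped <- participants$participant_id[
    participants$completion_fraction < completion_threshold]
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " participant(s) below completion threshold ",
            completion_threshold)
    participants <- participants[
      !participants$participant_id %in% dropped, , drop = FALSE]
    ratings <- ratings[!ratings$participant_id %in% dropped, , drop = FALSE]
  }
  orphan <- setdiff(unique(ratings$participant_id),
                    participants$participant_id)
  if (length(orphan)) {
    stop("ratings reference participant(s) without a profile: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  if (nrow(participants) >= 2L && sd(participants$loneliness_raw) > 0) {
    participants$loneliness_z <- standardize_z(participants$loneliness_raw)
  } else {
    participants$loneliness_z <- rep(NA_real_, nrow(participants))
  }
  rownames(ratings) <- NULL
  rownames(participants) <- NULL
  structure(
    list(study_id = as.character(study_id),
         emotion_set = emotion_set,
         include_same_state = isTRUE(include_same_state),
         targets_present = intersect(TARGET_LEVELS, unique(ratings$target)),
         ratings = ratings,
         participants = participants,
         n_dropped_completion = length(dropped)),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset> ", x$study_id, "\n",
      "  states: ", nrow(x$emotion_set),
      " (same-state ", if (x$include_same_state) "included" else "excluded",
      ")\n",
      "  participants: ", nrow(x$participants),
      "; ratings: ", nrow(x$ratings),
      "; targets: ", paste(x$targets_present, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Build a study configuration
#'
#' @param emotion_set data.frame (`label`, `valence`) or named valence
#'   vector.
#' @param include_same_state Design includes same-state transitions?
#' @param reverse_keys Reverse-keyed loneliness items.
#' @param completion_threshold Minimum completion fraction.
#' @return List of class `study_config`.
#' @export
study_config <- function(emotion_set,
                         include_same_state = TRUE,
                         reverse_keys = ucla_reverse_keys(),
                         completion_threshold = 0.5) {
  if (!is.data.frame(emotion_set)) {
    emotion_set <- data.frame(label = names(emotion_set),
                              valence = unname(unlist(emotion_set)),
                              stringsAsFactors = FALSE)
  }
  structure(list(emotion_set = emotion_set,
                 include_same_state = isTRUE(include_same_state),
                 reverse_keys = as.integer(reverse_keys),
                 completion_threshold = completion_threshold),
            class = "study_config")
}

#' Read a study configuration file (JSON or YAML)
#'
#' Expected fields: `emotion_set` (mapping label -> valence or a table),
#' `include_same_state`, optional `reverse_keys`, `completion_threshold`.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  es <- raw$emotion_set
  if (is.data.frame(es)) {
    emo <- es
  } else {
    emo <- data.frame(label = names(es), valence = unname(unlist(es)),
                      stringsAsFactors = FALSE)
  }
  study_config(
    emotion_set = emo,
    include_same_state = isTRUE(raw$include_same_state),
    reverse_keys = if (is.null(raw$reverse_keys)) ucla_reverse_keys()
                   else as.integer(raw$reverse_keys),
    completion_threshold = if (is.null(raw$completion_threshold)) 0.5
                           else raw$completion_threshold
  )
}

#' Read one study from ratings and participants CSV files
#'
#' Ratings CSV columns: `study_id,participant_id,target,from_state,to_state,
#' rating`.  Participants CSV columns: `study_id,participant_id` plus either
#' `item_1..item_20` (scored here) or a precomputed `loneliness_total`, and
#' `completion_fraction` (assumed 1 when absent).  Participants with missing
#' scale items are dropped with a message (scales are not prorated).
#'
#' @param ratings_path,participants_path CSV file paths.
#' @param config A `study_config`.
#' @return A `study_dataset`.
#' @export
read_study <- function(ratings_path, participants_path, config) {
  stopifnot(inherits(config, "study_config"))
  if (!file.exists(ratings_path)) stop("ratings file not found: ", ratings_path)
  if (!file.exists(participants_path)) {
    stop("participants file not found: ", participants_path)
  }
  ratings <- read.csv(ratings_path, stringsAsFactors = FALSE,
                      check.names = FALSE)
  req <- c("study_id", "participant_id", "target",
           "from_state", "to_state", "rating")
  miss <- setdiff(req, names(ratings))
  if (length(miss)) stop("ratings CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  parts <- read.csv(participants_path, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!"participant_id" %in% names(parts)) {
    stop("participants CSV missing column(s): participant_id")
  }
  item_cols <- paste0("item_", 1:20)
  if (all(item_cols %in% names(parts))) {
    ok <- complete.cases(parts[item_cols])
    if (any(!ok)) {
      message("dropping ", sum(!ok),
              " participant(s) with incomplete loneliness scales")
      ratings <- ratings[
        !ratings$participant_id %in% parts$participant_id[!ok], ,
        drop = FALSE]
      parts <- parts[ok, , drop = FALSE]
    }
    parts$loneliness_raw <- apply(parts[item_cols], 1L, score_ucla,
                                  reverse_keys = config$reverse_keys)
  } else if ("loneliness_total" %in% names(parts)) {
    parts$loneliness_raw <- parts$loneliness_total
  } else {
    stop("participants CSV needs item_1..item_20 or loneliness_total")
  }
  if (!"completion_fraction" %in% names(parts)) {
    parts$completion_fraction <- 1
  }
  study_id <- unique(ratings$study_id)
  if (length(study_id) != 1L) {
    stop("ratings CSV must contain exactly one study_id, found ",
         length(study_id))
  }
  study_dataset(
    study_id = study_id,
    emotion_set = config$emotion_set,
    ratings = ratings[req[-1L]],
    participants = parts[c("participant_id", "loneliness_raw",
                           "completion_fraction")],
    include_same_state = config$include_same_state,
    completion_threshold = config$completion_threshold
  )
}

#' Write a study to the CSV interchange schema
#'
#' Inverse of [read_study()] (participants are written with
#' `loneliness_total`, the scored scale).
#'
#' @param dataset A `study_dataset`.
#' @param ratings_path,participants_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_study <- function(dataset, ratings_path, participants_path) {
  stopifnot(inherits(dataset, "study_dataset"))
  r <- dataset$ratings
  r <- data.frame(study_id = dataset$study_id, r, stringsAsFactors = FALSE)
  write.csv(r, ratings_path, row.names = FALSE, quote = TRUE)
  p <- dataset$participants
  p <- data.frame(study_id = dataset$study_id,
                  participant_id = p$participant_id,
                  loneliness_total = p$loneliness_raw,
                  completion_fraction = p$completion_fraction,
                  stringsAsFactors = FALSE)
  write.csv(p, participants_path, row.names = FALSE, quote = TRUE)
  invisible(c(ratings_path, participants_path))
}

#' Valence map of a study dataset
#' @param dataset A `study_dataset`.
#' @return Named character vector label -> valence.
#' @export
valence_map_of <- function(dataset) {
  setNames(dataset$emotion_set$valence, dataset$emotion_set$label)
}

# internal: deterministic transition key and ordering shared by analyses
transition_key <- function(from, to) paste(from, to, sep = " -> ")
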