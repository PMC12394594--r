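# Shared fixtures: all built in code, no stored data.

six_states <- c("anxious", "sad", "amused", "satisfied", "hopeful", "content")

six_emotion_set <- function() {
  data.frame(label = six_states,
             valence = unname(default_valence_map()[six_states]),
             stringsAsFactors = FALSE)
}

# hand-built study from per-participant rating matrices (rows = participants)
toy_study <- function(self = NULL, other = NULL, loneliness_raw = NULL,
                      states = six_states, include_same_state = FALSE,
                      study_id = "toy") {
  tr <- enumerate_transitions(states, include_same_state)
  n <- nrow(if (is.null(self)) other else self)
  ids <- sprintf("p%03d", seq_len(n))
  long_one <- function(mat, target) {
    data.frame(participant_id = rep(ids, each = nrow(tr)),
               target = target,
               from_state = rep(tr$from, times = n),
               to_state = rep(tr$to, times = n),
               rating = as.vector(t(mat)),
               stringsAsFactors = FALSE)
  }
  ratings <- NULL
  if (!is.null(self)) ratings <- long_one(self, "self")
  if (!is.null(other)) ratings <- rbind(ratings, long_one(other, "other"))
  if (is.null(loneliness_raw)) loneliness_raw <- seq(5, 55, length.out = n)
  parts <- data.frame(participant_id = ids,
                      loneliness_raw = round(loneliness_raw),
                      completion_fraction = 1,
                      stringsAsFactors = FALSE)
  emo <- data.frame(label = states,
                    valence = unname(default_valence_map()[states]),
                    stringsAsFactors = FALSE)
  study_dataset(study_id, emo, ratings, parts,
                include_same_state = include_same_state)
}

# scaled-down all-null 7-study suite (one study self-only), used by the
# calibration checks; sizes chosen once for the time budget
null_suite <- function(rep_seed, n = 30) {
  lapply(1:7, function(i) {
    generate_study(null_config(synth_config(
      study_id = paste0("s", i), n_participants = n,
      targets = if (i == 7) "self" else c("self", "other"),
      seed = derive_seed(rep_seed, i))))
  })
}

suite_effects <- function(suite, rep_seed, n_perm = 100L) {
  do.call(rbind, lapply(seq_along(suite), function(i) {
    suppressMessages(study_effects(suite[[i]], n_perm = n_perm,
                                   seed = derive_seed(rep_seed, 100 + i)))
  }))
}
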