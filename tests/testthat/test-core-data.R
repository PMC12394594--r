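test_that("score_ucla reproduces the scale arithmetic", {
  keys <- ucla_reverse_keys()
  expect_identical(score_ucla(rep(0L, 20), keys), 27L)   # 9 reversed x 3
  hi <- rep(3L, 20); hi[keys] <- 0L
  expect_identical(score_ucla(hi, keys), 60L)            # maximum
  expect_identical(score_ucla(rep(3L, 20), keys), 33L)   # 11 x 3
  expect_error(score_ucla(rep(1L, 19)), "20 items")
  expect_error(score_ucla(c(rep(1L, 19), 4L)), "0,1,2,3")
  expect_error(score_ucla(c(rep(1L, 19), NA)), "missing")
  expect_error(score_ucla(rep(1L, 20), reverse_keys = 21L), "subset")
})

test_that("double reversal returns the plain sum", {
  set.seed(1)
  keys <- ucla_reverse_keys()
  for (i in 1:20) {
    x <- sample(0:3, 20, replace = TRUE)
    y <- x
    y[keys] <- 3L - y[keys]
    expect_identical(score_ucla(y, keys), sum(x))
  }
})

test_that("enumerate_transitions count formula holds exhaustively", {
  for (n in 1:20) {
    states <- paste0("e", seq_len(n))
    expect_identical(nrow(enumerate_transitions(states, TRUE)),
                     as.integer(n^2))
    expect_identical(nrow(enumerate_transitions(states, FALSE)),
                     as.integer(n * (n - 1)))
  }
  expect_identical(nrow(enumerate_transitions(six_states, FALSE)), 30L)
  expect_identical(nrow(enumerate_transitions("solo", FALSE)), 0L)
  expect_error(enumerate_transitions(c("a", "a")), "duplicate")
})

test_that("enumeration order is from-major in input order", {
  tr <- enumerate_transitions(c("b", "a"), TRUE)
  expect_identical(tr$from, c("b", "b", "a", "a"))
  expect_identical(tr$to, c("b", "a", "b", "a"))
  expect_identical(tr$same_state, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("classify_transition matches the worked examples", {
  expect_identical(classify_transition("calm", "happy"), "PP")
  expect_identical(classify_transition("calm", "irritable"), "PN")
  expect_identical(classify_transition("anxious", "calm"), "NP")
  expect_identical(classify_transition("irritable", "anxious"), "NN")
  expect_identical(classify_transition("full of thought", "happy"),
                   "NEUTRAL_INVOLVED")
  expect_identical(classify_transition("happy", "alert"),
                   "NEUTRAL_INVOLVED")
  expect_error(classify_transition("calm", "elated"), "missing")
})

test_that("classification is label-symmetric for non-neutral pairs", {
  vm <- default_valence_map()
  labs <- names(vm)[vm != "neutral"]
  set.seed(2)
  for (i in 1:30) {
    ab <- sample(labs, 2)
    fwd <- classify_transition(ab[1], ab[2])
    rev <- classify_transition(ab[2], ab[1])
    expect_identical(rev, paste0(substr(fwd, 2, 2), substr(fwd, 1, 1)))
  }
})

test_that("standardize_z has the defining properties", {
  expect_equal(standardize_z(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize_z(rep(4, 5)), "zero variance")
  expect_error(standardize_z(1), "at least 2")
  set.seed(3)
  for (i in 1:10) {
    z <- standardize_z(rnorm(20, sd = runif(1, 0.1, 10)))
    expect_lt(abs(mean(z)), 1e-12)
    expect_equal(sd(z), 1)
  }
})

test_that("study_dataset validates its invariants", {
  self <- rbind(c(10, 20, 30, 40, 50, 60), 1:6 * 10 + 3, 6:1 * 10)
  M <- matrix(50, 3, 30); M[, 1:6] <- self
  ds <- toy_study(self = M)
  expect_s3_class(ds, "study_dataset")
  expect_identical(ds$targets_present, "self")
  expect_equal(mean(ds$participants$loneliness_z), 0, tolerance = 1e-12)

  bad <- ds$ratings; bad$rating[5] <- 120
  expect_error(study_dataset("x", ds$emotion_set, bad, ds$participants,
                             include_same_state = FALSE), "row")
  bad2 <- ds$ratings; bad2$from_state[1] <- "elated"
  expect_error(study_dataset("x", ds$emotion_set, bad2, ds$participants,
                             include_same_state = FALSE), "unknown emotion")
  bad3 <- ds$ratings; bad3$to_state <- bad3$from_state
  expect_error(study_dataset("x", ds$emotion_set, bad3, ds$participants,
                             include_same_state = FALSE),
               "same-state|duplicate")
})

test_that("completion filter drops participants and their ratings", {
  M <- matrix(rep(c(20, 40, 60), 30), 3, 30)
  ds0 <- toy_study(self = M)
  parts <- ds0$participants
  parts$completion_fraction[2] <- 0.3
  expect_message(
    ds <- study_dataset("toy", ds0$emotion_set, ds0$ratings, parts,
                        include_same_state = FALSE),
    "completion")
  expect_identical(nrow(ds$participants), 2L)
  expect_false("p002" %in% ds$ratings$participant_id)
  expect_identical(ds$n_dropped_completion, 1L)
})

test_that("write/read round-trip is the identity on valid datasets", {
  ds <- generate_study(synth_config(study_id = "rt", n_participants = 12,
                                    seed = 9))
  rp <- tempfile(fileext = ".csv"); pp <- tempfile(fileext = ".csv")
  write_study(ds, rp, pp)
  cfg <- study_config(ds$emotion_set, include_same_state = FALSE)
  ds2 <- read_study(rp, pp, cfg)
  expect_identical(ds2$study_id, ds$study_id)
  expect_equal(ds2$ratings, ds$ratings)
  expect_equal(ds2$participants$loneliness_raw, ds$participants$loneliness_raw)
  expect_equal(ds2$participants$loneliness_z, ds$participants$loneliness_z)
})

test_that("read_study parses a minimal CSV and rejects bad input", {
  rp <- tempfile(fileext = ".csv"); pp <- tempfile(fileext = ".csv")
  writeLines(c("study_id,participant_id,target,from_state,to_state,rating",
               "s1,p1,self,anxious,sad,40",
               "s1,p1,self,sad,anxious,60"), rp)
  writeLines(c("participant_id,loneliness_total,completion_fraction",
               "p1,22,1"), pp)
  cfg <- study_config(six_emotion_set(), include_same_state = FALSE)
  ds <- read_study(rp, pp, cfg)
  expect_identical(nrow(ds$ratings), 2L)
  expect_identical(nrow(ds$participants), 1L)

  writeLines(c("study_id,participant_id,target,from_state,to_state,rating",
               "s1,p1,self,anxious,sad,120"), rp)
  expect_error(read_study(rp, pp, cfg), "\\[0, 100\\]")

  writeLines(c("study_id,participant_id,target,from_state",
               "s1,p1,self,anxious"), rp)
  expect_error(read_study(rp, pp, cfg), "missing column")
})

test_that("read_study scores items and drops incomplete scales", {
  rp <- tempfile(fileext = ".csv"); pp <- tempfile(fileext = ".csv")
  writeLines(c("study_id,participant_id,target,from_state,to_state,rating",
               "s1,p1,self,anxious,sad,40",
               "s1,p2,self,anxious,sad,60"), rp)
  items1 <- paste(rep(0, 20), collapse = ",")
  items2 <- paste(c(rep(1, 19), ""), collapse = ",")
  writeLines(c(paste0("participant_id,", paste0("item_", 1:20, collapse = ","),
                      ",completion_fraction"),
               paste0("p1,", items1, ",1"),
               paste0("p2,", items2, ",1")), pp)
  cfg <- study_config(six_emotion_set(), include_same_state = FALSE)
  expect_message(ds <- read_study(rp, pp, cfg), "incomplete")
  expect_identical(ds$participants$loneliness_raw, 27L)
})

test_that("study configs round-trip through JSON and YAML", {
  vm <- as.list(default_valence_map()[six_states])
  for (ext in c(".json", ".yaml")) {
    path <- tempfile(fileext = ext)
    payload <- list(emotion_set = vm, include_same_state = FALSE,
                    completion_threshold = 0.6)
    if (ext == ".json") {
      writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE), path)
    } else {
      yaml::write_yaml(payload, path)
    }
    cfg <- read_study_config(path)
    expect_identical(sort(cfg$emotion_set$label), sort(six_states))
    expect_false(cfg$include_same_state)
    expect_identical(cfg$completion_threshold, 0.6)
  }
})
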