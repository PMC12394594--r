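#' Synthetic study configuration
#'
#' Describes one simulated study of the emotion transition task.  The
#' generative model (see [generate_study()]) plants, per participant with
#' within-study loneliness z-score `L`:
#' idiosyncratic atypicality (`a`, active only for `L > 0`, the Anna
#' Karenina structure), self anti-positivity (`anti_positivity`), rating
#' compression with loneliness (`kappa`, the confidence effect), reduced
#' self-anchoring when predicting others (`w0`, `w1` through a logistic
#' anchoring weight), and perceived volatility of others (`volatility`).
#' All effect defaults are the package's own stated world; the directions
#' mirror the loneliness findings the pipeline is designed to estimate.
#'
#' @param study_id Unique study identifier.
#' @param n_participants Number of participants (>= 3).
#' @param states Character vector of emotion labels.
#' @param valence_map Named label -> valence vector covering `states`.
#' @param include_same_state Include same-state transitions?
#' @param n_transitions Optional size of a shared random subset of the
#'   enumerated transitions (mirrors subset designs); `NULL` keeps all.
#' @param targets Targets to generate: subset of `c("self", "other")`.
#' @param base_matrix Named base likelihoods (percent) per valence category
#'   plus `same_state`.
#' @param loneliness_mean,loneliness_sd Raw-scale (0--60) loneliness
#'   distribution parameters (normal, truncated to the scale, rounded).
#' @param atypicality Gain `a >= 0` on the unit-norm idiosyncrasy direction.
#' @param anchoring_intercept,anchoring_slope Logistic anchoring weight
#'   parameters `w0`, `w1` (`w = plogis(w0 - w1 * L)`).
#' @param volatility Gain `m` (percent per SD loneliness) on cross-valence
#'   vs. same-valence expectations for others.
#' @param anti_positivity Gain `c` (percent per SD loneliness) on
#'   positive-state exit vs. persistence for the self.
#' @param compression Gain `kappa >= 0`: per-participant deviations from
#'   their own mean rating are scaled by `exp(-kappa * L)`.
#' @param noise_sd Gaussian rating noise SD (percent).
#' @param seed Integer seed; identical configs generate identical data.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(study_id = "synth",
                         n_participants = 100,
                         states = c("anxious", "sad", "amused",
                                    "satisfied", "hopeful", "content"),
                         valence_map = default_valence_map(),
                         include_same_state = FALSE,
                         n_transitions = NULL,
                         targets = c("self", "other"),
                         base_matrix = c(same_state = 65, PP = 60, NN = 50,
                                         PN = 30, NP = 35,
                                         NEUTRAL_INVOLVED = 45),
                         loneliness_mean = 20,
                         loneliness_sd = 12,
                         atypicality = 0.5,
                         anchoring_intercept = 1.0,
                         anchoring_slope = 0.4,
                         volatility = 3,
                         anti_positivity = 3,
                         compression = 0.05,
                         noise_sd = 10,
                         seed = 1L) {
  stopifnot(n_participants >= 3, atypicality >= 0, compression >= 0,
            noise_sd >= 0, all(targets %in% TARGET_LEVELS),
            length(targets) >= 1)
  need <- c("same_state", "PP", "NN", "PN", "NP", "NEUTRAL_INVOLVED")
  if (!all(need %in% names(base_matrix))) {
    stop("base_matrix must name: ", paste(need, collapse = ", "))
  }
  if (any(base_matrix < 0 | base_matrix > 100)) {
    stop("infeasible base matrix: likelihoods must lie in [0, 100]")
  }
  gains <- c(atypicality, anchoring_intercept, anchoring_slope,
             volatility, anti_positivity, compression)
  if (any(!is.finite(gains))) stop("all effect gains must be finite")
  structure(list(
    study_id = study_id, n_participants = as.integer(n_participants),
    states = states, valence_map = valence_map,
    include_same_state = isTRUE(include_same_state),
    n_transitions = n_transitions, targets = targets,
    base_matrix = base_matrix,
    loneliness_mean = loneliness_mean, loneliness_sd = loneliness_sd,
    atypicality = atypicality,
    anchoring_intercept = anchoring_intercept,
    anchoring_slope = anchoring_slope,
    volatility = volatility, anti_positivity = anti_positivity,
    compression = compression, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "synth_config")
}

#' Switch off every planted effect in a config (null world)
#' @param config A `synth_config`.
#' @return The config with all loneliness-dependent gains set to 0.
#' @export
null_config <- function(config) {
  config$atypicality <- 0
  config$anchoring_slope <- 0
  config$volatility <- 0
  config$anti_positivity <- 0
  config$compression <- 0
  config
}

# truncated-normal sampler on [lo, hi], rounded to integers
rtrunc_round <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  round(out[seq_len(n)])
}

#' Generate one synthetic study
#'
#' Per participant `i` with loneliness z-score `L_i`:
#' \enumerate{
#'   \item base likelihoods `B(t)` per valence category (same-state pairs
#'     use the `same_state` entry);
#'   \item unit-norm idiosyncrasy direction `D_i` over transitions;
#'   \item self ratings
#'     `S_i = B + a*max(L_i,0)*D_i*100 + c*L_i*dir_self + eps`,
#'     `dir_self` = -1 for PP, +1 for PN, 0 otherwise;
#'   \item compression: deviations of `S_i` from its own mean scaled by
#'     `exp(-kappa*L_i)`;
#'   \item anchoring weight `w_i = plogis(w0 - w1*L_i)`;
#'   \item other ratings
#'     `O_i = w_i*S_i + (1-w_i)*(B + m*L_i*dir_vol) +
#'     a*max(L_i,0)*D'_i*100 + eps'`,
#'     `dir_vol` = +1 for PN/NP, -1 for PP/NN, 0 otherwise, and `D'_i` an
#'     independent unit-norm idiosyncrasy direction (lonely participants'
#'     models of others are themselves idiosyncratic, not merely filtered
#'     through reduced self-anchoring), then the same compression;
#'   \item truncation to \[0, 100\] (fraction recorded in attribute
#'     `truncation_fraction`).
#' }
#'
#' @param config A `synth_config`.
#' @return A `study_dataset`; identical seed implies identical output.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  trans <- enumerate_transitions(cfg$states, cfg$include_same_state)
  if (!is.null(cfg$n_transitions)) {
    if (cfg$n_transitions > nrow(trans)) {
      stop("n_transitions exceeds the number of enumerable transitions")
    }
    keep <- sort(sample.int(nrow(trans), cfg$n_transitions))
    trans <- trans[keep, , drop = FALSE]
  }
  Tn <- nrow(trans)
  cat_t <- classify_transition(trans$from, trans$to, cfg$valence_map)
  B <- ifelse(trans$same_state, cfg$base_matrix[["same_state"]],
              cfg$base_matrix[cat_t])
  dir_self <- ifelse(cat_t == "PP", -1, ifelse(cat_t == "PN", 1, 0))
  dir_vol <- ifelse(cat_t %in% c("PN", "NP"), 1,
                    ifelse(cat_t %in% c("PP", "NN"), -1, 0))

  n <- cfg$n_participants
  raw <- rtrunc_round(n, cfg$loneliness_mean, cfg$loneliness_sd, 0, 60)
  # degenerate draw guard: force minimal spread so z-scores exist
  if (sd(raw) == 0) raw[1L] <- raw[1L] + if (raw[1L] < 60) 1 else -1
  L <- standardize_z(raw)

  ids <- sprintf("%s_p%04d", cfg$study_id, seq_len(n))
  n_trunc <- 0L
  total <- 0L
  self_mat <- matrix(NA_real_, n, Tn)
  other_mat <- if ("other" %in% cfg$targets) matrix(NA_real_, n, Tn) else NULL
  for (i in seq_len(n)) {
    D <- rnorm(Tn)
    D <- D / sqrt(sum(D^2))
    S <- B + cfg$atypicality * max(L[i], 0) * D * 100 +
      cfg$anti_positivity * L[i] * dir_self +
      rnorm(Tn, 0, cfg$noise_sd)
    S <- mean(S) + (S - mean(S)) * exp(-cfg$compression * L[i])
    if (!is.null(other_mat)) {
      w <- plogis(cfg$anchoring_intercept - cfg$anchoring_slope * L[i])
      Dp <- rnorm(Tn)
      Dp <- Dp / sqrt(sum(Dp^2))
      O <- w * S + (1 - w) * (B + cfg$volatility * L[i] * dir_vol) +
        cfg$atypicality * max(L[i], 0) * Dp * 100 +
        rnorm(Tn, 0, cfg$noise_sd)
      O <- mean(O) + (O - mean(O)) * exp(-cfg$compression * L[i])
      n_trunc <- n_trunc + sum(O < 0 | O > 100)
      total <- total + Tn
      other_mat[i, ] <- pmin(pmax(O, 0), 100)
    }
    n_trunc <- n_trunc + sum(S < 0 | S > 100)
    total <- total + Tn
    self_mat[i, ] <- pmin(pmax(S, 0), 100)
  }

  long_one <- function(mat, target) {
    data.frame(
      participant_id = rep(ids, each = Tn),
      target = target,
      from_state = rep(trans$from, times = n),
      to_state = rep(trans$to, times = n),
      rating = as.vector(t(mat)),
      stringsAsFactors = FALSE
    )
  }
  ratings <- NULL
  if ("self" %in% cfg$targets) ratings <- long_one(self_mat, "self")
  if (!is.null(other_mat)) {
    ratings <- rbind(ratings, long_one(other_mat, "other"))
  }
  participants <- data.frame(
    participant_id = ids,
    loneliness_raw = raw,
    completion_fraction = 1,
    stringsAsFactors = FALSE
  )
  emo <- data.frame(label = cfg$states,
                    valence = unname(cfg$valence_map[cfg$states]),
                    stringsAsFactors = FALSE)
  ds <- study_dataset(cfg$study_id, emo, ratings, participants,
                      include_same_state = cfg$include_same_state)
  attr(ds, "truncation_fraction") <- n_trunc / total
  attr(ds, "synth_config") <- cfg
  ds
}

#' Generate several independent synthetic studies
#'
#' @param configs List of `synth_config` with unique study ids (each
#'   carries its own seed; see [default_study_configs()] for deterministic
#'   derivation from a master seed).
#' @return List of `study_dataset` named by study id.
#' @export
generate_multistudy <- function(configs) {
  if (length(configs) < 1L) stop("need at least one config")
  ids <- vapply(configs, function(cf) cf$study_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate study_id among configs")
  out <- lapply(configs, generate_study)
  names(out) <- ids
  out
}

# synthetic valence assignment for the fifteen-state design variant
# (the authoritative assignment is not available; this is the package's own)
synthetic_15_state_map <- function() {
  c(assertive = "positive", confident = "positive", bold = "positive",
    lively = "positive", talkative = "positive", love = "positive",
    satisfaction = "positive",
    grouchy = "negative", sad = "negative", irritable = "negative",
    nervous = "negative", contempt = "negative", disgust = "negative",
    embarrassment = "negative",
    unrestrained = "neutral")
}

#' Default seven-study synthetic suite
#'
#' Mirrors the published multi-study design: per-study sample sizes
#' 113/185/376/91/68/41/856; studies 1--3 and 5 use seven states with
#' same-state transitions, study 4 uses a 75-transition subset of fifteen
#' states, studies 6--7 use six states without same-state transitions, and
#' study 7 contributes self-target data only.  Per-study seeds are derived
#' deterministically from `master_seed` (kept below 2^31).
#'
#' @param master_seed Integer master seed.
#' @param n_scale Multiplier on the per-study sample sizes (floor 12);
#'   used to scale simulations down for time-budgeted checks.
#' @param ... Effect parameters passed on to every [synth_config()]
#'   (e.g. `atypicality = 0` for a null suite).
#' @return List of 7 `synth_config`.
#' @export
default_study_configs <- function(master_seed = 1L, n_scale = 1, ...) {
  seven <- c("anxious", "calm", "happy", "irritable", "sad", "sluggish",
             "full of thought")
  seven5 <- c("anxious", "calm", "happy", "irritable", "sad", "sluggish",
              "alert")
  six <- c("anxious", "sad", "amused", "satisfied", "hopeful", "content")
  fifteen <- names(synthetic_15_state_map())
  ns <- c(113L, 185L, 376L, 91L, 68L, 41L, 856L)
  mln <- c(19.4, 23.23, 19.62, 23.01, 16.97, 19.27, 24.51)
  sdn <- c(13.76, 13.53, 9.88, 9.83, 11.45, 10.54, 12.50)
  states <- list(seven, seven, seven, fifteen, seven5, six, six)
  same <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  subs <- list(NULL, NULL, NULL, 75L, NULL, NULL, NULL)
  targets <- list(c("self", "other"), c("self", "other"),
                  c("self", "other"), c("self", "other"),
                  c("self", "other"), c("self", "other"), "self")
  vmaps <- list(default_valence_map(), default_valence_map(),
                default_valence_map(), synthetic_15_state_map(),
                default_valence_map(), default_valence_map(),
                default_valence_map())
  lapply(seq_len(7L), function(i) {
    synth_config(
      study_id = paste0("study", i),
      n_participants = max(12L, round(ns[i] * n_scale)),
      states = states[[i]],
      valence_map = vmaps[[i]],
      include_same_state = same[i],
      n_transitions = subs[[i]],
      targets = targets[[i]],
      loneliness_mean = mln[i],
      loneliness_sd = sdn[i],
      seed = derive_seed(master_seed, i),
      ...
    )
  })
}

#' Derive a per-stage seed from a master seed
#' @param master_seed Integer master seed.
#' @param index Stage/study index.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 7919 + index * 104729) %% 2147483587)
}
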