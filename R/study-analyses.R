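#' Ground-truth transition likelihoods
#'
#' The proxy for the actual transition likelihood of a typical other: the
#' arithmetic mean of the self-targeted ratings across all participants in
#' the study, per transition.
#'
#' @param dataset A `study_dataset` with self-target ratings.
#' @param leave_one_out If `TRUE`, an n x T matrix of per-participant
#'   leave-one-out means is attached as attribute `loo` (sensitivity
#'   option; the default matches the all-participant definition).
#' @return data.frame `from_state`, `to_state`, `ground_truth`
#'   (class `ground_truth`).
#' @export
build_ground_truth <- function(dataset, leave_one_out = FALSE) {
  r <- dataset$ratings[dataset$ratings$target == "self", , drop = FALSE]
  if (!nrow(r)) stop("no self-target ratings: ground truth undefined")
  agg <- aggregate(rating ~ from_state + to_state, data = r, FUN = mean)
  names(agg)[names(agg) == "rating"] <- "ground_truth"
  agg <- agg[order(agg$from_state, agg$to_state), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("ground_truth", class(agg))
  if (leave_one_out) {
    M <- rating_matrix(dataset, "self")
    cs <- colSums(M)
    loo <- sweep(-M, 2L, cs, "+") / (nrow(M) - 1L)
    attr(agg, "loo") <- loo
  }
  agg
}

# merged self/other/loneliness long table used by the moderated models
analysis_table <- function(dataset, target) {
  r <- dataset$ratings[dataset$ratings$target == target, , drop = FALSE]
  if (!nrow(r)) return(NULL)
  p <- dataset$participants
  r$loneliness_z <- p$loneliness_z[match(r$participant_id, p$participant_id)]
  r
}

#' Loneliness moderation of prediction accuracy
#'
#' Mixed model predicting the ground-truth likelihood of each transition
#' from the participant's other-targeted rating of that transition,
#' loneliness, and their interaction, with random intercepts for
#' participant, from-state and to-state.  The interaction coefficient is
#' the effect: a negative value means lonelier participants' predictions
#' track the ground truth less strongly.
#'
#' @param dataset A `study_dataset` with both targets.
#' @return One-row effect-size data.frame (`analysis = "accuracy"`), with
#'   the full `lmm_fit` in attribute `fit`; `NULL` (with a message) when
#'   the study has no other-target data.
#' @export
accuracy_effect <- function(dataset) {
  tab <- analysis_table(dataset, "other")
  if (is.null(tab)) {
    message(dataset$study_id, ": no other-target ratings; accuracy skipped")
    return(NULL)
  }
  gt <- build_ground_truth(dataset)
  key <- transition_key(tab$from_state, tab$to_state)
  gkey <- transition_key(gt$from_state, gt$to_state)
  tab$ground_truth <- gt$ground_truth[match(key, gkey)]
  tab <- tab[!is.na(tab$ground_truth), , drop = FALSE]
  tab$other_z <- standardize_z(tab$rating)
  fit <- fit_lmm(tab, lmm_spec(
    outcome = "ground_truth", fixed = ~ other_z * loneliness_z,
    random = c("participant_id", "from_state", "to_state")))
  b <- wald_table(fit)["other_z:loneliness_z", ]
  eff <- effect_size(dataset$study_id, "accuracy", b$estimate, b$se^2,
                     length(unique(tab$participant_id)), "beta")
  attr(eff, "fit") <- fit
  eff
}

#' Loneliness moderation of self-anchoring
#'
#' Mixed model predicting other-targeted ratings from self-targeted
#' ratings, loneliness, and their interaction (random intercepts for
#' participant, from-state, to-state).  A negative interaction means
#' lonelier participants anchor less on their own transitions when
#' predicting others'.
#'
#' @param dataset A `study_dataset` with both targets.
#' @return One-row effect-size data.frame (`analysis = "anchoring"`) with
#'   attribute `fit`, or `NULL` when other-target data are absent.
#' @export
anchoring_effect <- function(dataset) {
  other <- analysis_table(dataset, "other")
  if (is.null(other)) {
    message(dataset$study_id, ": no other-target ratings; anchoring skipped")
    return(NULL)
  }
  self <- dataset$ratings[dataset$ratings$target == "self", , drop = FALSE]
  m <- merge(other,
             self[c("participant_id", "from_state", "to_state", "rating")],
             by = c("participant_id", "from_state", "to_state"),
             suffixes = c("_other", "_self"))
  n_dropped <- nrow(other) - nrow(m)
  if (n_dropped > 0) {
    message(dataset$study_id, ": ", n_dropped,
            " other-target row(s) without a matching self rating dropped")
  }
  m$self_z <- m$rating_self
  fit <- fit_lmm(m, lmm_spec(
    outcome = "rating_other", fixed = ~ self_z * loneliness_z,
    random = c("participant_id", "from_state", "to_state")))
  b <- wald_table(fit)["self_z:loneliness_z", ]
  eff <- effect_size(dataset$study_id, "anchoring", b$estimate, b$se^2,
                     length(unique(m$participant_id)), "beta")
  attr(eff, "fit") <- fit
  eff
}

#' Loneliness simple slopes by valence-transition category
#'
#' Neutral-involving transitions are excluded; the remaining ratings are
#' modelled from the transition category (PP/PN/NP/NN), loneliness, and
#' their interaction (random intercepts for participant, from-state,
#' to-state); the per-category loneliness simple slopes are returned as
#' effect sizes.  For the other target a positive PN/NP slope with
#' negative PP/NN slopes reads as perceived volatility; for the self a
#' negative PP and positive PN slope reads as anti-positivity.
#'
#' @param dataset A `study_dataset`.
#' @param target `"self"` or `"other"`.
#' @return Effect-size data.frame with one row per category present
#'   (`analysis = "slope_<CAT>_<target>"`), attribute `fit`; `NULL` when
#'   the target is absent.
#' @export
valence_effects <- function(dataset, target = c("self", "other")) {
  target <- match.arg(target)
  tab <- analysis_table(dataset, target)
  if (is.null(tab)) {
    message(dataset$study_id, ": no ", target,
            "-target ratings; valence analysis skipped")
    return(NULL)
  }
  vm <- valence_map_of(dataset)
  tab$category <- classify_transition(tab$from_state, tab$to_state, vm)
  tab <- tab[tab$category != "NEUTRAL_INVOLVED", , drop = FALSE]
  present <- intersect(c("PP", "PN", "NP", "NN"), unique(tab$category))
  absent <- setdiff(c("PP", "PN", "NP", "NN"), present)
  if (length(absent)) {
    message(dataset$study_id, ": valence categor(ies) absent, slopes omitted: ",
            paste(absent, collapse = ", "))
  }
  counts <- table(unique(tab[c("from_state", "to_state", "category")])$category)
  if (length(present) < 2L || any(counts[present] < 2L)) {
    stop("need >= 2 non-neutral categories with >= 2 transitions each")
  }
  tab$category <- factor(tab$category, levels = present)
  fit <- fit_lmm(tab, lmm_spec(
    outcome = "rating", fixed = ~ category * loneliness_z,
    random = c("participant_id", "from_state", "to_state")))
  ss <- simple_slopes(fit, "loneliness_z", "category")
  n <- length(unique(tab$participant_id))
  out <- do.call(rbind, lapply(seq_len(nrow(ss)), function(i) {
    effect_size(dataset$study_id,
                paste0("slope_", ss$category[i], "_", target),
                ss$slope[i], ss$se[i]^2, n, "beta")
  }))
  attr(out, "fit") <- fit
  out
}

#' Loneliness and rating confidence
#'
#' Confidence is operationalized as the per-participant sample standard
#' deviation of transition ratings (a participant committing to high and
#' low likelihoods is read as more confident than one rating everything
#' near the midpoint).  The statistic is correlated with loneliness and
#' carried as Fisher z.
#'
#' @param dataset A `study_dataset`.
#' @param target `"self"` or `"other"`.
#' @return One-row effect-size data.frame
#'   (`analysis = "confidence_<target>"`) or `NULL` if the target is
#'   absent; per-participant SDs in attribute `sds`.
#' @export
confidence_effect <- function(dataset, target = c("self", "other")) {
  target <- match.arg(target)
  r <- dataset$ratings[dataset$ratings$target == target, , drop = FALSE]
  if (!nrow(r)) {
    message(dataset$study_id, ": no ", target,
            "-target ratings; confidence skipped")
    return(NULL)
  }
  cnt <- table(r$participant_id)
  if (any(cnt < 2L)) stop("every participant needs >= 2 ratings for an SD")
  sds <- tapply(r$rating, r$participant_id, sd)
  p <- dataset$participants
  lz <- p$loneliness_z[match(names(sds), p$participant_id)]
  eff <- cor_effect(as.numeric(sds), lz, dataset$study_id,
                    paste0("confidence_", target))
  attr(eff, "sds") <- sds
  eff
}

#' All study-level effect sizes for one study
#'
#' Runs every enabled analysis family and stacks the effect-size rows;
#' families requiring other-target data are skipped (with a message) for
#' studies that lack it.
#'
#' @param dataset A `study_dataset`.
#' @param typicality_mode Passed to [typicality_index()].
#' @param isrsa_model,n_perm IS-RSA settings (see [ak_isrsa()]).
#' @param seed Seed for the permutation tests.
#' @param analyses Families to run (default all): subset of
#'   `c("typicality", "isrsa", "accuracy", "anchoring", "valence",
#'   "confidence")`.
#' @return data.frame of effect rows; IS-RSA permutation details in
#'   attribute `isrsa`.
#' @export
study_effects <- function(dataset,
                          typicality_mode = "include_self",
                          isrsa_model = "ak_mean",
                          n_perm = 1000L,
                          seed = 1L,
                          analyses = c("typicality", "isrsa", "accuracy",
                                       "anchoring", "valence",
                                       "confidence")) {
  targets <- dataset$targets_present
  rows <- list()
  isrsa_details <- list()
  if ("typicality" %in% analyses) {
    for (tg in targets) {
      ti <- typicality_index(dataset, tg, typicality_mode)
      rows[[paste0("typ_", tg)]] <- typicality_effect(ti, dataset)
    }
  }
  if ("isrsa" %in% analyses) {
    for (tg in targets) {
      S <- similarity_matrix(dataset, tg)
      p <- dataset$participants
      lz <- p$loneliness_z[match(rownames(S), p$participant_id)]
      res <- ak_isrsa(S, lz, model = isrsa_model, n_perm = n_perm,
                      seed = derive_seed(seed, match(tg, TARGET_LEVELS)))
      isrsa_details[[tg]] <- res
      rows[[paste0("isrsa_", tg)]] <- isrsa_effect(res, dataset$study_id, tg)
    }
  }
  if ("accuracy" %in% analyses) rows$accuracy <- accuracy_effect(dataset)
  if ("anchoring" %in% analyses) rows$anchoring <- anchoring_effect(dataset)
  if ("valence" %in% analyses) {
    for (tg in targets) {
      rows[[paste0("valence_", tg)]] <- valence_effects(dataset, tg)
    }
  }
  if ("confidence" %in% analyses) {
    for (tg in targets) {
      rows[[paste0("conf_", tg)]] <- confidence_effect(dataset, tg)
    }
  }
  rows <- Filter(Negate(is.null), rows)
  out <- do.call(rbind, lapply(rows, function(x) {
    attributes(x)[setdiff(names(attributes(x)),
                          c("names", "row.names", "class"))] <- NULL
    x
  }))
  rownames(out) <- NULL
  attr(out, "isrsa") <- isrsa_details
  out
}
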