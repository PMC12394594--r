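#' Participant-by-transition rating matrix
#'
#' Internal backbone of the typicality and intersubject similarity
#' analyses.  Rows are participants with a complete rating vector for the
#' target (aligned on the (from, to) key); columns follow a deterministic
#' transition order.
#'
#' @param dataset A `study_dataset`.
#' @param target `"self"` or `"other"`.
#' @return Numeric matrix, dimnames = (sorted participant ids, transition
#'   keys); attribute `n_incomplete` counts dropped participants.
#' @export
rating_matrix <- function(dataset, target = c("self", "other")) {
  target <- match.arg(target)
  r <- dataset$ratings[dataset$ratings$target == target, , drop = FALSE]
  if (!nrow(r)) stop("no ratings for target '", target, "'")
  key <- transition_key(r$from_state, r$to_state)
  keys <- sort(unique(key))
  ids <- sort(unique(r$participant_id))
  M <- matrix(NA_real_, length(ids), length(keys),
              dimnames = list(ids, keys))
  M[cbind(match(r$participant_id, ids), match(key, keys))] <- r$rating
  complete <- rowSums(is.na(M)) == 0L
  out <- M[complete, , drop = FALSE]
  attr(out, "n_incomplete") <- sum(!complete)
  out
}

#' Per-participant typicality indices
#'
#' Pearson correlation between each participant's transition-rating vector
#' and the group average vector, either including the participant in the
#' average (`include_self`, the default reading of the procedure) or
#' leaving them out (`leave_one_out`, unbiased for small samples).
#' Participants whose rating vector has zero variance are excluded with a
#' warning.
#'
#' @param dataset A `study_dataset`.
#' @param target `"self"` or `"other"`.
#' @param mode `"include_self"` or `"leave_one_out"`.
#' @return Object of class `typicality_result`: data.frame `indices`
#'   (`participant_id`, `index`), plus `mode`, `target`, `n_used`.
#' @export
typicality_index <- function(dataset, target = c("self", "other"),
                             mode = c("include_self", "leave_one_out")) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  M <- rating_matrix(dataset, target)
  n <- nrow(M)
  if (n < 3L) stop("fewer than 3 participants with complete rating vectors")
  # zero-variance participants keep contributing to the group mean but have
  # no defined index of their own
  zv <- apply(M, 1L, sd) == 0
  if (any(zv)) {
    warning(sum(zv), " participant(s) with zero-variance rating vectors excluded")
  }
  if (mode == "include_self") {
    gm <- colMeans(M)
    idx <- vapply(seq_len(n), function(i) {
      if (zv[i]) NA_real_ else cor(M[i, ], gm)
    }, numeric(1))
  } else {
    cs <- colSums(M)
    idx <- vapply(seq_len(n), function(i) {
      if (zv[i]) NA_real_ else cor(M[i, ], (cs - M[i, ]) / (n - 1L))
    }, numeric(1))
  }
  keep <- !zv
  structure(list(
    indices = data.frame(participant_id = rownames(M)[keep],
                         index = unname(idx[keep]),
                         stringsAsFactors = FALSE),
    mode = mode, target = target, n_used = sum(keep),
    study_id = dataset$study_id), class = "typicality_result")
}

# one effect-size row (the meta-analysis input unit)
effect_size <- function(study_id, analysis, estimate, variance, n,
                        scale = c("beta", "fisher_z")) {
  scale <- match.arg(scale)
  if (!is.finite(variance) || variance <= 0) {
    stop("effect sampling variance must be positive (analysis ", analysis, ")")
  }
  data.frame(study_id = study_id, analysis = analysis,
             estimate = estimate, variance = variance,
             n = as.integer(n), scale = scale, stringsAsFactors = FALSE)
}

# Pearson correlation -> Fisher-z effect row; guards degenerate |r| = 1
cor_effect <- function(x, y, study_id, analysis) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations for ", analysis)
  if (sd(y) == 0) stop("constant loneliness scores: correlation undefined")
  if (sd(x) == 0) stop("constant statistic: correlation undefined for ", analysis)
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    stop("degenerate perfect correlation in ", analysis,
         ": Fisher z is infinite")
  }
  effect_size(study_id, analysis, atanh(r), 1 / (n - 3), n, "fisher_z")
}

#' Association of typicality with loneliness
#'
#' Pearson correlation between the typicality index and standardized
#' loneliness, carried as Fisher z with variance `1/(n-3)`.
#'
#' @param result A `typicality_result`.
#' @param dataset The `study_dataset` it came from (for loneliness scores).
#' @return One-row effect-size data.frame (`analysis = typicality_self` or
#'   `typicality_other`), with the raw correlation in attribute `raw_r`.
#' @export
typicality_effect <- function(result, dataset) {
  stopifnot(inherits(result, "typicality_result"))
  p <- dataset$participants
  lz <- p$loneliness_z[match(result$indices$participant_id,
                             p$participant_id)]
  eff <- cor_effect(result$indices$index, lz, dataset$study_id,
                    paste0("typicality_", result$target))
  attr(eff, "raw_r") <- tanh(eff$estimate)
  eff
}

#' Intersubject similarity matrix
#'
#' Pairwise Pearson correlations of participants' transition-rating
#' vectors, in deterministic (sorted id) order.
#'
#' @param dataset A `study_dataset`.
#' @param target `"self"` or `"other"`.
#' @return Symmetric matrix of class `similarity_matrix` with unit
#'   diagonal and participant ids as dimnames.
#' @export
similarity_matrix <- function(dataset, target = c("self", "other")) {
  target <- match.arg(target)
  M <- rating_matrix(dataset, target)
  zv <- apply(M, 1L, sd) == 0
  if (any(zv)) {
    warning(sum(zv), " zero-variance participant(s) excluded from similarity")
    M <- M[!zv, , drop = FALSE]
  }
  if (nrow(M) < 3L) stop("fewer than 3 usable participants for similarity")
  S <- cor(t(M))
  S <- (S + t(S)) / 2
  diag(S) <- 1
  class(S) <- c("similarity_matrix", class(S))
  S
}

#' Anna Karenina intersubject similarity analysis
#'
#' Associates a participant-pair similarity matrix with a loneliness-based
#' model matrix: under the Anna Karenina hypothesis, pairs with higher
#' (mean or min) loneliness are less similar, so the matrix-level Spearman
#' correlation `rho` is negative.  Inference is by a Mantel scheme:
#' participant labels of the loneliness vector are permuted and the model
#' matrix rebuilt each time; the two-sided p-value is
#' `(1 + #{|rho_perm| >= |rho_obs|}) / (1 + n_perm)`.
#'
#' @param sim A `similarity_matrix`.
#' @param loneliness_z Standardized loneliness aligned to `rownames(sim)`.
#' @param model `"ak_mean"` (pair mean), `"ak_min"` (pair minimum) or
#'   `"nn"` (nearest-neighbour, `-|L_i - L_j|`).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed (mandatory; permutations are reproducible).
#' @return Object of class `isrsa_result`: `rho`, `p_perm`, `n_perm`,
#'   `model`, `n`, and `effect` (Fisher-z effect row usable for pooling).
#' @export
ak_isrsa <- function(sim, loneliness_z, model = c("ak_mean", "ak_min", "nn"),
                     n_perm = 10000L, seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("`seed` is required for the permutation test")
  n <- nrow(sim)
  if (length(loneliness_z) != n) {
    stop("loneliness vector not aligned to the similarity matrix")
  }
  if (sd(loneliness_z) == 0) stop("constant loneliness: IS-RSA undefined")
  if (n_perm < 100L) stop("n_perm < 100 gives too coarse a p-value lattice")
  lt <- lower.tri(sim)
  s_rank <- rank(sim[lt])
  model_tri <- function(L) {
    M <- switch(model,
                ak_mean = outer(L, L, "+") / 2,
                ak_min = outer(L, L, pmin),
                nn = -abs(outer(L, L, "-")))
    M[lt]
  }
  spearman <- function(mtri) cor(s_rank, rank(mtri))
  rho_obs <- spearman(model_tri(loneliness_z))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    rho_b <- spearman(model_tri(sample(loneliness_z)))
    if (abs(rho_b) >= abs(rho_obs) - 1e-12) exceed <- exceed + 1L
  }
  p_perm <- (1 + exceed) / (1 + n_perm)
  structure(list(rho = rho_obs, p_perm = p_perm, n_perm = as.integer(n_perm),
                 model = model, n = n, seed = as.integer(seed)),
            class = "isrsa_result")
}

#' @export
print.isrsa_result <- function(x, ...) {
  cat(sprintf("<isrsa_result> model=%s rho=%.4f p_perm=%.4g (n=%d, n_perm=%d)\n",
              x$model, x$rho, x$p_perm, x$n, x$n_perm))
  invisible(x)
}

#' IS-RSA effect size for pooling
#'
#' Fisher-z transform of the matrix-level Spearman rho with variance
#' `1/(n-3)`, `n` the number of participants.
#'
#' @param result An `isrsa_result`.
#' @param study_id Study identifier.
#' @param target Target the similarity matrix was built from.
#' @return One-row effect-size data.frame.
#' @export
isrsa_effect <- function(result, study_id, target = c("self", "other")) {
  target <- match.arg(target)
  stopifnot(inherits(result, "isrsa_result"))
  if (abs(result$rho) >= 1 - 1e-12) {
    stop("degenerate |rho| = 1: Fisher z is infinite")
  }
  effect_size(study_id, paste0("isrsa_", target), atanh(result$rho),
              1 / (result$n - 3), result$n, "fisher_z")
}
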