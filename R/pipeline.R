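#' Expected pooled effect directions
#'
#' The qualitative sign pattern the multi-study analyses are designed to
#' detect: negative typicality and IS-RSA associations, negative accuracy
#' and anchoring interactions, other-target volatility (+PN, +NP, -PP,
#' -NN), self-target anti-positivity (+PN, -PP), and negative confidence
#' correlations.
#'
#' @return Named numeric vector of +1/-1 per analysis label.
#' @export
expected_directions <- function() {
  c(typicality_self = -1, typicality_other = -1,
    isrsa_self = -1, isrsa_other = -1,
    accuracy = -1, anchoring = -1,
    slope_PN_other = 1, slope_NP_other = 1,
    slope_PP_other = -1, slope_NN_other = -1,
    slope_PP_self = -1, slope_PN_self = 1,
    confidence_self = -1, confidence_other = -1)
}

#' Pipeline configuration
#'
#' @param studies Either a list of [synth_config()] objects or a list of
#'   lists with elements `ratings`, `participants`, `config` (file paths)
#'   for real data in the CSV interchange schema.
#' @param out_dir Output directory (created if needed).
#' @param master_seed Integer master seed (required: permutation tests and
#'   synthetic studies are seeded from it).
#' @param n_perm Mantel permutations per IS-RSA test.
#' @param typicality_mode `"include_self"` or `"leave_one_out"`.
#' @param isrsa_model `"ak_mean"`, `"ak_min"` or `"nn"`.
#' @param analyses Analysis families to run (see [study_effects()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(studies, out_dir, master_seed,
                            n_perm = 1000L,
                            typicality_mode = "include_self",
                            isrsa_model = "ak_mean",
                            analyses = c("typicality", "isrsa", "accuracy",
                                         "anchoring", "valence",
                                         "confidence")) {
  if (missing(master_seed)) stop("a master seed is required")
  structure(list(studies = studies, out_dir = out_dir,
                 master_seed = as.integer(master_seed),
                 n_perm = as.integer(n_perm),
                 typicality_mode = typicality_mode,
                 isrsa_model = isrsa_model, analyses = analyses),
            class = "pipeline_config")
}

# tiny polynomial rolling hash so the manifest can fingerprint the config
# without external digest dependencies (stays within exact double range)
config_hash <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_json <- function(config) {
  ser <- lapply(config$studies, function(s) {
    if (inherits(s, "synth_config")) unclass(s) else s
  })
  jsonlite::toJSON(list(
    studies = ser, master_seed = config$master_seed,
    n_perm = config$n_perm, typicality_mode = config$typicality_mode,
    isrsa_model = config$isrsa_model, analyses = config$analyses),
    auto_unbox = TRUE, digits = 12, pretty = TRUE, null = "null")
}

load_study <- function(s) {
  if (inherits(s, "synth_config")) {
    generate_study(s)
  } else if (inherits(s, "study_dataset")) {
    s
  } else {
    cfg <- if (inherits(s$config, "study_config")) s$config
           else read_study_config(s$config)
    read_study(s$ratings, s$participants, cfg)
  }
}

#' Run the full multi-study pipeline
#'
#' Loads or generates every study, computes all enabled per-study effect
#' sizes, pools each analysis family with the random-effects
#' meta-analysis, and writes `effects.csv`, `meta.json`,
#' `forest_<analysis>.csv`, `manifest.json` and `report.txt` to the
#' output directory.  Studies lacking other-target data are excluded from
#' other-target families (reducing k accordingly).  Outputs are fully
#' determined by the config and master seed.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with `datasets`, `effects`, `meta`,
#'   `report`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  datasets <- lapply(config$studies, load_study)
  ids <- vapply(datasets, function(d) d$study_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate study ids in pipeline config")
  names(datasets) <- ids

  effects <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    study_effects(datasets[[i]],
                  typicality_mode = config$typicality_mode,
                  isrsa_model = config$isrsa_model,
                  n_perm = config$n_perm,
                  seed = derive_seed(config$master_seed, 100 + i),
                  analyses = config$analyses)
  }))
  rownames(effects) <- NULL
  meta <- pool_all(effects)

  paths <- list(effects = file.path(config$out_dir, "effects.csv"),
                meta = file.path(config$out_dir, "meta.json"),
                manifest = file.path(config$out_dir, "manifest.json"),
                report = file.path(config$out_dir, "report.txt"))
  write.csv(effects, paths$effects, row.names = FALSE, quote = TRUE)
  meta_ser <- lapply(meta, function(m) {
    m <- unclass(m)
    m$weights <- NULL
    m
  })
  writeLines(jsonlite::toJSON(meta_ser, auto_unbox = TRUE, digits = 12,
                              pretty = TRUE, na = "null"),
             paths$meta)
  for (a in names(meta)) {
    ft <- forest_table(meta[[a]],
                       effects[effects$analysis == a, , drop = FALSE])
    write.csv(ft, file.path(config$out_dir, paste0("forest_", a, ".csv")),
              row.names = FALSE, quote = TRUE)
  }
  cj <- config_json(config)
  manifest <- list(
    package_version = as.character(utils::packageVersion("emotrans")),
    config_hash = config_hash(as.character(cj)),
    master_seed = config$master_seed,
    studies = ids,
    n_participants = vapply(datasets, function(d) nrow(d$participants),
                            integer(1)),
    targets = lapply(datasets, function(d) d$targets_present)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             paths$manifest)
  report <- make_report(meta, effects)
  writeLines(report, paths$report)
  invisible(list(datasets = datasets, effects = effects, meta = meta,
                 report = report, paths = paths))
}

fmt_row <- function(m) {
  sprintf("%-18s k=%d  %8.4f  [%8.4f, %8.4f]  p=%-10.3g tau2=%-9.4g I2=%5.1f%%",
          m$analysis, m$k, m$pooled, m$ci_lo, m$ci_hi, m$p, m$tau2,
          if (is.na(m$i2)) NaN else m$i2)
}

#' Human-readable pooled-results report
#'
#' Tables of pooled effects (CI, tau^2, I^2, k), per-study forest lines,
#' and a sign-pattern summary against the expected directions.
#'
#' @param meta Named list of `meta_result` (from [pool_all()]).
#' @param effects The stacked effect rows.
#' @return Character vector of report lines.
#' @export
make_report <- function(meta, effects) {
  lines <- c("Pooled random-effects estimates",
             strrep("-", 78))
  lines <- c(lines, vapply(meta, fmt_row, character(1)))
  exp_dir <- expected_directions()
  known <- intersect(names(meta), names(exp_dir))
  if (length(known)) {
    lines <- c(lines, "", "Sign pattern vs expected directions",
               strrep("-", 78))
    for (a in known) {
      obs <- sign(meta[[a]]$pooled)
      lines <- c(lines, sprintf("%-18s expected %s  observed %s  %s",
                                a, ifelse(exp_dir[a] > 0, "+", "-"),
                                ifelse(obs > 0, "+", "-"),
                                ifelse(obs == exp_dir[a], "match",
                                       "MISMATCH")))
    }
  }
  absent <- setdiff(names(exp_dir), names(meta))
  if (length(absent)) {
    lines <- c(lines, "", paste("Absent analysis families:",
                                paste(absent, collapse = ", ")))
  }
  lines <- c(lines, "", "Per-study effects", strrep("-", 78))
  for (a in names(meta)) {
    sub <- effects[effects$analysis == a, , drop = FALSE]
    lines <- c(lines, paste0(a, ":"),
               sprintf("  %-12s %9.4f (var %.5g, n=%d)",
                       sub$study_id, sub$estimate, sub$variance, sub$n))
  }
  lines
}
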