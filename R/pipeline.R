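#' Build and validate a pipeline run configuration
#'
#' A run configuration collects every tunable of the end-to-end analysis:
#' cohort design, acquisition parameters, integration-window overrides,
#' normalization choice and chemometrics settings. All fields have
#' defaults; validation happens here, before any computation.
#'
#' @param seed master RNG seed for the run.
#' @param n_per_class samples per class (scalar or named vector); the
#'   default 14 organic / 16 conventional mirrors a processed-milk retail
#'   cohort.
#' @param composition_jitter_sd per-species lognormal jitter sd.
#' @param class_presets optional named list of two [fa_profile()]s
#'   overriding the default organic/conventional presets.
#' @param lipid_scale per-class lipid-scale factors (see [cohort_spec()]).
#' @param acquisition named list of [acquisition_params()] overrides.
#' @param windows named list of integration-window overrides
#'   (see [integration_windows()]).
#' @param normalization `"norcont"` or `"unor"`.
#' @param n_components,n_segments,n_permutations,alpha chemometrics
#'   settings (latent variables, CV segments, permutations, outlier
#'   significance level).
#' @param out_dir output directory for run artifacts.
#' @param figures also write score/VIP figures (requires ggplot2).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_per_class = c(organic = 14, conventional = 16),
                       composition_jitter_sd = 0.05,
                       class_presets = NULL,
                       lipid_scale = list(organic = 1, conventional = c(1, 2)),
                       acquisition = list(),
                       windows = NULL,
                       normalization = c("norcont", "unor"),
                       n_components = 2, n_segments = 7,
                       n_permutations = 100, alpha = 0.05,
                       out_dir = tempfile("milknmr_run_"),
                       figures = FALSE) {
  normalization <- match.arg(normalization)
  params <- do.call(acquisition_params, acquisition)
  win <- integration_windows(windows)        # errors on overlap, pre-run
  cohort_args <- list(n_per_class = n_per_class, lipid_scale = lipid_scale,
                      composition_jitter_sd = composition_jitter_sd,
                      seed = seed)
  if (!is.null(class_presets)) cohort_args$class_presets <- class_presets
  spec <- do.call(cohort_spec, cohort_args)
  stopifnot(n_components >= 1, n_segments >= 2, n_permutations >= 20,
            alpha > 0, alpha < 1)
  structure(list(seed = as.integer(seed), cohort = spec, params = params,
                 windows = win, normalization = normalization,
                 n_components = n_components, n_segments = n_segments,
                 n_permutations = n_permutations, alpha = alpha,
                 out_dir = out_dir, figures = isTRUE(figures)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level YAML keys map onto the arguments of [run_config()]; window
#' overrides are given as `windows: {I2.33: [2.25, 2.38]}` etc.
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), "")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(y$n_per_class)) y$n_per_class <- unlist(y$n_per_class)
  do.call(run_config, y)
}

# tiny polynomial rolling hash of the serialized config, for the manifest
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(config)),
                           collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full simulation-to-validation pipeline
#'
#' Simulates a two-class cohort, recalibrates each spectrum against the
#' internal shift reference, quantifies the per-sample fatty-acid
#' composition, buckets the spectra, applies the chosen normalization and
#' Pareto scaling, screens for outliers on the first PCA components
#' (one-shot: flag, drop, refit), fits and cross-validates a PLS-DA model,
#' computes VIP scores and runs the permutation validation. All artifacts
#' are written under `config$out_dir` together with a run manifest
#' (package version, config hash, sample counts, dropped outliers,
#' warnings).
#'
#' @param config a `run_config`.
#' @return invisibly, a list with the run directory and all in-memory
#'   results (`composition`, `buckets`, `pca`, `outliers`, `model`, `cv`,
#'   `vip`, `permutation`, `manifest`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "run.log")
  warnings_seen <- character(0)
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = logfile, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  log_line("simulating cohort (seed %d)", config$seed)
  cohort <- stage("simulate", simulate_cohort(config$cohort, config$params))
  n <- length(cohort$spectra)
  log_line("%d samples: %s", n,
           paste(sprintf("%s=%d", levels(cohort$classes),
                         tabulate(cohort$classes)), collapse = ", "))

  cohort$spectra <- stage("reference_shift",
                          lapply(cohort$spectra, reference_shift))

  composition <- stage("quantify", {
    rows <- lapply(cohort$spectra, function(sp) {
      composition_report(extract_integral_set(sp, config$windows))
    })
    cbind(data.frame(sample_id = cohort$sample_ids,
                     class = as.character(cohort$classes)),
          do.call(rbind, rows))
  })
  utils::write.csv(composition, file.path(config$out_dir, "composition.csv"),
                   row.names = FALSE)

  bm <- stage("bucket", bucket_matrix(cohort$spectra, cohort$classes,
                                      cohort$sample_ids))
  if (config$normalization == "norcont") {
    bm <- stage("normalize", normalize_norcont(bm))
  }
  write_bucket_matrix(bm, file.path(config$out_dir, "buckets.csv"))

  scaled <- stage("pareto", pareto_scale(bm))
  pca <- stage("pca", pca_fit(scaled, config$n_components))
  out_flags <- stage("outliers", hotelling_outliers(pca$scores, config$alpha))
  dropped <- cohort$sample_ids[out_flags]
  if (length(dropped)) {
    log_line("dropping %d outlier(s) at %.0f%% confidence: %s",
             length(dropped), 100 * (1 - config$alpha),
             paste(dropped, collapse = ", "))
    keep <- !out_flags
    bm$values <- bm$values[keep, , drop = FALSE]
    bm$classes <- droplevels(bm$classes[keep])
    bm$sample_ids <- bm$sample_ids[keep]
    scaled <- stage("pareto", pareto_scale(bm))
    pca <- stage("pca", pca_fit(scaled, config$n_components))
  }

  set.seed(config$seed)
  model <- stage("plsda", plsda_fit(scaled, bm$classes, config$n_components))
  cv <- stage("cv", plsda_cv(scaled, bm$classes,
                             n_segments = config$n_segments,
                             n_components = config$n_components))
  vip_scores <- stage("vip", vip(model))
  perm <- stage("permutation",
                permutation_test(scaled, bm$classes,
                                 n_permutations = config$n_permutations,
                                 n_segments = config$n_segments,
                                 n_components = config$n_components))
  log_line("R2Y = %.3f, Q2 = %.3f, %.1f%% correct, Fisher p = %.3g",
           model$R2Y[model$n_components], cv$Q2, cv$pct_correct, cv$fisher_p)

  model_json <- list(
    n_components = model$n_components,
    R2Y = model$R2Y,
    explained_variance_pct = pca$explained_variance_pct,
    class_levels = model$class_levels
  )
  validation_json <- list(
    Q2 = cv$Q2, pct_correct = cv$pct_correct, fisher_p = cv$fisher_p,
    confusion = as.integer(cv$confusion),
    permutation = list(n = perm$n_permutations,
                       r2_intercept = perm$r2_intercept,
                       q2_intercept = perm$q2_intercept,
                       valid = perm$valid)
  )
  jsonlite::write_json(model_json, file.path(config$out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(validation_json,
                       file.path(config$out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(center_ppm = bm$centers, vip = vip_scores),
                   file.path(config$out_dir, "vip.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_id = bm$sample_ids,
                              class = as.character(bm$classes),
                              model$scores),
                   file.path(config$out_dir, "scores.csv"), row.names = FALSE)

  if (config$figures && requireNamespace("ggplot2", quietly = TRUE)) {
    stage("figures", write_run_figures(config$out_dir, model, bm, vip_scores))
  }

  manifest <- list(
    package = "milknmr",
    version = as.character(utils::packageVersion("milknmr")),
    config_hash = config_hash(config),
    seed = config$seed,
    n_samples = n,
    n_dropped = length(dropped),
    dropped = dropped,
    normalization = bm$normalization,
    warnings = warnings_seen
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(warnings_seen)) {
    log_line("%d warning(s) recorded in manifest", length(warnings_seen))
  }

  invisible(list(run_dir = config$out_dir, composition = composition,
                 buckets = bm, pca = pca, outliers = out_flags,
                 model = model, cv = cv, vip = vip_scores,
                 permutation = perm, manifest = manifest))
}

write_run_figures <- function(out_dir, model, bm, vip_scores) {
  sc <- data.frame(LV1 = model$scores[, 1],
                   LV2 = model$scores[, min(2, ncol(model$scores))],
                   class = bm$classes)
  g <- ggplot2::ggplot(sc, ggplot2::aes(x = LV1, y = LV2, colour = class)) +
    ggplot2::geom_point() + ggplot2::stat_ellipse(level = 0.95) +
    ggplot2::labs(title = "PLS-DA scores")
  ggplot2::ggsave(file.path(out_dir, "scores.png"), g, width = 5, height = 4)
  vd <- data.frame(ppm = bm$centers, vip = vip_scores)
  g2 <- ggplot2::ggplot(utils::head(vd[order(-vd$vip), ], 25),
                        ggplot2::aes(x = factor(ppm), y = vip)) +
    ggplot2::geom_col() + ggplot2::coord_flip() +
    ggplot2::labs(x = "bucket center (ppm)", y = "VIP")
  ggplot2::ggsave(file.path(out_dir, "vip.png"), g2, width = 5, height = 6)
  invisible(NULL)
}

annotate_ppm <- function(ppm, max_dist = 0.03,
                         assignments = assignment_table()) {
  vapply(ppm, function(p) {
    d <- abs(assignments$shift_ppm - p)
    if (min(d) <= max_dist) assignments$group_label[which.min(d)] else ""
  }, character(1))
}

#' Summarize a completed pipeline run as markdown
#'
#' Tabulates the per-class composition means with two-sample t-tests, the
#' model and validation statistics, and the top VIP buckets annotated with
#' the nearest resonance assignment. Regenerable idempotently from the run
#' artifacts.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param top_vip number of VIP buckets to list.
#' @return path of the written `report.md`, invisibly; the report text is
#'   also returned as attribute `text`.
#' @export
make_report <- function(run_dir, top_vip = 10) {
  need <- c("composition.csv", "model.json", "validation.json", "vip.csv",
            "manifest.json")
  have <- file.exists(file.path(run_dir, need))
  if (!all(have)) {
    stop("missing run artifact(s): ", paste(need[!have], collapse = ", "),
         call. = FALSE)
  }
  comp <- utils::read.csv(file.path(run_dir, "composition.csv"))
  model <- jsonlite::read_json(file.path(run_dir, "model.json"),
                               simplifyVector = TRUE)
  val <- jsonlite::read_json(file.path(run_dir, "validation.json"),
                             simplifyVector = TRUE)
  vip_tab <- utils::read.csv(file.path(run_dir, "vip.csv"))
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                                  simplifyVector = TRUE)

  species <- c("alpha_linolenic", "linoleic", "cla_ct", "cla_tt",
               "caproleic", "ufa", "mufa", "sfa", "omega_ratio")
  cls <- unique(comp$class)
  lines <- c(
    sprintf("# milknmr run report (%s)", manifest$config_hash),
    "",
    sprintf("Package version %s, seed %d, %d samples (%d dropped as outliers), %s buckets.",
            manifest$version, manifest$seed, manifest$n_samples,
            manifest$n_dropped, manifest$normalization),
    "",
    "## Composition (mean +/- sd, mole % of acyl chains)",
    "",
    sprintf("| quantity | %s | %s | t-test p |", cls[1], cls[2]),
    "|---|---|---|---|"
  )
  for (sp in species) {
    v1 <- comp[comp$class == cls[1], sp]
    v2 <- comp[comp$class == cls[2], sp]
    tt <- marker_ttest(v1, v2)
    lines <- c(lines, sprintf("| %s | %.3f +/- %.3f | %.3f +/- %.3f | %.2g |",
                              sp, mean(v1), stats::sd(v1), mean(v2),
                              stats::sd(v2), tt["p"]))
  }
  lines <- c(lines, "",
             "## Model and validation", "",
             sprintf("- R2Y (cumulative): %.3f",
                     model$R2Y[length(model$R2Y)]),
             sprintf("- PCA explained variance: %s",
                     paste(sprintf("%.1f%%", model$explained_variance_pct),
                           collapse = " + ")),
             sprintf("- Q2: %.3f", val$Q2),
             sprintf("- Correct predictions: %.1f%%", val$pct_correct),
             sprintf("- Fisher exact p: %.3g", val$fisher_p),
             sprintf("- Permutation (n = %d): Q2 intercept %.3f, model %s",
                     val$permutation$n, val$permutation$q2_intercept,
                     if (isTRUE(val$permutation$valid)) "valid" else "not validated"),
             "",
             sprintf("## Top %d VIP buckets", top_vip), "",
             "| center (ppm) | VIP | assignment |",
             "|---|---|---|")
  top <- utils::head(vip_tab[order(-vip_tab$vip), ], top_vip)
  ann <- annotate_ppm(top$center_ppm)
  for (i in seq_len(nrow(top))) {
    lines <- c(lines, sprintf("| %.3f | %.2f | %s |", top$center_ppm[i],
                              top$vip[i], ann[i]))
  }
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(structure(out, text = paste(lines, collapse = "\n")))
}
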