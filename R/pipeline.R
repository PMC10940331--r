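#' Default pipeline configuration
#'
#' A single config object drives the full analysis. Every default is
#' materialized here and written back to disk with the outputs, so each run
#' records exactly what it did.
#'
#' @param input list: \code{type} is \code{"synthetic"} (uses \code{sim}, a
#'   \code{\link{cohort_sim_config}}), \code{"csv"} (uses \code{path}) or
#'   \code{"fixture"} (the packaged printed score table).
#' @param hoirt list of chain controls for the two IRT fits.
#' @param models classifier names to benchmark.
#' @param feature_spaces feature-space names to benchmark.
#' @param split list: train \code{ratio} and CV \code{folds}.
#' @param bootstrap list: replication count \code{B}, and the
#'   \code{spaces}/\code{models} to bootstrap.
#' @param seed master seed.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = list(type = "synthetic",
                                         sim = cohort_sim_config()),
                            hoirt = list(n_iter = 800L, n_burn = 300L),
                            models = c("RF", "Tree"),
                            feature_spaces = c("F7", "F10", "F12", "F15",
                                               "F16"),
                            split = list(ratio = 0.8, folds = 5L),
                            bootstrap = list(B = 10L, spaces = "F15",
                                             models = "RF"),
                            seed = 1L) {
  structure(list(input = input, hoirt = hoirt, models = models,
                 feature_spaces = feature_spaces, split = split,
                 bootstrap = bootstrap, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(log, stage, t0, seed, n_in, n_out) {
  rbind(log, data.frame(stage = stage,
                        seconds = round(as.numeric(Sys.time()) - t0, 2),
                        seed = seed, rows_in = n_in, rows_out = n_out))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort acquisition, higher-order IRT scoring (2-domain
#' and 5-domain), composite fitting and application, optimal-cut search per
#' composite score, classifier benchmark over the configured feature spaces
#' (test-split and all-data views), and bootstrap evaluation. All result
#' tables are written as CSV into \code{out_dir} together with the resolved
#' configuration (YAML) and a run log carrying the config checksum and
#' seeds. Identical configurations produce identical outputs.
#'
#' Fixture input runs the verification surface instead: per-score cut table
#' (printed cuts and searched optima) plus the benchmark/bootstrap on the
#' fixture's score columns.
#'
#' @param config a \code{\link{pipeline_config}} or path to a YAML file of
#'   the same shape.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory tables.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    if (!is.null(raw$input$sim))
      raw$input$sim <- do.call(cohort_sim_config, raw$input$sim)
    config <- do.call(pipeline_config, raw)
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "resolved_config.yaml")
  yaml::write_yaml(unclass(rapply(config, unclass, how = "replace")),
                   cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log <- NULL
  emit <- function(tab, name) {
    utils::write.csv(cbind(tab, config_md5 = cfg_hash),
                     file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  run_stage <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    list(res = res, t0 = t0)
  }

  if (identical(config$input$type, "fixture")) {
    fx <- load_printed_fixture()
    bundle <- data.frame(composite3 = fx$composite3, ssho2d = fx$ssho2d,
                         composite5 = fx$composite5, age = fx$age)
    labels <- fx$impaired
    printed <- list(
      ssho2d = cut_rule(-0.026, "below"),
      composite5 = cut_rule(0.925, "above"))
    cut_tab <- do.call(rbind, lapply(names(bundle)[1:3], function(sc) {
      opt <- search_optimal_cut(bundle[[sc]], labels)
      row <- data.frame(score = sc,
                        optimal_cut = opt$rule$threshold,
                        optimal_direction = opt$rule$direction,
                        optimal_mismatches = opt$mismatches,
                        printed_cut = NA_real_, printed_mismatches = NA_integer_)
      if (!is.null(printed[[sc]])) {
        pr <- printed[[sc]]
        row$printed_cut <- pr$threshold
        row$printed_mismatches <-
          count_mismatches(classify_by_cut(bundle[[sc]], pr), labels)
      }
      row
    }))
    emit(cut_tab, "cut_table")
    features <- list(F15 = build_feature_matrix(bundle, c("age", "ssho2d")))
  } else {
    st <- run_stage("cohort", {
      if (identical(config$input$type, "csv"))
        list(cohort = read_cohort_csv(config$input$path), latents = NULL)
      else generate_cohort(config$input$sim)
    })
    cohort <- st$res$cohort
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    log <- stage_log(log, "cohort", st$t0, config$seed,
                     NA, length(cohort))

    st <- run_stage("hoirt", make_benchmark_fixture_from(cohort, config))
    fx <- st$res
    bundle <- fx$bundle
    labels <- cohort$patients$impaired
    emit(cbind(patient_id = cohort$patients$patient_id,
               impaired = labels, bundle), "scores")
    log <- stage_log(log, "hoirt+composites", st$t0, config$seed,
                     length(cohort), nrow(bundle))

    st <- run_stage("cuts", {
      do.call(rbind, lapply(
        c("ssho2d", paste0("composite", 1:5)), function(sc) {
          opt <- search_optimal_cut(bundle[[sc]], labels)
          data.frame(score = sc, cut = opt$rule$threshold,
                     direction = opt$rule$direction,
                     mismatches = opt$mismatches)
        }))
    })
    emit(st$res, "cut_table")
    log <- stage_log(log, "cuts", st$t0, config$seed, nrow(bundle),
                     nrow(st$res))
    features <- fx$features[config$feature_spaces]
  }

  st <- run_stage("bench", {
    rows <- list()
    for (spn in names(features)) {
      xm <- features[[spn]]
      if (anyNA(xm)) next
      sp <- split_cohort(labels, config$split$ratio, config$seed + 101L)
      for (mod in config$models) {
        fit <- grid_search_train(mod, xm[sp$train, , drop = FALSE],
                                 labels[sp$train],
                                 folds = config$split$folds,
                                 seed = config$seed + 211L)
        for (view in c("test", "all")) {
          ix <- if (view == "test") sp$test else seq_along(labels)
          pr <- predict(fit, xm[ix, , drop = FALSE])
          ev <- evaluate(pr$labels, labels[ix], scores = pr$scores)
          rows[[length(rows) + 1L]] <- data.frame(
            space = spn, model = mod, view = view,
            chosen = paste(names(fit$best_params),
                           unlist(fit$best_params), sep = "=",
                           collapse = ";"),
            precision = ev$precision, recall = ev$recall,
            accuracy = ev$accuracy, specificity = ev$specificity,
            f_score = ev$f_score, qwk = ev$qwk, auc = ev$auc)
        }
      }
    }
    do.call(rbind, rows)
  })
  emit(st$res, "benchmark")
  log <- stage_log(log, "bench", st$t0, config$seed, length(labels),
                   nrow(st$res))
  bench <- st$res

  st <- run_stage("bootstrap", {
    rows <- list()
    for (spn in intersect(config$bootstrap$spaces, names(features))) {
      for (mod in config$bootstrap$models) {
        bs <- bootstrap_evaluate(features[[spn]], labels, mod,
                                 B = config$bootstrap$B,
                                 seed = config$seed + 307L,
                                 ratio = config$split$ratio,
                                 folds = config$split$folds)
        rows[[length(rows) + 1L]] <- data.frame(
          space = spn, model = mod, B = bs$B,
          metric = names(bs$mean), mean = unname(bs$mean),
          sd = unname(bs$sd), used = unname(bs$n_used))
      }
    }
    do.call(rbind, rows)
  })
  emit(st$res, "bootstrap")
  log <- stage_log(log, "bootstrap", st$t0, config$seed, length(labels),
                   nrow(st$res))

  utils::write.csv(cbind(log, config_md5 = cfg_hash),
                   file.path(out_dir, "run_log.csv"), row.names = FALSE)
  invisible(list(out_dir = out_dir, benchmark = bench,
                 bootstrap = st$res, log = log))
}

# internal: benchmark fixture from an existing cohort (pipeline path)
make_benchmark_fixture_from <- function(cohort, config) {
  y2 <- response_matrix(cohort, c("DCCS", "PSM"))
  fit2 <- hoirt(y2, attr(y2, "domain"), n_iter = config$hoirt$n_iter,
                n_burn = config$hoirt$n_burn, seed = config$seed + 11L,
                store_chains = FALSE)
  y5 <- response_matrix(cohort)
  fit5 <- hoirt(y5, attr(y5, "domain"), n_iter = config$hoirt$n_iter,
                n_burn = config$hoirt$n_burn, seed = config$seed + 12L,
                store_chains = FALSE)
  bundle <- cbind(classical_scores(cohort), eap_scores(fit2),
                  eap_scores(fit5))
  for (v in c("gender", "race", "income", "education"))
    bundle[[v]] <- cohort$patients[[v]]
  labels <- cohort$patients$impaired
  comp_features <- list(
    composite1 = c("rate_arw", "nc_psm", "nc_nsm", "rate_dccs", "nc_mfs"),
    composite2 = c("ssho", "d5_arw", "d5_psm", "d5_nsm", "d5_dccs", "d5_mfs",
                   "rt_arw", "rt_dccs", "rt_psm"),
    composite3 = c("ssho2d", "d2_psm", "d2_dccs", "age"),
    composite4 = c("ssho2d", "d2_psm", "d2_dccs"),
    composite5 = c("nc_psm", "rate_dccs", "age"))
  composites <- lapply(names(comp_features), function(cn)
    fit_composite(bundle[comp_features[[cn]]], labels, name = cn))
  names(composites) <- names(comp_features)
  for (cn in names(composites))
    bundle[[cn]] <- apply_composite(composites[[cn]], bundle)
  features <- lapply(stats::setNames(nm = names(feature_spaces())),
                     function(sp) build_feature_matrix(bundle, sp))
  list(bundle = bundle, features = features,
       fits = list(hoirt2d = fit2, hoirt5d = fit5), composites = composites)
}

#' Verify the packaged fixture against the published result tables
#'
#' Recomputes, from the packaged per-patient score table alone, the
#' machine-checkable published quantities: cohort size, impaired count, the
#' mismatch counts of the published linear cuts (SSHO2D at -0.026,
#' Composite5 at 0.925), agreement of those cuts with the printed
#' predicted-label columns, and the random-forest-on-Composite3 mismatch
#' count. A corrupted fixture aborts before any check runs.
#'
#' @return Data frame with columns \code{check}, \code{observed},
#'   \code{expected}, \code{pass}.
#' @export
verify_against_paper <- function() {
  fx <- load_printed_fixture()
  lab <- fx$impaired
  ss_rule <- cut_rule(-0.026, "below")
  c5_rule <- cut_rule(0.925, "above")
  pd_ss <- classify_by_cut(fx$ssho2d, ss_rule)
  pd_c5 <- classify_by_cut(fx$composite5, c5_rule)
  checks <- list(
    list("fixture rows", nrow(fx), 86),
    list("impaired count", sum(lab), 19),
    list("SSHO2D cut -0.026 mismatches", count_mismatches(pd_ss, lab), 14),
    list("Composite5 cut 0.925 mismatches", count_mismatches(pd_c5, lab), 14),
    list("SSHO2D cut reproduces printed labels",
         sum(pd_ss != fx$pd_ssho2d_linear), 0),
    list("Composite5 cut reproduces printed labels",
         sum(pd_c5 != fx$pd_composite5_linear), 0),
    list("RF-on-Composite3 printed mismatches",
         count_mismatches(fx$pd_composite3_rf, lab), 4),
    list("optimal SSHO2D cut no worse than printed",
         search_optimal_cut(fx$ssho2d, lab)$mismatches <= 14, TRUE))
  out <- do.call(rbind, lapply(checks, function(ck)
    data.frame(check = ck[[1]], observed = as.numeric(ck[[2]]),
               expected = as.numeric(ck[[3]]),
               pass = ck[[2]] == ck[[3]])))
  out
}
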