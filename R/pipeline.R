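#' Read and write transition-count tables
#'
#' Tidy CSV serialization of [count_transitions()] results, as consumed by
#' the model-fitting stages.
#'
#' @param counts A `transition_counts` object.
#' @param path CSV path.
#' @param n_items,units Panel metadata when reading.
#' @return `read_counts` returns a `transition_counts` object.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "transition_counts"))
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, n_items, units = c("months", "years")) {
  units <- match.arg(units)
  df <- utils::read.csv(path)
  structure(df, class = c("transition_counts", "data.frame"),
            n_items = as.integer(n_items), units = units)
}

#' Serialize a ground truth as a structured config file
#'
#' @param truth A [ground_truth()].
#' @param path YAML file path.
#' @return `read_ground_truth` returns a [ground_truth()].
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  x <- unclass(truth)
  x$re_corr <- as.vector(x$re_corr)
  x$standardize <- list(center = as.list(x$standardize$center),
                        scale = as.list(x$standardize$scale))
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- yaml::read_yaml(path)
  x$re_corr <- matrix(unlist(x$re_corr), 4L, 4L)
  x$standardize <- list(center = unlist(x$standardize$center),
                        scale = unlist(x$standardize$scale))
  x$schedule <- unlist(x$schedule)
  do.call(ground_truth, x[setdiff(names(x), character(0))])
}

pipeline_stages <- c("simulate", "preprocess", "counts", "fit_mouse",
                     "derive", "state_survival", "report")

#' Run the staged analysis pipeline
#'
#' Executes the configured stages in canonical order —
#' simulate, preprocess, counts, fit_mouse, derive, state_survival, report —
#' writing every stage's outputs as CSV files into `out_dir` together with a
#' `manifest.json` (package version, seed, configuration digest, file list).
#' Stages read their inputs from the files written by earlier stages, so any
#' stage can be re-run from the serialized state. Outputs are byte-identical
#' across reruns of the same configuration.
#'
#' @param config A named list or the path of a YAML file. Top-level fields:
#'   `seed` (integer), `out_dir`, `stages` (subset of the canonical names),
#'   and optional per-stage blocks: `simulate` (`n_subjects`,
#'   `count_model`), `preprocess` (`min_gap`, `max_gap`, `prune`), `counts`
#'   (`bin_width`), `fit_mouse` (`chains`, `iter`, `warmup`,
#'   `adapt_delta`), `derive` (`times`), `state_survival`
#'   (`n_permutations`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages
  if (is.null(stages)) stages <- pipeline_stages
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown)) {
    stop(sprintf("unknown pipeline stage(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) "damagerepair_out" else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pfile <- function(...) file.path(out_dir, paste0(...))
  files <- character(0)
  log_stage <- function(s) message(sprintf("[pipeline] stage %s", s))
  opt <- function(block, name, default) {
    v <- config[[block]][[name]]
    if (is.null(v)) default else v
  }

  for (stage in pipeline_stages[pipeline_stages %in% stages]) {
    log_stage(stage)
    if (stage == "simulate") {
      truth <- ground_truth()
      co <- simulate_cohort(truth, n_subjects = opt("simulate", "n_subjects", 50L),
                            seed = seed,
                            count_model = opt("simulate", "count_model", "bernoulli"))
      write_panel(co$panel, pfile("cohort"))
      write_ground_truth(truth, pfile("ground_truth.yaml"))
      utils::write.csv(co$true_rates, pfile("true_rates.csv"), row.names = FALSE,
                       quote = FALSE)
      files <- c(files, "cohort_observations.csv", "cohort_subjects.csv",
                 "ground_truth.yaml", "true_rates.csv")
    } else if (stage == "preprocess") {
      panel <- read_panel(pfile("cohort"))
      panel <- impute_locf(panel)
      mg <- config$preprocess$min_gap; xg <- config$preprocess$max_gap
      if (!is.null(mg) || !is.null(xg)) panel <- filter_visits(panel, mg, xg)
      if (isTRUE(config$preprocess$prune)) panel <- prune_isolated_transitions(panel)
      write_panel(panel, pfile("processed"))
      files <- c(files, "processed_observations.csv", "processed_subjects.csv")
    } else if (stage == "counts") {
      panel <- read_panel(pfile(if (file.exists(pfile("processed_observations.csv")))
        "processed" else "cohort"))
      counts <- count_transitions(panel)
      write_counts(counts, pfile("transition_counts.csv"))
      bw <- opt("counts", "bin_width", 2)
      ages <- counts$age
      br <- binned_rates(counts, seq(floor(min(ages)), ceiling(max(ages)) + bw, by = bw))
      utils::write.csv(br, pfile("binned_rates.csv"), row.names = FALSE, quote = FALSE)
      utils::write.csv(item_transition_table(panel), pfile("item_transitions.csv"),
                       row.names = FALSE, quote = FALSE)
      files <- c(files, "transition_counts.csv", "binned_rates.csv",
                 "item_transitions.csv")
    } else if (stage == "fit_mouse") {
      panel <- read_panel(pfile(if (file.exists(pfile("processed_observations.csv")))
        "processed" else "cohort"))
      counts <- count_transitions(panel)
      fit <- fit_mouse_joint(counts,
                             chains = opt("fit_mouse", "chains", 2L),
                             iter = opt("fit_mouse", "iter", 500L),
                             warmup = opt("fit_mouse", "warmup", 500L),
                             adapt_delta = opt("fit_mouse", "adapt_delta", 0.8),
                             seed = seed, convergence = "warn")
      utils::write.csv(summary(fit), pfile("fit_mouse_summary.csv"),
                       row.names = FALSE, quote = FALSE)
      fx <- fit$diagnostics$parameter
      utils::write.csv(as.data.frame(fit, pars = fx), pfile("fit_mouse_draws.csv"),
                       row.names = FALSE, quote = FALSE)
      saveRDS(fit, file.path(tempdir(), "damagerepair_pipeline_fit.rds"))
      files <- c(files, "fit_mouse_summary.csv", "fit_mouse_draws.csv")
    } else if (stage == "derive") {
      fit <- readRDS(file.path(tempdir(), "damagerepair_pipeline_fit.rds"))
      times <- opt("derive", "times", NULL)
      if (is.null(times)) {
        cnt <- fit$counts
        times <- seq(min(cnt$t), max(cnt$t + cnt$dt), length.out = 40L)
      }
      curve <- rate_curve(fit, profile = list(), times = times)
      cv <- curvature_terms(curve)
      utils::write.csv(cv$summary, pfile("curvature.csv"), row.names = FALSE,
                       quote = FALSE)
      rates_df <- data.frame(
        time = rep(curve$times, each = nrow(curve$lambda_r)),
        draw = rep(seq_len(nrow(curve$lambda_r)), length(curve$times)),
        lambda_r = as.vector(curve$lambda_r),
        lambda_d = as.vector(curve$lambda_d),
        f = as.vector(curve$f))
      utils::write.csv(rates_df, pfile("rate_curves.csv"), row.names = FALSE,
                       quote = FALSE)
      if (isTRUE(fit$survival)) {
        hr <- hazard_ratio_per_sd(fit)
        utils::write.csv(hr$summary, pfile("hazard_ratios.csv"),
                         row.names = FALSE, quote = FALSE)
        files <- c(files, "hazard_ratios.csv")
      }
      files <- c(files, "curvature.csv", "rate_curves.csv")
    } else if (stage == "state_survival") {
      panel <- read_panel(pfile(if (file.exists(pfile("processed_observations.csv")))
        "processed" else "cohort"))
      recs <- extract_state_intervals(panel)
      utils::write.csv(as.data.frame(recs), pfile("state_intervals.csv"),
                       row.names = FALSE, quote = FALSE)
      files <- c(files, "state_intervals.csv")
      for (st in c("damaged", "undamaged")) {
        sub <- recs[recs$state == st, , drop = FALSE]
        if (nrow(sub) < 40L || sum(sub$censored == 0) < 5L) next
        est <- npmle_interval(sub)
        horizon <- max(c(est$intervals$p[is.finite(est$intervals$p)],
                         sub$t_censor), na.rm = TRUE)
        tgrid <- seq(0, horizon, length.out = 50L)
        utils::write.csv(data.frame(state = st, time = tgrid,
                                    survival = est$surv(tgrid)),
                         pfile("state_survival_", st, ".csv"),
                         row.names = FALSE, quote = FALSE)
        files <- c(files, paste0("state_survival_", st, ".csv"))
        if (!is.null(sub$treatment) && length(unique(sub$treatment)) > 1L) {
          glr <- generalized_logrank(sub, sub$treatment,
                                     opt("state_survival", "n_permutations", 499L),
                                     seed = seed)
          utils::write.csv(data.frame(state = st, statistic = glr$statistic,
                                      p_value = glr$p_value),
                           pfile("logrank_", st, ".csv"), row.names = FALSE,
                           quote = FALSE)
          files <- c(files, paste0("logrank_", st, ".csv"))
        }
      }
    } else if (stage == "report") {
      fitfile <- file.path(tempdir(), "damagerepair_pipeline_fit.rds")
      if (file.exists(fitfile)) {
        fit <- readRDS(fitfile)
        ppc <- posterior_predictive_check(fit, seed = seed)
        utils::write.csv(data.frame(outcome = c("repair", "damage"),
                                    r2 = c(mean(ppc$r2$repair), mean(ppc$r2$damage)),
                                    coverage = as.numeric(ppc$coverage),
                                    overfit = ppc$overfit_flag),
                         pfile("ppc_report.csv"), row.names = FALSE, quote = FALSE)
        files <- c(files, "ppc_report.csv")
      }
    }
  }

  cfg_file <- pfile("config_echo.yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    package = "damagerepair",
    version = as.character(utils::packageVersion("damagerepair")),
    seed = seed,
    stages = stages,
    config_md5 = unname(tools::md5sum(cfg_file)),
    files = sort(unique(files)))
  jsonlite::write_json(manifest, pfile("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
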