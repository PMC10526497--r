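# Trial runner and model comparison. Three variants of the agent are
# compared under uniform (noise-free) and nonuniform (fovea-noise) visual
# resolution:
#   infer_parallel - eyes fixed, parallel; perception only.
#   infer_vergence - action enabled, eyes (and angle beliefs) start on the
#                    closed-form fixation solution for the sampled target.
#   active_vision  - action enabled, eyes start at random angles; fixation
#                    and depth inference proceed through action-perception
#                    cycles.

#' Define an experimental condition
#'
#' @param variant One of `"infer_parallel"`, `"infer_vergence"`,
#'   `"active_vision"`.
#' @param resolution `"uniform"` (no visual noise) or `"nonuniform"`
#'   (fovea noise).
#' @param n_trials Number of trials.
#' @param master_seed Master seed; trial `i` uses seed `master_seed + i`.
#' @param cycled If `FALSE`, the scheduler is bypassed and action and
#'   perception run simultaneously every step (the stuck-prone control).
#' @param cfg Configuration list from [depthsim_config()].
#' @return Condition list.
#' @export
condition <- function(variant = c("active_vision", "infer_parallel",
                                  "infer_vergence"),
                      resolution = c("nonuniform", "uniform"),
                      n_trials = 50, master_seed = 1, cycled = TRUE,
                      cfg = depthsim_config()) {
  list(variant = match.arg(variant), resolution = match.arg(resolution),
       n_trials = as.integer(n_trials), master_seed = as.integer(master_seed),
       cycled = isTRUE(cycled), cfg = cfg)
}

#' Run a single trial
#'
#' Samples a target and initial beliefs from the trial's derived seed, builds
#' the world and agent for the condition's variant, and integrates the full
#' action-perception schedule. The estimation error is the Euclidean distance
#' between the true target and the absolute-position belief;
#' `steps_to_criterion` is the first step after which the error stays below
#' the success threshold until the end of the trial.
#'
#' @param cond Condition from [condition()].
#' @param trial_index Trial number (added to the master seed).
#' @param trace If `TRUE`, also return a per-step data frame of the state
#'   (step, phase, beliefs, image coordinates, free-energy proxy, error).
#' @param trace_file Optional path; when given (implies `trace`), the
#'   per-step trace is also written there as CSV.
#' @return List with `success`, `final_error`, `steps_to_criterion` (`NA` if
#'   never reached), `diverged`, `target`, and optionally `trace`.
#' @export
run_trial <- function(cond, trial_index = 1, trace = FALSE,
                      trace_file = NULL) {
  if (!is.null(trace_file)) trace <- TRUE
  cfg <- cond$cfg
  set.seed(cond$master_seed + trial_index)
  target <- c(stats::runif(1, cfg$depth_range[1], cfg$depth_range[2]),
              stats::runif(1, cfg$lateral_range[1], cfg$lateral_range[2]))
  mu_a0 <- c(stats::runif(1, cfg$depth_range[1], cfg$depth_range[2]), 0)

  if (cond$variant == "infer_parallel") {
    angles0 <- c(0, 0)
  } else if (cond$variant == "infer_vergence") {
    angles0 <- fixation_angles(target, cfg$L)
  } else {
    angles0 <- stats::runif(2, -cfg$angle_init_range, cfg$angle_init_range)
  }
  world <- world_state(target, angles0, cfg$L, cfg$f)
  noise <- fovea_noise(cond$resolution, cfg$k, cfg$sigma_as_variance)
  agent <- depth_agent(cfg, mu_a0, mu_theta0 = angles0,
                       action_enabled = cond$variant != "infer_parallel")
  sched <- phase_schedule(cfg$cycle_length, cfg$start_phase, cfg$mechanism)

  n_steps <- 2L * cfg$cycle_length * cfg$n_cycles
  err <- numeric(n_steps)
  prev_phase <- ""
  tr <- if (trace) vector("list", n_steps) else NULL
  diverged <- FALSE

  for (t in seq_len(n_steps) - 1L) {
    phase <- if (cond$variant == "infer_parallel") "perception"
             else if (!cond$cycled) "simultaneous"
             else schedule_phase(t, sched)
    if (phase == "action" && prev_phase != "action") agent$a <- c(0, 0)
    prev_phase <- phase

    obs <- tryCatch(observe(world, noise, cfg$far_clip), error = function(e) NULL)
    if (is.null(obs)) { diverged <- TRUE; break }  # target behind an eye
    agent <- step_agent(agent, obs, phase)
    if (agent$action_enabled && phase != "perception") {
      world <- apply_action(world, agent$a, cfg$dt, cfg$angle_limit)
    }
    err[t + 1L] <- sqrt(sum((agent$mu_a - target)^2))
    if (trace) {
      tr[[t + 1L]] <- c(step = t, phase = phase == "action",
                        mu_ax = agent$mu_a[1], mu_ay = agent$mu_a[2],
                        theta_a = agent$mu_theta[1], theta_v = agent$mu_theta[2],
                        true_theta_a = world$eye_angles[1],
                        true_theta_v = world$eye_angles[2],
                        c0 = agent$mu_c[1], c1 = agent$mu_c[2],
                        fe = agent$fe, err = err[t + 1L], d = obs$d)
    }
    if (agent$diverged) { diverged <- TRUE; break }
  }

  if (diverged) {
    res <- list(success = FALSE, final_error = Inf, steps_to_criterion = NA,
                diverged = TRUE, target = target, trial_index = trial_index)
  } else {
    final_error <- err[n_steps]
    above <- which(err >= cfg$threshold)
    steps <- if (final_error < cfg$threshold) {
      if (length(above)) max(above) + 1L else 1L
    } else NA
    res <- list(success = final_error < cfg$threshold,
                final_error = final_error, steps_to_criterion = steps,
                diverged = FALSE, target = target, trial_index = trial_index)
  }
  if (trace) {
    res$trace <- as.data.frame(do.call(rbind, tr[!vapply(tr, is.null, TRUE)]))
    if (!is.null(trace_file)) {
      dir.create(dirname(trace_file), recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(res$trace, trace_file, row.names = FALSE)
    }
  }
  res
}

#' Run all trials of a condition and summarize
#'
#' Trials use derived seeds `master_seed + 1 .. master_seed + n_trials` and
#' are independent of execution order. A trial that diverges counts as a
#' failure; for the time metric, trials that never reach the criterion are
#' scored with the full trial length.
#'
#' @param cond Condition from [condition()].
#' @param out_dir Optional directory; when given, per-trial and summary CSV
#'   files are written there.
#' @return List with the per-trial data frame (`trials`) and the summary
#'   (`accuracy`, `mean_error`, `median_error`, `mean_time`, dispersions).
#' @export
run_condition <- function(cond, out_dir = NULL) {
  n_steps <- 2L * cond$cfg$cycle_length * cond$cfg$n_cycles
  rows <- lapply(seq_len(cond$n_trials), function(i) {
    r <- run_trial(cond, i)
    data.frame(trial = i, target_x = r$target[1], target_y = r$target[2],
               success = r$success, final_error = r$final_error,
               steps_to_criterion = ifelse(is.na(r$steps_to_criterion),
                                           n_steps, r$steps_to_criterion),
               reached = !is.na(r$steps_to_criterion),
               diverged = r$diverged)
  })
  trials <- do.call(rbind, rows)
  fin <- trials$final_error[is.finite(trials$final_error)]
  summary <- list(
    variant = cond$variant, resolution = cond$resolution,
    cycled = cond$cycled, n_trials = cond$n_trials,
    accuracy = mean(trials$success),
    mean_error = if (length(fin)) mean(fin) else Inf,
    sd_error = if (length(fin) > 1) stats::sd(fin) else NA_real_,
    median_error = if (length(fin)) stats::median(fin) else Inf,
    n_diverged = sum(trials$diverged),
    mean_time = mean(trials$steps_to_criterion),
    sd_time = stats::sd(trials$steps_to_criterion)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- paste0(cond$variant, "_", cond$resolution,
                   if (!cond$cycled) "_simultaneous")
    utils::write.csv(trials, file.path(out_dir, paste0(stem, "_trials.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(summary),
                     file.path(out_dir, paste0(stem, "_summary.csv")),
                     row.names = FALSE)
  }
  list(trials = trials, summary = summary)
}

#' Compare condition summaries and issue ordering verdicts
#'
#' Builds the summary table for a set of conditions and evaluates the
#' qualitative orderings expected from the model: under nonuniform foveal
#' resolution the verging variants should beat the parallel-gaze variant in
#' accuracy (with active vision somewhat slower than pre-verged); under
#' uniform resolution the parallel-gaze variant should be at least as
#' accurate and at least as fast as active vision.
#'
#' @param summaries List of summary lists from [run_condition()].
#' @param out_dir Optional directory for `comparison.csv`, `verdicts.json`
#'   and a bar-chart figure.
#' @param plot If `TRUE` and `out_dir` is given, writes a PNG with
#'   accuracy/error/time panels.
#' @return List with `table` (data frame) and `verdicts` (named logicals;
#'   `NA` for orderings whose conditions are absent).
#' @export
compare_report <- function(summaries, out_dir = NULL, plot = FALSE) {
  tab <- do.call(rbind, lapply(summaries, function(s)
    data.frame(variant = s$variant, resolution = s$resolution,
               cycled = s$cycled, n_trials = s$n_trials,
               accuracy = s$accuracy, mean_error = s$mean_error,
               median_error = s$median_error, mean_time = s$mean_time)))
  get <- function(variant, resolution, field, cycled = TRUE) {
    i <- which(tab$variant == variant & tab$resolution == resolution &
                 tab$cycled == cycled)
    if (length(i) == 1) tab[[field]][i] else NA_real_
  }
  cmp <- function(a, b, op) if (is.na(a) || is.na(b)) NA else op(a, b)
  verdicts <- list(
    nonuniform_active_beats_parallel =
      cmp(get("active_vision", "nonuniform", "accuracy"),
          get("infer_parallel", "nonuniform", "accuracy"), `>`),
    nonuniform_vergence_beats_parallel =
      cmp(get("infer_vergence", "nonuniform", "accuracy"),
          get("infer_parallel", "nonuniform", "accuracy"), `>`),
    nonuniform_active_slower_than_vergence =
      cmp(get("active_vision", "nonuniform", "mean_time"),
          get("infer_vergence", "nonuniform", "mean_time"), `>=`),
    uniform_parallel_at_least_active_accuracy =
      cmp(get("infer_parallel", "uniform", "accuracy"),
          get("active_vision", "uniform", "accuracy"), `>=`),
    uniform_parallel_no_slower_than_active =
      cmp(get("infer_parallel", "uniform", "mean_time"),
          get("active_vision", "uniform", "mean_time"), `<=`)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(verdicts, file.path(out_dir, "verdicts.json"),
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
    if (plot) plot_comparison(tab, file.path(out_dir, "comparison.png"))
  }
  list(table = tab, verdicts = verdicts)
}

# three-panel bar chart (accuracy / mean error / mean time) per resolution
plot_comparison <- function(tab, path) {
  grDevices::png(path, width = 1200, height = 450)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(8, 4, 3, 1))
  for (field in c("accuracy", "mean_error", "mean_time")) {
    vals <- tab[[field]]
    vals[!is.finite(vals)] <- NA
    names(vals) <- paste(sub("infer_", "", tab$variant), tab$resolution)
    graphics::barplot(vals, las = 2, main = field,
                      col = ifelse(tab$resolution == "nonuniform",
                                   "steelblue", "grey70"))
  }
  invisible(path)
}

#' Run the full 3x2 comparison grid
#'
#' @param n_trials Trials per condition.
#' @param master_seed Master seed shared by all conditions.
#' @param cfg Configuration list.
#' @param out_dir Optional output directory passed through to
#'   [run_condition()] and [compare_report()].
#' @param plot Forwarded to [compare_report()].
#' @return The [compare_report()] result, plus `summaries`.
#' @export
run_grid <- function(n_trials = 50, master_seed = 1, cfg = depthsim_config(),
                     out_dir = NULL, plot = FALSE) {
  grid <- expand.grid(variant = c("infer_parallel", "infer_vergence",
                                  "active_vision"),
                      resolution = c("nonuniform", "uniform"),
                      stringsAsFactors = FALSE)
  summaries <- lapply(seq_len(nrow(grid)), function(i) {
    cond <- condition(grid$variant[i], grid$resolution[i], n_trials,
                      master_seed, cfg = cfg)
    run_condition(cond, out_dir = out_dir)$summary
  })
  rep <- compare_report(summaries, out_dir = out_dir, plot = plot)
  rep$summaries <- summaries
  rep
}
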