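# End-to-end pipeline: environment syntax -> state classification ->
# navigation summaries -> experienced metrics -> group statistics, with all
# outputs written as TSV plus one machine-readable JSON report.

#' Build and validate a pipeline configuration
#'
#' Either point the pipeline at input files (`environment`, `trajectories`,
#' `cognitive` paths) or let it simulate a synthetic cohort
#' (`simulate = TRUE`, the default when no paths are given).
#'
#' @param simulate generate a synthetic cohort instead of reading files.
#' @param environment,trajectories,cognitive input file paths (JSON / CSV /
#'   CSV); ignored when `simulate = TRUE`.
#' @param out_dir output directory (created if missing); `NULL` disables
#'   file output.
#' @param k number of navigation states (default 3).
#' @param k_range candidate k for clustering diagnostics.
#' @param bin_vm route-profile bin width in vm of route arclength.
#' @param n_perm permutations per route bin.
#' @param deviation_threshold route-error flag threshold in vm (default one
#'   street width for synthetic layouts, else `Inf`).
#' @param alpha_normal Shapiro-Wilk gate level.
#' @param bh_correct apply Benjamini-Hochberg correction to the per-bin
#'   permutation p-values (off by default; unadjusted p is reported either
#'   way).
#' @param seed master seed for simulation and permutation draws.
#' @param spec a [cohort_spec()] for simulation.
#' @param layout optional [env_layout()] to simulate in (default: a
#'   generated Manhattan-grid environment).
#' @return validated config list of class `nav_config`.
#' @export
pipeline_config <- function(simulate = TRUE,
                            environment = NULL, trajectories = NULL,
                            cognitive = NULL, out_dir = NULL,
                            k = 3, k_range = 2:6, bin_vm = 1,
                            n_perm = 1000, deviation_threshold = NULL,
                            alpha_normal = 0.05, bh_correct = FALSE,
                            seed = 1, spec = cohort_spec(), layout = NULL) {
  if (k < 2) stop("validation error: k must be at least 2")
  if (any(k_range < 2)) stop("validation error: k_range must be >= 2")
  if (bin_vm <= 0) stop("validation error: bin_vm must be positive")
  if (n_perm < 1) stop("validation error: n_perm must be >= 1")
  if (!simulate) {
    for (p in c(environment, trajectories)) {
      if (is.null(p) || !file.exists(p))
        stop("validation error: input path missing or nonexistent: ",
             if (is.null(p)) "(unset)" else p)
    }
  }
  structure(list(simulate = simulate, environment = environment,
                 trajectories = trajectories, cognitive = cognitive,
                 out_dir = out_dir, k = k, k_range = k_range,
                 bin_vm = bin_vm, n_perm = n_perm,
                 deviation_threshold = deviation_threshold,
                 alpha_normal = alpha_normal, bh_correct = bh_correct,
                 seed = seed, spec = spec, layout = layout),
            class = "nav_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path config file; `.json` or `.yaml`/`.yml`.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    obj <- yaml::read_yaml(path)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, obj)
}

#' Run the full navigation-analysis pipeline
#'
#' Sequences the stages: space-syntax scoring of the environment (axial +
#' visibility graphs), per-participant k-means state classification,
#' per-trial and per-participant navigation summaries, experienced
#' axial/visual metrics, normality-gated group tests, cognitive-score
#' correlations, the route-projected per-bin permutation profile, and the
#' wayfinding density map. With `out_dir` set, every table is written as TSV
#' and the whole report as deterministic JSON (identical config + seed gives
#' byte-identical output).
#'
#' @param config a [pipeline_config()] (or a path accepted by
#'   [read_config()]).
#' @return the report, a named list, invisibly when written to disk.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "nav_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- inputs ----
  cohort <- stage("input", {
    if (config$simulate) {
      generate_cohort(spec = config$spec, layout = config$layout,
                      seed = config$seed)
    } else {
      layout <- read_environment(config$environment)
      trajs <- read_trajectories(config$trajectories)
      cog <- if (!is.null(config$cognitive)) read_cognitive(config$cognitive)
      trials <- lapply(trajs, function(tt) lapply(tt, function(tr)
        list(traj = tr, truth = NULL)))
      grp <- if (!is.null(cog) && "group" %in% names(cog))
        cog$group[match(names(trials), cog$participant_id)]
      else rep(NA_character_, length(trials))
      list(layout = layout, routes = NULL,
           participants = data.frame(participant_id = names(trials),
                                     group = grp),
           trials = trials, cognitive = cog)
    }
  })
  layout <- cohort$layout
  dev_thr <- config$deviation_threshold
  if (is.null(dev_thr)) {
    st <- attr(layout, "streets")
    dev_thr <- if (is.null(st)) Inf else st$street_width
  }

  # ---- environment syntax ----
  axial <- stage("syntax", {
    g <- build_axial_graph(layout)
    axial_metrics(g)
  })
  grid <- stage("syntax", build_visibility_graph(layout))

  # ---- states + summaries ----
  ids <- cohort$participants$participant_id
  class_res <- stage("classify", lapply(seq_along(ids), function(p) {
    classify_participant(lapply(cohort$trials[[p]], `[[`, "traj"),
                         k = config$k)
  }))
  summaries <- stage("summarize", {
    rows <- list()
    for (p in seq_along(ids)) {
      trials <- cohort$trials[[p]]
      for (i in seq_along(trials)) {
        s <- summarize_navigation(trials[[i]]$traj, class_res[[p]]$states[[i]])
        s$error_flag <- if (!is.null(cohort$routes))
          flag_route_error(trials[[i]]$traj, cohort$routes[[i]], dev_thr)
        else NA
        rows[[length(rows) + 1]] <- s
      }
    }
    do.call(rbind, rows)
  })
  participant_summary <- stage("summarize", {
    agg <- lapply(split(summaries, summaries$participant_id), function(d) {
      nav <- sum(d$navigation_time)
      data.frame(participant_id = d$participant_id[1],
                 navigation_time = nav,
                 wayfinding_time = sum(d$wayfinding_time),
                 transition_time = sum(d$transition_time),
                 moving_time = sum(d$moving_time),
                 efficiency = (sum(d$moving_time) + sum(d$transition_time)) / nav,
                 distance = sum(d$distance),
                 errors = sum(d$error_flag))
    })
    out <- do.call(rbind, agg)
    out[match(ids, out$participant_id), ]
  })

  # ---- experienced metrics ----
  experienced <- stage("experienced", {
    rows <- lapply(seq_along(ids), function(p) {
      xy <- do.call(rbind, lapply(cohort$trials[[p]], function(tr)
        tr$traj[, c("x", "y")]))
      cbind(participant_id = ids[p],
            experienced_metrics(xy, layout, axial, grid))
    })
    do.call(rbind, rows)
  })

  # ---- statistics ----
  grp <- factor(cohort$participants$group, levels = c("older", "young"))
  have_groups <- nlevels(droplevels(grp[!is.na(grp)])) == 2
  group_tests <- NULL
  if (have_groups) {
    group_tests <- stage("stats", {
      vars <- cbind(participant_summary[, c("navigation_time",
                                            "wayfinding_time", "efficiency",
                                            "distance")],
                    experienced[, c("EAI", "EAC", "EMAD",
                                    "EVI", "EVC", "EVMD")])
      rows <- lapply(names(vars), function(v) {
        r <- tryCatch(
          choose_and_run_two_sample(vars[[v]][grp == "older"],
                                    vars[[v]][grp == "young"],
                                    alpha_normal = config$alpha_normal),
          error = function(e) NULL)   # e.g. a variable constant in a group
        if (is.null(r))
          return(data.frame(variable = v, test_name = "degenerate",
                            statistic = NA_real_, p_value = NA_real_,
                            n_older = sum(grp == "older"),
                            n_young = sum(grp == "young")))
        data.frame(variable = v, test_name = r$test_name,
                   statistic = r$statistic, p_value = r$p_value,
                   n_older = r$n[1], n_young = r$n[2])
      })
      do.call(rbind, rows)
    })
  }
  correlations <- NULL
  if (!is.null(cohort$cognitive)) {
    correlations <- stage("stats", {
      cog <- cohort$cognitive
      cog <- cog[match(ids, cog$participant_id), ]
      score_cols <- intersect(c("moca_adjusted", "mmse", "rocf_c", "rocf_d",
                                "tmta", "mrt"), names(cog))
      eff <- participant_summary$efficiency
      rows <- lapply(score_cols, function(v) {
        r <- tryCatch(
          choose_and_run_correlation(eff, cog[[v]],
                                     alpha_normal = config$alpha_normal),
          error = function(e) NULL)
        if (is.null(r))
          return(data.frame(variable_pair = paste0("efficiency~", v),
                            test_name = "degenerate", r = NA_real_,
                            p_value = NA_real_, n = length(eff)))
        data.frame(variable_pair = paste0("efficiency~", v),
                   test_name = r$test_name, r = r$statistic,
                   p_value = r$p_value, n = r$n)
      })
      do.call(rbind, rows)
    })
  }

  # ---- route profile ----
  profile <- NULL
  if (!is.null(cohort$routes) && have_groups) {
    profile <- stage("route_profile", {
      parts <- lapply(seq_along(ids), function(p) {
        lapply(seq_along(cohort$trials[[p]]), function(i)
          list(traj = cohort$trials[[p]][[i]]$traj,
               states = class_res[[p]]$states[[i]],
               route = cohort$routes[[i]]))
      })
      pr <- route_efficiency_profile(parts, grp, bin_vm = config$bin_vm,
                                     n_perm = config$n_perm,
                                     seed = config$seed + 1L,
                                     deviation_threshold = dev_thr)
      if (config$bh_correct)
        pr$bins$p_adj <- stats::p.adjust(pr$bins$p_perm, method = "BH")
      pr
    })
  }

  # ---- density map ----
  density <- stage("density", {
    pts <- list()
    for (p in seq_along(ids)) {
      for (i in seq_along(cohort$trials[[p]])) {
        tr <- cohort$trials[[p]][[i]]$traj
        way <- class_res[[p]]$states[[i]] == "WAYFINDING"
        if (any(way)) pts[[length(pts) + 1]] <- tr[way, c("x", "y")]
      }
    }
    pts <- do.call(rbind, pts)
    if (is.null(pts) || nrow(pts) == 0) NULL
    else wayfinding_density(pts$x, pts$y, layout)
  })

  report <- list(
    parameters = list(k = config$k, bin_vm = config$bin_vm,
                      n_perm = config$n_perm,
                      deviation_threshold = dev_thr,
                      alpha_normal = config$alpha_normal,
                      seed = config$seed,
                      grid_resolution = layout$grid_resolution),
    axial_metrics = axial,
    trial_summary = summaries,
    participant_summary = participant_summary,
    experienced_metrics = experienced,
    group_tests = group_tests,
    correlations = correlations,
    route_profile = if (!is.null(profile)) profile$bins,
    density_hotspots = if (!is.null(density))
      which(density$top_mask, arr.ind = TRUE)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(config$out_dir, f)
    write_tsv(axial, o("axial_metrics.tsv"))
    write_tsv(cbind(grid$cells, grid$metrics), o("visibility_metrics.tsv"))
    write_tsv(summaries, o("trial_summary.tsv"))
    write_tsv(participant_summary, o("participant_summary.tsv"))
    write_tsv(experienced, o("experienced_metrics.tsv"))
    if (!is.null(group_tests)) write_tsv(group_tests, o("group_tests.tsv"))
    if (!is.null(correlations)) write_tsv(correlations, o("correlations.tsv"))
    if (!is.null(profile)) write_tsv(profile$bins, o("route_profile.tsv"))
    if (!is.null(density)) {
      data.table::fwrite(as.data.frame(density$density), o("density.csv"))
      data.table::fwrite(as.data.frame(density$top_mask * 1), o("density_mask.csv"))
    }
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", na = "null", null = "null")
    writeLines(json, o("report.json"))
    return(invisible(report))
  }
  report
}
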