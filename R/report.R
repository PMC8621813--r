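# Figure-style output and the end-to-end pipeline.

#' Plot specification for cyclogram figures
#'
#' @param mode `"single_cyclogram"` (one loop, phases distinguishable),
#'   `"group_overlay"` (every cycle as a light point cloud plus the bold
#'   mean loop), or `"representative_grid"` (one panel per cyclogram).
#' @param show_phases Distinguish stance (filled markers) from swing (open
#'   markers)?
#' @param show_mean_bold Draw the pointwise mean loop as a bold line
#'   (group_overlay always does)?
#' @param show_swing Render swing-phase points? (Stance-only plots are
#'   occasionally useful for inspecting the stance arc shape.)
#' @return A `plot_spec` list.
#' @export
plot_spec <- function(mode = c("single_cyclogram", "group_overlay",
                               "representative_grid"),
                      show_phases = TRUE, show_mean_bold = TRUE,
                      show_swing = TRUE) {
  structure(list(mode = match.arg(mode), show_phases = show_phases,
                 show_mean_bold = show_mean_bold, show_swing = show_swing),
            class = "plot_spec")
}

# long data.frame of cyclogram points with phase labels
.cyclogram_points_df <- function(cyclos) {
  if (inherits(cyclos, "cyclogram")) cyclos <- list(cyclos)
  do.call(rbind, lapply(seq_along(cyclos), function(i) {
    cy <- cyclos[[i]]
    n <- nrow(cy$points)
    data.frame(
      id = paste0(cy$source$participant_id, "#", cy$source$cycle, "/", i),
      point = seq_len(n) - 1L,
      hip_deg = cy$points[, 1],
      knee_deg = cy$points[, 2],
      phase = ifelse(seq_len(n) - 1L <= cy$stance_end_index,
                     "stance", "swing"),
      stringsAsFactors = FALSE
    )
  }))
}

#' Render cyclogram figures
#'
#' Hip angle on the abscissa, knee angle on the ordinate; traversal in time
#' order renders normal-pattern loops clockwise. Output is deterministic
#' for a given input (cairo device, no timestamp metadata).
#'
#' @param cyclos A `cyclogram` or list of cyclograms.
#' @param spec A [plot_spec()].
#' @param out Output path ending in `.png` or `.svg`; `NULL` returns the
#'   ggplot object without writing.
#' @param width,height,dpi Device geometry (inches / dots per inch).
#' @return The ggplot object, invisibly; the image file is written when
#'   `out` is given.
#' @export
plot_cyclogram <- function(cyclos, spec = plot_spec(), out = NULL,
                           width = 6, height = 5, dpi = 120) {
  if (inherits(cyclos, "cyclogram")) cyclos <- list(cyclos)
  if (length(cyclos) == 0) stop("need at least one cyclogram", call. = FALSE)
  df <- .cyclogram_points_df(cyclos)
  if (!spec$show_swing) df <- df[df$phase == "stance", , drop = FALSE]

  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hip_deg, y = .data$knee_deg))
  if (spec$mode == "group_overlay") {
    gg <- gg + ggplot2::geom_point(color = "grey70", size = 0.4, alpha = 0.6)
    mean_df <- stats::aggregate(cbind(hip_deg, knee_deg) ~ point, df, mean)
    mean_df <- mean_df[order(mean_df$point), ]
    mean_df <- rbind(mean_df, mean_df[1, ])   # close the loop
    gg <- gg + ggplot2::geom_path(data = mean_df, linewidth = 1.2,
                                  color = "black")
  } else {
    if (spec$show_phases) {
      gg <- gg +
        ggplot2::geom_path(ggplot2::aes(group = .data$id), color = "grey40") +
        ggplot2::geom_point(ggplot2::aes(shape = .data$phase), size = 1.6) +
        ggplot2::scale_shape_manual(values = c(stance = 16, swing = 1))
    } else {
      gg <- gg + ggplot2::geom_path(ggplot2::aes(group = .data$id))
    }
    if (spec$show_mean_bold && length(cyclos) > 1) {
      mean_df <- stats::aggregate(cbind(hip_deg, knee_deg) ~ point, df, mean)
      mean_df <- rbind(mean_df, mean_df[1, ])
      gg <- gg + ggplot2::geom_path(data = mean_df, linewidth = 1.2,
                                    color = "black")
    }
    if (spec$mode == "representative_grid") {
      gg <- gg + ggplot2::facet_wrap(~id)
    }
  }
  gg <- gg +
    ggplot2::labs(x = "Hip joint angle (deg)", y = "Knee joint angle (deg)") +
    ggplot2::theme_bw()

  if (!is.null(out)) {
    ext <- tolower(tools::file_ext(out))
    if (ext == "png") {
      grDevices::png(out, width = width * dpi, height = height * dpi,
                     res = dpi, type = "cairo")
    } else if (ext == "svg") {
      grDevices::svg(out, width = width, height = height)
    } else {
      stop("unsupported image format: .", ext, call. = FALSE)
    }
    print(gg)
    grDevices::dev.off()
  }
  invisible(gg)
}

#' Analyze a cohort of traces
#'
#' Runs segmentation and cyclogram parameterization for every participant
#' of a manifest (or an in-memory list of traces) and assembles the
#' participant-level and per-cycle parameter tables.
#'
#' @param manifest Manifest `data.frame` (see [generate_cohort()],
#'   [read_manifest()]), or a list of `joint_angle_trace` objects.
#' @return List with `participants` (`participant_id`, `group`, `n_cycles`,
#'   eight parameter columns holding per-cycle means), `per_cycle`
#'   (`participant_id`, `group`, `cycle`, eight parameter columns), and
#'   `cycles` (named list of `gait_cycle` lists, for plotting).
#' @export
analyze_cohort <- function(manifest) {
  traces <- if (is.data.frame(manifest)) {
    mdir <- attr(manifest, "dir")
    lapply(seq_len(nrow(manifest)), function(i) {
      read_trace(.resolve_path(manifest$trace_path[i], mdir),
                 .resolve_path(manifest$events_path[i], mdir),
                 participant_id = manifest$participant_id[i],
                 group = manifest$group[i])
    })
  } else {
    manifest
  }
  part_rows <- list()
  cycle_rows <- list()
  all_cycles <- list()
  for (tr in traces) {
    pid <- tr$participant_id
    cycles <- tryCatch(
      segment_cycles(tr),
      error = function(e) stop("stage 'segment' failed for participant ", pid,
                               ": ", conditionMessage(e), call. = FALSE)
    )
    if (length(cycles) == 0) {
      warning("participant ", pid, " yielded no cycles; skipping",
              call. = FALSE)
      next
    }
    pp <- tryCatch(
      participant_params(cycles),
      error = function(e) stop("stage 'cyclogram' failed for participant ",
                               pid, ": ", conditionMessage(e), call. = FALSE)
    )
    all_cycles[[pid]] <- cycles
    part_rows[[pid]] <- data.frame(
      participant_id = pid, group = tr$group, n_cycles = length(cycles),
      as.data.frame(unclass(pp$mean)), stringsAsFactors = FALSE
    )
    cycle_rows[[pid]] <- data.frame(
      participant_id = pid, group = tr$group,
      pp$per_cycle, stringsAsFactors = FALSE
    )
  }
  if (length(part_rows) == 0) stop("no analyzable participants", call. = FALSE)
  list(
    participants = do.call(rbind, c(part_rows, list(make.row.names = FALSE))),
    per_cycle = do.call(rbind, c(cycle_rows, list(make.row.names = FALSE))),
    cycles = all_cycles
  )
}

#' Run the full pipeline
#'
#' Executes simulation (if requested) -> segmentation -> cyclogram
#' parameterization -> variability -> group comparison -> figures, writing
#' every table as CSV plus a JSON run log. The output bundle is a pure
#' function of `(config, seed)`.
#'
#' @param config Either a path to a YAML file or a list with elements:
#'   `out_dir` (required); `seed` (integer, default 1); one of `synth`
#'   (`TRUE` for the default three-group presets, a number for the cycles
#'   per participant, or a path to a profile YAML readable by
#'   [read_profiles()]) or `manifest` (path to an existing cohort manifest);
#'   `plots` (default `TRUE`).
#' @return Result bundle, invisibly: `manifest`, `analysis` (see
#'   [analyze_cohort()]), `cv` (see [cv_table()]), `comparison` (see
#'   [compare_groups()]; `NULL` when skipped), `paths` of written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # --- stage: synth / input ---
  manifest <- tryCatch({
    if (!is.null(config$manifest)) {
      read_manifest(config$manifest)
    } else {
      profiles <- if (is.character(config$synth)) {
        read_profiles(config$synth)
      } else if (is.numeric(config$synth)) {
        default_profiles(n_cycles_per_participant = config$synth)
      } else {
        default_profiles()
      }
      generate_cohort(profiles, seed, file.path(out_dir, "cohort"))
    }
  }, error = function(e) {
    stop("stage 'synth' failed: ", conditionMessage(e), call. = FALSE)
  })
  paths$manifest <- file.path(out_dir, "cohort", "manifest.csv")

  # --- stages: segment + cyclogram ---
  analysis <- analyze_cohort(manifest)
  paths$participants <- file.path(out_dir, "participant_params.csv")
  .write_num_csv(analysis$participants, paths$participants)
  paths$per_cycle <- file.path(out_dir, "per_cycle_params.csv")
  .write_num_csv(analysis$per_cycle, paths$per_cycle)

  # --- stage: variability ---
  cv <- tryCatch(cv_table(analysis$per_cycle), error = function(e) {
    stop("stage 'variability' failed: ", conditionMessage(e), call. = FALSE)
  })
  paths$cv <- file.path(out_dir, "cv_records.csv")
  .write_num_csv(cv$cv, paths$cv)
  paths$cv_summary <- file.path(out_dir, "cv_summary.csv")
  .write_num_csv(cv$summary, paths$cv_summary)

  # --- stage: stats ---
  groups <- table(analysis$participants$group)
  comparison <- NULL
  cv_comparison <- NULL
  if (length(groups) >= 2 && all(groups >= 2)) {
    comparison <- compare_groups(analysis$participants)
    paths$comparison <- file.path(out_dir, "comparison_params.csv")
    .write_num_csv(comparison_table(comparison), paths$comparison)
    cv_wide <- stats::reshape(cv$cv, idvar = c("participant_id", "group"),
                              timevar = "parameter", direction = "wide")
    names(cv_wide) <- sub("^cv_percent\\.", "", names(cv_wide))
    cv_comparison <- compare_groups(cv_wide)
    paths$cv_comparison <- file.path(out_dir, "comparison_cv.csv")
    .write_num_csv(comparison_table(cv_comparison), paths$cv_comparison)
  } else {
    warning("fewer than 2 groups with 2+ participants; comparison skipped",
            call. = FALSE)
  }

  # --- stage: report ---
  do_plots <- is.null(config$plots) || isTRUE(config$plots)
  if (do_plots) {
    for (g in names(split(analysis$participants, analysis$participants$group))) {
      pids <- analysis$participants$participant_id[
        analysis$participants$group == g]
      cyclos <- unlist(lapply(analysis$cycles[pids],
                              function(cl) lapply(cl, build_cyclogram)),
                       recursive = FALSE)
      f <- file.path(out_dir, paste0("cyclogram_", g, ".png"))
      plot_cyclogram(cyclos, plot_spec("group_overlay"), out = f)
      paths[[paste0("plot_", g)]] <- f
    }
  }

  log <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("cyclogait")),
    n_participants = nrow(analysis$participants),
    groups = as.list(groups),
    outputs = lapply(paths, function(p) basename(as.character(p)))
  )
  paths$log <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(manifest = manifest, analysis = analysis, cv = cv,
                 comparison = comparison, cv_comparison = cv_comparison,
                 paths = paths))
}

# numeric columns to a fixed decimal format so reruns are byte-identical
.write_num_csv <- function(df, path, digits = 4) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf(paste0("%.", digits, "f"),
                                                   out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
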