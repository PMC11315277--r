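# End-to-end orchestration: a set of recordings (tracking + optional depth
# + condition metadata) is turned into per-recording depth-noise and jitter
# summaries, condition comparisons, and report tables mirroring the usual
# publication layout (per-area random-error summaries, per-joint MDE table
# with a median/IQR row, stance-width five-number summaries, invalid-sample
# counts).

#' Configure an experiment run
#'
#' @param recordings List of recordings; each element is a list with
#'   `label` (condition/recording name), `tracking` (path to a tracking
#'   JSON file or a [tracking_sequence()]), optional `depth` (path to a
#'   depth-stack manifest/directory or a [depth_stack()]), and optional
#'   `metadata` (list, e.g. illuminance and infrared intensity).
#' @param rois List of [roi()] regions for the depth analysis (may be empty
#'   when no depth stacks are supplied).
#' @param cut Initial frames discarded from every recording (default 60).
#' @param N Centroid window half-width (default 30, the nominal frame rate).
#' @param joints Joint selection for the MDE table (default the 18-joint
#'   gait set).
#' @param alpha Significance level for all tests (default 0.05).
#' @param mode `"independent"` (distinct conditions; Kruskal-Wallis) or
#'   `"repeated"` (same condition re-recorded; Friedman across the same
#'   pixels). Statistical comparisons need >= 3 recordings.
#' @param ankle_pair Joint pair for the stance-width series.
#' @param seed Seed recorded in provenance and used for any simulation
#'   steps embedded in `recordings`.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(recordings, rois = list(), cut = 60, N = 30,
                              joints = included_joints(), alpha = 0.05,
                              mode = c("independent", "repeated"),
                              ankle_pair = c("ANKLE_LEFT", "ANKLE_RIGHT"),
                              seed = NULL) {
  mode <- match.arg(mode)
  if (length(recordings) < 1L) {
    stop("config needs >= 1 recording", call. = FALSE)
  }
  labels <- vapply(recordings, function(r) r$label %||% NA_character_,
                   character(1))
  if (anyNA(labels) || anyDuplicated(labels)) {
    stop("every recording needs a unique label", call. = FALSE)
  }
  if (mode == "independent" && length(recordings) >= 3L &&
      length(unique(labels)) < 3L) {
    stop("independent mode requires >= 3 distinct condition labels",
         call. = FALSE)
  }
  for (r in rois) stopifnot(inherits(r, "roi"))
  assert_joints(joints)
  structure(list(recordings = recordings, rois = rois, cut = cut, N = N,
                 joints = joints, alpha = alpha, mode = mode,
                 ankle_pair = ankle_pair, seed = seed),
            class = "experiment_config")
}

load_tracking <- function(x, label) {
  if (inherits(x, "tracking_sequence")) return(x)
  tryCatch(read_tracking_json(x),
           error = function(e) stop(sprintf("[%s, stage tracking-io] %s",
                                            label, conditionMessage(e)),
                                    call. = FALSE))
}

load_depth <- function(x, label) {
  if (is.null(x) || inherits(x, "depth_stack")) return(x)
  tryCatch(read_depth_stack(x),
           error = function(e) stop(sprintf("[%s, stage depth-io] %s",
                                            label, conditionMessage(e)),
                                    call. = FALSE))
}

#' Run an experiment end-to-end
#'
#' For each recording: reads the inputs, drops the start-up frames,
#' computes the per-joint MDE table, the stance-width series, and — when a
#' depth stack is present — per-region random-error maps, summaries and
#' invalid-sample counts. Across recordings it screens the random-error
#' distributions for normality and runs the omnibus + pairwise comparison
#' matching `mode`. Deterministic given inputs and config; every dropped
#' frame or undefined pixel is logged as a structured event.
#'
#' @param cfg An [experiment_config()].
#' @return An `experiment_report`: per-recording results plus assembled
#'   tables (`depth_summaries`, `mde_table`, `ankle_table`,
#'   `invalid_counts`, `normality`, `comparisons`), an `events` log and a
#'   `provenance` block (config hash, package version, seed).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  labels <- vapply(cfg$recordings, `[[`, character(1), "label")
  events <- list()
  log_event <- function(...) events[[length(events) + 1L]] <<- list(...)

  per_rec <- list()
  for (rec in cfg$recordings) {
    lab <- rec$label
    res <- list(label = lab, metadata = rec$metadata)
    seq <- load_tracking(rec$tracking, lab)
    for (g in seq$gaps) {
      log_event(recording = lab, stage = "tracking-io", event = "gap_frame",
                frame = g)
    }
    seq <- tryCatch(cut_frames(seq, cfg$cut),
                    error = function(e) stop(sprintf(
                      "[%s, stage cut] %s", lab, conditionMessage(e)),
                      call. = FALSE))
    res$n_frames_analyzed <- n_frames(seq)
    joints <- intersect(cfg$joints, seq$joint_set)
    res$mde <- compute_mde(seq, joints, N = cfg$N)
    if (all(cfg$ankle_pair %in% seq$joint_set)) {
      res$ankle <- joint_pair_distance(seq, cfg$ankle_pair[1],
                                       cfg$ankle_pair[2])
    }
    depth <- load_depth(rec$depth, lab)
    if (!is.null(depth)) {
      res$depth <- list()
      for (r in cfg$rois) {
        map <- tryCatch(compute_random_error(depth, r, cut = cfg$cut),
                        error = function(e) stop(sprintf(
                          "[%s, stage depth-metrics, roi %s] %s",
                          lab, r$name, conditionMessage(e)), call. = FALSE))
        n_undef <- sum(is.na(map$re))
        if (n_undef > 0L) {
          log_event(recording = lab, stage = "depth-metrics",
                    event = "undefined_pixels", roi = r$name, n = n_undef)
        }
        res$depth[[r$name]] <- list(map = map,
                                    summary = summarize_random_error(map),
                                    n_invalid = map$n_invalid)
      }
    }
    per_rec[[lab]] <- res
  }

  # assembled tables -------------------------------------------------------
  mde_table <- NULL
  for (lab in labels) {
    m <- per_rec[[lab]]$mde$mde
    col <- data.frame(joint = names(m), mde = unname(m),
                      recording = lab, stringsAsFactors = FALSE)
    mde_table <- rbind(mde_table, col)
  }

  ankle_table <- do.call(rbind, lapply(labels, function(lab) {
    a <- per_rec[[lab]]$ankle
    if (is.null(a)) return(NULL)
    cbind(data.frame(recording = lab, stringsAsFactors = FALSE),
          as.data.frame(a$summary))
  }))

  depth_summaries <- NULL
  invalid_counts <- NULL
  for (lab in labels) {
    for (rname in names(per_rec[[lab]]$depth)) {
      s <- per_rec[[lab]]$depth[[rname]]$summary
      depth_summaries <- rbind(depth_summaries, data.frame(
        area = rname, recording = lab, min = s$min, max = s$max,
        median = s$median, q1 = s$q1, q3 = s$q3,
        n_pixels_defined = s$n_pixels_defined, stringsAsFactors = FALSE))
      invalid_counts <- rbind(invalid_counts, data.frame(
        area = rname, recording = lab,
        n_invalid = per_rec[[lab]]$depth[[rname]]$n_invalid,
        stringsAsFactors = FALSE))
    }
  }

  # comparisons across recordings per region -------------------------------
  normality <- NULL
  comparisons <- list()
  with_depth <- labels[vapply(labels, function(l)
    !is.null(per_rec[[l]]$depth), logical(1))]
  if (length(with_depth) >= 3L && length(cfg$rois) > 0L) {
    for (r in cfg$rois) {
      re_maps <- lapply(with_depth, function(l)
        per_rec[[l]]$depth[[r$name]]$map$re)
      names(re_maps) <- with_depth
      groups <- lapply(re_maps, function(m) m[!is.na(m)])
      ns <- normality_screen(groups, alpha = cfg$alpha)
      ns$area <- r$name
      normality <- rbind(normality, ns)
      comparisons[[r$name]] <- if (cfg$mode == "independent") {
        compare_independent(groups, alpha = cfg$alpha)
      } else {
        blocks <- vapply(re_maps, as.vector,
                         numeric(length(re_maps[[1]])))
        compare_repeated(blocks, alpha = cfg$alpha)
      }
      if (cfg$mode == "repeated") {
        nd <- comparisons[[r$name]]$n_dropped_rows
        if (nd > 0L) {
          log_event(recording = "all", stage = "stats-compare",
                    event = "dropped_incomplete_pixels", roi = r$name,
                    n = nd)
        }
      }
    }
  }

  cfg_digest <- config_hash(list(
    labels = labels, cut = cfg$cut, N = cfg$N, joints = cfg$joints,
    alpha = cfg$alpha, mode = cfg$mode,
    rois = lapply(cfg$rois, unclass), seed = cfg$seed))

  structure(
    list(config = cfg, recordings = per_rec, mde_table = mde_table,
         ankle_table = ankle_table, depth_summaries = depth_summaries,
         invalid_counts = invalid_counts, normality = normality,
         comparisons = comparisons, events = events,
         provenance = list(
           config_hash = cfg_digest,
           package_version = as.character(utils::packageVersion("kinectqa")),
           seed = cfg$seed)),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d recording(s), mode %s\n",
              length(x$recordings), x$config$mode))
  if (!is.null(x$mde_table)) {
    med <- tapply(x$mde_table$mde, x$mde_table$recording, stats::median)
    cat("  MDE medians (mm):",
        paste(sprintf("%s %.2f", names(med), med), collapse = ", "), "\n")
  }
  if (length(x$comparisons) > 0L) {
    cat("  comparisons:",
        paste(sprintf("%s p=%.3g", names(x$comparisons),
                      vapply(x$comparisons, `[[`, numeric(1), "p_value")),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# full-precision numeric formatting so CSV bodies re-parse exactly
fmt_num_cols <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

#' Write report tables to CSV/JSON files
#'
#' Emits the publication-layout tables: per-area random-error summaries
#' (min, max, median, quartiles per recording), the per-joint MDE table in
#' wide form with the per-joint minimum flagged (ties flagged jointly) and
#' an across-joint median/q1/q3 footer, stance-width five-number summaries,
#' invalid-sample counts, normality screens, tidy pairwise comparison
#' results, the structured event log (JSON lines) and a provenance block.
#' Numeric cells are written in full precision, so re-parsing a table
#' recovers the report's numbers exactly.
#'
#' @param report An `experiment_report` from [run_experiment()].
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
make_report_tables <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit_csv <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(dir, name)
    utils::write.csv(fmt_num_cols(df), path, row.names = FALSE)
    written <<- c(written, path)
  }

  emit_csv(report$depth_summaries, "random_error_summary.csv")
  emit_csv(report$invalid_counts, "invalid_counts.csv")
  emit_csv(report$ankle_table, "ankle_distance.csv")
  emit_csv(report$normality, "normality.csv")

  if (!is.null(report$mde_table)) {
    labels <- unique(report$mde_table$recording)
    wide <- stats::reshape(report$mde_table, idvar = "joint",
                           timevar = "recording", direction = "wide")
    names(wide) <- sub("^mde\\.", "", names(wide))
    rownames(wide) <- NULL
    vals <- as.matrix(wide[, labels, drop = FALSE])
    is_min <- vals == apply(vals, 1, min)  # ties flagged jointly
    flags <- data.frame(joint = wide$joint, is_min,
                        check.names = FALSE, stringsAsFactors = FALSE)
    footer <- do.call(rbind, lapply(c("median", "q1", "q3"), function(stat) {
      p <- c(median = 0.5, q1 = 0.25, q3 = 0.75)[[stat]]
      row <- as.data.frame(as.list(apply(vals, 2, stats::quantile,
                                         probs = p, type = .QUANTILE_TYPE)),
                           check.names = FALSE)
      cbind(data.frame(joint = stat, stringsAsFactors = FALSE), row)
    }))
    emit_csv(rbind(wide, footer), "mde.csv")
    emit_csv(flags, "mde_min_flags.csv")
  }

  if (length(report$comparisons) > 0L) {
    omni <- do.call(rbind, lapply(names(report$comparisons), function(a) {
      cr <- report$comparisons[[a]]
      data.frame(area = a, test = cr$test_name, statistic = cr$statistic,
                 df = cr$df, p_value = cr$p_value, alpha = cr$alpha,
                 stringsAsFactors = FALSE)
    }))
    emit_csv(omni, "comparisons_omnibus.csv")
    pw <- do.call(rbind, lapply(names(report$comparisons), function(a) {
      cr <- report$comparisons[[a]]
      if (is.null(cr$pairwise)) return(NULL)
      cbind(data.frame(area = a, stringsAsFactors = FALSE), cr$pairwise)
    }))
    emit_csv(pw, "comparisons_pairwise.csv")
  }

  ev_path <- file.path(dir, "events.jsonl")
  writeLines(vapply(report$events, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE)), character(1)),
    ev_path)
  written <- c(written, ev_path)

  prov_path <- file.path(dir, "provenance.json")
  jsonlite::write_json(report$provenance, prov_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  written <- c(written, prov_path)
  invisible(written)
}
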