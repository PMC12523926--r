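#' @export
print.olf_eval_report <- function(x, ...) {
  cat("<olf_eval_report> task ", x$task, " (", x$model, "): ",
      x$n_trials, " trials / ", x$n_participants, " participants\n", sep = "")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %.3f +/- %.3f (95%% CI %.3f-%.3f, pooled %.3f)\n",
                m$metric[i], m$mean[i], m$sd[i], m$ci_lo[i], m$ci_hi[i],
                m$pooled[i]))
  }
  cf <- x$confusion
  cat(sprintf("  pooled confusion: TP %d FP %d TN %d FN %d\n",
              cf$tp, cf$fp, cf$tn, cf$fn))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `olf_eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per metric: fold `mean`, `sd`, `pooled`
#'   value and bootstrap CI bounds.
#' @method tidy olf_eval_report
#' @export
tidy.olf_eval_report <- function(x, ...) x$metrics

#' @rdname tidy.olf_eval_report
#' @return `glance()` returns a one-row tibble with the task, model,
#'   pooled confusion counts and headline metrics.
#' @method glance olf_eval_report
#' @export
glance.olf_eval_report <- function(x, ...) {
  m <- x$metrics
  pk <- function(name) {
    v <- m$pooled[m$metric == name]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    task = x$task, model = x$model,
    n_trials = x$n_trials, n_participants = x$n_participants,
    accuracy = pk("accuracy"), auc = pk("auc"), f1 = pk("f1"),
    sensitivity = pk("sensitivity"), specificity = pk("specificity"),
    tp = x$confusion$tp, fp = x$confusion$fp,
    tn = x$confusion$tn, fn = x$confusion$fn
  )
}

#' Plot an evaluation report
#'
#' Point estimates (fold means) with bootstrap 95% confidence intervals
#' per metric.
#'
#' @param object An `olf_eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot olf_eval_report
#' @export
autoplot.olf_eval_report <- function(object, ...) {
  m <- object$metrics
  ggplot2::ggplot(m, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      title = paste0("Task: ", object$task, " (", object$model, ")"),
      x = NULL, y = "fold mean with bootstrap 95% CI"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a feature-attribution ranking
#'
#' @param object An `olf_attribution` from [attribute_features()].
#' @param top Number of top features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot olf_attribution
#' @export
autoplot.olf_attribution <- function(object, top = 15, ...) {
  d <- utils::head(object$ranking, top)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_abs, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |attribution| (log-odds)", y = NULL,
                  title = "Feature attribution") +
    ggplot2::theme_minimal()
}

#' Plot an epoch collection
#'
#' Grand-average time course per species and label with a ribbon of +/- 1
#' SEM across epochs (averaged over retained channels).
#'
#' @param object An `olf_epochs`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot olf_epochs
#' @export
autoplot.olf_epochs <- function(object, ...) {
  rate <- object$sampling_rate
  mask <- object$channel_mask %||% rep(TRUE, dim(object$epochs[[1]]$data)[1])
  rows <- lapply(seq_along(object$epochs), function(i) {
    e <- object$epochs[[i]]
    avg <- apply(e$data[mask, , , drop = FALSE], c(2, 3), mean)
    tibble::tibble(
      epoch = i, label = e$label,
      species = rep(rownames(avg) %||% c("HbO", "Hb", "THb"), ncol(avg)),
      time_s = rep((seq_len(ncol(avg)) - 1) / rate - object$window[1],
                   each = nrow(avg)),
      value = as.vector(avg)
    )
  })
  d <- dplyr::bind_rows(rows)
  dd <- dplyr::summarise(
    dplyr::group_by(d, .data$label, .data$species, .data$time_s),
    mean = mean(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()), .groups = "drop"
  )
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$time_s, y = .data$mean,
                                   colour = .data$label, fill = .data$label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time from odor onset (s)",
                  y = expression(Delta * "concentration (" * mu * "M)")) +
    ggplot2::theme_minimal()
}

#' Write / read an evaluation report as JSON
#'
#' The on-disk schema is
#' `{task, model, metrics: {<name>: {mean, sd, pooled, ci95: [lo, hi]}},
#' confusion: {tp, fp, tn, fn}, folds: [...], seeds, config_hash}`.
#'
#' @param report An `olf_eval_report`.
#' @param path JSON path.
#' @return `write_eval_report()` returns `path` invisibly;
#'   `read_eval_report()` the parsed report (metrics and folds as
#'   tibbles).
#' @export
write_eval_report <- function(report, path) {
  m <- report$metrics
  metrics <- setNames(lapply(seq_len(nrow(m)), function(i) {
    list(mean = m$mean[i], sd = m$sd[i], pooled = m$pooled[i],
         ci95 = c(m$ci_lo[i], m$ci_hi[i]))
  }), m$metric)
  folds <- lapply(
    split(report$fold_metrics, ~ repeat_i + fold, drop = TRUE),
    function(d) list(repeat_i = d$repeat_i[1], fold = d$fold[1],
                     metrics = setNames(as.list(d$value), d$metric))
  )
  out <- list(
    task = report$task, model = report$model, metrics = metrics,
    confusion = report$confusion, folds = unname(folds),
    n_trials = report$n_trials, n_participants = report$n_participants,
    seeds = report$seeds, config_hash = report$config_hash
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  if (!file.exists(path)) abort(paste0("report not found: ", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Render an evaluation report as markdown
#'
#' @param report An `olf_eval_report` (or a path to its JSON).
#' @param path Output markdown path.
#' @return `path`, invisibly.
#' @export
render_report_md <- function(report, path) {
  if (is.character(report)) report <- read_eval_report(report)
  m <- if (inherits(report, "olf_eval_report")) {
    report$metrics
  } else {
    mm <- report$metrics
    tibble::tibble(
      metric = names(mm),
      mean = vapply(mm, function(x) x$mean, 1),
      sd = vapply(mm, function(x) x$sd, 1),
      pooled = vapply(mm, function(x) x$pooled, 1),
      ci_lo = vapply(mm, function(x) x$ci95[1], 1),
      ci_hi = vapply(mm, function(x) x$ci95[2], 1)
    )
  }
  cf <- report$confusion
  lines <- c(
    paste0("# Evaluation report: ", report$task, " (", report$model, ")"),
    "",
    sprintf("- trials: %s, participants: %s", report$n_trials, report$n_participants),
    sprintf("- pooled confusion: TP %d, FP %d, TN %d, FN %d",
            cf$tp, cf$fp, cf$tn, cf$fn),
    "",
    "| metric | fold mean | SD | pooled | 95% CI |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.3f | %.3f | %.3f | [%.3f, %.3f] |",
            m$metric, m$mean, m$sd, m$pooled, m$ci_lo, m$ci_hi)
  )
  writeLines(lines, path)
  invisible(path)
}
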