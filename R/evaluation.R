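#' Participant-grouped cross-validation plan
#'
#' Builds k outer folds of participants, repeated with different seeds.
#' All trials of a participant fall in exactly one test fold per repeat;
#' fold sizes differ by at most one participant. Inner tuning folds
#' partition only the outer-training participants and are derived
#' deterministically from the repeat seed.
#'
#' @param participants Character vector of participant ids.
#' @param k Outer folds (default 10).
#' @param repeats Outer repeats (default 5).
#' @param seeds One seed per repeat; derived from `base_seed` when `NULL`.
#' @param inner_k Inner folds recorded in the plan (default 5).
#' @param base_seed Base seed used when `seeds` is `NULL`.
#' @return An `olf_split_plan`: list with `outer` (tibble `repeat_i`,
#'   `fold`, `participant_id`), `seeds`, `k`, `repeats`, `inner_k`.
#' @export
make_split_plan <- function(participants, k = 10, repeats = 5, seeds = NULL,
                            inner_k = 5, base_seed = 2024L) {
  participants <- unique(as.character(participants))
  if (length(participants) < k) {
    abort("need at least as many participants as outer folds")
  }
  seeds <- seeds %||% vapply(seq_len(repeats), function(r) {
    derive_seed(base_seed, "repeat", r)
  }, integer(1))
  stopifnot(length(seeds) == repeats)
  outer <- dplyr::bind_rows(lapply(seq_len(repeats), function(r) {
    set.seed(seeds[r])
    shuffled <- sample(participants)
    tibble::tibble(
      repeat_i = r,
      fold = rep_len(seq_len(k), length(shuffled)),
      participant_id = shuffled
    )
  }))
  structure(
    list(outer = dplyr::arrange(outer, .data$repeat_i, .data$fold),
         seeds = as.integer(seeds), k = as.integer(k),
         repeats = as.integer(repeats), inner_k = as.integer(inner_k)),
    class = "olf_split_plan"
  )
}

#' @export
print.olf_split_plan <- function(x, ...) {
  cat("<olf_split_plan> ", x$k, "-fold x ", x$repeats, " repeats over ",
      length(unique(x$outer$participant_id)), " participants (inner k = ",
      x$inner_k, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.olf_split_plan <- function(x, ...) x$outer

#' Randomly under-sample the majority class
#'
#' Keeps every minority-class row and a uniformly random subset of the
#' majority class of equal size.
#'
#' @param labels Binary labels (see [fit_model()]).
#' @param seed Integer seed.
#' @return Sorted integer indices of the retained rows.
#' @export
undersample_majority <- function(labels, seed = 1L) {
  y <- as_binary_label(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  if (n1 == n0) return(seq_along(y))
  minority <- if (n1 < n0) 1L else 0L
  keep_min <- which(y == minority)
  set.seed(seed)
  keep_maj <- sample(which(y != minority), length(keep_min))
  sort(c(keep_min, keep_maj))
}

#' Classification metrics from confusion counts
#'
#' Textbook definitions: accuracy `(tp+tn)/total`, sensitivity
#' `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision `tp/(tp+fp)`,
#' positive-class F1 `2*prec*rec/(prec+rec)`; AUC is added as the
#' Mann-Whitney rank statistic when per-trial `scores` and `labels` are
#' supplied. Zero-denominator cases return 0 and are flagged.
#'
#' @param counts Named list or vector with `tp`, `fp`, `tn`, `fn`.
#' @param scores,labels Optional per-trial classifier scores and true
#'   labels for the AUC.
#' @return A tibble with columns `metric`, `value`, `degenerate`.
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  counts <- as.list(counts)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  total <- tp + fp + tn + fn
  if (total <= 0) abort("confusion counts sum to zero")
  safe <- function(num, den) {
    if (den == 0) c(0, TRUE) else c(num / den, FALSE)
  }
  acc <- safe(tp + tn, total)
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f1 <- if (prec[1] + sens[1] == 0) c(0, TRUE) else {
    c(2 * prec[1] * sens[1] / (prec[1] + sens[1]), FALSE)
  }
  out <- tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity", "f1"),
    value = c(acc[1], sens[1], spec[1], f1[1]),
    degenerate = as.logical(c(acc[2], sens[2], spec[2], f1[2]))
  )
  if (!is.null(scores)) {
    a <- auc_rank(scores, labels)
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = "auc", value = if (is.na(a)) 0 else a, degenerate = is.na(a)
    ))
  }
  out
}

#' Participant-grouped stratified bootstrap confidence interval
#'
#' Resamples participants (never individual trials) with replacement,
#' stratified by each participant's majority class, recomputes the
#' statistic on the pooled trials of the resampled participants, and
#' returns the percentile interval.
#'
#' @param data Tibble of per-trial rows including a grouping column.
#' @param stat_fn Function `data -> scalar` computing the statistic.
#' @param group Name of the grouping (participant) column.
#' @param strata_of Optional named vector mapping each participant to a
#'   stratum; defaults to the participant's majority `label` when a
#'   `label` column exists, otherwise a single stratum.
#' @param B Bootstrap replicates (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(data, stat_fn, group = "participant_id",
                         strata_of = NULL, B = 2000, level = 0.95, seed = 1L) {
  g <- as.character(data[[group]])
  ug <- unique(g)
  if (length(ug) < 2) abort("grouped bootstrap needs at least 2 participants")
  if (is.null(strata_of)) {
    strata_of <- if ("label" %in% names(data)) {
      vapply(split(as.character(data$label), g), function(l) {
        names(sort(table(l), decreasing = TRUE))[1]
      }, "")
    } else {
      setNames(rep("all", length(ug)), ug)
    }
  }
  strata <- split(ug, strata_of[ug])
  rows_of <- split(seq_len(nrow(data)), g)
  set.seed(seed)
  stats_b <- vapply(seq_len(B), function(b) {
    picked <- unlist(lapply(strata, function(ids) {
      sample(ids, length(ids), replace = TRUE)
    }), use.names = FALSE)
    stat_fn(data[unlist(rows_of[picked], use.names = FALSE), , drop = FALSE])
  }, numeric(1))
  q <- stats::quantile(stats_b, c((1 - level) / 2, 1 - (1 - level) / 2),
                       na.rm = TRUE, names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Total TDI score and category
#'
#' Sums the threshold, discrimination and identification subdomain scores
#' of the psychophysical olfactory battery into the total TDI score
#' (range 1-36; subdomains: threshold in `[1, 12]`, discrimination and
#' identification in `[0, 12]`) and attaches the [classify_tdi()]
#' category.
#'
#' @param threshold,discrimination,identification Subdomain scores.
#' @return A tibble with the subdomain scores, `tdi` and `category`.
#' @export
tdi_total <- function(threshold, discrimination, identification) {
  if (threshold < 1 || threshold > 12) {
    abort("threshold score must lie in [1, 12]")
  }
  if (discrimination < 0 || discrimination > 12) {
    abort("discrimination score must lie in [0, 12]")
  }
  if (identification < 0 || identification > 12) {
    abort("identification score must lie in [0, 12]")
  }
  tdi <- threshold + discrimination + identification
  tibble::tibble(
    threshold = threshold, discrimination = discrimination,
    identification = identification, tdi = tdi,
    category = classify_tdi(tdi)
  )
}

#' Olfactory-function category from a TDI score
#'
#' Normosmic above 21, hyposmic in (14.5, 21], anosmic at or below 14.5.
#'
#' @param tdi Total TDI score in `[1, 36]`.
#' @return `"normosmic"`, `"hyposmic"` or `"anosmic"`.
#' @export
classify_tdi <- function(tdi) {
  if (any(tdi < 1 | tdi > 36)) abort("TDI must lie in [1, 36]")
  ifelse(tdi > 21, "normosmic", ifelse(tdi > 14.5, "hyposmic", "anosmic"))
}

#' Run a full decoding experiment for one task
#'
#' The experiment harness: preprocesses each session, restricts to the
#' task's epochs, extracts features (tabular models) or epoch tensors
#' (attention-CNN), and evaluates under the participant-grouped repeated
#' cross-validation plan. Inside every outer-training fold --- and never
#' outside it --- features are standardized, classes balanced (random
#' under-sampling for threshold and discrimination, class weights for
#' identification), and hyperparameters tuned by inner grouped k-fold CV.
#' Test-fold predictions are pooled over all folds and repeats into a
#' confusion matrix; per-metric mean and SD across folds and grouped
#' bootstrap 95% CIs are reported, at the trial level and aggregated to
#' participants by majority vote.
#'
#' @param task `"threshold"`, `"discrimination"` or `"identification"`.
#' @param cohort List of [raw_session()] objects, or a precomputed
#'   feature table (tibble) for tabular tasks.
#' @param config An [pipeline_config()].
#' @param model Model kind; defaults to the config's tabular model, or
#'   `attention_cnn` for the identification task.
#' @return An `olf_eval_report`.
#' @export
run_experiment <- function(task = c("threshold", "discrimination", "identification"),
                           cohort, config = pipeline_config(), model = NULL) {
  task <- match.arg(task)
  model <- model %||% if (task == "identification") "attention_cnn" else config$model
  balance <- if (task == "identification") "class_weight" else "undersample"
  if (model == "attention_cnn") {
    run_experiment_deep(task, cohort, config)
  } else {
    run_experiment_tabular(task, cohort, config, model, balance)
  }
}

cohort_features <- function(cohort, task, config) {
  if (is.data.frame(cohort)) {
    tab <- dplyr::filter(cohort, .data$task == !!task)
  } else {
    tab <- dplyr::bind_rows(lapply(cohort, function(s) {
      ep <- preprocess_session(s, config)
      ep$epochs <- ep$epochs[ep$meta$task == task]
      ep$meta <- ep$meta[ep$meta$task == task, ]
      extract_features(ep, config$features)
    }))
  }
  if (!nrow(tab)) abort(paste0("no epochs for task ", task))
  if (any(tab$label == "unknown")) abort("task labels are missing")
  tab
}

run_experiment_tabular <- function(task, cohort, config, model, balance) {
  tab <- cohort_features(cohort, task, config)
  plan <- make_split_plan(tab$participant_id, k = config$outer_k,
                          repeats = config$repeats, inner_k = config$inner_k,
                          base_seed = config$seed)
  spec <- model_spec(model, grid = config$grid,
                     class_weight = if (balance == "class_weight") "balanced" else "none",
                     seed = derive_seed(config$seed, "fit"))
  preds <- list()
  for (r in seq_len(plan$repeats)) {
    assign_r <- plan$outer[plan$outer$repeat_i == r, ]
    for (f in seq_len(plan$k)) {
      test_p <- assign_r$participant_id[assign_r$fold == f]
      te <- tab$participant_id %in% test_p
      train_tab <- tab[!te, ]
      std <- standardize_features(tab, which(!te))
      xs <- std$table
      tr_idx <- which(!te)
      if (balance == "undersample") {
        keep <- undersample_majority(tab$label[tr_idx],
                                     seed = derive_seed(config$seed, "us", r, f))
        tr_idx <- tr_idx[keep]
      }
      if (length(unique(tab$label[tr_idx])) < 2) next
      fit <- fit_model(spec, xs[tr_idx, ], tab$label[tr_idx],
                       groups = tab$participant_id[tr_idx],
                       inner_k = plan$inner_k, tune = config$tune)
      p <- predict_proba(fit, xs[te, ])
      preds[[length(preds) + 1]] <- tibble::tibble(
        repeat_i = r, fold = f,
        participant_id = tab$participant_id[te],
        trial_id = tab$trial_id[te], label = tab$label[te], score = p
      )
    }
  }
  build_report(task, dplyr::bind_rows(preds), plan, config, model)
}

run_experiment_deep <- function(task, cohort, config) {
  if (is.data.frame(cohort)) {
    abort("the attention_cnn consumes raw epochs; pass a session cohort")
  }
  tens <- list(); metas <- list()
  for (s in cohort) {
    ep <- preprocess_session(s, config)
    keep <- ep$meta$task == task
    ep$epochs <- ep$epochs[keep]
    ep$meta <- ep$meta[keep, ]
    tt <- epoch_tensor(ep, downsample = config$cnn$downsample)
    tens[[length(tens) + 1]] <- tt$x
    metas[[length(metas) + 1]] <- tt$meta
  }
  meta <- dplyr::bind_rows(metas)
  if (any(meta$label == "unknown")) abort("task labels are missing")
  d <- dim(tens[[1]])
  x <- array(0, c(nrow(meta), d[2], d[3], d[4]))
  at <- 0
  for (tt in tens) {
    x[at + seq_len(dim(tt)[1]), , , ] <- tt
    at <- at + dim(tt)[1]
  }
  plan <- make_split_plan(meta$participant_id, k = config$outer_k,
                          repeats = config$repeats, inner_k = config$inner_k,
                          base_seed = config$seed)
  preds <- list()
  for (r in seq_len(plan$repeats)) {
    assign_r <- plan$outer[plan$outer$repeat_i == r, ]
    for (f in seq_len(plan$k)) {
      test_p <- assign_r$participant_id[assign_r$fold == f]
      te <- meta$participant_id %in% test_p
      tr_idx <- which(!te)
      # per-channel/species z-scaling from training epochs only
      mu <- apply(x[tr_idx, , , , drop = FALSE], c(2, 3), mean)
      sg <- apply(x[tr_idx, , , , drop = FALSE], c(2, 3), stats::sd)
      sg[sg == 0] <- 1
      xs <- x
      for (ci in seq_len(d[2])) for (si in seq_len(d[3])) {
        xs[, ci, si, ] <- (x[, ci, si, ] - mu[ci, si]) / sg[ci, si]
      }
      # validation = one inner split of training participants
      tr_p <- unique(meta$participant_id[tr_idx])
      set.seed(derive_seed(config$seed, "val", r, f))
      val_p <- sample(tr_p, max(1, round(length(tr_p) / plan$inner_k)))
      fit_idx <- which(!te)
      val_idx_local <- which(meta$participant_id[fit_idx] %in% val_p)
      if (length(unique(meta$label[fit_idx])) < 2) next
      net <- build_attention_cnn(d[2], d[3], d[4], config$cnn,
                                 seed = derive_seed(config$seed, "cnn", r, f))
      net <- train_deep(net, xs[fit_idx, , , , drop = FALSE],
                        meta$label[fit_idx], val = val_idx_local,
                        seed = derive_seed(config$seed, "cnnfit", r, f))
      p <- predict_proba(net, xs[te, , , , drop = FALSE])
      preds[[length(preds) + 1]] <- tibble::tibble(
        repeat_i = r, fold = f,
        participant_id = meta$participant_id[te],
        trial_id = meta$trial_id[te], label = meta$label[te], score = p
      )
    }
  }
  build_report(task, dplyr::bind_rows(preds), plan, config, "attention_cnn")
}

confusion_from <- function(labels, scores, threshold = 0.5) {
  y <- as_binary_label(labels)
  pred <- as.integer(scores >= threshold)
  list(tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == 0),
       tn = sum(pred == 0 & y == 0), fn = sum(pred == 0 & y == 1))
}

build_report <- function(task, preds, plan, config, model) {
  if (!nrow(preds)) abort("no test predictions were produced")
  pooled <- confusion_from(preds$label, preds$score)
  pooled_metrics <- compute_metrics(pooled, preds$score, preds$label)
  # per-fold metrics; folds with a single test class drop out of the AUC mean
  fold_metrics <- dplyr::group_modify(
    dplyr::group_by(preds, .data$repeat_i, .data$fold),
    function(d, key) {
      cm <- compute_metrics(confusion_from(d$label, d$score), d$score, d$label)
      dplyr::select(cm, "metric", "value", "degenerate")
    }
  )
  fold_metrics <- dplyr::ungroup(fold_metrics)
  summary <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(fold_metrics, !.data$degenerate), .data$metric),
    mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop"
  )
  ci <- lapply(setNames(nm = summary$metric), function(m) {
    bootstrap_ci(
      preds,
      function(d) {
        cm <- compute_metrics(confusion_from(d$label, d$score), d$score, d$label)
        cm$value[cm$metric == m]
      },
      B = config$bootstrap_reps, seed = derive_seed(config$seed, "boot", m)
    )
  })
  metrics <- dplyr::mutate(
    summary,
    pooled = pooled_metrics$value[match(.data$metric, pooled_metrics$metric)],
    ci_lo = vapply(.data$metric, function(m) ci[[m]]["lo"], 1),
    ci_hi = vapply(.data$metric, function(m) ci[[m]]["hi"], 1)
  )
  # participant-level majority vote
  part <- dplyr::summarise(
    dplyr::group_by(preds, .data$participant_id),
    label = names(sort(table(.data$label), decreasing = TRUE))[1],
    score = mean(.data$score), .groups = "drop"
  )
  part_metrics <- compute_metrics(confusion_from(part$label, part$score),
                                  part$score, part$label)
  structure(
    list(
      task = task, model = model, metrics = metrics,
      confusion = pooled, predictions = preds,
      fold_metrics = fold_metrics, participant_metrics = part_metrics,
      seeds = plan$seeds, config_hash = config_hash(config),
      n_trials = length(unique(paste(preds$participant_id, preds$trial_id))),
      n_participants = length(unique(preds$participant_id))
    ),
    class = "olf_eval_report"
  )
}
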