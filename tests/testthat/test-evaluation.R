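test_that("split plans are grouped, balanced and seed-deterministic", {
  ids <- sprintf("P%03d", 1:100)
  plan <- make_split_plan(ids, k = 10, repeats = 5, base_seed = 42)
  for (r in 1:5) {
    pr <- plan$outer[plan$outer$repeat_i == r, ]
    # every participant in exactly one test fold
    expect_setequal(pr$participant_id, ids)
    expect_equal(nrow(pr), 100)
    expect_true(all(table(pr$fold) == 10))
    # train/test disjoint by construction of a partition
    for (f in 1:10) {
      te <- pr$participant_id[pr$fold == f]
      expect_length(intersect(te, setdiff(ids, te)), 0)
    }
  }
  # deterministic per seed; different seeds give different partitions
  plan2 <- make_split_plan(ids, k = 10, repeats = 5, base_seed = 42)
  expect_identical(plan$outer, plan2$outer)
  plan3 <- make_split_plan(ids, k = 10, repeats = 1, seeds = 7L)
  plan4 <- make_split_plan(ids, k = 10, repeats = 1, seeds = 8L)
  expect_false(identical(plan3$outer$participant_id, plan4$outer$participant_id))
  # uneven division: fold sizes differ by at most one
  plan5 <- make_split_plan(sprintf("Q%02d", 1:23), k = 10, repeats = 1)
  sizes <- table(plan5$outer$fold)
  expect_lte(diff(range(sizes)), 1)
  expect_error(make_split_plan(ids[1:5], k = 10), "at least as many")
  expect_s3_class(tidy(plan), "tbl_df")
})

test_that("majority under-sampling balances classes and samples uniformly", {
  y <- c(rep("correct", 80), rep("incorrect", 20))
  keep <- undersample_majority(y, seed = 1)
  expect_equal(sum(y[keep] == "correct"), 20)
  expect_equal(sum(y[keep] == "incorrect"), 20)
  expect_true(all(which(y == "incorrect") %in% keep))
  # balanced input unchanged
  yb <- rep(c("correct", "incorrect"), 10)
  expect_equal(undersample_majority(yb, seed = 1), 1:20)
  expect_error(undersample_majority(rep("correct", 5)), "both classes")
  # uniform inclusion of majority rows across seeds
  inc <- numeric(80)
  for (s in 1:500) {
    k <- undersample_majority(y, seed = s)
    inc <- inc + (1:80 %in% k)
  }
  freq <- inc / 500
  se <- sqrt(0.25 * 0.75 / 500)
  expect_true(all(abs(freq - 0.25) < 4 * se + 0.02))
})

test_that("metrics match textbook formulas on random confusion matrices", {
  set.seed(25)
  for (i in 1:1000) {
    cm <- as.list(setNames(rpois(4, 20), c("tp", "fp", "tn", "fn")))
    if (Reduce(`+`, cm) == 0) next
    got <- compute_metrics(cm)
    want <- brute_metrics(cm$tp, cm$fp, cm$tn, cm$fn)
    expect_equal(setNames(got$value, got$metric), want[got$metric])
  }
  # degenerate denominators are flagged and zero
  g <- compute_metrics(list(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_equal(g$value[g$metric == "sensitivity"], 0)
  expect_true(g$degenerate[g$metric == "sensitivity"])
  # perfect separation gives AUC 1
  a <- compute_metrics(list(tp = 2, fp = 0, tn = 2, fn = 0),
                       scores = c(0.9, 0.8, 0.1, 0.2), labels = c(1, 1, 0, 0))
  expect_equal(a$value[a$metric == "auc"], 1)
})

test_that("grouped bootstrap is deterministic, sane and covers the truth", {
  d <- tibble::tibble(participant_id = rep(sprintf("g%02d", 1:20), each = 4),
                      y = 1)
  ci <- bootstrap_ci(d, function(dd) mean(dd$y), B = 200, seed = 3)
  expect_equal(unname(ci), c(1, 1)) # identical outcomes: zero width
  set.seed(26)
  d2 <- tibble::tibble(
    participant_id = rep(sprintf("g%02d", 1:30), each = 4),
    y = rbinom(120, 1, 0.7),
    label = "correct"
  )
  ci2 <- bootstrap_ci(d2, function(dd) mean(dd$y), B = 400, seed = 4)
  ci2b <- bootstrap_ci(d2, function(dd) mean(dd$y), B = 400, seed = 4)
  expect_identical(ci2, ci2b)
  expect_lte(ci2["lo"], mean(d2$y))
  expect_gte(ci2["hi"], mean(d2$y))
  expect_error(bootstrap_ci(d2[1:4, ], mean, B = 10), "at least 2")
  # coverage near nominal over seeded replications (reduced-scale check;
  # the full-scale sweep runs in the acceptance suite)
  p <- 0.8
  cover <- 0
  for (r in 1:60) {
    set.seed(500 + r)
    dd <- tibble::tibble(
      participant_id = rep(sprintf("g%03d", 1:50), each = 4),
      y = rbinom(200, 1, p)
    )
    ci <- bootstrap_ci(dd, function(z) mean(z$y), B = 300, seed = 900 + r)
    cover <- cover + (ci["lo"] <= p && p <= ci["hi"])
  }
  expect_gte(cover / 60, 0.85)
})

test_that("TDI scoring sums subdomains and applies the category cutoffs", {
  s <- tdi_total(8, 8, 8)
  expect_equal(s$tdi, 24)
  expect_equal(s$category, "normosmic")
  # boundary handling
  expect_equal(classify_tdi(21.5), "normosmic")
  expect_equal(classify_tdi(21.0), "hyposmic")
  expect_equal(classify_tdi(14.6), "hyposmic")
  expect_equal(classify_tdi(14.5), "anosmic")
  expect_equal(classify_tdi(1), "anosmic")
  expect_equal(classify_tdi(36), "normosmic")
  # minimal admissible region works without error
  low <- tdi_total(1, 0.5, 0.5)
  expect_equal(low$tdi, 2)
  expect_equal(low$category, "anosmic")
  # the sum property over random valid triples
  set.seed(27)
  for (i in 1:50) {
    t <- runif(1, 1, 12); d <- runif(1, 0, 12); id <- runif(1, 0, 12)
    expect_equal(tdi_total(t, d, id)$tdi, t + d + id)
  }
  expect_error(tdi_total(0.5, 5, 5), "threshold")
  expect_error(tdi_total(2, 13, 5), "discrimination")
  expect_error(classify_tdi(40), "TDI")
})

test_that("run_experiment produces a coherent grouped evaluation report", {
  m <- montage_config(n_channels = 4)
  sc <- sim_config(n_participants = 8,
                   trials_per_task = c(threshold = 4, discrimination = 4,
                                       identification = 0),
                   effect_amp = 0.6, seed = 51)
  cohort <- simulate_cohort(sc, m)
  cfg <- fast_config(montage = m)
  rep <- run_experiment("threshold", cohort, cfg)
  expect_s3_class(rep, "olf_eval_report")
  expect_equal(rep$n_participants, 8)
  m1 <- rep$metrics
  expect_true(all(c("accuracy", "auc", "f1") %in% m1$metric))
  expect_true(all(m1$ci_lo <= m1$ci_hi))
  expect_true(all(m1$pooled >= 0 & m1$pooled <= 1))
  # no test participant ever appears in its own training fold: every
  # prediction row is unique per repeat
  expect_equal(nrow(rep$predictions),
               dplyr::n_distinct(rep$predictions[c("repeat_i",
                                                   "participant_id",
                                                   "trial_id")]))
  g <- glance(rep)
  expect_equal(g$tp + g$fp + g$tn + g$fn, nrow(rep$predictions))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(autoplot(rep), "ggplot")
})
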