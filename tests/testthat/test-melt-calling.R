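# build a partition table whose blue window-1 raw ratios are exactly `r`
# (blue_T1 = 1000, blue_T2 = 1000 * r); all other readings constant
table_with_blue_w1_ratio <- function(r, well_id = "ratios") {
  n <- length(r)
  fl <- matrix(1000, n, 16, dimnames = list(NULL, meltplex:::fluor_columns()))
  fl[, "blue_T2"] <- 1000 * r
  partition_table(well_id, fl)
}

# a ratio_table with prescribed normalized values in one track (bypasses
# normalization so call_partitions can be tested against exact values)
ratio_table_with_norm <- function(norm) {
  tracks <- as.vector(vapply(c("blue", "green", "yellow", "red"),
                             function(ch) paste0(ch, "_w", 1:3), character(3)))
  n <- nrow(norm)
  full <- matrix(1, n, length(tracks), dimnames = list(NULL, tracks))
  full[, colnames(norm)] <- norm
  structure(list(raw = full, norm = full,
                 preliminary_negative = full <= 1,
                 excluded = matrix(FALSE, n, length(tracks),
                                   dimnames = list(NULL, tracks)),
                 n = n, preliminary_negative_cutoff = 1, well_id = "synthetic"),
            class = "ratio_table")
}

test_that("raw ratios are upper over lower temperature per window", {
  fl <- matrix(1000, 2, 16, dimnames = list(NULL, meltplex:::fluor_columns()))
  fl[2, c("green_T1", "green_T2", "green_T3", "green_T4")] <-
    c(800, 1000, 1000, 1000)
  tab <- partition_table("w", fl)
  r <- compute_ratios(tab, default_prototype_panel())
  expect_equal(unname(r$raw[1, c("green_w1", "green_w2", "green_w3")]),
               c(1, 1, 1))
  expect_equal(unname(r$raw[2, c("green_w1", "green_w2", "green_w3")]),
               c(1.25, 1, 1))
  expect_false(any(r$excluded))
  # preliminary negative at the cutoff (<= 1.0)
  expect_true(r$preliminary_negative[1, "green_w1"])
  expect_false(r$preliminary_negative[2, "green_w1"])
})

test_that("zero denominators are excluded per track, never imputed", {
  fl <- matrix(1000, 6, 16, dimnames = list(NULL, meltplex:::fluor_columns()))
  fl[3, "blue_T1"] <- 0
  tab <- partition_table("w", fl)
  r <- compute_ratios(tab, default_prototype_panel())
  expect_true(r$excluded[3, "blue_w1"])
  expect_true(is.na(r$raw[3, "blue_w1"]))
  # only window 1 of blue is affected (T1 is not a denominator elsewhere)
  expect_false(any(r$excluded[, setdiff(colnames(r$excluded), "blue_w1")]))

  cfg <- normalization_config(window_size = 3L)
  calls <- call_partitions(normalize_ratios(r, cfg), default_prototype_panel())
  s <- calls$summary
  expect_equal(s$analyzed[s$probe_id == "P1-A"], 5L)  # blue/w1 probe
  expect_equal(s$analyzed[s$probe_id == "P1-B"], 6L)
})

test_that("a constant baseline divides out exactly", {
  tab <- table_with_blue_w1_ratio(rep(0.98, 300))
  r <- normalize_ratios(compute_ratios(tab, default_prototype_panel()),
                        normalization_config(window_size = 101L))
  expect_equal(unname(r$norm[, "blue_w1"]), rep(1, 300))
})

test_that("rolling median tracks a flat baseline with sparse positives", {
  set.seed(21)
  n <- 4000L
  raw <- rep(0.98, n)
  pos <- sort(sample(n, n * 0.01))
  raw[pos] <- 1.30
  tab <- table_with_blue_w1_ratio(raw)
  for (statistic in c("rolling_median",
                      "rolling_mean_of_preliminary_negatives")) {
    cfg <- normalization_config(window_size = 401L, statistic = statistic)
    r <- normalize_ratios(compute_ratios(tab, default_prototype_panel()), cfg)
    nr <- r$norm[, "blue_w1"]
    expect_lt(abs(mean(nr[-pos]) - 1), 0.005, label = statistic)
    expect_equal(unname(nr[pos]), rep(1.30 / 0.98, length(pos)),
                 tolerance = 0.01, label = statistic)
  }
})

test_that("rolling normalization follows linear baseline drift", {
  n <- 4000L
  drift <- seq(0.95, 1.05, length.out = n)
  tab <- table_with_blue_w1_ratio(drift)
  for (statistic in c("rolling_median",
                      "rolling_mean_of_preliminary_negatives")) {
    cfg <- normalization_config(window_size = 401L, statistic = statistic)
    r <- normalize_ratios(compute_ratios(tab, default_prototype_panel()), cfg)
    nr <- r$norm[, "blue_w1"]
    for (block in split(nr, (seq_len(n) - 1L) %/% 1000L)) {
      expect_lt(abs(mean(block) - 1), 0.005, label = statistic)
    }
  }
})

test_that("normalization guards its preconditions", {
  tab <- table_with_blue_w1_ratio(rep(1.0, 50))
  r <- compute_ratios(tab, default_prototype_panel())
  expect_error(normalize_ratios(r, normalization_config(window_size = 101L)),
               "larger than")
  expect_error(normalization_config(window_size = 100L), "odd")
})

test_that("a track with essentially no preliminary negatives is flagged saturated", {
  panel <- default_prototype_panel()
  # every partition melt-shifted in blue window 1: ratio 1.4 throughout;
  # rolling normalization would flatten this to ~1 and miss every positive
  tab <- table_with_blue_w1_ratio(rep(1.4, 200))
  r <- normalize_ratios(compute_ratios(tab, panel),
                        normalization_config(window_size = 51L))
  calls <- call_partitions(r, panel)
  s <- calls$summary
  expect_equal(s$positives[s$probe_id == "P1-A"],
               s$analyzed[s$probe_id == "P1-A"])
  q <- quantify_targets(calls, panel)
  expect_true(q$saturated[q$probe_id == "P1-A"])
})

test_that("threshold comparison is strictly greater-than", {
  panel <- default_prototype_panel()  # P1-A on blue/w1, threshold 1.075
  norm <- matrix(c(1.08, 1.075, 1.0749999, 2.5),
                 dimnames = list(NULL, "blue_w1"))
  # guard disabled: this synthetic track is all-positive by construction
  calls <- call_partitions(ratio_table_with_norm(norm), panel,
                           min_negative_fraction = 0)
  expect_equal(unname(calls$positive[, "P1-A"]), c(TRUE, FALSE, FALSE, TRUE))
  s <- calls$summary
  expect_equal(s$positives[s$probe_id == "P1-A"], 2L)
  # a track of exact ones yields zero positives for every probe
  ones <- ratio_table_with_norm(matrix(1, 10, 1,
                                       dimnames = list(NULL, "blue_w1")))
  expect_equal(call_partitions(ones, panel)$summary$positives, rep(0L, 12L))
})

test_that("calls agree with a brute-force per-element oracle", {
  panel <- default_prototype_panel()
  pt <- meltplex:::panel_probe_table(panel)
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(50:200, 1L)
    tracks <- paste0(rep(c("blue", "green", "yellow", "red"), each = 3),
                     "_w", 1:3)
    norm <- matrix(runif(n * 12, 0.9, 1.3), n, 12,
                   dimnames = list(NULL, tracks))
    calls <- call_partitions(ratio_table_with_norm(norm), panel)
    for (i in seq_len(nrow(pt))) {
      key <- paste0(pt$channel[i], "_w", pt$melt_window[i])
      oracle <- vapply(seq_len(n),
                       function(p) norm[p, key] > pt$threshold[i], TRUE)
      expect_identical(unname(calls$positive[, pt$probe_id[i]]), oracle)
    }
  }
})

test_that("raising a threshold never increases the positive count", {
  set.seed(13)
  panel <- default_prototype_panel()
  norm <- matrix(runif(500, 0.95, 1.25), dimnames = list(NULL, "blue_w1"))
  rt <- ratio_table_with_norm(norm)
  counts <- vapply(c(1.01, 1.05, 1.075, 1.1, 1.2), function(th) {
    panel$probes[[1L]]$threshold <- th
    s <- call_partitions(rt, panel, min_negative_fraction = 0)$summary
    s$positives[s$probe_id == "P1-A"]
  }, 1L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("calls are channel-independent and scale-invariant", {
  panel <- test_panel(partitions = 2048L)
  pt <- meltplex:::panel_probe_table(panel)
  copies <- setNames(rep(120, 12), pt$probe_id)
  sim <- simulate_well(simulation_config(panel, copies, seed = 5))
  base_calls <- call_partitions(
    normalize_ratios(compute_ratios(sim$table, panel), panel$normalization),
    panel)

  # scale the green channel by 3.7x: green ratios unchanged, and calls in
  # all channels identical
  tab2 <- data.table::copy(sim$table)
  for (col in paste0("green_T", 1:4)) tab2[[col]] <- tab2[[col]] * 3.7
  calls2 <- call_partitions(
    normalize_ratios(compute_ratios(tab2, panel), panel$normalization), panel)
  expect_identical(calls2$positive, base_calls$positive)

  # corrupt the yellow channel: only yellow-channel probes may change
  tab3 <- data.table::copy(sim$table)
  set.seed(6)
  for (col in paste0("yellow_T", 1:4)) {
    tab3[[col]] <- tab3[[col]] * runif(nrow(tab3), 0.5, 2)
  }
  calls3 <- call_partitions(
    normalize_ratios(compute_ratios(tab3, panel), panel$normalization), panel)
  other <- pt$probe_id[pt$channel != "yellow"]
  expect_identical(calls3$positive[, other], base_calls$positive[, other])
})

test_that("simulated blank wells stay under 0.1% false calls per probe", {
  panel <- test_panel(partitions = 4096L, window_size = 401L)
  sim <- simulate_well(simulation_config(panel, seed = 101))
  calls <- call_partitions(
    normalize_ratios(compute_ratios(sim$table, panel), panel$normalization),
    panel)
  expect_true(all(calls$summary$positives / calls$summary$analyzed <= 0.001))
  # and negative-partition normalized ratios center on 1
  r <- normalize_ratios(compute_ratios(sim$table, panel), panel$normalization)
  expect_true(all(abs(colMeans(r$norm) - 1) < 0.01))
})

test_that("well QC checks count, signal floor and denominators", {
  panel <- test_panel(partitions = 512L, window_size = 101L)
  sim <- simulate_well(simulation_config(panel, seed = 8))
  qc <- qc_well(sim$table, panel)
  expect_true(qc$pass)

  # wrong partition count
  short <- partition_table("w", as.data.frame(sim$table)[1:100,
                            meltplex:::fluor_columns()])
  qc2 <- qc_well(short, panel)
  expect_false(qc2$pass)
  expect_false(qc2$checks$pass[qc2$checks$name == "partition_count"])

  # dead reference (red) channel
  df <- as.data.frame(sim$table)[, meltplex:::fluor_columns()]
  df[, paste0("red_T", 1:4)] <- 0
  qc3 <- qc_well(partition_table("w", df), panel)
  expect_false(qc3$checks$pass[qc3$checks$name == "reference_signal"])
  expect_false(qc3$checks$pass[qc3$checks$name == "zero_denominators"])
})

test_that("ratio debug export has one row per partition per track", {
  panel <- test_panel(partitions = 128L, window_size = 21L)
  sim <- simulate_well(simulation_config(panel, seed = 2))
  r <- normalize_ratios(compute_ratios(sim$table, panel), panel$normalization)
  calls <- call_partitions(r, panel)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratio_debug(r, path, calls = calls, panel = panel)
  out <- data.table::fread(path)
  expect_equal(nrow(out), 128L * 12L)
  expect_named(out, c("partition", "channel", "window", "raw_ratio",
                      "norm_ratio", "call"))
})
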