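## Melt-window ratio calling.
##
## Each optical channel is imaged at four temperatures T1..T4; melt window w
## spans T_w -> T_{w+1}. A cleaved (target-positive) probe is quenched below
## its final-hairpin melt temperature, so its fluorescence *rises* across
## its melt window and the ratio F(T_{w+1}) / F(T_w) exceeds 1. Negative
## partitions sit near ratio 1 in every window.

#' Compute raw melt-window ratios for every partition
#'
#' For each partition, channel and melt window `w`, the raw ratio is the
#' fluorescence at the window's upper imaging temperature divided by the
#' fluorescence at its lower temperature. Partitions whose denominator falls
#' below `denominator_floor` are excluded from that track (never imputed)
#' and reported via the `excluded` matrix.
#'
#' @param table A `partition_table`.
#' @param panel A `panel_config` (defines the normalization cutoff).
#' @param denominator_floor RFU floor below which a denominator is treated
#'   as zero (default 1e-9).
#' @return An object of class `ratio_table`: list with matrices `raw`,
#'   `norm` (NULL until [normalize_ratios()]), `preliminary_negative`,
#'   `excluded` (all partitions x 12 tracks, columns `blue_w1..red_w3`), the
#'   partition count `n` and the cutoff used.
#' @export
compute_ratios <- function(table, panel, denominator_floor = 1e-9) {
  stopifnot(inherits(table, "partition_table"))
  n <- nrow(table)
  tracks <- as.vector(vapply(MDPCR_CHANNELS,
                             function(ch) track_key(ch, MDPCR_WINDOWS),
                             character(3)))
  raw <- matrix(NA_real_, n, length(tracks), dimnames = list(NULL, tracks))
  excluded <- matrix(FALSE, n, length(tracks), dimnames = list(NULL, tracks))
  for (ch in MDPCR_CHANNELS) {
    for (w in MDPCR_WINDOWS) {
      den <- table[[paste0(ch, "_T", w)]]
      num <- table[[paste0(ch, "_T", w + 1L)]]
      key <- track_key(ch, w)
      bad <- den < denominator_floor
      excluded[, key] <- bad
      raw[!bad, key] <- num[!bad] / den[!bad]
    }
  }
  if (all(excluded)) {
    stop("all partitions have zero/near-zero denominators; nothing to analyze")
  }
  cutoff <- panel$normalization$preliminary_negative_cutoff
  structure(
    list(
      raw = raw,
      norm = NULL,
      preliminary_negative = !is.na(raw) & raw <= cutoff,
      excluded = excluded,
      n = n,
      preliminary_negative_cutoff = cutoff,
      well_id = table$well[1L]
    ),
    class = "ratio_table"
  )
}

## Rolling median over a centered window of k partitions; the window
## shrinks symmetrically at the edges (half-width min(h, p-1, n-p)).
rolling_median_centered <- function(x, k) {
  n <- length(x)
  if (k > n) stop("rolling window (", k, ") larger than partition count (", n, ")")
  h <- (k - 1L) %/% 2L
  if (anyNA(x)) {
    hp <- pmin(h, seq_len(n) - 1L, n - seq_len(n))
    return(vapply(seq_len(n), function(p) {
      stats::median(x[(p - hp[p]):(p + hp[p])], na.rm = TRUE)
    }, 0.0))
  }
  out <- stats::runmed(x, k, endrule = "keep")
  edge <- seq_len(min(h, n))
  for (p in edge) {
    hp <- min(h, p - 1L, n - p)
    out[p] <- stats::median(x[(p - hp):(p + hp)])
    q <- n - p + 1L
    hq <- min(h, q - 1L, n - q)
    out[q] <- stats::median(x[(q - hq):(q + hq)])
  }
  out
}

## Rolling mean of preliminary-negative partitions over the same centered,
## edge-shrinking window. The cutoff is applied to ratios detrended by a
## first-pass rolling median, so the negative set stays well defined under
## baseline drift; the returned baseline is median * mean(detrended
## negatives). Errors if some window still contains no negatives.
rolling_mean_of_negatives <- function(x, k, cutoff) {
  n <- length(x)
  if (k > n) stop("rolling window (", k, ") larger than partition count (", n, ")")
  h <- (k - 1L) %/% 2L
  b0 <- rolling_median_centered(x, k)
  detrended <- x / b0
  use <- !is.na(detrended) & detrended <= cutoff
  xs <- ifelse(use, detrended, 0)
  cs <- c(0, cumsum(xs))
  cn <- c(0, cumsum(use))
  p <- seq_len(n)
  hp <- pmin(h, p - 1L, n - p)
  lo <- p - hp
  hi <- p + hp
  cnt <- cn[hi + 1L] - cn[lo]
  if (any(cnt == 0L)) {
    stop("rolling mean of preliminary negatives undefined: window(s) around ",
         "partition(s) ", paste(head(which(cnt == 0L) - 1L, 5L), collapse = ", "),
         " contain no preliminary-negative partitions")
  }
  b0 * (cs[hi + 1L] - cs[lo]) / cnt
}

#' Normalize melt-window ratios with a rolling baseline
#'
#' Each (channel, window) track is normalized independently: the raw ratio
#' of partition `p` is divided by a rolling baseline estimated from the
#' partitions surrounding `p` in file order, so that the average normalized
#' ratio of a negative partition is ~1 even under baseline drift. The
#' default estimator is the rolling median (robust to up to ~50% positive
#' partitions); `rolling_mean_of_preliminary_negatives` restricts the mean
#' to partitions whose raw ratio is at or below the preliminary-negative
#' cutoff.
#'
#' @param ratios A `ratio_table` from [compute_ratios()].
#' @param cfg A [normalization_config()]; defaults to the one implied by the
#'   ratio table's cutoff with the package defaults.
#' @return The `ratio_table` with `norm` filled in (and `baseline` kept for
#'   inspection).
#' @export
normalize_ratios <- function(ratios, cfg = normalization_config()) {
  stopifnot(inherits(ratios, "ratio_table"))
  raw <- ratios$raw
  norm <- raw
  baseline <- raw
  for (j in colnames(raw)) {
    x <- raw[, j]
    if (all(is.na(x))) next
    b <- switch(cfg$statistic,
      rolling_median = rolling_median_centered(x, cfg$window_size),
      rolling_mean_of_preliminary_negatives = rolling_mean_of_negatives(
        x, cfg$window_size, cfg$preliminary_negative_cutoff)
    )
    baseline[, j] <- b
    norm[, j] <- x / b
  }
  ratios$norm <- norm
  ratios$baseline <- baseline
  ratios$normalization <- cfg
  ratios
}

#' Call partitions positive or negative for each probe
#'
#' Partition `p` is positive for a probe iff the normalized ratio in the
#' probe's (channel, melt window) track is strictly greater than the probe's
#' threshold; ties are negative. Excluded partitions (zero denominator) are
#' NA and removed from the analyzed count.
#'
#' Rolling normalization assumes negative partitions dominate each window;
#' when virtually no partition of a track is preliminarily negative (raw
#' ratio at or below the cutoff), the baseline estimate is itself built from
#' positives and normalized ratios collapse towards 1. Such a track is a
#' saturated well in disguise, so if its preliminary-negative fraction falls
#' below `min_negative_fraction` every analyzable partition is called
#' positive, which propagates a `saturated` flag through quantification
#' instead of silently reporting zero copies.
#'
#' @param ratios A normalized `ratio_table`.
#' @param panel A `panel_config`.
#' @param min_negative_fraction Minimum fraction of preliminary-negative
#'   partitions for a track to be considered quantifiable (default 0.05).
#' @return An object of class `call_table`: list with logical matrix
#'   `positive` (partitions x probes, NA = excluded) and data.frame
#'   `summary` (`probe_id`, `positives`, `analyzed`).
#' @export
call_partitions <- function(ratios, panel, min_negative_fraction = 0.05) {
  stopifnot(inherits(ratios, "ratio_table"))
  if (is.null(ratios$norm)) {
    stop("ratios are not normalized; run normalize_ratios() first")
  }
  pt <- panel_probe_table(panel)
  keys <- track_key(pt$channel, pt$melt_window)
  miss <- setdiff(keys, colnames(ratios$norm))
  if (length(miss)) {
    stop("probe references undefined (channel, window) track(s): ",
         paste(miss, collapse = ", "))
  }
  analyzable <- !ratios$excluded
  neg_frac <- colSums(ratios$preliminary_negative) /
    pmax(1L, colSums(analyzable))
  pos <- matrix(NA, ratios$n, nrow(pt),
                dimnames = list(NULL, pt$probe_id))
  for (i in seq_len(nrow(pt))) {
    if (neg_frac[keys[i]] < min_negative_fraction) {
      # saturated track: baseline is dominated by positives, normalized
      # ratios are meaningless; call everything positive to flag saturation
      pos[analyzable[, keys[i]], i] <- TRUE
    } else {
      pos[, i] <- ratios$norm[, keys[i]] > pt$threshold[i]
    }
  }
  summary <- data.frame(
    probe_id = pt$probe_id,
    positives = as.integer(colSums(pos, na.rm = TRUE)),
    analyzed = as.integer(colSums(!is.na(pos))),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(positive = pos, summary = summary, well_id = ratios$well_id),
            class = "call_table")
}

#' @export
print.call_table <- function(x, ...) {
  cat("mdPCR call table, well", x$well_id, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Well-level quality control
#'
#' Runs the per-well data-quality checks: expected partition count, finite
#' fluorescence everywhere, adequate signal in the reference channel (the
#' red/AP593 channel by default), and a bounded fraction of zero-denominator
#' partitions.
#'
#' @param table A `partition_table`.
#' @param panel A `panel_config`.
#' @param reference_channel Channel used for the signal-floor check.
#' @param reference_floor Minimum acceptable median T1 fluorescence (RFU) in
#'   the reference channel.
#' @param max_excluded_fraction Maximum tolerated fraction of partitions
#'   with a zero/near-zero denominator in any track (default 0.01).
#' @param denominator_floor RFU floor, as in [compute_ratios()].
#' @return An object of class `qc_report` with fields `well_id`, `pass`
#'   and a data.frame `checks` (`name`, `pass`, `message`).
#' @export
qc_well <- function(table, panel, reference_channel = "red",
                    reference_floor = 50, max_excluded_fraction = 0.01,
                    denominator_floor = 1e-9) {
  stopifnot(inherits(table, "partition_table"))
  checks <- list()
  add <- function(name, pass, message) {
    checks[[length(checks) + 1L]] <<- data.frame(
      name = name, pass = pass, message = message, stringsAsFactors = FALSE)
  }
  n <- nrow(table)
  add("partition_count", n == panel$partitions_per_well,
      sprintf("%d partitions (expected %d)", n, panel$partitions_per_well))
  vals <- as.matrix(table[, fluor_columns(), with = FALSE])
  add("finite_fluorescence", all(is.finite(vals)),
      "all fluorescence values finite")
  ref_med <- stats::median(table[[paste0(reference_channel, "_T1")]])
  add("reference_signal", ref_med > reference_floor,
      sprintf("%s channel median T1 fluorescence %.1f RFU (floor %.1f)",
              reference_channel, ref_med, reference_floor))
  den_cols <- as.vector(vapply(MDPCR_CHANNELS,
                               function(ch) paste0(ch, "_T", 1:3), character(3)))
  frac_bad <- max(colMeans(as.matrix(table[, den_cols, with = FALSE]) <
                             denominator_floor))
  add("zero_denominators", frac_bad < max_excluded_fraction,
      sprintf("worst-track zero-denominator fraction %.4f (max %.4f)",
              frac_bad, max_excluded_fraction))
  checks <- do.call(rbind, checks)
  structure(
    list(well_id = table$well[1L], pass = all(checks$pass), checks = checks,
         reference_channel = reference_channel),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC well %s: %s\n", x$well_id, if (x$pass) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%s] %-22s %s\n",
                if (x$checks$pass[i]) "ok" else "FAIL",
                x$checks$name[i], x$checks$message[i]))
  }
  invisible(x)
}

#' Export a per-partition ratio/call debug table
#'
#' Long-format CSV (`partition, channel, window, raw_ratio, norm_ratio,
#' call`) suitable for scatter plots of normalized ratios by track.
#'
#' @param ratios A normalized `ratio_table`.
#' @param calls A `call_table` (optional; calls column left NA if absent).
#' @param panel A `panel_config` (needed to map probes to tracks when
#'   `calls` is given).
#' @param path Output CSV path.
#' @export
write_ratio_debug <- function(ratios, path, calls = NULL, panel = NULL) {
  stopifnot(inherits(ratios, "ratio_table"))
  tracks <- colnames(ratios$raw)
  parts <- strsplit(tracks, "_w", fixed = TRUE)
  out <- data.table::rbindlist(lapply(seq_along(tracks), function(j) {
    call_col <- NA
    if (!is.null(calls) && !is.null(panel)) {
      pt <- panel_probe_table(panel)
      hit <- which(track_key(pt$channel, pt$melt_window) == tracks[j])
      if (length(hit) == 1L) call_col <- calls$positive[, pt$probe_id[hit]]
    }
    data.table::data.table(
      partition = seq_len(ratios$n) - 1L,
      channel = parts[[j]][1L],
      window = as.integer(parts[[j]][2L]),
      raw_ratio = ratios$raw[, j],
      norm_ratio = if (is.null(ratios$norm)) NA_real_ else ratios$norm[, j],
      call = call_col
    )
  }))
  data.table::fwrite(out, path, sep = ",", quote = FALSE, eol = "\n", na = "NA")
  invisible(path)
}
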