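## Poisson absolute quantification and detection-limit statistics.
##
## With N analyzed partitions of which m are negative for a target, the mean
## occupancy per partition is lambda-hat = -ln(m/N), and copies per assay
## input scale by the analyzed partition count over the loaded fraction.

#' Estimate the Poisson mean occupancy from partition counts
#'
#' `lambda_hat = -ln(m/N)` with `m = analyzed - positives` negative
#' partitions. The 95% CI uses the delta-method standard error on the
#' negative fraction, `SE = sqrt((N - m) / (N * m))`, with a 1.96
#' multiplier, truncated at 0. With zero positives the point estimate is 0
#' and the upper bound is the one-sided 95% "rule of three" bound `3/N`.
#' A saturated well (no negative partitions) cannot be quantified and is an
#' error: the sample must be re-diluted.
#'
#' @param positives Number of positive partitions.
#' @param analyzed Number of analyzed partitions (>= 1).
#' @return List with `lambda_hat` and `ci95 = c(low, high)` in copies per
#'   partition.
#' @export
estimate_lambda <- function(positives, analyzed) {
  positives <- as.numeric(positives)
  analyzed <- as.numeric(analyzed)
  stopifnot(length(positives) == 1L, length(analyzed) == 1L)
  if (is.na(positives) || is.na(analyzed) || analyzed < 1 ||
      positives < 0 || positives > analyzed) {
    stop("require 0 <= positives <= analyzed and analyzed >= 1 (got ",
         positives, "/", analyzed, ")")
  }
  if (positives == 0) {
    return(list(lambda_hat = 0, ci95 = c(0, 3 / analyzed)))
  }
  if (positives == analyzed) {
    stop("saturated well: all ", analyzed, " partitions positive; ",
         "copy number is inestimable - re-dilute the sample")
  }
  m <- analyzed - positives
  lambda <- -log(m / analyzed)
  se <- sqrt((analyzed - m) / (analyzed * m))
  list(lambda_hat = lambda,
       ci95 = c(max(0, lambda - 1.96 * se), lambda + 1.96 * se))
}

#' Quantify every probe target from a call table
#'
#' Scales the per-partition Poisson estimate to copies per assay input:
#' `total_copies = lambda_hat * analyzed / loaded_fraction`, and to
#' concentration `copies_per_uL = total_copies / reaction_volume_uL`.
#' Confidence bounds are scaled identically. Saturated probes are flagged
#' (`saturated = TRUE`, copies NA); the remaining probes are still reported.
#'
#' @param calls A `call_table` from [call_partitions()].
#' @param panel A `panel_config`.
#' @return A data.frame of class `target_quantification`, one row per probe:
#'   `probe_id`, `positives`, `analyzed`, `lambda_hat`, `lambda_ci95_low/high`,
#'   `copies_per_uL`, `total_copies`, `total_ci95_low/high`, `saturated`.
#' @export
quantify_targets <- function(calls, panel) {
  stopifnot(inherits(calls, "call_table"))
  s <- calls$summary
  rows <- lapply(seq_len(nrow(s)), function(i) {
    out <- data.frame(
      probe_id = s$probe_id[i], positives = s$positives[i],
      analyzed = s$analyzed[i],
      lambda_hat = NA_real_, lambda_ci95_low = NA_real_,
      lambda_ci95_high = NA_real_, copies_per_uL = NA_real_,
      total_copies = NA_real_, total_ci95_low = NA_real_,
      total_ci95_high = NA_real_, saturated = FALSE,
      stringsAsFactors = FALSE
    )
    if (s$positives[i] == s$analyzed[i] && s$positives[i] > 0) {
      out$saturated <- TRUE
      return(out)
    }
    est <- estimate_lambda(s$positives[i], s$analyzed[i])
    scale <- s$analyzed[i] / panel$loaded_fraction
    out$lambda_hat <- est$lambda_hat
    out$lambda_ci95_low <- est$ci95[1L]
    out$lambda_ci95_high <- est$ci95[2L]
    out$total_copies <- est$lambda_hat * scale
    out$total_ci95_low <- est$ci95[1L] * scale
    out$total_ci95_high <- est$ci95[2L] * scale
    out$copies_per_uL <- out$total_copies / panel$reaction_volume_uL
    out
  })
  structure(do.call(rbind, rows),
            class = c("target_quantification", "data.frame"))
}

#' Per-locus allele fractions
#'
#' For each biallelic locus with quantified copies `c_A` and `c_B`,
#' `AF_A = c_A / (c_A + c_B)` and the minor fraction is `min(AF_A, 1 - AF_A)`.
#'
#' @param quants A `target_quantification` data.frame.
#' @param panel A `panel_config` (maps probes to loci/alleles).
#' @return A data.frame, one row per locus: `locus_id`, `copies_A`,
#'   `copies_B`, `allele_fraction_A`, `minor_fraction`. Loci with zero total
#'   copies or a saturated allele get NA fractions with a warning.
#' @export
allele_fractions <- function(quants, panel) {
  pt <- panel_probe_table(panel)
  qmap <- merge(pt[, c("probe_id", "locus_id", "allele")],
                as.data.frame(quants)[, c("probe_id", "total_copies", "saturated")],
                by = "probe_id")
  loci <- sort(unique(qmap$locus_id))
  rows <- lapply(loci, function(loc) {
    sub <- qmap[qmap$locus_id == loc, ]
    cA <- sub$total_copies[sub$allele == "A"]
    cB <- sub$total_copies[sub$allele == "B"]
    cA <- if (length(cA)) cA else NA_real_
    cB <- if (length(cB)) cB else NA_real_
    af <- NA_real_
    if (any(sub$saturated) || is.na(cA) || is.na(cB)) {
      warning("locus ", loc, ": allele fraction undefined (saturated or ",
              "missing allele)", call. = FALSE)
    } else if (cA + cB <= 0) {
      warning("locus ", loc, ": allele fraction undefined (zero total copies)",
              call. = FALSE)
    } else {
      af <- cA / (cA + cB)
    }
    data.frame(locus_id = loc, copies_A = cA, copies_B = cB,
               allele_fraction_A = af,
               minor_fraction = ifelse(is.na(af), NA_real_, pmin(af, 1 - af)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## round half away from zero (Table-style presentation of frequencies;
## base round() rounds half to even)
round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Detection-limit frequency
#'
#' Expresses a partition-scale detection limit (LoB or LoD, in partitions)
#' as a percentage of the total copies measured for the sample:
#' `partitions / total_copies * 100`.
#'
#' @param partitions LoB or LoD in partitions.
#' @param total_copies Total copies per sample (denominator).
#' @param rounded Round half-away-from-zero to 2 decimals (presentation
#'   convention) when TRUE; full precision otherwise.
#' @return Frequency in percent.
#' @export
detection_frequency_pct <- function(partitions, total_copies, rounded = TRUE) {
  stopifnot(all(partitions >= 0), all(total_copies > 0))
  f <- partitions / total_copies * 100
  if (rounded) round_half_away(f, 2L) else f
}

#' Limit of blank from replicate false-positive counts
#'
#' `LoB(partitions) = mean(fp) + 1.645 * sd(fp)` with the n-1 sample SD;
#' the 1.645 factor is the one-sided 95th percentile of the normal
#' distribution. The LoB frequency is the LoB expressed as a percentage of
#' the total copies measured for the sample,
#' `LoB_freq = LoB / total_copies * 100`, reported both at full precision
#' and rounded half-away-from-zero to two decimals.
#'
#' @param fp_counts Numeric vector of false-positive partition counts, one
#'   per blank replicate (>= 2 replicates). Non-integer counts are allowed
#'   (normalization can yield fractional effective partitions) but warned.
#' @param total_copies Denominator: measured total copies per sample.
#' @param probe_id Optional probe label carried through.
#' @return A list of class `detection_limits` with fields `probe_id`,
#'   `n_replicates`, `fp_mean`, `fp_sd`, `lob_partitions`,
#'   `lob_frequency_pct`, `lob_frequency_pct_rounded`,
#'   `total_copies_denominator` (LoD fields NA until
#'   [limit_of_detection()]).
#' @export
limit_of_blank <- function(fp_counts, total_copies, probe_id = NA_character_) {
  fp_counts <- as.numeric(fp_counts)
  if (length(fp_counts) < 2L) {
    stop("limit of blank requires >= 2 blank replicates, got ",
         length(fp_counts))
  }
  if (any(is.na(fp_counts)) || any(fp_counts < 0)) {
    stop("false-positive counts must be non-negative and non-missing")
  }
  if (any(fp_counts != round(fp_counts))) {
    warning("non-integer false-positive counts supplied", call. = FALSE)
  }
  stopifnot(is.numeric(total_copies), total_copies > 0)
  m <- mean(fp_counts)
  s <- stats::sd(fp_counts)
  lob <- m + 1.645 * s
  structure(
    list(
      probe_id = probe_id,
      n_replicates = length(fp_counts),
      fp_mean = m,
      fp_sd = s,
      lob_partitions = lob,
      lob_frequency_pct = lob / total_copies * 100,
      lob_frequency_pct_rounded = round_half_away(lob / total_copies * 100, 2L),
      lod_partitions = NA_real_,
      lod_frequency_pct = NA_real_,
      lod_frequency_pct_rounded = NA_real_,
      total_copies_denominator = as.numeric(total_copies)
    ),
    class = "detection_limits"
  )
}

#' Analytical limit of detection from a limit of blank
#'
#' `LoD(partitions) = LoB(partitions) + 1.645 * sd(fp)`, i.e. the LoB plus
#' the same one-sided 95th-percentile allowance for the spread of
#' low-concentration results; frequency as in [limit_of_blank()].
#'
#' @param lob A `detection_limits` object with LoB fields populated.
#' @return The object with `lod_partitions`, `lod_frequency_pct` and
#'   `lod_frequency_pct_rounded` filled in.
#' @export
limit_of_detection <- function(lob) {
  stopifnot(inherits(lob, "detection_limits"))
  if (is.na(lob$lob_partitions)) stop("LoB fields not populated")
  lob$lod_partitions <- lob$lob_partitions + 1.645 * lob$fp_sd
  lob$lod_frequency_pct <- lob$lod_partitions / lob$total_copies_denominator * 100
  lob$lod_frequency_pct_rounded <- round_half_away(lob$lod_frequency_pct, 2L)
  lob
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf(
    "detection limits%s (n = %d blanks, denominator %s copies)\n",
    if (is.na(x$probe_id)) "" else paste0(" for ", x$probe_id),
    x$n_replicates, format(x$total_copies_denominator)))
  cat(sprintf("  LoB: %.2f partitions (%.2f%%)\n",
              x$lob_partitions, x$lob_frequency_pct_rounded))
  if (!is.na(x$lod_partitions)) {
    cat(sprintf("  LoD: %.2f partitions (%.2f%%)\n",
                x$lod_partitions, x$lod_frequency_pct_rounded))
  }
  invisible(x)
}

#' Replicate summary statistics
#'
#' Mean, n-1 sample SD, coefficient of variation and the normal-theory 95%
#' CI of the mean (`mean +/- 1.96 * sd / sqrt(n)`).
#'
#' @param values Numeric vector, length >= 2.
#' @return List with `mean`, `sd`, `cv_pct`, `ci95 = c(low, high)`, `n`.
#' @export
replicate_stats <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("replicate statistics require n >= 2, got ", n)
  if (anyNA(values)) stop("missing values in replicates")
  m <- mean(values)
  s <- stats::sd(values)
  if (m == 0) stop("CV undefined for mean 0")
  list(mean = m, sd = s, cv_pct = s / m * 100,
       ci95 = c(m - 1.96 * s / sqrt(n), m + 1.96 * s / sqrt(n)), n = n)
}

#' Inter-run concordance on the log10 copy scale
#'
#' Pearson correlation and ordinary-least-squares fit of `log10(y)` on
#' `log10(x)` for paired copy-number measurements (e.g., two laboratory
#' sites).
#'
#' @param x,y Positive copy numbers, equal length >= 3.
#' @return List of class `concordance_result`: `n`, `pearson_r`,
#'   `r_squared`, `slope`, `intercept`.
#' @export
concordance <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("concordance requires n >= 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0)) {
    stop("copy numbers must be positive and finite (log10 scale)")
  }
  lx <- log10(x)
  ly <- log10(y)
  if (stats::var(lx) == 0) stop("zero variance in x on the log10 scale")
  fit <- stats::lm.fit(cbind(1, lx), ly)
  r <- stats::cor(lx, ly)
  structure(
    list(n = length(x), pearson_r = r, r_squared = r^2,
         slope = unname(fit$coefficients[2L]),
         intercept = unname(fit$coefficients[1L])),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "concordance (n = %d, log10 copies): r = %.4f, r^2 = %.4f, slope = %.4f, intercept = %.4f\n",
    x$n, x$pearson_r, x$r_squared, x$slope, x$intercept))
  invisible(x)
}

#' Run the full calling and quantification pipeline on one well
#'
#' Convenience wrapper: QC -> ratios -> normalization -> calls -> Poisson
#' quantification -> allele fractions.
#'
#' @param table A `partition_table`.
#' @param panel A `panel_config`.
#' @param qc_must_pass Abort if QC fails (default TRUE).
#' @return List with `qc`, `ratios`, `calls`, `quants`, `loci`.
#' @export
quantify_well <- function(table, panel, qc_must_pass = TRUE) {
  qc <- qc_well(table, panel)
  if (qc_must_pass && !qc$pass) {
    stop("well ", qc$well_id, " failed QC: ",
         paste(qc$checks$name[!qc$checks$pass], collapse = ", "))
  }
  ratios <- compute_ratios(table, panel)
  ratios <- normalize_ratios(ratios, panel$normalization)
  calls <- call_partitions(ratios, panel)
  quants <- quantify_targets(calls, panel)
  loci <- suppressWarnings(allele_fractions(quants, panel))
  list(qc = qc, ratios = ratios, calls = calls, quants = quants, loci = loci)
}
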