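#' @importFrom stats median rnorm rpois rbinom runif sd qnorm
#' @importFrom utils head tail packageVersion
NULL

## Optical channels of the platform, in imaging order.
MDPCR_CHANNELS <- c("blue", "green", "yellow", "red")

## Melt windows: window w spans imaging temperatures T_w -> T_{w+1}.
MDPCR_WINDOWS <- 1:3

#' Define a single melt-based hairpin probe
#'
#' A probe is identified by its fluorophore channel and the melt window in
#' which its final (extended, quenched) hairpin denatures. The threshold is
#' the normalized melt-window ratio strictly above which a partition is
#' called positive for the probe. `tm_final_hairpin` and `amplitude` are
#' used only by the simulator.
#'
#' @param probe_id Probe label, e.g. `"P1-A"`.
#' @param locus_id Locus label, e.g. `"P1"`.
#' @param allele Allele label, `"A"` or `"B"`.
#' @param channel Optical channel: one of `"blue"`, `"green"`, `"yellow"`,
#'   `"red"`.
#' @param melt_window Integer in 1..3; window `w` spans imaging temperatures
#'   `T_w` to `T_{w+1}`.
#' @param threshold Positivity threshold on the normalized ratio (> 1).
#' @param tm_final_hairpin Final-hairpin melt temperature in deg C
#'   (simulator only); must lie strictly inside the probe's melt window.
#' @param amplitude Relative fluorescence amplitude of the probe
#'   (simulator only).
#' @return A list of class `probe_spec`.
#' @export
probe_spec <- function(probe_id, locus_id, allele, channel, melt_window,
                       threshold, tm_final_hairpin = NA_real_,
                       amplitude = 1) {
  stopifnot(is.character(probe_id), length(probe_id) == 1L)
  channel <- match.arg(channel, MDPCR_CHANNELS)
  melt_window <- as.integer(melt_window)
  p <- list(
    probe_id = probe_id,
    locus_id = as.character(locus_id),
    allele = as.character(allele),
    channel = channel,
    melt_window = melt_window,
    threshold = as.numeric(threshold),
    tm_final_hairpin = as.numeric(tm_final_hairpin),
    amplitude = as.numeric(amplitude)
  )
  class(p) <- "probe_spec"
  p
}

#' Rolling-window normalization settings
#'
#' @param window_size Odd integer >= 3: number of partitions in the centered
#'   rolling window (shrinks symmetrically at the edges).
#' @param statistic Baseline estimator: `"rolling_median"` (default; robust
#'   to up to ~50% positive partitions) or
#'   `"rolling_mean_of_preliminary_negatives"` (the literal construction:
#'   mean of partitions whose raw ratio is at or below the cutoff).
#' @param preliminary_negative_cutoff Raw-ratio cutoff at or below which a
#'   partition is preliminarily assessed as target negative (default 1.0).
#' @return A list of class `normalization_config`.
#' @export
normalization_config <- function(window_size = 1001L,
                                 statistic = c("rolling_median",
                                               "rolling_mean_of_preliminary_negatives"),
                                 preliminary_negative_cutoff = 1.0) {
  statistic <- match.arg(statistic)
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 3L || window_size %% 2L == 0L) {
    stop("window_size must be an odd integer >= 3, got ", window_size)
  }
  structure(
    list(window_size = window_size, statistic = statistic,
         preliminary_negative_cutoff = as.numeric(preliminary_negative_cutoff)),
    class = "normalization_config"
  )
}

#' Assemble a panel/platform configuration
#'
#' @param temperatures Strictly increasing vector of the 4 imaging
#'   temperatures in deg C.
#' @param probes List of [probe_spec()] objects.
#' @param partitions_per_well Number of partitions per well.
#' @param loaded_fraction Fraction of the reaction volume that is digitized
#'   into partitions (0, 1].
#' @param reaction_volume_uL Reaction volume in microlitres.
#' @param dna_input_uL DNA input volume in microlitres.
#' @param normalization A [normalization_config()].
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(temperatures, probes, partitions_per_well,
                         loaded_fraction = 0.9, reaction_volume_uL = 10,
                         dna_input_uL = 4,
                         normalization = normalization_config()) {
  panel <- structure(
    list(
      temperatures = as.numeric(temperatures),
      probes = probes,
      partitions_per_well = as.integer(partitions_per_well),
      loaded_fraction = as.numeric(loaded_fraction),
      reaction_volume_uL = as.numeric(reaction_volume_uL),
      dna_input_uL = as.numeric(dna_input_uL),
      normalization = normalization
    ),
    class = "panel_config"
  )
  v <- validate_panel(panel)
  if (nrow(v) > 0L) {
    stop("invalid panel configuration:\n",
         paste0("  - [", v$field, "] ", v$message, collapse = "\n"))
  }
  panel
}

#' The default 12-probe prototype panel
#'
#' Six biallelic indel loci (P1..P6), two allele-specific probes each,
#' three probes per optical channel across four channels. Positivity
#' thresholds are the experimentally optimized values published for the
#' prototype assay. The probe-to-(channel, window) assignment is a
#' deterministic round-robin stand-in (the true identities are not public);
#' calling results depend only on thresholds and window membership.
#' Simulator melt temperatures default to the midpoint of each window.
#'
#' @return A `panel_config` with 12 probes, imaging temperatures
#'   60/72/81/92 deg C, 20,480 partitions per well and loaded fraction 0.9.
#' @export
default_prototype_panel <- function() {
  thresholds <- c(
    "P1-A" = 1.075, "P1-B" = 1.1,  "P2-A" = 1.06,  "P2-B" = 1.11,
    "P3-A" = 1.08,  "P3-B" = 1.12, "P4-A" = 1.07,  "P4-B" = 1.1,
    "P5-A" = 1.085, "P5-B" = 1.1,  "P6-A" = 1.08,  "P6-B" = 1.075
  )
  temps <- c(60, 72, 81, 92)
  ## window midpoints: (60+72)/2, (72+81)/2, (81+92)/2
  tm_mid <- (temps[-4] + temps[-1]) / 2
  ids <- names(thresholds)
  probes <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    channel <- MDPCR_CHANNELS[((i - 1L) %/% 3L) + 1L]
    window <- ((i - 1L) %% 3L) + 1L
    parts <- strsplit(ids[i], "-", fixed = TRUE)[[1L]]
    probes[[i]] <- probe_spec(
      probe_id = ids[i], locus_id = parts[1L], allele = parts[2L],
      channel = channel, melt_window = window,
      threshold = unname(thresholds[i]),
      tm_final_hairpin = tm_mid[window], amplitude = 1
    )
  }
  panel_config(
    temperatures = temps, probes = probes,
    partitions_per_well = 20480L, loaded_fraction = 0.9,
    reaction_volume_uL = 10, dna_input_uL = 4,
    normalization = normalization_config()
  )
}

#' Validate a panel configuration
#'
#' Checks every structural invariant of the panel and its probes. Violations
#' are returned, not raised, so the function can be used both as a gate and
#' as a linter.
#'
#' @param panel A `panel_config` (possibly invalid).
#' @return A data.frame with columns `field` and `message`; zero rows iff
#'   the panel is valid.
#' @export
validate_panel <- function(panel) {
  bad <- list()
  note <- function(field, message) {
    bad[[length(bad) + 1L]] <<- data.frame(field = field, message = message,
                                           stringsAsFactors = FALSE)
  }
  temps <- panel$temperatures
  if (length(temps) != 4L || anyNA(temps)) {
    note("temperatures", "exactly 4 finite imaging temperatures required")
  } else if (any(diff(temps) <= 0)) {
    note("temperatures", "imaging temperatures must be strictly increasing")
  }
  if (is.na(panel$partitions_per_well) || panel$partitions_per_well < 1L) {
    note("partitions_per_well", "must be a positive integer")
  }
  if (is.na(panel$loaded_fraction) || panel$loaded_fraction <= 0 ||
      panel$loaded_fraction > 1) {
    note("loaded_fraction", "must be in (0, 1]")
  }
  if (is.na(panel$reaction_volume_uL) || panel$reaction_volume_uL <= 0) {
    note("reaction_volume_uL", "must be positive")
  }
  probes <- panel$probes
  if (length(probes) > length(MDPCR_CHANNELS) * length(MDPCR_WINDOWS)) {
    note("probes", sprintf(
      "panel capacity exceeded: %d probes > %d channels x %d windows",
      length(probes), length(MDPCR_CHANNELS), length(MDPCR_WINDOWS)))
  }
  seen <- character(0)
  for (p in probes) {
    pid <- p$probe_id
    if (!p$channel %in% MDPCR_CHANNELS) {
      note(paste0(pid, ".channel"), paste0("unknown channel '", p$channel, "'"))
    }
    if (!p$melt_window %in% MDPCR_WINDOWS) {
      note(paste0(pid, ".melt_window"), "melt_window must be 1, 2 or 3")
    }
    if (is.na(p$threshold) || p$threshold <= 1.0) {
      note(paste0(pid, ".threshold"),
           sprintf("threshold must be > 1.0, got %s", format(p$threshold)))
    }
    key <- paste0(p$channel, "/w", p$melt_window)
    if (key %in% seen) {
      note(paste0(pid, ".channel_window"),
           paste0("duplicate assignment to (", key, ")"))
    }
    seen <- c(seen, key)
    if (!is.na(p$tm_final_hairpin) && length(temps) == 4L &&
        p$melt_window %in% MDPCR_WINDOWS) {
      lo <- temps[p$melt_window]
      hi <- temps[p$melt_window + 1L]
      if (!is.na(lo) && !is.na(hi) &&
          (p$tm_final_hairpin <= lo || p$tm_final_hairpin >= hi)) {
        note(paste0(pid, ".tm_final_hairpin"), sprintf(
          "Tm %.1f outside melt window %d (%.1f, %.1f)",
          p$tm_final_hairpin, p$melt_window, lo, hi))
      }
    }
  }
  ## biallelic loci: exactly two alleles per declared locus
  loci <- split(vapply(probes, `[[`, "", "allele"),
                vapply(probes, `[[`, "", "locus_id"))
  for (loc in names(loci)) {
    al <- loci[[loc]]
    if (length(al) == 2L && length(unique(al)) != 2L) {
      note(paste0(loc, ".alleles"),
           "biallelic locus must carry two distinct alleles")
    }
    if (length(al) > 2L) {
      note(paste0(loc, ".alleles"),
           sprintf("locus has %d probes; at most 2 supported", length(al)))
    }
  }
  if (length(bad) == 0L) {
    return(data.frame(field = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}

panel_to_list <- function(panel) {
  list(
    temperatures = panel$temperatures,
    partitions_per_well = panel$partitions_per_well,
    loaded_fraction = panel$loaded_fraction,
    reaction_volume_uL = panel$reaction_volume_uL,
    dna_input_uL = panel$dna_input_uL,
    normalization = unclass(panel$normalization),
    probes = lapply(panel$probes, function(p) unclass(p))
  )
}

#' Save a panel configuration to YAML or JSON
#'
#' @param panel A valid `panel_config`.
#' @param path Output file path.
#' @param format `"auto"` (from extension), `"yaml"` or `"json"`.
#' @export
save_panel_config <- function(panel, path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  x <- panel_to_list(panel)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Load and validate a panel configuration
#'
#' Accepts YAML (primary) or JSON with top-level keys `temperatures`,
#' `partitions_per_well`, `loaded_fraction`, `reaction_volume_uL`,
#' `dna_input_uL`, `normalization{window_size,statistic,
#' preliminary_negative_cutoff}` and `probes[]`.
#'
#' @param path Config file path.
#' @param format `"auto"` (from extension), `"yaml"` or `"json"`.
#' @return A validated `panel_config`.
#' @export
load_panel_config <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("panel config file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  x <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  required <- c("temperatures", "partitions_per_well", "probes")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("panel config missing required key(s): ", paste(miss, collapse = ", "))
  }
  norm <- x$normalization
  normalization <- if (is.null(norm)) normalization_config() else {
    normalization_config(
      window_size = norm$window_size %||% 1001L,
      statistic = norm$statistic %||% "rolling_median",
      preliminary_negative_cutoff = norm$preliminary_negative_cutoff %||% 1.0
    )
  }
  probes <- lapply(x$probes, function(p) {
    need <- c("probe_id", "locus_id", "allele", "channel", "melt_window",
              "threshold")
    pm <- setdiff(need, names(p))
    if (length(pm)) {
      stop("probe entry missing field(s): ", paste(pm, collapse = ", "))
    }
    probe_spec(
      probe_id = p$probe_id, locus_id = p$locus_id, allele = p$allele,
      channel = p$channel, melt_window = p$melt_window,
      threshold = p$threshold,
      tm_final_hairpin = p$tm_final_hairpin %||% NA_real_,
      amplitude = p$amplitude %||% 1
    )
  })
  panel_config(
    temperatures = x$temperatures, probes = probes,
    partitions_per_well = x$partitions_per_well,
    loaded_fraction = x$loaded_fraction %||% 0.9,
    reaction_volume_uL = x$reaction_volume_uL %||% 10,
    dna_input_uL = x$dna_input_uL %||% 4,
    normalization = normalization
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf(
    "mdPCR panel: %d probes, %d partitions/well, imaging at %s degC\n",
    length(x$probes), x$partitions_per_well,
    paste(x$temperatures, collapse = "/")))
  for (p in x$probes) {
    cat(sprintf("  %-6s locus %-3s allele %s  %s/w%d  threshold > %s\n",
                p$probe_id, p$locus_id, p$allele, p$channel, p$melt_window,
                format(p$threshold)))
  }
  invisible(x)
}

## track key for a (channel, window) pair, used throughout the pipeline
track_key <- function(channel, window) paste0(channel, "_w", window)

## probe metadata as a data.frame (one row per probe, track attached)
panel_probe_table <- function(panel) {
  data.frame(
    probe_id = vapply(panel$probes, `[[`, "", "probe_id"),
    locus_id = vapply(panel$probes, `[[`, "", "locus_id"),
    allele = vapply(panel$probes, `[[`, "", "allele"),
    channel = vapply(panel$probes, `[[`, "", "channel"),
    melt_window = vapply(panel$probes, function(p) as.integer(p$melt_window), 1L),
    threshold = vapply(panel$probes, function(p) as.numeric(p$threshold), 1.0),
    tm_final_hairpin = vapply(panel$probes,
                              function(p) as.numeric(p$tm_final_hairpin), 1.0),
    amplitude = vapply(panel$probes, function(p) as.numeric(p$amplitude), 1.0),
    stringsAsFactors = FALSE
  )
}
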