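## Ground-truthed simulator of partition fluorescence.
##
## Two layers: (1) Poisson loading of target molecules into partitions,
## lambda_k = copies_k * loaded_fraction / N; (2) a phenomenological
## hairpin-melt fluorescence model. An occupied partition fully cleaves its
## probe (endpoint plateau); a cleaved probe is quenched below its
## final-hairpin melt temperature, recovering via a logistic transition of
## steepness `melt_steepness` centered at its Tm, down to a residual
## `residual_quench` fraction. Uncleaved probes fluoresce at amplitude at
## all temperatures, so negative partitions sit at ratio ~1 in every melt
## window.

## evaluate `code` under a fixed seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation settings for one well
#'
#' @param panel A `panel_config`.
#' @param copies_per_target Named numeric vector, probe_id -> expected
#'   copies per assay input; probes not named get 0 copies.
#' @param noise_sd_frac SD of the multiplicative Gaussian noise applied to
#'   every fluorescence reading (default 0.01).
#' @param amplitude_cv Partition-to-partition CV of each probe's amplitude
#'   (default 0.05; negative draws are resampled).
#' @param residual_quench Fraction of a cleaved probe's fluorescence that
#'   remains below its melt temperature (default 0.05).
#' @param melt_steepness Temperature scale (deg C) of the logistic melt
#'   transition (default 0.8).
#' @param false_positive_rate Per-probe per-partition probability of
#'   spontaneous cleavage in the absence of target (default 0).
#' @param cleavage_fraction Fraction of full quenching reached at endpoint
#'   (default 1 = plateau; < 1 models incomplete cleavage).
#' @param base_fluorescence RFU scale of one probe's unquenched signal
#'   (default 1000).
#' @param crosstalk Optional 4x4 channel bleed matrix (rows = observed,
#'   cols = source, channel order blue/green/yellow/red); default identity.
#' @param seed Integer RNG seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(panel, copies_per_target = numeric(0),
                              noise_sd_frac = 0.01, amplitude_cv = 0.05,
                              residual_quench = 0.05, melt_steepness = 0.8,
                              false_positive_rate = 0, cleavage_fraction = 1,
                              base_fluorescence = 1000, crosstalk = NULL,
                              seed = 1L) {
  stopifnot(inherits(panel, "panel_config"))
  pt <- panel_probe_table(panel)
  copies <- stats::setNames(rep(0, nrow(pt)), pt$probe_id)
  if (length(copies_per_target)) {
    unknown <- setdiff(names(copies_per_target), pt$probe_id)
    if (length(unknown)) {
      stop("copies_per_target names not in panel: ",
           paste(unknown, collapse = ", "))
    }
    copies[names(copies_per_target)] <- as.numeric(copies_per_target)
  }
  if (any(copies < 0)) stop("copies per target must be >= 0")
  if (residual_quench < 0 || residual_quench >= 1) {
    stop("residual_quench must be in [0, 1)")
  }
  if (noise_sd_frac < 0) stop("noise_sd_frac must be >= 0")
  if (any(is.na(pt$tm_final_hairpin))) {
    stop("all probes need tm_final_hairpin for simulation")
  }
  if (!is.null(crosstalk)) {
    stopifnot(is.matrix(crosstalk), all(dim(crosstalk) == c(4L, 4L)))
  }
  structure(
    list(panel = panel, copies_per_target = copies,
         noise_sd_frac = noise_sd_frac, amplitude_cv = amplitude_cv,
         residual_quench = residual_quench, melt_steepness = melt_steepness,
         false_positive_rate = false_positive_rate,
         cleavage_fraction = cleavage_fraction,
         base_fluorescence = base_fluorescence,
         crosstalk = crosstalk, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate one digital PCR well with ground truth
#'
#' Targets load into partitions as independent Poisson draws with
#' `lambda_k = copies_k * loaded_fraction / N`. Any occupied partition is
#' fully cleaved for that probe (endpoint plateau); unoccupied partitions
#' cleave spontaneously with `false_positive_rate`. Channel fluorescence at
#' temperature T sums the amplitudes of the channel's probes, each scaled by
#' its melt state, then picks up multiplicative Gaussian read noise.
#' Identical config and seed give a byte-identical table.
#'
#' @param cfg A `simulation_config`.
#' @param well_id Well label for the output table.
#' @return List with `table` (a `partition_table`) and `truth` (class
#'   `ground_truth`: per-probe input and digitized copies plus the
#'   partition-by-probe occupancy matrix).
#' @export
simulate_well <- function(cfg, well_id = "sim01") {
  stopifnot(inherits(cfg, "simulation_config"))
  panel <- cfg$panel
  pt <- panel_probe_table(panel)
  n <- panel$partitions_per_well
  k <- nrow(pt)
  temps <- panel$temperatures
  with_local_seed(cfg$seed, {
    lambda <- cfg$copies_per_target[pt$probe_id] * panel$loaded_fraction / n
    occ <- matrix(stats::rpois(n * k, rep(lambda, each = n)), n, k,
                  dimnames = list(NULL, pt$probe_id))
    cleaved <- occ > 0L
    if (cfg$false_positive_rate > 0) {
      spont <- matrix(stats::runif(n * k) < cfg$false_positive_rate, n, k)
      cleaved <- cleaved | (spont & occ == 0L)
    }
    amp <- matrix(1 + stats::rnorm(n * k, 0, cfg$amplitude_cv), n, k)
    while (any(amp <= 0)) {
      bad <- amp <= 0
      amp[bad] <- 1 + stats::rnorm(sum(bad), 0, cfg$amplitude_cv)
    }
    amp <- amp * rep(pt$amplitude, each = n)
    q <- cfg$residual_quench
    cf <- cfg$cleavage_fraction
    ## channel totals per temperature, before noise
    raw <- array(0, c(n, 4L, 4L),
                 dimnames = list(NULL, MDPCR_CHANNELS, paste0("T", 1:4)))
    for (ti in 1:4) {
      ## per-probe melt state at this temperature (scalar per probe)
      sig <- q + (1 - q) * stats::plogis((temps[ti] - pt$tm_final_hairpin) /
                                           cfg$melt_steepness)
      melt_cleaved <- 1 - cf * (1 - sig)
      state <- amp * (cleaved * rep(melt_cleaved, each = n) + !cleaved)
      for (ci in seq_along(MDPCR_CHANNELS)) {
        in_ch <- which(pt$channel == MDPCR_CHANNELS[ci])
        raw[, ci, ti] <- if (length(in_ch)) {
          rowSums(state[, in_ch, drop = FALSE])
        } else 1  # probe-free channel: stable unit baseline
      }
      if (!is.null(cfg$crosstalk)) {
        raw[, , ti] <- raw[, , ti] %*% t(cfg$crosstalk)
      }
    }
    fl <- matrix(0, n, 16L, dimnames = list(NULL, fluor_columns()))
    for (ci in seq_along(MDPCR_CHANNELS)) {
      for (ti in 1:4) {
        noise <- 1 + stats::rnorm(n, 0, cfg$noise_sd_frac)
        fl[, paste0(MDPCR_CHANNELS[ci], "_T", ti)] <-
          pmax(0, cfg$base_fluorescence * raw[, ci, ti] * noise)
      }
    }
    truth <- structure(
      list(
        probe_id = pt$probe_id,
        true_copies_input = unname(cfg$copies_per_target[pt$probe_id]),
        true_copies_digitized = unname(colSums(occ)),
        occupancy = occ,
        seed = cfg$seed
      ),
      class = "ground_truth"
    )
    list(table = partition_table(well_id, fl), truth = truth)
  })
}

## allele doses of a genotype string: "A/A" -> c(A = 1), "A/B" -> c(A = .5, B = .5)
genotype_doses <- function(genotype) {
  al <- strsplit(genotype, "/", fixed = TRUE)[[1L]]
  if (length(al) != 2L) stop("genotype must be 'X/Y', got '", genotype, "'")
  tab <- table(al) / 2
  stats::setNames(as.numeric(tab), names(tab))
}

## per-probe copies for a mixture of two genotyped sources at minor fraction f
mixture_copies <- function(panel, genotype_major, genotype_minor, total_hge, f) {
  pt <- panel_probe_table(panel)
  loci <- unique(pt$locus_id)
  miss <- setdiff(loci, intersect(names(genotype_major), names(genotype_minor)))
  if (length(miss)) {
    stop("genotype missing locus/loci: ", paste(miss, collapse = ", "))
  }
  copies <- stats::setNames(numeric(nrow(pt)), pt$probe_id)
  for (i in seq_len(nrow(pt))) {
    dmaj <- genotype_doses(genotype_major[[pt$locus_id[i]]])
    dmin <- genotype_doses(genotype_minor[[pt$locus_id[i]]])
    a <- pt$allele[i]
    dose <- (1 - f) * (if (a %in% names(dmaj)) dmaj[[a]] else 0) +
      f * (if (a %in% names(dmin)) dmin[[a]] else 0)
    copies[i] <- total_hge * dose
  }
  copies
}

#' Simulate a two-genotype mixture dilution series
#'
#' Emulates mixing genomic DNA of two individuals at a set of minor
#' fractions: the copies of allele `a` at locus `L` are
#' `total_hge * ((1-f) * dose_major(L,a) + f * dose_minor(L,a))`, where a
#' homozygous genotype contributes dose 1 to its allele and a heterozygous
#' genotype 0.5 to each (1 hge = 1 allele copy per locus). Each
#' fraction x replicate well is simulated with its own derived seed.
#'
#' @param panel A `panel_config`.
#' @param genotype_major,genotype_minor Named character vectors (or lists),
#'   locus_id -> genotype `"A/A"`, `"A/B"` or `"B/B"`.
#' @param total_hge Total assay input in haploid genome equivalents.
#' @param fractions Minor fractions in \[0, 1\].
#' @param replicates Wells per fraction.
#' @param seed Master seed; per-well seeds are derived deterministically.
#' @param ... Further arguments to [simulation_config()] (noise etc.).
#' @return List of wells; each element has `fraction`, `replicate`,
#'   `well_id`, `table`, `truth` and `seed`.
#' @export
simulate_mixture_series <- function(panel, genotype_major, genotype_minor,
                                    total_hge, fractions, replicates = 4L,
                                    seed = 1L, ...) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("minor fractions must lie in [0, 1]")
  }
  stopifnot(replicates >= 1L)
  nwell <- length(fractions) * replicates
  well_seeds <- with_local_seed(seed,
                                sample.int(.Machine$integer.max, nwell))
  out <- vector("list", nwell)
  idx <- 0L
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    copies <- mixture_copies(panel, genotype_major, genotype_minor,
                             total_hge, f)
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      cfg <- simulation_config(panel, copies_per_target = copies,
                               seed = well_seeds[idx], ...)
      wid <- sprintf("mix_f%s_r%d", format(f), r)
      sim <- simulate_well(cfg, well_id = wid)
      out[[idx]] <- list(fraction = f, replicate = r, well_id = wid,
                         table = sim$table, truth = sim$truth,
                         seed = well_seeds[idx])
    }
  }
  out
}

#' Simulate blank replicate wells and count false-positive partitions
#'
#' All targets absent; spontaneous cleavage occurs at `false_positive_rate`
#' per probe per partition. With `method = "pipeline"` each well's
#' fluorescence is simulated and pushed through ratio computation,
#' normalization and threshold calling, so noise-induced false calls are
#' included; `method = "counts"` counts the simulated cleavage events
#' directly (a fast binomial shortcut for statistical checks).
#'
#' @param panel A `panel_config`.
#' @param n Number of blank replicate wells (>= 2).
#' @param false_positive_rate Per-probe per-partition spontaneous cleavage
#'   probability.
#' @param seed Master seed.
#' @param method `"pipeline"` or `"counts"`.
#' @param ... Further arguments to [simulation_config()].
#' @return Named list, probe_id -> integer vector of per-replicate
#'   false-positive partition counts (feeds [limit_of_blank()]).
#' @export
simulate_blank_replicates <- function(panel, n = 16L, false_positive_rate = 0,
                                      seed = 1L,
                                      method = c("pipeline", "counts"), ...) {
  method <- match.arg(method)
  n <- as.integer(n)
  if (n < 2L) stop("blank study requires >= 2 replicate wells, got ", n)
  pt <- panel_probe_table(panel)
  well_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max, n))
  counts <- matrix(0L, n, nrow(pt), dimnames = list(NULL, pt$probe_id))
  for (i in seq_len(n)) {
    if (method == "counts") {
      counts[i, ] <- with_local_seed(
        well_seeds[i],
        stats::rbinom(nrow(pt), panel$partitions_per_well,
                      false_positive_rate))
    } else {
      cfg <- simulation_config(panel,
                               false_positive_rate = false_positive_rate,
                               seed = well_seeds[i], ...)
      sim <- simulate_well(cfg, well_id = sprintf("blank_r%02d", i))
      ratios <- normalize_ratios(compute_ratios(sim$table, panel),
                                 panel$normalization)
      calls <- call_partitions(ratios, panel)
      counts[i, ] <- calls$summary$positives
    }
  }
  lapply(stats::setNames(pt$probe_id, pt$probe_id),
         function(p) unname(counts[, p]))
}

#' Opposing homozygous genotypes for every locus of a panel
#'
#' Convenience for mixture studies: the major source is `A/A` and the minor
#' source `B/B` at every locus, so every B probe measures the minor
#' fraction directly.
#'
#' @param panel A `panel_config`.
#' @return List with `major` and `minor` genotype vectors.
#' @export
opposing_homozygotes <- function(panel) {
  loci <- unique(panel_probe_table(panel)$locus_id)
  list(major = stats::setNames(rep("A/A", length(loci)), loci),
       minor = stats::setNames(rep("B/B", length(loci)), loci))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("simulation ground truth (seed", x$seed, ")\n")
  print(data.frame(probe_id = x$probe_id,
                   input_copies = x$true_copies_input,
                   digitized_copies = x$true_copies_digitized),
        row.names = FALSE)
  invisible(x)
}

#' Write simulation ground truth as JSON
#'
#' @param truth A `ground_truth`.
#' @param path Output JSON path.
#' @param cfg Optional `simulation_config` echoed into the file.
#' @export
write_ground_truth <- function(truth, path, cfg = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  per_probe <- stats::setNames(lapply(seq_along(truth$probe_id), function(i) {
    list(input_copies = truth$true_copies_input[i],
         digitized_copies = truth$true_copies_digitized[i])
  }), truth$probe_id)
  obj <- list(seed = truth$seed, probes = per_probe)
  if (!is.null(cfg)) {
    obj$config <- list(
      noise_sd_frac = cfg$noise_sd_frac, amplitude_cv = cfg$amplitude_cv,
      residual_quench = cfg$residual_quench,
      melt_steepness = cfg$melt_steepness,
      false_positive_rate = cfg$false_positive_rate,
      base_fluorescence = cfg$base_fluorescence)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
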