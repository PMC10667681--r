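## Partition summary table dialect: one row per partition, columns
## well, partition, <channel>_T1..<channel>_T4 for the four channels.

fluor_columns <- function() {
  as.vector(vapply(MDPCR_CHANNELS,
                   function(ch) paste0(ch, "_T", 1:4), character(4)))
}

#' Construct a partition table
#'
#' @param well_id Well label.
#' @param fluorescence data.frame or matrix of raw fluorescence (RFU), one
#'   row per partition, with the 16 columns `blue_T1..red_T4`.
#' @return An object of class `partition_table`: a data.table with columns
#'   `well`, `partition` (0-based, contiguous) and the 16 fluorescence
#'   columns, in partition order.
#' @export
partition_table <- function(well_id, fluorescence) {
  cols <- fluor_columns()
  fl <- as.data.frame(fluorescence)
  miss <- setdiff(cols, names(fl))
  if (length(miss)) {
    stop("missing fluorescence column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(fl) == 0L) stop("a partition table must contain at least one partition")
  fl <- fl[, cols, drop = FALSE]
  vals <- as.matrix(fl)
  if (any(!is.finite(vals))) {
    stop("non-finite fluorescence at row(s): ",
         paste(head(which(rowSums(!is.finite(vals)) > 0), 10L), collapse = ", "))
  }
  if (any(vals < 0)) {
    stop("negative fluorescence at row(s): ",
         paste(head(which(rowSums(vals < 0) > 0), 10L), collapse = ", "))
  }
  dt <- data.table::data.table(
    well = as.character(well_id),
    partition = seq_len(nrow(fl)) - 1L
  )
  dt <- cbind(dt, data.table::as.data.table(fl))
  data.table::setattr(dt, "class", c("partition_table", class(dt)))
  dt
}

#' Read a partition summary table (CSV)
#'
#' Expects the dialect `well,partition,blue_T1..blue_T4,green_T1..green_T4,
#' yellow_T1..yellow_T4,red_T1..red_T4`. Row order is preserved: rolling
#' normalization operates on file order.
#'
#' @param path CSV file path.
#' @return A `partition_table`.
#' @export
read_partition_table <- function(path) {
  if (!file.exists(path)) stop("partition table not found: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = list(character = "well"))
  if (nrow(dt) == 0L) stop("empty partition table: ", path)
  need <- c("well", "partition", fluor_columns())
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("partition table missing column(s): ", paste(miss, collapse = ", "))
  }
  idx <- dt$partition
  if (anyDuplicated(idx)) {
    stop("duplicate partition index(es): ",
         paste(head(unique(idx[duplicated(idx)]), 10L), collapse = ", "))
  }
  if (!identical(as.integer(idx), seq_len(nrow(dt)) - 1L)) {
    stop("partition indices must be contiguous from 0 in file order")
  }
  tab <- partition_table(dt$well[1L], dt[, fluor_columns(), with = FALSE])
  tab
}

#' Write a partition summary table (CSV)
#'
#' The written file round-trips through [read_partition_table()] at full
#' precision, and writing the same table twice yields identical bytes.
#'
#' @param table A `partition_table`.
#' @param path Output CSV path.
#' @export
write_partition_table <- function(table, path) {
  stopifnot(inherits(table, "partition_table"))
  if (nrow(table) == 0L) stop("refusing to write a zero-partition table")
  data.table::fwrite(data.table::as.data.table(unclass(table)), path,
                     sep = ",", quote = FALSE, eol = "\n")
  invisible(path)
}

#' Assemble a per-probe results table
#'
#' One record per probe per well, with partition counts, the Poisson
#' estimate and its scaled confidence interval.
#'
#' @param df data.frame with columns `probe_id`, `positives`, `analyzed`,
#'   `lambda`, `copies_per_uL`, `total_copies`, `ci95_low`, `ci95_high`,
#'   and optionally `allele_fraction` and `flags`.
#' @return An object of class `results_table`.
#' @export
results_table <- function(df) {
  need <- c("probe_id", "positives", "analyzed", "lambda", "copies_per_uL",
            "total_copies", "ci95_low", "ci95_high")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("results missing column(s): ", paste(miss, collapse = ", "))
  if (!"allele_fraction" %in% names(df)) df$allele_fraction <- NA_real_
  if (!"flags" %in% names(df)) df$flags <- ""
  ok <- is.na(df$total_copies) |
    (df$ci95_low <= df$total_copies + 1e-12 &
       df$total_copies <= df$ci95_high + 1e-12)
  if (any(!ok)) {
    stop("invariant violated (ci95_low <= total_copies <= ci95_high) for: ",
         paste(df$probe_id[!ok], collapse = ", "))
  }
  bad_n <- !is.na(df$positives) &
    (df$positives < 0 | df$positives > df$analyzed)
  if (any(bad_n)) {
    stop("invariant violated (0 <= positives <= analyzed) for: ",
         paste(df$probe_id[bad_n], collapse = ", "))
  }
  structure(df[, c(need, "allele_fraction", "flags")],
            class = c("results_table", "data.frame"))
}

#' Write a results table with a JSON metadata sidecar
#'
#' Floats are written at 6 significant digits. The sidecar
#' (`<path>.meta.json`) records panel hash, seed and software version so a
#' results file is traceable to the run that produced it.
#'
#' @param results A `results_table`.
#' @param path Output CSV path.
#' @param panel Optional `panel_config` used for the run (hashed into the
#'   sidecar).
#' @param seed Optional RNG seed of the run.
#' @export
write_results <- function(results, path, panel = NULL, seed = NA_integer_) {
  results <- results_table(as.data.frame(results))
  out <- as.data.frame(results)
  for (col in c("lambda", "copies_per_uL", "total_copies", "ci95_low",
                "ci95_high", "allele_fraction")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  data.table::fwrite(out, path, sep = ",", quote = FALSE, eol = "\n", na = "NA")
  meta <- list(
    panel_hash = if (is.null(panel)) NA else panel_hash(panel),
    seed = seed,
    software = paste0("meltplex ", as.character(utils::packageVersion("meltplex")))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path CSV path.
#' @return A `results_table`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  df <- as.data.frame(data.table::fread(path, sep = ","))
  results_table(df)
}

## deterministic content hash of a panel (md5 of its canonical JSON)
panel_hash <- function(panel) {
  j <- jsonlite::toJSON(panel_to_list(panel), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(j, tmp)
  unname(tools::md5sum(tmp))
}
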