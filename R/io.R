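# Plain-text readers/writers for the package's tabular interchange formats.
# Gas series: long TSV with columns time_h, gas, amount_umol, sampled,
# injected_umol. OTU data: counts TSV (OTUs x samples), metadata TSV and
# ddPCR TSV. Trajectories: wide TSV with one column per species.

#' Read a gas series from TSV
#'
#' Expects columns `time_h`, `gas`, `amount_umol`, `sampled` (0/1) and
#' optionally `injected_umol` (amount injected at that time), one row per
#' (time, gas).
#'
#' @param path file path.
#' @return A [GasSeries-class].
#' @export
readGasSeriesTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("time_h", "gas", "amount_umol", "sampled")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stopf("gas TSV is missing columns: %s", paste(missing, collapse = ", "))
  times <- sort(unique(df$time_h))
  gases <- unique(df$gas)
  amounts <- matrix(0, nrow = length(gases), ncol = length(times),
                    dimnames = list(gases, NULL))
  sampled <- rep(FALSE, length(times))
  for (r in seq_len(nrow(df))) {
    i <- match(df$gas[r], gases); j <- match(df$time_h[r], times)
    amounts[i, j] <- df$amount_umol[r]
    if (df$sampled[r] != 0) sampled[j] <- TRUE
  }
  inj <- NULL
  if ("injected_umol" %in% names(df)) {
    keep <- !is.na(df$injected_umol) & df$injected_umol > 0
    if (any(keep))
      inj <- data.frame(time = df$time_h[keep], gas = df$gas[keep],
                        amount = df$injected_umol[keep])
  }
  gasSeries(times, amounts, sampled = sampled, injections = inj)
}

#' Write a gas series to TSV
#'
#' @param series A [GasSeries-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeGasSeriesTSV <- function(series, path) {
  gases <- rownames(series@amounts)
  df <- expand.grid(gas = gases, idx = seq_along(series@times),
                    stringsAsFactors = FALSE)
  df <- data.frame(time_h = series@times[df$idx], gas = df$gas,
                   amount_umol = series@amounts[cbind(match(df$gas, gases), df$idx)],
                   sampled = as.integer(series@sampled[df$idx]),
                   injected_umol = 0)
  inj <- series@injections
  for (r in seq_len(nrow(inj))) {
    hit <- df$gas == inj$gas[r] & df$time_h == inj$time[r]
    df$injected_umol[hit] <- df$injected_umol[hit] + inj$amount[r]
  }
  df <- df[order(df$time_h, df$gas), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU experiment from TSV files
#'
#' @param counts_path counts TSV: first column `otu_id`, remaining columns
#'   one per sample, integer counts.
#' @param meta_path metadata TSV with columns `sample_id`, `line`,
#'   `replicate`, `cycle`, `substrate`.
#' @param ddpcr_path optional ddPCR TSV with columns `sample_id`,
#'   `copies_per_vial`.
#' @return An [OTUExperiment-class].
#' @export
readOTUTableTSV <- function(counts_path, meta_path, ddpcr_path = NULL) {
  cts <- utils::read.delim(counts_path, check.names = FALSE)
  otu_ids <- cts[[1]]
  cts <- as.matrix(cts[, -1, drop = FALSE])
  rownames(cts) <- otu_ids
  storage.mode(cts) <- "integer"
  meta <- utils::read.delim(meta_path, check.names = FALSE)
  totals <- NULL
  if (!is.null(ddpcr_path)) {
    dd <- utils::read.delim(ddpcr_path, check.names = FALSE)
    totals <- setNames(dd$copies_per_vial, dd$sample_id)
  }
  otuExperiment(cts, meta, total_copies = totals)
}

#' Write an OTU experiment to TSV files
#'
#' @param x An [OTUExperiment-class].
#' @param counts_path,meta_path,ddpcr_path output paths; ddPCR totals are
#'   written only if present and `ddpcr_path` is given.
#' @return `counts_path`, invisibly.
#' @export
writeOTUTableTSV <- function(x, counts_path, meta_path, ddpcr_path = NULL) {
  cts <- SummarizedExperiment::assay(x, "counts")
  out <- data.frame(otu_id = rownames(cts), cts, check.names = FALSE)
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  meta <- data.frame(sample_id = colnames(x),
                     cd[, c("line", "replicate", "cycle", "substrate")])
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(ddpcr_path) && "total_copies" %in% colnames(cd)) {
    dd <- data.frame(sample_id = colnames(x), copies_per_vial = cd$total_copies)
    utils::write.table(dd, ddpcr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(counts_path)
}

#' Write a trajectory to TSV
#'
#' Columns: `time_h`, `enrichment_index`, `substrate`, then one column per
#' species (biomass units).
#'
#' @param traj A [Trajectory-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryTSV <- function(traj, path) {
  nb <- traj@enrichment_boundaries
  enr <- findInterval(seq_along(traj@times), nb)
  df <- data.frame(time_h = traj@times, enrichment_index = enr,
                   substrate = traj@enrichment_substrate[enr],
                   t(traj@abundances), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
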