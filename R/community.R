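# OTU-level statistics across the dual-enrichment series: rarefaction,
# ddPCR-scaled absolute abundances, per-enrichment ratios R_i, niche
# classification, Ward clade clustering, SIMPER and PCA.

#' Rarefy samples to a common depth
#'
#' Samples with fewer than `depth` total reads are dropped (and listed in the
#' `"dropped"` attribute); the remainder are subsampled without replacement to
#' exactly `depth` reads.
#'
#' @param x An [OTUExperiment-class].
#' @param depth target read depth, default 9000.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @return A rarefied [OTUExperiment-class]; dropped sample ids in
#'   `attr(, "dropped")`.
#' @export
rarefySamples <- function(x, depth = 9000, seed = 1L) {
  if (depth <= 0) stopf("depth must be > 0")
  cts <- SummarizedExperiment::assay(x, "counts")
  tot <- colSums(cts)
  drop <- colnames(cts)[tot < depth]
  if (length(drop) > 0)
    message(sprintf("dropping %d sample(s) below %d reads: %s",
                    length(drop), depth, paste(drop, collapse = ", ")))
  keep <- setdiff(colnames(cts), drop)
  x <- x[, keep]
  if (length(keep) == 0L) {
    attr(x, "dropped") <- drop
    return(x)
  }
  cts <- SummarizedExperiment::assay(x, "counts")
  ## vegan warns whenever the smallest positive entry exceeds 1 (a heuristic
  ## for non-count data); our assay is integer counts by construction.
  rare <- withSeed(seed, t(withCallingHandlers(
    vegan::rrarefy(t(cts), sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })))
  storage.mode(rare) <- "integer"
  SummarizedExperiment::assay(x, "counts") <- rare
  out <- x
  attr(out, "dropped") <- drop
  out
}

#' Relative OTU abundances
#'
#' @param x An [OTUExperiment-class] or a counts matrix (OTUs x samples).
#' @return Matrix of per-sample relative abundances (columns sum to 1).
#' @export
relativeAbundance <- function(x) {
  cts <- if (is(x, "OTUExperiment")) SummarizedExperiment::assay(x, "counts") else x
  tot <- colSums(cts)
  if (any(tot == 0)) stopf("samples with zero total reads: %s",
                           paste(colnames(cts)[tot == 0], collapse = ", "))
  sweep(cts, 2, tot, "/")
}

#' Absolute OTU abundances from ddPCR totals
#'
#' Scales relative abundances by the per-sample total 16S copy number:
#' `abs[s, k] = (count[s, k] / sum_k count[s, k]) * total_s`, so that column
#' sums reproduce the ddPCR totals exactly.
#'
#' @param x An [OTUExperiment-class] with ddPCR totals attached, or a counts
#'   matrix.
#' @param totals named numeric vector of 16S copies per vial; taken from
#'   `totalCopies(x)` when omitted.
#' @return Matrix, OTUs x samples, 16S copies per vial.
#' @export
absoluteAbundance <- function(x, totals = NULL) {
  if (is.null(totals)) totals <- totalCopies(x)
  rel <- relativeAbundance(x)
  missing <- setdiff(colnames(rel), names(totals))
  if (length(missing) > 0)
    stopf("samples missing from ddPCR totals: %s", paste(missing, collapse = ", "))
  sweep(rel, 2, totals[colnames(rel)], "*")
}

#' Per-enrichment relative-increase statistic R_i
#'
#' `R_i = ln(N(i) / (N(i-1) * f))`: the net log change of an OTU's absolute
#' abundance across one enrichment, corrected for the transfer dilution f.
#' Zero means pure dilution (no net growth or death), positive net growth.
#'
#' @param N_curr,N_prev absolute abundances at the end of the current and
#'   foregoing enrichment (copies per vial).
#' @param f transfer fraction in (0, 1], default 0.1.
#' @param pseudo pseudo-abundance substituted for zeros (copies per vial),
#'   default 0.5.
#' @param pseudo_curr pseudo-abundance for the current-side zeros; defaults
#'   to `pseudo`.
#' @return Numeric vector of R values, with attribute `"flagged"` marking
#'   entries where a pseudo-abundance was substituted; `NA` where both
#'   abundances were zero.
#' @export
enrichmentRatio <- function(N_curr, N_prev, f = 0.1, pseudo = 0.5,
                            pseudo_curr = pseudo) {
  if (f <= 0 || f > 1) stopf("f must lie in (0, 1]")
  flagged <- (N_curr == 0) | (N_prev == 0)
  both0 <- (N_curr == 0) & (N_prev == 0)
  Nc <- ifelse(N_curr == 0, pseudo_curr, N_curr)
  Np <- ifelse(N_prev == 0, pseudo, N_prev)
  out <- log(Nc / (Np * f))
  out[both0] <- NA_real_
  attr(out, "flagged") <- flagged
  out
}

#' R_i table for a whole enrichment series
#'
#' Computes [enrichmentRatio()] for every OTU across every pair of
#' consecutive cycles within each line x replicate series (cycle 0 inocula
#' serve as the predecessor of cycle 1). Sterile-control samples are ignored.
#'
#' @param x An [OTUExperiment-class] with ddPCR totals.
#' @param f transfer fraction, default 0.1.
#' @param pseudo pseudo-abundance for zero counts, in copies per vial. The
#'   default `NULL` scales it to the sample's detection limit: half a read's
#'   worth of copies, `0.5 / total_reads * total_copies`, so that
#'   sub-detection transitions contribute R values of detection-limit
#'   magnitude rather than arbitrarily large spikes. Supply a number for a
#'   fixed pseudo-abundance.
#' @return data.frame with columns `otu_id`, `line`, `replicate`, `cycle`,
#'   `substrate`, `R`, `flagged`.
#' @export
enrichmentRatios <- function(x, f = 0.1, pseudo = NULL) {
  ab <- absoluteAbundance(x)
  totals <- totalCopies(x)
  reads <- colSums(SummarizedExperiment::assay(x, "counts"))
  sample_pseudo <- if (is.null(pseudo)) 0.5 / reads * totals
                   else setNames(rep(pseudo, ncol(x)), colnames(x))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cd$sample_id <- colnames(x)
  cd <- cd[cd$substrate != "sterile_control", , drop = FALSE]

  out <- list()
  for (ln in unique(cd$line)) {
    for (rep_ in unique(cd$replicate[cd$line == ln])) {
      sel <- cd[cd$line == ln & cd$replicate == rep_, , drop = FALSE]
      sel <- sel[order(sel$cycle), , drop = FALSE]
      if (nrow(sel) < 2L) next
      for (k in 2:nrow(sel)) {
        ## only consecutive cycles form a transfer pair (rarefaction may have
        ## dropped a sample, breaking the chain)
        if (sel$cycle[k] != sel$cycle[k - 1] + 1L) next
        R <- enrichmentRatio(ab[, sel$sample_id[k]], ab[, sel$sample_id[k - 1]],
                             f = f,
                             pseudo = sample_pseudo[[sel$sample_id[k - 1]]],
                             pseudo_curr = sample_pseudo[[sel$sample_id[k]]])
        out[[length(out) + 1L]] <- data.frame(
          otu_id = rownames(ab), line = ln, replicate = rep_,
          cycle = sel$cycle[k], substrate = sel$substrate[k],
          R = as.numeric(R), flagged = attr(R, "flagged"),
          row.names = NULL)
      }
    }
  }
  if (length(out) == 0L) stopf("no consecutive cycle pairs found")
  do.call(rbind, out)
}

#' Classify OTUs into niche categories from R values
#'
#' Per OTU, R values are first averaged over all enrichments of each
#' substrate within a line x replicate series, then across series. An OTU is
#' a generalist when both mean R values exceed `threshold_high`; a soil
#' (digestate) specialist when its soil (digestate) mean exceeds
#' `threshold_high` while the other mean is at or below `threshold_low`;
#' anything else is washout.
#'
#' @param ratios data.frame from [enrichmentRatios()] (columns `otu_id`,
#'   `line`, `replicate`, `substrate`, `R`, optionally `flagged`).
#' @param threshold_high mean-R threshold for "grows here", default 2.0.
#' @param threshold_low upper bound for "low/negative", default 0.0.
#' @param include_flagged also average R values that rest on a
#'   pseudo-abundance substitution (default TRUE). Setting this to FALSE
#'   drops sub-detection transitions from the means, which silences the
#'   +/- ln(N/pseudo) spikes they inject but also discards the informative
#'   reappearance of specialists returning from below the detection limit.
#'   An OTU whose R values are all excluded in a substrate gets `NA` there,
#'   which is treated as "low".
#' @return data.frame with columns `otu_id`, `R_soil_mean`,
#'   `R_digestate_mean`, `category`.
#' @export
classifyNiche <- function(ratios, threshold_high = 2.0, threshold_low = 0.0,
                          include_flagged = TRUE) {
  ratios <- ratios[ratios$substrate %in% c("soil", "digestate"), , drop = FALSE]
  if (!include_flagged && "flagged" %in% names(ratios))
    ratios$R[ratios$flagged] <- NA_real_
  ## mean per OTU x substrate x (line, replicate), then across series
  series_means <- stats::aggregate(
    R ~ otu_id + substrate + line + replicate, data = ratios, FUN = mean,
    na.action = stats::na.omit)
  means <- stats::aggregate(R ~ otu_id + substrate, data = series_means,
                            FUN = mean)
  wide <- stats::reshape(means, idvar = "otu_id", timevar = "substrate",
                         direction = "wide")
  ## OTUs whose R values were all undefined (never detected) drop out of the
  ## aggregation; reinstate them so every input OTU receives a category.
  all_ids <- unique(ratios$otu_id)
  wide <- merge(data.frame(otu_id = all_ids), wide, by = "otu_id",
                all.x = TRUE, sort = FALSE)
  rs <- wide[["R.soil"]]
  rd <- wide[["R.digestate"]]
  if (is.null(rs)) rs <- rep(NA_real_, nrow(wide))
  if (is.null(rd)) rd <- rep(NA_real_, nrow(wide))

  above <- function(v) !is.na(v) & v > threshold_high
  below <- function(v) is.na(v) | v <= threshold_low
  category <- rep("washout", nrow(wide))
  category[above(rs) & above(rd)] <- "generalist"
  category[above(rs) & below(rd)] <- "soil_specialist"
  category[above(rd) & below(rs)] <- "digestate_specialist"

  data.frame(otu_id = wide$otu_id, R_soil_mean = rs, R_digestate_mean = rd,
             category = category, row.names = NULL)
}

#' Cluster OTU abundance profiles into clades
#'
#' Selects the `top_n` OTUs by summed abundance across all samples and
#' clusters their per-sample relative-abundance profiles (OTUs as items,
#' samples as features) by Euclidean distance and Ward variance-minimisation
#' linkage, cutting the tree into `n_clades` clades.
#'
#' @param x An [OTUExperiment-class] or a relative-abundance matrix
#'   (OTUs x samples).
#' @param top_n number of most abundant OTUs to cluster, default 500.
#' @param n_clades number of clades to cut, default 6.
#' @return A [CladeMap-class]; clade labels are `"A"`, `"B"`, ... in order of
#'   first appearance along the dendrogram.
#' @export
clusterClades <- function(x, top_n = 500L, n_clades = 6L) {
  rel <- if (is(x, "OTUExperiment")) relativeAbundance(x) else x
  top_n <- min(top_n, nrow(rel))
  if (n_clades > top_n) stopf("n_clades (%d) exceeds top_n (%d)", n_clades, top_n)
  keep <- order(rowSums(rel), decreasing = TRUE)[seq_len(top_n)]
  prof <- rel[keep, , drop = FALSE]
  tree <- stats::hclust(stats::dist(prof, method = "euclidean"),
                        method = "ward.D2")
  cut <- stats::cutree(tree, k = n_clades)
  labels <- LETTERS[seq_len(n_clades)]
  clades <- factor(labels[match(cut, unique(cut[tree$order]))], levels = labels)
  names(clades) <- rownames(prof)
  new("CladeMap", clades = clades, tree = tree)
}

#' SIMPER: per-OTU contributions to between-group dissimilarity
#'
#' For every cross-group sample pair (i, j) the per-OTU Bray-Curtis term is
#' `delta_k(i,j) = |x_ik - x_jk| / sum_m (x_im + x_jm)`; an OTU's
#' contribution is the mean of its terms over all pairs, expressed as a
#' percentage of the mean overall Bray-Curtis dissimilarity. Contributions
#' sum to 100%.
#'
#' @param x An [OTUExperiment-class] or relative-abundance matrix
#'   (OTUs x samples).
#' @param group_a,group_b character vectors of sample ids (non-empty,
#'   disjoint).
#' @return data.frame with columns `otu_id`, `mean_delta`, `contribution_pct`
#'   (sorted by decreasing contribution), with the mean overall dissimilarity
#'   in `attr(, "overall_dissimilarity")`.
#' @export
simperContributions <- function(x, group_a, group_b) {
  rel <- if (is(x, "OTUExperiment")) relativeAbundance(x) else x
  if (length(group_a) == 0L || length(group_b) == 0L)
    stopf("both groups must be non-empty")
  missing <- setdiff(c(group_a, group_b), colnames(rel))
  if (length(missing) > 0)
    stopf("unknown samples: %s", paste(missing, collapse = ", "))

  acc <- numeric(nrow(rel))
  npairs <- 0L
  for (i in group_a) for (j in group_b) {
    xi <- rel[, i]; xj <- rel[, j]
    denom <- sum(xi + xj)
    acc <- acc + abs(xi - xj) / denom
    npairs <- npairs + 1L
  }
  mean_delta <- acc / npairs
  overall <- sum(mean_delta)
  if (overall == 0) {
    warnf("groups are identical (overall dissimilarity 0); contributions undefined")
    contrib <- rep(NA_real_, nrow(rel))
  } else {
    contrib <- 100 * mean_delta / overall
  }
  out <- data.frame(otu_id = rownames(rel), mean_delta = mean_delta,
                    contribution_pct = contrib, row.names = NULL)
  out <- out[order(-out$mean_delta), ]
  attr(out, "overall_dissimilarity") <- overall
  out
}

#' Cell divisions equivalent to a summed enrichment ratio
#'
#' @param R_sum summed R_i over enrichments (natural-log units).
#' @return Number of doublings, `R_sum / ln 2`.
#' @export
doublings <- function(R_sum) R_sum / log(2)

#' PCA of community profiles
#'
#' Principal-component analysis on the covariance matrix of OTU relative
#' abundances (samples as observations, centred, unscaled).
#'
#' @param x An [OTUExperiment-class] or relative-abundance matrix
#'   (OTUs x samples).
#' @return A `prcomp` object (observations = samples).
#' @export
communityPCA <- function(x) {
  rel <- if (is(x, "OTUExperiment")) relativeAbundance(x) else x
  stats::prcomp(t(rel), center = TRUE, scale. = FALSE)
}
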