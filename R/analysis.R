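## Downstream statistics: joining population/clinical variant tables to
## predicted stability changes, allele-frequency binning, distribution
## summaries and the bootstrap difference of medians.

#' Join a variant table to predicted stability changes
#'
#' Inner join of a scan table and a variant annotation table on
#' (protein id, residue index, mutant amino acid), with wild-type
#' consistency enforced: rows whose stated wild type differs from the
#' structure's are rejected and counted. Variants at positions without
#' structure coverage are dropped. Join statistics (matched, wt_mismatch,
#' missing) are attached as attribute \code{"join_stats"}.
#'
#' @param scanTable a \linkS4class{ScanTable} or its record data.frame
#' @param variantTable data.frame with columns \code{protein_id},
#'   \code{residue_index}, \code{wt_aa}, \code{mut_aa}, and optionally
#'   \code{class} and \code{allele_frequency}
#' @return data.frame of annotated variants with a \code{ddg} column
#'   (kcal/mol)
#' @export
annotateVariants <- function(scanTable, variantTable) {
  scan <- if (is(scanTable, "ScanTable")) scanTable@records else scanTable
  v <- variantTable
  empty <- data.frame(protein_id = character(), residue_index = integer(),
                      wt_aa = character(), mut_aa = character(),
                      class = character(), allele_frequency = numeric(),
                      ddg = numeric(), stringsAsFactors = FALSE)
  stats <- c(matched = 0L, wt_mismatch = 0L, missing = 0L)
  if (nrow(v) == 0) {
    attr(empty, "join_stats") <- stats
    return(empty)
  }
  key_scan <- paste(scan$source_id, scan$residue_index, scan$mut_aa)
  key_var <- paste(v$protein_id, v$residue_index, v$mut_aa)
  hit <- match(key_var, key_scan)
  missing <- is.na(hit)
  wt_mismatch <- !missing & v$wt_aa != scan$wt_aa[hit]
  keep <- !missing & !wt_mismatch
  stats <- c(matched = sum(keep), wt_mismatch = sum(wt_mismatch),
             missing = sum(missing))
  if (any(wt_mismatch))
    message(sum(wt_mismatch), " variant(s) rejected: stated wild type ",
            "differs from the structure")
  out <- data.frame(
    protein_id = v$protein_id[keep], residue_index = v$residue_index[keep],
    wt_aa = v$wt_aa[keep], mut_aa = v$mut_aa[keep],
    class = if ("class" %in% names(v)) v$class[keep] else
      rep("unlabeled", sum(keep)),
    allele_frequency = if ("allele_frequency" %in% names(v))
      v$allele_frequency[keep] else rep(NA_real_, sum(keep)),
    ddg = scan$ddg_kcal_per_mol[hit[keep]], stringsAsFactors = FALSE)
  attr(out, "join_stats") <- stats
  out
}

#' Bin annotated variants by allele frequency
#'
#' Three bins: common (AF > \code{thresholds[1]}), intermediate
#' (\code{thresholds[1]} >= AF > \code{thresholds[2]}) and rare
#' (AF <= \code{thresholds[2]}), defaulting to 1e-2 and 1e-4. A frequency
#' exactly at a threshold goes to the lower bin. Rows without an allele
#' frequency are dropped; the partition over the remaining rows is
#' exhaustive and disjoint.
#'
#' @param annotations data.frame from \code{\link{annotateVariants}}
#' @param thresholds decreasing length-2 numeric vector of AF cutoffs
#' @return the input rows with AF, plus a factor column \code{af_bin} with
#'   levels \code{common}, \code{intermediate}, \code{rare}
#' @export
binByAlleleFrequency <- function(annotations, thresholds = c(1e-2, 1e-4)) {
  stopifnot(length(thresholds) == 2, thresholds[1] > thresholds[2])
  af <- annotations$allele_frequency
  if (any(af < 0, na.rm = TRUE)) stop("negative allele frequency")
  keep <- !is.na(af)
  out <- annotations[keep, , drop = FALSE]
  af <- af[keep]
  out$af_bin <- factor(
    ifelse(af > thresholds[1], "common",
           ifelse(af > thresholds[2], "intermediate", "rare")),
    levels = c("common", "intermediate", "rare"))
  out
}

#' Summarize a ddG group
#'
#' Median and the central 95\% range (2.5 and 97.5 percentiles, linear
#' interpolation between order statistics).
#'
#' @param ddg numeric vector, kcal/mol; must be non-empty
#' @return data.frame with \code{n}, \code{median_ddg}, \code{lo95},
#'   \code{hi95}
#' @export
summarizeDdg <- function(ddg) {
  if (length(ddg) == 0) stop("empty group")
  q <- quantile(ddg, c(0.025, 0.975), names = FALSE, type = 7)
  data.frame(n = length(ddg), median_ddg = median(ddg), lo95 = q[1],
             hi95 = q[2])
}

#' Bootstrap difference of medians
#'
#' Point estimate \code{median(a) - median(b)}; each sample is resampled
#' with replacement at its own size \code{nResamples} times and the 95\%
#' confidence interval is the 2.5/97.5 percentile range of the resampled
#' median differences. Deterministic given \code{seed}.
#'
#' @param a,b non-empty numeric samples
#' @param nResamples bootstrap resamples (default 1e4)
#' @param seed RNG seed
#' @return list with \code{diff}, \code{ci} (length 2), \code{nResamples}
#' @export
bootstrapMedianDifference <- function(a, b, nResamples = 10000L,
                                      seed = 1L) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  set.seed(seed)
  na <- length(a)
  nb <- length(b)
  diffs <- vapply(seq_len(nResamples), function(i)
    median(a[sample.int(na, na, replace = TRUE)]) -
      median(b[sample.int(nb, nb, replace = TRUE)]),
    numeric(1))
  list(diff = median(a) - median(b),
       ci = quantile(diffs, c(0.025, 0.975), names = FALSE, type = 7),
       nResamples = nResamples)
}
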