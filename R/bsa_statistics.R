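#' Alt-allele read fraction of a pool
#'
#' @param ref,alt read counts (vectorized); every site must have depth
#'   greater than zero (zero-depth sites are excluded upstream by the
#'   depth filter).
#' @return alt / (ref + alt).
#' @export
allele_frequency <- function(ref, alt) {
  depth <- ref + alt
  if (any(depth <= 0)) stop("zero-depth site: allele frequency undefined")
  alt / depth
}

#' Euclidean distance between the pools' allele-frequency vectors
#'
#' Computed over both allele coordinates of a biallelic site,
#' `sqrt((f_gt - f_wt)^2 + ((1-f_gt) - (1-f_wt))^2)`, which reduces to
#' `sqrt(2) * |f_gt - f_wt|`. Ranges from 0 (identical pools) to
#' `sqrt(2)` (opposite fixation).
#'
#' @param f_wt,f_gt alt-allele fractions in each pool (vectorized).
#' @return the ED statistic.
#' @export
euclidean_distance <- function(f_wt, f_gt) {
  .check_num(f_wt, "f_wt", 0, 1); .check_num(f_gt, "f_gt", 0, 1)
  sqrt((f_gt - f_wt)^2 + ((1 - f_gt) - (1 - f_wt))^2)
}

#' G-statistic of the 2x2 pool-by-allele read-count table
#'
#' The likelihood-ratio statistic `G = 2 * sum obs * ln(obs/exp)` with
#' expectations from the table margins and the convention
#' `0 * ln(0) = 0`. A zero margin (e.g. no alt reads in either pool)
#' yields `G = 0`.
#'
#' @param wt_ref,wt_alt,gt_ref,gt_alt read counts (vectorized).
#' @return the G statistic, one value per site.
#' @export
g_statistic <- function(wt_ref, wt_alt, gt_ref, gt_alt) {
  n <- wt_ref + wt_alt + gt_ref + gt_alt
  if (any(n <= 0)) stop("empty table: G undefined at zero total depth")
  rw <- wt_ref + wt_alt; rg <- gt_ref + gt_alt
  cr <- wt_ref + gt_ref; ca <- wt_alt + gt_alt
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  2 * (term(wt_ref, rw * cr / n) + term(wt_alt, rw * ca / n) +
       term(gt_ref, rg * cr / n) + term(gt_alt, rg * ca / n))
}

#' Signed allele-frequency difference between pools
#'
#' @inheritParams euclidean_distance
#' @return `f_gt - f_wt`.
#' @export
delta_af <- function(f_wt, f_gt) {
  .check_num(f_wt, "f_wt", 0, 1); .check_num(f_gt, "f_gt", 0, 1)
  f_gt - f_wt
}

#' Distance to the recessive "ideal frequency" pattern
#'
#' At the causal site of a fully recessive trait the mutant (GT) bulk is
#' fixed for the mutant allele and the phenotypically wild-type bulk
#' segregates 1/3 homozygous wild-type : 2/3 heterozygous, i.e. mutant
#' allele fraction 1/3 (a 1:2 mutant:wild-type allele ratio). The ideal
#' vector is therefore `(f_gt, f_wt) = (1, 1/3)`; smaller distances are
#' more candidate-like.
#'
#' @inheritParams euclidean_distance
#' @return `sqrt((f_gt - 1)^2 + (f_wt - 1/3)^2)`, in
#'   `[0, sqrt(1 + 4/9)]`.
#' @export
ideal_frequency_distance <- function(f_wt, f_gt) {
  .check_num(f_wt, "f_wt", 0, 1); .check_num(f_gt, "f_gt", 0, 1)
  sqrt((f_gt - 1)^2 + (f_wt - 1/3)^2)
}

#' Per-site association statistics for a two-pool site table
#'
#' Adds pool allele fractions and all four per-site statistics as columns.
#'
#' @param sites site table with count columns `wt_ref`, `wt_alt`,
#'   `gt_ref`, `gt_alt` (zero-depth pools must have been filtered out).
#' @return `sites` with added columns `f_wt`, `f_gt`, `ed`, `g_stat`,
#'   `delta_af`, `ed_ideal`.
#' @export
site_stats <- function(sites) {
  sites$f_wt <- allele_frequency(sites$wt_ref, sites$wt_alt)
  sites$f_gt <- allele_frequency(sites$gt_ref, sites$gt_alt)
  sites$ed <- euclidean_distance(sites$f_wt, sites$f_gt)
  sites$g_stat <- g_statistic(sites$wt_ref, sites$wt_alt,
                              sites$gt_ref, sites$gt_alt)
  sites$delta_af <- delta_af(sites$f_wt, sites$f_gt)
  sites$ed_ideal <- ideal_frequency_distance(sites$f_wt, sites$f_gt)
  sites
}
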