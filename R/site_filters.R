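#' Reconstruct a pool genotype call from read counts
#'
#' A pooled sample has no individual genotype, but for filtering purposes
#' a pool is called homozygous-reference, heterozygous-like or
#' homozygous-alternate from its alt read fraction. Calls mirror what a
#' diploid caller reports on a pool dominated by one genotype class.
#'
#' @param ref,alt read counts (vectorized).
#' @param hom_ref_max call `hom_ref` when alt fraction <= this (default 0.1).
#' @param hom_alt_min call `hom_alt` when alt fraction >= this (default 0.9).
#' @param min_call_depth below this depth the call is `nocall` (default 5).
#' @return `data.frame(call, alt_fraction)`; `call` is one of
#'   `"hom_ref"`, `"het"`, `"hom_alt"`, `"nocall"` (`alt_fraction` is `NA`
#'   at zero depth).
#' @export
call_pool_genotype <- function(ref, alt, hom_ref_max = 0.1,
                               hom_alt_min = 0.9, min_call_depth = 5) {
  stopifnot(hom_ref_max >= 0, hom_alt_min <= 1,
            hom_ref_max < hom_alt_min)
  if (any(ref < 0) || any(alt < 0)) stop("negative read counts")
  depth <- ref + alt
  af <- ifelse(depth > 0, alt / depth, NA_real_)
  call <- ifelse(depth < min_call_depth, "nocall",
          ifelse(af <= hom_ref_max, "hom_ref",
          ifelse(af >= hom_alt_min, "hom_alt", "het")))
  data.frame(call = call, alt_fraction = af)
}

# attach a one-row attrition record to a filtered table
.with_log <- function(out, name, n_in) {
  attr(out, "filter_log") <- data.frame(filter = name,
                                        removed = n_in - nrow(out),
                                        retained = nrow(out))
  out
}

#' Depth filter
#'
#' Retains sites whose depth lies in `[dp_min, dp_max]`. By default depth
#' is the combined depth of both pools (25--250 brackets the ~60x
#' expectation of two 30x pools); `per_pool = TRUE` applies the bounds to
#' each pool separately instead.
#'
#' @param sites site table with `wt_ref`, `wt_alt`, `gt_ref`, `gt_alt`.
#' @param dp_min,dp_max inclusive depth bounds (defaults 25 and 250).
#' @param per_pool apply bounds per pool rather than to the combined depth.
#' @return filtered table; attribute `filter_log` records attrition.
#' @export
filter_depth <- function(sites, dp_min = 25, dp_max = 250,
                         per_pool = FALSE) {
  wt_dp <- sites$wt_ref + sites$wt_alt
  gt_dp <- sites$gt_ref + sites$gt_alt
  keep <- if (per_pool)
    wt_dp >= dp_min & wt_dp <= dp_max & gt_dp >= dp_min & gt_dp <= dp_max
  else {
    total <- wt_dp + gt_dp
    total >= dp_min & total <= dp_max
  }
  .with_log(sites[keep, , drop = FALSE], "depth", nrow(sites))
}

#' Remove sites homozygous-alternate in both pools
#'
#' Such sites reflect fixed differences between the mapping parents and
#' the reference assembly, not segregation in the cross. Sites where
#' either pool is `nocall` are never removed on missing evidence.
#'
#' @inheritParams filter_depth
#' @param ... passed to [call_pool_genotype()].
#' @return filtered table with `filter_log` attribute.
#' @export
filter_shared_hom_alt <- function(sites, ...) {
  wt <- call_pool_genotype(sites$wt_ref, sites$wt_alt, ...)$call
  gt <- call_pool_genotype(sites$gt_ref, sites$gt_alt, ...)$call
  keep <- !(wt == "hom_alt" & gt == "hom_alt")
  out <- .with_log(sites[keep, , drop = FALSE], "shared_hom_alt",
                   nrow(sites))
  attr(out, "n_nocall") <- sum(wt == "nocall" | gt == "nocall")
  out
}

#' Remove sites heterozygous in both pools
#'
#' For a recessive qualitative trait the causal region cannot be
#' heterozygous in the mutant bulk, so sites het in both pools carry no
#' mapping signal and mostly mark residual parental heterozygosity or
#' collapsed repeats.
#'
#' @inheritParams filter_shared_hom_alt
#' @return filtered table with `filter_log` attribute.
#' @export
filter_shared_het <- function(sites, ...) {
  wt <- call_pool_genotype(sites$wt_ref, sites$wt_alt, ...)$call
  gt <- call_pool_genotype(sites$gt_ref, sites$gt_alt, ...)$call
  keep <- !(wt == "het" & gt == "het")
  .with_log(sites[keep, , drop = FALSE], "shared_het", nrow(sites))
}

#' Exact test for depletion of exonic variants
#'
#' Compares the observed proportion of exonic variants against the
#' genome-wide exonic fraction with an exact (binomial) test, the
#' one-sample analogue of a Fisher comparison of proportions.
#'
#' @param n_exonic_variants observed exonic variant count.
#' @param n_total_variants total variant count (> 0).
#' @param exonic_fraction_genome genomic exonic fraction, in (0, 1).
#' @return list with `p_value` (two-sided), `observed_fraction`,
#'   `expected_fraction`, and `direction` (`"depleted"`, `"enriched"` or
#'   `"none"`).
#' @export
exonic_depletion_test <- function(n_exonic_variants, n_total_variants,
                                  exonic_fraction_genome) {
  stopifnot(.is_count(n_exonic_variants), .is_count(n_total_variants))
  if (n_total_variants == 0) stop("zero total variants")
  if (exonic_fraction_genome <= 0 || exonic_fraction_genome >= 1)
    stop("exonic_fraction_genome must lie in (0, 1)")
  bt <- binom.test(n_exonic_variants, n_total_variants,
                   p = exonic_fraction_genome)
  obs <- n_exonic_variants / n_total_variants
  list(p_value = bt$p.value,
       observed_fraction = obs,
       expected_fraction = exonic_fraction_genome,
       direction = if (obs < exonic_fraction_genome) "depleted"
                   else if (obs > exonic_fraction_genome) "enriched"
                   else "none")
}
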