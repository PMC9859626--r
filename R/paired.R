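#' Fisher's exact test on tumor-normal supporting counts
#'
#' For a candidate with `n1` variant / `n0` reference reads in the normal
#' and `c1` variant / `c0` reference reads in the tumor, the point
#' probability of the observed 2x2 table is the hypergeometric mass
#' `p = (n1+n0)! (c1+c0)! (c1+n1)! (c0+n0)! /
#'      [n1! n0! c1! c0! (n1+n0+c1+c0)!]`,
#' evaluated in log-gamma space.  `fisher_one_sided_p()` sums the point
#' probabilities of all tables with the same margins and a normal-variant
#' count at most `n1` — the tail toward tumor enrichment, which is the
#' default p-value of the paired cascade (`fet_mode = "one_sided"`).
#'
#' @param n1,n0 Variant / reference supporting reads in the normal sample.
#' @param c1,c0 Variant / reference supporting reads in the tumor sample.
#' @return A probability in `[0, 1]`.
#' @examples
#' fisher_point_probability(0, 10, 0, 10)  # 1: only one table possible
#' fisher_one_sided_p(1, 99, 20, 80)
#' @export
fisher_point_probability <- function(n1, n0, c1, c0) {
  counts <- c(n1, n0, c1, c0)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be >= 0")
  lf <- function(x) lgamma(x + 1)
  lp <- lf(n1 + n0) + lf(c1 + c0) + lf(c1 + n1) + lf(c0 + n0) -
    (lf(n1) + lf(n0) + lf(c1) + lf(c0) + lf(n1 + n0 + c1 + c0))
  min(exp(lp), 1)
}

#' @rdname fisher_point_probability
#' @export
fisher_one_sided_p <- function(n1, n0, c1, c0) {
  counts <- c(n1, n0, c1, c0)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be >= 0")
  nn <- n1 + n0          # normal margin
  v <- n1 + c1           # variant margin
  ks <- 0:n1
  feasible <- ks >= max(0, v - (c1 + c0)) & ks <= min(nn, v)
  sum(vapply(ks[feasible], function(k)
    fisher_point_probability(k, nn - k, v - k, c1 + c0 - (v - k)),
    numeric(1)))
}

#' Tumor-normal somatic classification cascade
#'
#' A tumor candidate (already past the tumor LOD and evidence screens) is
#' tested against the matched normal in a fixed order:
#' \enumerate{
#'   \item Normal-frequency gate: reject unless the normal VAF is below
#'     `nf` percent or below `normal_ratio` (0.2) times the tumor VAF.
#'   \item Variants absent from the normal, or whose normal supporting
#'     reads all lie on one strand, are emitted directly.
#'   \item When the normal VAF is below `normal_lod_gate_ratio` (0.5)
#'     times the tumor VAF, the LOD of the variant in the normal sample
#'     decides: below `lod_threshold` (3.9) the variant is emitted;
#'     otherwise Fisher's exact test is computed and the variant is
#'     emitted iff `p <= fet_p_threshold`.
#'   \item Otherwise (gate 1 passed via `nf` alone) Fisher's exact test
#'     decides directly.
#' }
#'
#' @param tumor_vaf,normal_vaf VAFs in percent (duplicate-collapsed).
#' @param tumor_support,tumor_depth,normal_support,normal_depth
#'   Duplicate-collapsed counts.
#' @param normal_single_strand `TRUE` when every normal supporting read
#'   lies on one strand; such one-sided support is treated as artifact and
#'   the candidate is emitted.
#' @param normal_obs Normal-site observations for the LOD (data.frame with
#'   logical `is_alt`, `is_ref` and `qual`), or `NULL` to skip.
#' @param config A [caller_config()].
#' @return List: `emit`, `path_taken`, `fet_p`, `lod_normal`.
#' @export
classify_paired <- function(tumor_vaf, tumor_support, tumor_depth,
                            normal_vaf, normal_support, normal_depth,
                            normal_single_strand = FALSE,
                            normal_obs = NULL,
                            config = caller_config()) {
  config <- as_config(config)
  decision <- function(emit, path, p = NA_real_, lod = NA_real_)
    list(emit = emit, path_taken = path, fet_p = p, lod_normal = lod)
  if (is.na(normal_depth) || normal_depth == 0L)
    return(decision(FALSE, "no_normal_coverage"))
  ## (1) normal-frequency gate
  if (!(normal_vaf < config$nf ||
        normal_vaf < config$normal_ratio * tumor_vaf))
    return(decision(FALSE, "nf_gate_fail"))
  ## (2) absent or single-strand normal support
  if (normal_support == 0L) return(decision(TRUE, "absent_in_normal"))
  if (isTRUE(normal_single_strand))
    return(decision(TRUE, "same_direction_normal"))
  fet <- function() {
    n1 <- normal_support; n0 <- normal_depth - normal_support
    c1 <- tumor_support; c0 <- tumor_depth - tumor_support
    if (config$fet_mode == "point") fisher_point_probability(n1, n0, c1, c0)
    else fisher_one_sided_p(n1, n0, c1, c0)
  }
  ## (3) normal-LOD gate
  if (normal_vaf < config$normal_lod_gate_ratio * tumor_vaf) {
    lod_n <- if (is.null(normal_obs)) Inf else
      lod_from_indicators(normal_obs$is_alt, normal_obs$is_ref,
                          normal_obs$qual,
                          f = normal_support / normal_depth)
    if (lod_n < config$lod_threshold)
      return(decision(TRUE, "lod_gate_pass", lod = lod_n))
    p <- fet()
    return(decision(p <= config$fet_p_threshold,
                    if (p <= config$fet_p_threshold) "fet_pass" else "fet_fail",
                    p = p, lod = lod_n))
  }
  ## (4) straight to Fisher's exact test
  p <- fet()
  decision(p <= config$fet_p_threshold,
           if (p <= config$fet_p_threshold) "fet_pass" else "fet_fail",
           p = p)
}
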