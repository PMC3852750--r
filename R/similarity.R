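#' Similarity metrics on sparse fingerprints
#'
#' Dice is the default metric for similarity maps; Tanimoto is provided as
#' the pluggable alternative, and any function with the same contract
#' (two compatible `sparse_fp`, value in \[0, 1\], symmetric) can be passed
#' wherever a metric is accepted.
#'
#' Both metrics operate on the sparse entries only — no dense expansion —
#' so 2^32 bit-spaces cost nothing. The similarity of two *empty*
#' fingerprints is defined as 0, not 1: masking the only atom of a
#' one-atom molecule empties its fingerprint, and calling that perfectly
#' similar to anything would flip the sign of its weight.
#'
#' @name similarity
NULL

#' @noRd
check_compatible <- function(a, b) {
  if (!inherits(a, "sparse_fp") || !inherits(b, "sparse_fp")) {
    abort("metrics need two sparse_fp objects", "simmapr_metric_domain_error")
  }
  if (a$bitspace != b$bitspace || a$binary != b$binary) {
    abort(sprintf(
      "incompatible fingerprints: bitspace 2^%g/%s vs 2^%g/%s",
      log2(a$bitspace), if (a$binary) "binary" else "counts",
      log2(b$bitspace), if (b$binary) "binary" else "counts"
    ), "simmapr_metric_domain_error")
  }
}

#' @noRd
shared_min_sum <- function(a, b) {
  idx <- match(a$bits, b$bits)
  hit <- !is.na(idx)
  sum(pmin(a$counts[hit], b$counts[idx[hit]]))
}

#' Dice similarity
#'
#' `2 * sum_k min(a_k, b_k) / (sum_k a_k + sum_k b_k)` over fingerprint
#' entries; 0 when both fingerprints are empty.
#'
#' @param a,b `sparse_fp` objects over the same bitspace and mode
#' @return a number in \[0, 1\]
#' @export
dice <- function(a, b) {
  check_compatible(a, b)
  denom <- fp_total(a) + fp_total(b)
  if (denom == 0) {
    return(0)
  }
  2 * shared_min_sum(a, b) / denom
}

#' Tanimoto similarity
#'
#' `sum_k min(a_k, b_k) / (sum_k a_k + sum_k b_k - sum_k min(a_k, b_k))`;
#' 0 when both fingerprints are empty.
#'
#' @inheritParams dice
#' @return a number in \[0, 1\]
#' @export
tanimoto <- function(a, b) {
  check_compatible(a, b)
  if (fp_total(a) + fp_total(b) == 0) {
    return(0)
  }
  m <- shared_min_sum(a, b)
  m / (fp_total(a) + fp_total(b) - m)
}
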