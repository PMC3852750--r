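#' Atomic weights: the core of a similarity map
#'
#' The weight of atom *i* of a test (probe) molecule is the change a
#' similarity or predicted probability undergoes when the fingerprint bits
#' set by that atom are removed:
#' `raw_i = s_orig - s_mod(i)`, where `s_mod(i)` is recomputed against the
#' probe fingerprint with atom *i*'s bits masked. A positive weight means
#' the atom supports the similarity (or predicted activity); a negative
#' weight means removing it *increases* the score. Raw weights are
#' normalized by the maximum absolute value into \[-1, 1\] for rendering.
#'
#' @name atomic_weights
NULL

#' Remove one atom's bits from a fingerprint
#'
#' Count vectors: each owned bit's count drops by the atom's multiplicity
#' for that bit and entries reaching zero disappear. Binary vectors: each
#' owned bit is cleared entirely — even when another atom co-owns it
#' through a fold collision. That clearing rule is deliberate: it is what
#' produces the amide/linker collision artifact visible in folded circular
#' maps, and the package preserves it rather than repairing it. The input
#' fingerprint is never mutated.
#'
#' @param fp a `sparse_fp`
#' @param ownership the companion `atom_ownership`
#' @param atom atom index (1-based)
#' @return a new `sparse_fp`
#' @export
remove_atom_bits <- function(fp, ownership, atom) {
  stopifnot(inherits(fp, "sparse_fp"), inherits(ownership, "atom_ownership"))
  if (!is.numeric(atom) || length(atom) != 1L || atom < 1 ||
      atom > length(ownership) || atom != round(atom)) {
    abort(sprintf("invalid atom index %s for %d atoms",
                  format(atom), length(ownership)), "simmapr_index_error")
  }
  own <- ownership[[atom]]
  if (!nrow(own)) {
    return(fp)
  }
  bits <- fp$bits
  counts <- fp$counts
  idx <- match(own$bit, bits)
  if (anyNA(idx)) {
    abort("ownership references bits absent from the fingerprint",
          "simmapr_fp_error")
  }
  if (fp$binary) {
    keep <- setdiff(seq_along(bits), idx)
  } else {
    counts[idx] <- counts[idx] - own$mult
    keep <- which(counts > 0)
  }
  sparse_fp(bits[keep], counts[keep], binary = fp$binary,
            bitspace = fp$bitspace, spec = fp$spec)
}

#' Normalize raw atomic weights into \[-1, 1\]
#'
#' Division by the maximum absolute raw value; an all-zero vector stays
#' all-zero. Signs are preserved exactly.
#'
#' @param raw numeric vector of finite raw weights
#' @return numeric vector with `max(abs(.))` equal to 1 (or all zeros)
#' @export
normalize_weights <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw))) {
    abort("weights must be finite numbers", "simmapr_value_error")
  }
  m <- max(abs(raw))
  if (m == 0) {
    return(raw * 0)
  }
  raw / m
}

#' @noRd
new_atom_weights <- function(raw, mode, score_orig) {
  structure(
    list(raw = raw, normalized = normalize_weights(raw), mode = mode,
         score_orig = score_orig),
    class = "atom_weights"
  )
}

#' @export
print.atom_weights <- function(x, ...) {
  cat(sprintf(
    "<atom_weights (%s): %d atoms, original score %.4f, max |raw| %.4g>\n",
    x$mode, length(x$raw), x$score_orig, max(abs(x$raw))))
  invisible(x)
}

#' Per-atom similarity weights of a probe against a reference
#'
#' For each probe atom, its bits are removed from the probe fingerprint and
#' the similarity to the reference recomputed; the weight is the drop.
#' Atoms are masked one at a time against the unmodified fingerprint (no
#' joint masking).
#'
#' @param ref_fp reference `sparse_fp`
#' @param probe_fp probe `sparse_fp` (same flavor as the reference)
#' @param probe_ownership the probe's `atom_ownership`
#' @param metric similarity function, [dice()] by default
#' @return an `atom_weights` object with `raw`, `normalized`, `mode` and
#'   the original similarity `score_orig`
#' @export
similarity_weights <- function(ref_fp, probe_fp, probe_ownership,
                               metric = dice) {
  s_orig <- metric(ref_fp, probe_fp)
  raw <- vapply(seq_along(probe_ownership), function(a) {
    s_orig - metric(ref_fp, remove_atom_bits(probe_fp, probe_ownership, a))
  }, numeric(1))
  new_atom_weights(raw, "similarity", s_orig)
}

#' Per-atom predicted-probability weights under a classifier
#'
#' Same masking procedure, but the score is a model's P(active):
#' `raw_i = P(active | fp) - P(active | fp masked at i)`, or the
#' difference of log-probabilities in `"log_probability"` mode (the
#' default for naive Bayes models, whose evidence is multiplicative).
#' A zero probability in log mode raises a `simmapr_domain_error` rather
#' than clamping silently; switch to `"probability"` mode in that case.
#'
#' @param model an `activity_model`, or any function mapping a `sparse_fp`
#'   to a score in \[0, 1\] (a custom scorer plugs straight in: scoring
#'   with `function(fp) dice(ref_fp, fp)` makes this identical to
#'   [similarity_weights()])
#' @param probe_fp the probe's `sparse_fp` in the model's feature space
#' @param probe_ownership the probe's `atom_ownership`
#' @param mode `"probability"` or `"log_probability"`; defaults to log for
#'   naive Bayes and linear for everything else
#' @return an `atom_weights` object
#' @export
probability_weights <- function(model, probe_fp, probe_ownership,
                                mode = NULL) {
  stopifnot(inherits(model, "activity_model") || is.function(model))
  if (is.null(mode)) {
    mode <- if (!is.function(model) && model$kind == "bernoulli_nb") {
      "log_probability"
    } else {
      "probability"
    }
  }
  mode <- match.arg(mode, c("probability", "log_probability"))
  log_mode <- mode == "log_probability"
  fps <- c(list(probe_fp), lapply(seq_along(probe_ownership), function(a) {
    remove_atom_bits(probe_fp, probe_ownership, a)
  }))
  p <- if (is.function(model)) {
    vapply(fps, model, numeric(1))
  } else {
    # one batched prediction for the original plus every masked variant
    predict_prob_batch(model, fps)
  }
  scores <- if (log_mode) {
    if (any(p <= 0)) {
      abort("P(active) = 0 encountered in log mode; use probability mode",
            "simmapr_domain_error")
    }
    log(p)
  } else {
    p
  }
  raw <- scores[1] - scores[-1]
  new_atom_weights(raw, mode, scores[1])
}
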