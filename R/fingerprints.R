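#' Sparse fingerprints and atom ownership
#'
#' A fingerprint is stored sparsely as a set of bit-ids with positive
#' counts, a binary/count flag and a declared bit-space size: 2^32 for
#' count vectors (atom pairs, CountMorgan) and the folded size (default
#' 1024) for circular bit vectors. Alongside each fingerprint the package
#' builds an *ownership* table: for every atom, the multiset of bit-ids
#' whose generating feature involves that atom (an atom-pair descriptor
#' involves its two atoms; a circular environment involves its center and
#' every atom within the radius). Ownership is what makes per-atom bit
#' removal — the heart of a similarity map — well defined.
#'
#' Bit-ids are held as doubles because 2^32 exceeds R's integer range;
#' they are exact (all ids are far below 2^53).
#'
#' @name fingerprints
NULL

#' Construct a sparse fingerprint
#'
#' @param bits numeric vector of distinct bit-ids
#' @param counts positive integer counts, one per bit
#' @param binary if `TRUE` all counts must be 1
#' @param bitspace declared bit-space size (every id must be smaller)
#' @param spec the `fingerprint_spec` that produced it, if any
#' @return a `sparse_fp` object
#' @export
sparse_fp <- function(bits, counts, binary, bitspace, spec = NULL) {
  bits <- as.numeric(bits)
  counts <- as.numeric(counts)
  stopifnot(length(bits) == length(counts), !anyDuplicated(bits))
  if (any(counts < 1)) {
    abort("zero or negative counts are not representable", "simmapr_fp_error")
  }
  if (binary && any(counts != 1)) {
    abort("binary fingerprints must have all counts equal to 1",
          "simmapr_fp_error")
  }
  if (any(bits >= bitspace) || any(bits < 0)) {
    abort("bit-id outside the declared bitspace", "simmapr_fp_error")
  }
  o <- order(bits)
  structure(list(bits = bits[o], counts = counts[o], binary = binary,
                 bitspace = bitspace, spec = spec),
            class = "sparse_fp")
}

#' @export
print.sparse_fp <- function(x, ...) {
  cat(sprintf("<sparse_fp: %d set bits, total count %s, %s, bitspace 2^%g>\n",
              length(x$bits), format(sum(x$counts)),
              if (x$binary) "binary" else "counts", log2(x$bitspace)))
  invisible(x)
}

#' Total count of a sparse fingerprint
#' @param fp a `sparse_fp`
#' @export
fp_total <- function(fp) sum(fp$counts)

#' Describe a fingerprint flavor
#'
#' The three shipped flavors mirror common practice: `"ap"` (atom pairs as
#' a 2^32 count vector, classic atom-pair typing, topological distances up
#' to `max_path_length`), `"morgan"` (ECFP-style circular, radius 2 by
#' default: a 1024-bit folded vector when `as_counts = FALSE`, an unfolded
#' 2^32 count vector when `TRUE`) and `"feat_morgan"` (FCFP-style, atoms
#' typed by pharmacophoric features instead of elements).
#'
#' @param kind `"morgan"`, `"feat_morgan"` or `"ap"`
#' @param radius circular-environment radius (circular flavors only)
#' @param max_path_length topological distance cap (atom pairs only)
#' @param as_counts count vector (2^32 ids) instead of a folded bit vector
#' @param folded_size fold target for bit vectors; must be a power of two
#' @return a `fingerprint_spec` object
#' @export
fingerprint_spec <- function(kind = c("morgan", "feat_morgan", "ap"),
                             radius = 2L, max_path_length = 30L,
                             as_counts = NULL, folded_size = 1024L) {
  kind <- match.arg(kind)
  if (is.null(as_counts)) {
    as_counts <- kind == "ap"
  }
  if (kind == "ap" && !as_counts) {
    abort("atom-pair fingerprints are count vectors", "simmapr_fp_error")
  }
  stopifnot(radius >= 0, max_path_length >= 1)
  if (!as_counts) {
    if (folded_size < 2 || bitwAnd(as.integer(folded_size),
                                   as.integer(folded_size) - 1L) != 0L) {
      abort("folded_size must be a power of two", "simmapr_fp_error")
    }
  }
  structure(list(kind = kind, radius = as.integer(radius),
                 max_path_length = as.integer(max_path_length),
                 as_counts = as_counts,
                 folded_size = as.integer(folded_size)),
            class = "fingerprint_spec")
}

#' @export
print.fingerprint_spec <- function(x, ...) {
  cat(sprintf("<fingerprint_spec: %s, %s%s>\n", x$kind,
              if (x$as_counts) "counts (2^32)"
              else sprintf("binary (%d bits)", x$folded_size),
              if (x$kind == "ap") sprintf(", max path %d", x$max_path_length)
              else sprintf(", radius %d", x$radius)))
  invisible(x)
}

#' @noRd
new_ownership <- function(per_atom) {
  per_atom <- lapply(per_atom, function(df) {
    if (is.null(df) || !nrow(df)) {
      return(data.frame(bit = numeric(), mult = numeric()))
    }
    agg <- tapply(df$mult, df$bit, sum)
    data.frame(bit = as.numeric(names(agg)), mult = as.numeric(agg),
               row.names = NULL)
  })
  structure(per_atom, class = "atom_ownership")
}

#' @export
print.atom_ownership <- function(x, ...) {
  cat(sprintf("<atom_ownership: %d atoms, %d owned (bit, atom) records>\n",
              length(x), sum(vapply(x, nrow, integer(1)))))
  invisible(x)
}

#' @noRd
ap_from_pairs <- function(pairs, max_path_length, n_atom) {
  if (length(pairs)) {
    i <- vapply(pairs, function(p) p[[1]] + 1L, numeric(1))
    j <- vapply(pairs, function(p) p[[2]] + 1L, numeric(1))
    code <- vapply(pairs, function(p) as.numeric(p[[4]]), numeric(1))
  } else {
    i <- j <- code <- numeric()
  }
  agg <- if (length(code)) tapply(rep(1, length(code)), code, sum) else NULL
  fp <- sparse_fp(
    bits = if (length(code)) as.numeric(names(agg)) else numeric(),
    counts = if (length(code)) as.numeric(agg) else numeric(),
    binary = FALSE, bitspace = 2^32,
    spec = fingerprint_spec("ap", max_path_length = max_path_length)
  )
  own <- lapply(seq_len(n_atom), function(a) {
    sel <- i == a | j == a
    data.frame(bit = code[sel], mult = rep(1, sum(sel)))
  })
  list(fp = fp, ownership = new_ownership(own))
}

#' Atom-pair fingerprint with ownership
#'
#' Count vector over hashed (atom type, atom type, topological distance)
#' descriptors for every heavy-atom pair within `max_path_length` bonds.
#' Atom typing follows the classic atom-pair convention (element,
#' heavy-neighbor count, pi-electron count), delegated to the toolkit.
#' Each pair contributes multiplicity 1 to the ownership of both its
#' atoms, so masking an atom decrements every pair involving it by one.
#'
#' @param mol a `simmapr_mol`
#' @param max_path_length maximum topological distance (bonds), default 30
#' @return a list with components `fp` (`sparse_fp`) and `ownership`
#'   (`atom_ownership`)
#' @export
atom_pair_fingerprint <- function(mol, max_path_length = 30L) {
  stopifnot(inherits(mol, "simmapr_mol"), n_atoms(mol) >= 1)
  res <- rdkit_call("fingerprints", list(
    molecules = list(mol$smiles),
    flavors = list(list(kind = "ap", max_path_length = max_path_length))
  ))[[1]]
  ap_from_pairs(res$flavors[[1]]$pairs, max_path_length, n_atoms(mol))
}

#' @noRd
morgan_from_envs <- function(envs, spec, dists) {
  n_atom <- nrow(dists)
  if (length(envs)) {
    bit <- vapply(envs, function(e) as.numeric(e[[1]]), numeric(1))
    center <- vapply(envs, function(e) e[[2]] + 1L, numeric(1))
    radius <- vapply(envs, function(e) as.numeric(e[[3]]), numeric(1))
  } else {
    bit <- center <- radius <- numeric()
  }
  if (spec$as_counts) {
    agg <- tapply(rep(1, length(bit)), bit, sum)
    fp <- sparse_fp(as.numeric(names(agg)), as.numeric(agg),
                    binary = FALSE, bitspace = 2^32, spec = spec)
  } else {
    ub <- sort(unique(bit))
    fp <- sparse_fp(ub, rep(1, length(ub)), binary = TRUE,
                    bitspace = spec$folded_size, spec = spec)
  }
  own <- lapply(seq_len(n_atom), function(a) numeric())
  # every atom within `radius` bonds of the center is part of the
  # environment and therefore co-owns the bit
  per_atom_bits <- vector("list", n_atom)
  for (k in seq_along(bit)) {
    members <- which(dists[center[k], ] <= radius[k])
    for (a in members) {
      per_atom_bits[[a]] <- c(per_atom_bits[[a]], bit[k])
    }
  }
  own <- lapply(per_atom_bits, function(bs) {
    data.frame(bit = bs, mult = rep(1, length(bs)))
  })
  list(fp = fp, ownership = new_ownership(own))
}

#' Circular (Morgan/ECFP-style) fingerprint with ownership
#'
#' One feature per (center atom, radius 0..`spec$radius`) unique
#' environment, hashed by the toolkit into a 2^32 space (count mode) or
#' folded to `spec$folded_size` bits (binary mode; folding is `hash mod
#' size`, so distinct environments can collide on one bit — deliberately
#' preserved, see the vignette). Ownership maps each atom to every bit
#' whose generating environment contains it: the center *and* all atoms
#' within the environment radius, with multiplicity equal to the number of
#' such environments landing on the bit.
#'
#' @param mol a `simmapr_mol`
#' @param spec a `fingerprint_spec` with kind `"morgan"` or `"feat_morgan"`
#' @return a list with components `fp` and `ownership`
#' @export
circular_fingerprint <- function(mol, spec = fingerprint_spec("morgan")) {
  stopifnot(inherits(mol, "simmapr_mol"), n_atoms(mol) >= 1,
            inherits(spec, "fingerprint_spec"))
  if (!spec$kind %in% c("morgan", "feat_morgan")) {
    abort("circular_fingerprint needs a morgan or feat_morgan spec",
          "simmapr_fp_error")
  }
  res <- rdkit_call("fingerprints", list(
    molecules = list(mol$smiles),
    flavors = list(list(
      kind = spec$kind, radius = spec$radius,
      folded_size = if (spec$as_counts) NULL else spec$folded_size
    ))
  ))[[1]]
  morgan_from_envs(res$flavors[[1]]$envs, spec, topological_distances(mol))
}

#' Compute a fingerprint of any flavor
#'
#' Dispatches on `spec$kind`; see [atom_pair_fingerprint()] and
#' [circular_fingerprint()].
#'
#' @param mol a `simmapr_mol`
#' @param spec a `fingerprint_spec`
#' @return a list with components `fp` and `ownership`
#' @export
fingerprint <- function(mol, spec = fingerprint_spec("morgan")) {
  if (spec$kind == "ap") {
    atom_pair_fingerprint(mol, spec$max_path_length)
  } else {
    circular_fingerprint(mol, spec)
  }
}

#' Fingerprints for many molecules in one backend round-trip
#'
#' @param mols list of `simmapr_mol`
#' @param spec a `fingerprint_spec`
#' @return a list, one `list(fp, ownership)` per molecule
#' @export
fingerprints_batch <- function(mols, spec = fingerprint_spec("morgan")) {
  if (inherits(mols, "simmapr_mol")) {
    mols <- list(mols)
  }
  flavor <- if (spec$kind == "ap") {
    list(kind = "ap", max_path_length = spec$max_path_length)
  } else {
    list(kind = spec$kind, radius = spec$radius,
         folded_size = if (spec$as_counts) NULL else spec$folded_size)
  }
  res <- rdkit_call("fingerprints", list(
    molecules = lapply(mols, function(m) m$smiles), flavors = list(flavor)
  ))
  mapply(function(r, m) {
    if (spec$kind == "ap") {
      ap_from_pairs(r$flavors[[1]]$pairs, spec$max_path_length, n_atoms(m))
    } else {
      morgan_from_envs(r$flavors[[1]]$envs, spec, topological_distances(m))
    }
  }, res, mols, SIMPLIFY = FALSE)
}

#' Fold a count fingerprint to a binary vector
#'
#' Folding maps each id to `id mod size` and binarizes, matching the
#' toolkit's bit-vector generation, so folding an unfolded count
#' fingerprint reproduces the directly computed folded vector.
#'
#' @param fp a `sparse_fp`
#' @param size fold target, a power of two
#' @return a binary `sparse_fp` over `size` bits
#' @export
fold_fingerprint <- function(fp, size = 1024L) {
  stopifnot(inherits(fp, "sparse_fp"))
  folded <- sort(unique(fp$bits %% size))
  sparse_fp(folded, rep(1, length(folded)), binary = TRUE, bitspace = size)
}

#' Pharmacophoric feature types for every atom
#'
#' Evaluates the shipped structural pattern definitions (six classes:
#' donor, acceptor, aromatic, halogen, basic, acidic) against a molecule.
#' These are the feature classes underlying FCFP-style typing; the pattern
#' file is plain text and editable.
#'
#' @param mol a `simmapr_mol`
#' @param defs_path pattern definition file; defaults to the shipped one
#' @return a data.frame with one logical column per feature class, one row
#'   per atom, plus an integer `mask` column (bit 1 = donor ... bit 32 =
#'   acidic)
#' @export
assign_feature_types <- function(mol, defs_path = NULL) {
  if (is.null(defs_path)) {
    defs_path <- system.file("extdata", "feature_definitions.smarts",
                             package = "simmapr")
  }
  lines <- readLines(defs_path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cls <- sub("[[:space:]].*$", "", lines)
  pat <- sub("^[^[:space:]]+[[:space:]]+", "", lines)
  classes <- c("donor", "acceptor", "aromatic", "halogen", "basic", "acidic")
  if (!all(cls %in% classes)) {
    abort(paste("unknown feature class in", defs_path), "simmapr_fp_error")
  }
  hits <- match_smarts(mol, pat)[[1]]
  n <- n_atoms(mol)
  out <- as.data.frame(matrix(FALSE, n, length(classes)))
  names(out) <- classes
  for (k in seq_along(pat)) {
    atoms <- unique(unlist(hits[[k]]))
    if (length(atoms)) {
      out[atoms, cls[k]] <- TRUE
    }
  }
  out$mask <- as.integer(as.matrix(out[classes]) %*% 2^(0:5))
  out
}

#' Densify sparse fingerprints into a model feature matrix
#'
#' @param fps list of `sparse_fp` over a common folded bitspace
#' @return a numeric matrix, one row per fingerprint, columns `f1..fN`
#' @export
fp_matrix <- function(fps) {
  if (inherits(fps, "sparse_fp")) {
    fps <- list(fps)
  }
  sizes <- unique(vapply(fps, function(f) f$bitspace, numeric(1)))
  if (length(sizes) != 1 || sizes > 2^16) {
    abort("fp_matrix needs a common, folded (small) bitspace",
          "simmapr_fp_error")
  }
  n_bits <- as.integer(sizes)
  X <- matrix(0, length(fps), n_bits,
              dimnames = list(NULL, paste0("f", seq_len(n_bits))))
  for (r in seq_along(fps)) {
    X[r, fps[[r]]$bits + 1] <- fps[[r]]$counts
  }
  X
}
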