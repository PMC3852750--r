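#' Molecule objects
#'
#' simmapr represents a molecule as its heavy-atom graph: a table of atoms
#' (element, aromaticity, formal charge, attached hydrogens, heavy-neighbor
#' count), a table of bonds, and optional 2D depiction coordinates.
#' Hydrogens are implicit throughout; atom indices are 1-based, contiguous
#' and stable across every operation, and all atom weights refer to heavy
#' atoms only (maps color heavy atoms, as is standard in 2D depiction).
#'
#' @param text a single SMILES string or a MOL/SDF V2000 molblock
#' @param format one of `"smiles"` or `"molblock"`
#' @param name optional molecule name carried along for reporting
#' @return a `simmapr_mol` object with components `atoms` (data.frame),
#'   `bonds` (data.frame, 1-based endpoint indices), `coords` (n x 2 matrix
#'   or `NULL`), `smiles` (canonical SMILES) and `name`.
#' @details Parsing and sanitization (aromaticity perception included) are
#'   delegated to RDKit; a parse failure raises a `simmapr_parse_error`
#'   carrying the offending input rather than returning `NULL`.
#' @examples
#' \dontrun{
#' m <- parse_molecule("c1ccccc1", name = "benzene")
#' n_atoms(m)
#' }
#' @export
parse_molecule <- function(text, format = c("smiles", "molblock"), name = NULL) {
  format <- match.arg(format)
  stopifnot(is.character(text), length(text) == 1L)
  res <- rdkit_call("parse", list(
    molecules = list(list(text = text, format = format)),
    want_coords = FALSE
  ))[[1]]
  if (!isTRUE(res$ok)) {
    abort(paste0("cannot parse molecule: ", res$error), "simmapr_parse_error",
          input = text)
  }
  new_molecule(res, name = name)
}

#' @noRd
new_molecule <- function(res, name = NULL, coords = NULL) {
  atoms <- do.call(rbind, lapply(res$atoms, function(a) {
    data.frame(
      element = a$element, aromatic = a$aromatic, charge = a$charge,
      n_h = a$n_h, degree = a$degree, stringsAsFactors = FALSE
    )
  }))
  bonds <- if (length(res$bonds)) {
    do.call(rbind, lapply(res$bonds, function(b) {
      data.frame(a = b$a + 1L, b = b$b + 1L, order = b$order,
                 aromatic = b$aromatic)
    }))
  } else {
    data.frame(a = integer(), b = integer(), order = numeric(),
               aromatic = logical())
  }
  if (is.null(coords) && !is.null(res$coords)) {
    coords <- do.call(rbind, lapply(res$coords, unlist))
  }
  structure(
    list(atoms = atoms, bonds = bonds, coords = coords,
         smiles = res$smiles, name = name),
    class = "simmapr_mol"
  )
}

#' @export
print.simmapr_mol <- function(x, ...) {
  cat(sprintf("<simmapr_mol%s: %d atoms, %d bonds%s>\n  %s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              n_atoms(x), nrow(x$bonds),
              if (is.null(x$coords)) "" else ", 2D coords", x$smiles))
  invisible(x)
}

#' Number of heavy atoms in a molecule
#' @param mol a `simmapr_mol`
#' @export
n_atoms <- function(mol) {
  stopifnot(inherits(mol, "simmapr_mol"))
  nrow(mol$atoms)
}

#' Canonical SMILES of a molecule
#' @param mol a `simmapr_mol`
#' @export
write_smiles <- function(mol) {
  stopifnot(inherits(mol, "simmapr_mol"))
  mol$smiles
}

#' Ensure a molecule carries 2D depiction coordinates
#'
#' Coordinates already present are returned untouched; otherwise a 2D
#' layout is computed (deterministically for a fixed input) and attached.
#' Rendering requires coordinates; fingerprints do not.
#'
#' @param mol a `simmapr_mol`
#' @param layout_seed reserved for layout algorithms that randomize; the
#'   default RDKit layout is deterministic, so this is recorded but unused
#' @return the molecule with `coords` populated (one x,y pair per atom)
#' @export
ensure_2d_coords <- function(mol, layout_seed = 0xD3L) {
  stopifnot(inherits(mol, "simmapr_mol"))
  if (!is.null(mol$coords)) {
    return(mol)
  }
  res <- rdkit_call("parse", list(
    molecules = list(list(text = mol$smiles, format = "smiles")),
    want_coords = TRUE, layout_seed = layout_seed
  ))[[1]]
  if (!isTRUE(res$ok) || is.null(res$coords)) {
    abort("2D layout failed", "simmapr_layout_error")
  }
  coords <- do.call(rbind, lapply(res$coords, unlist))
  if (nrow(coords) != n_atoms(mol)) {
    abort("layout returned wrong atom count", "simmapr_layout_error")
  }
  mol$coords <- coords
  mol
}

#' Parse many molecules in one backend round-trip
#'
#' @param texts character vector of SMILES strings or molblocks
#' @param format `"smiles"` or `"molblock"`
#' @param names optional character vector of names
#' @return a list of `simmapr_mol`
#' @export
parse_molecules <- function(texts, format = c("smiles", "molblock"),
                            names = NULL) {
  format <- match.arg(format)
  res <- rdkit_call("parse", list(
    molecules = lapply(texts, function(t) list(text = t, format = format)),
    want_coords = FALSE
  ))
  lapply(seq_along(res), function(i) {
    if (!isTRUE(res[[i]]$ok)) {
      abort(paste0("cannot parse molecule: ", res[[i]]$error),
            "simmapr_parse_error", input = texts[[i]])
    }
    new_molecule(res[[i]], name = if (!is.null(names)) names[[i]] else NULL)
  })
}

#' Read molecules from a SMILES file
#'
#' One molecule per line, optionally followed by whitespace and a name.
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path file path
#' @return a list of `simmapr_mol`
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    parse_molecule(parts[1], "smiles",
                   name = if (length(parts) > 1) parts[2] else NULL)
  })
}

#' Read molecules from an SDF (V2000) file
#' @param path file path
#' @return a list of `simmapr_mol`
#' @export
read_sdf_file <- function(path) {
  lines <- readLines(path)
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) {
    ends <- length(lines)
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- mapply(function(s, e) paste(lines[s:e], collapse = "\n"),
                   starts, ends, SIMPLIFY = TRUE)
  blocks <- blocks[nzchar(trimws(gsub("\\$\\$\\$\\$", "", blocks)))]
  lapply(blocks, function(b) {
    nm <- trimws(strsplit(b, "\n")[[1]][1])
    parse_molecule(b, "molblock", name = if (nzchar(nm)) nm else NULL)
  })
}

#' Substructure matches of SMARTS patterns against molecules
#'
#' @param mols a `simmapr_mol` or list of them
#' @param smarts character vector of SMARTS patterns
#' @return a list (one per molecule) of lists (one per pattern) of integer
#'   vectors of matched atom indices (1-based); a pattern with no match
#'   yields an empty list entry
#' @export
match_smarts <- function(mols, smarts) {
  if (inherits(mols, "simmapr_mol")) {
    mols <- list(mols)
  }
  res <- rdkit_call("match", list(
    molecules = lapply(mols, function(m) m$smiles),
    smarts = as.list(smarts)
  ))
  lapply(res, function(r) {
    if (!isTRUE(r$ok)) {
      abort(paste0("match failed: ", r$error), "simmapr_parse_error")
    }
    lapply(r$matches, function(per_pat) {
      lapply(per_pat, function(m) vapply(m, function(i) i + 1L, integer(1)))
    })
  })
}

#' Topological (shortest-path) distance matrix of a molecule's heavy atoms
#'
#' Breadth-first search over the bond graph; disconnected atom pairs get
#' `Inf`. Used for circular-environment expansion and linker diagnostics.
#'
#' @param mol a `simmapr_mol`
#' @return an n x n numeric matrix of bond-count distances
#' @export
topological_distances <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]
    b <- mol$bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.infinite(d[s, nxt])]
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}
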