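# Shared fixtures and independent oracles. The ligand panel and the random
# molecule pool are built once per test run; the backend memoises repeated
# fingerprint requests within the session.

d3_ligands <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "d3_ligands.smi", package = "simmapr")
      mols <- read_smiles_file(path)
      names(mols) <- vapply(mols, function(m) m$name, character(1))
      cache <<- mols
    }
    cache
  }
})

# pool of small random molecules for property tests (generated, not stored)
random_mols <- local({
  cache <- NULL
  function(n = 100) {
    if (is.null(cache)) {
      screen <- make_synthetic_screen(40, 60, seed = 421L)
      cache <<- parse_molecules(screen$smiles, names = screen$name)
    }
    cache[seq_len(n)]
  }
})

# raw toolkit reports, fetched directly so oracles do not depend on the
# package's fingerprint/ownership construction
raw_ap_pairs <- function(mol, max_path_length = 30L) {
  res <- simmapr:::rdkit_call("fingerprints", list(
    molecules = list(mol$smiles),
    flavors = list(list(kind = "ap", max_path_length = max_path_length))
  ))[[1]]$flavors[[1]]$pairs
  if (!length(res)) {
    return(data.frame(i = integer(), j = integer(), d = integer(),
                      code = numeric()))
  }
  data.frame(
    i = vapply(res, function(p) p[[1]] + 1L, integer(1)),
    j = vapply(res, function(p) p[[2]] + 1L, integer(1)),
    d = vapply(res, function(p) p[[3]], integer(1)),
    code = vapply(res, function(p) as.numeric(p[[4]]), numeric(1))
  )
}

raw_morgan_envs <- function(mol, radius = 2L, folded_size = NULL) {
  res <- simmapr:::rdkit_call("fingerprints", list(
    molecules = list(mol$smiles),
    flavors = list(list(kind = "morgan", radius = radius,
                        folded_size = folded_size))
  ))[[1]]$flavors[[1]]$envs
  if (!length(res)) {
    return(data.frame(bit = numeric(), center = integer(), radius = integer()))
  }
  data.frame(
    bit = vapply(res, function(e) as.numeric(e[[1]]), numeric(1)),
    center = vapply(res, function(e) e[[2]] + 1L, integer(1)),
    radius = vapply(res, function(e) e[[3]], integer(1))
  )
}

# independent Dice on named count vectors (integer sums, so any correct
# evaluation gives bit-identical doubles)
dice_oracle <- function(a, b) {
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    return(0)
  }
  shared <- intersect(names(a), names(b))
  2 * sum(pmin(a[shared], b[shared])) / denom
}

counts_by_bit <- function(bits) {
  if (!length(bits)) {
    return(setNames(numeric(), character()))
  }
  tab <- table(as.character(format(bits, scientific = FALSE, trim = TRUE)))
  setNames(as.numeric(tab), names(tab))
}

# distance matrix via an independent BFS (single-source, queue-based),
# used to cross-check environment expansion
bfs_distances <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]
    b <- mol$bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  out <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          queue <- c(queue, u)
        }
      }
    }
    out[s, ] <- dist
  }
  out
}

# brute-force masked fingerprints, rebuilt from the raw toolkit reports
masked_ap_counts <- function(pairs, atom) {
  keep <- pairs$i != atom & pairs$j != atom
  counts_by_bit(pairs$code[keep])
}

masked_morgan_counts <- function(envs, dists, atom) {
  keep <- vapply(seq_len(nrow(envs)), function(k) {
    dists[envs$center[k], atom] > envs$radius[k]
  }, logical(1))
  counts_by_bit(envs$bit[keep])
}

masked_morgan_binary <- function(envs, dists, atom) {
  support <- unique(envs$bit)
  owned <- unique(envs$bit[vapply(seq_len(nrow(envs)), function(k) {
    dists[envs$center[k], atom] <= envs$radius[k]
  }, logical(1))])
  counts_by_bit(setdiff(support, owned))
}

fp_as_named <- function(fp) {
  setNames(fp$counts, format(fp$bits, scientific = FALSE, trim = TRUE))
}
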