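test_that("removing an atom's bits follows the ownership semantics", {
  propane <- parse_molecule("CCC")
  ap <- atom_pair_fingerprint(propane)
  # masking the middle atom leaves only the terminal-terminal pair
  masked <- remove_atom_bits(ap$fp, ap$ownership, 2)
  expect_length(masked$bits, 1)
  expect_equal(masked$counts, 1)
  tt_bit <- ap$fp$bits[ap$fp$counts == 1]
  expect_equal(masked$bits, tt_bit)

  # an atom owning no bits leaves the fingerprint untouched
  lone <- atom_pair_fingerprint(parse_molecule("C"))
  expect_identical(remove_atom_bits(lone$fp, lone$ownership, 1), lone$fp)

  expect_error(remove_atom_bits(ap$fp, ap$ownership, 9),
               class = "simmapr_index_error")
  expect_error(remove_atom_bits(ap$fp, ap$ownership, 0),
               class = "simmapr_index_error")
})

test_that("binary removal clears a collided bit for every co-owner", {
  fp <- sparse_fp(c(5, 9), c(1, 1), binary = TRUE, bitspace = 1024)
  own <- simmapr:::new_ownership(list(
    data.frame(bit = 5, mult = 1),
    data.frame(bit = c(5, 9), mult = c(1, 1))
  ))
  # atom 1 co-owns bit 5 with atom 2 (a fold collision); removing either
  # atom clears the bit entirely
  expect_equal(remove_atom_bits(fp, own, 1)$bits, 9)
  expect_length(remove_atom_bits(fp, own, 2)$bits, 0)
})

test_that("normalization divides by the max absolute value", {
  expect_equal(normalize_weights(c(0.02, -0.01, 0)), c(1, -0.5, 0))
  expect_equal(normalize_weights(c(0, 0, 0)), c(0, 0, 0))
  set.seed(4)
  for (k in 1:20) {
    w <- rnorm(sample(1:8, 1)) * 10^sample(-3:2, 1)
    n <- normalize_weights(w)
    expect_true(max(abs(n)) %in% c(0, 1))
    expect_identical(sign(n), sign(w))
  }
  expect_error(normalize_weights(c(1, NA)), class = "simmapr_value_error")
  expect_error(normalize_weights(c(1, Inf)), class = "simmapr_value_error")
})

test_that("masking the only atom of a one-atom probe drops to zero", {
  m <- parse_molecule("C")
  spec <- fingerprint_spec("morgan", as_counts = TRUE)
  probe <- circular_fingerprint(m, spec)
  w <- similarity_weights(probe$fp, probe$fp, probe$ownership)
  expect_equal(w$score_orig, 1)
  expect_equal(w$raw, 1)          # 1 - dice(nonempty, empty) = 1
  expect_equal(w$normalized, 1)
})

test_that("weights calls never mutate the probe fingerprint", {
  m2 <- d3_ligands()$mol2
  ref <- d3_ligands()$mol1
  res <- atom_pair_fingerprint(m2)
  ref_fp <- atom_pair_fingerprint(ref)$fp
  before <- unserialize(serialize(res$fp, NULL))
  invisible(similarity_weights(ref_fp, res$fp, res$ownership))
  expect_identical(res$fp, before)
})

test_that("atoms owning no bits get weight exactly zero", {
  # disconnected methane in a salt-like pair: the lone atom sees no pairs
  m <- parse_molecule("CCO.C")
  ap <- atom_pair_fingerprint(m)
  ref <- atom_pair_fingerprint(parse_molecule("CCO"))$fp
  # atom-pair descriptors only span connected pairs at distance >= 1
  lone_atoms <- which(vapply(ap$ownership, nrow, integer(1)) == 0)
  w <- similarity_weights(ref, ap$fp, ap$ownership)
  expect_true(all(w$raw[lone_atoms] == 0))
})

test_that("incremental weights equal brute-force masked recomputation", {
  mols <- random_mols(100)
  ref <- d3_ligands()$mol1

  # atom pairs (count vector)
  pairs_ref <- raw_ap_pairs(ref)
  ref_named <- counts_by_bit(pairs_ref$code)
  ap_ref <- atom_pair_fingerprint(ref)$fp
  res_all <- fingerprints_batch(mols, fingerprint_spec("ap"))
  for (k in seq_along(mols)) {
    res <- res_all[[k]]
    w <- similarity_weights(ap_ref, res$fp, res$ownership)
    pairs <- raw_ap_pairs(mols[[k]])
    s0 <- dice_oracle(ref_named, counts_by_bit(pairs$code))
    expect_identical(w$score_orig, s0)
    for (a in seq_len(n_atoms(mols[[k]]))) {
      expect_identical(w$raw[a],
                       s0 - dice_oracle(ref_named, masked_ap_counts(pairs, a)))
    }
  }

  # circular counts (2^32) and circular binary (1024)
  spec_c <- fingerprint_spec("morgan", as_counts = TRUE)
  spec_b <- fingerprint_spec("morgan")
  ref_c <- circular_fingerprint(ref, spec_c)$fp
  ref_b <- circular_fingerprint(ref, spec_b)$fp
  ref_c_named <- fp_as_named(ref_c)
  ref_b_named <- fp_as_named(ref_b)
  res_c_all <- fingerprints_batch(mols, spec_c)
  res_b_all <- fingerprints_batch(mols, spec_b)
  for (k in seq_along(mols)) {
    dists <- bfs_distances(mols[[k]])
    envs_c <- raw_morgan_envs(mols[[k]])
    envs_b <- raw_morgan_envs(mols[[k]], folded_size = 1024)

    w_c <- similarity_weights(ref_c, res_c_all[[k]]$fp,
                              res_c_all[[k]]$ownership)
    s0 <- dice_oracle(ref_c_named, counts_by_bit(envs_c$bit))
    expect_identical(w_c$score_orig, s0)
    for (a in seq_len(n_atoms(mols[[k]]))) {
      expect_identical(
        w_c$raw[a],
        s0 - dice_oracle(ref_c_named, masked_morgan_counts(envs_c, dists, a)))
    }

    w_b <- similarity_weights(ref_b, res_b_all[[k]]$fp,
                              res_b_all[[k]]$ownership)
    s0b <- dice_oracle(ref_b_named, counts_by_bit(unique(envs_b$bit)))
    expect_identical(w_b$score_orig, s0b)
    for (a in seq_len(n_atoms(mols[[k]]))) {
      expect_identical(
        w_b$raw[a],
        s0b - dice_oracle(ref_b_named, masked_morgan_binary(envs_b, dists, a)))
    }
  }
})

test_that("weights are invariant under bit-id relabeling", {
  set.seed(11)
  ref <- d3_ligands()$mol1
  m2 <- d3_ligands()$mol2
  ref_res <- atom_pair_fingerprint(ref)
  probe <- atom_pair_fingerprint(m2)
  w0 <- similarity_weights(ref_res$fp, probe$fp, probe$ownership)

  ids <- sort(unique(c(ref_res$fp$bits, probe$fp$bits)))
  new_ids <- sort(sample(2^31, length(ids)))
  relabel <- function(bits) new_ids[match(bits, ids)]
  remap_fp <- function(fp) sparse_fp(relabel(fp$bits), fp$counts,
                                     fp$binary, fp$bitspace)
  remap_own <- function(own) {
    simmapr:::new_ownership(lapply(own, function(o) {
      data.frame(bit = relabel(o$bit), mult = o$mult)
    }))
  }
  w1 <- similarity_weights(remap_fp(ref_res$fp), remap_fp(probe$fp),
                           remap_own(probe$ownership))
  expect_identical(w1$raw, w0$raw)
})

test_that("probability weights reduce to similarity weights for a dice scorer", {
  ref <- d3_ligands()$mol1
  m2 <- d3_ligands()$mol2
  ref_fp <- atom_pair_fingerprint(ref)$fp
  probe <- atom_pair_fingerprint(m2)
  scorer <- function(fp) dice(ref_fp, fp)
  w_sim <- similarity_weights(ref_fp, probe$fp, probe$ownership)
  w_prob <- probability_weights(scorer, probe$fp, probe$ownership,
                                mode = "probability")
  expect_identical(w_prob$raw, w_sim$raw)
  expect_identical(w_prob$normalized, w_sim$normalized)
})

test_that("a constant model yields all-zero weights", {
  m <- parse_molecule("CCOCC")
  res <- circular_fingerprint(m, fingerprint_spec("morgan"))
  w <- probability_weights(function(fp) 0.42, res$fp, res$ownership,
                           mode = "probability")
  expect_true(all(w$raw == 0))
  expect_true(all(w$normalized == 0))
})

test_that("log mode reports a domain error on zero probability", {
  m <- parse_molecule("CC")
  res <- circular_fingerprint(m, fingerprint_spec("morgan"))
  expect_error(
    probability_weights(function(fp) if (length(fp$bits)) 0.5 else 0,
                        res$fp, res$ownership, mode = "log_probability"),
    class = "simmapr_domain_error")
})
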