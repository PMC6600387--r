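# shared fixtures, built in code

translate_ligand <- function(lig, shift) {
  set_ligand_coords(lig, sweep(ligand_coords(lig), 2, -shift))
}

# p-xylene: benzene ring with methyls at positions 1 and 4; its heavy-atom
# graph has a non-trivial automorphism group (flips of the ring)
p_xylene <- function() {
  th <- 2 * pi * (0:5) / 6
  ring <- cbind(1.4 * cos(th), 1.4 * sin(th), 0)
  me <- rbind(2.9 * c(cos(th[1]), sin(th[1]), 0),
              2.9 * c(cos(th[4]), sin(th[4]), 0))
  cov_ligand(
    tibble::tibble(element = rep("C", 8),
                   x = c(ring[, 1], me[, 1]), y = c(ring[, 2], me[, 2]),
                   z = 0),
    tibble::tibble(i = c(1, 2, 3, 4, 5, 6, 1, 4),
                   j = c(2, 3, 4, 5, 6, 1, 7, 8),
                   order = 1L),  # aromatic ring as a uniform-order skeleton
    name = "p-xylene")
}

# brute-force minimum RMSD over every element- and bond-preserving atom
# permutation (independent of the igraph-based implementation path)
brute_force_min_rmsd <- function(pose, reference) {
  n <- n_heavy_atoms(reference)
  stopifnot(n <= 8)
  pc <- ligand_coords(pose); rc <- ligand_coords(reference)
  rel <- reference$atoms$element; pel <- pose$atoms$element
  bond_set <- function(lig, perm = seq_len(n)) {
    b <- lig$bonds
    sort(paste(pmin(perm[b$i], perm[b$j]), pmax(perm[b$i], perm[b$j]), b$order))
  }
  ref_bonds <- bond_set(reference)
  best <- Inf
  perms <- gtools_permutations(n)
  for (k in seq_len(nrow(perms))) {
    m <- perms[k, ]
    if (!identical(rel, pel[m])) next
    if (!identical(ref_bonds, bond_set(pose, order(m)))) next
    # mapping reference atom i -> pose atom m[i]: bonds of pose relabelled
    # back to reference indexing must equal the reference bond set
    cand <- sqrt(mean(rowSums((pc[m, , drop = FALSE] - rc)^2)))
    best <- min(best, cand)
  }
  best
}

# all permutations of 1..n (small n), no external dependency
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (s in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[s, ]])
    }
  }
  out
}

# minimal synthetic benchmark entry without touching the generator defaults
tiny_entry <- function(entry_id = "T001", resolution = 2.0,
                       warhead_class = "Nitrile(cys)",
                       receptor_type = "Hydrolase", uniprot_id = "P1",
                       seed = 7L) {
  make_entry(warhead_class, entry_id = entry_id, seed = seed,
             receptor_type = receptor_type, uniprot_id = uniprot_id,
             resolution = resolution)
}
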