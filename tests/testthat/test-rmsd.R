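test_that("no-fit RMSD of identity and uniform translations is exact", {
  ref <- warhead_example_ligand("Carbonyl(cys)")
  expect_identical(ligand_rmsd(ref, ref), 0)
  # a rigid translation's no-fit RMSD equals the translation norm (5-atom toy)
  toy <- chain_alkane(5)
  expect_equal(ligand_rmsd(translate_ligand(toy, c(3, 0, 0)), toy), 3.0,
               tolerance = 1e-12)
  expect_equal(ligand_rmsd(translate_ligand(toy, c(1, 2, 2)), toy), 3.0,
               tolerance = 1e-12)
})

test_that("symmetry-aware RMSD recognises topologically equivalent flips", {
  xy <- p_xylene()
  # rotate 180 degrees about the para axis: equivalent to the automorphism
  # swapping ring atoms 2<->6 and 3<->5, i.e. z and y negated here
  flipped <- set_ligand_coords(xy, ligand_coords(xy) %*% diag(c(1, -1, -1)))
  expect_equal(ligand_rmsd(flipped, xy, symmetry = TRUE), 0, tolerance = 1e-9)
  expect_gt(ligand_rmsd(flipped, xy, symmetry = FALSE), 0.5)
})

test_that("symmetry-aware RMSD equals the brute-force automorphism minimum", {
  set.seed(17)
  cases <- list(p_xylene(), chain_alkane(6),
                warhead_example_ligand("Guanyl"),
                warhead_example_ligand("Boronic acid"))
  for (ref in cases) {
    pose <- set_ligand_coords(ref, ligand_coords(ref) +
                                matrix(rnorm(3 * n_heavy_atoms(ref), sd = 0.8),
                                       ncol = 3))
    expect_equal(ligand_rmsd(pose, ref, symmetry = TRUE),
                 brute_force_min_rmsd(pose, ref), tolerance = 1e-9)
    # symmetry-on never exceeds symmetry-off
    expect_lte(ligand_rmsd(pose, ref, symmetry = TRUE),
               ligand_rmsd(pose, ref, symmetry = FALSE) + 1e-12)
  }
})

test_that("RMSD is symmetric, reorder-invariant and scales linearly", {
  set.seed(23)
  ref <- warhead_example_ligand("Lactone")
  pose <- set_ligand_coords(ref, ligand_coords(ref) +
                              matrix(rnorm(3 * n_heavy_atoms(ref), sd = 0.5),
                                     ncol = 3))
  expect_equal(ligand_rmsd(pose, ref), ligand_rmsd(ref, pose),
               tolerance = 1e-12)
  # consistent reordering of both inputs leaves the value unchanged
  perm <- sample(n_heavy_atoms(ref))
  reorder <- function(l) cov_ligand(l$atoms[perm, ],
                                    data.frame(i = order(perm)[l$bonds$i],
                                               j = order(perm)[l$bonds$j],
                                               order = l$bonds$order))
  expect_equal(ligand_rmsd(reorder(pose), reorder(ref)),
               ligand_rmsd(pose, ref), tolerance = 1e-12)
  # scaling both geometries about a common origin scales the RMSD
  sc <- function(l, c) set_ligand_coords(l, ligand_coords(l) * c)
  expect_equal(ligand_rmsd(sc(pose, 2.5), sc(ref, 2.5)),
               2.5 * ligand_rmsd(pose, ref), tolerance = 1e-9)
})

test_that("composition mismatches raise a correspondence error", {
  expect_error(ligand_rmsd(chain_alkane(5), chain_alkane(6)),
               "correspondence failure")
  co <- cov_ligand(data.frame(element = c("C", "O"), x = 0:1, y = 0, z = 0),
                   data.frame(i = 1, j = 2, order = 2))
  cc <- cov_ligand(data.frame(element = c("C", "C"), x = 0:1, y = 0, z = 0),
                   data.frame(i = 1, j = 2, order = 2))
  expect_error(ligand_rmsd(co, cc), "correspondence failure")
})

test_that("evaluate_run derives S1, S2, Smax and the flags", {
  entry <- tiny_entry()
  run <- make_run(entry, 1.2, 0.8, 6.0, n_poses = 10, seed = 3,
                  tool_id = "toolA")
  res <- evaluate_run(run, entry)
  expect_equal(res$s1, 1.2, tolerance = 1e-6)
  expect_equal(res$s2, 0.8, tolerance = 1e-6)
  expect_equal(res$smax, 6.0, tolerance = 1e-6)
  expect_equal(res$p_deviation, 0.4, tolerance = 1e-6)
  expect_true(res$success); expect_false(res$failure)
  expect_true(res$s2 <= res$s1 && res$s1 <= res$smax)

  # single-pose run: all three coincide
  run1 <- make_run(entry, 1.5, 1.5, 1.5, n_poses = 1, seed = 4)
  res1 <- evaluate_run(run1, entry)
  expect_equal(res1$s1, res1$s2)
  expect_equal(res1$s1, res1$smax)

  # a top pose at exactly the threshold is a success ("at most 2.0 A"):
  # axis-aligned translations make the boundary RMSD exactly representable
  ref <- entry$reference_ligand
  run2 <- docking_run("toolA", entry$entry_id, list(
    ligand_pose(translate_ligand(ref, c(2, 0, 0)), 1),
    ligand_pose(translate_ligand(ref, c(1, 0, 0)), 2),
    ligand_pose(translate_ligand(ref, c(4, 0, 0)), 3)))
  expect_true(evaluate_run(run2, entry)$success)
  # failure requires both S1 and S2 beyond the threshold
  run3 <- make_run(entry, 3.0, 1.0, 4.0, seed = 6)
  res3 <- evaluate_run(run3, entry)
  expect_false(res3$success); expect_false(res3$failure)
  run4 <- make_run(entry, 3.0, 2.5, 4.0, seed = 7)
  expect_true(evaluate_run(run4, entry)$failure)
})
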