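test_that("torsion angles match constructed rotations and bio3d", {
  # rotate p4 about the CA-CB (z) axis: the torsion equals the rotation angle
  torsion_case <- function(theta_deg) {
    th <- theta_deg * pi / 180
    p1 <- c(1, 0, -1); p2 <- c(0, 0, 0); p3 <- c(0, 0, 1.5)
    p4 <- c(cos(th), sin(th), 2.5)
    torsion_angle(p1, p2, p3, p4)
  }
  expect_equal(torsion_case(60), 60, tolerance = 1e-9)
  expect_equal(torsion_case(-75), -75, tolerance = 1e-9)
  # the +/-180 boundary reports as +180: exact anti-periplanar geometry
  expect_equal(torsion_angle(c(1, 0, -1), c(0, 0, 0), c(0, 0, 1.5),
                             c(-1, 0, 2.5)), 180)
  # mirror image flips the sign
  mirror <- function(p) p * c(1, -1, 1)
  th <- 60 * pi / 180
  p <- list(c(1, 0, -1), c(0, 0, 0), c(0, 0, 1.5), c(cos(th), sin(th), 2.5))
  expect_equal(torsion_angle(mirror(p[[1]]), mirror(p[[2]]), mirror(p[[3]]),
                             mirror(p[[4]])), -60, tolerance = 1e-9)
  # rigid rotation+translation invariance, cross-checked against bio3d
  set.seed(8)
  ang <- runif(3, -pi, pi)
  Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3)
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3)
  Rm <- Rz(ang[1]) %*% Rx(ang[2]) %*% Rz(ang[3])
  shift <- c(4, -2, 7)
  q <- lapply(p, function(v) as.numeric(Rm %*% v + shift))
  expect_equal(torsion_angle(q[[1]], q[[2]], q[[3]], q[[4]]), 60,
               tolerance = 1e-9)
  expect_equal(torsion_angle(p[[1]], p[[2]], p[[3]], p[[4]]),
               bio3d::torsion.xyz(unlist(p)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # collinear geometry is rejected
  expect_error(torsion_angle(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(0, 0, 3)),
               "degenerate")
})

test_that("anchor dihedral reads the N-CA-CB-SG torsion of an entry", {
  e <- tiny_entry()
  d <- anchor_dihedral(e)
  expect_true(d > -180 && d <= 180)
  a <- e$anchor
  expect_equal(d, torsion_angle(
    covbench:::anchor_atom_xyz(a, "N"), covbench:::anchor_atom_xyz(a, "CA"),
    covbench:::anchor_atom_xyz(a, "CB"), covbench:::anchor_atom_xyz(a, "SG")))
})

test_that("point-sampled SASA agrees with closed-form sphere geometry", {
  radii <- sasa_radii()
  # isolated atom: full sphere of radius vdW + probe
  lone <- data.frame(element = "C", x = 0, y = 0, z = 0)
  r <- radii$radii[["C"]] + radii$probe
  expect_equal(sasa_atoms(lone, n_points = 2000),
               4 * pi * r^2, tolerance = 1e-6)
  # two-atom case: accessible area of each sphere is the full sphere minus the
  # spherical cap buried in the neighbour (closed form, pairwise overlap only)
  d <- 2.0
  two <- data.frame(element = c("C", "C"), x = c(0, d), y = 0, z = 0)
  # cap height on sphere 1 cut by the radical plane of two equal spheres
  h <- r - d / 2
  analytic <- 4 * pi * r^2 - 2 * pi * r * h
  got <- sasa_atoms(two, n_points = 5000)
  expect_equal(got[1], analytic, tolerance = 0.01)
  expect_equal(got[2], analytic, tolerance = 0.01)
  # a dense higher-resolution sampling is the independent oracle
  expect_equal(got[1], sasa_atoms(two, n_points = 10000)[1], tolerance = 0.01)
})

test_that("SASA obeys burial and occlusion monotonicity", {
  radii <- sasa_radii()
  shell <- function(n, radius) {
    pts <- covbench:::sphere_points(n) * radius
    data.frame(element = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3])
  }
  target <- data.frame(element = "S", x = 0, y = 0, z = 0)
  # fully enclosed in a tight shell: SASA collapses to ~0
  buried <- rbind(target, shell(80, 4.0))
  expect_lt(sasa_atoms(buried, indices = 1)[1], 1e-6)
  # occlusion monotonicity: adding shell atoms never increases the target SASA
  s_few <- sasa_atoms(rbind(target, shell(10, 5.5)), indices = 1)[1]
  s_more <- sasa_atoms(rbind(target, shell(10, 5.5), shell(14, 6.0)),
                       indices = 1)[1]
  expect_lte(s_more, s_few + 1e-9)
  # enlarging the probe deepens the burial (accessible fraction) of a
  # pocket atom
  pocket <- rbind(target, shell(26, 5.2))
  frac_free <- function(probe) {
    r <- radii$radii[["S"]] + probe
    sasa_atoms(pocket, indices = 1, probe = probe)[1] / (4 * pi * r^2)
  }
  expect_lte(frac_free(2.8), frac_free(1.4) + 1e-9)
})

test_that("anchor SASA runs on the ligand-free receptor and errors on gaps", {
  e <- tiny_entry()
  s <- anchor_sasa(e)
  expect_gt(s, 0)
  e2 <- e
  e2$receptor <- e2$receptor[e2$receptor$name != "CB" |
                               e2$receptor$resno != 23, ]
  expect_error(anchor_sasa(e2), "CB")
})

test_that("accuracy binning reproduces a planted SASA gradient", {
  set.seed(44)
  n <- 60L
  desc <- tibble::tibble(entry_id = sprintf("e%02d", 1:n),
                         sasa = runif(n, 0, 40),
                         dihedral = runif(n, -180, 180),
                         kinase_domain = NA_character_)
  # planted: RMSD grows with SASA
  res <- tibble::tibble(tool_id = "A", entry_id = desc$entry_id,
                        s1 = 0.5 + 0.1 * desc$sasa, s2 = 0.4 + 0.1 * desc$sasa)
  tab <- accuracy_by_feature(res, desc, "sasa")
  meds <- tab$median_rmsd[!is.na(tab$median_rmsd)]
  expect_true(all(diff(meds) > 0))   # monotone bins recover the gradient
  expect_identical(sum(tab$n, na.rm = TRUE), n)
  # one bin only: the table equals the overall median
  tab1 <- accuracy_by_feature(res, desc, "sasa", binwidth = 100)
  expect_equal(tab1$median_rmsd[!is.na(tab1$median_rmsd)],
               stats::median(res$s1))
  # binned medians are invariant to row order
  perm <- sample(n)
  tab2 <- accuracy_by_feature(res[perm, ], desc, "sasa")
  expect_equal(tab, tab2)
})

test_that("kinase-domain binning recounts the shipped domain distribution", {
  kd <- readr::read_csv(
    system.file("extdata", "bcde", "kinase_domain_counts.csv",
                package = "covbench"), show_col_types = FALSE)
  n <- sum(kd$n)
  desc <- tibble::tibble(entry_id = sprintf("k%02d", seq_len(n)),
                         sasa = 5, dihedral = 0,
                         kinase_domain = rep(kd$kinase_domain, times = kd$n))
  res <- tibble::tibble(tool_id = "A", entry_id = desc$entry_id,
                        s1 = 1.5, s2 = 1.2)
  tab <- accuracy_by_feature(res, desc, "kinase_domain")
  counts <- setNames(tab$n, tab$bin)
  # the three most populated anchor domains
  expect_identical(counts[["Front pocket"]], 31L)
  expect_identical(counts[["DFG-3"]], 14L)
  expect_identical(counts[["P-loop"]], 9L)
  expect_equal(sum(tab$n), n, ignore_attr = TRUE)
})
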