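test_that("PDB fixtures parse with residue classification and altlocs", {
  atoms <- rbind(
    fx_atom("ATOM", "A", 1, "ALA", "CA", "C", 0, 0, 0),
    fx_atom("ATOM", "A", 2, "GLY", "CA", "C", 3.8, 0, 0),
    fx_atom("ATOM", "A", 3, "SER", "CA", "C", 7.6, 0, 0),
    fx_atom("ATOM", "B", 10, "U", "N3", "N", 0, 5, 0),
    fx_atom("HETATM", "W", 100, "HOH", "O", "O", 9, 9, 9),
    # altloc pair: B has the higher occupancy and must win
    fx_atom("ATOM", "A", 4, "VAL", "CB", "C", 1, 1, 1, occ = 0.4, altloc = "A"),
    fx_atom("ATOM", "A", 4, "VAL", "CB", "C", 2, 2, 2, occ = 0.6, altloc = "B")
  )
  path <- write_fixture_pdb(atoms, tempfile(fileext = ".pdb"))
  m <- read_structure(path)
  expect_s3_class(m, "structure_model")
  expect_equal(sum(m$atoms$class == "protein"), 4L)
  expect_equal(sum(m$atoms$class == "rna"), 1L)
  expect_equal(sum(m$atoms$class == "water"), 1L)
  cb <- m$atoms[m$atoms$atom == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$x, 2)
  # truncated coordinate records error out
  writeLines("ATOM      1  CA  ALA A   1      xx", path)
  expect_error(read_structure(path), "malformed|truncated|no ATOM")
})

test_that("mmCIF atom_site loops parse equivalently", {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_fixture", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy",
    "ATOM 1 C CA . ALA A 1 0.000 0.000 0.000 1.00",
    "ATOM 2 C CA . GLY A 2 3.800 0.000 0.000 1.00",
    "ATOM 3 N N3 . U B 10 0.000 5.000 0.000 1.00",
    "HETATM 4 O O . HOH W 100 9.000 9.000 9.000 1.00",
    "#"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 4L)
  expect_equal(sort(unique(m$atoms$class)), c("protein", "rna", "water"))
  writeLines(c("data_x", "# nothing"), path)
  expect_error(read_structure(path), "no _atom_site loop")
})

test_that("structure models round-trip through the PDB writer", {
  m <- recognition_fixture("U")
  path <- tempfile(fileext = ".pdb")
  write_pdb(m, path)
  m2 <- read_structure(path)
  expect_equal(m2$atoms[, c("chain", "resno", "atom", "class")],
               m$atoms[, c("chain", "resno", "atom", "class")])
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-3)
})

test_that("repeat segmentation tiles 35-residue windows from the anchor", {
  coords <- cbind(seq(0, by = 1, length.out = 450), 0, 0)
  atoms <- do.call(rbind, lapply(seq_len(450), function(i) {
    fx_atom("ATOM", "A", 122 + i, "ALA", "CA", "C",
            coords[i, 1], coords[i, 2], coords[i, 3])
  }))
  m <- read_structure(write_fixture_pdb(atoms, tempfile(fileext = ".pdb")))
  seg <- segment_repeats(m, anchor = 174L, n_repeats = 10L)
  expect_equal(seg$start_res, seq(174L, 489L, by = 35L))
  expect_equal(seg$end_res[10], 523L)
  expect_equal(seg$code5_resno, seg$start_res + 4L)
  expect_error(segment_repeats(m, anchor = 174L, n_repeats = 12L),
               "does not cover")
  expect_error(
    segment_repeats(m, ranges = data.frame(start_res = c(174L, 200L),
                                           end_res = c(208L, 234L))),
    "overlap")
  expect_error(
    segment_repeats(m, ranges = data.frame(start_res = 174L, end_res = 200L)),
    "exactly 35")
})

test_that("self-superposition is exact and rigid motion is invisible", {
  set.seed(41)
  coords <- matrix(rnorm(30, sd = 10), 10, 3)
  m <- ca_model(coords)
  res <- superpose(m, m)
  expect_equal(res$rmsd, 0)
  expect_equal(res$n_retained, 10L)
  expect_equal(det(res$R), 1, tolerance = 1e-6)
  rot <- transform_model(m, random_rotation(), c(5, -3, 12))
  expect_lt(superpose(m, rot)$rmsd, 1e-6)
  expect_lt(superpose(rot, m)$rmsd, 1e-6)
})

test_that("Kabsch RMSD equals the quaternion oracle on seeded instances", {
  set.seed(99)
  for (r in 1:20) {
    n <- sample(4:10, 1)
    P <- matrix(rnorm(3 * n, sd = 8), n, 3)
    Q <- matrix(rnorm(3 * n, sd = 8), n, 3)
    got <- superpose(ca_model(P), ca_model(Q), prune_sigma = Inf)
    expect_equal(got$rmsd, quat_rmsd(P, Q), tolerance = 1e-8)
    # symmetry of the minimal RMSD
    expect_equal(superpose(ca_model(Q), ca_model(P), prune_sigma = Inf)$rmsd,
                 got$rmsd, tolerance = 1e-6)
  }
})

test_that("iterative pruning drops outlier pairs and reports counts", {
  set.seed(7)
  P <- matrix(rnorm(60, sd = 10), 20, 3)
  Q <- P
  Q[3, ] <- Q[3, ] + 25  # one displaced residue
  res <- superpose(ca_model(P), ca_model(Q), prune_sigma = 2, max_cycles = 5)
  expect_equal(res$n_initial, 20L)
  expect_equal(res$n_retained, 19L)
  expect_lt(res$rmsd, 1e-6)
  expect_error(superpose(ca_model(P[1:3, ]), ca_model(Q[1:3, ] +
    matrix(rnorm(9, sd = 30), 3, 3)), prune_sigma = 0.01),
    "degenerate fit|fewer than 3")
})

test_that("superhelix parameters are recovered within 1% on a seeded sweep", {
  set.seed(55)
  for (r in 1:12) {
    rise <- runif(1, 3, 10)
    twist <- runif(1, 10, 60)
    radius <- runif(1, 10, 40)
    n <- sample(5:15, 1)
    h <- make_ideal_helix(rise, twist, radius, n, atoms_per_repeat = 4,
                          jitter_sd = 0.3, seed = r)
    fit <- superhelix(h$model, h$segmentation)
    expect_lt(abs(fit$rise - rise) / rise, 0.01)
    expect_lt(abs(fit$twist - twist) / twist, 0.01)
    expect_lt(abs(fit$radius - radius) / radius, 0.01)
    expect_equal(fit$handedness, "right")
  }
  # left-handed helices are reported as such
  h <- make_ideal_helix(7, -36, 25, 8)
  expect_equal(superhelix(h$model, h$segmentation)$handedness, "left")
})

test_that("superhelix degenerate and undersized inputs error", {
  h <- make_ideal_helix(7, 36, 25, 10)
  expect_error(superhelix(h$model, h$segmentation[1:3, ]), "at least 4")
  line <- ca_model(cbind(1:8 * 3.8, 0, 0))
  seg <- data.frame(repeat_index = 1:8, start_res = 1:8, end_res = 1:8)
  attr(seg, "chain") <- "A"
  expect_error(superhelix(line, seg), "collinear")
})

test_that("planted recognition H-bonds are detected with the right pattern", {
  m <- recognition_fixture("U")
  seg <- segment_repeats(m, anchor = 1, n_repeats = 1)
  res <- find_hbonds(m, seg)
  # uracil: one direct Asn5 bond to O2, one water bridge at position 35
  expect_equal(res$per_repeat$direct5, 1L)
  expect_equal(res$per_repeat$direct35, 0L)
  expect_equal(res$per_repeat$water, 1L)
  wb <- res$hbonds[res$hbonds$water_mediated, ]
  expect_equal(wb$base_atom, "N3")
  expect_equal(wb$prot_atom, "OD1")
  # guanine: two direct position-35 bonds (N1 and N2), no water
  g <- recognition_fixture("G")
  resg <- find_hbonds(g, segment_repeats(g, anchor = 1, n_repeats = 1))
  expect_equal(resg$per_repeat$direct35, 2L)
  expect_setequal(
    resg$hbonds$base_atom[resg$hbonds$position == 35 & !resg$hbonds$water_mediated],
    c("N1", "N2"))
  expect_equal(resg$per_repeat$water, 0L)
})

test_that("H-bond detection is invariant under rigid transforms", {
  m <- recognition_fixture("U")
  seg <- segment_repeats(m, anchor = 1, n_repeats = 1)
  before <- find_hbonds(m, seg)
  set.seed(3)
  moved <- transform_model(m, random_rotation(), c(-20, 4, 33))
  after <- find_hbonds(moved, segment_repeats(moved, anchor = 1, n_repeats = 1))
  expect_equal(after$per_repeat, before$per_repeat)
  expect_equal(after$hbonds$distance, before$hbonds$distance, tolerance = 1e-3)
})

test_that("distant atoms yield no bonds and missing RNA errors", {
  atoms <- rbind(
    fx_atom("ATOM", "A", 1, "GLY", "CA", "C", 0, 0, 0),
    fx_atom("ATOM", "A", 5, "ASN", "ND2", "N", 0, 0, 0),
    fx_atom("ATOM", "A", 35, "ASP", "OD1", "O", 1, 0, 0),
    fx_atom("ATOM", "B", 101, "U", "O2", "O", 10, 10, 10),
    fx_atom("ATOM", "B", 101, "U", "N3", "N", 11, 10, 10)
  )
  m <- read_structure(write_fixture_pdb(atoms, tempfile(fileext = ".pdb")))
  seg <- segment_repeats(m, anchor = 1, n_repeats = 1)
  expect_equal(nrow(find_hbonds(m, seg)$hbonds), 0L)

  prot_only <- read_structure(write_fixture_pdb(atoms[1:3, ],
                                                tempfile(fileext = ".pdb")))
  expect_error(find_hbonds(prot_only,
                           segment_repeats(prot_only, anchor = 1,
                                           n_repeats = 1)),
               "no rna chain")
})

test_that("contact report flags Val2 sandwich and Lys13 salt bridges", {
  m <- recognition_fixture("U")
  seg <- segment_repeats(m, anchor = 1, n_repeats = 1)
  rep1 <- contact_report(m, seg)
  expect_true(rep1$val2_own_base)
  expect_true(rep1$salt_bridge)
  expect_match(rep1$salt_partner, "OP1")
  expect_false(rep1$incomplete)
  # truncated side chains are flagged, not fatal
  trunc <- m
  trunc$atoms <- trunc$atoms[trunc$atoms$atom != "NZ", ]
  rep2 <- contact_report(trunc, seg)
  expect_true(rep2$incomplete)
  expect_false(rep2$salt_bridge)
})
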