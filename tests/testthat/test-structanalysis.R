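test_that("contact detection applies Bondi radii plus tolerance", {
  m <- tiny_model(list(
    list(name = "C1", resname = "ALA", chain = "A", resno = 1,
         xyz = c(0, 0, 0), ele = "C"),
    list(name = "C2", resname = "ALA", chain = "B", resno = 2,
         xyz = c(10, 0, 0), ele = "C")))
  hits <- find_contacts(m, 1, 2)
  expect_equal(nrow(hits), 0)
  # S (1.80) + C (1.70) + 0.5 = 4.0: a 3.8 A pair is a hydrophobic contact
  m2 <- tiny_model(list(
    list(name = "SP1", resname = "DT", chain = "A", resno = 1,
         xyz = c(0, 0, 0), ele = "S"),
    list(name = "CE", resname = "LYS", chain = "B", resno = 206,
         xyz = c(3.8, 0, 0), ele = "C")))
  hits2 <- find_contacts(m2, 1, 2)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$kind, "vdw_hydrophobic")
  expect_equal(hits2$distance, 3.8)
  # at 4.05 A the same pair is no longer in contact
  m3 <- m2; m3$atoms$x[2] <- 4.05
  expect_equal(nrow(find_contacts(m3, 1, 2)), 0)
})

test_that("contacts are classified polar only for N/O (or S-acceptor) pairs in range", {
  m <- tiny_model(list(
    list(name = "OP2", resname = "DT", chain = "A", resno = 1,
         xyz = c(0, 0, 0), ele = "O"),
    list(name = "NZ", resname = "LYS", chain = "B", resno = 9,
         xyz = c(2.9, 0, 0), ele = "N"),
    list(name = "CB", resname = "LYS", chain = "B", resno = 9,
         xyz = c(0, 3.1, 0), ele = "C")))
  hits <- find_contacts(m, 1, c(2, 3))
  polar <- hits[hits$kind == "polar", ]
  expect_equal(nrow(polar), 1)
  expect_match(polar$pair_label, "NZ")
  expect_equal(hits$kind[grepl("CB", hits$pair_label)], "vdw_hydrophobic")
})

test_that("contact detection is symmetric and rigid-motion invariant", {
  spec <- fixture_spec(4, c("Rp", "Sp", "Rp"))
  m <- build_ps_strand(spec)
  extra <- m$atoms[1, ]
  extra$serial <- max(m$atoms$serial) + 1L
  extra$name <- "CE"; extra$resname <- "LYS"; extra$chain <- "B"
  extra$resno <- 1L; extra$element <- "C"
  s1 <- which(m$atoms$element == "S")[1]
  extra$x <- m$atoms$x[s1] + 3.7; extra$y <- m$atoms$y[s1]
  extra$z <- m$atoms$z[s1]
  m$atoms <- rbind(m$atoms, extra)
  sel_dna <- select_atoms(m, chain = "A")
  sel_pro <- select_atoms(m, chain = "B")
  ab <- find_contacts(m, sel_dna, sel_pro)
  ba <- find_contacts(m, sel_pro, sel_dna)
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(ab$distance, ba$distance)
  moved <- apply_rigid(m, random_rigid(23))
  ab2 <- find_contacts(moved, sel_dna, sel_pro)
  expect_equal(sort(ab2$distance), sort(ab$distance), tolerance = 1e-9)
})

test_that("unknown elements and bad selections are refused", {
  m <- tiny_model(list(
    list(name = "X1", resname = "UNK", chain = "A", resno = 1,
         xyz = c(0, 0, 0), ele = "XX"),
    list(name = "C1", resname = "ALA", chain = "B", resno = 2,
         xyz = c(3, 0, 0), ele = "C")))
  expect_error(find_contacts(m, 1, 2), "XX")
  expect_error(find_contacts(m, integer(), 2), "non-empty")
  expect_error(find_contacts(m, 1, 1), "disjoint")
})

test_that("an engineered arginine/lysine pocket around a PS sulfur is recovered", {
  # synthetic stand-in for a PS-binding pocket: sulfur of a PS linkage
  # flanked by side-chain carbons of an arginine and a lysine
  s_pos <- c(0, 0, 0)
  m <- tiny_model(list(
    list(name = "SP1", resname = "DT", chain = "C", resno = 14,
         xyz = s_pos, ele = "S"),
    list(name = "P", resname = "DT", chain = "C", resno = 14,
         xyz = c(0, 0, 1.95), ele = "P"),
    list(name = "CD", resname = "ARG", chain = "A", resno = 205,
         xyz = c(3.7, 0.3, 0), ele = "C"),
    list(name = "CZ", resname = "ARG", chain = "A", resno = 205,
         xyz = c(3.7, 1.0, 0.3), ele = "C"),
    list(name = "CE", resname = "LYS", chain = "A", resno = 206,
         xyz = c(-3.6, 0.5, 0.2), ele = "C"),
    list(name = "CD", resname = "LYS", chain = "A", resno = 206,
         xyz = c(-3.5, 1.5, 0.2), ele = "C"),
    list(name = "CA", resname = "GLY", chain = "A", resno = 300,
         xyz = c(0, 25, 0), ele = "C")))
  dna <- select_atoms(m, chain = "C")
  pro <- select_atoms(m, chain = "A")
  contacts <- find_contacts(m, dna, pro)
  pocket <- summarize_pocket(contacts, m)
  expect_equal(nrow(pocket), 2)
  expect_setequal(pocket$resno, c(205, 206))
  expect_setequal(pocket$resname, c("ARG", "LYS"))
  expect_true(all(pocket$n_contacts == 2))
  # the remote glycine never appears
  expect_false(300 %in% pocket$resno)
})

test_that("a single engineered S...Lys-CE contact tops the pocket report", {
  m <- tiny_model(list(
    list(name = "SP1", resname = "DT", chain = "C", resno = 3,
         xyz = c(0, 0, 0), ele = "S"),
    list(name = "CE", resname = "LYS", chain = "A", resno = 115,
         xyz = c(3.8, 0, 0), ele = "C")))
  pocket <- summarize_pocket(find_contacts(m, 1, 2), m)
  expect_equal(nrow(pocket), 1)
  expect_equal(pocket$resname, "LYS")
  expect_equal(pocket$n_contacts, 1)
  expect_equal(pocket$min_distance, 3.8)
  empty <- summarize_pocket(find_contacts(m, 1, 2)[0, ], m)
  expect_equal(nrow(empty), 0)
})

test_that("water bridges are detected only when a water links both selections", {
  m <- tiny_model(list(
    list(name = "OP2", resname = "DT", chain = "C", resno = 13,
         xyz = c(0, 0, 0), ele = "O"),
    list(name = "O", resname = "HOH", chain = "W", resno = 500,
         xyz = c(2.8, 0, 0), ele = "O"),
    list(name = "O", resname = "LYS", chain = "A", resno = 204,
         xyz = c(5.5, 0, 0), ele = "O")))
  dna <- select_atoms(m, chain = "C")
  pro <- select_atoms(m, chain = "A")
  br <- find_water_bridges(m, dna, pro)
  expect_equal(nrow(br), 1)
  expect_match(br$label, "HOH")
  # pull the water out of range of the protein side: no bridge
  m2 <- m; m2$atoms$x[2] <- -3.0
  expect_equal(nrow(find_water_bridges(m2, dna, pro)), 0)
})

test_that("C-alpha matching pairs identical residues and respects deletions", {
  ch <- synthetic_ca_chain(120, seed = 1)
  pairs <- match_calpha(ch, ch, "A", "A")
  expect_equal(pairs$n, 120)
  expect_equal(pairs$xyz_a, pairs$xyz_b)
  # delete one residue from the copy
  del <- ch
  del$atoms <- del$atoms[del$atoms$resno != 60, ]
  pairs2 <- match_calpha(ch, del, "A", "A")
  expect_equal(pairs2$n, 119)
  expect_false(60 %in% pairs2$resno_b)
  short <- synthetic_ca_chain(10, seed = 2)
  expect_error(match_calpha(short, short, "A", "A"), "insufficient overlap")
})

test_that("superposition is exact for identical and rigidly moved sets", {
  ch <- synthetic_ca_chain(80, seed = 3)
  xyz <- as.matrix(ch$atoms[, c("x", "y", "z")])
  s0 <- superpose(xyz, xyz)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$n_atoms, 80)
  rig <- random_rigid(31)
  moved <- sweep(xyz %*% t(rig$R), 2, rig$t, "+")
  s1 <- superpose(xyz, moved)
  expect_lt(s1$rmsd, 1e-8)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-8)
  # recovered rotation undoes the applied one
  expect_equal(s1$rotation %*% rig$R, diag(3), tolerance = 1e-6)
})

test_that("superposition RMSD matches independent implementations on noisy pairs", {
  ch <- synthetic_ca_chain(150, seed = 4)
  xyz <- as.matrix(ch$atoms[, c("x", "y", "z")])
  set.seed(9)
  rig <- random_rigid(41)
  noisy <- sweep(xyz %*% t(rig$R), 2, rig$t, "+") +
    matrix(rnorm(length(xyz), 0, 0.3), ncol = 3)
  s <- superpose(xyz, noisy, max_cycles = 0)
  # oracle 1: closed-form quaternion superposition
  expect_equal(s$rmsd, quat_rmsd(xyz, noisy), tolerance = 1e-8)
  # oracle 2: bio3d least-squares fit
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.numeric(t(xyz)), as.numeric(t(noisy))))
  rms_bio3d <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) -
                                    xyz)^2)))
  expect_equal(s$rmsd, rms_bio3d, tolerance = 1e-6)
  # expectation: isotropic noise sd 0.3 -> rmsd ~ sqrt(3) * 0.3
  expect_equal(s$rmsd, sqrt(3) * 0.3, tolerance = 0.1)
})

test_that("Kabsch beats (or ties) a random-rotation search on small instances", {
  set.seed(12)
  ref <- matrix(rnorm(18, sd = 5), ncol = 3)
  mob <- ref %*% t(random_rigid(3)$R) + matrix(rnorm(18, 0, 0.5), ncol = 3)
  s <- superpose(ref, mob, max_cycles = 0)
  best <- brute_rotation_rmsd(ref, mob)
  expect_lte(s$rmsd, best + 1e-9)
  expect_lt(best - s$rmsd, 0.01)  # refined sampling comes close
})

test_that("outlier rejection cycles never increase the RMSD and report rejections", {
  ch <- synthetic_ca_chain(100, seed = 6)
  xyz <- as.matrix(ch$atoms[, c("x", "y", "z")])
  set.seed(13)
  noisy <- xyz + matrix(rnorm(length(xyz), 0, 0.2), ncol = 3)
  noisy[c(10, 50, 90), ] <- noisy[c(10, 50, 90), ] + 5  # gross outliers
  s <- superpose(xyz, noisy, reject_sigma = 2, max_cycles = 5)
  expect_true(all(diff(s$rmsd_history) <= 1e-12))
  expect_true(all(c(10, 50, 90) %in% s$rejected))
  expect_equal(s$n_atoms, 100 - length(s$rejected))
  expect_lt(s$rmsd, 0.5)
})

test_that("degenerate geometry is refused", {
  line <- cbind(1:10, 1:10, 1:10) * 1.0
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})
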