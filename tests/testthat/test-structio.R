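minimal_pdb <- function(path, lines) writeLines(lines, path)

pdb_atom_line <- function(serial, name, alt, resname, chain, resno,
                          x, y, z, occ, b, ele) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, b, ele)
}

test_that("a minimal PDB record maps onto one atom record with all fields", {
  tf <- tempfile(fileext = ".pdb")
  minimal_pdb(tf, c(pdb_atom_line(1, "P", " ", "DT", "A", 5,
                                  1.5, -2.25, 3.125, 0.50, 56.0, "P"), "END"))
  m <- read_structure(tf)
  expect_equal(nrow(m$atoms), 1)
  a <- m$atoms[1, ]
  expect_equal(a$name, "P")
  expect_equal(a$resname, "DT")
  expect_equal(a$chain, "A")
  expect_equal(a$resno, 5)
  expect_equal(c(a$x, a$y, a$z), c(1.5, -2.25, 3.125))
  expect_equal(a$occupancy, 0.50)
  expect_equal(a$b_factor, 56.0)
  expect_equal(a$element, "P")
})

test_that("dual altlocs are preserved as separate records with occupancies summing to 1", {
  tf <- tempfile(fileext = ".pdb")
  minimal_pdb(tf, c(
    pdb_atom_line(1, "OP1", "A", "DT", "A", 5, 1, 2, 3, 0.50, 30, "O"),
    pdb_atom_line(2, "OP1", "B", "DT", "A", 5, 2, 1, 3, 0.50, 30, "O"),
    "END"))
  m <- read_structure(tf)
  expect_equal(nrow(m$atoms), 2)
  expect_setequal(m$atoms$altloc, c("A", "B"))
  expect_equal(sum(m$atoms$occupancy), 1.0)
})

test_that("an empty file yields an empty model without error", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(character(), tf)
  m <- read_structure(tf)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 0)
})

test_that("atom record count equals ATOM/HETATM line count (altlocs never dropped)", {
  spec <- fixture_spec(8, c("Rp", "Sp", "mixed", "Rp", "mixed", "Sp", "Rp"))
  model <- build_ps_strand(spec)
  tf <- tempfile(fileext = ".pdb")
  write_structure(model, tf)
  n_lines <- sum(grepl("^(ATOM  |HETATM)", readLines(tf)))
  m2 <- read_structure(tf)
  expect_equal(nrow(m2$atoms), n_lines)
  expect_equal(nrow(m2$atoms), nrow(model$atoms))
})

test_that("PDB round trip preserves fields to format precision", {
  spec <- fixture_spec(6, c("Rp", "mixed", "Sp", "Rp", "Sp"),
                       b_profile = c(10, 20, 30, 40, 80))
  model <- build_ps_strand(spec)
  tf <- tempfile(fileext = ".pdb")
  write_structure(model, tf)
  m2 <- read_structure(tf)
  expect_equal(m2$atoms$name, model$atoms$name)
  expect_equal(m2$atoms$altloc, model$atoms$altloc)
  expect_equal(m2$atoms$resno, model$atoms$resno)
  expect_equal(m2$atoms$occupancy, model$atoms$occupancy)
  expect_equal(m2$atoms$b_factor, model$atoms$b_factor)
  expect_equal(m2$atoms$element, model$atoms$element)
  expect_equal(m2$atoms$x, model$atoms$x, tolerance = 1e-3)
  expect_equal(m2$atoms$z, model$atoms$z, tolerance = 1e-3)
})

test_that("mmCIF atom_site records are parsed like PDB records", {
  tf <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_synthetic",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 P P . DT A 1 5 ? 1.500 -2.250 3.125 0.50 56.00 ? 5 DT A P 1",
    "ATOM 2 O OP1 . DT A 1 5 ? 2.500 -1.250 3.125 1.00 30.00 ? 5 DT A OP1 1"),
    tf)
  m <- read_structure(tf)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$name[1], "P")
  expect_equal(m$atoms$occupancy[1], 0.5)
  expect_equal(m$atoms$b_factor[1], 56)
  expect_equal(m$atoms$x[1], 1.5)
})

test_that("structure model invariants are enforced", {
  base <- data.frame(serial = 1L, name = "P", altloc = "", resname = "DT",
                     chain = "A", resno = 1L, insert = "", x = 0, y = 0,
                     z = 0, occupancy = 1, b_factor = 10, element = "P",
                     stringsAsFactors = FALSE)
  bad_occ <- base; bad_occ$occupancy <- 1.5
  expect_error(structure_model(bad_occ), "occupancy")
  bad_b <- base; bad_b$b_factor <- -1
  expect_error(structure_model(bad_b), "b_factor")
  bad_ele <- base; bad_ele$element <- ""
  expect_error(structure_model(bad_ele), "element")
  dup <- rbind(base, base)
  expect_error(structure_model(dup), "duplicate")
})

test_that("CCP4 map write/read round-trips values, origin and spacing", {
  set.seed(1)
  g <- density_grid(array(rnorm(6 * 5 * 4), dim = c(6, 5, 4)),
                    origin = c(-3.5, 2.0, 10.25), spacing = c(0.5, 0.5, 0.5))
  tf <- tempfile(fileext = ".ccp4")
  write_map(g, tf)
  g2 <- read_map(tf)
  expect_equal(g2$dimensions, g$dimensions)
  expect_equal(g2$origin, g$origin, tolerance = 1e-6)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-6)
  expect_lt(max(abs(g2$values - g$values)) / max(abs(g$values)), 1e-6)
})

test_that("a constant map reads back flagged unusable (sigma 0)", {
  g <- density_grid(array(1.5, dim = c(4, 4, 4)))
  expect_false(g$usable)
  tf <- tempfile(fileext = ".ccp4")
  write_map(g, tf)
  g2 <- read_map(tf)
  expect_false(g2$usable)
  expect_equal(g2$sigma, 0)
})

test_that("sigma of a standard-normal grid is ~1 and equals the voxel SD", {
  set.seed(99)
  v <- array(rnorm(8 * 8 * 8), dim = c(8, 8, 8))
  g <- density_grid(v)
  expect_equal(g$sigma, sd(as.numeric(v)))
  expect_lt(abs(g$sigma - 1), 0.15)
})

test_that("the axis-order header fields are honoured when reading maps", {
  set.seed(2)
  vals <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  g <- density_grid(vals, origin = c(0, 0, 0), spacing = c(1, 1, 1))
  # write the same map with section-fastest order (MAPC=3, MAPR=1, MAPS=2):
  # stored array dims are then (z, x, y)
  tf <- tempfile(fileext = ".ccp4")
  con <- file(tf, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  perm_vals <- aperm(vals, c(3, 1, 2))
  d <- dim(perm_vals)
  wi(d); wi(2); wi(c(0, 0, 0)); wi(c(4, 5, 6))
  wf(c(4, 5, 6, 90, 90, 90))
  wi(c(3, 1, 2))
  wf(c(min(vals), max(vals), mean(vals)))
  wi(1); wi(0); wi(rep(0L, 25)); wf(c(0, 0, 0))
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(sd(vals)); wi(0); writeBin(raw(800), con)
  wf(as.numeric(perm_vals))
  close(con)
  g2 <- read_map(tf)
  expect_equal(g2$dimensions, dim(vals))
  expect_lt(max(abs(g2$values - vals)), 1e-6)
})

test_that("bad magic and unsupported modes are format errors", {
  tf <- tempfile()
  writeBin(as.raw(rep(7, 2048)), tf)
  expect_error(read_map(tf), "magic")
})

test_that("titration tables round-trip and enforce their schema", {
  p <- binding_params(5, 0.1, 0.15, 0.01)
  ser <- simulate_titration(p, noise_sd = 0.003, seed = 1,
                            oligo = "oligoX", condition = "Ca2+")
  tf <- tempfile(fileext = ".csv")
  write_titrations(ser, tf)
  back <- read_titrations(tf)
  expect_equal(length(back), 3)
  key <- paste("oligoX", "Ca2+", 2, sep = "|")
  expect_equal(back[[key]]$anisotropy, ser[[2]]$anisotropy)
  expect_equal(back[[key]]$protein_conc, ser[[2]]$protein_conc)
  expect_equal(back[[key]]$probe_conc, 0.05)

  df <- utils::read.csv(tf)
  df$anisotropy <- NULL
  tf2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, tf2, row.names = FALSE)
  expect_error(read_titrations(tf2), "anisotropy")

  df2 <- utils::read.csv(tf)
  df2$protein_conc_uM[3] <- -1
  utils::write.csv(df2, tf2, row.names = FALSE)
  expect_error(read_titrations(tf2), "negative protein")

  df3 <- utils::read.csv(tf)
  df3$extra_col <- 1
  utils::write.csv(df3, tf2, row.names = FALSE)
  expect_warning(read_titrations(tf2), "extra")
})

test_that("stereo-call tables are written with the documented schema", {
  spec <- fixture_spec(5, c("Rp", "Sp", "mixed", "Rp"))
  m <- build_ps_strand(spec)
  g <- render_anomalous_map(m)
  calls <- call_strand(g, m)
  tf <- tempfile(fileext = ".csv")
  write_calls(calls, tf)
  back <- utils::read.csv(tf)
  expect_named(back, c("linkage_id", "chain", "res5", "res3", "call",
                       "peak_Rp_sigma", "peak_Sp_sigma", "b_factor",
                       "reliable"))
  expect_equal(back$call, calls$call)
  expect_error(write_calls(data.frame(linkage_id = 1), tf), "lacks column")
})
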