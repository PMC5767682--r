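write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("PDB receptor parsing reads coordinates, chains and HETATM flags", {
  pdb <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      12.000   6.500  -5.500  1.00  0.00           C",
    "HETATM    3  C1  LIG B   9       1.500  -2.250   3.750  1.00  0.00           C")
  s <- read_receptor(write_lines_tmp(pdb, ".pdb"))
  expect_equal(nrow(s), 3)
  expect_equal(s$x, c(11.104, 12.000, 1.500))
  expect_equal(s$element, c("N", "C", "C"))
  expect_equal(s$chain, c("A", "A", "B"))
  expect_equal(s$is_hetero, c(FALSE, FALSE, TRUE))
  expect_equal(s$resno, c(1L, 1L, 9L))
})

test_that("altlocs resolve to highest occupancy, ties to A", {
  pdb <- c(
    "ATOM      1  CA ASER A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BSER A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB ASER A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BSER A   1       3.000   0.000   0.000  0.50  0.00           C")
  s <- read_receptor(write_lines_tmp(pdb, ".pdb"))
  expect_equal(nrow(s), 2)
  expect_equal(s$x[s$name == "CA"], 1.0) # occupancy 0.60 wins
  expect_equal(s$x[s$name == "CB"], 2.0) # tie -> altloc A
})

test_that("malformed and empty PDB files raise named errors", {
  bad <- "ATOM      1  CA  ALA A   1      xx.xxx   6.500  -5.500  1.00  0.00           C"
  expect_error(read_receptor(write_lines_tmp(bad, ".pdb")), "line 1")
  expect_error(read_receptor(write_lines_tmp("REMARK only", ".pdb")),
               "no atom records")
  expect_error(read_receptor(tempfile()), "not found")
})

test_that("blank element columns fall back to PDB v3 atom-name inference", {
  pdb <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2 1HB  ALA A   1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      3  OG1 THR A   2       2.000   0.000   0.000  1.00  0.00")
  s <- read_receptor(write_lines_tmp(pdb, ".pdb"))
  expect_equal(s$element, c("C", "H", "O"))
})

test_that("multi-MODEL pose files give one pose per model in file order", {
  hex <- make_symmetric_ligand(6, 1.4)
  poses <- list(hex, translate(hex, c(5, 0, 0)))
  path <- tempfile(fileext = ".pdb")
  write_poses_pdb(poses, path)
  ps <- read_poses(path, engine = "engine_A", ligand_id = "HEX")
  expect_equal(nrow(ps), 2)
  expect_equal(ps$pose_index, 1:2)
  expect_equal(ps$engine, rep("engine_A", 2))
  expect_equal(ps$atoms[[2]]$x, hex$x + 5, tolerance = 1e-9)
})

test_that("PDB pose round trip preserves coordinates to 3 decimals", {
  set.seed(71)
  pose <- random_pose(c("C", "N", "O", "S"), span = 40)
  path <- tempfile(fileext = ".pdb")
  write_poses_pdb(list(pose), path)
  back <- read_poses(path, engine = "x")$atoms[[1]]
  expect_equal(back$x, round(pose$x, 3))
  expect_equal(back$y, round(pose$y, 3))
  expect_equal(back$z, round(pose$z, 3))
  expect_equal(back$element, pose$element)
})

test_that("SDF conformer files parse with ChemmineR, order preserved", {
  sdf_block <- function(shift) c(
    "hexane-frag", "  condock", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            c(0 + shift, 1.5 + shift, 3 + shift), c(0, 0, 0), c(0, 0, 0),
            c("C", "C", "O")),
    "  1  2  1  0", "  2  3  1  0", "M  END", "$$$$")
  path <- write_lines_tmp(c(sdf_block(0), sdf_block(2)), ".sdf")
  ps <- read_poses(path, engine = "engine_B", ligand_id = "FRG")
  expect_equal(nrow(ps), 2)
  expect_equal(ps$atoms[[1]]$element, c("C", "C", "O"))
  expect_equal(ps$atoms[[2]]$x - ps$atoms[[1]]$x, rep(2, 3),
               tolerance = 1e-9)
})

test_that("MOL2 SYBYL atom types normalize to element symbols", {
  mol2 <- c(
    "@<TRIPOS>MOLECULE", "frag", "  3 2 1", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 C1   0.0000  0.0000  0.0000 C.ar  1 LIG 0.0000",
    "  2 N1   1.4000  0.0000  0.0000 N.4   1 LIG 0.0000",
    "  3 O1   2.8000  0.0000  0.0000 O.co2 1 LIG 0.0000",
    "@<TRIPOS>BOND", "  1 1 2 ar", "  2 2 3 1")
  ps <- read_poses(write_lines_tmp(mol2, ".mol2"), engine = "engine_A")
  expect_equal(nrow(ps), 1)
  expect_equal(ps$atoms[[1]]$element, c("C", "N", "O"))
  expect_equal(ps$atoms[[1]]$x, c(0, 1.4, 2.8))
})

test_that("pose sets enforce a consistent element multiset per ligand", {
  hex <- make_symmetric_ligand(6, 1.4)
  pent <- make_symmetric_ligand(5, 1.4)
  expect_error(pose_set(list(hex, pent), "L", "e"), "multiset")
})

test_that("score tables parse, flag incomplete rows, and reject duplicates", {
  csv <- c("ligand_id,engine,pose_index,vina,goldscore,chemplp",
           "L1,engine_A,1,,52.1,78.0",
           "L1,engine_A,2,,49.9,71.2",
           "L1,engine_B,1,-9.1,,")
  expect_warning(tab <- read_score_table(write_lines_tmp(csv, ".csv")),
                 "missing metric")
  expect_equal(nrow(tab), 3)
  expect_false(any(tab$metric_complete)) # every row misses some metric
  full <- c("ligand_id,engine,pose_index,vina,goldscore,chemplp",
            "L1,engine_A,1,-8.0,52.1,78.0",
            "L1,engine_A,2,-7.5,,71.2")
  expect_warning(tab2 <- read_score_table(write_lines_tmp(full, ".csv")),
                 "missing metric")
  expect_equal(tab2$metric_complete, c(TRUE, FALSE))
  dup <- c("ligand_id,engine,pose_index,vina",
           "L1,engine_A,1,-8.0", "L1,engine_A,1,-7.0")
  expect_error(read_score_table(write_lines_tmp(dup, ".csv")), "duplicate")
  hdr <- "ligand_id,engine,pose_index,vina"
  expect_warning(empty <- read_score_table(write_lines_tmp(hdr, ".csv")),
                 "no rows")
  expect_equal(nrow(empty), 0)
})
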