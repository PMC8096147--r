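test_that("PDB reading keeps coordinates, altlocs and waters", {
  f <- withr::local_tempfile(fileext = ".pdb")
  fmt <- "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  writeLines(c(
    sprintf(fmt, "ATOM", 1, "N1", " ", "A", "A", 2670, 0, 0, 0, 1, 0, "N"),
    sprintf(fmt, "ATOM", 2, "C2", "A", "A", "A", 2671, 1, 0.5, 0, 0.6, 0, "C"),
    sprintf(fmt, "ATOM", 3, "C2", "B", "A", "A", 2671, 1.2, 0.4, 0.1, 0.4, 0, "C"),
    sprintf(fmt, "HETATM", 4, "O", " ", "HOH", "W", 3001, 2, 0, 0, 1, 0, "O"),
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 4)
  expect_equal(m$atoms$x[1], 0)
  expect_setequal(m$atoms$altloc[m$atoms$residue_number == 2671], c("A", "B"))
  expect_true(m$atoms$is_water[4])
  expect_equal(m$atoms$occupancy[2], 0.6)

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_error(read_structure(empty))
  expect_error(read_structure("/nonexistent/file.pdb"), "not found")
})

test_that("toy base pair round-trips through the PDB writer and reader", {
  m <- gen_toy_base_pair("AU",
                         waters = list(list(anchor = "N3", distance = 2.8)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-3)
  expect_setequal(m2$atoms$atom_name, m$atoms$atom_name)
  expect_equal(sum(m2$atoms$is_water), 1)
})

test_that("superposition of a model onto itself gives rmsd 0", {
  m <- gen_toy_base_pair("GC")
  sp <- superpose(m, m)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
})

test_that("a known rigid transform is undone exactly", {
  m <- gen_toy_base_pair("AU")
  th <- 37 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% Rz
  m2$atoms$x <- xyz[, 1] + 1
  m2$atoms$y <- xyz[, 2] + 2
  m2$atoms$z <- xyz[, 3] + 3
  sp <- superpose(m2, m)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  # recovered rotation is the inverse of the applied one
  expect_equal(sp$rotation, t(Rz), tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
  # rmsd is symmetric under swapping the roles
  expect_equal(superpose(m, m2)$rmsd, sp$rmsd, tolerance = 1e-8)
})

test_that("Kabsch equals the brute-force rotation-grid oracle on small toys", {
  set.seed(5)
  P <- matrix(rnorm(18), ncol = 3)            # 6 atoms
  ang <- 0.7
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
  Q <- P %*% Rz + matrix(rnorm(18, 0, 0.05), ncol = 3)  # noisy copy
  mk <- function(X) {
    atoms <- data.frame(element = "C", atom_name = paste0("C", 1:6),
                        residue_name = "TOY", residue_number = 1L,
                        chain = "A", x = X[, 1], y = X[, 2], z = X[, 3],
                        occupancy = 1, altloc = "", is_water = FALSE)
    deazaRNA:::new_structure_model(atoms, "toy")
  }
  sp <- superpose(mk(P), mk(Q), mobile_idx = 1:6, target_idx = 1:6)
  oracle <- grid_superpose_rmsd(P, Q, n_grid = 72)
  expect_lte(sp$rmsd, oracle + 1e-9)              # never worse than the grid
  expect_lt(abs(sp$rmsd - oracle), 0.05)          # grid resolution
})

test_that("superposition rejects degenerate selections", {
  m <- gen_toy_base_pair("AU")
  expect_error(superpose(m, m, mobile_idx = 1:2, target_idx = 1:2),
               "at least 3")
  expect_error(superpose(m, m, mobile_idx = 1:4, target_idx = 1:3),
               "equal length")
  # collinear points
  atoms <- data.frame(element = "C", atom_name = paste0("C", 1:4),
                      residue_name = "TOY", residue_number = 1L, chain = "A",
                      x = 1:4, y = 2 * (1:4), z = 3 * (1:4),
                      occupancy = 1, altloc = "", is_water = FALSE)
  lin <- deazaRNA:::new_structure_model(atoms, "line")
  expect_error(superpose(lin, lin, mobile_idx = 1:4, target_idx = 1:4),
               "collinear")
})

test_that("isosteric matching superposes a 3-deaza pair onto its parent", {
  m_nat <- gen_toy_base_pair("AU")
  m_mod <- gen_toy_base_pair("AU", deaza3 = TRUE)
  sp <- superpose(m_mod, m_nat)  # C3 matched to N3 positionally
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  expect_equal(sp$n_atoms, nrow(m_nat$atoms))
})

test_that("hydration report finds placed waters with exact distances", {
  m <- gen_toy_base_pair("AU", waters = list(
    list(anchor = "N3", distance = 2.8),
    list(anchor = "O2'", distance = 3.1, direction = c(0, -1, 0))))
  rep <- minor_groove_waters(m, c(2650, 2670))
  expect_equal(nrow(rep), 2)
  expect_equal(rep$distance, c(2.8, 3.1), tolerance = 1e-9)  # sorted ascending
  expect_identical(rep$nearest_atom[1], "N3")
  expect_identical(rep$nearest_atom[2], "O2'")

  # empty when the cutoff is below every distance
  expect_equal(nrow(minor_groove_waters(m, c(2650, 2670), cutoff = 2.0)), 0)
  # monotone in cutoff: smaller-cutoff report is a prefix
  r_small <- minor_groove_waters(m, c(2650, 2670), cutoff = 3.0)
  r_big <- minor_groove_waters(m, c(2650, 2670), cutoff = 3.6)
  expect_true(all(r_small$water_number %in% r_big$water_number))
  expect_error(minor_groove_waters(m, c(1, 2)), "not found")
})

test_that("deaza C3 is a minor-groove face atom and low-occupancy waters are excluded", {
  m <- gen_toy_base_pair("AU", deaza3 = TRUE,
                         waters = list(list(anchor = "C3", distance = 3.3)))
  rep <- minor_groove_waters(m, c(2650, 2670))
  expect_identical(rep$nearest_atom[1], "C3")
  expect_equal(rep$distance[1], 3.3, tolerance = 1e-9)

  m$atoms$occupancy[m$atoms$is_water] <- 0.4
  expect_equal(nrow(minor_groove_waters(m, c(2650, 2670))), 0)
})

test_that("atom distances resolve unique selections", {
  m <- gen_toy_base_pair("AU", waters = list(list(anchor = "N3",
                                                  distance = 2.8)))
  d <- atom_distance(m,
                     list(residue_number = 2670, atom_name = "N3"),
                     list(residue_number = 3001, atom_name = "O",
                          include_water = TRUE))
  expect_equal(d, 2.8, tolerance = 1e-9)
  expect_equal(atom_distance(m,
                             list(residue_number = 2670, atom_name = "N3"),
                             list(residue_number = 2670, atom_name = "N3")),
               0)
  expect_error(atom_distance(m, list(atom_name = "C1'"),
                             list(atom_name = "N3")), "ambiguous")
  expect_error(atom_distance(m, list(atom_name = "XX"),
                             list(atom_name = "N3")), "no atom")
})

test_that("water placement clashes are rejected", {
  expect_error(gen_toy_base_pair("AU", waters = list(
    list(anchor = "N3", distance = 0.5))), "clash")
})
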