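test_that("parse_structure extracts Calpha beads with unit conversion", {
  pos <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.76, 0, 0))
  pdb <- make_pdb(pos, c("GLY", "ALA", "SER"))
  m <- parse_structure(pdb)
  expect_equal(n_beads(m), 3)
  expect_equal(m$positions, matrix(c(0, 0.38, 0.76, rep(0, 6)), 3, 3),
               tolerance = 1e-9)
  expect_equal(m$residue_names, c("G", "A", "S"))
  expect_true(all(m$resolved))
})

test_that("parse_structure rejects degenerate or malformed input", {
  expect_error(parse_structure("REMARK nothing here"), "Calpha")
  pdb <- make_pdb(rbind(c(0, 0, 0)), "XYZ")
  expect_error(parse_structure(pdb), "XYZ")
  # a residue with atoms but no Calpha is an error naming the residue
  cb <- sprintf(
    "ATOM  %5d  CB  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    9L, "ALA", "A", 4L, 1.0, 0.0, 0.0)
  pdb <- make_pdb(rbind(c(0, 0, 0)), "GLY", extra_atoms = cb)
  expect_error(parse_structure(pdb), "A 4")
})

test_that("chain breaks become unresolved beads (SEQRES fills names)", {
  pos <- matrix(0, 6, 3)
  pos[, 1] <- c(1:3, 7:9) * 0.38
  pdb <- make_pdb(pos, rep("ALA", 6), resseq = c(1:3, 7:9),
                  seqres = rep("ALA", 9))
  m <- parse_structure(pdb)
  expect_equal(n_beads(m), 9)
  expect_equal(which(!m$resolved), 4:6)
  expect_true(all(is.na(m$positions[4:6, 1])))
  m <- mark_disordered(m)
  expect_equal(which(m$disorder_mask), 4:6)
})

test_that("bead properties follow the residue code rules", {
  m <- new_cg_model(strsplit("DEKRFYW", "")[[1]], matrix(0, 7, 3))
  m <- assign_bead_properties(m)
  expect_equal(m$charges, c(-1, -1, 1, 1, 0, 0, 0))
  expect_equal(m$aromatic_flags, c(rep(FALSE, 4), rep(TRUE, 3)))
  m2 <- assign_bead_properties(new_cg_model(c("P", "R"), matrix(0, 2, 3)))
  expect_equal(m2$charges, c(0, 1))
  expect_false(any(m2$aromatic_flags))
  bad <- new_cg_model(c("A", "B"), matrix(0, 2, 3))
  expect_error(assign_bead_properties(bad), "B")
  # histidine neutral by default, configurable
  h <- assign_bead_properties(new_cg_model("H", matrix(0, 1, 3)))
  expect_equal(h$charges, 0)
})

test_that("disorder calling: <70 pLDDT and unresolved-wins", {
  m <- new_cg_model(c("A", "A", "A"), matrix(rnorm(9), 3, 3))
  m1 <- mark_disordered(m, integer(0), confidence_scores = c(90, 65, 90))
  expect_equal(m1$disorder_mask, c(FALSE, TRUE, FALSE))
  m2 <- mark_disordered(m, integer(0), confidence_scores = c(90, 70, 90))
  expect_false(any(m2$disorder_mask))  # strict: exactly 70 is structured
  m3 <- mark_disordered(m, unresolved_set = 2,
                        confidence_scores = c(90, 95, 90))
  expect_equal(m3$disorder_mask, c(FALSE, TRUE, FALSE))
  expect_error(mark_disordered(m, integer(0), confidence_scores = c(90, 65)),
               "cover")
})

test_that("elastic network uses the strict 1.4 nm rule", {
  m <- assign_bead_properties(
    new_cg_model(c("A", "A"), rbind(c(0, 0, 0), c(1.0, 0, 0))))
  m <- build_elastic_network(m)
  expect_equal(nrow(m$bonds), 1)
  expect_equal(m$bonds$b0, 1.0)
  m2 <- assign_bead_properties(
    new_cg_model(c("A", "A"), rbind(c(0, 0, 0), c(1.4, 0, 0))))
  m2 <- build_elastic_network(m2)
  expect_equal(nrow(m2$bonds), 0)
})

test_that("elastic network equals the all-pairs brute-force oracle", {
  # 10-bead toy helix
  t_ <- seq(0, 3 * pi, length.out = 10)
  pos <- cbind(cos(t_), sin(t_), 0.15 * t_)
  m <- assign_bead_properties(new_cg_model(rep("A", 10), pos))
  m <- build_elastic_network(m)
  expected <- NULL
  for (i in 1:9) for (j in (i + 1):10) {
    b <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (b < 1.4) expected <- rbind(expected, c(i, j, b))
  }
  got <- m$bonds[order(m$bonds$i, m$bonds$j), ]
  expect_equal(nrow(got), nrow(expected))
  expect_equal(got$i, expected[, 1])
  expect_equal(got$j, expected[, 2])
  expect_equal(got$b0, expected[, 3], tolerance = 1e-12)
})

test_that("disordered beads get backbone, never network, bonds", {
  pos <- matrix(c(0, 0.38, 0.76, 1.14, rep(0, 8)), 4, 3)
  m <- assign_bead_properties(new_cg_model(rep("A", 4), pos))
  m <- mark_disordered(m, unresolved_set = integer(0),
                       confidence_scores = c(90, 90, 50, 50))
  m <- build_elastic_network(m)
  net <- m$bonds[m$bonds$type == "network", ]
  expect_equal(nrow(net), 1)  # only the 1-2 structured pair
  expect_false(any(net$i %in% 3:4 | net$j %in% 3:4))
  bb <- m$bonds[m$bonds$type == "backbone", ]
  expect_equal(sort(bb$i), c(2, 3))  # bonds 2-3 and 3-4
})

test_that("polyPR construction: alternation, charge, NCPR", {
  pr1 <- build_polypr(1)
  expect_equal(pr1$residue_names, c("P", "R"))
  pr7 <- build_polypr(7)
  expect_equal(n_beads(pr7), 14)
  expect_equal(sum(pr7$charges), 7)
  for (n in c(2, 5, 20, 50)) {
    pr <- build_polypr(n)
    expect_equal(n_beads(pr), 2 * n)
    expect_equal(sum(pr$charges) / n_beads(pr), 0.5)  # NCPR exactly +0.5
    expect_equal(unique(pr$residue_names[seq(1, 2 * n, 2)]), "P")
  }
  pr50 <- build_polypr(50)
  expect_equal(sum(pr50$charges), 50)
  expect_error(build_polypr(0), "positive")
})

test_that("descriptors: dipole conventions and closed-form rg", {
  # +1/-1 at 1 nm: neutral, dipole 1 e nm regardless of origin
  m <- new_cg_model(c("K", "D"), rbind(c(0, 0, 0), c(1, 0, 0)))
  m <- assign_bead_properties(m)
  d <- compute_descriptors(m)
  expect_equal(d$dipole_M, 1)
  m$positions <- m$positions + 5.3
  expect_equal(compute_descriptors(m)$dipole_M, 1, tolerance = 1e-12)
  # unit square of neutral beads: rg = sqrt(2)/2
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  ms <- assign_bead_properties(new_cg_model(rep("S", 4), sq))
  ds <- compute_descriptors(ms)
  expect_equal(ds$ncpr, 0)
  expect_equal(ds$dipole_M, 0)
  expect_equal(ds$rg, sqrt(2) / 2, tolerance = 1e-12)
  expect_false(ds$time_averaged)
})

test_that("dipole of net-neutral molecules is translation invariant", {
  set.seed(42)
  for (rep_ in 1:5) {
    n <- 10
    res <- sample(c(rep("E", 3), rep("K", 3), rep("S", 4)))
    m <- assign_bead_properties(new_cg_model(res, matrix(rnorm(3 * n), n, 3)))
    d0 <- compute_descriptors(m)$dipole_M
    m$positions <- sweep(m$positions, 2, rnorm(3, sd = 10), "+")
    expect_equal(compute_descriptors(m)$dipole_M, d0, tolerance = 1e-10)
  }
})

test_that("descriptors average over trajectory frames when given", {
  m <- assign_bead_properties(new_cg_model(c("K", "D"),
                                           rbind(c(0, 0, 0), c(1, 0, 0))))
  f1 <- rbind(c(0, 0, 0), c(1, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(2, 0, 0))
  traj <- static_traj(list(f1, f2), box = 50)
  d <- compute_descriptors(m, trajectory = traj, production = FALSE)
  expect_equal(d$dipole_M, 1.5)
  expect_true(d$time_averaged)
  empty <- static_traj(list(f1), box = 50)
  empty$frames <- empty$frames[, , integer(0), drop = FALSE]
  expect_error(compute_descriptors(m, trajectory = empty, production = FALSE),
               "frames")
})

test_that("PDB round trip preserves beads and coordinates", {
  toy <- gen_toy_component(30, net_charge = -5, seed = 4)$model
  txt <- write_pdb(toy)
  back <- parse_structure(txt)
  expect_equal(n_beads(back), n_beads(toy))
  expect_equal(back$positions, toy$positions, tolerance = 1e-3)
  expect_equal(back$residue_names, toy$residue_names)
})

test_that("model JSON round trip is faithful", {
  toy <- gen_toy_component(25, net_charge = 3, seed = 9)$model
  path <- tempfile(fileext = ".json")
  write_cg_model(toy, path)
  back <- read_cg_model(path)
  expect_equal(back$positions, toy$positions, tolerance = 1e-12)
  expect_equal(back$charges, toy$charges)
  expect_equal(back$bonds$b0, toy$bonds$b0, tolerance = 1e-12)
  expect_equal(back$kind, toy$kind)
})

test_that("place_unresolved grows and keeps chain connectivity", {
  pos <- matrix(NA_real_, 9, 3)
  pos[c(1:3, 7:9), ] <- cbind(c(1:3, 7:9) * 0.38, 0, 0)
  m <- new_cg_model(rep("A", 9), pos, resolved = !is.na(pos[, 1]))
  m <- assign_bead_properties(m)
  m <- mark_disordered(m)
  m <- build_elastic_network(m)
  m <- place_unresolved(m, seed = 3)
  expect_false(anyNA(m$positions))
  # backbone neighbours of placed beads are at a plausible bond length
  d45 <- sqrt(sum((m$positions[4, ] - m$positions[5, ])^2))
  expect_lt(d45, 0.8)
  expect_gt(d45, 0.1)
})

test_that("NTF2 homodimer sequence gives the reference NCPR", {
  fa <- read_fasta(system.file("extdata", "ntf2_human.fasta",
                               package = "onebpa"))
  dimer <- rep(unname(fa[1]), 2)
  expect_lt(abs(ncpr_from_sequence(dimer) - (-0.047)), 5e-4)
})
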