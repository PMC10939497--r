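test_that("pair classification follows the interaction rules", {
  params <- default_force_field()
  toy <- gen_toy_component(20, net_charge = -4, frac_aromatic = 0.3,
                           seed = 11)$model
  pr <- build_polypr(3)
  pos <- rbind(toy$positions, sweep(pr$positions, 2, c(0, 5, 0), "+"))
  sys <- assemble_system(list(toy, pr), positions = pos, box = 30,
                         params = params)
  nc <- n_beads(toy)
  iR <- nc + which(sys$residue_names[(nc + 1):(nc + 6)] == "R")[1]
  iP <- nc + which(sys$residue_names[(nc + 1):(nc + 6)] == "P")[1]
  jF <- which(sys$residue_names[1:nc] == "F")[1]
  jS <- which(sys$residue_names[1:nc] == "S")[1]
  # polyPR arginine vs component aromatic: cation-pi, no elec (F neutral)
  cl <- classify_pair(sys, iR, jF)
  expect_equal(cl$nonbonded, "CATION_PI")
  expect_false(cl$elec)
  expect_equal(cl$eps_ij, params$eps_cp["R", "F"])
  # polyPR proline vs any component bead: excluded volume
  cl2 <- classify_pair(sys, iP, jS)
  expect_equal(cl2$nonbonded, "EXCLUDED")
  expect_equal(cl2$eps_ij, params$eps_excl)
  # network-bonded structured pair: no nonbonded class
  b1 <- sys$bonds[sys$bonds$type == "network", ][1, ]
  cl3 <- classify_pair(sys, b1$i, b1$j)
  expect_equal(cl3$nonbonded, "NONE")
  expect_equal(cl3$bonded, "NETWORK")
  # intra-polyPR backbone neighbours excluded; 1-3 pairs are HP
  cl4 <- classify_pair(sys, nc + 1, nc + 2)
  expect_equal(cl4$nonbonded, "NONE")
  expect_equal(cl4$bonded, "BACKBONE")
  cl5 <- classify_pair(sys, nc + 1, nc + 3)
  expect_equal(cl5$nonbonded, "HP")
  # classification is symmetric
  expect_equal(classify_pair(sys, jF, iR)$nonbonded, "CATION_PI")
})

test_that("forces are the exact analytic gradient of the energy", {
  for (seed in 1:6) {
    sys <- make_test_system(seed)
    ef <- total_energy_forces(sys)
    pos <- sys$positions
    h <- 1e-5
    ks <- sample(length(pos), 15)
    for (k in ks) {
      p1 <- pos; p1[k] <- p1[k] + h
      p2 <- pos; p2[k] <- p2[k] - h
      num <- (total_energy_forces(sys, p1)$energy -
              total_energy_forces(sys, p2)$energy) / (2 * h)
      expect_equal(-ef$forces[k], num,
                   tolerance = 1e-5 * max(1, abs(num)))
    }
  }
})

test_that("Newton's third law: forces sum to zero", {
  for (seed in 7:9) {
    sys <- make_test_system(seed)
    f <- total_energy_forces(sys)$forces
    scale <- max(abs(f), 1)
    expect_lt(max(abs(colSums(f))) / scale, 1e-9)
  }
})

test_that("energy is invariant under rigid translation across the boundary", {
  sys <- make_test_system(10)
  e0 <- total_energy_forces(sys)$energy
  for (shift in list(c(3.7, -1.2, 2.2), c(sys$box, 0, 0),
                     c(0.5 * sys$box, 0.9 * sys$box, -2 * sys$box))) {
    p <- sweep(sys$positions, 2, shift, "+")
    expect_equal(total_energy_forces(sys, p)$energy, e0,
                 tolerance = 1e-9 * max(1, abs(e0)))
  }
})

test_that("higher salt screens like-charge repulsion", {
  # two R beads of separate polyPR chains at a range of distances
  pr1 <- build_polypr(1)
  pr2 <- build_polypr(1)
  for (d in c(0.7, 1.0, 1.5, 2.0)) {
    pos <- rbind(pr1$positions,
                 sweep(pr2$positions, 2, c(0, d, 0), "+")) + 5
    e <- vapply(c(100, 200), function(salt) {
      sys <- assemble_system(list(pr1, pr2), positions = pos, box = 12,
                             params = default_force_field(salt = salt))
      total_energy_forces(sys)$energy
    }, numeric(1))
    expect_lte(e[2], e[1])
  }
})

test_that("overlapping beads raise an error naming the pair", {
  m <- assign_bead_properties(
    new_cg_model(c("S", "S"), rbind(c(1, 1, 1), c(1, 1, 1 + 1e-9))))
  sys <- assemble_system(list(m), box = 10)
  expect_error(total_energy_forces(sys), "overlap")
})

test_that("beads beyond the cutoff contribute nothing", {
  m1 <- assign_bead_properties(new_cg_model("S", matrix(1, 1, 3)))
  m2 <- assign_bead_properties(new_cg_model("S", matrix(5, 1, 3)))
  sys <- assemble_system(list(m1, m2), box = 20)
  ef <- total_energy_forces(sys)
  expect_equal(ef$energy, 0)
  expect_equal(max(abs(ef$forces)), 0)
})

test_that("neighbor list equals the brute-force oracle", {
  set.seed(31)
  n <- 200
  box <- 6
  pos <- matrix(runif(3 * n, 0, box), n, 3)
  cutoff <- 1.2
  nl <- neighbor_list(pos, box, cutoff)
  key <- paste(nl[, 1], nl[, 2])
  brute <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) <= cutoff) brute <- c(brute, paste(i, j))
  }
  expect_setequal(key, brute)
})

test_that("neighbor list sees pairs through the periodic boundary", {
  box <- 10
  pos <- rbind(c(0.2, 5, 5), c(9.7, 5, 5))  # 0.5 nm through the face
  nl <- neighbor_list(pos, box, 1)
  expect_equal(nrow(nl), 1)
  # three beads in a line spaced 0.9 nm, cutoff 1: pairs (1,2) and (2,3)
  pos3 <- cbind(c(1, 1.9, 2.8), 5, 5)
  nl3 <- neighbor_list(pos3, box, 1)
  expect_equal(nrow(nl3), 2)
  expect_error(neighbor_list(pos3, box, 6), "half")
})

test_that("force-field config round trip is bit exact", {
  p <- default_force_field(salt = 200)
  path <- tempfile(fileext = ".json")
  write_ff_config(p, path)
  q <- read_ff_config(path)
  for (f in c("eps_hp", "eps_rep", "sigma", "mix_exp", "Ss", "z", "kappa",
              "K_network", "rm_cp", "eps_excl", "coulomb", "cutoff"))
    expect_identical(q[[f]], p[[f]])
  expect_identical(q$eps_cp, p$eps_cp)
})
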