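test_that("static single-contact and no-contact fixtures", {
  # beads: 1 polyPR-like probe, 2 component beads; box large
  fr <- rbind(c(5, 5, 5), c(5.9, 5, 5), c(9, 1, 1))
  traj <- static_traj(list(fr, fr, fr), box = 20)
  cc <- count_contacts(traj, polypr_indices = 1, component_indices = 2:3,
                       production = FALSE)
  expect_equal(cc$ct, 1)
  expect_equal(cc$sem, 0)
  expect_equal(cc$ct_normalized, 1 / (2 * 1))
  far <- rbind(c(1, 1, 1), c(7, 7, 7), c(12, 12, 12))
  t2 <- static_traj(list(far, far, far), box = 30)
  cc2 <- count_contacts(t2, 1, 2:3, production = FALSE)
  expect_equal(cc2$ct, 0)
  expect_equal(cc2$ct_normalized, 0)
  expect_error(count_contacts(static_traj(list(fr, fr), box = 20), 1, 2:3,
                              production = FALSE), "3 frames")
})

test_that("contact criterion is closed (d <= cutoff) and minimum-image", {
  at <- function(d) static_traj(list(rbind(c(1, 1, 1), c(1 + d, 1, 1)),
                                     rbind(c(1, 1, 1), c(1 + d, 1, 1)),
                                     rbind(c(1, 1, 1), c(1 + d, 1, 1))),
                                box = 10)
  expect_equal(count_contacts(at(1.0), 1, 2, production = FALSE)$ct, 1)
  expect_equal(count_contacts(at(1.0 + 1e-9), 1, 2, production = FALSE)$ct, 0)
  # separation 0.6 through the periodic boundary
  wrap <- rbind(c(0.3, 5, 5), c(9.7, 5, 5))
  t3 <- static_traj(list(wrap, wrap, wrap), box = 10)
  expect_equal(count_contacts(t3, 1, 2, production = FALSE)$ct, 1)
})

test_that("contact probability counts frames with any partner in range", {
  near <- rbind(c(5, 5, 5), c(5.5, 5, 5))
  farr <- rbind(c(5, 5, 5), c(8, 8, 8))
  traj <- static_traj(list(near, farr, near, farr), box = 20)
  p <- contact_probability(traj, component_indices = 2, polypr_indices = 1,
                           production = FALSE)
  expect_equal(p, 0.5)
  pa <- contact_probability(static_traj(list(near, near), box = 20),
                            2, 1, production = FALSE)
  expect_equal(pa, 1.0)
  pf <- contact_probability(static_traj(list(farr, farr), box = 20),
                            2, 1, production = FALSE)
  expect_equal(pf, 0.0)
})

test_that("cell-list contacts equal the brute-force oracle exactly", {
  set.seed(77)
  n <- 30
  box <- 5  # small box so the cell path wraps
  frames <- lapply(1:50, function(f) matrix(runif(3 * n, 0, box), n, 3))
  traj <- static_traj(frames, box = box)
  idxA <- 1:12; idxB <- 13:30
  cc <- count_contacts(traj, idxA, idxB, production = FALSE)
  oracle <- brute_contacts(traj$frames, box, idxA, idxB, 1.0)
  expect_identical(as.integer(cc$per_frame), as.integer(oracle$per_frame))
  expect_equal(cc$ct, mean(oracle$per_frame))
  p <- contact_probability(traj, idxB, idxA, production = FALSE)
  expect_equal(p, oracle$b_frames / 50)
  # and SEM equals the 3-block formula applied by hand
  bl <- 50 %/% 3
  bm <- vapply(1:3, function(b)
    mean(oracle$per_frame[((b - 1) * bl + 1):(b * bl)]), numeric(1))
  expect_equal(cc$sem, sd(bm) / sqrt(3))
})

test_that("enlarging the cutoff never decreases contacts", {
  set.seed(13)
  n <- 20
  frames <- lapply(1:10, function(f) matrix(runif(3 * n, 0, 6), n, 3))
  traj <- static_traj(frames, box = 6)
  cuts <- c(0.5, 0.8, 1.0, 1.3)
  cts <- vapply(cuts, function(cu)
    count_contacts(traj, 1:8, 9:20, cutoff = cu, production = FALSE)$ct,
    numeric(1))
  expect_true(all(diff(cts) >= 0))
  probs <- vapply(cuts, function(cu)
    contact_probability(traj, 9:20, 1:8, cutoff = cu, production = FALSE),
    numeric(12))
  expect_true(all(diff(t(probs)) >= 0))
})

test_that("contact sites use a strict 0.10 threshold", {
  expect_equal(call_contact_sites(c(0.05, 0.11, 0.95)), c(2, 3))
  expect_equal(call_contact_sites(c(0.10, 0.10)), integer(0))
  expect_equal(call_contact_sites(rep(0, 5)), integer(0))
  expect_error(call_contact_sites(c(0.5, 1.2)), "0, 1")
})

test_that("n_shared is exact set intersection with bounds checking", {
  expect_equal(n_shared(1:5, 6:10), 0)
  expect_equal(n_shared(1:10, 3:6), 4)  # annotation subset of sites
  set.seed(5)
  for (rep_ in 1:10) {
    a <- sample(100, 20); b <- sample(100, 15)
    ann <- data.frame(partner = "x", residue_index = b)
    expect_equal(n_shared(a, ann), length(intersect(a, b)))
    expect_lte(n_shared(a, ann), min(length(a), length(unique(b))))
  }
  expect_error(n_shared(1:3, data.frame(partner = "x", residue_index = 200),
                        n_residues = 100), "bounds")
})

test_that("shared sites grow with polyPR length on nested fixtures", {
  # constructed nested contact-site sets emulate longer chains touching more
  sites <- list(PR7 = c(76:80), PR20 = c(70:85), PR50 = c(60:95))
  ann <- data.frame(partner = "NLS-cargo", residue_index = 72:90)
  ns <- vapply(sites, n_shared, integer(1), annotation = ann)
  expect_true(all(diff(ns) >= 0))
})

test_that("shared_site_table summarizes per partner", {
  m <- gen_toy_component(100, seed = 3)$model
  ann <- gen_annotation_pair(m, k = 4, size1 = 12, size2 = 9, seed = 2)
  probs <- rep(0, 100)
  probs[ann$residue_index[ann$partner == "partnerA"]] <- 0.5
  tab <- shared_site_table(probs, ann)
  expect_equal(tab$n_shared[tab$partner == "partnerA"], 12)
  expect_equal(tab$n_shared[tab$partner == "partnerB"], 4)
  expect_equal(tab$n_binding_sites, c(12, 9))
})

test_that("annotation TSV round trip and renumbering", {
  ann <- data.frame(partner = c("RanGTP", "RanGTP", "Impa"),
                    residue_index = c(10L, 20L, 30L))
  path <- tempfile(fileext = ".tsv")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_equal(back, ann)
  map <- data.frame(from = c(10, 20, 30), to = c(1, 11, 21))
  mapped <- read_annotation(path, mapping = map)
  expect_equal(mapped$residue_index, c(1, 11, 21))
})
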