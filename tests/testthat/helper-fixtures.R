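# programmatic fixtures shared across the test files

# minimal PDB text from Calpha positions given in nm
make_pdb <- function(pos_nm, resnames = rep("GLY", nrow(pos_nm)),
                     chain = "A", resseq = seq_len(nrow(pos_nm)),
                     seqres = NULL, extra_atoms = NULL) {
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(pos_nm)), resnames, chain, resseq,
    pos_nm[, 1] * 10, pos_nm[, 2] * 10, pos_nm[, 3] * 10)
  if (!is.null(seqres)) {
    # 13 residues per SEQRES line, chain id in column 12
    n <- length(seqres)
    sr <- character(0)
    for (k in seq_len(ceiling(n / 13))) {
      toks <- seqres[((k - 1) * 13 + 1):min(k * 13, n)]
      sr <- c(sr, sprintf("SEQRES %3d %1s %4d  %s", k, chain, n,
                          paste(toks, collapse = " ")))
    }
    lines <- c(sr, lines)
  }
  if (!is.null(extra_atoms)) lines <- c(lines, extra_atoms)
  c(lines, "END")
}

# small polyPR + toy component system with randomized positions, used by the
# force/gradient tests; returns the assembled cg_system
make_test_system <- function(seed = 1, n_comp = 12, n_repeats = 4,
                             box = 8, salt = 100) {
  set.seed(seed)
  params <- default_force_field(salt = salt)
  toy <- gen_toy_component(n_comp, net_charge = -2, frac_aromatic = 0.2,
                           seed = seed, params = params)$model
  pr <- build_polypr(n_repeats, params)
  n <- n_beads(toy) + n_beads(pr)
  # jittered grid keeps every pair at a safe distance with PBC wrapping
  g <- ceiling(n^(1 / 3))
  stopifnot(g * 0.9 < box)
  grid <- as.matrix(expand.grid(x = seq_len(g), y = seq_len(g),
                                z = seq_len(g))) * 0.9
  pos <- grid[sample(nrow(grid), n), ] + matrix(runif(3 * n, -0.15, 0.15),
                                                n, 3)
  assemble_system(list(toy, pr), positions = pos, box = box, params = params)
}

# physically consistent small complex (bonds at rest length) for dynamics
make_dynamics_system <- function(seed = 1, n_comp = 12, n_repeats = 4,
                                 salt = 100, distance = 2) {
  params <- default_force_field(salt = salt)
  toy <- gen_toy_component(n_comp, net_charge = -2, frac_aromatic = 0.2,
                           seed = seed, params = params)$model
  pr <- build_polypr(n_repeats, params)
  cfg <- sim_config(salt = salt, seed = seed)
  pl <- place_complex(pr, toy, cfg, seed = seed, distance = distance)
  assemble_system(list(toy, pr), positions = pl$positions, box = pl$box,
                  params = params)
}

# brute-force contact oracle: O(frames * N_A * N_B) double loop in R
brute_contacts <- function(frames, box, idxA, idxB, cutoff) {
  nf <- dim(frames)[3]
  counts <- integer(nf)
  touch <- matrix(FALSE, length(idxB), nf)
  for (f in seq_len(nf)) {
    for (bq in seq_along(idxB)) {
      j <- idxB[bq]
      for (a in seq_along(idxA)) {
        i <- idxA[a]
        d <- frames[i, , f] - frames[j, , f]
        d <- d - box * round(d / box)
        if (sqrt(sum(d * d)) <= cutoff) {
          counts[f] <- counts[f] + 1L
          touch[bq, f] <- TRUE
        }
      }
    }
  }
  list(per_frame = counts, b_frames = rowSums(touch))
}

# hand-built static trajectory from a list of N x 3 frames
static_traj <- function(frame_list, box, equil_fraction = 0) {
  n <- nrow(frame_list[[1]])
  arr <- array(unlist(frame_list), c(n, 3, length(frame_list)))
  structure(list(frames = arr, times = seq_along(frame_list) - 1,
                 box = box, pe = rep(0, length(frame_list)),
                 ke = rep(0, length(frame_list)),
                 config = list(equil_fraction = equil_fraction)),
            class = "cg_trajectory")
}
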