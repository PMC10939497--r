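# flat parameter list handed to the C++ kernels
.ff_list <- function(params) {
  list(sigma = params$sigma, eps_rep = params$eps_rep, kappa = params$kappa,
       Ss = params$Ss, z = params$z, rm_cp = params$rm_cp,
       coulomb = params$coulomb, cutoff = params$cutoff, skin = params$skin)
}

# Nonbonded class codes shared with src/engine.cpp
.CLS <- c(NONE = 0L, HP = 1L, CATION_PI = 2L, EXCLUDED = 3L)

#' Assemble a multi-molecule simulation system
#'
#' Merges one or more \code{cg_model}s into a single bead table with offset
#' bond indices and molecule ids, and precomputes the nonbonded pair
#' classification used by the energy/force kernels:
#' \itemize{
#'   \item bonded pairs (elastic network, disordered backbone) are excluded
#'     from all nonbonded terms;
#'   \item polyPR internal pairs -- and pairs between residues within the
#'     disordered regions of one component -- interact through the
#'     hydrophobic 8-6 potential with mixing
#'     \eqn{\epsilon_{ij} = \epsilon_{hp} (\epsilon_i \epsilon_j)^{0.27}},
#'     plus electrostatics;
#'   \item polyPR cation beads (R/K) against component aromatic beads
#'     (F/Y/W) interact through the cation-pi 8-6 potential plus
#'     electrostatics;
#'   \item every remaining pair gets excluded volume (the 8-6 potential with
#'     \eqn{\epsilon_{ij}} = 10 kJ/mol) plus electrostatics. Electrostatics
#'     is evaluated wherever both beads are charged, with no
#'     structured/disordered distinction.
#' }
#'
#' @param models list of \code{cg_model}s (properties assigned; positions
#'   set, e.g. by [place_complex()]).
#' @param positions optional replacement N x 3 position matrix (e.g. from
#'   [place_complex()]).
#' @param box cubic box edge in nm.
#' @param params force-field parameters.
#' @return a list of class \code{cg_system} with concatenated per-bead
#'   fields, the pair-class matrix \code{cls}, pair-strength matrix
#'   \code{epsm}, bond arrays, and bead index bookkeeping per molecule.
#' @export
assemble_system <- function(models, positions = NULL, box,
                            params = default_force_field()) {
  if (inherits(models, "cg_model")) models <- list(models)
  for (m in models) validate_cg_model(m, params)
  nper <- vapply(models, n_beads, integer(1))
  off <- cumsum(c(0L, nper[-length(nper)]))
  N <- sum(nper)
  pos <- do.call(rbind, lapply(models, `[[`, "positions"))
  if (!is.null(positions)) pos <- positions
  if (anyNA(pos)) stop("system has beads without positions")
  charges <- unlist(lapply(models, `[[`, "charges"))
  epsi <- unlist(lapply(models, `[[`, "hydro_strengths"))
  res <- unlist(lapply(models, `[[`, "residue_names"))
  dis <- unlist(lapply(models, `[[`, "disorder_mask"))
  mol <- rep(seq_along(models), nper)
  is_pr <- rep(vapply(models, function(m) m$kind == "polypr", logical(1)), nper)
  bonds <- do.call(rbind, lapply(seq_along(models), function(k) {
    b <- models[[k]]$bonds
    if (!nrow(b)) return(NULL)
    data.frame(i = b$i + off[k], j = b$j + off[k], b0 = b$b0, type = b$type)
  }))
  if (is.null(bonds))
    bonds <- data.frame(i = integer(0), j = integer(0), b0 = numeric(0),
                        type = character(0))

  cat_type <- ifelse(res == "R", 1L, ifelse(res == "K", 2L, 0L))
  aro_type <- ifelse(res == "F", 1L, ifelse(res == "Y", 2L,
                                            ifelse(res == "W", 3L, 0L)))
  tabs <- .build_pair_tables(N, mol, is_pr, dis, cat_type, aro_type, epsi,
                             bonds, params)
  structure(list(
    positions = pos, box = box, charges = charges, hydro = epsi,
    residue_names = res, disordered = dis, molecule = mol, is_polypr = is_pr,
    cat_type = cat_type, aro_type = aro_type,
    bonds = bonds,
    bonds_mat = as.matrix(bonds[c("i", "j")]),
    b0 = bonds$b0,
    cls = tabs$cls, epsm = tabs$epsm,
    n_per_molecule = nper, offsets = off,
    params = params
  ), class = "cg_system")
}

.build_pair_tables <- function(N, mol, is_pr, dis, cat_type, aro_type, epsi,
                               bonds, params) {
  pri <- matrix(is_pr, N, N); prj <- t(pri)
  same_mol <- outer(mol, mol, "==")
  both_dis <- outer(dis, dis, "&")
  cls <- matrix(.CLS[["EXCLUDED"]], N, N)
  epsm <- matrix(params$eps_excl, N, N)
  # hydrophobic mixing: both beads polyPR, or same-component disordered pair
  hp <- (pri & prj) | (same_mol & !pri & both_dis)
  eps_mix <- params$eps_hp * outer(epsi, epsi)^params$mix_exp
  cls[hp] <- .CLS[["HP"]]
  epsm[hp] <- eps_mix[hp]
  # cation-pi: polyPR R/K bead against component F/Y/W bead
  cat_i <- matrix(cat_type, N, N); aro_i <- matrix(aro_type, N, N)
  cp_ij <- pri & !prj & (cat_i > 0) & (t(aro_i) > 0)   # i is the cation
  cp_ji <- t(cp_ij)                                     # j is the cation
  cp <- cp_ij | cp_ji
  if (any(cp)) {
    ct <- ifelse(cp_ij, cat_i, t(cat_i))
    at <- ifelse(cp_ij, t(aro_i), aro_i)
    idx <- which(cp)
    epsm[idx] <- params$eps_cp[cbind(ct[idx], at[idx])]
    cls[idx] <- .CLS[["CATION_PI"]]
  }
  # bonded pairs and the diagonal drop out of the nonbonded sums entirely
  diag(cls) <- .CLS[["NONE"]]
  if (nrow(bonds)) {
    cls[cbind(bonds$i, bonds$j)] <- .CLS[["NONE"]]
    cls[cbind(bonds$j, bonds$i)] <- .CLS[["NONE"]]
  }
  list(cls = cls, epsm = epsm)
}

#' Classify the interaction of one bead pair
#'
#' Reports the deterministic, symmetric classification used by the force
#' field for beads \code{i} and \code{j} of an assembled system: the
#' nonbonded class ("HP", "CATION_PI", "EXCLUDED", or "NONE" for bonded
#' pairs), the bonded class ("NETWORK", "BACKBONE", or NA), and whether an
#' electrostatic term is evaluated (both beads charged and not bonded).
#'
#' @param system a \code{cg_system}.
#' @param i,j bead indices (1-based).
#' @return list with elements \code{nonbonded}, \code{bonded}, \code{elec},
#'   \code{eps_ij}.
#' @export
classify_pair <- function(system, i, j) {
  N <- nrow(system$positions)
  if (i < 1 || j < 1 || i > N || j > N) stop("bead index out of bounds")
  if (i == j) stop("i and j must differ")
  cl <- system$cls[i, j]
  nb <- names(.CLS)[match(cl, .CLS)]
  b <- system$bonds
  hit <- which((b$i == i & b$j == j) | (b$i == j & b$j == i))
  bonded <- if (length(hit)) toupper(b$type[hit[1]]) else NA_character_
  list(nonbonded = nb, bonded = bonded,
       elec = cl != 0L && system$charges[i] != 0 && system$charges[j] != 0,
       eps_ij = if (cl %in% c(1L, 3L)) system$epsm[i, j] else
                if (cl == 2L) system$epsm[i, j] else NA_real_)
}

#' Total potential energy and analytic forces
#'
#' Sums every classified pair interaction of the system under the
#' minimum-image periodic convention -- bonded harmonic terms plus truncated,
#' energy-shifted nonbonded terms -- and returns the exact analytic negative
#' gradient.
#'
#' @param system a \code{cg_system}.
#' @param positions optional N x 3 position matrix overriding the system's.
#' @return list with \code{energy} (kJ/mol) and \code{forces} (N x 3,
#'   kJ/mol/nm).
#' @export
total_energy_forces <- function(system, positions = NULL) {
  pos <- if (is.null(positions)) system$positions else positions
  if (any(!is.finite(pos))) stop("positions must be finite")
  .ff_eval_cpp(pos, system$box, system$cls, system$epsm, system$charges,
               system$bonds_mat, system$b0, system$params$K_network,
               .ff_list(system$params), FALSE)
}

#' Neighbour pair list under minimum image
#'
#' All unordered bead pairs within \code{cutoff} of each other in the
#' periodic cubic box (exact, equivalent to brute force).
#'
#' @param positions N x 3 matrix (nm).
#' @param box cubic box edge (nm).
#' @param cutoff pair cutoff (nm); must not exceed box/2.
#' @return two-column integer matrix of 1-based pairs (i < j).
#' @export
neighbor_list <- function(positions, box, cutoff) {
  if (cutoff > box / 2) stop("cutoff must not exceed half the box edge")
  .neighbor_pairs_cpp(as.matrix(positions), box, cutoff)
}
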