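#' Coarse-grained one-bead-per-residue model
#'
#' A \code{cg_model} holds one bead per residue at the Calpha position
#' (coordinates in nm), together with per-bead properties and the bond list.
#' Fields: \code{residue_names} (one-letter codes), \code{positions}
#' (N x 3 matrix, nm; NA rows for unresolved residues not yet placed),
#' \code{charges} (e), \code{hydro_strengths} (dimensionless, in (0,1)),
#' \code{aromatic_flags} (TRUE for F/Y/W), \code{disorder_mask}
#' (TRUE = disordered), \code{resolved} (had coordinates in the input
#' structure), \code{chain_ids}, \code{bonds} (data.frame i, j, b0, type with
#' type "network" or "backbone"), \code{kind} ("component" or "polypr").
#'
#' @param residue_names character vector of one-letter residue codes.
#' @param positions N x 3 numeric matrix in nm (NA allowed for unresolved).
#' @param chain_ids character vector (recycled if length 1).
#' @param kind "component" or "polypr".
#' @param resolved logical vector; residues with coordinates in the input.
#' @param name optional molecule name.
#' @return object of class \code{cg_model}.
#' @export
new_cg_model <- function(residue_names, positions, chain_ids = "A",
                         kind = c("component", "polypr"), resolved = NULL,
                         name = "") {
  kind <- match.arg(kind)
  n <- length(residue_names)
  positions <- matrix(as.numeric(positions), nrow = n, ncol = 3)
  if (length(chain_ids) == 1) chain_ids <- rep(chain_ids, n)
  if (is.null(resolved)) resolved <- !is.na(positions[, 1])
  m <- structure(list(
    name = name, kind = kind,
    residue_names = as.character(residue_names),
    positions = positions,
    charges = rep(NA_real_, n),
    hydro_strengths = rep(NA_real_, n),
    aromatic_flags = rep(NA, n),
    disorder_mask = rep(FALSE, n),
    resolved = as.logical(resolved),
    chain_ids = as.character(chain_ids),
    bonds = data.frame(i = integer(0), j = integer(0), b0 = numeric(0),
                       type = character(0))
  ), class = "cg_model")
  m
}

#' @export
print.cg_model <- function(x, ...) {
  cat(sprintf("cg_model '%s' (%s): %d beads, %d chain(s), %d bonds\n",
              x$name, x$kind, n_beads(x), length(unique(x$chain_ids)),
              nrow(x$bonds)))
  if (!anyNA(x$charges))
    cat(sprintf("  net charge %+g e, NCPR %+.4f e, %d disordered residues\n",
                sum(x$charges), sum(x$charges) / n_beads(x),
                sum(x$disorder_mask)))
  invisible(x)
}

#' @rdname new_cg_model
#' @param model a \code{cg_model}.
#' @export
n_beads <- function(model) length(model$residue_names)

#' Validate the internal invariants of a cg_model
#'
#' Checks equal field lengths, charge values in \{-1, 0, +1\}, hydrophobic
#' strengths in (0, 1), and that every bond joins two valid beads with
#' 0 < b0 < the elastic-network cutoff (network bonds).
#'
#' @param model a \code{cg_model}.
#' @param params force-field parameters (for the network cutoff).
#' @return invisibly TRUE; errors describe the violated invariant.
#' @export
validate_cg_model <- function(model, params = default_force_field()) {
  n <- n_beads(model)
  lens <- c(nrow(model$positions), length(model$charges),
            length(model$hydro_strengths), length(model$aromatic_flags),
            length(model$disorder_mask), length(model$chain_ids))
  if (any(lens != n)) stop("per-bead fields have inconsistent lengths")
  if (!anyNA(model$charges) && !all(model$charges %in% c(-1, 0, 1)))
    stop("charges must take values in {-1, 0, +1} e")
  if (!anyNA(model$hydro_strengths) &&
      (any(model$hydro_strengths <= 0) || any(model$hydro_strengths >= 1)))
    stop("hydrophobic strengths must lie in (0, 1)")
  if (nrow(model$bonds)) {
    b <- model$bonds
    if (any(b$i < 1 | b$i > n | b$j < 1 | b$j > n | b$i == b$j))
      stop("bond references an invalid bead index")
    if (any(b$b0 <= 0)) stop("bond rest length must be positive")
    if (any(b$b0[b$type == "network"] >= params$network_cutoff))
      stop("network bond rest length exceeds the network cutoff")
  }
  invisible(TRUE)
}

#' Assign per-bead physical properties from the sequence
#'
#' Populates charges (D/E -> -1, K/R -> +1, all others including histidine
#' 0; configurable via \code{his_charge}), relative hydrophobic strengths
#' from the supplied table, and aromatic flags (TRUE exactly for F, Y, W).
#'
#' @param model a \code{cg_model} with residue names.
#' @param hydropathy named numeric vector mapping one-letter codes to
#'   strengths in (0,1); defaults to the bundled stand-in table, see
#'   [read_hydropathy()].
#' @param his_charge charge assigned to histidine (default 0, neutral at
#'   pH 7.4).
#' @return the model with properties filled in.
#' @export
#' @examples
#' m <- build_polypr(1)
#' m$charges  # 0, +1
assign_bead_properties <- function(model, hydropathy = read_hydropathy(),
                                   his_charge = 0) {
  res <- model$residue_names
  bad <- setdiff(unique(res), names(hydropathy))
  if (length(bad))
    stop("residue code(s) missing from the hydropathy table: ",
         paste(bad, collapse = ", "))
  ch <- ifelse(res %in% c("D", "E"), -1,
        ifelse(res %in% c("K", "R"), 1,
        ifelse(res == "H", his_charge, 0)))
  model$charges <- as.numeric(ch)
  model$hydro_strengths <- unname(hydropathy[res])
  model$aromatic_flags <- res %in% c("F", "Y", "W")
  validate_cg_model(model)
  model
}

#' Mark disordered regions
#'
#' A residue is disordered when it is unresolved in the input structure or
#' when its per-residue confidence score (e.g. pLDDT) is below the threshold
#' (default 70). Unresolved always wins: an unresolved residue is disordered
#' regardless of its score.
#'
#' @param model a \code{cg_model}.
#' @param unresolved_set integer indices of unresolved residues; defaults to
#'   the residues without coordinates in the parsed structure.
#' @param confidence_scores optional numeric vector, one score per residue.
#' @param threshold confidence threshold below which a residue is disordered.
#' @return the model with \code{disorder_mask} set.
#' @export
mark_disordered <- function(model, unresolved_set = which(!model$resolved),
                            confidence_scores = NULL, threshold = 70) {
  n <- n_beads(model)
  if (length(unresolved_set) && (min(unresolved_set) < 1 || max(unresolved_set) > n))
    stop("unresolved indices out of bounds")
  mask <- rep(FALSE, n)
  mask[unresolved_set] <- TRUE
  if (!is.null(confidence_scores)) {
    if (length(confidence_scores) != n)
      stop("confidence scores must cover all residues")
    mask <- mask | (confidence_scores < threshold)
  }
  model$disorder_mask <- mask
  model
}

#' Build the elastic network of a folded component
#'
#' Adds a stiff harmonic bond between every pair of structured beads
#' (disorder_mask FALSE on both) whose distance in the reference structure is
#' strictly less than the network cutoff (1.4 nm), with rest length equal to
#' that distance. Bonds may join different chains of the same molecule (e.g.
#' the two monomers of a homodimer modeled as one unit). Disordered beads
#' never receive network bonds; consecutive residues involving a disordered
#' bead get a backbone bond at 0.38 nm instead.
#'
#' @param model a \code{cg_model} with positions for all structured beads.
#' @param params force-field parameters.
#' @return the model with the \code{bonds} table populated.
#' @export
build_elastic_network <- function(model, params = default_force_field()) {
  n <- n_beads(model)
  structured <- which(!model$disorder_mask & model$resolved)
  if (length(structured) && anyNA(model$positions[structured, ]))
    stop("structured beads must have positions before network construction")
  bonds <- NULL
  if (length(structured) >= 2) {
    p <- model$positions[structured, , drop = FALSE]
    d <- as.matrix(stats::dist(p))
    hit <- which(upper.tri(d) & d < params$network_cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      bonds <- data.frame(i = structured[hit[, 1]], j = structured[hit[, 2]],
                          b0 = d[hit], type = "network")
    }
  }
  # backbone bonds where a disordered bead is involved (chain connectivity)
  bb <- NULL
  if (n >= 2) {
    i <- seq_len(n - 1)
    sel <- model$chain_ids[i] == model$chain_ids[i + 1] &
      (model$disorder_mask[i] | model$disorder_mask[i + 1])
    if (any(sel))
      bb <- data.frame(i = i[sel], j = i[sel] + 1L,
                       b0 = params$b_backbone, type = "backbone")
  }
  model$bonds <- rbind(bonds, bb)
  if (is.null(model$bonds))
    model$bonds <- data.frame(i = integer(0), j = integer(0),
                              b0 = numeric(0), type = character(0))
  rownames(model$bonds) <- NULL
  model
}

#' Build a polyPR dipeptide-repeat chain
#'
#' A fully disordered chain of \code{2 n_repeats} beads alternating P and R
#' (total charge +n_repeats e), connected by harmonic backbone bonds at
#' 0.38 nm. The initial conformation is a compact serpentine zigzag (it only
#' seeds the dynamics and carries no physical meaning).
#'
#' @param n_repeats number of PR repeats (>= 1).
#' @param params force-field parameters.
#' @param hydropathy hydrophobic-strength table.
#' @return a \code{cg_model} of kind "polypr" named \code{PR<n>}.
#' @export
#' @examples
#' pr7 <- build_polypr(7)
#' sum(pr7$charges)  # +7
build_polypr <- function(n_repeats, params = default_force_field(),
                         hydropathy = read_hydropathy()) {
  if (length(n_repeats) != 1 || is.na(n_repeats) || n_repeats < 1)
    stop("n_repeats must be a positive integer")
  n_repeats <- as.integer(n_repeats)
  n <- 2L * n_repeats
  res <- rep(c("P", "R"), n_repeats)
  # near-extended zigzag start: non-bonded pairs stay outside the excluded
  # volume radius, so the initial conformation relaxes without large forces
  a <- params$b_backbone
  idx <- seq_len(n) - 1L
  zig <- 0.1 * a
  step_x <- sqrt(a^2 - zig^2)
  pos <- cbind(idx * step_x, zig * (idx %% 2L), 0)
  m <- new_cg_model(res, pos, chain_ids = "P", kind = "polypr",
                    resolved = rep(TRUE, n), name = paste0("PR", n_repeats))
  m$disorder_mask <- rep(TRUE, n)
  m <- assign_bead_properties(m, hydropathy)
  m$bonds <- data.frame(i = seq_len(n - 1), j = seq_len(n - 1) + 1L,
                        b0 = a, type = "backbone")
  validate_cg_model(m)
  m
}

#' Place unresolved residues by chain growth
#'
#' Residues without coordinates are grown from the nearest resolved anchor of
#' the same chain at 0.38 nm per step in a seeded random direction (biased
#' away from the fold's centre of geometry), then optionally relaxed by a
#' short steepest-descent minimization in which only the placed beads move.
#'
#' @param model a \code{cg_model} (properties assigned, disorder marked).
#' @param seed integer seed for the growth directions.
#' @param relax run the short minimization (default TRUE).
#' @param params force-field parameters.
#' @return the model with all positions defined.
#' @export
place_unresolved <- function(model, seed = 1, relax = TRUE,
                             params = default_force_field()) {
  unres <- which(!model$resolved)
  if (!length(unres)) return(model)
  set.seed(seed)
  pos <- model$positions
  centre <- colMeans(pos[model$resolved, , drop = FALSE])
  a <- params$b_backbone
  for (ch in unique(model$chain_ids)) {
    in_ch <- which(model$chain_ids == ch)
    todo <- intersect(unres, in_ch)
    while (length(todo)) {
      # grow each stretch outward from its resolved/placed neighbours
      progress <- FALSE
      for (k in todo) {
        nb <- intersect(c(k - 1L, k + 1L), in_ch)
        nb <- nb[!is.na(pos[nb, 1])]
        if (!length(nb)) next
        anchor <- pos[nb[1], ]
        dir <- anchor - centre + rnorm(3, sd = 0.5)
        nd <- sqrt(sum(dir^2))
        if (nd < 1e-8) dir <- c(1, 0, 0) else dir <- dir / nd
        pos[k, ] <- anchor + dir * a
        todo <- setdiff(todo, k)
        progress <- TRUE
      }
      if (!progress) {
        # isolated stretch with no anchored neighbour: start from centre
        k <- todo[1]
        pos[k, ] <- centre + rnorm(3, sd = 0.5)
        todo <- setdiff(todo, k)
      }
    }
  }
  model$positions <- pos
  if (relax && !anyNA(model$charges)) {
    sys <- assemble_system(list(model), box = 50 + max(abs(pos)) * 2,
                           params = params)
    movable <- rep(FALSE, n_beads(model))
    movable[unres] <- TRUE
    newpos <- .minimize_cpp(sys$positions, sys$box, sys$cls, sys$epsm,
                            sys$charges, sys$bonds_mat, sys$b0,
                            params$K_network, .ff_list(params), movable,
                            n_iter = 300L, max_step = 0.02)
    model$positions <- newpos
  }
  model
}
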