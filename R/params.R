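#' Force-field parameter set
#'
#' Returns the complete parameter set of the one-bead-per-amino-acid (1BPA)
#' force field used throughout the package: the piecewise 8-6
#' hydrophobic/hydrophilic potential, screened Coulomb electrostatics with a
#' distance-dependent dielectric, the 8-6 cation-pi potentials between
#' arginine/lysine and aromatic residues, excluded volume, and the stiff
#' harmonic elastic-network/backbone bonds.
#'
#' The default values are the reference constants of the model:
#' \itemize{
#'   \item \code{eps_hp} = 13 and \code{eps_rep} = 10 kJ/mol, \code{sigma} =
#'     0.6 nm, mixing exponent 0.27 for the hydrophobic potential;
#'   \item dielectric \code{Ss} = 80, \code{z} = 0.25 nm; Debye screening
#'     \code{kappa} = 1 nm^-1 at 100 mM and 1.5 nm^-1 at 200 mM monovalent salt;
#'   \item elastic network stiffness \code{K_network} = 8000 kJ/mol/nm^2,
#'     bonds between structured beads closer than 1.4 nm in the reference
#'     structure; disordered backbone bonds at 0.38 nm;
#'   \item cation-pi well depths (kJ/mol): RF 4.30, RY 5, RW 6.7, KF 1.79,
#'     KY 3.13, KW 4.26, with minimum at \code{rm_cp} = 0.45 nm;
#'   \item cross excluded volume \code{eps_excl} = 10 kJ/mol (which makes the
#'     8-6 potential vanish for r >= sigma).
#' }
#'
#' The nonbonded truncation (\code{cutoff}, default 2.5 nm, energy shifted to
#' zero at the cutoff) is a numerical choice of this implementation, not a
#' model constant.
#'
#' @param salt monovalent salt concentration in mM; 100 and 200 have reference
#'   screening lengths. Other values require an explicit \code{kappa}.
#' @param kappa inverse Debye screening length in nm^-1; overrides \code{salt}.
#' @param cutoff nonbonded truncation radius in nm.
#' @return a list of class \code{ff_params}.
#' @export
#' @examples
#' p <- default_force_field(salt = 100)
#' p$kappa
default_force_field <- function(salt = 100, kappa = NULL, cutoff = 2.5) {
  if (is.null(kappa)) {
    kappa <- switch(as.character(salt), "100" = 1.0, "200" = 1.5,
                    stop("no reference kappa for salt = ", salt,
                         " mM; pass kappa explicitly"))
  }
  eps_cp <- matrix(c(4.30, 5.00, 6.70,
                     1.79, 3.13, 4.26),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("R", "K"), c("F", "Y", "W")))
  structure(list(
    version = "reference-1",
    eps_hp = 13, eps_rep = 10, sigma = 0.6, mix_exp = 0.27,
    Ss = 80, z = 0.25, kappa = kappa, salt = salt,
    K_network = 8000, network_cutoff = 1.4, b_backbone = 0.38,
    rm_cp = 0.45, eps_cp = eps_cp, eps_excl = 10,
    coulomb = .COULOMB,
    cutoff = cutoff, skin = 0.3
  ), class = "ff_params")
}

#' Write / read a force-field configuration file
#'
#' A flat, versioned key-value (JSON) file holding every constant in
#' [default_force_field()]. Reading the written file reproduces the parameter
#' set bit-exactly.
#'
#' @param params an \code{ff_params} list.
#' @param path file path.
#' @return \code{read_ff_config} returns an \code{ff_params} list.
#' @export
write_ff_config <- function(params, path) {
  stopifnot(inherits(params, "ff_params"))
  out <- unclass(params)
  out$eps_cp <- list(dim = dim(params$eps_cp),
                     rownames = rownames(params$eps_cp),
                     colnames = colnames(params$eps_cp),
                     values = as.vector(params$eps_cp))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ff_config
#' @export
read_ff_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cp <- matrix(as.numeric(raw$eps_cp$values), nrow = raw$eps_cp$dim[1],
               dimnames = list(raw$eps_cp$rownames, raw$eps_cp$colnames))
  # JSON has no integer/double distinction; everything numeric is a double
  raw <- lapply(raw, function(x) if (is.numeric(x)) as.numeric(x) else x)
  raw$eps_cp <- cp
  structure(raw, class = "ff_params")
}
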