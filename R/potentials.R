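#' Distance-dependent dielectric permittivity
#'
#' The solvent dielectric used by the screened Coulomb potential:
#' \deqn{\epsilon_r(r) = S_s [1 - (r^2/z^2) e^{r/z} / (e^{r/z} - 1)^2]}
#' evaluated with a series expansion near r = 0 (where the closed form is
#' 0/0). It increases monotonically from 0 at contact to \code{Ss} (=80) at
#' large separation.
#'
#' @param r distance(s) in nm (may be a vector; r >= 0).
#' @param params force-field parameters, see [default_force_field()].
#' @return dielectric constant(s), dimensionless.
#' @export
dielectric_r <- function(r, params = default_force_field()) {
  if (any(r < 0)) stop("r must be non-negative")
  .eps_r_cpp(as.numeric(r), params$Ss, params$z)
}

#' Hydrophobic/hydrophilic 8-6 pair potential
#'
#' The two-branch potential acting between disordered-chain residues:
#' \deqn{\phi_{hp}(r) = \epsilon_{rep}(\sigma/r)^8 -
#'   \epsilon_{ij}[(4/3)(\sigma/r)^6 - 1/3]} for \eqn{r \le \sigma} and
#' \deqn{(\epsilon_{rep} - \epsilon_{ij})(\sigma/r)^8} for \eqn{r \ge \sigma},
#' with \eqn{\epsilon_{ij} = \epsilon_{hp}(\epsilon_i\epsilon_j)^{0.27}}.
#' The two branches agree in value and derivative at \eqn{r = \sigma}.
#' Setting \code{eps_ij = params$eps_excl} (10 kJ/mol, equal to
#' \code{eps_rep}) yields the purely repulsive excluded-volume potential that
#' vanishes for all \eqn{r \ge \sigma}.
#'
#' @param r distance(s) in nm, r > 0.
#' @param eps_i,eps_j relative hydrophobic strengths of the two residues,
#'   each in (0, 1).
#' @param params force-field parameters.
#' @param eps_ij optional direct pair strength in kJ/mol, overriding the
#'   mixing rule (used for excluded volume).
#' @return energy in kJ/mol.
#' @export
#' @examples
#' phi_hp(0.6, eps_ij = 10)  # excluded volume vanishes at sigma
phi_hp <- function(r, eps_i = 1, eps_j = 1, params = default_force_field(),
                   eps_ij = NULL) {
  if (any(r <= 0)) stop("r must be positive")
  if (is.null(eps_ij)) eps_ij <- params$eps_hp * (eps_i * eps_j)^params$mix_exp
  s6 <- (params$sigma / r)^6
  s8 <- s6 * (params$sigma / r)^2
  ifelse(r <= params$sigma,
         params$eps_rep * s8 - eps_ij * ((4 / 3) * s6 - 1 / 3),
         (params$eps_rep - eps_ij) * s8)
}

#' Screened Coulomb electrostatic pair potential
#'
#' Modified Coulomb law with Debye screening and the distance-dependent
#' dielectric [dielectric_r()]:
#' \deqn{\phi_{elec}(r) = \frac{q_i q_j}{4\pi\epsilon_0 \epsilon_r(r) r}
#'   e^{-\kappa r}.}
#'
#' @param r distance(s) in nm, r > 0.
#' @param qi,qj bead charges in elementary charge units.
#' @param kappa inverse screening length in nm^-1 (defaults to the value in
#'   \code{params}).
#' @param params force-field parameters.
#' @return energy in kJ/mol; exactly zero when either charge is zero.
#' @export
phi_elec <- function(r, qi, qj, kappa = params$kappa,
                     params = default_force_field()) {
  if (any(r <= 0)) stop("r must be positive")
  if (qi == 0 || qj == 0) return(rep(0, length(r)))
  params$coulomb * qi * qj * exp(-kappa * r) / (dielectric_r(r, params) * r)
}

#' Cation-pi 8-6 pair potential
#'
#' Acts between a polyPR cation bead (R, or K for GR/GK variants) and an
#' aromatic transport-component bead (F, Y, W), replacing the hydrophobic
#' potential for those pairs:
#' \deqn{\phi_{cp}(r) = \epsilon_{cp}[3 (r_m/r)^8 - 4 (r_m/r)^6],}
#' with minimum value \eqn{-\epsilon_{cp}} at exactly \eqn{r = r_m} (0.45 nm).
#'
#' @param r distance(s) in nm, r > 0.
#' @param pair one of "RF", "RY", "RW", "KF", "KY", "KW".
#' @param params force-field parameters.
#' @return energy in kJ/mol.
#' @export
#' @examples
#' phi_cp(0.45, "RF")  # -4.30 kJ/mol
phi_cp <- function(r, pair, params = default_force_field()) {
  if (any(r <= 0)) stop("r must be positive")
  pair <- as.character(pair)
  cat_res <- substr(pair, 1, 1)
  aro_res <- substr(pair, 2, 2)
  if (!cat_res %in% rownames(params$eps_cp) ||
      !aro_res %in% colnames(params$eps_cp))
    stop("unknown cation-pi pair key: ", pair)
  eps <- params$eps_cp[cat_res, aro_res]
  s6 <- (params$rm_cp / r)^6
  s8 <- s6 * (params$rm_cp / r)^2
  eps * (3 * s8 - 4 * s6)
}

#' Stiff harmonic network/backbone bond potential
#'
#' \deqn{\phi_{network}(r) = K (r - b)^2} with K = 8000 kJ/mol/nm^2; used both
#' for the elastic network preserving folded cores and for the backbone bonds
#' of disordered chains.
#'
#' @param r distance(s) in nm, r >= 0.
#' @param b rest length in nm, b > 0.
#' @param params force-field parameters.
#' @return energy in kJ/mol.
#' @export
phi_network <- function(r, b, params = default_force_field()) {
  if (any(r < 0)) stop("r must be non-negative")
  if (any(b <= 0)) stop("rest length b must be positive")
  params$K_network * (r - b)^2
}
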