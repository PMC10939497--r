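#' Simulation configuration
#'
#' Collects the Langevin dynamics protocol: 300 K, 0.02 ps timestep and
#' 0.02 ps^-1 friction by default (friction 0 switches the integrator to
#' plain velocity Verlet for NVE checks), with the monovalent salt
#' concentration selecting the Debye screening length (100 mM -> 1 nm^-1,
#' 200 mM -> 1.5 nm^-1). Desk-scale step counts (1e5-1e6) stand in for the
#' microsecond-scale production runs of full studies; analysis drops the
#' first \code{equil_fraction} of each run (default 0.2, mirroring the
#' convention of discarding the initial fifth of a production run).
#'
#' @param temperature K.
#' @param timestep ps.
#' @param friction Langevin friction coefficient, ps^-1 (>= 0).
#' @param salt monovalent salt in mM (100 or 200).
#' @param box cubic box edge in nm (NULL = auto-sized by [place_complex()]).
#' @param n_steps integration steps.
#' @param save_interval steps between saved frames.
#' @param seed RNG seed (trajectories are bitwise reproducible per seed).
#' @param equil_fraction initial fraction excluded from analysis.
#' @param mass uniform bead mass, g/mol (average amino-acid weight).
#' @param cutoff nonbonded truncation, nm.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(temperature = 300, timestep = 0.02, friction = 0.02,
                       salt = 100, box = NULL, n_steps = 1e5,
                       save_interval = 100, seed = 1, equil_fraction = 0.2,
                       mass = 110, cutoff = 2.5) {
  stopifnot(timestep > 0, friction >= 0, n_steps >= 1, save_interval >= 1,
            mass > 0, equil_fraction >= 0, equil_fraction < 1)
  if (!is.null(box)) stopifnot(box > 0)
  structure(list(temperature = temperature, timestep = timestep,
                 friction = friction, salt = salt, box = box,
                 n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 seed = as.integer(seed), equil_fraction = equil_fraction,
                 mass = mass, cutoff = cutoff), class = "sim_config")
}

#' Run Langevin dynamics
#'
#' Propagates an assembled system in the NVT ensemble (cubic periodic box)
#' with the BAOAB splitting of Langevin dynamics: velocity-Verlet drift/kick
#' steps around an exact Ornstein-Uhlenbeck friction/noise step. With
#' friction = 0 the scheme reduces to velocity Verlet (NVE). Velocities are
#' initialized from the Maxwell-Boltzmann distribution at the target
#' temperature. Trajectories are bitwise reproducible for a given (seed,
#' config) on one platform; the integrator aborts with the step index if
#' forces or the energy blow up.
#'
#' @param system a \code{cg_system} from [assemble_system()].
#' @param config a \code{sim_config}; its salt/cutoff must match the
#'   parameters used to assemble the system.
#' @return object of class \code{cg_trajectory}: \code{frames}
#'   (N x 3 x n_frames, nm, unwrapped), \code{times} (ps), \code{box},
#'   \code{pe}, \code{ke} (kJ/mol), \code{config}.
#' @export
run_langevin <- function(system, config) {
  stopifnot(inherits(system, "cg_system"), inherits(config, "sim_config"))
  n <- nrow(system$positions)
  set.seed(config$seed)
  v0 <- matrix(rnorm(3 * n, sd = sqrt(.kB * config$temperature / config$mass)),
               n, 3)
  if (config$friction == 0) v0[] <- v0  # NVE still uses MB initial velocities
  res <- .run_langevin_cpp(system$positions, v0, system$box, system$cls,
                           system$epsm, system$charges, system$bonds_mat,
                           system$b0, system$params$K_network,
                           .ff_list(system$params), config$n_steps,
                           config$timestep, config$friction,
                           config$temperature, config$mass,
                           config$save_interval, FALSE)
  structure(list(frames = res$frames, times = res$times, box = system$box,
                 pe = res$pe, ke = res$ke, final_vel = res$final_vel,
                 config = config), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("cg_trajectory: %d beads, %d frames, %.1f ps, box %.2f nm\n",
              d[1], d[3], max(x$times), x$box))
  invisible(x)
}

# free-particle / ideal propagation used by diffusion and free-flight tests;
# identical integrator with all nonbonded and bonded terms switched off
.run_ideal <- function(positions, config, velocities = NULL) {
  n <- nrow(positions)
  set.seed(config$seed)
  if (is.null(velocities))
    velocities <- matrix(
      rnorm(3 * n, sd = sqrt(.kB * config$temperature / config$mass)), n, 3)
  cls <- matrix(0L, n, n)
  epsm <- matrix(0, n, n)
  params <- default_force_field(salt = config$salt, cutoff = config$cutoff)
  res <- .run_langevin_cpp(positions, velocities, config$box, cls, epsm,
                           rep(0, n), matrix(integer(0), 0, 2), numeric(0),
                           0, .ff_list(params), config$n_steps,
                           config$timestep, config$friction,
                           config$temperature, config$mass,
                           config$save_interval, TRUE)
  structure(list(frames = res$frames, times = res$times, box = config$box,
                 pe = res$pe, ke = res$ke, final_vel = res$final_vel,
                 config = config), class = "cg_trajectory")
}

#' Production-window frame indices of a trajectory
#'
#' Frames after the equilibration fraction recorded in the trajectory's
#' config (default: the last 80\% of the run).
#'
#' @param traj a \code{cg_trajectory}.
#' @param equil_fraction override for the equilibration fraction.
#' @return integer frame indices.
#' @export
production_frames <- function(traj, equil_fraction = NULL) {
  f <- dim(traj$frames)[3]
  ef <- if (!is.null(equil_fraction)) equil_fraction
        else if (!is.null(traj$config$equil_fraction))
          traj$config$equil_fraction else 0.2
  idx <- which(traj$times > ef * max(traj$times))
  if (!length(idx)) idx <- f
  idx
}

#' Kinetic temperature per frame
#'
#' @param traj a \code{cg_trajectory}.
#' @param n_beads number of beads (taken from the frames).
#' @return numeric vector, K.
#' @export
kinetic_temperature <- function(traj, n_beads = dim(traj$frames)[1]) {
  2 * traj$ke / (3 * n_beads * .kB)
}

#' Place a polyPR / transport-component complex in a box
#'
#' Centres the component, places the polyPR chain at a centre-to-centre
#' distance (default: component Rg + polyPR contour length / 2 + 1 nm) in a
#' seeded random direction with a seeded random rigid rotation, and
#' auto-sizes the cubic box to at least twice the largest molecular extent
#' plus the nonbonded cutoff (and large enough to hold the separation).
#' Placement retries (up to \code{max_tries}) until no inter-molecular bead
#' pair is closer than \code{min_sep}.
#'
#' @param polypr a polyPR \code{cg_model}.
#' @param component a component \code{cg_model} (all positions defined).
#' @param config a \code{sim_config} (for the cutoff and optional fixed box).
#' @param seed placement seed.
#' @param distance optional centre-to-centre distance in nm.
#' @param min_sep minimum allowed inter-molecular bead distance, nm.
#' @param max_tries placement attempts before erroring.
#' @return list: \code{positions} (stacked polyPR-after-component matrix for
#'   [assemble_system()] with \code{models = list(component, polypr)}),
#'   \code{box}, \code{distance}.
#' @export
place_complex <- function(polypr, component, config = sim_config(),
                          seed = config$seed, distance = NULL,
                          min_sep = 0.3, max_tries = 100) {
  stopifnot(polypr$kind == "polypr", component$kind == "component")
  set.seed(seed)
  pc <- sweep(component$positions, 2, colMeans(component$positions))
  pp0 <- sweep(polypr$positions, 2, colMeans(polypr$positions))
  rgc <- sqrt(mean(rowSums(pc^2)))
  contour <- 0.38 * (n_beads(polypr) - 1)
  if (is.null(distance)) distance <- rgc + contour / 2 + 1
  extent <- function(p) max(stats::dist(p))
  maxext <- max(extent(pc), extent(pp0))
  box <- if (!is.null(config$box)) config$box
         else max(2 * maxext + config$cutoff, 2 * (distance + config$cutoff))
  for (t in seq_len(max_tries)) {
    # uniform random rotation via QR of a Gaussian matrix
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    pp <- pp0 %*% R + matrix(u * distance, n_beads(polypr), 3, byrow = TRUE)
    dmin <- min(.cross_min_dist(pc, pp))
    if (dmin >= min_sep) {
      centre <- box / 2
      return(list(positions = rbind(pc, pp) + centre, box = box,
                  distance = distance))
    }
  }
  stop("could not place the complex without overlap after ", max_tries,
       " tries")
}

.cross_min_dist <- function(a, b) {
  # minimum distance between two point sets (no PBC; placement is central)
  min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)))
}
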