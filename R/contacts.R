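#' Time-averaged inter-molecular contact count
#'
#' Counts, in every analysed frame, the polyPR/component residue pairs whose
#' bead-centre distance under minimum image is within the cutoff (1 nm,
#' closed interval), and averages over frames:
#' \eqn{C_t = \langle |\{(i,j): d_{ij} \le 1\,nm\}| \rangle}. The count is
#' normalized by the component length \eqn{N_{TC}} and polyPR length
#' \eqn{N_{PR}}; the standard error of the mean comes from block averaging
#' with three equal contiguous blocks over the production window (trailing
#' partial frames dropped).
#'
#' @param traj a \code{cg_trajectory}.
#' @param polypr_indices bead indices of the polyPR chain in the system.
#' @param component_indices bead indices of the transport component.
#' @param cutoff contact distance in nm (default 1, \code{d <= cutoff}).
#' @param production restrict to production frames (default TRUE).
#' @param n_blocks number of SEM blocks (default 3).
#' @return object of class \code{contact_result}: \code{ct},
#'   \code{ct_normalized}, \code{sem}, \code{per_frame}, \code{n_frames},
#'   \code{ntc}, \code{npr}.
#' @export
count_contacts <- function(traj, polypr_indices, component_indices,
                           cutoff = 1.0, production = TRUE, n_blocks = 3) {
  idx <- if (production) production_frames(traj)
         else seq_len(dim(traj$frames)[3])
  if (!length(idx)) stop("no frames to analyse")
  res <- .contacts_cpp(traj$frames[, , idx, drop = FALSE], traj$box,
                       as.integer(polypr_indices),
                       as.integer(component_indices), cutoff)
  per_frame <- res$per_frame
  nf <- length(per_frame)
  ct <- mean(per_frame)
  ntc <- length(component_indices)
  npr <- length(polypr_indices)
  if (nf < n_blocks)
    stop("need at least ", n_blocks, " frames for block-averaged SEM")
  bl <- nf %/% n_blocks
  bm <- vapply(seq_len(n_blocks),
               function(b) mean(per_frame[((b - 1) * bl + 1):(b * bl)]),
               numeric(1))
  sem <- sd(bm) / sqrt(n_blocks)
  structure(list(ct = ct, ct_normalized = ct / (ntc * npr),
                 sem = sem, sem_normalized = sem / (ntc * npr),
                 per_frame = per_frame, n_frames = nf,
                 ntc = ntc, npr = npr, cutoff = cutoff),
            class = "contact_result")
}

#' @export
print.contact_result <- function(x, ...) {
  cat(sprintf(
    "contacts: Ct = %.3f +/- %.3f (normalized %.3e) over %d frames\n",
    x$ct, x$sem, x$ct_normalized, x$n_frames))
  invisible(x)
}

#' Per-residue contact probability
#'
#' For each transport-component residue, the fraction of analysed frames in
#' which at least one polyPR bead lies within the cutoff (1 nm) of it.
#'
#' @inheritParams count_contacts
#' @return numeric vector over \code{component_indices}, each in [0, 1].
#' @export
contact_probability <- function(traj, component_indices, polypr_indices,
                                cutoff = 1.0, production = TRUE) {
  idx <- if (production) production_frames(traj)
         else seq_len(dim(traj$frames)[3])
  if (!length(idx)) stop("no frames to analyse")
  res <- .contacts_cpp(traj$frames[, , idx, drop = FALSE], traj$box,
                       as.integer(polypr_indices),
                       as.integer(component_indices), cutoff)
  res$b_frames / length(idx)
}

#' Call contact sites from per-residue probabilities
#'
#' A residue is a contact site when its contact probability is strictly
#' greater than the threshold (0.10).
#'
#' @param probabilities numeric vector in [0, 1].
#' @param threshold strict threshold (default 0.10).
#' @return sorted integer residue indices.
#' @export
#' @examples
#' call_contact_sites(c(0.05, 0.11, 0.95))  # 2, 3
call_contact_sites <- function(probabilities, threshold = 0.10) {
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  sort(which(probabilities > threshold))
}

#' Shared contact / binding-site count
#'
#' The number of component residues that are polyPR contact sites and at the
#' same time annotated binding-site residues for a native partner.
#'
#' @param contact_sites integer residue indices (construct numbering).
#' @param annotation data.frame with columns partner, residue_index, or an
#'   integer vector of residue indices.
#' @param partner optional partner name to filter the annotation.
#' @param n_residues optional sequence length for bounds checking.
#' @return integer count.
#' @export
n_shared <- function(contact_sites, annotation, partner = NULL,
                     n_residues = NULL) {
  idx <- if (is.data.frame(annotation)) {
    a <- annotation
    if (!is.null(partner)) a <- a[a$partner == partner, , drop = FALSE]
    a$residue_index
  } else as.integer(annotation)
  if (!is.null(n_residues) && length(idx) &&
      (min(idx) < 1 || max(idx) > n_residues))
    stop("annotation indices out of bounds")
  length(intersect(as.integer(contact_sites), unique(idx)))
}

#' Summarize contacts against all annotated partners
#'
#' Convenience wrapper producing the per-partner shared-site table.
#'
#' @param probabilities per-residue contact probabilities.
#' @param annotation data.frame with partner, residue_index.
#' @param threshold contact-site threshold.
#' @return data.frame: partner, n_binding_sites, n_shared.
#' @export
shared_site_table <- function(probabilities, annotation, threshold = 0.10) {
  sites <- call_contact_sites(probabilities, threshold)
  partners <- unique(annotation$partner)
  data.frame(
    partner = partners,
    n_binding_sites = vapply(partners, function(p)
      length(unique(annotation$residue_index[annotation$partner == p])),
      integer(1)),
    n_shared = vapply(partners, function(p)
      n_shared(sites, annotation, partner = p,
               n_residues = length(probabilities)), integer(1)),
    row.names = NULL)
}
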