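#' Generate a toy folded transport component
#'
#' Builds a compact, fully structured "transport component" for pipeline
#' tests: beads on a jittered cubic-lattice serpentine (0.38 nm backbone
#' spacing, so consecutive beads and lattice neighbours fall inside the
#' elastic-network cutoff), with a sequence composed to hit the target net
#' charge exactly. The spatial charge distribution controls the dipole
#' moment: with \code{segregate = TRUE} negative residues are biased to one
#' side of the fold and positives to the other (high M, emulating a
#' RanGAP-like strongly charged, high-dipole extreme); with
#' \code{segregate = FALSE} charges are scattered uniformly (low M, a
#' Ran-like neutral case when \code{net_charge = 0}). Deterministic per
#' seed.
#'
#' @param n_residues number of beads (>= 10).
#' @param net_charge target total charge in e (attained exactly).
#' @param frac_aromatic fraction of aromatic (F) residues in [0, 1].
#' @param frac_charged_extra fraction of additional balanced +/- pairs
#'   beyond the net charge (charge texture).
#' @param segregate spatially segregate charges to build a large dipole.
#' @param seed RNG seed.
#' @param params force-field parameters.
#' @param name molecule name.
#' @return list with elements \code{model} (a \code{cg_model} with elastic
#'   network built) and \code{descriptors} (single-conformation
#'   [compute_descriptors()]).
#' @export
#' @examples
#' toy <- gen_toy_component(60, net_charge = -10, seed = 1)
#' sum(toy$model$charges)  # -10
gen_toy_component <- function(n_residues, net_charge = 0,
                              frac_aromatic = 0.1, frac_charged_extra = 0.05,
                              segregate = TRUE, seed = 1,
                              params = default_force_field(),
                              name = "toy") {
  if (n_residues < 10) stop("n_residues must be at least 10")
  if (abs(net_charge) > n_residues) stop("infeasible net charge for length")
  set.seed(seed)
  n <- as.integer(n_residues)
  extra <- round(frac_charged_extra * n)
  n_neg <- extra + max(0, -net_charge)
  n_pos <- extra + max(0, net_charge)
  n_aro <- round(frac_aromatic * n)
  if (n_neg + n_pos + n_aro > n)
    stop("infeasible composition: charged plus aromatic residues exceed length")

  # serpentine walk through a cubic lattice, spacing = backbone length
  a <- params$b_backbone
  L <- ceiling(n^(1 / 3))
  idx <- seq_len(n) - 1L
  layer <- idx %/% (L * L)
  rem <- idx %% (L * L)
  row <- rem %/% L
  col <- rem %% L
  col <- ifelse(row %% 2L == 0L, col, L - 1L - col)
  row <- ifelse(layer %% 2L == 0L, row, L - 1L - row)
  pos <- cbind(col, row, layer) * a + matrix(rnorm(3 * n, sd = 0.02), n, 3)

  res <- rep("S", n)
  if (segregate) {
    ord <- order(pos[, 1])          # x-sorted: negatives low-x, positives high-x
    neg_sites <- ord[seq_len(n_neg)]
    pos_sites <- ord[n - seq_len(n_pos) + 1L]
  } else {
    sites <- sample.int(n, n_neg + n_pos)
    neg_sites <- sites[seq_len(n_neg)]
    pos_sites <- setdiff(sites, neg_sites)
  }
  res[neg_sites] <- "E"
  res[pos_sites] <- "K"
  free <- which(res == "S")
  res[sample(free, n_aro)] <- "F"

  m <- new_cg_model(res, pos, chain_ids = "A", kind = "component",
                    resolved = rep(TRUE, n), name = name)
  m <- assign_bead_properties(m)
  m <- mark_disordered(m, unresolved_set = integer(0))
  m <- build_elastic_network(m, params)
  validate_cg_model(m, params)
  list(model = m, descriptors = compute_descriptors(m))
}

#' Generate a synthetic binding-site annotation
#'
#' Produces clustered or random per-residue binding-site lists emulating the
#' annotation stripes of native-partner interfaces.
#'
#' @param model a \code{cg_model}.
#' @param rule "cterm_quartile" (last quarter of the sequence),
#'   "nterm_quartile", or "random".
#' @param size number of residues for the "random" rule.
#' @param seed RNG seed (random rule).
#' @param partner partner label.
#' @return data.frame with columns partner, residue_index.
#' @export
#' @examples
#' m <- build_polypr(50)
#' head(gen_annotation(m, "cterm_quartile"))
gen_annotation <- function(model, rule = c("cterm_quartile",
                                           "nterm_quartile", "random"),
                           size = NULL, seed = 1, partner = "partner") {
  rule <- match.arg(rule)
  n <- n_beads(model)
  idx <- switch(rule,
    cterm_quartile = (floor(0.75 * n) + 1L):n,
    nterm_quartile = seq_len(ceiling(0.25 * n)),
    random = {
      if (is.null(size)) size <- max(1L, round(0.1 * n))
      set.seed(seed)
      sort(sample.int(n, size))
    })
  data.frame(partner = partner, residue_index = as.integer(idx))
}

#' Two annotations with a forced overlap
#'
#' Builds two partner annotations whose residue lists intersect in exactly
#' \code{k} residues (for exercising shared-site counting).
#'
#' @param model a \code{cg_model}.
#' @param k overlap size.
#' @param size1,size2 residue-list sizes (>= k).
#' @param seed RNG seed.
#' @return data.frame with both partners.
#' @export
gen_annotation_pair <- function(model, k, size1 = 10, size2 = 10, seed = 1) {
  n <- n_beads(model)
  if (size1 < k || size2 < k) stop("overlap larger than a list")
  if (size1 + size2 - k > n) stop("lists do not fit the sequence")
  set.seed(seed)
  all <- sample.int(n, size1 + size2 - k)
  a <- all[seq_len(size1)]
  b <- c(all[seq_len(k)], all[(size1 + 1):(size1 + size2 - k)])
  rbind(data.frame(partner = "partnerA", residue_index = sort(a)),
        data.frame(partner = "partnerB", residue_index = sort(b)))
}

#' Generate a synthetic charge-parameter correlation dataset
#'
#' Draws component descriptors from ranges spanning the realistic spread of
#' folded transport components (NCPR in [-0.25, 0.05] e, dipole moment in
#' [5, 120] e nm, Rg in [2, 3.5] nm) and builds normalized contact numbers
#' obeying the linear law
#' \deqn{y = slope (NCPR - f_{true} M / R_g) + intercept + noise}
#' per polyPR length and salt concentration, with mild group-specific slope
#' scaling (lower salt and longer chains bind more steeply). Ground truth is
#' recorded in the attributes.
#'
#' @param n_components number of synthetic components (default 9).
#' @param f_true true dipole weight (default 0.0036).
#' @param slope_true base slope (default -1; contacts grow as the charge
#'   parameter becomes more negative).
#' @param intercept_true base intercept.
#' @param noise_sd Gaussian noise sd on y (default 0.01).
#' @param lengths polyPR length labels.
#' @param salts salt concentrations in mM.
#' @param seed RNG seed.
#' @return data.frame of class \code{correlation_dataset} with attributes
#'   \code{f_true}, \code{slope_true}, \code{intercept_true},
#'   \code{noise_sd}.
#' @export
gen_correlation_dataset <- function(n_components = 9, f_true = 0.0036,
                                    slope_true = -1, intercept_true = 0.02,
                                    noise_sd = 0.01,
                                    lengths = c("PR20", "PR50"),
                                    salts = c(100, 200), seed = 1) {
  if (noise_sd < 0) stop("noise sd must be non-negative")
  set.seed(seed)
  ncpr <- runif(n_components, -0.25, 0.05)
  M <- runif(n_components, 5, 120)
  rg <- runif(n_components, 2, 3.5)
  rows <- list()
  for (len in lengths) {
    for (s in salts) {
      sc <- (1 + 0.3 * (len == "PR50")) * (1 + 0.5 * (s == 100))
      x <- charge_parameter(ncpr, M, rg, f_true)
      y <- slope_true * sc * x + intercept_true +
        rnorm(n_components, sd = noise_sd)
      rows[[paste(len, s)]] <- data.frame(
        name = paste0("toy", seq_len(n_components)),
        ncpr = ncpr, dipole_M = M, rg = rg,
        length = len, salt = s, ct_normalized = y,
        group = "general")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "f_true") <- f_true
  attr(out, "slope_true") <- slope_true
  attr(out, "intercept_true") <- intercept_true
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("correlation_dataset", "data.frame")
  out
}
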