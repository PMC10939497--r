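#' Charge parameter NCPR - f M / Rg
#'
#' The sequence/structure descriptor against which normalized contact
#' numbers correlate linearly: net charge per residue minus the dipole
#' moment per radius of gyration weighted by the dimensionless free
#' parameter f.
#'
#' @param ncpr net charge per residue, e.
#' @param dipole_M time-averaged dipole moment magnitude, e nm.
#' @param rg time-averaged radius of gyration, nm (> 0).
#' @param f dimensionless dipole weight (>= 0 by convention).
#' @return charge parameter in e per residue (vectorized).
#' @export
#' @examples
#' charge_parameter(-0.05, 10, 2, 0.0036)  # -0.068
charge_parameter <- function(ncpr, dipole_M, rg, f) {
  if (any(rg <= 0)) stop("rg must be positive")
  ncpr - f * dipole_M / rg
}

#' Ordinary least-squares line fit
#'
#' Simple linear regression with intercept, via the closed-form normal
#' equations; R^2 = 1 - SS_res/SS_tot (defined as 0 when y is constant).
#'
#' @param x,y numeric vectors (>= 3 points; x must vary).
#' @return list: slope, intercept, r_squared, n.
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (sd(x) == 0) stop("degenerate fit: x values are all equal")
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  ss_tot <- sum((y - my)^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r_squared = r2, n = length(x))
}

# fast R^2(f) for one group: squared Pearson correlation of y with
# x = ncpr - f * M/Rg (equals OLS R^2 with intercept); 0 for constant y
.r2_of_f <- function(f, ncpr, mrg, y) {
  x <- ncpr - f * mrg
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) return(0)
  cor(x, y)^2
}

#' Optimize the dipole weight f of the charge-parameter correlation
#'
#' Searches the dimensionless free parameter f that maximizes the quality of
#' the linear fits of normalized contact numbers against
#' [charge_parameter()], jointly over the named polyPR lengths (and every
#' salt concentration present). The aggregate objective is, by default, the
#' mean R^2 over groups; "min" and a pooled single regression are
#' selectable. The search is a dense grid on [0, 0.1] (step 1e-5) followed
#' by golden-section refinement when the optimum is interior; ties take the
#' smallest f.
#'
#' All per-group fits are computed and reported at the optimum; fits whose
#' R^2 falls below \code{r2_flag} are flagged (\code{low_r2}) rather than
#' dropped.
#'
#' @param dataset a correlation dataset: data.frame with columns
#'   \code{name}, \code{ncpr}, \code{dipole_M}, \code{rg}, \code{length}
#'   (e.g. "PR20"), \code{salt}, \code{ct_normalized} (and optionally
#'   \code{group}).
#' @param lengths polyPR lengths entering the objective (default PR20 and
#'   PR50).
#' @param aggregate "mean" (default), "min", or "pooled".
#' @param f_max upper end of the search domain.
#' @param f_step grid step.
#' @param r2_flag threshold below which a fit is flagged.
#' @return object of class \code{fit_result}: \code{f}, \code{objective},
#'   per-group data.frame \code{fits} (slope, intercept, r_squared, low_r2),
#'   \code{aggregate}.
#' @export
optimize_f <- function(dataset, lengths = c("PR20", "PR50"),
                       aggregate = c("mean", "min", "pooled"),
                       f_max = 0.1, f_step = 1e-5, r2_flag = 0.8) {
  aggregate <- match.arg(aggregate)
  d <- dataset[dataset$length %in% lengths, , drop = FALSE]
  if (!nrow(d)) stop("dataset has no rows for the requested lengths")
  key <- interaction(d$length, d$salt, drop = TRUE)
  groups <- split(d, key)
  if (any(vapply(groups, nrow, integer(1)) < 3))
    stop("each length/salt group needs at least 3 components")
  gdat <- lapply(groups, function(g)
    list(ncpr = g$ncpr, mrg = g$dipole_M / g$rg, y = g$ct_normalized))
  obj <- function(f) {
    if (aggregate == "pooled") {
      x <- unlist(lapply(gdat, function(g) g$ncpr - f * g$mrg))
      y <- unlist(lapply(gdat, function(g) g$y))
      if (sd(x) == 0 || sd(y) == 0) return(0)
      return(cor(x, y)^2)
    }
    r2 <- vapply(gdat, function(g) .r2_of_f(f, g$ncpr, g$mrg, g$y),
                 numeric(1))
    if (aggregate == "mean") mean(r2) else min(r2)
  }
  grid <- seq(0, f_max, by = f_step)
  vals <- vapply(grid, obj, numeric(1))
  k <- which.max(vals)  # ties resolve to the smallest f
  f_best <- grid[k]; v_best <- vals[k]
  if (k > 1 && k < length(grid) && vals[k - 1] < v_best && vals[k + 1] < v_best) {
    refine <- optimize(function(f) -obj(f),
                       lower = grid[k - 1], upper = grid[k + 1],
                       tol = 1e-10)
    if (-refine$objective > v_best) {
      f_best <- refine$minimum; v_best <- -refine$objective
    }
  }
  fits <- do.call(rbind, lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    x <- charge_parameter(g$ncpr, g$dipole_M, g$rg, f_best)
    fl <- fit_line(x, g$ct_normalized)
    data.frame(group = nm, length = g$length[1], salt = g$salt[1],
               slope = fl$slope, intercept = fl$intercept,
               r_squared = fl$r_squared, low_r2 = fl$r_squared < r2_flag,
               n = fl$n)
  }))
  rownames(fits) <- NULL
  structure(list(f = f_best, objective = v_best, fits = fits,
                 aggregate = aggregate, lengths = lengths,
                 r2_flag = r2_flag),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("charge-parameter fit: f = %.5g (aggregate %s R^2 = %.3f)\n",
              x$f, x$aggregate, x$objective))
  print(x$fits, ...)
  invisible(x)
}
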