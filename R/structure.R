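# Solution-structure observables: radial distribution functions, first-shell
# summary (R1, r_min1, n1), and the self-diffusion coefficient from the MSD.

#' Radial distribution function container
#'
#' @param r Bin centers, nm; strictly increasing and positive.
#' @param g Dimensionless RDF values, nonnegative.
#' @param rho_bulk Number density of the partner species, nm^-3.
#' @param pair_tag Identifier for the pair, e.g. `"MgOw"`.
#' @return An object of class `rdf`.
#' @export
rdf <- function(r, g, rho_bulk, pair_tag = "pair") {
  stopifnot(is.numeric(r), is.numeric(g), length(r) == length(g),
            length(r) >= 2L)
  if (any(r <= 0) || any(diff(r) <= 0))
    stop("'r' must be positive and strictly increasing")
  if (any(!is.finite(g)) || any(g < 0))
    stop("'g' must be finite and nonnegative")
  if (!is.finite(rho_bulk) || rho_bulk <= 0)
    stop("'rho_bulk' must be a positive number density (nm^-3)")
  structure(list(r = r, g = g, rho_bulk = rho_bulk, pair_tag = pair_tag),
            class = "rdf")
}

#' @export
print.rdf <- function(x, ...) {
  cat(sprintf("RDF [%s]: %d bins on %.4g-%.4g nm, rho_bulk = %.5g nm^-3\n",
              x$pair_tag, length(x$r), min(x$r), max(x$r), x$rho_bulk))
  invisible(x)
}

#' @export
plot.rdf <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r [nm]", ylab = "g(r)",
                 main = x$pair_tag, ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Radial distribution function from a trajectory
#'
#' Histograms minimum-image pair distances between two atom roles and
#' normalizes by the ideal-gas shell counts. Self-pairs are excluded when
#' both roles are identical. The partner bulk density is taken as the mean
#' partner count over volume across frames.
#'
#' @param traj A [trajectory].
#' @param pair Character vector of two role names, `c(central, partner)`.
#' @param bin_width Bin width in nm (> 0). Default 0.002 nm resolves the
#'   narrow Mg-O first peak to the precision of the structural targets.
#' @param r_max Histogram range, nm; must not exceed half the smallest box
#'   length (minimum-image validity).
#' @return An [rdf] object. The attribute `"pair_count"` carries the raw
#'   histogram sum for conservation checks.
#' @export
compute_rdf <- function(traj, pair, bin_width = 0.002, r_max = NULL) {
  stopifnot(inherits(traj, "trajectory"), length(pair) == 2L)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("'bin_width' must be positive")
  half_min_box <- min(traj$box) / 2
  if (is.null(r_max)) r_max <- half_min_box
  if (r_max > half_min_box + 1e-12)
    stop("'r_max' (", r_max, " nm) exceeds half the smallest box length (",
         signif(half_min_box, 6), " nm)")
  A <- traj$coords[[pair[1]]]; B <- traj$coords[[pair[2]]]
  if (is.null(A) || is.null(B))
    stop("trajectory lacks role(s): ",
         paste(setdiff(pair, names(traj$coords)), collapse = ", "))
  na <- dim(A)[2]; nb <- dim(B)[2]; nf <- dim(A)[1]
  if (na == 0L || nb == 0L) stop("empty atom group in pair ", paste(pair, collapse = "-"))
  same <- identical(pair[1], pair[2])
  d <- pair_distances(traj, pair[1], pair[2])
  if (same) for (i in seq_len(na)) d[, i, i] <- NA_real_
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + bin_width)
  dv <- d[!is.na(d) & d < edges[length(edges)]]
  h <- graphics::hist(dv, breaks = edges, plot = FALSE)$counts
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  mean_vol <- mean(traj$box[, 1] * traj$box[, 2] * traj$box[, 3])
  n_partner <- nb - if (same) 1L else 0L
  shell_vol <- (4 / 3) * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  ideal <- nf * na * shell_vol * n_partner / mean_vol
  g <- h / ideal
  out <- rdf(centers, g, rho_bulk = n_partner / mean_vol,
             pair_tag = paste(pair, collapse = ""))
  attr(out, "pair_count") <- sum(h)
  out
}

# 3-bin moving average used only for extremum detection (values reported
# from the unsmoothed curve).
.smooth3 <- function(g) {
  n <- length(g)
  s <- g
  if (n >= 3L) s[2:(n - 1)] <- (g[1:(n - 2)] + g[2:(n - 1)] + g[3:n]) / 3
  s
}

# Parabolic vertex through three equally spaced points centred at index i.
.parabolic_vertex <- function(x, y, i) {
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(denom) < .Machine$double.eps) return(x[i])
  x[i] + 0.5 * (x[i + 1] - x[i]) * (y[i - 1] - y[i + 1]) / denom
}

#' First hydration-shell summary from an RDF
#'
#' Locates the first peak position \eqn{R_1} (parabolic interpolation through
#' the three bins around the discrete maximum), the first minimum after the
#' peak \eqn{r_{min,1}}, and the coordination number
#' \deqn{n_1 = 4\pi\rho \int_0^{r_{min,1}} g(r) r^2 dr} (trapezoidal, on the
#' unsmoothed curve). Extremum detection runs on a 3-bin smoothed copy to
#' suppress noise-induced minima.
#'
#' @param x An [rdf] object.
#' @param r_min1 Optional forced first-minimum position (nm); skips minimum
#'   detection (useful for uniform or idealized RDFs).
#' @return An object of class `shell_summary` with fields `R1`, `r_min1`,
#'   `n1`.
#' @export
first_shell <- function(x, r_min1 = NULL) {
  stopifnot(inherits(x, "rdf"))
  r <- x$r; g <- x$g; n <- length(g)
  if (is.null(r_min1)) {
    gs <- .smooth3(g)
    ipk <- NA_integer_
    for (i in 2:(n - 1)) {
      if (gs[i] > gs[i - 1] && gs[i] >= gs[i + 1]) { ipk <- i; break }
    }
    if (is.na(ipk))
      stop("RDF has no interior maximum: cannot locate a first shell")
    imin <- NA_integer_
    for (i in (ipk + 1):(n - 1)) {
      if (gs[i] < gs[i - 1] && gs[i] <= gs[i + 1]) { imin <- i; break }
    }
    if (is.na(imin))
      stop("RDF has no minimum after the first peak: cannot close the shell")
    R1 <- .parabolic_vertex(r, g, ipk)
    r_min1 <- r[imin]
  } else {
    gs <- .smooth3(g)
    ipk <- which.max(gs[r < r_min1])
    R1 <- if (ipk > 1 && ipk < n) .parabolic_vertex(r, g, ipk) else r[ipk]
  }
  sel <- r <= r_min1
  # trapezoid of 4 pi rho g r^2 from the grid origin (extend to r = 0 with
  # g = g[1] only over the leading gap below the first bin centre: the gap is
  # inside the excluded-volume core for physical RDFs)
  rr <- c(0, r[sel]); gg <- c(if (g[1] < 1e-8) 0 else g[1], g[sel])
  integrand <- 4 * pi * x$rho_bulk * gg * rr^2
  n1 <- sum(diff(rr) * (integrand[-1] + integrand[-length(integrand)]) / 2)
  structure(list(R1 = R1, r_min1 = r_min1, n1 = n1),
            class = "shell_summary")
}

#' @export
print.shell_summary <- function(x, ...) {
  cat(sprintf("First shell: R1 = %.4f nm, r_min1 = %.4f nm, n1 = %.3f\n",
              x$R1, x$r_min1, x$n1))
  invisible(x)
}

#' Self-diffusion coefficient from the mean squared displacement
#'
#' Einstein relation \eqn{D = \lim_{t\to\infty} MSD(t)/(6t)}: the MSD is
#' averaged over atoms and (strided) time origins, then fit by least squares
#' over the requested lag window; \eqn{D} is the slope divided by 6. The
#' uncertainty is the block-averaged spread of per-block slopes.
#'
#' @param traj A [trajectory] with unwrapped or unwrappable coordinates.
#' @param role Atom role to analyse.
#' @param fit_window Lag-time interval `c(t_lo, t_hi)` in ps for the linear
#'   fit; must lie inside the trajectory span and cover at least 3 frames.
#' @param unwrap Remove periodic jumps before computing displacements
#'   (default `TRUE`).
#' @param n_blocks Blocks for the uncertainty estimate (default 3).
#' @param origin_stride Use every k-th frame as a time origin (default
#'   chosen to cap the number of origins at ~500).
#' @return List of class `diffusion_fit` with `D0` and `D0_err` in
#'   1e-5 cm^2/s, plus the lag grid and MSD used for the fit.
#' @export
msd_diffusion <- function(traj, role, fit_window, unwrap = TRUE,
                          n_blocks = 3L, origin_stride = NULL) {
  stopifnot(inherits(traj, "trajectory"), length(fit_window) == 2L)
  X <- if (unwrap) unwrap_coords(traj, role) else traj$coords[[role]]
  if (is.null(X)) stop("trajectory has no role '", role, "'")
  times <- traj$times
  dt <- diff(times[1:2])
  lag_idx <- which(times - times[1] >= fit_window[1] &
                   times - times[1] <= fit_window[2])
  lag_idx <- setdiff(lag_idx - 1L, 0L)  # lags in frames, excluding zero
  if (length(lag_idx) < 3L)
    stop("fit window covers fewer than 3 frames")
  nf <- dim(X)[1]; natm <- dim(X)[2]
  if (max(lag_idx) >= nf) stop("fit window extends beyond the trajectory span")
  if (is.null(origin_stride))
    origin_stride <- max(1L, floor((nf - max(lag_idx)) / 500L))
  msd_of <- function(frames) {
    v <- vapply(lag_idx, function(L) {
      orig <- seq(1L, length(frames) - L, by = origin_stride)
      if (length(orig) == 0L) return(NA_real_)
      i0 <- frames[orig]; i1 <- frames[orig + L]
      d2 <- 0
      for (k in 1:3) {
        dk <- matrix(X[i1, , k], length(orig), natm) -
              matrix(X[i0, , k], length(orig), natm)
        d2 <- d2 + dk * dk
      }
      mean(d2)
    }, numeric(1))
    v
  }
  taus <- lag_idx * dt
  msd <- msd_of(seq_len(nf))
  fit <- stats::lm(msd ~ taus)
  D_nm2ps <- unname(stats::coef(fit)[2]) / 6
  # block error: independent slope fits on contiguous trajectory thirds
  blk <- floor(nf / n_blocks)
  Db <- rep(NA_real_, n_blocks)
  if (blk > max(lag_idx) + 2L) {
    for (b in seq_len(n_blocks)) {
      frames <- ((b - 1L) * blk + 1L):(b * blk)
      mb <- msd_of(frames)
      ok <- is.finite(mb)
      if (sum(ok) >= 3L)
        Db[b] <- unname(stats::coef(stats::lm(mb[ok] ~ taus[ok]))[2]) / 6
    }
  }
  err <- if (all(is.finite(Db))) stats::sd(Db) / sqrt(n_blocks) else NA_real_
  structure(list(D0 = D_nm2ps * 1e3,                 # nm^2/ps -> 1e-5 cm^2/s
                 D0_err = if (is.na(err)) NA_real_ else err * 1e3,
                 tau = taus, msd = msd, residual = sum(stats::resid(fit)^2)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Self-diffusion: D0 = %.4g", x$D0))
  if (is.finite(x$D0_err)) cat(sprintf(" +- %.2g", x$D0_err))
  cat(" x 1e-5 cm^2/s\n")
  invisible(x)
}
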