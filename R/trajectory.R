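# Trajectory container for tagged atom subsets with periodic orthorhombic boxes.

#' Trajectory of tagged atom groups
#'
#' Time-ordered positions of tagged atom groups (central ions and candidate
#' ligand atoms) with per-frame orthorhombic box lengths. Coordinates are in
#' nm, times in ps. Triclinic boxes are not supported.
#'
#' @param times Strictly increasing frame times, ps.
#' @param coords Named list of 3-D arrays, one per atom role (e.g. `"Mg"`,
#'   `"Ow"`, `"Cl"`, `"OP"`), each with dim `c(n_frames, n_atoms, 3)`.
#' @param box Matrix `n_frames x 3` of box edge lengths (nm), or a length-3
#'   vector for a constant box.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, coords, box) {
  stopifnot(is.numeric(times), length(times) >= 1L)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  nf <- length(times)
  if (!is.list(coords) || is.null(names(coords)) || any(!nzchar(names(coords))))
    stop("'coords' must be a named list of arrays, one per atom role")
  for (role in names(coords)) {
    a <- coords[[role]]
    if (!is.array(a) || length(dim(a)) != 3L || dim(a)[3] != 3L)
      stop("coords[['", role, "']] must be an array [frames, atoms, 3]")
    if (dim(a)[1] != nf)
      stop("coords[['", role, "']] has ", dim(a)[1], " frames; expected ", nf)
  }
  if (is.null(dim(box))) {
    stopifnot(length(box) == 3L)
    box <- matrix(box, nrow = nf, ncol = 3L, byrow = TRUE)
  }
  if (!is.matrix(box) || nrow(box) != nf || ncol(box) != 3L)
    stop("'box' must be an n_frames x 3 matrix of orthorhombic box lengths")
  if (any(!is.finite(box)) || any(box <= 0))
    stop("box lengths must be positive and finite (triclinic boxes are not supported)")
  structure(list(times = times, coords = coords, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  roles <- vapply(names(x$coords),
                  function(r) sprintf("%s(%d)", r, dim(x$coords[[r]])[2]),
                  character(1))
  cat(sprintf("Trajectory: %d frames, %.4g ps span, roles: %s\n",
              length(x$times), diff(range(x$times)),
              paste(roles, collapse = ", ")))
  invisible(x)
}

#' @export
summary.trajectory <- function(object, ...) {
  print(object)
  cat(sprintf("  box (first frame): %.4g x %.4g x %.4g nm\n",
              object$box[1, 1], object$box[1, 2], object$box[1, 3]))
  invisible(object)
}

# Minimum-image pair distances between two roles.
# Returns array [frames, nA, nB]; vectorized over frames and B atoms.
pair_distances <- function(traj, role_a, role_b) {
  stopifnot(inherits(traj, "trajectory"))
  for (r in c(role_a, role_b))
    if (is.null(traj$coords[[r]]))
      stop("trajectory has no role '", r, "'")
  A <- traj$coords[[role_a]]
  B <- traj$coords[[role_b]]
  nf <- dim(A)[1]; na <- dim(A)[2]; nb <- dim(B)[2]
  out <- array(NA_real_, dim = c(nf, na, nb))
  for (i in seq_len(na)) {
    d2 <- matrix(0, nf, nb)
    for (k in 1:3) {
      d <- B[, , k, drop = TRUE] - A[, i, k]   # [nf, nb] minus nf-vector
      d <- matrix(d, nf, nb)
      bk <- traj$box[, k]
      d <- d - bk * round(d / bk)              # minimum image, column recycling
      d2 <- d2 + d * d
    }
    out[, i, ] <- sqrt(d2)
  }
  out
}

# Unwrap periodic jumps along the time axis (per-axis, minimum-image steps).
unwrap_coords <- function(traj, role) {
  X <- traj$coords[[role]]
  nf <- dim(X)[1]; na <- dim(X)[2]
  if (nf < 2L) return(X)
  for (k in 1:3) {
    bk <- traj$box[, k]
    d <- matrix(X[, , k], nf, na)
    steps <- d[-1, , drop = FALSE] - d[-nf, , drop = FALSE]
    steps <- steps - bk[-1] * round(steps / bk[-1])
    cum <- matrix(apply(steps, 2, cumsum), nf - 1L, na)
    X[, , k] <- rbind(d[1, , drop = FALSE],
                      cum + matrix(d[1, ], nf - 1L, na, byrow = TRUE))
  }
  X
}
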