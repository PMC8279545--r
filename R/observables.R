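#' Conversion factor from e*Angstrom to Debye
#' @keywords internal
.EA_TO_DEBYE <- 4.803205

.match_atoms <- function(frame, name, resid = NULL) {
  hit <- which(frame$atom == name &
                 (if (is.null(resid)) TRUE else frame$resid == resid))
  hit
}

#' Side-chain end-to-end distance
#'
#' Euclidean distance (Angstrom) between two named atoms of a molecular
#' frame — for diphenylalanine, the distance `d_ee` between the terminal
#' C-zeta atoms of the two phenyl side chains, the 1-D reaction coordinate
#' used for state assignment.
#'
#' @param frame A `molecular_frame` (see [read_pdb()]).
#' @param atoms Character vector of two atom names (default both `"CZ"`,
#'   disambiguated by residue id).
#' @return Distance in Angstrom; symmetric in the two atoms.
#' @export
end_to_end_distance <- function(frame, atoms = c("CZ", "CZ")) {
  stopifnot(inherits(frame, "molecular_frame"))
  if (length(atoms) == 1) atoms <- rep(atoms, 2)
  if (atoms[1] == atoms[2]) {
    hit <- .match_atoms(frame, atoms[1])
    if (length(hit) != 2)
      stop("atom '", atoms[1], "' must occur exactly twice; found ",
           length(hit), " (candidates: ",
           paste0(frame$atom[hit], "/", frame$resid[hit], collapse = ", "),
           ")")
    i <- hit[1]; j <- hit[2]
  } else {
    pick <- function(nm) {
      hit <- .match_atoms(frame, nm)
      if (length(hit) != 1)
        stop("atom '", nm, "' must occur exactly once; found ", length(hit),
             if (length(hit)) paste0(" (candidates: ",
                                     paste0(frame$atom[hit], "/",
                                            frame$resid[hit], collapse = ", "),
                                     ")") else "")
      hit
    }
    i <- pick(atoms[1]); j <- pick(atoms[2])
  }
  sqrt(sum((frame$xyz[i, ] - frame$xyz[j, ])^2))
}

.heavy_index <- function(frame) {
  nm <- sub("^[0-9]+", "", frame$atom)
  which(substr(nm, 1, 1) != "H")
}

#' Optimal-superposition heavy-atom RMSD
#'
#' Root-mean-square deviation between two frames after removing the optimal
#' rigid-body motion: both selections are centred and the rotation
#' minimising the RMSD is found by singular value decomposition of the
#' covariance matrix, with the determinant correction that excludes
#' reflections. The result is invariant to any rigid motion of either
#' frame.
#'
#' @param frame_a,frame_b `molecular_frame`s with matching selections
#'   (same atom count and order).
#' @param selection Integer indices of atoms to superpose; default all
#'   non-hydrogen atoms (element inferred from the atom-name leading
#'   character after stripping digits).
#' @return RMSD in Angstrom.
#' @export
heavy_atom_rmsd <- function(frame_a, frame_b, selection = NULL) {
  stopifnot(inherits(frame_a, "molecular_frame"),
            inherits(frame_b, "molecular_frame"))
  sa <- if (is.null(selection)) .heavy_index(frame_a) else selection
  sb <- if (is.null(selection)) .heavy_index(frame_b) else selection
  if (length(sa) != length(sb))
    stop("selections differ in atom count (", length(sa), " vs ",
         length(sb), ")")
  if (length(sa) == 0) stop("empty atom selection")
  A <- frame_a$xyz[sa, , drop = FALSE]
  B <- frame_b$xyz[sb, , drop = FALSE]
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  H <- crossprod(A, B)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)    # rotation applied to A
  Afit <- A %*% t(R)
  sqrt(mean(rowSums((Afit - B)^2)))
}

#' Molecular dipole moment magnitude
#'
#' `mu = |sum_i q_i (r_i - r_centroid)|`, converted from e*Angstrom to
#' Debye (1 e*A = 4.803205 D). For a net-neutral frame the result does not
#' depend on the reference point; a non-neutral frame triggers a warning
#' because the magnitude then depends on the centroid choice.
#'
#' @param frame A `molecular_frame` carrying per-atom partial charges
#'   (attach with [read_charges()] or set `frame$charge`).
#' @return Dipole moment magnitude in Debye.
#' @export
dipole_moment <- function(frame) {
  stopifnot(inherits(frame, "molecular_frame"))
  q <- frame$charge
  if (is.null(q) || anyNA(q))
    stop("frame has no (complete) partial charges")
  if (abs(sum(q)) > 1e-6)
    warning("frame is not net-neutral (total charge ", signif(sum(q), 3),
            " e): dipole magnitude depends on the reference point")
  r <- sweep(frame$xyz, 2, colMeans(frame$xyz))
  mu <- colSums(q * r)
  sqrt(sum(mu^2)) * .EA_TO_DEBYE
}

#' Binned density histogram with mode location
#'
#' Histogram of an observable series with fixed-width bins aligned to
#' multiples of the bin width, normalised as a density (integrates to 1).
#' The mode is the centre of the highest bin; ties resolve to the lowest
#' centre.
#'
#' @param x Nonempty numeric series.
#' @param bin_width Bin width in the series' units (default 0.1).
#' @param range Optional length-2 range; default spans the data.
#' @return An object of class `"obs_histogram"`: list with `breaks`,
#'   `mids`, `counts`, `density`, `mode`, `bin_width`.
#' @export
obs_histogram <- function(x, bin_width = 0.1, range = NULL) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty series")
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(range)) range <- base::range(x)
  lo <- floor(range[1] / bin_width) * bin_width
  hi <- ceiling(range[2] / bin_width) * bin_width
  if (hi <= lo) { lo <- lo - bin_width / 2; hi <- lo + bin_width }
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- hist(x, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  structure(list(breaks = h$breaks, mids = h$mids, counts = h$counts,
                 density = h$density, mode = h$mids[which.max(h$density)],
                 bin_width = bin_width),
            class = "obs_histogram")
}

#' @export
print.obs_histogram <- function(x, ...) {
  cat(sprintf("Histogram: %d bins of width %g, mode at %g\n",
              length(x$mids), x$bin_width, x$mode))
  invisible(x)
}

#' @export
plot.obs_histogram <- function(x, ...) {
  plot(x$mids, x$density, type = "h", xlab = "value", ylab = "density", ...)
  abline(v = x$mode, lty = 2)
  invisible(x)
}
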