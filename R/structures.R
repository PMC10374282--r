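#' Coarse bead structure
#'
#' A light-weight container for coarse-grained structural models: one bead
#' per residue (or any user-defined granularity) with a radius, a scattering
#' weight and optional rigid-body membership. All coordinates are in
#' Angstrom.
#'
#' @param xyz numeric matrix (n x 3) of bead coordinates in Angstrom.
#' @param radius per-bead radius in Angstrom (recycled); must be positive.
#' @param weight per-bead scattering weight \eqn{b_i} (recycled).
#' @param resid residue identifiers (defaults to 1..n).
#' @param chain chain identifiers (recycled).
#' @param body rigid-body membership tags (recycled).
#' @return an object of class `coarse_structure`.
#' @export
coarse_structure <- function(xyz, radius = 1.9, weight = 1,
                             resid = NULL, chain = "A", body = 1L) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have three columns")
  n <- nrow(xyz)
  if (n < 1L) stop("structure must contain at least one bead")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  radius <- rep_len(as.numeric(radius), n)
  if (any(radius <= 0)) stop("bead radii must be positive")
  weight <- rep_len(as.numeric(weight), n)
  if (is.null(resid)) resid <- seq_len(n)
  structure(
    list(xyz = unname(xyz), radius = radius, weight = weight,
         resid = rep_len(resid, n), chain = rep_len(chain, n),
         body = rep_len(body, n)),
    class = "coarse_structure")
}

#' @export
print.coarse_structure <- function(x, ...) {
  cat(sprintf("coarse_structure: %d beads, %d chain(s), %d rigid bodies\n",
              nrow(x$xyz), length(unique(x$chain)),
              length(unique(x$body))))
  ext <- apply(x$xyz, 2, range)
  cat(sprintf("  extent [A]: x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

n_beads <- function(s) nrow(s$xyz)

#' Read a structure file into a coarse bead model
#'
#' Reads PDB or mmCIF through bio3d and reduces the model to one bead per
#' residue at the C-alpha position. Bead radii default to 1.9 A (a C-alpha
#' excluded-volume radius); scattering weights are uniform.
#'
#' @param file path to a .pdb or .cif file.
#' @param radius bead radius in Angstrom.
#' @return a [coarse_structure()].
#' @export
read_structure <- function(file, radius = 1.9) {
  ext <- tolower(tools::file_ext(file))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(file)
         else bio3d::read.pdb(file)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  if (nrow(at) == 0L) stop("no C-alpha atoms found in ", file)
  coarse_structure(cbind(at$x, at$y, at$z), radius = radius,
                   resid = at$resno, chain = at$chain)
}

#' Write a coarse structure as a PDB file (one CA atom per bead)
#'
#' @param s a [coarse_structure()].
#' @param file output path.
#' @export
write_structure_pdb <- function(s, file) {
  n <- n_beads(s)
  bio3d::write.pdb(xyz = as.vector(t(s$xyz)), file = file,
                   resno = s$resid, chain = s$chain,
                   resid = rep("ALA", n), elety = rep("CA", n))
  invisible(file)
}

#' Kabsch superposition
#'
#' Least-squares rigid superposition of point set `P` onto `Q` (both n x 3).
#' Returns the rotation, translation, transformed coordinates and the RMSD
#' after superposition.
#'
#' @param P,Q n x 3 coordinate matrices with matched rows.
#' @return list with `R` (3 x 3 rotation), `t` (translation), `coords`
#'   (P after superposition) and `rmsd` in the coordinate units.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Pfit <- sweep(P0 %*% t(R), 2, cq, `+`)
  list(R = R, t = cq - as.vector(R %*% cp), coords = Pfit,
       rmsd = sqrt(mean(rowSums((Pfit - Q)^2))))
}

#' RMSD between two structures after optimal superposition
#'
#' @param s1,s2 [coarse_structure()] objects with identical bead counts.
#' @return RMSD in Angstrom.
#' @export
structure_rmsd <- function(s1, s2) {
  if (n_beads(s1) != n_beads(s2))
    stop("structures must share bead topology")
  kabsch_superpose(s1$xyz, s2$xyz)$rmsd
}

# rotate `xyz` about axis (unit vector) through `origin` by `angle` radians
rotate_about_axis <- function(xyz, axis, origin, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}
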