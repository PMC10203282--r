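#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `R %*% x + t` over the moving set against the reference set, via the SVD of
#' the cross-covariance matrix with the usual determinant correction so that
#' `det(R) = +1` (no reflections).
#'
#' @param coords_ref,coords_mov n x 3 numeric matrices of paired coordinates
#'   (n >= 3, not collinear).
#' @return An object of class `superposition`: list with `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom) and `rotation_angle` (degrees
#'   in \[0, 180\], from `acos((tr(R) - 1) / 2)`).
#' @export
superpose <- function(coords_ref, coords_mov) {
  coords_ref <- as.matrix(coords_ref); coords_mov <- as.matrix(coords_mov)
  if (!all(dim(coords_ref) == dim(coords_mov)) || ncol(coords_ref) != 3L)
    stop("coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(coords_ref)
  if (n < 3L) stop("need at least 3 paired points")
  cr <- colMeans(coords_ref); cm <- colMeans(coords_mov)
  P <- sweep(coords_mov, 2, cm); Q <- sweep(coords_ref, 2, cr)
  H <- crossprod(P, Q)                       # 3x3 cross-covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear or coincident) coordinates: superposition underdetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd,
                 rotation_angle = rotation_angle(R)),
            class = "superposition")
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3 x 3 proper rotation matrix.
#' @return Angle in degrees in \[0, 180\].
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Apply a superposition to coordinates
#'
#' @param sp a [superpose()] result.
#' @param coords n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A, rotation %.3f deg\n",
              x$rmsd, x$rotation_angle))
  invisible(x)
}

chain_ca <- function(model, chain) {
  a <- model$atoms
  ca <- a[a$chain == chain & a$atom == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("no Calpha atoms in chain '", chain, "' of ", model$structure_id)
  ca <- ca[order(ca$resid), , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resid
  m
}

#' Inter-structure rotational displacement of a trimer subunit
#'
#' Implements the two-structure subunit-angle comparison used for homologous
#' core vertex trimers: within each structure the rotation angle that maps the
#' alignment subunit onto the target subunit is computed (a quantity invariant
#' under global rigid motion, hence insensitive to how the two structures are
#' pre-aligned), and the two angles are subtracted.  A positive value means the
#' target chain of `trimer_b` is rotated further from the alignment chain than
#' in `trimer_a`; the operation is antisymmetric in its structure arguments.
#'
#' @param trimer_a,trimer_b [structure_model]s containing both chains.
#' @param align_chain chain id of the subunit the measurement is anchored on.
#' @param target_chain chain id of the subunit whose rotation is compared.
#' @return Signed angle difference in degrees (`angle_b - angle_a`).
#' @export
chain_rotation_displacement <- function(trimer_a, trimer_b,
                                        align_chain, target_chain) {
  angle_in <- function(model) {
    ref <- chain_ca(model, align_chain)
    mov <- chain_ca(model, target_chain)
    common <- intersect(rownames(ref), rownames(mov))
    unpaired <- c(setdiff(rownames(ref), rownames(mov)),
                  setdiff(rownames(mov), rownames(ref)))
    if (length(unpaired))
      stop("unmatched residue correspondence between chains '", align_chain,
           "' and '", target_chain, "' in ", model$structure_id,
           "; unpaired residues: ", paste(unpaired, collapse = ", "))
    superpose(ref[common, , drop = FALSE], mov[common, , drop = FALSE])$rotation_angle
  }
  angle_in(trimer_b) - angle_in(trimer_a)
}
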