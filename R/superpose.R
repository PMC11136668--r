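## Least-squares rigid-body superposition (Kabsch). Row-vector convention:
## the fitted coordinates are  mobile %*% rotation + translation  (each row
## one atom), with the rotation constrained to be proper (det = +1).

#' Optimal rigid superposition of two coordinate sets
#'
#' Computes the least-squares optimal rotation + translation mapping `mobile`
#' onto `reference` over a selection of atoms (Kabsch algorithm via SVD, with
#' a reflection guard so the rotation is always proper).
#'
#' @param mobile,reference n x 3 coordinate matrices of equal shape.
#' @param selection indices of the atoms used for the fit (default: all).
#'   At least 3 non-collinear atoms are required.
#' @return object of class `superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length 3, Angstrom) and `rmsd` (Angstrom, over
#'   the selection after the fit).
#' @export
superpose <- function(mobile, reference, selection = seq_len(nrow(mobile))) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop_ligdyn("validation", "mobile and reference shapes differ")
  if (length(selection) < 3L)
    stop_ligdyn("validation", "superposition needs >= 3 selected atoms, got %d",
                length(selection))
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)                     # 3 x 3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))     # rank < 2: collinear selection
    stop_ligdyn("validation", "degenerate (collinear) selection for superposition")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u) # maps column vectors; rows use t(R)
  rot <- t(R)                                # row convention: x %*% rot
  tr <- cb - drop(ca %*% rot)
  fitted <- sweep(A %*% rot, 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = rot, translation = tr, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param coordinates n x 3 matrix.
#' @param fit a `superposition` from [superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(coordinates, fit) {
  sweep(as.matrix(coordinates) %*% fit$rotation, 2, fit$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: rmsd %.4g A>\n", x$rmsd))
  invisible(x)
}
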