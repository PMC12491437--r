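# Minimal full-atom structure container used by the pose post-processing
# stage.  The membrane frame convention throughout: the z axis is the
# membrane normal, the membrane center sits at z = 0.

#' Construct a structure model
#'
#' A light full-atom container: one row per atom with chain, residue
#' number/name, atom name, element and coordinates in Angstrom. The
#' structure is assumed to be expressed in its membrane frame (z axis =
#' membrane normal, membrane center at z = 0).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `atom`,
#'   `element`, `x`, `y`, `z`.
#' @return An object of class `structure_model`.
#' @seealso [read_structure()] for PDB input.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  atoms <- atoms[, need]
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("non-finite coordinates in structure", call. = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Read a PDB file into a structure model
#'
#' Thin wrapper over `bio3d::read.pdb()`; keeps ATOM records only and infers
#' the element from the PDB element column (falling back to the first letter
#' of the atom name).
#'
#' @param path PDB file path.
#' @return A [structure_model()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  elem <- ifelse(is.na(elem) | elem == "",
                 substr(trimws(a$elety), 1, 1), trimws(elem))
  structure_model(data.frame(
    chain = a$chain, resno = a$resno, resid = a$resid,
    atom = trimws(a$elety), element = elem,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE))
}

# n x 3 coordinate matrix of all atoms
.coords <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

#' Calpha coordinates of a structure
#'
#' @param model a [structure_model()].
#' @return n x 3 matrix of CA coordinates in residue order.
#' @export
ca_coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  ca <- model$atoms[model$atoms$atom == "CA", , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("structure has no Calpha atoms", call. = FALSE)
  as.matrix(ca[, c("x", "y", "z")])
}

# heavy (non-hydrogen) atom subset
.heavy <- function(model) {
  model$atoms[toupper(model$atoms$element) != "H", , drop = FALSE]
}

#' Geometric center of the Calpha atoms
#'
#' @param model a [structure_model()].
#' @return length-3 numeric vector.
#' @export
ca_centroid <- function(model) colMeans(ca_coords(model))

#' Apply a rigid-body pose to a structure
#'
#' Transforms every atom by `x -> R x + t`.
#'
#' @param model a [structure_model()].
#' @param pose a [dock_pose()].
#' @return The transformed `structure_model`.
#' @export
apply_pose <- function(model, pose) {
  stopifnot(inherits(model, "structure_model"), inherits(pose, "dock_pose"))
  xyz <- .coords(model) %*% t(pose$rotation)
  xyz <- sweep(xyz, 2, pose$translation, "+")
  out <- model
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  out
}

#' Recover a rigid transform from posed coordinates
#'
#' Least-squares (Kabsch) estimate of the rotation and translation taking
#' the reference Calpha coordinates onto the posed ones. Used to ingest
#' directories of posed PDB models where the transform is not tabulated.
#'
#' @param reference,posed [structure_model()]s with matching Calpha sets.
#' @param pose_id,score metadata attached to the returned pose.
#' @return A [dock_pose()].
#' @export
pose_from_coords <- function(reference, posed, pose_id = 1L, score = 0) {
  A <- ca_coords(reference); B <- ca_coords(posed)
  if (nrow(A) != nrow(B))
    stop("reference and posed structures have different Calpha counts",
         call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cb - as.numeric(R %*% ca)
  dock_pose(pose_id, R, t, score)
}
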