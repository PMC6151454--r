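#' Rigid transform
#'
#' A proper rigid-body transform `y = R x + t` acting on column
#' 3-vectors (Angstrom).
#'
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation length-3 numeric vector.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-6) stop("rotation is not proper (det != 1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param t a [rigid_transform()].
#' @param coords N x 3 matrix or `"coordset"`.
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(t, coords) {
  m <- as_coords(coords)
  sweep(m %*% t(t$rotation), 2L, t$translation, "+")
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.vector(t(t$rotation) %*% t$translation))
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b [rigid_transform()] objects.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Rotation matrix about an axis (Rodrigues)
#' @param axis length-3 direction (normalized internally).
#' @param angle_deg rotation angle, degrees.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid rotation about a line in space
#' @param axis direction of the line.
#' @param angle_deg rotation angle, degrees.
#' @param point a point on the line.
#' @return a [rigid_transform()].
#' @export
rotation_about_line <- function(axis, angle_deg, point = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle_deg)
  rigid_transform(R, as.numeric(point - R %*% point))
}

rmsd_raw <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD of the
#' mobile set onto the reference, by SVD of the covariance matrix with
#' reflection correction.
#'
#' @param mobile,reference N x 3 matrices or `"coordset"` objects with
#'   identical atom correspondence (row i pairs with row i); N >= 3,
#'   points not all collinear.
#' @return object of class `"superposition"`: `transform`
#'   (a [rigid_transform()] mapping mobile onto reference), `rmsd`
#'   (Angstrom), `n_atoms`.
#' @export
superpose <- function(mobile, reference) {
  P <- as_coords(mobile)
  Q <- as_coords(reference)
  if (nrow(P) != nrow(Q)) {
    stop("pairing error: ", nrow(P), " vs ", nrow(Q), " atoms")
  }
  if (nrow(P) < 3L) stop("degenerate: need at least 3 points")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  sv_chk <- svd(Pc)$d
  if (sv_chk[2L] < 1e-9 * max(sv_chk[1L], 1)) {
    stop("degenerate: points are collinear")
  }
  H <- crossprod(Pc, Qc)  # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cq - R %*% cp)
  fitted <- sweep(Pc %*% t(R), 2L, cq, "+")
  structure(list(transform = rigid_transform(R, tr),
                 rmsd = rmsd_raw(fitted, Q),
                 n_atoms = nrow(P)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d atoms, rmsd %.4f A>\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Ensemble RMSD-to-mean statistics
#'
#' Iterative mean-structure procedure: all models are superposed on
#' model 1, coordinates averaged, then all models re-superposed on the
#' running mean and the mean recomputed, until the mean shifts by less
#' than `tol` (Angstrom) or `max_iter` iterations. Reports the RMSD of
#' each superposed model to the final mean, plus their mean and
#' standard deviation (n - 1 denominator).
#'
#' @param ensemble an `"ensemble"` with >= 2 models.
#' @param spec a [selection_spec()] naming the atoms entering the fit.
#' @param tol convergence tolerance on the maximum mean-coordinate
#'   shift, Angstrom.
#' @param max_iter iteration cap; non-convergence returns the last
#'   iterate with a warning.
#' @return `"ensemble_stats"`: `mean_coords` (coordset),
#'   `per_model_rmsd`, `mean_rmsd`, `sd_rmsd`, `n_iter`.
#' @export
ensemble_rmsd_to_mean <- function(ensemble, spec, tol = 1e-6,
                                  max_iter = 50L) {
  m <- n_models(ensemble)
  if (m < 2L) stop("need at least 2 models")
  sets <- lapply(seq_len(m), function(i) select_atoms(ensemble, spec, i))
  labels <- sets[[1L]]$labels
  coords <- lapply(sets, `[[`, "coords")
  ref <- coords[[1L]]
  fit_all <- function(reference) {
    lapply(coords, function(x) {
      apply_transform(superpose(x, reference)$transform, x)
    })
  }
  fitted <- fit_all(ref)
  mean_c <- Reduce(`+`, fitted) / m
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    fitted <- fit_all(mean_c)
    new_mean <- Reduce(`+`, fitted) / m
    shift <- max(abs(new_mean - mean_c))
    mean_c <- new_mean
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("mean structure did not converge in ",
                          max_iter, " iterations")
  per <- vapply(fitted, function(x) rmsd_raw(x, mean_c), numeric(1L))
  structure(list(mean_coords = coordset(labels, mean_c),
                 per_model_rmsd = per,
                 mean_rmsd = mean(per),
                 sd_rmsd = stats::sd(per),
                 n_iter = it),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("<ensemble_stats: %d models, RMSD to mean %.2f +/- %.2f A>\n",
              length(x$per_model_rmsd), x$mean_rmsd, x$sd_rmsd))
  invisible(x)
}

#' Screw (Chasles) decomposition of a rigid transform
#'
#' Any proper rigid transform is a rotation about an axis plus a
#' translation along that axis. The angle comes from the rotation
#' trace, the axis from the rotation's fixed direction, and the axis
#' point is chosen so the residual translation is parallel to the axis.
#' A near-identity rotation is treated as a pure translation (axis set
#' to the translation direction, or +z when the translation is also
#' negligible).
#'
#' @param t a [rigid_transform()].
#' @return `"screw"`: `axis` (unit vector), `angle` (degrees, in
#'   `[0, 180]`), `translation_along_axis` (Angstrom), `axis_point`.
#' @export
screw_decompose <- function(t) {
  R <- t$rotation
  tv <- t$translation
  cos_th <- (sum(diag(R)) - 1) / 2
  cos_th <- max(-1, min(1, cos_th))
  th <- acos(cos_th)
  if (th < 1e-8) {
    nt <- sqrt(sum(tv^2))
    axis <- if (nt > 1e-12) tv / nt else c(0, 0, 1)
    return(structure(list(axis = axis, angle = 0,
                          translation_along_axis = nt,
                          axis_point = c(0, 0, 0)),
                     class = "screw"))
  }
  if (abs(pi - th) > 1e-6) {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    axis <- v / (2 * sin(th))
  } else {
    # angle ~180: fixed direction from the symmetric part
    B <- (R + diag(3)) / 2          # B = a a^T at exactly 180 degrees
    j <- which.max(diag(B))
    axis <- B[, j] / sqrt(B[j, j])
  }
  axis <- axis / sqrt(sum(axis^2))
  d <- sum(tv * axis)
  t_perp <- tv - d * axis
  # point on the axis: p = (t_perp + cross(a, t_perp)/tan(th/2)) / 2
  cr <- c(axis[2] * t_perp[3] - axis[3] * t_perp[2],
          axis[3] * t_perp[1] - axis[1] * t_perp[3],
          axis[1] * t_perp[2] - axis[2] * t_perp[1])
  cot_half <- if (abs(pi - th) < 1e-9) 0 else 1 / tan(th / 2)
  p <- (t_perp + cot_half * cr) / 2
  structure(list(axis = axis, angle = th * 180 / pi,
                 translation_along_axis = d, axis_point = p),
            class = "screw")
}

#' Recompose a rigid transform from its screw description
#' @param s a `"screw"` object as returned by [screw_decompose()].
#' @return a [rigid_transform()].
#' @export
screw_recompose <- function(s) {
  if (s$angle == 0) {
    return(rigid_transform(diag(3), s$translation_along_axis * s$axis))
  }
  R <- rotation_matrix(s$axis, s$angle)
  tv <- as.numeric(s$axis_point - R %*% s$axis_point) +
    s$translation_along_axis * s$axis
  rigid_transform(R, tv)
}

#' @export
print.screw <- function(x, ...) {
  cat(sprintf(
    "<screw: angle %.2f deg about (%.3f, %.3f, %.3f), pitch %.2f A>\n",
    x$angle, x$axis[1], x$axis[2], x$axis[3], x$translation_along_axis))
  invisible(x)
}

#' Rotation angle of a 3 x 3 rotation matrix, degrees
#' @param R proper rotation matrix.
#' @export
rotation_angle <- function(R) {
  c_th <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, c_th))) * 180 / pi
}

angle_between <- function(u, v) {
  cu <- u / sqrt(sum(u^2))
  cv <- v / sqrt(sum(v^2))
  acos(max(-1, min(1, sum(cu * cv)))) * 180 / pi
}
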