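#' Torsion (dihedral) angle of four points
#' @param p1,p2,p3,p4 length-3 coordinates.
#' @return angle in degrees, in (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

backbone_of_chain <- function(ensemble, chain_id, model = 1L) {
  at <- ensemble$atoms
  co <- model_coords(ensemble, model)
  idx <- at$chain == chain_id & at$type == "ATOM"
  if (!any(idx)) stop("no ATOM records on chain '", chain_id, "'")
  resno <- sort(unique(at$resno[idx]))
  get <- function(rn, name) {
    j <- which(idx & at$resno == rn & at$elety == name)
    if (length(j) == 1L) co[j, ] else NULL
  }
  list(resno = resno, get = get)
}

#' Assign alpha-helical segments from backbone dihedrals
#'
#' A residue is called helical when its phi falls in `phi_range` and
#' its psi in `psi_range` (degrees); maximal runs of at least
#' `min_run` helical residues become segments. Terminal residues
#' (lacking one of the two dihedrals) and residues at numbering gaps
#' are non-helical; residues with missing backbone atoms are skipped
#' with a warning. The default window is deliberately permissive so
#' slightly curved solution-NMR helices are retained.
#'
#' @param ensemble an `"ensemble"`.
#' @param chain_id chain to analyse.
#' @param model model index.
#' @param phi_range,psi_range inclusive dihedral windows, degrees.
#' @param min_run minimum helical run length, residues.
#' @return data.frame of class `"helix_segments"` with columns
#'   `chain_id`, `start`, `end` (inclusive, author numbering).
#' @export
assign_helices <- function(ensemble, chain_id, model = 1L,
                           phi_range = c(-100, -30),
                           psi_range = c(-80, -5),
                           min_run = 4L) {
  bb <- backbone_of_chain(ensemble, chain_id, model)
  resno <- bb$resno
  n <- length(resno)
  if (n < 4L) stop("chain has fewer than 4 residues")
  helical <- logical(n)
  for (i in seq_len(n)) {
    rn <- resno[i]
    Ni <- bb$get(rn, "N"); CAi <- bb$get(rn, "CA"); Ci <- bb$get(rn, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) {
      warning("residue ", rn, " missing backbone atoms; skipped",
              call. = FALSE)
      next
    }
    prev_ok <- i > 1L && resno[i - 1L] == rn - 1L
    next_ok <- i < n && resno[i + 1L] == rn + 1L
    if (!prev_ok || !next_ok) next  # termini lack phi or psi
    Cprev <- bb$get(rn - 1L, "C")
    Nnext <- bb$get(rn + 1L, "N")
    if (is.null(Cprev) || is.null(Nnext)) next
    phi <- torsion_angle(Cprev, Ni, CAi, Ci)
    psi <- torsion_angle(Ni, CAi, Ci, Nnext)
    helical[i] <- phi >= phi_range[1L] && phi <= phi_range[2L] &&
      psi >= psi_range[1L] && psi <= psi_range[2L]
  }
  # maximal runs >= min_run (runs also break at numbering gaps)
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (helical[i]) {
      j <- i
      while (j < n && helical[j + 1L] && resno[j + 1L] == resno[j] + 1L) {
        j <- j + 1L
      }
      if (j - i + 1L >= min_run) {
        segs[[length(segs) + 1L]] <- c(resno[i], resno[j])
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out <- if (length(segs) == 0L) {
    data.frame(chain_id = character(), start = integer(), end = integer())
  } else {
    data.frame(chain_id = chain_id,
               start = vapply(segs, `[`, numeric(1L), 1L),
               end = vapply(segs, `[`, numeric(1L), 2L))
  }
  class(out) <- c("helix_segments", "data.frame")
  out
}

#' Fit a helix axis to ordered CA coordinates
#'
#' Local helix-centre points `p_i = (CA_{i-1} + 2 CA_i + CA_{i+1}) / 4`
#' are computed for the interior residues; the axis direction is the
#' principal eigenvector of their covariance, oriented N-to-C (positive
#' projection of last CA minus first CA). `fit_rms` is the RMS distance
#' of the centre points to the fitted line.
#'
#' @param ca ordered (N-to-C) CA coordinates: N x 3 matrix or
#'   `"coordset"`; at least 5 CA atoms.
#' @return `"helix_axis"`: `direction` (unit vector), `centroid`,
#'   `fit_rms` (Angstrom), `n_ca`.
#' @export
fit_helix_axis <- function(ca) {
  m <- as_coords(ca)
  n <- nrow(m)
  if (n < 5L) stop("degenerate: need at least 5 CA atoms")
  idx <- 2L:(n - 1L)
  p <- (m[idx - 1L, , drop = FALSE] + 2 * m[idx, , drop = FALSE] +
          m[idx + 1L, , drop = FALSE]) / 4
  centroid <- colMeans(p)
  pc <- sweep(p, 2L, centroid)
  ev <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)
  dir <- ev$vectors[, 1L]
  # De-bias the finite-arc line fit: for an ideal helix the second
  # differences of the centre points are purely centripetal (the axial
  # coordinate is linear in residue index), so the axis is the normal
  # of their span. Used when enough centre points exist and the points
  # are not collinear; falls back to the plain principal axis otherwise.
  if (nrow(p) >= 4L) {
    d2 <- p[-c(1L, nrow(p)), , drop = FALSE] * (-2) +
      p[-c(nrow(p) - 1L, nrow(p)), , drop = FALSE] +
      p[-c(1L, 2L), , drop = FALSE]
    if (max(abs(d2)) > 1e-8) {
      ev2 <- eigen(crossprod(d2), symmetric = TRUE)
      # need the in-plane directions actually spanned (rank >= 2)
      if (ev2$values[2L] > 1e-6 * ev2$values[1L]) {
        cand <- ev2$vectors[, 3L]
        if (sum(cand * dir) < 0) cand <- -cand
        dir <- cand
      }
    }
  }
  if (sum(dir * (m[n, ] - m[1L, ])) < 0) dir <- -dir
  dir <- dir / sqrt(sum(dir^2))
  # RMS distance of centre points to the axis line
  proj <- pc %*% dir
  perp2 <- rowSums(pc^2) - proj^2
  structure(list(direction = as.numeric(dir), centroid = centroid,
                 fit_rms = sqrt(mean(pmax(perp2, 0))), n_ca = n),
            class = "helix_axis")
}

#' @export
print.helix_axis <- function(x, ...) {
  cat(sprintf("<helix_axis: dir (%.3f, %.3f, %.3f), fit_rms %.2f A>\n",
              x$direction[1], x$direction[2], x$direction[3], x$fit_rms))
  invisible(x)
}

chain_ca <- function(ensemble, chain_id, resno_range, model = 1L) {
  at <- ensemble$atoms
  idx <- at$chain == chain_id & at$elety == "CA" & at$type == "ATOM" &
    at$resno >= resno_range[1L] & at$resno <= resno_range[2L]
  rn <- at$resno[idx]
  co <- model_coords(ensemble, model)[idx, , drop = FALSE]
  co[order(rn), , drop = FALSE]
}

#' Inter-helical (kink) angle at a split residue
#'
#' Fits independent axes to the CA atoms preceding and following
#' `split_residue` (the split residue itself, the tether, belongs to
#' neither segment) and returns the angle between the two N-to-C
#' directions, degrees in `[0, 180]`.
#'
#' @param ensemble an `"ensemble"`.
#' @param chain_id peptide chain.
#' @param split_residue author residue number of the tether.
#' @param flank optionally restrict each side to the `flank` residues
#'   nearest the split; `NULL` (default) uses all residues of the chain.
#' @param model model index; see [kink_angle_ensemble()] for ensemble
#'   averaging.
#' @return angle in degrees.
#' @export
kink_angle <- function(ensemble, chain_id, split_residue, flank = NULL,
                       model = 1L) {
  at <- ensemble$atoms
  rn_all <- sort(unique(at$resno[at$chain == chain_id & at$elety == "CA" &
                                   at$type == "ATOM"]))
  lo <- rn_all[rn_all < split_residue]
  hi <- rn_all[rn_all > split_residue]
  if (!is.null(flank)) {
    lo <- utils::tail(lo, flank)
    hi <- utils::head(hi, flank)
  }
  if (length(lo) < 5L || length(hi) < 5L) {
    stop("need at least 5 CA atoms on each side of residue ", split_residue)
  }
  a1 <- fit_helix_axis(chain_ca(ensemble, chain_id, range(lo), model))
  a2 <- fit_helix_axis(chain_ca(ensemble, chain_id, range(hi), model))
  angle_between(a1$direction, a2$direction)
}

#' Ensemble mean and sd of the kink angle
#' @inheritParams kink_angle
#' @return list with `mean`, `sd`, `per_model` (degrees).
#' @export
kink_angle_ensemble <- function(ensemble, chain_id, split_residue,
                                flank = NULL) {
  per <- vapply(seq_len(n_models(ensemble)), function(i) {
    kink_angle(ensemble, chain_id, split_residue, flank, model = i)
  }, numeric(1L))
  list(mean = mean(per), sd = if (length(per) > 1L) stats::sd(per) else 0,
       per_model = per)
}

#' Helical residue count and fraction of a chain
#'
#' @param segments a `"helix_segments"` data.frame (disjoint segments).
#' @param chain_length number of residues in the chain.
#' @return list with `count` (helical residues) and `fraction`
#'   (`count / chain_length`).
#' @export
helicity_fraction <- function(segments, chain_length) {
  if (chain_length < 1L) stop("chain_length must be >= 1")
  if (nrow(segments) > 1L) {
    s <- segments[order(segments$start), , drop = FALSE]
    if (any(s$start[-1L] <= s$end[-nrow(s)])) {
      stop("overlapping segments")
    }
  }
  count <- if (nrow(segments) == 0L) 0L else {
    as.integer(sum(segments$end - segments$start + 1))
  }
  list(count = count, fraction = count / chain_length)
}
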