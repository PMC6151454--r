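AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# internal-coordinate placement: position d with bond |c-d|, angle b-c-d,
# torsion a-b-c-d (NeRF construction)
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d_local <- c(-bond * cos(th), bond * sin(th) * cos(ph),
               -bond * sin(th) * sin(ph))  # sign fixes IUPAC handedness
  c + d_local[1L] * bc + d_local[2L] * m + d_local[3L] * n
}

# bond lengths (A) and angles (deg) of the ideal trans backbone
GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
             ca_cb = 1.53, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
             ang_c_n_ca = 121.7, ang_ca_c_o = 120.5, omega = 180)

seq_to_three <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence[1L]) > 1L) {
    sequence <- strsplit(toupper(sequence), "")[[1L]]
  }
  unknown <- setdiff(sequence, names(AA1TO3))
  if (length(unknown) > 0L) {
    stop("unknown residue letter(s): ", paste(unknown, collapse = ","))
  }
  unname(AA1TO3[sequence])
}

cb_position <- function(N, CA, C) {
  b1 <- N - CA
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- C - CA
  b2 <- b2 / sqrt(sum(b2^2))
  n <- b1 + b2
  n <- n / sqrt(sum(n^2))
  m <- c(b1[2] * b2[3] - b1[3] * b2[2],
         b1[3] * b2[1] - b1[1] * b2[3],
         b1[1] * b2[2] - b1[2] * b2[1])
  m <- m / sqrt(sum(m^2))
  half <- GEOM$ang_n_ca_c / 2 * pi / 180
  alpha <- cos(110.1 * pi / 180) / cos(half)
  beta <- sqrt(1 - alpha^2)
  CA + GEOM$ca_cb * (alpha * n + beta * m)
}

#' Build an ideal helical (or other regular) peptide backbone
#'
#' Places backbone atoms N, CA, C, O plus CB (except Gly) from ideal
#' internal coordinates with uniform (or per-residue) phi/psi and a
#' trans peptide bond. Defaults give a canonical alpha helix
#' (consecutive CA-CA distance 3.8 Angstrom).
#'
#' @param sequence one-letter amino-acid string (or character vector).
#' @param phi,psi backbone dihedrals, degrees; recycled to the
#'   sequence length, so per-residue vectors allow deliberately
#'   distorted stretches.
#' @param chain_id chain identifier for the built model.
#' @param start_resno author number of the first residue (numbering is
#'   preserved exactly, e.g. a peptide numbered 391-414).
#' @param id ensemble identifier.
#' @return a single-model `"ensemble"`.
#' @export
build_ideal_helix <- function(sequence, phi = -57, psi = -47,
                              chain_id = "P", start_resno = 1L,
                              id = "ideal_helix") {
  res3 <- seq_to_three(sequence)
  n <- length(res3)
  if (n < 2L) stop("sequence must have at least 2 residues")
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  N <- CA <- C <- O <- vector("list", n)
  N[[1L]] <- c(0, 0, 0)
  CA[[1L]] <- c(GEOM$n_ca, 0, 0)
  angA <- GEOM$ang_n_ca_c * pi / 180
  C[[1L]] <- CA[[1L]] + GEOM$ca_c * c(-cos(angA), sin(angA), 0)
  for (i in seq_len(n - 1L)) {
    N[[i + 1L]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                              GEOM$c_n, GEOM$ang_ca_c_n, psi[i])
    CA[[i + 1L]] <- place_atom(CA[[i]], C[[i]], N[[i + 1L]],
                               GEOM$n_ca, GEOM$ang_c_n_ca, GEOM$omega)
    C[[i + 1L]] <- place_atom(C[[i]], N[[i + 1L]], CA[[i + 1L]],
                              GEOM$ca_c, GEOM$ang_n_ca_c, phi[i + 1L])
  }
  for (i in seq_len(n)) {
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                         GEOM$c_o, GEOM$ang_ca_c_o, psi[i] + 180)
  }
  rows <- list()
  coords <- list()
  for (i in seq_len(n)) {
    names_i <- c("N", "CA", "C", "O")
    xyz_i <- list(N[[i]], CA[[i]], C[[i]], O[[i]])
    if (res3[i] != "GLY") {
      names_i <- c(names_i, "CB")
      xyz_i <- c(xyz_i, list(cb_position(N[[i]], CA[[i]], C[[i]])))
    }
    elesy <- substr(names_i, 1L, 1L)
    rows[[i]] <- data.frame(type = "ATOM", elety = names_i,
                            resid = res3[i], chain = chain_id,
                            resno = start_resno + i - 1L, elesy = elesy,
                            stringsAsFactors = FALSE)
    coords[[i]] <- do.call(rbind, xyz_i)
  }
  atoms <- do.call(rbind, rows)
  xyz <- as.vector(t(do.call(rbind, coords)))
  structure_ensemble(atoms, matrix(xyz, nrow = 1L), id = id)
}

#' Build a kinked helix: two ideal segments joined at an exact bend
#'
#' Builds an ideal helix, then rigidly rotates all residues after the
#' split residue by exactly `bend` degrees about an axis through the
#' split residue's CA, perpendicular to the N-segment axis. The split
#' residue itself is the tether between the two helical segments;
#' [kink_angle()] at the split recovers `bend` to within the axis-fit
#' noise (about 1 degree).
#'
#' @param sequence one-letter string.
#' @param split_index 1-based position of the tether residue, strictly
#'   inside the sequence.
#' @param bend kink angle, degrees in `[0, 90]`.
#' @inheritParams build_ideal_helix
#' @return a single-model `"ensemble"`.
#' @export
build_kinked_helix <- function(sequence, split_index, bend,
                               chain_id = "P", start_resno = 1L,
                               id = "kinked_helix") {
  if (bend < 0 || bend > 90) stop("bend outside [0, 90] degrees")
  ens <- build_ideal_helix(sequence, chain_id = chain_id,
                           start_resno = start_resno, id = id)
  n <- length(unique(ens$atoms$resno))
  if (split_index < 2L || split_index > n - 1L) {
    stop("split_index must be strictly inside the sequence")
  }
  if (bend == 0) return(ens)
  co <- model_coords(ens, 1L)
  at <- ens$atoms
  resno <- at$resno - start_resno + 1L  # 1-based index
  ca_all <- co[at$elety == "CA", , drop = FALSE]
  seg1 <- seq_len(split_index - 1L)
  d1 <- if (length(seg1) >= 5L) {
    fit_helix_axis(ca_all[seg1, , drop = FALSE])$direction
  } else fit_helix_axis(ca_all)$direction
  ref <- if (abs(d1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(d1[2] * ref[3] - d1[3] * ref[2],
         d1[3] * ref[1] - d1[1] * ref[3],
         d1[1] * ref[2] - d1[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  pivot <- ca_all[split_index, ]
  tr <- rotation_about_line(u, bend, pivot)
  move <- resno > split_index
  co[move, ] <- apply_transform(tr, co[move, , drop = FALSE])
  ens$xyz <- matrix(as.vector(t(co)), nrow = 1L)
  attr(ens, "bend") <- bend
  ens
}

#' Parameters for the pseudo-C2 toy complex generator
#'
#' @param peptide_length peptide residues.
#' @param kink_angle peptide kink, degrees.
#' @param kink_position tether residue index, strictly inside the
#'   peptide.
#' @param c2_twist extra rotation of domain B about the peptide axis
#'   beyond the ideal 180 degrees.
#' @param anchor_positions peptide indices carrying hydrophobic
#'   anchors (Ile; all other peptide residues are Ser).
#' @param noise_sigma per-coordinate Gaussian noise sd, Angstrom.
#' @param n_models number of models in the generated ensemble.
#' @param seed integer RNG seed; the generator is a pure function of
#'   (params, seed).
#' @export
toy_complex_params <- function(peptide_length = 24L, kink_angle = 17,
                               kink_position = 13L, c2_twist = 0,
                               anchor_positions = c(1L, 5L, 15L, 18L),
                               noise_sigma = 0, n_models = 1L,
                               seed = 1L) {
  if (kink_position < 2L || kink_position > peptide_length - 1L) {
    stop("kink_position must be strictly inside the peptide")
  }
  if (any(anchor_positions < 1L | anchor_positions > peptide_length)) {
    stop("anchor positions outside peptide")
  }
  if (n_models < 1L) stop("n_models must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(peptide_length = as.integer(peptide_length),
                 kink_angle = kink_angle,
                 kink_position = as.integer(kink_position),
                 c2_twist = c2_twist,
                 anchor_positions = sort(as.integer(anchor_positions)),
                 noise_sigma = noise_sigma,
                 n_models = as.integer(n_models),
                 seed = as.integer(seed)),
            class = "toy_complex_params")
}

# a minimal 5-atom residue whose CB sits at cb_pos with the rest of the
# residue stacked outward along `outward`
pocket_residue <- function(cb_pos, outward, resno, chain_id, resid) {
  w <- outward / sqrt(sum(outward^2))
  ref <- if (abs(w[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(w[2] * ref[3] - w[3] * ref[2],
         w[3] * ref[1] - w[1] * ref[3],
         w[1] * ref[2] - w[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  CA <- cb_pos + GEOM$ca_cb * w
  N <- CA + GEOM$n_ca * (0.5 * w + sqrt(0.75) * u)
  C <- CA + GEOM$ca_c * (0.5 * w - sqrt(0.75) * u)
  O <- C + GEOM$c_o * (0.4 * w - 0.7 * u + 0.59 * v)
  atoms <- data.frame(type = "ATOM", elety = c("N", "CA", "C", "O", "CB"),
                      resid = resid, chain = chain_id, resno = resno,
                      elesy = c("N", "C", "C", "O", "C"),
                      stringsAsFactors = FALSE)
  list(atoms = atoms, coords = rbind(N, CA, C, O, cb_pos))
}

#' Generate a pseudo-C2 toy complex with known ground truth
#'
#' Builds a kinked Ile/Ser peptide helix, places a Leu "pocket"
#' residue 3.8 Angstrom outside each anchor's CB, completes receptor
#' domain A (30 residues, chain "R", numbered 1-30) with a spectator
#' Ser helix, and creates domain B (numbered 101-130) as the exact
#' image of domain A under a screw transform: rotation of
#' `180 + c2_twist` degrees about the fitted peptide helix axis plus a
#' translation along it. Pocket residues for anchors in the C-terminal
#' half of the peptide are pre-imaged through the screw transform so
#' that, after the transform, they line the C-half anchors. The
#' construction makes every downstream quantity exactly known:
#' the interdomain rotation is `180 + c2_twist` about the peptide
#' axis, so the pseudo-C2 deviation equals `c2_twist`; anchors are
#' recovered at `anchor_positions`. Gaussian coordinate noise of sd
#' `noise_sigma` is added independently per model.
#'
#' @param params a [toy_complex_params()] object.
#' @return an `"ensemble"` (chains "P" peptide, "R" receptor) with a
#'   `ground_truth` attribute (peptide axis, domain-B transform,
#'   twist, anchor positions).
#' @export
make_toy_complex <- function(params = toy_complex_params()) {
  stopifnot(inherits(params, "toy_complex_params"))
  L <- params$peptide_length
  seq1 <- rep("S", L)
  seq1[params$anchor_positions] <- "I"
  pep <- build_kinked_helix(paste(seq1, collapse = ""),
                            split_index = params$kink_position,
                            bend = params$kink_angle,
                            chain_id = "P", id = "toy_peptide")
  pco <- model_coords(pep, 1L)
  pat <- pep$atoms
  axis <- fit_helix_axis(pco[pat$elety == "CA", , drop = FALSE])
  a <- axis$direction
  cpt <- axis$centroid
  ca_all <- pco[pat$elety == "CA", , drop = FALSE]
  z <- as.numeric(sweep(ca_all, 2L, cpt) %*% a)
  shift <- (max(z) - min(z)) / 2
  R_b <- rotation_matrix(a, 180 + params$c2_twist)
  t_b <- rigid_transform(R_b, as.numeric(cpt - R_b %*% cpt) + shift * a)
  t_b_inv <- invert_transform(t_b)

  # pocket residues: one Leu per anchor, CB 3.8 A outside the anchor CB
  pockets <- list()
  outward_sum <- c(0, 0, 0)
  for (k in seq_along(params$anchor_positions)) {
    p <- params$anchor_positions[k]
    ca_p <- pco[pat$elety == "CA" & pat$resno == p, ]
    cb_p <- pco[pat$elety == "CB" & pat$resno == p, ]
    u <- (cb_p - ca_p) / sqrt(sum((cb_p - ca_p)^2))
    target <- cb_p + 3.8 * u
    if (p <= params$kink_position) {
      pos <- target
      dir <- u
      outward_sum <- outward_sum + u
    } else {
      pos <- as.numeric(apply_transform(t_b_inv, matrix(target, 1L)))
      dir <- as.numeric(t(R_b) %*% u)
    }
    pockets[[k]] <- pocket_residue(pos, dir, resno = k, chain_id = "R",
                                   resid = "LEU")
  }
  n_pocket <- length(pockets)
  n_filler <- 30L - n_pocket
  # spectator helix completing domain A, placed well away from the peptide
  w0 <- if (sum(outward_sum^2) > 1e-9) {
    o <- -outward_sum
    o <- o - sum(o * a) * a
    o / sqrt(sum(o^2))
  } else {
    ref <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * ref[3] - a[3] * ref[2],
           a[3] * ref[1] - a[1] * ref[3],
           a[1] * ref[2] - a[2] * ref[1])
    v / sqrt(sum(v^2))
  }
  filler <- build_ideal_helix(paste(rep("S", n_filler), collapse = ""),
                              chain_id = "R", start_resno = n_pocket + 1L,
                              id = "filler")
  fco <- model_coords(filler, 1L)
  fco <- sweep(fco, 2L, colMeans(fco))
  fco <- sweep(fco, 2L, cpt + 16 * w0, "+")

  dom_a_atoms <- rbind(do.call(rbind, lapply(pockets, `[[`, "atoms")),
                       filler$atoms)
  dom_a_coords <- rbind(do.call(rbind, lapply(pockets, `[[`, "coords")),
                        fco)
  dom_b_atoms <- dom_a_atoms
  dom_b_atoms$resno <- dom_b_atoms$resno + 100L
  dom_b_coords <- apply_transform(t_b, dom_a_coords)

  atoms <- rbind(pat, dom_a_atoms, dom_b_atoms)
  base <- rbind(pco, dom_a_coords, dom_b_coords)
  base_v <- as.vector(t(base))
  set.seed(params$seed)
  xyz <- matrix(0, nrow = params$n_models, ncol = length(base_v))
  for (m in seq_len(params$n_models)) {
    xyz[m, ] <- base_v + stats::rnorm(length(base_v), 0,
                                      params$noise_sigma)
  }
  ens <- structure_ensemble(atoms, xyz, id = "toy_complex")
  attr(ens, "ground_truth") <- list(
    peptide_axis = axis, transform_b = t_b, c2_twist = params$c2_twist,
    anchor_positions = params$anchor_positions, params = params)
  ens
}

#' Simulate free/bound amide shift tables with seeded hotspots
#'
#' Free-state shifts are drawn uniformly from typical amide ranges
#' (HN 7.5-9.5 ppm, N 105-130 ppm). Bound shifts add Gaussian noise of
#' sd `background_sd` (HN) and `5 * background_sd` (N) everywhere,
#' plus offsets of fixed magnitude `hotspot_scale * background_sd`
#' (HN; five-fold that in N) and random sign inside the hotspot
#' ranges. Deterministic for a given seed; the RNG stream order is
#' free-HN, free-N, residue names, bound-HN noise, bound-N noise,
#' hotspot signs.
#'
#' @param n_residues protein length.
#' @param hotspot_ranges list of inclusive residue ranges
#'   `c(start, end)`.
#' @param hotspot_scale hotspot offset in background-sd units.
#' @param background_sd sd of the HN background perturbation, ppm.
#' @param seed integer RNG seed.
#' @return list with `"shift_table"` elements `free` and `bound`.
#' @export
simulate_shift_tables <- function(n_residues = 148L,
                                  hotspot_ranges = list(c(19L, 20L),
                                                        c(76L, 85L)),
                                  hotspot_scale = 6,
                                  background_sd = 0.02,
                                  seed = 1L) {
  for (r in hotspot_ranges) {
    if (r[1L] < 1L || r[2L] > n_residues || r[1L] > r[2L]) {
      stop("hotspot range out of 1..n_residues")
    }
  }
  set.seed(seed)
  resno <- seq_len(n_residues)
  free_hn <- stats::runif(n_residues, 7.5, 9.5)
  free_n <- stats::runif(n_residues, 105, 130)
  resid <- sample(unname(AA1TO3), n_residues, replace = TRUE)
  bound_hn <- free_hn + stats::rnorm(n_residues, 0, background_sd)
  bound_n <- free_n + stats::rnorm(n_residues, 0, 5 * background_sd)
  hot <- unique(unlist(lapply(hotspot_ranges,
                              function(r) seq(r[1L], r[2L]))))
  sign <- sample(c(-1, 1), length(hot), replace = TRUE)
  bound_hn[hot] <- bound_hn[hot] + sign * hotspot_scale * background_sd
  bound_n[hot] <- bound_n[hot] + sign * 5 * hotspot_scale * background_sd
  mk <- function(hn, nn, label) {
    out <- data.frame(resno = resno, resid = resid, delta_HN = hn,
                      delta_N = nn, stringsAsFactors = FALSE)
    attr(out, "label") <- label
    class(out) <- c("shift_table", "data.frame")
    out
  }
  list(free = mk(free_hn, free_n, "free"),
       bound = mk(bound_hn, bound_n, "bound"))
}

#' Simulate a two-state CD spectrum from helix/coil basis curves
#'
#' Simple Gaussian-band basis spectra: the helix basis has negative
#' bands at 208 and 222 nm (amplitude `-11.1` at 222 nm per residue),
#' the coil basis a weak negative shoulder (`-0.3` at 222 nm). The
#' returned spectrum is `f * helix + (1 - f) * coil`.
#'
#' @param helix_fraction mixing fraction in `[0, 1]`.
#' @param wavelengths grid, nm.
#' @return a `"cd_spectrum"`.
#' @export
simulate_cd_spectrum <- function(helix_fraction,
                                 wavelengths = seq(190, 250, by = 0.5)) {
  if (helix_fraction < 0 || helix_fraction > 1) {
    stop("helix_fraction must be in [0, 1]")
  }
  shape_at <- function(w) {
    cbind(exp(-((w - 222)^2) / (2 * 9^2)),
          exp(-((w - 208)^2) / (2 * 6^2)),
          exp(-((w - 192)^2) / (2 * 5^2)),
          exp(-((w - 198)^2) / (2 * 6^2)))
  }
  S <- shape_at(wavelengths)
  s222 <- shape_at(222)
  helix_amp <- c(-11.1, -10.5, 25, 0)
  coil_amp <- c(-0.3, 0, 0, -4.5)
  # rescale so the basis values at 222 nm are exactly the two-state
  # reference coefficients (-11.1 and -0.3 per residue)
  helix <- as.numeric(S %*% helix_amp) * (-11.1 / sum(s222 * helix_amp))
  coil <- as.numeric(S %*% coil_amp) * (-0.3 / sum(s222 * coil_amp))
  cd_spectrum(wavelengths,
              helix_fraction * helix + (1 - helix_fraction) * coil)
}
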