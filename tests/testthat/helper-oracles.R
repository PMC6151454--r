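# Independent oracles and hand-built fixtures shared across test files.

# Brute-force RMSD minimisation over rotation space: quaternion grid
# followed by local Nelder-Mead refinement. Independent of the SVD path.
oracle_min_rmsd <- function(P, Q, n_grid = 400L) {
  Pc <- sweep(P, 2L, colMeans(P))
  Qc <- sweep(Q, 2L, colMeans(Q))
  quat_to_mat <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3L, 3L)
  }
  score <- function(R) sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  qs <- matrix(stats::rnorm(4L * n_grid), ncol = 4L)
  best_val <- Inf
  best_R <- diag(3)
  for (i in seq_len(n_grid)) {
    R <- quat_to_mat(qs[i, ])
    v <- score(R)
    if (v < best_val) {
      best_val <- v
      best_R <- R
    }
  }
  rotvec_mat <- function(p) {
    th <- sqrt(sum(p^2))
    if (th < 1e-12) return(diag(3))
    rotation_matrix(p / th, th * 180 / pi)
  }
  fn <- function(p) score(rotvec_mat(p) %*% best_R)
  opt <- stats::optim(c(0, 0, 0), fn, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000L))
  min(best_val, opt$value)
}

# O(N^2) residue-contact oracle: plain double loop over atom pairs.
oracle_contacts <- function(ensemble, group_a, group_b, cutoff,
                            model = 1L) {
  at <- ensemble$atoms
  co <- model_coords(ensemble, model)
  pick <- function(spec) {
    idx <- at$chain == spec$chain
    if (!spec$include_het) idx <- idx & at$type == "ATOM"
    if (!is.null(spec$range)) {
      idx <- idx & at$resno >= spec$range[1L] & at$resno <= spec$range[2L]
    }
    which(idx & !calmbind:::is_hydrogen(at$elety, at$elesy))
  }
  ia <- pick(group_a)
  ib <- pick(group_b)
  recs <- list()
  for (i in ia) {
    for (j in ib) {
      d <- sqrt(sum((co[i, ] - co[j, ])^2))
      if (d <= cutoff) {
        key <- paste(at$chain[i], at$resno[i], at$chain[j], at$resno[j])
        if (is.null(recs[[key]])) {
          recs[[key]] <- list(chain_a = at$chain[i], resno_a = at$resno[i],
                              chain_b = at$chain[j], resno_b = at$resno[j],
                              min_distance = d, n_atom_pairs = 1L)
        } else {
          recs[[key]]$min_distance <- min(recs[[key]]$min_distance, d)
          recs[[key]]$n_atom_pairs <- recs[[key]]$n_atom_pairs + 1L
        }
      }
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer(),
                      min_distance = numeric(), n_atom_pairs = integer()))
  }
  out <- do.call(rbind, lapply(recs, as.data.frame))
  out <- out[order(out$chain_a, out$resno_a, out$chain_b, out$resno_b), ]
  rownames(out) <- NULL
  out
}

# O(N^2) salt-bridge oracle.
oracle_salt_bridges <- function(ensemble, chain_a, chain_b, cutoff,
                                model = 1L) {
  at <- ensemble$atoms
  co <- model_coords(ensemble, model)
  n_atoms <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
  o_atoms <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))
  recs <- list()
  for (i in seq_len(nrow(at))) {
    if (!(at$chain[i] %in% c(chain_a, chain_b))) next
    tb <- n_atoms[[at$resid[i]]]
    if (is.null(tb) || !(at$elety[i] %in% tb)) next
    other <- setdiff(c(chain_a, chain_b), at$chain[i])
    for (j in seq_len(nrow(at))) {
      if (at$chain[j] != other) next
      ta <- o_atoms[[at$resid[j]]]
      if (is.null(ta) || !(at$elety[j] %in% ta)) next
      d <- sqrt(sum((co[i, ] - co[j, ])^2))
      if (d <= cutoff) {
        key <- paste(at$chain[i], at$resno[i], at$chain[j], at$resno[j])
        if (is.null(recs[[key]]) || d < recs[[key]]$min_NO_distance) {
          recs[[key]] <- list(basic_chain = at$chain[i],
                              basic_resno = at$resno[i],
                              acidic_chain = at$chain[j],
                              acidic_resno = at$resno[j],
                              min_NO_distance =
                                if (is.null(recs[[key]])) d
                                else min(d, recs[[key]]$min_NO_distance))
        }
      }
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(basic_chain = character(), basic_resno = integer(),
                      acidic_chain = character(), acidic_resno = integer(),
                      min_NO_distance = numeric()))
  }
  out <- do.call(rbind, lapply(recs, as.data.frame))
  out <- out[order(out$basic_chain, out$basic_resno, out$acidic_resno), ]
  rownames(out) <- NULL
  out
}

# Minimal hand-placed Arg/Glu pair with full charged side chains; the
# NH1-OE1 distance is `d` by construction.
make_arg_glu <- function(d) {
  arg <- rbind(N = c(0, 1.5, 0), CA = c(0, 0, 0), C = c(1.5, 0, 0),
               O = c(1.5, -1.2, 0), CB = c(-1, -1, 0), CG = c(-2, -2, 0),
               CD = c(-3, -3, 0), NE = c(-4, -3.5, 0), CZ = c(-5, -4, 0),
               NH1 = c(-6, -4.5, 0), NH2 = c(-5, -5.5, 0))
  glu <- rbind(N = c(0, 1.5, 0), CA = c(0, 0, 0), C = c(1.5, 0, 0),
               O = c(1.5, -1.2, 0), CB = c(-1, -1, 0), CG = c(-2, -2, 0),
               CD = c(-3, -3, 0), OE1 = c(-4, -3.5, 0),
               OE2 = c(-4.5, -4, 0))  # beyond OE1, so NH1-OE1 is minimal
  # place GLU so OE1 sits exactly d away from ARG NH1 along x
  shift <- arg["NH1", ] + c(-d, 0, 0) - glu["OE1", ]
  glu <- sweep(glu, 2L, shift, "+")
  atoms <- data.frame(
    type = "ATOM",
    elety = c(rownames(arg), rownames(glu)),
    resid = c(rep("ARG", nrow(arg)), rep("GLU", nrow(glu))),
    chain = c(rep("P", nrow(arg)), rep("A", nrow(glu))),
    resno = c(rep(392L, nrow(arg)), rep(47L, nrow(glu))),
    elesy = substr(c(rownames(arg), rownames(glu)), 1L, 1L),
    stringsAsFactors = FALSE)
  structure_ensemble(atoms, matrix(as.vector(t(rbind(arg, glu))),
                                   nrow = 1L), id = "arg_glu")
}

# Raw fixed-width PDB ATOM line, for hand-written parser fixtures.
pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     alt = " ", occ = 1, elem = substr(name, 1L, 1L)) {
  sprintf("ATOM  %5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4L, paste0(" ", name), name),
          alt, resn, chain, resno, x, y, z, occ, 0, elem)
}
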