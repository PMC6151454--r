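#' Domain specification
#' @param chain_id chain holding the domain.
#' @param range inclusive residue range `c(start, end)`, author numbering.
#' @param label `"N-domain"` or `"C-domain"`.
#' @export
domain_spec <- function(chain_id, range, label = c("N-domain", "C-domain")) {
  label <- match.arg(label)
  if (length(range) != 2L || range[1L] > range[2L]) {
    stop("range must be c(start, end) with start <= end")
  }
  structure(list(chain_id = chain_id, range = as.integer(range),
                 label = label), class = "domain_spec")
}

#' Interdomain rigid transform from a fixed residue correspondence
#'
#' Pairs residue `i` of the N-domain with residue `i + offset` of the
#' C-domain (the two CaM domains are internally homologous, so a fixed
#' sequence offset gives a deterministic correspondence) and returns
#' the least-squares rigid transform mapping the N-domain CA
#' coordinates onto the corresponding C-domain CAs.
#'
#' @param ensemble an `"ensemble"`.
#' @param n_spec,c_spec [domain_spec()] objects; ranges must be
#'   disjoint when on the same chain.
#' @param offset residue-number offset of the correspondence
#'   (default 73, pairing CaM 5-72 with 78-145).
#' @param model model index.
#' @return a [rigid_transform()] with attributes `rmsd`, `n_pairs`,
#'   and `pairs` (the correspondence table used).
#' @export
interdomain_transform <- function(ensemble, n_spec, c_spec, offset = 73L,
                                  model = 1L) {
  if (n_spec$chain_id == c_spec$chain_id &&
      n_spec$range[1L] <= c_spec$range[2L] &&
      c_spec$range[1L] <= n_spec$range[2L]) {
    stop("domain ranges overlap")
  }
  at <- ensemble$atoms
  ca_of <- function(spec) {
    idx <- at$chain == spec$chain_id & at$elety == "CA" &
      at$type == "ATOM" &
      at$resno >= spec$range[1L] & at$resno <= spec$range[2L]
    stats::setNames(which(idx), at$resno[idx])
  }
  n_ca <- ca_of(n_spec)
  c_ca <- ca_of(c_spec)
  i_n <- as.integer(names(n_ca))
  want_c <- i_n + offset
  have <- want_c %in% as.integer(names(c_ca))
  missing_pairs <- i_n[!have]
  if (sum(have) < 10L) {
    stop("fewer than 10 paired CA atoms (missing N-domain residues: ",
         paste(missing_pairs, collapse = ","), ")")
  }
  co <- model_coords(ensemble, model)
  P <- co[n_ca[have], , drop = FALSE]
  Q <- co[c_ca[as.character(want_c[have])], , drop = FALSE]
  fit <- superpose(P, Q)
  tr <- fit$transform
  attr(tr, "rmsd") <- fit$rmsd
  attr(tr, "n_pairs") <- fit$n_atoms
  attr(tr, "pairs") <- data.frame(n_resno = i_n[have],
                                  c_resno = want_c[have])
  tr
}

#' Deviation of an interdomain transform from ideal C2 symmetry
#'
#' Factors an ideal two-fold rotation about the peptide helix axis out
#' of the interdomain transform: `c2_deviation` is the rotation angle
#' of `R_t R_ideal^T`, i.e. the additional rotation (beyond 180 degrees
#' about the peptide axis) needed to superpose one domain onto the
#' other. Also reports the screw decomposition of the transform, the
#' tilt of its screw axis relative to the peptide axis (folded into
#' `[0, 90]` degrees), and the simpler alternative metric
#' `|screw angle - 180|`.
#'
#' @param t interdomain [rigid_transform()].
#' @param peptide_axis a `"helix_axis"` for the bound peptide.
#' @return `"symmetry_report"`: `interdomain` (screw), `axis_tilt`,
#'   `c2_deviation`, `screw_angle_deviation` (all degrees).
#' @export
c2_deviation <- function(t, peptide_axis) {
  R_ideal <- rotation_matrix(peptide_axis$direction, 180)
  dev <- rotation_angle(t$rotation %*% t(R_ideal))
  s <- screw_decompose(t)
  tilt <- angle_between(s$axis, peptide_axis$direction)
  if (tilt > 90) tilt <- 180 - tilt
  structure(list(interdomain = s, axis_tilt = tilt,
                 c2_deviation = dev,
                 screw_angle_deviation = abs(s$angle - 180)),
            class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat(sprintf(paste0("<symmetry_report: screw angle %.2f deg, ",
                     "C2 deviation %.2f deg, axis tilt %.2f deg>\n"),
              x$interdomain$angle, x$c2_deviation, x$axis_tilt))
  invisible(x)
}

#' Per-model C2 deviation over an ensemble
#'
#' @inheritParams interdomain_transform
#' @param peptide_chain chain of the bound peptide.
#' @param peptide_range residue range used for the peptide axis fit.
#' @return list with `mean`, `sd` and `per_model` C2 deviations
#'   (degrees); the peptide axis is refit on each model.
#' @export
c2_deviation_ensemble <- function(ensemble, n_spec, c_spec,
                                  peptide_chain, peptide_range,
                                  offset = 73L) {
  per <- vapply(seq_len(n_models(ensemble)), function(i) {
    tr <- interdomain_transform(ensemble, n_spec, c_spec, offset, model = i)
    ax <- fit_helix_axis(chain_ca(ensemble, peptide_chain, peptide_range, i))
    c2_deviation(tr, ax)$c2_deviation
  }, numeric(1L))
  list(mean = mean(per), sd = if (length(per) > 1L) stats::sd(per) else 0,
       per_model = per)
}
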