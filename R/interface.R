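HYDROPHOBIC_SET <- c("ILE", "LEU", "VAL", "PHE", "MET", "TRP", "TYR", "ALA")
BASIC_N_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
ACIDIC_O_ATOMS <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

group_index <- function(ensemble, spec) {
  at <- ensemble$atoms
  idx <- at$chain == spec$chain
  if (!spec$include_het) idx <- idx & at$type == "ATOM"
  if (!is.null(spec$range)) {
    idx <- idx & at$resno >= spec$range[1L] & at$resno <= spec$range[2L]
  }
  idx & !is_hydrogen(at$elety, at$elesy)
}

pairwise_dist <- function(A, B) {
  # |a - b| for all rows of A x rows of B
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Intermolecular heavy-atom residue contacts
#'
#' One record per residue pair with at least one heavy-atom pair within
#' `cutoff` Angstrom (a standard distance proxy for NOE-observable
#' contacts), sorted by the first group's residue then the second's.
#'
#' @param ensemble an `"ensemble"`.
#' @param group_a,group_b non-overlapping [selection_spec()]s
#'   (hydrogens are excluded regardless of the spec's `atoms` field).
#' @param cutoff heavy-atom distance cutoff, Angstrom.
#' @param model model index.
#' @return data.frame of class `"contact_table"`: `chain_a`, `resno_a`,
#'   `resid_a`, `chain_b`, `resno_b`, `resid_b`, `min_distance`,
#'   `n_atom_pairs`.
#' @export
heavy_atom_contacts <- function(ensemble, group_a, group_b, cutoff = 4.5,
                                model = 1L) {
  at <- ensemble$atoms
  ia <- group_index(ensemble, group_a)
  ib <- group_index(ensemble, group_b)
  if (any(ia & ib)) stop("groups overlap")
  if (!any(ia) || !any(ib)) stop("empty selection")
  co <- model_coords(ensemble, model)
  D <- pairwise_dist(co[ia, , drop = FALSE], co[ib, , drop = FALSE])
  hit <- which(D <= cutoff, arr.ind = TRUE)
  empty <- data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), chain_b = character(),
                      resno_b = integer(), resid_b = character(),
                      min_distance = numeric(), n_atom_pairs = integer())
  if (nrow(hit) == 0L) {
    class(empty) <- c("contact_table", "data.frame")
    return(empty)
  }
  wa <- which(ia)[hit[, 1L]]
  wb <- which(ib)[hit[, 2L]]
  key <- paste(at$chain[wa], at$resno[wa], at$chain[wb], at$resno[wb],
               sep = "|")
  d <- D[hit]
  agg_min <- tapply(d, key, min)
  agg_n <- tapply(d, key, length)
  first <- !duplicated(key)
  out <- data.frame(chain_a = at$chain[wa][first],
                    resno_a = at$resno[wa][first],
                    resid_a = at$resid[wa][first],
                    chain_b = at$chain[wb][first],
                    resno_b = at$resno[wb][first],
                    resid_b = at$resid[wb][first],
                    min_distance = as.numeric(agg_min[key[first]]),
                    n_atom_pairs = as.integer(agg_n[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain_a, out$resno_a, out$chain_b, out$resno_b), ]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Intermolecular salt bridges
#'
#' Arg/Lys side-chain nitrogen (NE, NH1, NH2, NZ) to Glu/Asp side-chain
#' oxygen (OE1, OE2, OD1, OD2) pairs across two chains with minimum N-O
#' distance at or below `cutoff`, deduplicated per residue pair.
#' Symmetric in chain order: bridges are searched in both directions.
#'
#' @param ensemble an `"ensemble"`.
#' @param chain_a,chain_b distinct chain ids.
#' @param cutoff N-O distance cutoff, Angstrom (default 4.0).
#' @param model model index.
#' @return data.frame of class `"salt_bridges"`: `basic_chain`,
#'   `basic_resno`, `basic_resid`, `acidic_chain`, `acidic_resno`,
#'   `acidic_resid`, `min_NO_distance`.
#' @export
find_salt_bridges <- function(ensemble, chain_a, chain_b, cutoff = 4.0,
                              model = 1L) {
  if (identical(chain_a, chain_b)) stop("chains must be distinct")
  at <- ensemble$atoms
  co <- model_coords(ensemble, model)
  side <- function(chain, table) {
    idx <- at$chain == chain & at$type == "ATOM" &
      ((at$resid == names(table)[1L] & at$elety %in% table[[1L]]) |
         (at$resid == names(table)[2L] & at$elety %in% table[[2L]]))
    which(idx)
  }
  rows <- list()
  for (chains in list(c(chain_a, chain_b), c(chain_b, chain_a))) {
    bi <- side(chains[1L], BASIC_N_ATOMS)
    ai <- side(chains[2L], ACIDIC_O_ATOMS)
    if (length(bi) == 0L || length(ai) == 0L) next
    D <- pairwise_dist(co[bi, , drop = FALSE], co[ai, , drop = FALSE])
    hit <- which(D <= cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    wb <- bi[hit[, 1L]]
    wa <- ai[hit[, 2L]]
    key <- paste(at$resno[wb], at$resno[wa], sep = "|")
    d <- D[hit]
    first <- !duplicated(key)
    agg <- tapply(d, key, min)
    rows[[length(rows) + 1L]] <- data.frame(
      basic_chain = at$chain[wb][first], basic_resno = at$resno[wb][first],
      basic_resid = at$resid[wb][first],
      acidic_chain = at$chain[wa][first],
      acidic_resno = at$resno[wa][first],
      acidic_resid = at$resid[wa][first],
      min_NO_distance = as.numeric(agg[key[first]]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0L) {
    data.frame(basic_chain = character(), basic_resno = integer(),
               basic_resid = character(), acidic_chain = character(),
               acidic_resno = integer(), acidic_resid = character(),
               min_NO_distance = numeric())
  } else do.call(rbind, rows)
  out <- out[order(out$basic_chain, out$basic_resno, out$acidic_resno), ]
  rownames(out) <- NULL
  class(out) <- c("salt_bridges", "data.frame")
  out
}

side_chain_heavy <- function(at) {
  !(at$elety %in% c(BACKBONE_ATOMS, "OXT")) & !is_hydrogen(at$elety, at$elesy)
}

#' Identify hydrophobic anchor residues of a bound peptide
#'
#' A peptide residue from the hydrophobic set (Ile, Leu, Val, Phe, Met,
#' Trp, Tyr, Ala) is an anchor when at least one of its side-chain
#' heavy atoms lies within `cutoff` of a side-chain heavy atom of a
#' hydrophobic receptor residue. `contact_count` is the number of
#' distinct receptor residues contacted; anchors with
#' `contact_count >= major_threshold` rank `"major"`, others
#' `"minor"`. `buried_domain` reports which receptor domain owns the
#' contacted residues.
#'
#' @param ensemble an `"ensemble"`.
#' @param peptide_spec [selection_spec()] for the peptide.
#' @param n_domain,c_domain [domain_spec()]s for the receptor domains.
#' @param cutoff side-chain heavy-atom cutoff, Angstrom.
#' @param major_threshold receptor-residue count for `"major"` rank.
#' @param model model index.
#' @return data.frame of class `"anchor_set"`: `chain`, `resno`,
#'   `resid`, `contact_count`, `buried_domain`, `rank`.
#' @export
identify_anchors <- function(ensemble, peptide_spec, n_domain, c_domain,
                             cutoff = 4.5, major_threshold = 5L,
                             model = 1L) {
  at <- ensemble$atoms
  co <- model_coords(ensemble, model)
  pep <- group_index(ensemble, peptide_spec) & side_chain_heavy(at) &
    at$resid %in% HYDROPHOBIC_SET
  in_domain <- function(d) {
    at$chain == d$chain_id & at$resno >= d$range[1L] &
      at$resno <= d$range[2L] & at$type == "ATOM"
  }
  rec <- (in_domain(n_domain) | in_domain(c_domain)) &
    side_chain_heavy(at) & at$resid %in% HYDROPHOBIC_SET
  empty <- data.frame(chain = character(), resno = integer(),
                      resid = character(), contact_count = integer(),
                      buried_domain = character(), rank = character())
  if (!any(pep) || !any(rec)) {
    class(empty) <- c("anchor_set", "data.frame")
    return(empty)
  }
  D <- pairwise_dist(co[pep, , drop = FALSE], co[rec, , drop = FALSE])
  hit <- which(D <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    class(empty) <- c("anchor_set", "data.frame")
    return(empty)
  }
  wp <- which(pep)[hit[, 1L]]
  wr <- which(rec)[hit[, 2L]]
  pep_res <- at$resno[wp]
  rec_key <- paste(at$chain[wr], at$resno[wr])
  rec_in_n <- in_domain(n_domain)[wr]
  rows <- lapply(sort(unique(pep_res)), function(rn) {
    sel <- pep_res == rn
    n_rec <- length(unique(rec_key[sel]))
    dom <- unique(rec_in_n[sel])
    data.frame(chain = at$chain[wp][sel][1L], resno = rn,
               resid = at$resid[wp][sel][1L],
               contact_count = n_rec,
               buried_domain = if (length(dom) > 1L) "both"
                 else if (dom) "N-domain" else "C-domain",
               rank = if (n_rec >= major_threshold) "major" else "minor",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anchor_set", "data.frame")
  out
}

#' Anchor spacing pattern and binding-mode label
#'
#' Expresses anchor positions one-based relative to the first anchor
#' (so anchors at 396, 400, 410, 413 become 1-5-15-18) and labels the
#' binding mode `"1-K"` with K the last index. Orientation is
#' `"parallel"` when the first (lowest-numbered) anchor is buried in
#' the receptor N-domain (CaMKK-like) and `"antiparallel"` when buried
#' in the C-domain (M13-like).
#'
#' @param anchors an `"anchor_set"` data.frame (single chain).
#' @return `"anchor_pattern"`: `indices`, `mode_label`, `orientation`.
#' @export
spacing_pattern <- function(anchors) {
  if (nrow(anchors) < 1L) stop("need at least one anchor")
  if (length(unique(anchors$chain)) > 1L) {
    stop("anchors span multiple chains")
  }
  rn <- sort(anchors$resno)
  indices <- rn - rn[1L] + 1L
  first_dom <- anchors$buried_domain[which.min(anchors$resno)]
  orientation <- switch(first_dom,
                        "N-domain" = "parallel",
                        "C-domain" = "antiparallel",
                        "ambiguous")
  structure(list(indices = as.integer(indices),
                 mode_label = paste0("1-", indices[length(indices)]),
                 orientation = orientation),
            class = "anchor_pattern")
}

#' @export
print.anchor_pattern <- function(x, ...) {
  cat(sprintf("<anchor_pattern: %s, mode %s, %s>\n",
              paste(x$indices, collapse = "-"), x$mode_label,
              x$orientation))
  invisible(x)
}

#' Ensemble-consensus residue contacts
#'
#' Computes [heavy_atom_contacts()] on every model and keeps residue
#' pairs present in at least `min_fraction` of models (NMR ensembles
#' fluctuate); reports the across-model mean of the minimum distance
#' and the fraction of models supporting each pair.
#'
#' @inheritParams heavy_atom_contacts
#' @param min_fraction consensus threshold in `(0, 1]`.
#' @export
consensus_contacts <- function(ensemble, group_a, group_b, cutoff = 4.5,
                               min_fraction = 0.5) {
  m <- n_models(ensemble)
  all_tabs <- lapply(seq_len(m), function(i) {
    heavy_atom_contacts(ensemble, group_a, group_b, cutoff, model = i)
  })
  tab <- do.call(rbind, all_tabs)
  if (nrow(tab) == 0L) return(tab)
  key <- paste(tab$chain_a, tab$resno_a, tab$chain_b, tab$resno_b)
  cnt <- table(key)
  keep <- names(cnt)[cnt / m >= min_fraction]
  first <- !duplicated(key) & key %in% keep
  out <- tab[first, , drop = FALSE]
  out$min_distance <- as.numeric(tapply(tab$min_distance, key, mean)[
    key[first]])
  out$fraction_of_models <- as.numeric(cnt[key[first]] / m)
  rownames(out) <- NULL
  out
}
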