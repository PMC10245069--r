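# Structure handling: loading predicted complex models, 4 Angstrom
# inter-chain contact mapping, rigid superposition and hinge-angle /
# inward-outward conformation analysis.

new_structure <- function(atoms, source = NA_character_, offsets = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resid", "elety", "x", "y", "z") %in%
                  names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  structure(list(atoms = atoms, chains = unique(atoms$chain),
                 source = source, offsets = offsets),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", nrow(x$atoms), "heavy atoms;",
      length(x$chains), "chain(s):",
      paste(x$chains, collapse = ", "), "\n")
  invisible(x)
}

#' Load a structure model from PDB or mmCIF
#'
#' Reads all chains, drops hydrogens, and resolves alternate locations to
#' the highest-occupancy conformer per atom. Residue numbers may optionally
#' be shifted per chain to full-length sequence numbering (predicted models
#' often omit signal peptides or disordered termini).
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param offsets Optional named numeric vector: value added to the residue
#'   numbers of each named chain (e.g. `c(C = 21)` when residues 1-21 were
#'   excluded from the model).
#' @return A `StructureModel`.
#' @export
load_structure <- function(path, offsets = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path, rm.alt = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0) stop("no atoms in ", path)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- substr(gsub("[0-9'\"]", "", a$elety), 1, 1)
  keep <- toupper(trimws(elem)) != "H" & a$type %in% c("ATOM", "HETATM")
  a <- a[keep, , drop = FALSE]
  # altloc: keep the highest-occupancy conformer of each atom
  alt <- a$alt %||% rep("", nrow(a))
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(a$chain, a$resno, a$elety)
    occ <- a$o %||% rep(1, nrow(a))
    occ[is.na(occ)] <- 1
    ord <- order(key, -occ)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$elety)), , drop = FALSE]
  }
  if (!is.null(offsets)) {
    for (ch in names(offsets)) {
      sel <- a$chain == ch
      a$resno[sel] <- a$resno[sel] + offsets[[ch]]
    }
  }
  atoms <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                      elety = trimws(a$elety),
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  new_structure(atoms, source = path, offsets = offsets)
}

#' Write a structure model as PDB
#'
#' @param model A `StructureModel`.
#' @param path Output PDB file.
#' @return The path, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, chain = a$chain,
                   resid = a$resid, elety = a$elety,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

# --- contact mapping ------------------------------------------------------

# All inter-group atom pairs closer than `cutoff`, via a spatial grid
# (cell-list) so only atoms in neighbouring cells are compared. Exact:
# equals the all-pairs search (tests enforce this).
grid_close_pairs <- function(xyzA, xyzB, cutoff) {
  stopifnot(cutoff > 0)
  cellA <- floor(sweep(xyzA, 2, rep(cutoff, 3), "/"))
  cellB <- floor(sweep(xyzB, 2, rep(cutoff, 3), "/"))
  keyB <- paste(cellB[, 1], cellB[, 2], cellB[, 3])
  lookup <- split(seq_len(nrow(xyzB)), keyB)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  keyA <- paste(cellA[, 1], cellA[, 2], cellA[, 3])
  groupsA <- split(seq_len(nrow(xyzA)), keyA)
  ia_out <- integer(0); ib_out <- integer(0); d_out <- numeric(0)
  for (ia in groupsA) {
    c0 <- cellA[ia[1], ]
    neigh <- sweep(offs, 2, as.numeric(c0), "+")
    nk <- paste(neigh[, 1], neigh[, 2], neigh[, 3])
    ib <- unlist(lookup[nk], use.names = FALSE)
    if (is.null(ib) || length(ib) == 0) next
    d2 <- outer(rowSums(xyzA[ia, , drop = FALSE]^2),
                rowSums(xyzB[ib, , drop = FALSE]^2), "+") -
      2 * (xyzA[ia, , drop = FALSE] %*% t(xyzB[ib, , drop = FALSE]))
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      ia_out <- c(ia_out, ia[hit[, 1]])
      ib_out <- c(ib_out, ib[hit[, 2]])
      d_out <- c(d_out, sqrt(pmax(d2[hit], 0)))
    }
  }
  list(ia = ia_out, ib = ib_out, dist = d_out)
}

#' Inter-chain residue contacts at a distance cutoff
#'
#' A residue pair across the two chain groups is a contact if any
#' heavy-atom pair is strictly closer than `cutoff` (default 4 Angstrom,
#' the interface criterion used for predicted complexes). The grid-based
#' neighbour search is exact and equals the all-pairs computation.
#'
#' @param model A `StructureModel`.
#' @param groupA,groupB Disjoint, non-empty chain-id sets.
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @return A `ContactMap`: data.frame `chain_a`, `res_a`, `chain_b`,
#'   `res_b`, `min_dist`, with the cutoff and groups as attributes.
#' @export
interchain_contacts <- function(model, groupA, groupB, cutoff = 4.0) {
  stopifnot(inherits(model, "StructureModel"),
            length(groupA) > 0, length(groupB) > 0,
            length(intersect(groupA, groupB)) == 0)
  a <- model$atoms
  A <- a[a$chain %in% groupA, , drop = FALSE]
  B <- a[a$chain %in% groupB, , drop = FALSE]
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty chain group")
  pr <- grid_close_pairs(as.matrix(A[, c("x", "y", "z")]),
                         as.matrix(B[, c("x", "y", "z")]), cutoff)
  if (length(pr$ia) == 0) {
    cm <- data.frame(chain_a = character(0), res_a = integer(0),
                     chain_b = character(0), res_b = integer(0),
                     min_dist = numeric(0))
  } else {
    df <- data.frame(chain_a = A$chain[pr$ia], res_a = A$resno[pr$ia],
                     chain_b = B$chain[pr$ib], res_b = B$resno[pr$ib],
                     dist = pr$dist)
    key <- paste(df$chain_a, df$res_a, df$chain_b, df$res_b)
    agg <- tapply(df$dist, key, min)
    first <- df[!duplicated(key), c("chain_a", "res_a", "chain_b", "res_b")]
    first$min_dist <- as.numeric(agg[paste(first$chain_a, first$res_a,
                                           first$chain_b, first$res_b)])
    cm <- first[order(first$chain_a, first$res_a,
                      first$chain_b, first$res_b), ]
    rownames(cm) <- NULL
  }
  structure(cm, cutoff = cutoff, groupA = groupA, groupB = groupB,
            class = c("ContactMap", "data.frame"))
}

#' Interface footprint on one side of a contact map
#'
#' @param contacts A `ContactMap`.
#' @param side Chain set matching one of the map's groups (`"A"` side or
#'   `"B"` side).
#' @return Sorted data.frame `chain`, `resno` of unique residues in at
#'   least one contact on that side.
#' @export
footprint <- function(contacts, side) {
  stopifnot(inherits(contacts, "ContactMap"))
  ga <- attr(contacts, "groupA"); gb <- attr(contacts, "groupB")
  if (setequal(side, ga)) {
    df <- unique(data.frame(chain = contacts$chain_a, resno = contacts$res_a))
  } else if (setequal(side, gb)) {
    df <- unique(data.frame(chain = contacts$chain_b, resno = contacts$res_b))
  } else stop("side does not match either chain group of the contact map")
  df[order(df$chain, df$resno), , drop = FALSE]
}

#' Overlap between an interface footprint and DMS hits
#'
#' Residue numbering on both sides must be full-length (apply model
#' numbering offsets when loading); disjoint ranges trigger a warning that
#' usually indicates a forgotten offset.
#'
#' @param fp Integer residue set (footprint, e.g. `footprint(...)$resno`).
#' @param hits Integer residue set (e.g. selected functional residues).
#' @return List with `n_fp`, `n_hits`, `n_overlap`, and membership vectors
#'   `overlap`, `fp_only`, `hits_only`.
#' @export
overlap_with_dms <- function(fp, hits) {
  fp <- sort(unique(as.integer(fp)))
  hits <- sort(unique(as.integer(hits)))
  if (length(fp) && length(hits) &&
      (max(fp) < min(hits) || max(hits) < min(fp)))
    warning("footprint and hit ranges are disjoint; check numbering offsets")
  list(n_fp = length(fp), n_hits = length(hits),
       n_overlap = length(intersect(fp, hits)),
       overlap = intersect(fp, hits),
       fp_only = setdiff(fp, hits), hits_only = setdiff(hits, fp))
}

#' Write a contact map as TSV
#'
#' @param contacts A `ContactMap`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_contacts_tsv <- function(contacts, path) {
  utils::write.table(as.data.frame(contacts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- rigid superposition and conformation metrics -------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' matched point sets, enforcing `det(R) = +1` (no reflection). The
#' rotation angle is `acos((trace(R) - 1) / 2)` in degrees.
#'
#' @param mobile,reference Numeric n x 3 matrices of matched points
#'   (n >= 3, non-degenerate).
#' @return A `RigidTransform`: list with `rotation` (3 x 3), `translation`
#'   (applied as `x %*% t(R) + t`), `rmsd` (Angstrom) and `rotation_angle`
#'   (degrees).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference), nrow(mobile) >= 3)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  sv <- svd(P)$d
  if (sum(sv > 1e-9 * max(sv, 1e-300)) < 2)
    stop("degenerate (colinear) point set")
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- cr - as.vector(R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 rotation_angle = ang),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param transform A `RigidTransform`.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

# C-alpha coordinates of a chain set, ordered by (chain, resno).
ca_coords <- function(model, chains) {
  a <- model$atoms
  ca <- a[a$chain %in% chains & a$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$chain, ca$resno), , drop = FALSE]
  as.matrix(ca[, c("x", "y", "z")])
}

#' Hinge angles and inward/outward ranking across complex models
#'
#' For a set of models of a carrier protein bound to a ring (e.g. one MlaC
#' on an MlaD hexamer): (a) superposes every model onto the first via ring
#' C-alpha atoms; (b) computes pairwise carrier rotation angles (the
#' rotation mapping one model's carrier C-alphas onto another's after ring
#' superposition) — the spread of these angles is the hinge flexibility of
#' the interface; (c) scores each model by the distance of the carrier
#' centroid to the ring symmetry axis (the principal axis of the ring
#' C-alphas with the smallest coordinate variance, i.e. the ring normal,
#' through the ring centroid). The minimum-score model is labelled
#' `"inward"` (carrier closest to the central pore axis) and the maximum
#' `"outward"`.
#'
#' @param models List of `StructureModel`s with identical ring and carrier
#'   chain composition.
#' @param ring_chains Chain ids of the ring.
#' @param carrier_chain Chain id of the carrier.
#' @param ring_rmsd_warn Warn if any ring superposition RMSD exceeds this
#'   (default 5 Angstrom).
#' @return List with `pairwise_angles` (matrix, degrees), `max_angle`,
#'   `axis_distance` (per model, Angstrom), `ring_rmsd`, and `labels`
#'   (`"inward"` / `"outward"` / `""`).
#' @export
conformation_metrics <- function(models, ring_chains, carrier_chain,
                                 ring_rmsd_warn = 5) {
  stopifnot(length(models) >= 1)
  n <- length(models)
  ref_ring <- ca_coords(models[[1]], ring_chains)
  carriers <- vector("list", n)
  ring_rmsd <- numeric(n)
  axis_distance <- numeric(n)
  for (i in seq_len(n)) {
    ring_i <- ca_coords(models[[i]], ring_chains)
    car_i <- ca_coords(models[[i]], carrier_chain)
    if (nrow(car_i) == 0) stop("missing carrier chain in model ", i)
    if (nrow(ring_i) != nrow(ref_ring))
      stop("ring C-alpha count mismatch in model ", i)
    tr <- superpose(ring_i, ref_ring)
    ring_rmsd[i] <- tr$rmsd
    if (tr$rmsd > ring_rmsd_warn)
      warning("ring superposition rmsd ", round(tr$rmsd, 2),
              " A in model ", i)
    ring_al <- apply_transform(ring_i, tr)
    carriers[[i]] <- apply_transform(car_i, tr)
    # ring symmetry axis: eigenvector of the ring CA covariance with the
    # smallest eigenvalue (normal of the ring plane), through the centroid
    ctr <- colMeans(ring_al)
    ev <- eigen(stats::cov(ring_al), symmetric = TRUE)
    axis <- ev$vectors[, 3]
    v <- colMeans(carriers[[i]]) - ctr
    axis_distance[i] <- sqrt(sum(v^2) - sum(v * axis)^2)
  }
  ang <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (nrow(carriers[[i]]) != nrow(carriers[[j]]))
        stop("carrier C-alpha count mismatch between models ", i, " and ", j)
      ang[i, j] <- ang[j, i] <-
        superpose(carriers[[i]], carriers[[j]])$rotation_angle
    }
  }
  labels <- rep("", n)
  if (n > 1) {
    labels[which.min(axis_distance)] <- "inward"
    labels[which.max(axis_distance)] <- "outward"
  }
  list(pairwise_angles = ang, max_angle = max(ang),
       axis_distance = axis_distance, ring_rmsd = ring_rmsd,
       labels = labels)
}

#' Read a one-column residue list
#'
#' @param path Text file with one residue number per line (comments with
#'   `#` allowed).
#' @return Integer vector.
#' @export
read_residue_list <- function(path) {
  x <- utils::read.table(path, comment.char = "#")[, 1]
  sort(unique(as.integer(x)))
}
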