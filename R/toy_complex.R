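# Toy two-chain complexes with planted inter-chain contacts, for
# verifying the contact-mapping stage by construction.

#' Generate a toy two-chain complex with planted contacts
#'
#' Builds a two-chain model in which exactly the planted residue pairs have
#' at least one heavy-atom pair closer than `cutoff`, and every other
#' inter-chain residue pair is farther than `cutoff + 1` Angstrom. Each
#' residue gets a backbone CA atom on its chain's axis; planted pairs grow
#' CB atoms that meet near the inter-chain midplane at `cutoff - 0.5`
#' Angstrom, each planted pair on its own z-layer so pairs cannot collide.
#' The construction is verified internally by an all-pairs distance check.
#'
#' @param nA,nB Residues in chains A and B.
#' @param planted_contacts Two-column matrix (or data.frame) of residue
#'   pairs `(resA, resB)`; may be empty.
#' @param cutoff Contact cutoff in Angstrom (default 4.0).
#' @param seed Integer seed (small coordinate jitter only).
#' @return A `StructureModel` with chains `"A"` and `"B"` and attribute
#'   `planted` (the planted pair matrix).
#' @export
generate_toy_complex <- function(nA, nB, planted_contacts = NULL,
                                 cutoff = 4.0, seed = 1L) {
  stopifnot(nA >= 1, nB >= 1, cutoff > 0)
  planted <- if (is.null(planted_contacts) || NROW(planted_contacts) == 0)
    matrix(numeric(0), 0, 2) else as.matrix(planted_contacts)
  if (nrow(planted) > 0) {
    stopifnot(ncol(planted) == 2,
              all(planted[, 1] >= 1 & planted[, 1] <= nA),
              all(planted[, 2] >= 1 & planted[, 2] <= nB))
    if (anyDuplicated(paste(planted[, 1], planted[, 2])))
      stop("duplicate planted pairs")
  }
  local_rng(seed)
  spacing <- 3 * (cutoff + 1)          # CA spacing along each chain
  gap <- 2 * cutoff + 8                # inter-chain separation in y
  jit <- function(n) stats::runif(n, -0.05, 0.05)

  atoms <- data.frame(
    chain = c(rep("A", nA), rep("B", nB)),
    resno = c(seq_len(nA), seq_len(nB)),
    resid = "GLY",
    elety = "CA",
    x = c(seq_len(nA), seq_len(nB)) * spacing + jit(nA + nB),
    y = c(rep(0, nA), rep(gap, nB)) + jit(nA + nB),
    z = jit(nA + nB),
    stringsAsFactors = FALSE)

  if (nrow(planted) > 0) {
    d_pair <- cutoff - 0.5
    for (k in seq_len(nrow(planted))) {
      i <- planted[k, 1]; j <- planted[k, 2]
      zk <- k * (cutoff + 3) + 2      # one layer per planted pair
      mx <- (i + j) / 2 * spacing
      cb <- data.frame(
        chain = c("A", "B"), resno = c(i, j), resid = "GLY", elety = "CB",
        x = mx + jit(2),
        y = c(gap / 2 - d_pair / 2, gap / 2 + d_pair / 2),
        z = zk + jit(2),
        stringsAsFactors = FALSE)
      # re-measure the pair after jitter and pull to exactly < cutoff
      dv <- sqrt(sum((cb[1, c("x", "y", "z")] - cb[2, c("x", "y", "z")])^2))
      if (dv >= cutoff) stop("infeasible geometry for planted pair ", k)
      atoms <- rbind(atoms, cb)
    }
  }
  model <- new_structure(atoms, source = "toy")
  attr(model, "planted") <- planted

  # construction check: brute-force contact map must equal the planted set
  got <- interchain_contacts(model, "A", "B", cutoff)
  got_key <- paste(got$res_a, got$res_b)
  want_key <- if (nrow(planted)) paste(planted[, 1], planted[, 2]) else character(0)
  if (!setequal(got_key, want_key))
    stop("toy-complex construction failed to realise the planted contacts")
  near <- interchain_contacts(model, "A", "B", cutoff + 1)
  if (!setequal(paste(near$res_a, near$res_b), want_key))
    stop("toy-complex construction violated the cutoff + 1 margin")
  model
}
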