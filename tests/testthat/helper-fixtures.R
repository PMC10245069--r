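# Shared fixtures and independent oracles.

# Tiny stop-free CDS fixtures built from explicit codons.
tiny_cds <- function() paste0("ATG", "GCT")          # M A  (L = 2)
small_cds <- function(L, seed = 42L) mlascan::random_cds(L, seed = seed)

# A 3-position x 21-symbol landscape with all mutation cells 0 except six
# cells at -3 in position 2 (wild type "MAG").
toy_selection_landscape <- function() {
  wt_aa <- c(`1` = "M", `2` = "A", `3` = "G")
  d <- matrix(0, 3, 21, dimnames = list(1:3, mlascan::aa_alphabet()))
  six <- setdiff(mlascan::aa_alphabet(), "A")[1:6]
  d[2, six] <- -3
  mlascan:::new_landscape(d, wt_aa = wt_aa)
}

# Frequency table built directly from a cpm matrix (bypasses counting).
make_freq <- function(cpm, wt_cpm, wt_aa, ...) {
  mlascan:::new_frequency_table(cpm = cpm, wt_cpm = wt_cpm, wt_aa = wt_aa, ...)
}

# Brute-force O(n^2) contact oracle over all inter-group atom pairs.
brute_contacts <- function(model, groupA, groupB, cutoff) {
  a <- model$atoms
  A <- a[a$chain %in% groupA, ]
  B <- a[a$chain %in% groupB, ]
  d <- outer(rowSums(A[, c("x", "y", "z")]^2),
             rowSums(B[, c("x", "y", "z")]^2), "+") -
    2 * as.matrix(A[, c("x", "y", "z")]) %*% t(as.matrix(B[, c("x", "y", "z")]))
  hit <- which(d < cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(character(0))
  unique(paste(A$chain[hit[, 1]], A$resno[hit[, 1]],
               B$chain[hit[, 2]], B$resno[hit[, 2]]))
}

contact_keys <- function(cm) {
  if (nrow(cm) == 0) return(character(0))
  paste(cm$chain_a, cm$res_a, cm$chain_b, cm$res_b)
}

# Rotation matrix about an axis by an angle (degrees).
rotation_about <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Toy hexameric ring + carrier models for conformation metrics: ring of
# 6 x n_per "chains" D1..D6 in the z = 0 plane, carrier chain C placed at a
# given radial distance, optionally rotated about a hinge.
make_ring_model <- function(carrier_radius, n_per = 8, carrier_z = 10,
                            rotate_carrier_deg = 0, seed = 1L) {
  set.seed(seed)
  atoms <- do.call(rbind, lapply(1:6, function(k) {
    phi <- 2 * pi * (k - 1) / 6
    th <- seq(0, 2 * pi, length.out = n_per + 1)[seq_len(n_per)]
    data.frame(chain = paste0("D", k), resno = seq_len(n_per), resid = "GLY",
               elety = "CA",
               x = 20 * cos(phi) + 3 * cos(th),
               y = 20 * sin(phi) + 3 * sin(th),
               z = 0.5 * sin(th), stringsAsFactors = FALSE)
  }))
  car <- data.frame(chain = "C", resno = 1:12, resid = "GLY", elety = "CA",
                    x = carrier_radius + rnorm(12, 0, 2),
                    y = rnorm(12, 0, 2),
                    z = carrier_z + rnorm(12, 0, 2),
                    stringsAsFactors = FALSE)
  if (rotate_carrier_deg != 0) {
    R <- rotation_about(c(0, 1, 0), rotate_carrier_deg)
    xyz <- as.matrix(car[, c("x", "y", "z")]) %*% t(R)
    car$x <- xyz[, 1]; car$y <- xyz[, 2]; car$z <- xyz[, 3]
  }
  mlascan:::new_structure(rbind(atoms, car))
}
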