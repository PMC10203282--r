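# Independent oracles and fixture builders shared across the suite.

# Horn (1987) closed-form quaternion superposition: an algorithm independent
# of the SVD route used by superpose().
horn_superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  n <- nrow(ref)
  P <- sweep(mov, 2, colMeans(mov))
  Q <- sweep(ref, 2, colMeans(ref))
  S <- crossprod(P, Q)                      # S[i, j] = sum p_i q_j
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],       S[3,1]-S[1,3],       S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],       S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  eig <- eigen(N, symmetric = TRUE)
  lambda <- eig$values[1]
  q <- eig$vectors[, 1]
  rmsd <- sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * lambda)) / n)
  angle <- 2 * acos(min(1, abs(q[1]))) * 180 / pi
  list(rmsd = rmsd, angle = angle)
}

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(
    1-2*(q[3]^2+q[4]^2), 2*(q[2]*q[3]-q[1]*q[4]), 2*(q[2]*q[4]+q[1]*q[3]),
    2*(q[2]*q[3]+q[1]*q[4]), 1-2*(q[2]^2+q[4]^2), 2*(q[3]*q[4]-q[1]*q[2]),
    2*(q[2]*q[4]-q[1]*q[3]), 2*(q[3]*q[4]+q[1]*q[2]), 1-2*(q[2]^2+q[3]^2)
  ), 3, 3, byrow = TRUE)
}

# Build a structure_model directly from Calpha coordinates.
make_ca_model <- function(coords, chain = "A", resid = seq_len(nrow(coords)),
                          id = "TEST", unobserved = NULL, atom = "CA",
                          element = "C") {
  atoms <- data.frame(chain = chain, resid = resid, resname = "ALA",
                      atom = atom, element = element, altloc = "",
                      occupancy = 1, x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], model = 1L, stringsAsFactors = FALSE)
  un <- if (is.null(unobserved)) metabolonr:::empty_unobs() else unobserved
  structure_model(id, atoms, un)
}

rigidly_move <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

# Handcrafted 3-residue mmCIF with residue 2 unobserved.
mini_cif <- function(with_unobs = TRUE) {
  txt <- c(
    "data_MINI", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 0.000 0.000 0.000 1.00 1",
    "ATOM 2 C CA . GLY A 3 3.000 4.000 0.000 1.00 1", "#")
  if (with_unobs) txt <- c(txt,
    "loop_", "_pdbx_unobs_or_zero_occ_residues.id",
    "_pdbx_unobs_or_zero_occ_residues.PDB_model_num",
    "_pdbx_unobs_or_zero_occ_residues.polymer_flag",
    "_pdbx_unobs_or_zero_occ_residues.occupancy_flag",
    "_pdbx_unobs_or_zero_occ_residues.auth_asym_id",
    "_pdbx_unobs_or_zero_occ_residues.auth_comp_id",
    "_pdbx_unobs_or_zero_occ_residues.auth_seq_id",
    "1 1 Y 1 A SER 2", "#")
  paste(txt, collapse = "\n")
}

# Model with two chains A and B from one coordinate block each.
make_two_chain_model <- function(coords_a, coords_b, id = "DIMER",
                                 chain_b = "B") {
  a <- make_ca_model(coords_a, chain = "A", id = id)$atoms
  b <- make_ca_model(coords_b, chain = chain_b, id = id)$atoms
  structure_model(id, rbind(a, b))
}

# Naive per-bin summary: independent of summarize_survey internals.
naive_bin_summary <- function(lengths, distances, edges) {
  lows <- c(0, edges[-length(edges)])
  out <- NULL
  for (i in seq_along(edges)) {
    d <- distances[lengths > lows[i] & lengths <= edges[i]]
    if (!length(d)) next
    d <- sort(d)
    qs <- sapply(seq(0, 1, 0.2), function(q) {
      h <- (length(d) - 1) * q
      lo <- floor(h)
      if (lo + 1 >= length(d)) d[length(d)]
      else d[lo + 1] + (h - lo) * (d[lo + 2] - d[lo + 1])
    })
    out <- rbind(out, c(i, length(d), mean(d), qs))
  }
  colnames(out) <- c("bin", "n", "mean", sprintf("q%.1f", seq(0, 1, 0.2)))
  out
}

# All-pairs contact oracle: plain double loop over heavy atoms.
contact_oracle <- function(receptor, pose, cutoff = 5) {
  ra <- receptor$atoms[!(toupper(receptor$atoms$element) %in% c("H", "D")), ]
  la <- pose$atoms[!(toupper(pose$atoms$element) %in% c("H", "D")), ]
  hits <- character()
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      d2 <- (ra$x[i]-la$x[j])^2 + (ra$y[i]-la$y[j])^2 + (ra$z[i]-la$z[j])^2
      if (d2 <= cutoff^2) {
        hits <- c(hits, paste(ra$chain[i], ra$resid[i], sep = ":"))
        break
      }
    }
  }
  sort(unique(hits))
}

# Dense grid-search oracle for the saturation model (offset fixed).
grid_fit_saturation <- function(x, y, A_grid, b_grid, offset = 3.5) {
  best <- c(NA, NA, Inf)
  for (b in b_grid) {
    g <- 1 - exp(-b * x)
    for (A in A_grid) {
      ss <- sum((y - A * g - offset)^2)
      if (ss < best[3]) best <- c(A, b, ss)
    }
  }
  list(A = best[1], b = best[2], ss = best[3])
}
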