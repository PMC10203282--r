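# Seeded generators for every input the pipeline consumes.  Each generator
# returns the artifact together with a ground-truth ledger so round-trip tests
# can compare pipeline output against known truth.  All randomness flows from
# the `seed` argument via set.seed(); fixed seed means byte-identical output.

aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a synthetic structure with excised internal segments
#'
#' Builds a Calpha trace as a 3.8 Angstrom-step random walk (not
#' self-avoiding; irrelevant to distance statistics), then moves chosen
#' internal segments into the unobserved category, emulating the unresolved
#' linker regions of deposited structures.  The ledger records each excised
#' region with its true flank-to-flank distance computed from the full-walk
#' coordinates, which the parse/extract/measure pipeline must reproduce.
#'
#' @param n_residues chain length (default 120).
#' @param n_gaps number of internal excised segments (default 2).
#' @param seed RNG seed.
#' @param gap_len_range inclusive range of segment lengths (default 2-8).
#' @param chain chain id (default "A").
#' @param step Calpha step length in Angstrom (default 3.8).
#' @return List: `text` (mmCIF), `model` ([structure_model]), `ledger`
#'   (data frame `chain`, `start`, `end`, `length`, `left_flank`,
#'   `right_flank`, `distance`), `seed`.
#' @export
gen_structure <- function(n_residues = 120, n_gaps = 2, seed = 1,
                          gap_len_range = c(2, 8), chain = "A", step = 3.8) {
  set.seed(seed)
  if (n_gaps > 0 &&
      n_gaps * gap_len_range[1] + n_gaps + 1 > n_residues)
    stop("infeasible gap layout: gaps plus separating observed residues exceed the chain")
  coords <- apply(rbind(c(0, 0, 0), step * random_unit_vectors(n_residues - 1)),
                  2, cumsum)
  # truth must describe the artifact as written: mmCIF carries 3 decimals
  coords <- round(coords, 3)
  resnames <- sample(aa3, n_residues, replace = TRUE)

  gap_res <- integer()
  regions <- NULL
  if (n_gaps > 0) {
    for (try in 1:2000) {
      len_choices <- seq(gap_len_range[1], gap_len_range[2])
      lens <- len_choices[sample.int(length(len_choices), n_gaps, replace = TRUE)]
      starts <- sort(sample(2:(n_residues - 1), n_gaps))
      ends <- starts + lens - 1L
      ok <- all(ends <= n_residues - 1L) &&
        (n_gaps == 1 || all(starts[-1] > ends[-n_gaps] + 1L))
      if (ok) break
      if (try == 2000) stop("infeasible gap layout: could not place gaps")
    }
    gap_res <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
    regions <- data.frame(
      chain = chain, start = as.integer(starts), end = as.integer(ends),
      length = as.integer(lens),
      left_flank = as.integer(starts - 1L), right_flank = as.integer(ends + 1L))
    regions$distance <- sqrt(rowSums(
      (coords[regions$left_flank, , drop = FALSE] -
       coords[regions$right_flank, , drop = FALSE])^2))
  } else {
    regions <- data.frame(chain = character(), start = integer(),
                          end = integer(), length = integer(),
                          left_flank = integer(), right_flank = integer(),
                          distance = numeric())
  }

  observed <- setdiff(seq_len(n_residues), gap_res)
  atoms <- data.frame(chain = chain, resid = observed,
                      resname = resnames[observed], atom = "CA",
                      element = "C", altloc = "", occupancy = 1,
                      x = coords[observed, 1], y = coords[observed, 2],
                      z = coords[observed, 3], model = 1L,
                      stringsAsFactors = FALSE)
  unobs <- if (length(gap_res)) data.frame(
    chain = chain, resid = gap_res, resname = resnames[gap_res],
    zero_occ = FALSE, stringsAsFactors = FALSE) else empty_unobs()
  model <- structure_model(sprintf("SYN%04d", seed %% 10000L), atoms, unobs)
  list(text = write_mmcif(model), model = model, ledger = regions, seed = seed)
}

#' Generate a binned mean-distance survey from the saturation model
#'
#' Evaluates `y = A (1 - exp(-b x)) + 3.5` at the midpoint of every bin of the
#' adaptive scheme covering `1..max_length` and adds Gaussian noise — the
#' substrate of fit-recovery experiments.
#'
#' @param A,b ground-truth model constants (defaults 11 Angstrom, 0.2 per
#'   residue).
#' @param max_length largest linker length covered (default 250).
#' @param noise_sd Gaussian noise on each bin mean, Angstrom (default 0.3).
#' @param seed RNG seed.
#' @param offset fixed model offset (default 3.5).
#' @return Data frame shaped like [summarize_survey()] output (`bin_left`,
#'   `bin_right`, `bin_mid`, `n`, `mean_distance`) with attributes `A`, `b`.
#' @export
gen_survey_points <- function(A = 11, b = 0.2, max_length = 250,
                              noise_sd = 0.3, seed = 1, offset = 3.5) {
  set.seed(seed)
  scheme <- build_bins(max_length)
  out <- data.frame(bin_left = scheme$left, bin_right = scheme$right,
                    bin_mid = scheme$mid, n = 1L,
                    mean_distance = A * (1 - exp(-b * scheme$mid)) + offset +
                      stats::rnorm(length(scheme$mid), 0, noise_sd))
  attr(out, "A") <- A; attr(out, "b") <- b; attr(out, "seed") <- seed
  out
}

#' Generate a crosslink ledger with a planted satisfied fraction
#'
#' Samples residue pairs from a structural model so that exactly
#' `round(n_links * frac_satisfied)` pairs have Calpha-Calpha distance at or
#' below the threshold, plus optional decoy rows referencing residues absent
#' from the model (which must come back unmapped).
#'
#' @param model a [structure_model] (single chain is assumed per protein).
#' @param n_links number of mappable links (default 100).
#' @param frac_satisfied planted satisfied fraction at `threshold` (default 0.8).
#' @param threshold satisfaction cutoff in Angstrom (default 30).
#' @param decoy_rate decoy rows as a fraction of `n_links` (default 0).
#' @param seed RNG seed.
#' @param protein protein identifier used in the ledger (default "SYN1").
#' @return List: `table` (ledger data frame with `ProteinA`, `ResA`,
#'   `ProteinB`, `ResB`, `Replicate`), `truth` (per-row `distance`,
#'   `satisfied`, `decoy`), `chain_map`, `threshold`, `seed`.
#' @export
gen_crosslinks <- function(model, n_links = 100, frac_satisfied = 0.8,
                           threshold = 30, decoy_rate = 0, seed = 1,
                           protein = "SYN1") {
  set.seed(seed)
  ca <- model$atoms[model$atoms$atom == "CA", , drop = FALSE]
  ch <- ca$chain[1]
  ca <- ca[ca$chain == ch, , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(xyz)
  dm <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  d <- dm[pairs]
  sat_pool <- which(d <= threshold)
  unsat_pool <- which(d > threshold)
  n_sat <- round(n_links * frac_satisfied)
  n_unsat <- n_links - n_sat
  if (length(sat_pool) < n_sat || length(unsat_pool) < n_unsat)
    stop("model too small to plant ", n_sat, " satisfied + ", n_unsat,
         " unsatisfied links")
  idx <- c(sample(sat_pool, n_sat), sample(unsat_pool, n_unsat))
  tab <- data.frame(ProteinA = protein, ResA = ca$resid[pairs[idx, 1]],
                    ProteinB = protein, ResB = ca$resid[pairs[idx, 2]],
                    Replicate = "rep1", stringsAsFactors = FALSE)
  truth <- data.frame(distance = d[idx], satisfied = d[idx] <= threshold,
                      decoy = FALSE)
  n_dec <- round(n_links * decoy_rate)
  if (n_dec > 0) {
    absent <- max(ca$resid) + seq_len(n_dec)
    tab <- rbind(tab, data.frame(ProteinA = protein,
                                 ResA = sample(ca$resid, n_dec, replace = TRUE),
                                 ProteinB = protein, ResB = absent,
                                 Replicate = "rep1"))
    truth <- rbind(truth, data.frame(distance = rep(NA_real_, n_dec),
                                     satisfied = rep(NA, n_dec),
                                     decoy = rep(TRUE, n_dec)))
  }
  cm <- stats::setNames(list(ch), protein)
  list(table = tab, truth = truth, chain_map = cm,
       threshold = threshold, seed = seed)
}

#' Generate a docking pose ensemble with a planted binding site
#'
#' Picks a spatially compact site on the receptor (all Calphas within
#' `site_radius` of a randomly chosen residue), then finds a ligand anchor
#' point whose distance to every site Calpha is below `cutoff` and to every
#' other Calpha above it, with a safety margin so that pose jitter cannot flip
#' contact membership.  On-site poses place a small ligand around that anchor;
#' off-site poses are placed at least 15 Angstrom away from every receptor
#' atom and therefore contact nothing.
#'
#' @param receptor a [structure_model]; a fresh gap-free synthetic chain is
#'   generated when `NULL`.
#' @param n_poses ensemble size (default 400, the scale of refined docking
#'   ensembles).
#' @param on_site_fraction fraction of poses at the planted site (default 0.8).
#' @param seed RNG seed.
#' @param cutoff contact cutoff the plant is calibrated to (default 5).
#' @param site_radius spatial radius defining the candidate site (default 6).
#' @return List: `ensemble` ([pose_ensemble]), `site` (planted residue keys
#'   `"chain:resid"`), `on_site` (per-pose flag), `seed`.
#' @export
gen_pose_ensemble <- function(receptor = NULL, n_poses = 400,
                              on_site_fraction = 0.8, seed = 1,
                              cutoff = 5, site_radius = 6) {
  set.seed(seed)
  if (is.null(receptor))
    receptor <- gen_structure(n_residues = 80, n_gaps = 0,
                              seed = seed + 1000L)$model
  ca <- receptor$atoms[receptor$atoms$atom == "CA", , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  margin <- 0.5

  anchor <- NULL
  for (attempt in 1:2000) {
    centre <- xyz[sample(nrow(xyz), 1), ]
    cand <- centre + c(stats::runif(1, -2, 2), stats::runif(1, -2, 2),
                       stats::runif(1, -2, 2))
    dd <- sqrt(colSums((t(xyz) - cand)^2))
    in_site <- dd < cutoff - margin
    near_boundary <- dd >= cutoff - margin & dd <= cutoff + margin
    if (sum(in_site) >= 2 && !any(near_boundary) && min(dd) > 2.5) {
      anchor <- cand
      site_idx <- which(in_site)
      break
    }
  }
  if (is.null(anchor))
    stop("could not place a ligand anchor with a clean contact margin")
  site <- sort(paste(ca$chain[site_idx], ca$resid[site_idx], sep = ":"))

  centroid <- colMeans(xyz)
  rmax <- max(sqrt(rowSums(sweep(xyz, 2, centroid)^2)))
  n_on <- round(n_poses * on_site_fraction)
  on_flags <- sample(rep(c(TRUE, FALSE), c(n_on, n_poses - n_on)))

  tri <- rbind(c(0.2, 0, 0), c(-0.1, 0.17, 0), c(-0.1, -0.17, 0))
  make_pose <- function(i, on) {
    pos <- if (on) anchor + stats::runif(3, -0.03, 0.03)
           else centroid + random_unit_vectors(1)[1, ] * (rmax + 20)
    at <- sweep(tri, 2, pos, "+")
    structure_model(sprintf("POSE%04d", i), data.frame(
      chain = "L", resid = 1L, resname = "LIG", atom = c("C1", "C2", "C3"),
      element = "C", altloc = "", occupancy = 1,
      x = at[, 1], y = at[, 2], z = at[, 3], model = 1L,
      stringsAsFactors = FALSE))
  }
  poses <- lapply(seq_len(n_poses), function(i) make_pose(i, on_flags[i]))
  list(ensemble = pose_ensemble(receptor, poses), site = site,
       on_site = on_flags, seed = seed)
}

#' Generate plate-reader kinetics traces under substrate-excess inhibition
#'
#' Rates follow `v = Vmax [S] / (KM + [S] (1 + [S]/Ki))`; `Ki = Inf` reduces
#' to Michaelis-Menten.  Product accumulates linearly at the initial rate
#' until a substrate-exhaustion cap (`cap_frac * [S]`), then plateaus, and is
#' converted to absorbance through the inverse Beer-Lambert relation with a
#' constant blank offset.  Noise is Gaussian, proportional to the
#' blank-subtracted signal.
#'
#' @param km,vmax,ki kinetic parameters (uM, uM min^-1, uM; defaults 22.81,
#'   1, 500 — a CoA-like titration with moderate excess inhibition).
#' @param concentrations substrate concentrations in uM.
#' @param noise proportional noise level (default 0).
#' @param constants an [assay_constants()] object.
#' @param seed RNG seed.
#' @param t_max trace duration in minutes, sampled every minute (default 60).
#' @param cap_frac product cap as a fraction of substrate (default 1).
#' @param blank constant blank absorbance (default 0.05).
#' @return List: `traces` (data frame `time_min`, `a460`, `substrate_uM`,
#'   `replicate`), `truth` (data frame `substrate_uM`, `v0`; plus `km`,
#'   `vmax`, `ki` attributes), `constants`, `seed`.
#' @export
gen_kinetics <- function(km = 22.81, vmax = 1, ki = 500,
                         concentrations = c(5, 10, 25, 50, 100, 250, 500, 1000),
                         noise = 0, constants = assay_constants(), seed = 1,
                         t_max = 60, cap_frac = 1, blank = 0.05) {
  set.seed(seed)
  t <- 0:t_max
  traces <- do.call(rbind, lapply(concentrations, function(s) {
    v0 <- vmax * s / (km + s * (1 + s / ki))
    p <- pmin(v0 * t, cap_frac * s)                     # uM product
    a <- blank + p * constants$epsilon * constants$path_cm / 1e6
    if (noise > 0) a <- a + stats::rnorm(length(a), 0, noise * (a - blank))
    data.frame(time_min = t, a460 = a, substrate_uM = s, replicate = "rep1")
  }))
  truth <- data.frame(substrate_uM = concentrations,
                      v0 = vmax * concentrations /
                        (km + concentrations * (1 + concentrations / ki)))
  attr(truth, "km") <- km; attr(truth, "vmax") <- vmax; attr(truth, "ki") <- ki
  list(traces = traces, truth = truth, constants = constants, seed = seed)
}

#' Generate an iBAQ abundance table with known copy numbers
#'
#' iBAQ scores are proportional to the true copies with multiplicative
#' log-normal noise of the given coefficient of variation.
#'
#' @param true_copies named numeric vector of ground-truth copies (default the
#'   24/20/8/4 E2o/E1o/E3/E3BPo-like composition).
#' @param oligomer named character vector (`"monomer"`/`"dimer"`) per protein.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (default 0).
#' @param seed RNG seed.
#' @param base arbitrary intensity scale (default 1e7).
#' @return List: `table` (data frame `protein`, `ibaq`, `oligomer`), `truth`
#'   (named copies), `seed`.
#' @export
gen_abundance <- function(true_copies = c(E2o = 24, E1o = 20, E3 = 8, E3BPo = 4),
                          oligomer = c(E2o = "monomer", E1o = "dimer",
                                       E3 = "dimer", E3BPo = "monomer"),
                          noise_cv = 0, seed = 1, base = 1e7) {
  set.seed(seed)
  prot <- names(true_copies)
  fac <- if (noise_cv > 0)
    exp(stats::rnorm(length(prot), 0, sqrt(log(1 + noise_cv^2)))) else 1
  tab <- data.frame(protein = prot,
                    ibaq = base * unname(true_copies) * fac,
                    oligomer = unname(oligomer[prot]),
                    stringsAsFactors = FALSE)
  list(table = tab, truth = true_copies, seed = seed)
}
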