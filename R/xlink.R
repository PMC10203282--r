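#' Load a crosslink ledger
#'
#' Reads a delimited residue-residue crosslink table (tab or comma separated,
#' autodetected), canonicalises each link as an unordered pair of
#' (protein, residue) endpoints, and deduplicates across replicates while
#' keeping replicate provenance.  Self pairs (same protein, same residue) and
#' rows with unparseable residue indices are skipped with a message.
#'
#' @param x path to a delimited file, or its content as a single string.
#' @param aliases named list of acceptable header names for the five mandatory
#'   columns `protein_a`, `res_a`, `protein_b`, `res_b`, `replicate`
#'   (a `score` column is optional).
#' @return Data frame of unique crosslinks: `protein_a`, `res_a`, `protein_b`,
#'   `res_b`, `link_type` (`"intra"`/`"inter"`), `replicates` (collapsed ids),
#'   `n_obs` (times observed), `score` (first non-missing, if present).
#' @export
load_ledger <- function(x, aliases = list(
    protein_a = c("ProteinA", "protein_a", "Protein1", "protein1"),
    res_a     = c("ResA", "res_a", "AbsPos1", "residue1"),
    protein_b = c("ProteinB", "protein_b", "Protein2", "protein2"),
    res_b     = c("ResB", "res_b", "AbsPos2", "residue2"),
    replicate = c("Replicate", "replicate", "Rep", "run"))) {
  txt <- if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    readLines(x, warn = FALSE) else unlist(strsplit(x, "\n", fixed = TRUE))
  sep <- if (grepl("\t", txt[1], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = txt, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(field) {
    hit <- intersect(aliases[[field]], names(df))
    if (!length(hit)) stop("crosslink ledger is missing column: ", field,
                           " (accepted names: ",
                           paste(aliases[[field]], collapse = ", "), ")")
    df[[hit[1]]]
  }
  out <- data.frame(protein_a = as.character(pick("protein_a")),
                    res_a = suppressWarnings(as.integer(pick("res_a"))),
                    protein_b = as.character(pick("protein_b")),
                    res_b = suppressWarnings(as.integer(pick("res_b"))),
                    replicate = as.character(pick("replicate")),
                    stringsAsFactors = FALSE)
  score_col <- intersect(c("Score", "score"), names(df))
  out$score <- if (length(score_col)) as.numeric(df[[score_col[1]]]) else NA_real_

  bad <- is.na(out$res_a) | is.na(out$res_b) | out$res_a < 1 | out$res_b < 1
  self <- !bad & out$protein_a == out$protein_b & out$res_a == out$res_b
  if (any(bad | self))
    message(sum(bad), " unparseable and ", sum(self),
            " self-pair row(s) skipped")
  out <- out[!(bad | self), , drop = FALSE]

  # canonical endpoint order, then collapse duplicates
  swap <- out$protein_b < out$protein_a |
    (out$protein_b == out$protein_a & out$res_b < out$res_a)
  tmp <- out[swap, c("protein_b", "res_b")]
  out[swap, c("protein_b", "res_b")] <- out[swap, c("protein_a", "res_a")]
  out[swap, c("protein_a", "res_a")] <- tmp
  key <- paste(out$protein_a, out$res_a, out$protein_b, out$res_b, sep = "\r")
  reps <- split(out$replicate, key)[unique(key)]
  uniq <- out[!duplicated(key), , drop = FALSE]
  uniq$replicates <- vapply(reps, function(r) paste(sort(unique(r)), collapse = ";"),
                            character(1))
  uniq$n_obs <- vapply(reps, length, integer(1))
  uniq$replicate <- NULL
  uniq$link_type <- ifelse(uniq$protein_a == uniq$protein_b, "intra", "inter")
  rownames(uniq) <- NULL
  uniq[, c("protein_a", "res_a", "protein_b", "res_b", "link_type",
           "replicates", "n_obs", "score")]
}

#' Map crosslinks onto a structural model
#'
#' For each crosslink the Calpha-Calpha distance is computed under every
#' allowed chain-pair assignment (a protein may map to several chains, e.g. a
#' homodimer) and the minimum is taken — the standard resolution of homomer
#' ambiguity.  A link whose residues lack a Calpha in every candidate chain,
#' or whose protein is absent from `chain_map`, gets `distance = NA`
#' (unmapped); unmapped is data, not an error.
#'
#' @param model a [structure_model].
#' @param records crosslink table from [load_ledger()].
#' @param chain_map named list: protein identifier -> character vector of
#'   chain ids in `model`.
#' @param threshold satisfaction cutoff in Angstrom used to flag each mapped
#'   link (default 30, a conventional BS3 Calpha-Calpha bound).
#' @return `records` with `distance`, `chains` (chosen assignment) and
#'   `satisfied` columns added.
#' @export
map_links <- function(model, records, chain_map, threshold = 30) {
  ca <- ca_lookup(model)
  one <- function(pa, ra, pb, rb) {
    cha <- chain_map[[pa]]; chb <- chain_map[[pb]]
    if (is.null(cha) || is.null(chb)) return(list(NA_real_, NA_character_))
    best <- Inf; best_pair <- NA_character_
    for (c1 in cha) for (c2 in chb) {
      if (c1 == c2 && ra == rb) next
      k1 <- paste(c1, ra, sep = ":"); k2 <- paste(c2, rb, sep = ":")
      if (!(k1 %in% rownames(ca)) || !(k2 %in% rownames(ca))) next
      d <- sqrt(sum((ca[k1, ] - ca[k2, ])^2))
      if (d < best) { best <- d; best_pair <- paste(c1, c2, sep = "-") }
    }
    if (is.finite(best)) list(best, best_pair) else list(NA_real_, NA_character_)
  }
  hits <- mapply(one, records$protein_a, records$res_a,
                 records$protein_b, records$res_b, SIMPLIFY = FALSE)
  records$distance <- vapply(hits, function(h) h[[1]], numeric(1))
  records$chains <- vapply(hits, function(h) h[[2]], character(1))
  records$satisfied <- ifelse(is.na(records$distance), NA,
                              records$distance <= threshold)
  records
}

#' Crosslink satisfaction statistics
#'
#' Fraction of mapped links whose Calpha-Calpha distance is at or below the
#' cutoff (inclusive); unmapped links are excluded from the denominator.
#'
#' @param mapped table from [map_links()] (needs a `distance` column).
#' @param threshold cutoff in Angstrom (> 0); default 30.
#' @return List: `fraction`, `n_satisfied`, `n_mapped`, `n_unmapped`,
#'   `threshold`.
#' @export
satisfaction <- function(mapped, threshold = 30) {
  stopifnot(threshold > 0)
  d <- mapped$distance
  n_mapped <- sum(!is.na(d))
  if (n_mapped == 0) stop("no mapped links: satisfaction undefined")
  n_sat <- sum(d <= threshold, na.rm = TRUE)
  list(fraction = n_sat / n_mapped, n_satisfied = n_sat,
       n_mapped = n_mapped, n_unmapped = sum(is.na(d)), threshold = threshold)
}

#' Satisfaction at several cutoffs
#'
#' The experimental cutoff behind published satisfaction percentages is often
#' unstated, so fractions are reported over a small cutoff grid.
#'
#' @inheritParams satisfaction
#' @param thresholds vector of cutoffs in Angstrom (default 25, 30, 35).
#' @return Data frame `threshold`, `fraction`, `n_satisfied`, `n_mapped`.
#' @export
satisfaction_profile <- function(mapped, thresholds = c(25, 30, 35)) {
  do.call(rbind, lapply(thresholds, function(t) {
    s <- satisfaction(mapped, t)
    data.frame(threshold = t, fraction = s$fraction,
               n_satisfied = s$n_satisfied, n_mapped = s$n_mapped)
  }))
}

#' Log-normal fit of the mapped-distance distribution
#'
#' Maximum-likelihood log-normal parameters (mean and standard deviation of
#' the log distances, n-denominator) with a Kolmogorov-Smirnov statistic of
#' the sample against the fitted distribution — crosslink distances on a
#' sound model are expected to follow a log-normal law.
#'
#' @param mapped [map_links()] table or a numeric vector of distances; at
#'   least 5 positive mapped distances required.
#' @return Object of class `distance_distribution`: `distances`, `mu`,
#'   `sigma`, `ks_stat`, `n`.
#' @export
fit_distance_distribution <- function(mapped) {
  d <- if (is.numeric(mapped)) mapped else mapped$distance
  d <- d[!is.na(d)]
  if (length(d) < 5) stop("need at least 5 mapped distances")
  if (any(d <= 0)) stop("non-positive distances cannot be log-normal")
  lg <- log(d)
  mu <- mean(lg)
  sigma <- sqrt(mean((lg - mu)^2))
  if (sigma < 1e-10) stop("degenerate sample: all distances identical")
  ks <- suppressWarnings(
    stats::ks.test(d, stats::plnorm, meanlog = mu, sdlog = sigma))
  structure(list(distances = d, mu = mu, sigma = sigma,
                 ks_stat = unname(ks$statistic), n = length(d)),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<distance_distribution> lognormal(mu=%.3f, sigma=%.3f), KS=%.4f, n=%d\n",
              x$mu, x$sigma, x$ks_stat, x$n))
  invisible(x)
}

#' Per-protein and per-pair unique link counts
#'
#' Counts unique intra-molecular links per protein and inter-molecular links
#' per unordered protein pair, optionally restricted to a protein set (both
#' endpoints must be in the set).
#'
#' @param records crosslink table from [load_ledger()].
#' @param proteins optional character vector restricting the summary.
#' @return List: `intra` (data frame `protein`, `n`), `inter` (data frame
#'   `protein_a`, `protein_b`, `n`), `totals` (`n_intra`, `n_inter`,
#'   `n_unique`), and `per_protein` (links touching each protein, intra or
#'   inter).
#' @export
link_summary <- function(records, proteins = NULL) {
  r <- records
  if (!is.null(proteins))
    r <- r[r$protein_a %in% proteins & r$protein_b %in% proteins, , drop = FALSE]
  intra <- r[r$link_type == "intra", , drop = FALSE]
  inter <- r[r$link_type == "inter", , drop = FALSE]
  intra_tab <- as.data.frame(table(protein = intra$protein_a),
                             stringsAsFactors = FALSE)
  names(intra_tab) <- c("protein", "n")
  pair_key <- paste(inter$protein_a, inter$protein_b, sep = "|")
  inter_tab <- as.data.frame(table(pair = pair_key), stringsAsFactors = FALSE)
  inter_tab <- if (nrow(inter_tab)) {
    parts <- strsplit(inter_tab$pair, "|", fixed = TRUE)
    data.frame(protein_a = vapply(parts, `[`, "", 1),
               protein_b = vapply(parts, `[`, "", 2),
               n = inter_tab$Freq, stringsAsFactors = FALSE)
  } else data.frame(protein_a = character(), protein_b = character(),
                    n = integer())
  touch <- c(r$protein_a, r$protein_b[r$link_type == "inter"])
  per_protein <- as.data.frame(table(protein = touch), stringsAsFactors = FALSE)
  names(per_protein) <- c("protein", "n_links")
  list(intra = intra_tab, inter = inter_tab,
       totals = list(n_intra = nrow(intra), n_inter = nrow(inter),
                     n_unique = nrow(r)),
       per_protein = per_protein)
}
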