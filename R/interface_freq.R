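#' Docking pose ensemble
#'
#' Bundles one receptor with N ligand pose models for contact-frequency
#' ("guiding surface") analysis.  Receptor and ligand chain ids must be
#' disjoint.
#'
#' @param receptor a [structure_model].
#' @param poses list of ligand [structure_model]s (>= 1).
#' @return Object of class `pose_ensemble`.
#' @export
pose_ensemble <- function(receptor, poses) {
  stopifnot(inherits(receptor, "structure_model"), length(poses) >= 1)
  rc <- unique(receptor$atoms$chain)
  for (p in poses)
    if (length(intersect(rc, unique(p$atoms$chain))))
      stop("receptor and ligand chains must be disjoint")
  structure(list(receptor = receptor, poses = poses,
                 n_poses = length(poses)),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf("<pose_ensemble> %d poses over receptor %s (%d residues)\n",
              x$n_poses, x$receptor$structure_id,
              nrow(unique(x$receptor$atoms[, c("chain", "resid")]))))
  invisible(x)
}

heavy_atoms <- function(model) {
  a <- model$atoms
  a[!(toupper(a$element) %in% c("H", "D")), , drop = FALSE]
}

#' Receptor residues in contact with one ligand pose
#'
#' A receptor residue is an interface residue of a pose if any of its heavy
#' atoms lies within `cutoff` of any ligand heavy atom (minimum heavy-atom
#' pair distance, inclusive).  Hydrogens are excluded because hydrogen
#' presence varies across refined models.  A bounding-box prefilter skips
#' receptor atoms that cannot be within reach; the result is identical to the
#' all-pairs scan.
#'
#' @param receptor,pose [structure_model]s.
#' @param cutoff contact distance in Angstrom (> 0; default 5).
#' @return Sorted character vector of residue keys `"chain:resid"`.
#' @export
contact_residues <- function(receptor, pose, cutoff = 5) {
  stopifnot(cutoff > 0)
  ra <- heavy_atoms(receptor)
  la <- heavy_atoms(pose)
  if (!nrow(la)) stop("empty pose: no ligand heavy atoms")
  if (!nrow(ra)) stop("receptor has no heavy atoms")
  L <- as.matrix(la[, c("x", "y", "z")])
  lo <- apply(L, 2, min) - cutoff
  hi <- apply(L, 2, max) + cutoff
  near <- ra$x >= lo[1] & ra$x <= hi[1] &
          ra$y >= lo[2] & ra$y <= hi[2] &
          ra$z >= lo[3] & ra$z <= hi[3]
  ra <- ra[near, , drop = FALSE]
  if (!nrow(ra)) return(character())
  R <- as.matrix(ra[, c("x", "y", "z")])
  d2 <- outer(rowSums(R^2), rowSums(L^2), "+") - 2 * R %*% t(L)
  hit <- apply(d2 <= cutoff^2, 1, any)
  sort(unique(paste(ra$chain[hit], ra$resid[hit], sep = ":")))
}

#' Per-residue contact frequency over a pose ensemble
#'
#' Counts, for every receptor residue, the number of poses in which it is an
#' interface residue, and normalises by the ensemble size.
#'
#' @param ensemble a [pose_ensemble()].
#' @param cutoff contact distance in Angstrom (default 5).
#' @return Data frame with one row per receptor residue: `chain`, `resid`,
#'   `contact_count`, `frequency`, ordered by chain then residue.
#' @export
frequency_table <- function(ensemble, cutoff = 5) {
  ra <- heavy_atoms(ensemble$receptor)
  res <- unique(ra[, c("chain", "resid")])
  res <- res[order(res$chain, res$resid), , drop = FALSE]
  keys <- paste(res$chain, res$resid, sep = ":")
  counts <- integer(length(keys))
  names(counts) <- keys
  for (p in ensemble$poses) {
    hit <- contact_residues(ensemble$receptor, p, cutoff)
    counts[hit] <- counts[hit] + 1L
  }
  data.frame(chain = res$chain, resid = res$resid,
             contact_count = unname(counts),
             frequency = unname(counts) / ensemble$n_poses,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Guiding-surface hotspots from a contact-frequency table
#'
#' Extracts the highly frequent interface residues.  Two readings of a
#' "top quartile" rule are available: `"percentile"` (default) keeps residues
#' whose frequency reaches the 75th percentile of the nonzero frequencies
#' (ties at the percentile included); `"absolute"` keeps residues contacted in
#' more than `frac` of the poses.
#'
#' @param table a [frequency_table()] result.
#' @param rule `"percentile"` or `"absolute"`.
#' @param frac pose fraction for the absolute rule (default 0.25).
#' @return Subset of `table` rows that are hotspots.
#' @export
hotspots <- function(table, rule = c("percentile", "absolute"), frac = 0.25) {
  rule <- match.arg(rule)
  if (!nrow(table)) stop("empty frequency table")
  f <- table$frequency
  sel <- if (rule == "percentile") {
    nz <- f[f > 0]
    if (!length(nz)) rep(FALSE, length(f))
    else f > 0 & f >= stats::quantile(nz, 0.75, type = 7)
  } else {
    f > frac
  }
  table[sel, , drop = FALSE]
}

#' Contact-frequency bar plot
#'
#' @param table a [frequency_table()] result.
#' @param hotspot_rule rule passed to [hotspots()] for highlighting.
#' @return A ggplot object with hotspots highlighted.
#' @export
plot_contact_frequencies <- function(table, hotspot_rule = "percentile") {
  hs <- hotspots(table, hotspot_rule)
  table$hotspot <- paste(table$chain, table$resid) %in% paste(hs$chain, hs$resid)
  ggplot2::ggplot(table, ggplot2::aes(x = .data$resid, y = .data$frequency,
                                      fill = .data$hotspot)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue")) +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "receptor residue", y = "contact frequency")
}
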