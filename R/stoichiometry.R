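#' Copy numbers from iBAQ abundances anchored to a reference subunit
#'
#' iBAQ intensities are proportional to molar protein amounts, so relative
#' copy numbers follow from linear anchoring: the anchor protein (typically
#' the 24-mer E2o core, whose copy number is known from structure) is fixed at
#' its known copies and every other protein scales by its iBAQ ratio to the
#' anchor.  Copies are divided by the oligomer size to give assembly units
#' (e.g. dimers for E1o and E3).  No rounding is applied — the estimates are
#' qualitative bands, not integers.
#'
#' @param table data frame with columns `protein`, `ibaq` and `oligomer`
#'   (`"monomer"`/`"dimer"` or a numeric subunit count).
#' @param anchor_protein protein fixed at a known copy number (default
#'   `"E2o"`).
#' @param anchor_copies its copy number (default 24).
#' @return Data frame of class `stoichiometry_estimate`: `protein`, `ibaq`,
#'   `oligomer_size`, `copies`, `assembly_units`; the anchor is carried in
#'   attributes `anchor_protein` / `anchor_copies`.
#' @export
relative_copies <- function(table, anchor_protein = "E2o", anchor_copies = 24) {
  stopifnot(all(c("protein", "ibaq") %in% names(table)))
  if (any(table$ibaq < 0, na.rm = TRUE)) stop("negative iBAQ score")
  i <- match(anchor_protein, table$protein)
  if (is.na(i)) stop("anchor protein '", anchor_protein, "' not in table")
  if (is.na(table$ibaq[i]) || table$ibaq[i] <= 0)
    stop("anchor protein has non-positive iBAQ abundance")
  olig <- if ("oligomer" %in% names(table)) table$oligomer else "monomer"
  size <- if (is.numeric(olig)) olig else
    ifelse(olig == "dimer", 2, ifelse(olig == "monomer", 1, NA))
  if (any(is.na(size))) stop("oligomer must be 'monomer', 'dimer' or numeric")
  out <- data.frame(protein = table$protein, ibaq = table$ibaq,
                    oligomer_size = size,
                    copies = anchor_copies * table$ibaq / table$ibaq[i],
                    stringsAsFactors = FALSE)
  out$assembly_units <- out$copies / out$oligomer_size
  attr(out, "anchor_protein") <- anchor_protein
  attr(out, "anchor_copies") <- anchor_copies
  class(out) <- c("stoichiometry_estimate", class(out))
  out
}

#' Maximal-occupancy chain count of the metabolon
#'
#' Total polypeptide chains when every tether site of the core is occupied:
#' the core monomers, plus the tether monomers, plus two chains per dimer of
#' each peripheral dimer class.  With 24 core E2o, 24 E3BPo tethers and 12
#' each of E1o and E3 dimers this gives the 96-chain maximal metabolon.
#'
#' @param core_monomers number of core subunits.
#' @param tether_monomers number of monomeric tether subunits.
#' @param dimers_per_class integer vector, dimer count per peripheral class.
#' @return Integer total chain count.
#' @export
max_occupancy_chains <- function(core_monomers, tether_monomers,
                                 dimers_per_class = integer()) {
  vals <- c(core_monomers, tether_monomers, dimers_per_class)
  if (any(vals < 0) || any(vals != as.integer(vals)))
    stop("all counts must be non-negative integers")
  as.integer(core_monomers + tether_monomers + sum(2L * dimers_per_class))
}
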