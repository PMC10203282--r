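#' Structure container
#'
#' A `structure_model` bundles the polymer atom records of one coordinate model
#' with the raw unobserved / zero-occupancy residue records of the same entry.
#' Atoms live in a data frame with columns `chain`, `resid` (author numbering),
#' `resname`, `atom`, `element`, `altloc`, `occupancy`, `x`, `y`, `z`, `model`;
#' unobserved records carry `chain`, `resid`, `resname`, `zero_occ`.
#'
#' @param structure_id character scalar identifying the entry.
#' @param atoms data frame of atom records (see above).
#' @param unobserved data frame of unobserved-residue records (may have 0 rows).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(structure_id, atoms, unobserved = empty_unobs()) {
  stopifnot(is.character(structure_id), length(structure_id) == 1L)
  need <- c("chain", "resid", "resname", "atom", "element", "altloc",
            "occupancy", "x", "y", "z", "model")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) && any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (nrow(atoms) && any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  structure(list(structure_id = structure_id,
                 atoms = atoms,
                 unobserved = unobserved),
            class = "structure_model")
}

empty_unobs <- function() {
  data.frame(chain = character(), resid = integer(),
             resname = character(), zero_occ = logical())
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, %d chains, %d unobserved residues\n",
              x$structure_id, nrow(x$atoms),
              length(unique(x$atoms$chain)), nrow(x$unobserved)))
  invisible(x)
}

# --- minimal mmCIF reading ---------------------------------------------------
#
# Only the two categories the pipeline consumes are materialised: `atom_site`
# and `_pdbx_unobs_or_zero_occ_residues`.  The tokenizer handles loop_ blocks
# with quoted values; multi-line semicolon text fields are not supported (they
# do not occur in either category).

cif_split_tokens <- function(line) {
  line <- sub("#.*$", "", line)
  if (!nzchar(trimws(line))) return(character())
  scan(text = line, what = character(), quote = "\"'", quiet = TRUE)
}

cif_read_loops <- function(lines, keep = NULL) {
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      loop_line <- i
      i <- i + 1L
      tags <- character()
      while (i <= n && startsWith(trimws(lines[i]), "_")) {
        tags <- c(tags, trimws(lines[i]))
        i <- i + 1L
      }
      category <- sub("\\..*$", "", tags[1])
      values <- character()
      while (i <= n) {
        tl <- trimws(lines[i])
        if (tl == "loop_" || startsWith(tl, "_") || startsWith(tl, "data_") ||
            startsWith(tl, "#"))
          break
        values <- c(values, cif_split_tokens(lines[i]))
        i <- i + 1L
      }
      if (is.null(keep) || category %in% keep) {
        if (length(tags) == 0L || length(values) %% length(tags) != 0L)
          stop(sprintf("malformed mmCIF loop in category '%s' starting at line %d",
                       category, loop_line))
        m <- matrix(values, ncol = length(tags), byrow = TRUE)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- sub("^[^.]*\\.", "", tags)
        out[[category]] <- df
      }
    } else {
      i <- i + 1L
    }
  }
  out
}

cif_col <- function(df, candidates, default = NULL) {
  for (cc in candidates) if (cc %in% names(df)) return(df[[cc]])
  if (is.null(default)) return(NULL)
  rep(default, nrow(df))
}

#' Parse an mmCIF file into a structure model
#'
#' Reads the `atom_site` loop (coordinates) and, when present, the
#' `_pdbx_unobs_or_zero_occ_residues` loop that records residues present in the
#' deposited sequence but absent from the model — the raw material of the
#' unresolved-linker survey.  Author numbering (`auth_seq_id`) is used
#' throughout because the unobserved category is authored in it.  Only polymer
#' (`ATOM`) records of the first model are retained; zero-occupancy records are
#' treated identically to fully unobserved ones; among altloc duplicates the
#' highest-occupancy conformer wins, ties broken alphabetically.
#'
#' @param x path to an mmCIF file, or the file content as a character vector
#'   (a single string with newlines, or one string per line).
#' @return A [structure_model].
#' @export
parse_structure <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  id_line <- grep("^data_", lines, value = TRUE)
  structure_id <- if (length(id_line)) sub("^data_", "", id_line[1]) else "unknown"

  loops <- cif_read_loops(lines, keep = c("_atom_site", "_pdbx_unobs_or_zero_occ_residues"))
  as <- loops[["_atom_site"]]
  if (is.null(as)) stop("mmCIF input has no atom_site loop")

  atoms <- data.frame(
    chain     = cif_col(as, c("auth_asym_id", "label_asym_id")),
    resid     = as.integer(cif_col(as, c("auth_seq_id", "label_seq_id"))),
    resname   = cif_col(as, c("auth_comp_id", "label_comp_id")),
    atom      = cif_col(as, c("auth_atom_id", "label_atom_id")),
    element   = cif_col(as, "type_symbol", default = NA_character_),
    altloc    = cif_col(as, "label_alt_id", default = "."),
    occupancy = as.numeric(cif_col(as, "occupancy", default = "1")),
    x         = as.numeric(cif_col(as, "Cartn_x")),
    y         = as.numeric(cif_col(as, "Cartn_y")),
    z         = as.numeric(cif_col(as, "Cartn_z")),
    model     = as.integer(cif_col(as, "pdbx_PDB_model_num", default = "1")),
    group     = cif_col(as, "group_PDB", default = "ATOM"),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$group == "ATOM", , drop = FALSE]
  atoms$group <- NULL
  atoms$altloc[atoms$altloc %in% c(".", "?")] <- ""
  atoms$element[is.na(atoms$element)] <-
    toupper(substr(atoms$atom[is.na(atoms$element)], 1, 1))
  if (nrow(atoms)) atoms <- atoms[atoms$model == min(atoms$model), , drop = FALSE]

  # altloc resolution: highest occupancy first, then alphabetical altloc
  if (nrow(atoms)) {
    ord <- order(atoms$chain, atoms$resid, atoms$atom,
                 -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    key <- paste(atoms$chain, atoms$resid, atoms$atom, sep = "\r")
    atoms <- atoms[!duplicated(key), , drop = FALSE]
    atoms <- atoms[order(atoms$chain, atoms$resid, atoms$atom), , drop = FALSE]
    rownames(atoms) <- NULL
  }

  un <- loops[["_pdbx_unobs_or_zero_occ_residues"]]
  if (is.null(un)) {
    unobs <- empty_unobs()
  } else {
    pf <- cif_col(un, "polymer_flag", default = "Y")
    mn <- as.integer(cif_col(un, "PDB_model_num", default = "1"))
    keep <- pf %in% c("Y", "y") & mn == min(mn)
    unobs <- data.frame(
      chain   = cif_col(un, c("auth_asym_id", "label_asym_id"))[keep],
      resid   = as.integer(cif_col(un, c("auth_seq_id", "label_seq_id"))[keep]),
      resname = cif_col(un, c("auth_comp_id", "label_comp_id"))[keep],
      zero_occ = (cif_col(un, "occupancy_flag", default = "1") == "0")[keep],
      stringsAsFactors = FALSE
    )
    # a residue modelled with a Calpha cannot also count as unobserved
    ca <- atoms[atoms$atom == "CA", c("chain", "resid")]
    dup <- paste(unobs$chain, unobs$resid) %in% paste(ca$chain, ca$resid)
    if (any(dup)) {
      warning(sum(dup), " unobserved record(s) also modelled with a Calpha; dropped")
      unobs <- unobs[!dup, , drop = FALSE]
    }
    unobs <- unobs[order(unobs$chain, unobs$resid), , drop = FALSE]
    rownames(unobs) <- NULL
  }
  structure_model(structure_id, atoms, unobs)
}

#' Write a structure model as minimal mmCIF text
#'
#' Emits an `atom_site` loop and, when the model carries unobserved residues, a
#' `_pdbx_unobs_or_zero_occ_residues` loop.  Coordinates are fixed to three
#' decimals so output is byte-reproducible.
#'
#' @param model a [structure_model].
#' @param path optional file path; when `NULL` the text is returned invisibly.
#' @return The mmCIF text, invisibly when written to `path`.
#' @export
write_mmcif <- function(model, path = NULL) {
  a <- model$atoms
  hdr <- c(paste0("data_", model$structure_id), "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_seq_id", "auth_seq_id", "auth_asym_id",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "pdbx_PDB_model_num")))
  rows <- if (nrow(a)) sprintf(
    "ATOM %d %s %s %s %s %s %d %d %s %.3f %.3f %.3f %.2f %d",
    seq_len(nrow(a)), a$element, a$atom,
    ifelse(nzchar(a$altloc), a$altloc, "."),
    a$resname, a$chain, a$resid, a$resid, a$chain,
    a$x, a$y, a$z, a$occupancy, a$model) else character()
  txt <- c(hdr, rows, "#")
  u <- model$unobserved
  if (nrow(u)) {
    txt <- c(txt, "loop_",
             paste0("_pdbx_unobs_or_zero_occ_residues.",
                    c("id", "PDB_model_num", "polymer_flag", "occupancy_flag",
                      "auth_asym_id", "auth_comp_id", "auth_seq_id")),
             sprintf("%d 1 Y %d %s %s %d", seq_len(nrow(u)),
                     as.integer(u$zero_occ), u$chain, u$resname, u$resid),
             "#")
  }
  out <- paste0(paste(txt, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(out))
  }
  out
}

#' Write a structure model as a minimal PDB file
#'
#' Fixture-grade writer: `ATOM` records of model 1 only, no header metadata.
#'
#' @inheritParams write_mmcif
#' @return The PDB text, invisibly when written to `path`.
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model$atoms
  rows <- if (nrow(a)) sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
    ifelse(nzchar(a$altloc), a$altloc, " "),
    a$resname, a$chain, a$resid, a$x, a$y, a$z, a$occupancy, 0, a$element
  ) else character()
  txt <- c(rows, "END")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(paste0(paste(txt, collapse = "\n"), "\n")))
  }
  paste0(paste(txt, collapse = "\n"), "\n")
}

# --- unobserved regions ------------------------------------------------------

#' Extract maximal unobserved regions from a structure model
#'
#' Consecutive unobserved residues within one chain are merged into one region;
#' the flanks are the nearest observed residues on either side, or `NA` at a
#' chain terminus (such terminal regions are retained but are ineligible for
#' end-to-end distance measurement).
#'
#' @param model a [structure_model].
#' @return Data frame with columns `structure_id`, `chain`, `start`, `end`,
#'   `length`, `left_flank`, `right_flank`.
#' @export
extract_missing_regions <- function(model) {
  u <- model$unobserved
  empty <- data.frame(structure_id = character(), chain = character(),
                      start = integer(), end = integer(), length = integer(),
                      left_flank = integer(), right_flank = integer())
  if (!nrow(u)) return(empty)
  res <- lapply(split(u$resid, u$chain), function(r) {
    r <- sort(unique(r))
    grp <- cumsum(c(1L, diff(r) != 1L))
    t(vapply(split(r, grp), function(run) c(min(run), max(run)), numeric(2)))
  })
  out <- do.call(rbind, lapply(names(res), function(ch) {
    runs <- res[[ch]]
    observed <- sort(unique(model$atoms$resid[model$atoms$chain == ch]))
    data.frame(
      structure_id = model$structure_id,
      chain = ch,
      start = as.integer(runs[, 1]),
      end = as.integer(runs[, 2]),
      length = as.integer(runs[, 2] - runs[, 1] + 1L),
      left_flank = vapply(runs[, 1], function(s) {
        lo <- observed[observed < s]
        if (length(lo)) as.integer(max(lo)) else NA_integer_
      }, integer(1)),
      right_flank = vapply(runs[, 2], function(e) {
        hi <- observed[observed > e]
        if (length(hi)) as.integer(min(hi)) else NA_integer_
      }, integer(1))
    )
  }))
  rownames(out) <- NULL
  out
}

ca_lookup <- function(model) {
  ca <- model$atoms[model$atoms$atom == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- paste(ca$chain, ca$resid, sep = ":")
  m
}

#' End-to-end Calpha distance across unobserved regions
#'
#' For each region the Euclidean distance between the Calpha atoms of the two
#' flanking observed residues is measured; regions with an absent flank or a
#' flank without a Calpha are flagged ineligible (`distance = NA`), which is
#' data, not an error.
#'
#' @param model a [structure_model].
#' @param regions region table from [extract_missing_regions()]; computed from
#'   `model` when omitted.
#' @return `regions` with columns `distance` (Angstrom) and `eligible` added.
#' @export
flank_distance <- function(model, regions = extract_missing_regions(model)) {
  ca <- ca_lookup(model)
  dist1 <- function(ch, l, r) {
    kl <- paste(ch, l, sep = ":"); kr <- paste(ch, r, sep = ":")
    if (is.na(l) || is.na(r) || !(kl %in% rownames(ca)) || !(kr %in% rownames(ca)))
      return(NA_real_)
    sqrt(sum((ca[kl, ] - ca[kr, ])^2))
  }
  regions$distance <- mapply(dist1, regions$chain, regions$left_flank,
                             regions$right_flank)
  regions$eligible <- !is.na(regions$distance)
  regions
}

#' One-call region survey of a structure
#'
#' Convenience wrapper: [extract_missing_regions()] followed by
#' [flank_distance()], giving the per-region table the linker survey consumes.
#'
#' @param model a [structure_model].
#' @return Region table with distances and eligibility flags.
#' @export
region_distances <- function(model) {
  flank_distance(model, extract_missing_regions(model))
}
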