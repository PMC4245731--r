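# Structure input/output: PDB parsing (biological assemblies arrive as
# multi-MODEL *.pdb1 files), sanitization, van der Waals radius assignment,
# site-annotation and cohort-manifest loading.

#' Bondi van der Waals radius table
#'
#' Element-level Bondi radii; elements missing from the table fall back to the
#' default (carbon-like, 1.70 A).
#'
#' @param values Named numeric vector of radii (A) keyed by upper-case element
#'   symbol. Defaults to the Bondi set.
#' @param default Radius used for unknown elements (A).
#' @return Object of class `radius_table`.
#' @export
radius_table <- function(values = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                                    S = 1.80, P = 1.80, F = 1.47, CL = 1.75,
                                    BR = 1.85, I = 1.98, SE = 1.90),
                         default = 1.70) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (any(values <= 0.5 | values >= 3.0) || default <= 0.5 || default >= 3.0)
    chan_error("chanatomy_value_error", "vdW radii must lie in (0.5, 3.0) A")
  structure(list(values = values, default = default), class = "radius_table")
}

# covalent radii (A) for the covalently-bound-ligand test; metals are
# deliberately absent so metal coordination never counts as covalent
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, SE = 1.20, F = 0.57, CL = 1.02, BR = 1.20,
                     I = 1.39, B = 0.84)

.metal_elements <- c("LI", "NA", "K", "RB", "CS", "MG", "CA", "SR", "BA",
                     "MN", "FE", "CO", "NI", "CU", "ZN", "MO", "W", "V",
                     "CD", "HG", "AL", "CR", "PT", "AU", "AG", "PB", "GA")

.water_resnames <- c("HOH", "DOD", "WAT", "H2O", "TIP", "SOL")

new_structure <- function(atoms, id = "structure") {
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "chan_structure")
}

#' @export
print.chan_structure <- function(x, ...) {
  cat(sprintf("<chan_structure> %s: %d atoms, %d residues, %d chain(s), %d assembly cop%s\n",
              x$id, nrow(x$atoms), nrow(unique(x$atoms[c("chain", "resno", "icode", "copy")])),
              length(unique(x$atoms$chain)), length(unique(x$atoms$copy)),
              if (length(unique(x$atoms$copy)) == 1) "y" else "ies"))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s A `chan_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Parse a PDB file or text into a structure
#'
#' Reads ATOM/HETATM records (wwPDB v3.3 columns) via [bio3d::read.pdb()].
#' Biological assemblies distribute their copies over MODEL blocks; with
#' `model_policy = "merge_all"` every model is retained and atoms carry a
#' 0-based `copy` index, with `"first_only"` only the first model is kept.
#' Alternate locations are reduced to the highest-occupancy conformer (first
#' on ties). Duplicate atom serials trigger a warning and renumbering.
#'
#' @param file Path to a PDB file (mutually exclusive with `text`).
#' @param text Character scalar (or vector of lines) of PDB content.
#' @param model_policy `"merge_all"` or `"first_only"`.
#' @param id Structure identifier; defaults to the file base name.
#' @return A `chan_structure` whose `$atoms` data frame has columns
#'   serial, name, element, resname, chain, resno, icode, x, y, z, occ, het,
#'   copy, radius (radius is `NA` until [assign_radii()]).
#' @export
parse_pdb <- function(file = NULL, text = NULL,
                      model_policy = c("merge_all", "first_only"),
                      id = NULL) {
  model_policy <- match.arg(model_policy)
  if (is.null(file) == is.null(text))
    chan_error("chanatomy_value_error", "supply exactly one of file, text")
  if (!is.null(text)) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text,
               file)
    id <- id %||% "structure"
  } else {
    if (!file.exists(file))
      chan_error("chanatomy_io_error", paste0("file not found: ", file))
    id <- id %||% sub("\\.(pdb1?|ent)(\\.gz)?$", "", basename(file))
  }
  lines <- readLines(file, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec))
    chan_error("chanatomy_parse_error",
               sprintf("no ATOM/HETATM record in %d line(s) (first line: %s)",
                       length(lines), substr(lines[1] %||% "", 1, 20)))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) chan_error("chanatomy_parse_error",
                                   paste0("PDB parse failed: ", conditionMessage(e))))
  at <- pdb$atom
  n_model <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  n_keep <- if (model_policy == "merge_all") n_model else 1L
  one <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = toupper(trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                                    substr(trimws(at$elety), 1, 1), at$elesy))),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", at$insert),
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  pieces <- vector("list", n_keep)
  for (m in seq_len(n_keep)) {
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[m, ] else pdb$xyz
    co <- matrix(xyz, ncol = 3, byrow = TRUE)
    pm <- one
    pm$x <- co[, 1]; pm$y <- co[, 2]; pm$z <- co[, 3]
    pm$copy <- m - 1L
    pieces[[m]] <- pm
  }
  atoms <- do.call(rbind, pieces)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    chan_error("chanatomy_parse_error", "non-finite coordinates in PDB input")
  # alternate locations: keep highest occupancy (first wins ties)
  if (any(nzchar(atoms$alt))) {
    key <- paste(atoms$copy, atoms$chain, atoms$resno, atoms$icode,
                 atoms$resname, atoms$name, sep = "|")
    ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
    atoms <- atoms[ord, ][!duplicated(key[ord]), ]
    atoms <- atoms[order(atoms$copy, match(atoms$serial, one$serial)), ]
  }
  atoms$alt <- NULL
  if (anyDuplicated(atoms$serial[atoms$copy == 0L])) {
    warning("duplicate atom serials within a model; renumbering", call. = FALSE)
    atoms$serial <- seq_len(nrow(atoms))
  }
  atoms$radius <- NA_real_
  new_structure(atoms, id = id)
}

#' Remove hydrogens, waters and non-covalent ligands
#'
#' Hydrogen/deuterium atoms and waters are always removed. HETATM groups are
#' removed unless some non-metal atom of the group lies within
#' 1.05 x (sum of covalent radii) of a polymer heavy atom
#' (`covalent_policy = "keep_covalent"`); metal coordination does not count
#' as covalent, so heme-like cofactors are removed. With
#' `covalent_policy = "drop_all"` every HETATM group goes.
#'
#' @param s A `chan_structure`.
#' @param covalent_policy `"keep_covalent"` (default) or `"drop_all"`.
#' @return Sanitized `chan_structure`.
#' @export
sanitize <- function(s, covalent_policy = c("keep_covalent", "drop_all")) {
  covalent_policy <- match.arg(covalent_policy)
  stopifnot(inherits(s, "chan_structure"))
  at <- s$atoms
  if (nrow(at) == 0)
    chan_error("chanatomy_value_error", "empty structure")
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  at <- at[!(at$het & at$resname %in% .water_resnames), , drop = FALSE]
  het <- which(at$het)
  if (length(het) && covalent_policy == "keep_covalent") {
    poly <- which(!at$het)
    keep_grp <- character(0)
    if (length(poly)) {
      grp <- paste(at$copy[het], at$chain[het], at$resno[het], at$icode[het],
                   at$resname[het], sep = "|")
      pxyz <- as.matrix(at[poly, c("x", "y", "z")])
      pcov <- .covalent_radii[at$element[poly]]
      pcov[is.na(pcov)] <- 1.2
      for (g in unique(grp)) {
        gi <- het[grp == g]
        gi <- gi[!(at$element[gi] %in% .metal_elements)]
        bonded <- FALSE
        for (i in gi) {
          ci <- .covalent_radii[at$element[i]]
          if (is.na(ci)) ci <- 1.2
          d <- sqrt((pxyz[, 1] - at$x[i])^2 + (pxyz[, 2] - at$y[i])^2 +
                    (pxyz[, 3] - at$z[i])^2)
          if (any(d <= 1.05 * (ci + pcov))) { bonded <- TRUE; break }
        }
        if (bonded) keep_grp <- c(keep_grp, g)
      }
      grp_all <- paste(at$copy, at$chain, at$resno, at$icode, at$resname, sep = "|")
      at <- at[!at$het | grp_all %in% keep_grp, , drop = FALSE]
    } else {
      at <- at[!at$het, , drop = FALSE]
    }
  } else if (length(het) && covalent_policy == "drop_all") {
    at <- at[!at$het, , drop = FALSE]
  }
  if (nrow(at) < 4)
    chan_error("chanatomy_degenerate_error",
               sprintf("structure %s has %d atoms after sanitization (< 4)",
                       s$id, nrow(at)))
  new_structure(at, id = s$id)
}

#' Assign van der Waals radii from an element table
#'
#' @param s A `chan_structure`.
#' @param table A [radius_table()].
#' @return The structure with `$atoms$radius` populated; unknown elements get
#'   the table default with a warning.
#' @export
assign_radii <- function(s, table = radius_table()) {
  stopifnot(inherits(s, "chan_structure"), inherits(table, "radius_table"))
  r <- table$values[s$atoms$element]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s assigned default radius %.2f A",
                    paste(unique(s$atoms$element[unknown]), collapse = ", "),
                    table$default), call. = FALSE)
    r[unknown] <- table$default
  }
  s$atoms$radius <- unname(r)
  s
}

#' Write a structure to PDB format
#'
#' Assembly copies are emitted as MODEL/ENDMDL blocks so that a
#' parse-write-parse round trip preserves the copy structure.
#'
#' @param s A `chan_structure`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(s, file) {
  stopifnot(inherits(s, "chan_structure"))
  at <- s$atoms
  multi <- length(unique(at$copy)) > 1
  con <- file(file, "w")
  on.exit(close(con))
  for (cp in sort(unique(at$copy))) {
    if (multi) writeLines(sprintf("MODEL     %4d", cp + 1L), con)
    a <- at[at$copy == cp, , drop = FALSE]
    nm <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name), a$name)
    writeLines(sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       ifelse(a$het, "HETATM", "ATOM"),
                       a$serial %% 100000L, nm, "", a$resname, a$chain,
                       a$resno %% 10000L, a$icode, a$x, a$y, a$z, a$occ, 0,
                       a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Load active-site annotations (Catalytic Site Atlas style)
#'
#' Expects a CSV with header and columns `site_id`, `chain`, `resno`,
#' `resname` (a `structure_id` column is allowed and ignored here). Rows are
#' grouped by `site_id`.
#'
#' @param file Path to the CSV (or `text =` content).
#' @param text CSV content as a character scalar.
#' @return Named list of site annotations; each element is a list with
#'   `site_id` and `residues` (data frame chain/resno/resname).
#' @export
load_sites <- function(file = NULL, text = NULL) {
  df <- if (!is.null(text)) read.csv(text = text, stringsAsFactors = FALSE)
        else read.csv(file, stringsAsFactors = FALSE)
  need <- c("site_id", "chain", "resno", "resname")
  miss <- setdiff(need, names(df))
  if (length(miss))
    chan_error("chanatomy_schema_error",
               paste0("site annotation missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(df) == 0)
    chan_error("chanatomy_value_error", "empty site annotation")
  df$resname <- toupper(trimws(df$resname))
  df$chain <- as.character(df$chain)
  lapply(split(df, df$site_id), function(d)
    list(site_id = as.character(d$site_id[1]),
         residues = d[c("chain", "resno", "resname")]))
}

#' Load and validate a cohort manifest
#'
#' The manifest is a CSV with mandatory columns `structure_id`, `ec`,
#' `structure_path`, `sites_path` and optional `resolution` and `method`.
#' Optional columns are validated against the thresholds, producing per-entry
#' pass/fail flags; entries are never silently dropped (dataset curation is a
#' property of the supplied manifest, not of this loader).
#'
#' @param file Path to the manifest CSV (or `text =` content).
#' @param text CSV content as a character scalar.
#' @param resolution_threshold Maximum accepted resolution (A).
#' @param methods_allowed Accepted experimental methods (prefix match,
#'   case-insensitive), or `NULL` to accept all.
#' @param base_dir Directory against which relative paths are resolved.
#' @return Data frame of manifest entries with `ec_class`, `valid_ec`,
#'   `pass` and `fail_reason` columns.
#' @export
load_manifest <- function(file = NULL, text = NULL, resolution_threshold = 2.5,
                          methods_allowed = c("X-RAY"), base_dir = NULL) {
  df <- if (!is.null(text)) read.csv(text = text, stringsAsFactors = FALSE)
        else read.csv(file, stringsAsFactors = FALSE)
  need <- c("structure_id", "ec", "structure_path", "sites_path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    chan_error("chanatomy_schema_error",
               paste0("manifest missing column(s): ", paste(miss, collapse = ", ")))
  if (is.null(base_dir) && !is.null(file)) base_dir <- dirname(file)
  if (!is.null(base_dir)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df$structure_path)
    df$structure_path[rel] <- file.path(base_dir, df$structure_path[rel])
    rel <- !grepl("^(/|[A-Za-z]:)", df$sites_path)
    df$sites_path[rel] <- file.path(base_dir, df$sites_path[rel])
  }
  top <- sub("^\\s*([0-9]+).*$", "\\1", as.character(df$ec))
  valid <- grepl("^[0-9]+$", top) & top %in% as.character(1:6)
  df$ec_class <- ifelse(valid, paste0("EC", top), NA_character_)
  df$valid_ec <- valid
  fail <- character(nrow(df))
  fail[!valid] <- "invalid-EC"
  if ("resolution" %in% names(df)) {
    bad <- !is.na(df$resolution) & df$resolution > resolution_threshold
    fail[bad] <- ifelse(nzchar(fail[bad]), paste0(fail[bad], ";resolution"), "resolution")
  }
  if ("method" %in% names(df) && !is.null(methods_allowed)) {
    ok <- toupper(substr(df$method, 1, 5)) %in% toupper(substr(methods_allowed, 1, 5)) |
      is.na(df$method)
    fail[!ok] <- ifelse(nzchar(fail[!ok]), paste0(fail[!ok], ";method"), "method")
  }
  df$fail_reason <- fail
  df$pass <- !nzchar(fail)
  df
}
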