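# Reading and writing predicted models (PDB / mmCIF) and PAE matrices (JSON).
#
# A predicted model is represented as an atom-level tibble (one row per atom)
# carrying the per-residue confidence value in the `b` column exactly as the
# prediction program wrote it. Residue identity is (chain, resno, icode) and
# file order is never changed by parsing.

model_atom_cols <- c(
  "serial", "atom", "alt", "resid", "chain", "resno", "icode",
  "x", "y", "z", "occ", "b", "element"
)

#' Construct a predicted model from an atom table
#'
#' Builds the atom-level tibble used throughout mrprep. One row per atom;
#' required columns are `atom` (atom name), `resid` (3-letter residue code),
#' `chain`, `resno` (author residue number), `x`, `y`, `z`, `occ`, `b`.
#' Optional columns: `serial`, `alt`, `icode`, `element`.
#'
#' @param atoms A data frame of atoms, one row per atom.
#' @param source_tag Free-text provenance string.
#' @param title Optional title string.
#' @return A `predicted_model` tibble.
#' @export
predicted_model <- function(atoms, source_tag = "", title = NULL) {
  atoms <- as_tibble(atoms)
  needed <- c("atom", "resid", "chain", "resno", "x", "y", "z", "occ", "b")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    mr_abort(paste0("malformed input: missing columns ",
                    paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) mr_abort("no atoms")
  if (is.null(atoms[["serial"]])) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms[["alt"]])) atoms$alt <- ""
  if (is.null(atoms[["icode"]])) atoms$icode <- ""
  if (is.null(atoms[["element"]])) atoms$element <- substr(trimws(atoms$atom), 1, 1)
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[, model_atom_cols]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    mr_abort("malformed input: non-finite coordinates")
  }
  if (any(is.na(atoms$occ)) || any(atoms$occ < 0 | atoms$occ > 1)) {
    mr_abort("malformed input: occupancy outside [0,1]")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  if (anyDuplicated(rle(key)$values)) {
    mr_abort("malformed input: duplicate residue identifiers")
  }
  structure(
    atoms,
    source_tag = source_tag,
    title = title,
    class = c("predicted_model", class(tibble()))
  )
}

#' @export
print.predicted_model <- function(x, ...) {
  res <- residues(x)
  cat(sprintf("<predicted_model> %d atoms, %d residues, %d chain(s)\n",
              nrow(x), nrow(res), length(unique(res$chain))))
  tag <- attr(x, "source_tag")
  if (!is.null(tag) && nzchar(tag)) cat("source:", tag, "\n")
  NextMethod()
}

model_source_tag <- function(model) attr(model, "source_tag") %||% ""

append_source_tag <- function(model, note) {
  tag <- model_source_tag(model)
  attr(model, "source_tag") <- if (nzchar(tag)) paste(tag, note, sep = "; ") else note
  model
}

#' Per-residue view of a predicted model
#'
#' Collapses the atom table to one row per residue in file order. The
#' representative confidence value `raw_confidence` is the B-column value of
#' the C-alpha atom, falling back to the residue's first atom.
#'
#' @param model A `predicted_model`.
#' @return A tibble with one row per residue: `res_index` (1-based position in
#'   file order), `chain`, `resno`, `icode`, `resid`, `n_atoms`, `has_ca`,
#'   `ca_x`, `ca_y`, `ca_z`, `raw_confidence`.
#' @export
residues <- function(model) {
  stopifnot(inherits(model, "predicted_model"))
  key <- paste(model$chain, model$resno, model$icode, sep = "\r")
  idx <- match(key, unique(key))
  ca <- trimws(model$atom) == "CA"
  res <- tibble(
    res_index = seq_along(unique(key)),
    chain  = model$chain[!duplicated(idx)],
    resno  = model$resno[!duplicated(idx)],
    icode  = model$icode[!duplicated(idx)],
    resid  = model$resid[!duplicated(idx)],
    n_atoms = as.integer(tabulate(idx))
  )
  first_of <- which(!duplicated(idx))
  ca_row <- rep(NA_integer_, nrow(res))
  ca_idx <- which(ca)
  ca_row[idx[ca_idx][!duplicated(idx[ca_idx])]] <- ca_idx[!duplicated(idx[ca_idx])]
  rep_row <- ifelse(is.na(ca_row), first_of, ca_row)
  res$has_ca <- !is.na(ca_row)
  res$ca_x <- ifelse(res$has_ca, model$x[ca_row], NA_real_)
  res$ca_y <- ifelse(res$has_ca, model$y[ca_row], NA_real_)
  res$ca_z <- ifelse(res$has_ca, model$z[ca_row], NA_real_)
  res$raw_confidence <- model$b[rep_row]
  res
}

residue_index_of_atoms <- function(model) {
  key <- paste(model$chain, model$resno, model$icode, sep = "\r")
  match(key, unique(key))
}

# Resolve a path / connection / character text into a file path we can hand to
# bio3d readers. Returns list(path, cleanup).
resolve_source <- function(source) {
  if (inherits(source, "connection")) {
    lines <- readLines(source, warn = FALSE)
    path <- tempfile(fileext = ".txt")
    writeLines(lines, path)
    return(list(path = path, cleanup = TRUE))
  }
  if (is.character(source) && length(source) == 1 && !grepl("\n", source) &&
      file.exists(source)) {
    return(list(path = source, cleanup = FALSE))
  }
  if (is.character(source)) {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".txt")
    writeLines(lines, path)
    return(list(path = path, cleanup = TRUE))
  }
  mr_abort("malformed input: unsupported source type")
}

sniff_format <- function(path) {
  first <- ""
  lines <- readLines(path, n = 50, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0) first <- trimws(lines[[1]])
  if (startsWith(first, "data_") || any(grepl("^_atom_site\\.", lines))) {
    "mmcif"
  } else {
    "pdb"
  }
}

#' Read a predicted model from PDB or mmCIF
#'
#' Loads polymer atoms (ATOM records / `atom_site` rows) from a file path, a
#' connection, or in-memory text. HETATM records, waters and ligands are
#' dropped; alternate locations other than blank/'A' are dropped; only the
#' first model of a multi-model file is kept. The B column is loaded verbatim
#' (it usually carries pLDDT or an estimated r.m.s.d. for predicted models).
#'
#' @param source File path, connection, or character text of the file.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`. `"auto"` decides from
#'   the leading bytes (`data_` or an `_atom_site.` loop means mmCIF).
#' @return A [predicted_model] tibble.
#' @export
read_model <- function(source, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  src <- resolve_source(source)
  if (src$cleanup) on.exit(unlink(src$path))
  if (format == "auto") format <- sniff_format(src$path)
  parsed <- tryCatch(
    suppressWarnings(suppressMessages(
      if (format == "pdb") {
        bio3d::read.pdb(src$path, multi = FALSE, verbose = FALSE)
      } else {
        bio3d::read.cif(src$path, verbose = FALSE)
      }
    )),
    error = function(e) mr_abort(paste0("malformed input: ", conditionMessage(e)))
  )
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  alt <- at$alt
  alt[is.na(alt)] <- ""
  at <- at[alt %in% c("", "A"), , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0) mr_abort("no atoms")
  atoms <- tibble(
    serial = as.integer(at$eleno),
    atom = as.character(at$elety),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    resid = as.character(at$resid),
    chain = ifelse(is.na(at$chain), "A", as.character(at$chain)),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    element = ifelse(is.na(at$elesy), substr(trimws(at$elety), 1, 1),
                     as.character(at$elesy))
  )
  predicted_model(atoms, source_tag = format)
}

#' Write a predicted model to PDB or mmCIF
#'
#' PDB output uses the standard fixed-width columns (coordinates `%8.3f`,
#' occupancy and B `%6.2f`); mmCIF output writes a minimal `atom_site`
#' category with `B_iso_or_equiv`. Residue and atom order is preserved.
#'
#' @param model A [predicted_model].
#' @param path Output file path, or `NULL` to return the text lines.
#' @param format `"pdb"` or `"mmcif"`.
#' @return Invisibly, the path (or the character vector of lines if
#'   `path = NULL`).
#' @export
write_model <- function(model, path = NULL, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  if (!inherits(model, "predicted_model") || nrow(model) == 0) {
    mr_abort("no atoms")
  }
  if (format == "pdb") {
    xyz <- c(model$x, model$y, model$z)
    if (any(xyz >= 1e4 | xyz <= -1e3) || any(model$b >= 1e3)) {
      mr_abort("unrepresentable in PDB fixed-width columns (use mmCIF)")
    }
    out <- path %||% tempfile(fileext = ".pdb")
    bio3d::write.pdb(
      pdb = NULL, file = out,
      xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
      type = rep("ATOM", nrow(model)),
      resno = model$resno, resid = model$resid, eleno = model$serial,
      elety = model$atom, chain = model$chain,
      insert = ifelse(nzchar(model$icode), model$icode, ""),
      alt = ifelse(nzchar(model$alt), model$alt, ""),
      o = model$occ, b = model$b, elesy = model$element
    )
    if (is.null(path)) {
      lines <- readLines(out, warn = FALSE)
      unlink(out)
      return(invisible(lines))
    }
    return(invisible(path))
  }
  lines <- format_mmcif(model)
  if (is.null(path)) return(invisible(lines))
  writeLines(lines, path)
  invisible(path)
}

# Minimal atom_site mmCIF serialization (bio3d has no mmCIF writer).
format_mmcif <- function(model) {
  res_idx <- residue_index_of_atoms(model)
  fields <- c(
    "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
    "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
    "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
    "auth_atom_id", "pdbx_PDB_model_num"
  )
  rows <- sprintf(
    "ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    model$serial, model$element, model$atom,
    ifelse(nzchar(model$alt), model$alt, "."),
    model$resid, model$chain, res_idx,
    ifelse(nzchar(model$icode), model$icode, "?"),
    model$x, model$y, model$z, model$occ, model$b,
    model$resno, model$resid, model$chain, model$atom
  )
  c(
    "data_mrprep",
    "#",
    "loop_",
    paste0("_atom_site.", fields),
    rows,
    "#"
  )
}

#' Construct a PAE matrix object
#'
#' @param values Square numeric matrix of predicted aligned errors
#'   (Angstroms, non-negative).
#' @param max_pae Optional stated maximum PAE (Angstroms).
#' @return A `pae_matrix` (numeric matrix with class attribute).
#' @export
pae_matrix <- function(values, max_pae = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) mr_abort("inconsistent PAE: matrix not square")
  if (any(!is.finite(values))) mr_abort("invalid PAE value: non-finite entry")
  if (any(values < 0)) mr_abort("invalid PAE value: negative entry")
  if (!is.null(max_pae) && any(values > max_pae + 1e-9)) {
    mr_abort("invalid PAE value: entry exceeds max_pae")
  }
  structure(values, max_pae = max_pae, class = c("pae_matrix", "matrix", "array"))
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat(sprintf("<pae_matrix> %d x %d residues", nrow(x), ncol(x)))
  mp <- attr(x, "max_pae")
  if (!is.null(mp)) cat(sprintf(", max_pae = %g A", mp))
  cat(sprintf(", mean = %.2f A\n", mean(x)))
  invisible(x)
}

#' Read a predicted aligned error matrix from JSON
#'
#' Understands the three dialects in circulation: (a) the legacy AFDB flat
#' form with `residue1`/`residue2`/`distance` lists, (b) the current AFDB
#' nested-list form keyed `predicted_aligned_error` (plus
#' `max_predicted_aligned_error`), and (c) a bare `pae` key with nested lists
#' (ColabFold). All parse to the same dense L x L matrix.
#'
#' @param source File path, connection, or JSON text.
#' @return A [pae_matrix].
#' @export
read_pae_json <- function(source) {
  src <- resolve_source(source)
  if (src$cleanup) on.exit(unlink(src$path))
  parsed <- tryCatch(jsonlite::fromJSON(src$path, simplifyVector = TRUE),
                     error = function(e) mr_abort(paste0("malformed input: ", conditionMessage(e))))
  # AFDB wraps the object in a one-element array; unwrap data.frame/list forms
  if (is.data.frame(parsed) && nrow(parsed) == 1) {
    parsed <- lapply(parsed, function(col) col[[1]])
  } else if (is.list(parsed) && is.null(names(parsed)) && length(parsed) == 1) {
    parsed <- parsed[[1]]
  }
  nm <- names(parsed)
  if (!is.null(nm) && all(c("residue1", "residue2", "distance") %in% nm)) {
    r1 <- as.integer(parsed$residue1)
    r2 <- as.integer(parsed$residue2)
    d <- as.numeric(parsed$distance)
    n <- max(c(r1, r2))
    if (length(r1) != length(r2) || length(r1) != length(d) ||
        length(d) != n * n || anyDuplicated(cbind(r1, r2)) ||
        min(c(r1, r2)) < 1) {
      mr_abort("inconsistent PAE: flat dialect does not cover all residue pairs")
    }
    m <- matrix(NA_real_, n, n)
    m[cbind(r1, r2)] <- d
    return(pae_matrix(m, max_pae = as_scalar(parsed$max_predicted_aligned_error)))
  }
  key <- intersect(c("predicted_aligned_error", "pae"), nm)
  if (length(key) == 0) mr_abort("unknown PAE dialect")
  vals <- parsed[[key[[1]]]]
  if (is.list(vals)) {
    lens <- lengths(vals)
    if (length(unique(lens)) != 1) mr_abort("inconsistent PAE: ragged rows")
    vals <- do.call(rbind, vals)
  }
  if (!is.matrix(vals) || nrow(vals) != ncol(vals)) {
    mr_abort("inconsistent PAE: matrix not square")
  }
  pae_matrix(vals, max_pae = as_scalar(parsed$max_predicted_aligned_error))
}

as_scalar <- function(x) if (is.null(x)) NULL else as.numeric(x)[[1]]

#' Serialize a PAE matrix to JSON
#'
#' Writes any of the three dialects accepted by [read_pae_json()]; round trips
#' are entrywise exact at the printed precision.
#'
#' @param pae A [pae_matrix].
#' @param path Output path, or `NULL` to return the JSON string.
#' @param dialect `"afdb_flat"` (residue1/residue2/distance), `"afdb_nested"`
#'   (`predicted_aligned_error`), or `"pae"`.
#' @return Invisibly the path, or the JSON string if `path = NULL`.
#' @export
write_pae_json <- function(pae, path = NULL,
                           dialect = c("afdb_nested", "afdb_flat", "pae")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(pae, "pae_matrix"))
  n <- nrow(pae)
  mp <- attr(pae, "max_pae") %||% max(pae)
  m <- unclass(pae)
  attr(m, "max_pae") <- NULL
  body <- switch(dialect,
    afdb_flat = {
      idx <- expand.grid(residue2 = seq_len(n), residue1 = seq_len(n))
      list(list(
        residue1 = idx$residue1,
        residue2 = idx$residue2,
        distance = m[cbind(idx$residue1, idx$residue2)],
        max_predicted_aligned_error = mp
      ))
    },
    afdb_nested = list(list(
      predicted_aligned_error = m,
      max_predicted_aligned_error = mp
    )),
    pae = list(pae = m)
  )
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(as.character(json), path)
  invisible(path)
}

#' AlphaFold Database file URLs for a UniProt accession
#'
#' Builds the deterministic AFDB download URLs for the model (PDB and mmCIF)
#' and the predicted aligned error JSON of an entry. No network access is
#' performed; the v4 naming convention is used with the version overridable.
#'
#' @param uniprot_id UniProt accession (e.g. `"P69905"`).
#' @param version AFDB model version (integer >= 1, default 4).
#' @return Named list with `model_pdb`, `model_cif`, `pae_json` URL strings.
#' @export
afdb_entry_urls <- function(uniprot_id, version = 4) {
  acc_re <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"
  if (!is.character(uniprot_id) || length(uniprot_id) != 1 ||
      !grepl(acc_re, uniprot_id)) {
    mr_abort("invalid accession")
  }
  if (!is.numeric(version) || length(version) != 1 || version < 1 ||
      version != round(version)) {
    mr_abort("invalid accession: version must be a positive integer")
  }
  base <- sprintf("https://alphafold.ebi.ac.uk/files/AF-%s-F1", uniprot_id)
  list(
    model_pdb = sprintf("%s-model_v%d.pdb", base, as.integer(version)),
    model_cif = sprintf("%s-model_v%d.cif", base, as.integer(version)),
    pae_json = sprintf("%s-predicted_aligned_error_v%d.json", base, as.integer(version))
  )
}
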