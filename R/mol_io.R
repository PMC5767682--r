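#' Read a receptor structure from PDB
#'
#' Parses a PDB file into an atom tibble. Alternate locations are resolved
#' to a single conformer: the altloc with the highest occupancy is kept,
#' ties going to altloc `"A"`, so downstream geometry is deterministic.
#' When the element column is blank, the element is inferred from the atom
#' name (PDB v3 rules: columns 13-14 carry the right-justified symbol).
#'
#' @param path path to a PDB file.
#' @param chain_offsets optional named integer vector of per-chain residue
#'   renumbering offsets (added to `resno`), e.g. `c(A = -22)`; used when a
#'   file's numbering differs from the mature-protein numbering used in
#'   reports. Default: no offset.
#' @return an atom tibble (see [as_atoms()]); one row per resolved atom,
#'   `is_hetero` distinguishing HETATM records.
#' @export
read_receptor <- function(path, chain_offsets = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  if (!any(keep)) abort(paste0("no atom records in ", path))
  atoms <- parse_pdb_atoms(lines[keep], which(keep))
  atoms <- resolve_altloc(atoms)
  atoms$altloc <- NULL
  if (!is.null(chain_offsets)) {
    for (ch in names(chain_offsets)) {
      sel <- atoms$chain == ch
      atoms$resno[sel] <- atoms$resno[sel] + chain_offsets[[ch]]
    }
  }
  as_atoms(atoms)
}

parse_pdb_atoms <- function(lines, line_numbers) {
  num <- function(s, lo, hi, what) {
    v <- suppressWarnings(as.numeric(substr(s, lo, hi)))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(paste0("malformed PDB ", what, " field at line ",
                   line_numbers[bad[1]]))
    }
    v
  }
  element <- trimws(substr(lines, 77, 78))
  name <- trimws(substr(lines, 13, 16))
  blank <- element == ""
  if (any(blank)) {
    element[blank] <- element_from_name(substr(lines[blank], 13, 16))
  }
  tibble(
    serial = as.integer(num(lines, 7, 11, "serial")),
    name = name,
    altloc = substr(lines, 17, 17),
    element = element,
    x = num(lines, 31, 38, "x"),
    y = num(lines, 39, 46, "y"),
    z = num(lines, 47, 54, "z"),
    resname = trimws(substr(lines, 18, 20)),
    resno = as.integer(num(lines, 23, 26, "residue number")),
    chain = substr(lines, 22, 22),
    is_hetero = substr(lines, 1, 6) == "HETATM",
    occ = {
      o <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
      ifelse(is.na(o), 1, o)
    }
  )
}

# PDB v3: element occupies columns 13-14 of the atom-name field,
# right-justified; a digit in column 13 marks hydrogens like "1HB1"
element_from_name <- function(name_field) {
  two <- substr(name_field, 1, 2)
  vapply(two, function(s) {
    c1 <- substr(s, 1, 1); c2 <- substr(s, 2, 2)
    if (grepl("[0-9]", c1)) return("H")
    if (c1 == " ") return(toupper(c2))
    cand <- toupper(s)
    if (cand %in% rownames(element_data)) cand else toupper(c1)
  }, character(1), USE.NAMES = FALSE)
}

resolve_altloc <- function(atoms) {
  if (all(atoms$altloc %in% c(" ", ""))) return(atoms)
  atoms |>
    group_by(.data$chain, .data$resno, .data$resname, .data$name) |>
    arrange(desc(.data$occ), .data$altloc, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$serial)
}

#' Read docked ligand poses
#'
#' Reads a multi-pose ligand file into a pose-set tibble, one row per
#' MODEL (PDB), record (SDF) or molecule (MOL2), preserving file order so
#' that `pose_index` always equals the position in the file. Hydrogens are
#' retained in the atom tables; all RMSD computations drop them by default.
#'
#' SDF parsing uses ChemmineR; MOL2 element symbols are normalized from
#' SYBYL atom types (`C.ar` -> `C`).
#'
#' @param path path to a PDB/SDF/MOL2 file of poses.
#' @param engine engine label stored with every pose (e.g. `"gold"`,
#'   `"vina"`).
#' @param ligand_id ligand identifier; default: file name without
#'   extension.
#' @param format `"pdb"`, `"sdf"` or `"mol2"`; default: from extension.
#' @return a pose-set tibble (see [pose_set()]).
#' @export
read_poses <- function(path, engine, ligand_id = NULL,
                       format = c("auto", "pdb", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      pdb = "pdb", ent = "pdb", sdf = "sdf", sd = "sdf", mol2 = "mol2",
      abort(paste0("cannot infer pose format from extension of ", path))
    )
  }
  ligand_id <- ligand_id %||% tools::file_path_sans_ext(basename(path))
  atoms_list <- switch(format,
    pdb = read_poses_pdb(path),
    sdf = read_poses_sdf(path),
    mol2 = read_poses_mol2(path)
  )
  if (!length(atoms_list)) abort(paste0("no poses found in ", path))
  pose_set(atoms_list, ligand_id = ligand_id, engine = engine)
}

read_poses_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (!length(model_starts)) {
    keep <- rec %in% c("ATOM  ", "HETATM")
    a <- parse_pdb_atoms(lines[keep], which(keep))
    a$altloc <- NULL
    return(list(a))
  }
  model_ends <- which(rec == "ENDMDL")
  map2(model_starts, model_ends, function(s, e) {
    block <- lines[s:e]
    keep <- substr(block, 1, 6) %in% c("ATOM  ", "HETATM")
    a <- parse_pdb_atoms(block[keep], s + which(keep) - 1)
    a$altloc <- NULL
    a
  })
}

read_poses_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort("SDF input requires the ChemmineR package")
  }
  sdf <- ChemmineR::read.SDFset(path)
  map(seq_along(ChemmineR::cid(sdf)), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    el <- sub("_[0-9]+$", "", rownames(ab))
    tibble(element = el, name = rownames(ab),
           x = unname(ab[, 1]), y = unname(ab[, 2]), z = unname(ab[, 3]))
  })
}

read_poses_mol2 <- function(path) {
  mol <- bio3d::read.mol2(path)
  mols <- if (inherits(mol, "mol2")) list(mol) else mol
  map(mols, function(m) {
    a <- m$atom
    tibble(
      serial = as.integer(a$eleno),
      name = a$elena,
      element = normalize_element(a$elety),
      x = as.numeric(a$x), y = as.numeric(a$y), z = as.numeric(a$z),
      resname = if ("resid" %in% names(a)) as.character(a$resid) else "LIG",
      resno = 1L, chain = "A", is_hetero = TRUE
    )
  })
}

#' Write poses as a multi-MODEL PDB file
#'
#' Coordinates are written with the standard 3-decimal PDB precision, so a
#' write/read round trip reproduces them exactly at that precision.
#'
#' @param poses a pose-set tibble or a list of atom tables.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_poses_pdb <- function(poses, path) {
  atoms_list <- if (is.data.frame(poses) && "atoms" %in% names(poses)) {
    poses$atoms
  } else if (is.data.frame(poses)) list(poses) else poses
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(atoms_list)) {
    a <- as_atoms(atoms_list[[i]])
    writeLines(sprintf("MODEL %8d", i), con)
    writeLines(sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(a$is_hetero, "HETATM", "ATOM"),
      a$serial, substr(a$name, 1, 4), substr(a$resname, 1, 3),
      substr(a$chain, 1, 1), a$resno, a$x, a$y, a$z, a$occ, 0, a$element
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a docking score table
#'
#' Reads a delimited text file of per-pose scores keyed by
#' `(ligand_id, engine, pose_index)`, with one column per scoring metric.
#' Rows with missing metric values are kept but flagged: the ranking stage
#' excludes metric-incomplete poses with a warning rather than silently
#' imputing.
#'
#' @param path path to a CSV/TSV file with header
#'   `ligand_id,engine,pose_index,<metric1>,<metric2>,...`.
#' @return tibble with the key columns, the metric columns, and a logical
#'   `metric_complete`.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  key <- c("ligand_id", "engine", "pose_index")
  missing <- setdiff(key, names(tab))
  if (length(missing)) {
    abort(paste0("score table lacks key column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tab[key])) abort("duplicate (ligand_id, engine, pose_index) rows")
  metric_cols <- setdiff(names(tab), key)
  if (nrow(tab) == 0) warn("score table has a header but no rows")
  tab$metric_complete <- if (length(metric_cols)) {
    stats::complete.cases(tab[metric_cols])
  } else {
    logical(nrow(tab))
  }
  if (any(!tab$metric_complete)) {
    warn(paste0(sum(!tab$metric_complete),
                " pose(s) have missing metric values and will be excluded",
                " from ranking"))
  }
  tab
}
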