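#' Atom tables, poses and pose sets
#'
#' `condock` represents molecular coordinates as plain tibbles so that every
#' result can be manipulated with dplyr verbs and piped between stages.
#'
#' * An *atom table* has one row per atom with columns `serial`, `name`,
#'   `element`, `x`, `y`, `z`, `resname`, `resno`, `chain`, `is_hetero`
#'   (and optionally `occ`). A receptor [Structure][read_receptor] and a
#'   ligand pose are both atom tables; all coordinates live in one shared
#'   rigid receptor frame and are never superposed.
#' * A *pose set* has one row per docked pose with columns `ligand_id`,
#'   `engine`, `pose_index` and a list-column `atoms` of atom tables.
#'
#' @param df a data frame with at least `element`, `x`, `y`, `z`.
#' @return `as_atoms()` returns a validated atom tibble.
#' @examples
#' as_atoms(data.frame(element = "C", x = 0, y = 0, z = 0))
#' @export
as_atoms <- function(df) {
  df <- as_tibble(df)
  required <- c("element", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("atom table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  defaults <- list(
    serial = seq_len(nrow(df)), name = df$element, resname = "LIG",
    resno = 1L, chain = "A", is_hetero = TRUE, occ = 1
  )
  for (col in names(defaults)) {
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  }
  df$element <- normalize_element(df$element)
  bad <- !df$element %in% rownames(element_data)
  if (any(bad)) {
    abort(paste0("unknown element symbol(s): ",
                 paste(unique(df$element[bad]), collapse = ", ")))
  }
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("non-finite atom coordinates")
  }
  df[c("serial", "name", "element", "x", "y", "z",
       "resname", "resno", "chain", "is_hetero", "occ")]
}

#' @rdname as_atoms
#' @param atoms an atom table.
#' @return `coords()` returns an n x 3 numeric matrix of coordinates.
#' @export
coords <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

#' @rdname as_atoms
#' @return `heavy_atoms()` returns the atom table with hydrogens removed.
#' @export
heavy_atoms <- function(atoms) {
  atoms[atoms$element != "H", , drop = FALSE]
}

# minimal periodic data: atomic number per symbol, used for element
# validation and Gaussian amplitudes in simulated maps
element_data <- local({
  sym <- c("H", "C", "N", "O", "F", "P", "S", "CL", "BR", "I", "SE",
           "NA", "MG", "K", "CA", "ZN", "FE", "MN", "CU", "B")
  z <- c(1, 6, 7, 8, 9, 15, 16, 17, 35, 53, 34,
         11, 12, 19, 20, 30, 26, 25, 29, 5)
  m <- matrix(z, ncol = 1, dimnames = list(sym, "z"))
  m
})

atomic_number <- function(element) {
  element_data[normalize_element(element), "z"]
}

normalize_element <- function(element) {
  e <- toupper(trimws(element))
  # strip SYBYL subtypes like "C.ar", "N.4", "O.co2"
  e <- sub("\\..*$", "", e)
  e
}

#' Build a pose set from a list of atom tables
#'
#' @param atoms_list list of atom tables, one per pose, in file order.
#' @param ligand_id ligand identifier shared by all poses.
#' @param engine label of the docking engine that produced the poses.
#' @return a pose-set tibble (`ligand_id`, `engine`, `pose_index`, `atoms`).
#' @export
pose_set <- function(atoms_list, ligand_id, engine) {
  atoms_list <- map(atoms_list, as_atoms)
  multisets <- map_chr(atoms_list, function(a) {
    paste(sort(table(heavy_atoms(a)$element)), sort(unique(heavy_atoms(a)$element)),
          collapse = ";")
  })
  if (length(unique(multisets)) > 1) {
    abort(paste0("inconsistent heavy-atom element multiset across poses of ",
                 "ligand '", ligand_id, "'"))
  }
  if (any(map_int(atoms_list, function(a) nrow(heavy_atoms(a))) < 1)) {
    abort("every pose needs at least one heavy atom")
  }
  tibble(
    ligand_id = ligand_id,
    engine = engine,
    pose_index = seq_along(atoms_list),
    atoms = atoms_list
  )
}
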