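## Nonbonded parameter tables and their assignment to structures.

#' Read a nonbonded parameter table
#'
#' TSV with columns residue_name, atom_name, radius_A, charge_e,
#' lj_epsilon, lj_rmin_half.  Rows with residue_name `"*"` are fallbacks
#' matched by atom name; rows with residue_name `"*"` and atom_name
#' `"@<El>"` are element-level fallbacks (e.g. `"@S"` for any sulphur atom
#' not matched by name).  The packaged default table carries Bondi-type
#' radii and toy charges constructed to be neutral per residue; it is a
#' stand-in for force-field nonbonded parameters, not derived from them.
#'
#' @param path TSV file; defaults to the packaged table.
#' @return a [ParamTable-class].
#' @export
readParamTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nonbonded_params.tsv", package = "oxfold")
  t <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  new("ParamTable", table = t)
}

#' Assign nonbonded parameters to every atom
#'
#' Lookup order per atom: exact (residue name, atom name), then wildcard
#' (`"*"`, atom name), then element fallback (`"*"`, `"@<element>"`).  The
#' lookup is total: any atom not resolved by the chain raises a
#' parameterization error listing every offending (residue, atom) pair.
#'
#' @param structure a [Structure-class].
#' @param table a [ParamTable-class]; default the packaged table.
#' @return the structure with radius, charge and Lennard-Jones columns
#'   populated; all other fields untouched.
#' @export
assignParams <- function(structure, table = readParamTable()) {
  stopifnot(is(structure, "Structure"), is(table, "ParamTable"))
  t <- table@table
  key <- paste(t$residue_name, toupper(t$atom_name))
  a <- structure@atoms
  k1 <- paste(toupper(a$resname), toupper(a$name))
  k2 <- paste("*", toupper(a$name))
  k3 <- paste("*", paste0("@", toupper(a$element)))
  row <- match(k1, key)
  row[is.na(row)] <- match(k2, key)[is.na(row)]
  row[is.na(row)] <- match(k3, key)[is.na(row)]
  if (anyNA(row)) {
    bad <- unique(paste0("(", a$resname[is.na(row)], ", ",
                         a$name[is.na(row)], ")"))
    oxStop(paste("unresolvable atoms:", paste(bad, collapse = " ")),
           "oxfold_parameterization_error")
  }
  a$radius <- t$radius_A[row]
  a$charge <- t$charge_e[row]
  a$ljEpsilon <- t$lj_epsilon[row]
  a$ljRminHalf <- t$lj_rmin_half[row]
  structure@atoms <- a
  structure
}
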