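## Atom-selection mini-grammar.
##
## expr    := orExpr
## orExpr  := andExpr ("or" andExpr)*
## andExpr := notExpr ("and" notExpr)*
## notExpr := "not" notExpr | "(" expr ")" | primary
## primary := "resid" INT+ | "resname" NAME+ | "name" NAME+
##          | "sidechain" | "backbone" | "protein" | "solvent" | "all"
##
## Backbone convention: atom names N, CA, C, O, H, HA (plus terminal OXT);
## everything else in a protein residue is side chain.

PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
  "HSE", "ILE", "LEU", "LYS", "MET", "MSX", "PHE", "PRO", "SER", "THR",
  "TRP", "TYR", "VAL")
SOLVENT_RESNAMES <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "SPC")
BACKBONE_NAMES <- c("N", "CA", "C", "O", "H", "HA", "OXT", "HN",
                    "HA1", "HA2", "HT1", "HT2", "HT3")

selTokenize <- function(spec) {
  spec <- gsub("\\(", " ( ", spec)
  spec <- gsub("\\)", " ) ", spec)
  toks <- strsplit(trimws(spec), "\\s+")[[1]]
  toks[nzchar(toks)]
}

## Recursive-descent parser over a token stream held in an environment.
selParse <- function(toks, atomTab) {
  env <- new.env()
  env$toks <- toks
  env$pos <- 1L
  peek <- function() if (env$pos <= length(env$toks)) env$toks[env$pos] else NA
  advance <- function() {
    t <- peek()
    env$pos <- env$pos + 1L
    t
  }
  isKeyword <- function(t) !is.na(t) && t %in% c(
    "and", "or", "not", "(", ")", "resid", "resname", "name", "sidechain",
    "backbone", "protein", "solvent", "all")

  primary <- function() {
    t <- advance()
    if (is.na(t)) oxStop("unexpected end of selection", "oxfold_grammar_error")
    switch(t,
      "resid" = {
        vals <- integer(0)
        while (!is.na(peek()) && grepl("^-?[0-9]+$", peek()))
          vals <- c(vals, as.integer(advance()))
        if (!length(vals))
          oxStop("'resid' needs at least one integer", "oxfold_grammar_error")
        atomTab$resid %in% vals
      },
      "resname" = {
        vals <- character(0)
        while (!is.na(peek()) && !isKeyword(peek()))
          vals <- c(vals, advance())
        if (!length(vals))
          oxStop("'resname' needs at least one name", "oxfold_grammar_error")
        atomTab$resname %in% toupper(vals)
      },
      "name" = {
        vals <- character(0)
        while (!is.na(peek()) && !isKeyword(peek()))
          vals <- c(vals, advance())
        if (!length(vals))
          oxStop("'name' needs at least one atom name", "oxfold_grammar_error")
        atomTab$name %in% toupper(vals)
      },
      "sidechain" = atomTab$resname %in% PROTEIN_RESNAMES &
        !(atomTab$name %in% BACKBONE_NAMES),
      "backbone" = atomTab$resname %in% PROTEIN_RESNAMES &
        atomTab$name %in% BACKBONE_NAMES,
      "protein" = atomTab$resname %in% PROTEIN_RESNAMES,
      "solvent" = atomTab$resname %in% SOLVENT_RESNAMES,
      "all" = rep(TRUE, nrow(atomTab)),
      "(" = {
        m <- orExpr()
        if (!identical(advance(), ")"))
          oxStop("unbalanced parentheses in selection",
                 "oxfold_grammar_error")
        m
      },
      oxStop(paste("unknown selection keyword:", t), "oxfold_grammar_error"))
  }
  notExpr <- function() {
    if (identical(peek(), "not")) {
      advance()
      !notExpr()
    } else primary()
  }
  andExpr <- function() {
    m <- notExpr()
    while (identical(peek(), "and")) {
      advance()
      m <- m & notExpr()
    }
    m
  }
  orExpr <- function() {
    m <- andExpr()
    while (identical(peek(), "or")) {
      advance()
      m <- m | andExpr()
    }
    m
  }
  m <- orExpr()
  if (!is.na(peek()))
    oxStop(paste("trailing tokens in selection:",
                 paste(env$toks[env$pos:length(env$toks)], collapse = " ")),
           "oxfold_grammar_error")
  m
}

#' Select atoms with the mini-grammar
#'
#' Deterministic selection language over residue ids, residue names, atom
#' names, the sidechain/backbone split (backbone = N, CA, C, O, H, HA),
#' `protein`, `solvent` and `all`, combined with `and`, `or`, `not` and
#' parentheses.  `not` complements within the whole structure, so
#' `select(s, spec)` and `select(s, paste("not (", spec, ")"))` partition
#' the universe.
#'
#' @param structure a [Structure-class].
#' @param spec selection expression, e.g. `"resid 1606 and sidechain"` or
#'   `"protein and not resid 1606"`.
#' @return an [AtomSet-class].
#' @examples
#' pdb <- system.file("extdata", "met_fixture.pdb", package = "oxfold")
#' s <- readPDB(pdb)
#' selectAtoms(s, "resid 1606 and sidechain")
#' @export
selectAtoms <- function(structure, spec) {
  stopifnot(is(structure, "Structure"))
  toks <- selTokenize(spec)
  if (!length(toks)) oxStop("empty selection expression", "oxfold_grammar_error")
  a <- structure@atoms
  tab <- data.frame(resid = a$resid, resname = toupper(a$resname),
                    name = toupper(a$name), stringsAsFactors = FALSE)
  mask <- selParse(toks, tab)
  idx <- which(mask)
  if (!length(idx))
    oxStop(paste("selection matched no atoms:", spec),
           "oxfold_empty_selection")
  new("AtomSet", indices = as.integer(idx),
      universeSize = nrow(a), label = spec)
}

#' Complement of an atom set within its universe
#'
#' @param set an [AtomSet-class].
#' @param universe optional [AtomSet-class] to complement within (defaults
#'   to the whole structure the set was built from).
#' @return an [AtomSet-class].
#' @export
complementSet <- function(set, universe = NULL) {
  all <- if (is.null(universe)) seq_len(set@universeSize)
         else universe@indices
  idx <- setdiff(all, set@indices)
  if (!length(idx))
    oxStop("complement is empty", "oxfold_empty_selection")
  new("AtomSet", indices = as.integer(sort(idx)),
      universeSize = set@universeSize,
      label = paste0("not(", set@label, ")"))
}

#' Build an AtomSet from explicit indices
#'
#' @param indices 1-based atom positions.
#' @param universeSize number of atoms in the parent structure.
#' @param label description.
#' @return an [AtomSet-class].
#' @export
atomSet <- function(indices, universeSize, label = "") {
  new("AtomSet", indices = as.integer(sort(unique(indices))),
      universeSize = as.integer(universeSize), label = label)
}
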