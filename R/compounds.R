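# The 22-compound 2-substituted pyridine library: loading, validation and
# constitutional descriptors.

#' Load the pyridine compound library
#'
#' Reads a compound table (by default the packaged 22-compound fixture of
#' 2-(thiofluoroalkyl)- and 2-(sulfonylfluoroalkyl)pyridines with their
#' printed experimental logD at pH 7.4 and pKa values), parses every SMILES,
#' and validates the structural invariants: the fluorine count implied by the
#' substituent name matches the parsed structure, sulfones carry exactly two
#' oxygens on sulfur, thioethers none.
#'
#' Experimental values are stored exactly as printed to two decimals; values
#' that were never determined (the two water-unstable compounds have no logD,
#' sulfones and some thioethers no pKa) are `NA`, never zero.
#'
#' @param path CSV file with columns
#'   `id,name,smiles,series,sulfur_state,logd_exp,pka_exp`. Defaults to the
#'   packaged fixture.
#' @return A data.frame of class `compound_library` with an added
#'   `n_fluorine` column and a `structures` attribute holding the parsed
#'   graphs (named by compound id).
#' @examples
#' lib <- load_compounds()
#' subset(lib, sulfur_state == "thioether", c(id, name, logd_exp, pka_exp))
#' @export
load_compounds <- function(path = system.file("extdata", "pyridines.csv",
                                              package = "thiofluor")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "name", "smiles", "series", "sulfur_state",
                "logd_exp", "pka_exp")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("compound table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(df$series %in% c("methyl", "ethyl")))
    stop("series must be 'methyl' or 'ethyl'")
  if (!all(df$sulfur_state %in% c("thioether", "sulfone")))
    stop("sulfur_state must be 'thioether' or 'sulfone'")
  if (anyDuplicated(df$id)) stop("duplicate compound ids")

  structures <- lapply(df$smiles, parse_structure)
  names(structures) <- as.character(df$id)
  df$n_fluorine <- vapply(structures, function(g) sum(g$atoms$element == "F"),
                          numeric(1))

  for (k in seq_len(nrow(df))) {
    g <- structures[[k]]
    n_oxo <- oxygens_on_sulfur(g)
    want <- if (df$sulfur_state[k] == "sulfone") 2L else 0L
    if (n_oxo != want)
      stop(sprintf("compound %s: %s should have %d oxygens on sulfur, found %d",
                   df$id[k], df$sulfur_state[k], want, n_oxo))
    implied <- fluorines_from_name(df$name[k])
    if (!is.na(implied) && implied != df$n_fluorine[k])
      stop(sprintf("compound %s: name implies %d fluorines, structure has %d",
                   df$id[k], implied, df$n_fluorine[k]))
  }
  attr(df, "structures") <- structures
  class(df) <- c("compound_library", "data.frame")
  df
}

oxygens_on_sulfur <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  s_idx <- which(a$element == "S")
  total <- 0L
  for (i in s_idx) {
    rows <- which(b$from == i | b$to == i)
    nb <- ifelse(b$from[rows] == i, b$to[rows], b$from[rows])
    total <- total + sum(a$element[nb] == "O")
  }
  total
}

# Fluorine count implied by the substituent name; NA when the name carries
# no fluorine prefix information.
fluorines_from_name <- function(name) {
  n <- tolower(name)
  if (!grepl("fluoro", n)) return(0L)
  if (grepl("perfluoroethyl", n)) return(5L)
  if (grepl("perfluoromethyl", n)) return(3L)
  count <- if (grepl("tetrafluoro", n)) 4L else if (grepl("trifluoro", n)) 3L
           else if (grepl("difluoro", n)) 2L else 1L
  count
}

#' Count fluorine atoms (#F)
#'
#' @param x A `mol_graph`, a SMILES string, or a `compound_library` (in which
#'   case a named vector over the library is returned).
#' @return Non-negative integer count(s); the descriptor labelled "#F".
#' @export
count_fluorines <- function(x) {
  if (inherits(x, "compound_library")) {
    out <- x$n_fluorine
    names(out) <- as.character(x$id)
    return(out)
  }
  if (is.character(x)) x <- parse_structure(x)
  stopifnot(inherits(x, "mol_graph"))
  sum(x$atoms$element == "F")
}

#' Constitutional descriptors for one molecule
#'
#' @param mol A `mol_graph` or SMILES string.
#' @return Named numeric vector: `n_atoms` (including hydrogens),
#'   `n_heavy`, `#F`, `MW`, `TPSA`.
#' @export
constitutional_descriptors <- function(mol) {
  if (is.character(mol)) mol <- parse_structure(mol)
  stopifnot(inherits(mol, "mol_graph"))
  n_heavy <- nrow(mol$atoms)
  c("n_atoms" = n_heavy + sum(mol$atoms$h_count),
    "n_heavy" = n_heavy,
    "#F" = count_fluorines(mol),
    "MW" = molecular_weight(mol),
    "TPSA" = tpsa(mol))
}

#' Constitutional descriptor table for a compound library
#'
#' @param library A `compound_library` from [load_compounds()].
#' @return A [descriptor_table] with provenance "constitutional".
#' @export
library_descriptors <- function(library) {
  stopifnot(inherits(library, "compound_library"))
  structures <- attr(library, "structures")
  mat <- t(vapply(structures, constitutional_descriptors, numeric(5)))
  rownames(mat) <- as.character(library$id)
  descriptor_table(mat, provenance = "constitutional")
}
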