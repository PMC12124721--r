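# Minimal SMILES machinery for the small neutral organics handled here.
# Covers the organic subset (B C N O P S F Cl Br I, aromatic b c n o p s),
# bracket atoms with explicit H/charge, branches, ring closures (incl. %nn),
# and single/double/triple/aromatic bonds. No stereochemistry.

STANDARD_ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998403, P = 30.973762, S = 32.06, Cl = 35.45, Br = 79.904,
  I = 126.90447
)

# Default valences used to assign implicit hydrogens; hypervalent states
# (e.g. sulfonyl S) pick the smallest listed valence >= bond-order sum.
DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

smiles_error <- function(smiles, pos, what) {
  stop(sprintf("SMILES parse error in %s at position %d: %s",
               dQuote(smiles), pos, what), call. = FALSE)
}

tokenize_smiles <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- list()
  i <- 1L
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) smiles_error(smiles, i, "unterminated bracket atom")
      push("bracket_atom", paste(chars[(i + 1L):(j - 1L)], collapse = ""), i)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      push("atom", paste0(ch, chars[i + 1L]), i)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "p", "s")) {
      push("atom", ch, i)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      push("bond", ch, i)
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      push("ring", ch, i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("[0-9][0-9]", paste0(chars[i + 1L], chars[i + 2L])))
        smiles_error(smiles, i, "expected two digits after '%'")
      push("ring", paste0(chars[i + 1L], chars[i + 2L]), i)
      i <- i + 3L
    } else if (ch == "(") {
      push("open", "(", i); i <- i + 1L
    } else if (ch == ")") {
      push("close", ")", i); i <- i + 1L
    } else if (ch == ".") {
      smiles_error(smiles, i, "disconnected structures ('.') are not supported")
    } else {
      smiles_error(smiles, i, sprintf("unexpected token %s", dQuote(ch)))
    }
  }
  tokens
}

parse_bracket_atom <- function(body, smiles, pos) {
  # [<isotope><symbol><chiral><Hcount><charge>]
  m <- regmatches(body, regexec(
    "^([0-9]*)(se|as|[A-Z][a-z]?|[bcnops])(@{0,2})(H([0-9]*))?((\\+{1,2}|-{1,2})([0-9]*)?)?$",
    body))[[1]]
  if (length(m) == 0L)
    smiles_error(smiles, pos, sprintf("cannot interpret bracket atom [%s]", body))
  sym <- m[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  } else sym
  if (!element %in% c(names(DEFAULT_VALENCES), "H"))
    smiles_error(smiles, pos,
                 sprintf("unsupported element %s in bracket atom", dQuote(sym)))
  h <- if (m[5] == "") 0L else if (m[6] == "") 1L else as.integer(m[6])
  charge <- 0L
  if (m[7] != "") {
    sign <- if (substr(m[8], 1, 1) == "+") 1L else -1L
    mag <- if (!is.na(m[9]) && m[9] != "") as.integer(m[9]) else nchar(m[8])
    charge <- sign * mag
  }
  list(element = element, aromatic = aromatic, h_explicit = h,
       charge = charge, bracket = TRUE)
}

#' Parse a SMILES string into an atom/bond graph
#'
#' Produces the element and bond multiset needed for atom counting, implicit
#' hydrogen assignment, molecular weight, and fragment-based TPSA typing.
#' Parsing is deterministic; stereo markers are accepted and ignored.
#'
#' @param smiles A single SMILES string for a neutral organic molecule.
#' @return An object of class `mol_graph`: a list with `atoms` (data.frame of
#'   `element`, `aromatic`, `charge`, `h_count`) and `bonds` (data.frame of
#'   `from`, `to`, `order`, `aromatic`).
#' @examples
#' g <- parse_structure("FC(F)(F)Sc1ccccn1")
#' sum(g$atoms$element == "F")
#' @export
parse_structure <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (nchar(smiles) == 0L) smiles_error(smiles, 1L, "empty string")
  tokens <- tokenize_smiles(smiles)

  atoms <- list()
  bonds <- list()
  prev <- NA_integer_       # index of previous atom
  stack <- integer(0)       # branch stack
  pending_bond <- NULL      # bond symbol awaiting next atom
  ring_open <- list()       # ring-closure bookkeeping

  add_atom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    length(atoms)
  }
  add_bond <- function(from, to, symbol, arom_pair) {
    if (is.null(symbol) || symbol %in% c("/", "\\")) {
      order <- if (arom_pair) 1.5 else 1
      aromatic <- arom_pair
    } else {
      order <- switch(symbol, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5)
      aromatic <- identical(symbol, ":")
    }
    bonds[[length(bonds) + 1L]] <<- list(from = from, to = to,
                                         order = order, aromatic = aromatic)
  }

  for (tok in tokens) {
    if (tok$type %in% c("atom", "bracket_atom")) {
      a <- if (tok$type == "bracket_atom") {
        parse_bracket_atom(tok$value, smiles, tok$pos)
      } else {
        sym <- tok$value
        aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
        element <- if (aromatic) toupper(sym) else sym
        if (!element %in% names(DEFAULT_VALENCES))
          smiles_error(smiles, tok$pos,
                       sprintf("element %s outside the organic subset", dQuote(sym)))
        list(element = element, aromatic = aromatic, h_explicit = NA_integer_,
             charge = 0L, bracket = FALSE)
      }
      idx <- add_atom(a)
      if (!is.na(prev)) {
        arom_pair <- atoms[[prev]]$aromatic && a$aromatic
        add_bond(prev, idx, pending_bond, arom_pair)
      }
      pending_bond <- NULL
      prev <- idx
    } else if (tok$type == "bond") {
      pending_bond <- tok$value
    } else if (tok$type == "ring") {
      if (is.na(prev)) smiles_error(smiles, tok$pos, "ring digit before any atom")
      key <- tok$value
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- list(atom = prev, bond = pending_bond)
      } else {
        partner <- ring_open[[key]]
        sym <- if (!is.null(pending_bond)) pending_bond else partner$bond
        arom_pair <- atoms[[partner$atom]]$aromatic && atoms[[prev]]$aromatic
        add_bond(partner$atom, prev, sym, arom_pair)
        ring_open[[key]] <- NULL
      }
      pending_bond <- NULL
    } else if (tok$type == "open") {
      if (is.na(prev)) smiles_error(smiles, tok$pos, "branch before any atom")
      stack <- c(stack, prev)
    } else if (tok$type == "close") {
      if (length(stack) == 0L) smiles_error(smiles, tok$pos, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    }
  }
  open_rings <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_rings) > 0L)
    smiles_error(smiles, nchar(smiles),
                 sprintf("unclosed ring bond(s): %s", paste(open_rings, collapse = ", ")))
  if (length(stack) > 0L)
    smiles_error(smiles, nchar(smiles), "unclosed branch '('")

  atom_df <- data.frame(
    element = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), integer(1)),
    h_explicit = vapply(atoms, function(a) as.integer(a$h_explicit), integer(1)),
    stringsAsFactors = FALSE
  )
  bond_df <- if (length(bonds) > 0L) {
    data.frame(
      from = vapply(bonds, `[[`, numeric(1), "from"),
      to = vapply(bonds, `[[`, numeric(1), "to"),
      order = vapply(bonds, `[[`, numeric(1), "order"),
      aromatic = vapply(bonds, `[[`, logical(1), "aromatic")
    )
  } else {
    data.frame(from = numeric(0), to = numeric(0), order = numeric(0),
               aromatic = logical(0))
  }

  atom_df$h_count <- assign_implicit_h(atom_df, bond_df, smiles)
  structure(list(atoms = atom_df, bonds = bond_df, smiles = smiles),
            class = "mol_graph")
}

# Bond-order sum per atom; aromatic bonds count 1.5 and aromatic atoms gain
# +0.5 overall (so aromatic C with two ring bonds carries one H, aromatic N
# with two ring bonds carries none -- the usual Kekule-free accounting).
bond_order_sums <- function(atoms, bonds) {
  s <- numeric(nrow(atoms))
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      s[bonds$from[k]] <- s[bonds$from[k]] + bonds$order[k]
      s[bonds$to[k]] <- s[bonds$to[k]] + bonds$order[k]
    }
  }
  s + ifelse(atoms$aromatic, 0.5, 0)
}

assign_implicit_h <- function(atoms, bonds, smiles) {
  bsum <- bond_order_sums(atoms, bonds)
  h <- integer(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    if (!is.na(atoms$h_explicit[i])) {  # bracket atom: explicit H only
      h[i] <- atoms$h_explicit[i]
      next
    }
    valences <- DEFAULT_VALENCES[[atoms$element[i]]]
    # aromatic accounting leaves half-integer sums (two ring bonds at 1.5
    # plus the 0.5 atom correction); rounding down reproduces the usual
    # rules: benzene C -> 1H, pyridine-type n -> 0H
    need <- floor(bsum[i] + 1e-9)
    v <- valences[valences >= need]
    h[i] <- if (length(v) == 0L) 0L else as.integer(v[1] - need)
  }
  h
}

#' @export
print.mol_graph <- function(x, ...) {
  comp <- table(x$atoms$element)
  htot <- sum(x$atoms$h_count)
  formula <- paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
  cat(sprintf("<mol_graph> %s  heavy formula %s + %dH, %d bonds\n",
              x$smiles, formula, htot, nrow(x$bonds)))
  invisible(x)
}

# Ertl fragment contributions for the polar atom environments occurring in
# the pyridine library, plus a few common neighbours for robustness. Atoms
# of N/O/S type that match no row raise an error rather than contributing 0.
TPSA_CONTRIBUTIONS <- data.frame(
  label = c("n_aromatic_2conn", "n_aromatic_3conn", "nH_aromatic",
            "N_amine_3conn", "NH_amine", "NH2_amine", "N_nitrile",
            "O_ether", "OH_hydroxyl", "O_double",
            "S_thioether", "S_sulfoxide", "S_sulfone", "SH_thiol",
            "S_double"),
  contribution = c(12.89, 4.41, 15.79,
                   3.24, 12.03, 26.02, 23.79,
                   9.23, 20.23, 17.07,
                   25.30, 19.21, 8.38, 38.80,
                   32.09),
  stringsAsFactors = FALSE
)

classify_polar_atom <- function(i, atoms, bonds) {
  el <- atoms$element[i]
  h <- atoms$h_count[i]
  arom <- atoms$aromatic[i]
  rows <- which(bonds$from == i | bonds$to == i)
  deg <- length(rows)
  n_double <- sum(bonds$order[rows] == 2)
  n_triple <- sum(bonds$order[rows] == 3)
  if (el == "N") {
    if (arom && deg == 2 && h == 0) return("n_aromatic_2conn")
    if (arom && deg == 3 && h == 0) return("n_aromatic_3conn")
    if (arom && deg == 2 && h == 1) return("nH_aromatic")
    if (n_triple == 1 && deg == 1) return("N_nitrile")
    if (!arom && n_double == 0 && h == 0 && deg == 3) return("N_amine_3conn")
    if (!arom && n_double == 0 && h == 1 && deg == 2) return("NH_amine")
    if (!arom && n_double == 0 && h == 2 && deg == 1) return("NH2_amine")
  } else if (el == "O") {
    if (n_double == 1 && deg == 1 && h == 0) return("O_double")
    if (n_double == 0 && deg == 2 && h == 0) return("O_ether")
    if (n_double == 0 && deg == 1 && h == 1) return("OH_hydroxyl")
  } else if (el == "S") {
    # count doubly-bonded oxygens to distinguish oxidation states
    nb <- ifelse(bonds$from[rows] == i, bonds$to[rows], bonds$from[rows])
    n_oxo <- sum(atoms$element[nb] == "O" & bonds$order[rows] == 2)
    if (n_oxo == 2 && deg == 4) return("S_sulfone")
    if (n_oxo == 1 && deg == 3) return("S_sulfoxide")
    if (n_double == 1 && deg == 1) return("S_double")
    if (deg == 2 && h == 0 && n_double == 0) return("S_thioether")
    if (deg == 1 && h == 1) return("SH_thiol")
  }
  NA_character_
}

#' Topological polar surface area by fragment contributions
#'
#' Sums published fragment contributions over the polar (N, O, S) atom
#' environments present in the molecule. Coverage is intentionally limited
#' to the environments occurring in the 2-substituted pyridine library
#' (aromatic N, thioether S, sulfonyl S and O) plus a handful of common
#' neighbours; an N/O/S atom matching no tabulated environment is an error,
#' never a silent zero.
#'
#' @param mol A `mol_graph` from [parse_structure()].
#' @return TPSA in squared Angstroms.
#' @export
tpsa <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  atoms <- mol$atoms
  bonds <- mol$bonds
  polar <- which(atoms$element %in% c("N", "O", "S"))
  total <- 0
  for (i in polar) {
    lab <- classify_polar_atom(i, atoms, bonds)
    if (is.na(lab)) {
      stop(sprintf(
        "no TPSA contribution tabulated for %s atom %d in %s (aromatic=%s, H=%d)",
        atoms$element[i], i, mol$smiles, atoms$aromatic[i], atoms$h_count[i]),
        call. = FALSE)
    }
    total <- total +
      TPSA_CONTRIBUTIONS$contribution[TPSA_CONTRIBUTIONS$label == lab]
  }
  total
}

#' Molecular weight from the parsed graph
#'
#' @param mol A `mol_graph`.
#' @return Average molecular weight in g/mol, including implicit hydrogens.
#' @export
molecular_weight <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  sum(STANDARD_ATOMIC_WEIGHTS[mol$atoms$element]) +
    sum(mol$atoms$h_count) * STANDARD_ATOMIC_WEIGHTS[["H"]]
}
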