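# Descriptor table container: assembly, transform expansion, min-max scaling.

RESERVED_DESCRIPTOR_NAMES <- c("#F", "q_S", "q_N", "q_O", "TPSA", "QPSA",
                               "dG_wat", "E_HOMO", "dipole", "volume")
QPSA_ALIASES <- c("QPSA", "QMPSA")  # one descriptor, two names in the wild

#' Construct a descriptor table
#'
#' A compounds-by-descriptors numeric matrix with per-column provenance
#' (`constitutional`, `dft_ingested` or `transform`), a record of any
#' min-max scaling applied, and for transform columns the parent column and
#' transform name.
#'
#' @param values Numeric matrix, rows = compounds (rownames are compound
#'   ids), columns = descriptors (colnames are descriptor names).
#' @param provenance Single string or per-column character vector.
#' @param scaling `NULL` (unscaled) or a data.frame `name,min,max`.
#' @param transforms data.frame `name,parent,transform` for transform columns.
#' @return An object of class `descriptor_table`.
#' @export
descriptor_table <- function(values, provenance = "dft_ingested",
                             scaling = NULL,
                             transforms = empty_transform_record()) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("values must carry compound ids as rownames")
  if (is.null(colnames(values))) stop("values must carry descriptor names as colnames")
  if (length(provenance) == 1L)
    provenance <- stats::setNames(rep(provenance, ncol(values)), colnames(values))
  stopifnot(length(provenance) == ncol(values))
  names(provenance) <- colnames(values)
  structure(list(values = values, provenance = provenance,
                 scaling = scaling, transforms = transforms),
            class = "descriptor_table")
}

empty_transform_record <- function() {
  data.frame(name = character(0), parent = character(0),
             transform = character(0), stringsAsFactors = FALSE)
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("<descriptor_table> %d compounds x %d descriptors (%s)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$scaling)) "unscaled" else "min-max scaled"))
  prov <- table(x$provenance)
  cat("  provenance:", paste(sprintf("%s=%d", names(prov), prov), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

#' @export
as.data.frame.descriptor_table <- function(x, ...) {
  data.frame(compound_id = rownames(x$values), x$values,
             check.names = FALSE, stringsAsFactors = FALSE)
}

compound_ids <- function(t) rownames(t$values)
descriptor_names <- function(t) colnames(t$values)

#' Read a DFT descriptor CSV and merge it with existing descriptors
#'
#' The CSV carries one compound per row, compound id in the first column and
#' numeric descriptor columns after it (the shape of a supporting-information
#' table of Mulliken charges, orbital energies, solvation free energies and
#' the like). Cells must be numeric: a non-numeric cell is reported with its
#' row and column address. The alias "QMPSA" is normalised to "QPSA".
#'
#' @param path CSV path ('.' decimal separator, header row).
#' @param base Optional `descriptor_table` (e.g. constitutional descriptors)
#'   to merge with by compound id. Column name collisions are an error;
#'   compounds present in only one source are dropped with a warning.
#' @return A `descriptor_table` with provenance recorded per column.
#' @export
ingest_dft_descriptors <- function(path, base = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("descriptor CSV needs an id column plus >=1 descriptor")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate compound ids in ", path)
  cols <- names(df)[-1L]
  mat <- matrix(NA_real_, nrow(df), length(cols),
                dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(is.na(raw) | raw %in% c("", "NA")))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric cell at row %d, column %s in %s: %s",
                   bad[1L], dQuote(cols[j]), path, dQuote(raw[bad[1L]])))
    if (anyNA(num))
      stop(sprintf("missing value at row %d, column %s in %s",
                   which(is.na(num))[1L], dQuote(cols[j]), path))
    mat[, j] <- num
  }
  colnames(mat)[colnames(mat) == "QMPSA"] <- "QPSA"
  tab <- descriptor_table(mat, provenance = "dft_ingested")
  if (is.null(base)) return(tab)
  merge_descriptors(base, tab)
}

#' Merge two descriptor tables by compound id
#'
#' @param a,b `descriptor_table` objects (both unscaled).
#' @return Merged `descriptor_table` over the common compounds.
#' @export
merge_descriptors <- function(a, b) {
  stopifnot(inherits(a, "descriptor_table"), inherits(b, "descriptor_table"))
  if (!is.null(a$scaling) || !is.null(b$scaling))
    stop("merge descriptor tables before scaling")
  clash <- intersect(descriptor_names(a), descriptor_names(b))
  if (length(clash) > 0L)
    stop("descriptor name collision: ", paste(clash, collapse = ", "))
  common <- intersect(compound_ids(a), compound_ids(b))
  if (length(common) == 0L) stop("no common compound ids to merge on")
  dropped <- setdiff(union(compound_ids(a), compound_ids(b)), common)
  if (length(dropped) > 0L)
    warning("dropping compounds absent from one source: ",
            paste(dropped, collapse = ", "))
  values <- cbind(a$values[common, , drop = FALSE],
                  b$values[common, , drop = FALSE])
  descriptor_table(values,
                   provenance = c(a$provenance, b$provenance),
                   transforms = rbind(a$transforms, b$transforms))
}

DEFAULT_TRANSFORMS <- c("inverse", "square", "inverse_square", "log")

transform_fun <- function(name) {
  switch(name,
         inverse = function(x) 1 / x,
         square = function(x) x^2,
         inverse_square = function(x) 1 / x^2,
         log = function(x) log10(x),
         stop("unknown transform: ", name))
}

transform_colname <- function(transform, parent) {
  switch(transform,
         inverse = paste0("1/", parent),
         square = paste0(parent, "^2"),
         inverse_square = paste0("1/", parent, "^2"),
         log = paste0("log(", parent, ")"))
}

transform_valid <- function(transform, x) {
  switch(transform,
         inverse = all(abs(x) > 1e-12),
         inverse_square = all(abs(x) > 1e-12),
         square = TRUE,
         log = all(x > 0))
}

#' Expand a descriptor table with nonlinear transforms
#'
#' For each base column x, adds 1/x, x^2, 1/x^2 and log10(x) columns, each
#' only where the transform is finite on every compound (inverses require no
#' zero, log requires strictly positive values throughout). Invalid
#' transforms are skipped whole-column and logged via `message()`, never
#' partially applied. Must be applied before scaling: transform semantics
#' change on scaled values.
#'
#' @param t An unscaled `descriptor_table`.
#' @param transforms Character subset of
#'   `c("inverse", "square", "inverse_square", "log")`.
#' @return A `descriptor_table` with the added columns (provenance
#'   "transform", parent and transform recorded).
#' @export
expand_transforms <- function(t, transforms = DEFAULT_TRANSFORMS) {
  stopifnot(inherits(t, "descriptor_table"))
  if (!is.null(t$scaling)) stop("expand transforms before scaling")
  stopifnot(all(transforms %in% DEFAULT_TRANSFORMS))
  base_cols <- descriptor_names(t)[t$provenance != "transform"]
  new_cols <- list()
  record <- empty_transform_record()
  for (col in base_cols) {
    x <- t$values[, col]
    for (tr in transforms) {
      nm <- transform_colname(tr, col)
      if (nm %in% descriptor_names(t)) next
      if (!transform_valid(tr, x)) {
        message(sprintf("skipping %s on %s: not finite on all compounds", tr, col))
        next
      }
      new_cols[[nm]] <- transform_fun(tr)(x)
      record <- rbind(record, data.frame(name = nm, parent = col,
                                         transform = tr,
                                         stringsAsFactors = FALSE))
    }
  }
  if (length(new_cols) == 0L) return(t)
  add <- do.call(cbind, new_cols)
  rownames(add) <- compound_ids(t)
  values <- cbind(t$values, add)
  descriptor_table(values,
                   provenance = c(t$provenance,
                                  stats::setNames(rep("transform", ncol(add)),
                                                  colnames(add))),
                   transforms = rbind(t$transforms, record))
}

#' Min-max scale every descriptor column to [0, 1]
#'
#' x' = (x - min)/(max - min) per column; the (min, max) pair of each column
#' is stored on the table so that prediction inputs can be scaled with the
#' training ranges later. Constant columns (range < `tol`) are dropped with
#' a warning before scaling. Scaling an already scaled table is the identity.
#'
#' @param t A `descriptor_table`.
#' @param tol Range below which a column counts as constant.
#' @return A scaled `descriptor_table`; every column spans [0, 1] with the
#'   min attained at 0 and the max at 1.
#' @export
scale_minmax <- function(t, tol = 1e-12) {
  stopifnot(inherits(t, "descriptor_table"))
  rng <- apply(t$values, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  constant <- span < tol
  if (any(constant)) {
    warning("dropping constant descriptor column(s): ",
            paste(colnames(t$values)[constant], collapse = ", "))
    t$values <- t$values[, !constant, drop = FALSE]
    t$provenance <- t$provenance[!constant]
    rng <- rng[, !constant, drop = FALSE]
    span <- span[!constant]
  }
  if (ncol(t$values) == 0L) stop("no non-constant descriptor columns left")
  scaled <- sweep(sweep(t$values, 2L, rng[1L, ], "-"), 2L, span, "/")
  prior <- t$scaling  # compose with any earlier scaling
  record <- data.frame(name = colnames(t$values),
                       min = rng[1L, ], max = rng[2L, ],
                       stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(prior)) {
    i <- match(record$name, prior$name)
    keep <- !is.na(i)
    # x'' = (x' - m)/(M - m) with x' = (x - a)/(b - a)  =>  affine in x
    a <- prior$min[i[keep]]; b <- prior$max[i[keep]]
    record$min[keep] <- a + record$min[keep] * (b - a)
    record$max[keep] <- a + record$max[keep] * (b - a)
  }
  descriptor_table(scaled, provenance = t$provenance, scaling = record,
                   transforms = t$transforms)
}

#' Invert min-max scaling
#'
#' @param t A scaled `descriptor_table`.
#' @return The table on the original descriptor scale.
#' @export
inverse_scale <- function(t) {
  stopifnot(inherits(t, "descriptor_table"))
  if (is.null(t$scaling)) stop("table is not scaled")
  s <- t$scaling[match(colnames(t$values), t$scaling$name), ]
  raw <- sweep(sweep(t$values, 2L, s$max - s$min, "*"), 2L, s$min, "+")
  descriptor_table(raw, provenance = t$provenance, scaling = NULL,
                   transforms = t$transforms)
}

#' Write a descriptor table as CSV
#'
#' Emits the same dialect the readers accept: header row, compound id first,
#' '.' decimal separator.
#'
#' @param t A `descriptor_table`.
#' @param path Output CSV path.
#' @export
write_descriptors <- function(t, path) {
  stopifnot(inherits(t, "descriptor_table"))
  df <- as.data.frame(t)
  # %.17g round-trips IEEE doubles exactly, so write -> read -> write is
  # bit-stable
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
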