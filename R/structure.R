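#' Atomic structure container
#'
#' Creates an `atomic_structure`: element symbols, Cartesian coordinates in
#' Angstrom, per-atom masses in amu (derived from the symbols unless
#' overridden), total charge and spin multiplicity.
#'
#' @param symbols Character vector of element symbols.
#' @param coordinates Numeric N x 3 matrix of positions in Angstrom.
#' @param masses Optional numeric vector of masses in amu; defaults to the
#'   standard atomic weights of `symbols`.
#' @param charge Integer total charge (default 0).
#' @param multiplicity Integer spin multiplicity (default 1).
#' @param comment Optional comment string (carried through XYZ I/O).
#' @return An object of class `atomic_structure`.
#' @export
atomic_structure <- function(symbols, coordinates, masses = NULL,
                             charge = 0L, multiplicity = 1L, comment = "") {
  symbols <- as.character(symbols)
  coordinates <- matrix(as.numeric(coordinates), ncol = 3)
  n <- length(symbols)
  if (nrow(coordinates) != n)
    stop("coordinates must have one row per symbol", call. = FALSE)
  if (n > 0 && !all(is.finite(coordinates)))
    stop("coordinates must be finite", call. = FALSE)
  if (is.null(masses)) {
    masses <- if (n > 0) unname(atomic_mass(symbols)) else numeric(0)
  } else {
    masses <- as.numeric(masses)
    if (length(masses) != n) stop("need one mass per atom", call. = FALSE)
  }
  if (any(masses <= 0)) stop("all masses must be > 0", call. = FALSE)
  dimnames(coordinates) <- NULL
  structure(list(symbols = symbols, coordinates = coordinates,
                 masses = masses, charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 comment = as.character(comment)),
            class = "atomic_structure")
}

#' Number of atoms in a structure
#' @param structure An `atomic_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) length(structure$symbols)

#' @export
print.atomic_structure <- function(x, ...) {
  cat("<atomic_structure> ", n_atoms(x), " atoms",
      if (nzchar(x$comment)) paste0(" | ", x$comment), "\n", sep = "")
  invisible(x)
}

#' Read a structure from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `symbol x y z` line per atom (coordinates in Angstrom). The comment line
#' is preserved and may carry `charge=` / `multiplicity=` key=value tokens,
#' which are picked up.
#'
#' @param path Path to an XYZ file.
#' @return An [atomic_structure()].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("empty XYZ file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0)
    stop("malformed atom count on line 1 of ", path, call. = FALSE)
  comment <- if (length(lines) >= 2) lines[2] else ""
  if (length(lines) < 2 + n)
    stop("XYZ file ", path, " declares ", n, " atoms but has only ",
         max(0L, length(lines) - 2L), " atom lines", call. = FALSE)
  symbols <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[2 + i]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop("malformed atom line ", 2 + i, " in ", path, call. = FALSE)
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop("non-numeric coordinate on line ", 2 + i, " in ", path,
           call. = FALSE)
    symbols[i] <- tok[1]
    coords[i, ] <- xyz
  }
  kv <- .parse_comment_kv(comment)
  atomic_structure(symbols, coords,
                   charge = if (!is.null(kv$charge)) as.integer(kv$charge) else 0L,
                   multiplicity = if (!is.null(kv$multiplicity))
                     as.integer(kv$multiplicity) else 1L,
                   comment = comment)
}

.parse_comment_kv <- function(comment) {
  tok <- strsplit(trimws(comment), "\\s+")[[1]]
  tok <- tok[grepl("=", tok, fixed = TRUE)]
  out <- list()
  for (t in tok) {
    parts <- strsplit(t, "=", fixed = TRUE)[[1]]
    if (length(parts) == 2) out[[tolower(parts[1])]] <- parts[2]
  }
  out
}

#' Write a structure to an XYZ file
#'
#' @param structure An [atomic_structure()].
#' @param path Output path.
#' @param digits Number of coordinate decimals (>= 6).
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(structure, path, digits = 10) {
  stopifnot(inherits(structure, "atomic_structure"), digits >= 6)
  n <- n_atoms(structure)
  comment <- structure$comment
  if (!nzchar(comment) && (structure$charge != 0L || structure$multiplicity != 1L))
    comment <- sprintf("charge=%d multiplicity=%d",
                       structure$charge, structure$multiplicity)
  body <- if (n > 0) {
    sprintf(paste0("%-3s %", digits + 6, ".", digits, "f %",
                   digits + 6, ".", digits, "f %", digits + 6, ".", digits, "f"),
            structure$symbols, structure$coordinates[, 1],
            structure$coordinates[, 2], structure$coordinates[, 3])
  } else character(0)
  writeLines(c(as.character(n), comment, body), con = path)
  invisible(path)
}
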