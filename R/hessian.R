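#' Hessian container
#'
#' Holds a symmetric 3N x 3N second-derivative matrix together with the N
#' atom indices it spans. Partial Hessians (environment atoms frozen) span
#' only the atoms of a QM region; `frozen_context = TRUE` marks them.
#'
#' @param matrix Symmetric 3N x 3N numeric matrix (Hartree/Bohr^2 by
#'   default).
#' @param atom_ids Integer vector of the N atoms spanned, in row-block
#'   order.
#' @param frozen_context Logical; `TRUE` when environment atoms were frozen.
#' @param units Unit label, `"hartree_bohr2"` (default) or `"si"`.
#' @return An object of class `hessian_data`.
#' @export
hessian_data <- function(matrix, atom_ids, frozen_context = FALSE,
                         units = "hartree_bohr2") {
  matrix <- as.matrix(matrix)
  atom_ids <- as.integer(atom_ids)
  if (nrow(matrix) != ncol(matrix) || nrow(matrix) != 3L * length(atom_ids))
    stop("Hessian dimension must be 3 x number of atoms", call. = FALSE)
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-8 * max(1, max(abs(matrix))))
    stop("Hessian is not symmetric (max asymmetry ", signif(asym, 3), ")",
         call. = FALSE)
  matrix <- (matrix + t(matrix)) / 2
  structure(list(matrix = matrix, atom_ids = atom_ids,
                 frozen_context = isTRUE(frozen_context), units = units),
            class = "hessian_data")
}

#' Read a plain-text Hessian file
#'
#' Whitespace-delimited 3N x 3N matrix, row-major.
#'
#' @param path File path.
#' @param atom_ids Atom indices the Hessian spans; defaults to `1..N`.
#' @inheritParams hessian_data
#' @return A [hessian_data()].
#' @export
read_hessian <- function(path, atom_ids = NULL, frozen_context = FALSE,
                         units = "hartree_bohr2") {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  dim3n <- sqrt(length(vals))
  if (dim3n != round(dim3n) || round(dim3n) %% 3 != 0)
    stop("Hessian file must contain a square 3N x 3N matrix; got ",
         length(vals), " values", call. = FALSE)
  dim3n <- as.integer(dim3n)
  H <- matrix(vals, dim3n, dim3n, byrow = TRUE)
  if (is.null(atom_ids)) atom_ids <- seq_len(dim3n %/% 3L)
  hessian_data(H, atom_ids, frozen_context, units)
}

#' Write a Hessian to a plain-text file
#'
#' @param hessian A [hessian_data()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hessian <- function(hessian, path) {
  stopifnot(inherits(hessian, "hessian_data"))
  lines <- apply(hessian$matrix, 1, function(r)
    paste(sprintf("% .12e", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
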