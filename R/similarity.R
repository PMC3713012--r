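field_values <- function(f) if (inherits(f, "ScalarField")) f$values else as.numeric(f)

check_same_grid <- function(fa, fb) {
  if (inherits(fa, "ScalarField") && inherits(fb, "ScalarField") &&
      !same_grid(fa$grid, fb$grid)) {
    stop("fields are defined on different grids")
  }
  if (length(field_values(fa)) != length(field_values(fb))) {
    stop("fields have different lengths")
  }
}

#' Hodgkin field-similarity index
#'
#' `H = 2 sum(PA PB) / (sum(PA^2) + sum(PB^2))`, summed over all grid
#' points. Used here for electrostatic fields. Two all-zero fields are
#' identically empty and score 1; one zero field against a nonzero field
#' scores 0.
#'
#' @param fa,fb `ScalarField`s on the same grid (or plain numeric
#'   vectors of equal length).
#' @return similarity in \[-1, 1\].
#' @export
hodgkin <- function(fa, fb) {
  check_same_grid(fa, fb)
  a <- field_values(fa); b <- field_values(fb)
  den <- sum(a * a) + sum(b * b)
  if (den == 0) return(1)
  2 * sum(a * b) / den
}

#' Carbo field-similarity index
#'
#' `C = sum(PA PB) / sqrt(sum(PA^2) sum(PB^2))`. For binary shape fields
#' this equals `U / sqrt(TA TB)` with U the shared interior point count
#' and TA, TB the interior counts. Zero-field conventions as in
#' [hodgkin()].
#'
#' @inheritParams hodgkin
#' @return similarity in \[-1, 1\] (in \[0, 1\] for non-negative fields).
#' @export
carbo <- function(fa, fb) {
  check_same_grid(fa, fb)
  a <- field_values(fa); b <- field_values(fb)
  sa <- sum(a * a); sb <- sum(b * b)
  if (sa == 0 && sb == 0) return(1)
  if (sa == 0 || sb == 0) return(0)
  sum(a * b) / sqrt(sa * sb)
}

#' Meyer shape-similarity index
#'
#' Arithmetic-mean overlap form for binary fields:
#' `2 U / (TA + TB)`; coincides with the binary Carbo value only when
#' TA = TB.
#'
#' @inheritParams hodgkin
#' @return similarity in \[0, 1\].
#' @export
meyer <- function(fa, fb) {
  check_same_grid(fa, fb)
  a <- field_values(fa); b <- field_values(fb)
  den <- sum(a != 0) + sum(b != 0)
  if (den == 0) return(1)
  2 * sum(a != 0 & b != 0) / den
}

#' Assemble the double (shape + electrostatic) similarity matrix
#'
#' Shape entries use the Carbo index on binary shape fields (Meyer form
#' behind `shape_index = "meyer"`); electrostatic entries use the Hodgkin
#' index. Both matrices are symmetric with unit diagonal for molecules
#' with nonempty fields.
#'
#' @param shape_fields named list of shape `ScalarField`s, one per
#'   molecule id.
#' @param elec_fields named list of electrostatic `ScalarField`s with the
#'   same names.
#' @param shape_index `"carbo"` (default) or `"meyer"`.
#' @return object of class `SimilarityMatrix`: list with `ids`, `shape`
#'   and `electrostatic` matrices.
#' @export
build_similarity_matrix <- function(shape_fields, elec_fields,
                                    shape_index = c("carbo", "meyer")) {
  shape_index <- match.arg(shape_index)
  ids <- names(shape_fields)
  if (is.null(ids) || any(!nzchar(ids))) stop("shape_fields must be a named list")
  missing_e <- setdiff(ids, names(elec_fields))
  if (length(missing_e) > 0L) {
    stop("missing electrostatic field for molecule(s): ",
         paste(missing_e, collapse = ", "))
  }
  n <- length(ids)
  sfun <- if (shape_index == "carbo") carbo else meyer
  S <- E <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    S[i, i] <- sfun(shape_fields[[i]], shape_fields[[i]])
    E[i, i] <- hodgkin(elec_fields[[ids[i]]], elec_fields[[ids[i]]])
    if (i < n) for (j in (i + 1L):n) {
      S[i, j] <- S[j, i] <- sfun(shape_fields[[i]], shape_fields[[j]])
      E[i, j] <- E[j, i] <- hodgkin(elec_fields[[ids[i]]], elec_fields[[ids[j]]])
    }
  }
  structure(list(ids = ids, shape = S, electrostatic = E),
            class = "SimilarityMatrix")
}

#' @export
print.SimilarityMatrix <- function(x, ...) {
  off <- function(m) if (length(x$ids) > 1) range(m[upper.tri(m)]) else c(1, 1)
  rs <- off(x$shape); re <- off(x$electrostatic)
  cat(sprintf("<SimilarityMatrix: %d molecules; shape [%.3f, %.3f], electrostatic [%.3f, %.3f]>\n",
              length(x$ids), rs[1], rs[2], re[1], re[2]))
  invisible(x)
}

#' Write/read similarity matrices as CSV
#'
#' One CSV per field with molecule ids as header row and first column.
#'
#' @param sim a `SimilarityMatrix`.
#' @param shape_path,elec_path output CSV paths.
#' @return paths, invisibly.
#' @export
write_similarity_matrix <- function(sim, shape_path, elec_path) {
  utils::write.csv(sim$shape, shape_path)
  utils::write.csv(sim$electrostatic, elec_path)
  invisible(c(shape_path, elec_path))
}

#' @rdname write_similarity_matrix
#' @return for `read_similarity_matrix`, a `SimilarityMatrix`.
#' @export
read_similarity_matrix <- function(shape_path, elec_path) {
  S <- as.matrix(utils::read.csv(shape_path, row.names = 1, check.names = FALSE))
  E <- as.matrix(utils::read.csv(elec_path, row.names = 1, check.names = FALSE))
  colnames(S) <- rownames(S); colnames(E) <- rownames(E)
  if (!identical(rownames(S), rownames(E))) {
    stop("shape and electrostatic CSVs list different molecules")
  }
  structure(list(ids = rownames(S), shape = S, electrostatic = E),
            class = "SimilarityMatrix")
}
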