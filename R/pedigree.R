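## Pedigree handling and the additive (numerator) relationship matrix.

#' Normalize unknown-parent codes
#'
#' Accepts empty string, "0", "NA" and NA as unknown; returns NA_character_.
#' @noRd
normalize_parent <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == "" | x == "0" | toupper(x) == "NA"] <- NA_character_
  x
}

#' Construct and validate a pedigree
#'
#' Builds a `fh_pedigree` from id/sire/dam vectors: normalizes unknown-parent
#' codes, promotes parents that are referenced but never listed to founders
#' (with a warning), checks uniqueness and acyclicity, and sorts the entries
#' topologically (parents before offspring).
#'
#' @param id,sire,dam character vectors; `sire`/`dam` may contain unknowns
#'   encoded as `NA`, `""`, `"0"` or `"NA"`.
#' @return A data frame of class `fh_pedigree` with columns `id`, `sire`,
#'   `dam` in topological order. Promoted founders are recorded in the
#'   `"promoted_founders"` attribute.
#' @examples
#' pedigree(c("F1", "S1"), c(NA, "F1"), c(NA, NA))
#' @export
pedigree <- function(id, sire, dam) {
  id <- trimws(as.character(id))
  if (anyNA(id) || any(id == "")) stop("individual ids must be non-missing", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  sire <- normalize_parent(sire)
  dam <- normalize_parent(dam)
  if (length(sire) != length(id) || length(dam) != length(id)) {
    stop("id, sire and dam must have equal length", call. = FALSE)
  }

  ## promote parents that never appear as individuals to founders
  parents <- unique(c(sire, dam))
  parents <- parents[!is.na(parents)]
  promoted <- setdiff(parents, id)
  if (length(promoted) > 0) {
    warning("parent(s) not listed as individuals promoted to founders: ",
            paste(promoted, collapse = ", "), call. = FALSE)
    id <- c(promoted, id)
    sire <- c(rep(NA_character_, length(promoted)), sire)
    dam <- c(rep(NA_character_, length(promoted)), dam)
  }

  ## Kahn topological sort; failure to place everyone means a cycle
  n <- length(id)
  placed <- logical(n)
  order <- integer(0)
  known <- character(0)
  repeat {
    ready <- !placed &
      (is.na(sire) | sire %in% known) &
      (is.na(dam) | dam %in% known)
    if (!any(ready)) break
    order <- c(order, which(ready))
    placed[ready] <- TRUE
    known <- id[placed]
  }
  if (!all(placed)) {
    stop("pedigree contains a cycle involving: ",
         paste(id[!placed], collapse = ", "), call. = FALSE)
  }

  out <- data.frame(id = id[order], sire = sire[order], dam = dam[order],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "promoted_founders") <- promoted
  class(out) <- c("fh_pedigree", "data.frame")
  out
}

#' Read a pedigree from a delimited text file
#'
#' The file must have a header with columns `id`, `sire` and `dam`
#' (case-insensitive); comma or tab delimiters are auto-detected. Unknown
#' parents may be encoded as empty fields, `"0"` or `"NA"`. The result is
#' validated and returned in topological order; parents referenced but never
#' defined are auto-promoted to founders with a warning.
#'
#' @param path path to the pedigree file.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- read_delimited(path)
  names(df) <- tolower(names(df))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns id, sire, dam (found: ",
         paste(names(df), collapse = ", "), ")", call. = FALSE)
  }
  pedigree(df$id, df$sire, df$dam)
}

#' Write a pedigree to CSV
#'
#' @param ped a [pedigree()] object.
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  write.csv(as.data.frame(ped)[c("id", "sire", "dam")], path,
            row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.fh_pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("Pedigree: %d individuals (%d founders)\n", nrow(x), founders))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat(sprintf("... %d more rows\n", nrow(x) - 8))
  invisible(x)
}

#' Additive (numerator) relationship matrix
#'
#' Computes the expected additive relatedness matrix A by the recursive
#' tabular method: processing individuals in topological order,
#' `A[i, j] = (A[j, sire(i)] + A[j, dam(i)]) / 2` for previously processed
#' `j`, and `A[i, i] = 1 + A[sire(i), dam(i)] / 2`; unknown parents
#' contribute 0. Parent-offspring and full sibs get 0.5, half sibs 0.25, and
#' diagonals are `1 + F` where `F` is the individual's inbreeding
#' coefficient.
#'
#' @param ped a [pedigree()] object (or id/sire/dam data frame).
#' @return A symmetric matrix of class `fh_amatrix` with individual ids as
#'   dimnames, ordered as in the (topologically sorted) pedigree.
#' @examples
#' ped <- pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
#' additive_relationship_matrix(ped)["s", "o"]  # 0.5
#' @export
additive_relationship_matrix <- function(ped) {
  if (!inherits(ped, "fh_pedigree")) ped <- pedigree(ped$id, ped$sire, ped$dam)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])

  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in idx) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else 0
      ad_ <- if (d > 0L) A[j, d] else 0
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  class(A) <- c("fh_amatrix", class(A))
  A
}

#' Inbreeding coefficients from a relationship matrix
#'
#' `F_i = A[i, i] - 1`; zero for non-inbred individuals, 0.25 for offspring
#' of full-sib matings.
#'
#' @param A an [additive_relationship_matrix()].
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding_coefficients <- function(A) {
  diag(as.matrix(unclass(A))) - 1
}

#' Write / read a labelled relationship matrix as TSV
#'
#' @param A matrix with individual ids as dimnames.
#' @param path file path.
#' @return `read_relationship_matrix` returns the matrix (class
#'   `fh_amatrix`).
#' @export
write_relationship_matrix <- function(A, path) {
  df <- data.frame(id = rownames(A), as.data.frame(unclass(A), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_relationship_matrix
#' @export
read_relationship_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df[[1]]
  storage.mode(A) <- "double"
  class(A) <- c("fh_amatrix", class(A))
  A
}
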