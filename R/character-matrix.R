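# The character matrix: cells x edit sites, categorical states.
#
# States are stored as integers: 0 = unedited, 1..S = lineage-mark index,
# NA = missing (not detected). On disk missing entries are written as -1.

#' Construct a character matrix of lineage-mark states
#'
#' @param mat Integer matrix, cells in rows and edit sites in columns.
#'   Allowed values are 0 (unedited), `1..n_marks` (installed LM) and `NA`
#'   (missing, i.e. not detected).
#' @param n_marks Number of distinct lineage marks `S` in the alphabet.
#' @return An integer matrix of class `"character_matrix"` with attribute
#'   `n_marks`. Row names are cell ids, column names are edit-site ids;
#'   defaults are generated when absent.
#' @export
character_matrix <- function(mat, n_marks) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  stopifnot(length(n_marks) == 1L, n_marks >= 1)
  bad <- which(!is.na(mat) & (mat < 0L | mat > n_marks))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(mat))
    stop2("invalid_state",
          "invalid state code %d at cell '%s', site '%s' (alphabet 0..%d or NA)",
          mat[bad[1L]],
          (rownames(mat) %||% as.character(seq_len(nrow(mat))))[ij[1L]],
          (colnames(mat) %||% as.character(seq_len(ncol(mat))))[ij[2L]],
          n_marks)
  }
  if (is.null(rownames(mat))) rownames(mat) <- paste0("cell", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("site", seq_len(ncol(mat)))
  structure(mat, n_marks = as.integer(n_marks), class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character matrix: %d cells x %d edit sites, S = %d marks\n",
              nrow(x), ncol(x), attr(x, "n_marks")))
  cat(sprintf("missing entries: %.1f%%\n", 100 * mean(is.na(x))))
  invisible(x)
}

n_marks <- function(cm) attr(cm, "n_marks") %||% max(0L, max(cm, na.rm = TRUE))

# Strip the class/attrs for plain-matrix arithmetic.
cm_data <- function(cm) {
  m <- unclass(cm)
  attr(m, "n_marks") <- NULL
  m
}

#' Read a character matrix from TSV
#'
#' The on-disk dialect is a TSV with a header row of edit-site ids, a first
#' column `cell` of cell ids, and integer state codes: 0 = unedited, 1..S =
#' lineage mark, -1 = missing.
#'
#' @param path File path.
#' @param n_marks Mark alphabet size `S`; defaults to the maximum positive
#'   code present.
#' @return A [character_matrix()].
#' @export
read_character_matrix <- function(path, n_marks = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (nrow(dt) == 0L || ncol(dt) < 2L) {
    stop2("EMPTY_INPUT", "no character data in '%s'", path)
  }
  cells <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- cells
  S <- n_marks %||% max(1L, suppressWarnings(max(m[m > 0L], na.rm = TRUE)))
  bad <- which(m < -1L | m > S)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(m))
    stop2("invalid_state", "invalid state code %d at cell '%s', site '%s' in '%s'",
          m[bad[1L]], cells[ij[1L]], colnames(m)[ij[2L]], path)
  }
  m[m == -1L] <- NA_integer_
  character_matrix(m, S)
}

#' Write a character matrix to TSV
#'
#' @param cm A [character_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(cm, path) {
  m <- cm_data(cm)
  m[is.na(m)] <- -1L
  dt <- data.table::data.table(cell = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
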