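#' Construct an LD matrix of squared correlations
#'
#' Square symmetric matrix of pairwise squared correlations (r-squared)
#' between variants, unit diagonal, with rsids as dimnames. This is the only
#' LD representation the package consumes (clumping); it can come from a
#' reference panel computed elsewhere or from [simulate_pair()].
#'
#' @param r2 Square numeric matrix, values in \[0, 1\], symmetric, diagonal 1.
#' @param rsids Character vector of variant ids, one per row/column.
#' @return A matrix of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, rsids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(rsids)) stop_bad_arg("ld_matrix: rsids are required")
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(rsids)) {
    stop_bad_arg("ld_matrix: r2 must be square with one rsid per row")
  }
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop_bad_arg("ld_matrix: values must be in [0, 1]")
  }
  if (max(abs(r2 - t(r2))) > 1e-12) stop_bad_arg("ld_matrix: must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-12) stop_bad_arg("ld_matrix: diagonal must be 1")
  dimnames(r2) <- list(rsids, rsids)
  class(r2) <- c("ld_matrix", "matrix", "array")
  r2
}

#' @rdname ld_matrix
#' @param path File path. The on-disk format is a dense whitespace-delimited
#'   square matrix preceded by a single header row of rsids.
#' @export
write_ld_matrix <- function(r2, path) {
  stopifnot(inherits(r2, "ld_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(r2), collapse = "\t"), con)
  utils::write.table(format(unclass(r2), digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname ld_matrix
#' @export
read_ld_matrix <- function(path) {
  rsids <- strsplit(readLines(path, n = 1), "[ \t]+")[[1]]
  m <- as.matrix(utils::read.table(path, skip = 1, header = FALSE))
  ld_matrix(m, rsids)
}
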