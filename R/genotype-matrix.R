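#' Genotype matrix container
#'
#' Holds biallelic SNP calls (`AA`, `AB`, `BB`, no-call) for a set of markers
#' genotyped on a set of samples, together with the role of each sample.
#' For a CP (cross-pollinated, outbred F1) mapping dataset the roles are one
#' `father`, one `mother` and any number of `progeny`; derivative lines
#' screened for alien introgressions carry the role `line`.
#'
#' @param calls character matrix (markers x samples) with values in
#'   `AA`, `AB`, `BB`, `NC` (or `NA`), or an integer matrix coded
#'   0/1/2/`NA`. Row names are marker ids, column names sample ids.
#' @param roles character vector of sample roles, one per column of
#'   `calls`, each in `father`, `mother`, `progeny`, `line`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno` (integer matrix, 0 = AA, 1 = AB, 2 = BB, `NA` = no call) and
#'   `roles` (named character vector).
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c("AA", "AB", "AB", "AB", "AA", "NC"), nrow = 2,
#'          dimnames = list(c("m1", "m2"), c("P1", "P2", "F1"))),
#'   roles = c("father", "mother", "progeny"))
#' dim(gm)
#' @export
genotype_matrix <- function(calls, roles) {
  if ((nrow(calls) > 0 && is.null(rownames(calls))) ||
      (ncol(calls) > 0 && is.null(colnames(calls)))) {
    stop2("calls must have marker row names and sample column names")
  }
  if (anyDuplicated(rownames(calls))) stop2("duplicate marker ids")
  if (anyDuplicated(colnames(calls))) stop2("duplicate sample ids")
  if (length(roles) != ncol(calls)) {
    stop2("roles must have one entry per sample")
  }
  ok_roles <- c("father", "mother", "progeny", "line")
  if (!all(roles %in% ok_roles)) {
    stop2("unknown role(s): ", paste(setdiff(roles, ok_roles), collapse = ", "))
  }
  if (is.character(calls)) {
    geno <- matrix(code_call(calls), nrow = nrow(calls),
                   dimnames = dimnames(calls))
  } else {
    geno <- calls
    storage.mode(geno) <- "integer"
    if (any(!is.na(geno) & !(geno %in% 0:2))) stop2("integer calls must be 0/1/2/NA")
  }
  names(roles) <- colnames(geno)
  structure(list(geno = geno, roles = roles), class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d samples (%s)\n",
              nrow(x$geno), ncol(x$geno),
              paste(sprintf("%d %s", table(x$roles), names(table(x$roles))),
                    collapse = ", ")))
  invisible(x)
}

marker_ids <- function(gm) rownames(gm$geno)
sample_ids <- function(gm) colnames(gm$geno)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i marker index (id, integer or logical).
#' @param j sample index.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  genotype_matrix(x$geno[i, j, drop = FALSE], unname(x$roles[j]))
}

# Single father / mother column index of a CP dataset (validated).
parent_columns <- function(gm) {
  f <- which(gm$roles == "father")
  m <- which(gm$roles == "mother")
  if (length(f) != 1L || length(m) != 1L) {
    stop2("a CP genotype matrix needs exactly one father and one mother")
  }
  c(father = unname(f), mother = unname(m))
}

progeny_columns <- function(gm) which(gm$roles == "progeny")
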