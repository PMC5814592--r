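# TSV readers/writers for the pipeline's artifacts. All writers are
# deterministic (no timestamps); an optional header comment carries the
# tool version and parameter hash so artifacts are traceable.

write_tsv_artifact <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_artifact <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read and write the genotype-matrix TSV dialect
#'
#' Dialect: a header row `marker_id` followed by sample ids; a metadata
#' row `role` giving each sample's role (`father`/`mother`/`progeny`/
#' `line`); then one row per marker with calls in `AA`, `AB`, `BB`, `NC`.
#' A write/read round trip is the identity.
#'
#' @param path file path.
#' @param gm a [genotype_matrix()].
#' @param comment optional header comment for the writer.
#' @return `read_genotype_matrix` returns a [genotype_matrix()];
#'   `write_genotype_matrix` returns `path` invisibly.
#' @export
read_genotype_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2) stop2("genotype TSV needs a header and a role row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "marker_id") stop2("first header field must be 'marker_id'")
  samples <- header[-1]
  role_row <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (role_row[1] != "role") stop2("second row must be the 'role' row")
  roles <- role_row[-1]
  if (length(roles) != length(samples)) stop2("role row length mismatch")
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  nfield <- lengths(body)
  bad <- which(nfield != length(samples) + 1L)
  if (length(bad)) stop2("malformed genotype row at line ", bad[1] + 2L)
  ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop2("duplicate marker id: ", ids[anyDuplicated(ids)])
  }
  calls <- matrix(NA_integer_, length(ids), length(samples),
                  dimnames = list(ids, samples))
  for (i in seq_along(body)) {
    row <- body[[i]][-1L]
    coded <- tryCatch(code_call(row), error = function(e) e)
    if (inherits(coded, "error")) {
      col <- which(!(row %in% c(CALL_LEVELS, "NC")))[1]
      stop2("line ", i + 2L, ", sample '", samples[col], "': ",
            conditionMessage(coded))
    }
    calls[i, ] <- coded
  }
  genotype_matrix(calls, roles)
}

#' @rdname read_genotype_matrix
#' @export
write_genotype_matrix <- function(gm, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("marker_id", colnames(gm$geno)), collapse = "\t"), con)
  writeLines(paste(c("role", unname(gm$roles)), collapse = "\t"), con)
  sym <- matrix(call_symbol(gm$geno), nrow = nrow(gm$geno))
  sym[is.na(sym)] <- "NC"
  body <- apply(cbind(rownames(gm$geno), sym), 1, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Import genotypes from a VCF file
#'
#' Maps diploid GT fields to array-style calls: `0/0 -> AA`,
#' `0/1`/`1/0 -> AB`, `1/1 -> BB`, missing -> `NC`. Requires the
#' optional vcfR package.
#'
#' @param path VCF path.
#' @param roles sample roles in VCF column order.
#' @return a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path, roles) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop2("the vcfR package is required for VCF import")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  coded <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  coded[gt %in% c("0/0")] <- 0L
  coded[gt %in% c("0/1", "1/0")] <- 1L
  coded[gt %in% c("1/1")] <- 2L
  genotype_matrix(coded, roles)
}

#' Read and write hit-table TSVs
#'
#' Columns: `marker_id`, `chrom`, `bp`, `e_value`, `identity`.
#'
#' @param path file path.
#' @param hits hit-table data.frame.
#' @param comment optional header comment.
#' @return `read_hit_table` returns the data.frame.
#' @export
read_hit_table <- function(path) {
  h <- read_tsv_artifact(path)
  req <- c("marker_id", "chrom", "bp", "e_value", "identity")
  missing_cols <- setdiff(req, names(h))
  if (length(missing_cols)) {
    stop2("hit table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  h
}

#' @rdname read_hit_table
#' @export
write_hit_table <- function(hits, path, comment = NULL) {
  write_tsv_artifact(hits, path, comment)
}

#' Write a genetic map as TSV
#'
#' Long format: `lg`, `locus_index`, `marker_id`, `position_cM`,
#' `pattern`.
#'
#' @param map a `genetic_map`.
#' @param path file path.
#' @param comment optional header comment.
#' @export
write_map_tsv <- function(map, path, comment = NULL) {
  tab <- map$table
  if (is.null(tab) || !nrow(tab)) {
    tab <- data.frame(lg = character(), locus_index = integer(),
                      marker_id = character(), position_cm = numeric(),
                      pattern = character())
  }
  names(tab)[names(tab) == "position_cm"] <- "position_cM"
  write_tsv_artifact(tab, path, comment)
}
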