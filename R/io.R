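# Readers and writers for the pipeline's canonical plain-text formats.
# All tables are TSV with a header; gzip-compressed inputs are accepted
# transparently (connection chosen by file extension).

#' @name pair_table_io
#' @title Read/write the canonical read-pair table
#' @description Columns: `gene_id`, `treatment`, `fwd5`, `txn_site`, `umi`,
#'   `mapq`, `first_base_mismatch`. Reading validates the invariants
#'   (`1 <= fwd5 <= txn_site`, 3-character UMI) and reports offending rows.
#' @param path File path (`.gz` allowed for reading).
#' @param records Data frame to write.
#' @return `read_pair_table` returns the validated data frame.
NULL

#' @rdname pair_table_io
#' @export
read_pair_table <- function(path) {
  records <- utils::read.delim(path, stringsAsFactors = FALSE)
  records$first_base_mismatch <- as.logical(records$first_base_mismatch)
  check_pair_table(records)
  records
}

#' @rdname pair_table_io
#' @export
write_pair_table <- function(records, path) {
  check_pair_table(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write BED-like per-site coverage counts
#'
#' Columns `gene_id`, `pos`, `drip`, `input` (non-negative integers).
#'
#' @param path File path.
#' @param coverage Data frame to write.
#' @return `read_coverage_table` returns the data frame.
#' @export
read_coverage_table <- function(path) {
  cov <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "pos", "drip", "input")
  miss <- setdiff(need, names(cov))
  if (length(miss) > 0L) {
    stop("coverage table missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(cov$drip < 0 | cov$input < 0)
  if (length(bad) > 0L) {
    stop("negative counts at rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  cov
}

#' @rdname read_coverage_table
#' @export
write_coverage_table <- function(coverage, path) {
  utils::write.table(coverage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a Newick tree, rejecting non-positive branch lengths
#'
#' @param path Newick file path.
#' @return A `phylo` object.
#' @export
read_tree_checked <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must have non-negative branch lengths")
  }
  tree
}

#' Read/write a site-by-tip genotype matrix
#'
#' TSV with a `site` identifier column followed by one column per tip;
#' entries are A/C/G/T characters.
#'
#' @param path File path.
#' @param genotypes Character matrix (rownames = site ids, colnames = tips).
#' @return `read_genotype_matrix` returns the character matrix.
#' @export
read_genotype_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (names(tab)[1] != "site") stop("first column must be 'site'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$site
  m
}

#' @rdname read_genotype_matrix
#' @export
write_genotype_matrix <- function(genotypes, path) {
  tab <- data.frame(site = rownames(genotypes), genotypes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a bedGraph-like per-nucleotide score track
#'
#' @param scores Data frame with at least `gene_id`, `pos` and one score
#'   column.
#' @param path File path.
#' @export
write_score_track <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
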