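#' Filter and deduplicate read-pair records
#'
#' Drops reads with mapping quality below 30 or a mismatch at the first 5'
#' nucleotide, then removes likely PCR duplicates: among records sharing
#' `(gene_id, treatment, fwd5, txn_site, umi)` exactly one is retained. The
#' result is independent of input row order (records are stably sorted by
#' the duplicate key first, and duplicates are identical in all used fields).
#'
#' @param records Data frame with columns `gene_id`, `treatment`, `fwd5`,
#'   `txn_site`, `umi`, `mapq`, `first_base_mismatch`.
#' @param min_mapq Minimum mapping quality retained (default 30; `mapq = 30`
#'   is kept, 29 is dropped).
#' @return The filtered, deduplicated data frame.
#' @export
filter_and_dedup <- function(records, min_mapq = 30L) {
  check_pair_table(records)
  keep <- records$mapq >= min_mapq & !records$first_base_mismatch
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) return(records)
  o <- order(records$gene_id, records$treatment, records$fwd5,
             records$txn_site, records$umi)
  records <- records[o, , drop = FALSE]
  key <- paste(records$gene_id, records$treatment, records$fwd5,
               records$txn_site, records$umi, sep = "\r")
  records <- records[!duplicated(key), , drop = FALSE]
  rownames(records) <- NULL
  records
}

check_pair_table <- function(records) {
  need <- c("gene_id", "treatment", "fwd5", "txn_site", "umi", "mapq",
            "first_base_mismatch")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("pair table missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(!(records$fwd5 >= 1L & records$fwd5 <= records$txn_site))
  if (length(bad) > 0L) {
    stop("malformed pair records (fwd5 outside [1, txn_site]) at rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad_umi <- which(nchar(records$umi) != 3L)
  if (length(bad_umi) > 0L) {
    stop("malformed UMI (length != 3) at rows: ",
         paste(utils::head(bad_umi, 5L), collapse = ", "))
  }
  invisible(records)
}

#' Tabulate RT stops per nucleotide from filtered read pairs
#'
#' The RT stop site is the base immediately preceding the forward read's 5'
#' end (`fwd5 - 1`); records with `fwd5 = 1` are mapped reads but contribute
#' no stop. Library totals `S` count all retained records per treatment,
#' including stop-less ones.
#'
#' @param records Filtered records (see [filter_and_dedup()]).
#' @param gene_lengths Named integer vector of gene lengths (names are gene
#'   ids); every gene listed here appears in the output even with no reads.
#' @return Data frame with one row per (gene, position): `gene_id`, `pos`,
#'   `n_nai`, `n_dmso`. Library totals are in attribute `S`, a named vector
#'   with elements `NAI` and `DMSO`.
#' @export
assign_rt_stops <- function(records, gene_lengths) {
  stopifnot(!is.null(names(gene_lengths)))
  genes <- names(gene_lengths)
  out <- data.frame(
    gene_id = rep(genes, gene_lengths),
    pos = unlist(lapply(gene_lengths, seq_len), use.names = FALSE),
    n_nai = 0L, n_dmso = 0L, stringsAsFactors = FALSE
  )
  S <- c(NAI = sum(records$treatment == "NAI"),
         DMSO = sum(records$treatment == "DMSO"))
  stopped <- records[records$fwd5 > 1L, , drop = FALSE]
  if (nrow(stopped) > 0L) {
    key_out <- paste(out$gene_id, out$pos)
    for (trt in c("NAI", "DMSO")) {
      r <- stopped[stopped$treatment == trt, , drop = FALSE]
      if (nrow(r) == 0L) next
      tab <- table(paste(r$gene_id, r$fwd5 - 1L))
      idx <- match(names(tab), key_out)
      if (anyNA(idx)) stop("RT stop outside annotated gene length")
      col <- if (trt == "NAI") "n_nai" else "n_dmso"
      out[[col]][idx] <- as.integer(tab)
    }
  }
  attr(out, "S") <- S
  out
}

#' Per-intermediate RT-stop density matrix for one gene
#'
#' Collects the NAI-treated read pairs of a single gene, partitions them by
#' transcription site (all pairs sharing a reverse-read position derive from
#' the same transcriptional intermediate), counts RT stops per nucleotide
#' within each intermediate, masks the `footprint` 3'-terminal nucleotides
#' covered by the elongation complex, and normalizes each intermediate's row
#' by two-sided winsorization (clipping at the `(1-winsor)/2` and
#' `1-(1-winsor)/2` quantiles, 5th/95th percentiles for the default 90%
#' winsorization) followed by scaling to a maximum of 1.
#'
#' @param records Filtered NAI records of one gene.
#' @param gene_length Gene length in nt.
#' @param footprint 3'-end nucleotides to mask (default 18).
#' @param winsor Central mass retained by winsorization (default 0.90).
#' @return An `intermediate_matrix`: list with `gene_id`, `lengths` (row
#'   intermediate lengths), `raw` and `density` matrices (rows = intermediate
#'   lengths, columns = nucleotide positions, masked cells `NA`), `footprint`.
#' @export
build_intermediate_matrix <- function(records, gene_length, footprint = 18L,
                                      winsor = 0.90) {
  gene_id <- if (nrow(records) > 0L) records$gene_id[1] else NA_character_
  if (nrow(records) > 0L && length(unique(records$gene_id)) > 1L) {
    stop("records must come from a single gene")
  }
  nai <- records[records$treatment == "NAI", , drop = FALSE]
  lengths <- seq(footprint + 1L, gene_length)
  if (length(lengths) == 0L || nrow(nai) == 0L) {
    if (nrow(nai) == 0L) warning("gene has no NAI records; empty matrix")
    lengths <- integer(0)
  }
  raw <- matrix(NA_real_, nrow = length(lengths), ncol = gene_length,
                dimnames = list(lengths, seq_len(gene_length)))
  for (r in seq_along(lengths)) {
    L <- lengths[r]
    raw[r, seq_len(L - footprint)] <- 0
  }
  if (nrow(nai) > 0L) {
    stops <- nai[nai$fwd5 > 1L, , drop = FALSE]
    if (nrow(stops) > 0L) {
      pos <- stops$fwd5 - 1L
      rr <- match(stops$txn_site, lengths)
      ok <- !is.na(rr) & pos <= stops$txn_site - footprint
      if (any(ok)) {
        tab <- table(paste(rr[ok], pos[ok]))
        ij <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
        ij <- cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))
        raw[ij] <- raw[ij] + as.integer(tab)
      }
    }
  }
  density <- raw
  for (r in seq_len(nrow(raw))) {
    density[r, ] <- winsorize_row(raw[r, ], winsor)
  }
  structure(list(gene_id = gene_id, lengths = lengths, raw = raw,
                 density = density, footprint = as.integer(footprint)),
            class = "intermediate_matrix")
}

#' Two-sided winsorization of a count row, max-scaled to 1
#'
#' Values below the lower or above the upper quantile (5th/95th percentile at
#' the default `winsor = 0.90`) are clipped to those quantiles; the clipped
#' row is then divided by its maximum (left untouched when the maximum is 0).
#' `NA` cells (the footprint mask) are ignored and preserved.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param winsor Central mass retained.
#' @return Winsorized, scaled vector of the same length.
#' @export
winsorize_row <- function(x, winsor = 0.90) {
  obs <- !is.na(x)
  if (!any(obs)) return(x)
  tail_p <- (1 - winsor) / 2
  q <- stats::quantile(x[obs], c(tail_p, 1 - tail_p), names = FALSE)
  y <- pmin(pmax(x, q[1]), q[2])
  mx <- max(y[obs])
  if (mx > 0) y <- y / mx
  y
}
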