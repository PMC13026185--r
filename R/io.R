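#' Read a replicate-PCR table from CSV
#'
#' Expected header: `sample_id,locus,replicate,allele1,allele2`, with 0 for
#' failed/missing alleles. Allele pairs are stored sorted ascending. At most
#' six replicates per sample x locus are allowed; duplicate
#' (sample, locus, replicate) rows and malformed rows are errors naming the
#' offending line.
#'
#' @param path CSV path.
#' @return A `replicate_table` data.frame.
#' @export
read_replicate_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "locus", "replicate", "allele1", "allele2")
  stop_if(!all(need %in% names(raw)), "header must contain: %s",
          paste(need, collapse = ","))
  for (cn in c("replicate", "allele1", "allele2")) {
    v <- suppressWarnings(as.integer(raw[[cn]]))
    bad <- which(is.na(v))
    stop_if(length(bad) > 0, "malformed %s at line %d", cn, bad[1] + 1L)
    raw[[cn]] <- v
  }
  stop_if(any(raw$replicate < 1 | raw$replicate > 6),
          "replicate index out of range 1..6 at line %d",
          which(raw$replicate < 1 | raw$replicate > 6)[1] + 1L)
  key <- paste(raw$sample_id, raw$locus, raw$replicate)
  dup <- which(duplicated(key))
  stop_if(length(dup) > 0, "duplicate (sample, locus, replicate) at line %d",
          dup[1] + 1L)
  a <- pmin(raw$allele1, raw$allele2); b <- pmax(raw$allele1, raw$allele2)
  raw$allele1 <- a; raw$allele2 <- b
  # a failed replicate carries no alleles at all
  half <- (raw$allele1 == 0) != (raw$allele2 == 0)
  stop_if(any(half), "half-missing allele pair at line %d", which(half)[1] + 1L)
  class(raw) <- c("replicate_table", "data.frame")
  raw
}

#' Write a replicate table to CSV
#' @param table A `replicate_table`.
#' @param path Output path.
#' @export
write_replicate_table <- function(table, path) {
  utils::write.csv(
    table[, c("sample_id", "locus", "replicate", "allele1", "allele2")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genotypes in a GenAlEx-style wide table
#'
#' One row per individual (or sample), two columns per locus
#' (`<locus>.1`, `<locus>.2`), 0 = missing. Round-trips losslessly through
#' [read_genalex()].
#'
#' @param geno Genotype matrix (rownames are ids).
#' @param path Output path.
#' @export
write_genalex <- function(geno, path) {
  out <- as.data.frame(geno)
  out[is.na(out)] <- 0L
  out <- cbind(id = rownames(geno), out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GenAlEx-style wide genotype table
#' @param path CSV written by [write_genalex()].
#' @return Genotype matrix with `NA` for 0 entries.
#' @export
read_genalex <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  m[m == 0L] <- NA_integer_
  rownames(m) <- raw[[1]]
  m
}

#' Read a taxon-assigned diet read table from CSV
#'
#' Expected header: `sample_id,pcr_replicate,taxon,reads`.
#'
#' @param path CSV path.
#' @return A `diet_read_table` data.frame.
#' @export
read_diet_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pcr_replicate", "taxon", "reads")
  stop_if(!all(need %in% names(raw)), "header must contain: %s",
          paste(need, collapse = ","))
  stop_if(any(raw$pcr_replicate < 1 | raw$pcr_replicate > 3),
          "pcr_replicate must be in 1..3")
  stop_if(any(raw$reads < 0), "negative read count")
  class(raw) <- c("diet_read_table", "data.frame")
  raw
}

#' Write a diet read table to CSV
#' @param table A `diet_read_table`.
#' @param path Output path.
#' @export
write_diet_table <- function(table, path) {
  utils::write.csv(
    table[, c("sample_id", "pcr_replicate", "taxon", "reads")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
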