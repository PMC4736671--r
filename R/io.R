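# Plain-text readers and writers: genotype TSV, PLINK RAW dialect, phenotype
# and truth-set TSVs, relationship-matrix TSV.

#' Write genotypes to TSV or PLINK RAW
#'
#' TSV layout: header row of marker ids, first column `animal_id`, cells are
#' allele counts in \{0, 1, 2\}. RAW layout follows the PLINK additive-recode
#' dialect (`FID IID PAT MAT SEX PHENOTYPE` then one `<marker>_A` column per
#' SNP); the `PAT` column carries the sire id when the genotype matrix has a
#' `sires` attribute.
#'
#' @param genotypes Allele-count matrix with animal row names.
#' @param path Output file path.
#' @param format `"tsv"` or `"raw"`.
#' @export
write_genotypes <- function(genotypes, path, format = c("tsv", "raw")) {
  format <- match.arg(format)
  check_genotypes(genotypes)
  if (format == "tsv") {
    df <- data.frame(animal_id = rownames(genotypes), genotypes,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    sires <- attr(genotypes, "sires")
    pat <- if (is.null(sires)) rep("0", nrow(genotypes)) else unname(sires)
    df <- data.frame(FID = pat, IID = rownames(genotypes), PAT = pat,
                     MAT = "0", SEX = 2L, PHENOTYPE = -9L, genotypes,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[-(1:6)] <- paste0(colnames(genotypes), "_A")
    utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read genotypes from TSV or PLINK RAW
#'
#' @param path Input file path.
#' @param format `"tsv"` or `"raw"` (see [write_genotypes()]).
#' @return Integer allele-count matrix with animal row names, marker column
#'   names and, for RAW input, a `sires` attribute from the `PAT` column.
#' @export
read_genotypes <- function(path, format = c("tsv", "raw")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = NA, stringsAsFactors = FALSE)
    geno <- as.matrix(df[, -1, drop = FALSE])
    rownames(geno) <- df[[1]]
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    geno <- as.matrix(df[, -(1:6), drop = FALSE])
    colnames(geno) <- sub("_A$", "", colnames(geno))
    rownames(geno) <- df$IID
    sires <- df$PAT
    if (!all(sires %in% "0")) {
      attr(geno, "sires") <- stats::setNames(sires, df$IID)
    }
  }
  storage.mode(geno) <- "integer"
  check_genotypes(geno)
  geno
}

#' Write / read phenotype records
#'
#' TSV with columns `animal_id`, `sire_id`, `trait`, `value`.
#'
#' @param records Phenotype data frame.
#' @param path File path.
#' @export
write_phenotypes <- function(records, path) {
  cols <- intersect(c("animal_id", "sire_id", "trait", "value"),
                    names(records))
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a simulation truth set
#'
#' Serializes the truth of a simulated population as two TSVs:
#' `<prefix>_snp.tsv` (marker, allele frequency, additive and dominance
#' effect) and `<prefix>_animal.tsv` (animal id, sire id, true breeding value,
#' dominance deviation and permanent-environmental effect).
#'
#' @param truth `sim_herd()$truth`.
#' @param prefix Path prefix for the two files.
#' @export
write_truth <- function(truth, prefix) {
  snp <- data.frame(marker = names(truth$freqs) %||%
                      as.character(seq_along(truth$freqs)),
                    freq = unname(truth$freqs), a = truth$a, d = truth$d,
                    stringsAsFactors = FALSE)
  utils::write.table(snp, paste0(prefix, "_snp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$animal, paste0(prefix, "_animal.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_truth
#' @export
read_truth <- function(prefix) {
  snp <- utils::read.delim(paste0(prefix, "_snp.tsv"), stringsAsFactors = FALSE)
  animal <- utils::read.delim(paste0(prefix, "_animal.tsv"),
                              stringsAsFactors = FALSE)
  list(freqs = stats::setNames(snp$freq, snp$marker), a = snp$a, d = snp$d,
       animal = animal)
}

#' Write / read a relationship matrix as TSV
#'
#' Square TSV with animal ids as both header row and first column; `kind` and
#' `denominator` attributes are stored in `#`-prefixed comment lines.
#'
#' @param K A `grm` matrix.
#' @param path File path.
#' @export
write_grm <- function(K, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", attr(K, "kind") %||% "unknown"), con)
  writeLines(sprintf("# denominator: %.17g", attr(K, "denominator") %||% NA), con)
  writeLines(sprintf("# n_snps: %d", attr(K, "n_snps") %||% NA), con)
  df <- data.frame(animal_id = rownames(K), unclass(K), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(ln)) trimws(sub(paste0("^# ", key, ":"), "", ln[1])) else NA
  }
  attr(K, "kind") <- get_meta("kind")
  attr(K, "denominator") <- as.numeric(get_meta("denominator"))
  attr(K, "n_snps") <- as.integer(get_meta("n_snps"))
  class(K) <- c("grm", class(K))
  K
}
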