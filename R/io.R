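# Readers and writers for the plain-text formats the pipeline exchanges:
# coded genotype matrix TSV, marker map TSV, weights/intakes TSVs, and the
# QC / QTL / null-parameter report tables. All tables are tab-separated with
# a header row; coordinates are 1-based.

#' Read a coded genotype matrix TSV
#'
#' Dialect: header row of marker ids, first column `animal_id`, cells in
#' `{0, 1, 2, NA}`.
#'
#' @param path File path.
#' @return Integer matrix animals x markers with dimnames.
#' @export
read_genotype_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, colClasses = NA)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  .check_geno(m)
}

#' Write a coded genotype matrix TSV
#'
#' @param geno Genotype matrix.
#' @param path File path.
#' @export
write_genotype_tsv <- function(geno, path) {
  d <- data.frame(animal_id = rownames(geno), geno, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker map TSV
#'
#' Columns: `marker_id`, `chrom`, `bp`, and optionally `allele_a`,
#' `allele_b`.
#'
#' @param path File path.
#' @return Validated marker-map tibble.
#' @export
read_marker_map <- function(path) {
  validate_marker_map(read.delim(path, colClasses = c(chrom = "character")))
}

#' Read biallelic genotypes from a VCF
#'
#' GT fields of biallelic sites are converted to 0/1/2 ALT-allele dosages
#' (phased or unphased; any missing allele gives NA). Multi-allelic sites
#' are dropped with a message. Requires the vcfR package.
#'
#' @param path VCF path (plain or bgzipped).
#' @return List with `geno` (animals x markers integer matrix) and `map`
#'   (marker-map tibble; `allele_a` = REF, `allele_b` = ALT).
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF files", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  bi <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  if (!all(bi)) {
    message("dropping ", sum(!bi), " non-biallelic site(s)")
    v <- v[bi, ]
    fix <- fix[bi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  map <- validate_marker_map(tibble::tibble(
    marker_id = ids, chrom = fix$CHROM, bp = as.integer(fix$POS),
    allele_a = fix$REF, allele_b = fix$ALT))
  geno <- t(dose)
  colnames(geno) <- ids
  list(geno = .check_geno(geno), map = map)
}

#' Read serial weights
#'
#' Columns: `animal_id`, `day`, `weight_kg`.
#' @param path File path.
#' @return Tibble.
#' @export
read_weights <- function(path) {
  d <- tibble::as_tibble(read.delim(path))
  stopifnot(all(c("animal_id", "day", "weight_kg") %in% names(d)))
  d
}

#' Read daily feed intakes
#'
#' Columns: `animal_id`, `day`, `intake_asfed_kg`, `dm_fraction`.
#' @param path File path.
#' @return Tibble.
#' @export
read_intakes <- function(path) {
  d <- tibble::as_tibble(read.delim(path))
  stopifnot(all(c("animal_id", "intake_asfed_kg", "dm_fraction") %in% names(d)))
  d
}

#' Write a tibble as TSV
#'
#' @param x Data frame.
#' @param path File path.
#' @export
write_report_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a report TSV written by [write_report_tsv()]
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_report_tsv <- function(path) {
  tibble::as_tibble(read.delim(path))
}
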