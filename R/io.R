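## CSV readers/writers for the domain tables. Dialect is fixed:
## comma-separated, "." decimal, UTF-8, header row. Writing then reading
## must reproduce each table exactly.

read_csv_strict <- function(path, colClasses) {
  if (!file.exists(path)) stop("file not found: ", path)
  # every data line must carry the header's field count (read.csv would
  # silently pad a short final line)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  nfld <- lengths(regmatches(lines, gregexpr(",", lines, fixed = TRUE))) + 1L
  bad <- which(nfld != nfld[1])[1]
  if (!is.na(bad))
    stop("parse error in ", path, " at line ", bad, ": expected ",
         nfld[1], " fields, found ", nfld[bad])
  out <- tryCatch(
    utils::read.csv(path, colClasses = colClasses, fileEncoding = "UTF-8"),
    error = function(e) e, warning = function(w) w)
  if (inherits(out, "condition"))
    stop("parse error in ", path, ": ", conditionMessage(out))
  out
}

#' Write / read a phenotype table as CSV
#' @param x a [phenotype_table].
#' @param path file path.
#' @return `read_phenotype_table` returns a [phenotype_table];
#'   `write_phenotype_table` returns `path` invisibly.
#' @export
write_phenotype_table <- function(x, path) {
  stopifnot(inherits(x, "phenotype_table") || is.data.frame(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_table
#' @export
read_phenotype_table <- function(path) {
  df <- read_csv_strict(path, colClasses = c(plant = "character",
    block = "character", period = "character", trait = "character",
    value = "numeric"))
  phenotype_table(df)
}

#' Write / read a SNP site table as CSV
#' @param x a [snp_sites] object.
#' @param path file path.
#' @export
write_snp_sites <- function(x, path) {
  stopifnot(inherits(x, "snp_sites"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @rdname write_snp_sites
#' @param amplicon_length amplicon length in bp.
#' @export
read_snp_sites <- function(path, amplicon_length = 370L) {
  df <- read_csv_strict(path, colClasses = c("integer", "integer",
                                             "character", "character"))
  snp_sites(df, amplicon_length = amplicon_length)
}

#' Write / read a haplotype table as CSV
#'
#' Only the haplotype block is written; the site table travels separately
#' (or is re-attached via `sites` on read).
#'
#' @param x a [haplotype_table].
#' @param path file path.
#' @param sites a [snp_sites] object to attach on read.
#' @export
write_haplotype_table <- function(x, path) {
  stopifnot(inherits(x, "haplotype_table"))
  utils::write.csv(x$haplotypes, path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @rdname write_haplotype_table
#' @export
read_haplotype_table <- function(path, sites) {
  df <- read_csv_strict(path, colClasses = c("integer", "character", "integer"))
  haplotype_table(df, sites)
}

#' Write / read an unphased genotype matrix as CSV
#'
#' One row per plant; one column per site named `posNNN`; calls are
#' `"A/G"` pairs, missing is `"./."`.
#'
#' @param x a [genotype_matrix].
#' @param path file path.
#' @param sites a [snp_sites] object to attach on read.
#' @export
write_genotype_matrix <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  df <- data.frame(plant = x$plants, x$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path, sites) {
  df <- read_csv_strict(path, colClasses = "character")
  exp_cols <- c("plant", paste0("pos", sites$position))
  if (!identical(names(df), exp_cols))
    stop("parse error in ", path, ": columns do not match site table")
  genotype_matrix(df$plant, sites, as.matrix(df[, -1, drop = FALSE]))
}

#' Export a genotype matrix as a VCF-like text file
#'
#' Minimal VCFv4.2 text for interoperability: CHROM is the amplicon id,
#' POS the 1-based site position, REF the first listed allele, ALT the
#' remaining allele(s); genotypes are unphased `a/b` index pairs. The CSV
#' form ([write_genotype_matrix]) remains the canonical representation.
#'
#' @param x a [genotype_matrix].
#' @param path output file path.
#' @param chrom amplicon identifier for the CHROM column.
#' @export
export_vcf <- function(x, path, chrom = "GAI_amplicon") {
  stopifnot(inherits(x, "genotype_matrix"))
  al <- site_alleles(x$sites)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chrom, ",length=",
                  attr(x$sites, "amplicon_length"), ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$plants), collapse = "\t"))
  rows <- vapply(seq_len(nrow(x$sites)), function(j) {
    a <- al[[j]]
    gt <- vapply(x$calls[, j], function(cl) {
      if (cl == "./.") return("./.")
      p <- strsplit(cl, "/", fixed = TRUE)[[1]]
      paste(sort(match(p, a) - 1L), collapse = "/")
    }, character(1))
    paste(c(chrom, x$sites$position[j], paste0("snp", x$sites$snp_no[j]),
            a[1], paste(a[-1], collapse = ","), ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(path)
}
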