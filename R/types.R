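#' @keywords internal
"_PACKAGE"

## Domain containers are light S3 wrappers around data.frames / lists so that
## every table survives a plain-CSV roundtrip bit-identically.

#' Construct a table of SNP sites
#'
#' A `snp_sites` object describes the ordered polymorphic sites of an
#' amplicon: 1-based position in bp, the observed alleles (2 or 3,
#' slash-separated, in the order they were reported) and the reported
#' frequency of the first-listed allele(s).
#'
#' @param df data.frame with columns `snp_no`, `position`, `alleles`
#'   (e.g. `"A/C"` or `"A/G/C"`), `reported_freq` (e.g. `"0.27"` or
#'   `"0.20/0.19"` for a triallelic site: frequencies of all but the last
#'   allele).
#' @param amplicon_length total amplicon length in bp (positions must not
#'   exceed it).
#' @return the validated data.frame with class `snp_sites` and attribute
#'   `amplicon_length`.
#' @export
snp_sites <- function(df, amplicon_length = 370L) {
  need <- c("snp_no", "position", "alleles", "reported_freq")
  if (!all(need %in% names(df)))
    stop("snp_sites: missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df <- as.data.frame(df)[need]
  df$snp_no <- as.integer(df$snp_no)
  df$position <- as.integer(df$position)
  df$alleles <- as.character(df$alleles)
  df$reported_freq <- as.character(df$reported_freq)
  if (any(df$position < 1L) || any(df$position > amplicon_length))
    stop("snp_sites: positions must lie in [1, ", amplicon_length, "]")
  if (is.unsorted(df$position, strictly = TRUE))
    stop("snp_sites: positions must be strictly increasing")
  na <- lengths(site_alleles(df))
  if (any(na < 2L) || any(na > 3L))
    stop("snp_sites: each site must have 2 or 3 alleles")
  fr <- site_freqs(df)
  if (any(vapply(fr, function(f) any(f <= 0 | f >= 1), logical(1))))
    stop("snp_sites: allele frequencies must lie in (0, 1)")
  attr(df, "amplicon_length") <- as.integer(amplicon_length)
  class(df) <- c("snp_sites", "data.frame")
  df
}

#' Alleles of each site as a list of character vectors
#' @param sites a `snp_sites` object (or compatible data.frame).
#' @return list of character vectors, one per site.
#' @export
site_alleles <- function(sites) strsplit(as.character(sites$alleles), "/", fixed = TRUE)

#' Reported allele frequencies of each site
#'
#' Expands the reported-frequency column to a full per-allele frequency
#' vector: the reported values are the frequencies of the first-listed
#' allele(s); the last allele receives the complement.
#'
#' @inheritParams site_alleles
#' @return list of named numeric vectors summing to 1.
#' @export
site_freqs <- function(sites) {
  al <- site_alleles(sites)
  fr <- strsplit(as.character(sites$reported_freq), "/", fixed = TRUE)
  Map(function(a, f) {
    f <- as.numeric(f)
    if (length(f) != length(a) - 1L)
      stop("site_freqs: expected ", length(a) - 1L, " reported frequencies, got ", length(f))
    out <- c(f, 1 - sum(f))
    names(out) <- a
    out
  }, al, fr)
}

#' Construct a haplotype table
#'
#' Phased haplotype strings over an ordered set of SNP sites, with the
#' number of times each haplotype was observed (or inferred) in the
#' sample. Column `i` of each string is the allele at the `i`-th site in
#' position order.
#'
#' @param haplotypes data.frame with columns `haplotype_no`, `haplotype`
#'   (string), `count` (non-negative integer).
#' @param sites a [snp_sites] object.
#' @return list with elements `sites` and `haplotypes`, class
#'   `haplotype_table`.
#' @export
haplotype_table <- function(haplotypes, sites) {
  stopifnot(inherits(sites, "snp_sites"))
  need <- c("haplotype_no", "haplotype", "count")
  if (!all(need %in% names(haplotypes)))
    stop("haplotype_table: missing columns: ",
         paste(setdiff(need, names(haplotypes)), collapse = ", "))
  h <- as.data.frame(haplotypes)[need]
  h$haplotype_no <- as.integer(h$haplotype_no)
  h$haplotype <- as.character(h$haplotype)
  h$count <- as.integer(h$count)
  if (any(nchar(h$haplotype) != nrow(sites)))
    stop("haplotype_table: haplotype string length must equal number of sites (",
         nrow(sites), ")")
  if (anyDuplicated(h$haplotype))
    stop("haplotype_table: duplicate haplotype strings")
  if (any(h$count < 0L)) stop("haplotype_table: counts must be >= 0")
  al <- site_alleles(sites)
  M <- hap_char_matrix(h$haplotype)
  for (j in seq_len(ncol(M)))
    if (!all(M[, j] %in% al[[j]]))
      stop("haplotype_table: illegal allele at site ", j, " (position ",
           sites$position[j], ")")
  structure(list(sites = sites, haplotypes = h), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", nrow(x$haplotypes), "haplotypes over",
      nrow(x$sites), "sites; total count", sum(x$haplotypes$count), "\n")
  invisible(x)
}

hap_char_matrix <- function(haps) {
  do.call(rbind, strsplit(haps, "", fixed = TRUE))
}

#' Count-weighted haplotype frequencies
#' @param pool a `haplotype_table`.
#' @return named numeric vector (names = haplotype strings) summing to 1.
#' @export
haplotype_freqs <- function(pool) {
  stopifnot(inherits(pool, "haplotype_table"))
  f <- pool$haplotypes$count / sum(pool$haplotypes$count)
  names(f) <- pool$haplotypes$haplotype
  f
}

#' Construct an unphased genotype matrix
#'
#' Diploid genotype calls at ordered amplicon sites. Each call is an
#' unordered allele pair written `"A/G"` (alphabetically ordered) or
#' `"./."` when missing.
#'
#' @param plants character vector of plant ids.
#' @param sites a [snp_sites] object.
#' @param calls character matrix, plants x sites.
#' @return list with class `genotype_matrix`.
#' @export
genotype_matrix <- function(plants, sites, calls) {
  stopifnot(inherits(sites, "snp_sites"))
  calls <- as.matrix(calls)
  if (nrow(calls) != length(plants) || ncol(calls) != nrow(sites))
    stop("genotype_matrix: calls must be ", length(plants), " x ", nrow(sites))
  al <- site_alleles(sites)
  for (j in seq_len(ncol(calls))) {
    cj <- calls[, j]
    ok <- cj == "./."
    parts <- strsplit(cj[!ok], "/", fixed = TRUE)
    bad <- vapply(parts, function(p)
      length(p) != 2L || !all(p %in% al[[j]]), logical(1))
    if (any(bad))
      stop("genotype_matrix: illegal call at site ", j, " (position ",
           sites$position[j], "): ", cj[!ok][bad][1])
    # canonical order within the unordered pair
    calls[!ok, j] <- vapply(parts, function(p) paste(sort(p), collapse = "/"),
                            character(1))
  }
  dimnames(calls) <- list(plants, paste0("pos", sites$position))
  structure(list(plants = as.character(plants), sites = sites, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$plants), "plants x", nrow(x$sites),
      "sites;", sum(x$calls == "./."), "missing calls\n")
  invisible(x)
}

#' Encode a diploid call from two alleles
#' @param a1,a2 single allele characters.
#' @return canonical `"a/b"` call string (alphabetical order).
#' @export
make_call <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), collapse = NULL, sep = "/")
}

#' Validate a phenotype table
#'
#' Long-format per-plant trait values: one row per
#' (plant, block, period, trait). Traits are `Llength` (mm), `LERmax`
#' (mm per degree-day) and `LED` (degree-days). For genotype-level
#' (adjusted-mean) tables, use `block = "adj"`.
#'
#' @param df data.frame with columns `plant`, `block`, `period`, `trait`,
#'   `value`.
#' @return validated data.frame with class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  need <- c("plant", "block", "period", "trait", "value")
  if (!all(need %in% names(df)))
    stop("phenotype_table: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- as.data.frame(df)[need]
  for (v in c("plant", "block", "period", "trait")) df[[v]] <- as.character(df[[v]])
  df$value <- as.numeric(df$value)
  key <- do.call(paste, c(df[c("plant", "block", "period", "trait")], sep = "\r"))
  if (anyDuplicated(key))
    stop("phenotype_table: duplicate (plant, block, period, trait) rows")
  if (any(!is.finite(df$value)) || any(df$value <= 0))
    stop("phenotype_table: values must be finite and positive")
  class(df) <- c("phenotype_table", "data.frame")
  df
}
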