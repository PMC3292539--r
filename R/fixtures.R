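## Packaged transcriptions of the published GAI amplicon tables for the
## 'Herbie' synthetic variety: 20 SNP sites in a 370 bp amplicon, the 39
## phased haplotypes with their inferred sample counts, and the printed
## variance components / trait summaries used for desk recomputations.

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "gaileaf", mustWork = FALSE)
  if (p == "") {
    # during in-source development (pkgload) inst/ may be unexpanded
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) stop("packaged fixture not found: ", file)
  p
}

#' The 20 GAI SNP sites of 'Herbie'
#'
#' Loads the packaged description of the 20 SNPs observed in the 370 bp
#' GAI amplicon: position (bp, 1-based), alleles and reported frequency
#' of the first-listed allele(s). One site (position 39) is triallelic.
#'
#' @return a [snp_sites] object with 20 rows sorted by position.
#' @export
gai_snp_sites <- function() {
  df <- utils::read.csv(extdata_path("gai_snp_sites.csv"),
                        colClasses = c("integer", "integer", "character", "character"))
  sites <- snp_sites(df, amplicon_length = 370L)
  if (nrow(sites) != 20L)
    stop("gai_snp_sites: fixture integrity error: expected 20 sites, found ", nrow(sites))
  sites
}

#' The 39 GAI haplotypes of 'Herbie'
#'
#' Loads the packaged table of the 39 distinct haplotype strings over the
#' 20 GAI SNP sites, with the number of copies inferred in the sample of
#' 190 sequenced plants (counts sum to 380 gametes).
#'
#' @param sites site table to attach; defaults to [gai_snp_sites()].
#' @return a [haplotype_table].
#' @export
gai_haplotype_pool <- function(sites = gai_snp_sites()) {
  df <- utils::read.csv(extdata_path("gai_haplotypes.csv"),
                        colClasses = c("integer", "character", "integer"))
  tab <- haplotype_table(df, sites)
  if (nrow(tab$haplotypes) != 39L)
    stop("gai_haplotype_pool: fixture integrity error: expected 39 haplotypes, found ",
         nrow(tab$haplotypes))
  tab
}

#' Published variance components for the 'Herbie' leaf traits
#'
#' Per-period (residual + genotypic) and cross-period (+ period and
#' genotype-by-period) REML variance components as printed, together with
#' the printed residual CV and broad-sense heritability, for downstream
#' desk recomputation of h2.
#'
#' @return data.frame with columns `population`, `period`, `trait`,
#'   `sigma2_E`, `sigma2_GE`, `sigma2_Period`, `sigma2_GExPeriod`,
#'   `cv_pct`, `H2`.
#' @export
herbie_variance_components <- function() {
  utils::read.csv(extdata_path("herbie_variance_components.csv"),
                  colClasses = c("character", "character", "character",
                                 rep("numeric", 6)))
}

#' Published distribution summaries of the 'Herbie' leaf traits
#' @return data.frame with columns `population`, `period`, `trait`,
#'   `mean`, `minimum`, `maximum`, `cv_pct`.
#' @export
herbie_trait_summary <- function() {
  utils::read.csv(extdata_path("herbie_trait_summary.csv"),
                  colClasses = c("character", "character", "character",
                                 rep("numeric", 4)))
}
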