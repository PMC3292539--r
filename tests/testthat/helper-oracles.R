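# Independent oracles kept deliberately naive: they cross-check package
# results without sharing code paths.

# unordered haplotype pair key
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# brute-force 2x2 r2 from explicit haplotype counts
r2_bruteforce <- function(counts) {
  # counts: named c(AB=, Ab=, aB=, ab=)
  n <- sum(counts)
  pA <- (counts[["AB"]] + counts[["Ab"]]) / n
  pB <- (counts[["AB"]] + counts[["aB"]]) / n
  D <- counts[["AB"]] / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# naive Fitch parsimony score of a rooted/unrooted binary tree over
# character strings (tips named)
fitch_score <- function(tree, seqs) {
  tree <- ape::multi2di(tree)
  n_tip <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  children <- split(tree$edge[, 2], tree$edge[, 1])
  L <- nchar(seqs[[1]])
  total <- 0
  for (s in seq_len(L)) {
    sets <- vector("list", max(tree$edge))
    for (i in seq_len(n_tip))
      sets[[i]] <- substr(seqs[[tree$tip.label[i]]], s, s)
    score <- 0
    rec <- function(node) {
      if (node <= n_tip) return(sets[[node]])
      kids <- lapply(children[[as.character(node)]], rec)
      st <- Reduce(intersect, kids)
      if (length(st) == 0) {
        st <- Reduce(union, kids)
        score <<- score + length(kids) - 1L
      }
      st
    }
    rec(root)
    total <- total + score
  }
  total
}

# random resolved topology over given tip labels
random_topology <- function(labels) {
  ape::rtree(length(labels), tip.label = sample(labels), br = NULL)
}

# small two-site genotype matrix builder for LD tests
two_site_gm <- function(calls1, calls2) {
  sites <- snp_sites(data.frame(snp_no = 1:2, position = c(10L, 20L),
                                alleles = c("A/C", "G/T"),
                                reported_freq = c("0.5", "0.5")),
                     amplicon_length = 30L)
  genotype_matrix(sprintf("P%02d", seq_along(calls1)), sites,
                  cbind(calls1, calls2))
}

# tiny deterministic phenotype table
toy_pheno <- function() {
  phenotype_table(data.frame(
    plant = rep(c("P1", "P2", "P3"), each = 2),
    block = rep(c("B1", "B2"), 3),
    period = "spring", trait = "Llength",
    value = c(300, 310, 350, 360, 280, 290)))
}
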