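# SNPs-to-genes collapsing by supervised PCA: per gene, SNPs in the locus
# +/- 5000 bp are scored by a two-sample t of dosage vs case/control status,
# the most associated subset is retained, and the first principal component
# of the retained (mean-imputed, centred) dosages becomes the gene score.

#' Supervised-PCA configuration
#'
#' @param selection `"median"` (retain SNPs with |t| at or above the
#'   gene-wise median — the default, since the supervision threshold is a
#'   free choice), `"top_fraction"`, or `"threshold"`.
#' @param top_fraction fraction of SNPs kept under `"top_fraction"`.
#' @param t_threshold absolute-t cutoff under `"threshold"`.
#' @param min_snps genes retaining fewer SNPs than this are dropped.
#' @param flank gene-region flank in base pairs (locus +/- flank).
#' @return list of class `spca_config`.
#' @export
spca_config <- function(selection = c("median", "top_fraction", "threshold"),
                        top_fraction = 0.5, t_threshold = 2,
                        min_snps = 1, flank = 5000) {
  structure(list(selection = match.arg(selection),
                 top_fraction = top_fraction, t_threshold = t_threshold,
                 min_snps = min_snps, flank = flank),
            class = "spca_config")
}

# pooled-variance two-sample t of each column of m against binary g
.snp_t <- function(m, g) {
  n0 <- sum(g == 0); n1 <- sum(g == 1)
  m0 <- colMeans(m[g == 0, , drop = FALSE])
  m1 <- colMeans(m[g == 1, , drop = FALSE])
  v0 <- apply(m[g == 0, , drop = FALSE], 2, var)
  v1 <- apply(m[g == 1, , drop = FALSE], 2, var)
  sp <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
  tt <- (m1 - m0) / sqrt(sp * (1 / n0 + 1 / n1))
  tt[!is.finite(tt)] <- 0
  tt
}

#' Collapse genotypes to per-gene supervised PC1 scores
#'
#' For each gene: SNPs within `[start - flank, end + flank]` on the same
#' chromosome are assigned; missing dosages are mean-imputed per SNP;
#' constant columns are dropped; SNPs are selected by |t| of dosage vs group
#' per `cfg$selection`; the first principal component of the centred retained
#' dosages is the gene score, oriented so that its correlation with the group
#' is non-negative (cases tend to score higher). Genes retaining no SNP are
#' omitted with a message.
#'
#' @param geno a [genotype_matrix].
#' @param group binary vector (0/1) per sample.
#' @param cfg an [spca_config].
#' @return a [gene_score_matrix]; attribute `dropped_genes` lists omitted
#'   genes with reasons.
#' @export
spca_gene_scores <- function(geno, group, cfg = spca_config()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  group <- as.integer(group)
  stopifnot(length(group) == nrow(geno$geno))
  if (min(sum(group == 0), sum(group == 1)) < 2)
    stop("need at least 2 samples per group")
  sc <- geno$snp_coords
  loci <- geno$gene_loci
  scores <- list()
  dropped <- character(0)
  for (gi in seq_len(nrow(loci))) {
    gene <- loci$gene[gi]
    in_region <- sc$chr == loci$chr[gi] &
      sc$pos >= loci$start[gi] - cfg$flank &
      sc$pos <= loci$end[gi] + cfg$flank
    snps <- intersect(sc$snp[in_region], colnames(geno$geno))
    if (length(snps) == 0) {
      dropped[gene] <- "no SNPs in region"
      next
    }
    m <- geno$geno[, snps, drop = FALSE]
    # mean-impute missing dosages per SNP
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mean(m[, j], na.rm = TRUE)
    }
    keep <- apply(m, 2, var) > 0
    if (!any(keep)) {
      dropped[gene] <- "all SNP columns constant"
      next
    }
    m <- m[, keep, drop = FALSE]
    tt <- abs(.snp_t(m, group))
    sel <- switch(cfg$selection,
                  median = tt >= median(tt),
                  top_fraction = tt >= quantile(tt, 1 - cfg$top_fraction,
                                                names = FALSE),
                  threshold = tt >= cfg$t_threshold)
    if (sum(sel) < cfg$min_snps) {
      dropped[gene] <- sprintf("only %d SNP(s) pass selection", sum(sel))
      next
    }
    m <- scale(m[, sel, drop = FALSE], center = TRUE, scale = FALSE)
    pc1 <- prcomp(m, center = FALSE, scale. = FALSE)$x[, 1]
    r <- suppressWarnings(cor(pc1, group))
    if (!is.na(r) && r < 0) pc1 <- -pc1
    scores[[gene]] <- pc1
  }
  if (length(scores) == 0)
    stop("no gene region overlaps any SNP")
  if (length(dropped) > 0)
    message(sprintf("spca_gene_scores: %d gene(s) dropped (%s)",
                    length(dropped),
                    paste(names(dropped), dropped, sep = ": ",
                          collapse = "; ")))
  out <- gene_score_matrix(do.call(cbind, scores), group)
  rownames(out$scores) <- rownames(geno$geno)
  attr(out, "dropped_genes") <- dropped
  out
}
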