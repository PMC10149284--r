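#' Generate gene annotations, gene sets, a tissue expression matrix and a
#' toy disease-variant catalogue
#'
#' Genes tile the simulated chromosomes with configurable inter-gene gaps;
#' a fraction of gaps is drawn just below and just above the 100-kb fusion
#' distance so the gene-fusion step is exercised at its boundary. The
#' expression matrix (genes x tissues) is log-normal noise except for one
#' designated tissue in which one designated gene set is upregulated by
#' `planted_fold`. The disease catalogue lists SNP ids with trait labels
#' and mapped genes, with a configurable number of entries drawn from a
#' supplied SNP pool (so overlap with association results is plantable).
#'
#' @param n_genes number of genes.
#' @param n_sets number of gene sets (0 gives a valid empty collection).
#' @param n_tissues number of tissues (the study's reference count is 54).
#' @param seed integer seed.
#' @param n_chrom chromosomes to tile.
#' @param gene_len_range gene body length range in bp.
#' @param gap_choices inter-gene gap sizes sampled uniformly; includes
#'   values straddling the 100-kb fusion boundary.
#' @param set_size_range members per gene set.
#' @param planted_set index of the set upregulated in the planted tissue
#'   (`NA` plants nothing).
#' @param planted_tissue index of the upregulated tissue.
#' @param planted_fold expression fold-change of the planted set.
#' @param snp_pool character vector of SNP ids from which catalogue
#'   entries are drawn (`NULL` generates fresh ids).
#' @param catalogue_traits named integer vector: number of catalogue
#'   entries per trait.
#' @return List with `annotation` (data.table: `gene`, `chr`, `start`,
#'   `end`, `strand`, `tss`, `tes`, `biotype`), `sets` (named list of
#'   character vectors, GMT-style), `expression` (matrix genes x tissues),
#'   `catalogue` (data.table: `SNP`, `TRAIT`, `MAPPED_GENE`,
#'   `SOURCE_PMID`), and `planted` (list describing the planted signal).
#' @export
gen_annotations_and_sets <- function(n_genes, n_sets, n_tissues, seed = 1,
                                     n_chrom = 2,
                                     gene_len_range = c(5000, 50000),
                                     gap_choices = c(20000, 50000, 99999,
                                                     100001, 150000, 250000),
                                     set_size_range = c(5, 30),
                                     planted_set = 1, planted_tissue = 1,
                                     planted_fold = 3,
                                     snp_pool = NULL,
                                     catalogue_traits = c(hypertension = 6,
                                                          glaucoma = 3)) {
  stopifnot(n_genes >= 1, n_sets >= 0, n_tissues >= 1)
  set.seed(substream_seed(seed, "annotations"))
  per_chr <- ceiling(n_genes / n_chrom)
  chr <- ((seq_len(n_genes) - 1) %/% per_chr) + 1L
  lens <- round(stats::runif(n_genes, gene_len_range[1], gene_len_range[2]))
  gaps <- sample(gap_choices, n_genes, replace = TRUE)
  start <- integer(n_genes); end <- integer(n_genes)
  for (cc in unique(chr)) {
    j <- which(chr == cc)
    pos <- 1e6L
    for (g in j) {
      start[g] <- pos
      end[g] <- pos + lens[g] - 1L
      pos <- end[g] + gaps[g] + 1L  # gap = intervening bases
    }
  }
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  biotype <- sample(c("protein_coding", "lincRNA", "pseudogene"),
                    n_genes, replace = TRUE, prob = c(0.8, 0.15, 0.05))
  gene <- sprintf("GENE%04d", seq_len(n_genes))
  annotation <- data.table::data.table(
    gene = gene, chr = chr, start = start, end = end, strand = strand,
    tss = ifelse(strand == "+", start, end),
    tes = ifelse(strand == "+", end, start),
    biotype = biotype)

  sets <- list()
  if (n_sets > 0) {
    for (s in seq_len(n_sets)) {
      sz <- sample(set_size_range[1]:set_size_range[2], 1)
      sets[[sprintf("SET%03d", s)]] <- sample(gene, min(sz, n_genes))
    }
  }

  expression <- matrix(stats::rlnorm(n_genes * n_tissues, meanlog = 2,
                                     sdlog = 0.45),
                       n_genes, n_tissues,
                       dimnames = list(gene,
                                       sprintf("tissue%02d",
                                               seq_len(n_tissues))))
  planted <- list(set = NA_character_, tissue = NA_character_)
  if (!is.na(planted_set) && n_sets >= planted_set) {
    members <- sets[[planted_set]]
    expression[members, planted_tissue] <-
      expression[members, planted_tissue] * planted_fold
    planted <- list(set = names(sets)[planted_set],
                    tissue = colnames(expression)[planted_tissue])
  }

  n_cat <- sum(catalogue_traits)
  cat_snps <- if (is.null(snp_pool)) sprintf("rsC%05d", seq_len(n_cat))
              else sample(snp_pool, min(n_cat, length(snp_pool)))
  catalogue <- data.table::data.table(
    SNP = cat_snps,
    TRAIT = rep(names(catalogue_traits),
                times = catalogue_traits)[seq_along(cat_snps)],
    MAPPED_GENE = sample(gene, length(cat_snps), replace = TRUE),
    SOURCE_PMID = sprintf("PMID%07d", sample.int(1e7, length(cat_snps))))

  list(annotation = annotation, sets = sets, expression = expression,
       catalogue = catalogue, planted = planted)
}
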