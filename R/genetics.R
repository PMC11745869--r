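#' SNP metadata
#'
#' Describes a biallelic SNP: identifiers, alleles and the genetic-model
#' contrast used when the SNP enters a regression as a binary covariate.
#'
#' @param rsid SNP identifier.
#' @param gene Gene symbol.
#' @param chrom Chromosome label.
#' @param major_allele,minor_allele Allele characters (distinct).
#' @param maf Minor allele frequency in \[0, 0.5\].
#' @param model Genetic-model label: one of `"dominant"`, `"recessive"`,
#'   `"overdominant"`, `"additive"`.
#' @param exposed For the non-additive models, which side of the contrast is
#'   the at-risk (coded 1) group: `"alt"` (the default side of the named
#'   model, e.g. minor-allele carriers under `"dominant"`, heterozygotes
#'   under `"overdominant"`) or `"ref"` to invert the coding (e.g.
#'   homozygotes at risk in a heterozygote-vs-homozygote contrast).
#' @return A one-row data.frame of class `snp_info`.
#' @export
snp_info <- function(rsid, gene = NA_character_, chrom = NA_character_,
                     major_allele = "A", minor_allele = "B", maf = NA_real_,
                     model = "additive", exposed = "alt") {
  if (!is.na(maf) && (maf < 0 || maf > 0.5))
    stop("maf must lie in [0, 0.5]")
  if (identical(major_allele, minor_allele))
    stop("major and minor alleles must be distinct")
  model <- match.arg(model,
                     c("dominant", "recessive", "overdominant", "additive"))
  exposed <- match.arg(exposed, c("alt", "ref"))
  structure(data.frame(rsid = rsid, gene = gene, chrom = chrom,
                       major_allele = major_allele,
                       minor_allele = minor_allele,
                       maf = maf, model = model, exposed = exposed,
                       stringsAsFactors = FALSE),
            class = c("snp_info", "data.frame"))
}

#' Minor allele frequency from genotype counts
#'
#' Computes the allele frequency of the nominally minor allele,
#' `(het + 2 * minor_hom) / (2n)`, and folds it to at most 0.5, recording
#' whether the allele labels had to be swapped.
#'
#' @param n_major_hom,n_het,n_minor_hom Genotype class counts (major
#'   homozygote, heterozygote, minor homozygote).
#' @return A list with `maf`, `folded` (TRUE if the labels were swapped to
#'   keep the frequency at or below 0.5) and `n`.
#' @export
compute_maf <- function(n_major_hom, n_het, n_minor_hom) {
  n <- n_major_hom + n_het + n_minor_hom
  if (n <= 0) stop("no genotyped subjects")
  p <- (n_het + 2 * n_minor_hom) / (2 * n)
  folded <- p > 0.5
  list(maf = if (folded) 1 - p else p, folded = folded, n = n)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square of the observed genotype counts
#' against the expectation `(p^2, 2pq, q^2) * n` computed from the sample
#' allele frequency; the p-value uses the asymptotic chi-square(1)
#' distribution (not the exact test).
#'
#' @inheritParams compute_maf
#' @return A list with `chisq`, `p_value`, `df` (= 1), `expected` (the three
#'   expected counts) and `low_expected` (TRUE if any expected count < 1).
#' @export
hwe_chi2 <- function(n_major_hom, n_het, n_minor_hom) {
  obs <- c(n_major_hom, n_het, n_minor_hom)
  n <- sum(obs)
  if (n <= 0) stop("no genotyped subjects")
  q <- (n_het + 2 * n_minor_hom) / (2 * n)  # minor-allele freq (unfolded)
  p <- 1 - q
  expected <- n * c(p^2, 2 * p * q, q^2)
  if (any(expected == 0)) {
    chisq <- 0  # monomorphic: trivially in HWE
  } else {
    chisq <- sum((obs - expected)^2 / expected)
  }
  low <- any(expected < 1)
  if (low) warning("expected genotype count < 1; chi-square approximation unreliable")
  list(chisq = chisq, p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       df = 1L, expected = expected, low_expected = low)
}

#' Encode genotypes under a genetic model
#'
#' Collapses minor-allele counts (0/1/2) into the binary at-risk contrast of
#' a genetic model. Under `"dominant"` the minor-allele carriers (1 or 2
#' copies) form the `"alt"` side; under `"recessive"` the minor homozygotes;
#' under `"overdominant"` the heterozygotes. `exposed = "ref"` inverts the
#' coding so that the complementary group is the at-risk (coded 1) group, as
#' needed when a heterozygote-vs-homozygote contrast has the homozygotes at
#' risk. `"additive"` returns the counts unchanged. Missing genotypes
#' propagate as `NA`.
#'
#' @param counts Integer vector of minor-allele counts in \{0, 1, 2\} (NA
#'   allowed).
#' @param model Genetic-model label (see [snp_info()]).
#' @param exposed `"alt"` (default) or `"ref"`.
#' @return Numeric vector: 0/1 (or 0/1/2 for `"additive"`).
#' @export
encode_genotype <- function(counts, model, exposed = "alt") {
  model <- match.arg(model,
                     c("dominant", "recessive", "overdominant", "additive"))
  exposed <- match.arg(exposed, c("alt", "ref"))
  bad <- !is.na(counts) & !(counts %in% 0:2)
  if (any(bad)) stop("genotype counts must be 0, 1, 2 or NA")
  out <- switch(model,
    dominant = as.numeric(counts >= 1),
    recessive = as.numeric(counts == 2),
    overdominant = as.numeric(counts == 1),
    additive = as.numeric(counts))
  if (model != "additive" && exposed == "ref") out <- 1 - out
  out
}

#' Genotype matrix with per-SNP metadata
#'
#' @param genotypes Integer matrix (subjects x SNPs) of minor-allele counts
#'   with `NA` for missing; column names are rsids.
#' @param info A data.frame of [snp_info()] rows (one per column), matched by
#'   `rsid`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, info) {
  genotypes <- as.matrix(genotypes)
  ok <- is.na(genotypes) | genotypes %in% 0:2
  if (!all(ok)) stop("genotype entries must be 0, 1, 2 or NA")
  if (is.null(colnames(genotypes)))
    stop("genotype matrix must have rsid column names")
  info <- info[match(colnames(genotypes), info$rsid), , drop = FALSE]
  if (anyNA(info$rsid))
    stop("missing snp_info for: ",
         paste(setdiff(colnames(genotypes), info$rsid), collapse = ", "))
  structure(list(genotypes = genotypes, info = info),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d subjects x %d SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  print(x$info[, c("rsid", "gene", "major_allele", "minor_allele", "maf",
                   "model")])
  invisible(x)
}

#' Per-SNP summary: MAF and Hardy-Weinberg test
#'
#' Complete-case per SNP (missing genotypes are dropped column-wise).
#'
#' @param gm A [genotype_matrix()].
#' @return A data.frame with one row per SNP: counts, sample MAF, whether the
#'   allele labels were folded, HWE chi-square and p-value.
#' @export
genotype_summary <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  res <- lapply(seq_len(ncol(gm$genotypes)), function(j) {
    g <- gm$genotypes[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0)
      return(data.frame(rsid = gm$info$rsid[j], n = 0L, n0 = NA, n1 = NA,
                        n2 = NA, maf = NA, folded = NA, hwe_chisq = NA,
                        hwe_p = NA, all_missing = TRUE))
    cnt <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    maf <- compute_maf(cnt[1], cnt[2], cnt[3])
    hwe <- suppressWarnings(hwe_chi2(cnt[1], cnt[2], cnt[3]))
    data.frame(rsid = gm$info$rsid[j], n = length(g),
               n0 = cnt[1], n1 = cnt[2], n2 = cnt[3],
               maf = maf$maf, folded = maf$folded,
               hwe_chisq = hwe$chisq, hwe_p = hwe$p_value,
               all_missing = FALSE)
  })
  do.call(rbind, res)
}

#' Encode all SNPs of a genotype matrix per their configured genetic models
#'
#' @param gm A [genotype_matrix()].
#' @return Numeric matrix (subjects x SNPs) of encoded covariates.
#' @export
encode_all <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- vapply(seq_len(ncol(gm$genotypes)), function(j) {
    encode_genotype(gm$genotypes[, j], gm$info$model[j], gm$info$exposed[j])
  }, numeric(nrow(gm$genotypes)))
  out <- matrix(out, nrow = nrow(gm$genotypes))
  dimnames(out) <- dimnames(gm$genotypes)
  out
}

#' Read a genotype matrix from CSV or VCF
#'
#' CSV: first column subject id, remaining columns one per rsid with values
#' 0/1/2/NA (minor-allele counts). VCF (requires the `vcfR` package):
#' biallelic sites only, genotypes taken from the GT field; multi-allelic
#' records are rejected.
#'
#' @param path File path; format inferred from the extension (`.vcf` /
#'   `.vcf.gz` vs anything else as CSV).
#' @param info Optional data.frame of [snp_info()] rows; if omitted, minimal
#'   metadata (additive model) is constructed.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, info = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single record
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi))
      stop("multi-allelic records are not supported: ",
           paste(fix[multi, "ID"], collapse = ", "))
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(x) {
      ifelse(is.na(x), NA_integer_,
             vapply(strsplit(gsub("\\|", "/", x), "/"),
                    function(a) sum(a == "1"), integer(1)))
    }
    mat <- t(apply(gt, 1, count_alt))
    mat <- t(mat)  # subjects x SNPs
    colnames(mat) <- fix[, "ID"]
    rownames(mat) <- colnames(gt)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    mat <- as.matrix(tab[, -1, drop = FALSE])
    mode(mat) <- "numeric"
    rownames(mat) <- as.character(tab[[1]])
  }
  if (is.null(info)) {
    info <- do.call(rbind, lapply(colnames(mat), function(r)
      snp_info(rsid = r, model = "additive")))
  }
  genotype_matrix(mat, info)
}
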