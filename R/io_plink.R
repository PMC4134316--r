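## PLINK text ped/map input/output and population assignment tables.

#' Read PLINK text ped/map files
#'
#' Reads whitespace-separated PLINK `.ped`/`.map` files into a
#' [genotype_dataset()]. Genotypes are recoded as counts of `allele_B`;
#' when the data do not dictate otherwise, `allele_B` is the minor allele
#' (FLK is symmetric to allele relabelling so the choice is inert).
#' `0 0` allele pairs become missing. SNPs are sorted by
#' (chromosome, position) with the genotype columns permuted consistently.
#'
#' @param ped_path path to the `.ped` file: 6 mandatory columns
#'   (family, individual, father, mother, sex, phenotype) then two allele
#'   columns per SNP.
#' @param map_path path to the `.map` file: 4 columns
#'   (chromosome, SNP id, genetic position, bp position).
#' @return A [genotype_dataset()].
#' @export
read_plink <- function(ped_path, map_path) {
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "numeric"))
  names(map) <- c("chrom", "snp_id", "gpos", "pos")
  m <- nrow(map)
  ped <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  expected <- 6L + 2L * m
  if (ncol(ped) != expected)
    stop("ped/map column mismatch: ped has ", ncol(ped),
         " columns, expected ", expected, " for ", m, " SNPs")
  ids <- ped[[2]]
  if (anyDuplicated(ids)) ids <- paste(ped[[1]], ped[[2]], sep = "_")
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  n <- nrow(ped)
  geno <- matrix(NA_integer_, n, m)
  allele_A <- character(m); allele_B <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    al <- sort(unique(obs))
    if (length(al) > 2L)
      stop("more than two alleles observed at SNP ", map$snp_id[j])
    if (length(al) == 0L) al <- c("A", "B")   # fully missing column
    if (length(al) == 1L) al <- c(al, if (al == "A") "B" else "A")
    ## minor allele as allele_B
    cnt2 <- sum(obs == al[2])
    if (cnt2 > length(obs) / 2) al <- rev(al)
    allele_A[j] <- al[1]; allele_B[j] <- al[2]
    g <- (x1 == al[2]) + (x2 == al[2])
    g[miss] <- NA_integer_
    geno[, j] <- as.integer(g)
  }
  map$allele_A <- allele_A
  map$allele_B <- allele_B
  genotype_dataset(geno, ids, map, phase_known = FALSE)
}

#' Write a genotype dataset as PLINK ped/map
#'
#' Inverse of [read_plink()] up to allele labelling; a write/read round trip
#' reproduces the genotype matrix exactly.
#'
#' @param dataset a [genotype_dataset()].
#' @param ped_path,map_path output file paths.
#' @param pops optional [population_set()]; populations become family ids.
#' @return Invisibly, `dataset`.
#' @export
write_plink <- function(dataset, ped_path, map_path, pops = NULL) {
  map <- dataset$snp_map
  write.table(map[, c("chrom", "snp_id", "gpos", "pos")], map_path,
              quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  g <- dataset$genotypes
  n <- nrow(g); m <- ncol(g)
  fam <- if (is.null(pops)) rep("FAM", n) else
    unname(pops$pop[dataset$individual_ids])
  out <- matrix("0", n, 6L + 2L * m)
  out[, 1] <- fam
  out[, 2] <- dataset$individual_ids
  out[, 5] <- "0"; out[, 6] <- "-9"
  for (j in seq_len(m)) {
    a <- map$allele_A[j]; b <- map$allele_B[j]
    gj <- g[, j]
    x1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1L, b, a))
    x2 <- ifelse(is.na(gj), "0", ifelse(gj == 2L, b, a))
    out[, 6L + 2L * j - 1L] <- x1
    out[, 6L + 2L * j] <- x2
  }
  write.table(out, ped_path, quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(dataset)
}

#' Read a population assignment table
#'
#' Three-column whitespace/tab separated file: individual, population, group.
#' A header line is detected and skipped if its first field is
#' `"individual"`.
#'
#' @param path file path.
#' @return A [population_set()].
#' @export
read_pop_assignments <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) != 3L)
    stop("population assignment file must have 3 columns, found ", ncol(tab))
  if (tolower(tab[1, 1]) == "individual") tab <- tab[-1, , drop = FALSE]
  population_set(tab[[1]], tab[[2]], tab[[3]])
}

#' Write a population assignment table
#' @param pops a [population_set()].
#' @param path output path.
#' @return Invisibly, `pops`.
#' @export
write_pop_assignments <- function(pops, path) {
  tab <- data.frame(individual = names(pops$pop),
                    population = unname(pops$pop),
                    group = unname(pops$group[pops$pop]))
  write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(pops)
}
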