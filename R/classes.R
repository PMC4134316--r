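## Core containers. Kept deliberately light: plain lists with validators,
## in the style of ape's "phylo" rather than formal S4.

#' Construct a genotype dataset
#'
#' Bundles a diploid genotype matrix with its SNP map. Genotypes are counts of
#' `allele_B` (0, 1, 2 or `NA` for missing). SNPs are stored sorted by
#' (chromosome, position); the genotype columns are permuted accordingly.
#'
#' @param genotypes integer matrix, individuals x SNPs, values in
#'   `c(0, 1, 2, NA)`.
#' @param individual_ids character vector of unique individual identifiers.
#' @param snp_map data frame with columns `chrom`, `snp_id`, `gpos`
#'   (genetic position, may be 0), `pos` (bp, 1-based), `allele_A`,
#'   `allele_B`.
#' @param phase_known logical; `FALSE` for unphased genotype data.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, individual_ids, snp_map,
                             phase_known = FALSE) {
  genotypes <- as.matrix(genotypes)
  if (length(individual_ids) != nrow(genotypes))
    stop("individual_ids length does not match genotype rows")
  if (anyDuplicated(individual_ids))
    stop("individual_ids must be unique")
  if (nrow(snp_map) != ncol(genotypes))
    stop("snp_map rows do not match genotype columns")
  need <- c("chrom", "snp_id", "gpos", "pos", "allele_A", "allele_B")
  miss <- setdiff(need, names(snp_map))
  if (length(miss)) stop("snp_map missing columns: ", paste(miss, collapse = ", "))
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA")
  if (any(snp_map$allele_A == snp_map$allele_B))
    stop("allele_A must differ from allele_B: ",
         snp_map$snp_id[which(snp_map$allele_A == snp_map$allele_B)[1]])
  ## sort by (chrom, pos), permute genotype columns consistently
  ord <- order(snp_map$chrom, snp_map$pos)
  snp_map <- snp_map[ord, , drop = FALSE]
  rownames(snp_map) <- NULL
  genotypes <- genotypes[, ord, drop = FALSE]
  for (ch in unique(snp_map$chrom)) {
    p <- snp_map$pos[snp_map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- individual_ids
  colnames(genotypes) <- snp_map$snp_id
  structure(list(genotypes = genotypes,
                 individual_ids = as.character(individual_ids),
                 snp_map = snp_map,
                 phase_known = isTRUE(phase_known)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "SNPs on",
      length(unique(x$snp_map$chrom)), "chromosome(s);",
      if (x$phase_known) "phased" else "unphased", "\n")
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param x a [genotype_dataset()].
#' @param individuals character vector of individual ids (default all).
#' @param chrom optional chromosome to restrict to.
#' @param snps optional character vector of SNP ids.
#' @return A `genotype_dataset`.
#' @export
subset_dataset <- function(x, individuals = NULL, chrom = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_dataset"))
  keep_i <- if (is.null(individuals)) x$individual_ids else individuals
  if (!all(keep_i %in% x$individual_ids)) stop("unknown individual id")
  keep_j <- rep(TRUE, ncol(x$genotypes))
  if (!is.null(chrom)) keep_j <- keep_j & x$snp_map$chrom %in% chrom
  if (!is.null(snps)) keep_j <- keep_j & x$snp_map$snp_id %in% snps
  genotype_dataset(x$genotypes[keep_i, keep_j, drop = FALSE], keep_i,
                   x$snp_map[keep_j, , drop = FALSE], x$phase_known)
}

#' Construct a population set
#'
#' Maps individuals to populations and populations to (geographic) groups.
#'
#' @param individual character vector of individual ids.
#' @param population character vector, same length, population of each
#'   individual.
#' @param group character vector, same length, group of each individual's
#'   population (a population must belong to exactly one group).
#' @return An object of class `population_set` with elements `pop`
#'   (named by individual), `group` (named by population) and `sizes`
#'   (named integer vector of per-population diploid sample sizes).
#' @export
population_set <- function(individual, population, group) {
  stopifnot(length(individual) == length(population),
            length(individual) == length(group))
  individual <- as.character(individual)
  population <- as.character(population)
  group <- as.character(group)
  dup <- duplicated(individual)
  if (any(dup)) {
    ## duplicates allowed only if fully consistent
    for (id in unique(individual[dup])) {
      rows <- individual == id
      if (length(unique(population[rows])) > 1L)
        stop("individual ", id, " listed with conflicting populations")
    }
    keep <- !dup
    individual <- individual[keep]; population <- population[keep]
    group <- group[keep]
  }
  pg <- unique(data.frame(population, group, stringsAsFactors = FALSE))
  if (anyDuplicated(pg$population))
    stop("population assigned to more than one group: ",
         pg$population[duplicated(pg$population)][1])
  pop <- setNames(population, individual)
  grp <- setNames(pg$group, pg$population)
  sizes <- table(population)
  sizes <- setNames(as.integer(sizes), names(sizes))
  structure(list(pop = pop, group = grp, sizes = sizes),
            class = "population_set")
}

#' @export
print.population_set <- function(x, ...) {
  cat("population_set:", length(x$pop), "individuals,",
      length(x$group), "populations,",
      length(unique(x$group)), "group(s)\n")
  invisible(x)
}

#' Populations belonging to a group
#' @param pops a [population_set()].
#' @param group group label.
#' @return Character vector of population labels.
#' @export
group_populations <- function(pops, group) {
  names(pops$group)[pops$group == group]
}

## internal: individuals of the given populations, in dataset order
individuals_of <- function(dataset, pops, populations) {
  ids <- names(pops$pop)[pops$pop %in% populations]
  intersect(dataset$individual_ids, ids)
}
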