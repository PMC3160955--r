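# Readers/writers for the plain-text table formats.
#
# All inputs are CSV with headers; missing values may be written as NA, an
# empty field or "-". Genotypes are 0/1/2 counts of the B allele.

#' Read a genetic map CSV
#'
#' Expects header `marker,chr,pos` with positions in cM.
#' @param path CSV path.
#' @return A validated map tibble.
#' @export
read_genemap <- function(path) {
  tab <- readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE,
    na = c("NA", "", "-")
  )
  validate_genemap(tab)
}

#' Read a genotype CSV
#'
#' Expects an `id` column followed by one column per marker, entries in
#' 0/1/2 or missing (`NA`, empty, `-`).
#' @param path CSV path.
#' @return A numeric matrix, rows named by individual id.
#' @export
read_genotypes <- function(path) {
  tab <- readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE,
    na = c("NA", "", "-")
  )
  if (!"id" %in% names(tab)) stop("genotype file is missing the id column")
  G <- as.matrix(tab[, setdiff(names(tab), "id"), drop = FALSE])
  mode(G) <- "numeric"
  bad <- !(G %in% c(0, 1, 2) | is.na(G))
  if (any(bad)) {
    stop(
      "genotype values must be 0, 1, 2 or missing; offending value(s): ",
      paste(utils::head(unique(G[bad]), 5), collapse = ", ")
    )
  }
  rownames(G) <- as.character(tab$id)
  G
}

#' Read a phenotype/covariate CSV
#'
#' Expects an `id` column, a phenotype column `y`, and any number of
#' covariate columns.
#' @param path CSV path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE,
    na = c("NA", "", "-")
  )
  if (!"id" %in% names(tab)) stop("phenotype file is missing the id column")
  tab$id <- as.character(tab$id)
  tab
}

#' Read and cross-validate the full input set
#'
#' Reads the pedigree, map, genotype and phenotype tables and checks them
#' against each other: phenotype ids must be a subset of pedigree ids,
#' genotype markers must all be on the map (columns are reordered to map
#' order), and genotype ids must be a subset of pedigree ids.
#'
#' @param pedigree,genemap,genotypes,phenotypes File paths; any may be
#'   `NULL` to skip.
#' @return A list with elements `ped`, `map`, `geno`, `pheno` (those
#'   requested).
#' @export
read_tables <- function(pedigree = NULL, genemap = NULL, genotypes = NULL,
                        phenotypes = NULL) {
  out <- list()
  if (!is.null(pedigree)) out$ped <- read_pedigree(pedigree)
  if (!is.null(genemap)) out$map <- read_genemap(genemap)
  if (!is.null(genotypes)) out$geno <- read_genotypes(genotypes)
  if (!is.null(phenotypes)) out$pheno <- read_phenotypes(phenotypes)

  if (!is.null(out$geno) && !is.null(out$map)) {
    extra <- setdiff(colnames(out$geno), out$map$marker)
    if (length(extra) > 0) {
      stop("genotyped marker(s) absent from map: ", paste(extra, collapse = ", "))
    }
    out$geno <- out$geno[, intersect(out$map$marker, colnames(out$geno)), drop = FALSE]
  }
  if (!is.null(out$pheno) && !is.null(out$ped)) {
    bad <- setdiff(out$pheno$id, out$ped$id)
    if (length(bad) > 0) {
      stop("phenotyped id(s) absent from pedigree: ", paste(bad, collapse = ", "))
    }
  }
  if (!is.null(out$geno) && !is.null(out$ped)) {
    bad <- setdiff(rownames(out$geno), out$ped$id)
    if (length(bad) > 0) {
      stop("genotyped id(s) absent from pedigree: ", paste(bad, collapse = ", "))
    }
  }
  out
}

#' Write a pedigree, genotype matrix or phenotype table to CSV
#'
#' @param ped Pedigree tibble.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  readr::write_csv(as.data.frame(ped)[, c("id", "sire", "dam", "sex", "generation")],
    path,
    progress = FALSE
  )
  invisible(ped)
}

#' @rdname write_pedigree
#' @param map Map tibble.
#' @export
write_genemap <- function(map, path) {
  readr::write_csv(map, path, progress = FALSE)
  invisible(map)
}

#' @rdname write_pedigree
#' @param geno Genotype matrix with row names.
#' @export
write_genotypes <- function(geno, path) {
  tab <- dplyr::bind_cols(
    tibble::tibble(id = rownames(geno)),
    tibble::as_tibble(geno)
  )
  readr::write_csv(tab, path, progress = FALSE)
  invisible(geno)
}

#' @rdname write_pedigree
#' @param pheno Phenotype tibble.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_csv(pheno, path, progress = FALSE)
  invisible(pheno)
}

#' Write a genome-scan result to TSV
#'
#' Columns: `marker,chr,pos_cM,df,LRT,LOD,p,add_effect,dom_effect,testable`.
#' @param scan A `"pedscan_scan"` tibble.
#' @param path Output path.
#' @return The scan, invisibly.
#' @export
write_scan <- function(scan, path) {
  out <- tibble::tibble(
    marker = scan$marker, chr = scan$chr, pos_cM = scan$pos, df = scan$df,
    LRT = scan$lrt, LOD = scan$lod, p = scan$p,
    add_effect = scan$add_effect, dom_effect = scan$dom_effect,
    testable = scan$testable
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(scan)
}
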