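# Domain types and file I/O: bin maps, genotype matrices, phenotypes, gene
# catalogs. All files are UTF-8 TSV with a header row; lines starting with
# "#" are ignored.

GENO_CODES <- c("A", "H", "B")

#' Construct a bin map
#'
#' A bin map is the genome coordinate system of the analysis: an ordered set
#' of marker bins with chromosome and genetic (cM) positions, optionally
#' annotated with physical (bp) intervals. Rows are sorted by
#' (chromosome, pos_cM); all cM distances, QTL grouping and gene association
#' are computed on this map.
#'
#' @param bin_id character vector of unique bin identifiers.
#' @param chrom character vector of chromosome names.
#' @param pos_cM numeric vector of non-negative map positions in centi-Morgan.
#' @param bp_start,bp_end optional integer physical coordinates (annotation
#'   only; never used in distance computations).
#' @return A `bin_map` object (a data frame with one row per bin, sorted by
#'   chromosome then cM position).
#' @examples
#' bm <- bin_map(c("Bin1", "Bin2", "Bin3"), c("1", "1", "2"), c(0, 1.2, 0))
#' nrow(bm)
#' @export
bin_map <- function(bin_id, chrom, pos_cM, bp_start = NULL, bp_end = NULL) {
  bin_id <- as.character(bin_id)
  chrom <- as.character(chrom)
  pos_cM <- as.numeric(pos_cM)
  if (anyDuplicated(bin_id)) {
    stop("duplicate bin_id: ", paste(unique(bin_id[duplicated(bin_id)]), collapse = ", "))
  }
  if (anyNA(pos_cM)) stop("non-numeric or missing pos_cM")
  if (any(pos_cM < 0)) stop("pos_cM must be >= 0")
  n <- length(bin_id)
  if (length(chrom) != n || length(pos_cM) != n) stop("field lengths differ")
  if (n < 2) stop("a bin map needs more than one bin")
  df <- data.frame(bin_id = bin_id, chrom = chrom, pos_cM = pos_cM,
                   stringsAsFactors = FALSE)
  if (!is.null(bp_start)) df$bp_start <- as.integer(bp_start)
  if (!is.null(bp_end)) df$bp_end <- as.integer(bp_end)
  ord <- order(df$chrom, df$pos_cM)
  if (is.unsorted(ord, strictly = FALSE) && any(ord != seq_len(n))) {
    warning("bin map rows were not sorted by (chrom, pos_cM); re-sorting")
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("bin_map", "data.frame")
  df
}

#' Read a bin map from a TSV file
#'
#' Expects columns `bin_id`, `chrom`, `pos_cM` and optionally `bp_start`,
#' `bp_end`. Out-of-order rows are re-sorted with a warning; duplicate bin
#' ids are an error.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A [bin_map()].
#' @export
read_bin_map <- function(path) {
  df <- read_tsv_strict(path, c("bin_id", "chrom", "pos_cM"))
  pos <- suppressWarnings(as.numeric(df$pos_cM))
  if (anyNA(pos)) {
    bad <- df$bin_id[is.na(pos)]
    stop("non-numeric pos_cM for bin(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  bin_map(df$bin_id, df$chrom, pos,
          bp_start = if ("bp_start" %in% names(df)) df$bp_start,
          bp_end = if ("bp_end" %in% names(df)) df$bp_end)
}

#' @export
write_bin_map <- function(map, path) {
  write_tsv_plain(as.data.frame(map), path)
  invisible(path)
}

#' Construct a genotype matrix
#'
#' Genotypes of a biparental population at the map's bins, coded `A` and `B`
#' for the two parental homozygotes and `H` for the heterozygote. No missing
#' values are allowed. Columns that never show both parental alleles
#' (monomorphic bins) are retained but flagged; they are excluded from the
#' candidate effect set downstream.
#'
#' @param codes character matrix (individuals x bins) over {A,H,B}.
#' @param individual_ids,bin_ids row and column identifiers; default to the
#'   dimnames of `codes`.
#' @return A `geno_matrix`: a character matrix with row/column names and a
#'   `monomorphic` attribute (logical per column).
#' @export
geno_matrix <- function(codes, individual_ids = rownames(codes),
                        bin_ids = colnames(codes)) {
  codes <- as.matrix(codes)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(codes)))
  if (is.null(bin_ids)) stop("bin_ids required")
  bad <- !(codes %in% GENO_CODES)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(codes)), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype code '%s' at individual '%s', bin '%s'",
                 codes[idx[1], idx[2]], individual_ids[idx[1]], bin_ids[idx[2]]))
  }
  dimnames(codes) <- list(as.character(individual_ids), as.character(bin_ids))
  mono <- apply(codes, 2, function(col) !any(col %in% c("A", "B")))
  attr(codes, "monomorphic") <- mono
  class(codes) <- c("geno_matrix", class(codes))
  codes
}

#' Read genotypes from TSV, column-ordered against a bin map
#'
#' File layout: first column `individual_id`, remaining columns one per bin
#' (header = bin ids), cells in {A,H,B}. Columns are reordered to the map's
#' bin order; the file must cover every map bin.
#'
#' @param path TSV file path.
#' @param map a [bin_map()] defining the required bins and their order.
#' @return A [geno_matrix()] with columns in map order.
#' @export
read_genotypes <- function(path, map) {
  df <- read_tsv_strict(path, "individual_id")
  bins <- setdiff(names(df), "individual_id")
  missing <- setdiff(map$bin_id, bins)
  if (length(missing)) {
    stop("genotype file does not cover map bins: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  m <- as.matrix(df[, map$bin_id, drop = FALSE])
  geno_matrix(m, individual_ids = df$individual_id, bin_ids = map$bin_id)
}

#' @export
write_genotypes <- function(G, path) {
  df <- data.frame(individual_id = rownames(G), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(unclass(G)[, , drop = FALSE]))
  write_tsv_plain(df, path)
  invisible(path)
}

#' Read phenotypes from TSV
#'
#' File layout: `individual_id` plus one numeric column per trait. Row order
#' is aligned to the genotype matrix when `G` is given.
#'
#' @param path TSV file path.
#' @param trait trait column to extract; default first trait column.
#' @param G optional [geno_matrix()]; individuals are matched by id.
#' @return A named numeric vector (one phenotype value per individual) with
#'   attribute `trait`.
#' @export
read_phenotypes <- function(path, trait = NULL, G = NULL) {
  df <- read_tsv_strict(path, "individual_id")
  traits <- setdiff(names(df), "individual_id")
  if (!length(traits)) stop("no trait columns in ", path)
  if (is.null(trait)) trait <- traits[[1]]
  if (!trait %in% traits) stop("trait '", trait, "' not in file")
  y <- as.numeric(df[[trait]])
  names(y) <- df$individual_id
  if (!all(is.finite(y))) stop("non-finite phenotype values for trait ", trait)
  if (!is.null(G)) {
    if (!all(rownames(G) %in% names(y))) stop("phenotypes missing for some individuals")
    y <- y[rownames(G)]
  }
  attr(y, "trait") <- trait
  y
}

#' @export
write_phenotypes <- function(y, path, trait = attr(y, "trait") %||% "trait1") {
  df <- data.frame(individual_id = names(y), y, stringsAsFactors = FALSE)
  names(df)[2] <- trait
  write_tsv_plain(df, path)
  invisible(path)
}

#' Read a gene catalog (gene_name, chrom, pos_cM)
#'
#' A user-supplied list of genes with genetic-map positions, used only for
#' proximity annotation of mapped QTLs. Chromosomes must exist in the map.
#'
#' @param path TSV file path.
#' @param map a [bin_map()] used to validate chromosome names.
#' @return data frame with columns gene_name, chrom, pos_cM.
#' @export
read_gene_catalog <- function(path, map) {
  df <- read_tsv_strict(path, c("gene_name", "chrom", "pos_cM"))
  df$pos_cM <- as.numeric(df$pos_cM)
  if (anyNA(df$pos_cM)) stop("non-numeric gene pos_cM")
  unknown <- setdiff(unique(df$chrom), unique(map$chrom))
  if (length(unknown)) stop("gene catalog chromosomes not in map: ",
                            paste(unknown, collapse = ", "))
  df[, c("gene_name", "chrom", "pos_cM")]
}

#' Genetic distance between two bins
#'
#' Distance in cM along the map. Bins on different chromosomes are
#' incomparable and return `Inf`: cross-chromosome cM differences are
#' meaningless, so such pairs are never grouped together nor gene-associated.
#'
#' @param map a [bin_map()].
#' @param bin_a,bin_b bin ids present in the map.
#' @return absolute cM distance, or `Inf` across chromosomes.
#' @export
cm_distance <- function(map, bin_a, bin_b) {
  ia <- match(bin_a, map$bin_id)
  ib <- match(bin_b, map$bin_id)
  if (is.na(ia)) stop("unknown bin: ", bin_a)
  if (is.na(ib)) stop("unknown bin: ", bin_b)
  ifelse(map$chrom[ia] == map$chrom[ib], abs(map$pos_cM[ia] - map$pos_cM[ib]), Inf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strict TSV reader: header, "#" comments, required columns
read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop(path, ": missing required column(s): ",
                         paste(miss, collapse = ", "))
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
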