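#' Write / read a genotype matrix TSV
#'
#' One row per SNP: `chrom`, `pos`, the eight founder allele columns, then
#' one column per strain with its calls (0/1, `NA` = missing call).
#'
#' @param panel A `founder_panel`.
#' @param genotypes SNPs x strains matrix of strain calls.
#' @param path Output path.
#' @export
write_genotype_tsv <- function(panel, genotypes, path) {
  df <- cbind(panel$map, as.data.frame(panel$alleles),
              as.data.frame(genotypes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @return `read_genotype_tsv`: list with a reconstructed `founder_panel`
#'   (chromosome lengths taken as the last SNP position) and the strain
#'   `genotypes` matrix.
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  fcols <- names(cc_founders)
  strains <- setdiff(names(df), c("chrom", "pos", fcols))
  chroms <- unique(df$chrom)
  panel <- structure(list(
    founder_ids = fcols,
    chromosomes = data.frame(
      name = chroms,
      length = vapply(chroms, function(c) max(df$pos[df$chrom == c]), 0)),
    map = df[, c("chrom", "pos")],
    alleles = as.matrix(df[, fcols])
  ), class = "founder_panel")
  list(panel = panel, genotypes = as.matrix(df[, strains, drop = FALSE]))
}

#' Write a trait table TSV
#' @param trait_table data.frame from [derive_trait_table()].
#' @param path Output path.
#' @export
write_trait_table <- function(trait_table, path) {
  utils::write.table(trait_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a scar image pair as 16-bit grayscale TIFFs
#'
#' @param pair A `scar_image_pair`.
#' @param polarized_path,brightfield_path Output paths.
#' @export
write_scar_pair_tiff <- function(pair, polarized_path, brightfield_path) {
  tiff::writeTIFF(pair$polarized, polarized_path, bits.per.sample = 16L)
  tiff::writeTIFF(pair$brightfield_blue, brightfield_path,
                  bits.per.sample = 16L)
  invisible(c(polarized_path, brightfield_path))
}

#' Read a scar image pair from grayscale TIFF or PNG files
#'
#' @param polarized_path,brightfield_path Image paths (`.tif`/`.tiff`/`.png`).
#' @param pixel_size Pixel edge length in micrometres (required; the imaging
#'   field of view does not travel with the files).
#' @return A `scar_image_pair`.
#' @export
read_scar_pair <- function(polarized_path, brightfield_path, pixel_size) {
  rd <- function(p) {
    img <- if (grepl("\\.png$", p, ignore.case = TRUE))
      png::readPNG(p) else tiff::readTIFF(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  }
  p <- rd(polarized_path); b <- rd(brightfield_path)
  if (!identical(dim(p), dim(b))) stop("image shapes do not match")
  structure(list(polarized = p, brightfield_blue = b,
                 pixel_size = pixel_size),
            class = "scar_image_pair")
}

#' Write simulation ground truth as JSON
#' @param truth List of ground-truth values.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
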