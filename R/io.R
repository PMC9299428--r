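# Readers and writers for the plain-text interchange formats.  Every
# writer puts a single `# prsjoint seed=<seed>` comment line at the top
# as an audit trail; readers skip `#` comments.

#' Write / read GWAS summary statistics (TSV)
#'
#' Tab-separated with columns `SNP`, `CHR`, `BP`, `A1`, `A2`, `BETA`,
#' `SE`, `P`.
#'
#' @param stats Summary-statistics tibble.
#' @param path File path.
#' @param seed Seed recorded in the header comment.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_summary_stats <- function(stats, path, seed = NA) {
  writeLines(sprintf("# prsjoint seed=%s", seed), path)
  readr::write_tsv(
    stats[c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P")],
    path,
    append = TRUE, col_names = TRUE
  )
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  readr::read_tsv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      SNP = "c", CHR = "c", BP = "i", A1 = "c", A2 = "c",
      BETA = "d", SE = "d", P = "d"
    )
  )
}

#' Write / read a dosage panel (PLINK-.raw-style TSV)
#'
#' First two columns `FID` and `IID`, then one column per variant named
#' by its id, holding the dosage of the counted allele.  Variant
#' metadata travels in a sidecar `<path>.vars` TSV (id, chrom, pos, a1,
#' a2, maf, block).
#'
#' @param panel `genotype_panel`.
#' @param path File path.
#' @return `path`, invisibly (writer); a `genotype_panel` (reader).
#' @export
write_dosages <- function(panel, path) {
  writeLines(sprintf("# prsjoint seed=%s", panel$seed %||% NA), path)
  d <- tibble::as_tibble(panel$dosages)
  out <- dplyr::bind_cols(
    tibble::tibble(FID = panel$individuals$iid, IID = panel$individuals$iid),
    d
  )
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  readr::write_tsv(panel$variants, paste0(path, ".vars"))
  invisible(path)
}

#' @rdname write_dosages
#' @export
read_dosages <- function(path) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  variants <- readr::read_tsv(paste0(path, ".vars"), show_col_types = FALSE)
  dos <- as.matrix(d[, -(1:2)])
  storage.mode(dos) <- "integer"
  dimnames(dos) <- list(d$IID, colnames(dos))
  structure(
    list(
      individuals = tibble::tibble(iid = d$IID),
      variants = variants,
      dosages = dos,
      seed = NA
    ),
    class = "genotype_panel"
  )
}

#' Write / read a cohort table (CSV)
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @param seed Seed recorded in the header comment.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_cohort <- function(cohort, path, seed = NA) {
  writeLines(sprintf("# prsjoint seed=%s", seed), path)
  readr::write_csv(cohort, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write ground truth as JSON
#'
#' @param truth A `ground_truth` list.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
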