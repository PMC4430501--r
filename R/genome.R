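#' Genome model
#'
#' A genome model holds the ordered chromosome lengths and the mappable
#' genome size `M` used by the uniform background null of the significance
#' tests. Unless given, the mappable size defaults to 80% of the summed
#' chromosome lengths, a typical uniquely-mappable fraction for short tags.
#'
#' @param chromosomes A data frame with columns `chrom` and `length` (bp),
#'   or a named numeric vector of lengths.
#' @param mappable_size Mappable genome size in bp (`M`). Default
#'   `0.8 * sum(lengths)`.
#' @return An object of class `genome_model`.
#' @export
#' @examples
#' genome_model(c(chr1 = 2e6, chr2 = 2e6))
genome_model <- function(chromosomes, mappable_size = NULL) {
  if (is.numeric(chromosomes)) {
    stopifnot(!is.null(names(chromosomes)))
    chromosomes <- tibble::tibble(
      chrom = names(chromosomes),
      length = as.numeric(chromosomes)
    )
  }
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  if (anyDuplicated(chromosomes$chrom)) stop("duplicated chromosome names")
  total <- sum(chromosomes$length)
  if (is.null(mappable_size)) mappable_size <- 0.8 * total
  if (mappable_size <= 0 || mappable_size > total) {
    stop("mappable_size must lie in (0, total genome length]")
  }
  structure(
    list(chromosomes = chromosomes, mappable_size = mappable_size),
    class = "genome_model"
  )
}

#' Read a chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path File path.
#' @inheritParams genome_model
#' @return A [genome_model()].
#' @export
read_chrom_sizes <- function(path, mappable_size = NULL) {
  tab <- readr::read_tsv(
    path,
    col_names = c("chrom", "length"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      length = readr::col_double()
    ),
    progress = FALSE
  )
  genome_model(tab, mappable_size = mappable_size)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$chromosomes), " chromosomes, ",
      format(sum(x$chromosomes$length), big.mark = ","), " bp (mappable ",
      format(x$mappable_size, big.mark = ","), " bp)\n", sep = "")
  invisible(x)
}

genome_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$chrom)
  genome$chromosomes$length[i]
}
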