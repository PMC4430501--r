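#' Build a read-pair table
#'
#' Orders each mate pair by coordinate (within a chromosome, or by genome
#' chromosome order across chromosomes), assigns the strand-orientation
#' label of the ordered pair, and validates chromosomes against the genome
#' model. The aligned location of a mate is its 5' end: the interval start
#' for + strand mates and `end - 1` for - strand mates.
#'
#' @param pairs A data frame with columns `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2` (positions are 0-based aligned locations).
#' @param genome A [genome_model()].
#' @param dedup Drop duplicate pairs (identical coordinates and strands)?
#'   Default `FALSE`.
#' @return A tibble of class `chia_pairs` with an added `orientation`
#'   column and attributes `genome` and `counts`.
#' @export
chia_pairs <- function(pairs, genome, dedup = FALSE) {
  pairs <- tibble::as_tibble(pairs)
  need <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  stopifnot(all(need %in% names(pairs)))
  if (nrow(pairs) == 0) stop("no read pairs")
  if (!all(c(pairs$strand1, pairs$strand2) %in% c("+", "-"))) {
    stop("strands must be '+' or '-'")
  }
  chrom_order <- genome$chromosomes$chrom
  known <- pairs$chrom1 %in% chrom_order & pairs$chrom2 %in% chrom_order
  if (!all(known)) {
    message(sum(!known), " read pair(s) on unknown chromosomes dropped")
    pairs <- pairs[known, ]
    if (nrow(pairs) == 0) stop("no read pairs on known chromosomes")
  }
  c1 <- match(pairs$chrom1, chrom_order)
  c2 <- match(pairs$chrom2, chrom_order)
  swap <- c2 < c1 | (c1 == c2 & pairs$pos2 < pairs$pos1)
  out <- tibble::tibble(
    chrom1 = ifelse(swap, pairs$chrom2, pairs$chrom1),
    pos1 = ifelse(swap, pairs$pos2, pairs$pos1),
    strand1 = ifelse(swap, pairs$strand2, pairs$strand1),
    chrom2 = ifelse(swap, pairs$chrom1, pairs$chrom2),
    pos2 = ifelse(swap, pairs$pos1, pairs$pos2),
    strand2 = ifelse(swap, pairs$strand1, pairs$strand2)
  )
  if ("label" %in% names(pairs)) out$label <- pairs$label
  if (dedup) {
    out <- dplyr::distinct(
      out, .data$chrom1, .data$pos1, .data$strand1,
      .data$chrom2, .data$pos2, .data$strand2,
      .keep_all = TRUE
    )
  }
  out$orientation <- paste0(out$strand1, out$strand2)
  new_chia_pairs(out, genome)
}

new_chia_pairs <- function(tbl, genome) {
  counts <- c(
    N = nrow(tbl),
    `N++` = sum(tbl$orientation == "++"),
    `N+-` = sum(tbl$orientation == "+-"),
    `N-+` = sum(tbl$orientation == "-+"),
    `N--` = sum(tbl$orientation == "--")
  )
  structure(
    tbl,
    genome = genome,
    counts = counts,
    class = c("chia_pairs", class(tibble::tibble()))
  )
}

#' Read aligned read pairs from a BEDPE file
#'
#' Expects the standard 10-column BEDPE layout (chrom1, start1, end1,
#' chrom2, start2, end2, name, score, strand1, strand2). The aligned
#' location of each mate is its 5' end. Records on chromosomes absent from
#' the genome model are dropped with a message.
#'
#' @param path BEDPE file path.
#' @inheritParams chia_pairs
#' @return A `chia_pairs` tibble.
#' @export
read_bedpe <- function(path, genome, dedup = FALSE) {
  tab <- readr::read_tsv(
    path,
    col_names = c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "name", "score", "strand1", "strand2"),
    col_types = "cddcddcccc",
    progress = FALSE
  )
  if (nrow(tab) == 0) stop("empty BEDPE file: ", path)
  bad <- which(is.na(tab$start1) | is.na(tab$end1) | is.na(tab$start2) |
                 is.na(tab$end2) | !(tab$strand1 %in% c("+", "-")) |
                 !(tab$strand2 %in% c("+", "-")))
  if (length(bad) > 0) {
    stop("malformed BEDPE record at line ", bad[1], " of ", path)
  }
  pairs <- tibble::tibble(
    chrom1 = tab$chrom1,
    pos1 = ifelse(tab$strand1 == "+", tab$start1, tab$end1 - 1),
    strand1 = tab$strand1,
    chrom2 = tab$chrom2,
    pos2 = ifelse(tab$strand2 == "+", tab$start2, tab$end2 - 1),
    strand2 = tab$strand2
  )
  if (!all(tab$name %in% c(".", "", NA))) pairs$label <- tab$name
  chia_pairs(pairs, genome, dedup = dedup)
}

#' Orientation counts of a read-pair set
#'
#' @param pairs A `chia_pairs` tibble.
#' @return Named integer vector `N`, `N++`, `N+-`, `N-+`, `N--`.
#' @export
orientation_counts <- function(pairs) {
  attr(pairs, "counts")
}

#' Distance between the aligned mate locations
#'
#' Adds a `distance` column: `|pos2 - pos1|` for intra-chromosomal pairs,
#' `NA` for inter-chromosomal pairs.
#'
#' @param pairs A `chia_pairs` tibble (or compatible data frame).
#' @return The input with a `distance` column.
#' @export
pair_distance <- function(pairs) {
  pairs$distance <- ifelse(pairs$chrom1 == pairs$chrom2,
                           abs(pairs$pos2 - pairs$pos1), NA_real_)
  pairs
}

#' Partition read pairs by self-ligation-compatible orientation
#'
#' Self-ligation pairs always carry the -+ orientation and lie within one
#' chromosome, so only intra-chromosomal -+ pairs can be self-ligation.
#' Inter-chromosomal -+ pairs join the inter-ligation-only partition.
#'
#' @param pairs A `chia_pairs` tibble.
#' @return A list with elements `minus_plus` (intra-chromosomal -+ pairs)
#'   and `other` (everything else), both `chia_pairs`.
#' @export
split_by_orientation <- function(pairs) {
  genome <- attr(pairs, "genome")
  is_mp <- pairs$orientation == "-+" & pairs$chrom1 == pairs$chrom2
  tbl <- tibble::as_tibble(pairs)
  list(
    minus_plus = new_chia_pairs(tbl[is_mp, ], genome),
    other = new_chia_pairs(tbl[!is_mp, ], genome)
  )
}

#' @export
print.chia_pairs <- function(x, ...) {
  cts <- attr(x, "counts")
  cat("<chia_pairs> ", cts["N"], " read pairs (",
      paste(names(cts)[-1], cts[-1], sep = "=", collapse = ", "), ")\n",
      sep = "")
  NextMethod()
}
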