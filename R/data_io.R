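#' Read an ASV count table
#'
#' Reads a tab-separated taxa-by-samples table whose first column is headed
#' `taxon_id` and whose remaining columns are integer read counts, one
#' column per sample. Sample metadata (station, date, covariates) can be
#' supplied as the companion TSV read by [readSampleMetadata()]; without
#' it, all samples are assigned to one station with times 0, 1, 2, ...
#'
#' @param path path to the ASV table TSV.
#' @param metadata optional: path to a metadata TSV, or the data.frame
#'   returned by [readSampleMetadata()].
#' @return A [CommunityMatrix-class].
#' @export
readAsvTable <- function(path, metadata = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (colnames(tab)[1] != "taxon_id")
    stop("first column of an ASV table must be headed 'taxon_id'")
  ids <- tab[[1]]
  if (anyDuplicated(ids)) stop("duplicate taxon_ids in ", path)
  if (anyDuplicated(colnames(tab)[-1]))
    stop("duplicate sample column names in ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(ids, colnames(tab)[-1])))
  if (any(is.na(num)) || any(num != round(num)) || any(num < 0))
    stop("ASV table cells must be non-negative integers: ", path)
  if (is.character(metadata)) metadata <- readSampleMetadata(metadata)
  if (is.null(metadata)) {
    CommunityMatrix(num, station = "S1", time = seq_len(ncol(num)) - 1)
  } else {
    idx <- match(colnames(num), metadata$sample_id)
    if (anyNA(idx)) stop("samples missing from metadata: ",
                         paste(colnames(num)[is.na(idx)], collapse = ", "))
    md <- metadata[idx, , drop = FALSE]
    CommunityMatrix(num, station = md$station, time = md$time, env = md)
  }
}

#' Write an ASV count table
#' @param cm a [CommunityMatrix-class]
#' @param path output TSV path
#' @return `path`, invisibly.
#' @export
writeAsvTable <- function(cm, path) {
  m <- counts(cm)
  df <- data.frame(taxon_id = rownames(m),
                   format(m, scientific = FALSE, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' The metadata TSV has columns `sample_id, station, date, salinity,
#' temperature, pH, NOx, PO4` with ISO-8601 dates. A `time` column (days
#' since the earliest date within each station) is computed on read.
#'
#' @param path TSV path
#' @return data.frame with a computed `time` column.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.delim(path, check.names = FALSE)
  need <- c("sample_id", "station", "date")
  if (!all(need %in% colnames(md)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_ids in ", path)
  d <- as.Date(md$date)
  if (anyNA(d)) stop("dates must be ISO 8601 (YYYY-MM-DD)")
  md$time <- as.numeric(d - ave(d, md$station, FUN = min))
  md
}

#' @rdname readSampleMetadata
#' @param cm a [CommunityMatrix-class]
#' @export
writeSampleMetadata <- function(cm, path) {
  env <- environmentSeries(cm)
  utils::write.table(env, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binarize counts to presence-absence
#'
#' @param cm a [CommunityMatrix-class]
#' @return A [CommunityMatrix-class] (`PresenceMatrix`) with entries
#'   1 where the count was positive. No minimum-count threshold is applied.
#' @export
binarize <- function(cm) {
  out <- cm
  SummarizedExperiment::assay(out, "counts") <- (counts(cm) > 0) * 1
  new("PresenceMatrix", out)
}

# Multivariate hypergeometric draw: subsample `depth` reads without
# replacement from one sample's read pool (sequential rhyper).
.rarefyColumn <- function(col, depth) {
  out <- numeric(length(col))
  remaining <- sum(col) - cumsum(col)
  left <- depth
  for (i in seq_along(col)) {
    if (left == 0) break
    if (remaining[i] == 0) { out[i] <- left; break }
    out[i] <- stats::rhyper(1, col[i], remaining[i], left)
    left <- left - out[i]
  }
  out
}

#' Rarefy a community matrix to fixed depth
#'
#' Subsamples every sample's reads without replacement (multivariate
#' hypergeometric) to a common `depth`, the standard normalization for
#' unequal sequencing effort. Taxa whose counts drop to zero everywhere
#' are retained so the taxon axis is stable across repetitions.
#'
#' @param cm a [CommunityMatrix-class]
#' @param depth target reads per sample; defaults to the minimum column sum.
#' @param seed integer seed (draws are reproducible and do not disturb the
#'   caller's RNG stream).
#' @return A rarefied [CommunityMatrix-class]; every column sums to `depth`.
#' @export
rarefy <- function(cm, depth = min(colSums(counts(cm))), seed = NULL) {
  m <- counts(cm)
  depth <- assertCount(depth, "depth")
  tot <- colSums(m)
  if (any(tot < depth))
    stop("samples shallower than depth ", depth, ": ",
         paste(colnames(m)[tot < depth], collapse = ", "))
  out <- withSeed(seed, apply(m, 2, .rarefyColumn, depth = depth))
  dimnames(out) <- dimnames(m)
  res <- cm
  SummarizedExperiment::assay(res, "counts") <- out
  res
}

#' Repeated rarefaction
#'
#' Performs `nRep` independent rarefactions with per-repetition seeds
#' derived from the master seed (`seed + repetition - 1`). Downstream
#' statistics are computed per repetition and averaged by the caller.
#'
#' @inheritParams rarefy
#' @param nRep number of repetitions (100 in the standard workflow).
#' @return list of `nRep` rarefied [CommunityMatrix-class] objects.
#' @export
repeatRarefy <- function(cm, depth = min(colSums(counts(cm))), nRep = 100,
                         seed = 1) {
  nRep <- assertCount(nRep, "nRep")
  lapply(seq_len(nRep) - 1L,
         function(i) rarefy(cm, depth, seed = deriveSeed(seed, i)))
}
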