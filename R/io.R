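#' Write / read an expression dataset as tab-delimited text
#'
#' `writeDataset()` serialises an [ExprSet-class] to two plain-text files:
#' `<prefix>_expression.tsv` (first column `gene_id`, one column per sample,
#' values printed at full double precision) and `<prefix>_samples.tsv`
#' (columns `sample_id`, `patient_id`, `tissue`, then one 0/1 column per
#' endpoint). `readDataset()` reverses the operation; the round trip is
#' exact, bit-for-bit, for values and identifiers.
#'
#' @param ds an [ExprSet-class].
#' @param prefix file path prefix; the two files are written next to it.
#' @return `writeDataset()` returns the two file paths invisibly;
#'   `readDataset()` returns an [ExprSet-class].
#' @examples
#' pair <- generatePaired(syntheticConfig(nPatients = 6, nGenes = 10,
#'                                        nInformative = 2, seed = 1))
#' pfx <- file.path(tempdir(), "toy")
#' writeDataset(pair$normal, pfx)
#' ds <- readDataset(pfx)
#' stopifnot(identical(exprMatrix(ds), exprMatrix(pair$normal)))
#' @export
writeDataset <- function(ds, prefix) {
  stopifnot(is(ds, "ExprSet"))
  exprFile <- paste0(prefix, "_expression.tsv")
  annotFile <- paste0(prefix, "_samples.tsv")
  m <- exprMatrix(ds)
  # %.17g round-trips IEEE doubles exactly
  body <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  lines <- c(
    paste(c("gene_id", colnames(m)), collapse = "\t"),
    paste(rownames(m), apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, exprFile)

  annot <- data.frame(sample_id = sampleIds(ds),
                      patient_id = patientIds(ds),
                      tissue = rep(tissueType(ds), ncol(ds)),
                      stringsAsFactors = FALSE)
  for (ep in endpointNames(ds))
    annot[[ep]] <- unname(endpointLabels(ds, ep))
  write.table(annot, annotFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(expression = exprFile, samples = annotFile))
}

#' @rdname writeDataset
#' @export
readDataset <- function(prefix) {
  exprFile <- paste0(prefix, "_expression.tsv")
  annotFile <- paste0(prefix, "_samples.tsv")
  for (f in c(exprFile, annotFile))
    if (!file.exists(f)) stop("missing dataset file: ", f)

  raw <- read.delim(exprFile, header = TRUE, colClasses = "character",
                    check.names = FALSE)
  if (colnames(raw)[1L] != "gene_id")
    stop("malformed expression header: first column must be 'gene_id'")
  if (ncol(raw) < 2L) stop("malformed expression file: no sample columns")
  gid <- raw[[1L]]
  dup <- gid[duplicated(gid)]
  if (length(dup))
    stop("duplicate gene id '", dup[1L], "' at row ",
         which(gid == dup[1L])[2L])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
    if (nrow(bad) == 0L) bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric expression value '%s' at row %d, column %d",
                 vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L]))
  }
  dimnames(num) <- list(gid, colnames(raw)[-1L])

  annot <- read.delim(annotFile, header = TRUE, colClasses = "character",
                      check.names = FALSE)
  need <- c("sample_id", "patient_id", "tissue")
  if (!all(need %in% colnames(annot)))
    stop("annotation file must contain columns: ",
         paste(need, collapse = ", "))
  if (!setequal(annot$sample_id, colnames(num)) ||
      anyDuplicated(annot$sample_id))
    stop("annotation sample ids do not match expression columns")
  annot <- annot[match(colnames(num), annot$sample_id), , drop = FALSE]
  badT <- which(!annot$tissue %in% c("normal", "tumour"))
  if (length(badT))
    stop(sprintf("invalid tissue value '%s' at annotation row %d",
                 annot$tissue[badT[1L]], badT[1L]))
  eps <- setdiff(colnames(annot), need)
  labels <- list()
  for (ep in eps) {
    v <- suppressWarnings(as.integer(annot[[ep]]))
    if (anyNA(v) || !all(v %in% c(0L, 1L)))
      stop("endpoint column '", ep, "' must be binary 0/1")
    labels[[ep]] <- v
  }
  ExprSet(num, tissue = annot$tissue[1L], patientId = annot$patient_id,
          labels = labels)
}

#' Read gene sets from a GMT file
#'
#' Thin wrapper over [fgsea::gmtPathways()]: one set per line, tab-separated
#' as set name, description, then gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character gene-id vectors.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}
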