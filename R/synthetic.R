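#' Generate a paired normal/tumour synthetic expression study
#'
#' Simulates one patient cohort sampled in both tissue compartments. Each
#' patient contributes one normal and one tumour sample; binary endpoint
#' labels are assigned at the patient level so the paired samples always
#' agree. Per-gene baseline expression is Gaussian with mean 0 and standard
#' deviation `noiseSd`, optionally with equicorrelated blocks. Each endpoint
#' owns a disjoint block of `nInformative` genes; those genes receive an
#' additive class-mean shift of `effectSize * noiseSd` in the positive class,
#' planted only in the compartment(s) named by `signalTissue`. Everything
#' else is class-independent noise, so downstream selection methods can be
#' tested for both recovery and tissue specificity.
#'
#' The number of positive labels per endpoint is `round(classBalance * n)`,
#' so generated labels are balanced to within one sample of the target.
#' The same seed always reproduces the same pair of datasets.
#'
#' @param config a [SyntheticConfig-class], see [syntheticConfig()].
#' @return Named list with elements `normal` and `tumour`, each an
#'   [ExprSet-class]. The informative gene ids per endpoint are recorded in
#'   `metadata(x)$informative`.
#' @examples
#' pair <- generatePaired(syntheticConfig(nPatients = 20, nGenes = 50,
#'                                        nInformative = 5, seed = 42))
#' pair$normal
#' S4Vectors::metadata(pair$normal)$informative$gleason
#' @export
generatePaired <- function(config) {
  validObject(config)
  nP <- config@nPatients
  nG <- config@nGenes
  withSeed(config@seed, {
    patients <- sprintf("P%03d", seq_len(nP))
    genes <- sprintf("g%04d", seq_len(nG))

    # patient-level labels per endpoint
    labels <- list()
    for (ep in config@endpoints) {
      nPos <- round(config@classBalance * nP)
      nPos <- min(max(nPos, 1L), nP - 1L)
      lab <- integer(nP)
      lab[sample.int(nP, nPos)] <- 1L
      labels[[ep]] <- lab
    }

    # disjoint informative blocks, one per endpoint
    informative <- list()
    if (config@nInformative > 0L) {
      pool <- sample.int(nG, length(config@endpoints) * config@nInformative)
      for (i in seq_along(config@endpoints)) {
        take <- pool[seq.int((i - 1L) * config@nInformative + 1L,
                             i * config@nInformative)]
        informative[[config@endpoints[i]]] <- sort(take)
      }
    } else {
      for (ep in config@endpoints) informative[[ep]] <- integer()
    }

    makeCompartment <- function(tissue) {
      # baseline: genes x samples Gaussian noise, optional equicorrelated
      # blocks realised through a shared per-block factor
      m <- matrix(rnorm(nG * nP, sd = config@noiseSd), nG, nP)
      if (config@blockCorrelation > 0) {
        rho <- config@blockCorrelation
        blocks <- split(seq_len(nG),
                        (seq_len(nG) - 1L) %/% config@blockSize)
        for (b in blocks) {
          z <- rnorm(nP, sd = config@noiseSd)
          m[b, ] <- sqrt(rho) * matrix(z, length(b), nP, byrow = TRUE) +
            sqrt(1 - rho) * m[b, ]
        }
      }
      hasSignal <- config@signalTissue == "both" ||
        config@signalTissue == tissue
      if (hasSignal && config@effectSize > 0) {
        shift <- config@effectSize * config@noiseSd
        for (ep in config@endpoints) {
          pos <- labels[[ep]] == 1L
          m[informative[[ep]], pos] <- m[informative[[ep]], pos] + shift
        }
      }
      suffix <- if (tissue == "normal") "N" else "T"
      colnames(m) <- paste0(patients, "_", suffix)
      rownames(m) <- genes
      es <- ExprSet(m, tissue = tissue, patientId = patients,
                    labels = labels)
      S4Vectors::metadata(es)$informative <-
        lapply(informative, function(ix) genes[ix])
      es
    }

    normal <- makeCompartment("normal")
    tumour <- makeCompartment("tumour")
    list(normal = normal, tumour = tumour)
  })
}
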