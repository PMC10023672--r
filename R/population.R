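# Population-composition simulation (food-specific LepR neurons among GABA
# neurons) and single-cell RNA-seq QC / neurotransmitter-labelling rules.

#' Deterministic Venn composition simulation
#'
#' Computes the expected composition of a GABAergic population: the number
#' of LepR neurons, of food-specific GABA neurons, of food-specific LepR
#' neurons, and the fraction of food-specific GABA neurons that are LepR.
#' Fractional counts are rounded half-to-even per count. At the default
#' parameters (1000 GABA, 10% LepR, 8% food-specific, 63% of LepR
#' food-specific) the result is 100/80/63 and 63/80 = 78.75%.
#'
#' @param params A [VennParams-class].
#' @return List `n_lepr`, `n_food_gaba`, `n_food_lepr`,
#'   `fraction_food_from_lepr`.
#' @export
vennSimulation <- function(params = vennParams()) {
  nLepr <- round(params@nGaba * params@pLepr)
  nFoodGaba <- round(params@nGaba * params@pFoodGaba)
  nFoodLepr <- round(nLepr * params@pFoodLepr)
  if (nFoodLepr > nFoodGaba)
    pcStop("parameterError",
           sprintf("inconsistent parameters: food-specific LepR count (%d) exceeds food-specific GABA count (%d)",
                   nFoodLepr, nFoodGaba))
  list(n_lepr = nLepr, n_food_gaba = nFoodGaba, n_food_lepr = nFoodLepr,
       fraction_food_from_lepr = nFoodLepr / nFoodGaba)
}

#' Stochastic Venn composition simulation
#'
#' Samples individual neuron memberships: each GABA neuron is LepR with
#' probability `pLepr`; LepR neurons are food-specific with probability
#' `pFoodLepr`; non-LepR neurons are food-specific with the complement rate
#' `(pFoodGaba - pLepr * pFoodLepr) / (1 - pLepr)` so that the overall
#' food-specific rate is `pFoodGaba` and every food-specific LepR neuron is
#' counted in the food-specific GABA total (the Venn subset structure).
#' Reports the sampling distribution of the LepR fraction among
#' food-specific neurons.
#'
#' @param params A [VennParams-class].
#' @param reps Number of replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param ciLevel Central percentile interval level (default 0.99).
#' @return List `fractions` (per replicate; `NA` when no food-specific
#'   neurons were drawn), `mean`, `ci` (percentile interval), `n_dropped`.
#' @export
vennSimulationStochastic <- function(params = vennParams(), reps = 10000,
                                     seed = 1L, ciLevel = 0.99) {
  if (reps < 1) pcStop("parameterError", "reps must be >= 1")
  pNon <- (params@pFoodGaba - params@pLepr * params@pFoodLepr) /
    (1 - params@pLepr)
  if (pNon < 0 || pNon > 1)
    pcStop("parameterError",
           "implied food-specific rate among non-LepR neurons outside [0, 1]")
  set.seed(seed)
  n <- params@nGaba
  nLepr <- stats::rbinom(reps, n, params@pLepr)
  nFoodLepr <- stats::rbinom(reps, nLepr, params@pFoodLepr)
  nFoodNon <- stats::rbinom(reps, n - nLepr, pNon)
  denom <- nFoodLepr + nFoodNon
  frac <- ifelse(denom > 0, nFoodLepr / denom, NA_real_)
  ok <- frac[!is.na(frac)]
  alpha <- (1 - ciLevel) / 2
  list(fractions = frac, mean = mean(ok),
       ci = stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE),
       n_dropped = sum(is.na(frac)))
}

#' Single-cell RNA-seq quality-control filter
#'
#' Discards cells with fewer than `minUmi` unique molecular identifiers or
#' more than `maxMito` mitochondrial read fraction (strict inequalities as
#' printed: exactly 500 UMIs or exactly 40% mitochondrial reads are kept).
#'
#' @param umi Per-cell total UMI counts.
#' @param mito Per-cell mitochondrial read fraction in \[0, 1\].
#' @param minUmi UMI threshold (default 500).
#' @param maxMito Mitochondrial-fraction threshold (default 0.40).
#' @return List `kept`, `discarded` (index vectors), `n_kept`,
#'   `n_discarded`.
#' @export
qcFilter <- function(umi, mito, minUmi = 500, maxMito = 0.40) {
  if (length(umi) != length(mito))
    pcStop("inputError", "umi and mito vectors must be aligned")
  if (any(mito < 0 | mito > 1))
    pcStop("inputError", "mito fractions must be in [0, 1]")
  discard <- umi < minUmi | mito > maxMito
  list(kept = which(!discard), discarded = which(discard),
       n_kept = sum(!discard), n_discarded = sum(discard))
}

#' Mitochondrial read fraction from a count matrix
#'
#' @param counts Gene x cell count matrix.
#' @param mitoPrefix Gene-name prefix identifying mitochondrial genes
#'   (default `"mt-"`).
#' @return List `umi` (per-cell totals), `mito` (per-cell mitochondrial
#'   fraction).
#' @export
countMatrixQcStats <- function(counts, mitoPrefix = "mt-") {
  umi <- colSums(counts)
  mitoGenes <- startsWith(rownames(counts), mitoPrefix)
  mito <- ifelse(umi > 0, colSums(counts[mitoGenes, , drop = FALSE]) / umi, 0)
  list(umi = umi, mito = mito)
}

#' Label clusters GABAergic or glutamatergic
#'
#' Within each cluster, the median expression of Slc32a1 (vesicular GABA
#' transporter) and Slc17a6 (vesicular glutamate transporter 2) are
#' compared: strictly greater Slc32a1 is `GABAergic`, strictly greater
#' Slc17a6 is `glutamatergic`, equality is `unclassified`.
#'
#' @param slc32a1,slc17a6 Per-cell expression of the two genes.
#' @param clusters Per-cell cluster labels.
#' @return data.frame `cluster`, `median_slc32a1`, `median_slc17a6`,
#'   `class`.
#' @export
classifyClusterNeurotransmitter <- function(slc32a1, slc17a6, clusters) {
  if (length(slc32a1) != length(clusters) ||
      length(slc17a6) != length(clusters))
    pcStop("inputError", "expression and cluster vectors must be aligned")
  ids <- unique(clusters)
  out <- data.frame(cluster = ids, median_slc32a1 = NA_real_,
                    median_slc17a6 = NA_real_, class = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    sel <- clusters == ids[k]
    if (!any(sel)) pcStop("inputError", paste("empty cluster:", ids[k]))
    m32 <- stats::median(slc32a1[sel])
    m17 <- stats::median(slc17a6[sel])
    out$median_slc32a1[k] <- m32
    out$median_slc17a6[k] <- m17
    out$class[k] <- if (m32 > m17) "GABAergic"
                    else if (m17 > m32) "glutamatergic"
                    else "unclassified"
  }
  out
}
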