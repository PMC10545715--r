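#' Abbott's correction for control mortality
#'
#' `corrected = (treated - control) / (1 - control)`.  When treated
#' mortality is below the control level the corrected value is clamped to
#' zero with a warning.
#'
#' @param treated_prop observed mortality proportion in the treatment,
#'   in `[0, 1]`.
#' @param control_prop observed control mortality, in `[0, 1)`.
#' @return Corrected mortality proportion(s) in `[0, 1]`.
#' @export
abbott_correct <- function(treated_prop, control_prop) {
  if (any(control_prop >= 1))
    stop("control mortality of 1 leaves no population to correct against")
  if (any(treated_prop < 0 | treated_prop > 1 | control_prop < 0))
    stop("proportions must lie in [0, 1]")
  out <- (treated_prop - control_prop) / (1 - control_prop)
  if (any(out < 0)) {
    warning("treated mortality below control; clamping to 0")
    out <- pmax(out, 0)
  }
  out
}

#' Normalized relative quantity (NRQ) for qPCR
#'
#' Efficiency-corrected relative quantities are computed against a
#' calibrator sample, `RQ_{g,s} = E_g^(Cq_{g,cal} - Cq_{g,s})`, and each
#' target gene's RQ is divided by the geometric mean of the reference
#' genes' RQs in the same sample.
#'
#' @param measurements long-format data frame with columns `sample`,
#'   `gene`, `role` ("target" or "reference"), `cq` and optionally
#'   `efficiency` (amplification factor per cycle; default 2).
#' @param calibrator_sample calibrator sample id (default: first sample).
#' @return Data frame `sample`, `gene`, `nrq` for every target gene; the
#'   calibrator's NRQ is exactly 1 for every gene.
#' @export
nrq <- function(measurements, calibrator_sample = NULL) {
  m <- measurements
  need <- c("sample", "gene", "role", "cq")
  if (!all(need %in% names(m)))
    stop("measurements need columns: ", paste(need, collapse = ", "))
  if (is.null(m$efficiency)) m$efficiency <- 2
  if (any(m$efficiency <= 1 | m$efficiency > 2.2))
    stop("efficiencies must lie in (1, 2.2]")
  if (any(m$cq <= 0)) stop("Cq values must be positive")
  samples <- unique(m$sample)
  if (is.null(calibrator_sample)) calibrator_sample <- samples[1]
  if (!calibrator_sample %in% samples) stop("calibrator sample not measured")
  refs <- unique(m$gene[m$role == "reference"])
  if (!length(refs)) stop("at least one reference gene is required")
  for (s in samples) for (g in refs)
    if (!any(m$sample == s & m$gene == g))
      stop(sprintf("missing reference measurement: sample '%s', gene '%s'",
                   s, g))
  cq_of <- function(s, g) {
    v <- m$cq[m$sample == s & m$gene == g]
    if (!length(v)) NA_real_ else mean(v)
  }
  eff_of <- function(g) m$efficiency[m$gene == g][1]
  rq <- function(s, g) eff_of(g)^(cq_of(calibrator_sample, g) - cq_of(s, g))
  targets <- unique(m$gene[m$role == "target"])
  out <- expand.grid(sample = samples, gene = targets,
                     stringsAsFactors = FALSE)
  out$nrq <- mapply(function(s, g) {
    rq_refs <- vapply(refs, function(r) rq(s, r), 0)
    rq(s, g) / exp(mean(log(rq_refs)))
  }, out$sample, out$gene)
  if (any(is.na(out$nrq)))
    stop("missing target measurement for some sample")
  rownames(out) <- NULL
  out
}
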