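#' Finite-sample-corrected Akaike Information Criterion
#'
#' Gaussian-residual form: AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n - k - 1).
#' Values are comparable only between models fit to the same scan set.
#' A zero RSS (perfect fit) returns -Inf with a warning.
#'
#' @param rss residual sum of squares (>= 0)
#' @param n number of observations
#' @param k number of free model parameters
#' @return AICc (scalar; -Inf when rss is 0)
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1)
    stopDoee(sprintf("AICc undefined: n (%d) must exceed k + 1 (%d)",
                     n, k + 1), "doeeDomainError")
  if (rss < 0) stopDoee("rss must be >= 0", "doeeDomainError")
  if (rss == 0) {
    warning("rss = 0: AICc is -Inf (perfect fit)", call. = FALSE)
    return(-Inf)
  }
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Relative likelihood of competing models from AICc
#'
#' exp((min AICc - AICc_i) / 2) for each model; the best model gets 1.
#' Interpretable as the likelihood that model i is better than the
#' AICc-best model.
#'
#' @param aiccValues named numeric vector of AICc values (>= 2 finite)
#' @return numeric vector of relative likelihoods, same names
#' @export
relativeLikelihood <- function(aiccValues) {
  if (sum(!is.na(aiccValues)) < 2L)
    stop("need at least two AICc values", call. = FALSE)
  best <- min(aiccValues)
  out <- exp((best - aiccValues) / 2)
  out[aiccValues == -Inf] <- ifelse(best == -Inf, 1, 0)
  out
}

# Fit the four competing models of SI as a function of MTA.
# doeeBy = "means": DOEE predictions come from arithmetic meanDE/meanOER
# (requires de, oer vectors). doeeBy = "ls": least-squares fit in the
# 1/MTA basis (for bare (MTA, SI) tables).
fitFourModels <- function(mta, si, de = NULL, oer = NULL,
                          doeeBy = c("means", "ls")) {
  doeeBy <- match.arg(doeeBy)
  n <- length(mta)
  stopifnot(length(si) == n)
  fits <- list()
  mMean <- stats::lm(si ~ 1)
  mLin  <- stats::lm(si ~ mta)
  mQuad <- stats::lm(si ~ mta + I(mta^2))
  if (doeeBy == "means") {
    meanDE <- mean(de)
    meanOER <- mean(oer)
    pred <- siEstimate(meanDE, meanOER, mta)
  } else {
    inv <- 1 / mta
    mInv <- stats::lm(si ~ inv)
    b <- stats::coef(mInv)
    meanOER <- 2 * (1 - b[[1]])
    meanDE <- -2 * b[[2]]
    pred <- siEstimate(meanDE, meanOER, mta)
  }
  rssOf <- function(m) sum(stats::resid(m)^2)
  rss <- c(mean = rssOf(mMean), linear = rssOf(mLin),
           quadratic = rssOf(mQuad), doee = sum((si - pred)^2))
  k <- c(mean = 1L, linear = 2L, quadratic = 3L, doee = 2L)
  aiccV <- vapply(names(rss), function(m) {
    withCallingHandlers(aicc(rss[[m]], n, k[[m]]),
                        warning = function(w) invokeRestart("muffleWarning"))
  }, 0)
  if (any(rss == 0))
    warning("one or more models fit perfectly (rss = 0); AICc is -Inf",
            call. = FALSE)
  params <- list(
    mean = stats::coef(mMean),
    linear = stats::coef(mLin),
    quadratic = stats::coef(mQuad),
    doee = c(meanDE = meanDE, meanOER = meanOER))
  list(models = data.frame(model = names(rss), k = unname(k),
                           rss = unname(rss), aicc = unname(aiccV),
                           rel_likelihood = unname(relativeLikelihood(aiccV)),
                           stringsAsFactors = FALSE),
       params = params, meanDE = meanDE, meanOER = meanOER,
       doeeFitMethod = if (doeeBy == "means") "means" else "least-squares")
}

#' Correlations between agreement measures and lesion burden
#'
#' Spearman rank correlation (with p-value) of MTA against each of DE, OE,
#' OER and SI, plus Pearson correlation of the observed SI against the
#' SI predicted from meanDE/meanOER, and of the residual (SI - prediction)
#' against MTA. Rank correlation is used for the burden battery because
#' the SI-versus-MTA relationship is explicitly non-linear. Spearman
#' p-values use the exact permutation distribution below n = 10 and the
#' t approximation from n = 10 on; ties get average ranks. A constant
#' column yields an NA coefficient with a warning.
#'
#' @param perScan data.frame with columns MTA, DE, OE, OER, SI
#' @return data.frame with columns pair, method, estimate, p_value
#' @export
correlationBattery <- function(perScan) {
  need <- c("MTA", "DE", "OE", "OER", "SI")
  stopifnot(all(need %in% names(perScan)))
  n <- nrow(perScan)
  if (n < 4L) stop("need at least 4 scans", call. = FALSE)
  one <- function(x, y, pair, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("constant column in pair '%s': coefficient undefined",
                      pair), call. = FALSE)
      return(data.frame(pair = pair, method = method, estimate = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(
      x, y, method = method, exact = if (method == "spearman") n < 10 else NULL))
    data.frame(pair = pair, method = method,
               estimate = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  }
  res <- rbind(
    one(perScan$MTA, perScan$DE, "MTA vs DE", "spearman"),
    one(perScan$MTA, perScan$OE, "MTA vs OE", "spearman"),
    one(perScan$MTA, perScan$OER, "MTA vs OER", "spearman"),
    one(perScan$MTA, perScan$SI, "MTA vs SI", "spearman"))
  meanDE <- mean(perScan$DE)
  meanOER <- mean(perScan$OER)
  pred <- siEstimate(meanDE, meanOER, perScan$MTA)
  res <- rbind(res,
    one(perScan$SI, pred, "SI vs SI_estimate", "pearson"),
    one(perScan$SI - pred, perScan$MTA, "residual vs MTA", "pearson"))
  rownames(res) <- NULL
  res
}

#' Fit and compare models of SI versus lesion burden
#'
#' Fits four competing models of the Similarity Index as a function of
#' MTA over the scans of a study: a constant (mean SI, k = 1), a linear
#' fit (k = 2), a quadratic fit (k = 3), and the detection/outline
#' decomposition SI = 1 - meanOER/2 - meanDE/(2 MTA) (k = 2). Models are
#' ranked by finite-sample-corrected AICc on a common residual sum of
#' squares; relative likelihoods are reported against the best model.
#'
#' When the input carries per-scan DE and OER (a list of
#' \linkS4class{ScanAgreement} or a full study table), meanDE and meanOER
#' are arithmetic means of the per-scan values — not least-squares
#' optimized — which makes the reported decomposition RSS conservative
#' relative to an optimized two-parameter fit. When the input is a bare
#' (MTA, SI) table, the decomposition is instead fit by least squares in
#' the 1/MTA basis (it is linear there) and meanDE/meanOER are read off
#' the coefficients.
#'
#' @param perScan list of \linkS4class{ScanAgreement}, or a data.frame
#'   with columns MTA and SI (optionally DE, OE, OER)
#' @return a \linkS4class{StudyFit}
#' @export
fitStudy <- function(perScan) {
  if (is.list(perScan) && !is.data.frame(perScan))
    perScan <- studyTable(perScan)
  stopifnot(all(c("MTA", "SI") %in% names(perScan)))
  n <- nrow(perScan)
  if (n < 5L)
    stopDoee(sprintf(
      "insufficient data: %d scan(s); need at least 5 (max parameters + 2)",
      n), "doeeInsufficientDataError")
  if (any(perScan$MTA <= 0))
    stopDoee("all scans must have MTA > 0", "doeeDomainError")
  haveErrors <- all(c("DE", "OER") %in% names(perScan))
  ft <- fitFourModels(perScan$MTA, perScan$SI,
                      de = if (haveErrors) perScan$DE,
                      oer = if (haveErrors) perScan$OER,
                      doeeBy = if (haveErrors) "means" else "ls")
  correlations <- if (haveErrors && "OE" %in% names(perScan) && n >= 4L)
    correlationBattery(perScan)
  else
    data.frame(pair = character(), method = character(),
               estimate = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  new("StudyFit", perScan = perScan, meanDE = ft$meanDE,
      meanOER = ft$meanOER, models = ft$models, params = ft$params,
      correlations = correlations, doeeFitMethod = ft$doeeFitMethod)
}

#' @export
setMethod("show", "StudyFit", function(object) {
  cat(sprintf("StudyFit: %d scans\n", nrow(object@perScan)))
  cat(sprintf("  meanDE = %.1f mm^2, meanOER = %.3f (%s)\n",
              object@meanDE, object@meanOER, object@doeeFitMethod))
  m <- object@models
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-9s k=%d  RSS=%.4g  AICc=%.2f  relLik=%.3g\n",
                m$model[i], m$k[i], m$rss[i], m$aicc[i],
                m$rel_likelihood[i]))
  if (nrow(object@correlations)) {
    cat("  correlations:\n")
    co <- object@correlations
    for (i in seq_len(nrow(co)))
      cat(sprintf("    %-18s %s = %.3f (p = %.3g)\n", co$pair[i],
                  if (co$method[i] == "spearman") "rho" else "r",
                  co$estimate[i], co$p_value[i]))
  }
  invisible(object)
})

#' Write a study report as JSON
#'
#' Serializes the per-scan table, meanDE/meanOER, the model comparison
#' table (with parameters) and the correlation battery.
#'
#' @param fit a \linkS4class{StudyFit}
#' @param path output path
#' @export
writeStudyReport <- function(fit, path) {
  stopifnot(is(fit, "StudyFit"))
  models <- fit@models
  models$params <- I(unname(lapply(models$model, function(m)
    as.list(fit@params[[m]]))))
  obj <- list(n_scans = nrow(fit@perScan),
              mean_de = fit@meanDE, mean_oer = fit@meanOER,
              doee_fit_method = fit@doeeFitMethod,
              per_scan = fit@perScan, models = models,
              correlations = fit@correlations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
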