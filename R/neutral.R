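.binomEnvelope <- function(p, n, level = 0.95) {
  # acceptance region for an observed frequency given a true frequency p:
  # exact binomial quantiles at the number of samples. (A Wilson interval
  # inverts the roles and over-flags taxa near f_pred ~ 1, where observing
  # n/n detections is the modal outcome.)
  a <- (1 - level) / 2
  cbind(lo = stats::qbinom(a, n, p) / n,
        hi = stats::qbinom(1 - a, n, p) / n)
}

#' Fit the Sloan neutral community model
#'
#' Fits occurrence frequency as a function of metacommunity abundance. For
#' each taxon, `p_i` is its mean relative abundance across samples and
#' `f_obs_i` the fraction of samples where it is detected. The neutral
#' expectation at detection limit `d = 1/N` is
#' `f_pred_i(m) = 1 - I_d(N m p_i, N m (1 - p_i))` (regularized incomplete
#' beta); the single immigration parameter `m` is chosen by nonlinear least
#' squares on the untransformed frequencies, bracketed in (1e-6, 1].
#' `R^2 = 1 - SSR/SST` about the mean observed frequency (reported as-is,
#' possibly negative). The 95% envelope is the binomial sampling
#' distribution of the observed frequency around `f_pred` at the number of
#' samples (exact quantiles); taxa are partitioned as `above`, `neutral`
#' or `below` the envelope.
#'
#' The beta-approximation scale of `m` used by the canonical fit differs
#' from the per-event immigration probability of the discrete urn model:
#' the urn's stationary beta parameter is `theta = m_urn (N-1) / (1 - m_urn)`
#' while the fit uses `theta = N m`. Both scales are reported; `mMoran`
#' (`= N m / (N - 1 + N m)`) is the fitted immigration expressed as the
#' urn's per-event probability and is the quantity to compare with the
#' simulators' `m`.
#'
#' @param x a `CommunityExperiment` with >= 5 samples at a common depth
#'   (the model assumes a fixed community size; unequal depths are
#'   refused).
#' @param detectionLimit relative-abundance detection limit (default
#'   `1/N`, one read).
#' @param globalPool optional named vector of metacommunity relative
#'   abundances to use instead of the table's own mean relative abundances
#'   (e.g. a whole-study pool when fitting one fire class).
#' @return a [NeutralFit-class] object.
#' @export
fitNeutral <- function(x, detectionLimit = NULL, globalPool = NULL) {
  m0 <- counts(x)
  nS <- ncol(m0)
  if (nS < 5) stop("need at least 5 samples to fit the neutral model")
  depths <- colSums(m0)
  if (length(unique(depths)) != 1L)
    stop("samples have unequal depths; rarefy to a common depth first ",
         "(the model assumes a fixed community size N)")
  N <- as.integer(depths[1])
  d <- if (is.null(detectionLimit)) 1 / N else detectionLimit

  p <- if (is.null(globalPool)) {
    rowMeans(sweep(m0, 2, depths, "/"))
  } else {
    if (is.null(names(globalPool)) ||
        !all(rownames(m0) %in% names(globalPool)))
      stop("globalPool must be named and cover all taxa")
    globalPool[rownames(m0)]
  }
  fObs <- rowMeans(m0 > 0)

  predict_f <- function(mm) 1 - pbeta(d, N * mm * p, N * mm * (1 - p))
  ssr <- function(mm) sum((fObs - predict_f(mm))^2)
  opt <- optimize(ssr, interval = c(1e-6, 1), tol = 1e-9)
  mHat <- opt$minimum
  boundary <- mHat < 1e-5 || mHat > 1 - 1e-5
  if (ssr(1) < opt$objective) { mHat <- 1; boundary <- TRUE }

  fPred <- predict_f(mHat)
  sst <- sum((fObs - mean(fObs))^2)
  r2 <- if (sst < 1e-12) {
    warning("all taxa have (nearly) identical occurrence frequency; ",
            "R^2 undefined")
    NA_real_
  } else 1 - ssr(mHat) / sst

  env <- .binomEnvelope(fPred, nS)
  partition <- ifelse(fObs > env[, "hi"], "above",
               ifelse(fObs < env[, "lo"], "below", "neutral"))
  taxa <- data.frame(taxon_id = rownames(m0), p = as.numeric(p),
                     fObs = as.numeric(fObs), fPred = as.numeric(fPred),
                     envelopeLo = as.numeric(env[, "lo"]),
                     envelopeHi = as.numeric(env[, "hi"]),
                     partition = partition, row.names = NULL)
  methods::new("NeutralFit", m = mHat,
               mMoran = N * mHat / (N - 1 + N * mHat),
               N = N, nSamples = as.integer(nS), rSquared = r2,
               detectionLimit = d, boundary = boundary, taxa = taxa)
}

#' Taxa outside the neutral envelope
#'
#' Splits the per-taxon records of a fit into taxa observed in fewer
#' samples than their metacommunity abundance predicts (`below` — under a
#' press disturbance, candidates for locally successful taxa) and taxa
#' observed in more samples than predicted (`above`).
#'
#' @param fit a [NeutralFit-class] object.
#' @return list with `below` and `above` `data.frame`s (columns `taxon_id`,
#'   `p`, `fObs`, `fPred`).
#' @export
neutralOutliers <- function(fit) {
  stopifnot(methods::is(fit, "NeutralFit"))
  tx <- fit@taxa
  cols <- c("taxon_id", "p", "fObs", "fPred")
  list(below = tx[tx$partition == "below", cols, drop = FALSE],
       above = tx[tx$partition == "above", cols, drop = FALSE])
}
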