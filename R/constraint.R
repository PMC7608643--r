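## Gene-constraint selection metrics: observed/expected ratios with exact
## Poisson-rate confidence intervals, signed depletion Z-scores, and pLI --
## the posterior probability of the haploinsufficient class in a
## three-class Poisson mixture over observed LOF counts -- fitted by EM.

#' Observed/expected ratio with an exact Poisson 90\% interval
#'
#' The interval is the exact gamma-quantile (Garwood-type) 90\% confidence
#' interval on the Poisson rate of the observed count, divided by the
#' expected count: lower bound \code{qgamma(0.05, obs)/exp} (0 when obs =
#' 0), upper bound \code{qgamma(0.95, obs + 1)/exp}.
#'
#' @param obs non-negative observed count(s).
#' @param exp positive expected count(s).
#' @return data.frame with columns \code{oe}, \code{oe_low}, \code{oe_high}.
#' @export
oeRatio <- function(obs, exp) {
  if (any(exp <= 0)) stop("expected count must be positive")
  if (any(obs < 0)) stop("observed count must be non-negative")
  data.frame(oe = obs / exp,
             oe_low = ifelse(obs == 0, 0, stats::qgamma(0.05, obs) / exp),
             oe_high = stats::qgamma(0.95, obs + 1) / exp)
}

#' Signed depletion Z-score
#'
#' \code{z = (exp - obs) / sqrt(exp) / divisor}: positive for depletion
#' (fewer variants observed than expected, the signature of selection
#' against the class), negative for excess. The default divisor 1 gives the
#' raw Z; per-class empirical scaling constants, where a constraint
#' framework defines them, can be supplied as \code{divisor}.
#'
#' @inheritParams oeRatio
#' @param divisor positive scaling constant.
#' @return numeric vector of Z-scores.
#' @export
zScore <- function(obs, exp, divisor = 1) {
  if (any(exp <= 0)) stop("expected count must be positive")
  if (any(divisor <= 0)) stop("divisor must be positive")
  (exp - obs) / sqrt(exp) / divisor
}

logSumExp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Fit the three-class Poisson mixture behind pLI
#'
#' Each gene's observed LOF count is modelled as Poisson with mean
#' \code{factor_k * expected}, where the factors (default 1 / 0.463 /
#' 0.089) encode the LOF depletion of the null, recessive and
#' haploinsufficient classes. With \code{estimatePriors = TRUE} the mixture
#' weights are fitted by EM: the E-step computes posterior responsibilities
#' (in log space with log-sum-exp), the M-step sets the weights to the mean
#' responsibilities, iterating until the log-likelihood increment falls
#' below \code{tol}. The log-likelihood is non-decreasing at every
#' iteration. With fixed priors the posteriors are a single Bayes update.
#'
#' @param obs non-negative observed LOF counts, one per gene.
#' @param exp positive expected LOF counts, one per gene.
#' @param config an \linkS4class{EMConfig}.
#' @return list: \code{posteriors} (matrix n x 3, columns \code{pNull},
#'   \code{pRec}, \code{pLI}), \code{priors} (fitted or fixed weights),
#'   \code{loglik} (trace, one value per iteration), \code{converged},
#'   \code{iterations}.
#' @export
pliEM <- function(obs, exp, config = emConfig()) {
  stopifnot(length(obs) == length(exp))
  if (any(exp <= 0)) stop("expected counts must be positive")
  n <- length(obs)
  f <- config@factors
  ## n x 3 log-likelihood of each gene under each class
  ll <- vapply(seq_len(3),
               function(k) stats::dpois(obs, f[k] * exp, log = TRUE),
               numeric(n))
  ll <- matrix(ll, nrow = n)
  pri <- config@priors
  posterior <- function(pri) {
    lp <- sweep(ll, 2, log(pri), "+")
    lse <- logSumExp(lp)
    list(post = exp(lp - lse), loglik = sum(lse))
  }
  if (!config@estimatePriors || n < 2) {
    st <- posterior(pri)
    post <- st$post
    colnames(post) <- c("pNull", "pRec", "pLI")
    return(list(posteriors = post, priors = pri, loglik = st$loglik,
                converged = TRUE, iterations = 0L))
  }
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config@maxIter)) {
    st <- posterior(pri)
    trace <- c(trace, st$loglik)
    if (it > 1) {
      inc <- trace[it] - trace[it - 1]
      if (inc < -1e-9 * (abs(trace[it - 1]) + 1))
        stop("EM log-likelihood decreased; numerical failure")
      if (abs(inc) < config@tol) { converged <- TRUE; break }
    }
    pri <- colMeans(st$post)
  }
  post <- st$post
  colnames(post) <- c("pNull", "pRec", "pLI")
  if (!converged)
    warning("EM did not converge in ", config@maxIter,
            " iterations; best iterate returned")
  list(posteriors = post, priors = pri, loglik = trace,
       converged = converged, iterations = length(trace))
}

#' Constraint labels from thresholds
#'
#' A gene is LOF tolerant at pLI <= 0.1 and LOF intolerant at pLI >= 0.9;
#' synonymous and missense Z-scores are significant beyond |Z| > 3.71 and
#' |Z| > 3.09 respectively (positive = depletion, negative = excess); a
#' 90\% o/e confidence interval with upper bound < 0.35 marks strong
#' mutation intolerance.
#'
#' @param pli pLI value.
#' @param zSyn,zMis raw Z-scores (or NA to skip).
#' @param oeLofHigh upper bound of the LOF o/e 90\% CI (or NA to skip).
#' @param zSynThreshold,zMisThreshold two-sided Z thresholds.
#' @return named logical/character list of labels: \code{lof_tolerant},
#'   \code{lof_intolerant}, \code{syn_significant}, \code{syn_direction},
#'   \code{mis_significant}, \code{mis_direction},
#'   \code{strong_intolerance}.
#' @export
constraintLabels <- function(pli, zSyn = NA, zMis = NA, oeLofHigh = NA,
                             zSynThreshold = 3.71, zMisThreshold = 3.09) {
  dir <- function(z) if (is.na(z)) NA_character_ else
    if (z > 0) "depletion" else if (z < 0) "excess" else "none"
  list(lof_tolerant = pli <= 0.1,
       lof_intolerant = pli >= 0.9,
       syn_significant = if (is.na(zSyn)) NA else abs(zSyn) > zSynThreshold,
       syn_direction = dir(zSyn),
       mis_significant = if (is.na(zMis)) NA else abs(zMis) > zMisThreshold,
       mis_direction = dir(zMis),
       strong_intolerance = if (is.na(oeLofHigh)) NA else oeLofHigh < 0.35)
}

#' Full constraint results for a gene table
#'
#' Computes, per gene and per mutation class (synonymous, missense, LOF),
#' the o/e ratio with its exact 90\% interval and the raw Z-score, then the
#' pLI / pRec / pNull posteriors from the LOF counts (single Bayes update
#' under the config's priors for one gene, EM-fitted priors for several),
#' and the threshold labels.
#'
#' @param genes data.frame with columns \code{gene}, \code{obs_syn},
#'   \code{exp_syn}, \code{obs_mis}, \code{exp_mis}, \code{obs_lof},
#'   \code{exp_lof}.
#' @param config an \linkS4class{EMConfig}.
#' @param zDivisors named numeric, per-class Z divisors
#'   (default all 1 = raw Z).
#' @return data.frame, one row per gene, with \code{oe_*}, \code{z_*},
#'   \code{pNull}, \code{pRec}, \code{pLI} and label columns; the EM fit is
#'   attached as attribute \code{"fit"}.
#' @export
geneConstraint <- function(genes, config = emConfig(),
                           zDivisors = c(syn = 1, mis = 1, lof = 1)) {
  need <- c("gene", "obs_syn", "exp_syn", "obs_mis", "exp_mis",
            "obs_lof", "exp_lof")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(gene = genes$gene, stringsAsFactors = FALSE)
  for (cl in c("syn", "mis", "lof")) {
    oe <- oeRatio(genes[[paste0("obs_", cl)]], genes[[paste0("exp_", cl)]])
    out[[paste0("oe_", cl)]] <- oe$oe
    out[[paste0("oe_", cl, "_low")]] <- oe$oe_low
    out[[paste0("oe_", cl, "_high")]] <- oe$oe_high
    out[[paste0("z_", cl)]] <- zScore(genes[[paste0("obs_", cl)]],
                                      genes[[paste0("exp_", cl)]],
                                      zDivisors[[cl]])
  }
  fit <- pliEM(genes$obs_lof, genes$exp_lof, config)
  out$pNull <- fit$posteriors[, "pNull"]
  out$pRec <- fit$posteriors[, "pRec"]
  out$pLI <- fit$posteriors[, "pLI"]
  lab <- lapply(seq_len(nrow(out)), function(i)
    constraintLabels(out$pLI[i], out$z_syn[i], out$z_mis[i],
                     out$oe_lof_high[i]))
  out$lof_tolerant <- vapply(lab, `[[`, TRUE, "lof_tolerant")
  out$lof_intolerant <- vapply(lab, `[[`, TRUE, "lof_intolerant")
  out$syn_significant <- vapply(lab, `[[`, TRUE, "syn_significant")
  out$mis_significant <- vapply(lab, `[[`, TRUE, "mis_significant")
  out$strong_intolerance <- vapply(lab, `[[`, TRUE, "strong_intolerance")
  attr(out, "fit") <- fit
  out
}
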