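#' Operational-model-of-allosterism parameter set
#'
#' Parameters of the operational model of allosterism for a ternary
#' agonist (A) / modulator (B) / receptor system:
#' \deqn{E = \frac{E_m\,(\tau_A [A](K_B+\alpha\beta[B]) + \tau_B [B] K_A)^n}
#' {([A]K_B + K_A K_B + K_A[B] + \alpha[A][B])^n +
#'  (\tau_A [A](K_B+\alpha\beta[B]) + \tau_B [B] K_A)^n}}
#' with operational efficacies \eqn{\tau_A, \tau_B}, dissociation
#' constants \eqn{K_A, K_B} (molar), affinity cooperativity \eqn{\alpha},
#' efficacy cooperativity \eqn{\beta} and transducer slope n. The
#' composite cooperativity is reported as
#' \eqn{\log_{10}(\alpha\beta)}; functional data identify only the
#' product, so the parameterisation carries `logab` and `logalpha`
#' (with \eqn{\beta = \alpha\beta/\alpha} implied).
#'
#' @param Em maximal system response (response units).
#' @param n transducer slope.
#' @param tauA,tauB operational efficacies (> 0; `tauB = 0` allowed for a
#'   modulator without direct agonism).
#' @param pKA,pKB -log10 molar dissociation constants.
#' @param logab composite cooperativity log10(alpha*beta).
#' @param logalpha log10 affinity cooperativity (0 unless binding data
#'   justify splitting the product).
#' @return list of class `operational_pars`.
#' @export
operational_pars <- function(Em = 100, n = 1, tauA = 3, tauB = 0.2,
                             pKA = 7.25, pKB = 7, logab = 1.3,
                             logalpha = 0) {
  stopifnot(Em > 0, n > 0, tauA > 0, tauB >= 0, is.finite(logab),
            is.finite(logalpha))
  structure(list(Em = Em, n = n, tauA = tauA, tauB = tauB, pKA = pKA,
                 pKB = pKB, logab = logab, logalpha = logalpha),
            class = "operational_pars")
}

#' Operational-model response surface
#'
#' Evaluates the model of [operational_pars()] at agonist/modulator
#' concentration pairs. At `B = 0` it reduces exactly to the operational
#' model of agonism, `E = Em (tauA A)^n / ((A + KA)^n + (tauA A)^n)`.
#'
#' @param A agonist concentrations (molar, > 0).
#' @param B modulator concentrations (molar, >= 0), recycled against `A`.
#' @param pars an `operational_pars` list.
#' @return numeric vector of responses.
#' @export
operational_response <- function(A, B, pars) {
  stopifnot(inherits(pars, "operational_pars"))
  KA <- 10^(-pars$pKA); KB <- 10^(-pars$pKB)
  alpha <- 10^pars$logalpha
  ab <- 10^pars$logab
  num <- pars$tauA * A * (KB + ab * B) + pars$tauB * B * KA
  den <- A * KB + KA * KB + KA * B + alpha * A * B
  pars$Em * num^pars$n / (den^pars$n + num^pars$n)
}

#' Unit-slope 3-parameter logistic response
#'
#' `E = bottom + (top - bottom) / (1 + EC50 / A)` with
#' `EC50 = 10^-pec50`.
#'
#' @param A agonist concentrations (molar).
#' @param pec50 potency (-log10 molar).
#' @param top,bottom asymptotes.
#' @return numeric vector of responses.
#' @export
logistic3_response <- function(A, pec50, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + 10^(-pec50) / A)
}

#' Composite cooperativity Log(alpha*beta)
#'
#' For numeric cooperativities, the arithmetic `log10(alpha * beta)`.
#' For a fitted [fit_operational_allosterism()] object, the estimate with
#' its standard error from the fit covariance (the model is
#' parameterised in `logab` directly, so no delta-method step is needed;
#' when alpha and beta are supplied separately the delta method gives
#' `se(logab)^2 = se(logalpha)^2 + se(logbeta)^2 + 2 cov`).
#'
#' @param alpha affinity cooperativity (> 0), or an
#'   `allodyn_allostery_fit`.
#' @param beta efficacy cooperativity (> 0) when `alpha` is numeric.
#' @return numeric scalar, or a list with `estimate` and `se` for a fit.
#' @export
logab <- function(alpha, beta = NULL) {
  if (inherits(alpha, "allodyn_allostery_fit")) {
    return(list(estimate = alpha$summary$logab,
                se = alpha$summary$logab_se))
  }
  if (any(alpha <= 0) || any(beta <= 0))
    stop("cooperativities alpha and beta must be positive")
  log10(alpha * beta)
}
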