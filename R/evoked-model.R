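## Piecewise rate families for evoked population counts.
##
## ON-cells: exponential rise toward the switch time ts, then single- or
## double-exponential recovery, with continuity enforced through the
## constraint k_slow = k_pre + r_pre - r_post - k_fast.
## OFF-cells: sigmoidal suppression through (ts, u0), then either
## linear + exponential or double-exponential recovery.
## Rates are in counts per bin for the pooled population.

PIECEWISE_VARIANTS <- c("on_double_exp", "on_single_exp",
                        "off_linear_exp", "off_double_exp", "null_constant")

#' Continuity-derived slow amplitude for the ON model
#'
#' The ON rate is continuous at the switch time when
#' \code{kSlow = kPre + rPre - rPost - kFast}: the response branch ends at
#' \code{rPre + kPre} and the recovery branch starts at
#' \code{rPost + kFast + kSlow}.
#'
#' @param rPre,rPost pre/post baselines (counts/bin).
#' @param kPre response amplitude (counts/bin).
#' @param kFast fast recovery amplitude (counts/bin).
#' @return The slow recovery amplitude \code{kSlow}.
#' @examples
#' deriveKslow(20, 18, 10, 4)  # 8
#' @export
deriveKslow <- function(rPre, rPost, kPre, kFast) {
  kPre + rPre - rPost - kFast
}

#' Sigmoid midpoint placing the OFF response through (ts, u0)
#'
#' The four-parameter sigmoid \code{b + (a-b)/(1+exp(-k (t - tStar)))} is
#' reparameterized so that it passes exactly through the joining point
#' \code{(ts, u0)}:
#' \deqn{t^* = t_s + \frac{1}{k}\log\left(\frac{a-b}{u_0-b} - 1\right).}
#'
#' @param a upper asymptote (counts/bin).
#' @param b lower asymptote (counts/bin), \code{b < u0 < a}.
#' @param k sigmoid slope (1/s), nonzero.
#' @param u0 rate at the switch (counts/bin).
#' @param ts switch time (s).
#' @return The sigmoid midpoint \code{tStar} (s).
#' @examples
#' deriveTstar(a = 10, b = 2, k = 1, u0 = 4, ts = 0)  # log(3)
#' @export
deriveTstar <- function(a, b, k, u0, ts) {
  if (any(u0 <= b) || any(u0 >= a))
    stop("u0 must lie strictly between b and a")
  if (any(k == 0)) stop("k must be nonzero")
  ts + (1 / k) * log((a - b) / (u0 - b) - 1)
}

sigmoid_off <- function(t, a, b, k, tStar) {
  b + (a - b) / (1 + exp(pmin(-k * (t - tStar), 700)))
}

#' Evaluate a piecewise evoked rate family
#'
#' Computes the model rate \eqn{\lambda(t)} (counts per bin) at times
#' \code{t} (s, relative to the alignment event) for one of the five model
#' variants. All variants are continuous at the switch time \code{ts}.
#'
#' \describe{
#'   \item{on_double_exp}{response \code{rPre + kPre e^{(t-ts)/tau1}} for
#'     \code{t <= ts}; recovery
#'     \code{rPost + kFast e^{-(t-ts)/tau2} + kSlow e^{-(t-ts)/tau3}} with
#'     \code{kSlow} from [deriveKslow()].}
#'   \item{on_single_exp}{as above without the fast term
#'     (\code{kSlow = kPre + rPre - rPost}).}
#'   \item{off_linear_exp}{sigmoid through \code{(ts, u0)} for
#'     \code{t <= ts}; recovery
#'     \code{u0 + (c - u0)(1 - e^{-(t-ts)/tau}) + k3 (t-ts)}.}
#'   \item{off_double_exp}{sigmoid response; recovery
#'     \code{u0 + (c-u0)(1-e^{-(t-ts)/tauSlow}) +
#'     (d-u0)(1-e^{-(t-ts)/tauFast})}.}
#'   \item{null_constant}{constant \code{r0}.}
#' }
#'
#' @param variant one of the variant names above.
#' @param params named list of parameters for the variant (see details).
#' @param t numeric times (s).
#' @return Numeric rate vector (counts/bin), positive.
#' @export
evaluateRate <- function(variant, params, t) {
  variant <- match.arg(variant, PIECEWISE_VARIANTS)
  p <- params
  resp <- t <= p$ts
  out <- numeric(length(t))
  if (variant %in% c("on_double_exp", "on_single_exp")) {
    kFast <- if (variant == "on_double_exp") p$kFast else 0
    tau2 <- if (variant == "on_double_exp") p$tau2 else 1
    kSlow <- deriveKslow(p$rPre, p$rPost, p$kPre, kFast)
    out[resp] <- p$rPre + p$kPre * exp((t[resp] - p$ts) / p$tau1)
    dt <- t[!resp] - p$ts
    out[!resp] <- p$rPost + kFast * exp(-dt / tau2) + kSlow * exp(-dt / p$tau3)
  } else if (variant == "off_linear_exp") {
    tStar <- deriveTstar(p$a, p$b, p$k, p$u0, p$ts)
    out[resp] <- sigmoid_off(t[resp], p$a, p$b, p$k, tStar)
    dt <- t[!resp] - p$ts
    out[!resp] <- p$u0 + (p$c - p$u0) * (1 - exp(-dt / p$tau)) + p$k3 * dt
  } else if (variant == "off_double_exp") {
    tStar <- deriveTstar(p$a, p$b, p$k, p$u0, p$ts)
    out[resp] <- sigmoid_off(t[resp], p$a, p$b, p$k, tStar)
    dt <- t[!resp] - p$ts
    out[!resp] <- p$u0 + (p$c - p$u0) * (1 - exp(-dt / p$tauSlow)) +
      (p$d - p$u0) * (1 - exp(-dt / p$tauFast))
  } else {
    out[] <- p$r0
  }
  out
}

variant_cell_class <- function(variant) {
  switch(variant,
    on_double_exp = , on_single_exp = "ON",
    off_linear_exp = , off_double_exp = "OFF",
    null_constant = "ANY")
}
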