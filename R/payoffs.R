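#' Enumerate the eight pure-strategy profiles
#'
#' One row per combination of hospital strategy (`compliant` / `illegal`),
#' third-party strategy (`true_investigation` / `false_investigation`) and
#' government strategy (`strict` / `non_supervision`).
#'
#' @return Data frame with columns `hospital`, `third_party`, `government`
#'   (8 rows).
#' @export
strategy_profiles <- function() {
  expand.grid(hospital = c("compliant", "illegal"),
              third_party = c("true_investigation", "false_investigation"),
              government = c("strict", "non_supervision"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Payoffs of one pure-strategy profile
#'
#' Returns the payoff cell for the given profile.  The full matrix is the
#' single source of truth for the model; expected payoffs and the
#' matrix-derived replicator field are computed from it.  Representative
#' cells: (compliant, true, strict) pays
#' `(Ih1 + Ah - Ch1, It1 - Ct1, Ig1 - Cg - Ah + Ag)`;
#' (illegal, false, non-supervision) pays
#' `(Ih2 - Ch2, It2 - Ct2, Ig2 - Pg)`.
#'
#' @inheritParams validate_params
#' @param hospital `"compliant"` or `"illegal"`.
#' @param third_party `"true_investigation"` or `"false_investigation"`.
#' @param government `"strict"` or `"non_supervision"`.
#' @return Named numeric vector `c(hospital=, third_party=, government=)`.
#' @examples
#' payoff_for_profile(scenario_params(1), "compliant", "true_investigation",
#'                    "strict")   # c(3, 1, -1)
#' @export
payoff_for_profile <- function(params, hospital, third_party, government) {
  p <- as.list(coerce_params(params))
  hospital <- match.arg(hospital, c("compliant", "illegal"))
  third_party <- match.arg(third_party,
                           c("true_investigation", "false_investigation"))
  government <- match.arg(government, c("strict", "non_supervision"))
  comp <- hospital == "compliant"
  true_inv <- third_party == "true_investigation"
  strict <- government == "strict"

  h <- if (comp) {
    p$Ih1 - p$Ch1 + if (strict) p$Ah else 0
  } else {
    # an illegal hospital is fined unless both supervisors look away
    p$Ih2 - p$Ch2 - if (!true_inv && !strict) 0 else p$Ph
  }
  t <- if (true_inv) {
    p$It1 - p$Ct1
  } else {
    base <- if (comp) p$It1 else p$It2          # bribe only from an illegal hospital
    base - p$Ct2 - if (strict) p$Pt else 0
  }
  g <- if (strict) {
    soc <- if (comp) p$Ig1 else p$Ig2
    soc - p$Cg + p$Ag +
      (if (comp) -p$Ah else p$Ph) +
      (if (!true_inv) p$Pt else 0)
  } else {
    if (comp) p$Ig1
    else if (true_inv) p$Ig2 + p$Ph
    else p$Ig2 - p$Pg
  }
  c(hospital = h, third_party = t, government = g)
}

#' The full payoff matrix of the game
#'
#' All eight pure-strategy profiles with the payoff triple of each player.
#'
#' @inheritParams validate_params
#' @return Data frame: profile columns (`hospital`, `third_party`,
#'   `government`) plus payoff columns `hospital_payoff`,
#'   `third_party_payoff`, `government_payoff`.
#' @export
payoff_matrix <- function(params) {
  params <- coerce_params(params)
  prof <- strategy_profiles()
  pay <- t(mapply(payoff_for_profile,
                  hospital = prof$hospital,
                  third_party = prof$third_party,
                  government = prof$government,
                  MoreArgs = list(params = params)))
  prof$hospital_payoff <- pay[, "hospital"]
  prof$third_party_payoff <- pay[, "third_party"]
  prof$government_payoff <- pay[, "government"]
  prof
}

check_state <- function(state) {
  state <- as.numeric(unlist(state))
  if (length(state) != 3L || anyNA(state))
    stop("state must be a numeric triple (x, y, z)")
  if (any(state < 0 | state > 1))
    stop("state (x, y, z) must lie in [0, 1]^3")
  names(state) <- c("x", "y", "z")
  state
}

#' Expected payoffs at a mixed state
#'
#' Probability-weights the payoff matrix at the mixed state `(x, y, z)`:
#' `x` is the probability of compliant hospital operation, `y` of a true
#' investigation, `z` of strict supervision.  Returns each player's expected
#' payoff per own pure strategy (`E11`/`E12` hospital compliant/illegal,
#' `E21`/`E22` third party true/false, `E31`/`E32` government
#' strict/non-supervision) and the population averages `E1bar`, `E2bar`,
#' `E3bar`.
#'
#' @inheritParams validate_params
#' @param state numeric triple `(x, y, z)` in the unit cube.
#' @return Named list with elements `E11`, `E12`, `E1bar`, `E21`, `E22`,
#'   `E2bar`, `E31`, `E32`, `E3bar`.
#' @examples
#' expected_payoffs(scenario_params(1), c(0.8, 0.5, 0.2))
#' @export
expected_payoffs <- function(params, state) {
  params <- coerce_params(params)
  s <- check_state(state)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  pm <- payoff_matrix(params)
  px <- ifelse(pm$hospital == "compliant", x, 1 - x)
  py <- ifelse(pm$third_party == "true_investigation", y, 1 - y)
  pz <- ifelse(pm$government == "strict", z, 1 - z)

  # conditional expectation for one player's fixed pure strategy: weight by
  # the opponents' probabilities only
  hos_c <- pm$hospital == "compliant"
  tp_t <- pm$third_party == "true_investigation"
  gov_s <- pm$government == "strict"

  E11 <- sum((py * pz * pm$hospital_payoff)[hos_c])
  E12 <- sum((py * pz * pm$hospital_payoff)[!hos_c])
  E21 <- sum((px * pz * pm$third_party_payoff)[tp_t])
  E22 <- sum((px * pz * pm$third_party_payoff)[!tp_t])
  E31 <- sum((px * py * pm$government_payoff)[gov_s])
  E32 <- sum((px * py * pm$government_payoff)[!gov_s])
  list(E11 = E11, E12 = E12, E1bar = x * E11 + (1 - x) * E12,
       E21 = E21, E22 = E22, E2bar = y * E21 + (1 - y) * E22,
       E31 = E31, E32 = E32, E3bar = z * E31 + (1 - z) * E32)
}
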