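#' The 16 parameter names of the supervision game
#'
#' Order: costs (`Ch1`, `Ch2`, `Ct1`, `Ct2`, `Cg`), incomes (`Ih1`, `Ih2`,
#' `It1`, `It2`, `Ig1`, `Ig2`), then the reward-punishment mechanism
#' (`Ah`, `Ph`, `Pt`, `Ag`, `Pg`).
#'
#' @format Character vector of length 16.
#' @export
param_names <- c("Ch1", "Ch2", "Ct1", "Ct2", "Cg",
                 "Ih1", "Ih2", "It1", "It2", "Ig1", "Ig2",
                 "Ah", "Ph", "Pt", "Ag", "Pg")

#' Construct a parameter set for the supervision game
#'
#' Bundles the 16 monetary parameters of the tripartite healthcare-fraud
#' supervision game: operating costs and incomes of the hospital (`Ch1`,
#' `Ch2`, `Ih1`, `Ih2`), investigation costs and incomes of the third party
#' (`Ct1`, `Ct2`, `It1`, `It2`), the local government's supervision cost and
#' social benefits (`Cg`, `Ig1`, `Ig2`), and the reward-punishment mechanism:
#' reward `Ah` to a compliant hospital, fines `Ph` (hospital) and `Pt` (third
#' party), superior-government reward `Ag` and fine `Pg` on the local
#' government.  All values are non-negative reals in a common (arbitrary)
#' currency unit.
#'
#' @param Ch1,Ch2 hospital costs of compliant / illegal operation (`Ch1 > Ch2`).
#' @param Ct1,Ct2 third-party costs of true / false investigation (`Ct1 > Ct2`).
#' @param Cg government cost of strict supervision (`Cg > 0`).
#' @param Ih1,Ih2 hospital incomes under compliant / illegal operation
#'   (`Ih2 > Ih1`).
#' @param It1,It2 third-party incomes under true / false investigation
#'   (`It2 > It1`; the excess is the bribe collected from an illegal hospital).
#' @param Ig1,Ig2 social benefits to the government under compliant / illegal
#'   hospital operation (`Ig1 > Ig2`).
#' @param Ah reward to a compliant hospital under strict supervision
#'   (`Ah < Ch1`).
#' @param Ph fine on an illegal hospital once detected.
#' @param Pt fine on a rent-seeking (false-investigating) third party.
#' @param Ag superior-government reward for strict supervision (`Ag < Cg`).
#' @param Pg superior-government fine on an unsupervising government that let
#'   fraud pass.
#' @param validate if `TRUE` (default), stop when the constraints are violated.
#' @param strict passed to [validate_params()]: additionally require strictly
#'   positive fines (`Ph`, `Pt`, `Pg`), which the threshold formulas divide by.
#'
#' @return A named numeric vector of length 16 with class `"game_params"`.
#' @seealso [validate_params()], [scenario_params()], [read_params()]
#' @examples
#' p <- scenario_params(1)
#' p["Ph"] <- 3
#' p <- game_params_vec(p)   # revalidate after editing
#' @export
game_params <- function(Ch1, Ch2, Ct1, Ct2, Cg, Ih1, Ih2, It1, It2,
                        Ig1, Ig2, Ah, Ph, Pt, Ag, Pg,
                        validate = TRUE, strict = TRUE) {
  vals <- c(Ch1 = Ch1, Ch2 = Ch2, Ct1 = Ct1, Ct2 = Ct2, Cg = Cg,
            Ih1 = Ih1, Ih2 = Ih2, It1 = It1, It2 = It2, Ig1 = Ig1, Ig2 = Ig2,
            Ah = Ah, Ph = Ph, Pt = Pt, Ag = Ag, Pg = Pg)
  game_params_vec(vals, validate = validate, strict = strict)
}

#' Construct a parameter set from a named vector or list
#'
#' @param x named numeric vector or list holding exactly the 16 parameters
#'   named in [param_names]; unknown or missing names are an error.
#' @inheritParams game_params
#' @return A `"game_params"` object.
#' @export
game_params_vec <- function(x, validate = TRUE, strict = TRUE) {
  x <- unlist(x)
  unknown <- setdiff(names(x), param_names)
  if (length(unknown) > 0L)
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(param_names, names(x))
  if (length(missing) > 0L)
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  x <- x[param_names]
  bad <- !vapply(x, function(v) is.numeric(v) && is.finite(v), logical(1))
  if (any(bad))
    stop("non-numeric or non-finite value for parameter(s): ",
         paste(param_names[bad], collapse = ", "))
  x <- as.numeric(x)
  names(x) <- param_names
  class(x) <- "game_params"
  if (validate) {
    viol <- validate_params(x, strict = strict)
    if (length(viol) > 0L)
      stop("parameter constraints violated: ", paste(viol, collapse = "; "))
  }
  x
}

#' Validate the ordering constraints of a parameter set
#'
#' Checks the model's standing assumptions: costs order (`Ch1 > Ch2 >= 0`,
#' `Ct1 > Ct2 >= 0`, `Cg > 0`), incomes order (`Ih2 > Ih1 >= 0`,
#' `It2 > It1 >= 0`, `Ig1 > Ig2 >= 0`), the reward bounds (`Ah < Ch1`,
#' `Ag < Cg`) and non-negativity of all rewards and fines.  With
#' `strict = TRUE` the fines must additionally be strictly positive
#' (`Ph > 0`, `Pt > 0`, `Pg > 0`): the threshold and intercept formulas divide
#' by `Ph`, `Pt`, `It2 - It1` and `Ah + Pg + Ph`.
#'
#' @param params a `"game_params"` object or named numeric vector of the 16
#'   parameters.
#' @param strict also require strictly positive fines (default `TRUE`).
#' @return Character vector naming every violated constraint (e.g. `"Ah<Ch1"`);
#'   empty when the set is valid.
#' @examples
#' validate_params(scenario_params(1))           # character(0)
#' p <- unclass(scenario_params(1)); p["Ah"] <- 8
#' validate_params(p)                            # "Ah<Ch1"
#' @export
validate_params <- function(params, strict = TRUE) {
  p <- as.list(coerce_params(params))
  viol <- character(0)
  chk <- function(ok, label) if (!ok) viol[[length(viol) + 1L]] <<- label
  chk(p$Ch1 > p$Ch2, "Ch1>Ch2"); chk(p$Ch2 >= 0, "Ch2>=0")
  chk(p$Ct1 > p$Ct2, "Ct1>Ct2"); chk(p$Ct2 >= 0, "Ct2>=0")
  chk(p$Cg > 0, "Cg>0")
  chk(p$Ih2 > p$Ih1, "Ih2>Ih1"); chk(p$Ih1 >= 0, "Ih1>=0")
  chk(p$It2 > p$It1, "It2>It1"); chk(p$It1 >= 0, "It1>=0")
  chk(p$Ig1 > p$Ig2, "Ig1>Ig2"); chk(p$Ig2 >= 0, "Ig2>=0")
  chk(p$Ah < p$Ch1, "Ah<Ch1")
  chk(p$Ag < p$Cg, "Ag<Cg")
  for (nm in c("Ah", "Ph", "Pt", "Ag", "Pg"))
    chk(p[[nm]] >= 0, paste0(nm, ">=0"))
  if (strict) {
    chk(p$Ph > 0, "Ph>0")
    chk(p$Pt > 0, "Pt>0")
    chk(p$Pg > 0, "Pg>0")
  }
  unlist(viol)
}

# Accept game_params, named vector or list; no constraint checking here.
coerce_params <- function(params) {
  if (inherits(params, "game_params")) return(params)
  game_params_vec(params, validate = FALSE)
}

#' Built-in scenario parameter presets
#'
#' Three parameter sets under which the replicator dynamics settle on,
#' respectively, full defection `(0,0,0)` (illegal operation, false
#' investigation, non-supervision), supervised defection `(0,0,1)`, and the
#' policy target `(1,0,1)` (compliant operation under strict supervision).
#'
#' @param id scenario number 1, 2 or 3.
#' @return A `"game_params"` object.
#' @examples
#' scenario_params(3)
#' @export
scenario_params <- function(id) {
  stopifnot(length(id) == 1L, id %in% 1:3)
  vals <- switch(as.character(id),
    "1" = c(Ch1 = 8, Ch2 = 5, Ct1 = 2, Ct2 = 1, Cg = 9,
            Ih1 = 9, Ih2 = 10, It1 = 3, It2 = 4, Ig1 = 8, Ig2 = 5,
            Ah = 2, Ph = 2, Pt = 1, Ag = 2, Pg = 3),
    "2" = c(Ch1 = 7, Ch2 = 5, Ct1 = 2, Ct2 = 1, Cg = 5.5,
            Ih1 = 8, Ih2 = 9, It1 = 2.5, It2 = 3, Ig1 = 8, Ig2 = 5,
            Ah = 2, Ph = 0.8, Pt = 0.5, Ag = 2, Pg = 5),
    "3" = c(Ch1 = 6, Ch2 = 4.5, Ct1 = 2, Ct2 = 1, Cg = 5,
            Ih1 = 6.5, Ih2 = 7, It1 = 2.5, It2 = 3, Ig1 = 5.5, Ig2 = 4,
            Ah = 0.6, Ph = 4.5, Pt = 1.2, Ag = 4.9, Pg = 3))
  game_params_vec(vals)
}

#' Read a parameter set from a flat YAML or JSON file
#'
#' The file must contain exactly the 16 keys named in [param_names] at the top
#' level; unknown keys are rejected.  Format is chosen by extension
#' (`.json` vs `.yaml`/`.yml`); anything else is parsed as YAML.
#'
#' @param file path to the configuration file.
#' @inheritParams game_params
#' @return A `"game_params"` object.
#' @export
read_params <- function(file, validate = TRUE, strict = TRUE) {
  ext <- tolower(tools::file_ext(file))
  x <- if (ext == "json") jsonlite::read_json(file, simplifyVector = TRUE)
       else yaml::read_yaml(file)
  if (is.null(names(x)) || any(names(x) == ""))
    stop("parameter file must be a flat named mapping")
  game_params_vec(x, validate = validate, strict = strict)
}

#' Draw a random valid parameter set
#'
#' Seeded rejection sampler used for property checks: costs and incomes are
#' drawn uniformly on (0, 10], rewards and fines uniformly on (0, 5], and
#' draws are rejected until the strict validity constraints hold and, when
#' requested, one of the ESS conditions A, B or C (see [condition_flags()])
#' is satisfied.  The same seed always returns the same set.
#'
#' @param seed integer seed for the draw.
#' @param condition `"any"` (default) for plain validity, or `"A"`, `"B"`,
#'   `"C"` to additionally require that ESS condition.
#' @param max_draws rejection budget before giving up with an error.
#' @return A `"game_params"` object.
#' @examples
#' sample_valid_params(42)
#' sample_valid_params(42, condition = "B")
#' @export
sample_valid_params <- function(seed, condition = c("any", "A", "B", "C"),
                                max_draws = 1e5) {
  condition <- match.arg(condition)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- 0L
  while (draws < max_draws) {
    draws <- draws + 1L
    v <- c(stats::runif(11, 0, 10), stats::runif(5, 0, 5))
    names(v) <- param_names
    p <- game_params_vec(v, validate = FALSE)
    if (length(validate_params(p, strict = TRUE)) > 0L) next
    if (condition != "any") {
      fl <- condition_flags(p)
      if (!isTRUE(fl[[condition]])) next
    }
    return(p)
  }
  stop("rejection budget of ", max_draws,
       " draws exceeded while sampling condition ", condition)
}

#' @export
print.game_params <- function(x, ...) {
  cat("Healthcare-fraud supervision game parameters\n")
  m <- matrix(unclass(x), nrow = 1, dimnames = list("", names(x)))
  print(m, ...)
  viol <- validate_params(x, strict = TRUE)
  if (length(viol) > 0L)
    cat("violated constraints:", paste(viol, collapse = "; "), "\n")
  invisible(x)
}
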