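# Three-step parameter-selection workflow over candidate observable tables:
# (1) hydration filter on dG_solv / R1 / n1, (2) kinetics selection on the
# water-exchange rate, (3) combination-rule scaling selection for the Cl and
# RNA partner classes.

# declared grid-search ranges used for validation warnings
.SCALING_RANGES <- list(
  Cl  = list(lambda_sigma = c(1.00, 2.60), lambda_epsilon = c(0.01, 1.00)),
  RNA = list(lambda_sigma = c(0.97, 1.23), lambda_epsilon = c(0.08, 1.04))
)

#' Experimental target specification
#'
#' Per-observable experimental value plus absolute tolerance. Values may be
#' given as length-1 (value; a documented default tolerance applies) or
#' length-2 `c(value, tolerance)` numerics. Default tolerances:
#' dG_solv 5 kJ/mol, R1 0.004 nm (the experimental uncertainty), a_cc 0.02,
#' R_b 0.004 nm; n1 is matched exactly as an integer.
#'
#' @param ... Named observables among `dG_solv`, `R1`, `n1`, `k_exchange`,
#'   `a_cc`, `dG_b0`, `R_b`.
#' @return An object of class `target_spec`: named list of
#'   `list(value, tol)`.
#' @examples
#' target_spec(dG_solv = -2532, R1 = c(0.209, 0.004), n1 = 6)
#' @export
target_spec <- function(...) {
  args <- list(...)
  if (length(args) == 0L || is.null(names(args)) || any(!nzchar(names(args))))
    stop("all targets must be named")
  defaults <- c(dG_solv = 5, R1 = 0.004, n1 = 0, k_exchange = NA,
                a_cc = 0.02, dG_b0 = NA, R_b = 0.004)
  out <- lapply(names(args), function(nm) {
    v <- args[[nm]]
    stopifnot(is.numeric(v), length(v) %in% 1:2)
    tol <- if (length(v) == 2L) v[2] else unname(defaults[nm])
    if (!is.na(tol) && tol < 0) stop("tolerance for '", nm, "' must be >= 0")
    list(value = v[1], tol = tol)
  })
  names(out) <- names(args)
  structure(out, class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat("Targets:\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %g%s\n", nm, x[[nm]]$value,
                if (is.finite(x[[nm]]$tol) && x[[nm]]$tol > 0)
                  sprintf(" +- %g", x[[nm]]$tol) else ""))
  invisible(x)
}

.need_cols <- function(cands, cols, what) {
  miss <- setdiff(cols, names(cands))
  if (length(miss))
    stop(what, " requires candidate columns: ", paste(miss, collapse = ", "))
}

# deterministic tie-break ordering: smallest sigma then epsilon (or lambdas)
.order_candidates <- function(cands) {
  keys <- intersect(c("sigma_io", "epsilon_io", "lambda_sigma",
                      "lambda_epsilon"), names(cands))
  if (length(keys) == 0L) return(cands)
  cands[do.call(order, cands[keys]), , drop = FALSE]
}

#' Hydration-stage filter
#'
#' Step 1 of the selection workflow: retain candidate parameter combinations
#' whose solvation free energy and first-shell distance lie within tolerance
#' of the experimental targets and whose coordination number matches
#' exactly.
#'
#' @param cands Data frame of candidate rows carrying at least `dG_solv`,
#'   `R1`, `n1` (plus parameter columns).
#' @param targets A [target_spec] with `dG_solv`, `R1` and `n1` entries.
#' @return The retained rows (possibly empty, with a warning).
#' @export
filter_hydration <- function(cands, targets) {
  stopifnot(is.data.frame(cands), inherits(targets, "target_spec"))
  .need_cols(cands, c("dG_solv", "R1", "n1"), "filter_hydration")
  for (nm in c("dG_solv", "R1", "n1"))
    if (is.null(targets[[nm]])) stop("targets must include '", nm, "'")
  keep <- abs(cands$dG_solv - targets$dG_solv$value) <= targets$dG_solv$tol &
          abs(cands$R1 - targets$R1$value) <= targets$R1$tol &
          cands$n1 == round(targets$n1$value)
  out <- .order_candidates(cands[keep, , drop = FALSE])
  if (nrow(out) == 0L)
    warning("no candidate matches the hydration targets")
  out
}

#' Kinetics-stage selection
#'
#' Step 2: select the candidate whose water-exchange rate either matches the
#' experimental rate (smallest absolute log10 deviation) or is fastest.
#' Ties are broken deterministically by smallest parameters.
#'
#' @param cands Data frame carrying `k_exchange`.
#' @param k_exp Experimental exchange rate, s^-1 (used by
#'   `"match-experiment"`).
#' @param mode `"match-experiment"` (default) or `"fastest"`.
#' @return A single candidate row.
#' @export
select_kinetics <- function(cands, k_exp = NULL,
                            mode = c("match-experiment", "fastest")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(cands))
  if (nrow(cands) == 0L) stop("candidate list is empty")
  .need_cols(cands, "k_exchange", "select_kinetics")
  cands <- .order_candidates(cands)
  i <- if (mode == "match-experiment") {
    if (is.null(k_exp) || k_exp <= 0)
      stop("'k_exp' must be a positive rate for mode 'match-experiment'")
    which.min(abs(log10(cands$k_exchange / k_exp)))
  } else {
    which.max(cands$k_exchange)
  }
  cands[i, , drop = FALSE]
}

#' Scaling-stage selection
#'
#' Step 3: select combination-rule scaling factors on a lambda grid. The
#' chloride stage minimizes the deviation of the activity derivative from
#' its target; the RNA stage first restricts to rows within the binding
#' distance tolerance, then minimizes the binding-affinity deviation.
#' Grids outside the declared search ranges (Cl: lambda_sigma 1-2.6,
#' lambda_epsilon 0.01-1; RNA: lambda_sigma 0.97-1.23, lambda_epsilon
#' 0.08-1.04) trigger a configuration warning.
#'
#' @param cands Data frame of lambda-grid rows: `a_cc` for stage `"Cl"`;
#'   `dG_b0` and `R_b` for stage `"RNA"`.
#' @param targets A [target_spec] with `a_cc` (Cl) or `dG_b0` + `R_b` (RNA).
#' @param stage `"Cl"` or `"RNA"`.
#' @return A single candidate row.
#' @export
select_scaling <- function(cands, targets, stage = c("Cl", "RNA")) {
  stage <- match.arg(stage)
  stopifnot(is.data.frame(cands), inherits(targets, "target_spec"))
  if (nrow(cands) == 0L) stop("candidate list is empty")
  rng <- .SCALING_RANGES[[stage]]
  for (key in names(rng)) {
    if (key %in% names(cands)) {
      v <- cands[[key]]
      if (any(v < rng[[key]][1] - 1e-9 | v > rng[[key]][2] + 1e-9))
        warning(sprintf("%s grid extends outside the declared %s search range [%g, %g]",
                        key, stage, rng[[key]][1], rng[[key]][2]))
    }
  }
  cands <- .order_candidates(cands)
  if (stage == "Cl") {
    .need_cols(cands, "a_cc", "select_scaling (Cl)")
    if (is.null(targets$a_cc)) stop("targets must include 'a_cc'")
    i <- which.min(abs(cands$a_cc - targets$a_cc$value))
    return(cands[i, , drop = FALSE])
  }
  .need_cols(cands, c("dG_b0", "R_b"), "select_scaling (RNA)")
  for (nm in c("dG_b0", "R_b"))
    if (is.null(targets[[nm]])) stop("targets must include '", nm, "'")
  feas <- abs(cands$R_b - targets$R_b$value) <= targets$R_b$tol
  if (!any(feas))
    stop("no candidate within the R_b tolerance (",
         targets$R_b$value, " +- ", targets$R_b$tol, " nm)")
  sub <- cands[feas, , drop = FALSE]
  i <- which.min(abs(sub$dG_b0 - targets$dG_b0$value))
  sub[i, , drop = FALSE]
}
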